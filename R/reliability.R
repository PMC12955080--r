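#' Single-subject intraclass correlation, two-way absolute agreement
#'
#' Fits the two-way random-effects ANOVA decomposition (rows = network
#' elements, columns = repeated measurements, no interaction) and returns
#' the single-measure absolute-agreement intraclass correlation
#' (McGraw-Wong ICC(A,1)):
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1) MS_E +
#'   \frac{k}{N}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C} and \eqn{MS_E} are the row, column and
#' error mean squares. Negative estimates are reported as-is (flagged, not
#' truncated) since truncation would bias downstream group contrasts. A
#' matrix with zero total variance is flagged degenerate and gets an
#' undefined (NA) ICC.
#'
#' @param m numeric `N x k` matrix, `N >= 3` rows (parcels or
#'   connections), `k >= 2` repeated measurements; all entries finite.
#' @return An object of class `icc_a1` with components `icc`, `msr`,
#'   `msc`, `mse`, `n`, `k`, `degenerate` and `negative`.
#' @examples
#' fit <- icc_a1(cbind(test = c(1, 3, 5, 7), retest = c(2, 4, 6, 8)))
#' fit            # ICC(A,1) = 0.930
#' coef(fit)
#' @references McGraw, K.O. & Wong, S.P. (1996). Forming inferences about
#'   some intraclass correlation coefficients. Psychological Methods 1,
#'   30-46.
#' @export
icc_a1 <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m)
  k <- ncol(m)
  if (n < 3L || k < 2L) {
    stop("icc_a1: need at least 3 rows and 2 columns", call. = FALSE)
  }
  if (!all(is.finite(m))) {
    stop("icc_a1: input must be finite", call. = FALSE)
  }
  grand <- mean(m)
  rm_ <- rowMeans(m)
  cm <- colMeans(m)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  degenerate <- sst <= 1e4 * .Machine$double.eps * n * k *
    max(1, grand^2)
  icc <- if (degenerate) NA_real_ else {
    (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  }
  structure(list(icc = icc, msr = msr, msc = msc, mse = mse,
                 n = n, k = k, degenerate = degenerate,
                 negative = isTRUE(icc < 0), data = m),
            class = "icc_a1")
}

#' @export
print.icc_a1 <- function(x, digits = 4L, ...) {
  cat("Two-way absolute-agreement intraclass correlation ICC(A,1)\n")
  cat(sprintf("  N = %d elements, k = %d measurements\n", x$n, x$k))
  if (x$degenerate) {
    cat("  ICC undefined: zero total variance (degenerate input)\n")
  } else {
    cat(sprintf("  ICC(A,1) = %.*f%s\n", digits, x$icc,
                if (x$negative) "  (negative estimate, flagged)" else ""))
  }
  invisible(x)
}

#' @export
summary.icc_a1 <- function(object, ...) {
  print(object)
  cat(sprintf("  mean squares: rows %.6g, columns %.6g, error %.6g\n",
              object$msr, object$msc, object$mse))
  invisible(object)
}

#' @export
coef.icc_a1 <- function(object, ...) {
  c(icc = object$icc, msr = object$msr, msc = object$msc, mse = object$mse)
}

#' @export
plot.icc_a1 <- function(x, ...) {
  m <- x$data
  plot.default(m[, 1L], m[, 2L],
               xlab = colnames(m)[1L] %||% "measurement 1",
               ylab = colnames(m)[2L] %||% "measurement 2",
               main = if (x$degenerate) "ICC(A,1): degenerate" else
                 sprintf("ICC(A,1) = %.3f", x$icc), ...)
  abline(0, 1, lty = 2L)
  invisible(x)
}

#' Enumerate test-retest session pairings
#'
#' Within-visit pairings couple the two runs of the same visit; between-
#' visit pairings couple every run of an earlier visit with every run of a
#' later visit (all combinations are kept as separate rows, never
#' averaged).
#'
#' @param n_visits number of imaging visits.
#' @param runs run labels per visit.
#' @return Data frame with columns `visit_a`, `run_a`, `visit_b`, `run_b`,
#'   `pairing` (`"within"`/`"between"`).
#' @examples
#' table(session_pairings(3)$pairing) # 3 within, 12 between
#' @export
session_pairings <- function(n_visits, runs = c("test", "retest")) {
  stopifnot(n_visits >= 1L, length(runs) >= 2L)
  out <- data.frame(visit_a = seq_len(n_visits), run_a = runs[1L],
                    visit_b = seq_len(n_visits), run_b = runs[2L],
                    pairing = "within", stringsAsFactors = FALSE)
  if (n_visits >= 2L) {
    for (a in seq_len(n_visits - 1L)) for (b in (a + 1L):n_visits) {
      grid <- expand.grid(run_a = runs, run_b = runs,
                          stringsAsFactors = FALSE)
      out <- rbind(out, data.frame(visit_a = a, run_a = grid$run_a,
                                   visit_b = b, run_b = grid$run_b,
                                   pairing = "between",
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

#' Per-network reliability table
#'
#' Computes ICC(A,1) for every subject x condition x network x metric x
#' session pairing, using the fixed network element order of
#' [network_vector()] as rows and the paired runs as the two columns.
#' Missing runs are skipped with a warning rather than failing the batch.
#'
#' @param metric_store nested list
#'   `[[subject]][[visit]][[condition]][[run]]` where each entry holds
#'   `connectivity` (Fisher-z matrix) and `variability` (named vector),
#'   as built by [run_pipeline()] or [compute_run_metrics()].
#' @param parc a [parcellation()].
#' @param pairings data frame from [session_pairings()].
#' @param networks network names to evaluate.
#' @return Tidy data frame: subject, condition, network, metric, pairing,
#'   visit_pair, icc, msr, msc, mse, n, degenerate.
#' @export
icc_per_network <- function(metric_store, parc,
                            pairings = session_pairings(1L),
                            networks = names(parcel_networks(parc))) {
  rows <- list()
  for (subj in names(metric_store)) {
    for (cond in c("OFF", "ON")) {
      for (i in seq_len(nrow(pairings))) {
        pr <- pairings[i, ]
        ra <- metric_store[[subj]][[pr$visit_a]][[cond]][[pr$run_a]]
        rb <- metric_store[[subj]][[pr$visit_b]][[cond]][[pr$run_b]]
        if (is.null(ra) || is.null(rb)) {
          warning("icc_per_network: missing run for ", subj, " ", cond,
                  " visits ", pr$visit_a, "/", pr$visit_b, "; skipped",
                  call. = FALSE)
          next
        }
        for (net in networks) {
          for (metric in c("connectivity", "variability")) {
            xa <- if (metric == "connectivity") {
              network_vector(ra$connectivity, parc, net)
            } else network_vector(ra$variability, parc, net)
            xb <- if (metric == "connectivity") {
              network_vector(rb$connectivity, parc, net)
            } else network_vector(rb$variability, parc, net)
            fit <- icc_a1(cbind(test = xa, retest = xb))
            rows[[length(rows) + 1L]] <- data.frame(
              subject = subj, condition = cond, network = net,
              metric = metric, pairing = pr$pairing,
              visit_pair = paste0(pr$visit_a, "-", pr$visit_b),
              icc = fit$icc, msr = fit$msr, msc = fit$msc, mse = fit$mse,
              n = fit$n, degenerate = fit$degenerate,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  do.call(rbind, rows)
}
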