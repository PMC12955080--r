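#' Contrast result container
#'
#' Uniform return type for the group-level tests: test name, statistic,
#' uncorrected two-sided p-value, effect size (Pearson r or Cliff's
#' delta) with its 95% confidence interval, and sample sizes.
#'
#' @param test test name.
#' @param statistic test statistic.
#' @param p two-sided p-value (uncorrected).
#' @param effect_size named effect size (`r` or `delta`).
#' @param ci length-2 confidence interval (or `c(NA, NA)`).
#' @param n,n1,n2 sample sizes.
#' @param degenerate flag for undefined results.
#' @param note free-text annotation.
#' @return An object of class `contrast_result`.
#' @export
contrast_result <- function(test, statistic, p, effect_size,
                            ci = c(NA_real_, NA_real_), n = NA_integer_,
                            n1 = NA_integer_, n2 = NA_integer_,
                            degenerate = FALSE, note = "") {
  structure(list(test = test, statistic = statistic, p = p,
                 effect_size = effect_size, ci = ci, n = n, n1 = n1,
                 n2 = n2, degenerate = degenerate, note = note),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(x$test, "\n")
  if (x$degenerate) {
    cat("  degenerate: ", x$note, "\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("  statistic = %.4g, p = %.4g (two-sided, uncorrected)\n",
              x$statistic, x$p))
  es <- x$effect_size
  cat(sprintf("  %s = %.3f", names(es)[1L], es[[1L]]))
  if (all(is.finite(x$ci))) {
    cat(sprintf(", 95%% CI [%.3f, %.3f]", x$ci[1L], x$ci[2L]))
  }
  cat("\n")
  invisible(x)
}

# Exact signed-rank null: all 2^n sign patterns over the observed ranks.
signed_rank_exact_p <- function(w, ranks) {
  n <- length(ranks)
  bits <- matrix(0L, 2L^n, n)
  for (j in seq_len(n)) {
    bits[, j] <- rep(rep(c(0L, 1L), each = 2L^(j - 1L)),
                     length.out = 2L^n)
  }
  wall <- as.numeric(bits %*% ranks)
  tol <- 1e-9
  lo <- mean(wall <= w + tol)
  hi <- mean(wall >= w - tol)
  min(1, 2 * min(lo, hi))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (flagged in the note); tied absolute
#' differences get averaged ranks. The null distribution is exact (full
#' enumeration of sign patterns) for up to 15 non-zero pairs, and a
#' tie-corrected normal approximation with continuity correction beyond
#' that. The effect size is Cliff's delta between the two samples.
#'
#' @param x,y paired numeric vectors.
#' @return A [contrast_result()] with statistic `W` (sum of positive
#'   ranks).
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  n <- length(d)
  delta <- cliffs_delta(x, y)$effect_size[["delta"]]
  if (n == 0L) {
    return(contrast_result("Wilcoxon signed-rank", NA_real_, NA_real_,
                           c(delta = delta), degenerate = TRUE,
                           note = "all differences zero"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  note <- if (n_zero) sprintf("%d zero difference(s) dropped", n_zero)
          else ""
  if (n < 5L) note <- paste(note, "fewer than 5 non-zero pairs")
  p <- if (n <= 15L) {
    signed_rank_exact_p(w, r)
  } else {
    ties <- table(r)
    mu <- n * (n + 1) / 4
    v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(v)
    min(1, 2 * pnorm(-abs(z)))
  }
  contrast_result("Wilcoxon signed-rank", w, p, c(delta = delta),
                  n = length(x), note = trimws(note))
}

# Exact rank-sum null: every assignment of the combined ranks to group x.
rank_sum_exact_p <- function(u, rx, ry) {
  all_r <- c(rx, ry)
  n1 <- length(rx)
  combos <- combn(length(all_r), n1)
  uall <- apply(combos, 2L, function(ix) {
    sum(all_r[ix]) - n1 * (n1 + 1) / 2
  })
  tol <- 1e-9
  min(1, 2 * min(mean(uall <= u + tol), mean(uall >= u - tol)))
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact permutation null over the observed (tied) ranks when
#' `n1 + n2 <= 12`; tie-corrected normal approximation with continuity
#' correction otherwise. Effect size is Cliff's delta.
#'
#' @param x,y numeric samples.
#' @return A [contrast_result()] with statistic `U` (for `x` over `y`).
#' @export
wilcoxon_rank_sum <- function(x, y) {
  n1 <- length(x)
  n2 <- length(y)
  if (n1 == 0L || n2 == 0L) {
    stop("wilcoxon_rank_sum: both samples must be non-empty", call. = FALSE)
  }
  r <- rank(c(x, y))
  rx <- r[seq_len(n1)]
  u <- sum(rx) - n1 * (n1 + 1) / 2
  delta <- cliffs_delta(x, y)$effect_size[["delta"]]
  p <- if (n1 + n2 <= 12L) {
    rank_sum_exact_p(u, rx, r[-seq_len(n1)])
  } else {
    nn <- n1 + n2
    ties <- table(r)
    mu <- n1 * n2 / 2
    v <- n1 * n2 / 12 * (nn + 1 - sum(ties^3 - ties) / (nn * (nn - 1)))
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(v)
    min(1, 2 * pnorm(-abs(z)))
  }
  contrast_result("Wilcoxon rank-sum", u, p, c(delta = delta),
                  n1 = n1, n2 = n2)
}

#' Fisher-z confidence interval for a correlation
#'
#' \deqn{\tanh(\mathrm{atanh}(r) \pm z_{\alpha/2} / \sqrt{n - 3}).}
#'
#' @param r correlation coefficient.
#' @param n sample size (`>= 4`).
#' @param level confidence level.
#' @return Length-2 vector (lower, upper).
#' @examples
#' round(fisher_z_ci(0.61, 16), 2) # [0.17, 0.85]
#' @export
fisher_z_ci <- function(r, n, level = 0.95) {
  stopifnot(n >= 4L, abs(r) <= 1)
  if (abs(r) == 1) return(c(r, r))
  z <- atanh(r)
  half <- qnorm(1 - (1 - level) / 2) / sqrt(n - 3)
  tanh(c(z - half, z + half))
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' @param x,y numeric vectors (`n >= 4`, non-constant).
#' @param level confidence level.
#' @return A [contrast_result()] with statistic `t`, effect size `r` and
#'   the Fisher-z interval.
#' @export
pearson_with_ci <- function(x, y, level = 0.95) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("pearson_with_ci: need n >= 4", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("pearson_with_ci: constant input", call. = FALSE)
  }
  r <- cor(x, y)
  if (abs(r) >= 1) {
    return(contrast_result("Pearson correlation", Inf, 0, c(r = r),
                           ci = c(r, r), n = n,
                           note = "perfect correlation"))
  }
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  contrast_result("Pearson correlation", tstat, p, c(r = r),
                  ci = fisher_z_ci(r, n, level), n = n)
}

#' Cliff's delta with bootstrap confidence interval
#'
#' \deqn{\delta = (\#\{x_i > y_j\} - \#\{x_i < y_j\}) / (n_1 n_2),}
#' computed through the rank-based Mann-Whitney identity
#' \eqn{\delta = 2U/(n_1 n_2) - 1}. The optional CI is a seeded percentile
#' bootstrap; paired inputs are resampled jointly.
#'
#' @param x,y numeric samples.
#' @param ci_method `"none"` or `"bootstrap"`.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed (required for a reproducible CI).
#' @param paired resample (x, y) pairs jointly.
#' @param level confidence level.
#' @return A [contrast_result()] with effect size `delta`.
#' @export
cliffs_delta <- function(x, y, ci_method = c("none", "bootstrap"),
                         n_boot = 10000L, seed = NULL, paired = FALSE,
                         level = 0.95) {
  ci_method <- match.arg(ci_method)
  n1 <- length(x)
  n2 <- length(y)
  stopifnot(n1 >= 1L, n2 >= 1L)
  point <- function(a, b) {
    r <- rank(c(a, b))
    u <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
    2 * u / (length(a) * length(b)) - 1
  }
  d <- point(x, y)
  ci <- c(NA_real_, NA_real_)
  if (ci_method == "bootstrap") {
    boot_one <- function() {
      if (paired) {
        ix <- sample.int(n1, replace = TRUE)
        point(x[ix], y[ix])
      } else {
        point(x[sample.int(n1, replace = TRUE)],
              y[sample.int(n2, replace = TRUE)])
      }
    }
    reps <- if (is.null(seed)) {
      replicate(n_boot, boot_one())
    } else {
      with_seed(seed, replicate(n_boot, boot_one()))
    }
    alpha <- (1 - level) / 2
    ci <- unname(quantile(reps, c(alpha, 1 - alpha), type = 7))
  }
  contrast_result("Cliff's delta", d, NA_real_, c(delta = d), ci = ci,
                  n1 = n1, n2 = n2)
}

# One tidy row out of a contrast_result.
contrast_row <- function(effect, metric, network, cr) {
  es <- cr$effect_size
  data.frame(effect = effect, metric = metric, network = network,
             test = cr$test, statistic = cr$statistic, p = cr$p,
             effect_size_type = names(es)[1L], effect_size = es[[1L]],
             ci_low = cr$ci[1L], ci_high = cr$ci[2L],
             n = if (is.na(cr$n)) cr$n1 + cr$n2 else cr$n,
             stringsAsFactors = FALSE)
}

#' Group-level contrast battery
#'
#' Reproduces the study's suite of group tests on a tidy reliability
#' table: (a) ON-vs-OFF signed-rank and Pearson contrasts of subject ICCs
#' per network and metric; (b) affected vs unaffected vs whole-brain
#' signed-rank contrasts when an artifact table is supplied; (c) covariate
#' correlations (OFF ICC vs test-retest FD difference, tremor,
#' rigidity+bradykinesia; ON ICC vs motor improvement and whole-brain
#' connectivity response), a stimulation-target rank-sum per network, and
#' an age correlation. All p-values are two-sided and uncorrected; effect
#' sizes (Cliff's delta with seeded bootstrap CI, or Pearson r with
#' Fisher-z CI) are the primary quantities.
#'
#' @param rel tidy reliability table from [icc_per_network()] (within
#'   pairing rows are used).
#' @param covariates per-subject data frame (columns among: subject, age,
#'   target, improvement, fd_diff, tremor, rigidity, bradykinesia,
#'   fc_response). Missing covariates skip their contrast with a message.
#' @param artifact optional table from the artifact stratification stage
#'   (columns subject, condition, metric, subset, icc).
#' @param covariate_network network whose ICC is used for the covariate
#'   contrasts.
#' @param n_boot,seed bootstrap settings for the delta CIs.
#' @return Tidy data frame of contrasts (effect, test, statistic, p,
#'   effect size, CI, n).
#' @export
run_contrast_suite <- function(rel, covariates = NULL, artifact = NULL,
                               covariate_network = "whole_brain",
                               n_boot = 2000L, seed = 1L) {
  rel <- rel[rel$pairing == "within" & !rel$degenerate &
               is.finite(rel$icc), ]
  rows <- list()
  push <- function(df) rows[[length(rows) + 1L]] <<- df
  subj_icc <- function(metric, network, condition) {
    sub <- rel[rel$metric == metric & rel$network == network &
                 rel$condition == condition, ]
    tapply(sub$icc, sub$subject, mean)
  }
  nets <- unique(rel$network)
  for (metric in unique(rel$metric)) {
    for (net in nets) {
      off <- subj_icc(metric, net, "OFF")
      on <- subj_icc(metric, net, "ON")
      common <- intersect(names(off), names(on))
      if (length(common) >= 3L) {
        sr <- wilcoxon_signed_rank(off[common], on[common])
        sr$ci <- cliffs_delta(off[common], on[common], "bootstrap",
                              n_boot, seed, paired = TRUE)$ci
        push(contrast_row("stimulation OFF vs ON", metric, net, sr))
        if (length(common) >= 4L && sd(off[common]) > 0 &&
            sd(on[common]) > 0) {
          push(contrast_row("stimulation OFF vs ON agreement", metric,
                            net, pearson_with_ci(off[common], on[common])))
        }
      }
    }
  }
  if (!is.null(artifact)) {
    art <- artifact[is.finite(artifact$icc), ]
    for (metric in unique(art$metric)) {
      for (cond in unique(art$condition)) {
        one <- art[art$metric == metric & art$condition == cond, ]
        grab <- function(s) {
          v <- one$icc[one$subset == s]
          names(v) <- one$subject[one$subset == s]
          v
        }
        combos <- list(c("affected", "unaffected"),
                       c("affected", "whole"),
                       c("unaffected", "whole"))
        for (cb in combos) {
          a <- grab(cb[1L])
          b <- grab(cb[2L])
          common <- intersect(names(a), names(b))
          if (length(common) < 3L) next
          sr <- wilcoxon_signed_rank(a[common], b[common])
          sr$ci <- cliffs_delta(a[common], b[common], "bootstrap",
                                n_boot, seed, paired = TRUE)$ci
          push(contrast_row(
            sprintf("artifact DBS-%s %s vs %s", cond, cb[1L], cb[2L]),
            metric, "whole_brain", sr))
        }
      }
    }
  }
  if (!is.null(covariates)) {
    cov <- covariates
    corr_if <- function(effect, metric, icc_vec, col) {
      if (!col %in% names(cov)) {
        message("run_contrast_suite: covariate '", col, "' missing; ",
                effect, " skipped")
        return(invisible(NULL))
      }
      v <- cov[[col]][match(names(icc_vec), cov$subject)]
      ok <- is.finite(v) & is.finite(icc_vec)
      if (sum(ok) >= 4L && sd(v[ok]) > 0 && sd(icc_vec[ok]) > 0) {
        push(contrast_row(effect, metric, covariate_network,
                          pearson_with_ci(icc_vec[ok], v[ok])))
      }
    }
    for (metric in unique(rel$metric)) {
      off <- subj_icc(metric, covariate_network, "OFF")
      on <- subj_icc(metric, covariate_network, "ON")
      corr_if("OFF ICC vs FD difference", metric, off, "fd_diff")
      corr_if("OFF ICC vs tremor", metric, off, "tremor")
      if (all(c("rigidity", "bradykinesia") %in% names(cov))) {
        cov$rigidity_bradykinesia <- cov$rigidity + cov$bradykinesia
        corr_if("OFF ICC vs rigidity+bradykinesia", metric, off,
                "rigidity_bradykinesia")
      }
      corr_if("ON ICC vs motor improvement", metric, on, "improvement")
      corr_if("ON ICC vs connectivity response", metric, on, "fc_response")
      corr_if("ICC vs age", metric, off, "age")
      if ("target" %in% names(cov)) {
        for (net in nets) {
          for (cond in c("ON", "OFF")) {
            icc_vec <- subj_icc(metric, net, cond)
            tg <- cov$target[match(names(icc_vec), cov$subject)]
            stn <- icc_vec[tg == "STN"]
            gpi <- icc_vec[tg == "GPi"]
            if (length(stn) >= 2L && length(gpi) >= 2L) {
              rs <- wilcoxon_rank_sum(stn, gpi)
              rs$ci <- cliffs_delta(stn, gpi, "bootstrap", n_boot,
                                    seed)$ci
              push(contrast_row(
                sprintf("DBS-%s target STN vs GPi", cond), metric, net,
                rs))
            }
          }
        }
      }
    }
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
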