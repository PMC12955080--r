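#' Denoising configuration
#'
#' Parameters of the confound-regression + bandpass model applied to each
#' run before metric extraction: per-session linear polynomials, 6 rigid-body
#' motion parameters with first-order derivatives (12 regressors), one-hot
#' spike regressors for motion-contaminated outlier volumes (capped at 64),
#' and the top principal components of white-matter and CSF compartment
#' signal (5 + 5), followed by zero-phase bandpass filtering.
#'
#' @param band_low,band_high passband edges in Hz (standard 0.01-0.10;
#'   the exploratory upper edge of 0.25 Hz is capped at Nyquist by
#'   [denoise_run()]).
#' @param n_motion_regressors 12 (motion + derivatives) or 6 (motion only).
#' @param max_spike_frames maximum number of one-hot outlier regressors.
#' @param n_wm_components,n_csf_components principal components retained
#'   per tissue compartment.
#' @param polynomial_order per-session detrending polynomial order.
#' @param fd_spike_threshold framewise-displacement outlier threshold (mm).
#' @param global_z_threshold global-signal z-score outlier threshold.
#' @param min_dof warn when the effective degrees of freedom fall below
#'   this value.
#' @param drop_initial_frames non-steady-state frames to drop from raw
#'   inputs; the synthetic generator emulates runs with these already
#'   removed, so the default is 0 (use 2 for raw scanner runs).
#' @return An object of class `denoise_config`.
#' @export
denoise_config <- function(band_low = 0.01, band_high = 0.10,
                           n_motion_regressors = 12L, max_spike_frames = 64L,
                           n_wm_components = 5L, n_csf_components = 5L,
                           polynomial_order = 1L, fd_spike_threshold = 0.9,
                           global_z_threshold = 5, min_dof = 30L,
                           drop_initial_frames = 0L) {
  stopifnot(band_low > 0, band_high > band_low, max_spike_frames >= 0L,
            n_motion_regressors %in% c(6L, 12L), polynomial_order >= 0L)
  structure(list(band_low = band_low, band_high = band_high,
                 n_motion_regressors = as.integer(n_motion_regressors),
                 max_spike_frames = as.integer(max_spike_frames),
                 n_wm_components = as.integer(n_wm_components),
                 n_csf_components = as.integer(n_csf_components),
                 polynomial_order = as.integer(polynomial_order),
                 fd_spike_threshold = fd_spike_threshold,
                 global_z_threshold = global_z_threshold,
                 min_dof = as.integer(min_dof),
                 drop_initial_frames = as.integer(drop_initial_frames)),
            class = "denoise_config")
}

#' Flag motion-contaminated outlier volumes
#'
#' A frame is flagged when its framewise displacement exceeds
#' `fd_spike_threshold` or its global-signal z-score exceeds
#' `global_z_threshold` in absolute value. When more frames exceed the
#' thresholds than `max_spike_frames`, the worst offenders by FD are kept
#' (ties broken toward the earlier frame).
#'
#' @param motion `n x 6` motion trace (translations mm, rotations rad).
#' @param global_signal per-frame mean signal (length `n`).
#' @param config a [denoise_config()].
#' @return Sorted integer vector of flagged frame indices.
#' @export
detect_outlier_frames <- function(motion, global_signal,
                                  config = denoise_config()) {
  fd <- fd_series(motion)
  if (length(fd) != length(global_signal)) {
    stop("detect_outlier_frames: motion trace and global signal disagree ",
         "on frame count", call. = FALSE)
  }
  gs_sd <- sd(global_signal)
  z <- if (gs_sd > 0) (global_signal - mean(global_signal)) / gs_sd else
    rep(0, length(global_signal))
  hit <- which(fd > config$fd_spike_threshold |
                 abs(z) > config$global_z_threshold)
  if (length(hit) > config$max_spike_frames) {
    ord <- hit[order(-fd[hit], hit)]
    hit <- ord[seq_len(config$max_spike_frames)]
  }
  sort(hit)
}

#' Build the confound regressor matrix
#'
#' Assembles, in order: session polynomial columns (constant + linear by
#' default), motion parameters with backward-difference derivatives (first
#' derivative frame set to 0), one one-hot column per flagged frame, and the
#' top principal components of the demeaned white-matter and CSF voxel
#' matrices. Rank-deficient columns are dropped (recorded in the design's
#' `dropped` field) so the returned matrix always has full column rank.
#'
#' @param motion `n x 6` motion trace.
#' @param flags integer vector of outlier frames (possibly empty).
#' @param wm,csf `n x v` tissue voxel matrices.
#' @param config a [denoise_config()].
#' @return An object of class `confound_design`: list with `x` (the matrix),
#'   `labels`, `provenance` (polynomial/motion/spike/wm_pca/csf_pca per
#'   column) and `dropped`.
#' @export
build_confound_matrix <- function(motion, flags, wm, csf,
                                  config = denoise_config()) {
  n <- nrow(motion)
  if ((!is.null(wm) && nrow(wm) != n) || (!is.null(csf) && nrow(csf) != n)) {
    stop("build_confound_matrix: inputs disagree on frame count",
         call. = FALSE)
  }
  cols <- list()
  prov <- character(0)
  add <- function(mat, labels, kind) {
    cols[[length(cols) + 1L]] <<- mat
    prov <<- c(prov, rep(kind, ncol(mat)))
    colnames(cols[[length(cols)]]) <<- labels
  }
  tt <- seq_len(n) / n
  poly <- vapply(0:config$polynomial_order, function(d) tt^d, numeric(n))
  add(poly, paste0("poly_", 0:config$polynomial_order), "polynomial")
  mot <- as.matrix(motion)
  add(mot, paste0("motion_", seq_len(6L)), "motion")
  if (config$n_motion_regressors == 12L) {
    dmot <- rbind(0, diff(mot))
    add(dmot, paste0("motion_d", seq_len(6L)), "motion")
  }
  if (length(flags)) {
    sp <- matrix(0, n, length(flags))
    sp[cbind(flags, seq_along(flags))] <- 1
    add(sp, paste0("spike_", flags), "spike")
  }
  tissue_pcs <- function(x, k, kind) {
    if (is.null(x) || k == 0L) return(invisible(NULL))
    k_use <- min(k, ncol(x))
    if (k_use < k) {
      warning("build_confound_matrix: only ", ncol(x), " ", kind,
              " voxels available for ", k, " components", call. = FALSE)
    }
    pc <- prcomp(x, center = TRUE, scale. = FALSE)
    k_use <- min(k_use, ncol(pc$x))
    add(pc$x[, seq_len(k_use), drop = FALSE],
        paste0(kind, "_pc", seq_len(k_use)), paste0(kind, "_pca"))
  }
  tissue_pcs(wm, config$n_wm_components, "wm")
  tissue_pcs(csf, config$n_csf_components, "csf")
  x <- do.call(cbind, cols)
  labels <- colnames(x)
  qrx <- qr(x)
  dropped <- character(0)
  if (qrx$rank < ncol(x)) {
    keep <- qrx$pivot[seq_len(qrx$rank)]
    dropped <- labels[-keep]
    keep <- sort(keep)
    x <- x[, keep, drop = FALSE]
    labels <- labels[keep]
    prov <- prov[keep]
    message("build_confound_matrix: dropped ", length(dropped),
            " rank-deficient column(s): ", paste(dropped, collapse = ", "))
  }
  structure(list(x = x, labels = labels, provenance = prov,
                 dropped = dropped),
            class = "confound_design")
}

#' Regress confounds out of a time-series matrix
#'
#' Ordinary least-squares residualization of every channel against the full
#' confound design; residuals are orthogonal to each design column.
#'
#' @param series `n x channels` numeric matrix.
#' @param design a [build_confound_matrix()] result (or a plain matrix).
#' @return Residual matrix of the same shape.
#' @export
regress_confounds <- function(series, design) {
  x <- if (inherits(design, "confound_design")) design$x else as.matrix(design)
  series <- as.matrix(series)
  if (nrow(series) != nrow(x)) {
    stop("regress_confounds: series and design disagree on frame count",
         call. = FALSE)
  }
  qrx <- qr(x)
  if (qrx$rank < ncol(x)) {
    stop("regress_confounds: design matrix is rank deficient", call. = FALSE)
  }
  qr.resid(qrx, series)
}

#' Zero-phase rectangular bandpass filter
#'
#' Retains exactly the discrete-frequency bins with
#' `band_low <= f <= band_high` and zeroes all others (including DC), then
#' inverts the transform. The filter is zero-phase, idempotent and linear,
#' and the output has zero column means.
#'
#' @param series numeric vector or `n x channels` matrix.
#' @param tr repetition time in seconds.
#' @param band_low,band_high passband edges in Hz; `band_high` must not
#'   exceed the Nyquist frequency `1/(2 tr)`.
#' @return Filtered series of the same shape.
#' @export
bandpass_filter <- function(series, tr, band_low = 0.01, band_high = 0.10) {
  vec <- is.null(dim(series))
  x <- as.matrix(series)
  n <- nrow(x)
  if (n < 8L) stop("bandpass_filter: need at least 8 frames", call. = FALSE)
  nyq <- 1 / (2 * tr)
  if (band_high > nyq + 1e-12) {
    stop(sprintf(paste0("bandpass_filter: band_high = %g Hz exceeds the ",
                        "Nyquist frequency %.6g Hz at TR %g s"),
                 band_high, nyq, tr), call. = FALSE)
  }
  if (band_low <= 0 || band_low >= band_high) {
    stop("bandpass_filter: need 0 < band_low < band_high", call. = FALSE)
  }
  freq <- (seq_len(n) - 1L) / (n * tr)
  fold <- pmin(freq, 1 / tr - freq)
  keep <- fold >= band_low & fold <= band_high
  spec <- mvfft(x)
  spec[!keep, ] <- 0
  out <- Re(mvfft(spec, inverse = TRUE)) / n
  dimnames(out) <- dimnames(x)
  if (vec) out[, 1L] else out
}

#' Effective degrees of freedom after denoising
#'
#' Residual frames scaled by the retained bandwidth fraction:
#' \deqn{dof = (n - rank(design)) \times (f_{high} - f_{low}) / f_{Nyquist},}
#' floored at zero; `band_high` is capped at Nyquist.
#'
#' @param n_frames frames in the run.
#' @param design a `confound_design`, a matrix, or the design rank.
#' @param band_low,band_high passband edges in Hz.
#' @param tr repetition time in seconds.
#' @return Scalar dof estimate.
#' @export
effective_dof <- function(n_frames, design, band_low = 0.01,
                          band_high = 0.10, tr = 2.15) {
  rank <- if (inherits(design, "confound_design")) ncol(design$x)
          else if (is.matrix(design)) qr(design)$rank
          else as.numeric(design)
  nyq <- 1 / (2 * tr)
  hi <- min(band_high, nyq)
  max(0, (n_frames - rank)) * (hi - band_low) / nyq
}

#' Denoise one run of parcel (or voxel) time series
#'
#' The two-stage model applied per run: confound regression first, bandpass
#' filtering second. Outlier frames are detected from the motion trace and
#' the global signal, the confound matrix is assembled, channels are
#' residualized, and the residuals are bandpass filtered. The exploratory
#' band's upper edge is capped at Nyquist with a note in the report; a
#' warning (not an error) is emitted when the effective degrees of freedom
#' fall below `config$min_dof`.
#'
#' @param series `n x channels` time-series matrix.
#' @param motion `n x 6` motion trace.
#' @param wm,csf tissue voxel matrices (or `NULL`).
#' @param tr repetition time in seconds.
#' @param config a [denoise_config()].
#' @return An object of class `clean_series`: list with `series` (filtered
#'   residuals), `dof`, and `report` (flagged frames, regressor counts by
#'   provenance, dropped columns, band used).
#' @export
denoise_run <- function(series, motion, wm = NULL, csf = NULL, tr = 2.15,
                        config = denoise_config()) {
  series <- as.matrix(series)
  drop0 <- config$drop_initial_frames
  if (drop0 > 0L) {
    keep <- -seq_len(drop0)
    series <- series[keep, , drop = FALSE]
    motion <- motion[keep, , drop = FALSE]
    if (!is.null(wm)) wm <- wm[keep, , drop = FALSE]
    if (!is.null(csf)) csf <- csf[keep, , drop = FALSE]
  }
  nyq <- 1 / (2 * tr)
  hi <- min(config$band_high, nyq)
  capped <- hi < config$band_high
  flags <- detect_outlier_frames(motion, rowMeans(series), config)
  design <- build_confound_matrix(motion, flags, wm, csf, config)
  resid <- regress_confounds(series, design)
  filtered <- bandpass_filter(resid, tr, config$band_low, hi)
  dof <- effective_dof(nrow(series), design, config$band_low, hi, tr)
  if (dof < config$min_dof) {
    warning(sprintf("denoise_run: effective dof %.1f below target %d",
                    dof, config$min_dof), call. = FALSE)
  }
  structure(list(series = filtered, dof = dof,
                 report = list(flagged_frames = flags,
                               n_regressors = table(design$provenance),
                               dropped_columns = design$dropped,
                               band = c(config$band_low, hi),
                               band_capped = capped,
                               dropped_initial_frames = drop0)),
            class = "clean_series")
}

#' @export
print.clean_series <- function(x, ...) {
  cat(sprintf("Denoised run: %d frames x %d channels, effective dof %.1f\n",
              nrow(x$series), ncol(x$series), x$dof))
  cat(sprintf("  band %.3f-%.3f Hz%s; %d outlier frame(s); %d regressors\n",
              x$report$band[1L], x$report$band[2L],
              if (x$report$band_capped) " (capped at Nyquist)" else "",
              length(x$report$flagged_frames),
              sum(x$report$n_regressors)))
  invisible(x)
}
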