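#' Parcellation container
#'
#' Couples an integer label volume (0 = background) with the parcel
#' membership table that assigns each parcel to one or more functional
#' networks. The `whole_brain` network is implicit and always contains
#' every parcel.
#'
#' @param labels integer 3D array of voxel labels.
#' @param membership data frame with columns `parcel_id`, `parcel_name`
#'   and `networks` (semicolon-separated network names).
#' @return An object of class `parcellation`.
#' @export
parcellation <- function(labels, membership) {
  stopifnot(is.array(labels),
            all(c("parcel_id", "parcel_name", "networks") %in%
                  names(membership)))
  present <- sort(unique(as.integer(labels[labels > 0])))
  missing <- setdiff(membership$parcel_id, present)
  if (length(missing)) {
    stop("parcellation: membership lists parcel ids absent from the label ",
         "volume: ", paste(head(missing, 5L), collapse = ", "),
         call. = FALSE)
  }
  structure(list(labels = labels, membership = membership),
            class = "parcellation")
}

#' Network membership lookup
#'
#' @param parc a [parcellation()].
#' @return Named list mapping each network name (including `whole_brain`)
#'   to its sorted parcel ids.
#' @export
parcel_networks <- function(parc) {
  mem <- parc$membership
  nets <- strsplit(mem$networks, ";", fixed = TRUE)
  names(nets) <- mem$parcel_id
  out <- list(whole_brain = sort(mem$parcel_id))
  for (nm in sort(unique(trimws(unlist(nets))))) {
    ids <- mem$parcel_id[vapply(nets, function(x) nm %in% trimws(x),
                                logical(1L))]
    out[[nm]] <- sort(ids)
  }
  out
}

#' Average voxel time series within parcels
#'
#' @param voxel_series `frames x voxels` matrix.
#' @param voxel_labels integer vector assigning each column to a parcel id
#'   (0 = background, excluded).
#' @return `frames x parcels` matrix with parcel ids as column names;
#'   parcels without voxels are excluded with a message.
#' @export
extract_parcel_means <- function(voxel_series, voxel_labels) {
  voxel_series <- as.matrix(voxel_series)
  if (ncol(voxel_series) != length(voxel_labels)) {
    stop("extract_parcel_means: one label per voxel column required",
         call. = FALSE)
  }
  ids <- sort(unique(voxel_labels[voxel_labels > 0L]))
  if (!length(ids)) {
    stop("extract_parcel_means: empty parcellation", call. = FALSE)
  }
  out <- vapply(ids, function(id) {
    rowMeans(voxel_series[, voxel_labels == id, drop = FALSE])
  }, numeric(nrow(voxel_series)))
  colnames(out) <- ids
  out
}

#' Fisher-z functional connectivity matrix
#'
#' Pearson correlations between parcel mean time series, clipped to
#' `1 - 1e-7` in absolute value and Fisher transformed
#' (`z = atanh(r)`). The diagonal is `NA`; zero-variance parcels are
#' excluded with a message.
#'
#' @param parcel_series `frames x parcels` matrix (>= 3 frames).
#' @return Symmetric parcels-x-parcels matrix of Fisher-z values.
#' @export
connectivity_matrix <- function(parcel_series) {
  parcel_series <- as.matrix(parcel_series)
  if (nrow(parcel_series) < 3L) {
    stop("connectivity_matrix: need at least 3 frames", call. = FALSE)
  }
  v <- apply(parcel_series, 2L, var)
  if (any(v == 0)) {
    message("connectivity_matrix: excluding ", sum(v == 0),
            " zero-variance parcel(s)")
    parcel_series <- parcel_series[, v > 0, drop = FALSE]
  }
  r <- cor(parcel_series)
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  diag(z) <- NA_real_
  z
}

#' Vectorize a metric over one network
#'
#' For a connectivity matrix: the upper triangle (`i < j` by ascending
#' parcel id) of the submatrix restricted to the network's parcels,
#' vectorized row-major — the fixed element order consumed by the ICC
#' stage. For a per-parcel variability vector: the network's values in
#' ascending parcel-id order.
#'
#' @param x Fisher-z matrix (with parcel-id dimnames) or named per-parcel
#'   vector.
#' @param parc a [parcellation()].
#' @param network network name; `"whole_brain"` selects every parcel.
#' @return Numeric vector of network elements.
#' @export
network_vector <- function(x, parc, network = "whole_brain") {
  nets <- parcel_networks(parc)
  if (!network %in% names(nets)) {
    stop("network_vector: unknown network '", network,
         "'; available: ", paste(names(nets), collapse = ", "),
         call. = FALSE)
  }
  ids <- as.character(nets[[network]])
  if (is.matrix(x)) {
    ids <- intersect(ids, colnames(x))
    sub <- x[ids, ids, drop = FALSE]
    # row-major upper triangle: (1,2),(1,3),...,(1,k),(2,3),...
    tsub <- t(sub)
    out <- tsub[lower.tri(tsub)]
    pairs <- which(upper.tri(sub), arr.ind = TRUE)
    pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
    names(out) <- paste(ids[pairs[, 1L]], ids[pairs[, 2L]], sep = "-")
    out
  } else {
    ids <- intersect(ids, names(x))
    x[ids]
  }
}

#' Brain variability per parcel
#'
#' Temporal standard deviation of the BOLD signal summarized per parcel.
#' The default mode takes the sd over time of each parcel's mean series;
#' `"voxel_mean"` instead averages each voxel's temporal sd within the
#' parcel. Both use the sample sd (n-1 denominator) and coincide for
#' single-voxel parcels.
#'
#' @param series `frames x channels` matrix: parcel means for
#'   `"parcel_mean"` mode, voxel series (with `voxel_labels`) for
#'   `"voxel_mean"`.
#' @param mode `"parcel_mean"` or `"voxel_mean"`.
#' @param voxel_labels per-column parcel ids, required for voxel mode.
#' @return Named non-negative vector, one value per parcel.
#' @export
brain_variability <- function(series, mode = c("parcel_mean", "voxel_mean"),
                              voxel_labels = NULL) {
  mode <- match.arg(mode)
  series <- as.matrix(series)
  if (nrow(series) < 3L) {
    stop("brain_variability: need at least 3 frames", call. = FALSE)
  }
  if (mode == "parcel_mean") {
    out <- apply(series, 2L, sd)
    if (is.null(names(out)) && !is.null(colnames(series))) {
      names(out) <- colnames(series)
    }
    out
  } else {
    if (is.null(voxel_labels)) {
      stop("brain_variability: voxel_mean mode needs 'voxel_labels'",
           call. = FALSE)
    }
    vox_sd <- apply(series, 2L, sd)
    ids <- sort(unique(voxel_labels[voxel_labels > 0L]))
    out <- vapply(ids, function(id) mean(vox_sd[voxel_labels == id]),
                  numeric(1L))
    names(out) <- ids
    out
  }
}

# Per-frame framewise displacement from a 6-column rigid-body trace.
fd_series <- function(motion, radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) {
    stop("framewise displacement needs a 6-column motion trace",
         call. = FALSE)
  }
  d <- abs(rbind(0, diff(motion)))
  rowSums(d[, 1:3, drop = FALSE]) +
    radius_mm * rowSums(d[, 4:6, drop = FALSE])
}

#' Framewise displacement summary
#'
#' FD combines backward-difference translations with rotations projected
#' onto a sphere of `radius_mm`:
#' \eqn{FD_t = \sum |\Delta trans| + radius \sum |\Delta rot|}, with
#' \eqn{FD_1 = 0}. The summary statistic is the 95th percentile by linear
#' interpolation between order statistics.
#'
#' @param motion `n x 6` trace (translations mm, rotations rad).
#' @param radius_mm head-sphere radius for rotation projection.
#' @return List with `fd` (per-frame vector) and `p95`.
#' @export
framewise_displacement <- function(motion, radius_mm = 50) {
  fd <- fd_series(motion, radius_mm)
  list(fd = fd, p95 = unname(quantile(fd, 0.95, type = 7)))
}

#' Acute motor improvement with stimulation
#'
#' Percent reduction of the MDS-UPDRS-III motor score when DBS is turned
#' on: `((OFF - ON) / OFF) * 100`. Negative values indicate worsening.
#'
#' @param score_off,score_on motor exam scores (points); `score_off` must
#'   be positive.
#' @return Improvement in percent.
#' @examples
#' improvement_score(50, 25) # 50
#' @export
improvement_score <- function(score_off, score_on) {
  if (any(score_off <= 0)) {
    stop("improvement_score: undefined for score_off <= 0", call. = FALSE)
  }
  if (any(score_on < 0)) {
    stop("improvement_score: scores must be non-negative", call. = FALSE)
  }
  (score_off - score_on) / score_off * 100
}
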