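#' Otsu threshold of an intensity image
#'
#' Histogram-based threshold maximizing the between-class variance over
#' 256 equal-width bins spanning the in-mask intensity range; ties are
#' broken toward the lower threshold. The returned value is the upper edge
#' of the optimal low-class bin, so classification is `intensity <
#' threshold`.
#'
#' @param volume numeric array or vector of intensities.
#' @param mask optional logical array restricting the histogram (e.g. a
#'   brain mask).
#' @param n_bins histogram resolution.
#' @return Scalar threshold, with attributes `separability` (Otsu's
#'   eta = between-class / total variance at the optimum) and `cut`
#'   (optimal bin index).
#' @export
otsu_threshold <- function(volume, mask = NULL, n_bins = 256L) {
  x <- if (is.null(mask)) as.numeric(volume) else as.numeric(volume[mask])
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2L) {
    stop("otsu_threshold: need at least 2 distinct intensities",
         call. = FALSE)
  }
  lo <- min(x)
  hi <- max(x)
  bin <- pmin(pmax(floor((x - lo) / (hi - lo) * n_bins) + 1L, 1L), n_bins)
  counts <- tabulate(bin, nbins = n_bins)
  cut <- otsu_cut(counts)
  thr <- lo + cut$cut * (hi - lo) / n_bins
  structure(thr, separability = cut$separability, cut = cut$cut)
}

#' Otsu cut point of a histogram
#'
#' Between-class variance maximization on raw histogram counts: for every
#' cut `t` (low class = bins `1..t`), computes
#' \eqn{\sigma^2_B(t) = \omega_0 \omega_1 (\mu_0 - \mu_1)^2} from the
#' cumulative moments and returns the maximizing cut (lowest on ties).
#'
#' @param counts non-negative histogram counts per bin.
#' @param mids optional bin centers (defaults to bin indices).
#' @return List with `cut` (index of the last low-class bin),
#'   `separability` and `sigma2_between` (the full curve).
#' @export
otsu_cut <- function(counts, mids = seq_along(counts)) {
  stopifnot(length(counts) >= 2L, all(counts >= 0))
  total <- sum(counts)
  if (total == 0) stop("otsu_cut: empty histogram", call. = FALSE)
  p <- counts / total
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  denom <- omega * (1 - omega)
  sigma2 <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  sigma2 <- sigma2[-length(sigma2)]               # cut after last bin is void
  cut <- which.max(sigma2)                        # which.max takes lowest tie
  total_var <- sum(p * mids^2) - mu_t^2
  list(cut = cut,
       separability = if (total_var > 0) sigma2[cut] / total_var else 0,
       sigma2_between = sigma2)
}

# 26-connectivity component labelling of a logical 3D array (iterative BFS).
label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  idx <- which(mask)
  if (!length(idx)) return(lab)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0L, , drop = FALSE]
  coord <- arrayInd(idx, d)
  pos <- array(0L, dim = d)
  pos[idx] <- seq_along(idx)
  comp <- 0L
  for (i in seq_along(idx)) {
    if (lab[idx[i]] != 0L) next
    comp <- comp + 1L
    queue <- i
    lab[idx[i]] <- comp
    while (length(queue)) {
      j <- queue[length(queue)]
      queue <- queue[-length(queue)]
      here <- coord[j, ]
      for (o in seq_len(nrow(offs))) {
        nb <- here + offs[o, ]
        if (any(nb < 1L) || any(nb > d)) next
        k <- pos[nb[1L], nb[2L], nb[3L]]
        if (k > 0L && lab[idx[k]] == 0L) {
          lab[idx[k]] <- comp
          queue <- c(queue, k)
        }
      }
    }
  }
  lab
}

#' Segment hardware-related signal loss
#'
#' Thresholds the mean functional volume inside the brain mask (Otsu by
#' default), keeps voxels below the threshold, and removes connected
#' components smaller than `min_component` voxels (26-connectivity) — an
#' automated stand-in for manual mask cleaning. When the in-brain
#' histogram shows no class separation (Otsu separability below
#' `min_separability`, as for an artifact-free image), the mask is empty.
#'
#' @param volume mean functional intensity array.
#' @param brain_mask logical array on the same grid.
#' @param threshold intensity threshold; `NULL` for Otsu.
#' @param min_component smallest connected component kept, in voxels.
#' @param min_separability Otsu eta below which the image is declared
#'   artifact-free.
#' @return An object of class `artifact_mask`: list with `mask` (logical
#'   array), `threshold`, `separability`, `n_voxels`.
#' @export
segment_artifact <- function(volume, brain_mask, threshold = NULL,
                             min_component = 5L, min_separability = 0.85) {
  if (!identical(dim(volume), dim(brain_mask))) {
    stop("segment_artifact: volume and brain mask grids differ",
         call. = FALSE)
  }
  sep <- NA_real_
  if (is.null(threshold)) {
    thr <- otsu_threshold(volume, brain_mask)
    sep <- attr(thr, "separability")
    threshold <- as.numeric(thr)
    if (sep < min_separability) {
      return(structure(list(mask = array(FALSE, dim(volume)),
                            threshold = threshold, separability = sep,
                            n_voxels = 0L),
                       class = "artifact_mask"))
    }
  }
  mask <- (volume < threshold) & brain_mask
  if (min_component > 1L && any(mask)) {
    lab <- label_components(mask)
    sizes <- tabulate(lab[lab > 0L])
    small <- which(sizes < min_component)
    if (length(small)) mask[lab %in% small] <- FALSE
  }
  structure(list(mask = mask, threshold = threshold, separability = sep,
                 n_voxels = sum(mask)),
            class = "artifact_mask")
}

#' @export
print.artifact_mask <- function(x, ...) {
  cat(sprintf(
    "Artifact mask: %d voxel(s) below threshold %.3f (separability %.3f)\n",
    x$n_voxels, x$threshold, x$separability))
  invisible(x)
}

#' Stratify parcels and connections by artifact overlap
#'
#' A parcel is affected when at least `min_overlap_voxels` of its voxels
#' fall inside the artifact mask (default: any overlap). A connection is
#' affected when either endpoint parcel is affected.
#'
#' @param mask an [segment_artifact()] result or a logical array.
#' @param parc a [parcellation()] (or an integer label array).
#' @param min_overlap_voxels overlap rule parameter.
#' @return List with `affected_ids`, `unaffected_ids`, `overlap` (data
#'   frame: parcel_id, voxels, overlap_voxels, overlap_fraction) and the
#'   rule parameters.
#' @export
affected_parcels <- function(mask, parc, min_overlap_voxels = 1L) {
  m <- if (inherits(mask, "artifact_mask")) mask$mask else mask
  labels <- if (inherits(parc, "parcellation")) parc$labels else parc
  if (!identical(dim(m), dim(labels))) {
    stop("affected_parcels: mask and parcellation grids differ",
         call. = FALSE)
  }
  ids <- sort(unique(as.integer(labels[labels > 0L])))
  nvox <- tabulate(labels[labels > 0L])[ids]
  ov <- vapply(ids, function(id) sum(m[labels == id]), integer(1L))
  overlap <- data.frame(parcel_id = ids, voxels = nvox,
                        overlap_voxels = ov,
                        overlap_fraction = ov / nvox)
  affected <- ids[ov >= min_overlap_voxels]
  list(affected_ids = affected,
       unaffected_ids = setdiff(ids, affected),
       overlap = overlap,
       min_overlap_voxels = min_overlap_voxels)
}

#' Affected-connection indicator over the network element order
#'
#' @param affected_ids affected parcel ids.
#' @param ids parcel ids of the network, ascending.
#' @return Logical vector over the row-major upper-triangle connection
#'   order of [network_vector()]: `TRUE` when either endpoint is affected.
#' @export
affected_connections <- function(affected_ids, ids) {
  ids <- sort(ids)
  k <- length(ids)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  ids[pairs[, 1L]] %in% affected_ids | ids[pairs[, 2L]] %in% affected_ids
}

#' ICC split by artifact status
#'
#' Recomputes ICC(A,1) on the affected-element rows, the unaffected rows
#' and all rows of one test/retest matrix. Subsets with fewer than 3
#' elements are flagged (`NA` ICC) so they can be excluded from group
#' tests.
#'
#' @param m `N x 2` element matrix (rows in the fixed network order).
#' @param affected logical vector of length `N`.
#' @return Data frame with one row per subset (`affected`, `unaffected`,
#'   `whole`): icc, n, degenerate, insufficient.
#' @export
split_icc <- function(m, affected) {
  m <- as.matrix(m)
  stopifnot(nrow(m) == length(affected))
  one <- function(rows, label) {
    if (sum(rows) < 3L) {
      return(data.frame(subset = label, icc = NA_real_, n = sum(rows),
                        degenerate = FALSE, insufficient = TRUE,
                        stringsAsFactors = FALSE))
    }
    fit <- icc_a1(m[rows, , drop = FALSE])
    data.frame(subset = label, icc = fit$icc, n = fit$n,
               degenerate = fit$degenerate, insufficient = FALSE,
               stringsAsFactors = FALSE)
  }
  rbind(one(affected, "affected"),
        one(!affected, "unaffected"),
        one(rep(TRUE, nrow(m)), "whole"))
}
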