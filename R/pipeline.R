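#' Read and write tabular time series
#'
#' TSV codecs used throughout the package: a header row of channel ids,
#' one row per frame, full double precision. Write-then-read reproduces
#' the matrix exactly within float64 representation.
#'
#' @param x numeric matrix (frames x channels).
#' @param path file path.
#' @return `read_series_tsv` returns a numeric matrix with column names.
#' @export
write_series_tsv <- function(x, path) {
  df <- as.data.frame(x)
  utils::write.table(format(df, digits = 17, scientific = TRUE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_tsv
#' @export
read_series_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  as.matrix(df)
}

#' NIfTI-1 volume codecs
#'
#' Thin wrappers over RNifti keeping the package's on-disk contract in one
#' place. `read_label_volume` additionally validates that the volume holds
#' integer labels, as required for a parcellation image.
#'
#' @param x numeric/integer array.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume` returns a plain numeric array.
#' @export
write_volume <- function(x, path) {
  RNifti::writeNifti(RNifti::asNifti(x), path)
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path) {
  v <- RNifti::readNifti(path)
  array(as.numeric(v), dim = dim(v))
}

#' @rdname write_volume
#' @export
read_label_volume <- function(path) {
  v <- read_volume(path)
  if (any(v != round(v)) || any(v < 0)) {
    stop("read_label_volume: '", path,
         "' does not contain non-negative integer labels", call. = FALSE)
  }
  array(as.integer(round(v)), dim = dim(v))
}

#' Write a synthetic cohort to disk
#'
#' Materializes a [generate_dataset()] cohort using the package's on-disk
#' layout: a YAML config echo, a JSON ground-truth file, the parcellation
#' label volume, brain mask and membership TSV at the root, and per
#' subject/visit/condition/run TSV time series, motion traces, tissue
#' series and a JSON sidecar (tr, n_frames, condition, visit, run), plus
#' one phantom mean-EPI volume per subject.
#'
#' @param cohort a `synth_cohort`.
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_dataset <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- cohort$config
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  truth <- cohort$truth
  truth$element_values <- NULL   # matrices regenerate from config + seed
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_volume(cohort$parcellation$labels,
               file.path(dir, "parcellation.nii.gz"))
  write_volume((cohort$parcellation$labels > 0) * 1L,
               file.path(dir, "brain_mask.nii.gz"))
  utils::write.table(cohort$parcellation$membership,
                     file.path(dir, "membership.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (subj in names(cohort$subjects)) {
    sdir <- file.path(dir, subj)
    dir.create(sdir, showWarnings = FALSE)
    write_volume(cohort$phantoms[[subj]]$intensity,
                 file.path(sdir, "mean_epi.nii.gz"))
    visits <- cohort$subjects[[subj]]
    for (v in seq_along(visits)) {
      for (cond in names(visits[[v]])) {
        for (run in names(visits[[v]][[cond]])) {
          stem <- file.path(sdir, sprintf("%s_ses-%d_cond-%s_run-%s",
                                          subj, v, cond, run))
          rr <- visits[[v]][[cond]][[run]]
          write_series_tsv(rr$parcel_series, paste0(stem, "_bold.tsv"))
          write_series_tsv(rr$motion, paste0(stem, "_motion.tsv"))
          write_series_tsv(rr$wm, paste0(stem, "_wm.tsv"))
          write_series_tsv(rr$csf, paste0(stem, "_csf.tsv"))
          jsonlite::write_json(
            list(tr = cfg$tr, n_frames = cfg$n_frames, subject = subj,
                 visit = v, condition = cond, run = run),
            paste0(stem, ".json"), auto_unbox = TRUE)
        }
      }
    }
  }
  invisible(dir)
}

#' Denoise one run and compute its metrics
#'
#' Parcel means are extracted from the voxel series, denoised with
#' [denoise_run()], and summarized as the Fisher-z connectivity matrix,
#' the per-parcel brain-variability vector and the framewise-displacement
#' summary.
#'
#' @param run one run entry of a `synth_cohort` (or an equivalent list
#'   with `voxel_series`, `voxel_labels`, `motion`, `wm`, `csf`).
#' @param tr repetition time in seconds.
#' @param config a [denoise_config()].
#' @param variability_mode passed to [brain_variability()].
#' @return List with `connectivity`, `variability`, `motion` (fd + p95),
#'   `dof` and the denoise `report`.
#' @export
compute_run_metrics <- function(run, tr = 2.15, config = denoise_config(),
                                variability_mode = "parcel_mean") {
  parcel <- extract_parcel_means(run$voxel_series, run$voxel_labels)
  clean <- denoise_run(parcel, run$motion, run$wm, run$csf, tr, config)
  conn <- connectivity_matrix(clean$series)
  bv <- if (variability_mode == "parcel_mean") {
    brain_variability(clean$series, "parcel_mean")
  } else {
    vox_clean <- denoise_run(run$voxel_series, run$motion, run$wm,
                             run$csf, tr, config)
    brain_variability(vox_clean$series, "voxel_mean", run$voxel_labels)
  }
  list(connectivity = conn, variability = bv,
       motion = framewise_displacement(run$motion), dof = clean$dof,
       report = clean$report)
}

#' Run the full reliability pipeline on a synthetic cohort
#'
#' Chains the stages end to end: simulate -> denoise -> metrics ->
#' reliability -> artifact stratification -> group contrasts. The result
#' is bit-identical under a fixed configuration (the master seed lives in
#' the synthesis config; bootstrap intervals derive their seed from it).
#'
#' @param synth a [synth_config()].
#' @param denoise a [denoise_config()].
#' @param band `"standard"` (0.01-0.10 Hz) or `"exploratory"` (0.01-0.25
#'   Hz, upper edge capped at Nyquist inside the denoiser).
#' @param variability_mode passed to [brain_variability()].
#' @param out_dir optional directory; when given, the reliability,
#'   artifact and contrast tables, the denoise reports and a provenance
#'   manifest are written there.
#' @return An object of class `dbs_pipeline`: list with `cohort`,
#'   `metrics` (nested store), `reliability`, `artifact`, `covariates`,
#'   `contrasts`, `affected`, `manifest`.
#' @export
run_pipeline <- function(synth = synth_config(),
                         denoise = denoise_config(),
                         band = c("standard", "exploratory"),
                         variability_mode = "parcel_mean",
                         out_dir = NULL) {
  band <- match.arg(band)
  if (band == "exploratory") denoise$band_high <- 0.25
  cohort <- generate_dataset(synth)
  parc <- cohort$parcellation
  # artifact segmentation per subject on the phantom volume
  affected_by_subj <- lapply(cohort$phantoms, function(ph) {
    seg <- segment_artifact(ph$intensity, ph$brain_mask)
    affected_parcels(seg, parc)
  })
  metric_store <- lapply(cohort$subjects, function(visits) {
    lapply(visits, function(conds) {
      lapply(conds, function(runs) {
        lapply(runs, compute_run_metrics, tr = synth$tr, config = denoise,
               variability_mode = variability_mode)
      })
    })
  })
  pairings <- session_pairings(synth$n_visits)
  rel <- icc_per_network(metric_store, parc, pairings)
  # artifact-stratified ICC (within pairing, visit 1)
  art_rows <- list()
  nets <- parcel_networks(parc)
  all_ids <- nets$whole_brain
  for (subj in names(metric_store)) {
    aff_ids <- affected_by_subj[[subj]]$affected_ids
    aff_conn <- affected_connections(aff_ids, all_ids)
    aff_parc <- all_ids %in% aff_ids
    for (cond in c("OFF", "ON")) {
      runs <- metric_store[[subj]][[1L]][[cond]]
      for (metric in c("connectivity", "variability")) {
        get_vec <- function(rr) {
          if (metric == "connectivity") {
            network_vector(rr$connectivity, parc, "whole_brain")
          } else network_vector(rr$variability, parc, "whole_brain")
        }
        m <- cbind(test = get_vec(runs$test),
                   retest = get_vec(runs$retest))
        aff <- if (metric == "connectivity") aff_conn else aff_parc
        sp <- split_icc(m, aff)
        sp$subject <- subj
        sp$condition <- cond
        sp$metric <- metric
        art_rows[[length(art_rows) + 1L]] <- sp
      }
    }
  }
  artifact <- do.call(rbind, art_rows)
  # per-subject covariates: clinical scores + motion and FC response
  cov <- cohort$clinical
  cov$fd_diff <- vapply(names(cohort$subjects), function(subj) {
    runs <- cohort$subjects[[subj]][[1L]][["OFF"]]
    abs(framewise_displacement(runs$test$motion)$p95 -
          framewise_displacement(runs$retest$motion)$p95)
  }, numeric(1L))
  cov$fc_response <- vapply(names(metric_store), function(subj) {
    mean_fc <- function(cond) {
      mean(vapply(metric_store[[subj]][[1L]][[cond]], function(rr) {
        mean(network_vector(rr$connectivity, parc, "whole_brain"))
      }, numeric(1L)))
    }
    mean_fc("ON") - mean_fc("OFF")
  }, numeric(1L))
  contrasts <- run_contrast_suite(rel, cov, artifact,
                                  seed = synth$seed + 101L)
  manifest <- list(
    package = "dbsretest",
    version = as.character(utils::packageVersion("dbsretest")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = synth$seed, band = band,
    synth_config = unclass(synth), denoise_config = unclass(denoise),
    reliability_checksum = table_checksum(rel))
  out <- structure(list(cohort = cohort, metrics = metric_store,
                        reliability = rel, artifact = artifact,
                        covariates = cov, contrasts = contrasts,
                        affected = affected_by_subj, manifest = manifest),
                   class = "dbs_pipeline")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, f) {
      utils::write.table(df, file.path(out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    wt(rel, "reliability.tsv")
    wt(artifact, "artifact_icc.tsv")
    wt(cov, "covariates.tsv")
    if (!is.null(contrasts)) wt(contrasts, "contrasts.tsv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

# md5 of a table's serialized text form; used for the provenance manifest
# and determinism checks.
table_checksum <- function(df) {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  utils::write.table(format(df, digits = 15), tmp, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  unname(tools::md5sum(tmp))
}

#' @export
print.dbs_pipeline <- function(x, ...) {
  cat("DBS test-retest reliability pipeline\n")
  print(x$cohort)
  med <- stats::aggregate(icc ~ metric + condition,
                          data = x$reliability[x$reliability$network ==
                                                 "whole_brain", ],
                          FUN = function(v) median(v, na.rm = TRUE))
  cat("  median whole-brain ICC by metric and condition:\n")
  for (i in seq_len(nrow(med))) {
    cat(sprintf("    %-13s %-4s %.3f\n", med$metric[i], med$condition[i],
                med$icc[i]))
  }
  cat(sprintf("  %d contrast row(s); manifest checksum %s\n",
              if (is.null(x$contrasts)) 0L else nrow(x$contrasts),
              substr(x$manifest$reliability_checksum, 1L, 8L)))
  invisible(x)
}
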