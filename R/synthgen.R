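#' Configuration for the synthetic test-retest cohort generator
#'
#' Defines the study conditions emulated by [generate_dataset()]: a cohort of
#' DBS patients scanned twice (test/retest, less than a minute apart) under
#' each stimulation condition (OFF/ON), with six-minute runs at a repetition
#' time of 2.15 s. Parcel-level signal amplitudes follow a two-way
#' variance-components model \eqn{m_{ir} = \mu_i + s_r + e_{ir}} with
#' between-parcel spread `sigma_row`, session shifts `sigma_session` and run
#' noise `sigma_noise`, so the true single-subject reliability of the derived
#' brain-variability metric is known in closed form:
#' \deqn{ICC = \sigma_b^2 / (\sigma_b^2 + \sigma_s^2 + \sigma_e^2).}
#'
#' @param n_subjects number of simulated patients.
#' @param n_parcels number of atlas parcels.
#' @param voxels_per_parcel voxels rendered per parcel on the phantom grid.
#' @param n_frames frames per run (>= 40).
#' @param tr repetition time in seconds.
#' @param sigma_row between-element (parcel) amplitude sd, \eqn{\sigma_b}.
#' @param sigma_session session-shift sd, \eqn{\sigma_s}.
#' @param sigma_noise run-noise sd, \eqn{\sigma_e}.
#' @param artifact_parcel_fraction fraction of parcels affected by the
#'   simulated metal artifact, in `[0, 1]`.
#' @param artifact_attenuation multiplicative amplitude gain in `(0, 1]`
#'   applied to affected parcels (1 = no artifact).
#' @param artifact_noise_sd sd of extra run-specific noise mixed into the
#'   signal of affected parcels (units of parcel-signal sd); emulates the
#'   reduced SNR near implanted hardware.
#' @param on_modulation_sd sd of the parcel-specific multiplicative
#'   stimulation gains applied in the DBS-ON condition.
#' @param motion_spike_rate per-frame probability of a transient head-motion
#'   spike.
#' @param amp_base baseline signal amplitude added to every element value so
#'   amplitudes stay positive.
#' @param voxel_noise_sd sd of iid white noise added per voxel on top of the
#'   shared parcel signal.
#' @param network_coupling range of the within-network coupling \eqn{\rho}
#'   drawn per parcel and subject.
#' @param n_visits number of imaging visits (sessions months apart).
#' @param seed master integer seed; per-subject substreams are derived from
#'   it so output is bit-identical under a fixed configuration.
#'
#' @return An object of class `synth_config` (a validated list).
#' @seealso [generate_dataset()], [generate_motion_trace()],
#'   [generate_phantom_volume()]
#' @export
synth_config <- function(n_subjects = 8L, n_parcels = 100L,
                         voxels_per_parcel = 27L, n_frames = 165L,
                         tr = 2.15, sigma_row = 1, sigma_session = 0.3,
                         sigma_noise = 0.5, artifact_parcel_fraction = 0.1,
                         artifact_attenuation = 0.4, artifact_noise_sd = 0.5,
                         on_modulation_sd = 0.1, motion_spike_rate = 0.02,
                         amp_base = 10, voxel_noise_sd = 1,
                         network_coupling = c(0.3, 0.7), n_visits = 1L,
                         seed = 1L) {
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_parcels = as.integer(n_parcels),
              voxels_per_parcel = as.integer(voxels_per_parcel),
              n_frames = as.integer(n_frames), tr = tr,
              sigma_row = sigma_row, sigma_session = sigma_session,
              sigma_noise = sigma_noise,
              artifact_parcel_fraction = artifact_parcel_fraction,
              artifact_attenuation = artifact_attenuation,
              artifact_noise_sd = artifact_noise_sd,
              on_modulation_sd = on_modulation_sd,
              motion_spike_rate = motion_spike_rate,
              amp_base = amp_base, voxel_noise_sd = voxel_noise_sd,
              network_coupling = network_coupling,
              n_visits = as.integer(n_visits), seed = as.integer(seed))
  for (f in c("n_subjects", "n_parcels", "voxels_per_parcel", "n_visits")) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) {
      stop("synth_config: '", f, "' must be a positive integer", call. = FALSE)
    }
  }
  if (cfg$n_frames < 40L) {
    stop("synth_config: 'n_frames' must be >= 40", call. = FALSE)
  }
  if (cfg$tr <= 0) stop("synth_config: 'tr' must be positive", call. = FALSE)
  sds <- c("sigma_row", "sigma_session", "sigma_noise", "artifact_noise_sd",
           "on_modulation_sd", "voxel_noise_sd")
  for (f in sds) {
    if (cfg[[f]] < 0) stop("synth_config: '", f, "' must be >= 0",
                           call. = FALSE)
  }
  if (cfg$artifact_parcel_fraction < 0 || cfg$artifact_parcel_fraction > 1) {
    stop("synth_config: 'artifact_parcel_fraction' must lie in [0, 1]",
         call. = FALSE)
  }
  if (cfg$artifact_attenuation <= 0 || cfg$artifact_attenuation > 1) {
    stop("synth_config: 'artifact_attenuation' must lie in (0, 1]",
         call. = FALSE)
  }
  if (cfg$motion_spike_rate < 0 || cfg$motion_spike_rate > 1) {
    stop("synth_config: 'motion_spike_rate' must lie in [0, 1]",
         call. = FALSE)
  }
  class(cfg) <- "synth_config"
  cfg
}

#' Band-limited Gaussian signals
#'
#' Draws `m` columns of length `n` by placing complex-Gaussian coefficients
#' on the discrete-frequency bins within `[lo, hi]` Hz and inverting the
#' transform; each column is rescaled to unit sample standard deviation and
#' has exactly zero mean (no DC component). Because the signal lives only on
#' in-band bins, the package's rectangular bandpass filter is an identity on
#' it, which is what makes the generator's reliability analytically known
#' through the denoising path.
#'
#' @param n number of frames.
#' @param tr repetition time in seconds.
#' @param lo,hi passband edges in Hz.
#' @param m number of independent columns.
#' @return An `n x m` numeric matrix.
#' @export
band_limited_signal <- function(n, tr, lo = 0.01, hi = 0.10, m = 1L) {
  stopifnot(n >= 8L, tr > 0, m >= 1L)
  freq <- (seq_len(n) - 1L) / (n * tr)
  half <- which(freq >= lo & freq <= hi & seq_len(n) - 1L <= n %/% 2)
  if (length(half) == 0L) {
    stop("band_limited_signal: no frequency bins inside [", lo, ", ", hi,
         "] Hz for n = ", n, ", tr = ", tr, call. = FALSE)
  }
  spec <- matrix(0 + 0i, n, m)
  coefs <- matrix(complex(real = rnorm(length(half) * m),
                          imaginary = rnorm(length(half) * m)),
                  length(half), m)
  spec[half, ] <- coefs
  # mirror onto conjugate bins so the inverse transform is real
  mirror <- n - (half - 1L) + 1L
  ok <- mirror >= 1L & mirror <= n & mirror != half
  spec[mirror[ok], ] <- Conj(coefs[ok, , drop = FALSE])
  x <- Re(mvfft(spec, inverse = TRUE)) / n
  sds <- apply(x, 2L, sd)
  sds[sds == 0] <- 1
  sweep(x, 2L, sds, "/")
}

#' Simulate two-way variance-components element values
#'
#' The statistical core of the generator: draws an `n_elements x k` matrix
#' under \eqn{m_{ir} = \mu_i + s_r + e_{ir}} with row effects
#' \eqn{\mu_i \sim N(0, \sigma_b^2)}, column (session) shifts
#' \eqn{s_r \sim N(0, \sigma_s^2)} and residual noise
#' \eqn{e_{ir} \sim N(0, \sigma_e^2)}. The population intraclass
#' correlation of such a matrix is
#' \eqn{\sigma_b^2/(\sigma_b^2+\sigma_s^2+\sigma_e^2)}.
#'
#' @param n_elements number of rows (parcels or connections).
#' @param sigma_row,sigma_session,sigma_noise component standard deviations.
#' @param k number of repeated measurements (columns).
#' @return Numeric matrix of element values.
#' @export
simulate_element_matrix <- function(n_elements, sigma_row, sigma_session,
                                    sigma_noise, k = 2L) {
  stopifnot(n_elements >= 1L, k >= 2L)
  mu <- rnorm(n_elements, 0, sigma_row)
  s <- rnorm(k, 0, sigma_session)
  e <- matrix(rnorm(n_elements * k, 0, sigma_noise), n_elements, k)
  mu + matrix(s, n_elements, k, byrow = TRUE) + e
}

#' Simulate a six-column head-motion trace
#'
#' Produces smooth sinusoidal baseline drift in all six rigid-body parameters
#' (translations in mm, rotations in radians) plus transient translation
#' spikes occurring independently per frame with probability
#' `motion_spike_rate`. Spiked frames are returned so downstream outlier
#' detection can be scored against ground truth.
#'
#' @param config a [synth_config()].
#' @param drift_amplitude peak drift amplitude (mm or rad); set to 0 for a
#'   perfectly still trace.
#' @param spike_size translation jump at a spike, in mm.
#' @return A list with `trace` (an `n_frames x 6` matrix with columns
#'   `trans_x`, `trans_y`, `trans_z`, `rot_x`, `rot_y`, `rot_z`) and
#'   `spike_frames` (integer vector).
#' @export
generate_motion_trace <- function(config, drift_amplitude = 0.1,
                                  spike_size = 1.5) {
  n <- config$n_frames
  stopifnot(n >= 2L)
  cols <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  trace <- matrix(0, n, 6L, dimnames = list(NULL, cols))
  t01 <- seq_len(n) / n
  for (j in seq_len(6L)) {
    amp <- drift_amplitude * runif(1L, 0.3, 1) * if (j > 3L) 0.01 else 1
    trace[, j] <- amp * sin(2 * pi * runif(1L, 0.5, 2) * t01 +
                              runif(1L, 0, 2 * pi))
  }
  spikes <- which(rbinom(n, 1L, config$motion_spike_rate) == 1L)
  spikes <- spikes[spikes > 1L]
  if (length(spikes)) {
    trace[spikes, "trans_x"] <- trace[spikes, "trans_x"] +
      spike_size * sample(c(-1, 1), length(spikes), replace = TRUE)
  }
  list(trace = trace, spike_frames = spikes)
}

# Lay parcels out as compact blocks on a coarse 3D grid with a one-voxel
# dark margin; returns the integer label volume.
parcel_geometry <- function(n_parcels, voxels_per_parcel) {
  block <- max(1L, ceiling(voxels_per_parcel^(1 / 3) - 1e-9))
  grid <- ceiling(n_parcels^(1 / 3) - 1e-9)
  side <- grid * block + 2L
  labels <- array(0L, dim = c(side, side, side))
  p <- 0L
  for (gz in seq_len(grid)) for (gy in seq_len(grid)) for (gx in seq_len(grid)) {
    p <- p + 1L
    if (p > n_parcels) break
    xs <- 1L + (gx - 1L) * block + seq_len(block)
    ys <- 1L + (gy - 1L) * block + seq_len(block)
    zs <- 1L + (gz - 1L) * block + seq_len(block)
    idx <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
    idx <- idx[seq_len(min(voxels_per_parcel, nrow(idx))), , drop = FALSE]
    labels[idx] <- p
  }
  labels
}

#' Render a hypointense-artifact phantom volume
#'
#' Builds the "mean EPI" companion image for a simulated subject: brain
#' voxels at a bright baseline intensity (100, with sd-2 Gaussian texture),
#' affected parcels scaled down by `artifact_attenuation`, and a dark
#' exterior. By construction the in-brain histogram is bimodal whenever the
#' attenuation is < 1, which is what the Otsu segmentation stage consumes.
#'
#' @param config a [synth_config()].
#' @param affected_ids integer parcel labels rendered hypointense.
#' @param labels optional precomputed label volume (from the same config).
#' @return List with `intensity` (numeric 3D array), `labels` (integer 3D
#'   array) and `brain_mask` (logical 3D array).
#' @export
generate_phantom_volume <- function(config, affected_ids,
                                    labels = NULL) {
  if (is.null(labels)) {
    labels <- parcel_geometry(config$n_parcels, config$voxels_per_parcel)
  }
  affected_ids <- as.integer(affected_ids)
  if (length(affected_ids) &&
      (any(affected_ids < 1L) || any(affected_ids > config$n_parcels))) {
    stop("generate_phantom_volume: affected ids outside the label range",
         call. = FALSE)
  }
  brain <- labels > 0L
  intensity <- array(0, dim = dim(labels))
  intensity[brain] <- 100 + rnorm(sum(brain), 0, 2)
  if (length(affected_ids)) {
    dark <- labels %in% affected_ids
    intensity[dark] <- intensity[dark] * config$artifact_attenuation
  }
  list(intensity = intensity, labels = labels, brain_mask = brain)
}

# One run's signals for a subject: parcel time series with the configured
# amplitude, optional voxel expansion, nuisance compartments and motion.
simulate_run <- function(config, amp, rho, net_of, affected) {
  n <- config$n_frames
  p <- config$n_parcels
  nets <- sort(unique(net_of))
  g <- band_limited_signal(n, config$tr, m = length(nets))
  colnames(g) <- nets
  eta <- band_limited_signal(n, config$tr, m = p)
  core <- sweep(g[, net_of, drop = FALSE], 2L, sqrt(rho), "*") +
    sweep(eta, 2L, sqrt(1 - rho), "*")
  if (length(affected) && config$artifact_noise_sd > 0) {
    zeta <- band_limited_signal(n, config$tr, m = length(affected))
    core[, affected] <- core[, affected] + config$artifact_noise_sd * zeta
  }
  sds <- apply(core, 2L, sd)
  core <- sweep(core, 2L, sds, "/")
  parcel_series <- sweep(core, 2L, amp, "*")
  mot <- generate_motion_trace(config)
  if (length(mot$spike_frames)) {
    parcel_series[mot$spike_frames, ] <-
      parcel_series[mot$spike_frames, , drop = FALSE] +
      matrix(3 * amp, length(mot$spike_frames), p, byrow = TRUE)
  }
  vpp <- config$voxels_per_parcel
  if (vpp > 1L) {
    voxel_labels <- rep(seq_len(p), each = vpp)
    voxel_series <- parcel_series[, voxel_labels, drop = FALSE] +
      matrix(rnorm(n * p * vpp, 0, config$voxel_noise_sd), n, p * vpp)
  } else {
    voxel_labels <- seq_len(p)
    voxel_series <- parcel_series
  }
  colnames(parcel_series) <- sprintf("p%03d", seq_len(p))
  nuisance <- function() {
    lat <- band_limited_signal(n, config$tr, lo = 0.005, hi = 0.12, m = 3L)
    load <- matrix(runif(3L * 30L, -1, 1), 3L, 30L)
    lat %*% load + matrix(rnorm(n * 30L, 0, 0.5), n, 30L)
  }
  list(parcel_series = parcel_series, voxel_series = voxel_series,
       voxel_labels = voxel_labels, motion = mot$trace,
       spike_frames = mot$spike_frames, wm = nuisance(), csf = nuisance())
}

#' Generate a synthetic multi-subject test-retest dataset
#'
#' Simulates, for every subject, visit, stimulation condition (OFF/ON) and
#' run (test/retest), parcel- and voxel-level BOLD time series realized as
#' band-limited (0.01-0.1 Hz) Gaussian processes whose per-parcel amplitude
#' carries the two-way variance-components model of [synth_config()];
#' the temporal standard deviation of each raw parcel series equals its
#' element value exactly, so the derived brain-variability metric inherits
#' the configured reliability. Within-network coupling gives connectivity
#' matrices a block structure that is stable across runs of a subject.
#' Affected parcels receive attenuated amplitude, extra run noise, and a
#' matching hypointense region on the subject's phantom volume.
#'
#' @param config a [synth_config()].
#' @return An object of class `synth_cohort`: a list with elements
#'   `config`, `parcellation` (label volume + network membership table),
#'   `subjects` (nested run data), `phantoms`, `clinical` (simulated
#'   covariates) and `truth` (a `GroundTruth` list holding `true_icc`,
#'   `affected_parcel_ids`, per-parcel stimulation gains, per-run element
#'   values and outlier flags).
#' @examples
#' cohort <- generate_dataset(synth_config(n_subjects = 2, n_parcels = 20,
#'                                         voxels_per_parcel = 1, seed = 42))
#' cohort$truth$true_icc
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  p <- config$n_parcels
  labels <- parcel_geometry(p, config$voxels_per_parcel)
  nets <- c("motor", "limbic", "associative")
  net_of <- nets[(seq_len(p) - 1L) %% 3L + 1L]
  membership <- data.frame(parcel_id = seq_len(p),
                           parcel_name = sprintf("parcel_%03d", seq_len(p)),
                           networks = net_of, stringsAsFactors = FALSE)
  n_aff <- round(config$artifact_parcel_fraction * p)
  affected <- if (n_aff > 0L) sort(sample.int(p, n_aff)) else integer(0)
  clin <- data.frame(
    subject = sprintf("sub-%02d", seq_len(config$n_subjects)),
    age = round(runif(config$n_subjects, 50, 77), 1),
    target = sample(c("STN", "GPi"), config$n_subjects, replace = TRUE),
    updrs_off = round(runif(config$n_subjects, 27, 63)),
    stringsAsFactors = FALSE)
  clin$updrs_on <- round(clin$updrs_off * (1 - runif(config$n_subjects,
                                                     0.2, 0.6)))
  clin$improvement <- mapply(improvement_score, clin$updrs_off,
                             clin$updrs_on)
  clin$tremor <- round(runif(config$n_subjects, 3, 19))
  clin$rigidity <- round(runif(config$n_subjects, 3, 13))
  clin$bradykinesia <- round(runif(config$n_subjects, 14, 33))
  subjects <- vector("list", config$n_subjects)
  phantoms <- vector("list", config$n_subjects)
  gains <- matrix(0, config$n_subjects, p)
  elements <- list()
  outliers <- list()
  for (s in seq_len(config$n_subjects)) {
    set.seed(config$seed + 7919L * s)
    rho <- runif(p, config$network_coupling[1L], config$network_coupling[2L])
    mu <- rnorm(p, 0, config$sigma_row)
    gain <- rnorm(p, 0, config$on_modulation_sd)
    gains[s, ] <- gain
    phantoms[[s]] <- generate_phantom_volume(config, affected, labels)
    visits <- vector("list", config$n_visits)
    for (v in seq_len(config$n_visits)) {
      conds <- list()
      for (cond in c("OFF", "ON")) {
        runs <- list()
        elem <- matrix(NA_real_, p, 2L,
                       dimnames = list(NULL, c("test", "retest")))
        for (r in c("test", "retest")) {
          sshift <- rnorm(1L, 0, config$sigma_session)
          e <- rnorm(p, 0, config$sigma_noise)
          m <- config$amp_base + mu + sshift + e
          elem[, r] <- m
          amp <- m
          if (cond == "ON") amp <- amp * (1 + gain)
          if (length(affected)) {
            amp[affected] <- amp[affected] * config$artifact_attenuation
          }
          amp <- pmax(amp, 0.05)
          run <- simulate_run(config, amp, rho, net_of, affected)
          runs[[r]] <- run
          outliers[[paste(s, v, cond, r, sep = "/")]] <- run$spike_frames
        }
        conds[[cond]] <- runs
        elements[[paste(s, v, cond, sep = "/")]] <- elem
      }
      visits[[v]] <- conds
    }
    subjects[[s]] <- visits
  }
  names(subjects) <- clin$subject
  names(phantoms) <- clin$subject
  tot <- config$sigma_row^2 + config$sigma_session^2 + config$sigma_noise^2
  truth <- list(
    true_icc = if (config$sigma_row == 0) 0 else config$sigma_row^2 / tot,
    degenerate = config$sigma_row == 0,
    affected_parcel_ids = affected,
    on_gains = gains,
    element_values = elements,
    outlier_flags = outliers)
  structure(list(config = config,
                 parcellation = parcellation(labels, membership),
                 subjects = subjects, phantoms = phantoms, clinical = clin,
                 truth = truth),
            class = "synth_cohort")
}

#' @export
print.synth_cohort <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic DBS test-retest cohort\n")
  cat(sprintf("  %d subjects x %d visit(s) x 2 conditions x 2 runs\n",
              cfg$n_subjects, cfg$n_visits))
  cat(sprintf("  %d parcels (%d voxels each), %d frames @ TR %.2f s\n",
              cfg$n_parcels, cfg$voxels_per_parcel, cfg$n_frames, cfg$tr))
  cat(sprintf("  true ICC %.4f; %d artifact-affected parcels\n",
              x$truth$true_icc, length(x$truth$affected_parcel_ids)))
  invisible(x)
}
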