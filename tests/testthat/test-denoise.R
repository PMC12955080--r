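make_motion <- function(n) {
  matrix(0, n, 6,
         dimnames = list(NULL, c("trans_x", "trans_y", "trans_z",
                                 "rot_x", "rot_y", "rot_z")))
}

test_that("outlier detection flags FD and global-signal excursions", {
  n <- 100
  cfg <- denoise_config()
  mot <- make_motion(n)
  expect_identical(detect_outlier_frames(mot, rep(1, n), cfg), integer(0))
  mot[40, "trans_x"] <- 2.0
  flags <- detect_outlier_frames(mot, rep(1, n), cfg)
  expect_true(40 %in% flags)   # the 2 mm excursion (and its return frame)
  expect_true(all(flags %in% c(40, 41)))
  gs <- rep(0, n)
  gs[10] <- 100
  expect_true(10 %in% detect_outlier_frames(make_motion(n), gs, cfg))
  expect_error(detect_outlier_frames(make_motion(n), rep(0, n - 1), cfg),
               "frame count")
})

test_that("the spike cap keeps the worst frames by FD, earlier index on ties", {
  n <- 200
  cfg <- denoise_config(max_spike_frames = 5)
  mot <- make_motion(n)
  # steps of strictly increasing size at even frames; FD at frame i equals
  # the step there, so the largest FDs sit at the latest steps
  steps <- seq(1, 2, length.out = 50)
  frames <- seq(4, 102, by = 2)
  pos <- 0
  for (i in seq_along(frames)) {
    pos <- pos + steps[i]
    mot[frames[i]:n, "trans_y"] <- pos
  }
  flags <- detect_outlier_frames(mot, rep(0, n), cfg)
  expect_length(flags, 5)
  expect_identical(flags, as.integer(sort(frames[46:50])))
  # exact ties resolve toward the earlier frame
  mot2 <- make_motion(n)
  tie_frames <- c(10, 30, 50, 70, 90, 110, 130)
  for (f in tie_frames) mot2[f, "trans_z"] <- 1.5
  cfg2 <- denoise_config(max_spike_frames = 3)
  flags2 <- detect_outlier_frames(mot2, rep(0, n), cfg2)
  expect_identical(flags2, c(10L, 11L, 30L))
})

test_that("confound matrix has the documented column structure", {
  set.seed(1)
  n <- 165
  mot <- make_motion(n) + matrix(rnorm(n * 6, 0, 0.05), n, 6)
  wm <- matrix(rnorm(n * 10), n, 10)
  csf <- matrix(rnorm(n * 10), n, 10)
  des <- build_confound_matrix(mot, integer(0), wm, csf)
  expect_equal(ncol(des$x), 2 + 12 + 0 + 5 + 5)
  expect_equal(as.integer(table(des$provenance)[c("polynomial", "motion",
                                                  "wm_pca", "csf_pca")]),
               c(2L, 12L, 5L, 5L))
  # spike columns are one-hot
  des2 <- build_confound_matrix(mot, c(7L, 9L), wm, csf)
  sp <- des2$x[, des2$provenance == "spike", drop = FALSE]
  expect_equal(colSums(sp), c(spike_7 = 1, spike_9 = 1))
  expect_equal(which(sp[, 1] == 1), 7L)
})

test_that("rank-1 tissue matrices and duplicated columns are handled", {
  set.seed(2)
  n <- 120
  mot <- make_motion(n) + matrix(rnorm(n * 6, 0, 0.05), n, 6)
  base <- rnorm(n)
  wm <- outer(base, runif(8, 0.5, 2)) +
    matrix(rnorm(n * 8, 0, 1e-6), n, 8)
  des <- build_confound_matrix(mot, integer(0), wm, NULL)
  pcs <- prcomp(wm)
  expect_gt(pcs$sdev[1]^2 / sum(pcs$sdev^2), 0.99)
  # duplicated motion column: one of the pair dropped, full rank kept
  mot_dup <- mot
  mot_dup[, 2] <- mot_dup[, 1]
  expect_message(
    des_dup <- build_confound_matrix(mot_dup, integer(0), NULL, NULL),
    "dropped")
  expect_equal(qr(des_dup$x)$rank, ncol(des_dup$x))
  expect_gt(length(des_dup$dropped), 0)
})

test_that("confound regression is exact least squares", {
  set.seed(3)
  n <- 150
  mot <- make_motion(n) + matrix(rnorm(n * 6, 0, 0.1), n, 6)
  des <- build_confound_matrix(mot, integer(0), NULL, NULL)
  # a design column regresses to zero
  r1 <- regress_confounds(des$x[, 4, drop = FALSE], des)
  expect_lt(max(abs(r1)), 1e-10)
  # residuals orthogonal to every column for random input
  y <- matrix(rnorm(n * 5), n, 5)
  res <- regress_confounds(y, des)
  expect_lt(max(abs(crossprod(des$x, res))),
            1e-8 * max(abs(y)) * max(abs(des$x)) * n)
  # a known mixture: residual recovers the added sinusoid
  sine <- sin(2 * pi * 0.05 * (1:n) * 2.15)
  sine_resid <- regress_confounds(cbind(sine), des)
  y2 <- 2 * mot[, 1] + sine
  r2 <- regress_confounds(cbind(y2), des)
  expect_lt(sqrt(mean((r2 - sine_resid)^2)), 1e-8)
})

test_that("bandpass filter keeps the passband and removes the rest", {
  n <- 165
  tr <- 2.15
  t <- (0:(n - 1)) * tr
  expect_equal(bandpass_filter(rep(5, n), tr), rep(0, n),
               tolerance = 1e-12)
  inband <- sin(2 * pi * 0.05 * t)
  out <- bandpass_filter(inband, tr)
  expect_gt(sd(out) / sd(inband), 0.98)
  high <- sin(2 * pi * 0.20 * t)
  expect_lt(sd(bandpass_filter(high, tr)) / sd(high), 0.05)
  # idempotence and linearity
  set.seed(4)
  x <- rnorm(n)
  y <- rnorm(n)
  fx <- bandpass_filter(x, tr)
  expect_equal(bandpass_filter(fx, tr), fx, tolerance = 1e-10)
  expect_equal(bandpass_filter(2 * x + 3 * y, tr),
               2 * fx + 3 * bandpass_filter(y, tr), tolerance = 1e-10)
  expect_error(bandpass_filter(x, tr, 0.01, 0.25), "Nyquist")
  expect_error(bandpass_filter(x[1:4], tr), "8 frames")
})

test_that("effective dof follows the bandwidth-scaled formula", {
  nyq <- 1 / (2 * 2.15)
  expect_equal(effective_dof(165, 24, 0.01, 0.10, 2.15),
               141 * 0.09 / nyq, tolerance = 1e-12)
  expect_gt(effective_dof(165, 24, 0.01, 0.10, 2.15), 30)
  expect_equal(effective_dof(100, 100, 0.01, 0.10, 2.15), 0)
  expect_gt(effective_dof(165, 24, 0.01, 0.25, 2.15),
            effective_dof(165, 24, 0.10, 0.10001, 2.15))
  expect_gt(effective_dof(165, 24, 0.01, 0.25, 2.15),
            effective_dof(165, 24, 0.01, 0.10, 2.15))
})

test_that("denoise_run composes regression before filtering and is linear", {
  set.seed(5)
  cfg <- synth_config(n_subjects = 1, n_parcels = 6, voxels_per_parcel = 1,
                      seed = 31)
  run <- generate_dataset(cfg)$subjects[[1]][[1]]$OFF$test
  dcfg <- denoise_config()
  clean <- suppressWarnings(
    denoise_run(run$parcel_series, run$motion, run$wm, run$csf, 2.15, dcfg))
  expect_equal(colMeans(clean$series), rep(0, 6), tolerance = 1e-9,
               ignore_attr = TRUE)
  # two-stage composition: regression then filtering, in that order
  flags <- detect_outlier_frames(run$motion, rowMeans(run$parcel_series),
                                 dcfg)
  des <- build_confound_matrix(run$motion, flags, run$wm, run$csf, dcfg)
  manual <- bandpass_filter(regress_confounds(run$parcel_series, des),
                            2.15, dcfg$band_low, dcfg$band_high)
  expect_equal(unname(clean$series), unname(manual), tolerance = 1e-12)
  # linearity of the fixed-design denoiser
  a <- run$parcel_series[, 1]
  b <- run$parcel_series[, 2]
  lin <- bandpass_filter(regress_confounds(cbind(3 * a - 2 * b), des),
                         2.15, dcfg$band_low, dcfg$band_high)
  expect_equal(as.numeric(lin), 3 * manual[, 1] - 2 * manual[, 2],
               tolerance = 1e-9)
  # exploratory band is capped at Nyquist with a report note
  dcfg2 <- denoise_config(band_high = 0.25)
  clean2 <- suppressWarnings(
    denoise_run(run$parcel_series, run$motion, run$wm, run$csf, 2.15,
                dcfg2))
  expect_true(clean2$report$band_capped)
  expect_lte(clean2$report$band[2], 1 / (2 * 2.15))
  expect_gt(clean2$dof, clean$dof)
  # saturated designs trigger the dof warning
  tiny <- matrix(rnorm(40 * 3), 40, 3)
  expect_warning(
    denoise_run(tiny, make_motion(40) + matrix(rnorm(240, 0, 0.05), 40, 6),
                matrix(rnorm(40 * 8), 40, 8), matrix(rnorm(40 * 8), 40, 8),
                2.15, denoise_config()),
    "dof")
})
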