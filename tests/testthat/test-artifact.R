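test_that("Otsu cut equals the exhaustive maximizer on random histograms", {
  set.seed(14)
  for (i in 1:100) {
    counts <- rpois(sample(8:64, 1), lambda = runif(1, 0.5, 20))
    if (sum(counts > 0) < 2) next
    expect_identical(otsu_cut(counts)$cut, otsu_oracle(counts))
  }
})

test_that("two-level images threshold between the levels", {
  img <- c(rep(20, 40), rep(100, 360))
  thr <- otsu_threshold(img)
  expect_gt(thr, 20)
  expect_lt(thr, 100)
  expect_gt(attr(thr, "separability"), 0.95)
  expect_error(otsu_threshold(rep(7, 10)), "distinct")
})

test_that("Otsu separates a well-spaced Gaussian mixture", {
  set.seed(15)
  n <- 1e5
  labels <- rbinom(n, 1, 0.5)
  x <- ifelse(labels == 1, rnorm(n, 120, 10), rnorm(n, 30, 5))
  thr <- otsu_threshold(x)
  miscls <- mean((x >= thr) != (labels == 1))
  expect_lt(miscls, 0.01)
})

test_that("segmentation recovers the generator's artifact voxels", {
  cfg <- synth_config(n_parcels = 60, voxels_per_parcel = 27,
                      artifact_parcel_fraction = 0.1,
                      artifact_attenuation = 0.2, seed = 16)
  set.seed(16)
  affected <- sort(sample.int(60, 6))
  ph <- generate_phantom_volume(cfg, affected)
  seg <- segment_artifact(ph$intensity, ph$brain_mask)
  truth <- ph$labels %in% affected
  dice <- 2 * sum(seg$mask & truth) / (sum(seg$mask) + sum(truth))
  expect_gte(dice, 0.95)
  # attenuation-free phantom gives an empty mask
  cfg1 <- synth_config(n_parcels = 60, voxels_per_parcel = 27,
                       artifact_attenuation = 1, seed = 16)
  ph1 <- generate_phantom_volume(cfg1, integer(0))
  seg1 <- segment_artifact(ph1$intensity, ph1$brain_mask)
  expect_equal(seg1$n_voxels, 0)
  expect_error(segment_artifact(ph$intensity, ph$brain_mask[1:3, , ]),
               "grid")
})

test_that("mask post-processing follows the stated rules", {
  vol <- array(100, dim = c(10, 10, 10))
  brain <- array(TRUE, dim = c(10, 10, 10))
  # 3-voxel dark speckle removed by the 5-voxel component filter
  vol[2:4, 2, 2] <- 10
  seg <- segment_artifact(vol + rnorm(1000, 0, 0.01), brain,
                          threshold = 50)
  expect_equal(seg$n_voxels, 0)
  # a 6-voxel component survives
  vol[2:4, 5:6, 5] <- 10
  seg2 <- segment_artifact(vol, brain, threshold = 50)
  expect_equal(seg2$n_voxels, 6)
  # monotonicity: raising the threshold never shrinks the raw mask
  set.seed(17)
  vol2 <- array(runif(1000, 0, 100), dim = c(10, 10, 10))
  m1 <- segment_artifact(vol2, brain, threshold = 30, min_component = 1)
  m2 <- segment_artifact(vol2, brain, threshold = 60, min_component = 1)
  expect_true(all(m2$mask[m1$mask]))
})

test_that("affected parcels and connections follow the overlap rules", {
  labels <- array(0L, dim = c(6, 2, 2))
  for (i in 1:6) labels[i, , ] <- i
  mask <- array(FALSE, dim = dim(labels))
  parc <- parcellation(labels,
                       data.frame(parcel_id = 1:6,
                                  parcel_name = paste0("P", 1:6),
                                  networks = "motor"))
  none <- affected_parcels(mask, parc)
  expect_length(none$affected_ids, 0)
  expect_equal(sum(affected_connections(none$affected_ids, 1:6)), 0)
  # one affected parcel touches P - 1 connections
  mask[3, 1, 1] <- TRUE
  one <- affected_parcels(mask, parc)
  expect_equal(one$affected_ids, 3L)
  expect_equal(sum(affected_connections(3L, 1:6)), 5)
  # two affected of six: C(6,2) - C(4,2) = 9 affected connections
  mask[5, , ] <- TRUE
  two <- affected_parcels(mask, parc)
  expect_equal(two$affected_ids, c(3L, 5L))
  expect_equal(sum(affected_connections(c(3L, 5L), 1:6)), 9)
  # the min-overlap rule excludes light touches
  strict <- affected_parcels(mask, parc, min_overlap_voxels = 2)
  expect_equal(strict$affected_ids, 5L)
  expect_true(all(two$overlap$overlap_fraction >= 0 &
                    two$overlap$overlap_fraction <= 1))
})

test_that("split reliability partitions elements and flags small subsets", {
  set.seed(18)
  m <- matrix(rnorm(40), 20, 2)
  aff <- rep(c(TRUE, FALSE), each = 10)
  sp <- split_icc(m, aff)
  expect_equal(sp$n[sp$subset == "affected"] +
                 sp$n[sp$subset == "unaffected"],
               sp$n[sp$subset == "whole"])
  expect_false(any(sp$insufficient))
  # all-unaffected labels: affected subset flagged, unaffected equals whole
  sp2 <- split_icc(m, rep(FALSE, 20))
  expect_true(sp2$insufficient[sp2$subset == "affected"])
  expect_equal(sp2$icc[sp2$subset == "unaffected"],
               sp2$icc[sp2$subset == "whole"])
  # extra noise on affected rows lowers their subset ICC
  base <- matrix(rnorm(200, sd = 1), 100, 2) + rnorm(100) * 2
  noisy <- base
  noisy[1:50, ] <- noisy[1:50, ] + matrix(rnorm(100, sd = 2), 50, 2)
  sp3 <- split_icc(noisy, rep(c(TRUE, FALSE), each = 50))
  expect_lt(sp3$icc[sp3$subset == "affected"],
            sp3$icc[sp3$subset == "unaffected"])
})
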