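test_that("signed-rank test matches exact enumeration and conventions", {
  x <- 1:6
  y <- x + 1
  res <- wilcoxon_signed_rank(x, y)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 2 / 2^6)
  # degenerate when all differences vanish
  deg <- wilcoxon_signed_rank(1:5, 1:5)
  expect_true(deg$degenerate)
  expect_true(is.na(deg$p))
  # symmetric +/- differences sit at the null center
  xs <- c(1, 2, 3, 4, 5, 6)
  ys <- c(2, 1, 4, 3, 6, 5)
  expect_gt(wilcoxon_signed_rank(xs, ys)$p, 0.9)
  # random small samples agree with the enumeration oracle
  set.seed(19)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    a <- rnorm(n)
    b <- a + rnorm(n, 0.3)
    res <- wilcoxon_signed_rank(a, b)
    orc <- signed_rank_oracle(a, b)
    expect_equal(res$statistic, orc$w)
    expect_equal(res$p, orc$p, tolerance = 1e-12)
  }
  # zero differences are dropped and noted
  zr <- wilcoxon_signed_rank(c(1, 2, 3, 4, 5, 5), c(2, 3, 4, 5, 6, 5))
  expect_match(zr$note, "zero difference")
})

test_that("rank-sum test matches exact enumeration and handles ties", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(10, 20, 30))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 0.1)
  expect_equal(res$effect_size[["delta"]], -1)
  same <- wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 3 * 3 / 2)
  expect_gt(same$p, 0.9)
  set.seed(20)
  for (i in 1:20) {
    n1 <- sample(3:6, 1)
    n2 <- sample(3:6, 1)
    a <- sample(1:5, n1, replace = TRUE)   # heavy ties
    b <- sample(2:6, n2, replace = TRUE)
    res <- wilcoxon_rank_sum(a, b)
    orc <- rank_sum_oracle(a, b)
    expect_equal(res$statistic, orc$u)
    expect_equal(res$p, orc$p, tolerance = 1e-12)
  }
  # tie correction shrinks the large-sample variance
  nn <- 30
  r_tied <- rank(c(rep(1, 15), rep(2, 15), rep(1, 15), rep(2, 15)))
  ties <- table(r_tied)
  v_tied <- nn * nn / 12 *
    (2 * nn + 1 - sum(ties^3 - ties) / (2 * nn * (2 * nn - 1)))
  v_free <- nn * nn * (2 * nn + 1) / 12
  expect_lt(v_tied, v_free)
  expect_error(wilcoxon_rank_sum(numeric(0), 1:3), "non-empty")
})

test_that("large-sample branches agree with the reference implementation", {
  set.seed(21)
  x <- rnorm(25)
  y <- x + rnorm(25, 0.4)
  mine <- wilcoxon_signed_rank(x, y)
  ref <- suppressWarnings(wilcox.test(x, y, paired = TRUE, exact = FALSE,
                                      correct = TRUE))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  a <- rnorm(20)
  b <- rnorm(18, 0.5)
  mine2 <- wilcoxon_rank_sum(a, b)
  ref2 <- suppressWarnings(wilcox.test(a, b, exact = FALSE,
                                       correct = TRUE))
  expect_equal(mine2$statistic, unname(ref2$statistic))
  expect_equal(mine2$p, ref2$p.value, tolerance = 1e-10)
})

test_that("Pearson correlation and Fisher-z interval behave", {
  x <- 1:10
  res <- pearson_with_ci(x, 2 * x + 1)
  expect_equal(res$effect_size[["r"]], 1)
  expect_equal(res$ci, c(1, 1))
  # printed-value reproduction: r = 0.61, n = 16 -> ~[0.17, 0.85]
  # (the published lower bound reflects rounding of r upstream; the
  # interval from the printed r itself is [0.164, 0.849])
  expect_equal(fisher_z_ci(0.61, 16), c(0.17, 0.85), tolerance = 0.05)
  expect_equal(fisher_z_ci(0.76, 16), c(0.42, 0.91), tolerance = 0.05)
  # orthogonal zero-mean inputs give r = 0
  xo <- c(1, -1, 1, -1, 1, -1, 1, -1)
  yo <- c(1, 1, -1, -1, 1, 1, -1, -1)
  expect_lt(abs(pearson_with_ci(xo, yo)$effect_size[["r"]]), 1e-12)
  set.seed(22)
  xr <- rnorm(16)
  yr <- rnorm(16)
  mine <- pearson_with_ci(xr, yr)
  ref <- cor.test(xr, yr)
  expect_equal(mine$effect_size[["r"]], unname(ref$estimate))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  expect_equal(mine$ci, as.numeric(ref$conf.int), tolerance = 1e-6)
  expect_error(pearson_with_ci(rep(1, 8), rnorm(8)), "constant")
  expect_error(pearson_with_ci(1:3, 3:1), "n >= 4")
})

test_that("Cliff's delta matches pair enumeration and is antisymmetric", {
  expect_equal(cliffs_delta(4:6, 1:3)$effect_size[["delta"]], 1)
  expect_equal(cliffs_delta(c(1, 2, 3), c(2, 2, 2))$effect_size[["delta"]],
               0)
  set.seed(23)
  for (i in 1:25) {
    a <- rnorm(sample(2:12, 1))
    b <- rnorm(sample(2:12, 1), sample(c(-1, 0, 1), 1))
    d <- cliffs_delta(a, b)$effect_size[["delta"]]
    expect_equal(d, cliff_oracle(a, b), tolerance = 1e-12)
    expect_equal(cliffs_delta(b, a)$effect_size[["delta"]], -d,
                 tolerance = 1e-12)
    expect_gte(d, -1)
    expect_lte(d, 1)
  }
  # bootstrap CI is deterministic under a fixed seed and brackets the point
  a <- rnorm(12)
  b <- rnorm(12, 0.8)
  c1 <- cliffs_delta(a, b, "bootstrap", n_boot = 500, seed = 7)
  c2 <- cliffs_delta(a, b, "bootstrap", n_boot = 500, seed = 7)
  expect_identical(c1$ci, c2$ci)
  expect_lte(c1$ci[1], c1$ci[2])
  p1 <- cliffs_delta(a, b, "bootstrap", n_boot = 500, seed = 7,
                     paired = TRUE)
  expect_false(identical(p1$ci, c1$ci))
})

test_that("the contrast battery enumerates the expected rows", {
  set.seed(24)
  subjects <- sprintf("s%02d", 1:8)
  grid <- expand.grid(subject = subjects, condition = c("OFF", "ON"),
                      network = c("whole_brain", "motor", "limbic",
                                  "associative"),
                      metric = c("connectivity", "variability"),
                      stringsAsFactors = FALSE)
  grid$pairing <- "within"
  grid$visit_pair <- "1-1"
  grid$icc <- runif(nrow(grid), 0.3, 0.9)
  grid$degenerate <- FALSE
  out <- run_contrast_suite(grid, n_boot = 200)
  # one ON-vs-OFF signed-rank and one correlation per metric x network
  expect_equal(sum(out$test == "Wilcoxon signed-rank"), 8)
  expect_equal(sum(out$test == "Pearson correlation"), 8)
  # identical ON/OFF data: effect sizes collapse to zero
  same <- grid
  same$icc <- rep(runif(length(subjects) * 4 * 2, 0.3, 0.9), 2)
  same$icc <- ave(same$icc, same$subject, same$network, same$metric,
                  FUN = function(v) v[1])
  out2 <- run_contrast_suite(same, n_boot = 200)
  es <- out2$effect_size[out2$test == "Wilcoxon signed-rank"]
  expect_true(all(abs(es) < 1e-12))
  cov <- data.frame(subject = subjects, age = rnorm(8, 65, 5),
                    target = rep(c("STN", "GPi"), 4),
                    improvement = runif(8, 20, 60),
                    fd_diff = runif(8, 0, 0.4),
                    tremor = runif(8, 3, 19),
                    rigidity = runif(8, 3, 13),
                    bradykinesia = runif(8, 14, 33),
                    fc_response = rnorm(8, 0, 0.1))
  out3 <- run_contrast_suite(grid, covariates = cov, n_boot = 200)
  expect_true(any(grepl("FD difference", out3$effect)))
  expect_true(any(grepl("target STN vs GPi", out3$effect)))
  expect_equal(sum(grepl("target", out3$effect)), 2 * 4 * 2)
  # missing covariate skips its contrast with a message
  expect_message(
    out4 <- run_contrast_suite(grid, covariates = cov[, -5],
                               n_boot = 200),
    "fd_diff")
  expect_false(any(grepl("FD difference", out4$effect)))
})
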