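# Independent brute-force oracles, written from the definitions and kept
# free of any package internals so they can arbitrate the implementations.

# Two-way ANOVA decomposition with explicit loops; ICC(A,1) from the mean
# squares.
icc_oracle <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  grand <- sum(m) / (n * k)
  row_means <- sapply(seq_len(n), function(i) sum(m[i, ]) / k)
  col_means <- sapply(seq_len(k), function(j) sum(m[, j]) / n)
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (row_means[i] - grand)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (col_means[j] - grand)^2
  sse <- 0
  for (i in seq_len(n)) for (j in seq_len(k)) {
    sse <- sse + (m[i, j] - row_means[i] - col_means[j] + grand)^2
  }
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  list(msr = msr, msc = msc, mse = mse,
       icc = (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse)))
}

# Exhaustive Otsu: recompute both class weights and means from scratch at
# every candidate cut and return the between-class-variance maximizer.
otsu_oracle <- function(counts, mids = seq_along(counts)) {
  total <- sum(counts)
  best <- -Inf
  best_cut <- NA_integer_
  for (t in seq_len(length(counts) - 1L)) {
    lowc <- counts[1:t]
    highc <- counts[(t + 1L):length(counts)]
    w0 <- sum(lowc) / total
    w1 <- sum(highc) / total
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(lowc * mids[1:t]) / sum(lowc)
    mu1 <- sum(highc * mids[(t + 1L):length(counts)]) / sum(highc)
    sb <- w0 * w1 * (mu0 - mu1)^2
    if (sb > best + 1e-12) {
      best <- sb
      best_cut <- t
    }
  }
  best_cut
}

# Exact signed-rank two-sided p by enumerating every sign pattern.
signed_rank_oracle <- function(x, y) {
  d <- (x - y)
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  tol <- 1e-9
  p <- 2 * min(mean(w_all <= w_obs + tol), mean(w_all >= w_obs - tol))
  list(w = w_obs, p = min(1, p))
}

# Exact rank-sum two-sided p by enumerating all group assignments of the
# combined observations.
rank_sum_oracle <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- combn(length(pooled), n1)
  u_all <- apply(combos, 2L, function(ix) {
    rr <- rank(pooled)
    sum(rr[ix]) - n1 * (n1 + 1) / 2
  })
  tol <- 1e-9
  p <- 2 * min(mean(u_all <= u_obs + tol), mean(u_all >= u_obs - tol))
  list(u = u_obs, p = min(1, p))
}

# Cliff's delta by direct pair enumeration.
cliff_oracle <- function(x, y) {
  gt <- 0
  lt <- 0
  for (xi in x) for (yj in y) {
    if (xi > yj) gt <- gt + 1
    if (xi < yj) lt <- lt + 1
  }
  (gt - lt) / (length(x) * length(y))
}
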