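# Independent oracles used across the test files.

# expected value of the maximum of k independent standard normals,
# by numerical integration of the order-statistic density
expected_max_normal <- function(k) {
  stats::integrate(function(z) k * z * dnorm(z) * pnorm(z)^(k - 1),
                   -Inf, Inf, rel.tol = 1e-10)$value
}

# selection by exhaustive sort (ties: lowest index, as order() is stable)
sort_select_oracle <- function(x) {
  ord <- order(x, decreasing = TRUE)
  list(s = ord[1], r = ord[2])
}

# dense-grid maximiser of the profile log-likelihood over [0, upper]
grid_profile_oracle <- function(xt, w, upper = 50, n = 200001) {
  grid <- seq(0, upper, length.out = n)
  ll <- sapply(grid, function(t2) {
    v <- w + t2
    mu <- sum(xt / v) / sum(1 / v)
    -0.5 * sum(log(v) + (xt - mu)^2 / v)
  })
  grid[which.max(ll)]
}

# Rao-Blackwell conditional-simulation oracle for the UMVCUE at fixed
# (Z, X_r): E[Y_s | Z, X_s >= X_r] where, given Z, Y_s = Z + w1 * D with
# D ~ N(0, sigma1^2 + sigma2^2) truncated to D <= (Z - X_r) / w2.
# Sampled by inverse-CDF, which shares no code with the estimator.
rb_umvcue_oracle <- function(z, xr, sigma1, sigma2, n = 4e5) {
  w1 <- (1 / sigma1^2) / (1 / sigma1^2 + 1 / sigma2^2)
  w2 <- 1 - w1
  sd_d <- sqrt(sigma1^2 + sigma2^2)
  cap <- pnorm((z - xr) / (w2 * sd_d))
  d <- sd_d * qnorm(runif(n) * cap)
  y <- z + w1 * d
  c(mean = mean(y), se = sd(y) / sqrt(n))
}

# random unequal-variance meta view, selected arm at the maximum
random_view <- function(k = 6) {
  as_meta_view(rnorm(k, sd = runif(1, 0.5, 2)), runif(k, 0.25, 4))
}
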