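toy_design <- dtl_design(6, 1, 1)
toy_outcome <- dtl_outcome(c(0, 0, 0, 0, 0, 3), y_s = 1)

test_that("UMVCUE equals the MLE when the selection margin is huge", {
  o <- dtl_outcome(c(rep(0, 5), 100), y_s = 99)
  mle <- estimate_mle(o, toy_design)$estimate
  expect_equal(estimate_umvcue(o, toy_design)$estimate, mle,
               tolerance = 1e-10)
})

test_that("UMVCUE matches the Rao-Blackwell conditional-simulation oracle", {
  set.seed(71)
  cases <- list(c(1, 1), c(2, 1), c(1, 2), c(1.5, 0.7))
  for (sig in cases) {
    d <- dtl_design(4, sig[1], sig[2])
    o <- dtl_outcome(c(-0.5, 0.1, 0.6, 0.9), y_s = 0.2)
    z <- combined_mle(o, d)$estimate
    oracle <- rb_umvcue_oracle(z, o$x[o$r], sig[1], sig[2])
    expect_lt(abs(estimate_umvcue(o, d)$estimate - oracle["mean"]),
              3 * oracle["se"])
  }
})

test_that("UMVCUE survives extreme lower-tail Mills-ratio arguments", {
  # runner-up far above the combined estimate: v deep in the lower tail
  o <- dtl_outcome(c(rep(-60, 4), 0.001, 0), y_s = -70, strict = TRUE)
  u <- estimate_umvcue(o, toy_design)$estimate
  expect_true(is.finite(u))
  # deep-tail branch agrees with the exact ratio where both are computable
  v <- c(-31, -35, -40)
  expect_equal(dtlshrink:::.inv_mills(v),
               exp(dnorm(v, log = TRUE) - pnorm(v, log.p = TRUE)),
               tolerance = 1e-3)
})

test_that("Lindley factor matches hand arithmetic and the plus-rule", {
  # k = 6, sigma1 = 1, sum of squares 6 -> C+ = 0.5
  x <- c(rep(-1, 3), rep(1, 3))            # mean 0, ss = 6
  lf <- lindley_factor(x, sigma1 = 1)
  expect_equal(lf$c_plus, 0.5)
  expect_equal(lf$grand_mean, 0)
  x9 <- c(rep(-sqrt(1.5), 3), rep(sqrt(1.5), 3))  # ss = 9
  expect_equal(lindley_factor(x9, 1)$c_plus, 2 / 3)
  expect_equal(lindley_factor(c(0, 0.1, 0, -0.1, 0, 0), 1)$c_plus, 0)
  expect_equal(lindley_factor(rep(2, 6), 1)$c_plus, 0)  # zero dispersion
  expect_error(lindley_factor(rnorm(3), 1), "k >= 4")
  expect_equal(lindley_factor(c(0, 0, 3), 1, k_adjust = TRUE)$c_plus,
               1 - 1 / 6)                  # (k-2) = 1, ss = 6
})

test_that("Carreras-Brannath estimator reproduces the worked example", {
  fit <- estimate_cb(toy_outcome, toy_design)
  expect_equal(fit$shrink_factor, 0.6)
  expect_equal(fit$grand_mean, 0.5)
  expect_equal(fit$estimate, 1.5)
  # with no apparent between-arm dispersion the stage-1 component shrinks
  # all the way to the stage-1 mean
  o <- dtl_outcome(c(0, 0.05, 0, 0, 0, 0.1), y_s = 1)
  expect_equal(lindley_factor(o$x, 1)$c_plus, 0)
  expect_equal(estimate_cb(o, toy_design)$estimate,
               (mean(o$x) + o$y_s) / 2)
  # and with enormous dispersion the shrinkage vanishes: CB -> MLE
  o2 <- dtl_outcome(c(0, 0, 0, 0, 0, 1e8), y_s = 1)
  expect_equal(estimate_cb(o2, toy_design)$estimate,
               estimate_mle(o2, toy_design)$estimate)
})

test_that("direct plug-in reduces to the fixed-effects mean at tau2 = 0", {
  v <- as_meta_view(c(0.2, 0.21, 0.2, 0.2, 0.2, 0.22),
                    c(1, 1, 1, 1, 1, 0.5))
  fit <- estimate_direct(v)
  expect_equal(fit$tau2, 0)
  expect_equal(fit$estimate, fixed_effect_mean(v$xt, v$w))
  # forced large tau2: weight tends to 1 and the estimate to xt_s
  big <- as_meta_view(c(-50, 0, 50, 100), rep(1, 4))
  fitb <- estimate_direct(big)
  expect_gt(fitb$shrink_factor, 0.999)
  expect_equal(fitb$estimate, 100, tolerance = 0.05)
})

test_that("direct plug-in matches the grid-search oracle", {
  xt <- c(0, 0, 4, 4)
  w <- rep(1, 4)
  v <- as_meta_view(xt, w, s = 3)
  fit <- estimate_direct(v)
  t2 <- grid_profile_oracle(xt, w)
  mu <- sum(xt / (w + t2)) / sum(1 / (w + t2))
  expect_equal(fit$estimate, (t2 * xt[3] + w[3] * mu) / (w[3] + t2),
               tolerance = 1e-3)
})

test_that("Carter-Rolph factors reduce to the Lindley factor for equal variances", {
  x <- toy_outcome$x                       # ss = 7.5, Q(0) = 7.5 > k - 1
  v1 <- as_meta_view(x, rep(1, 6))         # stage-1-only view
  lind <- lindley_factor(x, 1)
  std <- estimate_cr_standard(v1)
  prop <- estimate_cr_proportional(v1)
  expect_equal(std$shrink_factor, lind$c_plus, tolerance = 1e-8)
  expect_equal(prop$shrink_factor, lind$c_plus, tolerance = 1e-12)
  # both equal the Lindley estimate for the selected arm: 0.5 + 0.6*2.5 = 2
  expect_equal(std$estimate, 2, tolerance = 1e-8)
  expect_equal(prop$estimate, 2, tolerance = 1e-12)
})

test_that("standard-prior factor keeps its floor when tau2_PM = 0", {
  v <- as_meta_view(c(0, 0.1, 0, 0.05, 0, 0.2), c(1, 1, 1, 1, 1, 0.5),
                    s = 6)
  fit <- estimate_cr_standard(v)
  expect_equal(fit$tau2, 0)
  expect_equal(fit$shrink_factor, 1 - 3 / 5)   # 1 - (k-3)/(k-1)
  expect_gt(abs(fit$estimate - fit$grand_mean), 0)
})

test_that("proportional-prior estimator follows its closed form", {
  # Q(0) <= k - 3: full shrinkage to the fixed-effects mean
  v0 <- as_meta_view(c(0, 0.1, -0.1, 0.05, 0, 0.02), rep(1, 6))
  fit0 <- estimate_cr_proportional(v0)
  expect_equal(fit0$shrink_factor, 0)
  expect_equal(fit0$estimate, fixed_effect_mean(v0$xt, v0$w))
  # equal variances, ss = 6 -> Q(0) = 6 -> C+ = 0.5
  v6 <- as_meta_view(c(rep(-1, 3), rep(1, 3)), rep(1, 6))
  expect_equal(estimate_cr_proportional(v6)$shrink_factor, 0.5)
})

test_that("limited translation clips to the one-SE corridor", {
  set.seed(81)
  for (i in 1:1000) {
    v <- random_view(sample(4:8, 1))
    base <- estimate_cr_proportional(v)$estimate
    lt <- estimate_cr_proportional_lt(v)$estimate
    xs <- v$xt[v$s]
    half <- sqrt(v$w[v$s])
    expect_lte(abs(lt - xs), half + 1e-12)
    expect_lte(abs(lt - base), abs(base - xs) + 1e-12)
    if (abs(base - xs) <= half) expect_equal(lt, base)
  }
  # exact clip when the base estimate falls below the corridor
  v <- as_meta_view(c(0, 0, 0, 0, 0, 2.8), rep(1, 6))
  expect_lt(estimate_cr_proportional(v)$estimate, 2.8 - 1)
  expect_equal(estimate_cr_proportional_lt(v)$estimate, 2.8 - 1)
})

test_that("shrinkage estimates are convex combinations after the plus-rule", {
  set.seed(91)
  for (i in 1:300) {
    v <- random_view(6)
    for (f in list(estimate_direct, estimate_cr_standard,
                   estimate_cr_proportional)) {
      fit <- f(v)
      expect_true(fit$shrink_factor >= 0 && fit$shrink_factor <= 1)
      lo <- min(fit$grand_mean, v$xt[v$s]) - 1e-10
      hi <- max(fit$grand_mean, v$xt[v$s]) + 1e-10
      expect_true(fit$estimate >= lo && fit$estimate <= hi)
    }
  }
})

test_that("MLE, UMVCUE and CB are strictly increasing in the stage-2 estimate", {
  x <- c(0.3, -1, 0.2, 1.1, 0.5, -0.2)
  ys <- seq(-2, 2, by = 0.25)
  for (f in list(estimate_mle, estimate_umvcue, estimate_cb)) {
    est <- sapply(ys, function(y)
      f(dtl_outcome(x, y_s = y), toy_design)$estimate)
    expect_true(all(diff(est) > 0))
  }
})

test_that("k = 3 requires the small-k fix and substitutes (k - 2)", {
  v3 <- as_meta_view(c(0, 1, 3), rep(1, 3))
  expect_error(estimate_cr_proportional(v3), "small_k_fix")
  fit <- estimate_cr_proportional(v3, small_k_fix = TRUE)
  q0 <- generalized_q(0, v3$xt, v3$w)
  expect_equal(fit$shrink_factor, 1 - 1 / q0)
  d3 <- dtl_design(3, 1, 1, small_k_fix = TRUE)
  o3 <- dtl_outcome(c(0, 1, 3), y_s = 2)
  expect_true(is.finite(estimate_cb(o3, d3)$estimate))
  expect_error(estimate_cb(o3, dtl_design(3, 1, 1)), "small_k_fix")
})

test_that("estimate_all agrees with the individual estimators", {
  tab <- estimate_all(toy_outcome, toy_design)
  expect_equal(tab$method, dtl_methods())
  view <- meta_view(toy_outcome, toy_design)
  expect_equal(tab$estimate[tab$method == "mle"],
               estimate_mle(toy_outcome, toy_design)$estimate)
  expect_equal(tab$estimate[tab$method == "cb"], 1.5)
  expect_equal(tab$estimate[tab$method == "direct"],
               estimate_direct(view)$estimate)
  expect_equal(tab$estimate[tab$method == "cr_proportional_lt"],
               estimate_cr_proportional_lt(view)$estimate)
  sub <- estimate_all(toy_outcome, toy_design, methods = c("mle", "cb"))
  expect_equal(nrow(sub), 2L)
})
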