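# Seven point estimators of the selected arm's mean.  Each returns a
# `shrinkage_fit`: the estimate plus the grand mean, tau2 and shrinkage
# factor it used (NA where the method has none).

.new_fit <- function(estimate, method, grand_mean = NA_real_,
                     tau2 = NA_real_, shrink_factor = NA_real_) {
  structure(list(estimate = estimate, method = method,
                 grand_mean = grand_mean, tau2 = tau2,
                 shrink_factor = shrink_factor),
            class = "shrinkage_fit")
}

#' @export
print.shrinkage_fit <- function(x, ...) {
  cat(sprintf("%s estimate of the selected mean: %.6g\n", x$method, x$estimate))
  if (!is.na(x$shrink_factor))
    cat(sprintf("  grand mean %.6g, tau2 %s, shrink factor %.4g\n",
                x$grand_mean,
                if (is.na(x$tau2)) "-" else sprintf("%.6g", x$tau2),
                x$shrink_factor))
  invisible(x)
}

# (k - 3), or (k - 2) under the small-k fix; shrinkage undefined below that
.shrink_const <- function(k, small_k_fix) {
  if (k >= 4L) return(k - 3)
  if (k == 3L && small_k_fix) return(k - 2)
  stop("shrinkage estimators need k >= 4, or k = 3 with small_k_fix enabled")
}

# phi(v)/Phi(v), switching to the asymptotic expansion of the Mills ratio
# for v < -30 where pnorm underflows
.inv_mills <- function(v) {
  out <- numeric(length(v))
  lo <- v < -30
  out[!lo] <- stats::dnorm(v[!lo]) / stats::pnorm(v[!lo])
  if (any(lo)) {
    t <- -v[lo]
    out[lo] <- t / (1 - 1 / t^2 + 3 / t^4)
  }
  out
}

#' Maximum likelihood estimate of the selected arm's mean
#'
#' The precision-weighted combination of the selected arm's two stage
#' estimates (see [combined_mle()]), wrapped as a `shrinkage_fit`.  Positively
#' biased because it ignores the stage-1 selection.
#'
#' @param outcome A [dtl_outcome()].
#' @param design A [dtl_design()].
#' @return A `shrinkage_fit` with method `"mle"`.
#' @export
estimate_mle <- function(outcome, design) {
  .new_fit(combined_mle(outcome, design)$estimate, "mle")
}

#' Uniformly minimum variance conditionally unbiased estimator (UMVCUE)
#'
#' Rao-Blackwellisation of the unbiased stage-2 estimate given the combined
#' MLE and the selection event: with `Z` the combined MLE and `X_r` the
#' runner-up stage-1 estimate,
#' \deqn{U = Z - \frac{\sigma_2^2}{\sqrt{\sigma_1^2+\sigma_2^2}}
#'           \frac{\phi(v)}{\Phi(v)}, \qquad
#'       v = \frac{\sqrt{\sigma_1^2+\sigma_2^2}}{\sigma_1^2}(Z - X_r).}
#' Unbiased conditional on the selection for any configuration of true
#' means.  The Mills ratio is evaluated by its asymptotic expansion when `v`
#' is far in the lower tail.
#'
#' @inheritParams estimate_mle
#' @return A `shrinkage_fit` with method `"umvcue"`.
#' @export
estimate_umvcue <- function(outcome, design) {
  stopifnot(inherits(outcome, "dtl_outcome"), inherits(design, "dtl_design"))
  s1sq <- design$sigma1^2
  s2sq <- design$sigma2^2
  z <- combined_mle(outcome, design)$estimate
  v <- sqrt(s1sq + s2sq) * (z - outcome$x[outcome$r]) / s1sq
  .new_fit(z - s2sq / sqrt(s1sq + s2sq) * .inv_mills(v), "umvcue")
}

#' Lindley shrinkage factor for equal-variance stage-1 estimates
#'
#' `C = 1 - (k - 3) * sigma1^2 / sum((x - mean(x))^2)`, returned after the
#' plus-rule `C+ = max(C, 0)`, together with the unweighted stage-1 mean the
#' estimates are shrunk towards.  Zero stage-1 dispersion yields `C+ = 0`
#' (full shrinkage to the common value).
#'
#' @param x Numeric vector of stage-1 estimates (length `k`).
#' @param sigma1 Common stage-1 standard error.
#' @param k_adjust Logical; at `k = 3` use `(k - 2)` in place of `(k - 3)`.
#' @return A list with `c_plus` and `grand_mean`.
#' @examples
#' lindley_factor(c(0, 0, 0, 0, 0, 3), sigma1 = 1)  # c_plus = 0.6
#' @export
lindley_factor <- function(x, sigma1, k_adjust = FALSE) {
  km <- .shrink_const(length(x), k_adjust)
  ss <- sum((x - mean(x))^2)
  c_plus <- if (ss == 0) 0 else max(1 - km * sigma1^2 / ss, 0)
  list(c_plus = c_plus, grand_mean = mean(x))
}

#' Carreras-Brannath shrinkage estimator
#'
#' Stage-1 estimates alone define the Lindley shrinkage estimate for the
#' selected arm, `L_s = xbar + C+ (X_s - xbar)`; this then replaces `X_s` in
#' the precision-weighted combination with the stage-2 estimate.  When
#' `C+ = 0` the estimator collapses to the MLE.  Under an i.i.d. normal prior
#' on the true means it dominates the MLE in mean squared error.
#'
#' @inheritParams estimate_mle
#' @return A `shrinkage_fit` with method `"cb"`.
#' @export
estimate_cb <- function(outcome, design) {
  stopifnot(inherits(outcome, "dtl_outcome"), inherits(design, "dtl_design"))
  lf <- lindley_factor(outcome$x, design$sigma1, design$small_k_fix)
  l_s <- lf$grand_mean + lf$c_plus * (outcome$x[outcome$s] - lf$grand_mean)
  p1 <- 1 / design$sigma1^2
  p2 <- 1 / design$sigma2^2
  .new_fit((l_s * p1 + outcome$y_s * p2) / (p1 + p2), "cb",
           grand_mean = lf$grand_mean, shrink_factor = lf$c_plus)
}

#' Direct empirical-Bayes plug-in estimator
#'
#' Treats the meta-analytic view as `k` normal estimates whose true means are
#' i.i.d. `N(mu, tau2)`, estimates `tau2` by maximising the profile
#' likelihood ([maximize_profile_tau2()]) and `mu` by the weighted mean at
#' that `tau2`, then plugs both into the oracle posterior mean for the
#' selected arm,
#' `(tau2 * xt_s + W_s * mu) / (W_s + tau2)`.
#' The posterior weight is intrinsically in `[0, 1]`, so no plus-rule is
#' needed; at `tau2 = 0` the estimate reduces to the fixed-effects grand
#' mean.
#'
#' @param view A `dtl_meta_view` (see [meta_view()]).
#' @return A `shrinkage_fit` with method `"direct"`.
#' @export
estimate_direct <- function(view) {
  stopifnot(inherits(view, "dtl_meta_view"))
  fit <- maximize_profile_tau2(view$xt, view$w)
  ws <- view$w[view$s]
  weight <- fit$tau2 / (ws + fit$tau2)        # 0 when tau2 = 0
  est <- weight * view$xt[view$s] + (1 - weight) * fit$mu_hat
  .new_fit(est, "direct", grand_mean = fit$mu_hat, tau2 = fit$tau2,
           shrink_factor = weight)
}

#' Carter-Rolph standard-prior shrinkage estimator
#'
#' Estimates the between-arm variance by Paule-Mandel, takes the
#' random-effects grand mean at that estimate, and shrinks with the factor
#' `C = 1 - ((k-3)/(k-1)) * W_s / (W_s + tau2_PM)` (plus-rule applied).  The
#' factor reduces exactly to the Lindley factor when all variances are
#' equal, and stays strictly positive when `tau2_PM = 0`, so the estimate
#' never collapses all the way to the grand mean.
#'
#' @inheritParams estimate_direct
#' @param small_k_fix Logical; at `k = 3` substitute `(k - 2)` for `(k - 3)`.
#' @return A `shrinkage_fit` with method `"cr_standard"`.
#' @export
estimate_cr_standard <- function(view, small_k_fix = FALSE) {
  stopifnot(inherits(view, "dtl_meta_view"))
  km <- .shrink_const(view$k, small_k_fix)
  fit <- paule_mandel_tau2(view$xt, view$w)
  ws <- view$w[view$s]
  c_plus <- max(1 - (km / (view$k - 1)) * ws / (ws + fit$tau2), 0)
  .new_fit(fit$mu_hat + c_plus * (view$xt[view$s] - fit$mu_hat),
           "cr_standard", grand_mean = fit$mu_hat, tau2 = fit$tau2,
           shrink_factor = c_plus)
}

#' Carter-Rolph proportional-prior shrinkage estimator
#'
#' Assumes each arm's prior variance is proportional to its estimate's
#' variance (`mu_i ~ N(mu, W_i * tau2)`), which makes the posterior shrinkage
#' weight common across arms and removes the need to estimate `tau2`
#' iteratively: the factor is `C = 1 - (k-3)/Q(0)` with `Q(0)` Cochran's
#' heterogeneity statistic, applied (after the plus-rule) around the
#' fixed-effects grand mean.  Zero dispersion (`Q(0) = 0`) yields `C+ = 0`.
#'
#' @inheritParams estimate_cr_standard
#' @return A `shrinkage_fit` with method `"cr_proportional"`.
#' @export
estimate_cr_proportional <- function(view, small_k_fix = FALSE) {
  stopifnot(inherits(view, "dtl_meta_view"))
  km <- .shrink_const(view$k, small_k_fix)
  q0 <- generalized_q(0, view$xt, view$w)
  mu_fe <- fixed_effect_mean(view$xt, view$w)
  c_plus <- if (q0 == 0) 0 else max(1 - km / q0, 0)
  .new_fit(mu_fe + c_plus * (view$xt[view$s] - mu_fe), "cr_proportional",
           grand_mean = mu_fe, tau2 = NA_real_, shrink_factor = c_plus)
}

#' Limited-translation proportional-prior estimator
#'
#' The proportional-prior estimate clipped to lie within `lt_width` naive
#' standard errors of the MLE, i.e. to
#' `[xt_s - lt_width*sqrt(W_s), xt_s + lt_width*sqrt(W_s)]`.  Limiting
#' translation protects the most extreme component of a shrinkage system
#' from over-shrinkage; the default width of one standard error is the usual
#' practical choice.
#'
#' @inheritParams estimate_cr_standard
#' @param lt_width Half-width of the protection corridor in units of the
#'   MLE's naive standard error (default 1).
#' @return A `shrinkage_fit` with method `"cr_proportional_lt"`.
#' @export
estimate_cr_proportional_lt <- function(view, small_k_fix = FALSE,
                                        lt_width = 1) {
  stopifnot(lt_width >= 0)
  base <- estimate_cr_proportional(view, small_k_fix)
  xs <- view$xt[view$s]
  half <- lt_width * sqrt(view$w[view$s])
  est <- min(max(base$estimate, xs - half), xs + half)
  .new_fit(est, "cr_proportional_lt", grand_mean = base$grand_mean,
           tau2 = NA_real_, shrink_factor = base$shrink_factor)
}

#' Available estimation methods
#'
#' @return Character vector of the method labels understood by
#'   [estimate_all()] and the simulation engine.
#' @export
dtl_methods <- function() {
  c("mle", "umvcue", "cb", "direct", "cr_standard", "cr_proportional",
    "cr_proportional_lt")
}

#' Compute all requested estimators for one trial
#'
#' @inheritParams estimate_mle
#' @param methods Character vector, a subset of [dtl_methods()].
#' @param lt_width Corridor half-width for the limited-translation variant.
#' @return A data frame with one row per method and columns `method`,
#'   `estimate`, `grand_mean`, `tau2`, `shrink_factor`.
#' @examples
#' d <- dtl_design(6, 1, 1)
#' o <- dtl_outcome(c(0, 0, 0, 0, 0, 3), y_s = 1)
#' estimate_all(o, d)
#' @export
estimate_all <- function(outcome, design, methods = dtl_methods(),
                         lt_width = 1) {
  methods <- match.arg(methods, dtl_methods(), several.ok = TRUE)
  view <- meta_view(outcome, design)
  fits <- lapply(methods, function(m) {
    switch(m,
      mle = estimate_mle(outcome, design),
      umvcue = estimate_umvcue(outcome, design),
      cb = estimate_cb(outcome, design),
      direct = estimate_direct(view),
      cr_standard = estimate_cr_standard(view, design$small_k_fix),
      cr_proportional = estimate_cr_proportional(view, design$small_k_fix),
      cr_proportional_lt = estimate_cr_proportional_lt(
        view, design$small_k_fix, lt_width))
  })
  data.frame(
    method = vapply(fits, `[[`, character(1), "method"),
    estimate = vapply(fits, `[[`, numeric(1), "estimate"),
    grand_mean = vapply(fits, `[[`, numeric(1), "grand_mean"),
    tau2 = vapply(fits, `[[`, numeric(1), "tau2"),
    shrink_factor = vapply(fits, `[[`, numeric(1), "shrink_factor")
  )
}
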