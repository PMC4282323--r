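# Meta-analytic numerics shared by the shrinkage estimators.  All functions
# operate on plain numeric vectors (estimates xt with known variances w) and
# can be used standalone for ordinary inverse-variance meta-analysis.

# inverse-(w + tau2)-weighted grand mean
.wmean <- function(xt, w, tau2) {
  iv <- 1 / (w + tau2)
  sum(xt * iv) / sum(iv)
}

.check_xw <- function(xt, w) {
  if (length(xt) != length(w)) stop("'xt' and 'w' must have equal length")
  if (length(xt) < 2L) stop("need at least 2 estimates")
  if (any(!is.finite(xt)) || any(!is.finite(w))) stop("inputs must be finite")
  if (any(w <= 0)) stop("all variances must be positive")
}

# bracket [0, hi] expanded until pred(hi) holds; pred TRUE means "far enough"
.expand_upper <- function(xt, w, pred) {
  hi <- 10 * max(stats::var(xt), max(w))
  for (i in 1:60) {
    if (pred(hi)) return(hi)
    hi <- 2 * hi
  }
  stop("failed to bracket after 60 expansions; inputs: xt range ",
       paste(range(xt), collapse = ".."), ", w range ",
       paste(range(w), collapse = ".."))
}

#' Generalised Q statistic
#'
#' `Q(tau2) = sum((xt - mu_V)^2 / (w + tau2))` with
#' `mu_V = sum(xt/(w+tau2)) / sum(1/(w+tau2))`.  At `tau2 = 0` this is
#' Cochran's heterogeneity statistic; it is non-increasing in `tau2` and
#' tends to 0 as `tau2` grows.
#'
#' @param tau2 Between-arm variance (scalar or vector, each `>= 0`).
#' @param xt Numeric vector of estimates.
#' @param w Numeric vector of known within-arm variances.
#' @return `Q(tau2)`, vectorised over `tau2`.
#' @examples
#' generalized_q(0, c(0, 1, 2), c(1, 1, 1))  # 2
#' @export
generalized_q <- function(tau2, xt, w) {
  .check_xw(xt, w)
  if (any(!is.finite(tau2)) || any(tau2 < 0)) stop("'tau2' must be >= 0")
  vapply(tau2, function(t2) {
    mu <- .wmean(xt, w, t2)
    sum((xt - mu)^2 / (w + t2))
  }, numeric(1))
}

.new_het_fit <- function(tau2, xt, w, method, converged = TRUE, q0, ...) {
  structure(
    c(list(tau2 = tau2, mu_hat = .wmean(xt, w, tau2), method = method,
           converged = converged, q0 = q0, k = length(xt)), list(...)),
    class = "heterogeneity_fit"
  )
}

#' @export
print.heterogeneity_fit <- function(x, ...) {
  cat(sprintf("Heterogeneity fit (%s): tau2 = %.6g, mu_hat = %.6g, Q(0) = %.4g\n",
              x$method, x$tau2, x$mu_hat, x$q0))
  if (!is.null(x$i2)) cat(sprintf("  I2 = %.1f%%\n", 100 * x$i2))
  invisible(x)
}

#' Paule-Mandel estimate of the between-arm variance
#'
#' Finds `tau2` solving the moment equation `Q(tau2) = k - 1` by bracketed
#' root-finding; when `Q(0) <= k - 1` the estimate is truncated at 0.  The
#' reported grand mean is the inverse-`(w + tau2)`-weighted mean evaluated at
#' the estimate, so it coincides with the fixed-effects mean when `tau2 = 0`.
#'
#' @inheritParams generalized_q
#' @return A `heterogeneity_fit` with fields `tau2`, `mu_hat`, `method`,
#'   `converged`, `q0`.
#' @examples
#' paule_mandel_tau2(c(0, 0, 4, 4), rep(1, 4))$tau2  # 13/3
#' @export
paule_mandel_tau2 <- function(xt, w) {
  .check_xw(xt, w)
  k <- length(xt)
  q0 <- generalized_q(0, xt, w)
  if (q0 <= k - 1)
    return(.new_het_fit(0, xt, w, "paule_mandel", TRUE, q0))
  f <- function(t2) generalized_q(t2, xt, w) - (k - 1)
  hi <- .expand_upper(xt, w, function(h) f(h) < 0)
  root <- stats::uniroot(f, c(0, hi), tol = 1e-12)$root
  if (abs(f(root)) > 1e-8)
    stop("Paule-Mandel solver did not converge: |Q - (k-1)| = ", abs(f(root)))
  .new_het_fit(root, xt, w, "paule_mandel", TRUE, q0)
}

#' Fixed-effects grand mean
#'
#' Inverse-variance weighted mean `sum(xt/w) / sum(1/w)`, the meta-analytic
#' fixed-effects estimate of the common mean.  Invariant to rescaling all
#' weights by a constant.
#'
#' @inheritParams generalized_q
#' @export
fixed_effect_mean <- function(xt, w) {
  if (length(xt) == 0L) stop("empty input")
  if (length(xt) != length(w)) stop("'xt' and 'w' must have equal length")
  if (any(!is.finite(xt)) || any(w <= 0)) stop("invalid input")
  .wmean(xt, w, 0)
}

#' DerSimonian-Laird estimate of the between-arm variance
#'
#' Closed-form moment estimator
#' `max(0, (Q(0) - (k-1)) / (sum(1/w) - sum(1/w^2)/sum(1/w)))`, with the
#' inconsistency measure `I2 = max(0, (Q(0) - (k-1))/Q(0))` reported
#' alongside.  Coincides with the Paule-Mandel estimate when all variances
#' are equal.
#'
#' @inheritParams generalized_q
#' @return A `heterogeneity_fit` with additional field `i2`.
#' @export
dersimonian_laird_tau2 <- function(xt, w) {
  .check_xw(xt, w)
  k <- length(xt)
  q0 <- generalized_q(0, xt, w)
  denom <- sum(1 / w) - sum(1 / w^2) / sum(1 / w)
  if (denom <= 0) stop("degenerate weight configuration")
  tau2 <- max(0, (q0 - (k - 1)) / denom)
  i2 <- if (q0 > 0) max(0, (q0 - (k - 1)) / q0) else 0
  .new_het_fit(tau2, xt, w, "dersimonian_laird", TRUE, q0, i2 = i2)
}

#' Profile log-likelihood in the between-arm variance
#'
#' `ll(tau2) = -0.5 * sum(log(w + tau2) + (xt - mu(tau2))^2/(w + tau2))`
#' where `mu(tau2)` is the inverse-`(w + tau2)`-weighted mean (the MLE of the
#' grand mean at that `tau2`).
#'
#' @inheritParams generalized_q
#' @return The profile log-likelihood, vectorised over `tau2`.
#' @export
profile_loglik_tau2 <- function(tau2, xt, w) {
  .check_xw(xt, w)
  if (any(!is.finite(tau2)) || any(tau2 < 0)) stop("'tau2' must be >= 0")
  vapply(tau2, function(t2) {
    v <- w + t2
    mu <- .wmean(xt, w, t2)
    -0.5 * sum(log(v) + (xt - mu)^2 / v)
  }, numeric(1))
}

# shared bracketing: coarse quadratic grid on [0, hi], hi expanded while the
# likelihood is still rising; returns grid argmax and its neighbours
.profile_bracket <- function(xt, w, ngrid = 33L) {
  hi <- 10 * max(stats::var(xt), max(w))
  for (i in 1:60) {
    if (profile_loglik_tau2(2 * hi, xt, w) <= profile_loglik_tau2(hi, xt, w))
      break
    hi <- 2 * hi
  }
  grid <- hi * seq(0, 1, length.out = ngrid)^2
  ll <- profile_loglik_tau2(grid, xt, w)
  j <- which.max(ll)
  list(lo = grid[max(j - 1L, 1L)], mid = grid[j],
       hi = grid[min(j + 1L, ngrid)])
}

#' Maximise the profile likelihood in the between-arm variance
#'
#' Bounded one-dimensional optimisation of [profile_loglik_tau2()] over
#' `[0, tau2_max]` with an expanding upper bound; a coarse grid locates the
#' mode before local refinement, and a maximiser at the boundary 0 is
#' allowed.  This is the heterogeneity estimate used by the direct
#' empirical-Bayes plug-in estimator.
#'
#' @inheritParams generalized_q
#' @return A `heterogeneity_fit` with method `"profile_likelihood"`.
#' @export
maximize_profile_tau2 <- function(xt, w) {
  .check_xw(xt, w)
  q0 <- generalized_q(0, xt, w)
  br <- .profile_bracket(xt, w)
  if (br$lo == br$hi) {            # flat bracket: degenerate dispersion
    tau2 <- br$mid
  } else {
    opt <- stats::optimize(function(t2) profile_loglik_tau2(t2, xt, w),
                           lower = br$lo, upper = br$hi, maximum = TRUE,
                           tol = 1e-10)
    tau2 <- opt$maximum
    # accept the boundary when it beats the interior optimum
    if (profile_loglik_tau2(0, xt, w) >= opt$objective) tau2 <- 0
    if (tau2 < 1e-8) tau2 <- 0
  }
  .new_het_fit(tau2, xt, w, "profile_likelihood", TRUE, q0)
}
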