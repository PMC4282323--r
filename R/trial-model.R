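#' Two-stage drop-the-loser trial design
#'
#' Describes a trial in which `k` experimental arms are estimated at stage 1
#' with a common known standard error `sigma1`, the arm with the largest
#' stage-1 estimate is selected, and that arm alone is re-estimated on an
#' independent stage-2 population with known standard error `sigma2`.
#' Variances are design constants supplied by the user; the package never
#' estimates them from raw data.
#'
#' @param k Number of experimental arms (integer, at least 2).
#' @param sigma1 Stage-1 standard error of each arm's estimate (positive,
#'   common across arms).
#' @param sigma2 Stage-2 standard error of the selected arm's estimate
#'   (positive).
#' @param small_k_fix Logical; when `k = 3`, replace the factor `(k - 3)`
#'   appearing in the shrinkage constants by `(k - 2)`.  This is a crude
#'   device that makes the shrinkage estimators usable at `k = 3`; it has no
#'   effect for `k >= 4`.
#'
#' @return An object of class `dtl_design`.
#' @examples
#' dtl_design(k = 6, sigma1 = 1, sigma2 = 1)
#' @export
dtl_design <- function(k, sigma1, sigma2, small_k_fix = FALSE) {
  k <- as.integer(k)
  stopifnot(length(k) == 1L, length(sigma1) == 1L, length(sigma2) == 1L)
  if (is.na(k) || k < 2L) stop("'k' must be an integer >= 2")
  if (!is.finite(sigma1) || sigma1 <= 0) stop("'sigma1' must be positive")
  if (!is.finite(sigma2) || sigma2 <= 0) stop("'sigma2' must be positive")
  structure(
    list(k = k, sigma1 = sigma1, sigma2 = sigma2,
         small_k_fix = isTRUE(small_k_fix)),
    class = "dtl_design"
  )
}

#' @export
print.dtl_design <- function(x, ...) {
  cat("Two-stage drop-the-loser design\n")
  cat(sprintf("  arms k = %d, sigma1 = %g, sigma2 = %g%s\n", x$k, x$sigma1,
              x$sigma2, if (x$small_k_fix) ", small-k fix on" else ""))
  invisible(x)
}

# naive variance of the combined stage-1/stage-2 MLE
.sigma_tilde2 <- function(design) {
  1 / (1 / design$sigma1^2 + 1 / design$sigma2^2)
}

#' Select the best and runner-up arms from stage-1 estimates
#'
#' The selected arm `s` carries the largest stage-1 estimate; the runner-up
#' `r` carries the largest estimate among the remaining arms.  Ties are broken
#' by the lowest index (they have probability zero under the continuous
#' model; the rule makes the function deterministic on arbitrary input).
#'
#' @param x Numeric vector of stage-1 estimates, length at least 2.
#' @return A list with integer components `s` and `r`.
#' @examples
#' select_best(c(0.2, 1.5, -0.3))  # s = 2, r = 1
#' @export
select_best <- function(x) {
  if (length(x) < 2L) stop("need at least 2 arms: runner-up undefined")
  if (anyNA(x)) stop("stage-1 estimates must not contain NA")
  s <- which.max(x)           # which.max breaks ties by lowest index
  r <- which.max(replace(x, s, -Inf))
  list(s = as.integer(s), r = as.integer(r))
}

#' Trial outcome of a two-stage drop-the-loser trial
#'
#' Bundles the stage-1 estimates for all arms, the indices of the selected
#' and runner-up arms, and the stage-2 estimate of the selected arm.  No
#' stage-2 data exist for dropped arms.
#'
#' @param x Numeric vector of `k` stage-1 estimates.
#' @param y_s Stage-2 estimate for the selected arm.
#' @param s,r Optional indices of the selected and runner-up arms; computed
#'   with [select_best()] when omitted.
#' @param strict Logical; when `TRUE` (default) an error is raised unless
#'   `x[s]` is the stage-1 maximum and `x[r]` the maximum of the rest.  Data
#'   where the continued arm was chosen by other criteria can be represented
#'   with `strict = FALSE`, but the selection-bias corrections implemented
#'   here are then void.
#' @return An object of class `dtl_outcome` with fields `x`, `s`, `r`, `y_s`.
#' @export
dtl_outcome <- function(x, y_s, s = NULL, r = NULL, strict = TRUE) {
  x <- as.numeric(x)
  if (length(x) < 2L) stop("need at least 2 arms")
  if (anyNA(x) || !is.finite(y_s)) stop("estimates must be finite")
  if (is.null(s) || is.null(r)) {
    sel <- select_best(x)
    if (is.null(s)) s <- sel$s
    if (is.null(r)) r <- sel$r
  }
  s <- as.integer(s); r <- as.integer(r)
  if (s < 1L || s > length(x) || r < 1L || r > length(x) || s == r)
    stop("'s' and 'r' must be distinct valid arm indices")
  if (strict) {
    if (x[s] < max(x)) stop("x[s] is not the stage-1 maximum")
    if (x[r] < max(x[-s])) stop("x[r] is not the runner-up maximum")
  }
  structure(list(x = x, s = s, r = r, y_s = as.numeric(y_s)),
            class = "dtl_outcome")
}

#' @export
print.dtl_outcome <- function(x, ...) {
  cat(sprintf("Drop-the-loser outcome: k = %d arms\n", length(x$x)))
  cat("  stage 1:", paste(signif(x$x, 4), collapse = " "), "\n")
  cat(sprintf("  selected arm %d (runner-up %d), stage-2 estimate %g\n",
              x$s, x$r, x$y_s))
  invisible(x)
}

#' Simulate one two-stage drop-the-loser trial
#'
#' Stage-1 estimates are drawn independently as `N(mu[i], sigma1^2)`; the arm
#' with the largest draw is selected and its stage-2 estimate is drawn
#' independently as `N(mu[s], sigma2^2)`.
#'
#' @param design A [dtl_design()].
#' @param mu Numeric vector of the `k` true arm means.
#' @return A [dtl_outcome()].
#' @examples
#' simulate_trial(dtl_design(6, 1, 1), mu = rep(0, 6))
#' @export
simulate_trial <- function(design, mu) {
  stopifnot(inherits(design, "dtl_design"))
  mu <- as.numeric(mu)
  if (length(mu) != design$k) stop("'mu' must have length design$k")
  x <- stats::rnorm(design$k, mean = mu, sd = design$sigma1)
  sel <- select_best(x)
  y_s <- stats::rnorm(1L, mean = mu[sel$s], sd = design$sigma2)
  dtl_outcome(x, y_s, s = sel$s, r = sel$r)
}

#' Combined maximum likelihood estimate of the selected arm's mean
#'
#' The precision-weighted combination of the selected arm's stage-1 and
#' stage-2 estimates,
#' `(X_s/sigma1^2 + Y_s/sigma2^2) / (1/sigma1^2 + 1/sigma2^2)`,
#' together with its naive variance
#' `sigma_tilde^2 = (1/sigma1^2 + 1/sigma2^2)^-1`.  Both ignore the
#' selection of `X_s` as the stage-1 maximum, so the estimate is positively
#' biased and the variance understated.
#'
#' @param outcome A [dtl_outcome()].
#' @param design A [dtl_design()].
#' @return A list with `estimate` and `naive_variance`.
#' @examples
#' d <- dtl_design(2, 1, 1)
#' combined_mle(dtl_outcome(c(0, 2), y_s = 1), d)  # 1.5, variance 0.5
#' @export
combined_mle <- function(outcome, design) {
  stopifnot(inherits(outcome, "dtl_outcome"), inherits(design, "dtl_design"))
  p1 <- 1 / design$sigma1^2
  p2 <- 1 / design$sigma2^2
  list(estimate = (outcome$x[outcome$s] * p1 + outcome$y_s * p2) / (p1 + p2),
       naive_variance = 1 / (p1 + p2))
}

#' Meta-analytic view of a drop-the-loser trial
#'
#' Recasts the trial as `k` independent estimates with known but unequal
#' variances, the container on which the unequal-variance shrinkage
#' estimators operate: non-selected arms keep their stage-1 estimate with
#' variance `sigma1^2`, while the selected arm carries the combined MLE with
#' the (smaller) naive variance `sigma_tilde^2`.  As `sigma2` grows without
#' bound the view degenerates to the stage-1 data and all variances become
#' equal.
#'
#' @inheritParams combined_mle
#' @return An object of class `dtl_meta_view` with fields `xt` (estimates),
#'   `w` (variances), `s` (selected index) and `k`.
#' @export
meta_view <- function(outcome, design) {
  stopifnot(inherits(outcome, "dtl_outcome"), inherits(design, "dtl_design"))
  cm <- combined_mle(outcome, design)
  xt <- outcome$x
  xt[outcome$s] <- cm$estimate
  w <- rep(design$sigma1^2, design$k)
  w[outcome$s] <- cm$naive_variance
  structure(list(xt = xt, w = w, s = outcome$s, k = design$k),
            class = "dtl_meta_view")
}

#' Construct a meta-analytic view directly from estimates and variances
#'
#' Low-level constructor for users holding per-arm estimates with known
#' variances (for instance a stage-1-only analysis, where all variances are
#' equal).
#'
#' @param xt Numeric vector of per-arm estimates.
#' @param w Numeric vector of known variances, same length.
#' @param s Index of the selected arm (defaults to `which.max(xt)`).
#' @return A `dtl_meta_view`.
#' @export
as_meta_view <- function(xt, w, s = which.max(xt)) {
  xt <- as.numeric(xt); w <- as.numeric(w)
  if (length(xt) != length(w)) stop("'xt' and 'w' must have equal length")
  if (length(xt) < 2L) stop("need at least 2 arms")
  if (any(!is.finite(xt)) || any(!is.finite(w)) || any(w <= 0))
    stop("estimates must be finite and variances positive")
  s <- as.integer(s)
  if (s < 1L || s > length(xt)) stop("invalid selected index")
  structure(list(xt = xt, w = w, s = s, k = length(xt)),
            class = "dtl_meta_view")
}

#' @export
print.dtl_meta_view <- function(x, ...) {
  cat(sprintf("Meta-analytic view of %d arms (selected: %d)\n", x$k, x$s))
  print(data.frame(arm = seq_len(x$k), estimate = x$xt, variance = x$w),
        row.names = FALSE)
  invisible(x)
}
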