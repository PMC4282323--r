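# Scenario engine: Monte Carlo comparison of the estimators under the four
# benchmark configurations of the true arm means, plus parameter sweeps.
#
# Scenarios for the k true means:
#   I   - redrawn i.i.d. N(mu, tau2) every replicate (default tau2 = 1)
#   II  - all equal to mu (default 0); selection bias is maximal here
#   III - one arm at mu + delta (default delta = 1), the rest at mu
#   IV  - as III with delta = 1.5
#
# Errors are measured against the replicate's realised selected-arm mean
# mu_s (a mixture over the selection event, not a fixed parameter), and both
# bias and root-MSE are reported in units of the MLE's naive standard error
# sigma_tilde so that configurations with different variances are
# comparable.

.scenario_mu <- function(scenario, k, reps, mu, delta, tau2) {
  switch(scenario,
    I = matrix(stats::rnorm(reps * k, mu, sqrt(tau2)), reps, k),
    II = rep(mu, k),
    III = c(mu + delta, rep(mu, k - 1L)),
    IV = c(mu + delta, rep(mu, k - 1L)),
    stop("unknown scenario: ", scenario))
}

#' Run one simulation scenario
#'
#' Simulates `reps` two-stage drop-the-loser trials under the requested
#' scenario, computes every requested estimator per replicate, and summarises
#' scaled bias and scaled root-MSE with Monte Carlo standard errors.
#'
#' @param design A [dtl_design()].
#' @param scenario One of `"I"` (means redrawn i.i.d. normal each replicate),
#'   `"II"` (all means equal), `"III"`/`"IV"` (one arm raised by `delta`).
#' @param reps Number of simulated trials (default 50000).
#' @param seed Optional integer seed; identical seeds give identical results.
#' @param methods Subset of [dtl_methods()].
#' @param mu Baseline true mean (location shift; default 0).
#' @param delta Raised-arm effect for scenarios III/IV (defaults 1 and 1.5).
#' @param tau2 Between-arm variance of the mean prior in scenario I
#'   (default 1).
#' @param lt_width Corridor half-width for the limited-translation variant.
#' @return A data frame with one row per method: `scaled_bias`,
#'   `scaled_rmse`, their Monte Carlo standard errors, `e_mu_s` (the mean
#'   realised selected-arm mean), `n_failed`, `reps`.  The naive SE used for
#'   scaling is attached as attribute `sigma_tilde`.
#' @examples
#' run_scenario(dtl_design(6, 1, 1), "II", reps = 2000, seed = 1,
#'              methods = c("mle", "umvcue"))
#' @export
run_scenario <- function(design, scenario = c("I", "II", "III", "IV"),
                         reps = 50000, seed = NULL,
                         methods = dtl_methods(), mu = 0, delta = NULL,
                         tau2 = NULL, lt_width = 1) {
  stopifnot(inherits(design, "dtl_design"), reps >= 1)
  scenario <- match.arg(scenario)
  methods <- match.arg(methods, dtl_methods(), several.ok = TRUE)
  if (is.null(delta)) delta <- if (scenario == "IV") 1.5 else 1
  if (is.null(tau2)) tau2 <- 1
  if (!is.null(seed)) set.seed(seed)
  mu_true <- .scenario_mu(scenario, design$k, reps, mu, delta, tau2)
  sim <- .sim_batch(design, mu_true, reps)
  est <- .estimate_batch(sim, design, methods, lt_width)
  err <- est - sim$mu_s
  sigt <- sqrt(.sigma_tilde2(design))
  ok <- is.finite(err)
  n_failed <- colSums(!ok)
  err[!ok] <- NA_real_
  n_ok <- colSums(ok)
  bias <- colMeans(err, na.rm = TRUE)
  mse <- colMeans(err^2, na.rm = TRUE)
  rmse <- sqrt(mse)
  bias_se <- sqrt(apply(err, 2, stats::var, na.rm = TRUE) / n_ok)
  rmse_se <- apply(err^2, 2, stats::sd, na.rm = TRUE) /
    (2 * rmse * sqrt(n_ok))
  res <- data.frame(
    method = methods,
    scaled_bias = bias / sigt,
    scaled_rmse = rmse / sigt,
    bias_mc_se = bias_se / sigt,
    rmse_mc_se = rmse_se / sigt,
    e_mu_s = mean(sim$mu_s),
    n_failed = n_failed,
    reps = reps,
    row.names = NULL
  )
  attr(res, "sigma_tilde") <- sigt
  attr(res, "scenario") <- scenario
  res
}

# independently reproducible per-cell seeds derived from one master seed
.cell_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  set.seed(seed)
  as.list(sample.int(.Machine$integer.max - 1L, n))
}

#' Scenario-by-variance benchmark table
#'
#' Crosses scenarios I-IV with a set of `(sigma1, sigma2)` levels and
#' reports, per cell, the scaled bias of every estimator except the UMVCUE
#' (whose bias is zero up to sampling error) and the scaled root-MSE of all
#' estimators.  Each cell runs on its own seed derived from `seed`, so cells
#' are individually reproducible.
#'
#' @param reps Replicates per cell (default 50000).
#' @param seed Optional master seed.
#' @param k Number of arms (default 6).
#' @param sigma_levels List of `c(sigma1, sigma2)` pairs; the first two
#'   default levels (1,1) and (2,1) are the conventional benchmark settings,
#'   the remaining two are freely configurable.
#' @param methods Subset of [dtl_methods()].
#' @return A wide data frame with one row per scenario-by-variance cell:
#'   columns `scenario`, `sigma1`, `sigma2`, `e_mu_s`, then `bias_*` and
#'   `rmse_*` per method.
#' @export
run_table1 <- function(reps = 50000, seed = NULL, k = 6,
                       sigma_levels = list(c(1, 1), c(2, 1), c(1, 2),
                                           c(2, 2)),
                       methods = dtl_methods()) {
  methods <- match.arg(methods, dtl_methods(), several.ok = TRUE)
  scenarios <- c("I", "II", "III", "IV")
  cells <- expand.grid(level = seq_along(sigma_levels),
                       scenario = scenarios, stringsAsFactors = FALSE)
  seeds <- .cell_seeds(seed, nrow(cells))
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sig <- sigma_levels[[cells$level[i]]]
    des <- dtl_design(k, sig[1], sig[2])
    res <- run_scenario(des, cells$scenario[i], reps = reps,
                        seed = seeds[[i]], methods = methods)
    row <- data.frame(scenario = cells$scenario[i], sigma1 = sig[1],
                      sigma2 = sig[2], e_mu_s = res$e_mu_s[1])
    for (m in setdiff(methods, "umvcue"))
      row[[paste0("bias_", m)]] <- res$scaled_bias[res$method == m]
    for (m in methods)
      row[[paste0("rmse_", m)]] <- res$scaled_rmse[res$method == m]
    row
  })
  out <- do.call(rbind, rows)
  out[order(match(out$scenario, scenarios)), , drop = FALSE]
}

#' Sweep a design parameter across a grid
#'
#' Re-runs a scenario along a grid of one parameter: `"delta"` (one raised
#' arm, scenario III), `"tau2"` (i.i.d. normal means, scenario I) or `"k"`
#' (number of arms, scenario I at `tau2 = 1`).  Each grid point gets its own
#' seed derived from `seed`.
#'
#' @param param One of `"delta"`, `"tau2"`, `"k"`.
#' @param grid Numeric vector of parameter values (non-empty).
#' @param design Base [dtl_design()]; its `k` is overridden along a `"k"`
#'   sweep.
#' @param reps Replicates per grid point (default 10000).
#' @param seed Optional master seed.
#' @param methods Subset of [dtl_methods()].
#' @param lt_width Corridor half-width for the limited-translation variant.
#' @return A long data frame: `param`, `value`, then the [run_scenario()]
#'   summary columns.
#' @export
dtl_sweep <- function(param = c("delta", "tau2", "k"), grid, design,
                      reps = 10000, seed = NULL, methods = dtl_methods(),
                      lt_width = 1) {
  param <- match.arg(param)
  stopifnot(inherits(design, "dtl_design"), length(grid) >= 1)
  if (param == "k" && any(grid < 2 | grid != round(grid)))
    stop("'k' grid must contain integers >= 2")
  seeds <- .cell_seeds(seed, length(grid))
  rows <- lapply(seq_along(grid), function(i) {
    g <- grid[i]
    res <- switch(param,
      delta = run_scenario(design, "III", reps = reps, seed = seeds[[i]],
                           methods = methods, delta = g,
                           lt_width = lt_width),
      tau2 = run_scenario(design, "I", reps = reps, seed = seeds[[i]],
                          methods = methods, tau2 = g,
                          lt_width = lt_width),
      k = run_scenario(dtl_design(g, design$sigma1, design$sigma2,
                                  design$small_k_fix),
                       "I", reps = reps, seed = seeds[[i]],
                       methods = methods, tau2 = 1, lt_width = lt_width))
    cbind(param = param, value = g, res)
  })
  do.call(rbind, rows)
}
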