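# Vectorised Monte Carlo engine.  All quantities are computed on
# replicate-by-arm matrices so that 50000-replicate studies run in seconds;
# the per-trial functions in estimators.R define the reference semantics and
# the two code paths are held together by tests.

# Simulate `reps` trials at once.  `mu` is a length-k vector or a reps-by-k
# matrix (one row per replicate, for scenarios that redraw the true means).
# Draw order is fixed (stage-1 matrix, then stage-2 vector) so results are
# reproducible from a single seeded stream.
.sim_batch <- function(design, mu, reps) {
  k <- design$k
  mu_m <- if (is.matrix(mu)) mu else matrix(mu, reps, k, byrow = TRUE)
  X <- matrix(stats::rnorm(reps * k), reps, k) * design$sigma1 + mu_m
  s <- max.col(X, ties.method = "first")
  idx <- cbind(seq_len(reps), s)
  xs <- X[idx]
  X2 <- X
  X2[idx] <- -Inf
  r <- max.col(X2, ties.method = "first")
  xr <- X[cbind(seq_len(reps), r)]
  mu_s <- mu_m[idx]
  ys <- stats::rnorm(reps, mu_s, design$sigma2)
  list(X = X, s = s, r = r, idx = idx, xs = xs, xr = xr, ys = ys, mu_s = mu_s)
}

# Q(tau2) per row; tau2 is a scalar or a per-row vector (column-major
# recycling adds it row-wise)
.q_rows <- function(tau2, xt, w) {
  iv <- 1 / (w + tau2)
  mu <- rowSums(xt * iv) / rowSums(iv)
  rowSums((xt - mu)^2 * iv)
}

.wmean_rows <- function(tau2, xt, w) {
  iv <- 1 / (w + tau2)
  rowSums(xt * iv) / rowSums(iv)
}

.loglik_rows <- function(tau2, xt, w) {
  v <- w + tau2
  iv <- 1 / v
  mu <- rowSums(xt * iv) / rowSums(iv)
  -0.5 * rowSums(log(v) + (xt - mu)^2 * iv)
}

.row_var <- function(xt) {
  rowSums((xt - rowMeans(xt))^2) / (ncol(xt) - 1)
}

# Paule-Mandel per row: bisection on Q(tau2) = k - 1 after bracket expansion
.pm_rows <- function(xt, w) {
  k <- ncol(xt)
  target <- k - 1
  tau2 <- numeric(nrow(xt))
  act <- which(.q_rows(0, xt, w) > target)
  if (length(act)) {
    xa <- xt[act, , drop = FALSE]
    wa <- w[act, , drop = FALSE]
    hi <- 10 * pmax(.row_var(xa), apply(wa, 1, max))
    for (i in 1:60) {
      bad <- .q_rows(hi, xa, wa) > target
      if (!any(bad)) break
      hi[bad] <- 2 * hi[bad]
    }
    lo <- numeric(length(act))
    for (i in 1:90) {
      mid <- (lo + hi) / 2
      up <- .q_rows(mid, xa, wa) > target
      lo[up] <- mid[up]
      hi[!up] <- mid[!up]
    }
    tau2[act] <- (lo + hi) / 2
  }
  tau2
}

# Profile-likelihood maximiser per row: the same quadratic coarse grid as the
# scalar version, then golden-section refinement within the bracket
.profile_rows <- function(xt, w, ngrid = 33L, iter = 80L) {
  n <- nrow(xt)
  hi <- 10 * pmax(.row_var(xt), apply(w, 1, max))
  for (i in 1:60) {
    bad <- .loglik_rows(2 * hi, xt, w) > .loglik_rows(hi, xt, w)
    if (!any(bad)) break
    hi[bad] <- 2 * hi[bad]
  }
  frac <- seq(0, 1, length.out = ngrid)^2
  ll <- matrix(NA_real_, n, ngrid)
  for (j in seq_len(ngrid)) ll[, j] <- .loglik_rows(hi * frac[j], xt, w)
  best <- max.col(ll, ties.method = "first")
  a <- hi * frac[pmax(best - 1L, 1L)]
  b <- hi * frac[pmin(best + 1L, ngrid)]
  g <- (sqrt(5) - 1) / 2
  for (i in seq_len(iter)) {
    x1 <- b - g * (b - a)
    x2 <- a + g * (b - a)
    f1 <- .loglik_rows(x1, xt, w)
    f2 <- .loglik_rows(x2, xt, w)
    swap <- f1 > f2
    b[swap] <- x2[swap]
    a[!swap] <- x1[!swap]
  }
  tau2 <- (a + b) / 2
  tau2[tau2 < 1e-8] <- 0
  tau2
}

# Per-replicate estimates for the requested methods; returns a reps-by-method
# matrix.  Mirrors estimators.R exactly.
.estimate_batch <- function(sim, design, methods, lt_width = 1) {
  reps <- length(sim$ys)
  k <- design$k
  s1sq <- design$sigma1^2
  s2sq <- design$sigma2^2
  p1 <- 1 / s1sq
  p2 <- 1 / s2sq
  sigt2 <- 1 / (p1 + p2)
  z <- (sim$xs * p1 + sim$ys * p2) / (p1 + p2)
  out <- matrix(NA_real_, reps, length(methods),
                dimnames = list(NULL, methods))
  need_view <- any(methods %in%
                     c("direct", "cr_standard", "cr_proportional",
                       "cr_proportional_lt"))
  if (need_view) {
    xt <- sim$X
    xt[sim$idx] <- z
    w <- matrix(s1sq, reps, k)
    w[sim$idx] <- sigt2
    ws <- sigt2
  }
  if (any(methods %in% c("cb", "cr_standard", "cr_proportional",
                         "cr_proportional_lt")))
    km <- .shrink_const(k, design$small_k_fix)
  for (m in methods) {
    out[, m] <- switch(m,
      mle = z,
      umvcue = {
        v <- sqrt(s1sq + s2sq) * (z - sim$xr) / s1sq
        z - s2sq / sqrt(s1sq + s2sq) * .inv_mills(v)
      },
      cb = {
        xbar <- rowMeans(sim$X)
        ss <- rowSums((sim$X - xbar)^2)
        c_plus <- ifelse(ss == 0, 0, pmax(1 - km * s1sq / ss, 0))
        l_s <- xbar + c_plus * (sim$xs - xbar)
        (l_s * p1 + sim$ys * p2) / (p1 + p2)
      },
      direct = {
        tau2 <- .profile_rows(xt, w)
        mu <- .wmean_rows(tau2, xt, w)
        (tau2 * z + ws * mu) / (ws + tau2)
      },
      cr_standard = {
        tau2 <- .pm_rows(xt, w)
        mu <- .wmean_rows(tau2, xt, w)
        c_plus <- pmax(1 - (km / (k - 1)) * ws / (ws + tau2), 0)
        mu + c_plus * (z - mu)
      },
      cr_proportional = {
        q0 <- .q_rows(0, xt, w)
        mu_fe <- .wmean_rows(0, xt, w)
        c_plus <- ifelse(q0 == 0, 0, pmax(1 - km / q0, 0))
        mu_fe + c_plus * (z - mu_fe)
      },
      cr_proportional_lt = {
        q0 <- .q_rows(0, xt, w)
        mu_fe <- .wmean_rows(0, xt, w)
        c_plus <- ifelse(q0 == 0, 0, pmax(1 - km / q0, 0))
        est <- mu_fe + c_plus * (z - mu_fe)
        half <- lt_width * sqrt(ws)
        pmin(pmax(est, z - half), z + half)
      },
      stop("unknown method: ", m))
  }
  out
}
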