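# Independent oracles used across the suite. These deliberately avoid the
# package's own solution paths: the grey parameters come from the literal
# normal equations, the box-constrained least-squares optimum from exhaustive
# enumeration of bound configurations, and the affine correction map from a
# direct derivation of the correction formula.

# (a, b) via the literal normal equations (B'B)^{-1} B'Y.
gm11_normal_equations <- function(x0) {
  n <- length(x0)
  x1 <- cumsum(x0)
  z1 <- (x1[-1] + x1[-n]) / 2
  B <- cbind(-z1, 1)
  Y <- x0[-1]
  ab <- solve(t(B) %*% B) %*% t(B) %*% Y
  c(a = ab[1, 1], b = ab[2, 1])
}

# The corrected series is affine in alpha: F(alpha) = base + M %*% alpha.
# Derived directly from the correction formula: for each correctable time t,
# the propagated state weights w = P[state(t-1), ] contribute
# sum_i w_i * (U_i + alpha_i (L_i - U_i)).
affine_correction_map <- function(fit, part, trans) {
  n <- fit$n
  r <- part$r
  base <- fitted(fit)
  M <- matrix(0, n, r)
  for (t in 3:n) {
    w <- trans$matrix[part$labels[t - 2], ]
    base[t] <- base[t] + sum(w * part$upper)
    M[t, ] <- w * (part$lower - part$upper)
  }
  list(base = base, M = M)
}

# Exact box-constrained linear least squares min ||y - A x||^2, lo <= x <= hi,
# by enumerating every {free, at-lower, at-upper} configuration (3^r for the
# small r used here) and keeping the best feasible candidate.
box_ls_oracle <- function(A, y, lo = 0, hi = 1) {
  r <- ncol(A)
  cfgs <- expand.grid(rep(list(0:2), r))
  best <- NULL
  for (k in seq_len(nrow(cfgs))) {
    cfg <- as.integer(cfgs[k, ])
    x <- numeric(r)
    x[cfg == 1L] <- lo
    x[cfg == 2L] <- hi
    free <- cfg == 0L
    if (any(free)) {
      Af <- A[, free, drop = FALSE]
      rhs <- y - A[, !free, drop = FALSE] %*% x[!free]
      sol <- tryCatch(qr.solve(Af, as.numeric(rhs)), error = function(e) NULL)
      if (is.null(sol)) next
      x[free] <- sol
    }
    if (any(x < lo - 1e-9 | x > hi + 1e-9)) next
    rss <- sum((y - A %*% x)^2)
    if (is.null(best) || rss < best$rss) best <- list(x = x, rss = rss)
  }
  best
}

# A small family of fitted series with Markov-switching noise, used wherever
# a realistic residual structure is needed.
noisy_fixture <- function(seed, r = 3, n = 12) {
  s <- sim_grey_series(a = -0.12, b = 2, x1 = 2, n = n,
                       noise_states = rbind(c(1, 0.25), c(1, -0.1), c(1, -0.2)),
                       seed = seed)
  fit <- gm11(s)
  part <- partition_states(residuals(fit)[-1], r = r)
  trans <- estimate_transitions(part$labels, r = r, m = 1)
  list(series = s, fit = fit, part = part, trans = trans)
}
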