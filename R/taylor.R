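#' Control parameters for the whitening-coefficient optimizer
#'
#' @param step_ratio step-length ratio `R` of the forward finite difference:
#'   the probe step for coordinate `i` is `C_i = alpha_i / R` (default 200).
#' @param tol convergence tolerance `eps` on the linearized residual `Q`, on
#'   the step norm and on the realized coefficient change (default 1e-8).
#' @param max_iter iteration cap (default 100).
#' @param alpha0 starting coefficients; default all 0.5.
#' @param min_fd_step floor for the finite-difference step so `alpha_i = 0`
#'   does not yield a zero probe (default 1e-4).
#' @return a list of class `"optimizer_control"`.
#' @export
optimizer_control <- function(step_ratio = 200, tol = 1e-8, max_iter = 100L,
                              alpha0 = NULL, min_fd_step = 1e-4) {
  if (step_ratio <= 0) stop("step_ratio must be > 0")
  if (tol <= 0) stop("tol must be > 0")
  if (!is.null(alpha0) && any(alpha0 < 0 | alpha0 > 1))
    stop("alpha0 entries must lie in [0, 1]")
  structure(list(step_ratio = step_ratio, tol = tol,
                 max_iter = as.integer(max_iter), alpha0 = alpha0,
                 min_fd_step = min_fd_step),
            class = "optimizer_control")
}

#' Objective vector of the whitening optimization
#'
#' The observed series as the target the corrected series is matched
#' against.
#'
#' @param series an [obs_series] (or the series inside a [gm11] fit).
#' @return numeric vector of the observations.
#' @export
objective_vector <- function(series) {
  as_obs_series(series)$values
}

#' Approximating vector at a given whitening coefficient
#'
#' The Markov-corrected series evaluated at `alpha` — the function whose
#' distance to [objective_vector] the optimizer minimizes. It is affine in
#' `alpha`, which makes the Gauss-Newton iteration exact up to the box
#' constraints.
#'
#' @inheritParams corrected_series
#' @return numeric vector of length `n`.
#' @export
approx_vector <- function(fit, partition, transitions, alpha) {
  corrected_series(fit, partition, transitions, alpha)
}

#' Forward finite-difference Jacobian of the corrected series
#'
#' Column `i` is `[F(alpha + C_i e_i) - F(alpha)] / C_i` with probe step
#' `C_i = max(alpha_i / R, min_fd_step)`. Because the corrected series is
#' affine in `alpha`, the forward difference is exact for any step size.
#'
#' @inheritParams corrected_series
#' @param control an [optimizer_control] list.
#' @return an `n x r` matrix.
#' @export
fd_jacobian <- function(fit, partition, transitions, alpha,
                        control = optimizer_control()) {
  r <- partition$r
  F0 <- approx_vector(fit, partition, transitions, alpha)
  A <- matrix(0, fit$n, r)
  for (i in seq_len(r)) {
    Ci <- max(alpha[i] / control$step_ratio, control$min_fd_step)
    ai <- alpha
    ai[i] <- ai[i] + Ci
    A[, i] <- (corrected_affine(fit, partition, transitions, ai) - F0) / Ci
  }
  A
}

# corrected_series without the [0,1] check on alpha: finite-difference probes
# may step slightly above 1, where the affine map is still well defined.
corrected_affine <- function(fit, partition, transitions, alpha) {
  v <- alpha * partition$lower + (1 - alpha) * partition$upper
  P <- transitions$matrix
  out <- fit$fitted
  lab <- partition$labels
  for (t in 3:fit$n) {
    a0 <- numeric(partition$r)
    a0[lab[t - 2L]] <- 1
    out[t] <- fit$fitted[t] + sum(as.numeric(a0 %*% P) * v)
  }
  out
}

# Least-squares solve with SVD pseudo-inverse fallback for rank deficiency.
ls_solve <- function(A, y, warn = TRUE) {
  qra <- qr(A)
  if (qra$rank == ncol(A)) return(as.numeric(qr.coef(qra, y)))
  if (warn) warning("rank-deficient Jacobian: using pseudo-inverse step")
  sv <- svd(A)
  pos <- sv$d > max(dim(A)) * .Machine$double.eps * max(sv$d, 1)
  as.numeric(sv$v[, pos, drop = FALSE] %*%
               ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos]))
}

#' One plain Gauss-Newton update of the whitening coefficients
#'
#' Solves the linearized problem `A eta ~ FD` by least squares and applies
#' the update clamped to the unit box. This is the raw one-step iteration;
#' [optimize_alpha] wraps it with bound handling and convergence control.
#'
#' @param A Jacobian matrix (`n x r`), from [fd_jacobian].
#' @param FD deviation vector `G - F(alpha)`.
#' @param alpha current coefficients.
#' @return list with `alpha` (updated, clamped to `[0, 1]`) and `eta` (the
#'   unconstrained step).
#' @export
gauss_newton_step <- function(A, FD, alpha) {
  if (nrow(A) != length(FD) || ncol(A) != length(alpha))
    stop("shape mismatch between A, FD and alpha")
  eta <- ls_solve(A, FD)
  list(alpha = pmin(pmax(alpha + eta, 0), 1), eta = eta)
}

#' Linearized residual of a candidate step
#'
#' The evaluation function `Q = || FD - A eta ||^2`: the squared norm of the
#' deviation left after the linearized step `eta`.
#'
#' @inheritParams gauss_newton_step
#' @param eta candidate step.
#' @return a single non-negative number.
#' @export
evaluate_q <- function(A, FD, eta) {
  sum((FD - A %*% eta)^2)
}

# Bound-constrained least-squares step: min ||FD - A d||^2 subject to
# 0 <= alpha + d <= 1, by active-set iteration (Lawson-Hanson style).
# Guarantees the Gauss-Newton fixed point is the box-constrained optimum.
bounded_gn_step <- function(A, FD, alpha, max_pass = NULL) {
  r <- ncol(A)
  if (is.null(max_pass)) max_pass <- 4L * r + 8L
  at_lo <- rep(FALSE, r)
  at_hi <- rep(FALSE, r)
  d <- numeric(r)
  for (pass in seq_len(max_pass)) {
    d[at_lo] <- -alpha[at_lo]
    d[at_hi] <- 1 - alpha[at_hi]
    free <- !(at_lo | at_hi)
    if (any(free)) {
      rhs <- FD - A[, !free, drop = FALSE] %*% d[!free]
      d[free] <- ls_solve(A[, free, drop = FALSE], as.numeric(rhs),
                          warn = FALSE)
    }
    x <- alpha + d
    viol_lo <- free & x < -1e-12
    viol_hi <- free & x > 1 + 1e-12
    if (any(viol_lo | viol_hi)) {
      at_lo[viol_lo] <- TRUE
      at_hi[viol_hi] <- TRUE
      next
    }
    # KKT: release bound coordinates whose gradient points back inside
    g <- -as.numeric(crossprod(A, FD - A %*% d))
    rel_lo <- at_lo & g < -1e-10
    rel_hi <- at_hi & g > 1e-10
    if (!any(rel_lo | rel_hi)) break
    at_lo[rel_lo] <- FALSE
    at_hi[rel_hi] <- FALSE
  }
  pmin(pmax(alpha + d, 0), 1) - alpha
}

#' Optimize the whitening coefficients by Gauss-Newton iteration
#'
#' Iterates the Taylor-approximation scheme: evaluate the corrected series
#' `F(alpha)`, form the deviation `FD = G - F(alpha)`, build the
#' finite-difference Jacobian, take a least-squares step restricted to the
#' unit box, and repeat until the linearized residual `Q`, the step, or the
#' realized coefficient change falls below `tol`, or `max_iter` is hit.
#' Each step solves the bound-constrained linear least-squares subproblem by
#' active-set iteration, so on this affine objective the fixed point is the
#' box-constrained least-squares optimum. The procedure is fully
#' deterministic.
#'
#' @inheritParams fd_jacobian
#' @return An object of class `"alpha_opt"`: list with `alpha` (optimized
#'   coefficients in `[0, 1]^r`), `q_trace` (`Q` per iteration),
#'   `iterations` and `converged`.
#' @examples
#' fit <- gm11(example_series("HD"))
#' p <- partition_states(residuals(fit)[-1], 3)
#' tm <- estimate_transitions(p$labels, 3)
#' optimize_alpha(fit, p, tm)$alpha
#' @export
optimize_alpha <- function(fit, partition, transitions,
                           control = optimizer_control()) {
  r <- partition$r
  alpha <- if (is.null(control$alpha0)) rep(0.5, r) else {
    if (length(control$alpha0) != r) stop("alpha0 must have length r")
    as.numeric(control$alpha0)
  }
  G <- objective_vector(fit$series)
  q_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (K in seq_len(control$max_iter)) {
    iter <- K
    F0 <- approx_vector(fit, partition, transitions, alpha)
    FD <- G - F0
    A <- fd_jacobian(fit, partition, transitions, alpha, control)
    eta <- bounded_gn_step(A, FD, alpha)
    Q <- evaluate_q(A, FD, eta)
    if (!is.finite(Q))
      stop("non-finite evaluation function Q at iteration ", K,
           " (trace: ", paste(signif(q_trace, 6), collapse = ", "), ")")
    q_trace <- c(q_trace, Q)
    alpha_new <- pmin(pmax(alpha + eta, 0), 1)
    delta <- max(abs(alpha_new - alpha))
    alpha <- alpha_new
    if (Q <= control$tol || max(abs(eta)) <= control$tol ||
        delta <= control$tol) {
      converged <- TRUE
      break
    }
  }
  structure(list(alpha = alpha, q_trace = q_trace, iterations = iter,
                 converged = converged),
            class = "alpha_opt")
}

#' @export
print.alpha_opt <- function(x, ...) {
  cat("Whitening coefficients (Gauss-Newton,",
      x$iterations, "iterations,",
      if (x$converged) "converged" else "iteration cap reached", ")\n")
  cat("  alpha:", paste(sprintf("%.4f", x$alpha), collapse = " "), "\n")
  cat("  final Q:", format(x$q_trace[length(x$q_trace)], digits = 6), "\n")
  invisible(x)
}
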