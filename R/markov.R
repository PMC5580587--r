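#' Partition signed residuals into equal-width error states
#'
#' Splits the range of the signed fit errors into `r` equal-width intervals
#' with bounds `L_j = min(e) + (j-1)/r * (max(e) - min(e))` and
#' `U_j = min(e) + j/r * (max(e) - min(e))`, and labels every residual with
#' its state. Labels use half-open intervals `[L_j, U_j)` except the last
#' state, which is closed; a residual exactly on an internal boundary goes to
#' the higher state. Residuals are signed (actual minus predicted) so that
#' the additive Markov correction keeps direction.
#'
#' @param residuals signed residuals of the labeled points (for a [gm11] fit
#'   these are points 2..n, i.e. `residuals(fit)[-1]`); at least 2, not all
#'   equal.
#' @param r number of states (>= 1).
#' @return An object of class `"state_partition"`: list with `r`, `lower`,
#'   `upper` (length-`r` bounds) and `labels` (1-based state per residual).
#' @examples
#' partition_states(c(-1, 0, 2), r = 3)
#' @export
partition_states <- function(residuals, r = 3L) {
  e <- as.numeric(residuals)
  if (length(e) < 2L) stop("need at least 2 residuals to partition")
  if (r < 1L) stop("r must be >= 1")
  lo <- min(e); hi <- max(e)
  if (hi <= lo)
    stop("degenerate partition: all residuals identical; equal-width states ",
         "need a positive error range (r = 1 with zero width is not supported)")
  width <- (hi - lo) / r
  lower <- lo + (seq_len(r) - 1L) * width
  upper <- lo + seq_len(r) * width
  labels <- pmin(findInterval(e, lower), r)  # ties go up; last state closed
  structure(list(r = as.integer(r), lower = lower, upper = upper,
                 labels = as.integer(labels)),
            class = "state_partition")
}

#' @export
print.state_partition <- function(x, ...) {
  cat("Residual partition into", x$r, "equal-width states\n")
  for (j in seq_len(x$r))
    cat(sprintf("  S%d: [%.4g, %.4g%s  n = %d\n", j, x$lower[j], x$upper[j],
                if (j < x$r) ")" else "]", sum(x$labels == j)))
  invisible(x)
}

#' Estimate the m-step Markov transition matrix of residual states
#'
#' Counts transitions `M_ij(m)` over all label pairs `(t, t+m)`; the row
#' totals `M_i` count label-`i` occurrences that have an `m`-step successor
#' (the final `m` labels have none and are excluded). Rows with no
#' occurrences are set to the uniform vector `1/r` to keep the matrix
#' row-stochastic.
#'
#' @param labels integer state labels in time order (from
#'   [partition_states]).
#' @param r number of states.
#' @param m transition step (default 1; the forecasting pipeline uses only
#'   `m = 1`).
#' @return An object of class `"transition_model"`: list with `step`,
#'   `counts` (r x r), `totals` (length r) and `matrix` (row-stochastic
#'   r x r).
#' @examples
#' estimate_transitions(c(1, 1, 2, 1), r = 2)$matrix
#' @export
estimate_transitions <- function(labels, r, m = 1L) {
  labels <- as.integer(labels)
  if (m < 1L) stop("m must be >= 1")
  if (m >= length(labels)) stop("m must be smaller than the number of labels")
  if (any(labels < 1L | labels > r)) stop("labels out of range 1..r")
  counts <- matrix(0L, r, r)
  nl <- length(labels)
  for (t in seq_len(nl - m))
    counts[labels[t], labels[t + m]] <- counts[labels[t], labels[t + m]] + 1L
  totals <- rowSums(counts)
  P <- matrix(1 / r, r, r)
  nz <- totals > 0
  P[nz, ] <- counts[nz, , drop = FALSE] / totals[nz]
  structure(list(step = as.integer(m), counts = counts,
                 totals = as.integer(totals), matrix = P),
            class = "transition_model")
}

#' @export
print.transition_model <- function(x, ...) {
  cat("Markov residual-state transitions (step m =", x$step, ")\n")
  print(round(x$matrix, 4))
  invisible(x)
}

#' Propagate a state-probability vector through a transition matrix
#'
#' Post-multiplies `a0` by `P`, `steps` times: `a(t) = a(t-1) P`.
#'
#' @param a0 probability vector over the `r` states.
#' @param P row-stochastic r x r matrix (or a [estimate_transitions] result).
#' @param steps number of applications (>= 0).
#' @return probability vector of length `r`.
#' @examples
#' propagate(c(1, 0), matrix(c(0.5, 1, 0.5, 0), 2), steps = 2)  # 0.75 0.25
#' @export
propagate <- function(a0, P, steps = 1L) {
  if (inherits(P, "transition_model")) P <- P$matrix
  if (!is.matrix(P) || nrow(P) != ncol(P)) stop("P must be square")
  if (length(a0) != nrow(P)) stop("dimension mismatch between a0 and P")
  if (any(a0 < 0) || abs(sum(a0) - 1) > 1e-8)
    stop("a0 must be a probability vector")
  a <- as.numeric(a0)
  for (k in seq_len(steps)) a <- as.numeric(a %*% P)
  a
}

#' Whiten the state intervals into point corrections
#'
#' Collapses each grey interval correction `[L_i, U_i]` to the point value
#' `v_i = alpha_i * L_i + (1 - alpha_i) * U_i`, with whitening coefficients
#' `alpha_i` in `[0, 1]`.
#'
#' @param partition a [partition_states] result.
#' @param alpha numeric vector in `[0, 1]^r`.
#' @return numeric vector `v` of length `r`, each `v_i` in `[L_i, U_i]`.
#' @examples
#' p <- partition_states(c(-1, 0, 2), 3)
#' whiten(p, c(0.5, 0.5, 0.5))
#' @export
whiten <- function(partition, alpha) {
  alpha <- as.numeric(alpha)
  if (length(alpha) != partition$r) stop("alpha must have length r")
  if (any(alpha < 0 | alpha > 1)) stop("alpha entries must lie in [0, 1]")
  alpha * partition$lower + (1 - alpha) * partition$upper
}

# Correction context: everything the Markov correction needs beyond the fit.
new_correction_ctx <- function(partition, transitions, alpha) {
  stopifnot(inherits(partition, "state_partition"),
            inherits(transitions, "transition_model"))
  structure(list(partition = partition, transitions = transitions,
                 alpha = as.numeric(alpha)),
            class = "correction_ctx")
}

#' Markov-corrected in-sample series
#'
#' Adds the expected whitened residual correction to the grey fitted values:
#' `xtilde(t) = xhat(t) + sum_i a_i(t-1) v_i`, where in-sample `a(t-1)` is
#' the indicator of the observed residual state at `t - 1` propagated one
#' step through `P(1)`, and `v` is the whitened interval vector. The anchor
#' (t = 1) and the first labeled point (t = 2, which has no labeled
#' predecessor) are returned uncorrected.
#'
#' @param fit a [gm11] fit.
#' @param partition partition of `residuals(fit)[-1]`.
#' @param transitions one-step [estimate_transitions] model.
#' @param alpha whitening coefficients in `[0, 1]^r`.
#' @return numeric vector of length `n`: the corrected fitted series.
#' @export
corrected_series <- function(fit, partition, transitions, alpha) {
  v <- whiten(partition, alpha)
  P <- transitions$matrix
  out <- fit$fitted
  n <- fit$n
  lab <- partition$labels             # lab[k] is the state at time k + 1
  for (t in 3:n) {
    a0 <- numeric(partition$r)
    a0[lab[t - 2L]] <- 1
    out[t] <- fit$fitted[t] + sum(propagate(a0, P) * v)
  }
  out
}

#' Markov-corrected forecasts
#'
#' Beyond the sample the state is no longer observed: the chain starts from
#' the indicator of the last in-sample residual state and is propagated `h`
#' steps through `P(1)` for the `h`-th forecast, whose correction is the
#' probability-weighted whitened value.
#'
#' @inheritParams corrected_series
#' @param horizon number of steps ahead (>= 0).
#' @return numeric vector of length `horizon`.
#' @export
forecast_corrected <- function(fit, partition, transitions, alpha, horizon) {
  if (horizon < 0) stop("horizon must be >= 0")
  if (horizon == 0) return(numeric(0))
  v <- whiten(partition, alpha)
  base <- forecast_gm11(fit, horizon)
  a <- numeric(partition$r)
  a[partition$labels[length(partition$labels)]] <- 1
  out <- numeric(horizon)
  for (h in seq_len(horizon)) {
    a <- propagate(a, transitions$matrix)
    out[h] <- base[h] + sum(a * v)
  }
  out
}
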