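#' Accumulated generating operation (AGO)
#'
#' Cumulative sum of the raw series: the first-order accumulation `x1` that
#' smooths randomness before the grey model is fitted.
#'
#' @param values non-empty numeric vector.
#' @return numeric vector of the same length; element `j` is the sum of the
#'   first `j` inputs.
#' @examples
#' ago(c(2.3, 3, 3.3))  # 2.3 5.3 8.6
#' @export
ago <- function(values) {
  if (!length(values)) stop("empty input")
  cumsum(as.numeric(values))
}

#' Background (mean-generated) sequence
#'
#' Consecutive-pair averages of the accumulated series,
#' `z1(k) = (x1(k-1) + x1(k)) / 2`, used as the regressor in the grey
#' difference equation.
#'
#' @param x1 accumulated series of length >= 2.
#' @return numeric vector of length `length(x1) - 1`.
#' @examples
#' mean_sequence(c(2.3, 5.3, 8.6))  # 3.8 6.95
#' @export
mean_sequence <- function(x1) {
  n <- length(x1)
  if (n < 2L) stop("need at least 2 accumulated values")
  (x1[-1L] + x1[-n]) / 2
}

#' Fit the GM(1,1) grey model
#'
#' Estimates the developing coefficient `a` and grey action `b` of the grey
#' difference equation `x0(j) + a * z1(j) = b` (j = 2..n) by least squares on
#' the design matrix with rows `(-z1(j), 1)`, then restores fitted values of
#' the raw series through the model's exponential time response. The first
#' fitted value is anchored at the first observation, so its residual is
#' structurally zero.
#'
#' @param series an [obs_series] or a positive numeric vector (n >= 4).
#' @return An object of class `"gm11"`: a list with components
#'   \describe{
#'     \item{a, b}{developing coefficient and grey action.}
#'     \item{fitted}{restored series `xhat0`, anchored at the first point.}
#'     \item{residuals}{signed errors `x0 - xhat0` (first element 0).}
#'     \item{series}{the input series.}
#'   }
#'   Supported methods: `print`, `summary`, `coef`, `fitted`, `residuals`,
#'   `predict`, `plot`.
#' @examples
#' fit <- gm11(example_series("HD"))
#' coef(fit)
#' predict(fit, horizon = 3)
#' @export
gm11 <- function(series) {
  series <- as_obs_series(series)
  x0 <- series$values
  n <- length(x0)
  z1 <- mean_sequence(ago(x0))
  B <- cbind(-z1, 1)
  Y <- x0[-1L]
  qrB <- qr(B)
  if (qrB$rank < 2L)
    stop("singular normal equations: background sequence is degenerate")
  ab <- qr.coef(qrB, Y)
  fit <- structure(
    list(a = unname(ab[1L]), b = unname(ab[2L]), x0_first = x0[1L],
         n = n, series = series, call = match.call()),
    class = "gm11")
  fit$fitted <- vapply(0:(n - 1L), function(i) restore_gm11(fit, i), 0)
  if (any(!is.finite(fit$fitted)))
    stop("non-finite restored values (|a| too large for the sample span)")
  fit$residuals <- x0 - fit$fitted
  fit
}

#' Restored (fitted) value of a GM(1,1) model at lag i
#'
#' Evaluates the grey model's restored raw value
#' `xhat0(i+1) = (x0(1) - b/a) * (1 - exp(a)) * exp(-a * i)` for `i >= 1`;
#' `i = 0` returns the anchor `x0(1)`. For `|a| < 1e-12` the analytic
#' `a -> 0` limit `b` is returned instead of the 0/0 form.
#'
#' @param fit a [gm11] fit.
#' @param i non-negative integer lag (0 is the anchor year).
#' @return the restored value, a single number.
#' @export
restore_gm11 <- function(fit, i) {
  if (i < 0) stop("i must be >= 0")
  if (i == 0) return(fit$x0_first)
  a <- fit$a
  if (abs(a) < 1e-12) return(fit$b)
  (fit$x0_first - fit$b / a) * (1 - exp(a)) * exp(-a * i)
}

#' Out-of-sample GM(1,1) forecasts
#'
#' Continues the restored exponential beyond the sample.
#'
#' @param fit a [gm11] fit.
#' @param horizon number of steps ahead (>= 0).
#' @return numeric vector of length `horizon` (forecast years are
#'   `max(years) + 1:horizon`).
#' @export
forecast_gm11 <- function(fit, horizon) {
  if (horizon < 0) stop("horizon must be >= 0")
  if (horizon == 0) return(numeric(0))
  vapply(fit$n - 1L + seq_len(horizon), function(i) restore_gm11(fit, i), 0)
}

#' @export
coef.gm11 <- function(object, ...) c(a = object$a, b = object$b)

#' @export
fitted.gm11 <- function(object, ...) object$fitted

#' @export
residuals.gm11 <- function(object, ...) object$residuals

#' @rdname forecast_gm11
#' @param object a [gm11] fit.
#' @param ... unused.
#' @export
predict.gm11 <- function(object, horizon = 1L, ...) {
  f <- forecast_gm11(object, horizon)
  stats::setNames(f, object$series$years[object$n] + seq_len(horizon))
}

#' @export
print.gm11 <- function(x, ...) {
  cat("GM(1,1) grey model on '", x$series$name, "' (n = ", x$n, ")\n", sep = "")
  cat(sprintf("  developing coefficient a = %.6g\n  grey action          b = %.6g\n",
              x$a, x$b))
  invisible(x)
}

#' @export
summary.gm11 <- function(object, ...) {
  s <- object$series
  out <- list(fit = object,
              mape = mape(s$values, object$fitted),
              rmse = rmse(s$values, object$fitted))
  class(out) <- "summary.gm11"
  out
}

#' @export
print.summary.gm11 <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  in-sample MAPE %.2f%%, RMSE %.4f\n", x$mape, x$rmse))
  invisible(x)
}

#' @export
plot.gm11 <- function(x, horizon = 0L, ...) {
  s <- x$series
  yrs <- s$years
  fyrs <- if (horizon > 0) yrs[x$n] + seq_len(horizon) else integer(0)
  fc <- forecast_gm11(x, horizon)
  ylim <- range(s$values, x$fitted, fc)
  plot(yrs, s$values, type = "b", pch = 16, xlab = "year",
       ylab = s$name, xlim = range(c(yrs, fyrs)), ylim = ylim, ...)
  graphics::lines(c(yrs, fyrs), c(x$fitted, fc), col = 2, lty = 2, type = "b",
                  pch = 1)
  graphics::legend("topleft", bty = "n", pch = c(16, 1), col = c(1, 2),
                   legend = c("observed", "GM(1,1)"))
  invisible(x)
}
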