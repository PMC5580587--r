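#' Mean absolute percentage error
#'
#' `100/n * sum(|actual - predicted| / actual)`, in percent. `skip_first`
#' drops the first point, which in a grey fit carries a structurally zero
#' anchor error; the package default keeps it (see the methods vignette for
#' the calibration behind that choice).
#'
#' @param actual positive numeric vector.
#' @param predicted numeric vector of the same length.
#' @param skip_first drop the first point before averaging?
#' @return percentage, a single number.
#' @examples
#' mape(10, 11)            # 10
#' @export
mape <- function(actual, predicted, skip_first = FALSE) {
  if (length(actual) != length(predicted)) stop("length mismatch")
  if (skip_first) { actual <- actual[-1L]; predicted <- predicted[-1L] }
  if (any(actual == 0)) stop("MAPE undefined for zero actual values")
  100 * mean(abs(actual - predicted) / abs(actual))
}

#' Root mean square error
#'
#' @inheritParams mape
#' @return a single non-negative number.
#' @examples
#' rmse(c(0, 0), c(3, 4))  # sqrt(12.5)
#' @export
rmse <- function(actual, predicted, skip_first = FALSE) {
  if (length(actual) != length(predicted)) stop("length mismatch")
  if (skip_first) { actual <- actual[-1L]; predicted <- predicted[-1L] }
  sqrt(mean((actual - predicted)^2))
}
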