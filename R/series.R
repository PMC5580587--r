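#' Annual observation series
#'
#' Container for a univariate annual series of strictly positive rates, the
#' raw input of the grey model. Values are typically per-mille two-week
#' hospitalization rates, but any positive-valued annual indicator
#' is accepted.
#'
#' @param values numeric vector of strictly positive observations.
#' @param years integer vector of consecutive years, same length as
#'   `values`. Defaults to `1:length(values)`.
#' @param name label for the series (used in printing and reports).
#' @return An object of class `"obs_series"`: a list with elements
#'   `name`, `years` and `values`.
#' @examples
#' obs_series(c(2.3, 3, 3.3, 7.6, 8.2), years = 2006:2010, name = "DD")
#' @export
obs_series <- function(values, years = seq_along(values), name = "series") {
  values <- as.numeric(values)
  years <- as.integer(years)
  if (length(values) < 4L)
    stop("an observation series needs at least 4 points, got ", length(values))
  if (length(years) != length(values))
    stop("'years' and 'values' must have the same length")
  if (anyNA(values) || anyNA(years))
    stop("missing values are not supported")
  if (any(values <= 0)) {
    bad <- years[values <= 0][1L]
    stop("all values must be strictly positive (grey-model precondition); ",
         "offending year: ", bad)
  }
  if (any(diff(years) != 1L))
    stop("'years' must increase by exactly 1")
  structure(list(name = as.character(name)[1L], years = years, values = values),
            class = "obs_series")
}

#' @export
print.obs_series <- function(x, ...) {
  cat("Annual series '", x$name, "' (", length(x$values), " points, ",
      x$years[1L], "-", x$years[length(x$years)], ")\n", sep = "")
  print(stats::setNames(x$values, x$years))
  invisible(x)
}

#' @export
as.data.frame.obs_series <- function(x, ...) {
  df <- data.frame(year = x$years, value = x$values)
  names(df)[2L] <- x$name
  df
}

#' @export
length.obs_series <- function(x) length(x$values)

#' Read an annual series from CSV or JSON
#'
#' Reads one column of a multi-series file. CSV files need a header with a
#' `year` column; JSON files hold an object of equal-length arrays with a
#' `"year"` key mirroring the same schema.
#'
#' @param path path to a `.csv` or `.json` file.
#' @param column name of the series column to extract.
#' @param format `"auto"` (by file extension), `"csv"` or `"json"`.
#' @return An [obs_series] named after `column`.
#' @examples
#' path <- system.file("extdata", "urban_hospitalization_2006_2015.csv",
#'                     package = "tmcgm")
#' read_series(path, "HD")
#' @export
read_series <- function(path, column, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  tab <- if (format == "json") {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, check.names = FALSE)
  }
  if (!"year" %in% names(tab)) stop("input must contain a 'year' column")
  if (missing(column) || !column %in% names(tab))
    stop("column '", if (missing(column)) "<missing>" else column,
         "' not present; available: ",
         paste(setdiff(names(tab), "year"), collapse = ", "))
  vals <- suppressWarnings(as.numeric(tab[[column]]))
  if (anyNA(vals)) stop("column '", column, "' does not parse as numeric")
  obs_series(vals, years = tab$year, name = column)
}

#' Write one or more annual series to CSV or JSON
#'
#' @param ... one or more [obs_series] objects sharing the same years.
#' @param path output path; `.json` extension selects JSON, anything else CSV.
#' @return `path`, invisibly.
#' @export
write_series <- function(..., path) {
  ser <- list(...)
  if (!length(ser)) stop("no series given")
  yrs <- ser[[1L]]$years
  for (s in ser) {
    if (!inherits(s, "obs_series")) stop("all inputs must be obs_series")
    if (!identical(s$years, yrs)) stop("all series must share the same years")
  }
  cols <- c(list(year = yrs), stats::setNames(lapply(ser, `[[`, "values"),
                                              vapply(ser, `[[`, "", "name")))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cols, path, digits = NA, auto_unbox = FALSE)
  } else {
    utils::write.csv(as.data.frame(cols, check.names = FALSE), path,
                     row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Bundled urban two-week hospitalization rates, 2006--2015
#'
#' Convenience loader for the example data shipped with the package: annual
#' urban two-week hospitalization rates (per mille) in China for diabetes
#' (`"DD"`), heart disease (`"HD"`) and cerebrovascular disease (`"CD"`),
#' 2006--2015, from the China Health Statistics Yearbook.
#'
#' @param column one of `"DD"`, `"HD"`, `"CD"`.
#' @return An [obs_series] of 10 annual values.
#' @examples
#' example_series("DD")
#' @export
example_series <- function(column = c("DD", "HD", "CD")) {
  column <- match.arg(column)
  read_series(system.file("extdata", "urban_hospitalization_2006_2015.csv",
                          package = "tmcgm", mustWork = TRUE), column)
}

#' Generate a synthetic grey series, optionally with Markov-switching noise
#'
#' The noiseless branch inverts the grey difference equation
#' `x0(j) + a * z1(j) = b`: given the running cumulative sum `x1` and the
#' background value `z1(j) = x1(j-1) + x0(j)/2`, each new point solves
#' `x0(j) = (b - a * x1(j-1)) / (1 + a/2)` exactly, so a GM(1,1) least-squares
#' fit recovers `(a, b)` to machine precision. The noise branch then adds the
#' offset of a state drawn from a Markov chain over `noise_states`.
#'
#' The noise chain starts from the uniform distribution over its states (a
#' stationary-agnostic default for the short chains simulated here); its
#' transition matrix defaults to i.i.d. draws with the given weights, i.e.
#' every row equals the normalized weight vector. Pass an explicit
#' `transition` matrix for persistent or alternating regimes.
#'
#' @param a developing coefficient of the generating model (`a != -2`).
#' @param b grey action (level) of the generating model.
#' @param x1 first value of the series (strictly positive).
#' @param n series length (>= 4).
#' @param noise_states optional list of `c(weight, offset)` pairs (or a
#'   2-column matrix, one row per state) defining additive noise regimes.
#' @param transition optional row-stochastic matrix over the noise states;
#'   default: rows all equal to the normalized weights.
#' @param seed optional integer; seeded runs are bit-reproducible.
#' @param years years to attach, default `1:n`.
#' @param name series label.
#' @return An [obs_series]; with noise, attributes `"noise_state"` (the drawn
#'   state path) and `"clean"` (the noiseless values) are attached.
#' @examples
#' s <- sim_grey_series(a = -0.2, b = 1, x1 = 1, n = 8)
#' coef(gm11(s))   # recovers a = -0.2, b = 1
#' @export
sim_grey_series <- function(a, b, x1, n, noise_states = NULL, transition = NULL,
                            seed = NULL, years = seq_len(n), name = "sim") {
  if (n < 4L) stop("n must be at least 4")
  if (abs(1 + a / 2) < 1e-12) stop("a = -2 makes the recurrence degenerate")
  x <- numeric(n)
  x[1L] <- x1
  cum <- x1
  for (j in 2:n) {
    x[j] <- (b - a * cum) / (1 + a / 2)
    cum <- cum + x[j]
  }
  clean <- x
  states <- NULL
  if (!is.null(noise_states)) {
    ns <- if (is.matrix(noise_states)) noise_states else
      do.call(rbind, lapply(noise_states, function(p) as.numeric(p)))
    if (ncol(ns) != 2L) stop("noise_states must be (weight, offset) pairs")
    k <- nrow(ns)
    w <- ns[, 1L] / sum(ns[, 1L])
    P <- if (is.null(transition)) matrix(w, k, k, byrow = TRUE) else transition
    if (!is.matrix(P) || any(dim(P) != k) ||
        any(abs(rowSums(P) - 1) > 1e-8) || any(P < 0))
      stop("'transition' must be a ", k, "x", k, " row-stochastic matrix")
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(as.integer(seed))
    }
    states <- integer(n)
    states[1L] <- sample.int(k, 1L)                # uniform initial state
    for (j in 2:n) states[j] <- sample.int(k, 1L, prob = P[states[j - 1L], ])
    x <- x + ns[states, 2L]
  }
  if (any(x <= 0))
    stop("parameters produce a non-positive value at position ",
         which(x <= 0)[1L])
  out <- obs_series(x, years = years, name = name)
  if (!is.null(states)) {
    attr(out, "noise_state") <- states
    attr(out, "clean") <- clean
  }
  out
}

# Coerce numeric input to obs_series where a series is expected.
as_obs_series <- function(x, name = "series") {
  if (inherits(x, "obs_series")) return(x)
  if (is.numeric(x)) return(obs_series(x, name = name))
  stop("expected an obs_series or a numeric vector")
}
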