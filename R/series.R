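#' Build a uniformly sampled time series
#'
#' The universal signal container of the package is a plain tibble with two
#' columns, `time` (seconds from acquisition start) and `value`
#' (signal units, dimensionless after baseline normalization). A *uniform*
#' series has a constant sampling interval `dt`; most pipeline stages require
#' one and check for it.
#'
#' @param values Numeric vector of samples (finite).
#' @param t0 Time of the first sample, seconds.
#' @param dt Sampling interval, seconds (> 0).
#' @return A tibble with columns `time` and `value`.
#' @examples
#' uniform_series(sin(seq(0, 2 * pi, length.out = 50)), t0 = 0, dt = 0.1)
#' @export
uniform_series <- function(values, t0 = 0, dt = 0.05) {
  stopifnot(is.numeric(values), length(values) >= 1)
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    stop("`dt` must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("series values must be finite", call. = FALSE)
  }
  tibble::tibble(time = t0 + (seq_along(values) - 1) * dt, value = as.numeric(values))
}

#' Validate a raw (possibly irregular) trace
#'
#' Raw traces come from linescan or ultrasound acquisitions and may be
#' irregularly sampled; times must be strictly increasing and values finite.
#'
#' @param trace Data frame with columns `time` and `value`.
#' @param min_len Minimum number of samples required.
#' @return The trace as a tibble, invisibly validated.
#' @export
as_raw_trace <- function(trace, min_len = 2) {
  trace <- check_series_frame(trace)
  if (nrow(trace) < min_len) {
    stop("trace must have at least ", min_len, " samples", call. = FALSE)
  }
  if (any(diff(trace$time) <= 0)) {
    stop("trace times must be strictly increasing", call. = FALSE)
  }
  trace
}

# shared column/type validation for series data frames
check_series_frame <- function(x, arg = deparse(substitute(x))) {
  if (!is.data.frame(x)) {
    stop("`", arg, "` must be a data frame with columns `time` and `value`",
         call. = FALSE)
  }
  if (!all(c("time", "value") %in% names(x))) {
    stop("`", arg, "` must have columns `time` and `value`", call. = FALSE)
  }
  if (!is.numeric(x$time) || !is.numeric(x$value)) {
    stop("`time` and `value` must be numeric", call. = FALSE)
  }
  if (any(!is.finite(x$time)) || any(!is.finite(x$value))) {
    stop("`", arg, "` contains non-finite entries", call. = FALSE)
  }
  tibble::as_tibble(x[c("time", "value", setdiff(names(x), c("time", "value")))])
}

#' Sampling interval of a uniform series
#'
#' @param series Data frame with columns `time` and `value` on a uniform grid.
#' @param tol Relative tolerance on grid uniformity.
#' @return The sampling interval `dt` in seconds.
#' @export
series_dt <- function(series, tol = 1e-6) {
  series <- check_series_frame(series)
  if (nrow(series) < 2) stop("series too short to infer `dt`", call. = FALSE)
  d <- diff(series$time)
  dt <- stats::median(d)
  if (dt <= 0 || any(abs(d - dt) > tol * max(dt, 1))) {
    stop("series is not uniformly sampled", call. = FALSE)
  }
  dt
}

is_uniform_series <- function(series, tol = 1e-6) {
  ok <- try(series_dt(series, tol), silent = TRUE)
  !inherits(ok, "try-error")
}

# check two series share the same grid
check_same_grid <- function(a, b, tol = 1e-8) {
  if (nrow(a) != nrow(b) || any(abs(a$time - b$time) > tol)) {
    stop("series grids do not match", call. = FALSE)
  }
  invisible(TRUE)
}
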