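#' Interpolate a trace onto a uniform grid
#'
#' Resamples a (possibly irregular) trace onto the grid
#' `t0 + k * dt` covering the trace span, using shape-preserving piecewise
#' cubic Hermite interpolation (pchip). pchip is monotone and does not
#' overshoot, which keeps onset kinetics of calcium and vascular transients
#' intact; ordinary cubic splines can ring at sharp rises.
#'
#' Calcium traces are conventionally interpolated at 10 ms when extracted and
#' re-interpolated at 50 ms before transfer-function fitting; RBC velocity at
#' 200 ms; power-Doppler at 50 ms (20 Hz).
#'
#' @param trace Data frame with columns `time`, `value`; strictly increasing
#'   times.
#' @param dt Target sampling interval, seconds; must not exceed the trace span.
#' @return A uniform tibble (`time`, `value`); no extrapolation beyond the
#'   trace span.
#' @examples
#' tr <- tibble::tibble(time = c(0, 0.3, 0.7, 1), value = c(0, 0.6, 1.4, 2))
#' interpolate_uniform(tr, dt = 0.1)
#' @export
interpolate_uniform <- function(trace, dt) {
  trace <- as_raw_trace(trace)
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    stop("`dt` must be a single positive number", call. = FALSE)
  }
  span <- trace$time[nrow(trace)] - trace$time[1]
  if (dt > span) {
    stop("`dt` (", dt, " s) exceeds the trace span (", span, " s)", call. = FALSE)
  }
  n_out <- floor(span / dt + 1e-9) + 1
  grid <- trace$time[1] + (seq_len(n_out) - 1) * dt
  # guard rounding drift past the last sample
  grid <- pmin(grid, trace$time[nrow(trace)])
  vals <- signal::interp1(trace$time, trace$value, grid, method = "pchip")
  tibble::tibble(time = grid, value = as.numeric(vals))
}

#' Baseline-normalize a series
#'
#' Subtracts the mean of the pre-stimulus baseline window (the `baseline_len`
#' seconds immediately preceding `stimulus_onset`), optionally dividing by it
#' to obtain a relative change. Calcium traces use the absolute form
#' (delta-Ca); vascular traces use the relative form (e.g. delta-RBC/RBC or
#' delta-PD/PD).
#'
#' @param series Uniform series tibble.
#' @param stimulus_onset Stimulus onset, seconds from acquisition start.
#' @param baseline_len Baseline window length, seconds (default 5).
#' @param relative If `TRUE`, divide by the baseline mean after subtracting.
#' @return Baseline-normalized tibble on the same grid.
#' @export
baseline_delta <- function(series, stimulus_onset, baseline_len = 5,
                           relative = FALSE) {
  series <- check_series_frame(series)
  lo <- stimulus_onset - baseline_len
  tol <- 1e-9
  in_window <- series$time >= lo - tol & series$time < stimulus_onset - tol
  if (lo < series$time[1] - tol || stimulus_onset > series$time[nrow(series)] + tol ||
      !any(in_window)) {
    stop("baseline window [", lo, ", ", stimulus_onset,
         ") s is not inside the series", call. = FALSE)
  }
  b <- mean(series$value[in_window])
  if (relative) {
    if (abs(b) < .Machine$double.eps^0.5 * max(1, max(abs(series$value)))) {
      stop("baseline mean is zero; relative normalization undefined", call. = FALSE)
    }
    series$value <- (series$value - b) / b
  } else {
    series$value <- series$value - b
  }
  series
}

#' Three-point median filter
#'
#' Replaces every interior sample by the median of itself and its two
#' neighbours; the endpoints are left unchanged. Used to attenuate isolated
#' overestimated RBC-velocity samples.
#'
#' @param series Series tibble with at least 3 samples.
#' @return Filtered tibble on the same grid.
#' @export
median_filter3 <- function(series) {
  series <- check_series_frame(series)
  n <- nrow(series)
  if (n < 3) stop("median filter needs at least 3 samples", call. = FALSE)
  v <- series$value
  interior <- pmax(pmin(v[-c(n - 1, n)], v[-c(1, n)]),
                   pmin(pmax(v[-c(n - 1, n)], v[-c(1, n)]), v[-c(1, 2)]))
  series$value <- c(v[1], interior, v[n])
  series
}

#' Cut a series to the transfer-function fit window
#'
#' Restricts a trace to the window used for fitting and scoring: 5-27 s for
#' 30 s acquisitions and 5-59 s for 60 s acquisitions (times from acquisition
#' start). The output grid starts at the smallest grid point >= the window
#' start; no sub-sample interpolation is performed.
#'
#' @param series Uniform series tibble.
#' @param acquisition_len Acquisition length in seconds (30 or 60), or `NULL`
#'   when `window` is given.
#' @param window Optional explicit `c(lo, hi)` override, seconds.
#' @return The sub-series tibble restricted to the window.
#' @export
cut_fit_window <- function(series, acquisition_len = NULL, window = NULL) {
  series <- check_series_frame(series)
  if (is.null(window)) {
    if (is.null(acquisition_len) || !acquisition_len %in% c(30, 60)) {
      stop("`acquisition_len` must be 30 or 60 s (or supply `window`)",
           call. = FALSE)
    }
    window <- if (acquisition_len == 30) c(5, 27) else c(5, 59)
  }
  if (length(window) != 2 || window[1] >= window[2]) {
    stop("`window` must be c(lo, hi) with lo < hi", call. = FALSE)
  }
  tol <- 1e-9
  if (window[1] < series$time[1] - tol ||
      window[2] > series$time[nrow(series)] + tol) {
    stop("fit window [", window[1], ", ", window[2],
         "] s is not contained in the series", call. = FALSE)
  }
  keep <- series$time >= window[1] - tol & series$time <= window[2] + tol
  series[keep, , drop = FALSE]
}

#' Preprocess a raw trace for transfer-function fitting
#'
#' Convenience composition of the standard preprocessing path: interpolation
#' onto a uniform grid, optional 3-point median filtering, baseline
#' normalization over the 5 s preceding stimulus onset, and restriction to
#' the fit window.
#'
#' @param trace Raw trace tibble (`time`, `value`).
#' @param stimulus_onset Stimulus onset, seconds.
#' @param acquisition_len Acquisition length, 30 or 60 s.
#' @param dt Target sampling interval (default 0.05 s, the canonical
#'   "From"-signal grid).
#' @param relative Relative (divide-by-baseline) normalization; use for
#'   vascular traces.
#' @param median3 Apply the 3-point median filter before normalization.
#' @param baseline_len Baseline length in seconds.
#' @return Preprocessed tibble restricted to the fit window.
#' @export
prepare_trace <- function(trace, stimulus_onset, acquisition_len,
                          dt = 0.05, relative = FALSE, median3 = FALSE,
                          baseline_len = 5) {
  out <- interpolate_uniform(trace, dt)
  if (median3) out <- median_filter3(out)
  out <- baseline_delta(out, stimulus_onset, baseline_len, relative = relative)
  cut_fit_window(out, acquisition_len)
}
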