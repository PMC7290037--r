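# Kernel bin weights for discrete causal convolution.
#
# The From signal is treated as a zero-order-hold step function: sample j
# holds its value over [t_j, t_j + dt). The contribution of input bin j to
# the output at grid time t_i integrates the kernel over one bin, so the
# weight at lag m is the exact bin integral
#   w_m = p4 * (P(p1, p2 (m dt - p3)) - P(p1, p2 ((m-1) dt - p3))),  w_0 = 0,
# with P the regularized lower incomplete gamma. The weights sum to p4 as
# n dt grows, so the amplitude parameter keeps a sampling-rate-independent
# meaning, and the response to a unit step matches the closed-form
# incomplete-gamma expression exactly at grid points.
tf_kernel_weights <- function(params, dt, n) {
  edges <- (0:(n - 1)) * dt - params$p3
  cdf <- numeric(n)
  pos <- edges > 0
  cdf[pos] <- stats::pgamma(edges[pos], shape = params$p1, rate = params$p2)
  params$p4 * c(0, diff(cdf))
}

# FFT-based causal convolution of a signal with kernel weights of equal
# length; returns the first length(x) samples (no wrap-around).
fft_causal_conv <- function(fx, w, n, m) {
  fw <- stats::fft(c(w, numeric(m - n)))
  Re(stats::fft(fx * fw, inverse = TRUE))[seq_len(n)] / m
}

# Precompute the FFT of a From signal once per fit; every objective
# evaluation then costs one kernel evaluation plus two FFTs.
make_conv_plan <- function(from_values) {
  n <- length(from_values)
  m <- stats::nextn(2 * n, 2)
  list(n = n, m = m, fx = stats::fft(c(from_values, numeric(m - n))))
}

conv_with_plan <- function(plan, params, dt) {
  w <- tf_kernel_weights(params, dt, plan$n)
  fft_causal_conv(plan$fx, w, plan$n, plan$m)
}

#' Predict a vascular response by convolution
#'
#' Convolves a From signal (canonically a calcium trace on a 50 ms grid, or
#' a stimulus step function) with a transfer-function kernel, then resamples
#' the result onto the grid of the To signal when one is supplied. The From
#' signal is treated as zero before its first sample, which is justified for
#' baseline-subtracted traces.
#'
#' @param from_sig Uniform series tibble (the neuronal / input signal).
#' @param params A [tf_params] kernel.
#' @param to_grid Optional numeric vector of target times (within the From
#'   span), or a series tibble whose `time` column is used. `NULL` keeps the
#'   From grid.
#' @return Prediction tibble (`time`, `value`) with attribute `scale = 1`.
#' @export
convolve_predict <- function(from_sig, params, to_grid = NULL) {
  from_sig <- check_series_frame(from_sig)
  params <- as_tf_params(params)
  if (nrow(from_sig) == 0) stop("empty From signal", call. = FALSE)
  dt <- series_dt(from_sig)
  plan <- make_conv_plan(from_sig$value)
  vals <- conv_with_plan(plan, params, dt)
  out <- tibble::tibble(time = from_sig$time, value = vals)
  if (!is.null(to_grid)) {
    if (is.data.frame(to_grid)) to_grid <- to_grid$time
    tol <- 1e-9
    if (min(to_grid) < out$time[1] - tol || max(to_grid) > out$time[nrow(out)] + tol) {
      stop("`to_grid` extends beyond the span of the From signal", call. = FALSE)
    }
    # exact subsetting when the target grid is a subset of the source grid
    idx <- round((to_grid - out$time[1]) / dt)
    if (all(abs(out$time[1] + idx * dt - to_grid) < tol) &&
        all(idx >= 0 & idx < nrow(out))) {
      out <- tibble::tibble(time = to_grid, value = vals[idx + 1])
    } else {
      out <- tibble::tibble(
        time = to_grid,
        value = as.numeric(signal::interp1(out$time, out$value, to_grid,
                                           method = "pchip")))
    }
  }
  attr(out, "scale") <- 1
  out
}

#' Rescale prediction amplitude against an observed response
#'
#' Finds the scalar k minimizing the sum of squared residuals between
#' k * prediction and the observed trace over a window running from 2 to 8 s
#' after stimulus onset, using a derivative-free bounded line search.
#' The rescaling changes only the amplitude of the prediction; the Pearson
#' coefficient against the observation is unaffected.
#'
#' @param pred Prediction tibble (from [convolve_predict()]).
#' @param observed Observed series tibble on the same grid.
#' @param stimulus_onset Stimulus onset, seconds.
#' @param window Offsets (s) after onset delimiting the cost window,
#'   default `c(2, 8)`.
#' @return Rescaled prediction tibble; the fitted factor is in
#'   `attr(, "scale")`.
#' @export
rescale_amplitude <- function(pred, observed, stimulus_onset,
                              window = c(2, 8)) {
  pred <- check_series_frame(pred)
  observed <- check_series_frame(observed)
  check_same_grid(pred, observed)
  lo <- stimulus_onset + window[1]
  hi <- stimulus_onset + window[2]
  tol <- 1e-9
  keep <- pred$time >= lo - tol & pred$time <= hi + tol
  if (!any(keep)) {
    stop("rescale window [", lo, ", ", hi, "] s not inside the series",
         call. = FALSE)
  }
  p <- pred$value[keep]
  o <- observed$value[keep]
  if (all(abs(p) < .Machine$double.eps)) {
    stop("prediction is identically zero on the rescale window", call. = FALSE)
  }
  cost <- function(k) sum((k * p - o)^2)
  # derivative-free bounded line search; the bracket is a generous
  # data-magnitude window around zero
  kmax <- 100 * max(abs(o), max(abs(p))) / max(abs(p))
  k <- stats::optimize(cost, c(-kmax, kmax), tol = 1e-12 * max(1, kmax))$minimum
  out <- pred
  out$value <- k * out$value
  attr(out, "scale") <- k
  out
}

#' Pearson correlation between two series
#'
#' The product-moment correlation of the two value sequences; the study's
#' universal metric of prediction quality.
#'
#' @param a,b Series tibbles on the same grid, length >= 3, nonzero variance.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson <- function(a, b) {
  a <- check_series_frame(a)
  b <- check_series_frame(b)
  check_same_grid(a, b)
  if (nrow(a) < 3) stop("need at least 3 samples for a correlation", call. = FALSE)
  if (stats::sd(a$value) == 0 || stats::sd(b$value) == 0) {
    stop("zero-variance input: correlation undefined", call. = FALSE)
  }
  stats::cor(a$value, b$value)
}

#' Sum of squared residuals between prediction and observation
#'
#' @param pred,observed Series tibbles on the same grid.
#' @return Nonnegative scalar, `sum((pred - observed)^2)`.
#' @export
sum_squared_residuals <- function(pred, observed) {
  pred <- check_series_frame(pred)
  observed <- check_series_frame(observed)
  check_same_grid(pred, observed)
  sum((pred$value - observed$value)^2)
}
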