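#' Transfer-function parameters
#'
#' The impulse-response kernel linking neuronal activity to the vascular
#' response is a shifted gamma density,
#' \deqn{TF(t) = H(t - p_3)\, p_4 \frac{(t - p_3)^{p_1 - 1} p_2^{p_1}
#'   e^{-p_2 (t - p_3)}}{\Gamma(p_1)},}
#' with shape \eqn{p_1} (dimensionless), rate \eqn{p_2} (1/s), time shift
#' \eqn{p_3} (s; a vascular delay), and amplitude \eqn{p_4} (the kernel's
#' integral, in output units per unit input times seconds). \eqn{H} is the
#' Heaviside step. A fitted kernel is only accepted when \eqn{p_1 > 1}, so
#' the curve starts at zero at \eqn{t = p_3} and is smooth beyond it.
#'
#' @param p1 Shape, > 0 (valid kernels need p1 > 1).
#' @param p2 Rate, 1/seconds, > 0.
#' @param p3 Time shift, seconds, >= 0 (1e-3 is the conventional numerical
#'   floor standing in for zero).
#' @param p4 Amplitude scale, > 0.
#' @return An object of class `tf_params`.
#' @examples
#' tf_params(1.3, 0.5, 0.27, 0.19) # a standard calcium -> RBC-velocity kernel
#' @export
tf_params <- function(p1, p2, p3, p4) {
  p <- c(p1 = p1, p2 = p2, p3 = p3, p4 = p4)
  if (length(p) != 4 || any(!is.finite(p))) {
    stop("all four parameters must be finite numbers", call. = FALSE)
  }
  if (p1 <= 0 || p2 <= 0 || p4 <= 0) {
    stop("p1, p2 and p4 must be positive", call. = FALSE)
  }
  if (p3 < 0) stop("time shift p3 must be >= 0", call. = FALSE)
  structure(as.list(p), class = "tf_params")
}

#' @export
print.tf_params <- function(x, ...) {
  cat(sprintf(
    "<tf_params> shape p1 = %.4g, rate p2 = %.4g /s, shift p3 = %.4g s, amplitude p4 = %.4g\n",
    x$p1, x$p2, x$p3, x$p4))
  if (x$p1 > 1) {
    cat(sprintf("  peak time: %.3g s\n", tf_peak_time(x)))
  }
  invisible(x)
}

#' @export
as.data.frame.tf_params <- function(x, ...) {
  as.data.frame(tibble::as_tibble(unclass(x)))
}

#' Tidy a set of transfer-function parameters
#'
#' @param x A `tf_params` object.
#' @param ... Unused.
#' @return One-row tibble with columns `p1`, `p2`, `p3`, `p4`.
#' @method tidy tf_params
#' @export
tidy.tf_params <- function(x, ...) {
  tibble::as_tibble(unclass(x))
}

#' Evaluate the transfer function on a time grid
#'
#' The kernel is `p4` times the gamma density with shape `p1` and rate `p2`,
#' delayed by `p3`; it is exactly zero for `t <= p3`.
#'
#' @param params A [tf_params] object.
#' @param times Numeric vector of times, seconds.
#' @return Numeric vector of kernel values at `times`.
#' @examples
#' evaluate_tf(tf_params(1.3, 0.5, 0.27, 0.19), seq(0, 10, 0.001))
#' @export
evaluate_tf <- function(params, times) {
  params <- as_tf_params(params)
  stopifnot(is.numeric(times), all(is.finite(times)))
  u <- times - params$p3
  out <- numeric(length(times))
  pos <- u > 0
  out[pos] <- params$p4 * stats::dgamma(u[pos], shape = params$p1, rate = params$p2)
  out
}

#' Peak time of a transfer function
#'
#' Closed form for the mode of the shifted gamma kernel:
#' `(p1 - 1) / p2 + p3`. Defined only for `p1 > 1` (otherwise the mode sits
#' at the onset and the kernel is not a valid fitted TF).
#'
#' @param params A [tf_params] object with `p1 > 1`.
#' @return Peak time in seconds.
#' @examples
#' tf_peak_time(tf_params(1.3, 0.5, 0.27, 0.19)) # 0.87 s
#' @export
tf_peak_time <- function(params) {
  params <- as_tf_params(params)
  if (params$p1 <= 1) {
    stop("peak time undefined: p1 <= 1 puts the mode at the onset", call. = FALSE)
  }
  (params$p1 - 1) / params$p2 + params$p3
}

#' Check validity of a fitted transfer function
#'
#' A candidate kernel is accepted only when its curve starts at the origin
#' (value zero at the time shift) and is at least twice differentiable beyond
#' it. For the shifted gamma this is equivalent to `p1 > 1`: at `p1 < 1` the
#' kernel diverges at onset and at `p1 = 1` it jumps to `p2 * p4`.
#'
#' @param params A [tf_params] object.
#' @param eps Numerical margin above 1 for the shape parameter.
#' @return Logical flag.
#' @export
check_validity <- function(params, eps = 1e-6) {
  params <- as_tf_params(params)
  params$p1 > 1 + eps
}

# accept tf_params or an unclassed list/vector with the right names
as_tf_params <- function(x) {
  if (inherits(x, "tf_params")) return(x)
  if (is.numeric(x) && length(x) == 4) {
    return(tf_params(x[[1]], x[[2]], x[[3]], x[[4]]))
  }
  if (is.list(x) && all(c("p1", "p2", "p3", "p4") %in% names(x))) {
    return(tf_params(x$p1, x$p2, x$p3, x$p4))
  }
  stop("cannot interpret input as transfer-function parameters", call. = FALSE)
}
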