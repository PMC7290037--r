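#' Configuration of the stochastic annealing fit protocol
#'
#' Controls the multi-start simulated-annealing optimization of the four
#' kernel parameters. Defaults follow the protocol used throughout the
#' package: box bounds 1e-3 to 10 on all parameters (the upper bound may be
#' raised to 20 for slow kernels), the first gamma component of the canonical
#' single-gamma HRF (6, 1, 0.001, 1) as the initial set, 50 annealing runs
#' per iteration, and at most 3 iterative restarts from the incumbent best
#' set.
#'
#' @param lower,upper Box bounds, scalars or length-4 vectors
#'   (p1, p2, p3, p4). Calcium-to-power-Doppler fits conventionally restrict
#'   the time shift with `upper = c(10, 10, 0.5, 10)`.
#' @param initial Initial parameter set for the first iteration.
#' @param runs_per_iteration Annealing runs per iteration (50-100 typical).
#' @param max_iterations Hard cap on iterative restarts.
#' @param rel_tol Relative Pearson improvement below which the protocol
#'   stops ("no longer improves in a significant manner").
#' @param t0 Initial annealing temperature.
#' @param cooling Exponential cooling factor per move (temperature at move k
#'   is `t0 * cooling^k`).
#' @param n_moves Metropolis moves per annealing run.
#' @param polish Run a short derivative-free Nelder-Mead refinement from the
#'   annealing endpoint of each run (clamped to the bounds).
#' @param polish_maxit Simplex iterations for the refinement.
#' @param seed Master seed; per-run seeds are derived deterministically so
#'   the nondeterministic algorithm is reproducible end to end.
#' @return A `fit_config` list.
#' @export
fit_config <- function(lower = 1e-3, upper = 10,
                       initial = c(6, 1, 0.001, 1),
                       runs_per_iteration = 50, max_iterations = 3,
                       rel_tol = 1e-3,
                       t0 = 100, cooling = 0.95, n_moves = 600,
                       polish = TRUE, polish_maxit = 250,
                       seed = 1L) {
  lower <- rep_len(as.numeric(lower), 4)
  upper <- rep_len(as.numeric(upper), 4)
  if (any(lower <= 0) || any(lower >= upper)) {
    stop("bounds must satisfy 0 < lower < upper", call. = FALSE)
  }
  initial <- rep_len(as.numeric(initial), 4)
  if (any(initial < lower) || any(initial > upper)) {
    stop("initial parameter set must lie within the bounds", call. = FALSE)
  }
  if (runs_per_iteration < 1 || max_iterations < 1) {
    stop("runs_per_iteration and max_iterations must be >= 1", call. = FALSE)
  }
  structure(list(
    lower = lower, upper = upper, initial = initial,
    runs_per_iteration = as.integer(runs_per_iteration),
    max_iterations = as.integer(max_iterations),
    rel_tol = rel_tol, t0 = t0, cooling = cooling,
    n_moves = as.integer(n_moves),
    polish = isTRUE(polish), polish_maxit = as.integer(polish_maxit),
    seed = as.integer(seed)
  ), class = "fit_config")
}

#' @export
print.fit_config <- function(x, ...) {
  cat("<fit_config>\n")
  cat(sprintf("  bounds: [%s] .. [%s]\n",
              paste(signif(x$lower, 3), collapse = ", "),
              paste(signif(x$upper, 3), collapse = ", ")))
  cat(sprintf("  initial: (%s)\n", paste(signif(x$initial, 3), collapse = ", ")))
  cat(sprintf("  %d runs x <= %d iterations, %d moves/run, T0 = %g, cooling = %g\n",
              x$runs_per_iteration, x$max_iterations, x$n_moves, x$t0, x$cooling))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Shared objective machinery: SSR of the convolution prediction against the
# To trace, with the From-signal FFT and To-grid interpolation weights
# precomputed once per fit.
make_fit_objective <- function(from_sig, to_sig) {
  from_sig <- check_series_frame(from_sig)
  to_sig <- check_series_frame(to_sig)
  dt <- series_dt(from_sig)
  tol <- 1e-6
  if (min(to_sig$time) < from_sig$time[1] - tol ||
      max(to_sig$time) > from_sig$time[nrow(from_sig)] + tol) {
    stop("From and To signals span mismatched windows", call. = FALSE)
  }
  plan <- make_conv_plan(from_sig$value)
  # linear resampling weights From grid -> To grid (exact when grids align)
  pos <- (to_sig$time - from_sig$time[1]) / dt
  i0 <- pmin(pmax(floor(pos + 1e-9), 0), plan$n - 1)
  wfrac <- pmin(pmax(pos - i0, 0), 1)
  i0 <- i0 + 1L
  i1 <- pmin(i0 + 1L, plan$n)
  to_vals <- to_sig$value
  list(
    dt = dt,
    to_vals = to_vals,
    predict = function(par) {
      v <- conv_with_plan(plan, list(p1 = par[1], p2 = par[2],
                                     p3 = par[3], p4 = par[4]), dt)
      v[i0] * (1 - wfrac) + v[i1] * wfrac
    },
    ssr = function(par) {
      v <- conv_with_plan(plan, list(p1 = par[1], p2 = par[2],
                                     p3 = par[3], p4 = par[4]), dt)
      p <- v[i0] * (1 - wfrac) + v[i1] * wfrac
      sum((p - to_vals)^2)
    }
  )
}

# fold a proposal back into the box (triangle-wave reflection)
reflect_into_box <- function(x, lower, upper) {
  r <- upper - lower
  y <- (x - lower) %% (2 * r)
  lower + pmin(y, 2 * r - y)
}

# one Metropolis simulated-annealing descent with exponential cooling;
# assumes the RNG is already seeded
sa_minimize <- function(obj, init, lower, upper, t0, cooling, n_moves) {
  x <- init
  fx <- obj(x)
  best <- x
  fbest <- fx
  range <- upper - lower
  for (k in seq_len(n_moves)) {
    temp <- t0 * cooling^k
    step <- range * max(sqrt(temp / t0), 0.01)
    prop <- reflect_into_box(x + stats::rnorm(4) * step, lower, upper)
    fp <- obj(prop)
    if (fp <= fx || stats::runif(1) < exp(-(fp - fx) / temp)) {
      x <- prop
      fx <- fp
    }
    if (fx < fbest) {
      best <- x
      fbest <- fx
    }
  }
  list(par = best, value = fbest)
}

#' One simulated-annealing run
#'
#' A single bounded annealing descent of the residual sum of squares between
#' the convolution prediction and the To trace, started from `init`, followed
#' (by default) by a short Nelder-Mead refinement clamped to the bounds. The
#' result is a reproducible function of the inputs and `run_seed`.
#'
#' @param from_sig,to_sig Preprocessed, window-cut series tibbles; the To
#'   grid must lie within the From span.
#' @param init Length-4 initial parameter vector (within bounds).
#' @param config A [fit_config].
#' @param run_seed Integer seed for this run.
#' @return A one-row tibble: `p1..p4`, `ssr`, `pearson`, `valid`.
#' @export
anneal_once <- function(from_sig, to_sig, init = NULL, config = fit_config(),
                        run_seed = config$seed) {
  obj <- make_fit_objective(from_sig, to_sig)
  if (is.null(init)) init <- config$initial
  anneal_once_impl(obj, init, config, run_seed)
}

# internal variant reusing a prebuilt objective across runs
anneal_once_impl <- function(obj, init, config, run_seed) {
  set.seed(as.integer(run_seed %% .Machine$integer.max))
  res <- sa_minimize(obj$ssr, init, config$lower, config$upper,
                     config$t0, config$cooling, config$n_moves)
  par <- res$par
  if (config$polish) {
    pen <- function(x) {
      xc <- pmin(pmax(x, config$lower), config$upper)
      obj$ssr(xc) + 1e6 * sum((x - xc)^2)
    }
    pol <- stats::optim(par, pen, method = "Nelder-Mead",
                        control = list(maxit = config$polish_maxit,
                                       reltol = 1e-12))
    par <- pmin(pmax(pol$par, config$lower), config$upper)
  }
  # keep returned parameters strictly inside the box
  margin <- 1e-9 * (config$upper - config$lower)
  par <- pmin(pmax(par, config$lower + margin), config$upper - margin)
  pred <- obj$predict(par)
  ssr <- sum((pred - obj$to_vals)^2)
  r <- if (stats::sd(pred) > 0 && stats::sd(obj$to_vals) > 0) {
    stats::cor(pred, obj$to_vals)
  } else NA_real_
  tibble::tibble(p1 = par[1], p2 = par[2], p3 = par[3], p4 = par[4],
                 ssr = ssr, pearson = r,
                 valid = check_validity(tf_params(par[1], par[2], par[3], par[4])))
}

#' Fit a transfer function by the iterative annealing protocol
#'
#' Runs `runs_per_iteration` independent annealing descents from the current
#' initial set, screens candidates for validity (the kernel must start at
#' zero and be smooth beyond the time shift, i.e. `p1 > 1`), scores valid
#' candidates by the Pearson coefficient of their prediction (residual sum
#' of squares breaking ties), and adopts the best as the next initial set.
#' The protocol stops when the relative Pearson improvement falls below
#' `rel_tol` or after `max_iterations` iterations, and returns the incumbent
#' best fit.
#'
#' @inheritParams anneal_once
#' @param config A [fit_config]; `config$seed` drives all randomness.
#' @return A `tf_fit` object: fitted `params` ([tf_params]), `ssr`,
#'   `pearson`, `valid`, the fitted prediction on the To grid, a run log
#'   tibble (one row per annealing run), and the per-iteration incumbent
#'   Pearson trace.
#' @examples
#' \donttest{
#' trial <- simulate_trial(sim_config(noise_sd_from = 0, noise_sd_to = 0))
#' fit <- fit_tf(trial$from, trial$to,
#'               fit_config(runs_per_iteration = 5, max_iterations = 1, seed = 2))
#' tf_peak_time(fit$params)
#' }
#' @export
fit_tf <- function(from_sig, to_sig, config = fit_config()) {
  obj <- make_fit_objective(from_sig, to_sig)
  set.seed(config$seed)
  run_seeds <- sample.int(.Machine$integer.max - 1L,
                          config$runs_per_iteration * config$max_iterations)
  incumbent <- NULL
  init <- config$initial
  log_rows <- list()
  incumbent_trace <- numeric(0)
  n_iter <- 0L
  for (iter in seq_len(config$max_iterations)) {
    n_iter <- iter
    runs <- purrr::map(seq_len(config$runs_per_iteration), function(rn) {
      seed_idx <- (iter - 1L) * config$runs_per_iteration + rn
      row <- anneal_once_impl(obj, init, config, run_seeds[seed_idx])
      row$iteration <- iter
      row$run <- rn
      row
    })
    iter_log <- dplyr::bind_rows(runs)
    log_rows[[iter]] <- iter_log
    cand <- dplyr::filter(iter_log, .data$valid, is.finite(.data$pearson))
    if (nrow(cand) == 0) {
      if (is.null(incumbent)) {
        stop("no valid transfer function found: every candidate violated ",
             "the validity screen (p1 > 1)", call. = FALSE)
      }
      break
    }
    best <- cand[order(-cand$pearson, cand$ssr), ][1, ]
    if (is.null(incumbent)) {
      improved <- TRUE
    } else {
      gain <- best$pearson - incumbent$pearson
      improved <- gain > config$rel_tol * max(abs(incumbent$pearson), 1e-12)
      if (gain <= 0) best <- incumbent  # keep the monotone incumbent
    }
    incumbent <- best
    init <- c(best$p1, best$p2, best$p3, best$p4)
    incumbent_trace <- c(incumbent_trace, incumbent$pearson)
    if (!improved) break
  }
  params <- tf_params(incumbent$p1, incumbent$p2, incumbent$p3, incumbent$p4)
  pred <- tibble::tibble(time = to_sig$time, value = obj$predict(init))
  structure(list(
    params = params,
    ssr = incumbent$ssr,
    pearson = incumbent$pearson,
    valid = incumbent$valid,
    prediction = pred,
    observed = tibble::as_tibble(to_sig[c("time", "value")]),
    run_log = dplyr::bind_rows(log_rows),
    incumbent_trace = incumbent_trace,
    n_iterations = n_iter,
    config = config
  ), class = "tf_fit")
}

#' @export
print.tf_fit <- function(x, ...) {
  cat("<tf_fit> shifted-gamma transfer function\n")
  print(x$params)
  cat(sprintf("  Pearson r = %.4f, SSR = %.4g, %d iteration(s), %d runs logged\n",
              x$pearson, x$ssr, x$n_iterations, nrow(x$run_log)))
  invisible(x)
}

#' Tidy a fitted transfer function
#'
#' @param x A `tf_fit` object.
#' @param ... Unused.
#' @return One-row tibble of the fitted parameters `p1..p4` plus `peak_time`.
#' @method tidy tf_fit
#' @export
tidy.tf_fit <- function(x, ...) {
  out <- tidy.tf_params(x$params)
  out$peak_time <- if (x$params$p1 > 1) tf_peak_time(x$params) else NA_real_
  out
}

#' One-row fit summary
#'
#' @param x A `tf_fit` object.
#' @param ... Unused.
#' @return Tibble with `pearson`, `ssr`, `valid`, `n_iterations`, `n_runs`,
#'   `seed`.
#' @method glance tf_fit
#' @export
glance.tf_fit <- function(x, ...) {
  tibble::tibble(pearson = x$pearson, ssr = x$ssr, valid = x$valid,
                 n_iterations = x$n_iterations, n_runs = nrow(x$run_log),
                 seed = x$config$seed)
}

#' Per-sample prediction table for a fitted transfer function
#'
#' @param x A `tf_fit` object.
#' @param ... Unused.
#' @return Tibble with `time`, `observed`, `predicted`, `residual`.
#' @method augment tf_fit
#' @export
augment.tf_fit <- function(x, ...) {
  tibble::tibble(time = x$observed$time,
                 observed = x$observed$value,
                 predicted = x$prediction$value,
                 residual = x$observed$value - x$prediction$value)
}

#' Plot a fitted transfer function and its prediction
#'
#' Left panel: the fitted kernel. Right panel: observed To trace with the
#' fitted convolution prediction overlaid.
#'
#' @param object A `tf_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tf_fit
#' @export
autoplot.tf_fit <- function(object, ...) {
  kern_t <- seq(0, tf_peak_time(object$params) * 4 + 1, length.out = 400)
  kern <- tibble::tibble(time = kern_t,
                         value = evaluate_tf(object$params, kern_t),
                         panel = "transfer function")
  comp <- dplyr::bind_rows(
    dplyr::mutate(object$observed, series = "observed"),
    dplyr::mutate(object$prediction, series = "predicted"))
  comp$panel <- "prediction"
  kern$series <- "kernel"
  dat <- dplyr::bind_rows(kern, comp)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time, y = .data$value,
                                    colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = "time (s)", y = "response",
                  title = sprintf("fitted TF (r = %.3f)", object$pearson)) +
    ggplot2::theme_minimal()
}
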