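#' Configuration of the synthetic trial generator
#'
#' Describes one stimulus-locked trial of the kind the fitting pipeline
#' consumes: a 30 s or 60 s acquisition with a 5 s pre-stimulus baseline,
#' an odor-like boxcar stimulus, a calcium transient with fast indicator
#' kinetics, and a vascular response generated by convolving the calcium
#' trace with a known ground-truth transfer function (optionally plus a
#' delayed secondary component) and adding Gaussian noise.
#'
#' @param acquisition_len 30 or 60, seconds.
#' @param dt_from,dt_to Sampling intervals of the neuronal and vascular
#'   traces, seconds (default 0.05 s, the canonical fitting grid).
#' @param stimulus_onset Stimulus onset, seconds (>= 5 so a full baseline
#'   exists; default 10 s).
#' @param stimulus_duration Odor duration, seconds (0.12, 1, 2 or 5 in the
#'   emulated protocols; default 5).
#' @param tau_on,tau_off Calcium indicator rise and decay time constants,
#'   seconds (GCaMP6f-like defaults 0.1 and 1).
#' @param true_tf Ground-truth [tf_params] (default the standard
#'   calcium-to-RBC-velocity kernel (1.3, 0.5, 0.27, 0.19)).
#' @param secondary_tf Optional delayed secondary [tf_params].
#' @param secondary_ratio Amplitude of the secondary component relative to
#'   the primary.
#' @param noise_sd_from,noise_sd_to Gaussian noise SDs as fractions of the
#'   respective noiseless response peaks.
#' @param n_subjects Cohort size for [make_cohort()].
#' @param inter_subject_jitter Fractional (lognormal) SD applied to each TF
#'   parameter per subject.
#' @param seed Master seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(acquisition_len = 30, dt_from = 0.05, dt_to = 0.05,
                       stimulus_onset = 10, stimulus_duration = 5,
                       tau_on = 0.1, tau_off = 1,
                       true_tf = tf_params(1.3, 0.5, 0.27, 0.19),
                       secondary_tf = NULL, secondary_ratio = 0.4,
                       noise_sd_from = 0.05, noise_sd_to = 0.05,
                       n_subjects = 1, inter_subject_jitter = 0,
                       seed = 1L) {
  if (!acquisition_len %in% c(30, 60)) {
    stop("acquisition_len must be 30 or 60 s", call. = FALSE)
  }
  if (stimulus_onset < 5) {
    stop("stimulus_onset must be >= 5 s so a 5 s baseline exists", call. = FALSE)
  }
  if (tau_on >= tau_off) {
    stop("calcium kinetics need tau_on < tau_off", call. = FALSE)
  }
  if (noise_sd_from < 0 || noise_sd_to < 0 || inter_subject_jitter < 0) {
    stop("noise and jitter SDs must be >= 0", call. = FALSE)
  }
  structure(list(
    acquisition_len = acquisition_len, dt_from = dt_from, dt_to = dt_to,
    stimulus_onset = stimulus_onset, stimulus_duration = stimulus_duration,
    tau_on = tau_on, tau_off = tau_off,
    true_tf = as_tf_params(true_tf),
    secondary_tf = if (!is.null(secondary_tf)) as_tf_params(secondary_tf),
    secondary_ratio = secondary_ratio,
    noise_sd_from = noise_sd_from, noise_sd_to = noise_sd_to,
    n_subjects = as.integer(n_subjects),
    inter_subject_jitter = inter_subject_jitter,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Boxcar stimulus trace
#'
#' Height-1 boxcar on `[onset, onset + duration)`, zero elsewhere, on the
#' From grid covering the full acquisition.
#'
#' @param config A [sim_config].
#' @return Uniform series tibble.
#' @export
make_stimulus <- function(config) {
  n <- round(config$acquisition_len / config$dt_from) + 1
  t <- (seq_len(n) - 1) * config$dt_from
  on <- t >= config$stimulus_onset - 1e-9 &
    t < config$stimulus_onset + config$stimulus_duration - 1e-9
  tibble::tibble(time = t, value = as.numeric(on))
}

# difference-of-exponentials indicator kernel, normalized to unit peak;
# bin-integrated (zero-order-hold) convolution keeps the closed-form
# plateau exact: integral = (tau_off - tau_on) / peak_value
calcium_kernel_cdf <- function(t, tau_on, tau_off) {
  tau_off * (1 - exp(-t / tau_off)) - tau_on * (1 - exp(-t / tau_on))
}

#' Calcium kernel integral (closed form)
#'
#' Integral of the unit-peak difference-of-exponentials indicator kernel;
#' the plateau level a long unit stimulus converges to.
#'
#' @param tau_on,tau_off Rise and decay time constants, seconds.
#' @return Scalar integral in seconds.
#' @export
calcium_kernel_integral <- function(tau_on = 0.1, tau_off = 1) {
  tpk <- log(tau_off / tau_on) * tau_on * tau_off / (tau_off - tau_on)
  peak <- exp(-tpk / tau_off) - exp(-tpk / tau_on)
  (tau_off - tau_on) / peak
}

#' Simulate a stimulus-locked calcium trace
#'
#' Convolves the boxcar stimulus with a normalized difference-of-exponentials
#' kernel (unit peak) and adds i.i.d. Gaussian noise scaled to the noiseless
#' peak. The noiseless response is exactly zero before stimulus onset.
#'
#' @param stimulus Stimulus tibble from [make_stimulus()].
#' @param config A [sim_config].
#' @param seed Seed for the noise draw.
#' @return Calcium series tibble on the From grid.
#' @export
make_calcium <- function(stimulus, config, seed = config$seed) {
  stimulus <- check_series_frame(stimulus)
  dt <- series_dt(stimulus)
  n <- nrow(stimulus)
  tpk <- log(config$tau_off / config$tau_on) * config$tau_on * config$tau_off /
    (config$tau_off - config$tau_on)
  peak <- exp(-tpk / config$tau_off) - exp(-tpk / config$tau_on)
  cdf <- calcium_kernel_cdf((0:n) * dt, config$tau_on, config$tau_off) / peak
  w <- diff(cdf)
  plan <- make_conv_plan(stimulus$value)
  vals <- fft_causal_conv(plan$fx, w, plan$n, plan$m)
  vals[abs(vals) < 1e-14] <- 0
  if (config$noise_sd_from > 0) {
    set.seed(as.integer(seed %% .Machine$integer.max))
    vals <- vals + stats::rnorm(n, sd = config$noise_sd_from * max(vals))
  }
  tibble::tibble(time = stimulus$time, value = vals)
}

#' Simulate a vascular response from a calcium trace
#'
#' Forward model of the package: the vascular trace is the convolution of
#' the calcium trace with the ground-truth transfer function, plus an
#' optional delayed secondary component, plus Gaussian noise scaled to the
#' noiseless peak.
#'
#' @param calcium Calcium series tibble.
#' @param config A [sim_config].
#' @param seed Seed for the noise draw.
#' @return Vascular series tibble on the To grid.
#' @export
make_vascular <- function(calcium, config, seed = config$seed + 1L) {
  calcium <- check_series_frame(calcium)
  to_grid <- seq(calcium$time[1], calcium$time[nrow(calcium)], by = config$dt_to)
  pred <- convolve_predict(calcium, config$true_tf, to_grid)
  vals <- pred$value
  if (!is.null(config$secondary_tf)) {
    vals <- vals + config$secondary_ratio *
      convolve_predict(calcium, config$secondary_tf, to_grid)$value
  }
  if (config$noise_sd_to > 0 && any(vals != 0)) {
    set.seed(as.integer(seed %% .Machine$integer.max))
    vals <- vals + stats::rnorm(length(vals),
                                sd = config$noise_sd_to * max(abs(vals)))
  }
  tibble::tibble(time = to_grid, value = vals)
}

#' Simulate one complete trial
#'
#' @param config A [sim_config].
#' @param seed Overrides `config$seed`.
#' @return A list with elements `stimulus`, `from` (calcium), `to`
#'   (vascular), `meta` (onset, duration, acquisition length) and `truth`
#'   (the generating kernels).
#' @export
simulate_trial <- function(config = sim_config(), seed = config$seed) {
  stim <- make_stimulus(config)
  ca <- make_calcium(stim, config, seed = seed)
  vasc <- make_vascular(ca, config, seed = seed + 1L)
  list(
    stimulus = stim, from = ca, to = vasc,
    meta = list(stimulus_onset_s = config$stimulus_onset,
                stimulus_duration_s = config$stimulus_duration,
                acquisition_len_s = config$acquisition_len),
    truth = list(true_tf = config$true_tf,
                 secondary_tf = config$secondary_tf,
                 secondary_ratio = config$secondary_ratio,
                 seed = seed)
  )
}

# multiplicative lognormal jitter on each parameter, redrawn until the
# jittered kernel stays valid (p1 > 1, all parameters positive)
jitter_tf <- function(params, jitter, max_redraws = 100) {
  if (jitter == 0) return(params)
  for (i in seq_len(max_redraws)) {
    f <- exp(stats::rnorm(4, sd = jitter))
    cand <- list(p1 = params$p1 * f[1], p2 = params$p2 * f[2],
                 p3 = params$p3 * f[3], p4 = params$p4 * f[4])
    if (cand$p1 > 1 + 1e-6) {
      return(tf_params(cand$p1, cand$p2, cand$p3, cand$p4))
    }
  }
  stop("inter-subject jitter too large: no valid kernel after ",
       max_redraws, " redraws", call. = FALSE)
}

#' Simulate a cohort of subjects
#'
#' Each subject receives a jittered copy of the ground-truth transfer
#' function (lognormal multiplicative jitter per parameter, redrawn until
#' valid) and fresh noise.
#'
#' @param config A [sim_config] with `n_subjects >= 1`.
#' @return A tibble with one row per subject: `subject`, list-columns
#'   `from`, `to` and `true_tf`, plus the trial metadata columns.
#' @export
make_cohort <- function(config = sim_config()) {
  stopifnot(config$n_subjects >= 1)
  set.seed(config$seed)
  subject_seeds <- sample.int(.Machine$integer.max - 2L, config$n_subjects)
  rows <- purrr::map(seq_len(config$n_subjects), function(i) {
    set.seed(subject_seeds[i])
    tf_i <- jitter_tf(config$true_tf, config$inter_subject_jitter)
    cfg_i <- config
    cfg_i$true_tf <- tf_i
    trial <- simulate_trial(cfg_i, seed = subject_seeds[i])
    tibble::tibble(
      subject = sprintf("s%02d", i),
      from = list(trial$from), to = list(trial$to),
      stimulus_onset = config$stimulus_onset,
      stimulus_duration = config$stimulus_duration,
      acquisition_len = config$acquisition_len,
      true_tf = list(tf_i))
  })
  dplyr::bind_rows(rows)
}
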