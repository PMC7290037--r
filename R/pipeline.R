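#' Run a pipeline command
#'
#' Programmatic entry point behind the command-line wrapper
#' (`inst/cli/nvctf.R`). Dispatches the subcommands `fit`, `predict`,
#' `crossval`, `secondary`, `simulate` and `rank-voxels`, reading and
#' writing the package's CSV/JSON formats. Every run records the master
#' seed and the effective configuration in its output artifacts.
#'
#' @param command One of `"fit"`, `"predict"`, `"crossval"`, `"secondary"`,
#'   `"simulate"`, `"rank-voxels"`.
#' @param options Named list of command options (paths and scalars; see
#'   Details).
#' @param seed Master seed.
#'
#' @details Options by command:
#' \describe{
#'   \item{fit}{`from`, `to`, `meta` (paths), optional `config` (JSON with
#'     [fit_config] fields), `out` (TF JSON path); a per-run log CSV is
#'     written next to `out`.}
#'   \item{predict}{`from`, `tf`, `meta`, optional `to` (for rescaling and
#'     scoring), `out` (prediction CSV).}
#'   \item{crossval}{`manifest` (JSON listing subjects with `from`, `to`,
#'     `meta` and optional `tf` paths), optional `config`, `out` (report
#'     JSON).}
#'   \item{secondary}{`from`, `to`, `meta`, `standard_tf`, optional
#'     `config`, `out` (two-component JSON).}
#'   \item{simulate}{optional `config` (JSON with [sim_config] fields),
#'     `out_dir`; writes per-subject CSVs, metadata sidecars, a
#'     `manifest.json` and a `ground_truth.json`.}
#'   \item{rank-voxels}{`panel` (long CSV with `voxel,time_s,value`),
#'     `window_lo`, `window_hi`, `out` (ranking CSV).}
#' }
#' @return The primary result object of the command, invisibly; artifacts
#'   are written to the requested paths.
#' @export
run_pipeline <- function(command, options = list(), seed = 1L) {
  seed <- as.integer(seed)
  switch(command,
    "fit" = pipeline_fit(options, seed),
    "predict" = pipeline_predict(options),
    "crossval" = pipeline_crossval(options, seed),
    "secondary" = pipeline_secondary(options, seed),
    "simulate" = pipeline_simulate(options, seed),
    "rank-voxels" = pipeline_rank_voxels(options),
    stop("unknown command: ", command,
         " (expected fit/predict/crossval/secondary/simulate/rank-voxels)",
         call. = FALSE)
  )
}

opt_required <- function(options, keys, command) {
  miss <- setdiff(keys, names(options))
  if (length(miss) > 0) {
    stop("`", command, "` requires option(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
}

load_fit_config <- function(path, seed) {
  args <- if (!is.null(path)) jsonlite::read_json(path, simplifyVector = TRUE) else list()
  args$seed <- seed
  do.call(fit_config, args)
}

# read + preprocess one trial: From at 50 ms (absolute delta), To at its
# native uniform grid (relative delta for vascular kinds), both window-cut
load_trial <- function(from_path, to_path, meta_path) {
  meta <- read_trial_meta(meta_path)
  onset <- meta$stimulus_onset_s
  acq <- meta$acquisition_len_s
  to_kind <- if (!is.null(meta$to_kind)) meta$to_kind else "rbc_velocity"
  to_dt <- if (!is.null(meta$to_dt_s)) meta$to_dt_s else 0.05
  from <- prepare_trace(read_series(from_path), onset, acq, dt = 0.05)
  to <- prepare_trace(read_series(to_path), onset, acq, dt = to_dt,
                      relative = to_kind %in% c("rbc_velocity", "power_doppler"),
                      median3 = isTRUE(meta$median3))
  list(from = from, to = to, meta = meta)
}

pipeline_fit <- function(options, seed) {
  opt_required(options, c("from", "to", "meta", "out"), "fit")
  trial <- load_trial(options$from, options$to, options$meta)
  config <- load_fit_config(options$config, seed)
  fit <- fit_tf(trial$from, trial$to, config)
  write_tf(fit$params, options$out,
           meta = list(from = "calcium",
                       to = if (!is.null(trial$meta$to_kind)) trial$meta$to_kind else "rbc_velocity",
                       stimulus = trial$meta$label,
                       pearson = fit$pearson, ssr = fit$ssr, seed = seed,
                       runs_per_iteration = config$runs_per_iteration,
                       max_iterations = config$max_iterations))
  readr::write_csv(fit$run_log, sub("\\.json$", "_runlog.csv", options$out),
                   progress = FALSE)
  invisible(fit)
}

pipeline_predict <- function(options) {
  opt_required(options, c("from", "tf", "meta", "out"), "predict")
  meta <- read_trial_meta(options$meta)
  params <- read_tf(options$tf)
  from <- prepare_trace(read_series(options$from), meta$stimulus_onset_s,
                        meta$acquisition_len_s, dt = 0.05)
  pred <- convolve_predict(from, params)
  r <- NA_real_
  if (!is.null(options$to)) {
    trial <- load_trial(options$from, options$to, options$meta)
    pred <- convolve_predict(trial$from, params, trial$to)
    pred <- rescale_amplitude(pred, trial$to, meta$stimulus_onset_s)
    r <- pearson(pred, trial$to)
    message(sprintf("Pearson r = %.4f (scale = %.4g)", r, attr(pred, "scale")))
  }
  write_series(pred, options$out)
  invisible(list(prediction = pred, pearson = r))
}

pipeline_crossval <- function(options, seed) {
  opt_required(options, c("manifest", "out"), "crossval")
  manifest <- jsonlite::read_json(options$manifest, simplifyVector = FALSE)
  base <- dirname(options$manifest)
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  config <- load_fit_config(options$config, seed)
  rows <- purrr::map(manifest$subjects, function(s) {
    trial <- load_trial(resolve(s$from), resolve(s$to), resolve(s$meta))
    meta <- trial$meta
    tibble::tibble(subject = s$id,
                   from = list(trial$from), to = list(trial$to),
                   stimulus_onset = meta$stimulus_onset_s,
                   acquisition_len = meta$acquisition_len_s,
                   tf_path = if (!is.null(s$tf)) resolve(s$tf) else NA_character_)
  })
  cohort <- dplyr::bind_rows(rows)
  params_list <- purrr::map(seq_len(nrow(cohort)), function(i) {
    if (!is.na(cohort$tf_path[i])) {
      read_tf(cohort$tf_path[i])
    } else {
      fit_tf(cohort$from[[i]], cohort$to[[i]], config)$params
    }
  })
  report <- loo_cross_validate(cohort, params_list)
  payload <- list(
    subjects = report$subjects,
    params = purrr::map(report$params, unclass),
    self_pearson = report$self_pearson,
    cross = report$cross,
    mean_cross = report$mean_cross,
    cv_cross = report$cv_cross,
    selected = report$selected,
    selected_subject = report$subjects[report$selected],
    seed = seed)
  jsonlite::write_json(payload, options$out, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(report)
}

pipeline_secondary <- function(options, seed) {
  opt_required(options, c("from", "to", "meta", "standard_tf", "out"),
               "secondary")
  trial <- load_trial(options$from, options$to, options$meta)
  std <- read_tf(options$standard_tf)
  resid <- residual_component(trial$to, trial$from, std,
                              trial$meta$stimulus_onset_s)
  cfg_args <- if (!is.null(options$config)) {
    jsonlite::read_json(options$config, simplifyVector = TRUE)
  } else list(upper = c(20, 20, 20, 20))
  cfg_args$seed <- seed
  config <- do.call(fit_config, cfg_args)
  fit2 <- fit_secondary(trial$from, resid, config)
  two <- two_component_tf(std, fit2$params)
  comb <- combined_predict(trial$from, two, trial$to, observed = trial$to)
  a <- attr(comb, "amplitudes")
  jsonlite::write_json(list(
    primary = unclass(std), secondary = unclass(fit2$params),
    amplitudes = a, combined_pearson = pearson(comb, trial$to),
    seed = seed), options$out, auto_unbox = TRUE, digits = NA)
  invisible(two_component_tf(std, fit2$params, a))
}

pipeline_simulate <- function(options, seed) {
  opt_required(options, "out_dir", "simulate")
  cfg_args <- if (!is.null(options$config)) {
    jsonlite::read_json(options$config, simplifyVector = TRUE)
  } else list()
  cfg_args$seed <- seed
  if (!is.null(cfg_args$true_tf)) cfg_args$true_tf <- as_tf_params(cfg_args$true_tf)
  if (!is.null(cfg_args$secondary_tf)) {
    cfg_args$secondary_tf <- as_tf_params(cfg_args$secondary_tf)
  }
  config <- do.call(sim_config, cfg_args)
  cohort <- make_cohort(config)
  dir.create(options$out_dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- purrr::map(seq_len(nrow(cohort)), function(i) {
    id <- cohort$subject[i]
    from_p <- file.path(options$out_dir, paste0(id, "_from.csv"))
    to_p <- file.path(options$out_dir, paste0(id, "_to.csv"))
    meta_p <- file.path(options$out_dir, paste0(id, "_meta.json"))
    write_series(cohort$from[[i]], from_p)
    write_series(cohort$to[[i]], to_p)
    jsonlite::write_json(list(
      stimulus_onset_s = cohort$stimulus_onset[i],
      stimulus_duration_s = cohort$stimulus_duration[i],
      acquisition_len_s = cohort$acquisition_len[i],
      label = "synthetic", from_kind = "calcium", to_kind = "generic"),
      meta_p, auto_unbox = TRUE, digits = NA)
    list(id = id, from = basename(from_p), to = basename(to_p),
         meta = basename(meta_p))
  })
  jsonlite::write_json(list(seed = seed, subjects = subjects),
                       file.path(options$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(
    seed = seed,
    true_tf = purrr::map(cohort$true_tf, unclass),
    secondary_tf = if (!is.null(config$secondary_tf)) unclass(config$secondary_tf),
    secondary_ratio = config$secondary_ratio,
    noise_sd_from = config$noise_sd_from, noise_sd_to = config$noise_sd_to,
    inter_subject_jitter = config$inter_subject_jitter),
    file.path(options$out_dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, null = "null")
  invisible(cohort)
}

pipeline_rank_voxels <- function(options) {
  opt_required(options, c("panel", "window_lo", "window_hi", "out"),
               "rank-voxels")
  df <- readr::read_csv(options$panel,
                        col_types = readr::cols(
                          voxel = readr::col_character(),
                          time_s = readr::col_double(),
                          value = readr::col_double()),
                        progress = FALSE)
  panel <- dplyr::rename(df, time = "time_s")
  ranking <- rank_voxels_by_auc(
    panel, c(as.numeric(options$window_lo), as.numeric(options$window_hi)))
  readr::write_csv(ranking, options$out, progress = FALSE)
  invisible(ranking)
}
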