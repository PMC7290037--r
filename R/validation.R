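#' Self-validation of a fitted transfer function
#'
#' Scores a subject's own transfer function on its own trial: the From trace
#' is convolved with the kernel and the Pearson coefficient against the
#' observed To trace over the fit window is returned. The post-hoc amplitude
#' rescale is deliberately not applied before scoring — a positive scale
#' factor cannot change the coefficient, and scoring the raw prediction
#' keeps anti-correlated (e.g. sign-flipped) data visibly negative instead
#' of letting a negative scale factor mask it.
#'
#' @param from_sig,to_sig Preprocessed series tibbles for the subject.
#' @param params The subject's fitted [tf_params].
#' @param stimulus_onset Stimulus onset, seconds (kept for interface
#'   symmetry with the rescaled prediction path; not used in scoring).
#' @return Pearson coefficient.
#' @export
self_validate <- function(from_sig, to_sig, params, stimulus_onset = NULL) {
  pred <- convolve_predict(from_sig, params, to_sig)
  pearson(pred, to_sig)
}

#' Leave-one-out cross-validation of transfer functions across a cohort
#'
#' Fills the full cross matrix: the kernel fitted on subject i is convolved
#' with the From trace of subject j, amplitude-rescaled, and scored by
#' Pearson correlation against subject j's To trace over the fit window.
#' The diagonal holds the self-validation coefficients. Off-diagonal means
#' and coefficients of variability summarize pure cross-subject transfer;
#' the standard-kernel selection additionally weighs each kernel's
#' performance on its own dataset (see [select_standard_tf()]).
#'
#' @param cohort Cohort tibble as produced by [make_cohort()]: one row per
#'   subject with `subject`, list-columns `from` and `to`, `stimulus_onset`
#'   and `acquisition_len`. Traces are full-acquisition, baseline-normalized
#'   series; the fit window is cut here.
#' @param params_list List of fitted [tf_params] (or `tf_fit` objects), one
#'   per subject, in cohort row order.
#' @return A `cohort_report`: subjects, kernels, `self_pearson`, `cross`
#'   matrix, off-diagonal summaries `mean_cross` and `cv_cross`, full-row
#'   summaries `overall_mean` and `overall_cv` (used for selection), and the
#'   `selected` index.
#' @export
loo_cross_validate <- function(cohort, params_list) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1,
            length(params_list) == nrow(cohort))
  params_list <- purrr::map(params_list, function(p) {
    if (inherits(p, "tf_fit")) p$params else as_tf_params(p)
  })
  n <- nrow(cohort)
  prep <- purrr::map(seq_len(n), function(j) {
    list(from = cut_fit_window(cohort$from[[j]], cohort$acquisition_len[j]),
         to = cut_fit_window(cohort$to[[j]], cohort$acquisition_len[j]),
         onset = cohort$stimulus_onset[j])
  })
  cross <- matrix(NA_real_, n, n,
                  dimnames = list(tf = cohort$subject, data = cohort$subject))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      cross[i, j] <- self_validate(prep[[j]]$from, prep[[j]]$to,
                                   params_list[[i]], prep[[j]]$onset)
    }
  }
  self_p <- diag(cross)
  if (n >= 2) {
    off <- cross
    diag(off) <- NA_real_
    mean_cross <- rowMeans(off, na.rm = TRUE)
    cv_cross <- apply(off, 1, stats::sd, na.rm = TRUE) / mean_cross
    # selection considers performance on the kernel's own dataset as well
    # as on the other subjects' datasets (full row of the matrix)
    overall_mean <- rowMeans(cross)
    overall_cv <- apply(cross, 1, stats::sd) / overall_mean
  } else {
    mean_cross <- cv_cross <- overall_mean <- overall_cv <- NA_real_
  }
  report <- structure(list(
    subjects = cohort$subject,
    params = params_list,
    self_pearson = unname(self_p),
    cross = cross,
    mean_cross = unname(mean_cross),
    cv_cross = unname(cv_cross),
    overall_mean = unname(overall_mean),
    overall_cv = unname(overall_cv),
    self_only = n < 2,
    selected = NA_integer_
  ), class = "cohort_report")
  report$selected <- select_standard_tf(report)
  report
}

#' Select the standard transfer function from a cohort report
#'
#' The standard kernel is the one performing best on its own dataset *and*
#' on the other subjects' datasets, judged on the full row of the
#' cross-validation matrix (self plus cross entries): the kernel with both
#' the highest average Pearson coefficient and the smallest coefficient of
#' variability wins; when no kernel satisfies both, the first condition
#' (highest average) is preferred. Including the self entry matters: a
#' kernel fitted on a corrupted recording can still predict clean subjects
#' reasonably, but betrays itself on its own noisy data, whereas all clean
#' kernels are penalized equally by a noisy column. A single-subject cohort
#' selects that subject.
#'
#' @param report A `cohort_report` from [loo_cross_validate()]. Reports
#'   lacking the full-row summaries (`overall_mean`/`overall_cv`) fall back
#'   to the off-diagonal statistics.
#' @return Integer index of the selected subject.
#' @export
select_standard_tf <- function(report) {
  stopifnot(inherits(report, "cohort_report"))
  n <- length(report$subjects)
  if (n == 0) stop("empty cohort report", call. = FALSE)
  if (n == 1 || report$self_only) return(1L)
  score_mean <- report$overall_mean %||% report$mean_cross
  score_cv <- report$overall_cv %||% report$cv_cross
  best_mean <- which(score_mean == max(score_mean))
  best_cv <- which(score_cv == min(score_cv))
  both <- intersect(best_mean, best_cv)
  if (length(both) >= 1) return(both[1])
  best_mean[1]
}

#' @export
print.cohort_report <- function(x, ...) {
  n <- length(x$subjects)
  cat(sprintf("<cohort_report> %d subject(s)\n", n))
  if (x$self_only) {
    cat(sprintf("  self-only: self Pearson = %.3f\n", x$self_pearson[1]))
  } else {
    cat(sprintf("  mean self Pearson: %.3f; mean cross Pearson: %.3f\n",
                mean(x$self_pearson), mean(x$mean_cross)))
    cat(sprintf("  selected standard TF: %s (mean cross r = %.3f, CV = %.3f)\n",
                x$subjects[x$selected], x$mean_cross[x$selected],
                x$cv_cross[x$selected]))
  }
  invisible(x)
}

#' Long-format cross-validation matrix
#'
#' @param x A `cohort_report`.
#' @param ... Unused.
#' @return Tibble with `tf_subject`, `data_subject`, `pearson`, `self`.
#' @method tidy cohort_report
#' @export
tidy.cohort_report <- function(x, ...) {
  n <- length(x$subjects)
  out <- tibble::tibble(
    tf_subject = rep(x$subjects, each = n),
    data_subject = rep(x$subjects, times = n),
    pearson = as.vector(t(x$cross)))
  out$self <- out$tf_subject == out$data_subject
  out
}

#' Per-kernel cross-validation summary
#'
#' @param x A `cohort_report`.
#' @param ... Unused.
#' @return Tibble with one row per subject kernel: `subject`,
#'   `self_pearson`, `mean_cross`, `cv_cross`, `selected`.
#' @method glance cohort_report
#' @export
glance.cohort_report <- function(x, ...) {
  tibble::tibble(
    subject = x$subjects,
    self_pearson = x$self_pearson,
    mean_cross = if (x$self_only) NA_real_ else x$mean_cross,
    cv_cross = if (x$self_only) NA_real_ else x$cv_cross,
    overall_mean = if (x$self_only) NA_real_ else x$overall_mean %||% NA_real_,
    selected = seq_along(x$subjects) == x$selected)
}

#' Heatmap of the leave-one-out cross-validation matrix
#'
#' @param object A `cohort_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cohort_report
#' @export
autoplot.cohort_report <- function(object, ...) {
  dat <- tidy.cohort_report(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$data_subject,
                                    y = .data$tf_subject,
                                    fill = .data$pearson)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$pearson)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0,
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = "data from subject", y = "TF fitted on subject",
                  fill = "Pearson r") +
    ggplot2::theme_minimal()
}

#' Rank voxel responses by area under the curve
#'
#' Computes the trapezoidal integral of each voxel's relative power-Doppler
#' response over the response window and ranks voxels in descending order of
#' AUC (dense ranking: rank 1 is the largest, ties share a rank).
#'
#' @param panel Long tibble with columns `voxel`, `time`, `value`; all
#'   voxels must share one grid.
#' @param window `c(lo, hi)` response window in seconds (conventionally
#'   stimulus onset to the end of the fit window).
#' @return Tibble with `voxel`, `auc`, `rank`, sorted by rank.
#' @export
rank_voxels_by_auc <- function(panel, window) {
  stopifnot(is.data.frame(panel),
            all(c("voxel", "time", "value") %in% names(panel)))
  voxels <- unique(panel$voxel)
  if (length(voxels) < 2) stop("need at least 2 voxels to rank", call. = FALSE)
  grids <- split(panel$time, panel$voxel)
  ref <- grids[[1]]
  if (!all(purrr::map_lgl(grids, ~ length(.x) == length(ref) &&
                            all(abs(.x - ref) < 1e-9)))) {
    stop("all voxels must share a common time grid", call. = FALSE)
  }
  tol <- 1e-9
  if (window[1] < min(ref) - tol || window[2] > max(ref) + tol) {
    stop("response window outside the panel grid", call. = FALSE)
  }
  out <- panel |>
    dplyr::filter(.data$time >= window[1] - tol, .data$time <= window[2] + tol) |>
    dplyr::group_by(.data$voxel) |>
    dplyr::summarise(auc = pracma::trapz(.data$time, .data$value),
                     .groups = "drop") |>
    dplyr::mutate(rank = dplyr::dense_rank(dplyr::desc(round(.data$auc, 12)))) |>
    dplyr::arrange(.data$rank, .data$voxel)
  out
}
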