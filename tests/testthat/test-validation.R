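test_that("self-validation is near-perfect on self-generated data", {
  tr <- noiseless_trial(seed = 1)
  r <- self_validate(tr$from, tr$to, standard_tf(), stimulus_onset = 10)
  expect_gt(r, 0.999)
})

test_that("self-validation against white noise is small", {
  tr <- noiseless_trial(seed = 2)
  set.seed(101)
  rs <- replicate(20, {
    noise <- tr$to
    noise$value <- rnorm(nrow(noise))
    self_validate(tr$from, noise, standard_tf(), stimulus_onset = 10)
  })
  expect_lt(stats::median(abs(rs)), 0.3)
})

test_that("identical subjects give a constant cross matrix", {
  cfg <- sim_config(noise_sd_from = 0, noise_sd_to = 0, n_subjects = 3,
                    inter_subject_jitter = 0, seed = 5)
  cohort <- make_cohort(cfg)
  report <- loo_cross_validate(cohort, rep(list(standard_tf()), 3))
  expect_equal(unname(diag(report$cross)), report$self_pearson)
  expect_true(all(abs(report$cross - report$cross[1, 1]) < 1e-9))
  expect_true(all(report$cross >= 0.999))
})

test_that("a sign-flipped subject produces a negative cross column", {
  cfg <- sim_config(noise_sd_from = 0.02, noise_sd_to = 0.05, n_subjects = 3,
                    seed = 6)
  cohort <- make_cohort(cfg)
  cohort$to[[2]]$value <- -cohort$to[[2]]$value
  report <- loo_cross_validate(cohort, rep(list(standard_tf()), 3))
  expect_true(all(report$cross[, 2] < 0))
  expect_true(all(report$cross[, c(1, 3)] > 0))
})

test_that("a single-subject cohort is flagged self-only", {
  cfg <- sim_config(noise_sd_from = 0, noise_sd_to = 0, n_subjects = 1, seed = 7)
  cohort <- make_cohort(cfg)
  report <- loo_cross_validate(cohort, list(standard_tf()))
  expect_true(report$self_only)
  expect_equal(report$selected, 1L)
  expect_true(is.na(glance(report)$mean_cross))
})

test_that("standard-TF selection follows the two-criterion rule", {
  fake_report <- function(mean_cross, cv_cross) {
    structure(list(subjects = sprintf("s%02d", seq_along(mean_cross)),
                   params = vector("list", length(mean_cross)),
                   self_pearson = mean_cross,
                   cross = diag(length(mean_cross)),
                   mean_cross = mean_cross, cv_cross = cv_cross,
                   self_only = FALSE, selected = NA_integer_),
              class = "cohort_report")
  }
  # A dominates both criteria
  expect_equal(select_standard_tf(fake_report(c(0.9, 0.8), c(0.1, 0.2))), 1L)
  # A has the highest mean, B the smallest CV: the first criterion wins
  expect_equal(select_standard_tf(fake_report(c(0.9, 0.8), c(0.3, 0.1))), 1L)
  expect_equal(select_standard_tf(fake_report(c(0.7, 0.95), c(0.05, 0.2))), 2L)
})

test_that("selection is equivariant under subject relabeling", {
  cfg <- sim_config(noise_sd_from = 0.02, noise_sd_to = 0.05, n_subjects = 4,
                    inter_subject_jitter = 0.1, seed = 8)
  cohort <- make_cohort(cfg)
  params <- purrr::map(cohort$true_tf, identity)
  report <- loo_cross_validate(cohort, params)
  perm <- c(3, 1, 4, 2)
  report_p <- loo_cross_validate(cohort[perm, ], params[perm])
  expect_equal(report_p$subjects[report_p$selected],
               report$subjects[report$selected])
  expect_equal(report_p$cross[order(perm), order(perm)],
               report$cross[, , drop = FALSE],
               ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("tidy and autoplot views of the cohort report are consistent", {
  cfg <- sim_config(noise_sd_from = 0, noise_sd_to = 0.05, n_subjects = 3, seed = 9)
  cohort <- make_cohort(cfg)
  report <- loo_cross_validate(cohort, rep(list(standard_tf()), 3))
  td <- tidy(report)
  expect_equal(nrow(td), 9)
  expect_equal(td$pearson[td$self], report$self_pearson)
  gl <- glance(report)
  expect_equal(sum(gl$selected), 1)
  expect_s3_class(autoplot(report), "ggplot")
})

test_that("voxel AUC ranking matches a Riemann-sum oracle and handles ties", {
  dt <- 0.1
  t <- seq(0, 20, dt)
  resp <- exp(-(t - 8)^2 / 4)
  amps <- c(A = 1, B = 3, C = 2, D = 1)
  panel <- purrr::map_dfr(names(amps), function(v) {
    tibble::tibble(voxel = v, time = t, value = amps[[v]] * resp)
  })
  rk <- rank_voxels_by_auc(panel, window = c(2, 18))
  expect_equal(rk$rank[match(c("B", "C", "A", "D"), rk$voxel)], c(1, 2, 3, 3))
  # oracle: trapezoid by hand on one voxel
  w <- t >= 2 & t <= 18
  brute <- sum(diff(t[w]) * (head(resp[w], -1) + tail(resp[w], -1)) / 2)
  expect_equal(rk$auc[rk$voxel == "A"], brute, tolerance = 1e-12)
  expect_error(rank_voxels_by_auc(panel, window = c(-5, 18)), "window")
  one <- panel[panel$voxel == "A", ]
  expect_error(rank_voxels_by_auc(one, c(2, 18)), "at least 2")
})

test_that("AUC ranking is invariant to trace scaling convention", {
  t <- seq(0, 10, 0.05)
  panel <- dplyr::bind_rows(
    tibble::tibble(voxel = "x", time = t, value = sin(t / 3)^2),
    tibble::tibble(voxel = "y", time = t, value = 2 * sin(t / 3)^2))
  rk <- rank_voxels_by_auc(panel, c(0, 10))
  expect_equal(rk$voxel[rk$rank == 1], "y")
  expect_equal(rk$auc[rk$voxel == "y"] / rk$auc[rk$voxel == "x"], 2,
               tolerance = 1e-12)
})
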