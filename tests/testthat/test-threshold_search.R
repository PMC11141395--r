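ann_for <- function(series, bites) {
  data.frame(video_id = vapply(series, `[[`, "", "video_id"),
             participant_id = vapply(series, `[[`, "", "participant_id"),
             meal_type = "lunch", texture_condition = "fast_soft",
             processing_condition = "processed",
             annotated_bites = as.integer(bites))
}

test_that("the scorer is the negative mean absolute count error", {
  series <- list(make_spike_series(10, "v1"), make_spike_series(20, "v2"))
  # exact annotations score 0 at any separating threshold
  expect_equal(score_threshold(0.5, series, ann_for(series, c(10, 20)),
                               window = 1), 0)
  # predicted (10, 20) against annotated (12, 18) -> -2
  expect_equal(score_threshold(0.5, series, ann_for(series, c(12, 18)),
                               window = 1), -2)
  # brute-force recomputation on a random fixture
  set.seed(8)
  rser <- lapply(1:4, function(i)
    make_ratio(runif(150), video_id = paste0("r", i), smoothed = TRUE,
               window = 1L))
  ann <- ann_for(rser, sample(10:30, 4))
  theta <- 0.7
  manual <- -mean(abs(vapply(rser, function(s) oracle_count(s$ratio, theta), 0L) -
                        ann$annotated_bites))
  expect_equal(score_threshold(theta, rser, ann, window = 1), manual)
  expect_lte(score_threshold(0.2, rser, ann, window = 1), 0)
  # unmatched video is a pairing error
  expect_error(score_threshold(0.5, series, ann[0, ]), "annotation")
})

test_that("meals under the bite minimum are discarded, boundary kept", {
  series <- lapply(1:3, function(i) make_spike_series(5, paste0("v", i)))
  ann <- ann_for(series, c(9, 10, 25))
  kept <- filter_meals(series, ann, min_bites = 10)
  expect_identical(vapply(kept$series, `[[`, "", "video_id"), c("v2", "v3"))
  expect_identical(nrow(kept$annotations), 2L)
  expect_error(filter_meals(series, ann_for(series, c(1, 2, 3))), "cannot tune")
})

test_that("fold count follows the 2-to-5 clamp rule", {
  expect_identical(cv_folds(14), 5L)
  expect_identical(cv_folds(3), 3L)
  expect_identical(cv_folds(2), 2L)
  expect_identical(cv_folds(100), 5L)
  expect_warning(k <- cv_folds(1), "no-CV")
  expect_true(is.na(k))
})

test_that("grid search equals exhaustive evaluation of the grid", {
  set.seed(21)
  coh <- simulate_cohort(n_participants = 1, videos_per_participant = 5,
                         template = trace_config(noise_sd = 0.03), seed = 21)
  ctrl <- search_control(grid_step = 0.05, seed = 4)
  res <- tune_threshold(coh$series, coh$annotations, "grid", ctrl)
  # independent oracle: rebuild the CV objective and scan the grid
  thetas <- seq(0.05, 1.5, by = 0.05)
  smoothed <- lapply(coh$series, smooth_ratio, window = 5L)
  set.seed(4)
  k <- suppressWarnings(cv_folds(length(smoothed)))
  fold_id <- sample(rep_len(seq_len(k), length(smoothed)))
  ann <- coh$annotations$annotated_bites[
    match(vapply(smoothed, `[[`, "", "video_id"), coh$annotations$video_id)]
  cvscore <- function(th) {
    mean(vapply(split(seq_along(smoothed), fold_id), function(idx) {
      preds <- vapply(idx, function(i) oracle_count(smoothed[[i]]$ratio, th), 0L)
      -mean(abs(preds - ann[idx]))
    }, 0))
  }
  scores <- vapply(thetas, cvscore, 0)
  best <- max(scores)
  expect_equal(res$cv_score, best)
  expect_equal(res$best_theta, min(thetas[scores == best]))
  expect_equal(res$candidates$score, scores)
})

test_that("all three methods recover the separating band on noise-free data", {
  coh <- simulate_cohort(n_participants = 1, videos_per_participant = 6,
                         template = trace_config(noise_sd = 0), seed = 31)
  band <- coh$truth$participant_bands[, 1]
  for (m in c("grid", "random", "bayesian")) {
    res <- tune_threshold(coh$series, coh$annotations, m,
                          search_control(seed = 2))
    expect_equal(res$cv_score, 0, info = m)
    expect_gt(res$best_theta, band[["lo"]])
    expect_lt(res$best_theta, band[["hi"]])
    expect_identical(res$method, m)
    expect_identical(res$seed, 2L)
  }
})

test_that("only one threshold is perfect on a two-level fixture", {
  # spikes of height 1 and extra spikes of height 0.4: only thresholds in
  # (0.4, 1) count exactly the tall spikes
  two_level <- function(n_tall, n_small, id) {
    x <- rep(0, 3 * (n_tall + n_small) + 3)
    x[3 * seq_len(n_tall)] <- 1
    x[3 * (n_tall + seq_len(n_small))] <- 0.4
    make_ratio(x, video_id = id, smoothed = TRUE, window = 1L)
  }
  series <- lapply(1:4, function(i) two_level(12, 8, paste0("v", i)))
  ann <- ann_for(series, rep(12, 4))
  ctrl <- search_control(grid_step = 0.1, window = 1, seed = 1)
  res <- tune_threshold(series, ann, "grid", ctrl)
  expect_equal(res$cv_score, 0)
  expect_gt(res$best_theta, 0.4)
  expect_lte(res$best_theta, 1)
  # ties break toward the smaller threshold: first grid point above 0.4
  expect_equal(res$best_theta, 0.45)
})

test_that("seeded searches are exactly reproducible", {
  coh <- simulate_cohort(n_participants = 1, videos_per_participant = 4,
                         template = trace_config(noise_sd = 0.02), seed = 13)
  for (m in c("random", "bayesian")) {
    a <- tune_threshold(coh$series, coh$annotations, m,
                        search_control(seed = 99))
    b <- tune_threshold(coh$series, coh$annotations, m,
                        search_control(seed = 99))
    expect_identical(a$best_theta, b$best_theta)
    expect_identical(a$candidates, b$candidates)
  }
})

test_that("leave-one-out transfer averages everyone but the target", {
  expect_equal(loocv_transfer(c(a = 0.4, b = 0.4, c = 0.4), "b"), 0.4)
  th <- setNames(1:15, paste0("P", 1:15))
  expect_equal(loocv_transfer(th, "P15"), 7.5)
  all_t <- loocv_thresholds(th)
  expect_identical(length(all_t), 15L)
  expect_identical(length(unique(all_t)), 15L)
  # the target's own value never enters its transferred mean
  for (p in names(th))
    expect_equal(all_t[[p]], mean(th[names(th) != p]))
  expect_error(loocv_transfer(th, "someone"), "unknown")
  expect_error(loocv_transfer(c(solo = 1), "solo"), "at least 2")
})
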