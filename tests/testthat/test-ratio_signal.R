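pts_with <- function(upper, lower, left, right) {
  pts <- matrix(runif(468 * 3), 468, 3)
  pts[1, ] <- upper    # mesh index 0
  pts[18, ] <- lower   # mesh index 17
  pts[62, ] <- left    # mesh index 61
  pts[292, ] <- right  # mesh index 291
  pts
}

test_that("mouth ratio matches hand-computed distances", {
  expect_equal(mouth_ratio(pts_with(c(0, 1, 0), c(0, -1, 0),
                                    c(-1, 0, 0), c(1, 0, 0))), 1)
  lips <- c(0.3, 0.4, 0.1)
  expect_equal(mouth_ratio(pts_with(lips, lips, c(0, 0, 0), c(1, 0, 0))), 0)
  # ||(1,2,2)-(1,0,0)|| / ||(0,0,0)-(3,0,0)|| = sqrt(8)/3
  expect_equal(mouth_ratio(pts_with(c(1, 2, 2), c(1, 0, 0),
                                    c(0, 0, 0), c(3, 0, 0))),
               0.94281, tolerance = 1e-5)
  # coincident corners are degenerate geometry
  expect_error(mouth_ratio(pts_with(c(0, 1, 0), c(0, 0, 0),
                                    c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5))),
               "degenerate")
  # no detected face is a missing value, not an error
  expect_identical(mouth_ratio(NULL), NA_real_)
  na_pts <- matrix(NA_real_, 468, 3)
  expect_identical(mouth_ratio(na_pts), NA_real_)
})

test_that("mouth ratio is invariant to rigid motion and uniform scale", {
  set.seed(42)
  for (i in 1:25) {
    pts <- matrix(rnorm(468 * 3), 468, 3)
    r0 <- mouth_ratio(pts)
    rot <- random_rotation()
    shift <- rnorm(3, sd = 10)
    scale <- runif(1, 0.1, 50)
    moved <- scale * (pts %*% rot) +
      matrix(shift, 468, 3, byrow = TRUE)
    expect_equal(mouth_ratio(moved), r0, tolerance = 1e-10)
  }
})

test_that("the 2D fallback ignores depth", {
  pts <- pts_with(c(0, 1, 5), c(0, -1, -5), c(-1, 0, 2), c(1, 0, 2))
  expect_equal(mouth_ratio(pts, use_z = FALSE), 1)
  expect_gt(mouth_ratio(pts, use_z = TRUE), 1)
})

test_that("ratio_series maps frames to values and gaps to missing", {
  pts <- array(rep(pts_with(c(0, 1, 0), c(0, -1, 0), c(-1, 0, 0), c(1, 0, 0)),
                   each = 5), c(5, 468, 3))
  ser <- landmark_series("v", "p", 30, pts)
  rs <- ratio_series(ser)
  expect_equal(rs$ratio, rep(1, 5))
  expect_false(rs$smoothed)

  pts[c(2, 4), , ] <- NA
  ser2 <- landmark_series("v", "p", 30, pts)
  rs2 <- ratio_series(ser2)
  expect_identical(is.na(rs2$ratio), c(FALSE, TRUE, FALSE, TRUE, FALSE))

  # per-frame degenerate geometry becomes missing with a warning
  pts3 <- pts
  pts3[3, 62, ] <- pts3[3, 292, ]
  ser3 <- landmark_series("v", "p", 30, pts3)
  expect_warning(rs3 <- ratio_series(ser3), "coincident")
  expect_true(is.na(rs3$ratio[3]))
  expect_equal(rs3$ratio[1], 1)
})

test_that("ratio_series inverts the landmark encoder to 1e-9", {
  cfg <- trace_config(duration_s = 4, n_bites = 2, seed = 9)
  lsim <- simulate_landmark_series(cfg)
  rsim <- simulate_ratio_trace(cfg)
  expect_equal(ratio_series(lsim$series)$ratio, rsim$series$ratio,
               tolerance = 1e-9)
})

test_that("trailing smoothing matches the brute-force windowed mean", {
  expect_equal(smooth_ratio(make_ratio(rep(0.3, 20)), 5)$ratio, rep(0.3, 20))
  expect_equal(smooth_ratio(make_ratio(c(0, 0, 0, 0, 5)), 5)$ratio[5], 1)
  set.seed(77)
  x <- runif(1000)
  x[sample(1000, 150)] <- NA
  for (w in c(1L, 2L, 5L, 31L)) {
    sm <- smooth_ratio(make_ratio(x), w)
    expect_equal(sm$ratio, oracle_smooth(x, w))
    expect_identical(length(sm), 1000L)
    expect_true(sm$smoothed)
    expect_identical(sm$window, w)
  }
  # w = 1 is the identity on non-missing values
  expect_equal(smooth_ratio(make_ratio(x), 1L)$ratio, x)
  expect_error(smooth_ratio(make_ratio(x), 0), "window")
  # an all-missing window stays missing
  y <- c(NA, NA, NA, 0.5)
  expect_identical(smooth_ratio(make_ratio(y), 2L)$ratio,
                   c(NA, NA, NA, 0.5))
})

test_that("outlier removal pools all of a participant's videos", {
  # single spike far above an otherwise flat signal
  x <- c(rep(0.1, 99), 10)
  rs <- make_ratio(x)
  out <- remove_outliers(rs, z_max = 3)
  expect_identical(which(is.na(out$ratio)), 100L)
  st <- attr(out, "outlier_stats")
  expect_equal(st[["center"]], mean(x))
  expect_equal(st[["scale"]], sd(x))
  expect_identical(st[["removed"]], 1)

  # removal count equals a direct z-score computation on random traces
  set.seed(5)
  lst <- lapply(1:3, function(i)
    make_ratio(abs(rnorm(200, 0.2, 0.3)), video_id = paste0("v", i)))
  pooled <- unlist(lapply(lst, `[[`, "ratio"))
  z <- abs(pooled - mean(pooled)) / sd(pooled)
  got <- remove_outliers(lst, z_max = 1.5)
  expect_identical(attr(got, "outlier_stats")[["removed"]],
                   as.numeric(sum(z > 1.5)))
  # frame counts unchanged
  expect_identical(vapply(got, length, 0L), vapply(lst, length, 0L))

  # sigma = 0: warn, change nothing
  flat <- make_ratio(rep(0.2, 50))
  expect_warning(unch <- remove_outliers(flat), "zero")
  expect_equal(unch$ratio, flat$ratio)

  # idempotent under frozen statistics
  st2 <- attr(out, "outlier_stats")
  again <- remove_outliers(out, z_max = 3,
                           center = st2[["center"]], scale = st2[["scale"]])
  expect_equal(again$ratio, out$ratio)
  expect_identical(attr(again, "outlier_stats")[["removed"]], 0)

  # videos of different participants must not be pooled
  other <- make_ratio(rep(0.2, 10), participant_id = "someone_else")
  expect_error(remove_outliers(list(rs, other)), "per participant")
})

test_that("ratio series round-trip through their CSV form", {
  rs <- smooth_ratio(make_ratio(c(0.1, NA, 0.5, 0.2), fps = 25), 2L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_ratio_series(rs, f)
  expect_equal(read_ratio_series(f), rs, tolerance = 1e-14)
})
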