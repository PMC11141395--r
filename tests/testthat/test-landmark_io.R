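test_that("landmark series round-trip through both CSV dialects", {
  set.seed(101)
  for (case in 1:4) {
    n <- sample(0:40, 1)
    ser <- random_landmark_series(n, gap_prob = ifelse(case %% 2, 0.3, 0))
    for (dialect in c("long", "wide")) {
      f <- withr::local_tempfile(fileext = ".csv")
      write_landmark_series(ser, f, dialect = dialect)
      back <- read_landmark_series(f)
      expect_equal(back, ser, tolerance = 1e-14)
      # reader never drops frames, gaps preserved as gaps
      expect_identical(length(back), length(ser))
      expect_identical(back$face_detected, ser$face_detected)
    }
  }
})

test_that("a multi-thousand-frame series survives a lossless round trip", {
  set.seed(7)
  ser <- random_landmark_series(2000, gap_prob = 0.05)
  f <- withr::local_tempfile(fileext = ".csv")
  write_landmark_series(ser, f, dialect = "long")
  expect_equal(read_landmark_series(f), ser, tolerance = 1e-14)
})

test_that("simulated landmark fixtures re-read identically", {
  sim <- simulate_landmark_series(trace_config(duration_s = 2, n_bites = 1,
                                               seed = 5))
  f <- withr::local_tempfile(fileext = ".csv")
  write_landmark_series(sim$series, f)
  expect_equal(read_landmark_series(f), sim$series, tolerance = 1e-14)
})

test_that("reader rejects malformed schemas and orderings", {
  set.seed(11)
  ser <- random_landmark_series(3, gap_prob = 0)
  f <- withr::local_tempfile(fileext = ".csv")

  # wide file with one coordinate column removed (467 points' worth)
  write_landmark_series(ser, f, dialect = "wide")
  lines <- readLines(f)
  hdr <- strsplit(lines[5], ",")[[1]]
  drop <- which(hdr == "x_467")
  fix <- vapply(lines[5:length(lines)], function(l) {
    paste(strsplit(l, ",")[[1]][-drop], collapse = ",")
  }, "")
  writeLines(c(lines[1:4], fix), f)
  expect_error(read_landmark_series(f), "x_467")

  # long file where one frame lost a point row
  write_landmark_series(ser, f, dialect = "long")
  lines <- readLines(f)
  writeLines(lines[-7], f)  # drop a point row of frame 0
  expect_error(read_landmark_series(f), "467")

  # long file with an extra column
  write_landmark_series(ser, f, dialect = "long")
  lines <- readLines(f)
  lines[5] <- paste0(lines[5], ",extra")
  lines[-(1:5)] <- paste0(lines[-(1:5)], ",1")
  writeLines(lines, f)
  expect_error(read_landmark_series(f), "extra")

  # non-monotone frame index
  write_landmark_series(ser, f, dialect = "wide")
  lines <- readLines(f)
  writeLines(c(lines[1:5], lines[8], lines[7], lines[6]), f)
  expect_error(read_landmark_series(f), "increasing|consecutive")
})

test_that("constructor enforces the 468-point and timing invariants", {
  expect_error(landmark_series("v", "p", 30,
                               array(0, c(2, 467, 3))), "468")
  pts <- array(runif(2 * 468 * 3), c(2, 468, 3))
  expect_error(landmark_series("v", "p", 30, pts, time_s = c(1, 1)),
               "increasing")
  expect_error(landmark_series("v", "p", -1, pts), "fps")
  # partially missing frame can be neither detected nor a gap
  pts[2, 5, 1] <- NA
  expect_error(landmark_series("v", "p", 30, pts), "face_detected")
  # empty series is fine
  empty <- landmark_series("v", "p", 30, array(0, c(0, 468, 3)))
  expect_identical(length(empty), 0L)
  f <- withr::local_tempfile(fileext = ".csv")
  write_landmark_series(empty, f)
  expect_equal(read_landmark_series(f), empty)
})

test_that("annotation tables are read and validated", {
  f <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(video_id = c("v1", "v2"), participant_id = "p1",
                   meal_type = c("lunch", "dessert"),
                   texture_condition = c("fast_soft", "slow_hard"),
                   processing_condition = c("processed", "unprocessed"),
                   annotated_bites = c(30L, 7L))
  write_annotations(df, f)
  got <- read_annotations(f)
  expect_identical(nrow(got), 2L)
  expect_identical(got$annotated_bites, c(30L, 7L))

  bad <- df; bad$texture_condition[1] <- "medium"
  expect_error(validate_annotations(bad), "medium")
  dup <- rbind(df, df[1, ])
  expect_error(validate_annotations(dup), "duplicate")
  neg <- df; neg$annotated_bites[1] <- -1L
  expect_error(validate_annotations(neg), "non-negative")
  short <- df[, -3]
  expect_error(validate_annotations(short), "meal_type")
})

test_that("a study-shaped cohort yields a 164-row annotation table", {
  coh <- simulate_cohort(seed = 3)
  f <- withr::local_tempfile(fileext = ".csv")
  write_annotations(coh$annotations, f)
  got <- read_annotations(f)
  expect_identical(nrow(got), 164L)
  expect_identical(length(unique(got$participant_id)), 15L)
})

test_that("extract_landmarks honours the pluggable backend contract", {
  face <- matrix(runif(468 * 3), 468, 3)
  fixed <- list(detect = function(img) face)
  ser <- extract_landmarks(vector("list", 5), fixed, fps = 30,
                           video_id = "vid", participant_id = "pp")
  expect_identical(length(ser), 5L)
  expect_true(all(ser$face_detected))
  expect_equal(ser$points[3, , ], face, ignore_attr = TRUE)

  alternating <- local({
    i <- 0L
    list(detect = function(img) {
      i <<- i + 1L
      if (i %% 2L) face else NULL
    })
  })
  ser2 <- extract_landmarks(vector("list", 6), alternating, fps = 30)
  expect_identical(ser2$face_detected, rep(c(TRUE, FALSE), 3))

  bad <- list(detect = function(img) face[1:467, ])
  expect_error(extract_landmarks(vector("list", 1), bad, fps = 30),
               "contract")

  # file-path source goes through the backend's own frame reader
  withfile <- list(detect = function(img) face,
                   read_frames = function(path) list(frames = vector("list", 4),
                                                     fps = 12))
  f <- withr::local_tempfile(fileext = ".mp4"); file.create(f)
  ser3 <- extract_landmarks(f, withfile)
  expect_identical(length(ser3), 4L)
  expect_identical(ser3$fps, 12)
  expect_error(extract_landmarks("nope.mp4", withfile), "cannot read")
  expect_error(extract_landmarks(f, fixed), "read_frames")
})
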