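# Independent oracles and fixture builders shared across tests.

# Brute-force bite counter: explicit state machine over frames. A bite
# starts whenever a frame is above threshold and the previous frame was
# not (missing counts as not above).
oracle_count <- function(x, theta) {
  n_runs <- 0L
  in_run <- FALSE
  for (v in x) {
    if (!is.na(v) && v > theta) {
      if (!in_run) n_runs <- n_runs + 1L
      in_run <- TRUE
    } else {
      in_run <- FALSE
    }
  }
  n_runs
}

# Brute-force trailing windowed mean over available values.
oracle_smooth <- function(x, w) {
  n <- length(x)
  out <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    win <- x[max(1L, t - w + 1L):t]
    win <- win[!is.na(win)]
    if (length(win)) out[t] <- mean(win)
  }
  out
}

# Spearman's rho from first principles: average ranks for ties, then
# the Pearson product-moment formula on the ranks.
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

make_ratio <- function(values, video_id = "v1", participant_id = "p1",
                       fps = 30, smoothed = FALSE, window = NA_integer_) {
  new_ratio_series(video_id, participant_id, fps, values,
                   smoothed = smoothed, window = window)
}

# A pre-smoothed series of isolated unit spikes on a zero baseline:
# count at any threshold in (0, 1) equals n_spikes exactly.
make_spike_series <- function(n_spikes, video_id = "v1",
                              participant_id = "p1") {
  x <- rep(0, 3 * n_spikes + 3)
  if (n_spikes > 0) x[3 * seq_len(n_spikes)] <- 1
  make_ratio(x, video_id, participant_id, smoothed = TRUE, window = 1L)
}

# Random landmark series with optional no-face gaps, for I/O round trips.
random_landmark_series <- function(n_frames, gap_prob = 0.2,
                                   video_id = "v1", participant_id = "p1",
                                   fps = 25) {
  pts <- array(runif(n_frames * 468 * 3), c(n_frames, 468L, 3L))
  gaps <- runif(n_frames) < gap_prob
  pts[gaps, , ] <- NA_real_
  landmark_series(video_id, participant_id, fps, points = pts)
}

# Random 3-D rotation matrix via QR decomposition.
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

# Annotated/predicted per-participant totals of the evaluation cohort
# (15 participants, three search methods), used by the report tests.
cohort_totals <- function() {
  list(
    participant = LETTERS[c(1:9, 12:17)][1:15],
    annotated = c(554, 502, 552, 450, 657, 241, 478, 607, 443, 668, 349,
                  389, 179, 406, 244),
    grid = c(524, 662, 917, 521, 490, 214, 520, 594, 327, 1031, 254, 354,
             256, 513, 246),
    random = c(532, 647, 597, 516, 572, 193, 516, 559, 328, 1019, 220,
               353, 264, 504, 240),
    bayesian = c(369, 1334, 947, 519, 490, 618, 525, 620, 327, 958, 252,
                 412, 256, 507, 243))
}
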