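#' Configuration of a synthetic mouth-ratio trace
#'
#' Describes the generative model behind the synthetic signals: a
#' baseline mouth ratio with Gaussian noise, a sub-threshold sinusoidal
#' chewing oscillation (chewing produces fairly uniform mouth ratios and
#' is deliberately kept below any sensible bite threshold), and smooth
#' raised-cosine bite bumps — one per planted bite — whose peaks clear
#' the noise floor. The separability invariant
#' `baseline + 3*noise_sd + chew_amp < baseline + bite_amp` guarantees
#' that in the noise-free limit a band of thresholds exists that
#' recovers every planted bite exactly.
#'
#' @param fps frames per second (default 30, a common camera rate).
#' @param duration_s video duration in seconds.
#' @param baseline resting (closed-mouth) ratio level.
#' @param noise_sd standard deviation of the per-frame Gaussian noise.
#' @param chew_amp,chew_freq amplitude (unitless, >= 0) and frequency
#'   (Hz) of the chewing oscillation; the oscillation is non-negative,
#'   riding on top of the baseline.
#' @param n_bites number of planted bites (>= 0).
#' @param bite_amp peak height of a bite bump above the baseline.
#' @param bite_width_s full width of the raised-cosine bump in seconds.
#' @param gap_s minimum separation between consecutive bite peaks in
#'   seconds (a refractory gap).
#' @param seed RNG seed; every simulated artifact is bit-identical under
#'   the same config.
#' @return An object of class `trace_config`.
#' @export
trace_config <- function(fps = 30, duration_s = 60, baseline = 0.12,
                         noise_sd = 0.02, chew_amp = 0.08, chew_freq = 1.5,
                         n_bites = 10L, bite_amp = 0.6, bite_width_s = 0.8,
                         gap_s = 2, seed = 1L) {
  if (fps <= 0 || duration_s <= 0) stop_("'fps' and 'duration_s' must be positive")
  if (baseline < 0 || noise_sd < 0 || chew_amp < 0 || bite_amp <= 0)
    stop_("amplitudes must be non-negative and 'bite_amp' positive")
  if (n_bites < 0 || n_bites != floor(n_bites)) stop_("'n_bites' must be a non-negative integer")
  if (3 * noise_sd + chew_amp >= bite_amp)
    stop_("planted bites are not separable: need 3*noise_sd + chew_amp < bite_amp")
  if (n_bites > 0 &&
      bite_width_s + (n_bites - 1) * gap_s > duration_s)
    stop_("config error: ", n_bites, " bites with a ", gap_s,
          "s gap do not fit in ", duration_s, "s")
  structure(list(fps = fps, duration_s = duration_s, baseline = baseline,
                 noise_sd = noise_sd, chew_amp = chew_amp,
                 chew_freq = chew_freq, n_bites = as.integer(n_bites),
                 bite_amp = bite_amp, bite_width_s = bite_width_s,
                 gap_s = gap_s, seed = as.integer(seed)),
            class = "trace_config")
}

# raised-cosine bump centred at tp, full width w, unit peak
.bump <- function(t, tp, w) {
  u <- (t - tp) / w
  ifelse(abs(u) <= 0.5, 0.5 * (1 + cos(2 * pi * u)), 0)
}

# noise-free trace components for a given set of peak times / phase
.nf_trace <- function(cfg, t, peaks, phase) {
  chew <- cfg$chew_amp * 0.5 * (1 + sin(2 * pi * cfg$chew_freq * t + phase))
  bumps <- rep(0, length(t))
  for (tp in peaks) bumps <- bumps + cfg$bite_amp * .bump(t, tp, cfg$bite_width_s)
  cfg$baseline + chew + bumps
}

# Separating-threshold band of the 5-frame trailing-smoothed noise-free
# trace — the signal the detector actually thresholds. The trailing
# window smears each bump forward by window-1 frames, so the bump
# support is extended accordingly when splitting inside from outside.
.truth_band <- function(cfg, t, peaks, phase, window = 5L) {
  nf <- .nf_trace(cfg, t, peaks, phase)
  nf_s <- smooth_ratio(new_ratio_series("nf", "nf", cfg$fps, nf, time_s = t),
                       window)$ratio
  half <- cfg$bite_width_s / 2
  tail_s <- (window - 1) / cfg$fps
  in_bump_ext <- rep(FALSE, length(t))
  for (tp in peaks)
    in_bump_ext <- in_bump_ext | (t >= tp - half & t <= tp + half + tail_s)
  lo <- max(nf_s[!in_bump_ext], cfg$baseline)
  hi <- if (length(peaks)) {
    min(vapply(peaks, function(tp) {
      max(nf_s[t >= tp - half & t <= tp + half + tail_s])
    }, 0))
  } else Inf
  c(lo = lo, hi = hi)
}

#' Simulate a mouth-ratio trace with planted bites
#'
#' Generates one video's worth of mouth-ratio signal from a
#' [trace_config()], together with its ground truth: the planted bite
#' peak times and the separating threshold band `[lo, hi]` within which
#' (in the noise-free limit, for both the raw and the 5-frame smoothed
#' trace) any strictly interior threshold recovers exactly the planted
#' bites. Peak times are placed with at least `gap_s` separation,
#' jittered uniformly within the available slack. Negative noise
#' excursions are clamped at zero since a ratio of distances cannot be
#' negative.
#'
#' @param config a [trace_config()].
#' @param video_id,participant_id identifiers for the generated series.
#' @return `list(series = <raw ratio_series>, truth = list(onsets_s,
#'   band, n_bites))`.
#' @export
#' @examples
#' sim <- simulate_ratio_trace(trace_config(n_bites = 3, noise_sd = 0))
#' count_bites(sim$series, mean(sim$truth$band))  # 3
simulate_ratio_trace <- function(config, video_id = "synthetic",
                                 participant_id = "synthetic") {
  stopifnot(inherits(config, "trace_config"))
  set.seed(config$seed)
  n <- round(config$fps * config$duration_s)
  t <- (seq_len(n) - 1) / config$fps
  phase <- runif(1, 0, 2 * pi)
  peaks <- numeric()
  if (config$n_bites > 0L) {
    half <- config$bite_width_s / 2
    span <- config$duration_s - 2 * half
    slack <- span - (config$n_bites - 1) * config$gap_s
    if (slack < 0) stop_("config error: bites do not fit in the duration")
    jit <- sort(runif(config$n_bites, 0, slack))
    peaks <- half + (seq_len(config$n_bites) - 1) * config$gap_s + jit
  }
  nf <- .nf_trace(config, t, peaks, phase)
  trace <- pmax(0, nf + rnorm(n, 0, config$noise_sd))
  band <- .truth_band(config, t, peaks, phase)
  if (band[["lo"]] >= band[["hi"]])
    stop_("config error: no separating threshold band exists ",
          "(bump too narrow for the smoothing window?)")
  series <- new_ratio_series(video_id, participant_id, config$fps, trace,
                             time_s = t)
  list(series = series,
       truth = list(onsets_s = peaks, band = band,
                    n_bites = config$n_bites))
}

#' Simulate a face-mesh landmark series encoding a known ratio trace
#'
#' Builds a full 468-point landmark series whose mouth key points are
#' placed so that [mouth_ratio()] reproduces the simulated trace
#' exactly: the mouth corners sit a fixed width apart and the lip
#' separation equals `trace * width`. The remaining 464 points form an
#' arbitrary but valid static lattice in normalized coordinates.
#'
#' @inheritParams simulate_ratio_trace
#' @param keymap a [mouth_keypoints()] map to encode through.
#' @return `list(series = <landmark_series>, truth = ...)`, with the
#'   same ground truth as [simulate_ratio_trace()].
#' @export
simulate_landmark_series <- function(config, video_id = "synthetic",
                                     participant_id = "synthetic",
                                     keymap = mouth_keypoints()) {
  sim <- simulate_ratio_trace(config, video_id, participant_id)
  r <- sim$series$ratio
  n <- length(r)
  width <- 0.2
  base <- matrix(0, 468L, 3L)
  i <- 0:467
  base[, 1L] <- 0.1 + 0.8 * ((i %% 26) / 25)
  base[, 2L] <- 0.1 + 0.8 * ((i %/% 26) / 17)
  base[, 3L] <- 0.02 * sin(i / 7)
  pts <- array(rep(base, each = n), c(n, 468L, 3L))
  pts[, keymap$left + 1L, ] <- matrix(rep(c(0.4, 0.5, 0), each = n), n)
  pts[, keymap$right + 1L, ] <- matrix(rep(c(0.6, 0.5, 0), each = n), n)
  pts[, keymap$upper + 1L, 1L] <- 0.5
  pts[, keymap$upper + 1L, 2L] <- 0.5 - r * width / 2
  pts[, keymap$upper + 1L, 3L] <- 0
  pts[, keymap$lower + 1L, 1L] <- 0.5
  pts[, keymap$lower + 1L, 2L] <- 0.5 + r * width / 2
  pts[, keymap$lower + 1L, 3L] <- 0
  series <- landmark_series(video_id, participant_id, config$fps,
                            points = pts, time_s = sim$series$time_s)
  list(series = series, truth = sim$truth)
}

#' Simulate an annotated cohort with known ground truth
#'
#' Generates a whole study's worth of mouth-ratio series plus the
#' matching annotation table, mirroring the structure of a 15
#' participant / 164 video eating-behavior dataset. Each participant
#' gets jittered baseline and amplitude parameters (creating a distinct
#' true threshold band); each video gets a texture condition that
#' shapes its bites — `fast_soft` meals have larger, wider mouth
#' openings but fewer bites, `slow_hard` meals smaller, narrower
#' openings and more bites. Annotated bite counts are filled from the
#' ground truth. Parameter draws violating the separability invariant
#' are rejected and resampled.
#'
#' @param n_participants number of participants (default 15).
#' @param videos_per_participant `NULL` for the study-shaped default
#'   (10, 14, 14, 13, 11, 6, 14, 14, 13, 13, 7, 12, 8, 9, 6 when
#'   `n_participants` is 15, otherwise draws from 6:14); a single
#'   number; a length-2 range; or a vector of length `n_participants`.
#' @param template a [trace_config()] providing fps, baseline, noise,
#'   chewing and bite-shape parameters (its `duration_s`, `n_bites` and
#'   `seed` are overridden per video).
#' @param jitter relative jitter of per-participant parameters
#'   (default 0.15).
#' @param bites_soft,bites_hard inclusive bite-count ranges per texture
#'   condition.
#' @param seed cohort RNG seed.
#' @return `list(series = <list of ratio_series>, annotations =
#'   <data.frame>, truth = list(per_video, participant_bands))`, where
#'   `participant_bands` is a 2-row (`lo`, `hi`) matrix of the per
#'   participant separating bands (intersection over their videos).
#' @export
#' @examples
#' coh <- simulate_cohort(n_participants = 2, videos_per_participant = 3,
#'                        seed = 42)
#' nrow(coh$annotations)  # 6
simulate_cohort <- function(n_participants = 15L,
                            videos_per_participant = NULL,
                            template = trace_config(),
                            jitter = 0.15,
                            bites_soft = c(15L, 35L),
                            bites_hard = c(30L, 55L),
                            seed = 1L) {
  stopifnot(inherits(template, "trace_config"))
  set.seed(seed)
  nv <- videos_per_participant
  if (is.null(nv)) {
    nv <- if (n_participants == 15L)
      c(10L, 14L, 14L, 13L, 11L, 6L, 14L, 14L, 13L, 13L, 7L, 12L, 8L, 9L, 6L)
    else sample(6:14, n_participants, replace = TRUE)
  } else if (length(nv) == 1L) {
    nv <- rep(as.integer(nv), n_participants)
  } else if (length(nv) == n_participants) {
    nv <- as.integer(nv)
  } else if (length(nv) == 2L) {
    nv <- sample(seq(nv[1L], nv[2L]), n_participants, replace = TRUE)
  } else stop_("'videos_per_participant' has an unusable length")
  pids <- sprintf("P%02d", seq_len(n_participants))
  series <- list()
  ann_rows <- list()
  per_video <- list()
  bands <- matrix(NA_real_, 2L, n_participants,
                  dimnames = list(c("lo", "hi"), pids))
  for (p in seq_len(n_participants)) {
    # participant-level parameter jitter, resampled until separable
    for (try in 1:100) {
      fac <- runif(3, 1 - jitter, 1 + jitter)
      baseline_p <- template$baseline * fac[1L]
      chew_p <- template$chew_amp * fac[2L]
      amp_p <- template$bite_amp * fac[3L]
      if (3 * template$noise_sd + chew_p < amp_p) break
      if (try == 100) stop_("could not draw separable participant parameters")
    }
    p_lo <- -Inf; p_hi <- Inf
    for (v in seq_len(nv[p])) {
      texture <- if (v %% 2L == 1L) "slow_hard" else "fast_soft"
      n_b <- if (texture == "fast_soft")
        sample(seq(bites_soft[1L], bites_soft[2L]), 1L)
      else sample(seq(bites_hard[1L], bites_hard[2L]), 1L)
      width_v <- template$bite_width_s * if (texture == "fast_soft") 1.3 else 0.8
      duration <- n_b * template$gap_s * 1.5 + 10
      vseed <- sample.int(2^30, 1L)
      cfg <- trace_config(fps = template$fps, duration_s = duration,
                          baseline = baseline_p,
                          noise_sd = template$noise_sd,
                          chew_amp = chew_p, chew_freq = template$chew_freq,
                          n_bites = n_b, bite_amp = amp_p,
                          bite_width_s = width_v, gap_s = template$gap_s,
                          seed = vseed)
      vid <- sprintf("%s_V%02d", pids[p], v)
      sim <- simulate_ratio_trace(cfg, video_id = vid,
                                  participant_id = pids[p])
      series[[vid]] <- sim$series
      per_video[[vid]] <- sim$truth
      p_lo <- max(p_lo, sim$truth$band[["lo"]])
      p_hi <- min(p_hi, sim$truth$band[["hi"]])
      ann_rows[[vid]] <- data.frame(
        video_id = vid, participant_id = pids[p],
        meal_type = .meal_types[(v - 1L) %% 4L + 1L],
        texture_condition = texture,
        processing_condition = .processing_conditions[(v - 1L) %% 2L + 1L],
        annotated_bites = n_b)
    }
    if (p_lo >= p_hi)
      stop_("no common separating band for participant ", pids[p])
    bands[, p] <- c(p_lo, p_hi)
  }
  list(series = series,
       annotations = validate_annotations(do.call(rbind, c(ann_rows, make.row.names = FALSE))),
       truth = list(per_video = per_video, participant_bands = bands))
}
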