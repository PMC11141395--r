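#' The bite-counting model
#'
#' The entire "model" of the rule-based counter: a mouth-ratio threshold,
#' the smoothing window, and the key-point map the ratio is computed
#' from. A bite is counted for every maximal run of consecutive frames
#' whose smoothed mouth ratio strictly exceeds the threshold — the run
#' (debouncing) rule prevents a single mouth opening from being counted
#' once per frame. The model has no trained parameters; the threshold is
#' tuned per participant by [tune_threshold()] / [fit_bite_counter()].
#'
#' @param threshold mouth-ratio threshold (> 0) above which the mouth
#'   counts as open for a bite.
#' @param window smoothing window in frames (default 5); applied by the
#'   detector when it is handed a raw series.
#' @param keymap a [mouth_keypoints()] map.
#' @param min_gap optional refractory rule: two above-threshold runs
#'   separated by `min_gap` or fewer below-threshold frames are merged
#'   into one event. Default 0 (off): runs separated even by a single
#'   below-threshold frame are distinct bites.
#' @param bridge_gaps optional gap bridging: a gap of missing frames of
#'   this length or shorter inside a run does not terminate it. Default
#'   0 (off): a missing frame always ends the run.
#' @return An object of class `bite_model`.
#' @seealso [detect_events()], [count_bites()]
#' @export
#' @examples
#' m <- bite_model(threshold = 0.5)
#' coef(m)
bite_model <- function(threshold, window = 5L, keymap = mouth_keypoints(),
                       min_gap = 0L, bridge_gaps = 0L) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      !is.finite(threshold) || threshold <= 0)
    stop_("'threshold' must be a single positive number")
  if (!is.numeric(window) || window < 1 || window != floor(window))
    stop_("'window' must be an integer >= 1")
  if (!inherits(keymap, "mouth_keypoints")) stop_("'keymap' must be a mouth_keypoints map")
  if (min_gap < 0 || bridge_gaps < 0) stop_("'min_gap'/'bridge_gaps' must be >= 0")
  structure(list(threshold = threshold, window = as.integer(window),
                 keymap = keymap, min_gap = as.integer(min_gap),
                 bridge_gaps = as.integer(bridge_gaps)),
            class = "bite_model")
}

#' @export
print.bite_model <- function(x, ...) {
  cat("Bite-count model: threshold", format(x$threshold),
      "| smoothing window", x$window, "frames\n")
  if (x$min_gap > 0) cat("  merging runs separated by <=", x$min_gap, "frames\n")
  if (x$bridge_gaps > 0) cat("  bridging missing gaps of <=", x$bridge_gaps, "frames\n")
  invisible(x)
}

#' @export
coef.bite_model <- function(object, ...) c(threshold = object$threshold)

.as_smoothed_ratio <- function(series, model) {
  if (inherits(series, "landmark_series"))
    series <- ratio_series(series, model$keymap)
  if (!inherits(series, "ratio_series"))
    stop_("'series' must be a ratio_series or landmark_series")
  if (!series$smoothed) {
    series <- smooth_ratio(series, model$window)
  } else if (!is.na(series$window) && series$window != model$window) {
    warn_("series was smoothed with window ", series$window,
          ", model expects ", model$window, "; using the series as given")
  }
  series
}

#' Detect bite events in a ratio series
#'
#' Scans the smoothed mouth-ratio trace and emits one timestamped event
#' per maximal run of consecutive frames with ratio strictly above the
#' model threshold. The event onset is the first frame of the run, its
#' peak the largest ratio within it. Missing frames (no face detected,
#' or removed as outliers) terminate a run, so an opening interrupted by
#' a detection drop-out is counted conservatively (see `bridge_gaps` in
#' [bite_model()] to relax this).
#'
#' @param series a `ratio_series` (smoothed with the model window, or
#'   raw — the detector then smooths internally) or a
#'   [landmark_series()].
#' @param model a [bite_model()].
#' @return An object of class `bite_result`: a list with `video_id`,
#'   `predicted_bites`, an `events` data.frame
#'   (`onset_frame,onset_time_s,peak_ratio,duration_frames`), and the
#'   producing `threshold` and `window`.
#' @export
#' @examples
#' rs <- new_ratio_series("v", "p", 30, c(.1, .6, .7, .2, .8, .1),
#'                        smoothed = TRUE, window = 1L)
#' detect_events(rs, bite_model(0.5, window = 1))$predicted_bites  # 2
detect_events <- function(series, model) {
  stopifnot(inherits(model, "bite_model"))
  series <- .as_smoothed_ratio(series, model)
  x <- series$ratio
  n <- length(x)
  above <- !is.na(x) & x > model$threshold
  if (model$bridge_gaps > 0L && n > 0L) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (!r$values[j] && j > 1L && j < length(r$values) &&
          r$lengths[j] <= model$bridge_gaps &&
          all(is.na(x[starts[j]:ends[j]])))
        above[starts[j]:ends[j]] <- TRUE
    }
  }
  if (model$min_gap > 0L && n > 0L) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in seq_along(r$values)) {
      if (!r$values[j] && j > 1L && j < length(r$values) &&
          r$lengths[j] <= model$min_gap)
        above[starts[j]:ends[j]] <- TRUE
    }
  }
  events <- data.frame(onset_frame = integer(), onset_time_s = numeric(),
                       peak_ratio = numeric(), duration_frames = integer())
  if (n > 0L && any(above)) {
    r <- rle(above)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    events <- data.frame(
      onset_frame = series$frame[starts[keep]],
      onset_time_s = series$time_s[starts[keep]],
      peak_ratio = vapply(keep, function(j)
        max(x[starts[j]:ends[j]], na.rm = TRUE), 0),
      duration_frames = r$lengths[keep])
  }
  structure(list(video_id = series$video_id,
                 participant_id = series$participant_id,
                 predicted_bites = nrow(events), events = events,
                 threshold = model$threshold, window = model$window),
            class = "bite_result")
}

#' @export
print.bite_result <- function(x, ...) {
  cat("Bite detection for '", x$video_id, "': ", x$predicted_bites,
      " bite(s) at threshold ", format(x$threshold), "\n", sep = "")
  if (x$predicted_bites > 0) print(utils::head(x$events, 10L))
  invisible(x)
}

#' Count bites in a ratio series
#'
#' Convenience wrapper over [detect_events()] returning only the number
#' of detected bite events.
#'
#' @param series a `ratio_series` or [landmark_series()].
#' @param threshold mouth-ratio threshold (> 0).
#' @param window smoothing window in frames (default 5).
#' @param ... further arguments to [bite_model()].
#' @return Integer bite count.
#' @export
count_bites <- function(series, threshold, window = 5L, ...) {
  detect_events(series, bite_model(threshold, window = window, ...))$predicted_bites
}

# Fast run counter used by the threshold search: number of maximal runs
# of x strictly above theta, NA terminating a run. Must agree with
# detect_events() at min_gap = bridge_gaps = 0.
count_runs <- function(x, theta) {
  above <- !is.na(x) & x > theta
  sum(above & !c(FALSE, head(above, -1L)))
}
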