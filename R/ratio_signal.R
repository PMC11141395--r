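#' Mouth key-point map
#'
#' Indices (0-based, into the 468-point face mesh) of the four landmarks
#' the mouth ratio is built from: upper lip (0), lower lip (17), left
#' mouth corner (61) and right mouth corner (291).
#'
#' @param upper,lower,left,right mesh indices in \[0, 467\], all distinct.
#' @return An object of class `mouth_keypoints`.
#' @export
#' @examples
#' mouth_keypoints()
mouth_keypoints <- function(upper = 0L, lower = 17L, left = 61L, right = 291L) {
  idx <- c(upper = upper, lower = lower, left = left, right = right)
  if (any(idx != floor(idx)) || any(idx < 0) || any(idx > 467))
    stop_("key-point indices must be integers in [0, 467]")
  if (anyDuplicated(idx)) stop_("key-point indices must be distinct")
  structure(lapply(as.list(idx), as.integer), class = "mouth_keypoints")
}

#' @export
print.mouth_keypoints <- function(x, ...) {
  cat("Mouth key points (face-mesh indices): upper", x$upper, "lower", x$lower,
      "left", x$left, "right", x$right, "\n")
  invisible(x)
}

#' Mouth ratio of a single frame
#'
#' The mouth ratio is the Euclidean distance between the upper and lower
#' lip key points divided by the distance between the left and right
#' mouth corners. It is near 0 for a closed mouth and rises during mouth
#' opening, which makes it the signal bites are detected on. Being a
#' ratio of distances it is invariant under translation, rotation and
#' uniform scaling of the face, so it needs no camera calibration.
#'
#' @param points 468 x 3 numeric matrix of (x, y, z) mesh coordinates for
#'   one frame, or `NULL`/all-`NA` for a frame with no detected face
#'   (returns `NA`).
#' @param keymap a [mouth_keypoints()] map.
#' @param use_z include the depth coordinate in the distances (default).
#'   Setting `FALSE` gives the 2D ratio used with 68-point detectors.
#' @return A non-negative scalar, or `NA_real_` when no face is present.
#'   Coincident mouth corners are a degenerate geometry and raise an
#'   error.
#' @export
#' @examples
#' pts <- matrix(0, 468, 3)
#' pts[1, ] <- c(0, 1, 0)    # upper lip (mesh index 0)
#' pts[18, ] <- c(0, -1, 0)  # lower lip (mesh index 17)
#' pts[62, ] <- c(-1, 0, 0)  # left corner (mesh index 61)
#' pts[292, ] <- c(1, 0, 0)  # right corner (mesh index 291)
#' mouth_ratio(pts)  # 1
mouth_ratio <- function(points, keymap = mouth_keypoints(), use_z = TRUE) {
  if (is.null(points)) return(NA_real_)
  idx <- c(keymap$upper, keymap$lower, keymap$left, keymap$right) + 1L
  p <- points[idx, , drop = FALSE]
  if (anyNA(p)) return(NA_real_)
  if (!use_z) p[, 3L] <- 0
  num <- sqrt(sum((p[1L, ] - p[2L, ])^2))
  den <- sqrt(sum((p[3L, ] - p[4L, ])^2))
  if (den == 0) stop_("degenerate geometry: mouth corners coincide")
  num / den
}

#' Construct a mouth-ratio series directly
#'
#' Low-level constructor used by [ratio_series()], the synthetic
#' generators and the readers. `ratio` may contain `NA` for frames where
#' no face was detected or the value was removed as an outlier.
#'
#' @param video_id,participant_id identifiers.
#' @param fps frames per second (> 0).
#' @param ratio numeric vector of per-frame mouth ratios (>= 0 or `NA`).
#' @param time_s frame timestamps, strictly increasing; default `frame/fps`.
#' @param smoothed whether `ratio` has already been smoothed.
#' @param window smoothing window length in frames (recorded when
#'   `smoothed` is `TRUE`).
#' @return An object of class `ratio_series`.
#' @export
new_ratio_series <- function(video_id, participant_id, fps, ratio,
                             time_s = NULL, smoothed = FALSE,
                             window = NA_integer_) {
  if (!is.numeric(fps) || fps <= 0) stop_("'fps' must be positive")
  n <- length(ratio)
  if (any(ratio < 0, na.rm = TRUE)) stop_("mouth ratios must be non-negative")
  if (is.null(time_s)) time_s <- if (n > 0L) (seq_len(n) - 1) / fps else numeric()
  if (length(time_s) != n) stop_("'time_s' length must equal length(ratio)")
  if (n > 1L && any(diff(time_s) <= 0)) stop_("'time_s' must be strictly increasing")
  if (isTRUE(smoothed) && (is.na(window) || window < 1L))
    stop_("a smoothed series must record its window length")
  structure(
    list(video_id = video_id, participant_id = participant_id, fps = fps,
         frame = if (n > 0L) seq_len(n) - 1L else integer(),
         time_s = as.numeric(time_s), ratio = as.numeric(ratio),
         smoothed = isTRUE(smoothed), window = as.integer(window)),
    class = "ratio_series")
}

#' @export
print.ratio_series <- function(x, ...) {
  cat("Mouth-ratio series '", x$video_id, "' (participant ",
      x$participant_id, ")\n", sep = "")
  cat("  ", length(x$frame), " frames at ", x$fps, " fps; ",
      sum(is.na(x$ratio)), " missing", sep = "")
  if (x$smoothed) cat("; smoothed, window ", x$window, " frames", sep = "")
  cat("\n")
  invisible(x)
}

#' @export
length.ratio_series <- function(x) length(x$frame)

#' @export
as.data.frame.ratio_series <- function(x, ...) {
  data.frame(video_id = rep(x$video_id, length(x$frame)),
             participant_id = rep(x$participant_id, length(x$frame)),
             frame = x$frame, time_s = x$time_s, ratio = x$ratio,
             smoothed = rep(x$smoothed, length(x$frame)))
}

#' Plot a mouth-ratio trace
#'
#' Draws the ratio against time, optionally with a horizontal threshold
#' line and the detected bite onsets marked — the trace-versus-threshold
#' view used to inspect why a bite was or was not counted.
#'
#' @param x a `ratio_series`.
#' @param threshold optional bite threshold to draw and detect against.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ratio_series <- function(x, threshold = NULL, ...) {
  plot(x$time_s, x$ratio, type = "l", col = "darkorange",
       xlab = "time (s)", ylab = "mouth ratio",
       main = paste0(x$video_id, if (x$smoothed)
         paste0(" (smoothed, w=", x$window, ")")), ...)
  if (!is.null(threshold)) {
    abline(h = threshold, col = "grey40", lty = 2)
    ev <- detect_events(x, bite_model(threshold,
                                      window = if (x$smoothed) x$window else 5L))
    if (ev$predicted_bites > 0)
      points(ev$events$onset_time_s,
             rep(threshold, ev$predicted_bites), pch = 17, col = "steelblue")
  }
  invisible(x)
}

#' Mouth-ratio series of a landmark series
#'
#' Computes the mouth ratio for every frame of a landmark series. Frames
#' without a detected face yield missing values; frames with coincident
#' mouth corners are degenerate and also become missing, with a single
#' warning reporting how many.
#'
#' @param series a [landmark_series()].
#' @param keymap a [mouth_keypoints()] map.
#' @param use_z include the depth coordinate (see [mouth_ratio()]).
#' @return A raw (unsmoothed) `ratio_series` of the same length.
#' @export
ratio_series <- function(series, keymap = mouth_keypoints(), use_z = TRUE) {
  stopifnot(inherits(series, "landmark_series"))
  idx <- c(keymap$upper, keymap$lower, keymap$left, keymap$right) + 1L
  n <- length(series$frame)
  if (n == 0L)
    return(new_ratio_series(series$video_id, series$participant_id,
                            series$fps, numeric()))
  p <- series$points[, idx, , drop = FALSE]   # n x 4 x 3
  if (!use_z) p[, , 3L] <- 0
  pt <- function(j) matrix(p[, j, ], nrow = n)
  num <- sqrt(rowSums((pt(1L) - pt(2L))^2))
  den <- sqrt(rowSums((pt(3L) - pt(4L))^2))
  r <- num / den
  degen <- !is.na(den) & den == 0
  if (any(degen)) {
    warn_(sum(degen), " frame(s) with coincident mouth corners set to missing")
    r[degen] <- NA_real_
  }
  r[!series$face_detected] <- NA_real_
  new_ratio_series(series$video_id, series$participant_id, series$fps,
                   ratio = r, time_s = series$time_s)
}

#' Smooth a ratio series with a trailing moving average
#'
#' The value at frame `t` is the mean of the available (non-missing) raw
#' values in frames `[t - window + 1, t]`. The window is trailing
#' (causal), so the smoothed signal is computable in real time; partial
#' windows at the start of the series average the frames available.
#' Missing frames are excluded from the mean rather than interpolated;
#' an all-missing window yields a missing output.
#'
#' @param series a `ratio_series` (raw or previously smoothed).
#' @param window window length in frames (default 5, >= 1). `window = 1`
#'   is the identity.
#' @return A `ratio_series` of identical length with `smoothed = TRUE`.
#' @export
#' @examples
#' rs <- new_ratio_series("v", "p", 30, c(0, 0, 0, 0, 5))
#' smooth_ratio(rs, 5)$ratio[5]  # 1
smooth_ratio <- function(series, window = 5L) {
  stopifnot(inherits(series, "ratio_series"))
  if (!is.numeric(window) || length(window) != 1L || is.na(window) ||
      window < 1 || window != floor(window))
    stop_("'window' must be an integer >= 1")
  window <- as.integer(window)
  x <- series$ratio
  n <- length(x)
  obs <- !is.na(x)
  xs <- ifelse(obs, x, 0)
  cs <- cumsum(xs)
  cn <- cumsum(obs)
  lag <- function(v) c(rep(0, min(window, n)), head(v, max(0L, n - window)))
  sums <- cs - lag(cs)
  cnts <- cn - lag(cn)
  out <- ifelse(cnts > 0, sums / cnts, NA_real_)
  res <- series
  res$ratio <- as.numeric(out)
  res$smoothed <- TRUE
  res$window <- window
  res
}

#' Per-participant outlier removal by z-score
#'
#' Pools every available mouth-ratio value across all of one
#' participant's videos, computes the pooled mean and standard
#' deviation, and sets values with `|r - mean| / sd > z_max` to missing.
#' Frame counts are unchanged — outliers become gaps, never zeros. When
#' the pooled standard deviation is zero no value can be an outlier and
#' the input is returned with a warning. Passing frozen `center`/`scale`
#' (e.g. from a first pass) makes the operation idempotent.
#'
#' @param series a `ratio_series` or a list of them, all from the same
#'   participant.
#' @param z_max z-score cutoff (default 3).
#' @param center,scale optional frozen statistics; computed from the
#'   pooled data when omitted.
#' @return The same shape as the input (single series or list), with an
#'   attribute `outlier_stats = c(center, scale, removed)`.
#' @export
remove_outliers <- function(series, z_max = 3, center = NULL, scale = NULL) {
  single <- inherits(series, "ratio_series")
  lst <- if (single) list(series) else series
  stopifnot(all(vapply(lst, inherits, TRUE, "ratio_series")))
  pid <- unique(vapply(lst, `[[`, "", "participant_id"))
  if (length(pid) > 1L)
    stop_("outlier removal is per participant; got ",
          paste(pid, collapse = ", "))
  pooled <- unlist(lapply(lst, `[[`, "ratio"))
  pooled <- pooled[!is.na(pooled)]
  if (length(pooled) < 2L)
    stop_("need at least 2 observed ratio values for outlier removal")
  mu <- center %||% mean(pooled)
  sigma <- scale %||% sd(pooled)
  removed <- 0L
  if (sigma == 0) {
    warn_("pooled standard deviation is zero; no outliers removed")
  } else {
    for (i in seq_along(lst)) {
      z <- abs(lst[[i]]$ratio - mu) / sigma
      out <- !is.na(z) & z > z_max
      removed <- removed + sum(out)
      lst[[i]]$ratio[out] <- NA_real_
    }
  }
  res <- if (single) lst[[1L]] else lst
  attr(res, "outlier_stats") <- c(center = mu, scale = sigma,
                                  removed = removed)
  res
}

#' Write or read a ratio-series CSV
#'
#' Columns `video_id,participant_id,frame,time_s,ratio,smoothed`;
#' missing ratios are empty fields. The smoothing window, when any, is
#' carried in a `#window=` header line.
#'
#' @param series a `ratio_series`.
#' @param path CSV path.
#' @return `write_ratio_series` returns `path` invisibly;
#'   `read_ratio_series` returns a `ratio_series`.
#' @export
write_ratio_series <- function(series, path) {
  stopifnot(inherits(series, "ratio_series"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(paste0("#fps=", formatC(series$fps, digits = 17, format = "g")),
               paste0("#window=", ifelse(is.na(series$window), "",
                                         series$window))), con)
  writeLines("video_id,participant_id,frame,time_s,ratio,smoothed", con)
  writeLines(paste(series$video_id, series$participant_id, series$frame,
                   .num_chr(series$time_s), .num_chr(series$ratio),
                   tolower(series$smoothed), sep = ","), con)
  invisible(path)
}

#' @rdname write_ratio_series
#' @export
read_ratio_series <- function(path) {
  if (!file.exists(path)) stop_("file not found: ", path)
  hdr <- .ls_meta_read(path)
  df <- read.csv(path, skip = hdr$skip, stringsAsFactors = FALSE)
  .check_columns(df, c("video_id", "participant_id", "frame", "time_s",
                       "ratio", "smoothed"), where = path)
  w <- hdr$meta$window
  w <- if (is.null(w) || w == "") NA_integer_ else as.integer(w)
  vid <- if (nrow(df)) as.character(df$video_id[1L]) else "video"
  pid <- if (nrow(df)) as.character(df$participant_id[1L]) else "unknown"
  new_ratio_series(vid, pid,
                   as.numeric(hdr$meta$fps), ratio = df$ratio,
                   time_s = df$time_s,
                   smoothed = isTRUE(as.logical(df$smoothed[1L])), window = w)
}
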