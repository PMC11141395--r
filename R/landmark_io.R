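#' Construct a landmark series
#'
#' A landmark series holds, for one meal video, the per-frame output of a
#' 468-point 3D face-mesh detector: normalized image coordinates
#' (x, y in \[0, 1\] relative to frame width/height, z a unitless relative
#' depth) for every frame in which a face was found. Frames where the
#' detector found no face are kept as gaps (`face_detected = FALSE`, all
#' coordinates `NA`) rather than dropped or zero-filled, so a closed mouth
#' is never faked downstream.
#'
#' @param video_id,participant_id character scalars identifying the video
#'   and the person eating.
#' @param fps frames per second of the recording (> 0). Normally taken
#'   from the video container metadata; it is stored explicitly because
#'   recorded files sometimes carry broken headers.
#' @param time_s numeric vector of frame timestamps in seconds, strictly
#'   increasing. Defaults to `frame / fps`.
#' @param points numeric array of dimension `n_frames x 468 x 3`
#'   (coordinate order x, y, z). Rows for undetected frames must be all
#'   `NA`; rows for detected frames must be complete.
#' @param face_detected logical vector, one flag per frame. Derived from
#'   `points` when omitted.
#'
#' @return An object of class `landmark_series` with elements `video_id`,
#'   `participant_id`, `fps`, `frame` (0-based indices), `time_s`,
#'   `face_detected` and `points`.
#' @seealso [read_landmark_series()], [ratio_series()],
#'   [simulate_landmark_series()]
#' @export
#' @examples
#' pts <- array(runif(2 * 468 * 3), c(2, 468, 3))
#' ls <- landmark_series("v1", "p1", fps = 30, points = pts)
#' ls$face_detected
landmark_series <- function(video_id, participant_id, fps, points,
                            time_s = NULL, face_detected = NULL) {
  if (!is.character(video_id) || length(video_id) != 1L)
    stop_("'video_id' must be a single string")
  if (!is.character(participant_id) || length(participant_id) != 1L)
    stop_("'participant_id' must be a single string")
  if (!is.numeric(fps) || length(fps) != 1L || !is.finite(fps) || fps <= 0)
    stop_("'fps' must be a single positive number")
  if (!is.array(points) || length(dim(points)) != 3L)
    stop_("'points' must be an n x 468 x 3 array")
  n <- dim(points)[1L]
  if (dim(points)[2L] != 468L)
    stop_("landmark frames must carry exactly 468 points, got ", dim(points)[2L])
  if (dim(points)[3L] != 3L)
    stop_("'points' must have 3 coordinates (x, y, z) per point")
  if (is.null(time_s)) time_s <- if (n > 0L) (seq_len(n) - 1) / fps else numeric()
  if (length(time_s) != n) stop_("'time_s' length must equal the number of frames")
  if (n > 1L && any(diff(time_s) <= 0))
    stop_("'time_s' must be strictly increasing")
  if (any(time_s < 0)) stop_("'time_s' must be non-negative")
  detected <- if (n > 0L) apply(points, 1L, function(m) !anyNA(m)) else logical()
  if (is.null(face_detected)) {
    face_detected <- detected
  } else {
    if (length(face_detected) != n) stop_("'face_detected' length mismatch")
    face_detected <- as.logical(face_detected)
  }
  # a detected frame must have all 468 points; an undetected one, none
  if (n > 0L) {
    partial <- face_detected & !detected
    if (any(partial))
      stop_("frame(s) ", paste(which(partial) - 1L, collapse = ", "),
            " flagged face_detected but have missing coordinates")
    ghost <- !face_detected & apply(points, 1L, function(m) any(!is.na(m)))
    if (any(ghost))
      stop_("frame(s) ", paste(which(ghost) - 1L, collapse = ", "),
            " carry coordinates but face_detected is FALSE")
  }
  structure(
    list(video_id = video_id, participant_id = participant_id, fps = fps,
         frame = if (n > 0L) seq_len(n) - 1L else integer(),
         time_s = as.numeric(time_s),
         face_detected = face_detected, points = points),
    class = "landmark_series")
}

#' @export
print.landmark_series <- function(x, ...) {
  n <- length(x$frame)
  cat("Landmark series '", x$video_id, "' (participant ", x$participant_id,
      ")\n", sep = "")
  cat("  ", n, " frames at ", x$fps, " fps (",
      sum(x$face_detected), " with a detected face)\n", sep = "")
  invisible(x)
}

#' @export
length.landmark_series <- function(x) length(x$frame)

.ls_meta_write <- function(series, dialect, con) {
  writeLines(c(
    paste0("#video_id=", series$video_id),
    paste0("#participant_id=", series$participant_id),
    paste0("#fps=", formatC(series$fps, digits = 17, format = "g")),
    paste0("#dialect=", dialect)), con)
}

.ls_meta_read <- function(path) {
  lines <- readLines(path, n = 16L)
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- sub("^#", "", meta_lines)
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  names(vals) <- keys
  list(meta = as.list(vals), skip = length(meta_lines))
}

.num_chr <- function(x) ifelse(is.na(x), "", formatC(x, digits = 17, format = "g"))

#' Write a landmark series to CSV
#'
#' Two dialects are supported. The canonical `"long"` dialect streams one
#' row per point and frame (`frame,time_s,point_index,x,y,z`; an
#' undetected frame is a single row with empty `point_index` and
#' coordinates). The `"wide"` dialect has one row per frame with 1404
#' coordinate columns `x_0,y_0,z_0,...,x_467,y_467,z_467`, convenient for
#' small fixtures. Both carry `video_id`, `participant_id` and `fps` in
#' `#key=value` header lines. Files are UTF-8, comma-delimited, with `.`
#' as the decimal mark; coordinates are written with enough digits to
#' round-trip doubles exactly.
#'
#' @param series a [landmark_series()].
#' @param path file path to write.
#' @param dialect `"long"` (default) or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_landmark_series <- function(series, path, dialect = c("long", "wide")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(series, "landmark_series"))
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop_("cannot open '", path, "' for writing"))
  on.exit(close(con))
  .ls_meta_write(series, dialect, con)
  n <- length(series$frame)
  if (dialect == "long") {
    writeLines("frame,time_s,point_index,x,y,z", con)
    det <- series$face_detected
    nf <- sum(det)
    rows_det <- character()
    if (nf > 0L) {
      xyz <- series$points[det, , , drop = FALSE]        # nf x 468 x 3
      col_of <- function(k) .num_chr(as.vector(t(xyz[, , k])))
      rows_det <- paste(rep(series$frame[det], each = 468L),
                        rep(.num_chr(series$time_s[det]), each = 468L),
                        rep.int(0:467, nf),
                        col_of(1L), col_of(2L), col_of(3L), sep = ",")
    }
    rows_gap <- paste(series$frame[!det], .num_chr(series$time_s[!det]),
                      "", "", "", "", sep = ",")
    key <- c(rep(series$frame[det], each = 468L), series$frame[!det])
    rows <- c(rows_det, if (any(!det)) rows_gap)[order(key)]
    writeLines(rows, con)
  } else {
    coord_cols <- paste0(rep(c("x_", "y_", "z_"), times = 468),
                         rep(0:467, each = 3))
    writeLines(paste(c("frame", "time_s", "face_detected", coord_cols),
                     collapse = ","), con)
    for (i in seq_len(n)) {
      coords <- if (series$face_detected[i])
        .num_chr(as.vector(t(series$points[i, , , drop = TRUE])))
      else rep("", 1404L)
      writeLines(paste(c(series$frame[i], .num_chr(series$time_s[i]),
                         tolower(series$face_detected[i]), coords),
                       collapse = ","), con)
    }
  }
  invisible(path)
}

#' Read a landmark series from CSV
#'
#' Reads either dialect written by [write_landmark_series()]; the dialect
#' is taken from the file header unless given. The reader never drops
#' frames: the output frame count equals the number of frame groups in
#' the file, with undetected frames preserved as gaps.
#'
#' @param path file to read.
#' @param dialect `"long"`, `"wide"`, or `NULL` to use the file header.
#' @return A [landmark_series()].
#' @export
read_landmark_series <- function(path, dialect = NULL) {
  if (!file.exists(path)) stop_("file not found: ", path)
  hdr <- .ls_meta_read(path)
  meta <- hdr$meta
  for (k in c("video_id", "participant_id", "fps"))
    if (is.null(meta[[k]])) stop_("missing '#", k, "=' header line in ", path)
  dialect <- dialect %||% meta$dialect %||% "long"
  df <- read.csv(path, skip = hdr$skip, colClasses = NA,
                 check.names = FALSE, stringsAsFactors = FALSE)
  fps <- as.numeric(meta$fps)
  if (dialect == "long") {
    need <- c("frame", "time_s", "point_index", "x", "y", "z")
    .check_columns(df, need, where = path)
    if (nrow(df) == 0L)
      return(landmark_series(meta$video_id, meta$participant_id, fps,
                             array(numeric(), c(0L, 468L, 3L))))
    idx <- unique(df$frame)
    if (any(diff(idx) <= 0)) stop_("frame index not strictly increasing in ", path)
    if (!identical(as.integer(idx), seq_along(idx) - 1L))
      stop_("frame index values must be consecutive from 0 in ", path)
    n <- length(idx)
    pts <- array(NA_real_, c(n, 468L, 3L))
    time_s <- numeric(n)
    grp <- split(seq_len(nrow(df)), factor(df$frame, levels = idx))
    for (i in seq_len(n)) {
      rows <- grp[[i]]
      time_s[i] <- df$time_s[rows[1L]]
      pi_ <- df$point_index[rows]
      if (length(rows) == 1L && is.na(pi_)) next  # no-face gap frame
      if (length(rows) != 468L)
        stop_("frame ", idx[i], " has ", length(rows),
              " point rows, expected 468, in ", path)
      ord <- order(pi_)
      pts[i, , 1L] <- df$x[rows][ord]
      pts[i, , 2L] <- df$y[rows][ord]
      pts[i, , 3L] <- df$z[rows][ord]
    }
  } else {
    coord_cols <- paste0(rep(c("x_", "y_", "z_"), times = 468),
                         rep(0:467, each = 3))
    .check_columns(df, c("frame", "time_s", "face_detected", coord_cols),
                   where = path)
    n <- nrow(df)
    if (n > 0L && any(diff(df$frame) <= 0))
      stop_("frame index not strictly increasing in ", path)
    pts <- array(NA_real_, c(n, 468L, 3L))
    if (n > 0L) {
      mat <- as.matrix(df[, coord_cols, drop = FALSE])
      det <- as.logical(df$face_detected)
      for (i in which(det)) {
        m <- matrix(mat[i, ], ncol = 3L, byrow = TRUE)
        pts[i, , ] <- m
      }
    }
    time_s <- df$time_s
  }
  landmark_series(meta$video_id, meta$participant_id, fps,
                  points = pts, time_s = time_s)
}

.check_columns <- function(df, need, where = "input") {
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_("schema error in ", where, ": missing column(s) ",
          paste(missing, collapse = ", "))
  extra <- setdiff(names(df), need)
  if (length(extra))
    stop_("schema error in ", where, ": unexpected column(s) ",
          paste(extra, collapse = ", "))
  invisible(TRUE)
}

.meal_types <- c("breakfast", "lunch", "dinner", "dessert")
.texture_conditions <- c("fast_soft", "slow_hard")
.processing_conditions <- c("unprocessed", "processed")

#' Read or validate a bite-annotation table
#'
#' The annotation table is the ground truth for tuning and evaluation:
#' one row per video with the manually annotated bite count and the meal
#' condition labels. Columns are
#' `video_id,participant_id,meal_type,texture_condition,processing_condition,annotated_bites`.
#' `meal_type` is one of breakfast/lunch/dinner/dessert;
#' `texture_condition` is `fast_soft` (large bites, fewer chews) or
#' `slow_hard` (small bites, many chews); `processing_condition` is
#' `unprocessed` or `processed` (NOVA-style label, metadata only).
#'
#' @param path CSV file with the documented header.
#' @return A `data.frame`, one validated row per annotated video.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_annotations(df, where = path)
}

#' @rdname read_annotations
#' @param annotations a data.frame to validate in place of a file.
#' @param where label used in error messages.
#' @export
validate_annotations <- function(annotations, where = "annotations") {
  need <- c("video_id", "participant_id", "meal_type", "texture_condition",
            "processing_condition", "annotated_bites")
  .check_columns(annotations, need, where = where)
  bad <- function(col, allowed) {
    u <- setdiff(unique(annotations[[col]]), allowed)
    if (length(u))
      stop_("invalid ", col, " value(s) in ", where, ": ",
            paste(u, collapse = ", "), " (allowed: ",
            paste(allowed, collapse = ", "), ")")
  }
  bad("meal_type", .meal_types)
  bad("texture_condition", .texture_conditions)
  bad("processing_condition", .processing_conditions)
  if (anyDuplicated(annotations$video_id))
    stop_("duplicate video_id in ", where, ": ",
          paste(unique(annotations$video_id[duplicated(annotations$video_id)]),
                collapse = ", "))
  ab <- annotations$annotated_bites
  if (!is.numeric(ab) || any(is.na(ab)) || any(ab < 0) || any(ab != floor(ab)))
    stop_("annotated_bites must be non-negative integers in ", where)
  annotations$annotated_bites <- as.integer(ab)
  annotations
}

#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path) {
  validate_annotations(annotations)
  write.table(annotations, path, sep = ",", row.names = FALSE, qmethod = "double")
  invisible(path)
}

#' Run a pluggable landmark backend over video frames
#'
#' The face-mesh engine is deliberately not part of this package: any
#' detector satisfying a two-function contract can be plugged in. A
#' backend is a list with
#' \describe{
#'   \item{`detect(image)`}{returns a 468 x 3 numeric matrix of (x, y, z)
#'     points for the frame, or `NULL` when no face is found;}
#'   \item{`read_frames(path)` (optional)}{returns
#'     `list(frames = <list of images>, fps = <number>)` for a video
#'     file, with `fps` taken from the container metadata.}
#' }
#' `source` may be a list of frame images (then `fps` is required) or a
#' file path (then the backend must provide `read_frames`).
#'
#' @param source list of frame images, or a video file path.
#' @param backend a backend list as described above.
#' @param fps frames per second; required when `source` is a frame list,
#'   otherwise overrides the container value.
#' @param video_id,participant_id identifiers stored in the result.
#' @return A [landmark_series()] with one frame per input frame, in order.
#' @export
extract_landmarks <- function(source, backend, fps = NULL,
                              video_id = "video", participant_id = "unknown") {
  if (!is.list(backend) || !is.function(backend$detect))
    stop_("'backend' must be a list with a detect(image) function")
  if (is.character(source)) {
    if (!is.function(backend$read_frames))
      stop_("backend has no read_frames(); pass frames directly or use a ",
            "backend that can open video files")
    if (!file.exists(source)) stop_("cannot read video source: ", source)
    decoded <- backend$read_frames(source)
    frames <- decoded$frames
    fps <- fps %||% decoded$fps
  } else if (is.list(source)) {
    frames <- source
  } else stop_("'source' must be a file path or a list of frames")
  if (is.null(fps)) stop_("'fps' is required when frames are passed directly")
  n <- length(frames)
  pts <- array(NA_real_, c(n, 468L, 3L))
  for (i in seq_len(n)) {
    p <- backend$detect(frames[[i]])
    if (is.null(p)) next
    p <- as.matrix(p)
    if (!identical(dim(p), c(468L, 3L)))
      stop_("backend contract violation at frame ", i - 1L, ": expected a ",
            "468 x 3 point matrix, got ", paste(dim(p), collapse = " x "))
    pts[i, , ] <- p
  }
  landmark_series(video_id, participant_id, fps, points = pts)
}
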