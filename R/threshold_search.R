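#' Scoring function for threshold candidates
#'
#' The tuning objective: the negative mean of the absolute differences
#' between predicted and manually annotated bite counts over a set of
#' videos. 0 is a perfect score; every miscounted bite lowers it by
#' `1/n`.
#'
#' @param theta candidate threshold (> 0).
#' @param series list of `ratio_series` (raw or smoothed).
#' @param annotations annotation data.frame with at least `video_id` and
#'   `annotated_bites`; every video in `series` must have a row.
#' @param window smoothing window applied to raw series (default 5).
#' @return Scalar score <= 0 (units: negative bites).
#' @export
#' @examples
#' # predictions [10, 20] against annotations [12, 18] score -2
score_threshold <- function(theta, series, annotations, window = 5L) {
  if (inherits(series, "ratio_series")) series <- list(series)
  ann <- .paired_annotation(series, annotations)
  preds <- vapply(series, count_bites, 0L, threshold = theta, window = window)
  -mean(abs(preds - ann))
}

.paired_annotation <- function(series, annotations) {
  ids <- vapply(series, `[[`, "", "video_id")
  pos <- match(ids, annotations$video_id)
  if (anyNA(pos))
    stop_("no annotation for video(s): ",
          paste(ids[is.na(pos)], collapse = ", "))
  annotations$annotated_bites[pos]
}

#' Drop meals too short to tune on
#'
#' Meals with fewer than `min_bites` annotated bites (typically
#' desserts) carry too little signal to drive the threshold search and
#' are discarded from tuning. The boundary is strict: a meal with
#' exactly `min_bites` bites is kept.
#'
#' @param series list of per-video series (any type carrying
#'   `$video_id`).
#' @param annotations annotation data.frame.
#' @param min_bites minimum annotated bite count to keep (default 10).
#' @return `list(series = ..., annotations = ...)`, both filtered to the
#'   retained videos. Errors if nothing survives the filter.
#' @export
filter_meals <- function(series, annotations, min_bites = 10L) {
  ann <- .paired_annotation(series, annotations)
  keep <- ann >= min_bites
  if (!any(keep))
    stop_("no meals with at least ", min_bites,
          " annotated bites; cannot tune")
  ids <- vapply(series, `[[`, "", "video_id")[keep]
  list(series = series[keep],
       annotations = annotations[annotations$video_id %in% ids, , drop = FALSE])
}

#' Number of cross-validation folds for a participant
#'
#' Folds are set between 2 and 5 based on the number of videos:
#' `k = min(5, max(2, n))`, never exceeding `n`. With fewer than 2
#' videos cross-validation is impossible; the search then falls back to
#' scoring on all videos, with a warning.
#'
#' @param n_videos number of videos available for tuning.
#' @return Integer `k`, or `NA` (with a warning) when `n_videos < 2`.
#' @export
cv_folds <- function(n_videos) {
  if (n_videos < 2L) {
    warn_("fewer than 2 videos; falling back to no-CV scoring")
    return(NA_integer_)
  }
  min(5L, max(2L, as.integer(n_videos)))
}

#' Search configuration
#'
#' Bounds, granularity and bookkeeping for the threshold search. The
#' defaults span the plausible mouth-ratio range generously: closed
#' mouths sit well below 1, so \[0.05, 1.5\] brackets any realistic
#' threshold.
#'
#' @param theta_range numeric length-2, search bounds (lo < hi).
#' @param grid_step grid spacing for grid search (default 0.01).
#' @param n_iter number of evaluations for random (default 60) and
#'   Bayesian (default 30) search; `NULL` picks the per-method default.
#' @param seed RNG seed recorded in all outputs; drives fold assignment
#'   and the random/Bayesian candidate streams.
#' @param min_bites meal filter passed to [filter_meals()] (default 10).
#' @param window smoothing window for counting (default 5 frames).
#' @return An object of class `search_control`.
#' @export
search_control <- function(theta_range = c(0.05, 1.5), grid_step = 0.01,
                           n_iter = NULL, seed = 1L, min_bites = 10L,
                           window = 5L) {
  if (length(theta_range) != 2L || !all(is.finite(theta_range)) ||
      theta_range[1L] >= theta_range[2L] || theta_range[1L] <= 0)
    stop_("'theta_range' must be positive bounds with lo < hi")
  if (grid_step <= 0) stop_("'grid_step' must be positive")
  structure(list(theta_range = as.numeric(theta_range),
                 grid_step = grid_step, n_iter = n_iter,
                 seed = as.integer(seed), min_bites = as.integer(min_bites),
                 window = as.integer(window)),
            class = "search_control")
}

# Evaluate candidate thresholds against precomputed smoothed traces.
# Returns the k-fold CV score (mean over folds of the validation-fold
# score) per candidate. The model has no fitted parameters, so CV here
# measures score stability across video subsets rather than guarding
# against overfitting a fit.
.cv_scorer <- function(traces, annotated, fold_id) {
  force(traces); force(annotated); force(fold_id)
  folds <- if (all(is.na(fold_id))) list(seq_along(traces))
           else split(seq_along(traces), fold_id)
  function(theta) {
    fold_scores <- vapply(folds, function(idx) {
      preds <- vapply(traces[idx], count_runs, 0L, theta = theta)
      -mean(abs(preds - annotated[idx]))
    }, 0)
    mean(fold_scores)
  }
}

# Minimal 1-D Gaussian-process expected-improvement optimizer: RBF
# kernel with fixed relative lengthscale, outputs standardized, EI
# maximized over a dense grid. Small and deterministic given the RNG
# state; the acceptance surface for Bayesian search is recovery on
# synthetic data, not any particular optimizer trajectory.
.bayes_opt_1d <- function(f, lo, hi, n_iter, n_init = 5L) {
  n_init <- min(n_init, n_iter)
  X <- lo + (hi - lo) * (seq_len(n_init) - 0.5) / n_init
  y <- vapply(X, f, 0)
  ell <- 0.15 * (hi - lo)
  cand <- seq(lo, hi, length.out = 257L)
  while (length(X) < n_iter) {
    mu0 <- mean(y)
    sy <- sd(y)
    if (!is.finite(sy) || sy < 1e-12) sy <- 1
    ys <- (y - mu0) / sy
    K <- exp(-0.5 * outer(X, X, "-")^2 / ell^2) + diag(1e-6, length(X))
    Kinv <- solve(K)
    a <- Kinv %*% ys
    kx <- exp(-0.5 * outer(cand, X, "-")^2 / ell^2)
    m <- as.vector(kx %*% a)
    v <- pmax(1e-12, 1 + 1e-6 - rowSums((kx %*% Kinv) * kx))
    s <- sqrt(v)
    z <- (m - max(ys)) / s
    ei <- s * (z * pnorm(z) + dnorm(z))
    # keep exploring if EI collapses or proposes a repeat
    x_new <- cand[which.max(ei)]
    if (min(abs(x_new - X)) < (hi - lo) * 1e-6 || max(ei) <= 0)
      x_new <- lo + (hi - lo) * runif(1L)
    X <- c(X, x_new)
    y <- c(y, f(x_new))
  }
  list(theta = X, score = y)
}

#' Tune the bite threshold for one participant
#'
#' Optimizes the threshold against the participant's annotated videos
#' using one of three 1-D search strategies over the same
#' cross-validated objective ([score_threshold()]):
#' \describe{
#'   \item{grid}{every value in `theta_range` at `grid_step` spacing;}
#'   \item{random}{`n_iter` uniform draws from `theta_range` (seeded);}
#'   \item{bayesian}{sequential model-based optimization (Gaussian
#'     process + expected improvement) with `n_iter` evaluations.}
#' }
#' Videos with fewer than `min_bites` annotated bites are discarded
#' first; the remaining videos are partitioned into `k = min(5, max(2,
#' n))` seeded folds and each candidate is scored by the mean
#' validation-fold score. Ties are broken toward the smaller threshold
#' so results are reproducible.
#'
#' @param series list of the participant's `ratio_series`.
#' @param annotations annotation data.frame covering those videos.
#' @param method `"grid"`, `"random"` or `"bayesian"`.
#' @param control a [search_control()].
#' @return An object of class `search_result`: `participant_id`,
#'   `method`, `best_theta`, `cv_score`, `fold_scores` at the optimum,
#'   the evaluated `candidates` (theta, score), `k`, `seed` and
#'   `n_videos`.
#' @export
tune_threshold <- function(series, annotations,
                           method = c("grid", "random", "bayesian"),
                           control = search_control()) {
  method <- match.arg(method)
  stopifnot(inherits(control, "search_control"))
  if (inherits(series, "ratio_series")) series <- list(series)
  kept <- filter_meals(series, annotations, control$min_bites)
  series <- kept$series
  ann <- .paired_annotation(series, kept$annotations)
  pid <- unique(vapply(series, `[[`, "", "participant_id"))
  if (length(pid) != 1L)
    stop_("tune_threshold expects videos of a single participant, got: ",
          paste(pid, collapse = ", "))
  n <- length(series)
  traces <- lapply(series, function(s)
    if (s$smoothed) s$ratio else smooth_ratio(s, control$window)$ratio)
  set.seed(control$seed)
  k <- cv_folds(n)
  fold_id <- if (is.na(k)) rep(NA_integer_, n) else sample(rep_len(seq_len(k), n))
  scorer <- .cv_scorer(traces, ann, fold_id)
  lo <- control$theta_range[1L]; hi <- control$theta_range[2L]
  if (method == "grid") {
    thetas <- seq(lo, hi, by = control$grid_step)
    scores <- vapply(thetas, scorer, 0)
  } else if (method == "random") {
    n_iter <- control$n_iter %||% 60L
    thetas <- lo + (hi - lo) * runif(n_iter)
    scores <- vapply(thetas, scorer, 0)
  } else {
    n_iter <- control$n_iter %||% 30L
    bo <- .bayes_opt_1d(scorer, lo, hi, n_iter)
    thetas <- bo$theta
    scores <- bo$score
  }
  best_score <- max(scores)
  best_theta <- min(thetas[scores == best_score])  # ties -> smaller theta
  fold_scores <- {
    folds <- if (is.na(k)) list(seq_len(n)) else split(seq_len(n), fold_id)
    vapply(folds, function(idx) {
      preds <- vapply(traces[idx], count_runs, 0L, theta = best_theta)
      -mean(abs(preds - ann[idx]))
    }, 0)
  }
  structure(list(participant_id = pid, method = method,
                 best_theta = best_theta, cv_score = best_score,
                 fold_scores = fold_scores,
                 candidates = data.frame(theta = thetas, score = scores),
                 k = k, seed = control$seed, n_videos = n),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("Threshold search (", x$method, ") for participant ", x$participant_id,
      "\n", sep = "")
  cat("  best threshold ", format(x$best_theta), " (CV score ",
      format(x$cv_score), " bites, k = ", x$k, ", ", x$n_videos,
      " videos, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Leave-one-out threshold transfer
#'
#' Estimates the threshold for a participant whose videos carry no
#' annotation as the unweighted mean of the thresholds tuned on all
#' other participants, the target's own value omitted. Over a cohort of
#' n participants this yields n distinct transferred thresholds, each
#' leaving out exactly one. By convention the donor thresholds come from
#' random search (the best-performing tuner); any named threshold vector
#' works.
#'
#' @param thresholds a named numeric vector of per-participant tuned
#'   thresholds, a list of `search_result`s, or a `bite_fit`.
#' @param target participant id to exclude (and transfer to).
#' @return The transferred threshold (scalar).
#' @export
#' @examples
#' loocv_transfer(c(a = 1, b = 2, c = 3), "c")  # 1.5
loocv_transfer <- function(thresholds, target) {
  th <- .threshold_vector(thresholds)
  if (!target %in% names(th))
    stop_("unknown participant '", target, "'")
  rest <- th[names(th) != target]
  if (length(rest) < 1L)
    stop_("need at least 2 participants for leave-one-out transfer")
  mean(rest)
}

#' @rdname loocv_transfer
#' @return `loocv_thresholds` returns the full named vector of
#'   transferred thresholds, one per participant.
#' @export
loocv_thresholds <- function(thresholds) {
  th <- .threshold_vector(thresholds)
  vapply(names(th), function(p) loocv_transfer(th, p), 0)
}

.threshold_vector <- function(x) {
  if (inherits(x, "bite_fit")) return(coef(x))
  if (is.list(x) && all(vapply(x, inherits, TRUE, "search_result"))) {
    th <- vapply(x, `[[`, 0, "best_theta")
    names(th) <- vapply(x, `[[`, "", "participant_id")
    return(th)
  }
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stop_("'thresholds' must be a named numeric vector, a list of ",
        "search_result objects, or a bite_fit")
}
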