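#' Fit the bite counter to an annotated cohort
#'
#' The main fitting function: tunes a per-participant mouth-ratio
#' threshold against the manually annotated bite counts and packages
#' the cohort result as a model object. For each participant the videos
#' are filtered ([filter_meals()]), the threshold is searched
#' ([tune_threshold()]) with the chosen strategy, and fitted per-video
#' bite counts are computed for every video (including those excluded
#' from tuning) at the participant's best threshold.
#'
#' @param series list of `ratio_series` (or [landmark_series()], which
#'   are converted), covering all participants.
#' @param annotations annotation data.frame (see [read_annotations()]).
#' @param method search strategy: `"grid"`, `"random"` or `"bayesian"`.
#' @param control a [search_control()].
#' @return An object of class `bite_fit` with components `results`
#'   (per-participant `search_result`s), `fitted` (per-video data.frame
#'   of annotated and predicted counts), `method`, `control` and `call`.
#'   Methods: [print()], [summary()] (participant accuracy report),
#'   [coef()] (named thresholds), [predict()], [residuals()], [plot()].
#' @seealso [loocv_transfer()] for unannotated participants.
#' @export
#' @examples
#' coh <- simulate_cohort(n_participants = 3, videos_per_participant = 4,
#'                        seed = 7)
#' fit <- fit_bite_counter(coh$series, coh$annotations, method = "grid",
#'                         control = search_control(grid_step = 0.05))
#' coef(fit)
#' summary(fit)
fit_bite_counter <- function(series, annotations,
                             method = c("random", "grid", "bayesian"),
                             control = search_control()) {
  method <- match.arg(method)
  cl <- match.call()
  series <- lapply(series, function(s)
    if (inherits(s, "landmark_series")) ratio_series(s) else s)
  stopifnot(all(vapply(series, inherits, TRUE, "ratio_series")))
  pids <- vapply(series, `[[`, "", "participant_id")
  results <- list()
  fitted_rows <- list()
  for (p in unique(pids)) {
    p_series <- series[pids == p]
    res <- tune_threshold(p_series, annotations, method = method,
                          control = control)
    results[[p]] <- res
    ann <- .paired_annotation(p_series, annotations)
    preds <- vapply(p_series, count_bites, 0L,
                    threshold = res$best_theta, window = control$window)
    fitted_rows[[p]] <- data.frame(
      video_id = vapply(p_series, `[[`, "", "video_id"),
      participant_id = p, annotated = ann, predicted = preds)
  }
  structure(list(results = results,
                 fitted = do.call(rbind, c(fitted_rows, make.row.names = FALSE)),
                 method = method, control = control, call = cl),
            class = "bite_fit")
}

#' @export
print.bite_fit <- function(x, ...) {
  cat("Rule-based bite counter (", x$method, " threshold search)\n", sep = "")
  cat("  ", length(x$results), " participant(s), ",
      nrow(x$fitted), " video(s)\n", sep = "")
  cat("Per-participant thresholds:\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
coef.bite_fit <- function(object, ...) {
  th <- vapply(object$results, `[[`, 0, "best_theta")
  names(th) <- names(object$results)
  th
}

#' @export
residuals.bite_fit <- function(object, ...) {
  r <- object$fitted$predicted - object$fitted$annotated
  names(r) <- object$fitted$video_id
  r
}

#' @describeIn fit_bite_counter participant accuracy report of the
#'   fitted counts (an `accuracy_report`; see [participant_report()]).
#' @param object,x a `bite_fit`.
#' @param ... unused.
#' @export
summary.bite_fit <- function(object, ...) {
  rep_ <- participant_report(object$fitted)
  attr(rep_, "method") <- object$method
  rep_
}

#' Predict bite counts for new videos
#'
#' Applies the fitted per-participant thresholds to new series. Videos
#' of participants absent from the fit are handled by leave-one-out
#' transfer: their threshold is the mean of all fitted thresholds (a
#' message notes this).
#'
#' @param object a `bite_fit`.
#' @param newdata a `ratio_series`/[landmark_series()] or a list of them.
#' @param type `"count"` for integer counts, `"events"` for full
#'   [detect_events()] results.
#' @param ... unused.
#' @return Named integer vector of counts, or a list of `bite_result`s.
#' @export
predict.bite_fit <- function(object, newdata, type = c("count", "events"),
                             ...) {
  type <- match.arg(type)
  if (inherits(newdata, c("ratio_series", "landmark_series")))
    newdata <- list(newdata)
  th <- coef(object)
  out <- lapply(newdata, function(s) {
    p <- s$participant_id
    theta <- if (p %in% names(th)) th[[p]] else {
      message("participant '", p, "' not in fit; using transferred mean threshold")
      mean(th)
    }
    detect_events(s, bite_model(theta, window = object$control$window))
  })
  names(out) <- vapply(newdata, `[[`, "", "video_id")
  if (type == "count") vapply(out, `[[`, 0L, "predicted_bites") else out
}

#' @describeIn fit_bite_counter per-participant accuracy bar plot.
#' @export
plot.bite_fit <- function(x, ...) {
  rep_ <- summary(x)
  acc <- rep_$accuracy
  names(acc) <- rep_$group
  bp <- barplot(acc, ylim = c(0, 100), ylab = "accuracy (%)",
                xlab = "participant", col = "steelblue",
                main = paste("Bite-count accuracy,", x$method, "search"), ...)
  abline(h = attr(rep_, "mean_accuracy"), lty = 2, col = "grey40")
  invisible(bp)
}
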