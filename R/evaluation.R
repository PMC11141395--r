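#' Pooled-count bite accuracy
#'
#' Accuracy of a predicted bite total against the annotated total of the
#' same videos: `A = | 100 - 100 * |P - T| / T |`, i.e. 100 times one
#' minus the relative absolute error, reported as a percentage in
#' \[0, 100\]. It is computed on pooled bite totals per meal or group,
#' never on per-bite matching.
#'
#' The outer absolute value matters only when the over-prediction
#' exceeds twice the annotation (`P > 2T`): the raw value then turns
#' negative and is folded back to positive. A fold-back accuracy is
#' arithmetically valid but misleading as a quality figure (a 2.7x
#' over-count can score 65.7), so a warning flags it;
#' `clamp_at_zero = TRUE` substitutes the alternative convention
#' `max(0, .)`.
#'
#' @param annotated annotated bite total(s) `T` (> 0).
#' @param predicted predicted bite total(s) `P` (>= 0).
#' @param clamp_at_zero use `max(0, .)` instead of the fold-back
#'   absolute value (default `FALSE`).
#' @param warn_foldback warn when any `P > 2T` (default `TRUE`).
#' @return Accuracy in percent, vectorized over inputs (not rounded;
#'   report builders round to one decimal, half-up).
#' @export
#' @examples
#' bite_accuracy(554, 524)              # 94.58...
#' bite_accuracy(502, 1334)             # fold-back: 65.73...
#' bite_accuracy(100, 0)                # 0
bite_accuracy <- function(annotated, predicted, clamp_at_zero = FALSE,
                          warn_foldback = TRUE) {
  if (any(annotated <= 0))
    stop_("accuracy is undefined for annotated totals <= 0")
  if (any(predicted < 0)) stop_("predicted totals must be >= 0")
  raw <- 100 - 100 * abs(predicted - annotated) / annotated
  fold <- predicted > 2 * annotated
  if (warn_foldback && any(fold))
    warn_(sum(fold), " group(s) over-predict beyond twice the annotation; ",
          "fold-back accuracy reported (see ?bite_accuracy)")
  if (clamp_at_zero) pmax(0, raw) else abs(raw)
}

.accuracy_report <- function(group, annotated, predicted, group_label,
                             clamp_at_zero = FALSE) {
  acc_raw <- bite_accuracy(annotated, predicted, clamp_at_zero = clamp_at_zero,
                           warn_foldback = FALSE)
  fold <- predicted > 2 * annotated
  tab <- data.frame(group = group, annotated = annotated,
                    predicted = predicted,
                    accuracy = round_half_up(acc_raw, 1),
                    foldback = fold)
  n <- nrow(tab)
  structure(tab,
            class = c("accuracy_report", "data.frame"),
            group_label = group_label,
            total_annotated = sum(annotated),
            total_predicted = sum(predicted),
            mean_accuracy = round_half_up(mean(acc_raw), 1),
            sd_accuracy = if (n > 1L) round_half_up(sd(acc_raw), 1) else 0,
            sd_defined = n > 1L)
}

#' Per-participant accuracy report
#'
#' Builds the per-participant evaluation table: for each participant the
#' annotated and predicted bite counts are summed over their videos and
#' [bite_accuracy()] is applied to the totals (pooled counts, not the
#' mean of per-video accuracies — `per_video = TRUE` gives the latter).
#' The footer carries the cohort totals and the unweighted mean and
#' standard deviation of the per-participant accuracies; with a single
#' participant the standard deviation is reported as 0 and flagged
#' undefined.
#'
#' @param data data.frame with columns `participant_id`, `annotated`,
#'   `predicted` — one row per video, or already-pooled totals (one row
#'   per participant sums to itself).
#' @param per_video average per-video accuracies instead of pooling
#'   counts (default `FALSE`).
#' @param clamp_at_zero accuracy convention, see [bite_accuracy()].
#' @return An `accuracy_report`: a data.frame
#'   (`group,annotated,predicted,accuracy,foldback`) with footer
#'   attributes `total_annotated`, `total_predicted`, `mean_accuracy`,
#'   `sd_accuracy` and `sd_defined`. Accuracies are rounded to one
#'   decimal, half-up.
#' @export
participant_report <- function(data, per_video = FALSE,
                               clamp_at_zero = FALSE) {
  need <- c("participant_id", "annotated", "predicted")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop_("missing column(s): ", paste(miss, collapse = ", "))
  empty <- !data$participant_id %in%
    data$participant_id[!is.na(data$annotated)]
  if (any(empty)) {
    warn_("excluding participant(s) with no videos: ",
          paste(unique(data$participant_id[empty]), collapse = ", "))
    data <- data[!empty, , drop = FALSE]
  }
  pid <- factor(data$participant_id, levels = unique(data$participant_id))
  if (per_video) {
    acc <- bite_accuracy(data$annotated, data$predicted,
                         clamp_at_zero = clamp_at_zero, warn_foldback = FALSE)
    T_ <- tapply(data$annotated, pid, sum)
    P_ <- tapply(data$predicted, pid, sum)
    a_ <- tapply(acc, pid, mean)
    rep_ <- .accuracy_report(levels(pid), as.vector(T_), as.vector(P_),
                             "participant", clamp_at_zero)
    rep_$accuracy <- round_half_up(as.vector(a_), 1)
    attr(rep_, "mean_accuracy") <- round_half_up(mean(as.vector(a_)), 1)
    attr(rep_, "sd_accuracy") <- if (nlevels(pid) > 1L)
      round_half_up(sd(as.vector(a_)), 1) else 0
    return(rep_)
  }
  T_ <- as.vector(tapply(data$annotated, pid, sum))
  P_ <- as.vector(tapply(data$predicted, pid, sum))
  .accuracy_report(levels(pid), T_, P_, "participant", clamp_at_zero)
}

#' Pooled accuracy by condition group
#'
#' Pools annotated and predicted bite counts across all videos within
#' each level of a grouping label (for instance the food-texture
#' condition) and applies [bite_accuracy()] to the pooled totals.
#'
#' @param data data.frame with columns `annotated`, `predicted`, and the
#'   grouping column — one row per video.
#' @param group_by name of the grouping column (default
#'   `"texture_condition"`).
#' @param clamp_at_zero accuracy convention, see [bite_accuracy()].
#' @return An `accuracy_report` with one row per non-empty group.
#' @export
#' @examples
#' d <- data.frame(texture_condition = c("fast_soft", "slow_hard"),
#'                 annotated = c(2871, 3848), predicted = c(2684, 4120))
#' pooled_accuracy(d)  # 93.5 and 92.9
pooled_accuracy <- function(data, group_by = "texture_condition",
                            clamp_at_zero = FALSE) {
  need <- c(group_by, "annotated", "predicted")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop_("missing column(s): ", paste(miss, collapse = ", "))
  g <- data[[group_by]]
  g <- if (is.factor(g)) g else factor(g)
  keep <- levels(g)[tabulate(g, nbins = nlevels(g)) > 0L]
  if (length(keep) < nlevels(g))
    warn_("excluding empty group(s): ",
          paste(setdiff(levels(g), keep), collapse = ", "))
  g <- factor(as.character(g), levels = keep)
  T_ <- as.vector(tapply(data$annotated, g, sum))
  P_ <- as.vector(tapply(data$predicted, g, sum))
  .accuracy_report(keep, T_, P_, group_by, clamp_at_zero)
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("Bite-count accuracy by ", attr(x, "group_label"), "\n", sep = "")
  df <- as.data.frame(x)
  df$accuracy <- formatC(df$accuracy, format = "f", digits = 1)
  df$foldback <- ifelse(df$foldback, "*", "")
  print(df, row.names = FALSE)
  cat("Total: ", attr(x, "total_annotated"), " annotated / ",
      attr(x, "total_predicted"), " predicted\n", sep = "")
  cat("Mean accuracy ", formatC(attr(x, "mean_accuracy"), format = "f",
                                digits = 1),
      " (sd ", formatC(attr(x, "sd_accuracy"), format = "f", digits = 1),
      if (!attr(x, "sd_defined")) ", undefined for a single group", ")\n",
      sep = "")
  if (any(x$foldback))
    cat("* over-prediction beyond twice the annotation (fold-back accuracy)\n")
  invisible(x)
}

#' Descriptive statistics of annotated bite counts
#'
#' Mean, median, mode (most frequent value, smallest on ties), range
#' (max minus min), variance and standard deviation (sample, n-1), and
#' quartiles by linear interpolation between closest ranks
#' ([stats::quantile()] type 7).
#'
#' @param counts numeric vector of per-video annotated bite counts
#'   (non-empty).
#' @return A one-row data.frame with columns `mean, median, mode, range,
#'   variance, sd, q1, q2, q3`.
#' @export
#' @examples
#' summary_stats(c(1, 2, 3))
summary_stats <- function(counts) {
  if (length(counts) == 0L || all(is.na(counts)))
    stop_("'counts' must contain at least one value")
  counts <- counts[!is.na(counts)]
  tab <- table(counts)
  mode_ <- as.numeric(names(tab)[tab == max(tab)])[1L]
  q <- quantile(counts, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  data.frame(mean = mean(counts), median = median(counts), mode = mode_,
             range = max(counts) - min(counts),
             variance = if (length(counts) > 1L) var(counts) else 0,
             sd = if (length(counts) > 1L) sd(counts) else 0,
             q1 = q[1L], q2 = q[2L], q3 = q[3L])
}

#' Spearman rank correlation of two count vectors
#'
#' Spearman's rho with average ranks for ties, used to compare
#' transferred-threshold predictions against manual annotation.
#'
#' @param x,y numeric vectors of equal length >= 2; neither constant.
#' @return rho in \[-1, 1\].
#' @export
rank_correlation <- function(x, y) {
  if (length(x) != length(y)) stop_("'x' and 'y' must have equal length")
  if (length(x) < 2L) stop_("need at least 2 observations")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop_("rank correlation is undefined for a constant vector")
  cor(x, y, method = "spearman")
}
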