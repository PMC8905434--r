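# Scoring predicted against observed fixation counts.
#
# The metric treats each distinct observed fixation-count value as a label,
# scores each label with binary F1, and averages the label scores weighted
# by their numbers of true instances.  Because the fixation-count
# distribution is heavily imbalanced (most words get exactly one fixation),
# the weighting keeps rare labels from dominating.

#' Binary F1 from confusion counts
#'
#' tp / (tp + 0.5 * (fp + fn)); defined as 0 when all three counts are 0.
#'
#' @param tp,fp,fn Nonnegative integer vectors (recycled).
#' @return Numeric vector in \[0, 1\].
#' @export
binary_f1 <- function(tp, fp, fn) {
  denom <- tp + 0.5 * (fp + fn)
  ifelse(denom == 0, 0, tp / denom)
}

join_tables <- function(observed, predicted) {
  check_fixation_table(observed)
  check_fixation_table(predicted)
  key <- function(t) paste(t$sequence_id, t$word_index, sep = "\r")
  miss_pred <- setdiff(key(observed), key(predicted))
  miss_obs <- setdiff(key(predicted), key(observed))
  if (length(miss_pred) > 0L || length(miss_obs) > 0L) {
    fmt <- function(k) paste(utils::head(gsub("\r", ":", k), 5L), collapse = ", ")
    rlang::abort(paste0(
      "observed and predicted tables cover different words",
      if (length(miss_pred)) paste0("; missing from predicted: ", fmt(miss_pred)),
      if (length(miss_obs)) paste0("; missing from observed: ", fmt(miss_obs))
    ))
  }
  dplyr::inner_join(
    dplyr::select(observed, "sequence_id", "word_index",
                  observed = "fixation_count"),
    dplyr::select(predicted, "sequence_id", "word_index",
                  predicted = "fixation_count"),
    by = c("sequence_id", "word_index")
  )
}

per_label_scores <- function(joined) {
  labels <- sort(unique(joined$observed))
  purrr::map_dfr(labels, function(c) {
    tp <- sum(joined$observed == c & joined$predicted == c)
    fn <- sum(joined$observed == c & joined$predicted != c)
    fp <- sum(joined$predicted == c & joined$observed != c)
    tibble::tibble(label = c, weight = tp + fn, tp = tp, fp = fp, fn = fn,
                   f1 = binary_f1(tp, fp, fn))
  })
}

#' Weighted F1 between observed and predicted fixation counts
#'
#' Labels are the distinct observed count values; each label's binary F1 is
#' weighted by its number of true instances.  A count value that is
#' predicted but never observed carries weight 0 and contributes only false
#' positives to the observed labels.
#'
#' @param observed,predicted Fixation tibbles over the same words.
#' @return Weighted F1 in percent (0-100).
#' @export
weighted_f1 <- function(observed, predicted) {
  scores <- per_label_scores(join_tables(observed, predicted))
  100 * sum(scores$weight * scores$f1) / sum(scores$weight)
}

#' Full evaluation report
#'
#' Per-label F1 with true-instance weights, the weighted-F1 aggregate, the
#' Skip/One/More confusion matrix, and the marginal label distributions.
#'
#' @param observed,predicted Fixation tibbles over the same words.
#' @return A `cogseg_eval` object; see [tidy.cogseg_eval()] and
#'   [glance.cogseg_eval()].
#' @export
evaluate_fixations <- function(observed, predicted) {
  joined <- join_tables(observed, predicted)
  scores <- per_label_scores(joined)
  conf <- dplyr::count(
    tibble::tibble(observed_label = label3(joined$observed),
                   predicted_label = label3(joined$predicted)),
    .data$observed_label, .data$predicted_label, .drop = FALSE,
    name = "n"
  )
  structure(
    list(
      per_label = scores,
      weighted_f1 = 100 * sum(scores$weight * scores$f1) / sum(scores$weight),
      confusion = conf,
      n_words = nrow(joined)
    ),
    class = "cogseg_eval"
  )
}

#' Skip/One/More confusion summary
#'
#' @param observed,predicted Fixation tibbles over the same words.
#' @return Tibble of the 3x3 confusion counts (`observed_label`,
#'   `predicted_label`, `n`).
#' @export
confusion_summary <- function(observed, predicted) {
  evaluate_fixations(observed, predicted)$confusion
}

#' @export
print.cogseg_eval <- function(x, ...) {
  cat("<cogseg_eval> ", x$n_words, " words, weighted F1 = ",
      sprintf("%.2f", x$weighted_f1), "%\n", sep = "")
  print(x$per_label)
  invisible(x)
}

#' Tidy an evaluation report: per-label scores
#' @param x A `cogseg_eval`.
#' @param ... Unused.
#' @export
tidy.cogseg_eval <- function(x, ...) x$per_label

#' @export
glance.cogseg_eval <- function(x, ...) {
  tibble::tibble(weighted_f1 = x$weighted_f1, n_words = x$n_words,
                 n_labels = nrow(x$per_label))
}

#' Confusion bubble plot of an evaluation report
#' @param object A `cogseg_eval`.
#' @param ... Unused.
#' @export
autoplot.cogseg_eval <- function(object, ...) {
  ggplot2::ggplot(object$confusion,
                  ggplot2::aes(x = .data$predicted_label,
                               y = .data$observed_label,
                               size = .data$n)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_size_area(max_size = 20) +
    ggplot2::labs(x = "predicted", y = "observed",
                  title = sprintf("Skip/One/More confusion (weighted F1 = %.2f%%)",
                                  object$weighted_f1)) +
    ggplot2::theme_minimal()
}

#' Unit-length-limit sweep
#'
#' Retrains the learner once per maximum-unit-length limit (each run on its
#' own seed-derived stream), predicts fixation counts, and scores them
#' against the observed table.  The peak of the resulting curve estimates
#' the effective perceptual span.
#'
#' @param corpus Corpus tibble used both for training and prediction.
#' @param observed Observed fixation tibble over the corpus words.
#' @param limits Positive integer vector of maximum effective unit lengths.
#' @param config Base [lib_config()]; its `max_unit_len` is overridden per
#'   limit.
#' @return A `cogseg_sweep` tibble (`limit`, `weighted_f1`) with attributes
#'   `best_limit` and `best_f1`.
#' @export
length_sweep <- function(corpus, observed, limits, config = lib_config()) {
  if (length(limits) == 0L) rlang::abort("`limits` must be nonempty")
  stopifnot(all(limits >= 1))
  seeds <- with_seed(config$seed, sample.int(.Machine$integer.max - 1L,
                                             length(limits)))
  rows <- purrr::map2_dfr(limits, seeds, function(lim, sd) {
    cfg <- config
    cfg$max_unit_len <- lim
    cfg$seed <- sd
    fit <- lib_train(corpus, cfg)
    seg <- segment_corpus(fit$lexicon, corpus, evaluate = TRUE)
    pred <- predict_fixation_counts(seg, corpus)
    tibble::tibble(limit = lim, weighted_f1 = weighted_f1(observed, pred))
  })
  best <- which.max(rows$weighted_f1)
  structure(rows, best_limit = rows$limit[best], best_f1 = rows$weighted_f1[best],
            class = c("cogseg_sweep", class(rows)))
}

#' Plot a unit-length sweep curve
#' @param object A `cogseg_sweep`.
#' @param ... Unused.
#' @export
autoplot.cogseg_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$limit, y = .data$weighted_f1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "best_limit"),
                        linetype = "dotted") +
    ggplot2::labs(x = "maximum unit length (characters)",
                  y = "weighted F1 (%)",
                  title = "Fixation prediction vs. unit-length limit") +
    ggplot2::theme_minimal()
}
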