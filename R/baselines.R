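# Word-based baselines: reading word by word, and shuffling observed
# counts among words of equal length.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Word-by-Word baseline
#'
#' Predicts exactly one first-pass fixation on every word: the reading
#' pattern a strictly word-based account would produce.
#'
#' @param corpus Corpus tibble.
#' @return Fixation tibble with `fixation_count = 1` for every word.
#' @export
predict_word_by_word <- function(corpus) {
  w <- corpus_words(corpus)
  tibble::tibble(sequence_id = w$sequence_id, word_index = w$word_index,
                 word = w$word, fixation_count = 1L)
}

#' Only-Length baseline
#'
#' Groups words by their number of letters and permutes the observed
#' fixation counts uniformly at random within each group, so each word's
#' prediction is the observed count of some word of the same length.  Only
#' length information survives; frequency, morphology and position are
#' destroyed.  The per-group count multisets are preserved exactly.
#'
#' @param observed Fixation tibble (must have a `word` column).
#' @param seed Optional integer seed for a reproducible shuffle.
#' @return Fixation tibble with permuted counts.
#' @export
predict_only_length <- function(observed, seed = NULL) {
  check_fixation_table(observed)
  if (!"word" %in% names(observed)) {
    rlang::abort("Only-Length needs the `word` column to group by length")
  }
  if (any(is.na(observed$word) | nchar(observed$word) == 0L)) {
    bad <- observed[is.na(observed$word) | nchar(observed$word) == 0L, ]
    rlang::abort(paste0("missing word form at (seq ", bad$sequence_id[1],
                        ", word ", bad$word_index[1], ")"))
  }
  with_seed(seed, {
    out <- observed
    grp <- nchar(out$word)
    for (g in unique(grp)) {
      i <- which(grp == g)
      out$fixation_count[i] <- out$fixation_count[i[sample.int(length(i))]]
    }
    out
  })
}

#' Only-Length score over repeated shuffles
#'
#' The shuffle is stochastic, so the score is reported as the mean weighted
#' F1 over `reps` independent shuffles together with its spread;
#' `reps = 1` scores a single shuffle.
#'
#' @param observed Fixation tibble.
#' @param reps Number of shuffles.
#' @param seed Integer seed.
#' @return Tibble with `mean_f1`, `sd_f1`, `reps`.
#' @export
only_length_score <- function(observed, reps = 100L, seed = 1L) {
  scores <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      weighted_f1(observed, predict_only_length(observed))
    }, numeric(1))
  })
  tibble::tibble(mean_f1 = mean(scores),
                 sd_f1 = if (reps > 1L) stats::sd(scores) else NA_real_,
                 reps = as.integer(reps))
}
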