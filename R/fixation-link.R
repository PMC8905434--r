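# The linking hypothesis: each segmented unit receives exactly one
# first-pass fixation, located at the center of its character span; the
# fixation is credited to the word containing that center.  Converting a
# segmentation into per-word predicted fixation counts therefore conserves
# the token count exactly.

#' Center locus of a unit token
#'
#' The effective span of a unit excludes its trailing boundary space but
#' includes internal spaces of multiword units.  Odd effective length puts
#' the center on the middle character (an integer position); even length
#' puts it on the boundary between the two middle characters (a half
#' position).  For the unit "i have" (effective length 6) the center falls
#' between "h" and "a".
#'
#' @param form Character vector of unit forms.
#' @param start Integer vector of 1-based start positions in the rendered
#'   sequence.
#' @return Numeric vector of center loci (integer = character position,
#'   half = boundary).
#' @export
unit_center <- function(form, start = 1L) {
  len <- effective_length(form)
  start + (len + 1) / 2 - 1
}

#' Predict per-word first-pass fixation counts from a segmentation
#'
#' Each unit contributes one fixation, assigned to the word containing its
#' center locus.  A center that falls on an inter-word space or on a
#' boundary between two words is assigned to the word contributing more
#' characters to the unit; an exact tie goes to the right-hand word.
#'
#' @param segmentation Segmentation tibble ([segment_corpus()] or a true
#'   segmentation from the synthetic generator).
#' @param corpus The corpus the segmentation covers.
#' @return Fixation tibble (`sequence_id`, `word_index`, `word`,
#'   `fixation_count`); the counts of one sequence sum to its token count.
#' @export
predict_fixation_counts <- function(segmentation, corpus) {
  check_corpus(corpus)
  words <- corpus_words(corpus)
  seg_by_seq <- split(segmentation, segmentation$sequence_id)
  words_by_seq <- split(words, words$sequence_id)
  out <- purrr::map_dfr(as.character(corpus$sequence_id), function(sid) {
    w <- words_by_seq[[sid]]
    s <- seg_by_seq[[sid]]
    counts <- integer(nrow(w))
    if (!is.null(s) && nrow(s) > 0L) {
      # character position -> word index (0 for spaces)
      rend_len <- max(w$end) + 1L
      char_word <- integer(rend_len)
      for (j in seq_len(nrow(w))) char_word[w$start[j]:w$end[j]] <- j
      center <- unit_center(s$form, s$start)
      eff_end <- s$start + effective_length(s$form) - 1L
      for (i in seq_len(nrow(s))) {
        lw <- char_word[floor(center[i])]
        rw <- char_word[ceiling(center[i])]
        if (lw != 0L && lw == rw) {
          target <- lw
        } else {
          cand <- which(w$start <= eff_end[i] & w$end >= s$start[i])
          overlap <- pmin(w$end[cand], eff_end[i]) - pmax(w$start[cand], s$start[i]) + 1L
          target <- cand[max(which(overlap == max(overlap)))]
        }
        counts[target] <- counts[target] + 1L
      }
    }
    tibble::tibble(sequence_id = w$sequence_id, word_index = w$word_index,
                   word = w$word, fixation_count = counts)
  })
  out
}

#' Merge model-word fixation counts onto reference words
#'
#' Hyphenated source tokens are processed as multiple words by the models
#' but counted as single words by word-level eye-tracking exports; this
#' sums the counts of all model words belonging to one reference word.
#'
#' @param model_counts Fixation tibble over model words.
#' @param ref_map Mapping tibble from [build_hyphen_map()] with columns
#'   `sequence_id`, `model_word_index`, `ref_word_index`, `ref_word`.
#' @return Fixation tibble keyed by (`sequence_id`, `ref_word_index`) with
#'   the reference word forms.
#' @export
align_reference_words <- function(model_counts, ref_map) {
  check_fixation_table(model_counts)
  joined <- dplyr::left_join(
    model_counts, ref_map,
    by = c("sequence_id", word_index = "model_word_index")
  )
  bad <- joined[is.na(joined$ref_word_index), , drop = FALSE]
  if (nrow(bad) > 0L) {
    rlang::abort(paste0(
      "unalignable model word(s): ",
      paste0("(seq ", bad$sequence_id, ", word ", bad$word_index, " \"",
             bad$word, "\")", collapse = ", ")
    ))
  }
  out <- dplyr::summarise(
    dplyr::group_by(joined, .data$sequence_id, .data$ref_word_index),
    word = .data$ref_word[1],
    fixation_count = sum(.data$fixation_count),
    .groups = "drop"
  )
  dplyr::rename(out, word_index = "ref_word_index")
}

#' Build a model-word to reference-word map from raw tokens
#'
#' Each raw reference token (possibly hyphenated) is normalised and split;
#' the resulting model words map back to the one reference token.
#'
#' @param raw_tokens List of character vectors, one vector of raw word
#'   tokens per sequence (in corpus order).
#' @return Mapping tibble for [align_reference_words()].
#' @export
build_hyphen_map <- function(raw_tokens) {
  purrr::imap_dfr(raw_tokens, function(tokens, sid) {
    model_i <- 0L
    purrr::imap_dfr(tokens, function(tok, ref_i) {
      norm <- normalize_text(tok)
      parts <- stringi::stri_split_regex(norm, paste0("[ ", cogseg_divider, "]+"))[[1]]
      parts <- parts[nchar(parts) > 0L]
      if (length(parts) == 0L) {
        rlang::abort(paste0("reference token normalises to nothing: sequence ",
                            sid, ", token ", ref_i, " \"", tok, "\""))
      }
      idx <- model_i + seq_along(parts)
      model_i <<- model_i + length(parts)
      tibble::tibble(sequence_id = sid, model_word_index = idx,
                     ref_word_index = ref_i, ref_word = norm)
    })
  })
}

#' Three-way fixation-count label
#'
#' Skip = 0 fixations, One = exactly 1, More = 2 or more.
#'
#' @param count Integer vector of fixation counts (>= 0).
#' @return Factor with levels Skip, One, More.
#' @export
label3 <- function(count) {
  if (any(count < 0)) rlang::abort("fixation counts must be >= 0")
  factor(
    dplyr::case_when(count == 0 ~ "Skip", count == 1 ~ "One", TRUE ~ "More"),
    levels = c("Skip", "One", "More")
  )
}

#' Mean observed unit length inferred from fixation counts
#'
#' Word-level exports give fixation counts, not positions.  Assuming every
#' fixation sits at the center of one reading unit and the units tile the
#' sequence, a sequence's mean unit length is its rendered length (one
#' inter-word space per boundary included) divided by its total fixation
#' count.  The corpus value is the fixation-count-weighted mean of the
#' per-sequence ratios (equivalently, total rendered length over total
#' fixations); `weighting = "sequence"` instead averages the per-sequence
#' ratios unweighted.  Sequences with zero fixations are excluded.
#'
#' @param observed Fixation tibble.
#' @param corpus Corpus tibble covering the same sequences.
#' @param weighting `"fixation"` (default) or `"sequence"`.
#' @return Mean unit length in characters.
#' @export
mean_observed_unit_length <- function(observed, corpus,
                                      weighting = c("fixation", "sequence")) {
  weighting <- match.arg(weighting)
  check_fixation_table(observed)
  check_corpus(corpus)
  per_seq <- dplyr::summarise(
    dplyr::group_by(observed, .data$sequence_id),
    total = sum(.data$fixation_count), .groups = "drop"
  )
  per_seq <- dplyr::inner_join(per_seq, corpus, by = "sequence_id")
  per_seq <- per_seq[per_seq$total > 0L, , drop = FALSE]
  if (nrow(per_seq) == 0L) rlang::abort("no sequence has a nonzero fixation count")
  len <- nchar(per_seq$rendered)
  if (weighting == "fixation") {
    sum(len) / sum(per_seq$total)
  } else {
    mean(len / per_seq$total)
  }
}

#' Mean effective token length of a segmentation
#' @param segmentation Segmentation tibble.
#' @return Mean effective unit length in characters (trailing boundary
#'   spaces excluded, internal spaces of multiword units included).
#' @export
mean_unit_length <- function(segmentation) {
  mean(effective_length(segmentation$form))
}

#' Mean word length of a corpus (letters only, no spaces)
#' @param corpus Corpus tibble.
#' @export
mean_word_length <- function(corpus) {
  mean(nchar(corpus_words(corpus)$word))
}
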