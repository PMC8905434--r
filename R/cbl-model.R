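# Chunk-Based Learner comparator.
#
# A frequentist, word-level chunker: initially each word is a chunk; the
# backward transitional probability (BTP) between adjacent chunks,
# count(left, right) / count(right), is compared against the running
# average of all BTPs evaluated so far, and a pair whose BTP exceeds that
# average is merged into a new chunk that replaces the pair in further
# processing.  Chunks can merge again, so the inventory grows multiword
# units of any depth.  There are no hyperparameters.  At test time the
# lexicon is frozen and sequences are segmented by greedy left-to-right
# longest match over whole words; CBL never produces subword units.

new_cbl_state <- function() {
  structure(
    list(
      uni = new.env(parent = emptyenv()),
      bi = new.env(parent = emptyenv()),
      inventory = new.env(parent = emptyenv()),
      btp_sum = 0,
      btp_n = 0L,
      max_chunk_words = 1L
    ),
    class = "cbl_state"
  )
}

env_inc <- function(env, key, by = 1L) {
  assign(key, (if (exists(key, envir = env, inherits = FALSE))
    get(key, envir = env) else 0L) + by, envir = env)
}

env_get0 <- function(env, key) {
  if (exists(key, envir = env, inherits = FALSE)) get(key, envir = env) else 0L
}

bi_key <- function(left, right) paste(left, right, sep = "\r")

#' Backward transitional probability between two chunks
#'
#' count(left, right) / count(right); the chunking signal of the learner.
#'
#' @param state A `cbl_state`.
#' @param left,right Chunk strings (words joined by single spaces).
#' @return Probability in \[0, 1\].  Error if `right` has never been
#'   observed.
#' @export
cbl_btp <- function(state, left, right) {
  stopifnot(inherits(state, "cbl_state"))
  denom <- env_get0(state$uni, right)
  if (denom == 0L) rlang::abort(paste0("chunk never observed: \"", right, "\""))
  env_get0(state$bi, bi_key(left, right)) / denom
}

#' Observe one sequence incrementally
#'
#' Updates unigram and bigram counts word by word.  After each bigram
#' update the pair's BTP is compared against the running average of all
#' BTPs evaluated so far; if it is strictly above, the concatenated chunk
#' is added to the inventory and becomes the current unit, so later words
#' can merge with it in the same pass.  The running average is updated
#' after every evaluation (the very first evaluation has no average to
#' beat and never merges).
#'
#' @param state A `cbl_state` (modified in place and returned).
#' @param words Character vector of the sequence's words.
#' @return The updated `cbl_state`, invisibly usable in a pipe.
#' @export
cbl_observe <- function(state, words) {
  stopifnot(inherits(state, "cbl_state"))
  if (length(words) == 0L) return(state)
  cur <- words[[1]]
  env_inc(state$uni, cur)
  for (w in words[-1L]) {
    env_inc(state$uni, w)
    env_inc(state$bi, bi_key(cur, w))
    btp <- env_get0(state$bi, bi_key(cur, w)) / env_get0(state$uni, w)
    merge <- state$btp_n > 0L && btp > state$btp_sum / state$btp_n
    state$btp_sum <- state$btp_sum + btp
    state$btp_n <- state$btp_n + 1L
    if (merge) {
      chunk <- paste(cur, w)
      env_inc(state$inventory, chunk, 0L)
      assign(chunk, env_get0(state$inventory, chunk) + 1L,
             envir = state$inventory)
      env_inc(state$uni, chunk)
      nw <- length(strsplit(chunk, " ", fixed = TRUE)[[1]])
      if (nw > state$max_chunk_words) state$max_chunk_words <- nw
      cur <- chunk
    } else {
      cur <- w
    }
  }
  state
}

#' Train the Chunk-Based Learner on a corpus
#'
#' One (configurable) incremental pass over the training corpus in order;
#' the model is deterministic, so passes are the only knob.
#'
#' @param corpus Corpus tibble.
#' @param passes Number of passes over the corpus.
#' @return A trained `cbl_state`.
#' @export
cbl_train <- function(corpus, passes = 1L) {
  check_corpus(corpus)
  state <- new_cbl_state()
  words_by_seq <- stringi::stri_split_fixed(
    stringi::stri_trim_both(corpus$rendered), " ")
  for (p in seq_len(passes)) {
    for (ws in words_by_seq) state <- cbl_observe(state, ws)
  }
  state
}

#' Segment a corpus with a frozen CBL lexicon
#'
#' Greedy left-to-right longest match of inventory chunks over the word
#' sequence; unmatched words come out as single-word tokens.  No counts are
#' updated.  Tokens always align to word boundaries and carry their
#' trailing boundary space, so the output is directly comparable with the
#' character-level learner's segmentations.
#'
#' @param state A trained `cbl_state`.
#' @param corpus Corpus tibble.
#' @return Segmentation tibble (`sequence_id`, `token_index`, `form`,
#'   `start`, `end`, `oov`).
#' @export
cbl_segment <- function(state, corpus) {
  stopifnot(inherits(state, "cbl_state"))
  check_corpus(corpus)
  words <- corpus_words(corpus)
  purrr::map_dfr(corpus$sequence_id, function(sid) {
    w <- words[words$sequence_id == sid, , drop = FALSE]
    n <- nrow(w)
    forms <- character(0)
    starts <- integer(0)
    i <- 1L
    while (i <= n) {
      take <- 1L
      for (k in seq.int(min(state$max_chunk_words, n - i + 1L), 1L)) {
        if (k == 1L) break
        cand <- paste(w$word[i:(i + k - 1L)], collapse = " ")
        if (env_get0(state$inventory, cand) > 0L) { take <- k; break }
      }
      forms <- c(forms, paste0(paste(w$word[i:(i + take - 1L)], collapse = " "), " "))
      starts <- c(starts, w$start[i])
      i <- i + take
    }
    tibble::tibble(sequence_id = sid, token_index = seq_along(forms),
                   form = forms, start = starts,
                   end = starts + nchar(forms) - 1L, oov = FALSE)
  })
}

#' @export
print.cbl_state <- function(x, ...) {
  cat("<cbl_state> ", length(ls(x$uni)), " tracked chunks, ",
      length(ls(x$inventory)), " multiword chunks, running mean BTP = ",
      if (x$btp_n > 0L) sprintf("%.4f", x$btp_sum / x$btp_n) else "NA",
      "\n", sep = "")
  invisible(x)
}

#' Tidy a CBL state: the multiword chunk inventory
#' @param x A `cbl_state`.
#' @param ... Unused.
#' @return Tibble with `chunk`, `times_formed`, `count` (unigram count as a
#'   processed unit), ordered by count.
#' @export
tidy.cbl_state <- function(x, ...) {
  chunks <- ls(x$inventory)
  out <- tibble::tibble(
    chunk = chunks,
    times_formed = vapply(chunks, function(k) env_get0(x$inventory, k), integer(1)),
    count = vapply(chunks, function(k) env_get0(x$uni, k), integer(1))
  )
  dplyr::arrange(out, dplyr::desc(.data$count))
}

#' @export
glance.cbl_state <- function(x, ...) {
  tibble::tibble(
    n_tracked = length(ls(x$uni)),
    n_multiword = length(ls(x$inventory)),
    mean_btp = if (x$btp_n > 0L) x$btp_sum / x$btp_n else NA_real_,
    btp_evaluations = x$btp_n
  )
}

#' Write the CBL chunk inventory, one chunk per line with counts
#' @param state A `cbl_state`.
#' @param path Output path.
#' @export
write_cbl_inventory <- function(state, path) {
  readr::write_tsv(tidy(state), path)
  invisible(path)
}
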