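# The Less-is-Better learner.
#
# Segmentation follows two mechanisms: larger-first selection (the longest
# lexicon form matching at the current position is the default choice) and
# counterfactual evaluation (the longest candidate is compared against the
# second-longest by greedily segmenting the following input with each and
# counting tokens up to the first shared end offset; strictly more tokens
# marks the longest candidate Bad and the second-longest is taken instead).
# The lexicon is updated per epoch by memorising sampled adjacent token
# pairs, re-ranking evaluated types, and forgetting unevaluated tail types.
#
# The batch segmentation loop is compiled (src/segment.cpp); the R
# functions below are the reference implementations used for small inputs
# and as cross-checks.

#' Lexicon candidates matching at a position
#'
#' All lexicon forms that are a prefix of `rendered` starting at
#' `position`, ordered longest first.  Two distinct matches always differ
#' in length, so the order is total.
#'
#' @param lexicon A `lib_lexicon`.
#' @param rendered Rendered sequence string.
#' @param position 1-based character position; must not point at a space.
#' @return Character vector of matching forms, longest first.
#' @export
match_candidates <- function(lexicon, rendered, position) {
  stopifnot(inherits(lexicon, "lib_lexicon"), position >= 1L,
            position <= nchar(rendered))
  if (substr(rendered, position, position) == " ") {
    rlang::abort("`position` points at a space; units never start on a space")
  }
  rest <- substr(rendered, position, nchar(rendered))
  hit <- startsWith(rest, lexicon$forms)
  cands <- lexicon$forms[hit]
  cands[order(nchar(cands), decreasing = TRUE)]
}

greedy_bounds_r <- function(lexicon, rendered, start, first_len) {
  # end offsets (position after the token's last character) of the greedy
  # larger-first path seeded with a token of first_len; spaces are absorbed
  n <- nchar(rendered)
  absorb <- function(end) {
    if (end <= n && substr(rendered, end, end) == " " &&
        substr(rendered, end - 1L, end - 1L) != " ") end + 1L else end
  }
  bounds <- integer(0)
  pos <- absorb(start + first_len)
  bounds <- c(bounds, pos)
  while (pos <= n) {
    if (substr(rendered, pos, pos) == " ") { pos <- pos + 1L; next }
    cands <- match_candidates(lexicon, rendered, pos)
    len <- if (length(cands) > 0L) nchar(cands[[1]]) else 1L
    pos <- absorb(pos + len)
    bounds <- c(bounds, pos)
  }
  bounds  # offsets are "next position", i.e. token end + 1
}

#' Token count of a greedy lookahead path
#'
#' Number of tokens produced by taking `first_form` at `start` and then
#' segmenting greedily (larger-first only, no nested counterfactuals) until
#' `horizon_end`; unknown symbols count as singleton tokens.
#'
#' @param lexicon A `lib_lexicon`.
#' @param rendered Rendered sequence string.
#' @param start 1-based start position of the first token.
#' @param first_form Form taken as the first token; must match at `start`.
#' @param horizon_end Last character position of the lookahead window
#'   (defaults to the end of the sequence).
#' @return Integer token count.
#' @export
lookahead_token_count <- function(lexicon, rendered, start, first_form,
                                  horizon_end = nchar(rendered)) {
  stopifnot(substr(rendered, start, start + nchar(first_form) - 1L) == first_form)
  bounds <- greedy_bounds_r(lexicon, rendered, start, nchar(first_form))
  sum(bounds <= horizon_end + 1L)
}

#' Select the unit token at a position (reference implementation)
#'
#' Larger-first selection with optional counterfactual evaluation.  With no
#' matching candidate the single symbol is emitted as an out-of-lexicon
#' token.  With two or more candidates and `evaluate = TRUE`, the largest
#' candidate B is compared with the second-largest S by greedy lookahead to
#' their first shared end offset: strictly more tokens for B marks it Bad
#' and selects S; otherwise (ties included) B is Good and selected.
#'
#' @inheritParams match_candidates
#' @param evaluate Run counterfactual evaluation when two candidates exist.
#' @return List with `form` (token form including any absorbed boundary
#'   space), `start`, `end`, `oov`, `verdict` (`"none"`, `"good"` or
#'   `"bad"`, describing the largest candidate), and the two lookahead
#'   counts when evaluated.
#' @export
choose_unit <- function(lexicon, rendered, position, evaluate = TRUE) {
  n <- nchar(rendered)
  cands <- match_candidates(lexicon, rendered, position)
  verdict <- "none"
  count_largest <- NA_integer_
  count_second <- NA_integer_
  oov <- FALSE
  if (length(cands) == 0L) {
    chosen_len <- 1L
    oov <- TRUE
  } else if (!evaluate || length(cands) == 1L) {
    chosen_len <- nchar(cands[[1]])
  } else {
    b_len <- nchar(cands[[1]])
    s_len <- nchar(cands[[2]])
    pb <- greedy_bounds_r(lexicon, rendered, position, b_len)
    ps <- greedy_bounds_r(lexicon, rendered, position, s_len)
    common <- intersect(pb, ps)[1]
    count_largest <- match(common, pb)
    count_second <- match(common, ps)
    if (count_largest > count_second) {
      verdict <- "bad"
      chosen_len <- s_len
    } else {
      verdict <- "good"
      chosen_len <- b_len
    }
  }
  end <- position + chosen_len - 1L
  if (end < n && substr(rendered, end + 1L, end + 1L) == " " &&
      substr(rendered, end, end) != " ") {
    end <- end + 1L
  }
  list(form = substr(rendered, position, end), start = position, end = end,
       oov = oov, verdict = verdict,
       verdict_form = if (length(cands) > 0L) cands[[1]] else NA_character_,
       count_largest = count_largest, count_second = count_second)
}

#' Segment every sequence of a corpus
#'
#' Runs the compiled larger-first / counterfactual segmentation over all
#' sequences with a fixed lexicon.  Concatenated token forms reproduce each
#' rendered sequence exactly; out-of-lexicon symbols are emitted as
#' singleton tokens.
#'
#' @param lexicon A `lib_lexicon`.
#' @param corpus Corpus tibble.
#' @param evaluate Run counterfactual evaluation at every selection with at
#'   least two candidates.
#' @return Segmentation tibble with columns `sequence_id`, `token_index`,
#'   `form`, `start`, `end`, `oov`.  Attribute `"verdicts"` holds a tibble
#'   of the per-selection evaluations (`sequence_id`, `form`, `verdict`,
#'   `count_largest`, `count_second`).
#' @export
segment_corpus <- function(lexicon, corpus, evaluate = TRUE) {
  stopifnot(inherits(lexicon, "lib_lexicon"))
  check_corpus(corpus)
  raw <- cpp_segment_batch(corpus$rendered, lexicon$forms, evaluate)
  seg <- purrr::map2_dfr(corpus$sequence_id, raw, function(sid, r) {
    tibble::tibble(
      sequence_id = sid,
      token_index = seq_along(r$form),
      form = r$form,
      start = r$start,
      end = r$start + nchar(r$form) - 1L,
      oov = r$oov
    )
  })
  verdicts <- purrr::map2_dfr(corpus$sequence_id, raw, function(sid, r) {
    tibble::tibble(
      sequence_id = sid,
      form = as.character(r$verdict_form),
      verdict = as.character(r$verdict),
      count_largest = as.integer(r$count_largest),
      count_second = as.integer(r$count_second)
    )
  })
  attr(seg, "verdicts") <- verdicts
  seg
}

#' Segment a single rendered sequence
#'
#' @inheritParams segment_corpus
#' @param rendered A rendered sequence string (trailing space required), or
#'   a character vector of words.
#' @return Segmentation tibble as in [segment_corpus()] with
#'   `sequence_id = 1`.
#' @export
segment_sequence <- function(lexicon, rendered, evaluate = TRUE) {
  if (length(rendered) > 1L || !endsWith(rendered[[1]], " ")) {
    rendered <- render_sequence(rendered)
  }
  segment_corpus(lexicon, new_corpus(stringr::str_trim(rendered)), evaluate)
}

#' Memorise sampled token pairs and novel symbols
#'
#' Novel out-of-lexicon symbols are always appended (without their absorbed
#' boundary space).  Each adjacent token pair within a sequence is sampled
#' with probability `p_memorize`; a sampled pair's concatenated form is
#' appended at the end of the lexicon (lowest rank) unless already present
#' or longer than the unit-length limit.
#'
#' @param segmentation Segmentation tibble from [segment_corpus()] run with
#'   the same lexicon.
#' @param lexicon A `lib_lexicon`.
#' @param config A [lib_config()].
#' @return The updated `lib_lexicon`.
#' @export
memorize_pairs <- function(segmentation, lexicon, config = lib_config()) {
  stopifnot(inherits(lexicon, "lib_lexicon"))
  new_forms <- character(0)
  if (any(segmentation$oov)) {
    syms <- unique(sub(" $", "", segmentation$form[segmentation$oov]))
    new_forms <- syms
  }
  seg <- dplyr::group_by(segmentation, .data$sequence_id)
  seg <- dplyr::mutate(seg, next_form = dplyr::lead(.data$form))
  seg <- dplyr::ungroup(seg)
  pairs <- seg$next_form
  keep <- !is.na(pairs)
  left <- seg$form[keep]
  right <- pairs[keep]
  if (length(left) > 0L && config$p_memorize > 0) {
    sampled <- stats::runif(length(left)) < config$p_memorize
    new_forms <- c(new_forms, paste0(left[sampled], right[sampled]))
  }
  new_forms <- unique(new_forms)
  new_forms <- new_forms[effective_length(new_forms) <= lexicon$max_unit_len]
  new_forms <- setdiff(new_forms, lexicon$forms)
  if (length(new_forms) == 0L) return(lexicon)
  lexicon$forms <- c(lexicon$forms, new_forms)
  lexicon$probation_age <- c(lexicon$probation_age, integer(length(new_forms)))
  lexicon$last_verdict <- c(lexicon$last_verdict, rep("none", length(new_forms)))
  lexicon
}

#' Re-rank evaluated unit types
#'
#' A Good unit at rank r moves forward to rank ceiling(r * promote_factor)
#' and its probation is cancelled; a Bad unit moves backward to rank
#' min(|L|, ceiling(r * demote_factor)).  Verdicts are applied in the order
#' given; the relative order of untouched entries is preserved.
#'
#' @param lexicon A `lib_lexicon`.
#' @param verdicts Tibble or data frame with columns `form` and `verdict`
#'   (`"good"` / `"bad"`); every form must be in the lexicon.
#' @param config A [lib_config()] supplying the move factors.
#' @return The re-ranked `lib_lexicon`.
#' @export
apply_rerank <- function(lexicon, verdicts, config = lib_config()) {
  stopifnot(inherits(lexicon, "lib_lexicon"))
  if (nrow(verdicts) == 0L) return(lexicon)
  forms <- lexicon$forms
  age <- lexicon$probation_age
  last <- lexicon$last_verdict
  for (i in seq_len(nrow(verdicts))) {
    f <- verdicts$form[[i]]
    v <- verdicts$verdict[[i]]
    r <- match(f, forms)
    if (is.na(r)) rlang::abort(paste0("verdict for unknown form: ", f))
    target <- if (v == "good") {
      max(1L, as.integer(ceiling(r * config$promote_factor)))
    } else {
      min(length(forms), as.integer(ceiling(r * config$demote_factor)))
    }
    if (v == "good") {
      age[r] <- 0L
      last[r] <- "good"
    } else {
      last[r] <- "bad"
    }
    if (target != r) {
      perm <- append(seq_along(forms)[-r], r, after = target - 1L)
      forms <- forms[perm]
      age <- age[perm]
      last <- last[perm]
    }
  }
  lexicon$forms <- forms
  lexicon$probation_age <- age
  lexicon$last_verdict <- last
  lexicon
}

#' Age and forget tail unit types
#'
#' Entries in the probation zone (the configured tail fraction of the
#' lexicon) have their probation age incremented; entries whose age has
#' reached the probation period without a Good verdict are removed.
#' Single-symbol types are never removed, so the alphabet always remains
#' segmentable.
#'
#' @param lexicon A `lib_lexicon`.
#' @param config A [lib_config()].
#' @return The pruned `lib_lexicon`.
#' @export
apply_forgetting <- function(lexicon, config = lib_config()) {
  stopifnot(inherits(lexicon, "lib_lexicon"))
  n <- length(lexicon$forms)
  if (n == 0L) return(lexicon)
  in_tail <- seq_len(n) > (1 - config$probation_zone) * n
  lexicon$probation_age[in_tail] <- lexicon$probation_age[in_tail] + 1L
  drop <- lexicon$probation_age >= config$probation_period &
    lexicon$last_verdict != "good" &
    effective_length(lexicon$forms) > 1L
  if (any(drop)) {
    lexicon$forms <- lexicon$forms[!drop]
    lexicon$probation_age <- lexicon$probation_age[!drop]
    lexicon$last_verdict <- lexicon$last_verdict[!drop]
  }
  lexicon
}

#' Shannon encoding bits of a token batch
#'
#' Code length of the batch under its own empirical token-form frequencies:
#' -sum over tokens of log2(f(form) / N).  This is the quantity whose
#' plateau stops small-corpus training.
#'
#' @param token_forms Character vector of token forms (one element per
#'   token occurrence).
#' @return Total bits (numeric scalar).
#' @export
encoding_bits <- function(token_forms) {
  if (length(token_forms) == 0L) rlang::abort("encoding_bits needs a nonempty batch")
  f <- table(token_forms)
  p <- as.numeric(f[token_forms]) / length(token_forms)
  -sum(log2(p))
}

#' Train the Less-is-Better learner
#'
#' Each epoch samples a batch of sequences (with replacement in
#' small-corpus mode; sequentially without replacement in large-corpus
#' mode), segments it with counterfactual evaluation against the current
#' lexicon, memorises sampled pairs and novel symbols, re-ranks the
#' evaluated types, applies forgetting, and records the batch encoding
#' bits.  Small-corpus training stops once the bits have produced no new
#' minimum for `stop_patience` consecutive epochs; large-corpus training
#' stops when the material is exhausted.  The run is deterministic under
#' the configured seed.
#'
#' @param corpus Corpus tibble.
#' @param config A [lib_config()].
#' @param large_corpus_mode Sample batches sequentially without replacement
#'   and stop at the end of the corpus.
#' @return A `lib_fit` object: list with `lexicon`, `report` (one row per
#'   epoch: `epoch`, `bits`, `lexicon_size`, `n_tokens`), `stop_reason`,
#'   and `config`.
#' @export
lib_train <- function(corpus, config = lib_config(), large_corpus_mode = FALSE) {
  check_corpus(corpus)
  if (nrow(corpus) == 0L) rlang::abort("cannot train on an empty corpus")
  set.seed(config$seed)
  lexicon <- new_lexicon(max_unit_len = config$max_unit_len)
  n_seq <- nrow(corpus)
  best_bits <- Inf
  stall <- 0L
  offset <- 0L
  epoch <- 0L
  report <- vector("list", 0L)
  stop_reason <- "max-epochs"
  repeat {
    epoch <- epoch + 1L
    if (large_corpus_mode) {
      idx <- seq.int(offset + 1L, min(offset + config$batch_size, n_seq))
      offset <- offset + length(idx)
    } else {
      idx <- sample.int(n_seq, min(config$batch_size, n_seq), replace = TRUE)
    }
    batch <- corpus[idx, , drop = FALSE]
    seg <- segment_corpus(lexicon, batch, evaluate = TRUE)
    lexicon <- memorize_pairs(seg, lexicon, config)
    lexicon <- apply_rerank(lexicon, attr(seg, "verdicts"), config)
    lexicon <- apply_forgetting(lexicon, config)
    bits <- encoding_bits(seg$form)
    report[[epoch]] <- tibble::tibble(
      epoch = epoch, bits = bits, lexicon_size = length(lexicon$forms),
      n_tokens = nrow(seg)
    )
    if (large_corpus_mode) {
      if (offset >= n_seq) { stop_reason <- "material-exhausted"; break }
    } else {
      if (bits < best_bits) {
        best_bits <- bits
        stall <- 0L
      } else {
        stall <- stall + 1L
      }
      if (stall >= config$stop_patience) { stop_reason <- "no-improvement"; break }
    }
    if (epoch >= config$max_epochs) { stop_reason <- "max-epochs"; break }
  }
  structure(
    list(lexicon = lexicon, report = dplyr::bind_rows(report),
         stop_reason = stop_reason, config = config),
    class = "lib_fit"
  )
}

#' @export
print.lib_fit <- function(x, ...) {
  cat("<lib_fit> ", nrow(x$report), " epochs, stop: ", x$stop_reason,
      ", lexicon: ", length(x$lexicon$forms), " unit types\n", sep = "")
  invisible(x)
}

#' Tidy a training run: the per-epoch report
#' @param x A `lib_fit`.
#' @param ... Unused.
#' @export
tidy.lib_fit <- function(x, ...) x$report

#' @export
glance.lib_fit <- function(x, ...) {
  tibble::tibble(
    epochs = nrow(x$report),
    final_bits = x$report$bits[nrow(x$report)],
    min_bits = min(x$report$bits),
    lexicon_size = length(x$lexicon$forms),
    stop_reason = x$stop_reason,
    seed = x$config$seed
  )
}

#' Plot the encoding-bits trajectory of a training run
#' @param object A `lib_fit`.
#' @param ... Unused.
#' @export
autoplot.lib_fit <- function(object, ...) {
  ggplot2::ggplot(object$report, ggplot2::aes(x = .data$epoch, y = .data$bits)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "epoch", y = "batch encoding bits",
                  title = "Less-is-Better training trajectory") +
    ggplot2::theme_minimal()
}
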