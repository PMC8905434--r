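# Synthetic ground truth: a chunk inventory with Zipfian token
# frequencies, corpora sampled from it, and fixation tables generated from
# the true segmentation by the center-of-unit rule.  Every stage of the
# pipeline is testable against this generator without any external
# eye-tracking download.

#' Synthetic-corpus configuration
#'
#' @param n_words Number of word chunk types (stored with a trailing
#'   space).
#' @param n_multiword Number of multiword chunk types (two- or three-word
#'   strings with internal and trailing spaces), built from the word
#'   types.
#' @param n_subword Number of subword chunk types (short letter strings
#'   with no trailing space; adjacent subword chunks concatenate into
#'   longer written words, emulating productive morphology).
#' @param zipf_s Zipf exponent for the chunk frequency spectrum.
#' @param n_sequences Number of sequences to sample.
#' @param chunks_per_sequence Integer range (min, max) of chunks drawn per
#'   sequence, sampled uniformly.
#' @param noise Per-word probability that a generated fixation count is
#'   perturbed by one (direction random, floored at zero).
#' @param alphabet_size Letters available for word and subword forms; kept
#'   small so that subword structure is learnable at small corpus sizes.
#' @param seed Integer seed.
#' @return A `synth_config` list.
#' @export
synth_config <- function(n_words = 25L, n_multiword = 20L, n_subword = 8L,
                         zipf_s = 1, n_sequences = 2000L,
                         chunks_per_sequence = c(3L, 8L), noise = 0,
                         alphabet_size = 12L, seed = 1L) {
  stopifnot(n_words >= 1L, n_multiword >= 0L, n_subword >= 0L, zipf_s > 0,
            n_sequences >= 1L, length(chunks_per_sequence) == 2L,
            chunks_per_sequence[1] >= 1L,
            chunks_per_sequence[2] >= chunks_per_sequence[1],
            noise >= 0, noise <= 1, alphabet_size >= 2L,
            alphabet_size <= 26L)
  structure(
    list(n_words = as.integer(n_words), n_multiword = as.integer(n_multiword),
         n_subword = as.integer(n_subword), zipf_s = zipf_s,
         n_sequences = as.integer(n_sequences),
         chunks_per_sequence = as.integer(chunks_per_sequence),
         noise = noise, alphabet_size = as.integer(alphabet_size),
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

random_forms <- function(n, len_range, alphabet) {
  out <- character(0)
  while (length(out) < n) {
    lens <- sample(seq.int(len_range[1], len_range[2]), n, replace = TRUE)
    forms <- vapply(lens, function(l) {
      paste(sample(alphabet, l, replace = TRUE), collapse = "")
    }, character(1))
    out <- unique(c(out, forms))
  }
  out[seq_len(n)]
}

#' Generate a ground-truth chunk inventory
#'
#' Word forms are random strings over a small alphabet; multiword chunks
#' are sampled word pairs and triples; subword chunks are short strings
#' that concatenate with following chunks into longer written words.
#' Zipfian weights are assigned by rank over a seeded permutation in which
#' the multiword chunks occupy the upper half of the ranks, emulating the
#' high-frequency collocations ("i was", "to do") that become reading
#' units in natural text.
#'
#' @param config A [synth_config()].
#' @return A `chunk_inventory` tibble with columns `chunk`, `type`
#'   (`subword`/`word`/`multiword`), `rank`, `weight`.
#' @export
make_inventory <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed, {
    alphabet <- letters[seq_len(config$alphabet_size)]
    words <- random_forms(config$n_words, c(2L, 7L), alphabet)
    multi <- character(0)
    if (config$n_multiword > 0L) {
      seen <- character(0)
      while (length(multi) < config$n_multiword) {
        k <- sample(2:3, 1L, prob = c(0.7, 0.3))
        cand <- paste(sample(words, k), collapse = " ")
        if (!cand %in% seen) {
          seen <- c(seen, cand)
          multi <- c(multi, cand)
        }
      }
    }
    sub <- if (config$n_subword > 0L) {
      random_forms(config$n_subword, c(2L, 4L), alphabet)
    } else character(0)
    # subword forms must not collide with word forms
    sub <- setdiff(sub, words)
    while (length(sub) < config$n_subword) {
      extra <- setdiff(random_forms(config$n_subword, c(2L, 4L), alphabet), c(words, sub))
      sub <- c(sub, extra)[seq_len(min(config$n_subword, length(sub) + length(extra)))]
    }
    with_space <- function(x) if (length(x)) paste0(x, " ") else character(0)
    chunks <- tibble::tibble(
      chunk = c(with_space(words), with_space(multi), sub),
      type = c(rep("word", length(words)), rep("multiword", length(multi)),
               rep("subword", length(sub)))
    )
    n <- nrow(chunks)
    # multiword chunks take seeded positions in the top half of the ranks
    ranks <- integer(n)
    is_multi <- chunks$type == "multiword"
    top_half <- seq_len(max(ceiling(n / 2), sum(is_multi)))
    multi_ranks <- sample(top_half, sum(is_multi))
    ranks[is_multi] <- multi_ranks
    ranks[!is_multi] <- sample(setdiff(seq_len(n), multi_ranks))
    chunks$rank <- ranks
    chunks$weight <- 1 / ranks^config$zipf_s
    out <- dplyr::arrange(chunks, .data$rank)
    class(out) <- c("chunk_inventory", class(out))
    attr(out, "config") <- config
    out
  })
}

#' Sample a corpus from a chunk inventory
#'
#' Each sequence is a concatenation of chunks drawn independently with the
#' inventory's Zipfian weights; the generating chunk boundaries are
#' recorded as the true segmentation.  A sequence ending in a subword
#' chunk gains the mandatory trailing space, which the final true token
#' absorbs.
#'
#' @param inventory A `chunk_inventory`.
#' @param config The [synth_config()] (defaults to the one stored on the
#'   inventory).
#' @return List with `corpus` (corpus tibble) and `segmentation` (true
#'   segmentation tibble in the same layout as [segment_corpus()]).
#' @export
sample_corpus <- function(inventory, config = attr(inventory, "config")) {
  stopifnot(inherits(inventory, "chunk_inventory"), inherits(config, "synth_config"))
  with_seed(config$seed + 1L, {
    rng <- config$chunks_per_sequence
    k <- sample(seq.int(rng[1], rng[2]), config$n_sequences, replace = TRUE)
    draws <- sample.int(nrow(inventory), sum(k), replace = TRUE,
                        prob = inventory$weight)
    chunk_of <- split(inventory$chunk[draws], rep(seq_along(k), k))
    rendered <- vapply(chunk_of, function(ch) {
      r <- paste(ch, collapse = "")
      if (!endsWith(r, " ")) r <- paste0(r, " ")
      r
    }, character(1))
    corpus <- new_corpus(stringr::str_trim(rendered), source_id = "synthetic")
    segmentation <- purrr::imap_dfr(chunk_of, function(ch, sid) {
      forms <- ch
      # the last token owns the sequence-final space
      if (!endsWith(forms[length(forms)], " ")) {
        forms[length(forms)] <- paste0(forms[length(forms)], " ")
      }
      len <- nchar(forms)
      start <- cumsum(c(1L, len[-length(len)]))
      tibble::tibble(sequence_id = as.integer(sid),
                     token_index = seq_along(forms), form = forms,
                     start = start, end = start + len - 1L, oov = FALSE)
    })
    list(corpus = corpus, segmentation = segmentation)
  })
}

#' Generate an observed fixation table from a true segmentation
#'
#' Counts are the center-rule predictions of the true segmentation; with
#' probability `noise` per word the count is perturbed by one (direction
#' random, floored at zero).  The noise model is a testing device, not a
#' model of reading variability.
#'
#' @param segmentation True segmentation tibble.
#' @param corpus The corpus it covers.
#' @param noise Per-word perturbation probability.
#' @param seed Integer seed for the perturbation.
#' @return Fixation tibble.
#' @export
synth_fixations <- function(segmentation, corpus, noise = 0, seed = 1L) {
  counts <- predict_fixation_counts(segmentation, corpus)
  if (noise > 0) {
    counts <- with_seed(seed, {
      hit <- stats::runif(nrow(counts)) < noise
      delta <- sample(c(-1L, 1L), nrow(counts), replace = TRUE)
      counts$fixation_count <- pmax(0L, counts$fixation_count + hit * delta)
      counts
    })
  }
  counts
}

#' Share of true chunks recovered near the top of a trained lexicon
#'
#' Fraction of the inventory's multiword (and/or subword) chunk types found
#' in the top fraction of the trained lexicon's ranks.  A chunk counts as
#' recovered whether its learned form carries the trailing boundary space
#' or not; the two spellings denote the same unit in different sentence
#' positions.
#'
#' @param lexicon A trained `lib_lexicon`.
#' @param inventory A `chunk_inventory`.
#' @param top_fraction Fraction of the lexicon (from the front) searched.
#' @param types Chunk types to score.
#' @return Recovered fraction in \[0, 1\].
#' @export
lexicon_recall <- function(lexicon, inventory, top_fraction = 1 / 3,
                           types = c("multiword", "subword")) {
  stopifnot(inherits(lexicon, "lib_lexicon"), length(lexicon$forms) > 0L)
  targets <- inventory$chunk[inventory$type %in% types]
  if (length(targets) == 0L) return(NA_real_)
  top <- lexicon$forms[seq_len(ceiling(top_fraction * length(lexicon$forms)))]
  top_all <- unique(c(top, sub(" $", "", top), paste0(top, " ")))
  mean(targets %in% top_all)
}
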