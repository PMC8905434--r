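# Text normalisation and sequence construction.
#
# The models operate on lowercase, diacritic-free text in which punctuation
# acts as a hard divider between input sequences and every word token ends
# with a space.  A corpus is a tibble with one row per sequence; the
# `rendered` column holds the words joined by single spaces plus one
# trailing space, so character offsets into `rendered` are stable and every
# segmentation can be checked against it exactly.

#' Reserved divider character
#'
#' Punctuation is replaced by this character during normalisation; sequences
#' are later split on it.  It never occurs in natural input after
#' normalisation.
#' @export
cogseg_divider <- "⟂"

#' Normalise raw text
#'
#' Lowercases, strips diacritics (canonical decomposition followed by
#' removal of combining marks, so e.g. a diaeresis-marked "e" becomes plain
#' "e"), replaces punctuation with the reserved divider character, and
#' collapses runs of whitespace to single spaces.  Apostrophes adjacent to a
#' letter are kept (possessives, contractions, and clitics such as Dutch
#' "'t"); free-standing apostrophes become dividers like any other
#' punctuation.  Digits pass through unchanged.
#'
#' @param raw Character vector of raw UTF-8 text.
#' @return Character vector of normalised text, same length as `raw`.
#' @examples
#' normalize_text("Hallo, Wereld!")
#' @export
normalize_text <- function(raw) {
  stopifnot(is.character(raw))
  if (length(raw) == 0L) return(character(0))
  x <- stringi::stri_trans_tolower(raw)
  x <- stringi::stri_trans_nfd(x)
  x <- stringi::stri_replace_all_regex(x, "\\p{Mn}", "")
  # keep apostrophes only when touching a letter or digit on either side
  x <- stringi::stri_replace_all_regex(x, "(?<![\\p{L}\\p{Nd}])'(?![\\p{L}\\p{Nd}])",
                                       cogseg_divider)
  # everything that is not a letter, digit, apostrophe or whitespace divides
  x <- stringi::stri_replace_all_regex(x, "[^\\p{L}\\p{Nd}'\\s⟂]",
                                       cogseg_divider)
  x <- stringi::stri_replace_all_regex(x, "\\s+", " ")
  stringi::stri_trim_both(x)
}

#' Split normalised text into a corpus of sequences
#'
#' Dividers (and, optionally, supplied line-break positions) split the text
#' into sequences; empty fragments are dropped; each fragment is tokenised
#' on spaces into words.  Line breaks split sentences that run across
#' display lines: the last word of one line and the first of the next are
#' too far apart to form a single perceptual unit.
#'
#' @param normalized Character scalar produced by [normalize_text()].
#' @param line_break_positions Integer vector of character positions (1-based,
#'   pointing at a character in `normalized`) before which an additional
#'   break is inserted.  Defaults to none.
#' @param source_id Label attached to the corpus.
#' @return A corpus tibble with columns `sequence_id` (integer) and
#'   `rendered` (words joined by single spaces, one trailing space).
#' @export
split_sequences <- function(normalized, line_break_positions = integer(),
                            source_id = "text") {
  stopifnot(is.character(normalized), length(normalized) == 1L)
  x <- normalized
  if (length(line_break_positions) > 0L) {
    pos <- sort(unique(as.integer(line_break_positions)))
    stopifnot(all(pos >= 1L), all(pos <= nchar(x) + 1L))
    pieces <- substring(x, c(1L, pos), c(pos - 1L, nchar(x)))
    x <- paste(pieces, collapse = cogseg_divider)
  }
  frags <- stringi::stri_split_fixed(x, cogseg_divider)[[1]]
  frags <- stringi::stri_trim_both(frags)
  frags <- frags[frags != ""]
  new_corpus(frags, source_id = source_id)
}

#' Build a corpus from word lists or pre-tokenised fragments
#'
#' @param fragments Character vector, each element the space-separated words
#'   of one sequence (no trailing space needed), or a list of character
#'   vectors of words.
#' @param source_id Label attached to the corpus.
#' @return A corpus tibble (`sequence_id`, `rendered`).
#' @export
new_corpus <- function(fragments, source_id = "text") {
  if (is.list(fragments)) {
    fragments <- vapply(fragments, paste, character(1), collapse = " ")
  }
  fragments <- fragments[nchar(fragments) > 0L]
  out <- tibble::tibble(
    sequence_id = seq_along(fragments),
    rendered = if (length(fragments)) paste0(fragments, " ") else character(0)
  )
  attr(out, "source_id") <- source_id
  out
}

#' Render a word vector as a sequence string
#'
#' Words are joined by single spaces and one trailing space is appended, so
#' that every word token ends with a space.  Length of the result is the sum
#' of the word lengths plus the number of words.
#'
#' @param words Character vector of words (no internal spaces).
#' @return Character scalar.
#' @examples
#' render_sequence(c("i", "have"))  # "i have "
#' @export
render_sequence <- function(words) {
  stopifnot(is.character(words), length(words) >= 1L,
            !any(stringr::str_detect(words, " ")))
  paste0(paste(words, collapse = " "), " ")
}

#' Per-word view of a corpus
#'
#' Expands a corpus tibble into one row per word with its character span in
#' `rendered`.  Spans are 1-based and inclusive; each word is followed by
#' exactly one space (the trailing-space boundary marker it owns).
#'
#' @param corpus Corpus tibble from [split_sequences()] or [new_corpus()].
#' @return Tibble with columns `sequence_id`, `word_index`, `word`, `start`,
#'   `end`.
#' @export
corpus_words <- function(corpus) {
  check_corpus(corpus)
  if (nrow(corpus) == 0L) {
    return(tibble::tibble(sequence_id = integer(0), word_index = integer(0),
                          word = character(0), start = integer(0),
                          end = integer(0)))
  }
  purrr::map2_dfr(corpus$sequence_id, corpus$rendered, function(sid, rend) {
    words <- stringi::stri_split_fixed(stringi::stri_trim_both(rend), " ")[[1]]
    len <- nchar(words)
    start <- cumsum(c(1L, len[-length(len)] + 1L))
    tibble::tibble(
      sequence_id = sid,
      word_index = seq_along(words),
      word = words,
      start = start,
      end = start + len - 1L
    )
  })
}

check_corpus <- function(corpus) {
  if (!is.data.frame(corpus) ||
      !all(c("sequence_id", "rendered") %in% names(corpus))) {
    rlang::abort("`corpus` must be a tibble with columns `sequence_id` and `rendered`.")
  }
  if (any(!grepl(" $", corpus$rendered))) {
    rlang::abort("every rendered sequence must end with a trailing space")
  }
  invisible(corpus)
}

#' Read a plain-text corpus
#'
#' One physical line is one display line: each line is normalised and split
#' on dividers independently, so sentences running across lines become
#' separate sequences.
#'
#' @param path Path to a UTF-8 text file.
#' @param source_id Label attached to the corpus; defaults to the file name.
#' @return A corpus tibble.
#' @export
read_corpus <- function(path, source_id = basename(path)) {
  if (!file.exists(path)) rlang::abort(paste0("corpus file not found: ", path))
  lines <- readr::read_lines(path)
  norm <- normalize_text(lines)
  frags <- unlist(lapply(norm, function(x) {
    f <- stringi::stri_split_fixed(x, cogseg_divider)[[1]]
    f <- stringi::stri_trim_both(f)
    f[f != ""]
  }), use.names = FALSE)
  new_corpus(frags, source_id = source_id)
}

#' Write a corpus to a text file, one rendered sequence per line
#' @param corpus Corpus tibble.
#' @param path Output path.
#' @export
write_corpus <- function(corpus, path) {
  check_corpus(corpus)
  readr::write_lines(corpus$rendered, path)
  invisible(path)
}

#' Read a word-level fixation-count table
#'
#' Expects a TSV with header columns `sequence_id`, `word_index`, `word`,
#' `fixation_count` — the adapter target for word-level first-pass
#' fixation-count exports from eye-tracking corpora.
#'
#' @param path Path to the TSV file.
#' @return Tibble with integer `fixation_count` keyed by
#'   (`sequence_id`, `word_index`).
#' @export
read_fixation_table <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("fixation table not found: ", path))
  tab <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    sequence_id = readr::col_integer(),
    word_index = readr::col_integer(),
    word = readr::col_character(),
    fixation_count = readr::col_integer()
  ))
  required <- c("sequence_id", "word_index", "word", "fixation_count")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    rlang::abort(paste0("fixation table missing columns: ",
                        paste(missing, collapse = ", ")))
  }
  bad <- which(is.na(tab$sequence_id) | is.na(tab$word_index) |
                 is.na(tab$fixation_count))
  if (length(bad) > 0L) {
    rlang::abort(paste0("malformed fixation-table row at line ",
                        paste(bad + 1L, collapse = ", ")))
  }
  neg <- which(tab$fixation_count < 0L)
  if (length(neg) > 0L) {
    rlang::abort(paste0("negative fixation count at line ",
                        paste(neg + 1L, collapse = ", ")))
  }
  check_fixation_table(tab)
  tab[required]
}

#' Write a fixation-count table as TSV
#' @param table Fixation tibble.
#' @param path Output path.
#' @export
write_fixation_table <- function(table, path) {
  check_fixation_table(table)
  readr::write_tsv(table, path)
  invisible(path)
}

check_fixation_table <- function(table) {
  required <- c("sequence_id", "word_index", "fixation_count")
  if (!is.data.frame(table) || !all(required %in% names(table))) {
    rlang::abort("fixation table needs columns sequence_id, word_index, fixation_count")
  }
  if (any(table$fixation_count < 0)) rlang::abort("fixation counts must be >= 0")
  if (anyDuplicated(table[, c("sequence_id", "word_index")]) > 0L) {
    rlang::abort("duplicate (sequence_id, word_index) keys in fixation table")
  }
  invisible(table)
}
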