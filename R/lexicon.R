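# The ordered lexicon of unit types.
#
# Rank encodes the model's confidence that a type is a cognitive unit:
# front = rank 1 = highest confidence.  No frequency statistics are stored;
# all learning signal lives in the ordering, the probation ages, and the
# last evaluation verdicts.

#' Create a unit lexicon
#'
#' @param forms Character vector of unit forms in rank order (front = rank
#'   1).  Forms may contain internal and trailing spaces ("do " is distinct
#'   from "do") but never start with a space; duplicates are an error.
#' @param max_unit_len Maximum effective unit length (characters excluding a
#'   trailing space) admitted into the lexicon, or `Inf` for unbounded.
#' @return An object of class `lib_lexicon`.
#' @export
new_lexicon <- function(forms = character(), max_unit_len = Inf) {
  stopifnot(is.character(forms))
  if (anyDuplicated(forms) > 0L) rlang::abort("lexicon forms must be unique")
  if (any(startsWith(forms, " "))) rlang::abort("unit forms cannot start with a space")
  if (any(nchar(forms) == 0L)) rlang::abort("unit forms cannot be empty")
  if (any(effective_length(forms) > max_unit_len)) {
    rlang::abort("a form exceeds max_unit_len")
  }
  structure(
    list(
      forms = forms,
      probation_age = integer(length(forms)),
      last_verdict = rep("none", length(forms)),
      max_unit_len = max_unit_len
    ),
    class = "lib_lexicon"
  )
}

#' Effective length of a unit form
#'
#' Characters in the form excluding a single trailing space; internal spaces
#' of multiword units count.  This is the length the unit-length limit and
#' the center rule operate on.
#' @param forms Character vector.
#' @return Integer vector.
#' @export
effective_length <- function(forms) {
  nchar(forms) - as.integer(endsWith(forms, " "))
}

#' @export
length.lib_lexicon <- function(x) length(x$forms)

#' @export
print.lib_lexicon <- function(x, n = 10L, ...) {
  cat("<lib_lexicon> ", length(x$forms), " unit types, max_unit_len = ",
      format(x$max_unit_len), "\n", sep = "")
  head_n <- utils::head(x$forms, n)
  if (length(head_n) > 0L) {
    cat(paste0("  ", seq_along(head_n), ". \"",
               gsub(" ", "␣", head_n), "\"", collapse = "\n"), "\n")
    if (length(x$forms) > n) cat("  ... and", length(x$forms) - n, "more\n")
  }
  invisible(x)
}

#' Tidy a lexicon into a tibble
#'
#' @param x A `lib_lexicon`.
#' @param ... Unused.
#' @return Tibble with columns `rank`, `form`, `effective_length`,
#'   `probation_age`, `last_verdict`.
#' @export
tidy.lib_lexicon <- function(x, ...) {
  tibble::tibble(
    rank = seq_along(x$forms),
    form = x$forms,
    effective_length = effective_length(x$forms),
    probation_age = x$probation_age,
    last_verdict = x$last_verdict
  )
}

#' @export
glance.lib_lexicon <- function(x, ...) {
  tibble::tibble(
    n_types = length(x$forms),
    n_single_symbol = sum(effective_length(x$forms) == 1L),
    n_multiword = sum(stringr::str_detect(stringr::str_trim(x$forms), " ")),
    mean_effective_length = if (length(x$forms)) mean(effective_length(x$forms)) else NA_real_,
    max_unit_len = x$max_unit_len
  )
}

#' Write a lexicon file
#'
#' One unit form per line in rank order, with spaces shown as the open-box
#' character so trailing spaces stay visible; a comment header echoes the
#' length limit.
#'
#' @param lexicon A `lib_lexicon`.
#' @param path Output path.
#' @export
write_lexicon <- function(lexicon, path) {
  stopifnot(inherits(lexicon, "lib_lexicon"))
  header <- c("# cogseg lexicon v1",
              paste0("# max_unit_len: ", format(lexicon$max_unit_len)))
  readr::write_lines(c(header, gsub(" ", "␣", lexicon$forms, fixed = TRUE)),
                     path)
  invisible(path)
}

#' Read a lexicon file written by [write_lexicon()]
#' @param path Path to the lexicon file.
#' @return A `lib_lexicon`.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("lexicon file not found: ", path))
  lines <- readr::read_lines(path)
  max_len <- Inf
  hdr <- grep("^# max_unit_len: ", lines, value = TRUE)
  if (length(hdr) == 1L) {
    val <- sub("^# max_unit_len: ", "", hdr)
    max_len <- if (val == "Inf") Inf else as.numeric(val)
  }
  forms <- gsub("␣", " ", lines[!startsWith(lines, "#")], fixed = TRUE)
  forms <- forms[nchar(forms) > 0L]
  new_lexicon(forms, max_unit_len = max_len)
}

#' Learner hyperparameters
#'
#' @param batch_size Sequences per training epoch (one batch per epoch).
#' @param p_memorize Probability that an adjacent token pair is memorised as
#'   a new unit type.
#' @param promote_factor Multiplier on the rank of a unit judged Good (in
#'   (0, 1); smaller promotes faster).
#' @param demote_factor Multiplier on the rank of a unit judged Bad (> 1).
#' @param probation_zone Tail fraction of the lexicon whose entries age
#'   toward forgetting each epoch.
#' @param probation_period Epochs a tail entry may survive without a Good
#'   verdict before it is forgotten.
#' @param stop_patience Epochs without a new encoding-bits minimum before
#'   training stops (small-corpus mode).
#' @param max_unit_len Maximum effective unit length, or `Inf`.
#' @param max_epochs Safety cap on the number of epochs.
#' @param seed Integer seed; all randomness in a run derives from it.
#' @return A `lib_config` list.
#' @export
lib_config <- function(batch_size = 200L, p_memorize = 0.1,
                       promote_factor = 0.5, demote_factor = 2,
                       probation_zone = 0.2, probation_period = 3L,
                       stop_patience = 3L, max_unit_len = Inf,
                       max_epochs = 200L, seed = 1L) {
  stopifnot(batch_size >= 1L, p_memorize >= 0, p_memorize <= 1,
            promote_factor > 0, promote_factor < 1, demote_factor > 1,
            probation_zone >= 0, probation_zone <= 1, probation_period >= 1L,
            stop_patience >= 1L, max_unit_len >= 1, max_epochs >= 1L)
  structure(
    list(batch_size = as.integer(batch_size), p_memorize = p_memorize,
         promote_factor = promote_factor, demote_factor = demote_factor,
         probation_zone = probation_zone,
         probation_period = as.integer(probation_period),
         stop_patience = as.integer(stop_patience),
         max_unit_len = max_unit_len, max_epochs = as.integer(max_epochs),
         seed = as.integer(seed)),
    class = "lib_config"
  )
}
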