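# Pipe-delimited segmentation files: one sequence per line, units joined
# by "|" ("i was |trying to |make |up |my mind |what |to do").  This is
# both the package's output format and the adapter for segmentations
# produced by external tools (e.g. Bayesian grammar-based segmenters),
# which are evaluated through the same linking rule.

#' Write a segmentation as pipe-delimited units
#'
#' @param segmentation Segmentation tibble.
#' @param path Output path.
#' @param header Optional character vector of `# `-prefixed comment lines
#'   (config echo) written before the data.
#' @export
write_segmentation <- function(segmentation, path, header = character()) {
  lines <- vapply(split(segmentation$form, segmentation$sequence_id),
                  function(forms) sub(" $", "", paste(forms, collapse = "|")),
                  character(1))
  readr::write_lines(c(header, lines), path)
  invisible(path)
}

#' Read a pipe-delimited segmentation file
#'
#' Reconstructs unit forms and character spans.  The sequence-final unit
#' regains its trailing boundary space; line order gives the sequence ids.
#' Lines starting with `#` are skipped.
#'
#' @param path Path to the segmentation file.
#' @return Segmentation tibble (`sequence_id`, `token_index`, `form`,
#'   `start`, `end`, `oov`).
#' @export
read_segmentation <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("segmentation file not found: ", path))
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "#")]
  lines <- lines[nchar(stringi::stri_trim_both(lines)) > 0L]
  purrr::imap_dfr(lines, function(line, sid) {
    forms <- stringi::stri_split_fixed(line, "|")[[1]]
    forms[length(forms)] <- paste0(sub(" $", "", forms[length(forms)]), " ")
    len <- nchar(forms)
    start <- cumsum(c(1L, len[-length(len)]))
    tibble::tibble(sequence_id = sid, token_index = seq_along(forms),
                   form = forms, start = start, end = start + len - 1L,
                   oov = FALSE)
  })
}

#' Rendered text covered by a segmentation
#'
#' Concatenates the token forms per sequence; equals the corpus `rendered`
#' column for any valid segmentation.
#'
#' @param segmentation Segmentation tibble.
#' @return Tibble (`sequence_id`, `rendered`).
#' @export
segmentation_text <- function(segmentation) {
  dplyr::summarise(
    dplyr::group_by(segmentation, .data$sequence_id),
    rendered = paste(.data$form, collapse = ""), .groups = "drop"
  )
}
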