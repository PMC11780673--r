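# External interfaces: JSON-lines response files (one response per line)
# and CSV ambiguity-label files. Human survey exports enter the pipeline
# through these readers in the same response format as machine runs.

#' Write a response set as JSON-lines
#'
#' One response object per line, with fields `respondent_id`,
#' `record_id`, `sign`, `verdict` (`true`/`false`/`null`),
#' `citation_raw`, `run_index`, `temperature`.
#'
#' @param responses A response tibble.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_responses <- function(responses, path) {
  responses <- tibble::as_tibble(responses)
  lines <- vapply(seq_len(nrow(responses)), function(i) {
    jsonlite::toJSON(as.list(responses[i, ]), auto_unbox = TRUE,
                     null = "null", na = "null")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a response set from JSON-lines
#'
#' @param path Path to a JSON-lines response file written by
#'   [write_responses()] or an external annotation tool.
#' @return A response tibble; `verdict` is logical with `NA` for the
#'   abstain state.
#' @export
read_responses <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    rec <- lapply(rec, function(x) if (is.null(x)) NA else x)
    tibble::as_tibble(rec)
  })
  out <- dplyr::bind_rows(rows)
  if ("verdict" %in% names(out)) out$verdict <- as_verdict(out$verdict)
  if ("run_index" %in% names(out)) {
    out$run_index <- as.integer(out$run_index)
  }
  if ("temperature" %in% names(out)) {
    out$temperature <- as.numeric(out$temperature)
  }
  out
}

#' Read an ambiguity-label file
#'
#' @param path CSV with columns `record_id`, `sign`, `ambiguity`.
#' @return A label tibble for [attach_ambiguity()].
#' @export
read_ambiguity_labels <- function(path) {
  out <- tibble::as_tibble(utils::read.csv(
    path, colClasses = "character", fileEncoding = "UTF-8"
  ))
  stopifnot(all(c("record_id", "sign", "ambiguity") %in% names(out)))
  out
}
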