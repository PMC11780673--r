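#' Sample size to estimate the sensitivity of a single test
#'
#' Computes the number of records needed to estimate a test's sensitivity
#' with a given margin of error, inflating the required number of
#' condition-positive records by the expected prevalence (Buderer's
#' approach). The required positive count is
#' \eqn{z^2 \, Se (1-Se) / d^2}, and the returned corpus size is that count
#' divided by the expected prevalence, with a single ceiling applied at the
#' final step.
#'
#' @param expected_sensitivity Anticipated sensitivity, in (0, 1).
#' @param margin_of_error Acceptable half-width of the confidence interval,
#'   in (0, 1).
#' @param expected_prevalence Anticipated prevalence of the condition among
#'   sampled records, in (0, 1]. A prevalence of 1 returns the positive
#'   count itself.
#' @param conf_level Two-sided confidence level, in (0, 1); determines the
#'   standard-normal critical value. Default 0.95.
#' @param z Optional explicit critical value overriding `conf_level`
#'   (e.g. the conventional 1.96).
#'
#' @return A positive integer count of records.
#'
#' @examples
#' # a study estimating 95% sensitivity to within 7 points, prevalence 15%
#' required_sample_size(0.95, 0.07, 0.15)
#'
#' @export
required_sample_size <- function(expected_sensitivity, margin_of_error,
                                 expected_prevalence, conf_level = 0.95,
                                 z = NULL) {
  check_prob(expected_sensitivity, "expected_sensitivity",
             open_left = TRUE, open_right = TRUE)
  check_prob(margin_of_error, "margin_of_error",
             open_left = TRUE, open_right = TRUE)
  check_prob(expected_prevalence, "expected_prevalence", open_left = TRUE)
  if (is.null(z)) {
    z <- z_from_level(conf_level)
  }
  if (!is.numeric(z) || length(z) != 1L || !is.finite(z) || z <= 0) {
    abort("`z` must be a single positive finite number",
          class = "ehrsigneval_validation_error")
  }
  n_positive <- z^2 * expected_sensitivity * (1 - expected_sensitivity) /
    margin_of_error^2
  as.integer(ceiling(n_positive / expected_prevalence))
}

#' Read a record corpus from CSV or JSON-lines
#'
#' Records carry five fields: `record_id`, `patient_id`, `admission_date`,
#' `presenting_complaint`, and `pertinent_history`. The format is chosen by
#' file extension: `.jsonl`/`.ndjson` is read as one JSON object per line,
#' anything else as comma-separated values with a header.
#'
#' @param path Path to a UTF-8 CSV or JSON-lines file.
#' @return A tibble with the five record fields (all character except
#'   `admission_date`, parsed as `Date` where possible).
#' @seealso [filter_corpus()] for the exclusion rules applied before
#'   analysis.
#' @export
read_corpus <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("corpus file not found: %s", path))
  }
  if (grepl("\\.(jsonl|ndjson)$", path, ignore.case = TRUE)) {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, function(l) {
      rec <- tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
      if (is.null(rec)) return(NULL)
      tibble::as_tibble(rec[lengths(rec) == 1L])
    })
    out <- dplyr::bind_rows(rows)
  } else {
    out <- tibble::as_tibble(utils::read.csv(
      path, colClasses = "character", fileEncoding = "UTF-8",
      check.names = FALSE
    ))
  }
  if ("admission_date" %in% names(out)) {
    parsed <- as.Date(out$admission_date, optional = TRUE)
    if (!anyNA(parsed)) out$admission_date <- parsed
  }
  out
}

#' Apply corpus exclusion rules
#'
#' Drops records that cannot enter the study: rows missing `record_id` or
#' `patient_id` (reason `"malformed"`), records whose pertinent-history text
#' is empty or whitespace-only (reason `"empty_history"`), and second or
#' later records for a patient already represented (reason
#' `"duplicate_patient"`; the earliest-sampled record is kept — replacement
#' sampling, if any, is the caller's loop). Every exclusion is logged;
#' `nrow(kept) + nrow(excluded)` always equals the input size.
#'
#' @param records A tibble of records as returned by [read_corpus()].
#' @return A list with elements `records` (kept rows) and `exclusions`
#'   (tibble of `record_id`, `reason`).
#' @examples
#' corpus <- tibble::tibble(
#'   record_id = c("r1", "r2", "r3"),
#'   patient_id = c("p1", "p1", "p2"),
#'   admission_date = as.Date("2020-01-01") + 0:2,
#'   presenting_complaint = "vomiting",
#'   pertinent_history = c("vomiting daily", "inappetent", "  ")
#' )
#' filter_corpus(corpus)
#' @export
filter_corpus <- function(records) {
  records <- tibble::as_tibble(records)
  needed <- c("record_id", "patient_id", "pertinent_history")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("corpus is missing required fields: ",
                 paste(missing_cols, collapse = ", ")))
  }
  malformed <- is.na(records$record_id) | !nzchar(trimws(records$record_id)) |
    is.na(records$patient_id) | !nzchar(trimws(records$patient_id))
  empty_hist <- !malformed &
    (is.na(records$pertinent_history) |
       !nzchar(trimws(records$pertinent_history)))
  dup <- !malformed & !empty_hist & duplicated(
    replace(records$patient_id, malformed | empty_hist, NA)
  )
  dup[malformed | empty_hist] <- FALSE
  reason <- rep(NA_character_, nrow(records))
  reason[malformed] <- "malformed"
  reason[empty_hist] <- "empty_history"
  reason[dup] <- "duplicate_patient"
  keep <- is.na(reason)
  exclusions <- tibble::tibble(
    record_id = ifelse(is.na(records$record_id[!keep]), "<missing>",
                       records$record_id[!keep]),
    reason = reason[!keep]
  )
  list(records = records[keep, , drop = FALSE], exclusions = exclusions)
}

#' Summarize a filtered corpus
#'
#' Reports the record count, the minimum/median/maximum word length of the
#' pertinent-history text (whitespace-delimited tokens), and the admission
#' date range.
#'
#' @param records A non-empty tibble of kept records.
#' @return A one-row tibble with columns `n`, `words_min`, `words_median`,
#'   `words_max`, `date_min`, `date_max`.
#' @export
corpus_summary <- function(records) {
  records <- tibble::as_tibble(records)
  if (nrow(records) == 0) {
    abort("cannot summarize an empty corpus")
  }
  w <- count_words(records$pertinent_history)
  dates <- records$admission_date
  if (!inherits(dates, "Date")) {
    dates <- tryCatch(as.Date(dates), error = function(e) as.Date(NA))
  }
  tibble::tibble(
    n = nrow(records),
    words_min = min(w),
    words_median = median(w),
    words_max = max(w),
    date_min = suppressWarnings(min(dates, na.rm = TRUE)),
    date_max = suppressWarnings(max(dates, na.rm = TRUE))
  )
}
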