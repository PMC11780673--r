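# Verbatim-citation auditing: segment extraction, the normalization
# ladder, and panel-level compliance / hallucination reporting.

normalize_quotes <- function(x) {
  # typographic double quotes to straight quotes
  chartr("“”„«»", "\"\"\"\"\"", x)
}

#' Extract quoted citation segments and format violations
#'
#' Citations must consist of quote-enclosed text sections separated by
#' white space, with no ellipses. Straight and typographic double quotes
#' are accepted. Non-whitespace text outside quotes raises an `unquoted`
#' violation; `...` or the ellipsis character inside a segment raises
#' `ellipsis_used`; unbalanced quotes yield a best-effort extraction plus
#' an `unquoted` violation. An empty citation field (a "false" verdict
#' with nothing to cite) is compliant by vacuity.
#'
#' @param raw The raw citation field text.
#' @return A list with `segments` (character vector, in order) and
#'   `violations` (subset of `c("unquoted", "no_whitespace_separation",
#'   "ellipsis_used")`).
#' @examples
#' extract_citations('"vomiting daily" "weight loss"')
#' @export
extract_citations <- function(raw) {
  if (is.null(raw) || length(raw) != 1L || is.na(raw) ||
      !nzchar(trimws(raw))) {
    return(list(segments = character(0), violations = character(0)))
  }
  txt <- normalize_quotes(raw)
  violations <- character(0)
  pos <- gregexpr("\"", txt)[[1]]
  segments <- character(0)
  if (pos[1] == -1) {
    violations <- c(violations, "unquoted")
  } else {
    if (length(pos) %% 2 == 1) {
      # unbalanced: treat the tail after the last quote as a final segment
      violations <- c(violations, "unquoted")
      pos <- c(pos, nchar(txt) + 1L)
    }
    opens <- pos[seq(1, length(pos), by = 2)]
    closes <- pos[seq(2, length(pos), by = 2)]
    segments <- substring(txt, opens + 1L, closes - 1L)
    # text outside the quoted spans
    outside <- txt
    for (i in seq_along(opens)) {
      substr(outside, opens[i], closes[i]) <-
        strrep(" ", closes[i] - opens[i] + 1L)
    }
    if (grepl("[^[:space:]]", outside)) {
      violations <- c(violations, "unquoted")
    }
    # adjacent segments must be whitespace-separated
    if (length(opens) > 1) {
      gaps <- substring(txt, closes[-length(closes)] + 1L, opens[-1] - 1L)
      if (any(!nzchar(gaps))) {
        violations <- c(violations, "no_whitespace_separation")
      }
    }
  }
  segments <- segments[nzchar(trimws(segments))]
  if (any(grepl("(\\.\\.\\.|…)", segments))) {
    violations <- c(violations, "ellipsis_used")
  }
  list(segments = segments, violations = unique(violations))
}

# index map from a normalized string back to original character positions
fold_with_map <- function(x) {
  chars <- strsplit(x, "")[[1]]
  lowered <- tolower(chars)
  keep_char <- !grepl("[^[:alnum:][:space:]]", lowered)
  out <- character(0)
  map <- integer(0)
  last_space <- TRUE
  for (i in seq_along(lowered)) {
    ch <- if (keep_char[i]) lowered[i] else " "
    if (grepl("[[:space:]]", ch)) {
      if (!last_space) {
        out <- c(out, " ")
        map <- c(map, i)
        last_space <- TRUE
      }
    } else {
      out <- c(out, ch)
      map <- c(map, i)
      last_space <- FALSE
    }
  }
  while (length(out) && out[length(out)] == " ") {
    out <- out[-length(out)]
    map <- map[-length(map)]
  }
  list(text = paste(out, collapse = ""), map = map)
}

# is `needle` an ordered subsequence (with gaps) of `haystack` tokens?
# returns first/last matched haystack token index or NULL
token_subsequence <- function(needle, haystack) {
  if (length(needle) == 0 || length(needle) > length(haystack)) return(NULL)
  j <- 1L
  first <- NA_integer_
  last <- NA_integer_
  for (i in seq_along(haystack)) {
    if (haystack[i] == needle[j]) {
      if (is.na(first)) first <- i
      last <- i
      j <- j + 1L
      if (j > length(needle)) return(c(first, last))
    }
  }
  NULL
}

#' Classify one citation segment against the record text
#'
#' Applies an ordered, exclusive normalization ladder and returns the
#' first level that fires:
#' `exact` (contiguous substring), `case_only` (substring after case
#' folding), `punct_space` (substring after collapsing whitespace and
#' stripping punctuation), `shortened` (segment tokens form an ordered
#' subsequence of the record tokens, with gaps), `scaffold_included`
#' (exact/case substring after removing known question or field-name
#' strings from the segment), `paraphrase` (token-set similarity at least
#' `tau_p` without a subsequence match), else `unmatched` — the
#' hallucination candidate level.
#'
#' @param segment One citation segment (non-empty).
#' @param ehr_text The record text shown to respondents (by convention the
#'   presenting complaint and pertinent history concatenated).
#' @param tau_p Token-set Jaccard threshold for `paraphrase` (default 0.5).
#' @param scaffold_strings Question/field-name strings to strip for the
#'   `scaffold_included` level (default from [prompt_spec()]).
#' @return A list with `level`, `start`, `end` (character interval in
#'   `ehr_text` when determinable, else `NA`), and `detail`.
#' @export
match_citation <- function(segment, ehr_text, tau_p = 0.5,
                           scaffold_strings = prompt_spec()$scaffold_strings) {
  stopifnot(is.character(segment), length(segment) == 1L, nzchar(segment))
  seg <- trimws(segment)
  res <- function(level, start = NA_integer_, end = NA_integer_,
                  detail = "") {
    list(level = level, start = start, end = end, detail = detail)
  }
  # 1: exact contiguous substring
  m <- regexpr(seg, ehr_text, fixed = TRUE)
  if (m > 0) {
    return(res("exact", m, m + attr(m, "match.length") - 1L))
  }
  # 2: case folding
  m <- regexpr(tolower(seg), tolower(ehr_text), fixed = TRUE)
  if (m > 0) {
    return(res("case_only", m, m + attr(m, "match.length") - 1L,
               "matches after case folding"))
  }
  # 3: collapse whitespace, strip punctuation
  fs <- fold_with_map(seg)
  fe <- fold_with_map(ehr_text)
  if (nzchar(fs$text)) {
    m <- regexpr(fs$text, fe$text, fixed = TRUE)
    if (m > 0) {
      i0 <- fe$map[m]
      i1 <- fe$map[m + attr(m, "match.length") - 1L]
      return(res("punct_space", i0, i1,
                 "matches after whitespace/punctuation normalization"))
    }
  }
  # 4: shortened — ordered token subsequence with gaps
  seg_tok <- fold_tokens(seg)
  ehr_tok <- fold_tokens(ehr_text)
  sub <- token_subsequence(seg_tok, ehr_tok)
  if (!is.null(sub)) {
    # char span of the first..last matched token in the original text;
    # per-character replacement keeps positions aligned with the original
    starts <- gregexpr("[^[:space:]]+",
                       gsub("[^[:alnum:][:space:]]", " ",
                            tolower(ehr_text)))[[1]]
    if (starts[1] > 0 && length(starts) >= sub[2]) {
      i0 <- starts[sub[1]]
      i1 <- starts[sub[2]] + attr(starts, "match.length")[sub[2]] - 1L
    } else {
      i0 <- NA_integer_; i1 <- NA_integer_
    }
    return(res("shortened", i0, i1,
               "tokens form an ordered subsequence of the record"))
  }
  # 5: scaffold included — remove known question/field-name strings
  stripped <- seg
  for (s in scaffold_strings) {
    stripped <- gsub(s, " ", stripped, fixed = TRUE)
    stripped <- gsub(sub(":\\s*$", "", s), " ", stripped, fixed = TRUE)
  }
  stripped <- trimws(gsub("[[:space:]]+", " ", stripped))
  if (nzchar(stripped) && !identical(stripped, seg)) {
    m <- regexpr(tolower(stripped), tolower(ehr_text), fixed = TRUE)
    if (m > 0) {
      return(res("scaffold_included", m,
                 m + attr(m, "match.length") - 1L,
                 "matches after removing question/field-name text"))
    }
  }
  # 6: paraphrase — token-set containment without subsequence structure
  # (fraction of the segment's distinct tokens present anywhere in the
  # record; plain Jaccard would vanish against a long record)
  if (length(seg_tok)) {
    overlap <- length(intersect(unique(seg_tok), ehr_tok)) /
      length(unique(seg_tok))
    if (overlap >= tau_p) {
      return(res("paraphrase", detail = sprintf(
        "token overlap %.2f >= %.2f without ordered match", overlap, tau_p)))
    }
  }
  res("unmatched", detail = "no ladder level fired")
}

#' Audit a response set for citation compliance and hallucinations
#'
#' Joins responses to their records, extracts and classifies every
#' citation segment, and reports per-respondent (and per-temperature)
#' compliance: a response is citation-compliant iff it has zero format
#' violations and every segment matches at level `exact`. Responses with
#' no citation are compliant by vacuity. Any `unmatched` segment puts the
#' response on the hallucination list.
#'
#' @param responses Response tibble (must carry `respondent_id`,
#'   `record_id`, `sign`, `citation_raw`; `temperature` if present is kept
#'   as a grouping key).
#' @param records Record tibble; matching is performed against the
#'   concatenation of `presenting_complaint` and `pertinent_history` (the
#'   fields shown to respondents).
#' @param tau_p,scaffold_strings Passed to [match_citation()].
#' @return A list with `segments` (one row per classified segment),
#'   `compliance` (per respondent/temperature: `compliance_rate`,
#'   `n_responses`, and counts per ladder level), and `hallucinations`
#'   (responses containing an unmatched segment).
#' @export
audit_panel <- function(responses, records, tau_p = 0.5,
                        scaffold_strings = prompt_spec()$scaffold_strings) {
  responses <- tibble::as_tibble(responses)
  records <- tibble::as_tibble(records)
  unknown <- setdiff(unique(responses$record_id), records$record_id)
  if (length(unknown) > 0) {
    abort(paste0("responses reference unknown record(s): ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  ehr_text <- setNames(
    paste(records$presenting_complaint, records$pertinent_history),
    records$record_id
  )
  if (!"temperature" %in% names(responses)) {
    responses$temperature <- NA_real_
  }
  if (!"run_index" %in% names(responses)) {
    responses$run_index <- NA_integer_
  }
  ladder <- c("exact", "case_only", "punct_space", "shortened",
              "scaffold_included", "paraphrase", "unmatched")
  per_response <- lapply(seq_len(nrow(responses)), function(i) {
    row <- responses[i, ]
    ext <- extract_citations(row$citation_raw)
    n_seg <- length(ext$segments)
    levels <- character(n_seg)
    if (n_seg > 0) {
      for (j in seq_len(n_seg)) {
        levels[j] <- match_citation(ext$segments[j],
                                    ehr_text[[row$record_id]],
                                    tau_p = tau_p,
                                    scaffold_strings = scaffold_strings)$level
      }
    }
    non_verbatim <- n_seg > 0 && any(levels != "exact")
    violated <- unique(c(ext$violations,
                         if (non_verbatim) "non_verbatim"))
    seg_rows <- if (n_seg > 0) {
      tibble::tibble(
        respondent_id = row$respondent_id, record_id = row$record_id,
        sign = row$sign, run_index = row$run_index,
        temperature = row$temperature,
        segment = ext$segments, level = levels
      )
    } else NULL
    list(
      segments = seg_rows,
      summary = tibble::tibble(
        respondent_id = row$respondent_id, record_id = row$record_id,
        sign = row$sign, run_index = row$run_index,
        temperature = row$temperature,
        n_segments = n_seg,
        compliant = length(violated) == 0,
        violations = paste(violated, collapse = ";"),
        hallucination = any(levels == "unmatched")
      )
    )
  })
  segments <- dplyr::bind_rows(lapply(per_response, `[[`, "segments"))
  summaries <- dplyr::bind_rows(lapply(per_response, `[[`, "summary"))
  if (nrow(segments) == 0) {
    segments <- tibble::tibble(
      respondent_id = character(0), record_id = character(0),
      sign = character(0), run_index = integer(0),
      temperature = numeric(0), segment = character(0), level = character(0)
    )
  }
  level_counts <- segments |>
    dplyr::mutate(level = factor(.data$level, levels = ladder)) |>
    dplyr::count(.data$respondent_id, .data$temperature, .data$level,
                 .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "level", values_from = "n",
                       values_fill = 0L)
  compliance <- summaries |>
    dplyr::group_by(.data$respondent_id, .data$temperature) |>
    dplyr::summarise(n_responses = dplyr::n(),
                     compliance_rate = mean(.data$compliant),
                     .groups = "drop") |>
    dplyr::left_join(level_counts, by = c("respondent_id", "temperature"))
  for (lv in ladder) {
    if (!lv %in% names(compliance)) compliance[[lv]] <- 0L
    compliance[[lv]][is.na(compliance[[lv]])] <- 0L
  }
  list(
    segments = segments,
    compliance = compliance,
    hallucinations = summaries[summaries$hallucination, , drop = FALSE]
  )
}
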