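# Error taxonomy: model-vs-consensus disagreements classified by error
# type, human-dissent stratum, discrepancy class, and ambiguity class.

#' Identify model-versus-reference errors
#'
#' An error is any question where the model's mode verdict and the human
#' majority verdict are both defined and differ. A `false_positive` is
#' model-true / humans-false; a `false_negative` the converse. Questions
#' with an undefined (`NA`) consensus on either side are excluded
#' upstream and do not appear.
#'
#' @param llm_mode Consensus tibble (`record_id`, `sign`, `verdict`) for
#'   the model (mode of repeated runs).
#' @param human_mode Consensus tibble for the human majority (the
#'   reference standard).
#' @return A tibble of `record_id`, `sign`, `llm_verdict`,
#'   `human_verdict`, `error_type`.
#' @export
identify_errors <- function(llm_mode, human_mode) {
  joined <- dplyr::inner_join(
    dplyr::rename(tibble::as_tibble(llm_mode), llm_verdict = "verdict"),
    dplyr::rename(tibble::as_tibble(human_mode), human_verdict = "verdict"),
    by = c("record_id", "sign")
  )
  err <- joined[!is.na(joined$llm_verdict) & !is.na(joined$human_verdict) &
                  joined$llm_verdict != joined$human_verdict, ,
                drop = FALSE]
  err$error_type <- ifelse(err$llm_verdict, "false_positive",
                           "false_negative")
  tibble::as_tibble(err)
}

#' Humans siding with the model on an error question
#'
#' For one question, counts the human panel verdicts equal to the model's
#' mode verdict. With an odd panel and a defined majority this is at most
#' `floor(panel/2)` (0, 1, or 2 for a five-human panel); errors where two
#' humans sided with the model indicate strong ambiguity.
#'
#' @param human_verdicts Logical verdicts of the human panel for the
#'   question.
#' @param llm_verdict The model's mode verdict for the question.
#' @return Integer count.
#' @examples
#' dissent_count(c(FALSE, FALSE, FALSE, TRUE, TRUE), TRUE)
#' @export
dissent_count <- function(human_verdicts, llm_verdict) {
  v <- as_verdict(human_verdicts)
  stopifnot(length(llm_verdict) == 1L, !is.na(llm_verdict))
  sum(v == as_verdict(llm_verdict), na.rm = TRUE)
}

# total length of a union of integer intervals given as a two-column
# matrix/data.frame (start, end), inclusive
interval_union_length <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0) return(0)
  iv <- iv[order(iv[[1]], iv[[2]]), , drop = FALSE]
  total <- 0
  cur_s <- iv[[1]][1]; cur_e <- iv[[2]][1]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      if (iv[[1]][i] <= cur_e + 1) {
        cur_e <- max(cur_e, iv[[2]][i])
      } else {
        total <- total + (cur_e - cur_s + 1)
        cur_s <- iv[[1]][i]; cur_e <- iv[[2]][i]
      }
    }
  }
  total + (cur_e - cur_s + 1)
}

# length of the intersection of two interval unions
interval_intersection_length <- function(a, b) {
  if (is.null(a) || is.null(b) || nrow(a) == 0 || nrow(b) == 0) return(0)
  total <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      lo <- max(a[[1]][i], b[[1]][j])
      hi <- min(a[[2]][i], b[[2]][j])
      if (hi >= lo) total <- total + (hi - lo + 1)
    }
  }
  # overlapping inputs within one side could double-count; merge first
  total
}

#' Classify an error as interpretation or citation discrepancy
#'
#' If the model and the majority-side humans cited the same text sections
#' but answered differently, the cause is a difference in interpretation;
#' if the cited text differs (or one side cited nothing), some respondents
#' presumably missed relevant sections. Citation spans are character
#' intervals in the record text, resolved by the citation audit; unmatched
#' citations contribute no interval. "Same sections" is operationalized as
#' interval-union Jaccard at least `overlap_threshold`. If both sides have
#' no resolved interval, or exactly one side has none, the error is a
#' `citation` discrepancy.
#'
#' @param llm_intervals,human_intervals Data frames with columns `start`,
#'   `end` (inclusive character positions), possibly empty or `NULL`.
#' @param overlap_threshold Jaccard threshold (default 0.5).
#' @return `"interpretation"` or `"citation"`.
#' @export
classify_discrepancy <- function(llm_intervals, human_intervals,
                                 overlap_threshold = 0.5) {
  clean <- function(iv) {
    if (is.null(iv)) return(NULL)
    iv <- as.data.frame(iv)
    iv <- iv[!is.na(iv$start) & !is.na(iv$end), c("start", "end"),
             drop = FALSE]
    if (nrow(iv) == 0) NULL else iv
  }
  a <- clean(llm_intervals)
  b <- clean(human_intervals)
  if (is.null(a) || is.null(b)) return("citation")
  len_a <- interval_union_length(a)
  len_b <- interval_union_length(b)
  inter <- interval_intersection_length(merge_intervals(a),
                                        merge_intervals(b))
  union_len <- len_a + len_b - inter
  jaccard <- if (union_len > 0) inter / union_len else 0
  if (jaccard >= overlap_threshold) "interpretation" else "citation"
}

# merge overlapping/adjacent intervals into a disjoint set
merge_intervals <- function(iv) {
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  out_s <- numeric(0); out_e <- numeric(0)
  for (i in seq_len(nrow(iv))) {
    if (length(out_s) && iv$start[i] <= out_e[length(out_e)] + 1) {
      out_e[length(out_e)] <- max(out_e[length(out_e)], iv$end[i])
    } else {
      out_s <- c(out_s, iv$start[i]); out_e <- c(out_e, iv$end[i])
    }
  }
  data.frame(start = out_s, end = out_e)
}

#' Attach adjudicated ambiguity labels to error cases
#'
#' Ambiguity (temporal vs qualitative) is a human adjudication supplied as
#' labels per (record, sign); it is copied onto error cases, never
#' inferred from text. Errors without a label are marked `unlabeled`.
#' Label keys outside the error set's corpus produce a warning.
#'
#' @param errors Error tibble from [identify_errors()] (or enriched).
#' @param labels Tibble with `record_id`, `sign`, `ambiguity` (each value
#'   one of `"temporal"`, `"qualitative"`, `"none"`).
#' @return `errors` with an `ambiguity` column filled.
#' @export
attach_ambiguity <- function(errors, labels = NULL) {
  errors <- tibble::as_tibble(errors)
  if (is.null(labels) || nrow(labels) == 0) {
    errors$ambiguity <- "unlabeled"
    return(errors)
  }
  labels <- tibble::as_tibble(labels)
  stopifnot(all(c("record_id", "sign", "ambiguity") %in% names(labels)))
  bad <- !labels$ambiguity %in% c("temporal", "qualitative", "none")
  if (any(bad)) {
    abort("ambiguity labels must be 'temporal', 'qualitative' or 'none'")
  }
  out <- dplyr::left_join(
    dplyr::select(errors, -dplyr::any_of("ambiguity")),
    labels, by = c("record_id", "sign")
  )
  out$ambiguity[is.na(out$ambiguity)] <- "unlabeled"
  out
}

#' Summarize an error ledger with marginal counts and percentages
#'
#' Produces the study-level summary of classification errors: the overall
#' error rate; the false-positive/false-negative split; the human-dissent
#' strata (how many humans sided with the model: 2, 1, or 0), each also as
#' a fraction of all questions; the interpretation/citation discrepancy
#' split; and, among interpretation errors, the temporal/qualitative
#' ambiguity split. Percentages are reported on the 0-100 scale; an empty
#' ledger reports zeros.
#'
#' @param errors Error tibble carrying (as available) `error_type`,
#'   `dissent_count`, `discrepancy`, `ambiguity`.
#' @param total_questions Total number of questions evaluated.
#' @return A list with `n_errors`, `total_questions`, `error_rate_pct`,
#'   and per-axis tibbles `by_type`, `by_dissent`, `by_discrepancy`,
#'   `by_ambiguity` (among interpretation errors), plus `cases` (the input
#'   ledger).
#' @export
summarize_ledger <- function(errors, total_questions) {
  errors <- tibble::as_tibble(errors)
  stopifnot(is.numeric(total_questions), total_questions >= 0)
  n_err <- nrow(errors)
  pct <- function(k, n) if (n > 0) 100 * k / n else 0
  axis <- function(values, levels, denom) {
    k <- vapply(levels, function(lv) sum(values == lv, na.rm = TRUE),
                integer(1), USE.NAMES = FALSE)
    tibble::tibble(level = levels, n = k,
                   pct_of_errors = vapply(k, pct, numeric(1), n = denom,
                                          USE.NAMES = FALSE),
                   pct_of_questions = vapply(k, pct, numeric(1),
                                             n = total_questions,
                                             USE.NAMES = FALSE))
  }
  by_type <- if ("error_type" %in% names(errors)) {
    axis(errors$error_type, c("false_positive", "false_negative"), n_err)
  } else NULL
  by_dissent <- if ("dissent_count" %in% names(errors)) {
    axis(as.character(errors$dissent_count), c("2", "1", "0"), n_err)
  } else NULL
  by_discrepancy <- if ("discrepancy" %in% names(errors)) {
    axis(errors$discrepancy, c("interpretation", "citation"), n_err)
  } else NULL
  by_ambiguity <- if (all(c("discrepancy", "ambiguity") %in%
                          names(errors))) {
    interp <- errors[errors$discrepancy == "interpretation", , drop = FALSE]
    axis(interp$ambiguity, c("temporal", "qualitative", "none",
                             "unlabeled"), nrow(interp))
  } else NULL
  list(
    n_errors = n_err,
    total_questions = as.integer(total_questions),
    error_rate_pct = pct(n_err, total_questions),
    by_type = by_type,
    by_dissent = by_dissent,
    by_discrepancy = by_discrepancy,
    by_ambiguity = by_ambiguity,
    cases = errors
  )
}

#' Build a full error ledger from responses
#'
#' Convenience pipeline: forms the model and human consensus, identifies
#' errors, computes dissent counts, resolves each side's citations to
#' intervals and classifies the discrepancy, and attaches ambiguity
#' labels.
#'
#' @param llm_responses Model response tibble (one temperature's runs).
#' @param human_responses Human panel response tibble.
#' @param records Record tibble (for citation resolution).
#' @param labels Optional ambiguity label tibble.
#' @param overlap_threshold Jaccard threshold for
#'   [classify_discrepancy()].
#' @param tau_p Paraphrase threshold for citation resolution.
#' @return The classified error tibble (one row per error).
#' @export
build_error_ledger <- function(llm_responses, human_responses, records,
                               labels = NULL, overlap_threshold = 0.5,
                               tau_p = 0.5) {
  llm_mode <- consensus_verdicts(llm_responses)
  human_mode <- consensus_verdicts(human_responses)
  errors <- identify_errors(llm_mode, human_mode)
  if (nrow(errors) == 0) {
    errors$dissent_count <- integer(0)
    errors$discrepancy <- character(0)
    return(attach_ambiguity(errors, labels))
  }
  ehr_text <- setNames(
    paste(records$presenting_complaint, records$pertinent_history),
    records$record_id
  )
  resolve_side <- function(responses, rid, sg, verdict_filter) {
    rows <- responses[responses$record_id == rid & responses$sign == sg, ,
                      drop = FALSE]
    if (!is.null(verdict_filter)) {
      rows <- rows[!is.na(rows$verdict) & rows$verdict == verdict_filter, ,
                   drop = FALSE]
    }
    if (nrow(rows) == 0) return(NULL)
    ivs <- lapply(rows$citation_raw, function(raw) {
      segs <- extract_citations(raw)$segments
      if (length(segs) == 0) return(NULL)
      out <- lapply(segs, function(sgm) {
        m <- match_citation(sgm, ehr_text[[rid]], tau_p = tau_p)
        if (!is.na(m$start)) data.frame(start = m$start, end = m$end)
        else NULL
      })
      do.call(rbind, out[!vapply(out, is.null, logical(1))])
    })
    ivs <- ivs[!vapply(ivs, is.null, logical(1))]
    if (length(ivs) == 0) NULL else do.call(rbind, ivs)
  }
  errors$dissent_count <- NA_integer_
  errors$discrepancy <- NA_character_
  for (i in seq_len(nrow(errors))) {
    rid <- errors$record_id[i]; sg <- errors$sign[i]
    hv <- human_responses[human_responses$record_id == rid &
                            human_responses$sign == sg, , drop = FALSE]
    errors$dissent_count[i] <- dissent_count(hv$verdict,
                                             errors$llm_verdict[i])
    llm_iv <- resolve_side(llm_responses, rid, sg, NULL)
    # majority-side humans only: those whose verdict equals the reference
    human_iv <- resolve_side(human_responses, rid, sg,
                             errors$human_verdict[i])
    errors$discrepancy[i] <- classify_discrepancy(
      llm_iv, human_iv, overlap_threshold = overlap_threshold
    )
  }
  attach_ambiguity(errors, labels)
}
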