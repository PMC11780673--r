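# Shared fixtures, built in code at test time.

tiny_corpus <- function() {
  tibble::tibble(
    record_id = c("r1", "r2", "r3"),
    patient_id = c("p1", "p2", "p3"),
    admission_date = as.Date("2020-06-01") + 0:2,
    presenting_complaint = c("vomiting and lethargy", "recheck visit",
                             "weight concern"),
    pertinent_history = c(
      "The cat has been vomiting daily, often after meals. Appetite fair.",
      "Occasionally strains in litter box to defecate, no diarrhea.",
      "Weight 16.5 lb in June, weight 20.5 lb last November."
    )
  )
}

# a response tibble in the standard format from bare vectors
make_responses <- function(respondent_id, record_id, sign, verdict,
                           citation_raw = "", run_index = NA_integer_,
                           temperature = NA_real_) {
  tibble::tibble(
    respondent_id = respondent_id, record_id = record_id, sign = sign,
    verdict = verdict, citation_raw = citation_raw,
    run_index = run_index, temperature = temperature
  )
}

# consensus tibble from named verdicts, one sign
make_consensus <- function(verdicts, sign = "vomiting") {
  tibble::tibble(record_id = names(verdicts), sign = sign,
                 verdict = unname(verdicts))
}

# well-formed model output for the default six signs
wellformed_output <- function(spec = prompt_spec(),
                              answers = rep(TRUE, length(spec$signs)),
                              citation = "\"vomiting daily\"") {
  entries <- lapply(seq_along(spec$signs), function(i) {
    list(answer = answers[i], citation = if (answers[i]) citation else "")
  })
  names(entries) <- spec$signs
  as.character(jsonlite::toJSON(entries, auto_unbox = TRUE))
}
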