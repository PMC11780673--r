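#' Specification of the classification + citation prompt
#'
#' Defines the fixed, ordered list of binary clinical-sign questions and
#' the instruction text rendered into every prompt. The default instruction
#' asks the respondent to decide, for each sign, whether it is current or
#' recently present, to answer only `true` or `false`, to cite supporting
#' text copy-pasted verbatim (each section enclosed in quotation marks,
#' sections separated by white space, no ellipses), and to return the
#' result as a single JSON object with one entry per sign.
#'
#' @param signs Character vector of sign names, in the order asked.
#' @param instruction Optional replacement instruction text; the template
#'   is editable text, not code.
#' @param scaffold_strings Known question/field-name strings that a
#'   respondent might erroneously include inside a citation; used by the
#'   citation audit's `scaffold_included` ladder level.
#' @return A `prompt_spec` list.
#' @export
prompt_spec <- function(signs = default_signs(), instruction = NULL,
                        scaffold_strings = NULL) {
  stopifnot(is.character(signs), length(signs) >= 1, !anyNA(signs))
  if (is.null(instruction)) {
    instruction <- paste(
      "You are reviewing one veterinary electronic health record.",
      "For each clinical sign listed below, decide whether the record",
      "indicates the sign is present. A \"current\" or \"recently present\"",
      "clinical sign qualifies as present. Allowed answers are true or",
      "false.",
      "For every answer, cite the pertinent sections of the record that",
      "support your decision. Only copy-pasted text may be provided; each",
      "text section must be enclosed in quotation marks; different",
      "sections must be separated by white space; ellipses must not be",
      "used to shorten the text. If the answer is false and no text is",
      "pertinent, leave the citation empty.",
      "Respond with a single JSON object. Use one key per clinical sign,",
      "exactly as written below, each mapping to an object with fields",
      "\"answer\" (true or false) and \"citation\" (a string).",
      sep = " "
    )
  }
  structure(
    list(signs = signs, instruction = instruction,
         scaffold_strings = scaffold_strings %||% c(
           "Presenting complaint:", "Pertinent history:", "Admission date:",
           paste0("Is ", signs, " present?")
         )),
    class = "prompt_spec"
  )
}

#' Render the prompt for one record
#'
#' Deterministically embeds the record's admission date, presenting
#' complaint, and pertinent history verbatim, followed by one question
#' block per sign and the instruction text.
#'
#' @param record A one-row tibble (or list) with `admission_date`,
#'   `presenting_complaint`, `pertinent_history`.
#' @param spec A [prompt_spec()].
#' @return A single character string.
#' @export
build_prompt <- function(record, spec = prompt_spec()) {
  stopifnot(inherits(spec, "prompt_spec"))
  record <- as.list(record)
  for (f in c("admission_date", "presenting_complaint",
              "pertinent_history")) {
    if (is.null(record[[f]]) || length(record[[f]]) != 1L ||
        is.na(record[[f]])) {
      abort(sprintf("record field `%s` is missing", f))
    }
  }
  questions <- paste0("Is ", spec$signs, " present?", collapse = "\n")
  paste0(
    spec$instruction, "\n\n",
    "Admission date: ", as.character(record$admission_date), "\n",
    "Presenting complaint: ", record$presenting_complaint, "\n",
    "Pertinent history: ", record$pertinent_history, "\n\n",
    questions, "\n"
  )
}

#' Run configuration for repeated machine analyses
#'
#' @param temperatures Non-negative sampling temperatures (default
#'   `c(0, 0.5, 1)`).
#' @param repeats Runs per temperature (default 5).
#' @param seed Integer seed (mock backend only).
#' @param max_retries Bounded retries for a failing backend call.
#' @return A `run_config` list.
#' @export
run_config <- function(temperatures = c(0, 0.5, 1), repeats = 5L,
                       seed = 1L, max_retries = 3L) {
  stopifnot(is.numeric(temperatures), all(temperatures >= 0),
            length(temperatures) >= 1,
            repeats >= 1, max_retries >= 0)
  structure(list(temperatures = temperatures, repeats = as.integer(repeats),
                 seed = as.integer(seed),
                 max_retries = as.integer(max_retries)),
            class = "run_config")
}

# Recover a single well-formed JSON object from decorated or slightly
# malformed model output. Conservative: only unambiguous fixes (strip prose
# and code fences around the outermost object, remove trailing separators,
# append missing closing brackets). Returns NULL when no single object can
# be recovered.
repair_json <- function(raw) {
  txt <- gsub("```[a-zA-Z]*", "", raw)
  first <- regexpr("[{]", txt)
  if (first < 0) return(NULL)
  last <- max(gregexpr("[}]", txt)[[1]])
  txt <- if (last > first) substr(txt, first, last) else substring(txt, first)
  # trailing separators before a closing bracket
  txt <- gsub(",[[:space:]]*([}\\]])", "\\1", txt, perl = TRUE)
  # balance brackets: append what is missing, in nesting order
  chars <- strsplit(txt, "")[[1]]
  stack <- character(0)
  in_str <- FALSE
  esc <- FALSE
  for (ch in chars) {
    if (esc) { esc <- FALSE; next }
    if (ch == "\\") { esc <- TRUE; next }
    if (ch == '"') { in_str <- !in_str; next }
    if (in_str) next
    if (ch %in% c("{", "[")) stack <- c(stack, ch)
    if (ch == "}" && length(stack) && stack[length(stack)] == "{") {
      stack <- stack[-length(stack)]
    }
    if (ch == "]" && length(stack) && stack[length(stack)] == "[") {
      stack <- stack[-length(stack)]
    }
  }
  if (in_str) txt <- paste0(txt, '"')
  if (length(stack)) {
    closers <- rev(ifelse(stack == "{", "}", "]"))
    txt <- paste0(txt, paste(closers, collapse = ""))
  }
  parsed <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                     error = function(e) NULL)
  if (is.list(parsed)) parsed else NULL
}

#' Parse one model output into per-sign responses and compliance events
#'
#' Never raises on content. Well-formed structured output yields one
#' response per sign and zero events. Deviations are surfaced as events:
#' a sign absent from the output gives verdict `NA` and a `missing_field`
#' event; an answer that is not literally true/false gives `NA` and
#' `non_boolean_answer`; output that parses only after conservative repair
#' (stripping prose fences, removing trailing separators, balancing
#' brackets) gives a `repaired_structure` event; output from which no
#' single object can be recovered gives all-`NA` verdicts and one
#' `invalid_structure` event; empty output gives `empty_output`.
#'
#' @param raw Raw model output text.
#' @param spec A [prompt_spec()].
#' @return A list with `responses` (tibble: `sign`, `verdict`,
#'   `citation_raw`) and `events` (tibble: `kind`, `detail`).
#' @export
parse_model_output <- function(raw, spec = prompt_spec()) {
  events <- tibble::tibble(kind = character(0), detail = character(0))
  blank <- tibble::tibble(sign = spec$signs, verdict = NA,
                          citation_raw = NA_character_)
  add_event <- function(kind, detail) {
    events <<- dplyr::bind_rows(events,
                                tibble::tibble(kind = kind, detail = detail))
  }
  if (is.null(raw) || length(raw) != 1L || is.na(raw) ||
      !nzchar(trimws(raw))) {
    add_event("empty_output", "no output text")
    return(list(responses = blank, events = events))
  }
  parsed <- tryCatch(jsonlite::fromJSON(raw, simplifyVector = FALSE),
                     error = function(e) NULL)
  if (!is.list(parsed)) {
    parsed <- repair_json(raw)
    if (is.list(parsed)) {
      add_event("repaired_structure",
                "recovered a single object from malformed output")
    } else {
      add_event("invalid_structure", "no single object recoverable")
      return(list(responses = blank, events = events))
    }
  }
  names(parsed) <- names(parsed) %||% character(length(parsed))
  rows <- lapply(spec$signs, function(sg) {
    entry <- parsed[[sg]]
    if (is.null(entry)) {
      add_event("missing_field", sprintf("sign '%s' absent from output", sg))
      return(tibble::tibble(sign = sg, verdict = NA,
                            citation_raw = NA_character_))
    }
    if (is.list(entry)) {
      ans <- entry$answer
      cit <- entry$citation
    } else {
      ans <- entry
      cit <- NULL
    }
    verdict <- if (is.logical(ans) && length(ans) == 1L && !is.na(ans)) {
      ans
    } else if (is.character(ans) && length(ans) == 1L &&
               tolower(ans) %in% c("true", "false")) {
      tolower(ans) == "true"
    } else {
      add_event("non_boolean_answer",
                sprintf("sign '%s': answer is not literally true/false", sg))
      NA
    }
    cit <- if (is.character(cit) && length(cit) == 1L) cit else NA_character_
    tibble::tibble(sign = sg, verdict = verdict, citation_raw = cit)
  })
  list(responses = dplyr::bind_rows(rows), events = events)
}

#' Deterministic offline mock backend
#'
#' A network-free stand-in for a hosted model, used in tests and examples.
#' It answers each sign question by keyword presence of the sign name in
#' the record text embedded in the prompt, citing the containing line, and
#' flips each answer with probability `flip_rate * temperature` so that
#' run-to-run variability grows with temperature. Output is a well-formed
#' JSON object. All randomness derives from `seed` and the call sequence,
#' so a fixed seed reproduces a panel bit-identically.
#'
#' @param spec A [prompt_spec()].
#' @param seed Integer seed.
#' @param flip_rate Per-unit-temperature flip probability (default 0.05).
#' @param fail_on Optional character vector of record text fragments; a
#'   prompt containing one triggers a simulated transport error (for
#'   testing retry handling).
#' @return A function `(prompt, temperature) -> raw JSON text`.
#' @export
mock_backend <- function(spec = prompt_spec(), seed = 1L, flip_rate = 0.05,
                         fail_on = character(0)) {
  count <- 0L
  function(prompt, temperature) {
    count <<- count + 1L
    if (length(fail_on) && any(vapply(fail_on, grepl, logical(1),
                                      x = prompt, fixed = TRUE))) {
      stop("mock transport failure")
    }
    # record block only: the question section always names every sign
    body <- sub("(?s).*\nAdmission date: ", "", prompt, perl = TRUE)
    body <- sub("(?s)\n\nIs .*", "", body, perl = TRUE)
    with_seed(child_seed(seed, paste0("call", count, "T", temperature)), {
      entries <- lapply(spec$signs, function(sg) {
        hit <- grepl(sg, body, ignore.case = TRUE)
        ans <- hit
        if (temperature > 0 && runif(1) < flip_rate * temperature) {
          ans <- !ans
        }
        cit <- if (ans && hit) {
          m <- regexpr(sprintf("[^.\n]*%s[^.\n]*", sg), body,
                       ignore.case = TRUE)
          hittxt <- trimws(regmatches(body, m))
          if (length(hittxt) == 1L) paste0('"', hittxt, '"') else ""
        } else ""
        list(answer = ans, citation = cit)
      })
      names(entries) <- spec$signs
      jsonlite::toJSON(entries, auto_unbox = TRUE)
    })
  }
}

#' Execute repeated runs of a model backend over a corpus
#'
#' For every record, temperature, and repeat, renders the prompt, calls
#' the backend (with bounded retries on transport failure), parses the
#' output, and accumulates responses and compliance events. The response
#' set always has cardinality records x signs x repeats x temperatures:
#' a record whose backend calls ultimately fail contributes all-`NA`
#' verdicts and a failure entry, never a hole.
#'
#' @param records Tibble of filtered records.
#' @param backend Function `(prompt, temperature) -> raw text`, e.g.
#'   [mock_backend()] or a live adapter.
#' @param spec A [prompt_spec()].
#' @param config A [run_config()].
#' @param respondent_id Label for this machine respondent (default
#'   `"llm"`).
#' @return A list with `responses` (tibble: `respondent_id`, `record_id`,
#'   `sign`, `verdict`, `citation_raw`, `run_index`, `temperature`),
#'   `events` (compliance events keyed by record/run/temperature), and
#'   `failures` (per-record transport failures).
#' @export
run_panel <- function(records, backend, spec = prompt_spec(),
                      config = run_config(), respondent_id = "llm") {
  records <- tibble::as_tibble(records)
  stopifnot(nrow(records) >= 1, is.function(backend),
            inherits(config, "run_config"))
  responses <- vector("list",
                      nrow(records) * length(config$temperatures) *
                        config$repeats)
  events <- list()
  failures <- list()
  slot <- 0L
  for (temp in config$temperatures) {
    for (run in seq_len(config$repeats)) {
      for (i in seq_len(nrow(records))) {
        rec <- records[i, ]
        prompt <- build_prompt(rec, spec)
        raw <- NULL
        for (attempt in seq_len(config$max_retries + 1L)) {
          raw <- tryCatch(backend(prompt, temp), error = function(e) e)
          if (!inherits(raw, "error")) break
        }
        if (inherits(raw, "error")) {
          failures[[length(failures) + 1L]] <- tibble::tibble(
            record_id = rec$record_id, run_index = run, temperature = temp,
            message = conditionMessage(raw)
          )
          parsed <- list(
            responses = tibble::tibble(sign = spec$signs, verdict = NA,
                                       citation_raw = NA_character_),
            events = tibble::tibble(kind = "empty_output",
                                    detail = "backend failure")
          )
        } else {
          parsed <- parse_model_output(raw, spec)
        }
        slot <- slot + 1L
        responses[[slot]] <- dplyr::mutate(
          parsed$responses,
          respondent_id = respondent_id, record_id = rec$record_id,
          run_index = run, temperature = temp, .before = 1
        )
        if (nrow(parsed$events)) {
          events[[length(events) + 1L]] <- dplyr::mutate(
            parsed$events,
            record_id = rec$record_id, run_index = run, temperature = temp,
            .before = 1
          )
        }
      }
    }
  }
  list(
    responses = dplyr::bind_rows(responses),
    events = if (length(events)) dplyr::bind_rows(events) else
      tibble::tibble(record_id = character(0), run_index = integer(0),
                     temperature = numeric(0), kind = character(0),
                     detail = character(0)),
    failures = if (length(failures)) dplyr::bind_rows(failures) else
      tibble::tibble(record_id = character(0), run_index = integer(0),
                     temperature = numeric(0), message = character(0))
  )
}

#' Compliance rates per respondent and temperature
#'
#' Summarizes adherence to the output contract: the fraction of runs with
#' valid structure (no `invalid_structure`/`empty_output` event), the
#' fraction of classification answers that were literally true/false, and
#' the fraction answered `NA`. Denominators are reported alongside.
#'
#' @param responses Response tibble from [run_panel()].
#' @param events Event tibble from [run_panel()].
#' @return A tibble with one row per (respondent, temperature).
#' @export
compliance_summary <- function(responses, events) {
  responses <- tibble::as_tibble(responses)
  if (nrow(responses) == 0) abort("empty response set")
  bad_runs <- events |>
    dplyr::filter(.data$kind %in% c("invalid_structure", "empty_output")) |>
    dplyr::distinct(.data$record_id, .data$run_index, .data$temperature) |>
    dplyr::mutate(bad = TRUE)
  runs <- responses |>
    dplyr::distinct(.data$respondent_id, .data$record_id, .data$run_index,
                    .data$temperature) |>
    dplyr::left_join(bad_runs,
                     by = c("record_id", "run_index", "temperature")) |>
    dplyr::group_by(.data$respondent_id, .data$temperature) |>
    dplyr::summarise(n_runs = dplyr::n(),
                     structure_rate = mean(is.na(.data$bad)),
                     .groups = "drop")
  answers <- responses |>
    dplyr::group_by(.data$respondent_id, .data$temperature) |>
    dplyr::summarise(n_questions = dplyr::n(),
                     boolean_rate = mean(!is.na(.data$verdict)),
                     na_rate = mean(is.na(.data$verdict)),
                     .groups = "drop")
  dplyr::left_join(runs, answers, by = c("respondent_id", "temperature"))
}
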