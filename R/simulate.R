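# Synthetic world: template-based corpora with known ground truth, a
# five-human annotator panel whose disagreement is driven by labelled
# ambiguity, and a machine annotator with correlated repeated runs.
# Template text generation (no language model) keeps tests hermetic and
# gold citation spans exact.

# Sentence templates per sign and class. Every sentence carries internal
# punctuation (so punctuation/spacing deviations are detectable) and
# avoids the scaffold words, the paraphrase replacement vocabulary, and
# the fabricated-citation vocabulary.
sim_templates <- function() {
  list(
    "decreased appetite" = list(
      clear = "The cat has shown decreased appetite for several days, refusing most meals.",
      temporal = "Appetite was decreased before the dental in March, improving afterwards.",
      qualitative = "Finishes only part of each meal, though still begs at the bowl.",
      negation = "Appetite remains excellent, no change in food interest."
    ),
    "vomiting" = list(
      clear = "The cat has been vomiting daily for the past week, often after eating.",
      temporal = "Vomiting was recorded in 2019, none mentioned at later rechecks.",
      qualitative = "Brings up small amounts of froth occasionally, possibly hairball related.",
      negation = "No vomiting reported, keeps all meals down."
    ),
    "weight loss" = list(
      clear = "Marked weight loss was noted over the last month, despite a normal diet.",
      temporal = "Weight 16.4 lb recorded on 6/30, weight 20.3 lb noted in 11/00.",
      qualitative = "Seems slimmer lately per the family, though scale readings vary.",
      negation = "Weight stable since last year, no loss documented."
    ),
    "diarrhea" = list(
      clear = "The cat has had watery diarrhea for three days, with increased urgency.",
      temporal = "Diarrhea occurred after boarding last year, resolved without treatment.",
      qualitative = "Stool sometimes soft at the edges, formed at the center.",
      negation = "Stools normal and formed, no diarrhea seen."
    ),
    "constipation" = list(
      clear = "The cat is straining with constipation, passing only small dry feces.",
      temporal = "An episode of constipation was managed in 2020, with stool softener at that time.",
      qualitative = "One bowel movement of hard crusty feces, covered by a softer outer layer.",
      negation = "Defecates daily without straining, no constipation."
    ),
    "polyphagia" = list(
      clear = "The cat displays striking polyphagia, begging for food at all hours.",
      temporal = "Noted as polyphagic at a prior visit, eating less since treatment began.",
      qualitative = "Eats quickly and asks for extra portions some evenings, not every day.",
      negation = "Food intake normal, no excessive hunger."
    )
  )
}

sim_fillers <- function() {
  c("Indoor cat, vaccinations current.",
    "Drinks water normally, litter habits unchanged otherwise.",
    "Coat in good condition, grooming regularly.",
    "No coughing or sneezing, breathing comfortable at rest.",
    "Lives with one other cat, both fed twice daily.",
    "On flea prevention, dewormed in spring.")
}

sim_complaints <- function() {
  c("wellness examination", "recheck visit", "second opinion",
    "annual checkup", "referral evaluation")
}

# vocabulary guaranteed absent from templates and fillers
paraphrase_vocab <- function() {
  c("seemingly", "reportedly", "apparently", "perhaps")
}

fabricated_pool <- function() {
  c("Parrot squawked loudly near the garden gnome yesterday evening.",
    "Chased shadows across the upstairs hallway, knocking over a vase.")
}

#' Configuration of the synthetic world
#'
#' Parameters of the generator: corpus size and sign prevalence, the
#' probabilities that a drawn sign sentence is temporally or qualitatively
#' ambiguous, annotator error and ambiguity-response rates, citation miss
#' and deviation probabilities, and the machine's run-to-run flip rate per
#' temperature (non-decreasing in temperature). Defaults describe a world
#' with 15% sign prevalence, ambiguity on a modest fraction of sign
#' sentences (so ambiguity-driven dissent lands on roughly 2% of
#' questions), a slightly error-prone human panel, and a machine annotator
#' that leans "true" on ambiguous text and is highly self-consistent at
#' low temperature.
#'
#' @param n_records Number of records (default 250).
#' @param signs Character vector of signs.
#' @param prevalence Per-sign probability a sign sentence is drawn
#'   (scalar, recycled; default 0.15).
#' @param p_temporal,p_qualitative Probability a drawn sign sentence is
#'   temporally / qualitatively ambiguous (defaults 0.10, 0.05).
#' @param negation_rate Fraction of absent questions that carry an
#'   explicit negation sentence (default 0.3).
#' @param epsilon_h Human error rate on unambiguous questions (0.01).
#' @param pi_h Human probability of answering true on an ambiguous
#'   question, independently per respondent (0.5) — the dissent engine.
#' @param mu_h Human probability of citing nothing despite a true verdict
#'   with an available gold span (0.1).
#' @param epsilon_m Machine base error rate on unambiguous questions
#'   (0.02).
#' @param pi_m Machine probability of a true base answer on an ambiguous
#'   question (0.9): the machine reads ambiguous mentions as present,
#'   making its errors false-positive dominated.
#' @param mu_m Machine citation-miss probability (0.05).
#' @param delta Named run-to-run flip probabilities per temperature,
#'   non-decreasing (default `c("0" = 0.002, "0.5" = 0.005, "1" = 0.01)`,
#'   landing run-pair agreement near the 0.98-0.93 kappa range).
#' @param repeats Machine runs per temperature (5).
#' @param n_humans Human panel size (5).
#' @param deviations_human,deviations_machine Named probabilities of
#'   citation deviations per ladder level (`case_only`, `punct_space`,
#'   `shortened`, `paraphrase`, `scaffold_included`, `fabricated`); the
#'   remainder is cited exactly.
#' @param seed Master integer seed; every stage derives its own stream.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_records = 250L,
                       signs = default_signs(),
                       prevalence = 0.15,
                       p_temporal = 0.10,
                       p_qualitative = 0.05,
                       negation_rate = 0.3,
                       epsilon_h = 0.01,
                       pi_h = 0.5,
                       mu_h = 0.1,
                       epsilon_m = 0.02,
                       pi_m = 0.9,
                       mu_m = 0.05,
                       delta = c("0" = 0.002, "0.5" = 0.005, "1" = 0.01),
                       repeats = 5L,
                       n_humans = 5L,
                       deviations_human = c(case_only = 0.03,
                                            punct_space = 0.03,
                                            shortened = 0.02,
                                            paraphrase = 0.01,
                                            scaffold_included = 0.01,
                                            fabricated = 0),
                       deviations_machine = c(case_only = 0.02,
                                              punct_space = 0.01,
                                              shortened = 0.01,
                                              paraphrase = 0.005,
                                              scaffold_included = 0.005,
                                              fabricated = 0),
                       seed = 1L) {
  stopifnot(n_records >= 1, length(signs) >= 1, repeats >= 1, n_humans >= 1)
  prevalence <- rep_len(prevalence, length(signs))
  check_prob(prevalence, "prevalence")
  check_prob(c(p_temporal, p_qualitative), "ambiguity probabilities")
  if (p_temporal + p_qualitative > 1) {
    abort("p_temporal + p_qualitative must not exceed 1")
  }
  check_prob(c(negation_rate, epsilon_h, pi_h, mu_h, epsilon_m, pi_m,
               mu_m), "rate parameters")
  check_prob(unname(delta), "delta")
  if (is.null(names(delta)) || anyNA(suppressWarnings(
    as.numeric(names(delta))))) {
    abort("`delta` must be named by temperature, e.g. c('0' = 0.002, ...)")
  }
  temps <- as.numeric(names(delta))
  if (is.unsorted(temps) || is.unsorted(unname(delta))) {
    abort("`delta` must be non-decreasing in temperature")
  }
  for (d in list(deviations_human, deviations_machine)) {
    check_prob(unname(d), "deviation probabilities")
    if (sum(d) > 1) abort("deviation probabilities must sum to at most 1")
  }
  structure(list(
    n_records = as.integer(n_records), signs = signs,
    prevalence = setNames(prevalence, signs),
    p_temporal = p_temporal, p_qualitative = p_qualitative,
    negation_rate = negation_rate,
    epsilon_h = epsilon_h, pi_h = pi_h, mu_h = mu_h,
    epsilon_m = epsilon_m, pi_m = pi_m, mu_m = mu_m,
    delta = delta, temperatures = temps,
    repeats = as.integer(repeats), n_humans = as.integer(n_humans),
    deviations_human = deviations_human,
    deviations_machine = deviations_machine,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a synthetic corpus with latent ground truth
#'
#' Each record's pertinent history is assembled from filler sentences
#' plus, for every sign drawn present, one template sentence of the drawn
#' ambiguity class (clear-present, temporally ambiguous such as dated
#' weights, qualitatively ambiguous such as an equivocal stool
#' description) and explicit negations for a subset of absent signs. Gold
#' citation spans (character intervals in the history) are recorded. The
#' output is fully determined by the config seed.
#'
#' @param config A [sim_config()].
#' @return A list with `records` (corpus tibble) and `truth` (tibble per
#'   record x sign: `status`, `ambiguity`, `truth` — `NA` for ambiguous
#'   questions, which have no single correct answer — plus
#'   `gold_citation`, `span_start`, `span_end`).
#' @export
generate_corpus <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  templates <- sim_templates()
  missing_tpl <- setdiff(config$signs, names(templates))
  if (length(missing_tpl) > 0) {
    abort(paste0("no sentence templates for sign(s): ",
                 paste(missing_tpl, collapse = ", ")),
          class = "ehrsigneval_config_error")
  }
  fillers <- sim_fillers()
  with_seed(child_seed(config$seed, "corpus"), {
    recs <- vector("list", config$n_records)
    truths <- vector("list", config$n_records)
    for (i in seq_len(config$n_records)) {
      rid <- sprintf("rec%04d", i)
      sentences <- sample(fillers, sample(2:3, 1))
      n_signs <- length(config$signs)
      status_v <- character(n_signs)
      amb_v <- character(n_signs)
      truth_v <- rep(NA, n_signs)
      gold_v <- rep(NA_character_, n_signs)
      for (s in seq_len(n_signs)) {
        sg <- config$signs[s]
        present <- runif(1) < config$prevalence[[sg]]
        if (present) {
          u <- runif(1)
          amb <- if (u < config$p_temporal) "temporal"
          else if (u < config$p_temporal + config$p_qualitative) {
            "qualitative"
          } else "none"
          cls <- switch(amb, temporal = "temporal",
                        qualitative = "qualitative", none = "clear")
          status_v[s] <- if (amb == "temporal") "historic" else "present"
          truth_v[s] <- if (amb == "none") TRUE else NA
          sentence <- templates[[sg]][[cls]]
          amb_v[s] <- amb
        } else {
          amb_v[s] <- "none"
          status_v[s] <- "absent"
          truth_v[s] <- FALSE
          sentence <- if (runif(1) < config$negation_rate) {
            templates[[sg]][["negation"]]
          } else NA_character_
        }
        if (!is.na(sentence)) {
          pos <- sample(seq_len(length(sentences) + 1L), 1)
          sentences <- append(sentences, sentence, after = pos - 1L)
          gold_v[s] <- sentence
        }
      }
      history <- paste(sentences, collapse = " ")
      tr <- tibble::tibble(
        record_id = rid, sign = config$signs, status = status_v,
        ambiguity = amb_v, truth = as.logical(truth_v),
        gold_citation = gold_v
      )
      # character interval of each gold sentence within the history
      tr$span_start <- NA_integer_
      tr$span_end <- NA_integer_
      has_gold <- !is.na(tr$gold_citation)
      for (k in which(has_gold)) {
        m <- regexpr(tr$gold_citation[k], history, fixed = TRUE)
        tr$span_start[k] <- as.integer(m)
        tr$span_end[k] <- as.integer(m) + attr(m, "match.length") - 1L
      }
      recs[[i]] <- tibble::tibble(
        record_id = rid,
        patient_id = sprintf("pat%04d", i),
        admission_date = as.Date("1991-01-01") +
          sample.int(as.integer(as.Date("2023-12-31") -
                                  as.Date("1991-01-01")), 1),
        presenting_complaint = sample(sim_complaints(), 1),
        pertinent_history = history
      )
      truths[[i]] <- tr
    }
    list(records = dplyr::bind_rows(recs),
         truth = dplyr::bind_rows(truths))
  })
}

# apply one citation deviation to a gold sentence; returns the cited text
apply_deviation <- function(text, level) {
  toks <- strsplit(text, " ")[[1]]
  switch(
    level,
    exact = text,
    case_only = toupper(text),
    # strip only inter-token punctuation (comma/period before a space or
    # at the end); intra-token punctuation like dates stays put so the
    # result still matches once whitespace/punctuation are normalized
    punct_space = gsub("[,.](?=\\s|$)", "", text, perl = TRUE),
    shortened = {
      drop <- unique(c(2L, max(3L, length(toks) - 1L)))
      drop <- drop[drop < length(toks)]
      paste(toks[-drop], collapse = " ")
    },
    paraphrase = {
      keep <- toks[seq(1, length(toks), by = 2)]
      keep <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", keep)
      repl <- paraphrase_vocab()
      paste(c(repl[1], keep, repl[2]), collapse = " ")
    },
    scaffold_included = paste0("Pertinent history: ", text),
    fabricated = fabricated_pool()[1],
    text
  )
}

# draw a deviation level (or "exact") from named probabilities
draw_deviation <- function(probs) {
  u <- runif(1)
  acc <- 0
  for (lv in names(probs)) {
    acc <- acc + probs[[lv]]
    if (u < acc) return(lv)
  }
  "exact"
}

# shared citation engine for both respondent kinds; a negation sentence
# never supports a "true" verdict, so absent-sign gold spans are not cited
cite_for <- function(verdict, gold, status, miss_prob, deviations) {
  if (!isTRUE(verdict) || is.na(gold) || status == "absent") return("")
  if (runif(1) < miss_prob) return("")
  lv <- draw_deviation(deviations)
  paste0('"', apply_deviation(gold, lv), '"')
}

#' Simulate a blinded human annotator panel
#'
#' Each respondent answers every (record, sign) question independently:
#' unambiguous questions correctly with probability `1 - epsilon_h`,
#' ambiguous questions "true" with probability `pi_h` (independent draws
#' across respondents create the dissent the error taxonomy studies).
#' True verdicts cite the gold span with probability `1 - mu_h`, subject
#' to the configured deviation probabilities; false verdicts cite
#' nothing.
#'
#' @param corpus Output of [generate_corpus()] (list with `records` and
#'   `truth`), or a records tibble if `truth` is supplied separately.
#' @param truth Truth tibble (defaults to `corpus$truth`).
#' @param config A [sim_config()].
#' @param n_respondents Panel size (defaults to `config$n_humans`).
#' @return A response tibble in the standard format (`respondent_id`,
#'   `record_id`, `sign`, `verdict`, `citation_raw`, `run_index`,
#'   `temperature`; the last two `NA` for humans).
#' @export
simulate_human_panel <- function(corpus, truth = NULL,
                                 config = sim_config(),
                                 n_respondents = NULL) {
  if (is.list(corpus) && !is.data.frame(corpus) && is.null(truth)) {
    truth <- corpus$truth
  }
  stopifnot(!is.null(truth))
  n_respondents <- n_respondents %||% config$n_humans
  out <- vector("list", n_respondents)
  for (h in seq_len(n_respondents)) {
    out[[h]] <- with_seed(child_seed(config$seed, paste0("human", h)), {
      v <- logical(nrow(truth))
      cit <- character(nrow(truth))
      ambiguous <- truth$ambiguity != "none"
      for (q in seq_len(nrow(truth))) {
        v[q] <- if (ambiguous[q]) {
          runif(1) < config$pi_h
        } else {
          correct <- truth$truth[q]
          if (runif(1) < config$epsilon_h) !correct else correct
        }
        cit[q] <- cite_for(v[q], truth$gold_citation[q], truth$status[q],
                           config$mu_h, config$deviations_human)
      }
      tibble::tibble(
        respondent_id = sprintf("human%d", h),
        record_id = truth$record_id, sign = truth$sign,
        verdict = v, citation_raw = cit,
        run_index = NA_integer_, temperature = NA_real_
      )
    })
  }
  dplyr::bind_rows(out)
}

#' Simulate repeated machine-annotator runs across temperatures
#'
#' A per-question base answer is drawn once (wrong with probability
#' `epsilon_m` on unambiguous questions; "true" with probability `pi_m`
#' on ambiguous ones), then each run at temperature T independently flips
#' the base answer with probability `delta[T]`. This base-plus-flip
#' structure makes self-agreement across runs far exceed the agreement of
#' independent annotators, while still decaying as temperature rises.
#' Citations behave as for humans, with machine-specific miss and
#' deviation rates.
#'
#' @inheritParams simulate_human_panel
#' @param respondent_id Label for the machine respondent (default
#'   `"llm"`).
#' @return A response tibble covering repeats x temperatures.
#' @export
simulate_llm_runs <- function(corpus, truth = NULL,
                              config = sim_config(),
                              respondent_id = "llm") {
  if (is.list(corpus) && !is.data.frame(corpus) && is.null(truth)) {
    truth <- corpus$truth
  }
  stopifnot(!is.null(truth))
  base <- with_seed(child_seed(config$seed, "llm_base"), {
    ambiguous <- truth$ambiguity != "none"
    vapply(seq_len(nrow(truth)), function(q) {
      if (ambiguous[q]) {
        runif(1) < config$pi_m
      } else {
        correct <- truth$truth[q]
        if (runif(1) < config$epsilon_m) !correct else correct
      }
    }, logical(1))
  })
  out <- list()
  for (t_idx in seq_along(config$temperatures)) {
    temp <- config$temperatures[t_idx]
    flip_p <- unname(config$delta[t_idx])
    for (r in seq_len(config$repeats)) {
      out[[length(out) + 1L]] <- with_seed(
        child_seed(config$seed, sprintf("llm_T%s_run%d", temp, r)), {
          flip <- runif(nrow(truth)) < flip_p
          v <- ifelse(flip, !base, base)
          cit <- character(nrow(truth))
          for (q in seq_len(nrow(truth))) {
            cit[q] <- cite_for(v[q], truth$gold_citation[q],
                               truth$status[q], config$mu_m,
                               config$deviations_machine)
          }
          tibble::tibble(
            respondent_id = respondent_id,
            record_id = truth$record_id, sign = truth$sign,
            verdict = v, citation_raw = cit,
            run_index = r, temperature = temp
          )
        })
    }
  }
  dplyr::bind_rows(out)
}

#' Export ground-truth artifacts for downstream modules
#'
#' Writes the ambiguity-label file consumed by [attach_ambiguity()] (one
#' row per ambiguous question) and, optionally, the full truth table used
#' by parameter-recovery tests.
#'
#' @param truth Truth tibble from [generate_corpus()].
#' @param labels_path Path for the CSV of `record_id`, `sign`,
#'   `ambiguity` (ambiguous questions only).
#' @param truth_path Optional path for the full truth table CSV.
#' @return Invisibly, the label tibble.
#' @export
export_ground_truth <- function(truth, labels_path, truth_path = NULL) {
  labels <- truth[truth$ambiguity != "none",
                  c("record_id", "sign", "ambiguity")]
  utils::write.csv(labels, labels_path, row.names = FALSE)
  if (!is.null(truth_path)) {
    utils::write.csv(truth, truth_path, row.names = FALSE)
  }
  invisible(tibble::as_tibble(labels))
}
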