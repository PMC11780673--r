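test_that("build_prompt is deterministic and embeds the record verbatim", {
  rec <- tiny_corpus()[1, ]
  spec <- prompt_spec()
  p1 <- build_prompt(rec, spec)
  p2 <- build_prompt(rec, spec)
  expect_identical(p1, p2)
  expect_true(grepl(rec$pertinent_history, p1, fixed = TRUE))
  expect_true(grepl(rec$presenting_complaint, p1, fixed = TRUE))
  expect_true(grepl(as.character(rec$admission_date), p1, fixed = TRUE))
  # exactly one question block per sign
  expect_equal(lengths(regmatches(p1, gregexpr("Is .* present\\?", p1))),
               1L)
  for (sg in spec$signs) {
    expect_true(grepl(paste0("Is ", sg, " present?"), p1, fixed = TRUE))
  }
  rec$pertinent_history <- NA
  expect_error(build_prompt(rec, spec), "missing")
})

test_that("well-formed output parses to six responses with zero events", {
  spec <- prompt_spec()
  out <- parse_model_output(wellformed_output(spec), spec)
  expect_equal(nrow(out$responses), 6)
  expect_equal(nrow(out$events), 0)
  expect_true(all(out$responses$verdict))
  expect_equal(out$responses$sign, spec$signs)
})

test_that("trailing separators are repaired and match the clean parse", {
  spec <- prompt_spec()
  clean <- wellformed_output(spec)
  mangled <- sub("\\}$", ",}", clean)
  expect_error(jsonlite::fromJSON(mangled))  # genuinely malformed
  out <- parse_model_output(mangled, spec)
  ref <- parse_model_output(clean, spec)
  expect_equal(out$responses$verdict, ref$responses$verdict)
  expect_equal(out$events$kind, "repaired_structure")
})

test_that("prose fences and truncated output are conservatively repaired", {
  spec <- prompt_spec()
  clean <- wellformed_output(spec)
  fenced <- paste0("Here is my answer:\n```json\n", clean, "\n```\nDone.")
  out <- parse_model_output(fenced, spec)
  expect_equal(out$responses$verdict,
               parse_model_output(clean, spec)$responses$verdict)
  expect_equal(out$events$kind, "repaired_structure")
  # a truncated object: missing closing braces are balanced; any field
  # lost to the truncation surfaces as its own event, never silently
  truncated <- substr(clean, 1, nchar(clean) - 2L)
  out2 <- parse_model_output(truncated, spec)
  expect_true("repaired_structure" %in% out2$events$kind)
  expect_equal(nrow(out2$responses), 6)
  expect_true(all(out2$responses$verdict[1:5]))
})

test_that("non-boolean, missing-field, invalid and empty outputs are evented", {
  spec <- prompt_spec()
  entries <- lapply(spec$signs, function(s) list(answer = TRUE,
                                                 citation = ""))
  names(entries) <- spec$signs
  entries[[2]]$answer <- "NA"
  raw <- as.character(jsonlite::toJSON(entries, auto_unbox = TRUE))
  out <- parse_model_output(raw, spec)
  expect_true(is.na(out$responses$verdict[2]))
  expect_equal(out$events$kind, "non_boolean_answer")

  entries2 <- entries[-3]
  raw2 <- as.character(jsonlite::toJSON(entries2[-2], auto_unbox = TRUE))
  out2 <- parse_model_output(raw2, spec)
  expect_true("missing_field" %in% out2$events$kind)
  expect_true(is.na(out2$responses$verdict[3]))

  out3 <- parse_model_output("total rubbish, not a structure", spec)
  expect_true(all(is.na(out3$responses$verdict)))
  expect_equal(out3$events$kind, "invalid_structure")

  out4 <- parse_model_output("   ", spec)
  expect_equal(out4$events$kind, "empty_output")
  expect_true(all(is.na(out4$responses$verdict)))
})

test_that("string booleans are accepted as literal answers", {
  spec <- prompt_spec()
  entries <- lapply(spec$signs, function(s) list(answer = "false",
                                                 citation = ""))
  names(entries) <- spec$signs
  out <- parse_model_output(
    as.character(jsonlite::toJSON(entries, auto_unbox = TRUE)), spec)
  expect_true(all(!out$responses$verdict))
  expect_equal(nrow(out$events), 0)
})

test_that("run_panel has exact cardinality and is seed-reproducible", {
  corpus <- tiny_corpus()[1:2, ]
  spec <- prompt_spec()
  cfg <- run_config(temperatures = 0, repeats = 5, seed = 9)
  res1 <- run_panel(corpus, mock_backend(spec, seed = 9), spec, cfg)
  expect_equal(nrow(res1$responses), 2 * 6 * 5 * 1)
  res2 <- run_panel(corpus, mock_backend(spec, seed = 9), spec, cfg)
  expect_identical(res1$responses, res2$responses)
  # two temperatures double the response count
  cfg2 <- run_config(temperatures = c(0, 1), repeats = 2, seed = 9)
  res3 <- run_panel(corpus, mock_backend(spec, seed = 9), spec, cfg2)
  expect_equal(nrow(res3$responses), 2 * 6 * 2 * 2)
})

test_that("a failing backend yields NA rows, not holes", {
  corpus <- tiny_corpus()
  spec <- prompt_spec()
  cfg <- run_config(temperatures = 0, repeats = 2, seed = 5,
                    max_retries = 1)
  backend <- mock_backend(spec, seed = 5,
                          fail_on = corpus$pertinent_history[2])
  res <- run_panel(corpus, backend, spec, cfg)
  expect_equal(nrow(res$responses), 3 * 6 * 2)
  expect_equal(nrow(res$failures), 2)  # one per failed run
  failed <- res$responses[res$responses$record_id == "r2", ]
  expect_true(all(is.na(failed$verdict)))
})

test_that("parse of a build-compliant output round-trips with no events", {
  spec <- prompt_spec()
  answers <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  raw <- wellformed_output(spec, answers = answers)
  out <- parse_model_output(raw, spec)
  expect_equal(out$responses$verdict, answers)
  expect_equal(nrow(out$events), 0)
})

test_that("compliance_summary reports exact rates and denominators", {
  corpus <- tiny_corpus()[1:2, ]
  spec <- prompt_spec()
  cfg <- run_config(temperatures = 0, repeats = 5, seed = 2)
  res <- run_panel(corpus, mock_backend(spec, seed = 2), spec, cfg)
  cs <- compliance_summary(res$responses, res$events)
  expect_equal(cs$structure_rate, 1)
  expect_equal(cs$boolean_rate, 1)
  expect_equal(cs$n_questions, 60L)

  # inject one NA verdict: boolean-answer rate (n-1)/n
  res$responses$verdict[17] <- NA
  cs2 <- compliance_summary(res$responses, res$events)
  expect_equal(cs2$boolean_rate, 59 / 60)
  expect_equal(cs2$na_rate, 1 / 60)

  # all-invalid structure drives the structure rate to 0
  blank <- res$responses
  blank$verdict <- NA
  ev <- dplyr::distinct(blank, record_id, run_index, temperature)
  ev$kind <- "invalid_structure"
  ev$detail <- ""
  cs3 <- compliance_summary(blank, ev)
  expect_equal(cs3$structure_rate, 0)
  expect_equal(cs3$na_rate, 1)
})

test_that("responses survive a JSON-lines round trip", {
  corpus <- tiny_corpus()[1, ]
  spec <- prompt_spec()
  res <- run_panel(corpus, mock_backend(spec, seed = 3), spec,
                   run_config(temperatures = 0, repeats = 2, seed = 3))
  path <- tempfile(fileext = ".jsonl")
  write_responses(res$responses, path)
  back <- read_responses(path)
  expect_equal(back$verdict, res$responses$verdict)
  expect_equal(back$record_id, res$responses$record_id)
  expect_equal(back$temperature, res$responses$temperature)
  unlink(path)
})
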