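test_that("generation is fully determined by the seed", {
  cfg <- sim_config(n_records = 40, seed = 123)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  ha <- simulate_human_panel(a, config = cfg)
  hb <- simulate_human_panel(b, config = cfg)
  expect_identical(ha, hb)
  la <- simulate_llm_runs(a, config = cfg)
  lb <- simulate_llm_runs(b, config = cfg)
  expect_identical(la, lb)
  # a different seed changes the corpus
  c_ <- generate_corpus(sim_config(n_records = 40, seed = 124))
  expect_false(identical(a$records$pertinent_history,
                         c_$records$pertinent_history))
})

test_that("zero prevalence gives all-absent truths and no sign text", {
  cfg <- sim_config(n_records = 30, prevalence = 0, negation_rate = 0,
                    seed = 2)
  corp <- generate_corpus(cfg)
  expect_true(all(corp$truth$status == "absent"))
  expect_true(all(!corp$truth$truth))
  expect_true(all(is.na(corp$truth$gold_citation)))
  # histories still non-empty (filler sentences)
  expect_true(all(nchar(corp$records$pertinent_history) > 0))
})

test_that("per-sign prevalence lands inside its own Wilson interval", {
  cfg <- sim_config(n_records = 500, seed = 33)
  corp <- generate_corpus(cfg)
  by_sign <- split(corp$truth$status != "absent", corp$truth$sign)
  # six simultaneous checks: each sign against a 99.9% interval (joint
  # false-alarm rate < 1%), the pooled fraction against the 95% interval
  for (sg in names(by_sign)) {
    k <- sum(by_sign[[sg]])
    ci <- wilson_ci(k, 500, conf_level = 0.999)
    expect_true(ci$low <= 0.15 && 0.15 <= ci$high)
  }
  pooled <- wilson_ci(sum(corp$truth$status != "absent"),
                      nrow(corp$truth))
  expect_true(pooled$low <= 0.15 && 0.15 <= pooled$high)
})

test_that("gold spans address the gold sentence inside the history", {
  corp <- generate_corpus(sim_config(n_records = 60, seed = 8))
  tr <- corp$truth[!is.na(corp$truth$gold_citation), ]
  recs <- corp$records
  for (i in seq_len(nrow(tr))) {
    hist <- recs$pertinent_history[recs$record_id == tr$record_id[i]]
    expect_equal(substr(hist, tr$span_start[i], tr$span_end[i]),
                 tr$gold_citation[i])
  }
})

test_that("an error-free unambiguous panel agrees perfectly", {
  cfg <- sim_config(n_records = 60, p_temporal = 0, p_qualitative = 0,
                    epsilon_h = 0, seed = 12)
  corp <- generate_corpus(cfg)
  h <- simulate_human_panel(corp, config = cfg)
  # every respondent equals the latent truth
  merged <- dplyr::left_join(h, corp$truth, by = c("record_id", "sign"))
  expect_true(all(merged$verdict == merged$truth))
  expect_equal(pairwise_kappa(h)$mean_kappa, 1)
})

test_that("ambiguous-question agreement matches the Bernoulli identity", {
  # two respondents answering true independently with p = 0.5 agree with
  # probability p^2 + (1-p)^2 = 0.5
  cfg <- sim_config(n_records = 400, prevalence = 0.5, p_temporal = 1,
                    p_qualitative = 0, pi_h = 0.5, seed = 71)
  corp <- generate_corpus(cfg)
  h <- simulate_human_panel(corp, config = cfg, n_respondents = 2)
  amb <- corp$truth[corp$truth$ambiguity != "none", c("record_id", "sign")]
  h1 <- dplyr::semi_join(h[h$respondent_id == "human1", ], amb,
                         by = c("record_id", "sign"))
  h2 <- dplyr::semi_join(h[h$respondent_id == "human2", ], amb,
                         by = c("record_id", "sign"))
  agree <- mean(h1$verdict == h2$verdict)
  expect_gt(nrow(h1), 800)
  expect_lt(abs(agree - 0.5), 0.05)
})

test_that("delta = 0 gives five identical runs with kappa 1", {
  cfg <- sim_config(n_records = 50, delta = c("0" = 0), seed = 9)
  corp <- generate_corpus(cfg)
  l <- simulate_llm_runs(corp, config = cfg)
  wide <- split(l$verdict, l$run_index)
  for (r in 2:5) expect_identical(wide[[r]], wide[[1]])
  l$respondent_id <- sprintf("run%d", l$run_index)
  expect_equal(pairwise_kappa(l)$mean_kappa, 1)
})

test_that("run-pair agreement decreases with temperature", {
  cfg <- sim_config(n_records = 200, delta = c("0" = 0.01, "1" = 0.08),
                    seed = 55)
  corp <- generate_corpus(cfg)
  l <- simulate_llm_runs(corp, config = cfg)
  mean_kappa_at <- function(temp) {
    lt <- l[l$temperature == temp, ]
    lt$respondent_id <- sprintf("run%d", lt$run_index)
    pairwise_kappa(lt)$mean_kappa
  }
  expect_gt(mean_kappa_at(0), mean_kappa_at(1))
})

test_that("zero-deviation citations all resolve at ladder level exact", {
  zero_dev <- c(case_only = 0, punct_space = 0, shortened = 0,
                paraphrase = 0, scaffold_included = 0, fabricated = 0)
  cfg <- sim_config(n_records = 80, mu_h = 0, mu_m = 0,
                    deviations_human = zero_dev,
                    deviations_machine = zero_dev, seed = 14)
  corp <- generate_corpus(cfg)
  h <- simulate_human_panel(corp, config = cfg)
  aud <- audit_panel(h, corp$records)
  expect_true(all(aud$compliance$compliance_rate == 1))
  expect_true(all(aud$segments$level == "exact"))
  expect_equal(nrow(aud$hallucinations), 0)
})

test_that("ground-truth export round-trips and covers ambiguity", {
  corp <- generate_corpus(sim_config(n_records = 60, seed = 4))
  labels_path <- tempfile(fileext = ".csv")
  truth_path <- tempfile(fileext = ".csv")
  labels <- export_ground_truth(corp$truth, labels_path, truth_path)
  expect_equal(names(labels), c("record_id", "sign", "ambiguity"))
  back <- read_ambiguity_labels(labels_path)
  expect_equal(nrow(back), sum(corp$truth$ambiguity != "none"))
  expect_equal(back$ambiguity, labels$ambiguity)
  full <- utils::read.csv(truth_path)
  expect_equal(nrow(full), nrow(corp$truth))
  unlink(c(labels_path, truth_path))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(p_temporal = 0.8, p_qualitative = 0.5),
               "exceed 1")
  expect_error(sim_config(delta = c("0" = 0.1, "1" = 0.05)),
               "non-decreasing")
  expect_error(sim_config(delta = c(0.1, 0.2)), "named")
  expect_error(sim_config(prevalence = 1.4), class =
                 "ehrsigneval_validation_error")
  expect_error(generate_corpus(sim_config(signs = c("vomiting",
                                                    "hiccups"))),
               class = "ehrsigneval_config_error")
})
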