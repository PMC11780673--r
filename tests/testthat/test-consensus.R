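test_that("mode_verdict drops NA then takes a strict majority", {
  expect_true(mode_verdict(c(TRUE, TRUE, TRUE, FALSE, FALSE)))
  expect_false(mode_verdict(c(FALSE, FALSE, FALSE, FALSE, FALSE)))
  # tie after NA removal -> NA; all-NA -> NA
  expect_true(is.na(mode_verdict(c(TRUE, TRUE, FALSE, FALSE, NA))))
  expect_true(is.na(mode_verdict(c(NA, NA))))
  expect_true(mode_verdict(c(TRUE, NA, NA, NA, NA)))
  expect_error(mode_verdict(logical(0)), "non-empty")
})

test_that("confusion_table classifies and excludes undefined consensus", {
  ref <- make_consensus(c(r1 = TRUE, r2 = FALSE))
  tst <- make_consensus(c(r1 = TRUE, r2 = TRUE))
  ct <- confusion_table(ref, tst)
  expect_equal(ct$tp, 1)
  expect_equal(ct$fp, 1)
  expect_equal(ct$tn + ct$fn + ct$excluded, 0)

  ref2 <- make_consensus(c(r1 = NA, r2 = TRUE))
  tst2 <- make_consensus(c(r1 = TRUE, r2 = TRUE))
  ct2 <- confusion_table(ref2, tst2)
  expect_equal(ct2$excluded, 1)
  expect_equal(ct2$tp, 1)

  expect_error(confusion_table(ref, tst[1, ]),
               class = "ehrsigneval_key_mismatch")
})

test_that("confusion counts equal a brute-force recount on a large panel", {
  cfg <- sim_config(n_records = 250, seed = 21)
  corp <- generate_corpus(cfg)
  h <- simulate_human_panel(corp, config = cfg)
  l <- simulate_llm_runs(corp, config = cfg)
  hm <- consensus_verdicts(h)
  lm <- consensus_verdicts(l, temperature = 0)
  ct <- confusion_table(hm, lm)
  expect_equal(sum(ct$tp + ct$fp + ct$tn + ct$fn + ct$excluded),
               nrow(corp$truth))
  # oracle: pairwise loop over every question
  joined <- merge(as.data.frame(hm), as.data.frame(lm),
                  by = c("record_id", "sign"))
  for (sg in unique(joined$sign)) {
    sub <- joined[joined$sign == sg, ]
    tp <- fp <- tn <- fn <- ex <- 0L
    for (i in seq_len(nrow(sub))) {
      a <- sub$verdict.x[i]; b <- sub$verdict.y[i]
      if (is.na(a) || is.na(b)) ex <- ex + 1L
      else if (a && b) tp <- tp + 1L
      else if (!a && b) fp <- fp + 1L
      else if (!a && !b) tn <- tn + 1L
      else fn <- fn + 1L
    }
    row <- ct[ct$sign == sg, ]
    expect_equal(c(row$tp, row$fp, row$tn, row$fn, row$excluded),
                 c(tp, fp, tn, fn, ex))
  }
})

test_that("wilson_ci matches its closed form on the spec examples", {
  ci <- wilson_ci(5, 10, z = 1.96)
  expect_equal(ci$low, 0.2366, tolerance = 1e-3)
  expect_equal(ci$high, 0.7634, tolerance = 1e-3)
  # symmetric about the adjusted center at p_hat = 0.5
  expect_equal(ci$high - 0.5, 0.5 - ci$low, tolerance = 1e-12)

  expect_equal(wilson_ci(0, 10, z = 1.96)$low, 0)
  ci9 <- wilson_ci(9, 10, z = 1.96)
  expect_equal(ci9$low, 0.596, tolerance = 1e-2)
  expect_equal(ci9$high, 0.982, tolerance = 1e-2)

  # n = 0 is an undefined marker, not an error
  expect_true(is.na(wilson_ci(0, 0)$estimate))
  expect_error(wilson_ci(11, 10), "0 <= k <= n")
})

test_that("wilson_ci always contains k/n, narrows with n, is exact at 0/1", {
  for (n in c(5, 20, 100)) {
    for (k in 0:min(n, 10)) {
      ci <- wilson_ci(k, n)
      expect_lte(ci$low, k / n + 1e-12)
      expect_gte(ci$high, k / n - 1e-12)
      expect_gte(ci$low, 0)
      expect_lte(ci$high, 1)
    }
  }
  widths <- vapply(c(10, 50, 250, 1000), function(n) {
    ci <- wilson_ci(round(0.3 * n), n)
    ci$high - ci$low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_equal(wilson_ci(0, 25)$low, 0)
  expect_equal(wilson_ci(25, 25)$high, 1)
})

test_that("performance_metrics matches hand arithmetic", {
  ct <- tibble::tibble(tp = 9, fp = 1, tn = 89, fn = 1)
  pm <- performance_metrics(ct)
  val <- function(m) pm$value[pm$metric == m]
  expect_equal(val("sensitivity"), 0.9)
  expect_equal(val("PPV"), 0.9)
  expect_equal(val("specificity"), 89 / 90)
  expect_equal(val("NPV"), 89 / 90)
  expect_equal(val("F1"), 0.9)
  expect_equal(val("balanced_accuracy"), (0.9 + 89 / 90) / 2)
  # count-based metrics carry Wilson CIs; derived metrics do not
  counted <- pm[pm$metric %in% c("sensitivity", "specificity", "PPV",
                                 "NPV"), ]
  expect_true(all(!is.na(counted$ci_low)))
  expect_true(all(counted$ci_low <= counted$value &
                    counted$value <= counted$ci_high))
  derived <- pm[pm$metric %in% c("F1", "balanced_accuracy"), ]
  expect_true(all(is.na(derived$ci_low)))
})

test_that("degenerate and perfect tables behave", {
  deg <- performance_metrics(tibble::tibble(tp = 0, fp = 0, tn = 10,
                                            fn = 0))
  expect_true(is.na(deg$value[deg$metric == "sensitivity"]))
  expect_true(is.na(deg$value[deg$metric == "PPV"]))
  expect_equal(deg$value[deg$metric == "specificity"], 1)
  expect_true(is.na(deg$value[deg$metric == "F1"]))

  perf <- performance_metrics(tibble::tibble(tp = 10, fp = 0, tn = 40,
                                             fn = 0))
  expect_true(all(perf$value == 1))
})

test_that("label swap exchanges Se/Sp and PPV/NPV, preserves BA", {
  set.seed(31)
  for (rep in 1:20) {
    counts <- as.list(sample(1:50, 4, replace = TRUE))
    names(counts) <- c("tp", "fp", "tn", "fn")
    pm <- performance_metrics(tibble::as_tibble(counts))
    swapped <- performance_metrics(tibble::tibble(
      tp = counts$tn, fp = counts$fn, tn = counts$tp, fn = counts$fp
    ))
    val <- function(m, p) p$value[p$metric == m]
    expect_equal(val("sensitivity", pm), val("specificity", swapped))
    expect_equal(val("PPV", pm), val("NPV", swapped))
    expect_equal(val("balanced_accuracy", pm),
                 val("balanced_accuracy", swapped))
    # F1 is bounded by its two components
    f1 <- val("F1", pm)
    expect_lte(f1, max(val("sensitivity", pm), val("PPV", pm)))
    expect_gte(f1, min(val("sensitivity", pm), val("PPV", pm)))
  }
})

test_that("summarize_across_signs uses interpolated quartiles", {
  m <- tibble::tibble(metric = "sensitivity", value = 1:6 / 6)
  s <- summarize_across_signs(m)
  expect_equal(s$median, median(1:6 / 6))
  expect_equal(s$median, 3.5 / 6)

  one <- summarize_across_signs(tibble::tibble(metric = "F1",
                                               value = 0.8))
  expect_equal(c(one$median, one$q1, one$q3), rep(0.8, 3))

  set.seed(7)
  vals <- runif(6)
  s2 <- summarize_across_signs(tibble::tibble(metric = "PPV",
                                              value = vals))
  expect_equal(s2$q1, unname(quantile(vals, 0.25, type = 7)))
  expect_equal(s2$q3, unname(quantile(vals, 0.75, type = 7)))
  expect_true(s2$q1 <= s2$median && s2$median <= s2$q3)

  # undefined values omitted and counted
  s3 <- summarize_across_signs(tibble::tibble(
    metric = "sensitivity", value = c(0.9, NA, 0.8)
  ))
  expect_equal(s3$n_undefined, 1)
  expect_equal(s3$n_signs, 2)
  s4 <- summarize_across_signs(tibble::tibble(metric = "PPV",
                                              value = NA_real_))
  expect_true(is.na(s4$median))
})
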