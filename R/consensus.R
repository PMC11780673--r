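#' Mode (majority) verdict of a respondent panel
#'
#' The reference standard for each question is the majority opinion (mode)
#' of the panel's verdicts. `NA` verdicts are removed first; a strict
#' majority of the remainder is returned. An exact tie, or a panel that
#' answered only `NA`, yields `NA` — such questions are excluded from
#' confusion tables downstream (and counted).
#'
#' @param verdicts Logical vector of verdicts (`TRUE`, `FALSE`, `NA`).
#' @return A single logical verdict.
#' @examples
#' mode_verdict(c(TRUE, TRUE, TRUE, FALSE, FALSE))
#' mode_verdict(c(TRUE, TRUE, FALSE, FALSE, NA))  # tie -> NA
#' @export
mode_verdict <- function(verdicts) {
  if (length(verdicts) == 0) {
    abort("`verdicts` must be non-empty")
  }
  v <- as_verdict(verdicts)
  v <- v[!is.na(v)]
  if (length(v) == 0) return(NA)
  n_true <- sum(v)
  n_false <- length(v) - n_true
  if (n_true > n_false) TRUE else if (n_false > n_true) FALSE else NA
}

#' Consensus verdict per question
#'
#' Collapses a response set to one mode verdict per (record, sign)
#' question. For machine respondents this is the mode across repeated runs
#' (optionally within one temperature); for humans, across the panel.
#'
#' @param responses A response tibble with columns `record_id`, `sign`,
#'   `verdict` (see [run_panel()] / [simulate_human_panel()]).
#' @param temperature If not `NULL`, restrict to responses at this
#'   temperature before taking the mode.
#' @return A tibble of `record_id`, `sign`, `verdict` (the consensus).
#' @export
consensus_verdicts <- function(responses, temperature = NULL) {
  responses <- tibble::as_tibble(responses)
  if (!is.null(temperature)) {
    responses <- responses[!is.na(responses$temperature) &
                             responses$temperature == temperature, ,
                           drop = FALSE]
  }
  if (nrow(responses) == 0) {
    abort("no responses to form a consensus from")
  }
  responses |>
    dplyr::group_by(.data$record_id, .data$sign) |>
    dplyr::summarise(verdict = mode_verdict(.data$verdict),
                     .groups = "drop")
}

#' Confusion counts per sign against a reference consensus
#'
#' Joins two consensus tables on (record, sign) and tallies, per sign, true
#' positives, false positives, true negatives, false negatives, and the
#' number of questions excluded because either consensus was `NA`
#' (undefined mode). The five counts always sum to the number of questions
#' for the sign.
#'
#' @param reference Consensus tibble (`record_id`, `sign`, `verdict`) that
#'   serves as the reference standard (typically the human majority).
#' @param test Consensus tibble for the classifier under evaluation.
#' @return A tibble with one row per sign: `sign`, `tp`, `fp`, `tn`, `fn`,
#'   `excluded`.
#' @export
confusion_table <- function(reference, test) {
  reference <- tibble::as_tibble(reference)
  test <- tibble::as_tibble(test)
  key_ref <- paste(reference$record_id, reference$sign, sep = "\r")
  key_test <- paste(test$record_id, test$sign, sep = "\r")
  missing <- c(setdiff(key_ref, key_test), setdiff(key_test, key_ref))
  if (length(missing) > 0) {
    abort(paste0("reference and test questions are not aligned; ",
                 length(missing), " unmatched key(s): ",
                 paste(head(gsub("\r", "/", missing), 5), collapse = ", ")),
          class = "ehrsigneval_key_mismatch")
  }
  joined <- dplyr::inner_join(
    dplyr::rename(reference, ref = "verdict"),
    dplyr::rename(test, test = "verdict"),
    by = c("record_id", "sign")
  )
  joined |>
    dplyr::group_by(.data$sign) |>
    dplyr::summarise(
      tp = sum(.data$ref & .data$test, na.rm = TRUE),
      fp = sum(!.data$ref & .data$test, na.rm = TRUE),
      tn = sum(!.data$ref & !.data$test, na.rm = TRUE),
      fn = sum(.data$ref & !.data$test, na.rm = TRUE),
      excluded = sum(is.na(.data$ref) | is.na(.data$test)),
      .groups = "drop"
    )
}

#' Wilson score confidence interval for a binomial proportion
#'
#' The score interval has center \eqn{(\hat p + z^2/2n) / (1 + z^2/n)} and
#' half-width \eqn{z \sqrt{\hat p (1-\hat p)/n + z^2/4n^2} / (1 + z^2/n)},
#' clipped to \[0, 1\]. Unlike the Wald interval it never collapses at
#' \eqn{\hat p \in \{0, 1\}} and always contains \eqn{k/n}.
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials. `n = 0` returns an undefined marker
#'   (`NA` bounds), not an error.
#' @param conf_level Two-sided confidence level (default 0.95).
#' @param z Optional explicit critical value overriding `conf_level`.
#' @return A list with `estimate`, `low`, `high`, `k`, `n`, `z`.
#' @examples
#' wilson_ci(9, 10)
#' @export
wilson_ci <- function(k, n, conf_level = 0.95, z = NULL) {
  if (is.null(z)) z <- z_from_level(conf_level)
  if (length(k) != 1L || length(n) != 1L || !is.finite(z) || z <= 0) {
    abort("`k`, `n` must be scalars and `z` positive")
  }
  if (n == 0) {
    return(list(estimate = NA_real_, low = NA_real_, high = NA_real_,
                k = as.integer(k), n = 0L, z = z))
  }
  if (k < 0 || k > n || n < 1) {
    abort("`k` must satisfy 0 <= k <= n with n >= 1")
  }
  p_hat <- k / n
  denom <- 1 + z^2 / n
  center <- (p_hat + z^2 / (2 * n)) / denom
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / denom
  list(estimate = p_hat,
       low = max(0, center - half),
       high = min(1, center + half),
       k = as.integer(k), n = as.integer(n), z = z)
}

#' Diagnostic performance metrics from a confusion table
#'
#' Computes sensitivity (recall), specificity, positive and negative
#' predictive value — each with a Wilson score confidence interval — plus
#' the F1 score (harmonic mean of sensitivity and PPV) and balanced
#' accuracy (arithmetic mean of sensitivity and specificity). F1 and
#' balanced accuracy are derived quantities and carry no interval. A zero
#' denominator yields an undefined marker (`NA`) that propagates into the
#' derived metrics.
#'
#' @param ct A one-row confusion table (`tp`, `fp`, `tn`, `fn`), or a
#'   multi-row per-sign table from [confusion_table()] (metrics are then
#'   computed per sign).
#' @param conf_level Two-sided confidence level for the Wilson intervals.
#' @return A tibble with columns `sign` (if present in `ct`), `metric`,
#'   `value`, `ci_low`, `ci_high`, `k`, `n`.
#' @export
performance_metrics <- function(ct, conf_level = 0.95) {
  ct <- tibble::as_tibble(ct)
  stopifnot(all(c("tp", "fp", "tn", "fn") %in% names(ct)))
  one <- function(row) {
    tp <- row$tp; fp <- row$fp; tn <- row$tn; fn <- row$fn
    counted <- function(name, k, n) {
      ci <- wilson_ci(k, n, conf_level = conf_level)
      tibble::tibble(metric = name, value = ci$estimate,
                     ci_low = ci$low, ci_high = ci$high,
                     k = as.integer(k), n = as.integer(n))
    }
    se <- counted("sensitivity", tp, tp + fn)
    sp <- counted("specificity", tn, tn + fp)
    ppv <- counted("PPV", tp, tp + fp)
    npv <- counted("NPV", tn, tn + fn)
    f1 <- if (is.na(se$value) || is.na(ppv$value) ||
              (se$value + ppv$value) == 0) {
      NA_real_
    } else {
      2 * se$value * ppv$value / (se$value + ppv$value)
    }
    ba <- (se$value + sp$value) / 2
    derived <- tibble::tibble(
      metric = c("F1", "balanced_accuracy"),
      value = c(f1, ba),
      ci_low = NA_real_, ci_high = NA_real_,
      k = NA_integer_, n = NA_integer_
    )
    dplyr::bind_rows(se, sp, ppv, npv, derived)
  }
  if ("sign" %in% names(ct)) {
    ct |>
      dplyr::group_by(.data$sign) |>
      dplyr::group_modify(~ one(.x)) |>
      dplyr::ungroup()
  } else {
    one(ct)
  }
}

#' Median and interquartile range of each metric across signs
#'
#' Summarizes per-sign performance into the panel-level figures reported
#' for a study: for each metric, the median and the first and third
#' quartiles across signs. Undefined (NA) values are omitted and their
#' count reported. Quartiles use linear interpolation between order
#' statistics by default (`stats::quantile` type 7); the convention is
#' configurable.
#'
#' @param metrics Per-sign metric tibble from [performance_metrics()].
#' @param quantile_type Quartile convention passed to [stats::quantile()]
#'   (default 7, linear interpolation).
#' @return A tibble with `metric`, `median`, `q1`, `q3`, `n_signs`,
#'   `n_undefined`.
#' @export
summarize_across_signs <- function(metrics, quantile_type = 7) {
  metrics <- tibble::as_tibble(metrics)
  stopifnot(all(c("metric", "value") %in% names(metrics)))
  out <- metrics |>
    dplyr::group_by(.data$metric) |>
    dplyr::summarise(
      median = if (any(!is.na(.data$value))) {
        unname(quantile(.data$value, 0.5, na.rm = TRUE,
                        type = quantile_type))
      } else NA_real_,
      q1 = if (any(!is.na(.data$value))) {
        unname(quantile(.data$value, 0.25, na.rm = TRUE,
                        type = quantile_type))
      } else NA_real_,
      q3 = if (any(!is.na(.data$value))) {
        unname(quantile(.data$value, 0.75, na.rm = TRUE,
                        type = quantile_type))
      } else NA_real_,
      n_signs = sum(!is.na(.data$value)),
      n_undefined = sum(is.na(.data$value)),
      .groups = "drop"
    )
  out
}
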