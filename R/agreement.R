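#' Cohen's kappa between two verdict vectors
#'
#' Chance-corrected agreement for paired binary verdicts. Question pairs
#' with `NA` on either side are dropped (pairwise deletion) and counted.
#' Observed agreement `p_o` is the fraction of identical verdicts; chance
#' agreement `p_e` comes from the marginal true/false rates of each vector;
#' `kappa = (p_o - p_e) / (1 - p_e)`. When both raters are constant and
#' identical (`p_o = p_e = 1`), kappa is reported as 1.
#'
#' @param v1,v2 Aligned logical verdict vectors of equal length.
#' @return A list with `kappa`, `p_o`, `p_e`, `n_pairs` (usable pairs),
#'   `n_dropped` (NA-containing pairs). Zero usable pairs give an
#'   undefined marker (`kappa = NA`).
#' @examples
#' cohens_kappa(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
cohens_kappa <- function(v1, v2) {
  v1 <- as_verdict(v1); v2 <- as_verdict(v2)
  if (length(v1) != length(v2)) {
    abort("`v1` and `v2` must be aligned vectors of equal length")
  }
  use <- !is.na(v1) & !is.na(v2)
  n_dropped <- sum(!use)
  v1 <- v1[use]; v2 <- v2[use]
  n <- length(v1)
  if (n == 0) {
    return(list(kappa = NA_real_, p_o = NA_real_, p_e = NA_real_,
                n_pairs = 0L, n_dropped = n_dropped))
  }
  p_o <- mean(v1 == v2)
  p1 <- mean(v1); p2 <- mean(v2)
  p_e <- p1 * p2 + (1 - p1) * (1 - p2)
  kappa <- if (p_e < 1) (p_o - p_e) / (1 - p_e) else if (p_o == 1) 1 else NA_real_
  list(kappa = kappa, p_o = p_o, p_e = p_e,
       n_pairs = as.integer(n), n_dropped = as.integer(n_dropped))
}

#' Pairwise Cohen's kappa across a respondent panel
#'
#' Reproducibility is measured as Cohen's kappa for every unique pair of
#' respondents (humans, or repeated machine runs), and the arithmetic mean
#' across pairs. Pairs with zero usable questions are excluded from the
#' mean and flagged.
#'
#' @param responses Response tibble with columns `record_id`, `sign`,
#'   `verdict`, and a respondent key column.
#' @param respondent Name of the column identifying respondents; repeated
#'   machine runs can be keyed by `run_index` (default `"respondent_id"`).
#' @return A list with `pairs` (tibble: `respondent_1`, `respondent_2`,
#'   `kappa`, `p_o`, `p_e`, `n_pairs`, `n_dropped`) and `mean_kappa`.
#' @export
pairwise_kappa <- function(responses, respondent = "respondent_id") {
  responses <- tibble::as_tibble(responses)
  stopifnot(respondent %in% names(responses))
  ids <- unique(responses[[respondent]])
  if (length(ids) < 2) {
    abort("need at least two respondents for pairwise agreement")
  }
  wide <- responses |>
    dplyr::select(dplyr::all_of(c("record_id", "sign", respondent,
                                  "verdict"))) |>
    tidyr::pivot_wider(names_from = dplyr::all_of(respondent),
                       values_from = "verdict")
  combos <- combn(as.character(ids), 2)
  rows <- lapply(seq_len(ncol(combos)), function(i) {
    a <- combos[1, i]; b <- combos[2, i]
    k <- cohens_kappa(wide[[a]], wide[[b]])
    tibble::tibble(respondent_1 = a, respondent_2 = b,
                   kappa = k$kappa, p_o = k$p_o, p_e = k$p_e,
                   n_pairs = k$n_pairs, n_dropped = k$n_dropped)
  })
  pairs <- dplyr::bind_rows(rows)
  defined <- !is.na(pairs$kappa)
  if (any(!defined)) {
    warn(sprintf("%d respondent pair(s) had no usable questions or undefined kappa and were excluded from the mean",
                 sum(!defined)))
  }
  list(pairs = pairs,
       mean_kappa = if (any(defined)) mean(pairs$kappa[defined]) else NA_real_)
}

#' McNemar's test with continuity correction
#'
#' Paired comparison of two classifiers on the same questions, using only
#' the discordant counts: `b` (first positive, second negative) and `c`
#' (the converse). The continuity-corrected statistic is
#' \eqn{\chi^2 = \max(|b - c| - 1, 0)^2 / (b + c)} with 1 degree of
#' freedom, so near-equal discordant counts give exactly 0 rather than a
#' positive artifact; `b + c = 0` gives \eqn{\chi^2 = 0}, `p = 1`.
#' Question pairs with `NA` on either side are dropped.
#'
#' @param v1,v2 Aligned logical verdict vectors (e.g. each classifier's
#'   per-question consensus), or `NULL` if `b` and `c` are given directly.
#' @param b,c Discordant counts, supplied instead of vectors.
#' @return A list with `b`, `c`, `chi2`, `p_value`, `df` (always 1),
#'   `n_pairs`, `n_dropped`.
#' @examples
#' mcnemar_test(b = 10, c = 0)
#' @export
mcnemar_test <- function(v1 = NULL, v2 = NULL, b = NULL, c = NULL) {
  if (is.null(b) != is.null(c)) {
    abort("supply both `b` and `c`, or neither")
  }
  n_pairs <- NA_integer_; n_dropped <- NA_integer_
  if (is.null(b)) {
    v1 <- as_verdict(v1); v2 <- as_verdict(v2)
    if (length(v1) != length(v2)) {
      abort("`v1` and `v2` must be aligned vectors of equal length")
    }
    use <- !is.na(v1) & !is.na(v2)
    n_dropped <- sum(!use)
    v1 <- v1[use]; v2 <- v2[use]
    n_pairs <- length(v1)
    b <- sum(v1 & !v2)
    c <- sum(!v1 & v2)
  }
  stopifnot(b >= 0, c >= 0)
  if (b + c == 0) {
    chi2 <- 0
    p <- 1
  } else {
    chi2 <- max(abs(b - c) - 1, 0)^2 / (b + c)
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  list(b = as.integer(b), c = as.integer(c), chi2 = chi2, p_value = p,
       df = 1L, n_pairs = n_pairs, n_dropped = n_dropped)
}
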