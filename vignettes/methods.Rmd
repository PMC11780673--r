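---
title: "Methods: evaluating clinical-sign extraction against a human panel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: evaluating clinical-sign extraction against a human panel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ehrsigneval)
```

## The evaluation problem

Free-text veterinary EHRs rarely carry structured diagnostic codes, so
retrospective studies extract clinical signs by reading the text. When a
language model does the reading, its output has to be validated against
human review — but individual humans disagree, so the reference standard
is itself a statistical object: the majority opinion (mode) of a blinded
panel. This package implements the full evaluation protocol around that
idea for binary sign questions: is sign *s* currently or recently
present in record *r*?

The unit of analysis throughout is the **question**, one (record, sign)
pair. A study with 250 records and six signs has 1,500 questions per
respondent. Verdicts are three-valued: `TRUE`, `FALSE`, or `NA` (an
abstention or unparseable answer).

## Study design

The corpus size comes from the standard precision calculation for
estimating the sensitivity of a single test: the number of
condition-positive records needed is \(z^2\,Se(1-Se)/d^2\) for
anticipated sensitivity \(Se\), margin of error \(d\) and standard
normal critical value \(z\); dividing by the anticipated prevalence and
taking the ceiling once, at the end, gives the record count.

```{r}
required_sample_size(expected_sensitivity = 0.95, margin_of_error = 0.07,
                     expected_prevalence = 0.15)
```

With a 5% type-I error rate, a 7% margin, 95% expected sensitivity and
15% prevalence this yields 249; studies typically round to a convenient
250. The function returns the formula value and leaves rounding to the
caller. Ceiling is applied only once so that the two stages of the
calculation do not accumulate rounding.

Corpus filtering (`filter_corpus()`) applies three exclusion rules —
malformed rows, empty pertinent-history text, duplicate patients (first
record kept) — and logs every exclusion with its reason, so
`kept + excluded` always equals the input and filtering is idempotent.

## Consensus and performance metrics

`mode_verdict()` removes `NA` verdicts and returns a strict majority.
**Tie handling** is a genuine design choice: with five human
respondents ties arise only through abstentions, and the package
resolves them as `NA`, excluding the question from the confusion table
and counting it in the `excluded` column. Exclusion-with-accounting is
conservative: no tie is silently converted into a verdict.

Sensitivity, specificity, PPV and NPV are binomial proportions and
carry **Wilson score intervals**,
\[
\frac{\hat p + z^2/2n}{1 + z^2/n} \;\pm\;
\frac{z\sqrt{\hat p(1-\hat p)/n + z^2/4n^2}}{1 + z^2/n},
\]
clipped to \([0,1]\). The Wilson interval behaves sensibly at \(\hat p
\in \{0, 1\}\) (the closed boundary is exact) and always contains
\(\hat p\), which a Wald interval does not guarantee. F1 (harmonic mean
of sensitivity and PPV) and balanced accuracy (arithmetic mean of
sensitivity and specificity) are derived quantities and are reported
without intervals. Zero denominators produce `NA` markers that
propagate rather than raise.

Cross-sign summaries report the median and interquartile range over the
six per-sign values. **Quartile convention**: linear interpolation
between order statistics (`stats::quantile` type 7, the R default),
configurable via `quantile_type` because the discrete conventions give
visibly different IQRs with only six values.

## Agreement statistics

Reproducibility is pairwise **Cohen's kappa**,
\(\kappa = (p_o - p_e)/(1 - p_e)\), with \(p_e\) from each rater's own
marginal rates, computed for every unique pair of respondents (human
pairs; machine run pairs within a temperature) and averaged. Pairs with
`NA` on either side are dropped and counted. The degenerate case
\(p_o = p_e = 1\) (two identical constant raters) is reported as
\(\kappa = 1\).

Paired model comparisons use **McNemar's test with continuity
correction**, \(\chi^2 = \max(|b-c|-1, 0)^2/(b+c)\) on the discordant
counts, df = 1. The `max(.,0)` form means near-equal discordant counts
give exactly 0 (and \(b+c=0\) gives \(\chi^2=0,\ p=1\)) instead of the
small positive artifact produced by squaring \(|b-c|-1\) when
\(|b-c|<1\); this matches how such comparisons are conventionally
printed. The comparison unit is the pooled set of questions using each
side's mode-of-runs verdict; a per-sign breakdown is available by
filtering the consensus tables before calling `mcnemar_test()`.

## Citation auditing

Respondents must support "true" verdicts with verbatim, quote-enclosed,
whitespace-separated, ellipsis-free citations. `extract_citations()`
enforces the format (typographic quotes are normalized to straight
quotes first); `match_citation()` classifies each segment against the
record text — the concatenation of presenting complaint and pertinent
history, the fields shown to respondents — with an ordered, exclusive
ladder. The first level that fires is returned:

1. `exact` — contiguous substring;
2. `case_only` — substring after case folding;
3. `punct_space` — substring after collapsing whitespace and stripping
   punctuation;
4. `shortened` — segment tokens form an ordered subsequence (with gaps)
   of the record tokens;
5. `scaffold_included` — exact/case substring after removing known
   question or field-name strings from the segment;
6. `paraphrase` — at least `tau_p` of the segment's distinct tokens
   occur in the record without the subsequence structure;
7. `unmatched` — the hallucination candidate level.

A response is **citation-compliant** iff it has no format violations and
every segment is `exact`; an empty citation on a "false" verdict is
compliant by vacuity. The shortened-vs-paraphrase boundary is this
package's operationalization of a distinction that is made by eye in
manual review: ordered-subsequence structure preserved versus not.
`tau_p` defaults to 0.5 — half of a segment's distinct tokens must
appear in the record — and is configurable; it is a declared convention,
not a fitted constant. Token-set *containment* is used rather than
Jaccard because a short quotation against a long record would make
Jaccard vanish for any citation.

Character intervals are reported for levels 1–5 (level 3 through an
index map from the normalized string, level 4 as the span from first to
last matched token); `paraphrase` has no well-defined span and
contributes no interval.

## Error taxonomy

Errors are questions where the machine's mode and the human majority
are both defined and differ. Each error is classified on four axes:

- **type** — false positive / false negative;
- **dissent stratum** — how many humans sided with the machine (0–2 in
  a five-human panel); high dissent marks ambiguity rather than model
  failure;
- **discrepancy** — *interpretation* (same text cited, different
  reading) vs *citation* (different text, someone missed a passage).
  "Same text" is interval-union Jaccard ≥ 0.5 on the citation spans
  resolved by the audit ladder, majority-side humans only. If either
  side has no resolved span the error is a citation discrepancy —
  including the both-empty case (nobody cited; someone missed
  something). The threshold is configurable;
- **ambiguity** — temporal / qualitative / none, copied from supplied
  adjudication labels and never inferred from text, mirroring the fact
  that this judgment is human work. Unlabelled errors are reported as
  `unlabeled`.

`summarize_ledger()` reports every marginal with counts and percentages
on both denominators (errors and total questions), with an `n = 0`
guard returning zeros for an empty ledger.

## The synthetic world

`sim_config()` + `generate_corpus()` + `simulate_human_panel()` +
`simulate_llm_runs()` produce a complete, seeded study. Text is
assembled from fixed sentence templates — one clear-present, one
temporally ambiguous (e.g. dated weights), one qualitatively ambiguous
(e.g. an equivocal stool description) and one negation sentence per
sign, plus neutral fillers — so every gold citation span is known
exactly and no language model is needed anywhere.

The response model:

- unambiguous questions are answered correctly except with probability
  \(\varepsilon\) (human 0.01, machine 0.02 by default);
- ambiguous questions have no single correct answer; each human answers
  "true" independently with \(\pi_h = 0.5\) (the dissent engine), the
  machine's base answer is "true" with \(\pi_m = 0.9\) — this asymmetry
  is what makes machine errors false-positive dominated;
- the machine draws one **base answer** per question, and each run at
  temperature \(T\) flips it independently with probability
  \(\delta(T)\), non-decreasing in \(T\). Base-plus-flip (rather than
  independent answers per run) is deliberate: observed run-to-run
  agreement in this class of study far exceeds human inter-rater
  agreement even at high temperature, implying strong within-model
  correlation. Defaults \(\delta = (0.002, 0.005, 0.01)\) at
  \(T = (0, 0.5, 1)\) put run-pair kappa near the 0.98–0.93 range at
  15% prevalence;
- citations: a true verdict cites its gold span unless it misses
  (probability \(\mu\)), with a deviation drawn from per-level
  probabilities; each deviation generator is constructed to land at
  exactly one ladder level. False verdicts cite nothing.

Defaults are chosen once as a realistic stated world: prevalence 0.15
per sign (the design prevalence), ambiguity probabilities
\(P(\text{temporal}) = 0.10\), \(P(\text{qualitative}) = 0.05\) given a
drawn sign, which with \(\pi_h = 0.5\) places ambiguity-driven dissent
on roughly 2% of questions — the order of magnitude reported for this
study class. These are illustrative parameters, not fits to any
dataset, and the tests do not depend on their exact values beyond the
stated bands.

**What a green test does and does not establish.** The generator
emulates the statistical structure the analysis assumes — prevalence,
ambiguity-driven dissent, correlated runs, ladder-classifiable citation
deviations — not real clinical language. Two consequences matter.
First, because false verdicts cite nothing in the simulator, simulated
errors virtually always resolve as *citation* discrepancies; the
interpretation branch (both sides citing the same sentence with
opposite readings) is exercised by constructed fixtures, not by the
simulator. Second, machine citation-deviation rates do not vary with
temperature in the simulator, although real systems drift; only the
verdict channel responds to temperature. Parameter recovery on the
synthetic world validates the estimators, not any claim about a real
model's accuracy.

## Numerical conventions and degenerate inputs

- All randomness flows from one master seed through named child streams
  (`child_seed()`), so corpus, each human, and each run are
  independently reproducible and below \(2^{31}\).
- `wilson_ci(k, 0)` returns an undefined marker, not an error; metric
  `NA`s propagate into F1/BA.
- Structured-output repair is conservative: only a single unambiguously
  recoverable object (strip fences/prose around the outermost braces,
  drop trailing separators, balance brackets) is accepted, and every
  repair emits an event; anything else becomes all-`NA` verdicts with
  an `invalid_structure` event. Cardinality of a run panel is exact by
  construction — failures appear as `NA` rows, never holes.
- Known limitation: the paraphrase containment measure ignores word
  order entirely, so a citation that scrambles record vocabulary can
  score as paraphrase rather than unmatched; raising `tau_p` tightens
  this at the cost of pushing borderline shortenings to `unmatched`.
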