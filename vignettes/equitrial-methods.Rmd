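---
title: "Measuring sex/gender representation and reporting in cardiovascular trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring sex/gender representation and reporting in cardiovascular trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equitrial)
```

## The problem

Women/females remain underrepresented as participants in cardiovascular
clinical trials, and published trial reports often fail to analyse or even
mention sex/gender beyond a demographics table. `equitrial` implements a
reproducible desk-scale pipeline for three linked questions about a corpus
of published trials:

1. **Participation.** How does the share of women/female participants in
   each trial compare with the share of women among people who actually have
   the studied disease?
2. **Reporting.** Do the published articles consider sex/gender in their
   demographics, results, endpoint analyses and discussion?
3. **Authorship.** Is the presence of women/females in leading author
   positions associated with better participation or reporting?

Throughout, "sex/gender" reflects that manuscripts rarely state how
participant sex or gender was ascertained, and author designation is
name-based; the analytical groups are women/females and men/males, with
`unknown` as an explicit value, never a guess.

## Participation-prevalence ratio (PPR)

For trial $i$ with $w_i$ women and $m_i$ men participants, the share is
$s_i = w_i / (w_i + m_i)$. The PPR divides this by the women's share among
prevalent cases of the trial's disease entity,
$$\mathrm{PPR}_i = \frac{s_i}{\pi_{e(i), r(i), t(i)}},$$
where $\pi$ is looked up by entity, World Bank region and year. A PPR
between 0.8 and 1.2 — endpoints inclusive — counts as optimal
representation; below/above otherwise.

Two conventions deserve explicit statement because the phrase "ratio of
prevalences" is ambiguous in parts of the literature:

* The denominator is the women's **share among cases**,
  $\pi = P_w / (P_w + P_m)$, not the ratio $P_w / P_m$. The packaged
  heart-failure values (0.50 unspecified, 0.42 HFrEF, 0.57 HFpEF) are
  shares, which fixes the convention.
* Prevalence lookup uses the most specific entry available, falling back
  (entity, region, year) → (entity, region, ANY) → (entity, ANY, ANY). For
  HeartFailure trials with a known subtype, the subtype entry is preferred
  and the unspecified entry is the fallback.

The packaged default prevalence table carries the three heart-failure
shares plus entity-level placeholder values for the other nine categories.
The placeholders are on the scale reported in the epidemiological
literature (e.g. ischemic heart disease below parity, pulmonary
hypertension female-predominant) but are deliberately coarse: users with
access to region- and year-specific estimates should replace the table via
`read_prevalence_table()`.

A trial's region is the **plurality** region of its authors' affiliation
countries (one ISO3 code per author). Ties are broken by list order: the
tied region appearing earliest in the author list — hence the first
author's region in a two-way tie — wins. The tie-break is a declared design
choice; any deterministic rule would do, and this one keeps the result
stable under permutations of non-leading authors.

## Sex/gender-sensitive reporting (SGR)

SGR scoring is a deterministic keyword scan of per-section article text
using eight tokens: six sex/gender terms ("gender", "sex", "male",
"female", "men", "women") and two locator terms ("subgroup", "adverse").
Matching is case-insensitive and whole-word with Unicode-aware boundaries;
hyphen and slash are boundaries, so "sex/gender" matches both tokens while
"men" never fires inside "management" or "women". Locator terms gate flags
but never count as sex/gender mentions themselves.

Four core subsection flags feed a 0–4 sum:

| flag | rule |
|------|------|
| demographics | curated baseline-table indicator, or (fallback heuristic) a methods/results sentence combining a sex/gender term with "baseline"/"characteristics" |
| results | sex/gender term anywhere in methods or results |
| endpoint | sex/gender term in the same sentence as a subgroup/interaction/stratification/adjustment locator, in results or supplementary material |
| discussion | sex/gender term in the discussion, limitations included |

A sum of at least 3 counts as **high SGR**. Title and abstract mentions are
reported alongside but excluded from the core sum, consistent with the
four-subsection definition of the score; this exclusion is flagged here
because the alternative reading (six inputs) is defensible. Adverse-event
stratification is scored only among articles that report adverse events,
as a sex/gender term in the same sentence as an "adverse" match.

Sentences are maximal spans split at `.`, `!` or `?` followed by
whitespace. The same-sentence window for co-occurrence rules is a
deterministic stand-in for human judgement of "analysed by sex/gender";
it will miss cross-sentence references and is intentionally conservative.
Missing sections score as empty text. The curated demographics boolean is
preferred over the textual heuristic because baseline tables are generally
not recoverable from flat text; `demographics_source` records which route
fired. A per-article override of keyword hits, if adjudication is desired,
can be applied by editing the score table before summarising.

## Authorship

Author sex/gender is designated from the given name (first whitespace
token, lowercased, diacritics folded) through a pluggable lookup table
with a confidence threshold (default 0.8). Initials-only names, names
absent from the lookup, and sub-threshold entries all resolve to
`unknown`. The packaged lookup is synthetic — it covers the generator's
name pools — and real analyses should substitute a validated table via
`read_gender_lookup()`; an external classifier can be wrapped by writing
its output into the same three-column format.

A trial is **women-led** when a woman/female is designated in the first
and/or last author position (a single author holds both). Trials whose
leading positions cannot be resolved are excluded from the women-led vs
men-led dichotomy rather than imputed; exclusion is independent of the
outcome given the true leading status, so it costs power, not validity.
The share of women among authors is computed over resolved authors only.

## Statistics

* **Medians** carry distribution-free 95% CIs from the binomial rank
  interval (the largest rank $l$ with $P(\mathrm{Bin}(n, 1/2) < l) \le
  \alpha/2$ gives $[x_{(l)}, x_{(n+1-l)}]$), which is conservative and
  deterministic; a seeded percentile bootstrap (B = 2000) is available.
  The order-statistic default is a declared substitute where the CI method
  behind published medians is unstated.
* **Time trends** are Pearson correlations of per-trial values against
  decimal publication time, coded year + (month − 0.5)/12, with the
  two-sided t-test on n − 2 df and the least-squares line.
* **Mann–Whitney** U uses midranks; combined samples up to 20 get an exact
  two-sided p by enumeration of the rank-sum distribution (dynamic
  programming over doubled ranks, so ties are handled exactly), larger
  samples the tie-corrected normal approximation with continuity
  correction.
* **Chi-square** on 2×2 tables is Pearson's statistic without continuity
  correction, df = 1; zero marginals error.
* **Odds ratios** come from maximum-likelihood logistic fits with Wald 95%
  CIs, $\exp(\hat\beta \pm 1.96\,\mathrm{SE})$; separation and
  non-convergence raise errors naming the predictor. The association suite
  fits high SGR on leading-woman authorship and on optimal PPR separately
  (univariate) and jointly (multiple).

All tests are two-sided at $\alpha = 0.05$; no multiple-testing correction
is applied, matching the descriptive character of the analysis.

## The synthetic-corpus generator

No trial-level dataset is deposited with the published analysis this
package operationalises, so the generator is a first-class module: it
draws corpora with the statistical structure the pipeline assumes, and its
defaults *are* the study conditions.

* Year, entity and region marginals use the published corpus counts as
  weights (e.g. ischemic heart disease 337/1593, Europe 591/1593).
* Trial sizes are log-uniform within the published quartile bands
  (≤ 72, 72–182, 182–617, > 617, capped at 20 000), one quarter each.
* Per-trial women shares are Beta-distributed around entity-level means
  anchored to the published per-entity participation shares
  (concentration κ = 30, chosen so per-trial shares spread realistically
  within an entity).
* Author counts are 2 + Poisson(5) (capped at 20); the probability that a
  given position is held by a woman interpolates linearly between the
  published 2018 and 2024 levels (first 0.324→0.438, last 0.224→0.302,
  interior 0.36→0.43). 3% of authors are listed with initials only, so
  designation genuinely exercises the `unknown` path.
* Couplings: women-led trials get `delta_share = +0.04` added to the mean
  women share; high SGR follows a logistic model with baseline 0.353 (the
  published men-led rate), odds ratio `or_sgr = 1.4` for leading-woman
  authorship and `or_sgr_ppr_above = 2.5` when the PPR exceeds 1.2
  (anchored to the published 58.3% vs 34.4% contrast).

The SGR coupling is modelled at the level of the composite outcome
(core sum ≥ 3), and the four-flag pattern is then drawn from the
independent-flags model — marginals 0.988/0.691/0.399/0.22 — conditioned
on the drawn high/low state. Modelling the coupling per flag instead would
induce a composite-outcome odds ratio well above the per-flag one (≈ 1.76
for a per-flag 1.5 at these marginals), so the composite parameterisation
is the one whose parameter the downstream logistic model actually
estimates; conveniently, the independent-flags model at these marginals
gives a 39.0% high-SGR rate, matching the published 39.3%.

Article texts are synthesized, not bypassed: each flag that should fire is
planted as a keyword-bearing template sentence (the endpoint template puts
"subgroup" and "sex" in one sentence of the supplementary material; the
adverse template avoids endpoint locators), and neutral filler includes
trap words ("management", "regimen", "acumen", "femoral") so the
whole-word matcher is exercised end to end. The generator does **not**
emulate: real English prose, section segmentation noise, correlated
authorship across trials, registry metadata quirks, or entity-specific
reporting styles. Passing pipeline tests on synthetic corpora therefore
demonstrates correctness of the computation and recoverability of the
modelled couplings — not that the keyword heuristics capture every way a
real article discusses sex/gender.

A 40% random subsample of trials receives full text, mirroring the
subsampling of the published SGR analysis (which additionally balanced by
entity and year; the generator's marginals are already balanced by
construction, so simple random subsampling suffices).

## Numerical and degenerate-input choices

* Display percentages round half-up to one decimal (`pct_women()`), the
  convention of published summary tables; base `round()` would round half
  to even.
* Quartile boundaries are type-7 quantiles of the observed trial sizes,
  overridable with published bounds (72/182/617) for replication-style
  tables.
* Duplicate registry IDs keep the first record and warn. Empty score
  lists, zero-participant trials, zero-variance trend inputs, degenerate
  outcomes and zero chi-square marginals all raise informative errors
  rather than propagating NaN.
* Generator feasibility is checked up front: a shifted mean share outside
  (0,1) is an error, not a silent truncation.

## Problem sizes used in the shipped checks

The packaged tests run the full pipeline at n = 5000 trials for parameter
recovery (100 replicates), n = 400 for null calibration (200 replicates),
and n = 1593 — the published corpus size — for the acceptance script's
headline quantities. These sizes were chosen so that recovery checks have
the power the couplings need while a complete run stays comfortable on a
single CPU.

## Limitations

Keyword scanning is a lower bound on genuine sex/gender consideration and
a (rarely) upper bound where terms appear incidentally; the curated
demographics indicator and the optional override column exist for exactly
that reason. Name-based designation misclassifies some authors and cannot
see gender identity. The placeholder prevalence values for non-HF entities
are not region- or year-specific; PPR levels for those entities shift with
the table supplied, though within-corpus comparisons are less sensitive.
Associations estimated by the suite are descriptive, not causal.
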