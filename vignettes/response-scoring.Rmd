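---
title: "Response scoring for neoadjuvant rectal cancer cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Response scoring for neoadjuvant rectal cancer cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(larcscore)
```

## The problem

In locally advanced rectal cancer treated with total neoadjuvant therapy,
pathologic complete response (pCR) after total mesorectal excision is the
short-term outcome that drives both prognosis and the case for omitting
surgery (watch-and-wait). `larcscore` implements the pre-surgical markers
proposed to predict it — the immunoscore from the baseline biopsy and the
MRI tumor regression grade (mrTRG) — and the neoadjuvant rectal (NAR)
score, a surrogate endpoint computed after treatment, together with the
statistics linking all of them to pCR and survival.

## Scores and their conventions

**Immunoscore.** CD3⁺ and CD8⁺ T-cell densities are recorded in the tumor
core and invasive margin (four marker-region values per patient). Each of
the four is converted to a percentile rank *within the analysis cohort*
using the Hazen plotting position `100 (rank − ½)/n` with mid-ranks for
ties; the immunoscore is the mean of the four percentiles, classed *high*
at or above the cutoff (default 62). The Hazen convention is symmetric,
keeps ranks off the 0/100 boundaries, and is standard for small cohorts;
because only ranks enter, the score is invariant to any positive affine
rescaling of the raw densities (a tested property). A mean of exactly 62
is classed high: the cutoff is described as the value that *distinguishes*
the groups, and a closed upper side is the conventional reading. The
reference distribution is deliberately cohort-internal — no external
reference table ships with the package — which matters for interpretation
(see *Limitations*).

**NAR score.** `nar_pathologic()` computes
`(5 pN − 3 (cT − pT) + 12)² / 9.61` from integer-encoded stages;
`nar_radiologic()` substitutes post-treatment MRI stages. Substage letters
(T3a–d, N1a–c …) collapse to the integer stage for this arithmetic, since
the formula is defined on integer stages; `Tis` maps to 0. Categories are
low < 8, intermediate 8–16 (inclusive), high > 16. Attainable values form
the finite set `k²/9.61` for integer `k` in 0–34, so the boundaries 8 and
16 can never be hit exactly — the inclusive assignment is fixed for the
contract but immaterial at runtime. Over the full encoded domain the inner
term is non-negative and the score is monotone: nondecreasing in pN and
pT, nonincreasing in cT (all verified exhaustively in the tests).

**Endpoints.** pCR is defined as pTRG 0 *and* ypN0 — complete response
conventionally means `ypT0N0`, and regression grading alone says nothing
about nodes. Near-pCR is pTRG ≤ 1. A missing grade or stage makes the
endpoint missing, never `FALSE`; every analysis then uses its own
complete-case denominator and reports it.

## Statistical machinery

The exact test of independence enumerates *every* table sharing the
observed row and column margins, assigns each its multivariate
hypergeometric probability, and sums the probabilities of tables no more
probable than the observed one (Freeman–Halton; identical to the classic
two-sided Fisher test for 2×2). Probabilities are compared on the log
scale with a relative tie tolerance of 1e-9 so that exact ties — common in
symmetric tables — are never lost to floating-point noise. All-zero rows
and columns are removed first, making the 2×3 test degrade gracefully to
the 2×2 one; if fewer than two informative rows or columns remain, p = 1
is returned with a warning. Tables larger than 2×3 are refused rather than
approximated. The test is validated two ways: against an independent
brute-force hypergeometric oracle on every 2×2 table with N ≤ 12, and
against `stats::fisher.test`.

Kaplan–Meier estimation is the standard product-limit estimator with
events ordered before censorings at tied times; without censoring it
equals one minus the empirical CDF of event times (a tested property).
The log-rank test is the K-group Mantel–Haenszel statistic with the full
hypergeometric covariance; a generalized inverse makes degenerate
configurations (identical groups) return χ² = 0 instead of failing. Both
are cross-checked against the `survival` package in the test suite. Mean
comparisons use Welch's unequal-variance t-test (`stats::t.test`): the
safer default when nothing is known about the group variances.

Event-free proportions "at the end of follow-up" are the KM estimate read
at the maximum observed time of the analysis at hand, matching how such
figures are quoted after a fixed administrative follow-up (40 months in
the emulated trial).

## The reference fixtures and their two inconsistencies

No patient-level data are published for the 35-patient cohort the package
emulates; the fixtures therefore rebuild what the aggregate record
determines uniquely. The joint distribution of immunoscore class × mrTRG 1
× pCR is fully pinned down by the published margins (35 total, 15 pCR, 23
IS-high, 14 mrTRG 1, 9 combined with 6 pCR): margin bookkeeping forces the
remaining cells to (high, TRG≠1) = 14 with 5 pCR, (low, TRG1) = 5 with 1
pCR, (low, TRG≠1) = 7 with 3 pCR. `fixture_joint_cohort()` emits these 35
records with internally consistent stages (pCR ⇒ pTRG 0, ypN0) and mrTRG 2
for all non-complete radiologic responders.

The published record is, however, not internally consistent, in two ways
that the package deliberately preserves rather than repairs:

1. the pCR × NAR tables and the grade breakdown imply 13 pCR patients,
   while the headline count is 15 — possibly missing NAR/grade data for
   two patients, possibly a typo; unknowable from the aggregate record.
   The printed tables are therefore stored verbatim as separate fixtures
   (`fixture_nar_tables()`, `fixture_grade_table()`), independent of the
   joint cohort, and `grade_breakdown()` surfaces the mismatch as a
   warning when given the expected pCR total;
2. one pCR patient sits in the intermediate pathologic NAR category, which
   the formula cannot produce for a pCR (ypT0N0) patient with baseline
   cT 2–4 (the maximum is (12 − 6)²/9.61 ≈ 3.75, firmly low). Stored as
   printed.

Fidelity to the printed record was preferred over forced consistency: a
single imputed patient-level dataset reproducing every printed number
simultaneously is demonstrably impossible.

## The synthetic-cohort simulator

`simulate_cohort()` generates cohorts with the structure the analysis
assumes, for property-based testing and power exploration. Defaults are
fixed to the emulated trial's conditions and are not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `n` | 35 | trial cohort size |
| `ct_probs` | (0.05, 0.90, 0.05) over cT2–4 | the cohort was almost entirely cT3 |
| `cn_probs` | (0.30, 0.50, 0.20) over cN0–2 | node-positive-skewed LARC mix |
| `is_effect` | 2 | latent link from immunoscore to response |
| `pcr_base_logit` | −1.36 | gives ≈ 0.43 population pCR prevalence |
| mrTRG thresholds | (1.26, 0.55, −0.15, −0.85) × `mrtrg_link` | give ≈ 0.40 mrTRG 1 prevalence |
| `dfs_hazards` | (0, 0.00264, 0.01468) /month | 40-month DFS ≈ 100/90/56% by NAR category |
| `os_hazards` | (0, 0, 0.00627) /month | 40-month OS ≈ 100/100/78% |
| `admin_censor_months` | 40 | trial follow-up |
| `seed` | 20180329 | arbitrary documented constant |

Densities are log-normal — non-negative, right-skewed, typical of cell
densities; only their ranks matter downstream — driven by a shared latent
immune level so the four marker-regions correlate within a patient. A
latent response `z = is_effect·IS/100 + N(0,1)` is thresholded into the
ordered mrTRG grades and drives pCR through a logistic model; non-pCR
records draw pTRG 1–3 from a residual fraction decreasing in `z`, with
ypT/ypN at most baseline. Survival times are exponential per pathologic
NAR category with administrative censoring; death always bounds the DFS
time. pCR records get ypT0/ypN0/pTRG 0, so the scoring-consistency
property `pCR ⇒ NAR = (12 − 3 cT)²/9.61` holds by construction and is
asserted in tests.

What the simulator does *not* emulate: under cohort-internal ranking the
IS-high fraction at cutoff 62 settles near 0.34, not the 0.66 observed in
the trial. That is a mathematical consequence of internal ranking — the
cohort mean of mean-of-four mid-ranks is exactly 50, so two thirds of a
cohort cannot sit above the 62nd internal percentile except in extreme
configurations — and is itself evidence that the trial's percentiles came
from an external reference scale. The exact 23/35 IS-high condition is
therefore carried by the deterministic fixture, not the simulator, and
passing simulator-based tests says nothing about any particular external
reference population. Other simplifications: exponential (constant-hazard)
survival, no correlation between tumor grade and response, no missingness
mechanism.

Problem sizes in the tests were chosen as the smallest that make the
stochastic checks sharp: prevalence recovery and hazard-ordering use
n = 10,000 (binomial SE ≈ 0.005, so a 3-SE band separates a real 0.43
from neighbouring values), exhaustive sweeps cover the full 5×5×3 stage
domain and all 2×2 tables with N ≤ 12.

## Numerical and design choices

* Percentages are carried as exact ratios and printed to one decimal next
  to their counts; an internal consistency check asserts every emitted
  percentage equals its count ratio. (The emulated record itself prints
  15/35 as 42.8%, which is a truncation of 42.857…%; the package reports
  the computed ratio.)
* The published crosstab analysis is described as 2×2 but printed as 2×3;
  the pipeline follows the printed shape and uses the Freeman–Halton 2×3
  test by default. The radiologic exact p computed this way (0.12801)
  matches the printed 0.128, supporting that choice. Both shapes are
  available through `fisher_exact()`.
* DFS is clocked from initial diagnosis (as the emulated trial defined
  it, and unusually — trials more often clock from randomization); the
  simulator uses the same clock, so the two are consistent.
* CSV interchange is deliberately minimal: comma-delimited UTF-8, header
  of canonical names, empty cell = missing, stages as AJCC text codes,
  events as 0/1, times in months. Invalid cells never abort a read; they
  become structured findings and missing fields, so one bad cell costs
  one field, not a cohort.

## Limitations

Cohort-internal percentile ranking means an individual immunoscore changes
with the cohort it is computed in; comparisons across cohorts need an
external reference scale, which this package does not provide. The exact
test is limited to 2×3 by design (enumeration is the point; larger tables
would need a network algorithm). Survival machinery covers estimation and
testing, not modelling (no Cox regression, no confidence bands). The
fixtures reproduce published aggregates, not patients: per-patient
survival analyses of the emulated trial are not recoverable, and the
corresponding published figures (per-category DFS/OS percentages and
log-rank p-values) are covered by simulator-level property tests instead.
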