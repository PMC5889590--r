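---
title: "Measuring adherence from claims: the continuous medication gap and self-report validity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring adherence from claims: the continuous medication gap and self-report validity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmgap)
```

## The measurement model

Pharmacy dispensing claims record when a patient obtained medication and
for how many days. The **continuous medication gap (CMG)** turns those
records into an adherence measure: the proportion of days, between a
patient's first and last fill of a therapeutic indication inside a
lookback window, on which no supply was on hand.

The unit of accounting is the *refill interval* — the span between two
consecutive fills of one ingredient. For interval $k$ of length $L_k$
days, the usable supply is

$$S_k = \text{days supply dispensed at the opening fill} + C_{k-1},$$

where $C_{k-1}$ is surplus carried over from the previous interval, and

$$\text{gap}_k = \max(0, L_k - S_k), \qquad
  C_k = \max(0, S_k - L_k), \qquad
  \mathrm{CMG} = \frac{\sum_k \text{gap}_k}{\sum_k L_k}.$$

Two properties of this *time-forward* scheme matter scientifically:

* **Stockpiling is credited, never back-dated.** A patient who refills
  early accumulates surplus that covers later late refills. But a large
  fill can never retroactively erase a gap already incurred — supply
  flows only forward in time. `time_forward_gaps()` implements the
  interval arithmetic; `daily_inventory_oracle()` re-derives the same
  quantity by brute-force day-at-a-time simulation, and the test suite
  holds the two equal on hundreds of randomized fill histories, along
  with causality properties (perturbing fill $k$'s supply never changes
  earlier intervals and never worsens later ones).
* **Observation ends at the last fill.** Every interval needs a closing
  fill, so supply remaining at the final fill is discarded and no
  terminal gap is imputed after it. This is the conservative reading of
  an interval-based measure; the alternative (extending the denominator
  to the assessment date) would require assumptions about
  discontinuation that claims cannot support.

### Calculability

CMG is only meaningful when the claims stream is complete and at least
one refill interval exists. Gates are applied in a fixed precedence so
that exclusion tallies are reproducible when several reasons apply:
insulin excluded (claims carry no fixed days supply for insulin), then
dual pharmacy coverage (fills invisible to the extract), then missing
continuous benefits over the lookback, then fewer than two fills of any
single ingredient. Non-calculable patients are reported alongside every
validity table rather than silently dropped: low-adherence patients have
fewer fills and are *more* likely to be non-calculable, so dropping them
silently would bias validity assessments optimistic.

### Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `window_days` | 365 | days | 12-month lookback preceding each assessment |
| `cmg_threshold` | 0.20 | gap fraction | optimal adherence = supply on hand ≥ 80% of observed days |
| `selection_mode` | `"first"` | — | first completed automated-query response, before coaching could shift behavior; `"last"` for sensitivity |
| `pairing_window_days` | 30 | days | maximum separation between query and interview responses in concordance pairs |
| `aggregation_mode` | `"pooled_days"` | — | multi-ingredient aggregation within an indication (below) |

The lookback is anchored **per source**: the automated-query analysis
uses each patient's selected query date as its index date and the
interview analysis uses the interview date, so the two validity analyses
each look back over the 12 months preceding their own assessment.

### Open design points and how they were settled

* **Multi-ingredient aggregation.** An indication (say, oral diabetes
  drugs) can contain several ingredients, each its own supply series —
  supply of one drug never covers days of another, and switching drugs
  within a class is treated as two separate series rather than
  cross-credited. The default indication CMG pools day counts
  ($\sum \text{gaps} / \sum \text{observed}$) across ingredients with at
  least two windowed fills, which weights each drug by its observed time
  and keeps the result a true proportion of days; an unweighted
  per-ingredient mean is available as `aggregation_mode =
  "mean_per_ingredient"` for sensitivity.
* **Run-in supply.** Fills dated before the window are ignored even if
  their supply would extend into it. This is the simplest auditable rule;
  it can overstate the first interval's gap for patients who stockpiled
  just before the window. Flagged as a limitation.
* **Concordance scale.** Cross-mode agreement compares raw missed-day
  counts (0–7), not the three analysis categories, because the direction
  labels ("higher disclosure on …") imply an ordering of reported days.
* **Pairing direction.** "Within 30 days" is interpreted symmetrically
  (|query date − interview date| ≤ 30), which maximizes pairs without
  favoring either mode.
* **Same-day duplicate responses** tie-break to the lower missed-day
  count, with a warning — deterministic and conservative toward
  adherence.

## The exact test

Convergent validity per indication and source is a 3×2 table: missed-day
category (0, 1, 2–7) × adherence (optimal, suboptimal). Expected counts
are routinely small, so homogeneity is tested exactly. Conditional on
the margins, table probabilities are multivariate hypergeometric,

$$P(T) = \frac{\prod_i r_i!\,\prod_j c_j!}{n!\,\prod_{ij} n_{ij}!},$$

and the two-sided Fisher–Freeman–Halton p-value sums $P(T)$ over all
tables with the observed margins whose probability does not exceed the
observed table's. `fisher_exact_rxc()` enumerates the tables exactly,
row by row in log-space. Numerical choices: the "no more probable"
comparison uses a $1+10^{-12}$ relative tolerance so that tables tied
with the observed one up to floating-point error are included; zero rows
and columns are dropped first; a table reduced to one row or column
returns $p = 1$. The suite verifies the implementation against an
independent full-grid enumeration oracle on hundreds of random tables
and against the classical conditional hypergeometric test on 2×2 tables.

## What the synthetic cohort emulates

Real dispensing extracts are confidential, so the generator produces
cohorts whose statistical structure matches what the analysis assumes,
with ground truth recorded:

* a latent per-patient, per-indication taking propensity
  $p \sim \mathrm{Beta}(8, 2)$ — mean 0.8, so the expected gap fraction
  $1 - p$ averages 0.2 and straddles the optimal-adherence cut, the
  regime where classification is hardest;
* refills driven by supply exhaustion plus a non-adherence delay:
  consecutive fills are $d + \text{delay}$ days apart ($d = 30$, the
  standard one-month fill), $\text{delay} \sim \mathrm{Geom}$ with mean
  $d(1-p)/p$, chosen so the expected uncovered fraction of an interval
  is exactly $1 - p$ and recovery of the propensity is a closed-form
  check;
* 7-day recalls $\mathrm{Binomial}(7, 1-p)$ per source, optionally
  thinned per missed day by `disclosure_prob` to reproduce the
  under-disclosure bias of self-report;
* deliberate non-calculable contamination: configurable fractions of
  patients receive exactly one fill or a dual-coverage flag (defaults
  0.05 each, a realistic minority).

Every fill is kept within `window_days - 35` of the first so that both
assessment anchors' lookbacks cover the full fill history (the interview
response may trail the query response by up to a week, plus margin).
That containment is what makes the pipeline's CMG **identical** to the
generator's realized uncovered-day fraction — the same gaps measured
through the interval engine and through the generator's bookkeeping — so
`recovery_report()` asserting `rmse_vs_truth = 0` certifies the entire
path from CSV emission to gap accounting, not an approximation.

Against the *structural* level $1 - p$ the agreement is statistical, not
exact: per-patient CMG is a ratio of sums of geometric delays, and the
finite window slightly favors histories whose last interval fits inside
it, so cohort mean CMG sits within Monte-Carlo error of
$\mathbb{E}[1-p]$ with a small negative bias (about 0.005 at the default
settings) that shrinks as the window grows.

What the generator does **not** emulate — and what passing tests
therefore do not demonstrate about real claims: dose changes mid-supply,
prescriber-initiated discontinuation, early-refill limits imposed by
payers, reversed or adjudicated claims, seasonal refill behavior,
multi-ingredient regimens within an indication (each synthetic
indication uses one ingredient, so the aggregation rule is exercised by
hand-built fixtures instead), and any dependence of disclosure on
language, literacy, or mode of assessment beyond a constant thinning
probability.

## Problem sizes and determinism

The property suites run 200 randomized fill histories against the daily
oracle, 500 random contingency tables against the enumeration oracle,
and a 500-patient recovery cohort; the end-to-end determinism checks use
50-patient runs. These sizes give stable verdicts for all the invariants
above while keeping the default test run fast. All randomness is
confined to the generator (`set.seed(params$seed)` at entry); the
analysis path is fully deterministic, and re-running a configured
pipeline reproduces the report bundle byte for byte.

## Known limitations

* Claims record dispensing, not ingestion: CMG measures supply on hand,
  an upper bound on consumption.
* The 7-day recall and the 12-month claims window measure different
  timeframes; discordance between them is partly structural.
* No run-in supply credit (above); first intervals after a stockpile may
  be scored too harshly.
* Primary non-adherence (never filling at all) is invisible: patients
  with zero or one fill are non-calculable, not suboptimal, and validity
  tables must be read together with their non-calculable tallies.
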