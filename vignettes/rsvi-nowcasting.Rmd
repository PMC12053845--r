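---
title: "Nowcasting incidence from search-interest ratios: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nowcasting incidence from search-interest ratios: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rsvicast)
```

## The model and its assumptions

Registry-reported cancer incidence lags the calendar by years. The model
implemented here nowcasts a region's count for year $t$ by scaling its
last reported count with the year-over-year ratio of the relative search
volume index (RSVI) — Google Trends' 0–100 popularity score for a search
topic within a chosen window and geography:

$$\widehat{Pr}_t = Ac_{t-1}\,\frac{RSVI_t}{RSVI_{t-1}},
\qquad
\%Error = \frac{Pr-Ac}{Ac}\times 100 .$$

The single substantive assumption is *proportional coupling*: that public
search interest in the topic moves proportionally with true incidence
between adjacent years. Everything the package does — one-step validation,
multi-year validation, chained projection — is this one equation applied
with care about precision, rounding and provenance. The model is
intentionally parameter-free: no trend is fitted, no window chosen, no
hyperparameter tuned. That makes it a transparent baseline, not a
replacement for structural incidence models; its role is short-term
nowcasting where registry data are not yet available.

Three aspects of the RSVI scale shape the implementation:

* RSVI is *relative within its query window* (the in-window maximum is
  100), so only ratios of values from the same query are meaningful —
  which is exactly how the model consumes them.
* RSVI 0 means "insufficient search data", not zero interest. A zero
  denominator (or any zero inside a chained span) is therefore an error
  naming the offending region/year, never a zero forecast.
* The exported scale is integer-rounded, which perturbs small values
  relatively more; the synthetic generator can emulate this (see below).

## Validation modes and provenance

`validate_year()` predicts each region's target-year count from the
*previous year's actual* and compares against the target year's actual.
`validate_multi_year()` repeats this per year — it never chains, because
where actuals exist they are always the better base. `project_unobserved()`
is the complement for years with no actuals: it chains the predictor,
carrying each step's unrounded prediction forward as the next base and
flagging every derived value with `provenance = "predicted"`. Chained error
compounds multiplicatively with horizon, so projections log a reminder to
that effect, and an actual value can never be overwritten by a predicted
one. Regions that cannot be validated or projected are returned in a
`skipped` table with one reason each — the packaged state table itself
silently lacks one state (Kansas: 49 states plus the District of Columbia),
which is a good argument for never dropping anything silently.

A paired-comparison helper, `compare_error_vectors()`, reduces two
region-keyed error vectors to per-region $|a|-|b|$ differences, each
model's mean absolute error, and win/tie counts, for comparing this model
against an external projection on common regions.

## Numerical conventions

**Full precision inside, rounding only at the surface.** Predictions use
the full-precision RSVI ratio; the packaged 2017 table reproduces all 50
predicted counts exactly under this convention and provably not under the
3-decimal display ratio (Alabama: 27550×86/89 = 26621.35 → 26621, while
27550×0.966 = 26613). Chained forecasts carry unrounded values between
steps, so the $k$-step forecast telescopes exactly (tested to 1e-9
relative) to the combined-ratio one-step form.

**Percentage errors are computed from the unrounded prediction.** The two
conventions (raw vs. integer-rounded prediction) differ in exactly one
cell of the 2017 table — North Dakota, where the raw prediction 3921.27
gives −1.649 → −1.6 as printed, while the rounded 3921 would give −1.655 →
−1.7. The package therefore computes record-level errors from
`predicted_raw`. The pure function `percent_error()` applies to whatever
pair it is given.

**Rounding rule.** All display rounding (counts to integers, ratios to 3
decimals, errors to 1 decimal) is round-half-away-from-zero
(`round_half_away()`). No printed cell lands on an exact .5 tie, so the
published tables cannot distinguish tie rules; one rule is fixed and
documented rather than left to `round()`'s half-to-even.

**Mean vs. median.** The source study reports a "median" percentage error
of −0.98% for its 2017 table, but −0.98 is numerically the *mean* of the
printed column; the median is −1.55. `error_summary()` therefore always
reports both, explicitly labelled, plus min, max and the proportion of
regions within a threshold (default ±6 percentage points, the bound quoted
for "most states").

**A pinned erratum.** Of the 150 predicted/actual/%error triples in the
2018–2020 table, 149 are internally consistent at 1-decimal display
rounding. The exception is Rhode Island 2018: the printed pair (6669,
6561) yields 1.646 → 1.6 under any rounding rule, but the printed error
cell is 1.7. The fixture stores the cell exactly as printed; the test
suite asserts the 149 agreements and pins this single discrepancy
precisely, so any second inconsistency would still fail.

## Input formats

Tidy CSVs carry `(region, year, cases)` or `(region, year, rsvi)`. The
Google Trends time-series export ("multiTimeline" dialect: a title line, a
blank line, a `Month,<topic>: (<region>)` header, then `YYYY-MM,<int>`
rows) is parsed directly; censored `"<1"` cells become 0.5, the midpoint
of the censored interval (any constant in (0,1) would do). Monthly values
aggregate to a yearly *arithmetic mean kept at full precision* — the
simplest defensible convention, isolated in one place so it can be
swapped; years with fewer than 12 exported months are excluded with a
warning by default, since a partial-year mean is biased by seasonality.
Years are never interpolated: the method is defined on consecutive
observed years only. Region display names normalise to USPS codes for US
states (DC included) and ISO 3166-1 alpha-2 for countries, giving stable
join keys; unknown names pass through unchanged.

The four packaged tables (`load_fixture()`) transcribe the published
validation study: the 2017 one-step table with its inputs, the 2018–2020
predicted/actual/%error table, and the 2021–2023 US and world projections.
The projections' RSVI inputs were never published, so those two tables are
reference values only — the mechanism that produced them (chained
prediction with unrounded carry-over and predicted-base provenance) is
tested, the values themselves are not recomputable. Display columns
(`ratio`, `pct_error`) are stored exactly as printed, separate from
anything recomputed; the Unicode minus of the source tables is normalised
to ASCII on transcription.

## The synthetic generator

`generate_synthetic()` exists so every operation is testable with known
ground truth and no download. It simulates, per region $r$:

$$cases_{r,t} = cases_{r,t-1}\,e^{\mu_r + \varepsilon_{r,t}},
\qquad \varepsilon \sim N(0, \sigma_\varepsilon^2),$$
$$rsvi^{raw}_{r,t} = s_r\, cases_{r,t}^{\gamma}\, e^{\eta_{r,t}},
\qquad \eta \sim N(0, \sigma_\eta^2),$$

then rescales each region's raw interest so its in-window maximum is 100
(mirroring how Trends normalises within a query window), optionally
rounding to integers with floor 1 to emulate the exported scale. Noise is
multiplicative log-normal because both quantities are positive and the
estimator is a ratio, making its error scale-free; the $\varepsilon$ and
$\eta$ streams are sub-seeded independently from the master seed so one
can be zeroed without shifting the other. Counts are kept continuous
(the incidence type requires only non-negative values), which lets the
exact-coupling limit hold to floating precision.

Defaults mirror the validation study's conditions: 50 regions, years
2016–2020, first-year counts uniform on 2,500–175,000 (the observed range
of the 2016 state counts), log-scale drift 0.02/year (state counts move a
few percent per year), incidence noise sd 0.02, coupling exponent
$\gamma = 1$, search noise sd 0.05 (chosen once as a realistic
moderate-coupling regime: it produces median absolute errors of a few
percent, the magnitude seen in the validation tables), integer rescaling
on.

What the generator establishes: with $\gamma = 1$ and both noise sds zero,
RSVI ratios equal incidence ratios exactly and the model's error is
identically zero — the headline correctness property; error grows
monotonically with search-noise sd; integer rescaling alone perturbs
errors within the ±0.5-per-term rounding bound (≤ 2% for index values
≥ 50); noise-free chains follow $base\cdot e^{k\mu}$. What it does *not*
emulate: the attention-displacement regime in which an external shock
(e.g. a pandemic) decouples search interest from incidence. Passing tests
therefore certify the estimator's arithmetic and its behaviour under
stationary proportional coupling with multiplicative noise — not the
empirical validity of the coupling premise on real data, which is exactly
the claim the packaged validation tables exist to document.

Test and acceptance runs use deliberately desk-scale problem sizes — 50
printed regions, synthetic runs of 4–200 regions over 2–5 years, 1,000
random vectors for the summary-statistic oracle — chosen because the model
is a scalar recurrence per region and nothing about it changes with scale.

## Known limitations

* The coupling premise is fragile under attention shocks; chained
  projections compound any such break multiplicatively with horizon.
* RSVI is relative within its query window, so values from different
  Trends queries are not comparable; the package treats each series as one
  query's output and never mixes windows.
* No uncertainty quantification: the model is a point nowcast and the
  source study provides no interval construction. Resampling the
  synthetic generator is the supported route to sensitivity analysis.
* Yearly aggregation of monthly exports and the topic-vs-search-term
  choice in Trends are conventions of the data producer, not of the
  model; both tidy (pre-aggregated) and monthly inputs are accepted so
  either interpretation can be fed in.
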