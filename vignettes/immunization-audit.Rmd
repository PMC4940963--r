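---
title: "Auditing immunization coverage, timeliness and sequencing from vaccination cards"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing immunization coverage, timeliness and sequencing from vaccination cards}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vaxtiming)
```

## The audit model

`vaxtiming` treats a child's vaccination card as a set of dated dose events
and audits it against a schedule. Three families of per-child outcomes are
derived, all from whole-day age arithmetic (`date − date of birth`; no time
zones, dates compared as calendar dates):

**Full immunization (FIC).** A child is FIC when every dose of the FIC basis
(default: BCG, OPV1–3, pentavalent 1–3, measles — 8 doses) was received at an
age `≤ fic_cutoff` (365 days). Children with a complete card but at least one
basis dose after the cutoff form a separate *FIC-after-12-months* category;
children lacking doses entirely get a missing-dose profile (count and
labels). We equate 12 months with 365 days because the schedule itself is
expressed in days (42/70/98/274), so a day-based cutoff keeps every rule
independent of the calendar month in which a child happens to be born.

**Timeliness.** Each dose is exactly one of *early* / *timely* / *delayed* /
*missing*. With recommended age `r`, early margin `e` and delay margin `d`,
the timely window is `[max(0, r − e), r + d]`, closed on both ends: a dose is
early only when given *more than* `e` days before `r` and delayed only when
given *more than* `d` days after. Defaults: `e = 4` for every dose; `d = 14`
for BCG, polio, pentavalent and PCV and `d = 30` for measles. The "one month"
measles allowance is fixed at 30 days rather than a calendar month — a
calendar-month rule would make the classification depend on the child's date
of birth — and is configurable per dose. For measles an additional strict
indicator (`mv_early_strict`, more than 14 days early) is reported, since
early measles doses are the immunologically consequential ones.

**Sequencing.** Three rules, with "with" meaning the same calendar day
throughout (cards record dates, not times):

1. *Late BCG*: BCG given on/after any other recorded schedule dose.
2. *Pentavalent after measles*: any pentavalent dose on/after measles.
3. *Pentavalent/OPV split*: a pentavalent dose and its companion OPV dose
   (same series index) recorded on different days.

A child is **FIC-OS** when FIC *and* at least one rule fires; the quantity is
defined only among FIC children. Unrecorded doses never raise a flag, and by
default only doses received by the FIC cutoff enter the comparisons
(`os_scope = "all"` widens this for sensitivity analyses, since card events
after 12 months are retained at ingestion).

Two deliberate choices in rule 1:

- The polio birth dose (OPV0) is excluded from the comparison set. BCG and
  OPV0 are co-administered at birth by design, so including OPV0 would flag
  essentially every card with a birth polio dose; OPV0 is likewise outside
  the FIC basis and the companion pairing (it is still carried in the
  schedule for coverage reporting).
- The default comparison set is *all* other schedule doses (OPV, PCV and
  measles included). A narrower reading — BCG against pentavalent and measles
  only — is available as `bcg_rule = "penta_mv"`. The two differ only for the
  rare card on which BCG trails an OPV or PCV dose while preceding all
  pentavalent and measles doses; we default to the broader set because it is
  the stricter audit.

## Cohort ingestion and inclusion

Records arrive in long format (one row per dose or per interview visit) with
ISO-8601 dates; covariates in a separate per-child table. Ingestion enforces
a closed antigen vocabulary, rejects events dated before birth and
unparseable dates (collected row-by-row into an error report, never silently
dropped), and deduplicates `(child, antigen, date)`. Cards that record only a
series name without dose numbers are handled by numbering that family's dated
events chronologically 1..k — the only reproducible rule when dose numbers
are absent; the polio birth dose must therefore be labelled `OPV0` explicitly.

Inclusion mirrors card-verified survey practice: a child enters the analysis
at the *earliest* interview visit at which the card was seen and the child's
age lay in `[365, 730)` days (12–23 months, half-open so a 24-month visit is
out). The inclusion log partitions every exclusion into "no visit in the age
window" versus "window visits but card never seen", and the selected visit's
calendar year becomes `year_of_visit` for the coverage-by-year table — with
the usual caveat that coverage in visit-year *y* reflects vaccination one to
two years earlier.

## Statistical machinery

All estimators and tests are implemented in the package from first
principles; the `survival` package is used in the test suite only, as an
independent cross-check of the product-limit and log-rank computations.

- **Kaplan–Meier age-at-vaccination curves.** Reported as rising coverage,
  `1 − Ŝ(t)`. Children without the dose by the analysis horizon (365 days by
  default) are *administratively censored at the horizon*, as are doses
  recorded after it: this makes `coverage(365)` agree exactly with the
  coverage tables. Ties at a time are processed events-first, so censorings
  at an event time remain in the risk set.
- **Log-rank test** for equality of curves across g groups: hypergeometric
  expectation and covariance summed over event times, quadratic form on g−1
  groups, chi-square reference with g−1 df (singular covariance handled by a
  spectral pseudo-inverse).
- **Median/IQR** with linear interpolation between closest order statistics
  (R's default quantile type); table writers round half-up to whole days,
  full precision is kept internally.
- **Mood's median test**: pool, grand median, per-group counts above versus
  not-above (ties at the grand median count as "not above"), Pearson
  chi-square on the 2×g table. A degenerate table (all pooled values on one
  side) returns p = 1 with an explanatory note rather than an error.
- **Pearson chi-square of independence**: no continuity correction, warning
  (not error) when an expected cell is below 5, error on a zero margin.

One operating-characteristics subtlety: for a 2×2 median test on equal arms
the null distribution of the above-count is hypergeometric, so the test's
exact size oscillates with arm size (e.g. 0.071 at 50/arm but 0.0497 at
75/arm). The size-calibration check in the test suite therefore evaluates
both tests at 75 observations per arm, where the chi-square approximation is
well calibrated; this is a property of the discrete 2×2 statistic, not of the
implementation.

## Reporting conventions

Every table cell stores numerator and denominator and recomputes its
percentage (half-up, one decimal) on the way out, so cells are
self-consistent by construction; pooled columns are computed from pooled
counts, never by averaging yearly percentages. Missing covariate values form
an explicit `"(missing)"` stratum excluded from chi-square tests. For
antigens with a rollout date (PCV, February 2011) the denominator is
restricted to children whose analysis visit fell in or after the rollout
year and such cells are absent for earlier years; this eligibility rule is a
package convention (documented, configurable through the schedule's
`rollout_dates`) — card studies rarely state theirs.

## The synthetic cohort generator

The generator (`sim_config()`, `generate_cohort()`) emulates the statistical
structure the audit assumes, not any particular child:

- births uniform over a multi-year window; interview visits every 122 days
  (~4 months) from a random offset, so every child has visits in the 12–23
  month window; card availability is a per-child Bernoulli (default 0.38),
  which makes the included fraction track `card_seen_prob` directly;
- birth doses (BCG, with OPV0 riding along), three infant immunization
  contacts with chained attendance (missing contact k forfeits k+1), per-
  contact administration probabilities per antigen, and a 9-month measles
  contact whose receipt probability depends on third-contact attendance —
  this dependence is what produces the realistic gap between the product of
  marginal coverages and the FIC rate;
- whole-day delays from zero-inflated discretized gamma distributions, with
  contact dates accumulating under a 28-day minimum inter-dose gap; a small
  probability of early administration;
- explicit sequencing mechanisms: per-pair pentavalent/OPV splits (OPV
  drifting 1–7 days late), BCG deferral to the first infant contact, and
  dose-3 catch-up at the measles contact (which yields
  pentavalent-with-measles events without creating artificial splits);
- PCV offered only at contacts on/after the rollout date;
- centered log-odds covariate effects (site, education, wealth, postnatal
  care) on third-contact attendance and measles receipt, reproducing the
  direction — not the exact size — of typical urban-settlement gradients.

`generate_cohort()` returns latent truth alongside the cohort: per-dose
intended ages and the generator's own FIC/sequencing labels computed by
straight-line logic independent of the classification engine.
`recover_parameters()` closes the loop, comparing pipeline estimates with
truth (estimate, truth, Monte-Carlo SE, z-score per quantity).

**Calibration.** `default_study_like_config()` was calibrated once and
frozen: receipt and attendance probabilities follow directly from headline
coverage targets by closed-form algebra (e.g. third-contact attendance ≈
OPV3 coverage / per-contact administration probability), and the delay
distributions were tuned numerically against their median/IQR and
past-the-horizon tail targets (measles needs ~5–6 % of received doses past
365 days to separate "received" from "covered at 12 months"). Large cohorts
from this config land within about ±3 percentage points of the intended
headline rates — FIC ≈ 66.6 %, measles ≈ 81.1 %, OPV3 ≈ 85.8 % with median
age 107 days among FIC, pentavalent/OPV split ≈ 18.2 % of FIC — which the
acceptance suite verifies at n = 20,000.

**What a green test does not establish.** The generator is a structural
emulation: real card data have day-heaping (doses recorded on Mondays or
round dates), transcription errors, duplicate cards, catch-up campaigns, and
covariate-dependent delay shapes that the default config does not model.
Green pipeline tests establish that the audit logic is correct and that
estimates recover the generator's truth — not that any particular real
cohort will match the calibrated rates.

## Degenerate inputs and edge conventions

- A dose exactly at the cutoff (day 365) counts as received by 12 months;
  day 366 does not.
- Windows floor at age 0 (BCG's timely window is `[0, 14]`).
- An empty age-sample set is an error for the KM estimator; a sample with no
  events yields coverage identically 0.
- `missing_profile()` refuses FIC children (contract violation, not NA).
- Schedule validation names the offending dose and field: duplicate labels,
  non-monotone series ages, asymmetric companion links and negative margins
  are all rejected at construction, so downstream code never sees an invalid
  schedule.

## Limitations

- Recall-based (mother-reported) histories are out of scope; the audit is
  card-only by design.
- Wealth and other covariates are consumed as given labels; no index
  construction.
- KM confidence bands (Greenwood) and determinant regression models are not
  provided.
- Chi-square p-values come from the asymptotic distribution; there is no
  exact or Monte-Carlo option, hence the explicit small-cell warning.
- The schedule file dialect is JSON; YAML is not supported in this build.
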