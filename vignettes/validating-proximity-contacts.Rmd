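---
title: "Validating proximity-sensor contact data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating proximity-sensor contact data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactvalid)
```

## The measurement problem

Wearable proximity badges (active RFID tags worn at chest height) record
face-to-face contacts as time-stamped dyadic intervals. The raw signal is
imperfect in systematic ways: a single continuous conversation is often
fragmented into several short on-intervals separated by gaps
("flickering", as the wearers' bodies rotate out of the badges' narrow
detection angle); in larger conversation groups some pairs are missed
outright; occasional spurious contacts are recorded between people who
merely stand near each other; and badge software typically reports no
duration below 10 s. `contactvalid` provides the machinery to quantify
how much these distortions matter and how much standard cleaning
strategies repair them:

* **construct validity** — second-by-second agreement with a ground-truth
  coding of the same event (e.g. video), summarized by sensitivity,
  specificity and accuracy over all dyad-seconds;
* **criterion validity** — association of aggregated contact minutes with
  self-reported interaction nominations, via logistic models.

## Data model

An event log is a tibble of intervals `(id_a, id_b, start, end)` with a
roster and a half-open observation window `[t0, t1)`. Internal times are
integer seconds: one second is the analysis resolution at which validity
is assessed, even where hardware timestamps are finer. Intervals are
half-open, so `duration = end - start`, durations are additive, and two
records that abut (`end == next start`) are indistinguishable from one
continuous signal and are merged during normalization. Normalization also
canonicalizes each dyad (lower identifier first) and merges overlapping
same-dyad records, so every analysis sees each dyad's timeline as a
disjoint union of maximal intervals.

`rasterize()` converts a log to the D × S binary dyad-second matrix
(D = N(N−1)/2 dyads, S seconds) on which all validity metrics are
defined; `events_from_raster()` inverts it exactly, and this round trip
is property-tested. Clock-time input (`HH:MM:SS`) is parsed as seconds of
day; recordings that cross midnight must carry explicit dates, otherwise
parsing fails rather than guessing.

## The three cleaning strategies

* `filter_min_duration(log, c)` deletes events **strictly** shorter than
  `c` seconds ("shorter than" is a strict inequality; an event of exactly
  `c` seconds survives).
* `interpolate_gaps(log, g)` merges same-dyad events separated by at most
  `g` seconds (**inclusive**: a gap of exactly `g` merges). Merging is
  transitive along chains in one pass over start-sorted events, which
  makes the operation idempotent and equivalent to filling every
  flanked zero-run of length ≤ `g` in the dyad-second raster — the
  second-level semantics the oracle tests enforce.
* `close_triads(log, k)` performs `k` iterations of triadic closure: if A
  is in contact with both B and C during a second, B–C is imputed for
  that second. Updates within an iteration are synchronous (computed from
  the pre-iteration state), so the result is independent of any update
  order; iterating reaches the per-second connected-component clique
  fixpoint in at most ⌈log₂ N⌉ iterations. The implementation works on
  maximal constant-activity segments rather than single seconds — the
  per-second contact graph only changes at event boundaries — which makes
  it exact (equality with a per-second brute force is tested) and fast on
  long windows.

Order matters when composing steps: deleting short fragments before
interpolating can destroy exactly the fragments interpolation would have
stitched into long contacts. `apply_pipeline()` therefore applies an
ordered step list and records it as provenance. For the combined
strategy the package defaults to interpolation (75 s) followed by
minimal-duration deletion at 55 s, with the 50 s variant reachable
through configuration: published recommendations state both values in
different places, and we surface rather than hide that ambiguity.

## Validity metrics

With ground truth V and observation R rasterized over identical dyads
and seconds, `confusion_counts()` tallies TP (both 1), FP (R only),
FN (V only), TN (neither); the four counts always sum to D × S.
`validity_metrics()` derives

* sensitivity = TP / (TP + FN),
* specificity = TN / (TN + FP),
* accuracy = (TP + TN) / (TP + FP + FN + TN),
* and their sum of sensitivity and specificity as the alternative
  criterion.

Accuracy weights every dyad-second equally and is the default criterion
optimized by `sweep_strategy()`; the sensitivity+specificity sum is
selectable for robustness analyses. Percentages are reported at one
decimal; internal values are never rounded. Cohen's κ
(`cohens_kappa()`) quantifies chance-corrected agreement between two
binary coders and is computed here on dyad-second indicators, the same
unit as the other indices; when the marginals make agreement certain,
perfect agreement is reported as κ = 1 by convention.

A note on definitions: one published account of this validation design
prints sensitivity as TP/(TP+TN) and specificity as TN/(TN+FN) in its
running text while reporting numeric values that only the standard
TP/(TP+FN) and TN/(TN+FP) reproduce. This package implements the
standard definitions.

## Criterion-validity stage

`aggregate_minutes()` collapses a log to the symmetric matrix of contact
minutes. Nominations are directed (row nominates column);
`symmetrize()` provides the weak (either reports) and strong (both
report) undirected variants, and `reciprocity()` the fraction of
directed ties that are returned. `duration_by_nomination_test()` is a
pooled-variance Student t test (the integer degrees of freedom
convention) with Cohen's d from the pooled SD.
`fit_duration_logit()` fits nominations on minutes by maximum-likelihood
logistic regression; the default unit is the directed dyad (all N(N−1)
ordered pairs, the undirected duration entering both directions), with
listwise deletion of rows whose nominator did not respond. Fit quality
is summarized by McFadden's pseudo-R² = 1 − ℓ/ℓ₀. `compare_fits()`
reports 2|ℓₐ − ℓᵦ| as a *descriptive* deviance difference with a
caller-supplied reference df (conventionally 2), not as a formal nested
likelihood-ratio test: models fit to differently processed duration
matrices are not nested.

## The synthetic world

No public dataset pairs badge output with a ground-truth coding, so the
package ships a generative stand-in with known parameters
(`make_world()`), built from four seeded components.

**Truth** (`simulate_truth()`): a discrete-time group-conversation
process. Each participant is solo or in exactly one conversation group;
each second each participant reconsiders their position with probability
`switch_rate`, going solo with probability `solo_prob` or else joining a
uniformly chosen other participant's group subject to `max_group`.
Group co-membership is pairwise-complete, so per-second truth graphs are
unions of cliques and triadic closure leaves truth invariant — a key
differential test against flickered observations.

Defaults (11 participants, 4602 s, `switch_rate = 0.02`,
`solo_prob = 0.15`, `max_group = 5`) were fixed once, by design, to
reproduce the descriptive regime reported for small stand-up social
events: roughly 20% of dyad-seconds spent in interaction, observed event
durations averaging ~25 s with ~1500 events per session, and same-dyad
re-engagement gaps (median ~100 s) sitting well above the seconds-scale
flicker gaps. That last separation is what gives gap interpolation a
finite optimum: bridging gaps at the flicker scale recovers true contact
time, while bridging much longer gaps starts pasting over genuine
absences.

**Sensor** (`observe()`): within each true interaction the signal follows
a two-state Markov (geometric on/off renewal) process with mean on-run
`on_mean_s = 50` and mean gap `off_mean_s = 20` — echoing the canonical
description of one 5-minute conversation recorded as a handful of ~50 s
signals. In a group of size k the re-detection hazard is multiplied by
`group_decay^(k-2)` (default 0.9), so dyads embedded in larger groups
have longer gaps and lower coverage; this is the "on-probability decays
with group size" mechanism, implemented on the hazard so that the gap
scale remains anchored to `off_mean_s`. False positives arise between
members of distinct co-existing groups at `fp_rate` (default 10⁻⁴) per
eligible dyad-second. Finally, events shorter than 10 s are reported at
10 s when `round_min_duration` is on, mimicking badge firmware.

**Raters** (`simulate_raters()`): two independent perturbations of truth
(event misses at 5%, boundary jitter SD 3 s by default), for exercising
κ and the split-time merging of doubly-coded material.

**Self-reports** (`generate_self_reports()`): directed nominations drawn
independently with probability `plogis(intercept + slope × minutes)`;
the defaults (−2.16, 0.02/min) are the published logistic estimates for
this design, used here as generating values so that refitting is a
genuine parameter-recovery exercise.

All component seeds derive from one master seed by a stable hash of the
component name, so adding a component never perturbs existing streams.

### What the generator does and does not emulate

It reproduces the qualitative structure the cleaning analysis assumes:
clique-structured group truth, seconds-scale flicker against
minutes-scale absences, group-size-dependent missingness, rare false
positives, the 10-s reporting floor, noisy raters, duration-driven
reports. It does **not** reproduce heavy-tailed duration distributions
beyond geometric mixing, spatial or room structure, badge-angle physics,
circadian or multi-day rhythms, or recall biases in self-reports.
Passing tests on synthetic worlds therefore demonstrate correctness of
the algorithms and recoverability of known parameters under these
assumptions — not that any particular sensor deployment is valid.

## Numerical and design choices

* Sample SDs (n−1 denominator) throughout.
* Aggregated dyadic duration statistics are computed over dyads with
  nonzero contact by default (`include_zero_dyads = FALSE`), the share
  of silent dyads being a separate descriptive.
* Sweep grids default to 0–150 s in 15 s steps for cutoffs and 0–4 for
  closure iterations; ties in the criterion break toward the smallest
  parameter value.
* Undefined ratios (empty truth-positive or truth-negative margins) are
  `NA`, never silently 0; an all-zero confusion table is an error.
* Degenerate predictors (constant duration) fall back to an
  intercept-only logistic fit and are flagged; perfect separation raises
  an explicit error.
* Normalization always precedes processing; all cleaning steps preserve
  the roster and window and never touch the truth log.

## Problem sizes

The test suite and the acceptance script run study-scale problems: 11
participants × 76.7 min (253,110 dyad-seconds) per synthetic world, 10
worlds per sweep-recovery experiment, and 55-participant (2,970 directed
dyads) criterion-validity fits. Oracle-equivalence checks run on 200
random small instances (≤ 6 participants, ≤ 120 s) where per-second
brute force is exact and cheap. These sizes were chosen to match the
validation designs the package addresses.

## Known limitations

* The event-log representation is dense in dyads at rasterization time
  (D × S integers); week-long recordings with hundreds of participants
  should be validated window-by-window.
* κ is computed at the dyad-second level; per-event agreement
  conventions would give different values and are not implemented.
* `compare_fits()` deliberately stops short of a formal model-selection
  test for non-nested predictors.
* The truth process is Markovian and stationary after burn-in; scheduled
  collective events (talks, meals) that synchronize whole rooms are out
  of scope.

## A worked example

```{r example, eval = FALSE}
library(contactvalid)

w <- make_world(seed = 7)                      # truth + flickered observation
validate_contacts(w$observed, w$truth,
                  list(step_interpolate(30)))  # raw vs processed fit

sw <- sweep_strategy(w$observed, w$truth, "interpolate", seq(0, 150, 15))
attr(sw, "optimum")                            # recovered flicker-gap scale
autoplot(sw, baseline = sw$accuracy[sw$value == 0])

x <- aggregate_minutes(w$observed)
y <- generate_self_reports(x, seed = 8)
fit <- fit_duration_logit(x, y)
tidy(fit); glance(fit)
```
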