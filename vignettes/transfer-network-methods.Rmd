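---
title: "Methods: interhospital transfer networks for emergency general surgery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interhospital transfer networks for emergency general surgery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(egsnet)
```

## Overview

`egsnet` implements an end-to-end observational workflow: starting from an
encounter-level claims extract, it links encounters into episodes of care,
extracts interhospital transfers, builds weighted directed transfer networks,
computes normalized degree centralities, constructs risk-adjusted hospital
outcome measures, and relates network position to hospital characteristics
with ANOVA and cluster-robust regression. Because real claims cannot be
shipped, the package also contains a synthetic claims generator with known
ground truth; every statistical component is validated against that truth or
against independent hand-coded oracles.

## Episode linkage

Encounters for one patient are sorted by admission date, discharge date, and
hospital. Two consecutive encounters are *temporally adjacent* when the second
admission falls on the same day as, or the day after, the first discharge.
Maximal runs of adjacent encounters form an *episode of care*. A transfer is
recorded for each adjacent cross-hospital pair whose downstream portion of the
episode reaches an inpatient encounter; an emergency-department (ED) visit
followed the next day by an ED visit elsewhere with no subsequent admission is
not a transfer. The transfer is typed by the origin setting — `ED-IP` when the
patient left from an ED, `IP-IP` when from an inpatient stay — so an
ED&nbsp;→&nbsp;ED&nbsp;→&nbsp;IP chain counts as one ED-IP and, if the second
hospital differs from the third, one IP-IP transfer.

An episode is an emergency general surgery (EGS) episode when any *inpatient*
encounter in it carries an EGS diagnosis code; ED-only diagnoses do not
qualify. The analysis cohort keeps EGS episodes with at least one transfer and
patient age ≥ 18, and reports a tally of exclusions (`not_egs`,
`no_transfer`, `under_age`).

One generator subtlety matters here: when a transfer happens on the admission
day itself, the destination stay is given a length of stay of at least one
day. Otherwise both encounters would carry identical date ranges and the
direction of the transfer would be unrecoverable from the claims alone — a
property linkage cannot and should not invent.

## Networks and centrality

Transfers aggregate into a weighted directed network (edge weight = number of
transferred patients origin → destination; self-loops are impossible by
construction). Five networks are built: `all`, the type partition
`ed_ip`/`ip_ip`, and the operation partition `op`/`no_op` (whether an
operating-room procedure occurred anywhere in the episode). The two partitions
each sum exactly to the `all` network — a tested invariant.

For hospital $i$ in a network with $n$ nodes and maximum edge weight
$W_{\max}$, the scaled weighted degree centralities are

$$
C^{in}_i = \frac{\sum_j w_{ji}}{(n-1)\,W_{\max}} \times 10{,}000,
\qquad
C^{out}_i = \frac{\sum_j w_{ij}}{(n-1)\,W_{\max}} \times 10{,}000 .
$$

A binary convention (distinct partners / $(n-1) \times 10{,}000$) is also
provided. The weighted convention is the default: on transfer networks of
several hundred hospitals, typical scaled medians in the tens-to-hundreds
arise only under weight-based normalization, because a few high-volume
corridors set $W_{\max}$ far above the typical edge; a distinct-partner
normalization on the same networks would sit much higher.

The *centrality ratio* $C^{in}_i / C^{out}_i$ summarizes whether a hospital
predominantly receives (ratio > 1) or sends (ratio < 1). It is undefined when
$C^{out}_i = 0$ and zero when $C^{in}_i = 0$; both cases are excluded from the
log scale and tallied, rather than patched with a pseudocount, because a
pseudocount would manufacture extreme ratios exactly at the hospitals where
the data say least. (`log_transform_ratios()` accepts an `epsilon` for users
who prefer a pseudocount.) The natural logarithm is used so that sending and
receiving are symmetric around 0.

## Risk adjustment and hospital outcomes

Episode-level comorbidity is a weighted sum over *distinct* comorbidity
categories mapped from diagnosis codes (an Elixhauser-style index; the
category map and weights are a replaceable JSON input). Logistic models for
in-hospital death and for failure to rescue (FTR: death among operated
episodes that had a complication; episodes without an operation or without a
complication are excluded from the FTR denominator) adjust for linear age,
sex, the comorbidity index, and EGS diagnosis-category indicators — no
operation term, since operation is part of the FTR definition. Hospital rates
are indirectly standardized: observed/expected × overall rate. EGS volume
counts a hospital's non-transferred inpatient EGS episodes. Volume, adjusted
mortality, and adjusted FTR are cut into quartiles at type-7 sample quartiles,
Q1 lowest, ties assigned to the lower quartile.

## Inference

Hospital characteristics form eight blocks: bed size (<100, 100–250, >250),
ICU beds (0–10, 11–25, >25), teaching status, trauma level, surgical
fellowship, and the three outcome quartiles. For each block a one-way ANOVA
on the log centrality ratio is followed by Tukey HSD pairwise contrasts
(hand-computed from the studentized range distribution; verified to match
`stats::TukeyHSD`). The joint model is OLS of the log ratio on all blocks
with state-clustered standard errors in the Stata convention — HC1-type
cluster sandwich with small-sample factor $\frac{G}{G-1}\cdot\frac{N-1}{N-K}$,
$t$ statistics on $G-1$ degrees of freedom — and a Wald partial $F$ per
block. The same specification is rerun on the four subnetworks as a
sensitivity analysis; frames that cannot support the model produce structured
skip records instead of errors.

## The synthetic generator as a testbed

Generator defaults are the study conditions and were fixed once, before any
test was run:

* 100 hospitals in 8 states, 10,000 patients, uniformly allocated to home
  hospitals. Uniform allocation means hospital volume carries no planted
  signal, so volume-quartile terms have a clean null — used to check
  confidence-interval calibration.
* Transfer destinations are drawn with probability proportional to
  $\exp(\text{strength} \times \text{resource score})$, where the resource
  score loads on log beds and log ICU beds with noise. Strength 1 plants the
  "transfers flow toward resource-rich hospitals" effect; strength 0 is the
  null arm.
* `complication_death_effect = 1.0` couples complications to subsequent
  death, which is what gives failure to rescue a signal to detect. The
  baseline death log-odds is `qlogis(0.05)`: with every covariate effect
  nulled the pooled crude mortality is 5%, and that is the configuration the
  calibration test checks. With the default effects switched on the synthetic
  cohort is deliberately high-acuity — the Elixhauser-style weights (up to 7
  per category) times `comorbidity_effect = 0.2` shift many episodes' risk
  substantially, so the default world's crude EGS mortality is roughly 0.27.
  The inferential machinery never depends on the level of that rate.
* Hospital quality effects (`quality_effect_sd = 0.3`) perturb death risk;
  setting the sd to 0 gives the homogeneous-hospital null used to test that
  adjusted-rate dispersion collapses to the binomial sampling floor.

## Validation strategy and problem sizes

The acceptance tests exercise, at minimum: exact recovery of planted
transfers on 5,000 patients; centrality against a brute-force oracle on 200
random graphs at 1e-12; risk-coefficient recovery within 3 standard errors at
20,000 episodes; adjusted-rate dispersion within 25% of the binomial
prediction at 50 × 200 episodes; Spearman correlation > 0.6 between adjusted
mortality and planted quality spanning ±0.5 log-odds; ANOVA type-I error in
[3.5%, 6.5%] over 1,000 null replicates; the clustered sandwich against a
hand-coded oracle at 1e-10; ≥ 90% power for the planted resource effect and
near-nominal coverage under the null across 50 replicates of a 400-hospital,
40,000-patient world; and byte-identical pipeline outputs under a repeated
seed.

## Limitations

The generator is a stylized claims process: lengths of stay are short and
geometric-like, diagnosis codes are synthetic stand-ins, and state is the only
geographic structure, so clustered standard errors are conservative rather
than realistic. The FTR model shares the death model's covariates; in real
data complication ascertainment would itself need validation. Centrality
scaling follows one published convention; comparisons across networks of very
different size should use the raw weights also written by the pipeline.
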