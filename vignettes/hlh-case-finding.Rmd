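---
title: "Case finding for secondary HLH in hyperferritinaemic cohorts: methods and modelling choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Case finding for secondary HLH: methods and modelling choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hlhscreen)
```

Secondary haemophagocytic lymphohistiocytosis (sHLH) is a hyperinflammatory
syndrome — over-activated cytotoxic T cells and histiocytes driving cytokine
storm and multi-organ failure — that is treatable but frequently missed,
because its features (fever, cytopaenias, hyperferritinaemia, organomegaly,
coagulopathy) all overlap with commoner critical illness. A practical
case-finding strategy starts from extreme serum ferritin, which laboratories
already flag: pull every patient whose peak ferritin exceeded a threshold
(here 5,000 ug/L), score each against established diagnostic criteria, and
ask how many probable cases the clinicians never labelled. `hlhscreen`
implements that pipeline end to end, together with the statistics such an
audit reports and a synthetic cohort generator that makes every stage
testable without patient-identifiable data.

## The cohort data model

A cohort is a data frame with one row per patient (`patient_record()`,
`hlh_cohort()`, `read_cohort()`/`write_cohort()`). Two representation
choices matter scientifically:

* **Censored ferritin.** The ferritin assay reports results above its upper
  limit of quantification (16,500 ug/L) only as ">16,500". We store the
  pair (value, censored flag), with the value *at* the ceiling, survival-data
  style. Under the default `"ceiling"` policy (`numeric_ferritin()`) a
  censored result contributes 16,500 to means and comparisons. This
  necessarily *understates* the true mean of a group containing censored
  values; the alternative `"exclude"` policy is available but discards most
  of the sickest patients. On read, a `">"`-prefixed or at-ceiling cell
  becomes a censored value; thousands separators are stripped.

* **Missing is not "no".** In a retrospective notes review, most absent
  laboratory results were simply never requested (in the motivating audit:
  triglycerides available for 20/120 patients, fibrinogen 78/120, AST
  5/120). Clinical flags and labs are therefore tri-state
  (`TRUE`/`FALSE`/`NA`), and each scoring engine decides explicitly what
  `NA` means under its policy object.

When a patient has several qualifying presentations,
`select_peak_presentation()` keeps the row with the maximal ferritin
(censored values compare as the ceiling), breaking ties by input order —
deterministic and order-stable; the source audit did not state its
tie-breaking rule.

## The HScore engine

`hscore()` computes the nine-component weighted score: temperature band
(0/33/49), hepato-/splenomegaly (0/23/38), immunosuppression (0/18),
ferritin (<2,000: 0; 2,000–6,000: 35; >6,000: 50), cytopaenic lineages
(haemoglobin ≤ 90 g/L, platelets ≤ 100×10⁹/L, neutrophils ≤ 1×10⁹/L;
≤1 lineage: 0; 2: 24; 3: 34), triglycerides (<1.5: 0; 1.5–4: 44; >4: 64
mmol/L), fibrinogen (<2.5 g/L: 30), transaminases (19) and
haemophagocytosis (35). Totals range over exactly [0, 337]; the unit tests
verify the engine against a brute-force enumeration of all 5,832
component-band combinations.

Three policy choices (`hscore_policy()`) replicate the audit setting and
deserve scrutiny before reuse elsewhere:

* **Documented fever scores 33.** Ward charts rarely survive into coded
  records, so when only a binary "fever documented" flag exists, a
  documented fever scores the middle band (33), never 49. With recorded
  temperatures the full 0/33/49 banding applies, with 38.4 °C scoring 33
  and 39.4 °C scoring 49 (the published banding overlaps at 38.4; we
  resolve the boundary upward and make it configurable).
* **Missing inputs score 0.** The only policy under which incomplete
  retrospective records remain scoreable; it biases totals *downward*, so
  positive counts from sparse records are conservative. A strict
  `missing = "error"` policy is available.
* **ALT substitution.** The transaminase component uses AST ≥ 30 U/L; when
  no AST result exists, ALT ≥ 100 U/L substitutes (ALT is essentially
  always measured). An available AST always takes precedence.

Positivity defaults to total ≥ 169; the original description says "scores
> 169", and both are selectable — the distinction is untestable on the
published patients, whose lowest positive total is 174.
`probability_band()` maps totals to the published probability-of-sHLH
labels ("54" … ">99") through a calibration table shipped as YAML. Only the
published (score, band) pairs anchor that table; boundaries between anchors
are interpolated at midpoints and flagged `interpolated_upper`, and scores
outside the anchored range clamp to the extreme bands.

## The revised HLH-2004 engine

`hlh04()` evaluates the eight-criterion checklist (fever; splenomegaly;
ferritin ≥ 500 ug/L; bicytopaenia; triglycerides ≥ 3 mmol/L *or* fibrinogen
≤ 1.5 g/L, jointly worth one point; haemophagocytosis; low NK-cell
activity; sCD25 ≥ 2,400 U/mL), positive at ≥ 5/8. Boundary values qualify,
matching the printed "≥"/"≤" inequalities. Under the default
missing-as-unmet policy, a cohort in which NK activity and sCD25 were never
assayed has an effective ceiling of 6/8 — the audit's own situation, and
the reason its HLH-2004 counts should be read as lower bounds. Whether the
source audit scored out of 8 or out of the 6 obtainable criteria is not
stated; our default (out of 8, missing = unmet) is an assumption the policy
object makes explicit. `compare_scoring_systems()` cross-tabulates the two
engines and lists discordant patients.

## Screening rules and their evaluation

`screening_rule()` builds conjunctions of: ferritin **strictly** above a
cutoff, documented fever, platelets strictly below a cutoff.
`evaluate_rule()` crosses rule outcomes with a reference standard into a
confusion matrix with sensitivity, specificity and Youden index;
`rule_grid()` sweeps cutoff combinations, sorted by Youden index (ties to
the lower, more sensitive, ferritin cutoff — a screening tool's priority).

The default reference standard is HLH-2004 positivity. The choice is
deliberate: the audit's printed screening sensitivities (94.1%, 82.4%)
equal 16/17 and 14/17 against its 17 HLH-2004 positives, whereas its
feature table (12/14 febrile HScore-positives) is arithmetically
incompatible with an HScore reference for a 100%-sensitive fever rule. The
reference is configurable (`"hscore"`, `"clinician"`, or an explicit label
vector such as generator truth). Missing predicate inputs default to "rule
not satisfied" (conservative for specificity claims); an
exclude-the-patient policy is available, and the printed specificities of
the source audit (68.3%, 59.6%, 81.6%, 72.7%) cannot be reconstructed as
integer fractions of its evaluable negatives under either policy — its
denominators were evidently affected by undocumented missing-data handling,
so we do not treat those four values as exact.

Percentages display rounded half-up to one decimal (`round_half_up()`):
16/17 prints as 94.1%, and 94.15 as 94.2 rather than banker's-rounding to
94.1.

## Replication statistics

The audit's statistics are deliberately simple, and we reproduce them
exactly rather than substituting better ones:

* `chi_squared_2x2()` — Pearson's statistic without continuity correction,
  1 df. No minimum-expected-count refusal: two of the published rows have
  expected cells below 5 and were evidently tested anyway; we warn instead.
  All eleven published statistics (12.6515 … 3.639) reproduce to printed
  precision from the published counts only when the correction is omitted,
  which is how the convention was identified. Fisher's exact test is
  offered as an explicitly non-replicating alternative.
* `mann_whitney_u()` — U from rank sums with midranks, z from the
  tie-corrected normal approximation without continuity correction, two
  tailed, signed so that z < 0 when the first (below-cutoff) group is
  stochastically smaller. Verified against an exhaustive pairwise-count
  oracle for all sample-size pairs up to 8, and against
  `stats::wilcox.test(correct = FALSE)` p-values.
* `population_z_ci()` — mean ± z·σ/√n with the **population**
  (divide-by-n) SD. With the 14 published positive-group ferritins
  (censored at the ceiling) this reproduces the printed mean 14,706 and
  interval 12,930–16,482 exactly — but only if the mean is rounded to the
  nearest integer *before* the bounds are formed, which is therefore the
  display policy (`$display`); the unrounded interval is kept alongside.
  A t-interval with the sample SD would be wider and is out of scope: the
  aim is replication, not improvement.

`build_table3()` reassembles the full group-comparison table (Mann-Whitney
on ferritin, chi-squared on eleven binary features) from any cohort, with
missing features counted as absent so that group denominators are the full
group sizes — the audit's own convention.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions so that the entire
pipeline is exercisable without any patient data: n = 120, a latent
positive fraction of 14/120, per-group binary feature rates equal to the
published group proportions (e.g. fever 37/106 vs 12/14), and laboratory
availability matching the audit's request rates (triglycerides 20/120,
fibrinogen 78/120, AST 5/120; ALT always present; NK activity and sCD25
never). Temperatures are always missing — only the documented-fever flag
exists, as in the audit.

Peak ferritin is log-normal per latent group, truncated below at the
5,000 ug/L inclusion floor (inverse-CDF sampling, so every draw qualifies)
and censored at the 16,500 ug/L ceiling. The parameters (negatives:
meanlog 8.82, sdlog 0.55; positives: meanlog 10.0, sdlog 0.75) were chosen
once, by numerical integration of the truncated-censored mean, to match the
published group means (~9,260 and ~14,706 ug/L) and a positive-group
censoring fraction near the published 10/14; they are configuration, not
fitted values. Masked labs are revealed with a residual probability chosen
so overall availability matches the target while every *qualifying* result
stays observed — the only way a retrospective count can have seen it.

Limitations to keep in mind when interpreting green tests: features are
drawn independently within group (only marginal rates were published), so
the generator understates the clustering of fever, cytopaenias and extreme
ferritin in real sHLH; ferritin is unimodal log-normal per group; and
latent "positive" is the generative label, not a clinical diagnosis.
Passing recovery tests therefore demonstrates internal consistency of the
pipeline under the published marginals, not external validity of any
screening rule. A single seed drives one generator stream, so a cohort is
a deterministic, byte-stable function of (configuration, seed).

## Problem sizes used in the tests

The test suite enumerates all 5,832 HScore band combinations and all 256
HLH-2004 criterion patterns exactly; rank-test oracles cover all sample
sizes up to 8 per group; the chi-squared type-I-error simulation uses
10,000 null tables of 100 patients per group; and screening recovery uses
replicate synthetic cohorts of n = 10,000 (twelve replicates, each
operating point checked against its binomial 95% bound, with the number of
bound misses itself tested at its binomial tolerance — a nominal-95%
interval is *expected* to miss 5% of the time). These sizes give sampling
errors well below the effects being checked while keeping the default
suite quick.

## Known limitations

* The probability-band table is anchored only at the published pairs;
  between anchors the boundaries are interpolations, clearly flagged.
* The audit's Mann-Whitney z (−3.95719) and its HLH-2004-positive group
  mean are not reproducible from published data (the 106 below-cutoff
  patient records were never printed) and are deliberately not targets.
* Scoring engines replicate retrospective-audit policies; none of this is
  diagnostic software, and the missing-data defaults are wrong for a
  prospective setting where tests can simply be ordered.
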