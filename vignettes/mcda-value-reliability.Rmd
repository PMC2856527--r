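---
title: "The MCDA value model and its test-retest reliability suite"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The MCDA value model and its test-retest reliability suite}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evidemr)
```

## The decision problem

Health technology appraisal asks a committee to integrate heterogeneous
considerations — how good the evidence is, how severe the disease, how
large the clinical benefit, what it costs — into one judgment. `evidemr`
implements the EVIDEM approach: the quantifiable considerations form a
Value Matrix of 15 intrinsic components in four clusters (quality of
evidence Q, disease impact D, intervention I, economics E), while six
extrinsic components (an ethical framework of utility, efficiency and
fairness, plus system capacity/appropriate use, stakeholder pressures and
political/historical context) are deliberated qualitatively and never
folded into the number. The deliberate split reflects the framework's
purpose: the value estimate organizes and exposes judgments, it does not
replace them, so nothing in this package adjusts the MCDA estimate from
extrinsic records.

## The linear additive value model

Each panelist supplies integer weights $w_i \in \{1,\dots,5\}$ — the
importance of component $i$, elicited independently of any intervention
and from a societal perspective — and integer scores
$s_i \in \{0,\dots,3\}$ rating the intervention against each component's
anchors. With $I$ the set of components the panelist scored,

$$V = \sum_{i \in I} \tilde w_i\, s_i, \qquad
  \tilde w_i = \frac{w_i}{\sum_{k \in I} w_k},$$

so $V$ lives on the scoring scale: an intervention scoring 3 everywhere
attains $V = 3$ for any weight profile, and multiplying all of a
panelist's weights by a constant changes nothing. $V$ is also reported as
an integer percent of the scale maximum, and decomposed into component
shares $100\,\tilde w_i s_i / V$ and their cluster sums.

Assumptions worth stating: the model is additive with no interactions
between components; weights are treated as ratio-scaled importances (a
weight of 4 counts twice a weight of 2 after normalization); and the
per-panelist estimate is the unit of analysis — the panel-level result is
the mean of individual estimates with sample ($n-1$) SD, minimum and
maximum, not the estimate of averaged inputs, because between-panelist
spread in values is part of what the instrument measures.

**Not-applicable components.** A case evaluation may leave a component
unscoreable (the bundled illustrative case marks Q1, adherence to the
requirements of a decisionmaking body, not applicable). Such components
are excluded from both the score sum and the normalization denominator —
keeping $V$ on the 0–3 scale without penalty — while their elicited
weights are retained, so weight reliability uses all 15 components (120
pairs for 8 panelists) and score reliability the remaining 14 (112
pairs). Applicability is a per-case override (`mark_not_applicable()`),
never a mutation of the shipped framework.

**Degenerate inputs.** An all-zero score vector gives $V = 0$;
contribution shares are then undefined and are reported as zeros with a
`degenerate` flag and a warning rather than dividing by zero. A zero or
empty normalization set is rejected: on a 1–5 weight scale a zero sum can
only arise from malformed input, and silent fallback to uniform weights
would misreport a panelist's values.

## Rounding

Every printed percent (percent-of-max, agreement percentages, extrinsic
tally fractions) is rounded half away from zero to an integer —
`percent_of_max(1.15, f)` is 38, not 38.33 truncated — while the
underlying reals are retained in the objects. On a 0–3 scale, percent of
maximum is $100\,V/3$; the package applies this single convention
throughout.

## Test-retest reliability

Because the tool elicits personal values, between-rater agreement is not
a meaningful validity criterion; stability within a rater across two
occasions is. Two Shrout–Fleiss single-rating intraclass correlations are
computed from an $n \times 2$ table of units by occasions:

- **ICC(1,1)**, one-way random: with between-unit mean square $BMS$ and
  within-unit mean square $WMS$,
  $\mathrm{ICC}(1,1) = (BMS - WMS)/(BMS + WMS)$ for $k = 2$. It treats
  the two occasions as interchangeable, so a systematic shift between
  test and retest lowers it.
- **ICC(3,1)**, two-way mixed, consistency: the occasion effect is
  removed first ($SS_{error} = SS_{within} - SS_{occasion}$, residual
  mean square $EMS$ on $(n-1)(k-1)$ degrees of freedom), giving
  $(BMS - EMS)/(BMS + EMS)$, invariant to a constant occasion shift.

For weights and scores the rated unit is one panelist × component cell,
pooled across panelists: with occasions as the two "raters" of each cell,
this is the only pooling that yields the 120/112/8 pair accounting above,
and it is what the `pair_testretest()` constructor produces. Missing
cells (a component scored on one occasion only) are dropped pairwise and
reported in a dropped-units attribute so exclusions stay auditable.

Numerical choices: both ICCs are computed from explicit sums of squares
(the test suite cross-checks them against `stats::aov()` mean squares to
1e-10 over random fixtures, $n$ from 2 to 30); negative estimates are
reported as computed, since truncating at zero hides degeneracy; when all
$2n$ values are identical both numerator and denominator vanish and the
statistic is returned as `NaN` with an `undefined` flag rather than an
arbitrary 0 or 1. Confidence intervals and the inter-rater forms
(ICC(2,1), averaged-rating versions) are out of scope.

Ordinal agreement is summarized as the proportions of pairs differing by
0, 1, and **2 or more** points. The open design choice is the last
bucket: "differs by 2" is implemented as $\ge 2$ so the three buckets
partition all pairs and the proportions sum to exactly 1; on the 1–5
weight scale a 3- or 4-point swing lands in the same bucket as a 2-point
swing.

**Outlier rule.** A panelist whose two value estimates satisfy
$|t - r| / \big((t + r)/2\big) > 0.5$ shows systematic error and is
excluded from panel summaries and reliability runs. The mean-based
denominator is the package's choice among the several readings of "differs
by more than 50%": it is symmetric in the two occasions, and it is
configurable (`threshold`, and callers may disable exclusion). A pair
with mean zero but unequal values has an undefined ratio and is flagged
with an explicit reason. The crafted pair (2.0, 1.15) in the bundled
fixture has relative difference 0.540 and is the canonical exclusion
case.

## The extrinsic tally

`extrinsic_tally()` reports, per component, the respondent count, the
fraction who would *not* consider the component (abstentions leave the
denominator), and impact-direction counts (positive / negative / mixed /
none) among those who would. Denominators are per-component because
panels rarely answer every item; the tally therefore always carries
`n_respondents` alongside each percentage. A survey mode extends the same
instrument to intrinsic component ids, for should-this-be-considered
surveys across the whole framework.

## The evidence layer

Evidence summaries attach free-text synthesized evidence to components;
the Quality Matrix scores each of five evidence types (clinical,
patient-reported outcomes, epidemiological, economic, budget impact) on
two criteria (completeness/consistency of reporting, relevance/validity)
through a three-stage review — first reviewer, second reviewer, expert
validation — modeled as a stage field with most-advanced-stage selection
rather than an interactive workflow. The economics arithmetic is
deliberately minimal: annual budget impact is the exact product of
per-patient annual cost and covered population, rendered to three
significant figures in millions; cost-per-QALY figures are carried as
verbatim evidence text because the models behind them are external. In
the bundled Turner-syndrome case bundle the evidence texts condense the
published appraisal materials, while the Quality Matrix *scores* are
illustrative reconstructions consistent with the recorded critical
analysis (the original cell scores were not published); they exercise the
data model, not the historical record.

## The synthetic-panel simulator

The simulator is the package's study-conditions generator, not a fitting
device. Its defaults emulate the kind of panel the framework was
exercised with: 9 panelists; weight tendencies near 4 on the 1–5 scale
(panels put most components in the important-to-very-important range) and
score tendencies near 1.3 on the 0–3 scale (a middling intervention);
between-panelist SD 0.9, which reproduces the "large variation across
panelists" character of real elicitation (weights spanning 2–5 per
component); and retest shift probabilities (0.55, 0.35, 0.10) for 0-, 1-
and 2-point changes, matching the roughly half-identical /
substantial-1-point / rare-2-point pattern real test-retest weight data
shows. These were chosen once as realistic panel behavior and are not
tuned.

Mechanics: each cell is a Gaussian draw centred on the component's
population tendency with SD `panelist_sd`, rounded to the integer scale
and clamped at its bounds — two documented parameters per component
rather than a full categorical distribution. The retest occasion shifts
each cell independently (magnitude from `retest_probs`, direction
uniform, clamped); an optional per-panelist constant bias
(`panelist_bias_sd`) produces the systematic shifts that separate
ICC(1,1) from ICC(3,1). Clamping at the scale edges converts some nominal
shifts into smaller realized ones, so the generator reports both nominal
and realized shift frequencies and downstream checks compare against the
realized values, which propagate exactly to `agreement_proportions()`.

What the simulator does *not* emulate: correlations between a panelist's
weights and scores, component-to-component correlation structure,
learning effects between occasions, and panelist-specific response styles
beyond a constant bias. Passing recovery tests therefore show the
statistics are computed correctly under a clean elicitation model, not
that real panels behave this way.

## Problem sizes and determinism

All randomness flows through explicit seeds (`with_seed` restores the
caller's RNG state, so simulation calls are deterministic and
side-effect-free; identical configs give byte-identical fixtures). The
test suite exercises: ICC-versus-oracle agreement on 120 random fixtures
($n \le 30$); property checks of the value model on 60 random 15-component
panels; simulator recovery on a 60-panelist (900-cell) run, with shift
proportions required within three binomial standard errors of the
configuration; and ICC(3,1) monotonicity in the no-shift probability over
a 4-point probability grid averaged across 5 seeds. These sizes were
picked to make sampling error small relative to the assertions while
keeping the full suite in seconds.

## Known limitations

- The additive model cannot express interactions or non-linear value
  functions, and weight elicitation is direct (no swing-weighting or
  AHP); these are properties of the framework itself.
- ICCs are point estimates without confidence intervals; with only 8–9
  estimate pairs they are unstable, which is precisely why the suite
  validates the estimators against an independent oracle rather than
  against any particular panel's values.
- The extrinsic tool is a structured record, not a deliberation aid; free
  text is collated verbatim.
- CSV input uses one canonical dialect (UTF-8, comma, header, literal
  `NA`) by design; files in other dialects must be converted first.
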