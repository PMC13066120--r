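---
title: "Measuring metacognition from confidence judgements"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring metacognition from confidence judgements}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metasense)
```

## The measurement problem

A confidence rating is useful only insofar as it discriminates the rater's
correct responses from their errors. Raw confidence–accuracy correlations
confound that *sensitivity* with *bias* (an agent that always says "95%"
can still ride a high accuracy to a decent correlation), so this package
centres on bias-free quantities:

* the **Type-2 AUROC**, a rank statistic invariant under any monotone
  transform of the rating scale;
* **meta-J**, the mutual information in bits between accuracy and
  binarized confidence, maximized over binarization thresholds; and
* **meta-J2r**, meta-J normalized by the Shannon entropy of accuracy —
  an *efficiency*: how much of the information that could exist (given
  the agent's error rate) the confidence channel actually carries.

The input throughout is the `trial_table`: one row per (agent, condition,
item) with `correct` in {0, 1} and `confidence` in [0, 100]. Conditions
carry a chance level — 0.5 for two-alternative, 0.25 for four-alternative,
0 for open-ended (practically, not mathematically) — used only where
accuracy must be standardized across formats.

## Estimator conventions

Papers typically name these measures without fixing the estimator. The
choices here, and why:

* **Type-2 ROC.** Criteria sweep the distinct observed confidences
  (descending) with an inclusive `>=` rule, plus a sentinel above the
  maximum so the curve starts at (0, 0). The area is trapezoidal, which is
  algebraically the tie-aware rank statistic (ties count 1/2). Ratings
  cluster on round numbers, so any other tie convention biases the
  estimate. Agents with no errors (or no hits) have *undefined*
  sensitivity; `type2_roc()` flags this rather than guessing, and group
  summaries exclude-and-count such agents (`n_excluded`). This exclusion
  is why denominator degrees of freedom in downstream ANOVAs can fall
  below the nominal subject count.
* **meta-J.** Plug-in mutual information of the 2×2 (accuracy ×
  high/low) table, log base 2, with `0 log 0 = 0`; degenerate margins give
  0 bits. The maximizing threshold is searched over midpoints between
  consecutive distinct confidences plus one candidate below the minimum
  and one above the maximum — the information is constant between
  midpoints, so this scan is exhaustive, and ties are broken toward the
  lowest threshold for determinism. For the pooled `"All"` row the
  threshold is re-optimized on the pooled trials (not averaged over
  conditions); with per-agent, per-condition thresholds elsewhere, both
  granularities are reported.
* **Folded X.** Item discriminability is the group-level correct rate
  mapped through `(p − chance)/(1 − chance)`, kept signed below chance.
  Items are cut at within-condition empirical quantiles (type 7), with
  right-closed intervals so an item exactly on an interior edge falls in
  the lower bin. If ties make the edges collapse, the cell degenerates to
  a single bin with a classed warning. A quartile may also end up with no
  trials of one correctness branch (e.g. no errors among the easiest
  two-choice items); such cells are reported as missing with
  `n_trials = 0`, never as zero confidence. Interpolated quantile edges
  can occasionally leave an interior bin without items; absent bins are
  omitted rather than padded.
* **Associations.** Two-sided tests throughout. The two-sample Fisher
  comparison is `z = (atanh r1 − atanh r2) / sqrt(1/(n1−3) + 1/(n2−3))`.
  The slope-difference test fits one OLS model with a group ×
  correct-rate interaction; its interaction coefficient equals the
  difference of separately fitted per-group slopes, and a zero-residual
  (exact) fit is flagged degenerate instead of reporting an unbounded t.
  Stimulus-level points are unweighted by how many agents answered.
* **Agent-level aggregation.** The agent-level point cloud defaults to
  one pooled point per agent; a `per_condition` switch yields one point
  per agent and condition (three times as many). Both are legitimate
  readings of "averaged across questions for each agent" and they give
  different regression degrees of freedom, so the switch is explicit
  rather than buried.

## Factorial machinery

Group comparisons use the split-plot design: a between-subjects factor
(agent group) crossed with one or two within-subjects factors (condition;
correctness × condition). `mixed_anova()` uses Type-III sums of squares
via sum-to-zero contrasts, delegating the sums-of-squares and sphericity
numerics to `car::Anova`'s repeated-measures machinery; the package owns
and tests the policy layered on top:

* **Greenhouse–Geisser.** `gg_epsilon()` implements Box's estimate from
  the double-centered covariance, bounded in `[1/(k−1), 1]` and exactly 1
  for two-level factors. Under the default `gg = "auto"`, corrected
  degrees of freedom are used when a within term has at least three
  levels *and* Mauchly's test rejects at 0.05; `"always"`/`"never"`
  force the behaviour for exact-reproduction runs, since publications
  rarely state their trigger.
* **Effect size.** Generalized eta squared,
  `SS_effect / (SS_effect + Σ SS_error)` over *all* error strata
  (subjects plus every within-error), comparable across between- and
  within-subject effects.
* **Post hocs.** `bonferroni_pairwise()` takes an explicitly enumerated
  family and multiplies raw p by the family size, capped at 1. Families
  are simple-effects blocks by construction — the three condition
  comparisons within one group form a family of m = 3 — because that is
  what blocks of reported p-values correspond to; the caller controls the
  family, so other definitions are one `filter()` away. Paired
  comparisons match by subject; independent ones use the pooled-variance
  two-sample t.
* The design must be complete and balanced within subjects; missing cells
  are an error, not an imputation. A single within level collapses to a
  one-way between-subjects ANOVA.

The implementation is verified against an independently coded cell-means
sums-of-squares oracle on balanced designs (agreement to 1e-8) and the
closed-form trace formula for epsilon.

## The synthetic cohort generator

There is no public generative model for confidence data of this kind, so
`generate_cohort()` implements the minimal signal-detection mechanism that
reproduces the phenomena the measures are designed to detect. Per trial:

1. ability `a_i ~ N(μ_a, σ_a)`, item difficulty `b_j ~ N(0, σ_b)` (items
   shared across groups, as when two populations answer one
   questionnaire);
2. discriminability `d = max(0, a_i − b_j + ε₁)`, `ε₁ ~ N(0, σ₁)`;
3. `P(correct) = g + (1 − g)(1 − e^{−λd})` with the condition's guess
   rate `g` — accuracy floors at chance and saturates with evidence;
4. metacognitive readout `r = d + ε₂` if correct, `r = d₀ − γd + ε₂` if
   incorrect, `ε₂ ~ N(0, σ_meta)` — the folded X by construction, with
   `γ` the steepness of error-confidence decline;
5. confidence `= clamp(0, 100, B + S·r)`, rounded to integers by default
   (raters report whole percents, and rounding keeps tie-handling code
   honestly exercised).

Defaults mirror the layout the package is designed around: two groups of
87 agents, 20 items in each of 2C/4C/OP. The presets encode the
qualitative contrast of interest: `human_like` (moderate bias B = 40,
large gain S = 30, small σ_meta = 0.35) produces graded,
difficulty-tracking confidence; `llm_like` (B = 92, S = 6, σ_meta = 2,
higher ability) produces high accuracy with compressed, ceiling-level,
weakly coupled confidence; `oracle` (σ_meta = 0, error readout strictly
below the correct branch) yields AUROC exactly 1; `independent` draws
confidence ignoring the readout, the AUROC = 0.5 / meta-J = 0 limit.
These parameter values were fixed from the intended phenomenology, once,
when the presets were written.

Determinism: one master stream seeds item difficulties and derives one
substream per agent, so a cohort is byte-identical under a repeated seed.

What the generator does *not* emulate: item content and semantic
clustering, sequential effects (fatigue, learning, order of conditions),
per-item guessing correlations between agents, and response styles beyond
a linear bias/gain (e.g. probability weighting of the confidence scale).
Tests passing on synthetic cohorts therefore validate the *estimators and
pipeline*, not claims about any particular empirical population.

## Numerical and degenerate-input choices

* Confidence is validated to [0, 100] and kept real-valued; integer input
  is not rounded further. Missing responses are rejected, not imputed.
* Duplicate (agent, condition, item) triples are an error at
  construction.
* `meta_j_max` with a zero-entropy accuracy margin returns meta-J = 0 and
  an undefined (NA) meta-J2r; `type2_roc` likewise returns an undefined
  signal rather than an arbitrary 0.5.
* Pipeline stages that a too-small input cannot support (ANOVAs on a
  five-row toy table, quartiles with three items) are skipped with
  classed warnings and recorded in the bundle manifest; data-model
  failures abort with the stage name.
* The report bundle manifests MD5 digests of every emitted CSV; identical
  config + seed reproduces identical digests.

## Problem sizes used by the test-suite

The suite exercises oracle equivalence on 200 random small instances
(n ≤ 20 with heavy ties) for both the AUROC rank identity and the
threshold scan; analytic limits at n = 10,000 trials; the noise-robustness
grid σ_meta ∈ {0, 1, 2, 4, 8} at 50 agents × 60 trials per point; and
full-layout cohorts (87 × 60) for structural checks such as the folded X.
These sizes give Monte-Carlo error comfortably below the asserted
tolerances while keeping the default test run fast.

## Known limitations

* Meta-J's plug-in estimator has a positive small-sample bias (of order
  `1/(2n ln 2)` per degree of freedom, inflated by threshold
  maximization); at the 20-trials-per-condition scale this is visible in
  absolute values and comparisons between cells with equal n are the
  safer use. No bias correction is applied, matching common practice for
  these measures.
* The max-information binarization discards within-branch gradation;
  agents whose confidence is informative only in its fine structure are
  under-credited relative to continuous-information measures.
* `mixed_anova` supports at most two within factors and one between
  factor — the designs this analysis family uses.
* Below-chance items keep negative discriminability; if a population
  systematically scores below chance, quartile interpretation changes
  meaning and should be inspected.
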