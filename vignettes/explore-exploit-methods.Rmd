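---
title: "Methods: explore/exploit state analysis for trial-aligned spike data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: explore/exploit state analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The task and the scientific question

The package analyses single-unit recordings from a serial object-search
task. A subject works through *problems*, each built on a display of four
objects and organised into four *cycles* of trials. At the start of a
problem, one or two of the objects are secretly designated as rewarded
targets. In Cycle 1 (the *explore* cycle) the subject samples objects one at
a time until every target has been found; in Cycles 2–4 (*exploit* cycles)
the targets can simply be reselected for further reward. Within a cycle,
reselecting a target that has already been chosen is not rewarded, so an
efficient searcher avoids revisits. Each trial presents the four objects at
random locations, a go cue, a touch, and visual feedback (correct/incorrect).

The scientific question is whether, and how, prefrontal firing
differentiates the explore state (information seeking) from the exploit
state (information use): whether the transition is one-shot after a single
reward, whether it is binary rather than driven by graded reward expectancy,
and whether the preference is conjunctive with trial phase — choice-array
onset (CH) versus feedback onset (FB).

## Data model

All functions operate on three flat tables (tibbles):

* a **trial table**, one row per trial, carrying the task factors, the
  display arrangement (a bijection of objects onto locations), the choice,
  the outcome and four event timestamps in seconds from trial start
  (`?trial_table_columns`);
* a long-format **spike table** (`cell_id`, `trial_id`, `spike_time_s`);
* a **cell table** (`cell_id`, `session_id`, `region`).

Analysis windows are half-open intervals `[start, start + width)` relative
to an alignment event, so adjacent windows partition time and a spike on the
boundary belongs to exactly one window.

## Analytic chance expectations

For a random searcher without revisits, the number of Cycle-1 trials needed
to find all targets equals the maximum of the targets' positions in a random
permutation of the four objects, with expectation
$n_t (n + 1) / (n_t + 1)$ for $n_t$ targets among $n$ objects: 2.50 trials
for one target among four, 10/3 ≈ 3.33 for two. A memoryless chooser
revisits with probability $k/4$ after $k$ objects have been sampled
(0/25/50/75%), and the first choice hits a target with probability
$n_t/4$. These closed forms (`expected_search_trials()`,
`chance_revisit_probability()`, `first_target_probability()`) are the
reference points for the behavioural summaries and are themselves checked
against Monte-Carlo simulation in the test suite.

## The synthetic-data generator

Because the recorded data are not redistributed, the package ships a
generator whose defaults encode the study conditions; every downstream
analysis is tested against its ground truth.

**Behaviour** (`simulate_behavior()`, `agent_config()`). The agent searches
without revisits up to memory lapses. We model Cycle-1 lapses as
*per-object forgetting*: on each trial every already-sampled object is
forgotten independently with probability `p_revisit_lapse` (default 0.35),
and the choice is uniform over objects not remembered as sampled. This
nests the two analytic reference agents exactly — probability 0 gives the
perfect searcher, probability 1 the memoryless chooser with revisit rates
25/50/75% — and it reproduces the empirical pattern that observed revisit
rates, as a fraction of chance, rise with the number of objects already
sampled (a constant per-opportunity lapse cannot do this). One-shot
learning succeeds with probability `p_learn_one_shot` (default 0.85); when
it fails, Cycle 2 begins with at least one error before the target is
re-found. Exploit lapse rates decline across cycles (defaults 0.10, 0.06,
0.04), the first Cycle-1 choice goes to a favoured display location with
probability 0.7, and event timestamps are drawn uniformly from the task's
timing ranges (wait 0.8–1.2 s, delay 1.2–2.0 s, hold 0.35–0.45 s). Defaults
were fixed once to sit between the two animals' published behavioural
summaries; they are conditions, not tuning knobs.

**Spiking** (`simulate_population()`, `population_config()`). Each cell's
rate is piecewise-constant across trial epochs:
baseline × state gain × phase gate × object/location/outcome tuning, with
Poisson spiking. Baselines are log-normal (median 5 spikes/s, sdlog 0.5, a
typical cortical range chosen so that the stated recovery condition — gain
1.5 with ≥ 40 selection trials per cycle — has high per-cell power).
Fractions of explore/exploit cells default to 7%/10% per phase, matching
the reported prevalence. A cell's state gain acts only within its phase
window, extending from 200 ms before the event to 500 ms after it, because
cycle preferences in the recordings are sustained and begin before event
onset; the conjunction is absolute by default (`phase_leakage = 0`), with
`phase_leakage = 1` available as a phase-general control for power
analyses. Graded expectancy signals are deliberately absent: the
explore/exploit state is binary, so the flat sampling-order,
correct/error and discovery-type profiles are the ground truth.

**Failed learning.** Failed-learning trials are correct Cycle-2 trials
preceded by at least one Cycle-2 error. In the generator, Cycle-2 error
trials of a failed problem are explore-state for every cell; on the first
correct Cycle-2 trial the explore subpopulation still holds the explore
state while the exploit subpopulation has already switched. This single
rule makes explore cells resemble Cycle 1 on failed trials (and differ from
regular Cycle 2), leaves exploit cells indistinguishable between failed and
regular trials, and places the population projection of failed trials
strictly between Cycle 1 and regular Cycle 2 — the full observed pattern. A
graded "partial gain" alternative was rejected because it cannot produce
the single-cell and population results simultaneously.

## Cell selection and validation

Problems in which the subject failed to respond on six or more trials of a
single cycle are excluded (`apply_problem_exclusion()`); aborted trials
(fixation break or key release) count toward the threshold, since both
indicate poor task focus — the log reports the split. Unless an analysis
requires errors, only correct trials are analysed.

Each cell's trials are split 50/50 into selection and validation halves
(`split_trials()`), stratified within cycle × targets × object set ×
location so both halves cover each condition; the seed is a required,
logged input. On the selection half (Cycles 1 and 4 only), a factorial
ANOVA of the 400 ms window rate on cycle(2) × targets(2) × object set(2) ×
location(4) is fitted per phase (`run_selection()`). We use Type II tests
on a main-effects model: with realistic trial counts the 2×2×2×4 grid is
sparse and unbalanced, a full factorial would alias high-order terms, and
only main effects are interpreted. Cells with a significant cycle effect
(α = 0.05, uncorrected across cells — the held-out half is the guard
against selection bias) are labelled *explore* (Cycle 1 > 4) or *exploit*
(Cycle 4 > 1). Validation recomputes the Cycle-4 − Cycle-1 difference on
the held-out half, per cell (two-sample t, two-tailed; one-tailed
alternatives can be read off the reported t sign) and per group
(across-cells one-sample t).

Normalisation: each cell's PSTH and group statistics are divided by its
mean activity, the unweighted mean over the selection-ANOVA condition cells
of both 400 ms windows. Cells with a constant below 0.1 spikes/s are
excluded from normalised group averages (degenerate, near-silent cells);
empty condition cells are skipped and the unweighted mean taken over the
available cells. PSTHs use 28 overlapping 100 ms windows centred −200 to
+475 ms in 25 ms steps.

## One-shot and expectancy analyses

The one-shot analyses (`one_shot_cycle_analysis()`,
`failed_learning_analysis()`) are restricted to 1-target problems, where
learning is typically one-shot; Cycles 1 and 4 use the validation half,
Cycles 2–3 all trials, and exploit cycles whose first response was an error
are excluded ("regular" trials). Tests treat the cell as the unit: paired t
between Cycles 1 and 2, repeated-measures F across Cycles 2–4.

The expectancy analyses hold selection effects constant by using only
trials at the animal's favoured first-choice location (modal first Cycle-1
choice; ties resolve to the lowest index and are flagged), removing
selection-half trials: activity by sampling position (1st–4th object),
correct versus error unweighted over serial positions 1–3 (an error is
impossible on the fourth), and the three target-discovery types (1-target,
first-of-two, second-of-two). Outcome coding is assessed on all completed
trials of both halves with a correct/error × object set × location ANOVA.

## Population analyses

**Temporal cross-generalization** (`cross_generalization_matrix()`). A
fresh random halving (independent of the selection split — the seeds are
separate configuration entries) yields two cycle-preference vectors
(Cycle 4 − Cycle 1 mean rate per cell, unweighted over location × targets)
for each of eight 100 ms windows (four from CH onset, four from FB onset).
The 8×8 matrix of Pearson correlations between half-A and half-B vectors
(Spearman available as an option) is summarised by the within-phase minus
cross-phase block contrast (`crossgen_phase_contrast()`).

**Mean-difference discriminant** (`fit_discriminant()`,
`discriminant_analysis()`). On a train half of Cycles 1 and 4, each cell is
centred on the unweighted mean of its two cycle means and scaled by the
unweighted mean of its two across-trial SDs; the discriminant is the
scaled Cycle-4 vector minus the scaled Cycle-1 vector in the full
cell-dimensional space — deliberately not an LDA with covariance
estimation. Conditions (held-out Cycles 1 and 4, regular Cycles 2 and 3,
failed-learning Cycle-2 trials) are projected by dot product after applying
the frozen train transform. Cells with zero scale get weight 0 and scale 1;
cells without data in a condition contribute 0 to the dot product, with a
coverage report.

**Permutation inference** (`permutation_test()`). For each condition pair,
condition labels are shuffled within each cell over the pooled trials,
means recomputed, re-projected on the fixed discriminant (centring cancels
in the difference; the train transform is never refitted), and the absolute
projection difference collected over 1000 replicates. The p value uses the
add-one rule $(k+1)/(n+1)$, so the attainable floor at 1000 permutations is
just below 0.001 and a reported p can never be 0.

## Numerical choices and degenerate inputs

* Zero rate variance or a single observed factor level: the factor is
  dropped (logged) or the p value is `NA` — such cells are never selected.
* Empty revisit bins are reported with `NA` statistics rather than errors.
* Repeated-measures tests use complete cases (cells with data in every
  condition); groups below two cells are skipped with a warning.
* All randomness flows through named integer seeds; identical configuration
  gives byte-identical numeric output (`run_pipeline()` records every seed
  in its manifest).

## Problem sizes used in tests and the acceptance script

Calibrations use sizes chosen to make the Monte-Carlo error small relative
to the assertion margins: 10^5 replicates for the search-length
expectations, 400–1000 simulated problems for behavioural rates, 1000 null
cells (five batches of 200) for the selection calibration, 500 null runs of
200 permutations each for permutation calibration, and 6–8 replicate
populations for the cross-generalization contrast. A single simulated
session of 69 one-target and 67 two-target problems — the reported
per-session problem counts — gives each cell roughly 100 selection trials
per cycle, comfortably above the ≥ 40 used as the stated recovery
condition.

## What passing tests do and do not show

The generator reproduces the statistical structure the analyses assume:
Poisson spiking with multiplicative condition gains, phase-conjunctive
binary state coding, one-shot behavioural learning with occasional
failures. It does not emulate spike-sorting artifacts, inter-neuron
correlations beyond shared condition rates, firing-rate drift, or graded
expectancy signals. Passing tests therefore demonstrate that the pipeline
recovers known ground truth under its own model assumptions and is
correctly calibrated under the null — not that the substantive conclusions
would replicate in new recordings.

## Known limitations

* The behavioural agent's lapse parameters are plausible defaults, not fits
  to the published percentages; analyses of real data are unaffected.
* With multiplicative object tuning and a multiplicative state gain, a
  genuine (if weak) cycle × object interaction exists on the additive scale
  of the ANOVA; the object-interaction screen is calibrated at α only when
  object tuning is absent.
* The discriminant assumes per-cell scaling is meaningful; near-silent
  cells are masked rather than regularised.
* Sessions are assumed statistically exchangeable; no session-level random
  effects are modelled (session enters only as the unit for the behavioural
  ANOVA, as in the original analysis).
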