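---
title: "Split-half reliability of computerized WCST measures: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Split-half reliability of computerized WCST measures: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, conventions, and design decisions
behind `wcstsplit`, in the spirit of a methods section: what exactly is
computed, which choices were genuinely open, and what the simulation-based
evidence does and does not establish.

## The task model

The computerized Wisconsin Card Sorting Test (cWCST) presents four fixed
key cards — one red triangle, two green stars, three yellow crosses, four
blue circles — so the four numbers, colors, and shapes are pairwise
distinct. A stimulus card is *valid* when its number, color, and shape
match three pairwise distinct key positions; the fourth key matches on no
dimension. There are 24 such cards. This construction makes the applied
sorting category perfectly inferable from the pressed key, which the whole
scoring scheme depends on: `evaluate_response()` maps a key press to
`color`, `shape`, `number`, or `other` (the no-match key), and feedback is
positive exactly when the applied category equals the prevailing one.

A session consists of a practice block ending after 6 switches of the
prevailing category and an experimental block ending after 40 switches or
when the practice + experimental trial count reaches 250, whichever comes
first. We read the trial cap as covering both blocks; the alternative
(experimental trials only) would let degenerate simulated participants
produce arbitrarily long records.

The prevailing category switches after a run of correct sorts whose
required length is drawn uniformly from `run_length_support`, by default
{2, ..., 6}; the successor category is drawn uniformly from the two
alternatives. A *correct sort* advances the run counter; errors neither
advance nor reset it (a switch announced in the middle of an error streak
would be undetectable by the participant). The uniform {2..6} support is a
calibrated guess — published descriptions of the task say only that
switches follow "runs of two or more" correct repetitions. It has a
visible consequence: 40 switches times a mean run of 4 already implies
about 160 correct sorts, and any feedback-driven search after a switch
adds 1.5–2 further trials per run, so simulated sessions average around
210 experimental trials and often meet the 250-trial cap. Empirical cohort
descriptions (about 169 trials, with switch and repeat trials roughly
balanced) suggest the original implementation used runs close to the
minimum of 2. We kept the {2..6} default because it is the documented
convention for this codebase and it is configurable (`wcst_task()`); the
calibration of the synthetic cohort therefore targets *per-trial-type
error probabilities* and RT moments, not trial-count moments, which are
unattainable under this support.

## Trial types and error scores

Over the experimental block, trial *t* (for *t* ≥ 2) is a **switch trial**
if feedback at *t* − 1 was negative and a **repeat trial** otherwise; the
first trial is unlabeled. An **inference trial** is a switch trial whose
predecessor was itself a switch trial on which the applied category was
switched and again answered negatively: two categories stand disconfirmed
and the third is deducible.

- **PE**: on a switch trial, the applied category equals the previous one.
- **SLE**: on a repeat trial, the applied category differs from the
  previous one.
- **IE**: on an inference trial, the applied category is not the
  prevailing one.

Three decisions here were genuinely open:

1. **PE and IE can coincide.** A perseverative response on an inference
   trial satisfies both definitions; both counters increment. The
   definitions are independent predicates and no exclusion hierarchy is
   documented; trials are excluded only once in RT filtering, so nothing
   is double-removed downstream.
2. **The no-match key.** Pressing the key that matches on no dimension
   counts as an SLE on repeat trials (it abandons the prevailing category)
   and as an IE on inference trials (it is not the prevailing category),
   but never as a PE (it repeats no category).
3. **No-match presses and the inference predicate.** We require both
   predecessors of an inference trial to have applied *genuine* categories:
   a no-match press disconfirms nothing, so the prevailing category is not
   deducible after one. A purely literal reading ("applied category
   switched", with `other` as a value) would label such trials inference
   trials; we follow the logic of deducibility instead. The simulator and
   scorer agree on this definition, and since no-match presses are rare the
   two readings differ on a small fraction of trials.

## Filtering

RT analysis excludes trials with RT strictly below 100 ms, trials above
the participant's individual cutoff (mean + 3 SD of *all* their
experimental trials, computed before any exclusion — the rules are applied
in that order), and trials carrying a PE, SLE, or IE. Mean RT is then
computed per trial type; inference trials, being a sub-type of switch
trials, contribute to both the switch and the inference mean. A type with
no valid trials yields `NA`, never zero.

Participant-level screening excludes anyone whose application count of any
category deviates from the cohort mean by strictly more than 3 cohort SDs.
The screen is a single pass — cohort statistics are not recomputed after
exclusion — which makes it idempotent. Counts, not proportions, enter the
rule, as the rule is stated in terms of applications. Sample standard
deviations (denominator *n* − 1) are used throughout, the convention in
psychological research; `wcst_filter(sd_denominator = "population")`
switches to the *n* denominator.

Participants with fewer than two experimental trials cannot be split into
halves and have no defined RT cutoff. Real cohorts do not produce such
records; degenerate simulated agents (perseveration probability near 1,
stuck in the practice block) can. The analysis treats them as excluded
alongside the validity screen, with the reason recorded.

## Split-half estimation

For each participant the completed experimental trials are split into
halves A and B; half-scores are recomputed from globally precomputed
labels, error flags, and the RT mask, restricted to the trials inside a
half. Error measures are raw counts (halves are balanced by construction,
so counts need no rescaling); RT measures are means over valid trials of
the type; conditional error probabilities (PE per switch trial, etc.) are
available as additional measures via
`wcst_measures(include_probs = TRUE)`.

Three split strategies: first/second (first ⌈n/2⌉ trials vs the rest),
odd/even (1-based parity), and random balanced splits, drawn independently
per participant — participants have different trial counts, so a shared
assignment pattern is not even well defined. For odd *n* the extra trial
lands in either half with probability 1/2. Splits cover *all* experimental
trials rather than stratifying by trial type, matching the notion of
splitting "the total of a participant's completed trials"; an analysis
stratified by type would change what is being estimated.

Pearson correlations between half-score vectors are corrected with the
Spearman–Brown formula r_SB = 2r/(1 + r), reported as computed (negative
values are not truncated). Participants with an undefined score in either
half are dropped pairwise, per measure and per split, with `n_pairs`
recorded; a zero-variance half-score vector leaves the estimate flagged
`NA` rather than silently propagating NaN. Random splitting is repeated
`n_samples = 1000` times; undefined iterations are counted and excluded
from the summary.

The sampled distribution is summarized by its median and a 95% highest
density interval computed by the sorted-window algorithm: with
k = ⌈0.95 n⌉, the narrowest window of k consecutive order statistics, ties
broken by the leftmost window. No distributional form is assumed; for
unimodal samples the interval is never wider than the equal-tailed one.

## The generative cohort model

`wcst_agent()` is a memoryless per-trial policy — the simplest structure
consistent with the scored measures. On a switch trial the agent
perseverates with probability `p_persev`; on a repeat trial it abandons
the set with probability `p_setloss`; on an inference trial it fails the
inference with probability `p_inferr` (given no perseveration), applying
the other disconfirmed category; an erroneous switch lands on the no-match
key with probability `p_other`. On a switch trial without inference
support, the agent guesses uniformly between the two categories it did not
just apply — this is not an error, just the only unbiased search policy
available to it. RTs are lognormal per trial type (positive, right-skewed,
the standard minimal RT model); richer attentional or sequential-sampling
accounts are deliberately out of scope.

`wcst_population()` adds between-participant heterogeneity: beta
distributions (mean + concentration) for the error probabilities, normal
distributions on the log scale for RT locations, with a shared
person-level general-speed factor correlating the per-type locations
(`rt_cor = 0.8`; slow people are slow everywhere — with independent
locations, the between-person SD of the switch-RT measure, which mixes in
inference trials, collapses well below its per-type target). Defaults were
calibrated once so that a default cohort lands near the descriptive
moments reported for large young-adult cohorts on this task: mean RT
1835/1241/1700 ms (between-person SD 694/441/636 ms) on
switch/repeat/inference trials, and on the order of 12 PE, 5 SLE, and 8.5
IE per participant (beta means 0.165, 0.045, 0.22 with concentrations 2.2,
8, 4). The error-count SDs implied by these betas are somewhat larger than
the published ones — heterogeneity feeds back into trial counts (a
perseverative participant generates more switch trials *and* more PE) —
and, as discussed above, trial-count means are higher than the published
169 under the {2..6} run support.

Optional linear drift adds a per-trial change to the RT location
(log-ms/trial) and to the error log-odds, drawn per participant from a
zero-mean normal with SD `drift_rt_sd` / `drift_logodds_sd`. This
implements heterogeneous long-term trends — practice effects in some
participants, fatigue in others. Such trends decorrelate first and second
half-scores while leaving odd/even splits nearly untouched, which is the
standard explanation for first/second estimates sitting below odd/even
estimates; the test suite reproduces this ordering in at least 90% of 50
replicate cohorts at `drift_rt_sd = 0.002` (about a ±1.5-fold cumulative
speed change over a session), and verifies that with zero drift the two
systematic estimates agree to within 0.02 on average.

What passing these tests shows — and what it does not: the simulation
validates the *estimator* (labels, scores, filters, splits, correction,
HDI) and its parameter-recovery behavior against an independent
Monte-Carlo oracle. It does not validate the agent as a model of human
card sorting: real performance has sequential dependencies, attentional
lapses, and RT–accuracy coupling the memoryless policy lacks, and real
cohorts' trial-count structure differs under the default run-length
support as described above.

## Parameter recovery and the oracle

`oracle_reliability()` estimates the expected Spearman–Brown coefficient
by brute force: many independent cohorts, one random split each, scores
computed directly from the flag definitions, a plain Pearson correlation,
and the correction formula — no shared split or correlation machinery with
`sample_reliability()`. Each oracle cohort passes the same validity screen
as the pipeline. The oracle reports the across-cohort SD alongside the SE
of its mean: a pipeline median computed on a *single* simulated cohort
carries that cohort's sampling variability, so agreement is judged against
the across-cohort SD (the predictive error of one cohort draw), not
against the much smaller SE of the oracle mean. The test suite runs this
recovery at three heterogeneity levels (perseveration beta concentration
12, 2.2, 0.9) with 375-participant cohorts, 1000 random splits, and
200-cohort oracles.

## Numerical and reproducibility choices

- All randomness flows through R's RNG; `run_session()`,
  `generate_cohort()`, `sample_reliability()` and friends take an optional
  `seed` and restore the caller's RNG state on exit. The pipeline derives
  two substream seeds (simulation, splits) from one master seed, so stages
  are independently reproducible and the whole run is byte-identical under
  a fixed seed.
- The Spearman–Brown map is undefined at r = −1 and returned as `NA`; its
  strict monotonicity on (−1, 1] is property-tested on a grid.
- Stimulus sampling is rejection sampling over the 24-card deck, excluding
  an exact repeat of the previous card.
- The session loop is implemented in C++ (via Rcpp) because
  parameter-recovery tests simulate tens of millions of trials; it draws
  from R's RNG stream, so results are identical across platforms for a
  given seed. Scoring, filtering, and reliability estimation are plain
  vectorized R.
- Problem sizes in the test suite (cohorts of 10–375 participants,
   120–1000 random splits, 50–200 replicate cohorts) were chosen to keep
  each property's Monte-Carlo error comfortably below its assertion
  tolerance.

## Known limitations

- The run-length distribution of the original task is unknown; trial-count
  moments under the default are not comparable to published ones (see
  above).
- The agent model is memoryless; it cannot express win-stay biases,
  streaky lapses, or speed–accuracy trade-offs.
- Conditional error probabilities and stratified splits are provided but
  off by default; the default analysis mirrors the count-based convention.
- Published cohort tables from real data cannot be regenerated without the
  original trial logs; `read_trial_logs()` + `run_pipeline()` will produce
  the corresponding tables when pointed at them.
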