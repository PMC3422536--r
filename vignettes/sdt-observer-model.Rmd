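---
title: "An equal-variance SDT observer for yes/no psychoacoustics: model, simulator and analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An equal-variance SDT observer for yes/no psychoacoustics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdtyesno)
```

## The model

`sdtyesno` simulates and analyses a yes/no tone-in-noise detection task of
the kind used in animal psychoacoustics (the bundled parameter presets are
fitted values for five ferrets). The observer is the classical
equal-variance signal detection theory (SDT) model with several
decision-related components layered on top:

* **Internal representation.** Each trial produces a sensory value on a dB
  scale: `level + e` on signal trials and `reference_level + e` on
  no-signal trials, with `e ~ N(0, internal_sd)`. The *reference level* is
  the signal level that would be indistinguishable from the background; the
  *internal s.d.* sets the psychometric-function slope. Everything is kept
  in dB throughout — no conversion to linear amplitude anywhere, since both
  the stimulus variable and all fitted parameters are expressed in dB.
* **Decision criterion.** The response is "yes" iff the internal value
  exceeds a criterion. Its resting point is the *optimal criterion*, the
  point where P(false alarm) = P(miss): the midpoint `(reference + L)/2`
  for a single-level (Method of Limits) session, and for a multi-level
  (Constant Stimuli) session the root of
  `1 - pnorm((c - ref)/sd) = mean_j pnorm((c - L_j)/sd)`, treating the
  session's signal distribution as an equal-weight Gaussian mixture over
  its levels. The mixture reading makes the optimum fall below the
  intersection point of the reference and mean-level densities, which is
  the qualitative signature one wants from a multi-level session. Whether
  the mixture should weight levels by trial count is not determined by the
  task description; equal weights are used (levels are presented equally
  often in the simulator, so the two coincide here).
* **Criterion bias** (dB): a block-level offset from the optimal point,
  fixed across a block of sessions and fitted per block.
* **Trial shifts** (dB, lags 1 and 2): after each response the criterion
  for the next trials moves by `trial_shift_1 * sign(resp[i-1]) +
  trial_shift_2 * sign(resp[i-2])` with sign(+1) for "yes". This is the
  choice-history component: it lowers the criterion after a "no" (e.g. a
  correct rejection) and raises it after a "yes", producing the observed
  dependency of P(yes) on the previous trial's outcome.
* **Guess rate**: with this probability a trial's response is a fair coin
  regardless of the stimulus — an attentional lapse. Guessing is applied
  at the response stage, not as extra sensory noise, so it compresses the
  top of the psychometric function without changing its slope elsewhere.

Units and defaults: `internal_sd > 0` dB (ferret fits: 7–12 dB),
`reference_level` in dB SPL, `criterion_bias` in dB (fits: 1–4 dB),
`guess_rate` in [0, 1] (fits: 1–5%), shifts ≥ 0 dB (fits: 1–3.5 dB).

## The session simulator

`run_session()` draws signal and no-signal trials with equal probability
until each quota (default 50 + 50, the conventional per-level minimum for
analysis) is filled. After an error the same stimulus is repeated —
*correction trials* — until answered correctly; corrections do not count
towards the quotas and are excluded from every rate, but they do occupy
slots in the response sequence. Three consequences worth knowing:

* a signal trial can never immediately follow a false alarm (the
  correction after a false alarm is a no-signal trial);
* history shifts are updated by **every** response, including correction
  and guess trials. The task description applies the shift "on each trial"
  and that simple uniform rule is retained; it is known not to reproduce
  the observed behaviour *on* correction trials themselves (responses
  there depend on both the previous response and its reward), and no extra
  parameters are spent on modelling that;
* a `max_trials` cap (40× the quota by default) terminates sessions whose
  observer cannot answer a correction trial correctly (e.g. degenerate
  parameter sets met during fitting); such truncated logs count as floor
  performance in staircase decisions.

Trials flagged `centre_reward` (water delivered at the centre spout,
probability `centre_reward_prob`, default 0) are excluded from all
analyses, mirroring the standard exclusion; the flag exists so that logs
with such trials can be consumed.

The three data-collection procedures are faithful to their classical
descriptions. `run_limits_block()` holds the start level for two sessions,
then descends 10 dB per session while session P(c)max ≥ 0.85, then 5 dB
every other session until the pooled P(c)max at a level drops below 0.71,
adding a third session at a level when its two sessions disagree by more
than 10 percentage points. The "2–3 sessions" convention at the top of a
block is implemented as exactly 2, the third arriving only through the
disagreement rule — this keeps schedules reproducible.
`run_adaptive_track()` uses 6 dB steps under 1-up/5-down until the first
error, 4 dB under 1-up/2-down until the fifth reversal (the midpoint of
the conventional "4–6", fixed for determinism), then 2 dB; the threshold
is the mean of the final-phase reversal levels (all of them, 8 by
default). During tracking the observer's optimal criterion follows the
current level and correction trials are not used, since the level moves
with every outcome.

## Psychometric analysis

`aggregate_rates()` pools a block per level after dropping correction and
centre-reward trials. For the Method of Limits a level is retained when
its pooled trials reach 50 signal + 50 no-signal. The classical
formulation asks for "two or more consecutive sessions" *and* that trial
minimum — written for real sessions of highly variable length, where
pooling across sessions is how the minimum is reached. With fixed-length
simulated sessions one 50+50 session already satisfies the trial minimum,
and requiring two sessions as well would discard every level the 10-dB
phase of the staircase visits once, leaving ~2 points per psychometric
function. The trial minimum is therefore the operative filter
(`min_sessions = 1` by default, configurable for variable-length logs).
For Constant Stimuli, no-signal trials carry no level, so each level's
false-alarm rate comes from a without-replacement sample of the pooled
no-signal trials matched in size to that level's signal-trial count,
drawn level by level from the session RNG for reproducibility.

d′ uses the quantile definition with rates of exactly 0 or 1 clipped to
`1/(2N)`; the clipping magnitude is tied to the trial count, which keeps
d′ finite without a free parameter. P(c)max = Φ(d′/2) is the
criterion-free performance measure, and the psychometric function is the
fixed-asymptote logistic `0.5 + 0.5/(1 + exp(-(x - m)/s))` fitted by least
squares (`optim`, Nelder–Mead on `(m, log s)`, relative tolerance 1e-14,
restarted once from its own solution). The floor and ceiling are fixed at
0.5 and 1.0 rather than freed as lapse parameters: the guess rate already
lives in the observer model, and the exact parameterisation used for the
original fits is not recorded — this is a documented choice, and
threshold estimates inherit a small upward bias from it when the observer
guesses (the measured ceiling sits near 1 − guess_rate/2 but the curve is
forced to 1). Thresholds invert the fitted curve at P(c)max = 0.71
(`m + s·log(0.21/0.29)`). Fits from fewer than three levels, or levels
that do not straddle 0.71, are flagged `low_confidence`; fits to constant
P(c)max values are rejected outright (no slope information).

`confidence_bands()` produces simulation-based 95% intervals (empirical
2.5/97.5 percentiles over replicate sessions; defaults 200 sessions per
level for Limits, 1000 for Constant Stimuli).

## Sequential dependencies

`build_dependency_tree()` estimates P(yes on trial i) conditioned on the
outcome at i−1 (and optionally i−2), separately for signal and no-signal
current trials and per level. Conditional frequencies are computed within
each session and then averaged **unweighted** across sessions — the
convention for this analysis — with pooled counts kept alongside for
testing. Depth is capped at 2: further lags are not statistically
detectable at these trial counts. `test_dependencies()` compares the
after-hit and after-correct-rejection branches with 2×2 chi-squared tests
on the pooled yes/no counts, without continuity correction (the exact
construction used originally is not recorded; the plain 2×2 form is the
natural reading and the choice is documented here), applying
Holm–Bonferroni within one family per current trial type — the per-panel
convention. `dependency_slope()` regresses the after-CR minus after-hit
difference on SNR; the slope is negative when history effects grow as
detection gets harder, which is exactly what the criterion-shift mechanism
predicts, because the signal and no-signal representations overlap more at
low SNR.

## Staged fitting

Observer parameters are fitted to per-level hit and false-alarm rates by
mean squared error, every entry weighted equally (for Constant Stimuli the
false-alarm rate is one entry per block, since it carries no level). The
loss is evaluated by simulation — 100 sessions per condition by default —
with **common random numbers**: every candidate re-seeds the simulator
identically, so the loss surface is deterministic and a downhill step
means a better candidate, not a lucky draw. The exact supervised staging
used originally is not recorded; the three-stage structure is:

1. `fit_stage1()`: coarse grid over (internal s.d., reference level), the
   per-block criterion bias initialised from the block's false-alarm rates
   (`c = ref + sd·qnorm(1 − FA)`, a method-of-moments inversion), then a
   Nelder–Mead polish over all of (s.d., reference, biases). Trial shifts
   and guess rate stay fixed at 2 dB, 1.5 dB and 1%.
2. `fit_stage2_guess()`: the guess rate is scanned over a preset grid
   (0–10%); stage-1 parameters are never modified.
3. `fit_stage3_shifts()`: the shifts barely move hit/false-alarm rates, so
   scanning them against that loss would be unidentifiable; they are
   scored instead against the after-hit/after-CR conditional probabilities
   of the dependency tree (grid 0–5 dB in 0.5 dB steps by default).

`evaluate_fit()` reports r² between observed per-level values and
SNR-matched simulated means (exp–sim), and the model correlated against
itself (sim–sim): 100 times, one simulated block is drawn from the pool
and correlated with the mean of the remainder. The sim–sim values bound
what any fit could achieve given the protocol's trial counts; false-alarm
correlations are skipped for Constant Stimuli, where no-signal trials are
not tied to an SNR. Parameter identifiability deserves a caveat: (s.d.,
reference) enter the rates only through `(L − ref)/(2·sd)` and
`bias/sd`, so the two trade off along a ridge. Recovery to within
±1.5 dB (s.d.) and ±3 dB (reference) needs blocks that sample the
psychometric function on both sides of threshold — with sub-threshold
levels included, as the experimental blocks' SNR range (24 down to −15 dB)
did; fits to staircase data that stop at the first sub-71% level are
noticeably less well conditioned.

## Reward analysis

`reward_curve()` evaluates the deterministic skeleton of the model (static
criterion, no guessing or history): sweeping the criterion gives P(yes)
and the expected proportion of rewarded trials,
`0.5·mean_j(1 − Φ((c − L_j)/sd)) + 0.5·Φ((c − ref)/sd)`. For a
single-level session the maximum sits exactly at the midpoint criterion,
where P(yes) = 0.5 — the equal-variance symmetry — and `argmax_reward()`
returns that closed form (the numeric golden-section route agrees to
<1e-6 dB and is used for multi-level sets, whose optimum is conservative:
P(yes) < 0.5). The reward gradient with respect to P(yes) (centred finite
differences along the swept curve; default grid step 0.05 dB spanning
ref ± 4·sd to max level + 4·sd) vanishes at the optimum and is shallower
at low SNR, which is the model's explanation for why criteria become
variable and conservatively biased in hard sessions: there is almost no
reward signal to climb. `reward_curve_family()` re-centres each SNR's
curve on its own optimum so gradients can be compared at equal distances
from it.

## What the synthetic data do and do not emulate

The simulator is the package's data generator: no behavioural data ship
with it. It reproduces the trial bookkeeping (equal trial-type
probabilities, correction-trial insertion, centre-reward exclusions),
session lengths (50 + 50 by default; real per-ferret trial counts varied
and are not recorded, so the conventional minimum is the default and the
quotas are configurable), the three stimulus procedures, and the fitted
decision dynamics. It does not emulate: motivational drift within or
across sessions, the reward-driven *learning* of the criterion (the
criterion components are fixed parameters, not an adaptive process), the
actual behaviour on correction trials (see above), or session-length
variability. Passing tests therefore certify the pipeline's arithmetic
and the model's internal consistency on data generated by this same model
family — not that real animals satisfy the model.

## Numerical choices and test problem sizes

* Optimal-criterion root finding: `uniroot` on
  `[min(ref, min L) − 10·sd, max L + 10·sd]` (widened once to ±20·sd if
  needed), tolerance 1e-12; the residual |P(fa) − P(miss)| is checked
  against 1e-9.
* Logistic fits: Nelder–Mead, reltol 1e-14, one restart; degenerate
  (zero-slope) inputs are rejected before optimisation.
* Staircase ties: the stopping decision at a 5-dB-phase level uses the
  level's pooled sessions, not the last session alone.
* Fitting stops when the Nelder–Mead loss improvement falls below its
  relative tolerance (1e-5) or the iteration cap; stage-2/3 grids are
  finite scans, so their optima are exact over the grid.
* The test suite scales simulations to keep the full run within a few
  minutes: 300 replicate blocks per arm for the threshold experiment
  (the acceptance script runs 800), 100-150 null replicates for the
  family-wise-error checks, and 100 sessions per condition for the
  recovery test, which uses three blocks sampling SNRs from +24 down to
  −11 dB. These sizes are stated here so that anyone re-running the suite
  knows the Monte-Carlo resolution they imply.

## Known limitations

* The fixed-asymptote logistic biases thresholds slightly upward for
  observers with non-zero guess rates (the analytic 71% crossing of the
  F2 observer sits ~0.6 dB below what the logistic fit reports on the
  same curve); a lapse-parameter fit does not remove the remaining
  protocol dependence, so the simple form is kept.
* Trial shifts applied uniformly on correction trials are a simplification
  (see above).
* The (s.d., reference) ridge limits recovery from staircase-only data.
* The adaptive-track observer assumes the criterion follows the current
  level's midpoint; animals plausibly track more slowly, which is one
  reason adaptive thresholds are more variable in practice than either
  fixed-level method — the simulator reproduces the extra variability but
  not its full magnitude.
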