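# sdtyesno

Simulation and analysis of yes/no (one-interval) psychoacoustic detection
behaviour under an equal-variance signal detection theory (SDT) observer
with decision-related components. The package grew out of animal
psychoacoustics — its bundled parameter presets are model fits for five
ferrets performing tone-in-noise detection — but the machinery is generic:
it is for anyone who needs to simulate realistic yes/no sessions (including
correction trials and choice-history effects), fit psychometric functions,
test sequential dependencies, recover observer parameters from hit and
false-alarm rates, or reason about reward-optimal criterion placement.

## The model

Each trial produces an internal value on a dB scale,

    X = L + e            (signal trial at level L, dB SPL)
    X = ref + e          (no-signal trial)         e ~ N(0, sigma)

and the response is "yes" iff `X > c`. The criterion is

    c_i = c_opt + b + s1 * sign(r_{i-1}) + s2 * sign(r_{i-2})

where `c_opt` makes P(false alarm) = P(miss) for the session's stimulus
set (the midpoint `(ref + L)/2` for a single level; for a multi-level set
the root of `1 - Phi((c - ref)/sigma) = mean_j Phi((c - L_j)/sigma)`),
`b` is a block-level criterion bias, `s1`, `s2` are trial-by-trial
criterion shifts keyed to the previous two responses (`sign(yes) = +1`),
and with probability `g` (guess rate) the response is a fair coin instead.
Sensitivity is summarised by `d' = z(H) - z(FA)` and the criterion-free
`P(c)max = Phi(d'/2)`; detection thresholds are read off fitted logistic
psychometric functions at `P(c)max = 0.71`.

Modules: session/block simulators for the Method of Limits, Method of
Constant Stimuli and adaptive (transformed up-down) tracking;
psychometric aggregation and fitting; dependency-tree analysis of
sequential effects with Holm-Bonferroni-corrected chi-squared tests; a
three-stage fitting procedure (internal s.d. + reference + per-block bias,
then guess rate, then trial shifts against the dependency tree) using
common random numbers; and a deterministic reward-optimality analysis.
See the vignette in `vignettes/sdt-observer-model.Rmd` for the full
account.

## Worked example

Simulate a descending Method of Limits block with the ferret-F2 fitted
observer, then extract its psychometric function and threshold:

```r
library(sdtyesno)

p <- ferret_params("F2", "limits")
#> SDT observer parameters
#>   internal s.d.   : 9.2 dB
#>   reference level : 37.35 dB SPL
#>   criterion bias  : 3.78 dB
#>   guess rate      : 0.01
#>   trial shift i-1 : 2 dB
#>   trial shift i-2 : 1.5 dB

bc <- block_config("limits", start_level = 72, noise_level = 48)
bl <- run_limits_block(bc, p, seed = 42)
bl$schedule
#>   session_index session_id level      phase     pcmax
#> 1             1     b1_s01    72      start 0.9714286
#> 2             2     b1_s02    72      start 0.9352553
#> 3             3     b1_s03    62   big_step 0.8544444
#> 4             4     b1_s04    52   big_step 0.7558139
#> 5             5     b1_s05    47 small_step 0.6431552
#> 6             6     b1_s06    47 small_step 0.7292092

psychometric_result(bl)
#> Logistic psychometric fit: midpoint 52.056 dB, scale 9.802 dB (sse 0.000325)
#> Threshold at P(c)max = 0.71: 48.89 dB SPL
#>  level snr n_sessions n_signal n_nosignal hit_rate fa_rate dprime  pcmax
#>     47  -1          2      100        100     0.59    0.23 0.9664 0.6855
#>     52   4          1       50         50     0.62    0.14 1.3858 0.7558
#>     62  14          1       50         50     0.76    0.08 2.1114 0.8544
#>     72  24          2      100        100     0.93    0.03 3.3566 0.9534
```

The staircase held 72 dB SPL for two sessions, dropped 10 dB per session
while P(c)max stayed at or above 85%, then 5 dB; it stopped once the pooled
P(c)max at 47 dB SPL fell below 71%. The fitted logistic puts the 71%
threshold at 48.9 dB SPL for this single block (about 1 dB SNR over the
48 dB SPL masker); averaging across replicate blocks tightens this
considerably.

Sequential dependencies in the same block — P(yes) after a hit
(`p_yes_1`) versus after a correct rejection (`p_yes_2`):

```r
tree <- test_dependencies(build_dependency_tree(bl, depth = 1))
tree$comparisons[, c("trial_type", "level", "p_yes_1", "p_yes_2", "p_adj")]
#>   trial_type level p_yes_1 p_yes_2  p_adj
#> 1   nosignal    47  0.1257  0.3557 0.0278
#> 2     signal    47  0.6039  0.5642 1.0000
#> 3   nosignal    52  0.1739  0.1111 0.7178
#> ...
```

A "yes" is more likely after a correct rejection than after a hit — the
observer heads for the spout opposite the one it was just rewarded at —
and the effect is concentrated at low SNR (here significant on no-signal
trials at 47 dB SPL after Holm correction).

Reward optimality of the criterion, for a single-level session:

```r
rc <- reward_curve(stimulus_set("limits", 47, 48), observer_params(9.2, 37.35))
argmax_reward(rc)
#> $criterion
#> [1] 42.175      # the midpoint (ref + L)/2
#> $p_yes
#> [1] 0.5         # rewards are maximised exactly at P(yes) = 0.5
#> $reward
#> [1] 0.700019
```

For multi-level (Constant Stimuli) sets the optimum shifts to a slightly
conservative criterion, `P(yes) < 0.5` — one of the model's testable
signatures.

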