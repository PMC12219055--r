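# whiskattn

History-cued attention analysis for Go/NoGo whisker-detection experiments.

In head-fixed whisker detection, a mouse reports brief deflections of one of
nine whiskers (Go trials) and withholds licking otherwise (NoGo trials).
Recent reward history cues attention: after one or more hits to a whisker,
detection of that same whisker improves on the following trials, while
detection of other whiskers degrades. `whiskattn` implements the complete
analysis chain for this phenomenon, for behavioural trial tables, two-photon
calcium imaging and spike recordings:

- **Trial-history classification** — every Go trial is categorised by the
  outcome, stimulus whisker and reward of the immediately preceding trials
  (`priorNoGo`, `prior1HitSame`, `priorGT1HitSame`, `prior1HitDiff`,
  `priorGT1HitDiff`, `priorMissSame`, `priorMissDiff`), with matched NoGo
  pools, hit-streak run lengths, facial offset classes and inter-Go
  intervals.
- **History-conditioned signal detection** — `d' = Z(HR) − Z(FA)` and
  criterion `c = −(Z(HR) + Z(FA))/2` (liberal responding negative) per
  history category, after sliding-d′ engagement-window trimming; somatotopic
  (Δd′ per facial offset class) and temporal (Δd′ per inter-Go interval,
  with exponential decay fits) profiles of the cueing effect.
- **Neural attentional modulation** — ΔF/F extraction with neuropil
  subtraction, evoked-response windows, permutation-test responsiveness
  with FDR correction, attention modulation indices
  `AMI = (Go_A − Go_B) / |Go_A + Go_B|`, per-condition linear baseline
  detrending for VIP cells, somatotopic spotlight profiles, and PSTHs.
- **Receptive-field shifts** — CW-centred 3×3 receptive fields per history
  condition, centre-of-mass shifts projected on the attention axis (CW →
  attended whisker, normalized), response modulation indices for CW and
  surround whiskers.
- **Single-trial population decoding** — per-session ridge logistic
  regression (10-fold cross-validated penalty) on outcome-balanced
  resamples, evaluated as the fraction of held-out trials called
  stimulus-present by history condition and field-best-whisker status.
- **Synthetic sessions with ground truth** — a generator that emulates the
  task (Go/NoGo draws, 3×3 whisker grid, ITI 3 ± 2 s, rewards, aborts), an
  effective-d′ behavioural model with spatial kernel and temporal decay,
  and tuned neural populations with a somatotopically confined attentional
  spotlight. Every stochastic output stores its generating truth, so all
  analyses are validated by parameter recovery.

## Worked example

```r
library(whiskattn)
library(dplyr)

grid <- whisker_grid()                                  # 3x3 array, D2 centre
session <- simulate_session(behavior_config_calibrated(n_trials = 600),
                            grid, seed = 42)
labels <- session |>
  trim_to_engagement(window = 50, cutoff = 0.5) |>
  classify_history(reward_threshold_fraction = 0.04)

history_sdt(labels) |>
  select(category, n_go, n_nogo, d_prime, criterion, delta_d)
#> # A tibble: 7 × 6
#>   category         n_go n_nogo d_prime criterion delta_d
#>   <chr>           <int>  <int>   <dbl>     <dbl>   <dbl>
#> 1 priorNoGo         140    112   1.21     0.0404  0
#> 2 prior1HitSame      39     81   1.89    -0.481   0.678
#> 3 priorGT1HitSame    10     15   2.12    -0.630   0.909
#> 4 prior1HitDiff      88     81   0.970   -0.0200 -0.243
#> 5 priorGT1HitDiff    21     15   0.611    0.125  -0.602
#> 6 priorMissSame      24     43   1.40     0.0280  0.192
#> 7 priorMissDiff      26     43   1.23     0.114  0.0202
```

Detection improves after hits to the same whisker — most after consecutive
hits (`delta_d = +0.91`) — and degrades after hits to a different whisker,
while the criterion shifts liberal (negative) after hits: the behavioural
signature of history-cued focal attention. Single-session `>1 hit`
categories carry few trials; pool sessions for stable estimates.

`run_pipeline(pipeline_config(seed = 1, out_dir = "run"))` executes the
whole chain (simulate → behaviour → neural → receptive fields → decoding →
report) and writes every metric table plus a JSON manifest with the derived
seeds and per-stage counts; identical config and seed give byte-identical
outputs.

## Tests

```r
# from the package root, after installation
testthat::test_dir("tests/testthat", package = "whiskattn",
                   load_package = "installed")
```

The suite covers exhaustive-enumeration oracles for the permutation tests,
a brute-force FDR cross-check, an inverse-normal SDT oracle, a hand-labelled
40-trial history fixture, closed-form AMI identities, and recovery of every
generator parameter (calibrated d′ levels, spatial kernel ordering, decay
constant, spotlight half-width, injected receptive-field shifts, decoder
benchmarks).

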