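---
title: "Models and methods for history-cued whisker attention analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for history-cued whisker attention analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(whiskattn)
```

`whiskattn` analyses history-cued focal attention in Go/NoGo whisker
detection: the improvement in detecting a specific whisker after recent
rewarded detections of that whisker, its somatotopic and temporal structure,
and its neural correlates in barrel cortex. This vignette documents the
models the package implements, the tunable parameters, the synthetic-data
generator used for validation, and the numerical and design choices made
where the methods left room.

## Signal detection model

Behaviour is summarised with the equal-variance Gaussian model. For hit
rate HR on Go trials and false-alarm rate FA on NoGo trials,

$$d' = Z(\mathrm{HR}) - Z(\mathrm{FA}), \qquad
  c = -\tfrac{1}{2}\left(Z(\mathrm{HR}) + Z(\mathrm{FA})\right),$$

with $Z$ the standard-normal quantile. The criterion carries the
liberal-negative sign convention: liberal responding (high HR *and* FA)
gives $c < 0$. The opposite sign convention also circulates; we use the one
under which reported liberal shifts after rewarded hits come out negative,
and state it in every function's documentation.

Rates of exactly 0 or 1 make $Z$ infinite. The default correction is
log-linear, replacing an extreme rate by $(k + 0.5)/(n + 1)$ — and only an
extreme rate, so mid-range estimates are untouched. `correction = "none"`
turns any extreme rate into an error instead. This matters mostly for
small history-conditioned cells; the correction also imposes a ceiling of
roughly $Z((n+0.5)/(n+1))$ on recoverable $d'$, which is why high-$d'$
conditions need on the order of a hundred trials before estimates stop
being compressed (see *Validation scales* below).

Sessions are trimmed to a task-engaged analysis window before any history
analysis: a sliding $d'$ (window of 50 non-aborted trials, centred, clamped
at the session edges) must reach a cutoff of 0.5 (1.2 is conventional for
spike recordings); the window runs from the first to the last qualifying
trial, excluding satiety-related low-performance epochs.

## Trial-history taxonomy

Each current Go trial is classified by the immediately preceding trials:
`priorNoGo`, a single prior hit to the same or a different whisker
(`prior1HitSame` / `prior1HitDiff`), two or more consecutive hits to one
consistent whisker (`priorGT1HitSame` / `priorGT1HitDiff`), or a prior miss
(`priorMissSame` / `priorMissDiff`). Streaks are maximal runs of hits to a
single whisker: a hit to a new whisker restarts the run at 1. Current NoGo
trials collapse whisker identity (`priorNoGo`, `prior1Hit`, `priorGT1Hit`,
`priorMiss`) and serve as the matched false-alarm pools — both the
same-whisker and different-whisker Go categories of a given depth share one
NoGo pool, since a NoGo trial has no current whisker.

Two look-back modes are provided. `consecutive` walks over all preceding
trials, so an intervening NoGo yields `priorNoGo`. `ignore-nogo` skips NoGo
trials, classifying by Go trials alone; it is the mode used for the
temporal profile, which asks how cueing decays with the time since the last
Go trial regardless of intervening NoGo trials. The two modes agree exactly
on sessions without NoGo trials (a property test enforces this).

Hits whose reward is below a configurable fraction of the session maximum
(default 4%) are flagged, and can optionally be treated as non-cueing
(`low_reward_as = "miss"`), reflecting the observation that unrewarded or
marginal rewards do not cue attention. Aborted trials are excluded as
current trials and skipped as history sources, but keep their place on the
session clock; whether they break a streak is configurable (default: they
do not, the methods being silent).

## Synthetic behaviour generator

The analyses this package implements presume no particular generative
behavioural model, so for validation the package adopts an effective-$d'$
formulation: history effects are injected
in $d'$ space and mapped to outcome probabilities through the same SDT
model the analyses assume. Per trial,

$$d'_{\mathrm{eff}} = d'_0 + \left(\beta_{\mathrm{same}} K(\Delta) -
  \beta_{\mathrm{diff}} (1 - K(\Delta))\right) \cdot e^{-\Delta t/\tau}
  \cdot f(\mathrm{run}),$$

where $K(\Delta)$ is a spatial kernel over the facial offset between the
prior-hit whisker and the current whisker (defaults: same = 1, same-row
adjacent = 0.8, same-arc adjacent = 0.45, diagonal = 0.05, further = 0),
$\tau$ the temporal decay constant (default 10 s), and $f$ = 1 after a
single hit and 1.75 after a streak. The observer's threshold is
$\lambda = d'_0/2 + c_t$, with $c_t$ shifted by a configurable amount
(default −0.2, i.e. liberal) on trials following any hit. Hit probability
is $\Phi(d'_{\mathrm{eff}} - \lambda)$ and false-alarm probability
$\Phi(-\lambda)$. Because the matched Go and NoGo pools share $\lambda$,
history-conditioned $d'$ estimates recover $d'_{\mathrm{eff}}$ exactly in
expectation — the criterion shift moves hit and false-alarm rates together
without biasing sensitivity recovery. Task structure follows the
experimental design: Go probability 0.55, uniform whisker identity on a
3×3 grid, inter-trial onset intervals uniform on 1–5 s (3 ± 2 s), graded
rewards with an occasional unrewarded hit, optional aborts. Every trial
stores its generating `gt_d_eff` and `gt_lambda`, and all recovery tests
compare estimates against this stored truth.

`behavior_config_calibrated()` pins the generating $d'$ of the three key
categories at reference point estimates — 2.45 after >1 same-whisker hits,
0.82 after >1 different-whisker hits, 1.13 after a NoGo — by disabling
temporal decay and flattening the kernel, so each category generates at
exactly its nominal value. The preset also raises the probability that a
Go trial repeats the previous Go whisker to 0.35 (the task variant that
manipulates local repetition probability while keeping marginal whisker
probabilities workable). This is a feasibility requirement, not an effect
tweak: under fully uniform sampling, 20 sessions of 600 trials contain only
about a dozen `priorGT1HitSame` Go trials, and with hit rates near 0.99 the
corrected inverse normal cannot reach 2.45 from a dozen trials no matter
the data. Repetition enrichment raises that count to ~150 without touching
the calibration constants.

Two further generator switches exist for specific study designs. For
temporal-decay studies (analysed with `ignore-nogo` labels),
`nogo_breaks_streak = FALSE` lets cueing persist across intervening NoGo
trials so the only attenuation is the elapsed-time decay; a Go miss always
resets the streak. And `multi_hit_scale = 1` makes the decay amplitude
independent of run length, so the binned same-vs-different $\Delta d'$
profile is a clean single exponential.

## Synthetic neural populations

Cells are scattered uniformly over the cortical map (optionally restricted
to an imaging field of ~1.5 columns around one whisker's column, which is
what makes a field best whisker meaningful), assigned to barrel columns by
centroid containment (outside every barrel → septal, with the nearest
column as columnar whisker), and tuned to whiskers by a Gaussian of the
distance between cell and column centroid (width 0.6 column widths by
default). Per-trial responses are `gain × tuning(stimulus) + noise`.

The attentional gain is multiplicative and comes in two modes. The
whisker-specific (pyramidal-like) mode is a somatotopic spotlight:
after prior hit(s) to whisker $a$, responses *to $a$* are multiplied by the
gain for cells within `gain_space_halfwidth` column widths of $a$'s
centroid (default 0.75 — the attended column plus the near half of its
neighbours), in the gain-bearing layers only. Making the gain
stimulus-specific is a deliberate modelling choice: a spatially uniform
multiplicative gain rescales a cell's whole receptive field and cannot move
its centre of mass, whereas the spotlight form simultaneously produces the
closed-form AMI identity on matching trials, the spatially confined
somatotopic profile, and receptive-field shifts toward the attended
whisker — the three phenomena the analyses quantify. The non-specific
(VIP-like) mode multiplies every cell's response after any prior hit,
regardless of stimulus or position; VIP traces additionally carry a
declining post-reward baseline (exponential, default amplitude 0.3 ΔF/F,
time constant 3 s) that exercises the detrending path. A single prior hit
applies half the full gain by default (`gain_run1_scale = 0.5`), matching
the qualitative single-vs-multi-hit ordering. Ground-truth per-trial,
per-cell gains are emitted alongside the responses.

## Neural metrics

ΔF/F is $(F_t - F_0)/F_0$ with $F_0$ the 20th percentile of the recording;
pyramidal-cell traces are neuropil-corrected first (raw − 0.3 × neuropil).
Evoked responses are the mean of a 7-frame (~0.8 s at 7.5 Hz)
post-stimulus window minus a 2-frame pre-stimulus baseline; windows are
specified in frames, with seconds derived, since frame counts are the
primitive the hardware defines. Optional z-scoring divides by the
baseline-epoch standard deviation pooled across trials. Spike responses
use a 0.5-s post-stimulus window against a pre-stimulus baseline, and
PSTHs use 10-ms bins.

Whisker-responsiveness uses a one-sided two-sample permutation test of Go
vs NoGo evoked responses per whisker (10,000 iterations by default),
FDR-corrected over the nine whiskers; a cell is responsive if at least one
whisker is significant *with a positive mean difference* — purely negative
modulations never qualify.

Attention modulation indices are normalized differences of condition-mean
evoked responses over current Go trials,
$\mathrm{AMI} = (\mathrm{Go}_A - \mathrm{Go}_B)/|\mathrm{Go}_A +
\mathrm{Go}_B|$, for (same vs NoGo), (different vs NoGo) and (same vs
different) histories. The denominator is the absolute value of the sum as
defined; below $10^{-6}$ (response units) the index is marked invalid
rather than clipped. Per-cell records require at least 3 trials in every
condition (the source methods exclude under-sampled cells without naming a
threshold; 3 is the package's choice). Under noiseless multiplicative gain
$g$ on matching trials the same-vs-NoGo AMI equals $(g-1)/(g+1)$ exactly,
which the tests verify.

VIP baseline detrending fits a line to the median pre-stimulus trace
(1.07-s window) of each history condition, extrapolates it over the whole
peri-stimulus extent, and subtracts it from every trial of that condition.
For exactly linear baselines the removal is exact (residual slope below
$10^{-9}$) and step-like evoked responses are preserved to the same
precision.

The somatotopic profile places every cell in a distance bin (default 0.25
column widths) from each reference whisker's column centre in turn,
averages evoked responses to that whisker per bin and history condition,
then averages over the nine reference whiskers with equal weight. The
attentional profile is the difference from the `priorNoGo` trace; the
*relative* profile divides by the `priorNoGo` somatotopy, normalizing out
tuning falloff so a boxcar spotlight appears as a step whose half-max
distance estimates the generating half-width. The half-max point is linearly
interpolated between bin centres.

## Receptive-field shifts

Per-cell receptive fields are 3×3 maps centred on the columnar whisker
(arc axis = x, rostral positive; row axis = y, upper rows positive),
with mean evoked response per stimulus offset and history condition, and a
sampling mask. The centre of mass is the response-weighted mean offset over
sampled positions; negative values are clipped to zero for weighting (the
CoM of a signed field is ill-defined) and the number of clipped positions
is reported. Best-whisker and surround-whisker selections break exact ties
row-major (upper rows first, then caudal to rostral) and flag them.

The shift along the attention axis projects the CoM displacement between
`priorNoGo` and attended conditions onto the unit vector from the CW
position to the attended whisker's offset, normalized by that distance, so
+1 means "moved all the way to the target" and negative values are shifts
away. Only offsets sampled in *both* conditions enter either CoM, at least
6 of the 9 positions must be shared, and per-cell shifts are averaged with
equal weight over the attended whiskers available for that cell.
Perturbation tests confirm the result is independent of values at
non-shared positions. Population-level CoMs weight cells equally.

Response modulation indices (CW and surround) use the same normalized
difference as the AMIs; the three surround whiskers with the strongest
baseline (`priorNoGo`) responses — selected among offsets sampled in both
conditions — define the SW pool.

## Population decoder

A separate ridge (L2) logistic regression per session predicts stimulus
presence from single-trial evoked responses of the included cells.
Training sets are rebalanced by undersampling so the four behavioural
outcomes (Hit, Miss, CR, FA) contribute equally; balancing is applied per
resampling iteration, before fold assignment. The ridge strength is chosen
by 10-fold cross-validated deviance over 30 logarithmically spaced values
spanning six decades, and performance is read from pre-validated (held-out
fold) predictions at the selected strength. Fold assignment is stratified
within class: with exactly balanced data, unstratified folds make the
held-out fold's class mix anti-correlate with its training set, which
depresses chance-level accuracy by several points; stratification removes
this artefact, and shuffled-label accuracy sits at 0.5 as it should.
Evaluation reports, per current-trial filter (any Go / field-best-whisker
Go / non-fBW Go / NoGo) and history category, the fraction of trials
called stimulus-present (threshold 0.5 on the logistic output) averaged
over 25 balancing iterations by default; trials outside a balanced sample
are scored by the model fit on that sample, so no trial is ever scored by
a model that trained on it, and balanced counts and fold disjointness are
asserted on every iteration. Shuffled-label controls run the identical
scheme.

## Orchestration and reproducibility

`run_pipeline()` chains simulate → behaviour → neural → receptive fields →
decoding → report, writing delimited tables and a JSON manifest (config
hash, derived seeds, per-stage counts). All randomness flows from one
master seed through a fixed counter scheme (`seed × 69069 + counter ×
10007 mod 2³¹−1`), so the manifest seeds reproduce every output exactly;
identical configuration and seed give byte-identical tables. Trial and
response tables are plain delimited text with fixed column sets; reading
validates monotone onsets, the Go ⇔ whisker-set invariant, outcome
domains, and referential integrity against the cell table, reporting the
offending row. Trial indices are 1-based throughout.

## Statistical machinery

Permutation tests use the add-one convention
$p = (1 + n_{\mathrm{extreme}})/(1 + n_{\mathrm{iterations}})$, so p-values
are never zero and remain valid at any iteration count; the two-sided
two-sample statistic is $|\bar a - \bar b|$, sign-flip resampling handles
paired differences, defaults are two-sided with 10,000 iterations, and
every test takes an explicit seed and reproduces bit-identically.
Multiple comparisons use Benjamini–Hochberg FDR; the two-category
binomial exact test is two-sided by minimum likelihood. Each of these is
cross-checked in the test suite against an independent brute-force oracle
(exhaustive label enumeration, exhaustive sign patterns, a from-definition
step-up, a direct minimum-likelihood sum).

## Validation scales and limitations

The test suite validates by parameter recovery at sizes chosen to leave
comfortable Monte-Carlo margins: behavioural calibration on 20 sessions ×
600 trials with session-level bootstrap CIs (about 150 `priorGT1HitSame`
trials under repetition enrichment); kernel-rank recovery on 30 × 800
trials with a widened-contrast kernel (adjacent-class gaps of ~0.3–0.5 d′
units, since rank stability needs gaps comfortably above per-class
standard errors); decay-constant recovery on 90 × 800 trials (fitted
against each bin's *mean* interval — intervals are not centred within
bins, and the first bin cannot reach below the minimum ITI, so bin
midpoints would bias the constant upward by ~10%); spotlight half-width
on 30 populations of 100 cells; receptive-field nulls on 500+ cells. The
recovery-bias bound for the whisker-specific Δd′ is tested as
|mean bias| < 0.1 + 2 SE over replicates, because the nominal 0.1-d′ bound
sits below single-replicate Monte-Carlo resolution at these scales.

What passing these tests shows — and what it does not: the generator
emulates the statistical structure the analyses assume (SDT outcomes,
multiplicative gains, Gaussian noise, exponential decay), so recovery
demonstrates the correctness of the estimators, not the biological
fidelity of the model. Real data violate several conveniences: calcium
indicators are nonlinear and temporally smeared, noise is correlated
across cells and time, engagement drifts continuously rather than only at
session edges, and attentional gain need not be a clean boxcar in space or
exponential in time. Analyses that depend only on exchangeability
(permutation tests, FDR, balancing) transfer directly; parametric
summaries (d′, AMI magnitudes, decay constants) inherit the usual caveats
of their models.
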