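---
title: "Methods: engagement states in CPT calcium imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: engagement states in CPT calcium imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cptstates)
```

This vignette is the package's account of its methods: the models, their
assumptions, the tunable parameters and why their defaults are what they
are, what the synthetic generator does and does not emulate, and the
numerical choices a maintainer would want written down.

## The task and its scoring

In the rodent continuous performance test a mouse watches a touchscreen on
which a rewarded target (S+) or an unrewarded non-target (S−) appears for a
stimulus duration (SD, 2 s), followed by a limited hold (LH, 2.5 s) during
which a touch still counts, and an inter-trial interval (2 or 3 s, drawn at
random). Touching S+ is a hit, touching S− a false alarm (FA); withholding
is a miss (S+) or correct rejection (CR, S−). A false alarm triggers a
correction trial: S− is re-presented until the animal withholds.

`score_session()` computes the signal-detection measures on free-choice
trials (correction trials are excluded by default — they are forced S−
re-presentations, and counting them would double-weight S− exposures):

- `HR = hits / (hits + misses)`, `FAR = FA / (FA + CR)`;
- discrimination `d′ = z(HR) − z(FAR)` with `z` the standard-normal
  quantile;
- criterion `c = −(z(HR) + z(FAR)) / 2`, the standard SDT response-bias
  measure (high `c` = conservative, non-responding strategy).

Extreme rates (0 or 1) would give infinite quantiles, so they are replaced
by the log-linear correction `(x + 0.5)/(n + 1)` — standard SDT practice;
non-extreme rates are left untouched.

Stage advancement uses the conventional thresholds: at least 60 hits in two
consecutive sessions (stage 2), d′ ≥ 0.6 on two consecutive days (stage 3),
and at least 55 hits for a session to count as a recording session.

**Disengagement periods.** `response_latency_series()` takes the intervals
between consecutive active responses (hits or FAs, merged in time order);
`detect_disengagement_periods()` flags intervals exceeding
`mean + 2·SD` of the session's own series, using the sample (n−1) SD. Each
period spans from the earlier to the later response bounding the gap. A
zero-variance series yields a threshold equal to the mean and no periods,
with a warning.

## Peri-event modulation classification

Traces are z-scored per neuron over the whole session. Around each event we
cut a visual window of 8 s on each side (161 frames at 10 Hz) and define
two statistical windows: pre = [−3, 0) s and post = [0, 3) s relative to
the event frame (`floor(time × rate)`, frames half-open so each window is
exactly 30 frames and the event frame belongs to post). The statistic is

Δ = mean over events of (mean post-window activity − mean pre-window
activity).

The null preserves both signals' autostructure: each of 1000 shuffles draws
one uniform offset in [1, T−1] frames and shifts *all* event frames by it
modulo T — a single shared offset per shuffle keeps the inter-event
interval structure intact, which matters because events cluster in engaged
periods. Windows of shifted events wrap around the session edge (the
exhaustive-enumeration oracle in the tests requires exactly this); observed
events whose visual window crosses an edge are dropped and counted rather
than padded. The bootstrap probability is the plain fraction of null Δ
values ≥ the observed Δ (ties counted as ≥, no (k+1)/(n+1) adjustment), and
a two-tailed rule labels a neuron up if `boot_p < α/2`, down if
`boot_p > 1 − α/2`, otherwise non-modulated (α = 0.05). With 1000 shuffles
this rule's exact nominal two-sided level is ≈0.049, slightly conservative;
the calibration tests interpret rates with that in mind.

Alignment is either to the screen touch (response time) or to the stimulus
onset of the same trials (`peri_event_times()`); hits and false alarms are
analyzed separately or pooled. The event-averaged visual-window trace is
attached per neuron (`mean_trace`) for inspection of ramp/slope shapes; no
bespoke slope statistic is defined.

One interaction worth knowing: when responding is strongly gated by a
latent engagement state, the engagement probability is necessarily highest
at the stimulus onset that produced the response — a few seconds *before*
the touch. Cells whose rate is elevated while engaged therefore show a
small genuine negative Δ at touch alignment. This is a property of
state-gated behavior, not an artifact of the test.

## Engagement-state inference

Preprocessing truncates to the first 45 min (27,000 frames at 10 Hz),
z-scores each neuron, applies a 1 s (10-frame) centered moving average
(partial windows at the session edges are normalized by the frames actually
available, so the output has full length with no missing values), and fits
PCA on the smoothed matrix. The HMM runs on the first 10 PC score columns;
the cumulative variance of the first 45 PCs is recorded as a quality check.
Both counts are configurable; 10 PCs keep the state model low-dimensional
while the 45-PC summary documents how much population variance the basis
spans.

The model is a k-state Gaussian HMM with diagonal covariance (k = 2 by
default), fitted by EM for up to 200 iterations with a convergence
tolerance of 0.01 on the total log-likelihood. Initialization is seeded
k-means on the scores with 0.95 stay-probability transitions; three seeded
restarts are run and the best training log-likelihood kept — a guard
against EM local optima, with every seed recorded. Variances are floored at
1e−6. Decoding uses the Viterbi path (a single discrete state sequence);
per-frame posterior argmax is available as an option and differs only at
ambiguous frames.

Model validation follows two routes. `select_state_count()` fits k = 1, 2, 3
with shared preprocessing and seed policy and reports training
log-likelihoods (the family is nested, so k = 2 can never fit worse than
k = 1; the tests assert this). `crossvalidate_hmm()` splits the session into
four contiguous quarters and, on fold f, trains on the first f quarters and
tests on quarter f+1 — always training on the past and testing on the
future, because network dynamics evolve within a session and shuffled CV
would leak future structure. Log-likelihoods are reported per frame for
comparability across unequal segments.

**Event posteriors and labeling.** Timestamps of hits, mistakes (false
alarms — the only active error in this task), and their union ("Any") are
converted to frame indices (`floor(t × 10)`, binarized so repeated events
in a frame count once), and `P(state_i | event type)` is the fraction of
those frames decoded in state i. The engaged label goes to the state with
the highest P(state | Any); relabeling states permutes nothing else
(asserted as an invariance test). Disengagement-period frames (all frames
inside detected latency-peak periods) are summarized the same way against
the complementary state.

`correlate_engagement_with_behavior()` relates the per-animal probability
of responses falling in the engaged state to behavioral metrics (mean
inter-response latency, its CV, criterion c, and raw counts as null
comparisons) with Pearson r and two-sided p.

## State-conditioned correlation networks

For each state, all frames decoded in it are collapsed and pairwise Pearson
correlations computed; self-correlations are set to zero. Per cell, the
maximum positive and most negative correlation with any partner are
extracted, and distributions are compared between states with the
two-sample Kolmogorov–Smirnov test.

**Pair significance.** The null for a pair correlation multiplies one
member by a random per-frame ±1 sign vector and recomputes r. A single
global flip would only negate r, so flips are per frame, which destroys the
cross-correlation while keeping marginal scales — an r ≈ 0 null. 10,000
iterations (over randomly drawn pairs) build one pooled null; a pair is
significantly positive above the 97.5th percentile, significantly negative
below the 2.5th (two-sided α = 0.05). Fewer than 100 iterations triggers an
instability warning.

**Spatial decay.** For each category (positive / negative /
non-significant) the model `y = A·exp(k·x)` is fitted to pair correlation
versus inter-cell distance (µm) by Levenberg–Marquardt least squares with a
log-linear start; non-convergence falls back to the log-linear estimate
with a flag. More negative k = faster decay. The negative category is
fitted on |r| (fitting a positive-A exponential to negative values is
ill-posed) and A's sign is restored in reporting. 95% CIs come from a
percentile bootstrap over pairs (1000 resamples); pair-level resampling
matches the fit's observation unit but ignores the dependence of pairs
sharing a cell, so the CIs are somewhat anti-conservative — a known caveat.
Decay rates of two fits are compared with
`z = (k₁ − k₂)/√(se₁² + se₂²)` using the bootstrap SEs.

**Clusters.** K-means runs on the correlation-matrix rows (a cell's
correlation profile — the feature space is not canonical, and profiles make
cells with similar partners cluster together); K is chosen by mean
silhouette over a 2..6 grid with seeded restarts. Cluster size and spatial
compactness (mean distance of member cells to the cluster's spatial
centroid; singletons get 0 with a flag) summarize spatial organization.
Matched pairs are partitioned intra-/inter-cluster × positive/negative
(sign-concordant across both states; discordant pairs are excluded and
counted) and compared between states with paired t-tests, plus Spearman's ρ
of correlation versus distance per state. Pairs at identical coordinates
get distance 0 and are retained.

## The synthetic generator

`generate_session()` produces the study's data structure with known ground
truth:

- **Latent states:** a discrete-time two-state Markov chain at 10 Hz with
  stay-probability `1 − 1/(dwell_s × 10)` (default 60 s mean dwell per
  state) — the same generative family the HMM assumes, so recovery tests
  are well-posed.
- **Behavior:** stage-conditional trial schedule (SD 2 s, LH 2.5 s, ITI
  2/3 s, 50% targets in stage 3, correction trials after FAs); the per-trial
  response probability is gated by the state at stimulus onset (defaults
  0.9 engaged / 0.05 disengaged); response latency is uniform on
  [0.5, SD+LH] s, a spread-out stand-in for the ~1.8 s mean latencies of
  trained mice.
- **Traces:** latent rate = state-dependent mean shift (default 1 SD on 50%
  of neurons, the strong-signal regime) + raised-cosine bumps of width 2 s
  centered at each touch (+ for up-modulated cells, − for down-modulated;
  amplitude in baseline-SD units, default 2) + a shared Gaussian component
  whose target correlation is `base · exp(−decay_rate · d_ij)` with
  assembly-block base levels per state (assemblies are spatially contiguous
  k-means groups of the centroids). The construction makes the planted
  pairwise-decay constant equal `spatial_decay_rate` (default 0.004 /µm)
  by design, so decay-recovery tests have an exact target. The latent rate
  passes through a single-exponential calcium kernel (τ = 0.7 s,
  GCaMP6f-like at 10 Hz; no rise time, which 10 Hz sampling cannot resolve
  anyway) and unit-SD white noise is added.
- **Geometry:** centroids uniform on a 450 µm square field of view, typical
  for miniscope recordings; all distances in µm.

Defaults are the study conditions: 45-min sessions at 10 Hz and 150 neurons
per session (per-session counts are not published; 150 is a realistic
single-animal yield consistent with pooled totals in the low thousands over
~13 mice).

What the generator does **not** emulate: photon/motion artifacts,
photobleaching, slow drift, cell-extraction cross-talk, non-Gaussian
transient shapes, multi-session registration, or stimulus-selective
responding (the synthetic animal discriminates at chance, like an
early-training session). Passing tests therefore demonstrate that the
pipeline recovers the statistical structure it targets — not that real
recordings satisfy these idealizations.

`generate_null_traces()` provides stationary AR(1) noise (coefficient 0.8
by default, roughly matching the autocorrelation a 0.7 s calcium kernel
imposes) with no event-locked structure, for calibrating the classifier's
false-positive rate. `generate_cohort()` derives per-animal seeds
deterministically from a base seed and can jitter response probabilities
across animals.

## Numerical choices and degenerate inputs

- Time→frame conversion is `floor(t × rate)` everywhere; windows are
  half-open in frames.
- Zero-variance cells: dropped with a warning before z-scoring; an error in
  HMM preprocessing (a constant cell there indicates a broken extraction);
  NA pairs in state correlation matrices.
- The EM log-likelihood is computed in a scaled forward pass (per-frame
  max-shifted densities) in compiled code; underflow raises an error rather
  than returning garbage.
- `boot_p` ties count as ≥; the classifier's nominal level is ≈0.049, and
  calibration bands in the tests are read against that.
- Empirical false-positive rates of the classifier carry Monte Carlo noise
  beyond the binomial component, because one event constellation is tested
  against 1000 sampled offsets; calibration checks therefore pool several
  independent event placements rather than widening their bands.
- K-means and EM are seeded everywhere; a global pipeline seed
  deterministically derives every stage seed, and rerunning a pipeline
  configuration reproduces outputs byte-for-byte (asserted in the tests).

## Problem sizes used by the tests

Unit tests run on sessions of 5–20 min with 10–60 neurons, where every
property already holds; the calibration and recovery suite uses the full
study scale where the claim demands it (500 neurons × 27,000 frames for
classifier calibration; ten 45-min, 150-neuron sessions for engagement
recovery; 27,000-frame simulations for transition-probability recovery).
These sizes were chosen as the smallest at which the targeted quantities
are estimated with comfortable margin relative to their sampling noise.

## Known limitations

- The HMM assumes conditionally independent Gaussian emissions in PC space;
  systematic non-stationarities (drift, bleaching) would be absorbed into
  state means and can masquerade as states. The forward cross-validation
  table is the diagnostic to watch.
- Bootstrap CIs for decay fits ignore shared-cell dependence between pairs
  (anti-conservative).
- The paired coupling comparison conditions on sign concordance across
  states, which discards sign-flipping pairs; their count is reported.
- Engagement labeling needs at least one active response; sessions with
  none leave the posterior undefined (flagged rather than guessed).
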