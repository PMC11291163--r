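# cptstates

Engagement-state analysis of single-cell calcium imaging recorded while
rodents perform a touchscreen continuous performance test (CPT).

Sustained attention fluctuates within a session: stretches of brisk
responding alternate with non-responsive lapses. `cptstates` implements a
complete, tested pipeline for asking how prefrontal population activity
tracks those fluctuations, for anyone working with miniscope/GCaMP trace
matrices plus touchscreen event logs:

- **Behavioral scoring** — outcome counts, hit rate `HR = hits/(hits+misses)`,
  false-alarm rate `FAR = FA/(FA+CR)`, discrimination index
  `d′ = z(HR) − z(FAR)`, response criterion `c = −(z(HR)+z(FAR))/2`,
  inter-response latency series, and non-responsive (disengagement) periods
  defined as latencies exceeding `mean + 2·SD`.
- **Peri-event modulation** — each neuron's Δ activity (mean z-scored
  activity in a 3 s post-event window minus a 3 s pre-event window, averaged
  over events) tested against a null built by circularly shifting the event
  times relative to the trace (1000 shuffles, two-tailed α = 0.05); neurons
  are labeled up-, down-, or non-modulated.
- **Engagement states** — z-score → 1 s centered moving average → PCA →
  two-state Gaussian HMM with diagonal covariance on the first 10 PCs (EM,
  ≤200 iterations), Viterbi decoding, forward three-fold cross-validation,
  and event-conditioned state posteriors
  `P(state_i | event) = (event frames decoded in state i) / (all event frames)`;
  the state that captures most responses is the engaged state.
- **State-conditioned correlation networks** — pairwise Pearson matrices per
  state (zero diagonal), sign-flip permutation significance (10,000
  iterations), exponential spatial decay fits `y = A·exp(k·x)` with bootstrap
  CIs and z-tests on `k`, K-means clustering of correlation profiles with
  silhouette-selected K, cluster size and spatial compactness, and paired
  intra-/inter-cluster coupling comparisons between states.
- **Synthetic sessions** — a generator with full ground truth (latent
  engaged/disengaged Markov chain gating response probability, planted
  up/down event-locked neurons, state-dependent spatially decaying
  correlations, exponential calcium kernel) so every stage is testable
  without animal data.

Everything is tibble-first and pipe-friendly; fitted objects have
`tidy()`/`glance()` methods and `autoplot()`/`plot_*()` figures.

## Worked example

```r
library(cptstates)

cfg <- synthetic_config(n_neurons = 60, session_length_s = 1200, seed = 42)
session <- generate_session(cfg)

score_session(session$trials)
#>    hits misses   FAs   CRs    HR   FAR d_prime       c mean_latency_hit_s
#> 1    30     26    23    20 0.536 0.535 0.00209 -0.0886               2.84
```

The synthetic animal responds at chance discrimination (d′ ≈ 0, as in an
early-training session) because its response probability depends on the
latent engagement state, not on the stimulus.

```r
w <- peri_event_windows(n_shuffles = 1000, seed = 0)
mod <- peri_event_analysis(session$traces,
                           peri_event_times(session$trials, "any"), w)
dplyr::count(mod, label)
#>   label     n
#> 1 up        9
#> 2 down     15
#> 3 non      36
```

All 9 planted up-modulated neurons are recovered (`session$truth$up_neurons`).
The down set contains the 6 planted down-modulated cells plus
state-modulated cells whose firing is elevated while engaged: responses are
conditioned on engagement at stimulus onset (seconds before the touch), so
engagement probability is slightly higher in the pre-window — a real, if
subtle, feature of state-gated behavior.

```r
hcfg <- hmm_config(truncate_s = 1200, n_pcs_retained = 30, seed = 1)
pcs <- preprocess_for_hmm(session$traces, hcfg)
model <- fit_hmm(pcs, 2, hcfg)
states <- decode_states(model, pcs)
event_state_posteriors(states, session$trials,
                       detect_disengagement_periods(session$trials))
#> engaged state: 1 | P(responses | engaged) = 0.944 |
#>   P(disengagement periods | disengaged) = 0.920
```

94% of behavioral responses fall in the decoded engaged state and 92% of
latency-peak frames fall in the disengaged state, recovering the planted
state gating. Downstream, `correlation_network()`, `fit_correlation_decay()`,
`cluster_states()`, and `compare_cluster_coupling()` characterize the
state-conditioned pairwise structure, and `run_pipeline()` chains every
stage with a manifest of seeds, parameters, and output hashes.

A command-line wrapper with `simulate` / `score-behavior` / `perievent` /
`engage` / `network` / `run-all` / `validate` subcommands is installed at
`inst/cli/cptstates.R`.

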