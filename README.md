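# tastedyn

Analysis pipeline for trial-structured gustatory-cortex electrophysiology
and jaw electromyography (EMG), built around a single scientific question:
cortical taste responses move through three sequential ensemble firing
states — taste **detection**, taste **identity**, and taste
**palatability** — and the single-trial timing of the transition into the
palatability state (C\_P) relates to when the animal begins the aversive
orofacial behavior (rhythmic 4–6 Hz *gaping*) by which rats reject bitter
tastes. The package is written for systems neuroscientists who want these
estimators as tested, reusable components, with a synthetic-data module
standing in for recorded sessions so every stage can be validated by
parameter recovery.

## What it implements

* **Ensemble change-point detection.** Spiking is collapsed to one
  categorical symbol per 10 ms bin (which neuron spiked; 0 = none). A
  constrained two-change-point model — emission distributions
  α\_D (one), α\_I (one per taste quality), α\_P (one per taste) over
  {0..N}, with C\_I ∈ [0.2, 0.6] s and C\_P ∈ [C\_I+0.2, 1.3] s — is fit
  by multi-restart **hard EM**: the E-step takes an exact argmax over all
  admissible (C\_I, C\_P) pairs, the M-step renormalizes pooled emission
  counts, and the best of (default) 100 random restarts is kept. Laser
  trials have their 0.5 s perturbation window excised and spliced;
  change-points in the 50 ms seam before laser onset are flagged.
* **Perturbation GLM.** Per-neuron spike counts S ~ Poisson(firing(T,O))
  with log-link mean μ\_T + μ\_O + μ\_{T,O}, hierarchical Normal/
  Half-Cauchy priors; a neuron is suppressed/enhanced when the 95% CI of
  the (control − laser) firing difference excludes 0.
* **Palatability dynamics.** Firing in 250 ms bins (25 ms steps) is
  z-scored per (neuron, bin), sign-aligned by each neuron's Spearman
  correlation with palatability rank, and regressed per bin:
  firing ~ Normal(β\_t · P, σ). The baseline-normalized β̄(t) series is
  summarized by a logistic sigmoid (lower asymptote 0) with peak latency
  t\_peak = ln(19)/k + t₀, the time of 95% of the asymptote L.
* **Gaping onset from EMG.** Channel difference → 1 kHz → Butterworth
  filters → envelope; each 300 ms window gets a Bayesian single-sinusoid
  frequency posterior on a 20-point 1–10 Hz grid, and Pr(Gape) is the
  posterior mass in 4–6 Hz. Per-bin Beta(a, b) distributions of gaping
  across trials are contrasted between quinine concentrations by
  closed-form KL divergence; the change-point C of a Bayesian
  piecewise-linear fit to the cumulative KL (C ~ Uniform(0, 2000) ms) is
  the mean gaping onset, and delays between conditions come from paired
  posterior draws.
* **Orchestration.** `run_transition_conditioned_analysis()` chains the
  two modalities: fit ensemble change-points, split laser trials by
  whether the transition preceded the laser, and estimate gaping-onset
  delays separately per split — the analysis that shows perturbation
  delays gaping only when it begins before the palatability transition.

MCMC is JAGS (`rjags`) with 4 seeded chains and a Gelman–Rubin R-hat
contract of [0.99, 1.01]; the change-point model deliberately uses EM
instead of sampling because its two-mode label-switching posterior defeats
MCMC convergence.

## Worked example

```r
library(tastedyn)

cfg <- ensemble_sim_config(n_neurons = 10, trials_per_taste = 15)
session <- simulate_ensemble_session(cfg, seed = 1)
session
#> <spike_train_set> 60 trials, 10 neurons, window [-0.5, 2.5] s
#>           control early middle late sustained
#>   DilSuc       15     0      0    0         0
#>   ConcSuc      15     0      0    0         0
#>   DilQui       15     0      0    0         0
#>   ConcQui      15     0      0    0         0

series <- make_categorical(session, "control", seed = 2)
fit <- fit_changepoints(series, restarts = 20, seed = 3)
fit
#> <changepoint_fit> condition control, 60 trials, log-likelihood -13895.369 (restart 6)

truth <- attr(session, "ground_truth")
median(abs(fit$trials$c_p_s - truth$c_p[series$trial]))  # seconds
#> 0.026

head(fit$trials[, c("trial", "taste", "c_i_s", "c_p_s", "post_prob")], 5)
#>   trial  taste c_i_s c_p_s  post_prob
#> 1     1 DilSuc  0.28  1.23 0.07683282
#> 2     2 DilSuc  0.31  0.73 0.09814084
#> 3     3 DilSuc  0.38  0.84 0.01686253
#> 4     4 DilSuc  0.56  0.95 0.07113820
#> 5     5 DilSuc  0.33  0.84 0.02404592
```

Each trial gets its identity- and palatability-state onset in seconds
(`c_i_s`, `c_p_s`) plus the posterior probability of that (C\_I, C\_P)
pair under the fitted emission distributions; on this 15-trials-per-taste
session the palatability transition is recovered with a median error of
26 ms (2–3 bins). The same session objects feed the GLM
(`spike_count_table()` → `fit_perturbation_glm()`), the palatability
index (`bin_spikes()` → `standardize_and_align()` →
`fit_palatability_index()` → `fit_sigmoid()`), and, for EMG sessions from
`simulate_emg_session()`, the gaping pipeline (`preprocess_emg()` →
`bsa_gape_probability()` → `beta_bin_series()` →
`kl_divergence_series()` → `fit_onset_changepoint()` →
`compare_onsets()`).

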