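---
title: "Models and methods: ensemble state dynamics and gaping onset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: ensemble state dynamics and gaping onset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`tastedyn` implements the statistical machinery for a single question about
cortical taste processing: rat gustatory-cortex ensembles pass through
three sequential firing states after a taste hits the tongue — a broadly
taste-nonspecific *detection* state, a *taste identity* state, and a
*palatability* state whose onset predicts the animal's consummatory
decision — and the transition time into the palatability state, estimated
on single trials, can be related to the onset of aversive orofacial
behavior (gaping) measured from jaw EMG. The package provides four
analysis engines plus a synthetic-data generator that emulates the latent
structure all of them assume:

1. a hierarchical Bayesian Poisson GLM quantifying how an optogenetic
   perturbation changes single-neuron firing;
2. a per-time-bin Bayesian regression of standardized firing on
   palatability rank, summarized by a logistic-sigmoid time-course model;
3. a constrained two-change-point model of categorical ensemble emissions
   fit by multi-restart hard EM;
4. an EMG pipeline: envelope extraction, windowed Bayesian spectrum
   analysis (BSA) of 4–6 Hz gaping rhythmicity, and a Beta/KL
   change-point estimator of mean gaping onset.

All Bayesian models are sampled with JAGS (via `rjags`) using one seeded
RNG stream per chain; convergence is monitored with the Gelman–Rubin
R-hat and accepted within \[0.99, 1.01\]. Credible intervals are
equal-tailed quantile intervals by default (HPD available), and
CI-excludes-zero is the significance convention throughout.

# Conventions

Time is in seconds relative to taste delivery at $t = 0$; all bins are
half-open $[t, t+\Delta)$, which prevents double counting when a step
equals the width. Palatability ranks are fixed: ConcSuc 4, DilSuc 3,
DilQui 2, ConcQui 1. Neuron indices run $1..N$, with 0 reserved for "no
spike" in the categorical coding. Perturbation (laser) windows are
early (0–0.5 s), middle (0.7–1.2 s), late (1.4–1.9 s) and a sustained
2.5 s variant.

# Perturbation GLM

Spike counts $S_{i,T,O}$ aggregated per trial over a window are modeled
as Poisson with log-mean $\mu_T + \mu_O + \mu_{T,O}$; each effect is drawn
around a shared fixed effect ($\mathcal N(0, 10)$) with Half-Cauchy(1)
spread. The inferential target is the cell mean $firing_{T,O}$, which is
identified even though the additive structure is not; no sum-to-zero
constraints are imposed. A neuron is called *suppressed*/*enhanced* when
the 95% CI of the (control − laser) difference lies entirely
above/below 0; the headline call uses the taste-averaged contrast, with
per-taste contrasts also reported.

The aggregation window is configurable; by default counts are taken over
each laser trial's own laser window and, for control trials, over the same
condition-matched window, making off/on cells directly comparable. Calibration on simulated Poisson neurons with equal
rates yields ≈5% false calls, and a 0.3× suppression at 15 trials/cell is
detected in >90% of neurons.

# Palatability index and its time course

Firing rates are binned at 250 ms moved by 25 ms from −0.25 to 1.5 s.
Standardization is per (neuron, bin) across trials (z-scores); bins with
zero across-trial variance are set to 0 and flagged rather than dropped,
preserving array shapes. Each neuron is then multiplied by the sign of its
time-averaged Spearman correlation with palatability rank; the averaging
window defaults to 0–1.5 s post-delivery, the analysis window. Per bin,
pooled standardized firing is regressed on rank with
$\beta \sim \mathcal N(0,1)$, $\sigma \sim$ Half-Cauchy(1); each bin is
fit independently (no temporal smoothing prior), with its own $\sigma$. The posterior-mean series is
baseline-normalized by subtracting its pre-stimulus average, so the
baseline of the normalized series is exactly zero.

The time course of the normalized index is summarized with a logistic
sigmoid whose lower asymptote is fixed at 0: upper asymptote
$L \sim \mathcal N(0, 0.1)$ truncated positive, slope
$k \sim \mathcal N(1, 1)$ truncated positive (per ms), inflection
$t_0 \sim \mathcal N(675, 75)$ ms truncated positive, noise
Half-Cauchy(1). Times are converted to milliseconds inside this fit
because the $t_0$ prior lives in ms. The fitted datum is the
posterior-mean index series itself — the model describes the averaged
time course, not raw rates. The peak latency $t_{peak} = \ln(19)/k + t_0$ is a
draw-wise transform, and the identity
$\mathrm{sigmoid}(t_{peak}) = 0.95\,L$ holds algebraically for every
draw. Fits on perturbation-era series violate curve-fitting stationarity;
they are produced but tagged with a warning (`stationary = FALSE`), and
slope estimates of such fits should not be interpreted.

# Ensemble change-point model

Spikes are collapsed to one categorical symbol per 10 ms bin (the index of
the spiking neuron, 0 if none; collisions resolved by a seeded uniform
pick). Each trial contributes 1.5 s (150 bins) of analyzable activity:
control trials use 0–1.5 s; on 0.5 s perturbation trials the laser window
is excised and the flanks concatenated (early: 0.5–2.0 s; middle:
0–0.7 s ∪ 1.2–2.0 s; late: 0–1.4 s ∪ 1.9–2.0 s). The spliced series is
treated as contiguous in the likelihood; the artifactual change-points
this produces at the splice are part of the method and are handled by the
seam rule below.

The model has one detection distribution $\alpha_D$, one identity
distribution per taste quality (sucrose vs quinine; a switch allows four),
and one palatability distribution per taste, each categorical over
$\{0..N\}$. $C_I$ is constrained to \[0.2, 0.6\] s of the analyzable
series (from 0.1 s in the early condition) and $C_P$ to
\[$C_I$+0.2, 1.3\] s (gap 0.1 s in the middle condition); interval
endpoints map to bin indices by flooring, bounds inclusive. Fitting is
hard EM: the E-step enumerates every admissible $(C_I, C_P)$ pair per
trial exactly and takes the argmax (ties broken toward the earliest pair,
deterministically); the M-step sets each distribution to its pooled,
normalized emission counts. Although the likelihood factorizes per trial,
the identity and palatability distributions are shared across
all trials of the condition, so M-step counts pool over every segment a
distribution governs. Each of the (default 100) restarts draws its
initial distributions from a symmetric Dirichlet(1); runs iterate to an
absolute log-likelihood tolerance of 1e-8 or 300 iterations, and the best
final log-likelihood wins. The log-likelihood is asserted non-decreasing
within every run. The categorical conversion is fixed once per seed;
restarts vary only the initialization. Zero-probability emissions are
handled with a large finite log-penalty (−1e9) rather than −Inf, which
keeps the cumulative-sum segment arithmetic of the E-step well defined on
sparse data.

Per trial the fit reports a posterior probability of the chosen pair —
the joint likelihood normalized over all admissible pairs under the final
distributions. `split_trials_by_transition()` partitions trials by
whether the palatability transition preceded laser onset by more than
50 ms; change-points inside that 50 ms seam are flagged and excluded, as
change-points in the two bins before a splice are uninterpretable. To
avoid an ambiguity in informal labels like "pre-transition", the groups
are named `transition_first` ($C_P <$ onset − 50 ms) and `laser_first`;
the perturbation is expected to delay gaping only in the `laser_first`
group, where it began before the ensemble had transitioned.

# EMG spectral analysis

Raw two-channel EMG at 30 kHz is differenced (cancelling common-mode
movement artifacts), block-averaged by 30 to 1000 Hz, highpass filtered
at 300 Hz (2nd-order Butterworth), rectified, and lowpass filtered at
15 Hz, yielding the envelope. Note the 300 Hz highpass leaves only the narrow 300–500 Hz band at the
1000 Hz rate; the cascade is implemented exactly in this order.
Filters are single-pass (causal) by default with a zero-phase option.

Each 300 ms envelope window, stepped by 1 ms and mean-subtracted (a
constant offset otherwise leaks into the lowest frequencies), is modeled
as a single sinusoid of unknown frequency, amplitude and phase plus
Gaussian noise. With flat priors on the two quadrature amplitudes and a
Jeffreys prior on the noise scale, both are marginalized analytically:
$p(f \mid d) \propto |G'G|^{-1/2} (d'd - h^2)^{-(N-2)/2}$ with $G$ the
cosine/sine design at $f$ and $h^2$ the projection of the data onto it.
The posterior is normalized over a 20-point grid spanning 1–10 Hz
(spacing ≈ 0.474 Hz), and Pr(Gape) is the mass on grid points inside the
closed 4–6 Hz band (four points). The implementation is verified against
a brute-force grid marginalization of amplitudes and noise on short
windows.

Pr(Gape) at time $t$ indexes the window *starting* at $t$. This choice
matters: a 4–6 Hz rhythm needs most of a window's worth of cycles before
it can dominate a faster competing rhythm (licking) in a winner-take-all
posterior, so start indexing places the detected rise at the rhythm's
onset, whereas center indexing would put it roughly half a window late.
Empirically the detected rise slightly anticipates the first gape,
matching how spectral gaping probability behaves on real recordings.

# Gaping onset

Per 1 ms bin and per quinine concentration, gaping across trials is
summarized as Beta(a, b) with a = trials with Pr(Gape) > 0.5 and
b = trials with Pr(Gape) < 0.5 (exact ties excluded); a Laplace
pseudo-count (+1, with a Jeffreys +0.5 option) keeps both parameters
positive in every bin. The divergence of concentrated from dilute quinine
is the closed-form Beta KL divergence (log-Beta difference plus digamma
terms, validated against an independent quadrature oracle to 1e-6). Its cumulative sum over time shows the onset
of gaping as a slope change, which is estimated with a Bayesian
piecewise-linear change-point: intercepts $\mathcal N(0,3)$, slopes
$\mathcal N(0,1)$ per ms, $C \sim$ Uniform(0, 2000) ms, noise
Half-Cauchy(0.5).

Two numerical choices matter here. First, the series is thinned from the
1 ms grid to every 10 ms before sampling (201 points over 0–2 s); the
cumulative sum is extremely smooth, and the thinning changes estimates
negligibly while keeping the sampler fast. Second, the series is scaled
to unit standard deviation before sampling (and the line parameters
scaled back afterwards): these priors are weakly informative for an
order-1 series, while a cumulative KL can reach thousands of nats, where
those priors would dominate the likelihood and bias $C$; $C$ itself lives
on the time axis and is invariant to the scaling. A fit whose $C$
posterior SD exceeds 300 ms is flagged non-identified (a single straight
line leaves $C$ near its uniform prior, SD ≈ 577 ms). Condition
comparisons use draw-wise differences of $C$ posteriors, with stars at
95/99/99.9% CI exclusion.

A calibration caveat, measured on synthetic replicates and worth stating
plainly: the model treats the cumulative-KL points as independent
Gaussian observations, but a cumulative series is strongly
autocorrelated, so the $C$ posterior quantifies curve-fit uncertainty
(typically ±10–20 ms) and understates across-replicate sampling
variability of the kink location (SD ≈ 90 ms at 10–25 trials per
condition). Delay point estimates between conditions are nearly unbiased,
but their 95% CIs are anti-conservative: in our null-delay replicate
experiments the CI contained zero in far fewer than 95% of runs. Users
comparing conditions should treat the CI as a relative, not frequentist,
measure; a conservative alternative is to require large delays relative
to the ≈90 ms replicate scale.

# The synthetic-data generator

The generator is the package's stand-in for recorded sessions, and its
defaults are the study conditions the tests assume. Ensemble sessions:
N = 10 neurons, 40 trials per taste × condition, 10 ms bins, per-bin
population spiking probability 0.5 (≈5 Hz per neuron, the low-rate
cortical regime), $C_I \sim U[0.2, 0.6]$ s,
$C_P \sim U[C_I + 0.2, 1.3]$ s, spikes placed at bin centers (only the
categorical representation is consumed downstream, so within-bin placement
is immaterial). The three state families are well separated and carry the
coding each epoch is supposed to carry: detection is uniform; identity
splits the ensemble into sucrose and quinine pools (90% of spiking mass,
10% uniform floor so every emission stays possible); the palatability
state combines graded per-neuron rank tuning consistent with the identity
pools (sucrose-pool neurons prefer palatable tastes, quinine-pool neurons
aversive ones — so single-neuron firing is monotone in rank across the
whole response and the pooled index rises and saturates) with a
rank-independent shift onto a palatability-active subpopulation (every
3rd neuron), which keeps the state change at $C_P$ well separated from
identity firing even for the middle ranks. At these defaults the
information limit of an ideal observer that knows the true distributions
is a median $|\hat C_P - C_P|$ of ≈15 ms, and the full hard-EM fit
achieves ≈13–26 ms — comfortably inside the 30 ms recovery target the
pipeline is tested against. Laser effects multiply every non-null
emission probability inside the laser window (renormalized against the
no-spike symbol), which keeps distributions valid for both suppression
and enhancement.

EMG sessions: two channels at 30 kHz whose difference carries
raised-cosine-enveloped packets of a 410 Hz carrier (the burst-like
character of muscle activity; the carrier survives block averaging and the
300 Hz highpass). Packets are full-duty — one raised cosine per rhythm
cycle — so the burst-train envelope is sinusoidal at the rhythm frequency
and free of strong envelope harmonics; half-duty packets were found to
flip the window posterior onto the second harmonic at certain phases.
Licks run at 7 Hz from delivery (persisting through the trial on
non-gaping trials, as for ingested tastes); on gaping trials a 4.5 Hz
gape train starts at the drawn onset and replaces licking. Gapes are
modestly larger than licks (amplitude 1.25 vs 1), consistent with gapes
being particularly large-amplitude events, which makes the detected
Pr(Gape) rise slightly anticipate the first gape. Gaping probability is
0.8 for concentrated and 0.35 for dilute quinine (concentrated more than
twice dilute) and 0 for sucrose; the first-gape latency is
$\mathcal N(1.0, 0.05)$ s truncated at 0.2 s. A square-pulse common-mode
artifact is added identically to both channels and must cancel under
differencing. The coupled generator ties the two modalities together: on
perturbed trials whose laser began before that trial's true $C_P$, the
gape onset is delayed (default +250 ms), encoding the
transition-gated mechanism the pipeline is designed to detect.

What the generator does *not* emulate — bursty non-Poisson spiking,
electrode drift, chewing artifacts that survive differencing, gape bouts
that pause and resume, session-to-session rate heterogeneity — bounds
what green tests mean: they certify the estimators against the latent
structure the models assume, not against every failure mode of real
recordings.

# Problem sizes and determinism

Every stochastic stage takes an explicit integer seed: generators seed R's
RNG; every JAGS model gets one Mersenne-Twister stream per chain derived
from the seed, so fits are bit-reproducible. The test-suite problem sizes
are deliberate reductions that preserve each test's discriminating power:
change-point recovery runs 20 restarts (the fit landscape at the default
separation is benign; 100 remains the function default), GLM calibration
uses 2 short chains per simulated neuron, and replicate counts for
calibration checks are in the tens with binomial tolerances. The
orchestration layer (`run_transition_conditioned_analysis()`) logs seeds,
parameters and convergence summaries to a manifest, and optionally caches
stage outputs content-addressed by the MD5 of their serialized inputs, so
re-running an unchanged configuration performs no recomputation.

# Known limitations

* The onset change-point CI anti-conservatism described above.
* The change-point posterior probability is conditional on the final
  emission distributions (no parameter uncertainty), as in hard EM
  generally; it is a sharpness diagnostic, not a full posterior.
* The 300–500 Hz EMG band implied by the filter cascade is narrow;
  pipelines that highpass before downsampling would widen it, at the cost
  of a heavier filtering step.
* With identical state distributions the change-point model is
  unidentifiable by construction; fits on such data return broadly
  spread change-points and a likelihood matching the no-change-point
  model, which the tests assert rather than hide.
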