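# Synthetic session generators. These emulate the latent structure the
# analysis stages assume -- three sequential ensemble firing states with
# uniformly-jittered transition times, and EMG traces whose envelope carries
# lick (~7 Hz) and gape (4-6 Hz) rhythms -- and always return the ground
# truth alongside, so every downstream stage can be tested by recovery.

gauss_profile <- function(n_neurons, mu, width) {
  exp(-0.5 * ((seq_len(n_neurons) - mu) / width)^2)
}

# Indicator pool profile with a uniform floor: members of `pool` share 90%
# of the spiking mass, the rest is spread over all neurons so no symbol has
# zero probability in any state.
pool_profile <- function(n_neurons, pool, concentration = 0.9) {
  w <- rep((1 - concentration) / n_neurons, n_neurons)
  w[pool] <- w[pool] + concentration / length(pool)
  w
}

# Categorical emission distribution over {0..N}: probability `p_spike` split
# across neurons with weights `w`, remainder on symbol 0 (no spike).
emission_dist <- function(w, p_spike) {
  c(1 - p_spike, p_spike * w / sum(w))
}

#' Configuration for the ensemble spike-train generator
#'
#' Defaults encode the study conditions the pipeline targets: N = 10 neurons,
#' 40 trials per (taste x laser condition), 10 ms bins, per-bin population
#' spiking probability 0.5 (about 5 Hz per neuron, in the low-rate cortical
#' regime), identity change-point drawn uniformly on \[0.2, 0.6\] s and the
#' palatability change-point uniformly on \[C_I + 0.2, 1.3\] s. The three
#' state emission families are well separated: one shared detection
#' distribution, two identity distributions (sucrose vs quinine neuron
#' pools), four palatability distributions (one neuron pool per taste).
#'
#' @param n_neurons number of neurons N.
#' @param trials_per_taste trials per (taste x laser condition).
#' @param conditions laser conditions to simulate (`"control"` plus any of
#'   `"early"`, `"middle"`, `"late"`, `"sustained"`).
#' @param p_spike per-bin probability that some neuron spikes.
#' @param tuning_strength log-scale palatability tuning gain of the default
#'   `alpha_p`: each neuron's emission weight is
#'   `exp(tuning_strength * s_n * (rank - 2.5))` with per-neuron tuning
#'   signs/magnitudes `s_n` alternating across the identity pools. The
#'   default (1.5) gives strongly rank-discriminable palatability states.
#' @param alpha_d,alpha_i,alpha_p optional explicit emission distributions
#'   over `{0..N}`: `alpha_d` a vector, `alpha_i` a 2 x (N+1) matrix (rows
#'   Suc, Qui), `alpha_p` a 4 x (N+1) matrix (taste order DilSuc, ConcSuc,
#'   DilQui, ConcQui). Each row must sum to 1.
#' @param ci_range uniform support of C_I, seconds.
#' @param cp_gap minimum gap C_P - C_I, seconds.
#' @param cp_max upper bound of C_P, seconds.
#' @param span post-delivery extent of simulated activity, seconds.
#' @param baseline pre-delivery extent (detection-state spontaneous
#'   activity), seconds.
#' @param bin emission bin width, seconds.
#' @param laser_factor multiplier applied to every non-null emission
#'   probability inside a trial's laser window (0.1 = strong suppression,
#'   1.5 = enhancement); mass is renormalized to/from the no-spike symbol.
#' @return an `ensemble_sim_config` list.
#' @export
ensemble_sim_config <- function(n_neurons = 10, trials_per_taste = 40,
                                conditions = "control", p_spike = 0.5,
                                alpha_d = NULL, alpha_i = NULL,
                                alpha_p = NULL,
                                tuning_strength = 1.5,
                                ci_range = c(0.2, 0.6), cp_gap = 0.2,
                                cp_max = 1.3, span = 2.5, baseline = 0.5,
                                bin = 0.01, laser_factor = 0.1) {
  N <- as.integer(n_neurons)
  # Default state families are well separated and carry the coding each
  # epoch is supposed to carry: detection = uniform; identity = sucrose
  # pool (first half of the ensemble) vs quinine pool (second half);
  # palatability = graded rank tuning, each neuron's emission weight
  # monotone in palatability rank with tuning signs alternating across the
  # identity halves (so the palatability distributions are distinct from
  # both identity distributions). A 10% uniform floor in the pooled states
  # keeps every emission possible everywhere.
  if (is.null(alpha_d))
    alpha_d <- emission_dist(rep(1, N), p_spike)
  if (is.null(alpha_i))
    alpha_i <- rbind(
      Suc = emission_dist(pool_profile(N, seq_len(floor(N / 2))), p_spike),
      Qui = emission_dist(pool_profile(N, (floor(N / 2) + 1):N), p_spike))
  if (is.null(alpha_p)) {
    # The palatability state combines (a) per-neuron rank tuning that is
    # consistent with the identity pools (sucrose-pool neurons fire more to
    # palatable tastes, quinine-pool neurons to aversive ones, magnitudes
    # graded within each pool), so single-neuron firing is monotone in
    # palatability across the whole response, with (b) a rank-independent
    # shift of activity onto a palatability-active subpopulation (odd
    # neurons, cutting across both identity pools), so the state change at
    # C_P is well separated from identity firing for every taste, middle
    # ranks included.
    h <- floor(N / 2)
    tuning <- c(seq_len(h) / h, -seq_len(N - h) / (N - h))
    base <- pool_profile(N, seq(1, N, by = 3))
    alpha_p <- do.call(rbind, stats::setNames(lapply(TASTE_LEVELS,
      function(tt) {
        rho <- PALATABILITY_RANKS[[tt]]
        emission_dist(base * exp(tuning_strength * tuning * (rho - 2.5)),
                      p_spike)
      }), TASTE_LEVELS))
  }
  check_dist <- function(a, nm) {
    a <- rbind(a)
    if (ncol(a) != N + 1 || any(a < 0) ||
        any(abs(rowSums(a) - 1) > 1e-8))
      stop("emission distribution '", nm,
           "' must be non-negative over {0..N} and sum to 1")
    a
  }
  alpha_i <- check_dist(alpha_i, "alpha_i")
  if (nrow(alpha_i) != 2) stop("alpha_i must have one row per taste quality")
  rownames(alpha_i) <- c("Suc", "Qui")
  alpha_p <- check_dist(alpha_p, "alpha_p")
  if (nrow(alpha_p) != 4) stop("alpha_p must have one row per taste")
  rownames(alpha_p) <- TASTE_LEVELS
  if (cp_max - cp_gap <= ci_range[2])
    stop("C_P interval is empty: need cp_max - cp_gap > max C_I")
  structure(list(
    n_neurons = N, trials_per_taste = as.integer(trials_per_taste),
    conditions = conditions, p_spike = p_spike,
    alpha_d = check_dist(alpha_d, "alpha_d")[1, ],
    alpha_i = alpha_i, alpha_p = alpha_p,
    ci_range = ci_range, cp_gap = cp_gap, cp_max = cp_max,
    span = span, baseline = baseline, bin = bin,
    laser_factor = laser_factor
  ), class = "ensemble_sim_config")
}

apply_laser <- function(p, factor) {
  spike_mass <- factor * sum(p[-1])
  if (spike_mass > 1)
    stop("laser factor ", factor, " pushes total spiking probability above 1")
  c(1 - spike_mass, factor * p[-1])
}

#' Simulate a spike-train session with three latent ensemble states
#'
#' Per trial, draws the identity change-point C_I uniformly on
#' `cfg$ci_range` and the palatability change-point C_P uniformly on
#' `[C_I + cfg$cp_gap, cfg$cp_max]`, then emits one categorical symbol
#' (which neuron spiked, 0 = none) per 10 ms bin: from the detection
#' distribution before C_I (and throughout the pre-delivery baseline), from
#' the taste-quality identity distribution on `[C_I, C_P)`, and from the
#' taste-specific palatability distribution from C_P to the end of the
#' simulated span. Symbols are converted to single spikes at bin centers.
#' On laser trials every non-null emission probability inside the laser
#' window is multiplied by `cfg$laser_factor` (renormalized against the
#' no-spike symbol).
#'
#' @param cfg an [ensemble_sim_config()].
#' @param seed integer RNG seed; identical seeds give identical sessions.
#' @return a [spike_train_set()] whose attribute `ground_truth` is a
#'   `data.frame` with per-trial `c_i`, `c_p` (seconds post delivery).
#' @export
simulate_ensemble_session <- function(cfg, seed = 1) {
  stopifnot(inherits(cfg, "ensemble_sim_config"))
  set.seed(seed)
  taste <- rep(rep(TASTE_LEVELS, each = cfg$trials_per_taste),
               times = length(cfg$conditions))
  cond <- rep(cfg$conditions, each = 4L * cfg$trials_per_taste)
  labels <- trial_labels(taste, cond)
  n_tr <- nrow(labels)
  c_i <- stats::runif(n_tr, cfg$ci_range[1], cfg$ci_range[2])
  c_p <- stats::runif(n_tr, c_i + cfg$cp_gap, cfg$cp_max)
  bins <- seq(-cfg$baseline, cfg$span - cfg$bin / 2, by = cfg$bin)
  N <- cfg$n_neurons
  spikes <- vector("list", n_tr)
  for (i in seq_len(n_tr)) {
    tt <- as.character(labels$taste_id[i])
    grp <- if (tt %in% c("DilSuc", "ConcSuc")) "Suc" else "Qui"
    sym <- integer(length(bins))
    for (b in seq_along(bins)) {
      tb <- bins[b]
      p <- if (tb < c_i[i]) cfg$alpha_d
           else if (tb < c_p[i]) cfg$alpha_i[grp, ]
           else cfg$alpha_p[tt, ]
      if (!is.na(labels$laser_start[i]) &&
          tb >= labels$laser_start[i] && tb < labels$laser_end[i])
        p <- apply_laser(p, cfg$laser_factor)
      sym[b] <- sample.int(N + 1, 1, prob = p) - 1L
    }
    tr <- replicate(N, numeric(0), simplify = FALSE)
    hit <- which(sym > 0)
    for (b in hit)
      tr[[sym[b]]] <- c(tr[[sym[b]]], bins[b] + cfg$bin / 2)
    spikes[[i]] <- tr
  }
  out <- spike_train_set(spikes, labels, n_neurons = N,
                         window = c(-cfg$baseline, cfg$span),
                         meta = list(generator = "simulate_ensemble_session",
                                     seed = seed))
  attr(out, "ground_truth") <- data.frame(trial = seq_len(n_tr),
                                          taste_id = labels$taste_id,
                                          laser_condition =
                                            labels$laser_condition,
                                          c_i = c_i, c_p = c_p)
  out
}

#' Configuration for the EMG generator
#'
#' Two-channel raw EMG at 30 kHz. The differential signal contains baseline
#' Gaussian noise plus amplitude-modulated carrier-frequency packets (raised
#' cosine envelopes on a ~410 Hz carrier, emulating muscle-fiber activity
#' bursts): nonspecific licks at ~7 Hz from taste delivery, and, on gaping
#' trials, a 4-6 Hz gape bout train from the drawn onset latency to the end
#' of the trial. A common-mode artifact is added identically to both
#' channels and cancels under differencing. Gape probability and onset
#' latency depend on quinine concentration; by default concentrated quinine
#' elicits gaping on more than twice as many trials as dilute.
#'
#' @param fs sampling rate, Hz.
#' @param duration trial length post delivery, seconds.
#' @param trials_per_taste trials per taste.
#' @param lick_freq,lick_amp,lick_duration lick rhythm (Hz, a.u., s). Licks
#'   run from delivery until the gape onset on gaping trials; on
#'   non-gaping trials rhythmic licking persists for `lick_duration`
#'   (default the whole trial, as for ingested tastes).
#' @param gape_freq,gape_amp gape rhythm frequency (must lie in \[4, 6\] Hz)
#'   and packet amplitude; gapes are larger-amplitude movements than licks,
#'   so the default exceeds `lick_amp`.
#' @param gape_prob named per-concentration gaping probabilities
#'   (`DilQui`, `ConcQui`).
#' @param onset_mean,onset_sd Gaussian first-gape latency (seconds).
#' @param carrier_freq carrier frequency of burst packets, Hz.
#' @param noise_sd per-channel Gaussian noise SD.
#' @param artifact_amp,artifact_n common-mode square-pulse artifacts per
#'   trial (amplitude, count).
#' @return an `emg_sim_config` list.
#' @export
emg_sim_config <- function(fs = 30000, duration = 2.5, trials_per_taste = 30,
                           lick_freq = 7, lick_amp = 1, lick_duration = Inf,
                           gape_freq = 4.5, gape_amp = 1.25,
                           gape_prob = c(DilQui = 0.35, ConcQui = 0.8),
                           onset_mean = 1.0, onset_sd = 0.05,
                           carrier_freq = 410, noise_sd = 0.05,
                           artifact_amp = 5, artifact_n = 2) {
  if (gape_freq < 4 || gape_freq > 6)
    stop("gape_freq must lie in the 4-6 Hz gaping band")
  if (lick_freq >= 4 && lick_freq <= 6)
    stop("lick_freq must lie outside the 4-6 Hz gaping band")
  structure(as.list(environment()), class = "emg_sim_config")
}

# Raised-cosine-enveloped carrier packets at `freq` Hz from t0 to t1.
# Full-duty packets: one raised-cosine movement per rhythm cycle, so the
# burst-train envelope is sinusoidal at `freq` (continuous rhythmic jaw
# movement, free of strong envelope harmonics).
packet_train <- function(t, t0, t1, freq, amp, carrier_freq) {
  out <- numeric(length(t))
  if (t1 <= t0) return(out)
  width <- 1 / freq
  starts <- seq(t0, t1, by = 1 / freq)
  for (s in starts) {
    idx <- which(t >= s & t < s + width)
    if (!length(idx)) next
    env <- amp * 0.5 * (1 - cos(2 * pi * (t[idx] - s) / width))
    out[idx] <- out[idx] + env * sin(2 * pi * carrier_freq * (t[idx] - s))
  }
  out
}

sim_emg_trial <- function(cfg, gaping, onset) {
  t <- seq(0, cfg$duration - 1 / cfg$fs, by = 1 / cfg$fs)
  lick_end <- if (gaping) min(onset, cfg$duration)
              else min(cfg$lick_duration, cfg$duration)
  sig <- packet_train(t, 0, lick_end, cfg$lick_freq, cfg$lick_amp,
                      cfg$carrier_freq)
  if (gaping)
    sig <- sig + packet_train(t, onset, cfg$duration, cfg$gape_freq,
                              cfg$gape_amp, cfg$carrier_freq)
  common <- numeric(length(t))
  if (cfg$artifact_n > 0) {
    at <- stats::runif(cfg$artifact_n, 0, cfg$duration - 0.05)
    for (a in at)
      common[t >= a & t < a + 0.05] <- common[t >= a & t < a + 0.05] +
        cfg$artifact_amp
  }
  ch1 <- sig / 2 + stats::rnorm(length(t), 0, cfg$noise_sd) + common
  ch2 <- -sig / 2 + stats::rnorm(length(t), 0, cfg$noise_sd) + common
  cbind(ch1 = ch1, ch2 = ch2)
}

#' Simulate a two-channel EMG session
#'
#' @param cfg an [emg_sim_config()].
#' @param seed integer RNG seed.
#' @param onset_override optional numeric vector (one per trial, `NA` where
#'   not overridden) forcing the gape-onset latency; used by the coupled
#'   session generator.
#' @return list with `emg` (list of 2-column matrices, attribute `fs`),
#'   `labels` (trial table) and `ground_truth` (`data.frame` of per-trial
#'   `gaping` and `onset`, `NA` onset on non-gaping trials).
#' @export
simulate_emg_session <- function(cfg, seed = 1, onset_override = NULL) {
  stopifnot(inherits(cfg, "emg_sim_config"))
  set.seed(seed)
  taste <- rep(TASTE_LEVELS, each = cfg$trials_per_taste)
  labels <- trial_labels(taste)
  n_tr <- nrow(labels)
  gaping <- logical(n_tr)
  onset <- rep(NA_real_, n_tr)
  for (i in seq_len(n_tr)) {
    tt <- as.character(labels$taste_id[i])
    p <- if (tt %in% names(cfg$gape_prob)) cfg$gape_prob[[tt]] else 0
    gaping[i] <- stats::runif(1) < p
    if (gaping[i]) {
      onset[i] <- max(0.2, stats::rnorm(1, cfg$onset_mean, cfg$onset_sd))
      if (!is.null(onset_override) && !is.na(onset_override[i]))
        onset[i] <- onset_override[i]
    }
  }
  emg <- lapply(seq_len(n_tr), function(i)
    sim_emg_trial(cfg, gaping[i], onset[i]))
  attr(emg, "fs") <- cfg$fs
  list(emg = emg, labels = labels,
       ground_truth = data.frame(trial = seq_len(n_tr),
                                 taste_id = labels$taste_id,
                                 gaping = gaping, onset = onset))
}
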