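# Orchestration: a coupled spikes+EMG session generator encoding the
# transition-gated perturbation mechanism, and the analysis that reproduces
# the trial-splitting result (gape-onset delay conditional on whether the
# palatability transition preceded the perturbation).

#' Simulate a coupled spikes + EMG session
#'
#' One session holding both modalities with shared trial indexing: ensemble
#' spike trains from [simulate_ensemble_session()] and EMG traces from the
#' [emg_sim_config()] generator. The coupling encodes the mechanism under
#' study: on laser trials of the perturbed condition, the gape onset is
#' delayed by `gape_delay` seconds only when the laser begins before that
#' trial's palatability transition (laser onset < true C_P); trials whose
#' transition completed first keep the control latency.
#'
#' @param ens_cfg an [ensemble_sim_config()]; its `conditions` must contain
#'   `"control"` and exactly one perturbed condition.
#' @param emg_cfg an [emg_sim_config()]; `trials_per_taste` is overridden to
#'   match `ens_cfg`.
#' @param gape_delay onset delay on laser-before-transition trials, seconds.
#' @param seed integer RNG seed.
#' @return list with `spikes` (a [spike_train_set()] with `ground_truth`
#'   attribute), `emg`, `emg_truth`, `labels`.
#' @export
simulate_coupled_session <- function(ens_cfg, emg_cfg, gape_delay = 0.25,
                                     seed = 1) {
  stopifnot(inherits(ens_cfg, "ensemble_sim_config"),
            inherits(emg_cfg, "emg_sim_config"))
  perturbed <- setdiff(ens_cfg$conditions, "control")
  if (length(perturbed) != 1)
    stop("ens_cfg$conditions must be 'control' plus one perturbed condition")
  spikes <- simulate_ensemble_session(ens_cfg, seed = seed)
  truth <- attr(spikes, "ground_truth")
  labels <- spikes$labels
  onset_lab <- LASER_WINDOWS[[perturbed]][1]
  emg_cfg$trials_per_taste <- 1L  # per-trial simulation below
  set.seed(seed + 1L)
  n_tr <- nrow(labels)
  gaping <- logical(n_tr)
  onset <- rep(NA_real_, n_tr)
  for (i in seq_len(n_tr)) {
    tt <- as.character(labels$taste_id[i])
    p <- if (tt %in% names(emg_cfg$gape_prob)) emg_cfg$gape_prob[[tt]] else 0
    gaping[i] <- stats::runif(1) < p
    if (gaping[i]) {
      onset[i] <- max(0.2, stats::rnorm(1, emg_cfg$onset_mean,
                                        emg_cfg$onset_sd))
      if (labels$laser_condition[i] == perturbed &&
          onset_lab < truth$c_p[i])
        onset[i] <- onset[i] + gape_delay
    }
  }
  emg <- lapply(seq_len(n_tr), function(i)
    sim_emg_trial(emg_cfg, gaping[i], onset[i]))
  attr(emg, "fs") <- emg_cfg$fs
  list(spikes = spikes, emg = emg,
       emg_truth = data.frame(trial = seq_len(n_tr), gaping = gaping,
                              onset = onset),
       labels = labels)
}

# Content-addressed memoization: key = md5 of the serialized inputs
# (uncompressed; hashing large raw EMG must not cost more than recomputing).
cache_key <- function(...) {
  args <- lapply(list(...), function(x) {
    attr(x, "cache_hit") <- NULL  # a hit marker must not change the key
    x
  })
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(args, f, compress = FALSE)
  unname(tools::md5sum(f))
}

with_cache <- function(cache_dir, key, expr) {
  if (is.null(cache_dir)) return(expr)
  dir.create(cache_dir, showWarnings = FALSE, recursive = TRUE)
  f <- file.path(cache_dir, paste0(key, ".rds"))
  if (file.exists(f)) {
    out <- readRDS(f)
    attr(out, "cache_hit") <- TRUE
    return(out)
  }
  out <- expr
  saveRDS(out, f)
  out
}

onset_fit_for <- function(pr, trials, seed, mcmc) {
  sub <- pr[trials$conc, , drop = FALSE]
  attr(sub, "times") <- attr(pr, "times")
  conc <- beta_bin_series(sub)
  sub <- pr[trials$dil, , drop = FALSE]
  attr(sub, "times") <- attr(pr, "times")
  dil <- beta_bin_series(sub)
  kl <- kl_divergence_series(conc, dil)
  do.call(fit_onset_changepoint,
          c(list(kl_series = kl, seed = seed), mcmc))
}

#' Transition-conditioned gape-onset analysis
#'
#' Full orchestration over a coupled session: (1) convert the perturbed
#' condition's trials to categorical series and fit the two-change-point
#' ensemble model; (2) partition laser trials by whether the palatability
#' transition preceded laser onset ([split_trials_by_transition()]);
#' (3) compute Pr(Gape) for every quinine trial's EMG; (4) estimate the
#' mean gape onset (Beta/KL/cumulative-sum change-point) separately for
#' control trials, all laser trials, and each partition; (5) report each
#' laser group's onset delay relative to control.
#'
#' @param session a coupled session from [simulate_coupled_session()] (or a
#'   list with the same fields).
#' @param condition the perturbed condition to analyze (default the one
#'   present).
#' @param restarts hard-EM restarts.
#' @param seed integer seed controlling every stochastic stage.
#' @param mcmc optional list of sampler settings forwarded to
#'   [fit_onset_changepoint()].
#' @param cache_dir optional directory for content-addressed caching of the
#'   expensive stages; re-running an unchanged configuration loads cached
#'   results instead of recomputing.
#' @return list with `changepoints` (the [fit_changepoints()] result),
#'   `split`, `onsets` (named list of [fit_onset_changepoint()] fits),
#'   `delays` (a `data.frame`: group, n trials, delay vs control, CI,
#'   stars) and `manifest` (seeds, parameters, convergence summaries).
#' @export
run_transition_conditioned_analysis <- function(session, condition = NULL,
                                                restarts = 20, seed = 1,
                                                mcmc = list(),
                                                cache_dir = NULL) {
  if (is.null(session$spikes) || is.null(session$emg))
    stop("session must contain both 'spikes' and 'emg' modalities")
  labels <- session$spikes$labels
  conds <- setdiff(unique(as.character(labels$laser_condition)), "control")
  if (is.null(condition)) {
    if (length(conds) > 1)
      stop("several perturbed conditions present; pick one")
    condition <- conds
  }
  qui <- as.character(labels$taste_id) %in% c("DilQui", "ConcQui")
  pr <- with_cache(cache_dir, cache_key("bsa", session$emg, qui), {
    fs <- attr(session$emg, "fs")
    emg_qui <- session$emg[qui]
    attr(emg_qui, "fs") <- fs
    out <- gape_probability_session(emg_qui)
    rownames(out) <- which(qui)
    out
  })
  trial_rows <- function(trials) {
    idx <- match(trials, as.integer(rownames(pr)))
    idx[!is.na(idx)]
  }
  groups <- list(control = which(labels$laser_condition == "control" & qui))
  delays <- NULL
  cpfit <- split <- NULL
  if (length(condition) == 1 && length(conds) >= 1) {
    series <- make_categorical(session$spikes, condition, seed = seed)
    cpfit <- with_cache(cache_dir,
                        cache_key("cp", series, restarts, seed),
                        fit_changepoints(series, restarts = restarts,
                                         seed = seed))
    split <- split_trials_by_transition(cpfit,
                                        LASER_WINDOWS[[condition]][1])
    groups$laser_all <- which(labels$laser_condition == condition & qui)
    groups$transition_first <- intersect(split$transition_first,
                                         groups$laser_all)
    groups$laser_first <- intersect(split$laser_first, groups$laser_all)
  }
  onsets <- list()
  for (g in names(groups)) {
    tr <- groups[[g]]
    sel <- list(
      conc = trial_rows(tr[as.character(labels$taste_id[tr]) == "ConcQui"]),
      dil = trial_rows(tr[as.character(labels$taste_id[tr]) == "DilQui"]))
    if (length(sel$conc) < 2 || length(sel$dil) < 2) next
    onsets[[g]] <- with_cache(cache_dir,
                              cache_key("onset", pr, sel, seed, mcmc),
                              onset_fit_for(pr, sel, seed, mcmc))
  }
  if (length(onsets) > 1 && "control" %in% names(onsets)) {
    rows <- lapply(setdiff(names(onsets), "control"), function(g) {
      cmp <- compare_onsets(onsets[[g]], onsets$control)
      data.frame(group = g, n_trials = length(groups[[g]]),
                 delay_ms = cmp$delay_ms, ci_low = cmp$ci[1],
                 ci_high = cmp$ci[2], significant = cmp$significant,
                 stars = cmp$stars)
    })
    delays <- do.call(rbind, rows)
  }
  manifest <- list(
    seed = seed, condition = condition, restarts = restarts,
    n_trials = nrow(labels),
    changepoint_loglik = if (!is.null(cpfit)) cpfit$loglik else NA,
    onset_rhat_max = vapply(onsets, function(f) max(f$rhat, na.rm = TRUE),
                            numeric(1)))
  list(changepoints = cpfit, split = split, onsets = onsets,
       delays = delays, manifest = manifest)
}
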