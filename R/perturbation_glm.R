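# Hierarchical Bayesian Poisson GLM for the effect of optogenetic
# perturbation on single-neuron firing. Spike counts aggregated per trial
# over a window are modeled as Poisson with a log-link mean composed of
# taste, perturbation, and interaction effects, each drawn around
# condition-agnostic fixed effects with Half-Cauchy-scaled spread.

GLM_MODEL <- "
model {
  for (k in 1:K) {
    S[k] ~ dpois(firing[T[k], O[k]])
  }
  for (t in 1:nT) { muT[t] ~ dnorm(F1, pow(s1, -2)) }
  for (o in 1:nO) { muO[o] ~ dnorm(F2, pow(s2, -2)) }
  for (t in 1:nT) {
    for (o in 1:nO) {
      muTO[t, o] ~ dnorm(F3, pow(s3, -2))
      log(firing[t, o]) <- muT[t] + muO[o] + muTO[t, o]
    }
  }
  F1 ~ dnorm(0, pow(10, -2))
  F2 ~ dnorm(0, pow(10, -2))
  F3 ~ dnorm(0, pow(10, -2))
  s1 ~ dt(0, 1, 1) T(0,)
  s2 ~ dt(0, 1, 1) T(0,)
  s3 ~ dt(0, 1, 1) T(0,)
}"

#' Aggregate spike counts per trial over a window
#'
#' Counts each neuron's spikes in a half-open window `[start, end)` per
#' trial, and labels each trial with its perturbation cell. With
#' `window = "auto"` the aggregation window is the trial's own laser window
#' on laser trials; control trials are counted once per laser condition
#' present in the session, in that condition's (condition-matched) window,
#' so that off/on cells are directly comparable.
#'
#' @param x a [spike_train_set()].
#' @param window `"auto"` or a numeric `c(start, end)` in seconds applied to
#'   every trial.
#' @return a `data.frame` with columns `trial`, `neuron`, `taste_id`,
#'   `condition` (the perturbation timing), `laser` (`"off"`/`"on"`),
#'   `cell` (`condition_laser`), `count`; attribute `window` records the
#'   window rule.
#' @export
spike_count_table <- function(x, window = "auto") {
  stopifnot(inherits(x, "spike_train_set"))
  lab <- x$labels
  conds <- setdiff(unique(as.character(lab$laser_condition)), "control")
  if (identical(window, "auto") && length(conds) == 0)
    stop("window = \"auto\" needs at least one laser condition; ",
         "give an explicit window for laser-free sessions")
  rows <- list()
  count_in <- function(i, w) {
    vapply(x$spikes[[i]],
           function(st) sum(st >= w[1] & st < w[2]), numeric(1))
  }
  add_rows <- function(i, cond, laser, w) {
    cnt <- count_in(i, w)
    rows[[length(rows) + 1]] <<- data.frame(
      trial = i, neuron = seq_len(x$n_neurons),
      taste_id = lab$taste_id[i], condition = cond, laser = laser,
      count = cnt)
  }
  for (i in seq_len(nrow(lab))) {
    ci <- as.character(lab$laser_condition[i])
    if (ci == "control") {
      if (identical(window, "auto")) {
        for (cond in conds) add_rows(i, cond, "off", LASER_WINDOWS[[cond]])
      } else add_rows(i, "none", "off", window)
    } else {
      w <- if (identical(window, "auto"))
        c(lab$laser_start[i], lab$laser_end[i]) else window
      add_rows(i, ci, "on", w)
    }
  }
  out <- do.call(rbind, rows)
  out$cell <- paste(out$condition, out$laser, sep = "_")
  attr(out, "window") <- window
  out
}

#' Fit the hierarchical Poisson GLM for one neuron
#'
#' Posterior over the mean spike count `firing[T, O]` for every
#' (taste, perturbation) cell, sampled by MCMC with 4 chains. Priors: fixed
#' effects Normal(0, 10); spread scales Half-Cauchy(1); cell means composed
#' on the log scale as `muT + muO + muTO`.
#'
#' @param counts rows of a [spike_count_table()] for a single neuron.
#' @param chains,n_adapt,n_burn,n_iter sampler settings.
#' @param seed integer RNG seed.
#' @return a [posterior_summary()] over `firing[taste, cell]` parameters,
#'   with attributes `tastes` and `cells` (level orders) and `pairs`
#'   (off/on cell pairing per condition). A warning is raised if any R-hat
#'   leaves the window \[0.99, 1.01\].
#' @export
fit_perturbation_glm <- function(counts, chains = 4, n_adapt = 1000,
                                 n_burn = 2000, n_iter = 2000, seed = 1) {
  if (length(unique(counts$neuron)) != 1)
    stop("fit_perturbation_glm() fits one neuron at a time; got ",
         length(unique(counts$neuron)), " neurons")
  tastes <- levels(droplevels(counts$taste_id))
  cells <- sort(unique(counts$cell))
  tab <- table(droplevels(counts$taste_id), counts$cell)
  if (any(tab == 0)) {
    empty <- which(tab == 0, arr.ind = TRUE)[1, ]
    stop("no trials in (taste, perturbation) cell (",
         rownames(tab)[empty[1]], ", ", colnames(tab)[empty[2]], ")")
  }
  dat <- list(
    S = counts$count,
    T = as.integer(factor(counts$taste_id, levels = tastes)),
    O = as.integer(factor(counts$cell, levels = cells)),
    K = nrow(counts), nT = length(tastes), nO = length(cells))
  samples <- run_jags(GLM_MODEL, dat, "firing", seed = seed,
                      chains = chains, n_adapt = n_adapt, n_burn = n_burn,
                      n_iter = n_iter)
  ps <- posterior_summary(samples)
  # rename firing[t,o] with level names
  nm <- ps$parameter
  idx <- regmatches(nm, regexec("firing\\[(\\d+),(\\d+)\\]", nm))
  ps$parameter <- vapply(idx, function(m)
    paste0("firing[", tastes[as.integer(m[2])], ",",
           cells[as.integer(m[3])], "]"), character(1))
  colnames(attr(ps, "draws")) <- ps$parameter
  conds <- unique(sub("_(off|on)$", "", cells))
  conds <- conds[paste0(conds, "_on") %in% cells &
                   paste0(conds, "_off") %in% cells]
  attr(ps, "tastes") <- tastes
  attr(ps, "cells") <- cells
  attr(ps, "pairs") <- conds
  check_convergence(ps)
  ps
}

#' Classify a neuron's perturbation effect
#'
#' For each perturbation condition with an off/on pair, forms the posterior
#' of the (control - laser) difference in mean spike count and calls the
#' neuron `suppressed` if the credible interval lies entirely above 0,
#' `enhanced` if entirely below, else `unchanged`. The headline call uses
#' the laser main-effect contrast (difference of taste-averaged firing);
#' per-taste calls are also returned.
#'
#' @param summary a fit from [fit_perturbation_glm()].
#' @param level credible level for the decision (default 0.95).
#' @return `data.frame` with columns `condition`, `taste` (`"all"` for the
#'   taste-averaged contrast), `diff_mean`, `ci_low`, `ci_high`, `effect`.
#' @export
classify_perturbation_effect <- function(summary, level = 0.95) {
  stopifnot(inherits(summary, "posterior_summary"))
  draws <- attr(summary, "draws")
  tastes <- attr(summary, "tastes")
  conds <- attr(summary, "pairs")
  if (is.null(conds) || length(conds) == 0)
    stop("summary has no off/on condition pairing to classify")
  a <- (1 - level) / 2
  rows <- list()
  for (cond in conds) {
    off <- draws[, paste0("firing[", tastes, ",", cond, "_off]"),
                 drop = FALSE]
    on <- draws[, paste0("firing[", tastes, ",", cond, "_on]"),
                drop = FALSE]
    contrasts <- cbind(all = rowMeans(off) - rowMeans(on), off - on)
    colnames(contrasts) <- c("all", tastes)
    for (tt in colnames(contrasts)) {
      ci <- stats::quantile(contrasts[, tt], c(a, 1 - a))
      rows[[length(rows) + 1]] <- data.frame(
        condition = cond, taste = tt, diff_mean = mean(contrasts[, tt]),
        ci_low = unname(ci[1]), ci_high = unname(ci[2]),
        effect = effect_call(ci))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Sign rule on a credible interval of (control - laser) firing.
effect_call <- function(ci) {
  if (ci[1] > 0) "suppressed" else if (ci[2] < 0) "enhanced" else "unchanged"
}
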