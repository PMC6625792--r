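# Canonical taste levels and their palatability ranks (higher = more palatable)
TASTE_LEVELS <- c("DilSuc", "ConcSuc", "DilQui", "ConcQui")
PALATABILITY_RANKS <- c(DilSuc = 3L, ConcSuc = 4L, DilQui = 2L, ConcQui = 1L)

# Laser (perturbation) conditions and their windows, seconds post taste delivery
LASER_CONDITIONS <- c("control", "early", "middle", "late", "sustained")
LASER_WINDOWS <- list(
  early     = c(0.0, 0.5),
  middle    = c(0.7, 1.2),
  late      = c(1.4, 1.9),
  sustained = c(0.0, 2.5)
)

#' Palatability rank of a taste
#'
#' Maps taste identities to the ordinal palatability scale used throughout the
#' package: `ConcSuc` = 4, `DilSuc` = 3, `DilQui` = 2, `ConcQui` = 1
#' (higher is more palatable).
#'
#' @param taste character vector of taste identities (levels `"DilSuc"`,
#'   `"ConcSuc"`, `"DilQui"`, `"ConcQui"`).
#' @return integer vector of ranks in 1..4.
#' @export
#' @examples
#' palatability_rank(c("ConcSuc", "ConcQui"))
palatability_rank <- function(taste) {
  taste <- as.character(taste)
  bad <- setdiff(unique(taste), TASTE_LEVELS)
  if (length(bad) > 0)
    stop("unknown taste identities: ", paste(bad, collapse = ", "))
  unname(PALATABILITY_RANKS[taste])
}

#' Trial label table
#'
#' Builds the per-trial metadata table: taste identity, palatability rank,
#' perturbation (laser) condition and laser window.
#'
#' @param taste character vector, one taste per trial.
#' @param laser_condition character vector (recycled), one of `"control"`,
#'   `"early"`, `"middle"`, `"late"`, `"sustained"`.
#' @return a `data.frame` with columns `trial`, `taste_id` (factor),
#'   `rank`, `laser_condition` (factor), `laser_start`, `laser_end`
#'   (`NA` for control trials).
#' @export
trial_labels <- function(taste, laser_condition = "control") {
  taste <- as.character(taste)
  n <- length(taste)
  laser_condition <- rep_len(as.character(laser_condition), n)
  bad <- setdiff(unique(laser_condition), LASER_CONDITIONS)
  if (length(bad) > 0)
    stop("unknown laser conditions: ", paste(bad, collapse = ", "))
  win <- t(vapply(laser_condition, function(cond) {
    if (cond == "control") c(NA_real_, NA_real_) else LASER_WINDOWS[[cond]]
  }, numeric(2)))
  data.frame(
    trial = seq_len(n),
    taste_id = factor(taste, levels = TASTE_LEVELS),
    rank = palatability_rank(taste),
    laser_condition = factor(laser_condition, levels = LASER_CONDITIONS),
    laser_start = win[, 1],
    laser_end = win[, 2],
    row.names = NULL
  )
}

#' Spike-train session container
#'
#' Bundles spike times for `N` neurons over repeated trials with trial
#' metadata. Spike times are in seconds relative to taste delivery at t = 0;
#' neuron indices run 1..N (index 0 is reserved downstream for "no spike" in
#' the categorical coding).
#'
#' @param spikes list over trials; each element a list over neurons of numeric
#'   vectors of spike times (seconds).
#' @param labels a trial-label table from [trial_labels()], one row per trial.
#' @param n_neurons number of neurons N (defaults to the length of the first
#'   trial's list).
#' @param window recorded trial extent `c(start, end)` in seconds.
#' @param meta optional named list of session identifiers / provenance.
#' @return an object of class `spike_train_set`.
#' @export
spike_train_set <- function(spikes, labels, n_neurons = NULL,
                            window = c(-2, 5), meta = list()) {
  stopifnot(is.list(spikes), is.data.frame(labels))
  if (length(spikes) != nrow(labels))
    stop("number of trials in `spikes` (", length(spikes),
         ") and `labels` (", nrow(labels), ") differ")
  if (is.null(n_neurons)) n_neurons <- length(spikes[[1]])
  for (i in seq_along(spikes)) {
    if (length(spikes[[i]]) != n_neurons)
      stop("trial ", i, " has ", length(spikes[[i]]),
           " neurons, expected ", n_neurons)
    for (n in seq_len(n_neurons)) {
      st <- spikes[[i]][[n]]
      if (length(st) && (min(st) < window[1] || max(st) > window[2]))
        stop("spike times outside the recorded window on trial ", i,
             ", neuron ", n)
      spikes[[i]][[n]] <- as.numeric(sort(st))
    }
  }
  structure(
    list(spikes = spikes, labels = labels, n_neurons = as.integer(n_neurons),
         window = as.numeric(window), meta = meta),
    class = "spike_train_set"
  )
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat("<spike_train_set> ", length(x$spikes), " trials, ", x$n_neurons,
      " neurons, window [", x$window[1], ", ", x$window[2], "] s\n", sep = "")
  print(table(x$labels$taste_id, x$labels$laser_condition))
  invisible(x)
}

#' Bin spike trains into firing rates
#'
#' Counts spikes in sliding half-open bins `[t, t + bin_width)` advanced by
#' `step`, and divides by the bin width to give rates in Hz.
#'
#' @param x a [spike_train_set()].
#' @param bin_width bin width, seconds (default 0.25).
#' @param step step between bin starts, seconds (default 0.025).
#' @param window analysis window `c(start, end)`, seconds; must lie inside the
#'   recorded trial window.
#' @return numeric array `trial x neuron x bin` of firing rates (Hz), with
#'   attribute `bin_starts` giving each bin's left edge (seconds).
#' @export
bin_spikes <- function(x, bin_width = 0.25, step = 0.025,
                       window = c(-0.25, 1.5)) {
  stopifnot(inherits(x, "spike_train_set"), bin_width > 0, step > 0)
  if (window[1] < x$window[1] || window[2] > x$window[2])
    stop("requested window [", window[1], ", ", window[2],
         "] lies outside the recorded range [", x$window[1], ", ",
         x$window[2], "]")
  starts <- seq(window[1], window[2] - bin_width, by = step)
  # guard against fp droop at the last bin
  starts <- starts[starts + bin_width <= window[2] + 1e-9]
  n_tr <- length(x$spikes)
  out <- array(0, dim = c(n_tr, x$n_neurons, length(starts)))
  for (i in seq_len(n_tr)) {
    for (n in seq_len(x$n_neurons)) {
      st <- x$spikes[[i]][[n]]
      if (!length(st)) next
      for (b in seq_along(starts)) {
        out[i, n, b] <- sum(st >= starts[b] & st < starts[b] + bin_width)
      }
    }
  }
  out <- out / bin_width
  attr(out, "bin_starts") <- starts
  attr(out, "bin_width") <- bin_width
  out
}

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a session to a plain-text directory layout
#'
#' The session container is a directory holding `meta.json` (neuron count,
#' recorded window, EMG sampling rate, session metadata), `trials.csv`
#' (taste_id, rank, laser_condition, laser_start, laser_end), `spikes.csv`
#' (trial, neuron, time) and, when EMG is present, one `emg_trial_<i>.csv`
#' per trial with columns `ch1`, `ch2`. Numeric fields are written with 17
#' significant digits so that `read_session(write_session(x)) == x` holds
#' bit-exactly.
#'
#' @param x a [spike_train_set()].
#' @param path directory to create/overwrite.
#' @param emg optional list over trials of 2-column matrices (raw EMG
#'   channels) plus attribute `fs` (sampling rate, Hz).
#' @return `path`, invisibly.
#' @export
write_session <- function(x, path, emg = NULL) {
  stopifnot(inherits(x, "spike_train_set"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  meta <- list(
    n_neurons = x$n_neurons, window = x$window, n_trials = length(x$spikes),
    emg_fs = if (!is.null(emg)) attr(emg, "fs") else NULL,
    session_meta = x$meta
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  lab <- x$labels
  lab$laser_start <- ifelse(is.na(lab$laser_start), "",
                            fmt_num(lab$laser_start))
  lab$laser_end <- ifelse(is.na(lab$laser_end), "", fmt_num(lab$laser_end))
  data.table::fwrite(lab, file.path(path, "trials.csv"))
  sp <- data.table::rbindlist(lapply(seq_along(x$spikes), function(i) {
    tr <- x$spikes[[i]]
    data.table::data.table(
      trial = rep(i, sum(lengths(tr))),
      neuron = rep(seq_along(tr), lengths(tr)),
      time = fmt_num(unlist(tr, use.names = FALSE))
    )
  }))
  if (nrow(sp) == 0)
    sp <- data.table::data.table(trial = integer(), neuron = integer(),
                                 time = character())
  data.table::fwrite(sp, file.path(path, "spikes.csv"))
  if (!is.null(emg)) {
    for (i in seq_along(emg)) {
      m <- emg[[i]]
      data.table::fwrite(
        data.table::data.table(ch1 = fmt_num(m[, 1]), ch2 = fmt_num(m[, 2])),
        file.path(path, sprintf("emg_trial_%d.csv", i))
      )
    }
  }
  invisible(path)
}

session_file <- function(path, name) {
  f <- file.path(path, name)
  if (!file.exists(f))
    stop("session at '", path, "' is missing required entry '", name,
         "': not a valid session layout")
  f
}

#' Read a session from the plain-text directory layout
#'
#' @param path session directory written by [write_session()].
#' @return a list with elements `spikes` (a [spike_train_set()]) and `emg`
#'   (list of 2-column matrices with attribute `fs`, or `NULL`).
#' @export
read_session <- function(path) {
  meta <- jsonlite::read_json(session_file(path, "meta.json"),
                              simplifyVector = TRUE)
  for (f in c("n_neurons", "window", "n_trials"))
    if (is.null(meta[[f]]))
      stop("session meta.json is missing required field '", f, "'")
  lab <- data.table::fread(session_file(path, "trials.csv"),
                           colClasses = list(character = c("taste_id",
                                                           "laser_condition")))
  need <- c("trial", "taste_id", "rank", "laser_condition",
            "laser_start", "laser_end")
  miss <- setdiff(need, names(lab))
  if (length(miss) > 0)
    stop("trials.csv is missing required columns: ",
         paste(miss, collapse = ", "))
  labels <- trial_labels(lab$taste_id, lab$laser_condition)
  sp <- data.table::fread(session_file(path, "spikes.csv"))
  spikes <- replicate(meta$n_trials,
                      replicate(meta$n_neurons, numeric(0), simplify = FALSE),
                      simplify = FALSE)
  if (nrow(sp) > 0) {
    sp_split <- split(sp, by = c("trial", "neuron"))
    for (chunk in sp_split) {
      spikes[[chunk$trial[1]]][[chunk$neuron[1]]] <- as.numeric(chunk$time)
    }
  }
  sts <- spike_train_set(spikes, labels, n_neurons = meta$n_neurons,
                         window = meta$window,
                         meta = as.list(meta$session_meta))
  emg <- NULL
  if (!is.null(meta$emg_fs)) {
    emg <- lapply(seq_len(meta$n_trials), function(i) {
      d <- data.table::fread(
        session_file(path, sprintf("emg_trial_%d.csv", i)))
      cbind(ch1 = as.numeric(d$ch1), ch2 = as.numeric(d$ch2))
    })
    attr(emg, "fs") <- meta$emg_fs
  }
  list(spikes = sts, emg = emg)
}

#' Summarize MCMC draws into a posterior table
#'
#' Generic container for posterior draws: per-parameter mean, equal-tailed
#' credible interval at a stated level, and the Gelman-Rubin R-hat
#' convergence diagnostic across chains. Equal-tailed quantile intervals are
#' the default; highest-posterior-density intervals are available via
#' `hpd = TRUE`.
#'
#' @param samples a `coda::mcmc.list` of draws from >= 2 chains.
#' @param level credible level (default 0.95).
#' @param hpd logical; use HPD intervals instead of equal-tailed quantiles.
#' @return object of class `posterior_summary`: a `data.frame` with columns
#'   `parameter`, `mean`, `ci_low`, `ci_high`, `rhat`, carrying the pooled
#'   draw matrix in attribute `draws` and `level`.
#' @export
posterior_summary <- function(samples, level = 0.95, hpd = FALSE) {
  stopifnot(inherits(samples, "mcmc.list"))
  draws <- as.matrix(samples)
  a <- (1 - level) / 2
  if (hpd) {
    hi <- coda::HPDinterval(coda::as.mcmc(draws), prob = level)
    lo <- hi[, 1]; up <- hi[, 2]
  } else {
    q <- apply(draws, 2, stats::quantile, probs = c(a, 1 - a))
    lo <- q[1, ]; up <- q[2, ]
  }
  rhat <- tryCatch(
    coda::gelman.diag(samples, autoburnin = FALSE,
                      multivariate = FALSE)$psrf[, 1],
    error = function(e) rep(NA_real_, ncol(draws))
  )
  out <- data.frame(
    parameter = colnames(draws),
    mean = colMeans(draws),
    ci_low = unname(lo),
    ci_high = unname(up),
    rhat = unname(rhat),
    row.names = NULL
  )
  structure(out, draws = draws, level = level,
            class = c("posterior_summary", "data.frame"))
}

#' Extract pooled posterior draws
#'
#' @param x a [posterior_summary()].
#' @param parameter optional parameter name; if given, returns that column.
#' @return draw matrix (iterations x parameters) or a numeric vector.
#' @export
posterior_draws <- function(x, parameter = NULL) {
  stopifnot(inherits(x, "posterior_summary"))
  d <- attr(x, "draws")
  if (is.null(parameter)) return(d)
  if (!parameter %in% colnames(d))
    stop("no draws for parameter '", parameter, "'")
  d[, parameter]
}

#' Check the Gelman-Rubin convergence contract
#'
#' Warns (and returns `FALSE`) if any parameter's R-hat falls outside the
#' accepted window, 0.99 to 1.01.
#'
#' @param x a [posterior_summary()].
#' @param lower,upper accepted R-hat window.
#' @return logical, `TRUE` when all R-hat values are inside the window.
#' @export
check_convergence <- function(x, lower = 0.99, upper = 1.01) {
  stopifnot(inherits(x, "posterior_summary"))
  r <- x$rhat[!is.na(x$rhat)]
  ok <- length(r) == 0 || (all(r >= lower) && all(r <= upper))
  if (!ok)
    warning("MCMC convergence suspect: max R-hat = ",
            format(max(r), digits = 4), call. = FALSE)
  ok
}
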