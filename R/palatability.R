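# Time course of palatability coding: per-bin Bayesian regression of
# standardized, sign-aligned firing on palatability rank, and a logistic
# sigmoid model of the resulting index's rise.

PALATABILITY_MODEL <- "
model {
  for (k in 1:K) {
    y[k] ~ dnorm(beta * P[k], tau)
  }
  beta ~ dnorm(0, 1)
  sigma ~ dt(0, 1, 1) T(0,)
  tau <- pow(sigma, -2)
}"

SIGMOID_MODEL <- "
model {
  for (k in 1:K) {
    y[k] ~ dnorm(L / (1 + exp(-k_slope * (t[k] - t0))), tau)
  }
  L ~ dnorm(0, pow(0.1, -2)) T(0,)
  k_slope ~ dnorm(1, pow(1, -2)) T(0,)
  t0 ~ dnorm(675, pow(75, -2)) T(0,)
  sigma ~ dt(0, 1, 1) T(0,)
  tau <- pow(sigma, -2)
}"

#' Standardize and sign-align binned firing rates
#'
#' Two-stage transform that puts all neurons on a common palatability axis:
#' (1) z-score each (neuron, bin) across trials (subtract the trial-averaged
#' rate, divide by the across-trial SD); (2) multiply each neuron by the
#' sign of the time-averaged Spearman correlation between its firing and the
#' palatability ranks, so that stronger-firing-to-palatable and
#' stronger-firing-to-aversive neurons point the same way. Bins with zero
#' across-trial variance are set to 0 and flagged rather than dropped.
#'
#' @param rates array `trial x neuron x bin` from [bin_spikes()] (attribute
#'   `bin_starts` required).
#' @param labels trial-label table aligned with the first array dimension.
#' @param sign_window window (seconds) over which the Spearman correlation
#'   is averaged before taking its sign; default 0 to 1.5 s post delivery.
#' @return object of class `standardized_firing`: list with `z` (same-shape
#'   array), `sign` (per-neuron -1/+1), `flagged` (logical neuron x bin
#'   matrix of zero-variance bins), `rank` (per-trial palatability rank),
#'   `bin_starts`.
#' @export
standardize_and_align <- function(rates, labels, sign_window = c(0, 1.5)) {
  starts <- attr(rates, "bin_starts")
  if (is.null(starts)) stop("`rates` must carry a `bin_starts` attribute")
  if (dim(rates)[1] < 2) stop("need at least 2 trials per bin to z-score")
  if (dim(rates)[1] != nrow(labels))
    stop("labels and rates disagree on the number of trials")
  n_neuron <- dim(rates)[2]; n_bin <- dim(rates)[3]
  z <- rates
  flagged <- matrix(FALSE, n_neuron, n_bin)
  for (n in seq_len(n_neuron)) {
    for (b in seq_len(n_bin)) {
      v <- rates[, n, b]
      s <- stats::sd(v)
      if (s == 0) {
        z[, n, b] <- 0
        flagged[n, b] <- TRUE
      } else {
        z[, n, b] <- (v - mean(v)) / s
      }
    }
  }
  rank <- labels$rank
  in_win <- which(starts >= sign_window[1] & starts <= sign_window[2])
  sign_vec <- vapply(seq_len(n_neuron), function(n) {
    rho <- vapply(in_win, function(b) {
      if (flagged[n, b]) return(NA_real_)
      suppressWarnings(stats::cor(rates[, n, b], rank, method = "spearman"))
    }, numeric(1))
    m <- mean(rho, na.rm = TRUE)
    if (!is.finite(m) || m == 0) 1 else sign(m)
  }, numeric(1))
  for (n in seq_len(n_neuron)) z[, n, ] <- z[, n, ] * sign_vec[n]
  structure(list(z = z, sign = sign_vec, flagged = flagged, rank = rank,
                 bin_starts = starts),
            class = "standardized_firing")
}

#' Per-bin Bayesian regression of firing on palatability rank
#'
#' For each time bin, pools the standardized firing of all neurons and fits
#' `firing ~ Normal(beta * P, sigma)` with priors `beta ~ Normal(0, 1)`,
#' `sigma ~ HalfCauchy(1)`, giving one posterior of the palatability index
#' `beta` per bin. The posterior-mean series is baseline-normalized by
#' subtracting its average over the pre-stimulus bins (bin start < 0).
#'
#' @param std a [standardize_and_align()] result.
#' @param chains,n_adapt,n_burn,n_iter sampler settings per bin.
#' @param sig_level credible level for the per-bin significance flag
#'   (default 0.99; a bin is flagged when that CI excludes 0).
#' @param seed integer RNG seed.
#' @param keep_draws keep per-bin beta draws (needed for anything beyond
#'   the summary table).
#' @return object of class `palatability_series`: a `data.frame` with one
#'   row per bin (`time` s, `beta_mean`, `ci_low`, `ci_high` at 95%,
#'   `sig_low`, `sig_high` at `sig_level`, `significant`, `beta_norm`,
#'   `rhat_max`), with attributes `baseline` (subtracted value) and
#'   `draws` (bins x iterations matrix when kept).
#' @export
fit_palatability_index <- function(std, chains = 4, n_adapt = 500,
                                   n_burn = 500, n_iter = 1000,
                                   sig_level = 0.99, seed = 1,
                                   keep_draws = TRUE) {
  stopifnot(inherits(std, "standardized_firing"))
  n_bin <- length(std$bin_starts)
  n_trial <- dim(std$z)[1]
  if (n_trial == 0) stop("empty input: no trials")
  P <- rep(std$rank, times = dim(std$z)[2])
  a95 <- 0.025; asig <- (1 - sig_level) / 2
  rows <- vector("list", n_bin)
  draw_list <- if (keep_draws) vector("list", n_bin) else NULL
  for (b in seq_len(n_bin)) {
    y <- as.vector(std$z[, , b])
    if (!length(y)) stop("empty bin at t = ", std$bin_starts[b])
    samples <- run_jags(PALATABILITY_MODEL,
                        list(y = y, P = P, K = length(y)),
                        c("beta", "sigma"), seed = seed + b,
                        chains = chains, n_adapt = n_adapt,
                        n_burn = n_burn, n_iter = n_iter)
    d <- as.matrix(samples)
    beta <- d[, "beta"]
    rhat <- coda::gelman.diag(samples, autoburnin = FALSE,
                              multivariate = FALSE)$psrf[, 1]
    qs <- stats::quantile(beta, c(a95, 1 - a95, asig, 1 - asig))
    rows[[b]] <- data.frame(
      time = std$bin_starts[b], beta_mean = mean(beta),
      ci_low = qs[1], ci_high = qs[2], sig_low = qs[3], sig_high = qs[4],
      significant = qs[3] > 0 | qs[4] < 0, rhat_max = max(rhat))
    if (keep_draws) draw_list[[b]] <- beta
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  base_bins <- out$time < 0
  baseline <- if (any(base_bins)) mean(out$beta_mean[base_bins]) else 0
  out$beta_norm <- out$beta_mean - baseline
  structure(out, baseline = baseline,
            draws = if (keep_draws) do.call(rbind, draw_list) else NULL,
            sig_level = sig_level,
            class = c("palatability_series", "data.frame"))
}

#' Evaluate the logistic sigmoid used for the index time course
#'
#' `sigmoid_value(t, L, k, t0) = L / (1 + exp(-k (t - t0)))`; lower
#' asymptote fixed at 0.
#'
#' @param t time (ms post delivery).
#' @param L upper asymptote.
#' @param k slope (per ms).
#' @param t0 inflection time (ms).
#' @return sigmoid value(s).
#' @export
sigmoid_value <- function(t, L, k, t0) L / (1 + exp(-k * (t - t0)))

#' Peak latency of the sigmoid
#'
#' The time at which the sigmoid reaches 95% of its upper asymptote:
#' `t_peak = ln(19) / k + t0`.
#'
#' @param k slope (per ms).
#' @param t0 inflection time (ms).
#' @return peak latency (ms).
#' @export
sigmoid_peak_time <- function(k, t0) log(19) / k + t0

#' Fit the sigmoid time-course model of the palatability index
#'
#' Models the baseline-normalized posterior-mean index series with a
#' logistic sigmoid whose lower asymptote is 0. Priors: upper asymptote
#' `L ~ Normal(0, 0.1)` truncated positive; slope `k ~ Normal(1, 1)`
#' truncated positive (per ms); inflection `t0 ~ Normal(675, 75)` ms
#' truncated positive; noise `sigma ~ HalfCauchy(1)`. The peak latency
#' posterior `t_peak = ln(19)/k + t0` is derived draw-by-draw.
#'
#' Series from perturbation conditions whose laser onset/offset falls inside
#' the analysis window violate the stationarity assumption of curve fitting;
#' pass `stationary = FALSE` to acknowledge this (a warning tags the fit).
#'
#' @param series a [fit_palatability_index()] result (times in seconds,
#'   converted to ms internally) or any data.frame with `time` and
#'   `beta_norm` columns on a uniform grid.
#' @param chains,n_adapt,n_burn,n_iter sampler settings.
#' @param seed integer RNG seed.
#' @param stationary set `FALSE` for perturbation-era series; the fit is
#'   still produced but tagged with a warning.
#' @return a [posterior_summary()] over `L`, `k`, `t0`, `sigma` and the
#'   derived `t_peak` (ms).
#' @export
fit_sigmoid <- function(series, chains = 4, n_adapt = 1000, n_burn = 1000,
                        n_iter = 2000, seed = 1, stationary = TRUE) {
  y <- series$beta_norm
  t_ms <- series$time * 1000
  if (any(!is.finite(y)) || any(!is.finite(t_ms)))
    stop("series contains non-finite values")
  if (!stationary)
    warning("series tagged non-stationary (perturbation onset/offset ",
            "inside the fit window); sigmoid features may be artifactual",
            call. = FALSE)
  samples <- run_jags(SIGMOID_MODEL,
                      list(y = y, t = t_ms, K = length(y)),
                      c("L", "k_slope", "t0", "sigma"), seed = seed,
                      chains = chains, n_adapt = n_adapt, n_burn = n_burn,
                      n_iter = n_iter)
  samples <- lapply(samples, function(ch) {
    ch <- as.matrix(ch)
    colnames(ch)[colnames(ch) == "k_slope"] <- "k"
    coda::as.mcmc(cbind(ch, t_peak = sigmoid_peak_time(ch[, "k"],
                                                       ch[, "t0"])))
  })
  ps <- posterior_summary(coda::mcmc.list(samples))
  check_convergence(ps)
  ps
}
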