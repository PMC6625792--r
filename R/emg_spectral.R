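# EMG preprocessing to an envelope signal, and windowed Bayesian spectrum
# analysis (single-sinusoid model, amplitudes and noise marginalized)
# yielding the per-time-point posterior probability of 4-6 Hz gaping.

#' Preprocess raw two-channel EMG to an envelope signal
#'
#' Pipeline: difference of the two channels (cancels common-mode movement
#' artifacts) -> down-sample to 1000 Hz by averaging consecutive blocks of
#' 30 samples -> 2nd-order Butterworth highpass at 300 Hz -> absolute value
#' -> 2nd-order Butterworth lowpass at 15 Hz, capturing the envelope of the
#' EMG signal. Filters are applied single-pass (causal) by default;
#' `zero_phase = TRUE` uses forward-backward filtering instead.
#'
#' @param raw numeric matrix of two equal-length channels (columns, or rows
#'   if 2 x n) sampled at `fs`.
#' @param fs input sampling rate, Hz (default 30000).
#' @param target_fs envelope sampling rate after block averaging (default
#'   1000; `fs` must be an integer multiple).
#' @param highpass,lowpass Butterworth cutoffs, Hz.
#' @param zero_phase logical; use `signal::filtfilt` instead of causal
#'   filtering.
#' @return numeric envelope vector with attribute `fs = target_fs`.
#' @export
preprocess_emg <- function(raw, fs = 30000, target_fs = 1000,
                           highpass = 300, lowpass = 15,
                           zero_phase = FALSE) {
  if (is.matrix(raw) && nrow(raw) == 2 && ncol(raw) > 2) raw <- t(raw)
  if (!is.matrix(raw) || ncol(raw) != 2)
    stop("`raw` must be a two-channel matrix")
  if (anyNA(raw)) stop("`raw` contains missing values")
  dec <- fs / target_fs
  if (dec != round(dec)) stop("fs must be an integer multiple of target_fs")
  d <- raw[, 1] - raw[, 2]
  n_blk <- floor(length(d) / dec)
  d <- colMeans(matrix(d[seq_len(n_blk * dec)], nrow = dec))
  apply_filter <- function(x, flt) {
    if (zero_phase) signal::filtfilt(flt, x)
    else as.numeric(signal::filter(flt, x))
  }
  hp <- signal::butter(2, highpass / (target_fs / 2), type = "high")
  lp <- signal::butter(2, lowpass / (target_fs / 2), type = "low")
  env <- apply_filter(abs(apply_filter(d, hp)), lp)
  attr(env, "fs") <- target_fs
  env
}

#' Windowed single-sinusoid Bayesian frequency posterior
#'
#' For each window of `window` seconds stepped by `step`, models the
#' (mean-subtracted) signal as a single sinusoid of unknown frequency,
#' amplitude and phase plus Gaussian noise, and computes the posterior over
#' a discrete frequency grid with the two quadrature amplitudes and the
#' noise scale marginalized analytically (flat priors on amplitudes,
#' Jeffreys prior on the noise): the marginal density at frequency f is
#' proportional to `det(G'G)^(-1/2) * (d'd - h^2)^(-(N-2)/2)`, where G is
#' the cosine/sine design and `h^2` the projection of the data onto it.
#' Posteriors are normalized over the grid, one row per window.
#'
#' @param env envelope vector at `fs` Hz (attribute `fs`, default 1000).
#' @param freqs frequency grid, Hz (default 20 points spanning 1-10 Hz).
#' @param window window width, seconds (default 0.3).
#' @param step window step, seconds (default 0.001).
#' @return matrix `windows x length(freqs)` of normalized posteriors, with
#'   attributes `freqs` and `times` (window start times, seconds). Windows
#'   that would extend past the end of the signal are dropped, so the
#'   series is truncated by `window` seconds.
#' @export
bsa_frequency_posterior <- function(env, freqs = seq(1, 10,
                                                     length.out = 20),
                                    window = 0.3, step = 0.001) {
  fs <- attr(env, "fs")
  if (is.null(fs)) fs <- 1000
  nw <- round(window * fs)
  nstep <- max(1L, round(step * fs))
  y <- as.numeric(env)
  if (length(y) < nw)
    stop("signal shorter (", length(y), " samples) than one window (",
         nw, ")")
  starts <- seq.int(1L, length(y) - nw + 1L, by = nstep)
  # windows x nw matrix of the signal
  W <- t(vapply(starts, function(s) y[s:(s + nw - 1L)], numeric(nw)))
  mu <- rowMeans(W)
  W <- W - mu
  dd <- rowSums(W^2)
  tt <- (seq_len(nw) - 1) / fs
  logpost <- matrix(NA_real_, length(starts), length(freqs))
  N <- nw
  for (f in seq_along(freqs)) {
    G <- cbind(cos(2 * pi * freqs[f] * tt), sin(2 * pi * freqs[f] * tt))
    GtG <- crossprod(G)
    P <- W %*% G                      # windows x 2 projections
    M <- solve(GtG)
    h2 <- rowSums((P %*% M) * P)
    resid <- pmax(dd - h2, .Machine$double.eps * pmax(dd, 1))
    logpost[, f] <- -0.5 * determinant(GtG)$modulus -
      ((N - 2) / 2) * log(resid)
  }
  post <- exp(logpost - apply(logpost, 1, max))
  post <- post / rowSums(post)
  attr(post, "freqs") <- freqs
  attr(post, "times") <- (starts - 1) / fs
  attr(post, "window_width") <- window
  post
}

#' Per-time-point probability of gaping from the EMG envelope
#'
#' Runs [bsa_frequency_posterior()] and sums the posterior mass over the
#' grid frequencies falling in the closed gaping band (4-6 Hz). Each
#' probability is indexed to the start of its 300 ms analysis window
#' (`Pr_Gape(t)` covers `[t, t + 0.3]`): a slow rhythm needs most of a
#' window of evidence before it dominates, so start indexing places the
#' detection at the rhythm's onset rather than half a window late when a
#' competing faster rhythm (licking) runs right up to the transition.
#' `align = "center"`/`"end"` index to the window's middle or right edge.
#'
#' @param env envelope vector from [preprocess_emg()].
#' @param band gaping frequency band, Hz (closed interval).
#' @param align which point of the window each probability is assigned to.
#' @param ... passed to [bsa_frequency_posterior()].
#' @return object of class `gape_probability`: `data.frame` with `time`
#'   (seconds) and `pr_gape` in \[0, 1\]; the full frequency posterior is
#'   kept in attribute `posterior`.
#' @export
bsa_gape_probability <- function(env, band = c(4, 6),
                                 align = c("start", "center", "end"), ...) {
  align <- match.arg(align)
  post <- bsa_frequency_posterior(env, ...)
  freqs <- attr(post, "freqs")
  in_band <- freqs >= band[1] & freqs <= band[2]
  pr <- pmin(pmax(rowSums(post[, in_band, drop = FALSE]), 0), 1)
  times <- attr(post, "times")
  width <- attr(post, "window_width")
  shift <- switch(align, center = width / 2, start = 0, end = width)
  out <- data.frame(time = times + shift, pr_gape = pr)
  structure(out, posterior = post, band = band,
            class = c("gape_probability", "data.frame"))
}

#' Gape probability series for a whole EMG session
#'
#' Preprocesses each trial's raw EMG and computes its gape probability
#' series; trials are required to share a duration so the series align.
#'
#' @param emg list of raw two-channel matrices (attribute `fs`), as
#'   produced by [simulate_emg_session()] or [read_session()].
#' @param ... passed to [bsa_gape_probability()].
#' @return matrix `trials x timepoints` of Pr(Gape), attribute `times`.
#' @export
gape_probability_session <- function(emg, ...) {
  fs <- attr(emg, "fs")
  if (is.null(fs)) stop("`emg` must carry an `fs` attribute")
  series <- lapply(emg, function(m) {
    env <- preprocess_emg(m, fs = fs)
    bsa_gape_probability(env, ...)
  })
  n <- unique(vapply(series, nrow, integer(1)))
  if (length(n) != 1) stop("trials differ in duration; cannot align series")
  out <- do.call(rbind, lapply(series, function(s) s$pr_gape))
  attr(out, "times") <- series[[1]]$time
  out
}
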