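rates_from_model <- function(f, trials = 12, neurons = 3, seed = 1,
                             window = c(-0.25, 1.5)) {
  # build a binned-rate array whose (trial, neuron, bin) entries follow a
  # caller-supplied function of (rank, neuron, bin time)
  set.seed(seed)
  taste <- rep(c("DilSuc", "ConcSuc", "DilQui", "ConcQui"),
               length.out = trials)
  lab <- trial_labels(taste)
  starts <- seq(window[1], window[2] - 0.25, by = 0.025)
  r <- array(0, dim = c(trials, neurons, length(starts)))
  for (i in seq_len(trials))
    for (n in seq_len(neurons))
      for (b in seq_along(starts))
        r[i, n, b] <- f(lab$rank[i], n, starts[b])
  attr(r, "bin_starts") <- starts
  attr(r, "bin_width") <- 0.25
  list(rates = r, labels = lab)
}

test_that("z-scoring is exact per (neuron, bin) and flags zero variance", {
  d <- rates_from_model(function(p, n, t) p * 2 + rnorm(1), trials = 16)
  std <- standardize_and_align(d$rates, d$labels)
  for (b in c(1, 30)) {
    expect_lt(abs(mean(std$z[, 2, b])), 1e-10)
    expect_lt(abs(stats::sd(std$z[, 2, b]) - 1), 1e-10)
  }
  # constant bin -> zero output, flagged
  d2 <- rates_from_model(function(p, n, t) if (t < 0) 5 else p + rnorm(1),
                         trials = 8)
  std2 <- standardize_and_align(d2$rates, d2$labels)
  pre <- which(attr(d2$rates, "bin_starts") + 0.25 <= 0)
  expect_true(all(std2$flagged[, pre]))
  expect_true(all(std2$z[, , pre] == 0))
})

test_that("sign alignment flips anti-palatability neurons positive", {
  d <- rates_from_model(function(p, n, t) {
    base <- if (t > 0.2) p else 0
    if (n == 1) -2 * base + rnorm(1, 0, 0.3) else 2 * base + rnorm(1, 0, 0.3)
  }, trials = 24)
  std <- standardize_and_align(d$rates, d$labels)
  expect_equal(std$sign[1], -1)
  expect_equal(std$sign[2], 1)
  post <- which(attr(d$rates, "bin_starts") > 0.3)
  rho <- stats::cor(std$z[, 1, post[5]], d$labels$rank, method = "spearman")
  expect_gt(rho, 0)
})

test_that("the index regression recovers a known palatability slope", {
  # generative form of the per-bin model: firing = beta * P + noise
  d <- rates_from_model(function(p, n, t) 0.5 * p + rnorm(1),
                        trials = 40, neurons = 1,
                        window = c(-0.25, 0.3))
  std <- structure(list(z = d$rates, sign = 1,
                        flagged = matrix(FALSE, 1, dim(d$rates)[3]),
                        rank = d$labels$rank,
                        bin_starts = attr(d$rates, "bin_starts")),
                   class = "standardized_firing")
  ser <- fit_palatability_index(std, seed = 2)
  expect_true(all(ser$rhat_max <= 1.01))
  expect_true(all(abs(ser$beta_mean - 0.5) < 3 * (ser$ci_high - ser$ci_low)))
  post <- ser$time >= 0
  expect_true(all(ser$significant[post]))
  expect_lt(abs(mean(ser$beta_norm[ser$time < 0])), 1e-12)
})

test_that("permuted ranks suppress significance to the nominal rate", {
  d <- rates_from_model(function(p, n, t) 0.5 * p + rnorm(1),
                        trials = 40, neurons = 2)
  set.seed(9)
  d$labels$rank <- sample(d$labels$rank)
  std <- standardize_and_align(d$rates, d$labels)
  ser <- fit_palatability_index(std, seed = 3)
  expect_lte(mean(ser$significant), 0.03)
})

test_that("the sigmoid peak identity holds for every posterior draw", {
  series <- data.frame(
    time = seq(-0.25, 1.475, by = 0.025))
  series$beta_norm <- sigmoid_value(series$time * 1000, 0.06, 0.01, 675) +
    rnorm(nrow(series), 0, 0.002)
  fit <- fit_sigmoid(series, seed = 4)
  d <- posterior_draws(fit)
  expect_true(all(d[, "L"] > 0 & d[, "k"] > 0 & d[, "t0"] > 0))
  ratio <- sigmoid_value(d[, "t_peak"], d[, "L"], d[, "k"], d[, "t0"]) /
    d[, "L"]
  expect_equal(ratio, rep(0.95, length(ratio)), tolerance = 1e-12)
  expect_equal(d[, "t_peak"] - d[, "t0"], log(19) / d[, "k"])
  # parameters recovered within their 95% intervals
  for (p in c(L = 0.06, k = 0.01, t0 = 675)) {
    nm <- names(which(c(L = 0.06, k = 0.01, t0 = 675) == p))[1]
    row <- fit[fit$parameter == nm, ]
    expect_true(row$ci_low <= p && p <= row$ci_high)
  }
})

test_that("a flat series yields a near-zero asymptote", {
  series <- data.frame(time = seq(-0.25, 1.475, by = 0.025))
  set.seed(5)
  series$beta_norm <- rnorm(nrow(series), 0, 0.003)
  # slope and inflection are unidentified on flat data, so a convergence
  # warning is expected alongside the shrunken asymptote
  fit <- suppressWarnings(fit_sigmoid(series, seed = 6))
  expect_lt(fit$mean[fit$parameter == "L"], 0.05)
  expect_warning(
    expect_warning(fit_sigmoid(series, seed = 6, stationary = FALSE),
                   "non-stationary"),
    "convergence")
})

test_that("stronger simulated coding raises the fitted asymptote", {
  Ls <- vapply(c(0.02, 0.06, 0.12), function(amp) {
    series <- data.frame(time = seq(-0.25, 1.475, by = 0.025))
    set.seed(7)
    series$beta_norm <- sigmoid_value(series$time * 1000, amp, 0.012, 600) +
      rnorm(nrow(series), 0, 0.004)
    fit <- fit_sigmoid(series, seed = 8)
    fit$mean[fit$parameter == "L"]
  }, numeric(1))
  expect_true(all(diff(Ls) > 0))
})
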