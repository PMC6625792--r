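test_that("closed-form Beta KL matches quadrature over a parameter grid", {
  vals <- c(0.5, 1, 2, 5, 20)
  worst <- 0
  for (a1 in vals) for (b1 in vals) for (a2 in vals) for (b2 in vals) {
    cf <- beta_kl(a1, b1, a2, b2)
    qd <- quadrature_beta_kl(a1, b1, a2, b2)
    worst <- max(worst, abs(cf - qd))
  }
  expect_lt(worst, 1e-6)
  expect_identical(beta_kl(2, 5, 2, 5), 0)
  # KL is asymmetric (note (2,5) vs (5,2) is NOT a counterexample: the
  # x -> 1-x reflection makes that particular pair symmetric)
  expect_false(isTRUE(all.equal(beta_kl(2, 5, 4, 3), beta_kl(4, 3, 2, 5))))
  expect_error(beta_kl(0, 1, 1, 1), "positive")
})

test_that("beta bin series counts gaping trials with a pseudo-count", {
  pr <- rbind(c(0.9, 0.2, 0.5), c(0.7, 0.1, 0.8), c(0.3, 0.3, 0.6))
  attr(pr, "times") <- c(0, 0.001, 0.002)
  bb <- beta_bin_series(pr)
  expect_equal(bb$a, c(2, 0, 2) + 1)  # ties at exactly 0.5 are excluded
  expect_equal(bb$b, c(1, 3, 0) + 1)
  jeff <- beta_bin_series(pr, pseudo = 0.5)
  expect_equal(jeff$a, c(2.5, 0.5, 2.5))
})

test_that("KL series is zero for identical conditions, non-negative always", {
  pr <- matrix(runif(300), 10)
  attr(pr, "times") <- seq(0, by = 0.001, length.out = 30)
  b1 <- beta_bin_series(pr)
  kl <- kl_divergence_series(b1, b1)
  expect_true(all(kl$kl == 0))
  set.seed(1)
  pr2 <- matrix(runif(300), 10)
  attr(pr2, "times") <- attr(pr, "times")
  kl2 <- kl_divergence_series(b1, beta_bin_series(pr2))
  expect_true(all(kl2$kl >= 0))
  expect_true(all(diff(kl2$kl_cumsum) >= 0))
  bad <- beta_bin_series(pr2[, 1:10, drop = FALSE])
  expect_error(kl_divergence_series(b1, bad), "time grids")
})

test_that("a configured separation point shows up in the KL series", {
  set.seed(2)
  n <- 20; times <- seq(0, 1.999, by = 0.001)
  sep <- times >= 1.0
  conc <- matrix(rbinom(n * length(times), 1,
                        rep(ifelse(sep, 0.8, 0.1), each = n)),
                 n)
  dil <- matrix(rbinom(n * length(times), 1,
                       rep(ifelse(sep, 0.3, 0.1), each = n)),
                n)
  attr(conc, "times") <- times; attr(dil, "times") <- times
  kl <- kl_divergence_series(beta_bin_series(conc), beta_bin_series(dil))
  expect_gt(mean(kl$kl[sep]), 10 * mean(kl$kl[!sep]))
})

test_that("the change-point lands on a clean kink", {
  t <- seq(0, 1.999, by = 0.001)
  set.seed(8)
  # a whisper of noise keeps the noise scale identified for the sampler
  y <- ifelse(t <= 0.8, 0.05 * t, 0.04 + 1.2 * (t - 0.8)) +
    rnorm(length(t), 0, 0.002)
  kl <- data.frame(time = t, kl_cumsum = y)
  # near-noiseless data makes the line parameters extremely precise, so the
  # chains need a little more length to mix them
  fit <- fit_onset_changepoint(kl, seed = 1, n_burn = 2000, n_iter = 4000)
  expect_lt(abs(attr(fit, "onset_ms") - 800), 20)
  expect_true(attr(fit, "identified"))
  expect_true(all(fit$rhat <= 1.01))
  expect_error(fit_onset_changepoint(
    data.frame(time = t, kl_cumsum = c(NA, y[-1]))), "non-finite")
})

test_that("a single straight line leaves the change-point diffuse", {
  t <- seq(0, 1.999, by = 0.001)
  set.seed(3)
  kl <- data.frame(time = t, kl_cumsum = 0.9 * t + rnorm(length(t), 0, 0.1))
  fit <- suppressWarnings(fit_onset_changepoint(kl, seed = 2))
  expect_false(attr(fit, "identified"))
  expect_gt(stats::sd(posterior_draws(fit, "C")), 300)
})

test_that("comparing a fit against itself centers the delay at zero", {
  t <- seq(0, 1.999, by = 0.001)
  y <- ifelse(t <= 0.9, 0.01 * t, 0.009 + 0.9 * (t - 0.9))
  kl <- data.frame(time = t, kl_cumsum = y + 0.005 * sin(t * 40))
  f1 <- suppressWarnings(fit_onset_changepoint(kl, seed = 5))
  f2 <- suppressWarnings(fit_onset_changepoint(kl, seed = 5))
  cmp <- compare_onsets(f1, f2)
  expect_lt(abs(cmp$delay_ms), 1e-9)
  expect_false(cmp$significant)
  expect_identical(cmp$stars, "")
})

test_that("the full EMG pipeline recovers a configured mean onset", {
  # fixed first-gape latency so the configured mean is exact
  ec <- emg_sim_config(trials_per_taste = 15, duration = 2.3,
                       onset_mean = 0.9, onset_sd = 0)
  es <- simulate_emg_session(ec, seed = 11)
  pr <- gape_probability_session(es$emg)
  tst <- as.character(es$labels$taste_id)
  mk <- function(sel) {
    m <- pr[tst == sel, , drop = FALSE]
    attr(m, "times") <- attr(pr, "times")
    beta_bin_series(m)
  }
  kl <- kl_divergence_series(mk("ConcQui"), mk("DilQui"))
  fit <- suppressWarnings(
    fit_onset_changepoint(kl, seed = 12, n_burn = 2000, n_iter = 3000))
  expect_lt(abs(attr(fit, "onset_ms") - 900), 50)

  # sucrose trials never count as gaping after the initial transient, so
  # folding them into the dilute condition leaves the divergence onset put
  suc <- pr[tst %in% c("DilSuc", "ConcSuc"), , drop = FALSE]
  late <- attr(pr, "times") > 0.5
  expect_true(all(suc[, late] < 0.5 | is.na(suc[, late])))
  aug <- rbind(pr[tst == "DilQui", , drop = FALSE], suc)
  attr(aug, "times") <- attr(pr, "times")
  kl_aug <- kl_divergence_series(mk("ConcQui"), beta_bin_series(aug))
  fit_aug <- suppressWarnings(
    fit_onset_changepoint(kl_aug, seed = 13, n_burn = 2000, n_iter = 3000))
  expect_lt(abs(attr(fit_aug, "onset_ms") - attr(fit, "onset_ms")), 75)
})

test_that("onset delays between conditions are recovered with sign", {
  run <- function(onset_mean, seed) {
    ec <- emg_sim_config(trials_per_taste = 12, duration = 2.3,
                         onset_mean = onset_mean, onset_sd = 0)
    es <- simulate_emg_session(ec, seed = seed)
    pr <- gape_probability_session(es$emg)
    tst <- as.character(es$labels$taste_id)
    mk <- function(sel) {
      m <- pr[tst == sel, , drop = FALSE]
      attr(m, "times") <- attr(pr, "times")
      beta_bin_series(m)
    }
    suppressWarnings(fit_onset_changepoint(
      kl_divergence_series(mk("ConcQui"), mk("DilQui")),
      seed = seed + 1, n_burn = 2000, n_iter = 3000))
  }
  f_base <- run(0.9, 51)
  f_late <- run(1.15, 52)
  cmp <- compare_onsets(f_late, f_base)
  expect_true(cmp$significant)
  expect_gt(cmp$delay_ms, 150)
  expect_lt(cmp$delay_ms, 350)
})
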