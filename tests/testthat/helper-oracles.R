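# Independent oracles used across tests. Each is a deliberately naive
# implementation (enumeration, quadrature, grid marginalization) kept
# separate from the package's code paths.

# Brute-force global maximizer of the hard-EM objective: enumerate every
# admissible (C_I, C_P) assignment jointly over trials, set each emission
# distribution to its closed-form (count-normalized) optimum, and return
# the maximal total log-likelihood.
bruteforce_changepoint_loglik <- function(S, taste, n_neurons, cons) {
  group <- ifelse(taste %in% c("DilSuc", "ConcSuc"), "Suc", "Qui")
  tastes <- c("DilSuc", "ConcSuc", "DilQui", "ConcQui")
  n_tr <- nrow(S)
  n_bins <- ncol(S)
  K <- n_neurons + 1L
  pairs <- list()
  for (a in cons$ci_min:cons$ci_max)
    for (b in seq.int(a + cons$gap, cons$cp_max))
      if (b < n_bins) pairs[[length(pairs) + 1]] <- c(a, b)
  combo_ll <- function(assign_idx) {
    cnt_d <- numeric(K)
    cnt_i <- matrix(0, 2, K, dimnames = list(c("Suc", "Qui"), NULL))
    cnt_p <- matrix(0, 4, K, dimnames = list(tastes, NULL))
    for (j in seq_len(n_tr)) {
      ci <- pairs[[assign_idx[j]]][1]
      cp <- pairs[[assign_idx[j]]][2]
      cnt_d <- cnt_d + tabulate(S[j, 1:ci] + 1L, K)
      cnt_i[group[j], ] <- cnt_i[group[j], ] +
        tabulate(S[j, (ci + 1L):cp] + 1L, K)
      cnt_p[taste[j], ] <- cnt_p[taste[j], ] +
        tabulate(S[j, (cp + 1L):n_bins] + 1L, K)
    }
    ll_part <- function(cnt) {
      tot <- sum(cnt)
      if (tot == 0) return(0)
      p <- cnt / tot
      sum(cnt[cnt > 0] * log(p[cnt > 0]))
    }
    ll_part(cnt_d) + sum(apply(cnt_i, 1, ll_part)) +
      sum(apply(cnt_p, 1, ll_part))
  }
  grid <- as.matrix(expand.grid(rep(list(seq_along(pairs)), n_tr)))
  max(apply(grid, 1, combo_ll))
}

# KL(Beta(a1,b1) || Beta(a2,b2)) by adaptive quadrature of p log(p/q),
# after the substitution x = sin^2(theta) which removes the integrable
# endpoint singularities of small-concentration Betas.
quadrature_beta_kl <- function(a1, b1, a2, b2) {
  g <- function(theta) {
    x <- sin(theta)^2
    p <- stats::dbeta(x, a1, b1)
    q <- stats::dbeta(x, a2, b2)
    ifelse(p > 0, p * (log(p) - log(q)), 0) * sin(2 * theta)
  }
  stats::integrate(g, 0, pi / 2, rel.tol = 1e-10,
                   subdivisions = 1000L)$value
}

# Single-sinusoid frequency posterior by brute-force grid marginalization
# of the two amplitudes and the noise scale (flat amplitude priors,
# Jeffreys 1/sigma prior), on a short mean-subtracted window.
bruteforce_bsa_posterior <- function(d, fs, freqs,
                                     amp_grid = seq(-3, 3, length.out = 61),
                                     sig_grid = exp(seq(log(0.02), log(3),
                                                        length.out = 50))) {
  n <- length(d)
  tt <- (seq_len(n) - 1) / fs
  d <- d - mean(d)
  logpost <- vapply(freqs, function(f) {
    x1 <- cos(2 * pi * f * tt)
    x2 <- sin(2 * pi * f * tt)
    ll <- array(NA_real_,
                c(length(amp_grid), length(amp_grid), length(sig_grid)))
    # Jeffreys prior is uniform in log(sigma); sig_grid is log-spaced, so
    # equal-weight summation over it implements the prior exactly.
    for (ia in seq_along(amp_grid)) {
      for (ib in seq_along(amp_grid)) {
        r2 <- sum((d - amp_grid[ia] * x1 - amp_grid[ib] * x2)^2)
        ll[ia, ib, ] <- -n * log(sig_grid) - r2 / (2 * sig_grid^2)
      }
    }
    m <- max(ll)
    m + log(sum(exp(ll - m)))
  }, numeric(1))
  post <- exp(logpost - max(logpost))
  post / sum(post)
}
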