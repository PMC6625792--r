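# Shared MCMC plumbing: every Bayesian model in the package is fit through
# run_jags(), which seeds one RNG stream per chain so a fit is reproducible
# given (model, data, seed).

jags_inits <- function(chains, seed) {
  lapply(seq_len(chains), function(k) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (seed + 7919L * k) %% 2147483647L)
  })
}

run_jags <- function(model_string, data, monitor, seed,
                     chains = 4, n_adapt = 1000, n_burn = 1000,
                     n_iter = 2000, thin = 1, inits_extra = NULL) {
  inits <- jags_inits(chains, seed)
  if (!is.null(inits_extra))
    inits <- lapply(inits, function(x) c(x, inits_extra))
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          inits = inits, n.chains = chains,
                          n.adapt = n_adapt, quiet = TRUE)
  if (n_burn > 0) update(jm, n_burn, progress.bar = "none")
  rjags::coda.samples(jm, monitor, n.iter = n_iter, thin = thin,
                      progress.bar = "none")
}
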