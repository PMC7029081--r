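# shared fixtures: small MCMC budgets and hand-built series/fit objects

quick_control <- function(seed = 1, chains = 2) {
  mcmc_control(n_chains = chains, n_iter = 1200, n_warmup = 400, thin = 2,
               seed = seed)
}

# a prevalence series built by hand (not via the generators)
manual_series <- function(df) {
  validate_prevalence_series(df)
  structure(df, class = c("prevalence_series", "data.frame"))
}

# a skeleton transmission_fit carrying given pooled draws (single parameter)
# or a draws array / log-lik matrix, for testing summary and comparison code
fake_fit <- function(draws, log_lik = NULL, fingerprint = "fp",
                     model = "si") {
  if (is.null(dim(draws))) draws <- array(draws, dim = c(length(draws), 1, 1),
                                          dimnames = list(NULL, NULL, "beta"))
  if (is.null(log_lik)) log_lik <- matrix(0, dim(draws)[1] * dim(draws)[2], 2)
  structure(list(draws = draws, log_lik = log_lik,
                 spec = list(model = model, free = dimnames(draws)[[3]],
                             fixed = list(),
                             init = matrix(c(49, 1, 0, 0), 1)),
                 control = mcmc_control(n_chains = dim(draws)[2],
                                        n_iter = 10, n_warmup = 0, thin = 1),
                 accept_rate = rep(0.3, dim(draws)[2]),
                 data_fingerprint = fingerprint, series = NULL),
            class = "transmission_fit")
}

random_symbiont_params <- function() {
  symbiont_params(beta_A = runif(1, 0, 2), beta_B = runif(1, 0, 2),
                  q = runif(1, 0, 2), psi = runif(1, 0, 2))
}

random_patch_state <- function(n_max = 200) {
  v <- stats::rmultinom(1, sample(10:n_max, 1), prob = runif(4, 0.05, 1))
  patch_state(v[1], v[2], v[3], v[4])
}
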