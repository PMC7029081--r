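test_that("uninformative data return the prior", {
  # observations at t = 0 only: the predicted fraction is I0/N whatever beta,
  # so the likelihood is flat and the posterior must reproduce the
  # half-Normal(0, 5) prior moments
  s <- manual_series(data.frame(replicate = 1:3, time = 0,
                                class = "infected", count = c(1, 1, 2),
                                n_assayed = 50))
  spec <- model_spec("si", init = c(S = 49, I = 1))
  fit <- fit_transmission(s, spec, control = mcmc_control(
    n_chains = 2, n_iter = 6000, n_warmup = 1000, thin = 1, seed = 21))
  dm <- pooled <- coef(fit)
  draws <- symbiodyn:::pooled_draws(fit)[, "beta"]
  expect_lt(abs(mean(draws) - 5 * sqrt(2 / pi)), 0.35)
  expect_lt(abs(sd(draws) - 5 * sqrt(1 - 2 / pi)), 0.35)
})

test_that("large balanced assays pin the transmission rate", {
  s <- simulate_release_experiment(beta = 0.5, seed = 31, n_replicates = 3,
                                   N = 50, n_assayed = 5000,
                                   sample_every = 1)
  fit <- fit_transmission(s, control = quick_control(seed = 31))
  expect_lt(abs(coef(fit)[["beta"]] - 0.5) / 0.5, 0.02)
})

test_that("doubling the assay size narrows the posterior", {
  sds <- vapply(c(10, 50, 250), function(n) {
    s <- simulate_release_experiment(beta = 0.5, seed = 41, n_assayed = n)
    fit <- fit_transmission(s, control = quick_control(seed = 41))
    sd(symbiodyn:::pooled_draws(fit)[, "beta"])
  }, numeric(1))
  expect_true(all(diff(sds) < 0))
})

test_that("chains, seeds and retained draw counts obey the configuration", {
  s <- simulate_release_experiment(beta = 0.5, seed = 51)
  ctl <- mcmc_control(n_chains = 2, n_iter = 900, n_warmup = 300, thin = 3,
                      seed = 51)
  fit <- fit_transmission(s, control = ctl)
  expect_equal(dim(fit$draws), c((900 - 300) %/% 3, 2, 1))
  expect_equal(nrow(fit$log_lik), 2 * ((900 - 300) %/% 3))
  expect_equal(ncol(fit$log_lik), nrow(s))
  fit2 <- fit_transmission(s, control = ctl)
  expect_identical(fit$draws, fit2$draws)
  expect_error(mcmc_control(n_iter = 100, n_warmup = 200))
})

test_that("posterior summaries follow the quantile conventions", {
  const <- fake_fit(rep(2.5, 100))
  s <- posterior_summary(const)
  expect_equal(s$q50, 2.5)
  expect_equal(s$q2.5, 2.5)
  expect_equal(s$q97.5, 2.5)
  # midpoint convention for a symmetric two-point sample
  two <- fake_fit(c(1, 3))
  expect_equal(posterior_summary(two)$q50, 2)
  # large-sample normal quantile oracle
  set.seed(1)
  z <- fake_fit(rnorm(10000))
  expect_lt(abs(posterior_summary(z)$q97.5 - 1.96), 0.05)
})

test_that("split R-hat and ESS behave on reference chains", {
  cst <- array(2, dim = c(500, 3, 1), dimnames = list(NULL, NULL, "beta"))
  expect_equal(fit_diagnostics(fake_fit(cst))$rhat, 1, tolerance = 1e-10)
  # exact copies of a mixing chain: no between-chain variance, R-hat ~ 1
  x <- matrix(rep(sin(1:500), 3), 500, 3)
  arr <- array(x, dim = c(500, 3, 1), dimnames = list(NULL, NULL, "beta"))
  d <- fit_diagnostics(fake_fit(arr))
  expect_lt(abs(d$rhat - 1), 0.01)

  set.seed(2)
  iid <- array(rnorm(3000), dim = c(1000, 3, 1),
               dimnames = list(NULL, NULL, "beta"))
  d2 <- fit_diagnostics(fake_fit(iid))
  expect_lt(d2$rhat, 1.01)
  expect_gt(d2$ess, 0.9 * 3000)
  expect_lt(d2$ess, 1.1 * 3000)

  one <- array(rnorm(500), dim = c(500, 1, 1),
               dimnames = list(NULL, NULL, "beta"))
  expect_true(is.na(fit_diagnostics(fake_fit(one))$rhat))
})

test_that("fit methods expose coherent predictions and residuals", {
  s <- simulate_release_experiment(beta = 0.5, seed = 61)
  fit <- fit_transmission(s, control = quick_control(seed = 61))
  pred <- predict(fit, times = seq(0, 20, 2))
  expect_equal(unique(pred$class), "infected")
  # the fraction at t = 0 is pinned at I0/N for every draw
  expect_equal(pred$q2.5[pred$time == 0], 0.02, tolerance = 1e-9)
  expect_equal(pred$q97.5[pred$time == 0], 0.02, tolerance = 1e-9)
  expect_true(all(pred$q2.5 <= pred$q50 & pred$q50 <= pred$q97.5))
  r <- residuals(fit)
  expect_equal(length(r), nrow(s))
  expect_lt(mean(abs(r)), 0.15)
  sims <- simulate(fit, nsim = 2, seed = 61)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "prevalence_series")
})

test_that("degenerate all-zero data complete with a wide posterior", {
  s <- manual_series(data.frame(replicate = 1, time = seq(0, 10, 2),
                                class = "infected", count = 0,
                                n_assayed = 20))
  spec <- model_spec("si", init = c(S = 49, I = 1))
  fit <- fit_transmission(s, spec, control = quick_control(seed = 71))
  dr <- symbiodyn:::pooled_draws(fit)[, "beta"]
  expect_true(is.finite(sd(dr)))
  # zero observed spread: the posterior concentrates near small beta but
  # remains proper
  expect_lt(coef(fit)[["beta"]], 0.5)
})
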