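test_that("SI integration matches the logistic closed form on a grid", {
  for (beta in c(0.1, 0.5, 1.0)) {
    for (N in c(50, 500)) {
      for (I0 in c(1, 5)) {
        times <- seq(0, 20, by = 2)
        tr <- integrate_model("si", list(beta = beta),
                              c(S = N - I0, I = I0), times)
        exact <- si_closed_form(times, beta, N, I0)
        rel <- abs(tr$states[, 1, "I_A"] - exact) / exact
        expect_lt(max(rel), 1e-6)
      }
    }
  }
})

test_that("integration respects initial conditions and degenerate rates", {
  tr <- integrate_model("si", list(beta = 0.5), c(S = 49, I = 1), c(0, 1))
  expect_equal(unname(tr$states[1, 1, "I_A"]), 1)
  tr0 <- integrate_model("si", list(beta = 0), c(S = 49, I = 1), 0:10)
  expect_equal(unname(tr0$states[, 1, "I_A"]), rep(1, 11), tolerance = 1e-10)
  expect_error(integrate_model("si", list(beta = 0.5), c(S = 49, I = 1),
                               c(0, 2, 1)), "increasing")
})

test_that("deterministic trajectories are bit-for-bit reproducible", {
  args <- list("two_symbiont", symbiont_params(), patch_state(90, 5, 5, 0),
               seq(0, 20, 2))
  t1 <- do.call(integrate_model, args)
  t2 <- do.call(integrate_model, args)
  expect_identical(t1$states, t2$states)
})

test_that("trajectory exports a tidy CSV that reads back", {
  tr <- integrate_model("two_symbiont", symbiont_params(),
                        patch_state(90, 5, 5, 0), seq(0, 10, 2))
  path <- file.path(tempdir(), "traj.csv")
  write_trajectory_csv(tr, path)
  back <- utils::read.csv(path)
  expect_identical(names(back), c("time", "patch", "S", "I_A", "I_B", "X"))
  expect_equal(nrow(back), 6)
  expect_equal(back$S + back$I_A + back$I_B + back$X, rep(100, 6),
               tolerance = 1e-6)
})

test_that("Gillespie runs are seeded, integer-valued and conservative", {
  a <- gillespie_simulate("si", list(beta = 0.5), c(S = 49, I = 1), 20,
                          seed = 3)
  b <- gillespie_simulate("si", list(beta = 0.5), c(S = 49, I = 1), 20,
                          seed = 3)
  expect_identical(a$states, b$states)
  expect_true(all(a$states == round(a$states)))
  expect_true(all(a$states >= 0))

  tw <- gillespie_simulate("two_symbiont", symbiont_params(),
                           patch_state(90, 5, 5, 0), 20, seed = 4)
  expect_equal(unname(apply(tw$states, 1, sum)), rep(100, 201))

  expect_error(gillespie_simulate("si", list(beta = 0.5),
                                  c(S = 49.5, I = 0.5), 10, seed = 1),
               "integer")
})

test_that("zero total rate freezes the state to the horizon", {
  tr <- gillespie_simulate("si", list(beta = 0), c(S = 49, I = 1), 10,
                           seed = 1)
  expect_equal(unname(tr$states[, 1, "I_A"]), rep(1, 201))
  # all-susceptible population is absorbing too
  tr2 <- gillespie_simulate("two_symbiont", symbiont_params(),
                            patch_state(100, 0, 0, 0), 10, seed = 1)
  expect_equal(unname(tr2$states[, 1, "S"]), rep(100, 201))
})

test_that("the first SI event waits an exponential time at rate 0.49", {
  # the single infection channel with I=1, N=50, beta=0.5 has rate 0.49;
  # the simulator's first waiting time must equal rexp(1, 0.49) at the seed
  set.seed(7L)
  t1 <- rexp(1, 0.49)
  grid <- seq(0, 20, by = 0.1)
  tr <- gillespie_simulate("si", list(beta = 0.5), c(S = 49, I = 1), 20,
                           seed = 7, record_times = grid)
  expect_true(all(tr$states[grid < t1, 1, "I_A"] == 1))
  expect_gte(tr$states[min(which(grid >= t1)) + 1, 1, "I_A"], 2)
})

test_that("Gillespie means match the exact master-equation mean", {
  # pure-birth SI chain: solve dp/dt exactly and compare replicate means
  N <- 60; beta <- 0.5; I0 <- 3; t_eval <- 4
  states <- I0:N
  lam <- beta * states * (N - states) / N
  p0 <- c(1, rep(0, length(states) - 1))
  sol <- deSolve::lsoda(p0, c(0, t_eval), function(t, p, parms) {
    list(c(0, lam[-length(lam)] * p[-length(p)]) - lam * p)
  }, NULL, rtol = 1e-10, atol = 1e-12)
  exact_mean <- drop(sol[2, -1] %*% states)

  n_rep <- 400
  finals <- vapply(seq_len(n_rep), function(k) {
    gillespie_simulate("si", list(beta = beta), c(S = N - I0, I = I0),
                       t_eval, seed = 1000 + k,
                       record_times = c(0, t_eval))$states[2, 1, "I_A"]
  }, numeric(1))
  z <- (mean(finals) - exact_mean) / (sd(finals) / sqrt(n_rep))
  expect_lt(abs(z), 3)
})

test_that("metacommunity Gillespie conserves hosts without demography", {
  rho <- matrix(c(0, 1, 1, 0), 2)
  mp <- model_params(symbiont_params(0.5, 0.3, 0.8, 1.2),
                     demography_params(),
                     migration_params(m = 0.2, rho = rho))
  init <- metacommunity_state(rbind(c(45, 5, 0, 0), c(50, 0, 5, 0)))
  tr <- gillespie_simulate("metacommunity", mp, init, 10, seed = 9)
  totals <- apply(tr$states, 1, sum)
  expect_equal(unname(totals), rep(105, 201))
})
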