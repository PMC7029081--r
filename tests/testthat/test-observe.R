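test_that("degenerate class fractions observe deterministically", {
  # all-susceptible: infected fraction 0 -> every count 0
  tr0 <- integrate_model("si", list(beta = 0.5), c(S = 50, I = 0), 0:10)
  s0 <- observe(tr0, observation_schedule(c(0, 5, 10), 50, 2, seed = 1))
  expect_true(all(s0$count == 0))
  # all-infected: fraction 1 -> every count equals n_assayed
  tr1 <- integrate_model("si", list(beta = 0.5), c(S = 0, I = 50), 0:10)
  s1 <- observe(tr1, observation_schedule(c(0, 5, 10), 50, 2, seed = 1))
  expect_true(all(s1$count == 50))
})

test_that("observation error has binomial moments", {
  # constant fraction 1/2: 10,000 draws of Bin(50, 0.5)
  tr <- integrate_model("si", list(beta = 0), c(S = 25, I = 25), c(0, 1))
  s <- observe(tr, observation_schedule(0:1, n_assayed = 50,
                                        n_replicates = 5000, seed = 99))
  counts <- s$count
  expect_equal(length(counts), 10000)
  expect_lt(abs(mean(counts) - 25), 0.2)
  expect_lt(abs(var(counts) - 12.5), 0.6)
})

test_that("observation substreams make replicates stable and reproducible", {
  tr <- integrate_model("si", list(beta = 0.5), c(S = 49, I = 1),
                        seq(0, 20, 2))
  sched3 <- observation_schedule(seq(0, 20, 2), 50, 3, seed = 5)
  sched1 <- observation_schedule(seq(0, 20, 2), 50, 1, seed = 5)
  a <- observe(tr, sched3)
  b <- observe(tr, sched3)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # replicate 1 is invariant to how many replicates are requested
  one <- observe(tr, sched1)
  expect_equal(as.data.frame(a[a$replicate == 1, ]),
               as.data.frame(one), ignore_attr = TRUE)
})

test_that("sampling outside the simulated span is rejected", {
  tr <- integrate_model("si", list(beta = 0.5), c(S = 49, I = 1), 0:10)
  expect_error(observe(tr, observation_schedule(c(0, 12), 50, 1, 1)),
               "span")
})

test_that("release experiment reproduces its published design", {
  s <- simulate_release_experiment(beta = 0.5, seed = 2)
  expect_equal(sort(unique(s$replicate)), 1:3)
  expect_true(all(s$n_assayed == 50))
  expect_equal(sort(unique(s$time)), seq(0, 20, 2))
  md <- attr(s, "metadata")
  expect_equal(md$N, 50)
  expect_equal(md$I0, 1)
  expect_equal(md$beta, 0.5)
  # the epidemic starts from a 2% infected fraction
  expect_true(all(s$count[s$time == 0] <= 10))
  expect_identical(as.data.frame(simulate_release_experiment(seed = 2)),
                   as.data.frame(s))
})

test_that("a zero transmission rate keeps prevalence flat in expectation", {
  s <- simulate_release_experiment(beta = 0, seed = 3, n_replicates = 50)
  # each count is Bin(50, 0.02); the mean over 550 draws is close to 1
  expect_lt(abs(mean(s$count) - 1), 0.35)
})

test_that("coinfection experiment starts from the four printed designs", {
  s <- simulate_coinfection_experiment(seed = 4)
  md <- attr(s, "metadata")
  expect_equal(unname(rowSums(md$inits)), rep(100, 4))
  expect_equal(unname(md$inits[1, ]), c(90, 0, 0, 10))
  expect_equal(unname(md$inits[2, ]), c(90, 5, 5, 0))
  expect_equal(unname(md$inits[3, ]), c(88, 10, 0, 2))
  expect_equal(unname(md$inits[4, ]), c(88, 0, 10, 2))
  expect_equal(sort(unique(s$replicate)), 1:4)
  expect_setequal(unique(s$class), c("I_A", "I_B", "X"))
  # population (a): 10% coinfected, no singly infected at t = 0
  t0 <- s[s$time == 0 & s$replicate == 1, ]
  expect_equal(t0$count[t0$class == "I_A"], 0)
  expect_equal(t0$count[t0$class == "I_B"], 0)
  expect_gt(t0$count[t0$class == "X"], 0)
  # class counts at any time never exceed the assay size
  sums <- tapply(s$count, paste(s$replicate, s$time), sum)
  expect_true(all(sums <= 100))
  expect_identical(as.data.frame(simulate_coinfection_experiment(seed = 4)),
                   as.data.frame(s))
})

test_that("all-zero transmission keeps coinfection classes constant", {
  s <- simulate_coinfection_experiment(
    params = symbiont_params(0, 0, 0, 0), seed = 6)
  # replicate 2 starts at 5/5/0 out of 100: binomial means are preserved
  r2 <- s[s$replicate == 2 & s$class == "I_A", ]
  expect_lt(abs(mean(r2$count) - 5), 3)
})
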