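test_that("SI rate of change matches hand evaluation and boundary cases", {
  expect_equal(si_rhs(I = 0, N = 50, beta = 0.5), 0)
  expect_equal(si_rhs(I = 50, N = 50, beta = 0.5), 0)
  expect_equal(si_rhs(I = 1, N = 50, beta = 0.5), 0.49)
  expect_error(si_rhs(I = 1, N = 0, beta = 0.5), "invalid population")
  expect_error(si_rhs(I = 60, N = 50, beta = 0.5), "\\[0, N\\]")
})

test_that("two-symbiont derivatives match term-by-term hand evaluation", {
  # beta (I+qX) S/N etc. with S=90, I_A=I_B=5, N=100, beta=0.5, q=psi=1:
  # infections 2.25 each, secondary 0.125 each
  d <- experiment_rhs(patch_state(90, 5, 5, 0),
                      symbiont_params(0.5, 0.5, q = 1, psi = 1))
  expect_equal(unname(d), c(-4.5, 2.125, 2.125, 0.25))

  # q=0 silences coinfected transmission; no singly infected exist
  d0 <- experiment_rhs(patch_state(90, 0, 0, 10),
                       symbiont_params(0.7, 0.3, q = 0, psi = 2))
  expect_equal(unname(d0), c(0, 0, 0, 0))

  # empty patch is stationary
  expect_equal(unname(experiment_rhs(patch_state(0, 0, 0, 0),
                                     symbiont_params())),
               c(0, 0, 0, 0))
})

test_that("closed population conserves hosts for random states and params", {
  set.seed(42)
  for (i in 1:200) {
    d <- experiment_rhs(random_patch_state(), random_symbiont_params())
    expect_equal(sum(d), 0, tolerance = 1e-12)
  }
})

test_that("symbiont labels are exchangeable", {
  set.seed(7)
  for (i in 1:50) {
    st <- random_patch_state()
    p <- random_symbiont_params()
    st_sw <- patch_state(st[["S"]], st[["I_B"]], st[["I_A"]], st[["X"]])
    p_sw <- symbiont_params(p$beta_B, p$beta_A, p$q, p$psi)
    d <- experiment_rhs(st, p)
    d_sw <- experiment_rhs(st_sw, p_sw)
    expect_equal(d_sw[["I_A"]], d[["I_B"]], tolerance = 1e-12)
    expect_equal(d_sw[["I_B"]], d[["I_A"]], tolerance = 1e-12)
    expect_equal(d_sw[["S"]], d[["S"]], tolerance = 1e-12)
    expect_equal(d_sw[["X"]], d[["X"]], tolerance = 1e-12)
  }
})

test_that("q = 1 pools coinfected hosts into the infectious class", {
  st <- patch_state(70, 12, 8, 10)
  p <- symbiont_params(0.6, 0.4, q = 1, psi = 1)
  N <- patch_total(st)
  d <- experiment_rhs(st, p)
  foi_A_pooled <- p$beta_A * (st[["I_A"]] + st[["X"]]) / N
  foi_B_pooled <- p$beta_B * (st[["I_B"]] + st[["X"]]) / N
  expect_equal(d[["S"]], -(foi_A_pooled + foi_B_pooled) * st[["S"]],
               tolerance = 1e-12)
})

test_that("metacommunity model reduces to the experiment and SI models", {
  set.seed(11)
  for (i in 1:30) {
    st <- random_patch_state()
    sp <- random_symbiont_params()
    mp <- model_params(sp, demography_params(), migration_params())
    d_meta <- metacommunity_rhs(metacommunity_state(matrix(st, 1)), mp)
    d_exp <- experiment_rhs(st, sp)
    expect_equal(unname(d_meta[1, ]), unname(d_exp), tolerance = 1e-12)
  }
  # one symbiont: I_A plays the role of I in the SI model
  st <- patch_state(40, 10, 0, 0)
  sp <- symbiont_params(0.5, 0, q = 1, psi = 1)
  expect_equal(experiment_rhs(st, sp)[["I_A"]], si_rhs(10, 50, 0.5),
               tolerance = 1e-12)
})

test_that("demography and vertical transmission terms match hand evaluation", {
  # phi = 1: every birth is susceptible; births = nu_b * N = 2, deaths 0.1/class
  mp <- model_params(symbiont_params(0, 0, 1, 1),
                     demography_params(nu_b = 0.1, nu_d = 0.1, phi = 1),
                     migration_params())
  st <- metacommunity_state(matrix(c(10, 10, 0, 0), 1))
  d <- metacommunity_rhs(st, mp)
  expect_equal(unname(d[1, ]), c(1, -1, 0, 0))

  # phi = 0, coinfected mothers split c_A = 0.3, c_B = 0.2
  mp2 <- model_params(symbiont_params(0, 0, 1, 1),
                      demography_params(nu_b = 1, nu_d = 0, phi = 0,
                                        c_A = 0.3, c_B = 0.2),
                      migration_params())
  st2 <- metacommunity_state(matrix(c(0, 0, 0, 10), 1))
  d2 <- metacommunity_rhs(st2, mp2)
  expect_equal(unname(d2[1, ]), c(0, 3, 2, 5))
  # births always total nu_b * N
  expect_equal(sum(d2), 10)
})

test_that("migration only redistributes hosts", {
  rho <- build_migration_matrix(matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3), 1)
  mp <- model_params(symbiont_params(0.5, 0.3, 0.8, 1.2),
                     demography_params(),
                     migration_params(m = 0.4, rho = rho))
  set.seed(3)
  P <- matrix(sample(5:50, 12), 3, 4)
  d <- metacommunity_rhs(metacommunity_state(P), mp)
  # with no demography the patch-summed derivatives equal the summed
  # within-patch transmission terms: migration cancels column-wise
  d_nomig <- t(sapply(1:3, function(j)
    experiment_rhs(patch_state(P[j, 1], P[j, 2], P[j, 3], P[j, 4]),
                   mp$symbiont)))
  expect_equal(colSums(d), colSums(d_nomig), tolerance = 1e-10)

  # two identical patches: immigration balances emigration exactly
  mp2 <- model_params(symbiont_params(0, 0, 1, 1), demography_params(),
                      migration_params(m = 0.7, rho = matrix(c(0, 1, 1, 0), 2)))
  P2 <- rbind(c(30, 5, 2, 1), c(30, 5, 2, 1))
  d2 <- metacommunity_rhs(metacommunity_state(P2), mp2)
  expect_equal(unname(d2), matrix(0, 2, 4), ignore_attr = TRUE)
})

test_that("dimension mismatches and empty patches are handled", {
  mp <- model_params(migration = migration_params(
    m = 0.1, rho = matrix(c(0, 1, 1, 0), 2)))
  expect_error(metacommunity_rhs(metacommunity_state(matrix(1, 3, 4)), mp),
               "patches")
  # empty patch: no hosts, no contacts, all derivatives zero
  mp1 <- model_params(symbiont_params(1, 1, 1, 1))
  d <- metacommunity_rhs(metacommunity_state(matrix(0, 1, 4)), mp1)
  expect_equal(unname(d[1, ]), c(0, 0, 0, 0))
})
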