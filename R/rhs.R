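#' Rate of change of the single-symbiont SI model
#'
#' The simplest transmission model for a closed host population of constant
#' size `N`: infected hosts `I` contact susceptibles `N - I` and transmit at
#' frequency-dependent rate `beta`, giving `I' = beta * I * (N - I) / N`.
#' This is the model fitted to single-symbiont release experiments.
#'
#' @param I Infected count (or density), `0 <= I <= N`.
#' @param N Population size, `> 0`.
#' @param beta Transmission rate (per day), `>= 0`.
#' @return The derivative `dI/dt`; zero when `I = 0` or `I = N`.
#' @examples
#' si_rhs(I = 1, N = 50, beta = 0.5) # 0.49
#' @export
si_rhs <- function(I, N, beta) {
  if (!is.finite(N) || N <= 0) stop("invalid population: N must be > 0",
                                    call. = FALSE)
  if (!is.finite(I) || I < 0 || I > N)
    stop("I must lie in [0, N]", call. = FALSE)
  if (!is.finite(beta) || beta < 0) stop("beta must be >= 0", call. = FALSE)
  beta * I * (N - I) / N
}

#' Rates of change of the two-symbiont experiment model
#'
#' The closed-population coinfection model used for multisymbiont laboratory
#' experiments: horizontal transmission only, no demography and no migration,
#' so the four derivatives always sum to zero. Forces of infection are
#' frequency dependent; coinfected hosts transmit each symbiont with modifier
#' `q`, and singly infected hosts acquire the second symbiont with
#' susceptibility modifier `psi`:
#' \deqn{S' = -\beta_A (I_A + qX) S/N - \beta_B (I_B + qX) S/N}
#' \deqn{I_A' = \beta_A (I_A + qX) S/N - \psi \beta_B (I_B + qX) I_A/N}
#' \deqn{I_B' = \beta_B (I_B + qX) S/N - \psi \beta_A (I_A + qX) I_B/N}
#' \deqn{X'  = \psi \beta_B (I_B + qX) I_A/N + \psi \beta_A (I_A + qX) I_B/N}
#'
#' @param state A [patch_state()] (or named numeric with `S`, `I_A`, `I_B`,
#'   `X`).
#' @param params A [symbiont_params()] object.
#' @return Named numeric vector of derivatives `(S, I_A, I_B, X)`; all zeros
#'   for an empty patch (`N = 0`).
#' @examples
#' experiment_rhs(patch_state(90, 5, 5, 0),
#'                symbiont_params(0.5, 0.5, q = 1, psi = 1))
#' @export
experiment_rhs <- function(state, params) {
  S <- state[["S"]]; IA <- state[["I_A"]]; IB <- state[["I_B"]]; X <- state[["X"]]
  N <- S + IA + IB + X
  if (N <= 0) return(c(S = 0, I_A = 0, I_B = 0, X = 0))
  foi_A <- params$beta_A * (IA + params$q * X) / N
  foi_B <- params$beta_B * (IB + params$q * X) / N
  inf_A <- foi_A * S            # S -> I_A
  inf_B <- foi_B * S            # S -> I_B
  sec_A <- params$psi * foi_B * IA  # I_A -> X (acquires B)
  sec_B <- params$psi * foi_A * IB  # I_B -> X (acquires A)
  c(S = -inf_A - inf_B,
    I_A = inf_A - sec_A,
    I_B = inf_B - sec_B,
    X = sec_A + sec_B)
}

#' Rates of change of the full metacommunity model
#'
#' Extends the two-symbiont experiment model with host demography, vertical
#' transmission, and migration between `J` habitat patches. All classes
#' reproduce at `nu_b` and die at `nu_d` (infection does not affect either
#' rate). A birth from an infected mother is symbiont-free with probability
#' `phi`; otherwise the offspring inherits the mother's infection, with
#' coinfected mothers producing A-only, B-only, or coinfected offspring with
#' conditional probabilities `c_A`, `c_B`, `1 - (c_A + c_B)`. Births from
#' susceptible mothers are always susceptible, so total births are
#' `nu_b * N`. Hosts emigrate at per-capita rate `m` and are routed by
#' `rho[destination, source]`; summed over patches, migration terms cancel.
#'
#' @param state A [metacommunity_state()] with `J` patches.
#' @param params A [model_params()] object with matching `J`.
#' @return A `J x 4` matrix of derivatives with columns `S`, `I_A`, `I_B`,
#'   `X`. Horizontal-transmission terms in an empty patch are zero.
#' @export
metacommunity_rhs <- function(state, params) {
  P <- state$patches
  J <- nrow(P)
  if (params$migration$J != J)
    stop("state has ", J, " patches but params expect ", params$migration$J,
         call. = FALSE)
  sym <- params$symbiont; dem <- params$demography; mig <- params$migration
  S <- P[, "S"]; IA <- P[, "I_A"]; IB <- P[, "I_B"]; X <- P[, "X"]
  N <- S + IA + IB + X
  Nsafe <- ifelse(N > 0, N, 1)  # empty patches: force of infection is 0 anyway
  foi_A <- sym$beta_A * (IA + sym$q * X) / Nsafe
  foi_B <- sym$beta_B * (IB + sym$q * X) / Nsafe
  inf_A <- foi_A * S
  inf_B <- foi_B * S
  sec_A <- sym$psi * foi_B * IA
  sec_B <- sym$psi * foi_A * IB

  births_S <- dem$nu_b * (dem$phi * (X + IA + IB) + S)
  births_A <- dem$nu_b * (1 - dem$phi) * (dem$c_A * X + IA)
  births_B <- dem$nu_b * (1 - dem$phi) * (dem$c_B * X + IB)
  births_X <- dem$nu_b * (1 - dem$phi) * (1 - (dem$c_A + dem$c_B)) * X

  m <- mig$m; rho <- mig$rho
  mig_term <- function(v) if (m > 0) -m * v + as.vector(rho %*% (m * v)) else 0 * v

  dS <- births_S - dem$nu_d * S - inf_A - inf_B + mig_term(S)
  dIA <- births_A - dem$nu_d * IA + inf_A - sec_A + mig_term(IA)
  dIB <- births_B - dem$nu_d * IB + inf_B - sec_B + mig_term(IB)
  dX <- births_X - dem$nu_d * X + sec_A + sec_B + mig_term(X)
  cbind(S = dS, I_A = dIA, I_B = dIB, X = dX)
}
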