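#' Exact stochastic simulation by Gillespie's direct method
#'
#' Event-driven simulation of the transmission models with integer host
#' counts. At each step the total event rate determines an exponential
#' waiting time and a categorical draw picks the event. The event set
#' comprises, per patch: each horizontal-infection channel, births (with the
#' offspring class drawn from the vertical-transmission split of the mother's
#' class), deaths of each class, and per-class emigration routed by the
#' migration matrix. Simulation ends at `t_max` or earlier if the total rate
#' reaches zero (absorbing state).
#'
#' @inheritParams integrate_model
#' @param init Initial state with non-negative integer counts.
#' @param t_max Simulation horizon (days), `> 0`.
#' @param seed Integer RNG seed; identical inputs and seed reproduce the
#'   trajectory exactly.
#' @param record_times Times at which to record the state; defaults to 201
#'   equispaced points on `[0, t_max]`. The state recorded at time `t` is the
#'   state just before the first event after `t`.
#' @return A stochastic `trajectory` object.
#' @examples
#' tr <- gillespie_simulate("si", list(beta = 0.5), c(S = 49, I = 1),
#'                          t_max = 20, seed = 1)
#' @export
gillespie_simulate <- function(model = c("si", "two_symbiont", "metacommunity"),
                               params, init, t_max, seed,
                               record_times = NULL) {
  model <- match.arg(model)
  if (!is.finite(t_max) || t_max <= 0) stop("t_max must be > 0", call. = FALSE)
  P <- normalise_init(model, init)
  if (any(P != round(P)) || any(P < 0))
    stop("Gillespie simulation requires non-negative integer counts",
         call. = FALSE)
  if (is.null(record_times)) record_times <- seq(0, t_max, length.out = 201)
  record_times <- record_times[record_times <= t_max + 1e-12]
  set.seed(as.integer(seed))
  rec <- switch(model,
    si = gillespie_si(params, P, t_max, record_times),
    two_symbiont = gillespie_two(params, P, t_max, record_times),
    metacommunity = gillespie_meta(params, P, t_max, record_times))
  new_trajectory(times = record_times, states = rec, model = model,
                 stochastic = TRUE)
}

# record helper: states snapshot array [time, J, 4] filled as time advances
make_recorder <- function(record_times, J) {
  arr <- array(NA_real_, dim = c(length(record_times), J, 4),
               dimnames = list(NULL, NULL, class_names))
  ptr <- 1L
  list(
    note = function(t_now, P) {
      # record the pre-event state for all grid points passed before t_now
      while (ptr <= length(record_times) && record_times[ptr] < t_now) {
        arr[ptr, , ] <<- P
        ptr <<- ptr + 1L
      }
    },
    finish = function(P) {
      while (ptr <= length(record_times)) {
        arr[ptr, , ] <<- P
        ptr <<- ptr + 1L
      }
      arr
    })
}

gillespie_si <- function(params, P, t_max, record_times) {
  beta <- if (is.list(params)) params$beta else as.numeric(params)
  I <- P[1, "I_A"]; N <- sum(P)
  rec <- make_recorder(record_times, 1L)
  t <- 0
  repeat {
    rate <- beta * I * (N - I) / N
    if (rate <= 0) break
    t <- t + stats::rexp(1L, rate)
    if (t > t_max) break
    rec$note(t, matrix(c(N - I, I, 0, 0), 1))
    I <- I + 1
  }
  rec$finish(matrix(c(N - I, I, 0, 0), 1))
}

gillespie_two <- function(params, P, t_max, record_times) {
  S <- P[1, "S"]; IA <- P[1, "I_A"]; IB <- P[1, "I_B"]; X <- P[1, "X"]
  bA <- params$beta_A; bB <- params$beta_B; q <- params$q; psi <- params$psi
  N <- S + IA + IB + X
  rec <- make_recorder(record_times, 1L)
  t <- 0
  repeat {
    foi_A <- bA * (IA + q * X) / N
    foi_B <- bB * (IB + q * X) / N
    r <- c(foi_A * S, foi_B * S, psi * foi_B * IA, psi * foi_A * IB)
    total <- sum(r)
    if (total <= 0) break
    t <- t + stats::rexp(1L, total)
    if (t > t_max) break
    rec$note(t, matrix(c(S, IA, IB, X), 1))
    ev <- sample.int(4L, 1L, prob = r)
    if (ev == 1L) { S <- S - 1; IA <- IA + 1 }
    else if (ev == 2L) { S <- S - 1; IB <- IB + 1 }
    else if (ev == 3L) { IA <- IA - 1; X <- X + 1 }
    else { IB <- IB - 1; X <- X + 1 }
  }
  rec$finish(matrix(c(S, IA, IB, X), 1))
}

gillespie_meta <- function(params, P, t_max, record_times) {
  sym <- params$symbiont; dem <- params$demography; mig <- params$migration
  J <- nrow(P)
  if (mig$J != J) stop("state has ", J, " patches but params expect ", mig$J,
                       call. = FALSE)
  rec <- make_recorder(record_times, J)
  t <- 0
  # per patch: 4 infection, 4 birth (by mother class), 4 death, 4 migration
  nch <- 16L
  repeat {
    rates <- numeric(J * nch)
    for (j in seq_len(J)) {
      S <- P[j, 1]; IA <- P[j, 2]; IB <- P[j, 3]; X <- P[j, 4]
      N <- S + IA + IB + X
      foi_A <- if (N > 0) sym$beta_A * (IA + sym$q * X) / N else 0
      foi_B <- if (N > 0) sym$beta_B * (IB + sym$q * X) / N else 0
      base <- (j - 1L) * nch
      rates[base + 1:4] <- c(foi_A * S, foi_B * S,
                             sym$psi * foi_B * IA, sym$psi * foi_A * IB)
      rates[base + 5:8] <- dem$nu_b * c(S, IA, IB, X)
      rates[base + 9:12] <- dem$nu_d * c(S, IA, IB, X)
      rates[base + 13:16] <- mig$m * c(S, IA, IB, X)
    }
    total <- sum(rates)
    if (total <= 0) break
    t <- t + stats::rexp(1L, total)
    if (t > t_max) break
    rec$note(t, P)
    ev <- sample.int(J * nch, 1L, prob = rates)
    j <- (ev - 1L) %/% nch + 1L
    ch <- (ev - 1L) %% nch + 1L
    if (ch <= 4L) {                       # horizontal infection
      if (ch == 1L) { P[j, 1] <- P[j, 1] - 1; P[j, 2] <- P[j, 2] + 1 }
      else if (ch == 2L) { P[j, 1] <- P[j, 1] - 1; P[j, 3] <- P[j, 3] + 1 }
      else if (ch == 3L) { P[j, 2] <- P[j, 2] - 1; P[j, 4] <- P[j, 4] + 1 }
      else { P[j, 3] <- P[j, 3] - 1; P[j, 4] <- P[j, 4] + 1 }
    } else if (ch <= 8L) {                # birth; offspring class by split
      mother <- ch - 4L
      off <- if (mother == 1L) 1L else if (mother == 2L) {
        if (stats::runif(1) < dem$phi) 1L else 2L
      } else if (mother == 3L) {
        if (stats::runif(1) < dem$phi) 1L else 3L
      } else {
        p <- c(dem$phi, (1 - dem$phi) * dem$c_A, (1 - dem$phi) * dem$c_B,
               (1 - dem$phi) * (1 - dem$c_A - dem$c_B))
        sample.int(4L, 1L, prob = p)
      }
      P[j, off] <- P[j, off] + 1
    } else if (ch <= 12L) {               # death
      cl <- ch - 8L
      P[j, cl] <- P[j, cl] - 1
    } else {                              # migration
      cl <- ch - 12L
      dest <- if (J == 1L) j else sample.int(J, 1L, prob = mig$rho[, j])
      if (dest != j) {
        P[j, cl] <- P[j, cl] - 1
        P[dest, cl] <- P[dest, cl] + 1
      }
    }
  }
  rec$finish(P)
}
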