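# deterministic substreams: replicate/chain k gets its own seed derived from
# the root seed, so replicate k is invariant to how many replicates are drawn
substream_seed <- function(seed, k, stride = 99991) {
  M <- 2147483647
  as.integer((as.numeric(seed) %% M + as.numeric(k) * stride) %% M)
}

#' Sampling design for observing a simulated epidemic
#'
#' @param times Sampling times (days), non-negative and increasing.
#' @param n_assayed Number of hosts assayed for infection status at each
#'   sampling time (the binomial index of the observation model).
#' @param n_replicates Number of replicate populations observed.
#' @param seed Integer root seed; each replicate draws from its own
#'   deterministic substream.
#' @return An object of class `observation_schedule`.
#' @export
observation_schedule <- function(times, n_assayed, n_replicates = 1, seed = 1) {
  if (any(times < 0) || is.unsorted(times, strictly = TRUE))
    stop("times must be non-negative and strictly increasing", call. = FALSE)
  if (n_assayed < 1) stop("n_assayed must be >= 1", call. = FALSE)
  if (n_replicates < 1) stop("n_replicates must be >= 1", call. = FALSE)
  structure(list(times = as.numeric(times), n_assayed = as.integer(n_assayed),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "observation_schedule")
}

new_prevalence_series <- function(df, metadata = list()) {
  rownames(df) <- NULL
  structure(df, metadata = metadata,
            class = c("prevalence_series", "data.frame"))
}

#' Validate a prevalence series
#'
#' @param series A `prevalence_series` (or plain data frame with columns
#'   `replicate`, `time`, `class`, `count`, `n_assayed`).
#' @return The series, invisibly; stops with an informative message on the
#'   first violated invariant.
#' @export
validate_prevalence_series <- function(series) {
  needed <- c("replicate", "time", "class", "count", "n_assayed")
  if (!all(needed %in% names(series)))
    stop("missing columns: ", paste(setdiff(needed, names(series)),
                                    collapse = ", "), call. = FALSE)
  if (nrow(series) == 0) return(invisible(series))
  if (any(series$count < 0) || any(series$count > series$n_assayed))
    stop("counts must lie in [0, n_assayed]", call. = FALSE)
  key <- paste(series$replicate, series$time, series$class)
  if (anyDuplicated(key))
    stop("duplicate (replicate, time, class) records", call. = FALSE)
  grp <- paste(series$replicate, series$time)
  sums <- tapply(series$count, grp, sum)
  n_by <- tapply(series$n_assayed, grp, max)
  if (any(sums > n_by))
    stop("class counts at one time exceed n_assayed", call. = FALSE)
  invisible(series)
}

#' @export
print.prevalence_series <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("Prevalence series: %d record(s), %d replicate(s), classes: %s\n",
              nrow(x), length(unique(x$replicate)),
              paste(unique(x$class), collapse = ", ")))
  if (!is.null(md$model)) cat(sprintf("  model: %s", md$model),
                              if (!is.null(md$seed)) sprintf(", seed: %d", md$seed),
                              "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("  ...", nrow(x) - 10, "more rows\n")
  invisible(x)
}

# fraction of each class at the schedule times, linearly interpolated
trajectory_fractions <- function(trajectory, times, patch = 1) {
  span <- range(trajectory$times)
  if (any(times < span[1] - 1e-9) || any(times > span[2] + 1e-9))
    stop("schedule times outside trajectory span", call. = FALSE)
  st <- trajectory$states[, patch, ]
  N <- rowSums(st)
  frac <- sweep(st, 1, ifelse(N > 0, N, 1), "/")
  out <- sapply(class_names, function(cl)
    stats::approx(trajectory$times, frac[, cl], xout = times, rule = 2)$y)
  out <- matrix(out, nrow = length(times), dimnames = list(NULL, class_names))
  if (any(out < -1e-9) || any(out > 1 + 1e-9))
    stop("class fractions outside [0, 1]: upstream integration fault",
         call. = FALSE)
  pmin(pmax(out, 0), 1)
}

#' Observe a trajectory with binomial sampling error
#'
#' Emulates assaying `n_assayed` hosts at each sampling time: the hosts'
#' infection classes are drawn from one multinomial over
#' `{S, I_A, I_B, X}` with probabilities equal to the model's class fractions
#' at that time, so each class count is marginally binomial. For the
#' single-symbiont model a single `infected` class is reported.
#'
#' @param trajectory A `trajectory` from [integrate_model()] or
#'   [gillespie_simulate()].
#' @param schedule An [observation_schedule()].
#' @param patch Patch to observe (for metacommunity trajectories).
#' @return A `prevalence_series` data frame with columns `replicate`, `time`,
#'   `class`, `count`, `n_assayed`.
#' @export
observe <- function(trajectory, schedule, patch = 1) {
  frac <- trajectory_fractions(trajectory, schedule$times, patch)
  si <- trajectory$model == "si"
  recs <- vector("list", schedule$n_replicates)
  for (r in seq_len(schedule$n_replicates)) {
    set.seed(substream_seed(schedule$seed, r))
    if (si) {
      counts <- stats::rbinom(length(schedule$times), schedule$n_assayed,
                              frac[, "I_A"])
      recs[[r]] <- data.frame(replicate = r, time = schedule$times,
                              class = "infected", count = counts,
                              n_assayed = schedule$n_assayed)
    } else {
      draws <- vapply(seq_len(nrow(frac)), function(i)
        as.vector(stats::rmultinom(1, schedule$n_assayed, frac[i, ])),
        numeric(4))
      recs[[r]] <- data.frame(
        replicate = r,
        time = rep(schedule$times, each = 3),
        class = rep(c("I_A", "I_B", "X"), times = length(schedule$times)),
        count = as.vector(draws[2:4, ]),
        n_assayed = schedule$n_assayed)
    }
  }
  out <- do.call(rbind, recs)
  validate_prevalence_series(out)
  new_prevalence_series(out, metadata = list(
    model = trajectory$model, seed = schedule$seed,
    n_assayed = schedule$n_assayed))
}

#' Simulate a single-symbiont release experiment
#'
#' Emulates releasing one infected host into a population of otherwise
#' susceptible hosts and following the infected fraction over time: by
#' default 3 replicate populations of `N = 50` hosts with one initial
#' infective, transmission rate 0.5 per day per host, sampled every 2 days
#' for 20 days, with binomial observation error from a full census
#' (`n_assayed = N`). The epidemic curve is the deterministic SI solution;
#' replicates differ only in observation noise.
#'
#' @param beta True horizontal transmission rate used to simulate (per day).
#' @param seed Integer root seed.
#' @param n_replicates Number of replicate populations.
#' @param N Population size per replicate.
#' @param I0 Initial number infected.
#' @param horizon Experiment duration (days).
#' @param sample_every Sampling interval (days).
#' @param n_assayed Hosts assayed per time point (defaults to full census).
#' @return A `prevalence_series`; its `metadata` attribute records `N`,
#'   `I0`, the generating `beta` and `seed`.
#' @examples
#' series <- simulate_release_experiment(beta = 0.5, seed = 1)
#' head(series)
#' @export
simulate_release_experiment <- function(beta = 0.5, seed = 1, n_replicates = 3,
                                        N = 50, I0 = 1, horizon = 20,
                                        sample_every = 2, n_assayed = N) {
  stopifnot(beta >= 0, N > I0, I0 >= 0)
  times <- seq(0, horizon, by = sample_every)
  tr <- integrate_model("si", list(beta = beta), c(S = N - I0, I = I0), times)
  sched <- observation_schedule(times, n_assayed = n_assayed,
                                n_replicates = n_replicates, seed = seed)
  out <- observe(tr, sched)
  md <- attr(out, "metadata")
  attr(out, "metadata") <- c(md, list(N = N, I0 = I0, beta = beta))
  out
}

#' Default initial conditions of the coinfection experiment
#'
#' Four populations of 100 hosts exposed to variable initial numbers of
#' singly and coinfected hosts; manipulating the starting conditions makes
#' the transient dynamics more variable and all four transmission parameters
#' estimable.
#'
#' @return A `4 x 4` matrix of counts with columns `S`, `I_A`, `I_B`, `X`.
#' @export
coinfection_initial_conditions <- function() {
  m <- rbind(c(90, 0, 0, 10),
             c(90, 5, 5, 0),
             c(88, 10, 0, 2),
             c(88, 0, 10, 2))
  colnames(m) <- class_names
  m
}

#' Simulate a multisymbiont coinfection experiment
#'
#' Four closed populations of 100 hosts start from the initial-condition
#' vectors of [coinfection_initial_conditions()] and evolve under the
#' two-symbiont experiment model ([experiment_rhs()]); all three infected
#' classes are observed with multinomial (marginally binomial) sampling
#' error at each sampling time.
#'
#' @param params True [symbiont_params()] used to simulate.
#' @param seed Integer root seed.
#' @param inits Matrix of initial conditions, one population per row.
#' @param horizon Experiment duration (days).
#' @param sample_every Sampling interval (days).
#' @param n_assayed Hosts assayed per time point (defaults to full census).
#' @return A `prevalence_series` with one replicate per population; its
#'   `metadata` attribute records the initial conditions, generating
#'   parameters and seed.
#' @export
simulate_coinfection_experiment <- function(params = symbiont_params(),
                                            seed = 1,
                                            inits = coinfection_initial_conditions(),
                                            horizon = 20, sample_every = 2,
                                            n_assayed = NULL) {
  times <- seq(0, horizon, by = sample_every)
  recs <- vector("list", nrow(inits))
  for (p in seq_len(nrow(inits))) {
    init <- patch_state(inits[p, 1], inits[p, 2], inits[p, 3], inits[p, 4])
    tr <- integrate_model("two_symbiont", params, init, times)
    na <- if (is.null(n_assayed)) as.integer(sum(inits[p, ])) else n_assayed
    sched <- observation_schedule(times, n_assayed = na, n_replicates = 1,
                                  seed = substream_seed(seed, p, stride = 7919))
    obs <- observe(tr, sched)
    obs$replicate <- p
    recs[[p]] <- as.data.frame(obs)
  }
  out <- do.call(rbind, recs)
  validate_prevalence_series(out)
  new_prevalence_series(out, metadata = list(
    model = "two_symbiont", seed = as.integer(seed), inits = inits,
    params = params))
}
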