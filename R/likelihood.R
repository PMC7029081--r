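model_par_names <- function(model) {
  switch(model,
    si = "beta",
    two_symbiont = c("beta_A", "beta_B", "q", "psi"),
    metacommunity = c("beta_A", "beta_B", "q", "psi", "nu_b", "nu_d", "phi",
                      "c_A", "c_B", "m"),
    stop("unknown model: ", model, call. = FALSE))
}

#' Specify which model variant is fitted and which parameters are free
#'
#' A model specification names the dynamical model, the initial conditions
#' the trajectories start from, and the split of the model's parameters into
#' free (estimated) and fixed. Free and fixed parameters must exactly cover
#' the chosen model's parameter set, which makes it easy to construct
#' restricted model versions (e.g. `q` and `psi` fixed at 1) for formal
#' model comparison.
#'
#' @param model `"si"`, `"two_symbiont"`, or `"metacommunity"`.
#' @param init Initial class counts: for `"si"` a named vector
#'   `c(S = , I = )`; otherwise a vector `(S, I_A, I_B, X)` shared by all
#'   replicates, or a matrix with one row per replicate.
#' @param free Character vector of parameter names to estimate; defaults to
#'   all parameters of the model.
#' @param fixed Named list of values for the remaining parameters.
#' @return An object of class `model_spec`.
#' @examples
#' model_spec("si", init = c(S = 49, I = 1))
#' model_spec("two_symbiont", init = coinfection_initial_conditions(),
#'            free = c("beta_A", "beta_B"), fixed = list(q = 1, psi = 1))
#' @export
model_spec <- function(model = c("si", "two_symbiont", "metacommunity"),
                       init, free = NULL, fixed = list()) {
  model <- match.arg(model)
  all_pars <- model_par_names(model)
  if (is.null(free)) free <- setdiff(all_pars, names(fixed))
  covered <- sort(c(free, names(fixed)))
  if (!identical(covered, sort(all_pars)))
    stop("free + fixed must exactly cover {", paste(all_pars, collapse = ", "),
         "}", call. = FALSE)
  if (model == "si") {
    if (is.null(names(init)) || !all(c("S", "I") %in% names(init)))
      stop("si init must be a named vector c(S = , I = )", call. = FALSE)
    init <- matrix(c(init[["S"]], init[["I"]], 0, 0), nrow = 1,
                   dimnames = list(NULL, class_names))
  } else {
    if (is.null(dim(init))) init <- matrix(init, nrow = 1)
    init <- as.matrix(init)
    colnames(init) <- class_names
  }
  structure(list(model = model, init = init, free = free, fixed = fixed),
            class = "model_spec")
}

#' Derive a model specification from a synthetic series' metadata
#'
#' @param series A `prevalence_series` produced by
#'   [simulate_release_experiment()] or [simulate_coinfection_experiment()].
#' @inheritParams model_spec
#' @return A [model_spec()].
#' @export
model_spec_from_series <- function(series, free = NULL, fixed = list()) {
  md <- attr(series, "metadata")
  if (is.null(md$model)) stop("series carries no model metadata; build a ",
                              "model_spec() explicitly", call. = FALSE)
  if (md$model == "si") {
    model_spec("si", init = c(S = md$N - md$I0, I = md$I0), free = free,
               fixed = fixed)
  } else {
    model_spec(md$model, init = md$inits, free = free, fixed = fixed)
  }
}

# full named parameter vector from free values + spec$fixed
complete_params <- function(spec, free_values) {
  full <- c(as.list(free_values), spec$fixed)
  unlist(full)[model_par_names(spec$model)]
}

# predicted class fractions at `times` for replicate r (row of spec$init)
predicted_fractions <- function(spec, params, times, replicate_row = 1) {
  init <- spec$init[min(replicate_row, nrow(spec$init)), ]
  N <- sum(init)
  if (spec$model == "si") {
    I <- si_closed_form(times, params[["beta"]], N, init[["I_A"]])
    cbind(S = 1 - I / N, I_A = I / N, I_B = 0, X = 0)
  } else if (spec$model == "two_symbiont") {
    sp <- symbiont_params(params[["beta_A"]], params[["beta_B"]],
                          params[["q"]], params[["psi"]])
    tt <- if (times[1] > 0) c(0, times) else times
    tr <- integrate_model("two_symbiont", sp, init, tt,
                          rtol = 1e-8, atol = 1e-10)
    frac <- tr$states[match(times, tt), 1, , drop = FALSE][, 1, ]
    frac <- matrix(frac, ncol = 4, dimnames = list(NULL, class_names))
    sweep(frac, 1, pmax(rowSums(frac), .Machine$double.eps), "/")
  } else {
    stop("metacommunity likelihood requires a full model_params object; ",
         "fit the reduced models to experimental series", call. = FALSE)
  }
}

# vectorised two-symbiont RHS over R stacked populations; y is length 4R
stacked_experiment_deriv <- function(y, R, bA, bB, q, psi) {
  m <- matrix(y, nrow = R)
  S <- m[, 1]; IA <- m[, 2]; IB <- m[, 3]; X <- m[, 4]
  N <- S + IA + IB + X
  N <- ifelse(N > 0, N, 1)
  foi_A <- bA * (IA + q * X) / N
  foi_B <- bB * (IB + q * X) / N
  inf_A <- foi_A * S; inf_B <- foi_B * S
  sec_A <- psi * foi_B * IA; sec_B <- psi * foi_A * IB
  c(-inf_A - inf_B, inf_A - sec_A, inf_B - sec_B, sec_A + sec_B)
}

# precompile the series into a fast likelihood closure: one call per proposed
# parameter vector, one stacked ODE solve per call for the ODE-based models
make_loglik <- function(series, spec) {
  ord <- order(series$replicate, series$time)
  df <- as.data.frame(series)[ord, , drop = FALSE]
  reps <- unique(df$replicate)
  R <- length(reps)
  if (spec$model == "si") {
    N <- sum(spec$init[1, ])
    I0 <- spec$init[1, "I_A"]
    count <- df$count; n <- df$n_assayed; tm <- df$time
    function(params) {
      p <- si_closed_form(tm, params[["beta"]], N, I0) / N
      pw <- stats::dbinom(count, n, pmin(pmax(p, 0), 1), log = TRUE)
      list(total = sum(pw), pointwise = pw, flagged = any(!is.finite(pw)))
    }
  } else if (spec$model == "two_symbiont") {
    times <- sort(unique(df$time))
    tt <- if (times[1] > 0) c(0, times) else times
    t_idx <- match(times, tt)
    init <- spec$init
    if (nrow(init) == 1 && R > 1)
      init <- init[rep(1, R), , drop = FALSE]
    Ntot <- rowSums(init)
    # one multinomial observation per (replicate, time)
    grp_rep <- integer(0); grp_tidx <- integer(0)
    K <- NULL; n_vec <- integer(0)
    for (ri in seq_len(R)) {
      sub <- df[df$replicate == reps[ri], , drop = FALSE]
      for (ti in sort(unique(sub$time))) {
        at <- sub[sub$time == ti, , drop = FALSE]
        k <- c(I_A = 0, I_B = 0, X = 0)
        k[at$class] <- at$count
        nn <- at$n_assayed[1]
        K <- rbind(K, c(nn - sum(k), k))
        n_vec <- c(n_vec, nn)
        grp_rep <- c(grp_rep, ri)
        grp_tidx <- c(grp_tidx, match(ti, times))
      }
    }
    lconst <- lgamma(n_vec + 1) - rowSums(lgamma(K + 1))
    y0 <- as.vector(init)
    function(params) {
      bA <- params[["beta_A"]]; bB <- params[["beta_B"]]
      q <- params[["q"]]; psi <- params[["psi"]]
      sol <- tryCatch(
        deSolve::lsoda(y = y0, times = tt,
                       func = function(t, y, p)
                         list(stacked_experiment_deriv(y, R, bA, bB, q, psi)),
                       parms = NULL, rtol = 1e-6, atol = 1e-10),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(sol) || nrow(sol) < length(tt) || anyNA(sol)) {
        warning("ODE solve failed at proposed parameters; likelihood -Inf")
        pw <- rep(-Inf, length(n_vec))
        return(list(total = -Inf, pointwise = pw, flagged = TRUE))
      }
      # class probabilities are smoothed as (p + eps)/(1 + 4 eps): the
      # experiment model's classes are strictly positive whenever reachable,
      # so near-zero predictions are dominated by solver truncation noise
      # (order atol); a hard zero or hard floor turns that noise into huge
      # discontinuous log-likelihood jumps that trap a random-walk sampler,
      # while eps = 1e-8 >> atol keeps the surface smooth and biases
      # realistic probabilities negligibly
      eps <- 1e-8
      Y <- pmax(sol[, -1, drop = FALSE], 0)
      pw <- numeric(length(n_vec))
      flagged <- FALSE
      for (g in seq_along(n_vec)) {
        y <- Y[t_idx[grp_tidx[g]], grp_rep[g] + (0:3) * R]
        p_raw <- y / max(sum(y), .Machine$double.eps)
        p <- (p_raw + eps) / (1 + 4 * eps)
        k <- K[g, ]
        term <- ifelse(k > 0, k * log(p), 0)
        pw[g] <- lconst[g] + sum(term)
        if (any(p_raw <= 0 & k > 0)) flagged <- TRUE
      }
      list(total = sum(pw), pointwise = pw, flagged = flagged)
    }
  } else {
    stop("metacommunity likelihood requires a full model_params object; ",
         "fit the reduced models to experimental series", call. = FALSE)
  }
}

#' Binomial / multinomial log-likelihood of a prevalence series
#'
#' For the single-symbiont model each observation contributes the binomial
#' log-probability of the observed infected count given `n_assayed` hosts and
#' the model's predicted infected fraction at that time. For the
#' two-symbiont model the class counts at one `(replicate, time)` form one
#' multinomial observation over `{S, I_A, I_B, X}`. Model predictions come
#' from the exact logistic solution (single symbiont) or a fresh ODE solve
#' (two symbionts) at the proposed parameters. A predicted fraction of zero
#' with a positive observed count yields `-Inf`, flagged rather than thrown;
#' an ODE failure likewise yields `-Inf` with a warning.
#'
#' @param series A `prevalence_series`.
#' @param spec A [model_spec()].
#' @param params Named numeric vector of the free parameters (fixed ones are
#'   taken from `spec`), or of the full parameter set.
#' @return A list with `total` (scalar log-likelihood), `pointwise` (one
#'   entry per `(replicate, time)` observation, ordered by replicate then
#'   time) and `flagged` (`TRUE` when an impossible datum or solver failure
#'   forced `-Inf`).
#' @examples
#' s <- simulate_release_experiment(seed = 1)
#' log_likelihood(s, model_spec_from_series(s), c(beta = 0.5))$total
#' @export
log_likelihood <- function(series, spec, params) {
  validate_prevalence_series(series)
  full <- complete_params(spec, params)
  make_loglik(series, spec)(full)
}
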