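#' MCMC sampler settings
#'
#' Defaults mirror a standard design for this class of problem: 3 chains of
#' 5,000 iterations with a 2,000-iteration warm-up and thinning by 3, giving
#' 3,000 retained draws. The sampler is an adaptive random-walk Metropolis on
#' log-transformed parameters; during warm-up the proposal scale targets the
#' dimension-appropriate acceptance rate and the proposal covariance is
#' estimated from the chain history, then both are frozen.
#'
#' @param n_chains Number of chains (`>= 1`; at least 2 for R-hat).
#' @param n_iter Total iterations per chain, `> n_warmup`.
#' @param n_warmup Warm-up (adaptation) iterations, discarded.
#' @param thin Post-warm-up thinning interval (`>= 1`).
#' @param seed Integer root seed; each chain runs on its own substream.
#' @param target_accept Acceptance rate targeted during adaptation; defaults
#'   to 0.44 for one free parameter and 0.234 otherwise.
#' @return An object of class `mcmc_control`.
#' @export
mcmc_control <- function(n_chains = 3, n_iter = 5000, n_warmup = 2000,
                         thin = 3, seed = 1, target_accept = NULL) {
  stopifnot(n_chains >= 1, n_warmup >= 0, n_iter > n_warmup, thin >= 1)
  structure(list(n_chains = as.integer(n_chains), n_iter = as.integer(n_iter),
                 n_warmup = as.integer(n_warmup), thin = as.integer(thin),
                 seed = as.integer(seed), target_accept = target_accept),
            class = "mcmc_control")
}

series_fingerprint <- function(series) {
  df <- as.data.frame(series)
  df <- df[order(df$replicate, df$time, df$class), ]
  sprintf("n%d_r%d_c%d_s%.8g", nrow(df), length(unique(df$replicate)),
          sum(df$count), sum(df$count * (df$time + 1)))
}

#' Fit a transmission model to prevalence data by MCMC
#'
#' The workhorse of the package: samples the posterior of the free
#' transmission parameters given observed prevalence counts, combining the
#' binomial/multinomial likelihood ([log_likelihood()]) with independent
#' priors ([prior_spec()]; vague half-Normal(0, 5) by default). Sampling
#' uses adaptive random-walk Metropolis on the log scale (with the Jacobian
#' of the transformation included), chains initialised from prior draws
#' (re-drawn up to 50 times if the likelihood is non-finite). Pointwise
#' log-likelihoods are retained for every kept draw so fitted models can be
#' compared with [compare_models()].
#'
#' @param series A `prevalence_series` (observed or synthetic).
#' @param spec A [model_spec()]; defaults to [model_spec_from_series()].
#' @param prior A [prior_spec()] covering the free parameters; default
#'   half-Normal(0, 5) on each.
#' @param control An [mcmc_control()].
#' @return An object of class `transmission_fit` with components `draws`
#'   (array `iterations x chains x parameters`, natural scale), `log_lik`
#'   (matrix `draws x observations` of pointwise log-likelihoods),
#'   `spec`, `prior`, `control`, `accept_rate`, and `data_fingerprint`.
#'   Use `summary()`, `coef()`, [fit_diagnostics()], `predict()` and
#'   [compare_models()] on it.
#' @examples
#' \donttest{
#' s <- simulate_release_experiment(beta = 0.5, seed = 1)
#' fit <- fit_transmission(s, control = mcmc_control(n_iter = 1500,
#'                                                   n_warmup = 500))
#' summary(fit)
#' }
#' @export
fit_transmission <- function(series, spec = NULL, prior = NULL,
                             control = mcmc_control()) {
  validate_prevalence_series(series)
  if (nrow(series) == 0) stop("series has no observations", call. = FALSE)
  if (is.null(spec)) spec <- model_spec_from_series(series)
  if (is.null(prior)) prior <- default_prior(spec$free)
  free <- spec$free
  d <- length(free)
  target <- if (is.null(control$target_accept)) {
    if (d == 1) 0.44 else 0.234
  } else control$target_accept

  loglik_fun <- make_loglik(series, spec)
  log_post <- function(eta) {
    theta <- stats::setNames(exp(eta), free)
    lp <- log_prior(theta, prior[free])
    if (!is.finite(lp)) return(list(lp = -Inf, pointwise = NULL))
    ll <- loglik_fun(complete_params(spec, theta))
    list(lp = lp + ll$total + sum(eta), pointwise = ll$pointwise)
  }

  n_keep <- (control$n_iter - control$n_warmup) %/% control$thin
  chains <- vector("list", control$n_chains)
  accept <- numeric(control$n_chains)
  for (ch in seq_len(control$n_chains)) {
    set.seed(substream_seed(control$seed, ch, stride = 104729))
    # initialise from the prior; retry while the posterior is non-finite
    cur <- NULL
    for (try in 1:50) {
      theta0 <- vapply(prior[free], draw_one, numeric(1))
      theta0[theta0 <= 0] <- 1e-3
      eta <- log(theta0)
      cand <- log_post(eta)
      if (is.finite(cand$lp)) { cur <- cand; break }
    }
    if (is.null(cur))
      stop("could not initialise chain ", ch,
           ": likelihood non-finite at 50 prior draws", call. = FALSE)
    if (d > 1) {
      # short mode search from the prior draw: a vague prior regularly lands
      # chains on flat, saturated regions that warm-up cannot escape
      opt <- tryCatch(stats::optim(eta, function(e) {
        v <- log_post(e)$lp
        if (is.finite(v)) -v else 1e10
      }, method = "Nelder-Mead", control = list(maxit = 300)),
      error = function(e) NULL)
      if (!is.null(opt) && opt$value < 1e9) {
        eta_try <- opt$par + stats::rnorm(d, 0, 0.2)
        cand <- log_post(eta_try)
        if (is.finite(cand$lp)) { eta <- eta_try; cur <- cand }
      }
    }
    log_scale <- log(0.5)
    chol_prop <- diag(d)
    warm_hist <- matrix(NA_real_, control$n_warmup, d)
    draws <- matrix(NA_real_, n_keep, d)
    ll_mat <- NULL
    kept <- 0L
    n_acc <- 0L
    iso_phase <- max(150L, control$n_warmup %/% 4L)
    for (it in seq_len(control$n_iter)) {
      step <- exp(log_scale) * as.vector(chol_prop %*% stats::rnorm(d))
      eta_new <- eta + step
      cand <- log_post(eta_new)
      acc_p <- if (is.finite(cand$lp)) min(1, exp(cand$lp - cur$lp)) else 0
      if (stats::runif(1) < acc_p) {
        eta <- eta_new; cur <- cand
        if (it > control$n_warmup) n_acc <- n_acc + 1L
      }
      if (it <= control$n_warmup) {
        warm_hist[it, ] <- eta
        # Robbins-Monro on the overall scale throughout warm-up; gain decays
        # slowly enough to re-tune after each covariance refresh
        log_scale <- log_scale + (acc_p - target) / max(10, it)^0.6
        if (d > 1 && it > iso_phase && it %% 50 == 0) {
          # covariance from the second half of warm-up history only, so the
          # initial transient from a dispersed prior draw does not inflate it
          win <- warm_hist[(it %/% 2):it, , drop = FALSE]
          cov_est <- stats::cov(win)
          cov_est <- 0.9 * cov_est + 0.1 * diag(diag(cov_est) + 1e-6, d)
          chol_prop <- t(chol(cov_est / max(mean(diag(cov_est)), 1e-12)))
        }
      } else if ((it - control$n_warmup) %% control$thin == 0) {
        kept <- kept + 1L
        draws[kept, ] <- exp(eta)
        if (is.null(ll_mat))
          ll_mat <- matrix(NA_real_, n_keep, length(cur$pointwise))
        ll_mat[kept, ] <- cur$pointwise
      }
    }
    chains[[ch]] <- list(draws = draws[seq_len(kept), , drop = FALSE],
                         log_lik = ll_mat[seq_len(kept), , drop = FALSE])
    accept[ch] <- n_acc / (control$n_iter - control$n_warmup)
    if (accept[ch] < 0.02)
      warning("chain ", ch, " accepted ", sprintf("%.1f%%", 100 * accept[ch]),
              " of post-warm-up proposals; inspect fit_diagnostics() and ",
              "consider a longer warm-up")
  }

  n_kept <- nrow(chains[[1]]$draws)
  arr <- array(NA_real_, dim = c(n_kept, control$n_chains, d),
               dimnames = list(NULL, NULL, free))
  for (ch in seq_len(control$n_chains)) arr[, ch, ] <- chains[[ch]]$draws
  log_lik <- do.call(rbind, lapply(chains, `[[`, "log_lik"))

  fit <- structure(list(
    draws = arr, log_lik = log_lik, spec = spec, prior = prior,
    control = control, accept_rate = accept,
    data_fingerprint = series_fingerprint(series),
    series = series), class = "transmission_fit")
  fit
}

# pooled draws matrix (chains stacked), natural scale
pooled_draws <- function(fit) {
  d <- dim(fit$draws)[3]
  out <- do.call(rbind, lapply(seq_len(dim(fit$draws)[2]), function(ch)
    matrix(fit$draws[, ch, ], ncol = d)))
  colnames(out) <- dimnames(fit$draws)[[3]]
  out
}
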