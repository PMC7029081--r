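#' Posterior summary of a fitted model
#'
#' Empirical quantiles over the pooled, post-warm-up, thinned chains. The
#' defaults give the posterior median and the central 95% credible interval.
#' Quantiles use linear interpolation of order statistics
#' ([stats::quantile()] type 7).
#'
#' @param fit A `transmission_fit`.
#' @param probs Quantile levels; default `c(0.025, 0.5, 0.975)`.
#' @return A data frame with one row per free parameter: the posterior mean
#'   and the requested quantiles.
#' @export
posterior_summary <- function(fit, probs = c(0.025, 0.5, 0.975)) {
  dm <- pooled_draws(fit)
  qs <- t(apply(dm, 2, stats::quantile, probs = probs, names = FALSE))
  out <- data.frame(parameter = colnames(dm), mean = colMeans(dm), qs,
                    row.names = NULL, stringsAsFactors = FALSE)
  names(out)[-(1:2)] <- paste0("q", formatC(100 * probs, format = "g"))
  out
}

#' @export
print.transmission_fit <- function(x, ...) {
  cat(sprintf("Bayesian %s transmission model fit\n", x$spec$model))
  cat(sprintf("  %d chain(s) x %d retained draws (thin %d), mean acceptance %.2f\n",
              dim(x$draws)[2], dim(x$draws)[1], x$control$thin,
              mean(x$accept_rate)))
  print(posterior_summary(x), digits = 4)
  invisible(x)
}

#' @export
summary.transmission_fit <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  s <- posterior_summary(object, probs)
  diag <- fit_diagnostics(object)
  out <- merge(s, diag, by = "parameter", sort = FALSE)
  class(out) <- c("summary.transmission_fit", "data.frame")
  out
}

#' @export
print.summary.transmission_fit <- function(x, ...) {
  cat("Posterior summary (pooled chains) with convergence diagnostics\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.transmission_fit <- function(object, ...) {
  dm <- pooled_draws(object)
  apply(dm, 2, stats::median)
}

#' Posterior predictive trajectory bands
#'
#' For each retained posterior draw (optionally a random subsample, for the
#' ODE-based models) the model trajectory is solved and the infected-class
#' fractions recorded; pointwise quantiles over draws give the median
#' prediction and credible band.
#'
#' @param object A `transmission_fit`.
#' @param times Prediction times (days); defaults to the observation times.
#' @param probs Pointwise quantile levels.
#' @param max_draws Upper bound on the number of draws used (subsampled
#'   deterministically); `Inf` uses all retained draws.
#' @param replicate Which replicate's initial conditions to predict from.
#' @param ... Unused.
#' @return A data frame with columns `time`, `class`, and one column per
#'   quantile level; a `skipped` attribute counts draws whose ODE solve
#'   failed.
#' @export
predict.transmission_fit <- function(object, times = NULL,
                                     probs = c(0.025, 0.5, 0.975),
                                     max_draws = 500, replicate = 1, ...) {
  if (is.null(times)) times <- sort(unique(object$series$time))
  dm <- pooled_draws(object)
  if (nrow(dm) > max_draws) {
    idx <- round(seq(1, nrow(dm), length.out = max_draws))
    dm <- dm[idx, , drop = FALSE]
  }
  cls <- if (object$spec$model == "si") "I_A" else c("I_A", "I_B", "X")
  acc <- array(NA_real_, dim = c(nrow(dm), length(times), length(cls)))
  skipped <- 0L
  for (s in seq_len(nrow(dm))) {
    full <- complete_params(object$spec, dm[s, ])
    frac <- tryCatch(
      predicted_fractions(object$spec, full, times, replicate),
      error = function(e) NULL)
    if (is.null(frac)) { skipped <- skipped + 1L; next }
    acc[s, , ] <- frac[, cls]
  }
  out <- do.call(rbind, lapply(seq_along(cls), function(ci) {
    qs <- apply(acc[, , ci, drop = FALSE], 2, stats::quantile, probs = probs,
                na.rm = TRUE, names = FALSE)
    qs <- matrix(qs, nrow = length(probs))
    df <- data.frame(time = times,
                     class = if (object$spec$model == "si") "infected"
                             else cls[ci])
    for (pi in seq_along(probs))
      df[[paste0("q", formatC(100 * probs[pi], format = "g"))]] <- qs[pi, ]
    df
  }))
  attr(out, "skipped") <- skipped
  out
}

#' @export
residuals.transmission_fit <- function(object, ...) {
  df <- as.data.frame(object$series)
  med <- coef(object)
  full <- complete_params(object$spec, med)
  reps <- unique(df$replicate)
  res <- numeric(nrow(df))
  for (ri in seq_along(reps)) {
    sel <- df$replicate == reps[ri]
    sub <- df[sel, , drop = FALSE]
    times <- sort(unique(sub$time))
    frac <- predicted_fractions(object$spec, full, times, ri)
    cl <- ifelse(sub$class == "infected", "I_A", sub$class)
    pred <- frac[cbind(match(sub$time, times), match(cl, class_names))]
    res[sel] <- sub$count / sub$n_assayed - pred
  }
  res
}

#' Posterior predictive simulation from a fitted model
#'
#' Each simulation draws one parameter vector from the pooled posterior and
#' regenerates a synthetic prevalence series under the fitted model and the
#' original design (initial conditions, sampling times, assay sizes).
#'
#' @param object A `transmission_fit`.
#' @param nsim Number of replicate datasets.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `prevalence_series` of length `nsim`.
#' @export
simulate.transmission_fit <- function(object, nsim = 1, seed = 1, ...) {
  dm <- pooled_draws(object)
  set.seed(substream_seed(seed, 0))
  idx <- sample.int(nrow(dm), nsim, replace = TRUE)
  times <- sort(unique(object$series$time))
  n_assayed <- max(object$series$n_assayed)
  lapply(seq_len(nsim), function(s) {
    full <- complete_params(object$spec, dm[idx[s], ])
    if (object$spec$model == "si") {
      init <- object$spec$init[1, ]
      simulate_release_experiment(
        beta = full[["beta"]], seed = substream_seed(seed, s),
        n_replicates = length(unique(object$series$replicate)),
        N = sum(init), I0 = init[["I_A"]],
        horizon = max(times), sample_every = diff(times)[1],
        n_assayed = n_assayed)
    } else {
      simulate_coinfection_experiment(
        params = symbiont_params(full[["beta_A"]], full[["beta_B"]],
                                 full[["q"]], full[["psi"]]),
        seed = substream_seed(seed, s), inits = object$spec$init,
        horizon = max(times), sample_every = diff(times)[1],
        n_assayed = n_assayed)
    }
  })
}

#' @export
plot.transmission_fit <- function(x, replicate = 1, ...) {
  df <- as.data.frame(x$series)
  times <- seq(min(df$time), max(df$time), length.out = 101)
  band <- predict(x, times = times, replicate = replicate)
  cls <- unique(band$class)
  cols <- grDevices::hcl.colors(max(3, length(cls)), "Dark 3")
  graphics::plot(NULL, xlim = range(times), ylim = c(0, 1),
                 xlab = "time (days)", ylab = "fraction of hosts", ...)
  for (ci in seq_along(cls)) {
    b <- band[band$class == cls[ci], ]
    graphics::polygon(c(b$time, rev(b$time)), c(b[[3]], rev(b[[5]])),
                      col = grDevices::adjustcolor(cols[ci], 0.25),
                      border = NA)
    graphics::lines(b$time, b[[4]], col = cols[ci], lwd = 2)
    obs_cl <- if (cls[ci] == "infected") "infected" else cls[ci]
    o <- df[df$class == obs_cl & df$replicate ==
              unique(df$replicate)[replicate], ]
    graphics::points(o$time, o$count / o$n_assayed, col = cols[ci], pch = 19)
  }
  graphics::legend("topleft", legend = cls, col = cols[seq_along(cls)],
                   lwd = 2, bty = "n")
  invisible(x)
}

#' Serialise a fit to disk
#'
#' Writes the pooled posterior draws to `<stem>_draws.csv` (one column per
#' parameter plus the chain index) and diagnostics, specification and seeds
#' to `<stem>_meta.json`.
#'
#' @param fit A `transmission_fit`.
#' @param stem Output path stem (no extension).
#' @return The two paths, invisibly.
#' @export
write_fit <- function(fit, stem) {
  dm <- pooled_draws(fit)
  n_kept <- dim(fit$draws)[1]
  df <- data.frame(chain = rep(seq_len(dim(fit$draws)[2]), each = n_kept), dm)
  draws_path <- paste0(stem, "_draws.csv")
  utils::write.csv(df, draws_path, row.names = FALSE, quote = FALSE)
  meta <- list(
    model = fit$spec$model, free = fit$spec$free, fixed = fit$spec$fixed,
    init = apply(fit$spec$init, 1, as.list, simplify = FALSE),
    control = unclass(fit$control), accept_rate = fit$accept_rate,
    diagnostics = fit_diagnostics(fit),
    summary = posterior_summary(fit),
    data_fingerprint = fit$data_fingerprint)
  meta_path <- paste0(stem, "_meta.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(c(draws_path, meta_path))
}
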