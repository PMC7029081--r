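# split-chain potential scale reduction (Gelman et al.), draws: iter x chain
split_rhat_matrix <- function(x) {
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  half <- n %/% 2
  halves <- cbind(x[seq_len(half), , drop = FALSE],
                  x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(halves)
  nn <- nrow(halves)
  means <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- nn * stats::var(means)
  if (W == 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

# effective sample size via Geyer's initial monotone positive sequence,
# chains combined as in BDA3
ess_matrix <- function(x) {
  n <- nrow(x); m <- ncol(x)
  if (n < 4) return(NA_real_)
  vars <- apply(x, 2, stats::var)
  W <- mean(vars)
  means <- colMeans(x)
  B_over_n <- if (m > 1) stats::var(means) else 0
  var_plus <- (n - 1) / n * W + B_over_n
  if (var_plus == 0) return(NA_real_)
  max_lag <- min(n - 2, 1000)
  # average autocovariance across chains
  acov <- matrix(0, max_lag + 1, m)
  for (ch in seq_len(m)) {
    a <- stats::acf(x[, ch], lag.max = max_lag, plot = FALSE,
                    type = "covariance", demean = TRUE)$acf[, 1, 1]
    acov[, ch] <- a
  }
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  rho[1] <- 1
  # Geyer: sum consecutive pairs while positive, enforce monotone decrease
  tau <- 1
  prev_pair <- Inf
  t <- 1
  while (t + 1 <= length(rho)) {
    pair <- rho[t + 1] + if (t + 2 <= length(rho)) rho[t + 2] else 0
    if (pair < 0) break
    pair <- min(pair, prev_pair)
    tau <- tau + 2 * pair
    prev_pair <- pair
    t <- t + 2
  }
  min(n * m / tau, n * m)
}

#' Convergence diagnostics for a fitted model
#'
#' Split-chain potential scale reduction (split R-hat) and effective sample
#' size per free parameter. Values of R-hat below about 1.05 and effective
#' sample sizes of a few hundred indicate the chains have mixed well enough
#' for the posterior summaries to be trusted. With a single chain R-hat is
#' undefined and reported as `NA` (the chain is still split in half for the
#' computation, but between-chain information is absent).
#'
#' @param fit A `transmission_fit`.
#' @return A data frame with columns `parameter`, `rhat`, `ess`.
#' @export
fit_diagnostics <- function(fit) {
  pars <- dimnames(fit$draws)[[3]]
  n_chain <- dim(fit$draws)[2]
  out <- data.frame(parameter = pars, rhat = NA_real_, ess = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(pars)) {
    x <- matrix(fit$draws[, , i], ncol = n_chain)
    out$rhat[i] <- if (n_chain >= 2) split_rhat_matrix(x) else NA_real_
    out$ess[i] <- ess_matrix(x)
  }
  out
}
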