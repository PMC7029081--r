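# WAIC from a pointwise log-likelihood matrix (draws x observations):
# elpd = sum_i [ log mean_s exp(ll_si) ] - sum_i var_s(ll_si)
waic_from_loglik <- function(ll) {
  lppd_i <- apply(ll, 2, function(col) {
    m <- max(col)
    m + log(mean(exp(col - m)))
  })
  p_i <- apply(ll, 2, stats::var)
  elpd_i <- lppd_i - p_i
  n <- length(elpd_i)
  list(elpd = sum(elpd_i), p_waic = sum(p_i),
       se = sqrt(n * stats::var(elpd_i)), pointwise = elpd_i)
}

#' Compare fitted models by expected log predictive density (WAIC)
#'
#' Formal model comparison across model variants fitted to the same data:
#' each fit's pointwise log-likelihood matrix yields a WAIC estimate of the
#' expected log pointwise predictive density (elpd), its standard error, and
#' pairwise elpd differences with standard errors computed from the
#' pointwise difference (which is the appropriate SE because the pointwise
#' contributions are paired across models). Larger elpd is better; a
#' difference smaller than a couple of its SEs is not decisive.
#'
#' @param ... Two or more `transmission_fit` objects fitted to the same
#'   series (checked via data fingerprints), optionally named.
#' @return An object of class `model_comparison`: a list with `table` (elpd,
#'   p_waic, se per model, ordered best first) and `differences` (pairwise
#'   elpd differences with SEs).
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "transmission_fit")) fits <- fits[[1]]
  if (length(fits) < 2) stop("need at least 2 fitted models to compare",
                             call. = FALSE)
  if (!all(vapply(fits, inherits, logical(1), "transmission_fit")))
    stop("all arguments must be transmission_fit objects", call. = FALSE)
  nms <- names(fits)
  if (is.null(nms) || any(nms == ""))
    nms <- vapply(seq_along(fits), function(i) {
      nm <- if (!is.null(nms) && nzchar(nms[i])) nms[i] else
        paste0(fits[[i]]$spec$model, "_", i)
      nm
    }, character(1))
  fps <- vapply(fits, `[[`, character(1), "data_fingerprint")
  if (length(unique(fps)) != 1)
    stop("fits were not computed on identical data (fingerprint mismatch)",
         call. = FALSE)
  w <- lapply(fits, function(f) waic_from_loglik(f$log_lik))
  tab <- data.frame(model = nms,
                    elpd = vapply(w, `[[`, numeric(1), "elpd"),
                    p_waic = vapply(w, `[[`, numeric(1), "p_waic"),
                    se = vapply(w, `[[`, numeric(1), "se"),
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$elpd), ]
  pairs <- utils::combn(seq_along(fits), 2)
  diffs <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    di <- w[[i]]$pointwise - w[[j]]$pointwise
    data.frame(model_a = nms[i], model_b = nms[j],
               elpd_diff = sum(di),
               se_diff = sqrt(length(di) * stats::var(di)),
               stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, differences = diffs), class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison by WAIC expected log predictive density\n")
  print.data.frame(x$table, digits = 4, row.names = FALSE)
  cat("\nPairwise differences (elpd_a - elpd_b):\n")
  print.data.frame(x$differences, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write a model-comparison table to CSV
#'
#' @param comparison A `model_comparison`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_comparison_csv <- function(comparison, path) {
  utils::write.csv(comparison$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
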