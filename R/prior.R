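#' Prior distributions for transmission parameters
#'
#' Constructors for the per-parameter prior families accepted by
#' [prior_spec()]. The default prior on rates and on the dimensionless
#' modifiers `q` and `psi` is a vague half-Normal with scale 5, i.e. a
#' Normal(0, 5) truncated to the non-negative half line, since negative
#' rates are meaningless.
#'
#' @param scale,mean,sd,min,max,rate Family hyperparameters.
#' @return A prior-family object.
#' @examples
#' prior_spec(beta = half_normal(5))
#' @export
half_normal <- function(scale = 5) {
  stopifnot(scale > 0)
  structure(list(family = "half_normal", scale = scale), class = "prior_family")
}

#' @rdname half_normal
#' @export
normal_prior <- function(mean = 0, sd = 1) {
  stopifnot(sd > 0)
  structure(list(family = "normal", mean = mean, sd = sd),
            class = "prior_family")
}

#' @rdname half_normal
#' @export
uniform_prior <- function(min = 0, max = 1) {
  stopifnot(max > min)
  structure(list(family = "uniform", min = min, max = max),
            class = "prior_family")
}

#' @rdname half_normal
#' @export
exponential_prior <- function(rate = 1) {
  stopifnot(rate > 0)
  structure(list(family = "exponential", rate = rate), class = "prior_family")
}

#' Assemble a named prior specification
#'
#' @param ... Named prior-family objects, one per model parameter (e.g.
#'   `beta_A = half_normal(5)`).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(...) {
  pr <- list(...)
  if (length(pr) && (is.null(names(pr)) || any(names(pr) == "")))
    stop("all priors must be named after a model parameter", call. = FALSE)
  ok <- vapply(pr, inherits, logical(1), "prior_family")
  if (!all(ok)) stop("priors must be built with the prior-family constructors",
                     call. = FALSE)
  structure(pr, class = "prior_spec")
}

default_prior <- function(par_names) {
  pr <- stats::setNames(lapply(par_names, function(p) half_normal(5)), par_names)
  structure(pr, class = "prior_spec")
}

log_density_one <- function(value, fam) {
  switch(fam$family,
    half_normal = if (value < 0) -Inf else
      stats::dnorm(value, 0, fam$scale, log = TRUE) + log(2),
    normal = stats::dnorm(value, fam$mean, fam$sd, log = TRUE),
    uniform = stats::dunif(value, fam$min, fam$max, log = TRUE),
    exponential = if (value < 0) -Inf else
      stats::dexp(value, fam$rate, log = TRUE),
    stop("unknown prior family: ", fam$family, call. = FALSE))
}

draw_one <- function(fam) {
  switch(fam$family,
    half_normal = abs(stats::rnorm(1, 0, fam$scale)),
    normal = stats::rnorm(1, fam$mean, fam$sd),
    uniform = stats::runif(1, fam$min, fam$max),
    exponential = stats::rexp(1, fam$rate))
}

#' Joint log prior density
#'
#' Parameters are a priori independent, so the joint log density is the sum
#' of the per-parameter log densities; values outside a parameter's support
#' give `-Inf`.
#'
#' @param params Named numeric vector of parameter values.
#' @param prior A [prior_spec()] covering (at least) the names of `params`.
#' @return The scalar joint log prior density.
#' @examples
#' log_prior(c(beta = 0), prior_spec(beta = half_normal(5)))
#' @export
log_prior <- function(params, prior) {
  missing_pr <- setdiff(names(params), names(prior))
  if (length(missing_pr))
    stop("no prior given for: ", paste(missing_pr, collapse = ", "),
         call. = FALSE)
  sum(vapply(names(params), function(p)
    log_density_one(params[[p]], prior[[p]]), numeric(1)))
}
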