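#' Closed-form solution of the SI model
#'
#' The SI equation `I' = beta * I * (N - I) / N` is logistic; its solution is
#' `I(t) = I0 * N / (I0 + (N - I0) * exp(-beta * t))`. Used as the exact
#' oracle for the numerical integrator and as the fast prediction path inside
#' the single-symbiont likelihood.
#'
#' @param t Time(s) in days.
#' @param beta Transmission rate (per day).
#' @param N Population size.
#' @param I0 Initial number infected.
#' @return Infected count(s) at `t`.
#' @examples
#' si_closed_form(2, beta = 0.5, N = 50, I0 = 1) # 2.628...
#' @export
si_closed_form <- function(t, beta, N, I0) {
  I0 * N / (I0 + (N - I0) * exp(-beta * t))
}

new_trajectory <- function(times, states, model, stochastic) {
  structure(list(times = times, states = states, model = model,
                 stochastic = stochastic),
            class = "trajectory")
}

class_names <- c("S", "I_A", "I_B", "X")

# init normalised to a J x 4 matrix whatever the model
normalise_init <- function(model, init) {
  if (inherits(init, "metacommunity_state")) return(init$patches)
  if (model == "si") {
    if (!is.null(names(init)) && all(c("S", "I") %in% names(init)))
      init <- c(S = unname(init[["S"]]), I_A = unname(init[["I"]]),
                I_B = 0, X = 0)
  }
  m <- matrix(as.numeric(init), nrow = 1)
  colnames(m) <- class_names
  m
}

#' Integrate a transmission model deterministically
#'
#' Solves the requested ODE system with an adaptive solver
#' ([deSolve::lsoda()]) at the requested output times. Tiny negative
#' excursions (within `-atol`) are clipped to zero.
#'
#' @param model One of `"si"` (single symbiont, [si_rhs()]),
#'   `"two_symbiont"` (closed-population coinfection, [experiment_rhs()]) or
#'   `"metacommunity"` (full model, [metacommunity_rhs()]).
#' @param params For `"si"`, a list with element `beta`; for
#'   `"two_symbiont"`, a [symbiont_params()]; for `"metacommunity"`, a
#'   [model_params()].
#' @param init Initial state: for `"si"` a named vector `c(S = , I = )`, for
#'   `"two_symbiont"` a [patch_state()], for `"metacommunity"` a
#'   [metacommunity_state()].
#' @param times Increasing output times (days); the first is the initial
#'   time.
#' @param rtol,atol Relative and absolute solver tolerances.
#' @return A `trajectory` object holding the output `times` and a
#'   `time x patch x class` state array. Coerce with
#'   `as.data.frame()` or export with [write_trajectory_csv()].
#' @examples
#' tr <- integrate_model("si", list(beta = 0.5), c(S = 49, I = 1), 0:20)
#' @export
integrate_model <- function(model = c("si", "two_symbiont", "metacommunity"),
                            params, init, times, rtol = 1e-8, atol = 1e-10) {
  model <- match.arg(model)
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  P0 <- normalise_init(model, init)
  J <- nrow(P0)
  deriv <- switch(model,
    si = {
      beta <- if (is.list(params)) params$beta else as.numeric(params)
      N <- sum(P0)
      function(t, y, p) {
        dI <- beta * y[2] * (N - y[2]) / N
        list(c(-dI, dI, 0, 0))
      }
    },
    two_symbiont = function(t, y, p) {
      names(y) <- class_names
      list(as.numeric(experiment_rhs(y, params)))
    },
    metacommunity = function(t, y, p) {
      st <- list(patches = matrix(y, nrow = J,
                                  dimnames = list(NULL, class_names)))
      list(as.vector(metacommunity_rhs(st, params)))
    })
  y0 <- as.vector(P0)
  sol <- deSolve::lsoda(y = y0, times = times, func = deriv, parms = NULL,
                        rtol = rtol, atol = atol)
  if (nrow(sol) < length(times) || anyNA(sol)) {
    ok <- stats::complete.cases(sol)
    last_good <- if (any(ok)) sol[max(which(ok)), ] else y0
    stop(structure(class = c("integration_error", "error", "condition"),
                   list(message = sprintf(
                          "integrator failed after t = %.4g",
                          if (any(ok)) sol[max(which(ok)), 1] else times[1]),
                        call = sys.call(-1), last_good = last_good)))
  }
  Y <- sol[, -1, drop = FALSE]
  if (any(Y < -atol * 100))
    warning("integrator produced negative classes beyond tolerance; clipped")
  Y[Y < 0] <- 0
  states <- array(Y, dim = c(length(times), J, 4),
                  dimnames = list(NULL, NULL, class_names))
  new_trajectory(times = as.numeric(times), states = states,
                 model = model, stochastic = FALSE)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("%s trajectory (%s): %d time points, %d patch(es), t in [%g, %g] d\n",
              if (x$stochastic) "Stochastic" else "Deterministic",
              x$model, length(x$times), dim(x$states)[2],
              min(x$times), max(x$times)))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  J <- dim(x$states)[2]
  out <- do.call(rbind, lapply(seq_len(J), function(j) {
    data.frame(time = x$times, patch = j,
               S = x$states[, j, "S"], I_A = x$states[, j, "I_A"],
               I_B = x$states[, j, "I_B"], X = x$states[, j, "X"])
  }))
  rownames(out) <- NULL
  out[order(out$time, out$patch), , drop = FALSE]
}

#' Export a trajectory to CSV
#'
#' Writes the tidy layout `time, patch, S, I_A, I_B, X` (one row per patch
#' and time point) with locale-independent formatting.
#'
#' @param trajectory A `trajectory` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  utils::write.csv(as.data.frame(trajectory), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @export
plot.trajectory <- function(x, patch = 1, ...) {
  cls <- if (x$model == "si") "I_A" else c("I_A", "I_B", "X")
  N <- rowSums(x$states[, patch, , drop = FALSE][, 1, ])
  frac <- x$states[, patch, cls, drop = FALSE][, 1, , drop = FALSE][, 1, ] / N
  frac <- as.matrix(frac)
  graphics::matplot(x$times, frac, type = "l", lty = 1, lwd = 2,
                    xlab = "time (days)", ylab = "fraction of hosts",
                    ylim = c(0, 1), ...)
  graphics::legend("topleft", legend = if (x$model == "si") "infected" else cls,
                   lty = 1, lwd = 2, col = seq_along(cls), bty = "n")
  invisible(x)
}
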