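#' Infection-class state of one host population (patch)
#'
#' A patch holds hosts that are susceptible (`S`), singly infected with
#' symbiont A or B (`I_A`, `I_B`), or coinfected (`X`). States are continuous
#' densities for ODE work; the Gillespie simulator additionally requires
#' integer counts.
#'
#' @param S,I_A,I_B,X Non-negative class sizes.
#' @return A named numeric vector of class `patch_state` with elements
#'   `S`, `I_A`, `I_B`, `X`; the total `N` is available via [patch_total()].
#' @examples
#' st <- patch_state(S = 90, I_A = 5, I_B = 5, X = 0)
#' patch_total(st) # 100
#' @export
patch_state <- function(S, I_A = 0, I_B = 0, X = 0) {
  x <- c(S = as.numeric(S), I_A = as.numeric(I_A),
         I_B = as.numeric(I_B), X = as.numeric(X))
  if (any(!is.finite(x)) || any(x < 0))
    stop("patch state classes must be finite and non-negative", call. = FALSE)
  structure(x, class = c("patch_state", "numeric"))
}

#' @rdname patch_state
#' @param state A `patch_state` or a numeric vector with the same layout.
#' @export
patch_total <- function(state) {
  unname(state[["S"]] + state[["I_A"]] + state[["I_B"]] + state[["X"]])
}

#' State of all patches in the host metacommunity at one time
#'
#' @param patches A `J x 4` matrix with columns `S`, `I_A`, `I_B`, `X`
#'   (one row per patch), or a list of [patch_state()] objects.
#' @param t Time in days, `>= 0`.
#' @return An object of class `metacommunity_state`: a list with the state
#'   matrix `patches` and the time `t`.
#' @export
metacommunity_state <- function(patches, t = 0) {
  if (is.list(patches)) patches <- do.call(rbind, patches)
  patches <- as.matrix(patches)
  if (ncol(patches) != 4) stop("patches must have 4 columns (S, I_A, I_B, X)",
                               call. = FALSE)
  colnames(patches) <- c("S", "I_A", "I_B", "X")
  if (any(!is.finite(patches)) || any(patches < 0))
    stop("all classes must be finite and non-negative", call. = FALSE)
  if (!is.finite(t) || t < 0) stop("t must be a non-negative time", call. = FALSE)
  structure(list(patches = patches, t = as.numeric(t)),
            class = "metacommunity_state")
}

#' @export
print.metacommunity_state <- function(x, ...) {
  cat(sprintf("Metacommunity state at t = %g d, J = %d patch(es)\n",
              x$t, nrow(x$patches)))
  print(x$patches)
  invisible(x)
}
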