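#' Build a distance-based migration routing matrix
#'
#' Converts pairwise distances between habitat patches into the routing
#' probabilities `rho[i, l]` that an emigrant from patch `l` settles in patch
#' `i`. Off-diagonal entries are proportional to a decaying kernel of the
#' distance and each source column is normalised to sum to one, so every
#' emigrant ends up in some other patch.
#'
#' @param distances Symmetric `J x J` matrix of non-negative pairwise
#'   distances with zero diagonal; `J >= 2`.
#' @param kernel_scale Positive length scale of the kernel (same units as
#'   `distances`).
#' @param kernel Kernel family: `"exponential"` (`exp(-d / scale)`, default)
#'   or `"gaussian"` (`exp(-(d / scale)^2)`).
#' @return A `J x J` routing matrix with zero diagonal and unit column sums.
#' @examples
#' d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
#' build_migration_matrix(d, kernel_scale = 1)
#' @export
build_migration_matrix <- function(distances, kernel_scale,
                                   kernel = c("exponential", "gaussian")) {
  kernel <- match.arg(kernel)
  distances <- as.matrix(distances)
  J <- nrow(distances)
  if (J < 2) stop("at least 2 patches are needed: an emigrant has no destination",
                  call. = FALSE)
  if (ncol(distances) != J) stop("distances must be square", call. = FALSE)
  if (any(!is.finite(distances))) stop("distances must be finite", call. = FALSE)
  if (any(distances < 0)) stop("distances must be non-negative", call. = FALSE)
  if (any(abs(distances - t(distances)) > 1e-12))
    stop("distances must be symmetric", call. = FALSE)
  if (any(diag(distances) != 0)) stop("distances must have zero diagonal",
                                      call. = FALSE)
  if (!is.finite(kernel_scale) || kernel_scale <= 0)
    stop("kernel_scale must be positive", call. = FALSE)
  w <- switch(kernel,
              exponential = exp(-distances / kernel_scale),
              gaussian = exp(-(distances / kernel_scale)^2))
  diag(w) <- 0
  sweep(w, 2, colSums(w), "/")
}
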