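#' Horizontal-transmission parameters for a two-symbiont system
#'
#' Bundles the rates governing contact (horizontal) transmission of two
#' heritable symbionts, A and B, between insect hosts. Transmission is
#' frequency dependent: the force of infection for symbiont A is
#' `beta_A * (I_A + q * X) / N`, so coinfected hosts (class X) transmit with
#' their infectiousness modulated by `q`, and singly infected hosts acquire
#' the second symbiont at a rate modulated by their susceptibility `psi`.
#'
#' @param beta_A Horizontal transmission rate of symbiont A (per day).
#' @param beta_B Horizontal transmission rate of symbiont B (per day).
#' @param q Transmissibility modifier of coinfected hosts (dimensionless);
#'   `q = 1` means coinfected hosts transmit each symbiont as effectively as
#'   singly infected hosts.
#' @param psi Susceptibility of singly infected hosts to acquiring the second
#'   symbiont (dimensionless); `psi = 1` means no interference or facilitation.
#' @return An object of class `symbiont_params`.
#' @examples
#' symbiont_params(beta_A = 0.5, beta_B = 0.35, q = 0.75, psi = 1.25)
#' @export
symbiont_params <- function(beta_A = 0.5, beta_B = 0.35, q = 0.75, psi = 1.25) {
  x <- structure(
    list(beta_A = as.numeric(beta_A), beta_B = as.numeric(beta_B),
         q = as.numeric(q), psi = as.numeric(psi)),
    class = "symbiont_params")
  stop_on_violations(validate_symbiont_params(x))
  x
}

#' Host demography and vertical-transmission parameters
#'
#' Hosts reproduce at per-capita rate `nu_b` and die at rate `nu_d`,
#' irrespective of infection status. A birth from an infected mother is fully
#' symbiont-free with probability `phi`; with probability `1 - phi` vertical
#' transmission occurs. A vertically transmitting coinfected mother produces
#' offspring singly infected with A with conditional probability `c_A`, with B
#' with probability `c_B`, and coinfected with probability `1 - (c_A + c_B)`.
#'
#' @param nu_b Per-capita birth rate (per day).
#' @param nu_d Per-capita death rate (per day).
#' @param phi Probability that a birth from an infected mother is symbiont
#'   free, in `[0, 1]`.
#' @param c_A,c_B Conditional probabilities that a vertically transmitting
#'   coinfected mother produces offspring singly infected with A or B;
#'   `c_A + c_B <= 1`.
#' @return An object of class `demography_params`.
#' @export
demography_params <- function(nu_b = 0, nu_d = 0, phi = 1, c_A = 0, c_B = 0) {
  x <- structure(
    list(nu_b = as.numeric(nu_b), nu_d = as.numeric(nu_d),
         phi = as.numeric(phi), c_A = as.numeric(c_A), c_B = as.numeric(c_B)),
    class = "demography_params")
  stop_on_violations(validate_demography_params(x))
  x
}

#' Migration parameters for a patchy host metapopulation
#'
#' Hosts emigrate from their patch at per-capita rate `m`; an emigrant leaving
#' patch `l` settles in patch `i` with probability `rho[i, l]`. Columns of
#' `rho` are source patches and rows are destinations; every emigrant ends up
#' in some other patch, so each column of `rho` has zero diagonal and sums to
#' one (when `J > 1`). Use [build_migration_matrix()] to derive `rho` from
#' pairwise distances.
#'
#' @param m Per-capita emigration rate (per day).
#' @param rho `J x J` routing matrix, `rho[destination, source]`. For a single
#'   patch (`J = 1`) use the `1 x 1` zero matrix.
#' @param J Number of patches; defaults to `nrow(rho)`.
#' @return An object of class `migration_params`.
#' @export
migration_params <- function(m = 0, rho = matrix(0, 1, 1), J = nrow(rho)) {
  rho <- as.matrix(rho)
  x <- structure(
    list(m = as.numeric(m), rho = rho, J = as.integer(J)),
    class = "migration_params")
  stop_on_violations(validate_migration_params(x))
  x
}

#' Full parameter set for the metacommunity transmission model
#'
#' @param symbiont A [symbiont_params()] object (horizontal transmission).
#' @param demography A [demography_params()] object (births, deaths, vertical
#'   transmission).
#' @param migration A [migration_params()] object (emigration and routing).
#' @return An object of class `model_params`.
#' @export
model_params <- function(symbiont = symbiont_params(),
                         demography = demography_params(),
                         migration = migration_params()) {
  x <- structure(
    list(symbiont = symbiont, demography = demography, migration = migration),
    class = "model_params")
  stop_on_violations(validate_params(x))
  x
}

violation <- function(code, message) {
  data.frame(code = code, message = message, stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(code = character(), message = character(), stringsAsFactors = FALSE)
}

stop_on_violations <- function(v) {
  if (nrow(v) > 0)
    stop("invalid parameters: ", paste(v$message, collapse = "; "), call. = FALSE)
  invisible(NULL)
}

validate_symbiont_params <- function(x) {
  v <- no_violations()
  for (nm in c("beta_A", "beta_B", "q", "psi")) {
    val <- x[[nm]]
    if (!is.finite(val))
      v <- rbind(v, violation(paste0("nonfinite:", nm), paste0(nm, " is not finite")))
    else if (val < 0)
      v <- rbind(v, violation(paste0("negative:", nm), paste0(nm, " < 0")))
  }
  v
}

validate_demography_params <- function(x) {
  v <- no_violations()
  for (nm in c("nu_b", "nu_d", "c_A", "c_B")) {
    val <- x[[nm]]
    if (!is.finite(val))
      v <- rbind(v, violation(paste0("nonfinite:", nm), paste0(nm, " is not finite")))
    else if (val < 0)
      v <- rbind(v, violation(paste0("negative:", nm), paste0(nm, " < 0")))
  }
  if (!is.finite(x$phi) || x$phi < 0 || x$phi > 1)
    v <- rbind(v, violation("phi_out_of_range", "phi not in [0, 1]"))
  if (is.finite(x$c_A) && is.finite(x$c_B) && x$c_A + x$c_B > 1 + 1e-12)
    v <- rbind(v, violation("vertical_split_exceeds_one", "c_A + c_B > 1"))
  v
}

validate_migration_params <- function(x) {
  v <- no_violations()
  if (!is.finite(x$m) || x$m < 0)
    v <- rbind(v, violation("negative:m", "m < 0 or not finite"))
  rho <- x$rho
  if (!is.matrix(rho) || nrow(rho) != ncol(rho) || nrow(rho) != x$J) {
    return(rbind(v, violation("rho_dimension", "rho is not a J x J matrix")))
  }
  if (any(!is.finite(rho)))
    return(rbind(v, violation("rho_nonfinite", "rho has non-finite entries")))
  if (any(diag(rho) != 0))
    v <- rbind(v, violation("rho_diagonal_nonzero", "rho has nonzero diagonal"))
  if (any(rho < 0))
    v <- rbind(v, violation("rho_negative", "rho has negative entries"))
  if (x$J > 1) {
    cs <- colSums(rho)
    if (any(abs(cs - 1) > 1e-12))
      v <- rbind(v, violation("routing_not_normalized",
                              "destination probabilities of a source do not sum to 1"))
  }
  v
}

#' Validate a parameter set and report every violated invariant
#'
#' Checks all type invariants (non-negative rates, `phi` in `[0, 1]`,
#' `c_A + c_B <= 1`, column-stochastic routing with zero diagonal) and returns
#' a data frame with one row per violation rather than stopping, so callers
#' can report all problems at once.
#'
#' @param params A [model_params()] object, or any of its components.
#' @return A data frame with columns `code` (machine readable) and `message`;
#'   zero rows when all invariants hold.
#' @examples
#' nrow(validate_params(model_params())) # 0
#' @export
validate_params <- function(params) {
  if (inherits(params, "symbiont_params")) return(validate_symbiont_params(params))
  if (inherits(params, "demography_params")) return(validate_demography_params(params))
  if (inherits(params, "migration_params")) return(validate_migration_params(params))
  if (!is.list(params) || is.null(params$symbiont))
    stop("not a model_params object", call. = FALSE)
  rbind(validate_symbiont_params(params$symbiont),
        validate_demography_params(params$demography),
        validate_migration_params(params$migration))
}

#' @export
print.model_params <- function(x, ...) {
  s <- x$symbiont; d <- x$demography; m <- x$migration
  cat("Metacommunity transmission parameters\n")
  cat(sprintf("  horizontal: beta_A = %.4g, beta_B = %.4g, q = %.4g, psi = %.4g\n",
              s$beta_A, s$beta_B, s$q, s$psi))
  cat(sprintf("  demography: nu_b = %.4g, nu_d = %.4g, phi = %.4g, c_A = %.4g, c_B = %.4g\n",
              d$nu_b, d$nu_d, d$phi, d$c_A, d$c_B))
  cat(sprintf("  migration:  m = %.4g over J = %d patch(es)\n", m$m, m$J))
  invisible(x)
}

#' Read or write a model configuration file
#'
#' Parameters serialise to a flat key-value YAML or JSON mapping with dotted
#' keys (`symbiont.beta_A`, `demography.phi`, `migration.m`, ...). The routing
#' matrix may be given explicitly as nested lists under `migration.rho`, or
#' implicitly through `migration.distances` plus `migration.kernel_scale`, in
#' which case [build_migration_matrix()] is applied.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `read_model_config()` returns a [model_params()] object;
#'   `write_model_config()` returns `path` invisibly.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  flat <- flatten_config(raw)
  pick <- function(key, default) {
    if (!is.null(flat[[key]])) flat[[key]] else default
  }
  sym <- symbiont_params(
    beta_A = pick("symbiont.beta_A", 0.5),
    beta_B = pick("symbiont.beta_B", 0.35),
    q = pick("symbiont.q", 0.75),
    psi = pick("symbiont.psi", 1.25))
  dem <- demography_params(
    nu_b = pick("demography.nu_b", 0),
    nu_d = pick("demography.nu_d", 0),
    phi = pick("demography.phi", 1),
    c_A = pick("demography.c_A", 0),
    c_B = pick("demography.c_B", 0))
  as_square_matrix <- function(x) {
    if (is.matrix(x)) x else do.call(rbind, lapply(x, unlist))
  }
  rho <- flat[["migration.rho"]]
  if (!is.null(rho)) {
    rho <- as_square_matrix(rho)
  } else if (!is.null(flat[["migration.distances"]])) {
    d <- as_square_matrix(flat[["migration.distances"]])
    rho <- build_migration_matrix(d, kernel_scale = pick("migration.kernel_scale", 1))
  } else {
    rho <- matrix(0, 1, 1)
  }
  mig <- migration_params(m = pick("migration.m", 0), rho = rho)
  model_params(symbiont = sym, demography = dem, migration = mig)
}

# nested list -> flat list with dotted keys; rho/distances kept nested
flatten_config <- function(x) {
  out <- list()
  for (top in names(x)) {
    val <- x[[top]]
    if (is.list(val) && !top %in% c("rho", "distances")) {
      for (sub in names(val)) {
        if (sub %in% c("rho", "distances")) {
          out[[paste(top, sub, sep = ".")]] <- val[[sub]]
        } else {
          out[[paste(top, sub, sep = ".")]] <- val[[sub]]
        }
      }
    } else {
      out[[top]] <- val
    }
  }
  out
}

#' @rdname read_model_config
#' @param params A [model_params()] object to serialise.
#' @export
write_model_config <- function(params, path) {
  stop_on_violations(validate_params(params))
  obj <- list(
    symbiont = params$symbiont[c("beta_A", "beta_B", "q", "psi")],
    demography = params$demography[c("nu_b", "nu_d", "phi", "c_A", "c_B")],
    migration = list(m = params$migration$m,
                     rho = apply(params$migration$rho, 1, as.list, simplify = FALSE)))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(obj, path, precision = 15)
  }
  invisible(path)
}
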