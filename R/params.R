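#' Model interaction and geometry parameters
#'
#' Bundles every energetic and geometric constant of the mean-field model.
#' Energies are in kT; `chi` and `chi_cr` follow the convention that
#' negative values mean attraction.  Because the protein--monomer attraction
#' enters the free energy as `chi * psi * phi / v_bar`, `chi` is a
#' per-protein quantity and magnitudes of order several hundred are typical
#' for multivalent transport proteins.
#'
#' @param chi dimensionless protein--monomer interaction strength (negative
#'   = attraction).
#' @param chi_cr dimensionless monomer--monomer cohesion (negative =
#'   attraction).
#' @param v_bar protein-to-monomer volume ratio, `v / l^3` (> 0).
#' @param l monomer linear size in nm; the monomer volume is `l^3`.
#' @param b Kuhn length in nm; one monomer occupies contour length `b`.
#' @param N number of monomers per chain (>= 1).
#' @param z maximal packing fraction used only when converting volume
#'   fractions to molar concentrations; in (0, 1].
#'
#' @return An object of class `"interaction_params"`.
#' @seealso [composition()], [reservoir_state()], [read_params_config()]
#' @export
#' @examples
#' p <- interaction_params(chi = -200, chi_cr = -1.5, v_bar = 125, N = 167)
#' p
interaction_params <- function(chi = 0, chi_cr = 0, v_bar = 125,
                               l = 1, b = 1.52, N = 167, z = 0.625) {
  stopifnot(length(chi) == 1, length(chi_cr) == 1, length(v_bar) == 1,
            length(l) == 1, length(b) == 1, length(N) == 1, length(z) == 1)
  if (!is.finite(v_bar) || v_bar <= 0)
    fg_domain_error("`v_bar` must be a positive finite number")
  if (!is.finite(l) || l <= 0 || !is.finite(b) || b <= 0)
    fg_domain_error("`l` and `b` must be positive (nm)")
  if (!is.finite(N) || N < 1)
    fg_domain_error("`N` must be >= 1")
  if (!is.finite(z) || z <= 0 || z > 1)
    fg_domain_error("`z` must lie in (0, 1]")
  structure(
    list(chi = as.numeric(chi), chi_cr = as.numeric(chi_cr),
         v_bar = as.numeric(v_bar), l = as.numeric(l), b = as.numeric(b),
         N = as.numeric(N), z = as.numeric(z)),
    class = "interaction_params"
  )
}

#' @export
print.interaction_params <- function(x, ...) {
  cat("Mean-field interaction parameters\n")
  cat(sprintf("  chi    = %8.3f   (protein-monomer, kT per protein)\n", x$chi))
  cat(sprintf("  chi_cr = %8.3f   (monomer-monomer cohesion)\n", x$chi_cr))
  cat(sprintf("  v_bar  = %8.3f   (protein/monomer volume ratio)\n", x$v_bar))
  cat(sprintf("  l      = %8.3f nm (monomer size, v0 = %.4g nm^3)\n",
              x$l, x$l^3))
  cat(sprintf("  b      = %8.3f nm (Kuhn length)\n", x$b))
  cat(sprintf("  N      = %8.0f    (monomers per chain)\n", x$N))
  cat(sprintf("  z      = %8.3f   (maximal packing fraction)\n", x$z))
  invisible(x)
}

#' Local composition of a polymer/protein/solvent mixture
#'
#' A composition is the pair of local volume fractions `(psi, phi)` of
#' chain monomers and transport proteins.  The solvent fraction
#' `1 - psi - phi` must stay strictly positive.  Vectors of equal length
#' (or length 1, recycled) are accepted, so compositions can describe whole
#' grids at once.
#'
#' @param psi polymer (monomer) volume fraction(s), >= 0.
#' @param phi protein volume fraction(s), >= 0.
#' @return An object of class `"composition"` with fields `psi` and `phi`.
#' @export
#' @examples
#' composition(0.3, 0.05)
composition <- function(psi, phi = 0) {
  n <- max(length(psi), length(phi))
  psi <- rep_len(as.numeric(psi), n)
  phi <- rep_len(as.numeric(phi), n)
  validate_fractions(psi, phi)
  structure(list(psi = psi, phi = phi), class = "composition")
}

validate_fractions <- function(psi, phi) {
  if (any(!is.finite(psi)) || any(!is.finite(phi)))
    fg_domain_error("volume fractions must be finite")
  if (any(psi < 0) || any(phi < 0))
    fg_domain_error("volume fractions must be non-negative")
  if (any(psi + phi >= 1))
    fg_domain_error(
      "psi + phi must be < 1 (the solvent fraction must stay positive)")
  invisible(TRUE)
}

as_composition <- function(x) {
  if (inherits(x, "composition")) return(x)
  if (is.numeric(x) && length(x) == 2) return(composition(x[1], x[2]))
  fg_domain_error("expected a `composition` or a numeric vector c(psi, phi)")
}

#' @export
print.composition <- function(x, ...) {
  cat(sprintf("composition: %d point(s); psi in [%g, %g], phi in [%g, %g]\n",
              length(x$psi), min(x$psi), max(x$psi), min(x$phi), max(x$phi)))
  invisible(x)
}

#' Ideal dilute protein reservoir
#'
#' The outside solution of transport proteins is assumed ideal, with
#' exchange chemical potential `mu = log(c)` (kT per protein) and osmotic
#' pressure `pi = c / v_bar` (kT per monomer volume).
#'
#' @param c protein volume fraction in the reservoir, in `[0, 1)`.
#' @param params an [interaction_params()] (supplies `v_bar`).
#' @return An object of class `"reservoir_state"` with fields `c`, `mu`,
#'   `pi`.  At `c = 0` the chemical potential is `-Inf`.
#' @export
reservoir_state <- function(c, params) {
  stopifnot(inherits(params, "interaction_params"), length(c) == 1)
  if (!is.finite(c) || c < 0 || c >= 1)
    fg_domain_error("reservoir fraction `c` must lie in [0, 1)")
  structure(list(c = c, mu = if (c > 0) log(c) else -Inf,
                 pi = c / params$v_bar),
            class = "reservoir_state")
}

# ---- configuration files ---------------------------------------------------

#' Read or write a parameter configuration file
#'
#' Parameter sets are serialized as flat YAML or JSON maps with keys
#' `chi`, `chi_cr`, `v_bar`, `l_nm`, `b_nm`, `N`, `z` (missing keys fall
#' back to the [interaction_params()] defaults).  The format is chosen from
#' the file extension (`.yml`/`.yaml` or `.json`).
#'
#' @param path file to read from or write to.
#' @param params an [interaction_params()] object (for writing).
#' @return `read_params_config()` returns an [interaction_params()];
#'   `write_params_config()` returns `path` invisibly.
#' @export
read_params_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("chi", "chi_cr", "v_bar", "l_nm", "b_nm", "N", "z")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    warning("ignoring unknown config keys: ", paste(extra, collapse = ", "))
  defaults <- interaction_params()
  gv <- function(key, fallback) if (!is.null(raw[[key]])) raw[[key]] else fallback
  interaction_params(
    chi = gv("chi", defaults$chi), chi_cr = gv("chi_cr", defaults$chi_cr),
    v_bar = gv("v_bar", defaults$v_bar), l = gv("l_nm", defaults$l),
    b = gv("b_nm", defaults$b), N = gv("N", defaults$N),
    z = gv("z", defaults$z))
}

#' @rdname read_params_config
#' @export
write_params_config <- function(params, path) {
  stopifnot(inherits(params, "interaction_params"))
  rec <- list(chi = params$chi, chi_cr = params$chi_cr, v_bar = params$v_bar,
              l_nm = params$l, b_nm = params$b, N = params$N, z = params$z)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(rec, path)
  }
  invisible(path)
}
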