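# Thermodynamic core: the mixing free-energy density of a
# monomer/protein/solvent lattice fluid, its analytic first derivatives,
# the species chemical potentials and the osmotic pressure.
#
# Internal kernels work on plain numeric vectors (psi, phi) and scalar
# parameters; the exported functions validate `composition` objects and
# dispatch to the kernels.  All closed forms were derived by hand from the
# free-energy density and are cross-checked against finite differences and
# the Gibbs-Duhem relation in the test suite.

# x*log(x) with the continuous limit 0 at x = 0.  Inputs are validated
# before this point; the clamp only guards against log(0) from exact zeros.
xlogx <- function(x) {
  out <- x * log(pmax(x, 1e-300))
  out[x == 0] <- 0
  out
}

log_safe <- function(x) log(pmax(x, 1e-300))

# f(psi, phi): mixing free-energy density, kT per monomer volume.
# Terms: protein translational entropy, solvent entropy, the asymmetric
# excluded-volume term (1/v_bar - 1)(1 - phi)log(1 - phi), protein-monomer
# attraction and monomer-monomer cohesion.
fe_mix <- function(psi, phi, chi, chi_cr, v_bar) {
  s <- 1 - psi - phi
  xlogx(phi) / v_bar + xlogx(s) + (1 / v_bar - 1) * xlogx(1 - phi) +
    chi * psi * phi / v_bar + 0.5 * chi_cr * psi^2
}

# f plus the chain translational entropy psi*log(psi)/N (bulk solutions).
fe_bulk <- function(psi, phi, chi, chi_cr, v_bar, N) {
  fe_mix(psi, phi, chi, chi_cr, v_bar) + xlogx(psi) / N
}

# d f / d psi (mixing form; the bulk form adds (log(psi) + 1)/N).
dfe_dpsi_mix <- function(psi, phi, chi, chi_cr, v_bar) {
  -log_safe(1 - psi - phi) - 1 + chi * phi / v_bar + chi_cr * psi
}

dfe_dpsi_bulk <- function(psi, phi, chi, chi_cr, v_bar, N) {
  dfe_dpsi_mix(psi, phi, chi, chi_cr, v_bar) + (log_safe(psi) + 1) / N
}

# d f / d phi (identical for mixing and bulk forms).
dfe_dphi <- function(psi, phi, chi, chi_cr, v_bar) {
  (log_safe(phi) + 1) / v_bar - log_safe(1 - psi - phi) - 1 -
    (1 / v_bar - 1) * (log_safe(1 - phi) + 1) + chi * psi / v_bar
}

# Exchange chemical potential of a protein (kT per protein): a protein
# inserted into the mixture replaces v_bar solvent units, so mu is v_bar
# times the density derivative and mu -> log(phi) in the dilute limit,
# matching the ideal-reservoir relation mu_c = log(c).
mu_protein_kernel <- function(psi, phi, chi, chi_cr, v_bar) {
  v_bar * dfe_dphi(psi, phi, chi, chi_cr, v_bar)
}

# Osmotic pressure Pi = psi f_psi + phi f_phi - f, kT per monomer volume.
pi_kernel <- function(psi, phi, chi, chi_cr, v_bar, N, bulk) {
  fp <- if (bulk) dfe_dpsi_bulk(psi, phi, chi, chi_cr, v_bar, N)
        else      dfe_dpsi_mix(psi, phi, chi, chi_cr, v_bar)
  f  <- if (bulk) fe_bulk(psi, phi, chi, chi_cr, v_bar, N)
        else      fe_mix(psi, phi, chi, chi_cr, v_bar)
  psi * fp + phi * dfe_dphi(psi, phi, chi, chi_cr, v_bar) - f
}

#' Mixing free-energy density
#'
#' Free energy of mixing per unit volume, in kT per monomer volume, for a
#' local composition of chain monomers (volume fraction `psi`), transport
#' proteins (`phi`, particles of `v_bar` monomer volumes each) and solvent
#' (`1 - psi - phi`):
#'
#' \deqn{f(\psi,\phi) = \frac{\phi}{\bar v}\ln\phi + (1-\psi-\phi)\ln(1-\psi-\phi)
#'   + \left(\frac{1}{\bar v}-1\right)(1-\phi)\ln(1-\phi)
#'   + \frac{\chi}{\bar v}\psi\phi + \frac{\chi_{cr}}{2}\psi^2.}
#'
#' `mixing_free_energy()` omits the chain translational entropy and is the
#' appropriate density for grafted layers and single chains;
#' `bulk_free_energy()` adds \eqn{\psi\ln(\psi)/N} for free chains in
#' solution.
#'
#' @param comp a [composition()] (vectorized).
#' @param params an [interaction_params()].
#' @return Numeric vector of energy densities (kT per monomer volume).
#' @export
#' @examples
#' p <- interaction_params(chi = -200, chi_cr = -1.5, v_bar = 125)
#' mixing_free_energy(composition(0.3, 0.2), p)
mixing_free_energy <- function(comp, params) {
  comp <- as_composition(comp)
  stopifnot(inherits(params, "interaction_params"))
  fe_mix(comp$psi, comp$phi, params$chi, params$chi_cr, params$v_bar)
}

#' @rdname mixing_free_energy
#' @export
bulk_free_energy <- function(comp, params) {
  comp <- as_composition(comp)
  stopifnot(inherits(params, "interaction_params"))
  fe_bulk(comp$psi, comp$phi, params$chi, params$chi_cr, params$v_bar,
          params$N)
}

#' Chemical potentials and osmotic pressure
#'
#' Analytic (closed-form) derivatives of the free-energy density.
#'
#' `chemical_potential_protein()` returns the exchange chemical potential of
#' one transport protein in kT per protein, normalized so that it tends to
#' `log(phi)` in the dilute limit; equality with the reservoir value
#' `log(c)` is the adsorption equilibrium condition.  The chain
#' translational term carries no `phi` dependence, so the value is the same
#' for the mixing and bulk free energies (the `bulk` flag is accepted for
#' interface symmetry).
#'
#' `chemical_potential_polymer()` returns the chain chemical potential per
#' monomer for the bulk free energy, including the `1/N`-scaled
#' translational term `(log(psi) + 1)/N`; it diverges as `log(psi)/N` in
#' the dilute limit.
#'
#' `osmotic_pressure()` returns \eqn{\Pi = \psi f_\psi + \phi f_\phi - f}
#' in kT per monomer volume; it vanishes for pure solvent and reduces to
#' the van 't Hoff law `phi / v_bar` for a dilute protein solution.
#'
#' @inheritParams mixing_free_energy
#' @param bulk logical; use the bulk free energy (chains free in solution)
#'   rather than the mixing form.
#' @return Numeric vector (kT per protein, kT per monomer, or kT per
#'   monomer volume respectively).
#' @export
#' @examples
#' p <- interaction_params(chi = -75, chi_cr = -1.5, v_bar = 40, N = 167)
#' chemical_potential_protein(composition(0.3, 0.05), p)
#' osmotic_pressure(composition(0.3, 0.05), p, bulk = TRUE)
chemical_potential_protein <- function(comp, params, bulk = FALSE) {
  comp <- as_composition(comp)
  stopifnot(inherits(params, "interaction_params"))
  mu_protein_kernel(comp$psi, comp$phi, params$chi, params$chi_cr,
                    params$v_bar)
}

#' @rdname chemical_potential_protein
#' @export
chemical_potential_polymer <- function(comp, params) {
  comp <- as_composition(comp)
  stopifnot(inherits(params, "interaction_params"))
  dfe_dpsi_bulk(comp$psi, comp$phi, params$chi, params$chi_cr, params$v_bar,
                params$N)
}

#' @rdname chemical_potential_protein
#' @export
osmotic_pressure <- function(comp, params, bulk = FALSE) {
  comp <- as_composition(comp)
  stopifnot(inherits(params, "interaction_params"))
  pi_kernel(comp$psi, comp$phi, params$chi, params$chi_cr, params$v_bar,
            params$N, bulk = isTRUE(bulk))
}
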