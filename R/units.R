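# Unit conversions between model quantities (volume fractions, kT
# interaction parameters) and laboratory quantities (kDa, g/cm^3, uM).

AVOGADRO <- 6.02214076e23
NM3_PER_KDA_G_CM3 <- 1e24 / AVOGADRO / 1000   # nm^3 per (kDa / (g/cm^3))

#' Protein volume from molecular mass
#'
#' Converts a molecular mass to a molecular volume assuming a uniform
#' protein mass density.  For globular proteins the density lies around
#' 1.2--1.5 g/cm^3; the default 1.35 g/cm^3 is the midpoint.
#'
#' @param mass_kda molecular mass in kDa (>= 0); vectorized.
#' @param density_g_cm3 protein mass density in g/cm^3 (> 0).
#' @return Volume(s) in nm^3.
#' @export
#' @examples
#' protein_volume_from_mass(33)    # NTF2-sized, ~ 41 nm^3
#' protein_volume_from_mass(100)   # Karyopherin-sized, ~ 123 nm^3
protein_volume_from_mass <- function(mass_kda, density_g_cm3 = 1.35) {
  if (any(!is.finite(mass_kda)) || any(mass_kda < 0))
    fg_domain_error("`mass_kda` must be >= 0")
  if (any(!is.finite(density_g_cm3)) || any(density_g_cm3 <= 0))
    fg_domain_error("`density_g_cm3` must be > 0")
  mass_kda * 1000 * NM3_PER_KDA_G_CM3 / density_g_cm3
}

#' Convert between volume fraction and molar concentration
#'
#' A volume fraction `x` of particles of volume `v` corresponds to a number
#' density `x * z / v`, where `z` is the maximal packing fraction assumed
#' for the dense state (the same convention is applied at all
#' concentrations so the map is linear and exactly invertible).
#'
#' @param fraction volume fraction(s) in `[0, 1]`.
#' @param particle_volume_nm3 particle volume in nm^3 (> 0).
#' @param z maximal packing fraction in (0, 1].
#' @return `volume_fraction_to_molar()`: concentration in micromolar (uM);
#'   `molar_to_volume_fraction()`: the volume fraction.
#' @export
#' @examples
#' volume_fraction_to_molar(1.2e-4, 125)   # ~ 1 uM of a Kap-sized protein
#' molar_to_volume_fraction(5, 167)        # 5 uM of an N = 167 chain (l = 1 nm)
volume_fraction_to_molar <- function(fraction, particle_volume_nm3,
                                     z = 0.625) {
  if (any(!is.finite(fraction)) || any(fraction < 0) || any(fraction > 1))
    fg_domain_error("`fraction` must lie in [0, 1]")
  check_vol_z(particle_volume_nm3, z)
  # mol / L = number per nm^3 * 1e24 / N_A; reported in uM
  fraction * z / particle_volume_nm3 * (1e24 / AVOGADRO) * 1e6
}

#' @rdname volume_fraction_to_molar
#' @param conc_uM concentration(s) in micromolar (>= 0).
#' @export
molar_to_volume_fraction <- function(conc_uM, particle_volume_nm3,
                                     z = 0.625) {
  if (any(!is.finite(conc_uM)) || any(conc_uM < 0))
    fg_domain_error("`conc_uM` must be >= 0")
  check_vol_z(particle_volume_nm3, z)
  conc_uM / 1e6 * particle_volume_nm3 / z / (1e24 / AVOGADRO)
}

check_vol_z <- function(particle_volume_nm3, z) {
  if (any(!is.finite(particle_volume_nm3)) || any(particle_volume_nm3 <= 0))
    fg_domain_error("`particle_volume_nm3` must be > 0")
  if (any(!is.finite(z)) || any(z <= 0) || any(z > 1))
    fg_domain_error("`z` must lie in (0, 1]")
  invisible(TRUE)
}

#' Interaction strength from per-site binding energies
#'
#' The effective protein--monomer interaction parameter is related to the
#' microscopic binding by `|chi| = n * eps * exp(eps)` with `n` binding
#' sites of depth `eps` (in kT); the exponential Boltzmann factor makes the
#' map strictly increasing in both arguments.  `eps_from_chi()` inverts it
#' by monotone root-finding.
#'
#' @param n_sites number of binding sites on the protein (>= 0).
#' @param eps_kT binding energy per site, kT (>= 0).
#' @return `chi_from_binding()`: the magnitude `|chi|` (callers apply the
#'   attractive sign); `eps_from_chi()`: the per-site energy in kT.
#' @export
#' @examples
#' chi_from_binding(6, 2.5)     # ~ 183, a Karyopherin-like strength
#' eps_from_chi(6, 182.7)
chi_from_binding <- function(n_sites, eps_kT) {
  if (any(!is.finite(n_sites)) || any(n_sites < 0))
    fg_domain_error("`n_sites` must be >= 0")
  if (any(!is.finite(eps_kT)) || any(eps_kT < 0))
    fg_domain_error("`eps_kT` must be >= 0")
  n_sites * eps_kT * exp(eps_kT)
}

#' @rdname chi_from_binding
#' @param chi_mag magnitude of the interaction parameter (>= 0).
#' @export
eps_from_chi <- function(n_sites, chi_mag) {
  if (length(chi_mag) != 1 || !is.finite(chi_mag) || chi_mag < 0)
    fg_domain_error("`chi_mag` must be a single value >= 0")
  if (!is.finite(n_sites) || n_sites <= 0)
    fg_domain_error("`n_sites` must be > 0 for the inverse map")
  if (chi_mag == 0) return(0)
  stats::uniroot(function(e) n_sites * e * exp(e) - chi_mag,
                 c(1e-12, 60), tol = 1e-14)$root
}

#' Amino acids per coarse-grained monomer
#'
#' One monomer occupies a contour length equal to the Kuhn length, so the
#' number of residues it lumps together is `b / residue`, with the backbone
#' spacing of about 0.38 nm per amino acid.
#'
#' @param b_nm Kuhn length in nm.
#' @param residue_nm backbone length per residue (default 0.38 nm).
#' @return Amino acids per monomer.
#' @export
#' @examples
#' amino_acids_per_monomer(1.52)   # = 4
amino_acids_per_monomer <- function(b_nm, residue_nm = 0.38) {
  if (any(b_nm <= 0) || any(residue_nm <= 0))
    fg_domain_error("lengths must be positive")
  b_nm / residue_nm
}
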