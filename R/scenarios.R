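# Named scenario library: the parameter sets used by the package's worked
# analyses, frozen in code so that every study can be re-run by name.
# Each scenario records where its numbers come from; values that are
# assumptions rather than measurements say so explicitly and can be
# overridden by rebuilding the parameter objects.

#' Default transport-protein species table for partitioning studies
#'
#' Protein and protein--cargo complexes partitioned against a cohesive
#' Nup98-like FG nup background (N = 167 monomers of 1 nm, chi_cr = -1.5).
#' Volumes are in monomer units (`v_bar`, monomer volume 1 nm^3):
#'
#' * NTF2 (`v_bar = 40`, `chi = -75`) and Importin-beta (`v_bar = 125`,
#'   `chi = -215`) use the interaction strengths inferred from grafted-layer
#'   analyses of the same protein pairs.
#' * Cargo complexes add the cargo volume computed from **assumed** masses
#'   via [protein_volume_from_mass()] (GFP 27 kDa, IBB domain 10 kDa, MBP
#'   42 kDa, ZsGreen 26 kDa; not measured quantities) and carry a slightly
#'   weakened attraction (`chi = -200`) standing in for direct cargo--chain
#'   repulsion.
#' * The (Importin-beta--ZsGreen) tetramer is assigned four times the
#'   single Importin-beta volume-plus-cargo and four times its interaction
#'   strength.
#' * TEV-mCherry (25 kDa) does not bind FG nups: `chi = 0`.
#'
#' @param density_g_cm3 protein density used for the assumed cargo masses.
#' @return Data frame with columns `name`, `v_bar`, `chi`, `assumption`.
#' @export
partitioning_species <- function(density_g_cm3 = 1.35) {
  vol <- function(kda) protein_volume_from_mass(kda, density_g_cm3)
  imp <- 125                         # Importin-beta volume, monomer units
  data.frame(
    name = c("NTF2", "Importin-beta", "Imp-beta/IBB-GFP",
             "Imp-beta/IBB-MBP-GFP", "Imp-beta/ZsGreen tetramer",
             "TEV-mCherry"),
    v_bar = c(40, imp,
              imp + vol(27 + 10),
              imp + vol(27 + 10 + 42),
              4 * (imp + vol(26)),
              vol(25)),
    chi = c(-75, -215, -200, -200, 4 * -215, 0),
    assumption = c("volume and chi from layer analyses", "as NTF2",
                   "cargo mass assumed 37 kDa", "cargo mass assumed 79 kDa",
                   "4x Imp-beta volume and chi; ZsGreen assumed 26 kDa",
                   "assumed 25 kDa, non-interacting"),
    stringsAsFactors = FALSE)
}

scenario_db <- function() {
  sc <- list()

  sc$layer_scaling <- list(
    description = "Protein-free grafted-layer height vs grafting distance for increasing cohesion; the log-log slope g grows from 2/3 (entropic brush) towards 2 (constant-density layer).",
    params = interaction_params(chi = 0, chi_cr = 0, v_bar = 125,
                                l = 1, b = 1.52),
    chi_cr_grid = c(0, -0.4, -0.8, -1.4, -2.5),
    fit_window = c(2, 10),
    provenance = "monomer of ~4 amino acids (l = 1 nm, b = 1.52 nm); cohesion series 0 to -2.5 spanning ideal-brush to collapsed-layer scaling")

  sc$layer_response_cohesion <- list(
    description = "Layer height vs reservoir concentration at fixed grafting (a = 5 nm) for a strongly binding Kap-sized particle; cohesion converts collapse into swelling.",
    params = interaction_params(chi = -550, chi_cr = 0,
                                v_bar = 125 / 0.67^3, l = 0.67, b = 1),
    a = 5,
    chi_cr_grid = c(0, -0.4, -0.8, -1.1),
    c_grid = 10^seq(-9, -3, length.out = 25),
    provenance = "fine monomer parameterization (l = 0.67 nm, b = 1 nm); chi = -550 per protein; particle volume 125 nm^3 (Kap-sized)")

  sc$layer_response_grafting <- list(
    description = "Layer response for a cohesive layer (chi_cr = -1) at grafting distances 3-6 nm; sparser grafting deepens the compaction.",
    params = interaction_params(chi = -530, chi_cr = -1,
                                v_bar = 125 / 0.67^3, l = 0.67, b = 1),
    a_grid = c(3, 4, 5, 6),
    c_grid = 10^seq(-9, -3, length.out = 25),
    provenance = "same monomer parameterization as layer_response_cohesion; chi = -530, chi_cr = -1")

  sc$phase_diagram_kap <- list(
    description = "Collapse/swelling map over grafting distance and interaction strength for a Karyopherin-sized particle (v_bar = 125), concentrations up to 1 uM.",
    params = interaction_params(chi = -200, chi_cr = -1, v_bar = 125,
                                l = 1, b = 1.52),
    a_grid = seq(2.5, 6, by = 0.5),
    chi_grid = seq(-700, -50, by = 50),
    c_max_uM = 1,
    provenance = "b = 1.52 nm, l = 1 nm; v_bar = 125 (Kap-sized); chi_cr = -1 assumed to match the layer-comparison parameterization (not stated with the diagram itself)")

  sc$phase_diagram_ntf2 <- list(
    description = "Same map for an NTF2-sized particle (v_bar = 40); collapse is deeper and sets in at weaker attraction.",
    params = interaction_params(chi = -100, chi_cr = -1, v_bar = 40,
                                l = 1, b = 1.52),
    a_grid = seq(2.5, 6, by = 0.5),
    chi_grid = seq(-400, -25, by = 25),
    c_max_uM = 1,
    provenance = "as phase_diagram_kap with v_bar = 40")

  sc$phase_diagram_alt <- list(
    description = "Sensitivity check of the collapse/swelling map with a different monomer choice (l = 0.75 nm, b = 1.4 nm, particle volume 124 nm^3, chi_cr = -1); the three-region topology is unchanged.",
    params = interaction_params(chi = -200, chi_cr = -1,
                                v_bar = 124 / 0.75^3, l = 0.75, b = 1.4),
    a_grid = seq(2.5, 6, by = 0.5),
    chi_grid = seq(-900, -100, by = 80),
    c_max_uM = 1,
    provenance = "alternative monomer parameterization l = 0.75 nm, b = 1.4 nm, v = 124 nm^3, chi_cr = -1")

  sc$layer_kap_ntf2 <- list(
    description = "Kap-beta1 vs NTF2 on an Nsp1-like layer: ranges of grafting distance and interaction strength for the two particle sizes.",
    params = interaction_params(chi = -180, chi_cr = -1, v_bar = 125,
                                l = 1, b = 1.52),
    kap = list(v_bar = 125, chi_range = c(-185, -175)),
    ntf2 = list(v_bar = 40, chi_range = c(-73, -63)),
    a_range = c(3.5, 4),
    provenance = "b = 1.52 nm, l = 1 nm, chi_cr = -1; binding-strength bands inferred from layer adsorption data")

  sc$binary_coexistence <- list(
    description = "Phase separation of Nup98-like FG nup solutions (no proteins): coexistence boundaries for N = 125 and N = 167 monomer chains.",
    params = interaction_params(chi = 0, chi_cr = -1.5, v_bar = 125,
                                l = 1, b = 1.52, N = 167, z = 0.625),
    N_values = c(125, 167),
    chi_cr = -1.5,
    provenance = "l = 1 nm, b = 1.52 nm (~4 amino acids per monomer); chi_cr = -1.5 inferred from the coexistence data; z = 0.625")

  sc$binary_coexistence_alt <- list(
    description = "Binary coexistence with a smaller monomer (v0 = 0.75 nm^3, ~3-4 amino acids) and packing fraction z = 0.75; N = 125, 167, 182.",
    params = interaction_params(chi = 0, chi_cr = -1.5, v_bar = 125 / 0.75,
                                l = 0.75^(1 / 3), b = 1.52, N = 167,
                                z = 0.75),
    N_values = c(125, 167, 182),
    provenance = "monomer volume 0.75 nm^3 and z = 0.75 accommodate additional FG nup species")

  sc$coil_dimensions <- list(
    description = "Relative dimensions of individual FG nup coils vs cohesion for chains of N = 43, 108, 137, 152 monomers; captures the extended/collapsed bimodality.",
    params = interaction_params(l = 1, b = 1.52),
    N_values = c(43, 108, 137, 152),
    chi_cr_grid = seq(0, -3, by = -0.1),
    provenance = "four amino acids per monomer; predictions depend only on l/b, not on the monomer volume")

  sc$ternary_coexistence <- list(
    description = "Two-phase region of an FG nup / transport-protein mixture, Imp-beta with a Nup98-like chain: N = 167, v_bar = 125, chi = -200, chi_cr = -1.5.",
    params = interaction_params(chi = -200, chi_cr = -1.5, v_bar = 125,
                                l = 1, b = 1.52, N = 167),
    provenance = "N = 167, v_bar = 125, chi = -200, chi_cr = -1.5 (chi/v_bar = -1.6)")

  sc$partitioning <- list(
    description = "Partitioning of transport proteins and cargo complexes into the dense phase of a Nup98-like FG nup solution (5 uM chains, 1 uM protein).",
    params = interaction_params(chi = -215, chi_cr = -1.5, v_bar = 125,
                                l = 1, b = 1.52, N = 167, z = 0.625),
    species = partitioning_species(),
    polymer_uM = 5,
    protein_uM = 1,
    provenance = "chain parameters from binary_coexistence; species volumes partly assumed from molecular masses (see partitioning_species)")

  sc$layer_nup98 <- list(
    description = "Nup98-like grafted layer adsorbing Kap-beta1: a = 3.95-4.45 nm, chi = -188 to -186, chi_cr = -1.5.",
    params = interaction_params(chi = -187, chi_cr = -1.5, v_bar = 125,
                                l = 1, b = 1.52),
    a_range = c(3.95, 4.45),
    chi_range = c(-188, -186),
    provenance = "b = 1.52 nm, l = 1 nm; layer parameters consistent with the bulk coexistence of the same FG nup")

  sc
}

#' Named parameter scenarios
#'
#' `fg_scenario()` returns a frozen, read-only bundle of model parameters
#' for one of the package's worked analyses; `fg_scenario_names()` lists
#' the available names.  Every scenario carries a `provenance` string
#' saying where its numbers come from; values that are assumptions rather
#' than measurements are flagged as such.
#'
#' @param name scenario name (see `fg_scenario_names()`).
#' @return A list with at least `description`, `params`
#'   (an [interaction_params()]) and `provenance`; scenario-specific grids
#'   (`a_grid`, `chi_cr_grid`, `c_grid`, `species`, ...) as applicable.
#' @export
#' @examples
#' fg_scenario_names()
#' fg_scenario("binary_coexistence")$params
fg_scenario <- function(name) {
  db <- scenario_db()
  if (!is.character(name) || length(name) != 1 || is.na(name) ||
      !name %in% names(db))
    fg_domain_error(paste0(
      "unknown scenario", if (is.character(name) && length(name) == 1)
        paste0(" '", name, "'") else "",
      "; available: ", paste(names(db), collapse = ", ")))
  c(db[[name]], list(name = name))
}

#' @rdname fg_scenario
#' @export
fg_scenario_names <- function() names(scenario_db())
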