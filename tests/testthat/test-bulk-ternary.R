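# Ternary coexistence: tie-lines, the two-phase region and partitioning.

p_imp <- interaction_params(chi = -200, chi_cr = -1.5, v_bar = 125, N = 167)

test_that("tie-lines satisfy coexistence equations and the lever rule", {
  ov <- composition(8e-4, 1.2e-4)
  tl <- ternary_tie_line(p_imp, ov)
  expect_identical(tl$status, "two-phase")
  expect_true(all(tl$residuals[c("mu_polymer", "mu_protein", "pi")] < 1e-8))
  # componentwise mass balance to 1e-10
  fr <- tl$dense_fraction
  expect_lt(abs(fr * tl$dense[["psi"]] + (1 - fr) * tl$dilute[["psi"]] -
                  ov$psi), 1e-10)
  expect_lt(abs(fr * tl$dense[["phi"]] + (1 - fr) * tl$dilute[["phi"]] -
                  ov$phi), 1e-10)
  expect_gte(tl$dense[["psi"]], tl$dilute[["psi"]])
  # direct equality of potentials, recomputed through the public API
  mu_d <- chemical_potential_polymer(composition(tl$dilute["psi"],
                                                 tl$dilute["phi"]), p_imp)
  mu_D <- chemical_potential_polymer(composition(tl$dense["psi"],
                                                 tl$dense["phi"]), p_imp)
  expect_lt(abs(mu_d - mu_D), 1e-8)
})

test_that("tie-lines agree with the tangent-plane (common tangent) construction", {
  tl <- ternary_tie_line(p_imp, composition(8e-4, 1.2e-4))
  tp <- tangent_plane_gap(tl, p_imp)
  # the dense phase lies on the dilute phase's tangent plane ...
  expect_lt(abs(tp$dense_gap), 1e-8)
  # ... and no sampled composition lies below it (global stability)
  expect_gt(tp$min_gap, -1e-9)
})

test_that("a non-interacting protein is excluded from the dense phase", {
  p0 <- p_imp
  p0$chi <- 0
  tl <- ternary_tie_line(p0, composition(8e-4, 3e-5))
  expect_identical(tl$status, "two-phase")
  expect_lt(tl$dense[["phi"]], tl$dilute[["phi"]])
})

test_that("stronger attraction loads the dense phase with more protein", {
  phis <- vapply(c(-180, -200, -260), function(chi) {
    p <- p_imp
    p$chi <- chi
    ternary_tie_line(p, composition(8e-4, 1e-4))$dense[["phi"]]
  }, numeric(1))
  expect_true(all(diff(phis) > 0))
})

test_that("high protein concentrations re-dissolve the dense phase", {
  expect_identical(ternary_tie_line(p_imp, composition(8e-4, 1e-4))$status,
                   "two-phase")
  expect_identical(ternary_tie_line(p_imp, composition(8e-4, 0.3))$status,
                   "single-phase")
})

test_that("single-phase compositions and subcritical cohesion are reported, not errors", {
  # overall polymer content above the dense binodal branch
  tl_dense <- ternary_tie_line(p_imp, composition(0.6, 1e-4))
  expect_identical(tl_dense$status, "single-phase")
  p_weak <- interaction_params(chi = -50, chi_cr = -0.5, v_bar = 125, N = 167)
  expect_identical(ternary_tie_line(p_weak, composition(8e-4, 1e-4))$status,
                   "single-phase")
  expect_error(ternary_tie_line(p_imp, composition(0, 1e-4)),
               class = "fgnupfield_domain_error")
})

test_that("phase-region map is empty for weak interactions and marks a boundary otherwise", {
  p_weak <- interaction_params(chi = -20, chi_cr = -0.5, v_bar = 125, N = 167)
  reg0 <- ternary_phase_region(p_weak, psi_grid = c(1e-4, 1e-2, 0.2),
                               phi_grid = c(1e-4, 1e-2, 0.2))
  expect_true(all(!reg0$grid$two_phase, na.rm = TRUE))
  expect_identical(nrow(reg0$boundary), 0L)
  reg <- ternary_phase_region(p_imp,
                              psi_grid = 10^seq(-4, -0.5, length.out = 4),
                              phi_grid = 10^seq(-4, -0.5, length.out = 4))
  expect_true(any(reg$grid$two_phase, na.rm = TRUE))
  expect_true(any(!reg$grid$two_phase, na.rm = TRUE))
  expect_gt(nrow(reg$boundary), 0)
  expect_gt(length(reg$tie_lines), 0)
})

test_that("partition report resolves one species at a time with conserved mass", {
  fg <- interaction_params(chi_cr = -1.5, N = 167, l = 1, z = 0.625)
  two <- partitioning_species()[c(1, 6), ]   # NTF2 and the inert control
  rep <- partition_report(two, fg)
  expect_identical(rep$status, rep(c("two-phase"), 2))
  expect_true(rep$partitions_in[rep$name == "NTF2"])
  expect_false(rep$partitions_in[rep$name == "TEV-mCherry"])
  expect_true(all(rep$max_residual < 1e-8))
  expect_gt(rep$partition_coefficient[1], 1)
  expect_lt(rep$partition_coefficient[2], 1)
})
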