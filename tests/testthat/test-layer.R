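# Grafted-layer grand potential, equilibrium solver and derived curves.

ia_fine <- interaction_params(chi = -550, chi_cr = -1.1,
                              v_bar = 125 / 0.67^3, l = 0.67, b = 1)
ia_brush <- interaction_params(chi = 0, chi_cr = 0, l = 1, b = 1.52)

test_that("grand potential matches a frozen symbolic evaluation", {
  # sigma_bar = 0.04 -> a = l / 0.2; h_bar = 0.2, phi = 0.05, c = 1e-6
  lp <- layer_params(ia_fine, a = ia_fine$l / 0.2)
  expect_equal(lp$sigma_bar, 0.04, tolerance = 1e-12)
  expect_equal(layer_grand_potential(0.2, 0.05, lp, c = 1e-6),
               -0.0264150856261674, tolerance = 1e-10)
})

test_that("protein-free grand potential is independent of chi", {
  ia2 <- ia_fine
  ia2$chi <- -5
  h <- c(0.1, 0.3, 0.7)
  expect_equal(layer_grand_potential(h, 0, layer_params(ia_fine, 5), c = 0),
               layer_grand_potential(h, 0, layer_params(ia2, 5), c = 0))
})

test_that("dilute protein-free layer reduces to the two-term brush energy", {
  lp <- layer_params(ia_brush, a = 20)
  K <- lp$sigma_bar * ia_brush$l / ia_brush$b
  h <- 0.12
  psi <- K / h
  two_term <- 0.5 * K * h^2 + h * (-psi + psi^2 / 2)
  expect_lt(abs(layer_grand_potential(h, 0, lp, 0) - two_term),
            h * psi^3)   # next order of the log expansion
})

test_that("infeasible heights and invalid reservoirs raise distinct errors", {
  lp <- layer_params(ia_brush, a = 2)
  K <- lp$sigma_bar * ia_brush$l / ia_brush$b
  expect_error(layer_grand_potential(K * 0.5, 0, lp, 0),
               class = "fgnupfield_infeasible_error")
  expect_error(layer_grand_potential(0.5, -0.1, lp, 0),
               class = "fgnupfield_domain_error")
  expect_error(solve_layer_equilibrium(lp, c = 1),
               class = "fgnupfield_domain_error")
})

test_that("empty reservoir gives the protein-free minimizer with phi = 0", {
  lp <- layer_params(ia_fine, a = 5)
  eq <- solve_layer_equilibrium(lp, c = 0)
  expect_identical(eq$phi, 0)
  # 1-D check against a dense independent scan of the profile
  oracle <- grid_layer_oracle(lp, c = 0)
  expect_equal(eq$h_bar, oracle$h_bar, tolerance = 3 * max(oracle$dh0, 1e-4))
  expect_lte(eq$objective, oracle$value + 1e-10)
})

test_that("ideal dilute brush approaches the closed-form height", {
  lp <- layer_params(ia_brush, a = 30)
  eq <- solve_layer_equilibrium(lp, c = 0)
  h_closed <- (lp$sigma_bar * ia_brush$l / (2 * ia_brush$b))^(1 / 3)
  expect_equal(eq$h_bar, h_closed, tolerance = 0.02)
})

test_that("optimizer matches the exhaustive 2-D grid oracle on random instances", {
  set.seed(42)
  for (k in 1:10) {
    ia <- interaction_params(chi = runif(1, -400, -50),
                             chi_cr = runif(1, -1.5, 0),
                             v_bar = sample(c(40, 125), 1),
                             l = 1, b = 1.52)
    lp <- layer_params(ia, a = runif(1, 2.5, 8))
    cv <- 10^runif(1, -7, -4)
    eq <- solve_layer_equilibrium(lp, c = cv)
    oracle <- grid_layer_oracle(lp, c = cv)
    expect_equal(eq$h_bar, oracle$h_bar,
                 tolerance = 3 * max(oracle$dh0, 1e-4))
    expect_lte(eq$objective, oracle$value + 1e-9)
  }
})

test_that("solutions conserve monomers and match the reservoir potential", {
  set.seed(43)
  for (k in 1:6) {
    ia <- interaction_params(chi = runif(1, -500, -100),
                             chi_cr = runif(1, -1.2, 0),
                             v_bar = 125, l = 1, b = 1.52)
    lp <- layer_params(ia, a = runif(1, 3, 6))
    cv <- 10^runif(1, -7, -4)
    eq <- solve_layer_equilibrium(lp, c = cv)
    K <- lp$sigma_bar * ia$l / ia$b
    expect_lt(abs(eq$psi * eq$h_bar - K), 1e-10)
    mu_in <- chemical_potential_protein(composition(eq$psi, eq$phi), ia)
    expect_lt(abs(mu_in - log(cv)), 1e-8)
    expect_true(eq$free_space > 0 && eq$free_space < 1)
  }
})

test_that("normalized results are independent of the contour length L", {
  ia <- interaction_params(chi = -200, chi_cr = -0.8, v_bar = 125,
                           l = 1, b = 1.52)
  e1 <- solve_layer_equilibrium(layer_params(ia, 4, L = 100), c = 1e-5)
  e2 <- solve_layer_equilibrium(layer_params(ia, 4, L = 200), c = 1e-5)
  expect_equal(e1$h_bar, e2$h_bar, tolerance = 1e-9)
  expect_equal(e1$phi, e2$phi, tolerance = 1e-9)
  expect_equal(e2$h_nm, 2 * e1$h_nm, tolerance = 1e-9)
})

test_that("cohesion compacts the protein-free layer monotonically", {
  heights <- vapply(c(0, -0.5, -1, -1.8, -2.5), function(ccr) {
    ia <- interaction_params(chi_cr = ccr, l = 1, b = 1.52)
    solve_layer_equilibrium(layer_params(ia, 4), c = 0)$h_bar
  }, numeric(1))
  expect_true(all(diff(heights) < 0))
})

test_that("height-vs-grafting curves decay with a and ignore L", {
  a_grid <- exp(seq(log(2), log(10), length.out = 9))
  crv <- height_vs_grafting(ia_brush, a_grid)
  expect_true(all(diff(crv$h_bar) < 0))
  crv2 <- height_vs_grafting(ia_brush, a_grid, L = 999)
  expect_equal(crv$h_bar, crv2$h_bar, tolerance = 1e-9)
  expect_error(height_vs_grafting(ia_brush, c(3, 2, 5)),
               class = "fgnupfield_domain_error")
})

test_that("scaling exponent fit: windows, degeneracy, dilute convergence", {
  crv <- height_vs_grafting(ia_brush,
                            exp(seq(log(2), log(10), length.out = 9)))
  g_all <- scaling_exponent_g(crv, window = NULL)
  expect_gt(g_all, 2 / 3)
  flat <- data.frame(a_nm = 1:6, h_bar = rep(0.3, 6))
  expect_error(scaling_exponent_g(flat, window = NULL),
               class = "fgnupfield_domain_error")
  expect_error(scaling_exponent_g(crv[1:3, ], window = NULL),
               class = "fgnupfield_domain_error")
  # the effective exponent decays towards the asymptotic 2/3 as the fit
  # window moves to sparser grafting
  g_near <- height_scaling_exponent(ia_brush, window = c(2, 10), n_points = 9)
  g_far <- height_scaling_exponent(ia_brush, window = c(40, 160), n_points = 9)
  expect_gt(g_near, g_far)
  expect_equal(g_far, 2 / 3, tolerance = 0.01)
})

test_that("response curve is continuous at vanishing concentration", {
  lp <- layer_params(ia_fine, a = 5)
  out <- layer_response_curve(lp, c(1e-12, 1e-10))
  expect_equal(out$h_rel[1], 1, tolerance = 1e-4)
  expect_error(layer_response_curve(lp, c(1e-5, 1e-6)),
               class = "fgnupfield_domain_error")
})

test_that("phase diagram marks inert cells at zero attraction", {
  ia <- interaction_params(chi = 0, chi_cr = -1, v_bar = 125, l = 1, b = 1.52)
  pd <- layer_phase_diagram(ia, a_grid = c(3, 5), chi_grid = c(0, -50),
                            c_max = 1.2e-4, n_c = 6)
  expect_true(all(pd$status == "ok"))
  inert <- pd[pd$chi == 0, ]
  expect_equal(inert$h_min_rel, rep(1, nrow(inert)), tolerance = 1e-4)
  expect_true(all(inert$region == "inert"))
})

test_that("cohesion recovery tolerates 5% multiplicative height noise", {
  ia <- interaction_params(chi_cr = -1.4, l = 1, b = 1.52)
  a_grid <- exp(seq(log(2.5), log(9), length.out = 8))
  crv <- height_vs_grafting(ia, a_grid)
  set.seed(1234)
  noisy <- crv
  noisy$h_bar <- crv$h_bar * (1 + 0.05 * rnorm(nrow(crv)))
  fit <- fit_cohesion(noisy, ia_brush, interval = c(-3, 0))
  expect_lt(abs(fit$chi_cr - (-1.4)), 0.15)
  expect_identical(fit$status, "ok")
})
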