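# Mixing free energy, chemical potentials and osmotic pressure.

p_ideal <- interaction_params(chi = 0, chi_cr = 0, v_bar = 1, N = 1)
p_kap <- interaction_params(chi = -200, chi_cr = -1.5, v_bar = 125, N = 125)

test_that("mixing free energy reproduces hand and symbolic evaluations", {
  expect_identical(mixing_free_energy(composition(0, 0), p_kap), 0)
  # two-component ideal mixture (v_bar = 1, no interactions)
  expect_equal(mixing_free_energy(composition(0, 0.5), p_ideal), log(0.5),
               tolerance = 1e-14)
  # frozen value from an independent symbolic-algebra evaluation
  expect_equal(mixing_free_energy(composition(0.3, 0.2), p_kap),
               -0.335561968616910353, tolerance = 1e-12)
})

test_that("bulk free energy = mixing + chain translational entropy", {
  # psi = 0 kills the chain term
  expect_equal(bulk_free_energy(composition(0, 0.3), p_kap),
               mixing_free_energy(composition(0, 0.3), p_kap))
  # N -> infinity recovers the mixing form pointwise
  p_inf <- interaction_params(chi = -200, chi_cr = -1.5, v_bar = 125,
                              N = 1e12)
  comp <- composition(c(0.05, 0.3, 0.6), c(0.02, 0.1, 0.05))
  expect_equal(bulk_free_energy(comp, p_inf), mixing_free_energy(comp, p_inf),
               tolerance = 1e-9)
  # frozen symbolic value at phi = 0
  expect_equal(bulk_free_energy(composition(0.4, 0), p_kap),
               -0.429427504601591706, tolerance = 1e-12)
  # identity on a stratified sample
  set.seed(11)
  psi <- runif(40, 1e-4, 0.9)
  phi <- runif(40) * (1 - psi) * 0.95
  expect_equal(bulk_free_energy(composition(psi, phi), p_kap) -
                 mixing_free_energy(composition(psi, phi), p_kap),
               psi * log(psi) / p_kap$N, tolerance = 1e-13)
})

test_that("compositions outside the simplex are rejected", {
  expect_error(composition(-0.1, 0.2), class = "fgnupfield_domain_error")
  expect_error(composition(0.6, 0.4), class = "fgnupfield_domain_error")
  expect_error(composition(0.5, NA), class = "fgnupfield_domain_error")
  # boundary values psi = 0 / phi = 0 are fine and finite everywhere
  vals <- c(mixing_free_energy(composition(0, 0), p_kap),
            mixing_free_energy(composition(0.3, 0), p_kap),
            bulk_free_energy(composition(0, 0.2), p_kap),
            osmotic_pressure(composition(0, 0), p_kap))
  expect_true(all(is.finite(vals)))
})

test_that("protein chemical potential: dilute limit, FD, and chi slope", {
  # mu -> log(phi) as the mixture empties (ideal-reservoir normalization)
  p1 <- interaction_params(chi = 0, chi_cr = 0, v_bar = 1)
  phi <- 1e-6
  expect_lt(abs(chemical_potential_protein(composition(0, phi), p1) -
                  log(phi)), 5e-6)
  # analytic derivative agrees with central differences of v_bar * f
  set.seed(7)
  for (k in 1:20) {
    psi <- runif(1, 0.01, 0.7)
    phi <- runif(1, 0.01, 0.95 * (1 - psi))
    mu_fd <- p_kap$v_bar *
      fd_central(function(x) mixing_free_energy(composition(psi, x), p_kap),
                 phi, h = 1e-6)
    mu <- chemical_potential_protein(composition(psi, phi), p_kap)
    expect_equal(mu, mu_fd, tolerance = 1e-7)
  }
  # d mu / d chi = psi exactly (per-protein convention)
  dchi <- 1e-3
  pa <- interaction_params(chi = -200 + dchi, chi_cr = -1.5, v_bar = 125)
  pb <- interaction_params(chi = -200 - dchi, chi_cr = -1.5, v_bar = 125)
  slope <- (chemical_potential_protein(composition(0.3, 0.2), pa) -
              chemical_potential_protein(composition(0.3, 0.2), pb)) /
    (2 * dchi)
  expect_equal(slope, 0.3, tolerance = 1e-10)
})

test_that("polymer chemical potential: FD agreement, cohesion slope, dilute sign", {
  set.seed(8)
  for (k in 1:20) {
    psi <- runif(1, 0.01, 0.7)
    phi <- runif(1, 0.01, 0.95 * (1 - psi))
    mu_fd <- fd_central(function(x)
      bulk_free_energy(composition(x, phi), p_kap), psi, h = 1e-6)
    expect_equal(chemical_potential_polymer(composition(psi, phi), p_kap),
                 mu_fd, tolerance = 1e-7)
  }
  # d mu_polymer / d chi_cr = psi (from the chi_cr psi^2 / 2 term)
  d <- 1e-3
  pa <- interaction_params(chi_cr = -1.5 + d, v_bar = 125, N = 125)
  pb <- interaction_params(chi_cr = -1.5 - d, v_bar = 125, N = 125)
  slope <- (chemical_potential_polymer(composition(0.4, 0), pa) -
              chemical_potential_polymer(composition(0.4, 0), pb)) / (2 * d)
  expect_equal(slope, 0.4, tolerance = 1e-9)
  # dilute divergence ~ log(psi) / N: negative and growing in magnitude
  mus <- chemical_potential_polymer(composition(c(1e-8, 1e-16), 0), p_kap)
  expect_true(all(mus < 0) && mus[2] < mus[1])
  expect_equal(mus[2] - mus[1], log(1e-16 / 1e-8) / p_kap$N,
               tolerance = 1e-6)
})

test_that("osmotic pressure: ideal limits and Gibbs-Duhem consistency", {
  expect_identical(osmotic_pressure(composition(0, 0), p_kap), 0)
  # van 't Hoff law for a dilute protein solution
  phi <- 1e-7
  expect_equal(osmotic_pressure(composition(0, phi), p_kap),
               phi / p_kap$v_bar, tolerance = 1e-3)
  # Gibbs-Duhem: dPi = psi dmu_polymer + (phi / v_bar) dmu_protein along
  # any composition direction
  set.seed(9)
  for (k in 1:50) {
    psi <- runif(1, 0.02, 0.7)
    phi <- runif(1, 0.02, 0.9 * (1 - psi))
    dir <- runif(2, -1, 1)
    h <- 1e-6
    num <- function(f) (f(psi + h * dir[1], phi + h * dir[2]) -
                          f(psi - h * dir[1], phi - h * dir[2])) / (2 * h)
    dPi <- num(function(a, b)
      osmotic_pressure(composition(a, b), p_kap, bulk = TRUE))
    dmu_p <- num(function(a, b)
      chemical_potential_polymer(composition(a, b), p_kap))
    dmu_f <- num(function(a, b)
      chemical_potential_protein(composition(a, b), p_kap))
    expect_lt(abs(dPi - (psi * dmu_p + phi / p_kap$v_bar * dmu_f)), 1e-8)
  }
})

test_that("degenerate symmetric mixture is psi/phi exchange symmetric", {
  p_sym <- interaction_params(chi = 0, chi_cr = 0, v_bar = 1, N = 1)
  set.seed(10)
  psi <- runif(20, 0.01, 0.8)
  phi <- runif(20) * (1 - psi) * 0.9
  expect_equal(bulk_free_energy(composition(psi, phi), p_sym),
               bulk_free_energy(composition(phi, psi), p_sym),
               tolerance = 1e-13)
})
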