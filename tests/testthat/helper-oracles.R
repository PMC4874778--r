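# Independent oracles used across the suite.  Each deliberately avoids the
# implementation path it checks: derivatives are verified by central
# differences of the energy, optimizers by exhaustive scans, and
# coexistence solvers by direct tangent constructions on dense grids.

# central finite difference of a scalar function
fd_central <- function(f, x, h = 1e-6) (f(x + h) - f(x - h)) / (2 * h)

# Exhaustive 2-D scan of the layer grand potential over (h_bar, phi),
# refined `refine` times around the incumbent minimum.
grid_layer_oracle <- function(lp, c, n = 400, refine = 2) {
  K <- lp$sigma_bar * lp$interaction$l / lp$interaction$b
  omega <- function(h, p) {
    psi <- K / h
    ifelse(psi + p >= 1 - 1e-12, Inf,
           layer_grand_potential(h, ifelse(psi + p >= 1 - 1e-12, 0, p),
                                 lp, c))
  }
  lh <- c(log(K / 0.995), log(2))
  dh0 <- diff(lh) / (n - 1)   # resolution of the first sweep
  lp_rng <- if (c > 0) c(log(1e-16), log(1 - 1e-6)) else NULL
  best <- NULL
  for (r in seq_len(refine + 1)) {
    hs <- exp(seq(lh[1], lh[2], length.out = n))
    if (c > 0) {
      ps <- exp(seq(lp_rng[1], lp_rng[2], length.out = n))
      vals <- outer(hs, ps, omega)
      idx <- arrayInd(which.min(vals), dim(vals))
      best <- list(h_bar = hs[idx[1]], phi = ps[idx[2]],
                   value = vals[idx[1], idx[2]],
                   dh = diff(log(hs))[1], dp = diff(log(ps))[1])
      i <- idx[1]; j <- idx[2]
      lh <- log(hs[c(max(1, i - 2), min(n, i + 2))])
      lp_rng <- log(ps[c(max(1, j - 2), min(n, j + 2))])
      best$dh0 <- dh0
    } else {
      vals <- omega(hs, 0)
      i <- which.min(vals)
      best <- list(h_bar = hs[i], phi = 0, value = vals[i],
                   dh = diff(log(hs))[1], dp = 0)
      lh <- log(hs[c(max(1, i - 2), min(n, i + 2))])
      best$dh0 <- dh0
    }
  }
  best
}

# Golden-section minimizer (independent of stats::optimize).
golden_section <- function(f, lo, hi, tol = 1e-10) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - gr * (b - a)
  c2 <- a + gr * (b - a)
  f1 <- f(c1); f2 <- f(c2)
  while (abs(b - a) > tol * (abs(a) + abs(b))) {
    if (f1 < f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- f(c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- f(c2)
    }
  }
  (a + b) / 2
}

# Common-tangent construction for the binary free energy on a dense grid:
# the lower convex hull of (psi, f(psi)); the coexistence interval is the
# hull facet spanning the largest composition gap.
common_tangent_binary <- function(N, chi_cr, n = 1e5) {
  psi <- exp(seq(log(1e-9), log(1 - 1e-3), length.out = n))
  f <- bulk_free_energy(composition(psi, 0),
                        interaction_params(chi_cr = chi_cr, N = N))
  # Andrew monotone-chain lower hull on (psi, f)
  hull <- integer(0)
  for (i in seq_along(psi)) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      cross <- (psi[b] - psi[a]) * (f[i] - f[a]) -
        (f[b] - f[a]) * (psi[i] - psi[a])
      if (cross <= 0) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, i)
  }
  gaps <- diff(psi[hull])
  k <- which.max(gaps)
  list(psi_dilute = psi[hull[k]], psi_dense = psi[hull[k + 1]],
       log_step = diff(log(psi))[1])
}

# Tangent-plane stability check for a ternary tie-line: the plane tangent
# to the bulk free energy at the dilute phase must (a) touch the dense
# phase and (b) lie below the free energy everywhere in the simplex.
tangent_plane_gap <- function(tl, params, n = 150) {
  d <- tl$dilute
  mu_psi <- chemical_potential_polymer(composition(d["psi"], d["phi"]), params)
  mu_phi_density <- chemical_potential_protein(
    composition(d["psi"], d["phi"]), params) / params$v_bar
  f_d <- bulk_free_energy(composition(d["psi"], d["phi"]), params)
  plane <- function(psi, phi) {
    f_d + mu_psi * (psi - d[["psi"]]) + mu_phi_density * (phi - d[["phi"]])
  }
  psi <- exp(seq(log(1e-8), log(0.95), length.out = n))
  phi <- exp(seq(log(1e-8), log(0.95), length.out = n))
  gr <- expand.grid(psi = psi, phi = phi)
  gr <- gr[gr$psi + gr$phi < 0.999, ]
  f <- bulk_free_energy(composition(gr$psi, gr$phi), params)
  list(min_gap = min(f - plane(gr$psi, gr$phi)),
       dense_gap = bulk_free_energy(composition(tl$dense["psi"],
                                                tl$dense["phi"]), params) -
         plane(tl$dense[["psi"]], tl$dense[["phi"]]))
}
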