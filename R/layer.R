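# Equilibrium of a surface-grafted FG nup layer in contact with a dilute
# transport-protein reservoir.
#
# The layer is treated as a box of uniform composition: chains grafted a
# distance `a` apart, each of contour length L = N*b, with the average
# height h normalized as h_bar = h/L.  Monomer bookkeeping fixes
# psi * h_bar = sigma_bar * l / b with sigma_bar = (l/a)^2, so the layer
# state is the pair (h_bar, phi).  The grand potential per unit area, in
# units of kT * L / l^3, is
#
#   Omega(h_bar, phi) = pref * sigma_bar * (l/b) * h_bar^2
#                       + h_bar * [ f(psi, phi) - phi * log(c) / v_bar ]
#
# with pref = 1/2 (Gaussian stretching) and f the mixing free-energy
# density.  Equilibrium minimizes Omega over h_bar and phi; at the solution
# the in-layer protein chemical potential equals log(c).  All normalized
# results are independent of L, which only scales dimensional heights.

#' Grafted-layer parameters
#'
#' @param interaction an [interaction_params()].
#' @param a grafting distance in nm (anchor spacing); the normalized
#'   grafting density is `sigma_bar = (l/a)^2`.
#' @param L chain contour length in nm, used only to report dimensional
#'   heights `h = h_bar * L`.  Defaults to `N * b` (one monomer per Kuhn
#'   segment of contour).
#' @param elastic_prefactor numeric prefactor of the Gaussian stretching
#'   term (default `1/2`).  The classical alternative `3/2` changes
#'   heights by a constant factor but no scaling exponent or phase-diagram
#'   topology.
#' @param include_reservoir_work if `TRUE`, subtract the (tiny) osmotic
#'   work term `pi_c * h_bar` done against the reservoir pressure
#'   `pi_c = c / v_bar`; negligible at micromolar concentrations and off
#'   by default.
#' @return An object of class `"layer_params"`.
#' @export
#' @examples
#' p <- interaction_params(chi = -550, chi_cr = -0.8, v_bar = 125 / 0.67^3,
#'                         l = 0.67, b = 1)
#' layer_params(p, a = 5)
layer_params <- function(interaction, a, L = NULL, elastic_prefactor = 0.5,
                         include_reservoir_work = FALSE) {
  stopifnot(inherits(interaction, "interaction_params"))
  if (!is.finite(a) || a <= 0) fg_domain_error("grafting distance `a` must be > 0")
  if (is.null(L)) L <- interaction$N * interaction$b
  if (!is.finite(L) || L <= 0) fg_domain_error("contour length `L` must be > 0")
  structure(
    list(interaction = interaction, a = a, L = L,
         sigma_bar = (interaction$l / a)^2,
         elastic_prefactor = elastic_prefactor,
         include_reservoir_work = isTRUE(include_reservoir_work)),
    class = "layer_params")
}

#' @export
print.layer_params <- function(x, ...) {
  cat(sprintf("Grafted layer: a = %.3g nm (sigma_bar = %.4g), L = %.3g nm\n",
              x$a, x$sigma_bar, x$L))
  print(x$interaction)
  invisible(x)
}

# monomer-conservation constant K = sigma_bar * l / b = psi * h_bar
layer_K <- function(params) params$sigma_bar * params$interaction$l / params$interaction$b

#' Grand potential per unit area of a grafted layer
#'
#' Evaluates the layer free energy (elastic stretching plus mixing free
#' energy plus the reservoir exchange term) at prescribed normalized height
#' and protein content.  The monomer fraction follows from conservation,
#' `psi = sigma_bar * (l/b) / h_bar`.  Units: kT * L / l^3 per unit area.
#'
#' @param h_bar normalized layer height `h / L` (> 0); vectorized.
#' @param phi protein volume fraction inside the layer; vectorized.
#' @param params a [layer_params()].
#' @param c reservoir protein volume fraction in `[0, 1)`.
#' @return Numeric vector of grand-potential values.
#' @export
layer_grand_potential <- function(h_bar, phi, params, c = 0) {
  stopifnot(inherits(params, "layer_params"))
  if (any(!is.finite(h_bar)) || any(h_bar <= 0))
    fg_domain_error("`h_bar` must be positive")
  if (any(!is.finite(phi)) || any(phi < 0))
    fg_domain_error("`phi` must be non-negative")
  if (!is.finite(c) || c < 0 || c >= 1)
    fg_domain_error("reservoir fraction `c` must lie in [0, 1)")
  if (c == 0 && any(phi > 0))
    fg_domain_error("phi > 0 requires a non-empty reservoir (c > 0)")
  K <- layer_K(params)
  psi <- K / h_bar
  if (any(psi + phi >= 1))
    fg_infeasible_error(
      "layer too thin: psi + phi >= 1 at the requested height",
      data = list(h_bar = h_bar, phi = phi))
  ia <- params$interaction
  mu_c <- if (c > 0) log(c) else 0   # phi = 0 whenever c = 0 (checked above)
  om <- params$elastic_prefactor * K * h_bar^2 +
    h_bar * (fe_mix(psi, phi, ia$chi, ia$chi_cr, ia$v_bar) -
               phi * mu_c / ia$v_bar)
  if (params$include_reservoir_work) om <- om + (c / ia$v_bar) * h_bar
  om
}

# Unvalidated kernel used by the solver grids: returns Inf outside the
# feasible set instead of raising.
layer_omega_kernel <- function(h_bar, phi, K, pref, chi, chi_cr, v_bar,
                               mu_c, pi_c = 0) {
  psi <- K / h_bar
  bad <- psi + phi >= 1
  om <- pref * K * h_bar^2 +
    h_bar * (fe_mix(pmin(psi, 1 - phi), phi, chi, chi_cr, v_bar) -
               phi * mu_c / v_bar) + pi_c * h_bar
  om[bad] <- Inf
  om
}

# Best phi at fixed h_bar: dense log-grid scan plus local refinement.
# Returns list(phi, value).  For c = 0 the optimum is phi = 0.
layer_best_phi <- function(h_bar, K, pref, chi, chi_cr, v_bar, mu_c, pi_c,
                           c, n_phi = 81) {
  psi <- K / h_bar
  if (psi >= 1 - 1e-12) return(list(phi = NA_real_, value = Inf))
  if (c == 0) {
    return(list(phi = 0,
                value = layer_omega_kernel(h_bar, 0, K, pref, chi, chi_cr,
                                           v_bar, mu_c, pi_c)))
  }
  lphi <- seq(log(1e-200), log((1 - psi) * (1 - 1e-10)), length.out = n_phi)
  vals <- layer_omega_kernel(h_bar, exp(lphi), K, pref, chi, chi_cr, v_bar,
                             mu_c, pi_c)
  i <- which.min(vals)
  lo <- lphi[max(1L, i - 1L)]
  hi <- lphi[min(n_phi, i + 1L)]
  op <- stats::optimize(
    function(t) layer_omega_kernel(h_bar, exp(t), K, pref, chi, chi_cr,
                                   v_bar, mu_c, pi_c),
    c(lo, hi), tol = 1e-12)
  list(phi = exp(op$minimum), value = op$objective)
}

#' Solve the grafted-layer equilibrium
#'
#' Finds the global minimizer of the layer grand potential over the
#' normalized height `h_bar` and the in-layer protein fraction `phi`,
#' subject to monomer conservation `psi * h_bar = sigma_bar * l / b`.
#' The search combines a dense logarithmic scan over `h_bar` (with an inner
#' one-dimensional protein-content minimization at every height) with local
#' refinement and a Newton polish of the stationarity conditions; among
#' near-degenerate minima the larger height wins.  At the solution with
#' `phi > 0` the in-layer protein chemical potential equals the reservoir
#' value `log(c)`.
#'
#' @param params a [layer_params()].
#' @param c reservoir protein volume fraction in `[0, 1)`; `c = 0` gives
#'   the protein-free layer.
#' @param control list of solver knobs: `n_h`, `n_phi` (grid sizes),
#'   `h_max` (upper bracket for `h_bar`), `tol` (stationarity residual
#'   target).
#' @param warm optional previous solution (a `"layer_equilibrium"` or
#'   `list(h_bar, phi)`) used as an extra candidate when tracking a branch
#'   along a concentration or parameter sweep.
#' @return An object of class `"layer_equilibrium"`: fields `h_bar`, `psi`,
#'   `phi`, `free_space`, `uptake_per_monomer` (`phi / (v_bar * psi)`),
#'   `h_nm`, `objective`, `c`, `residuals` (height stationarity and
#'   chemical-potential match) and `diagnostics`.
#' @export
#' @examples
#' p <- layer_params(interaction_params(chi_cr = -0.8, l = 1, b = 1.52), a = 4)
#' solve_layer_equilibrium(p, c = 0)
solve_layer_equilibrium <- function(params, c = 0, control = list(),
                                    warm = NULL) {
  stopifnot(inherits(params, "layer_params"))
  if (!is.finite(c) || c < 0 || c >= 1)
    fg_domain_error("reservoir fraction `c` must lie in [0, 1)")
  ctl <- modifyList(list(n_h = 144, n_phi = 81, h_max = 2, tol = 1e-9), control)
  ia <- params$interaction
  K <- layer_K(params)
  pref <- params$elastic_prefactor
  mu_c <- if (c > 0) log(c) else 0
  pi_c <- if (params$include_reservoir_work) c / ia$v_bar else 0
  if (K >= ctl$h_max)
    fg_infeasible_error("grafting so dense that psi >= 1 at h_max")

  lh <- seq(log(K / 0.995), log(ctl$h_max), length.out = ctl$n_h)
  prof_val <- numeric(ctl$n_h)
  prof_phi <- numeric(ctl$n_h)
  for (i in seq_along(lh)) {
    r <- layer_best_phi(exp(lh[i]), K, pref, ia$chi, ia$chi_cr, ia$v_bar,
                        mu_c, pi_c, c, ctl$n_phi)
    prof_val[i] <- r$value
    prof_phi[i] <- if (is.na(r$phi)) 0 else r$phi
  }
  profile_min <- function(t) {
    layer_best_phi(exp(t), K, pref, ia$chi, ia$chi_cr, ia$v_bar,
                   mu_c, pi_c, c, ctl$n_phi)$value
  }
  # ties toward larger h_bar: among grid values within tolerance of the
  # minimum pick the rightmost, then refine locally
  vmin <- min(prof_val)
  cand_idx <- max(which(prof_val <= vmin + 1e-12 * (1 + abs(vmin))))
  refine <- function(i) {
    lo <- lh[max(1L, i - 1L)]
    hi <- lh[min(ctl$n_h, i + 1L)]
    op <- stats::optimize(profile_min, c(lo, hi), tol = 1e-13)
    op
  }
  best <- refine(cand_idx)
  if (!is.null(warm)) {
    wh <- if (inherits(warm, "layer_equilibrium")) warm$h_bar else warm$h_bar
    if (is.finite(wh) && wh > K && wh < ctl$h_max) {
      i_w <- which.min(abs(lh - log(wh)))
      alt <- refine(i_w)
      if (alt$objective < best$objective - 1e-12 ||
          (abs(alt$objective - best$objective) <= 1e-12 &&
           alt$minimum > best$minimum)) best <- alt
    }
  }
  h_bar <- exp(best$minimum)
  phi <- layer_best_phi(h_bar, K, pref, ia$chi, ia$chi_cr, ia$v_bar,
                        mu_c, pi_c, c, ctl$n_phi)$phi

  # Newton polish of the stationarity system; variables log(h_bar) [, log(phi)]
  stat_resid <- function(h_bar, phi) {
    psi <- K / h_bar
    w <- fe_mix(psi, phi, ia$chi, ia$chi_cr, ia$v_bar) -
      phi * mu_c / ia$v_bar
    g1 <- 2 * pref * K * h_bar + w -
      psi * dfe_dpsi_mix(psi, phi, ia$chi, ia$chi_cr, ia$v_bar) + pi_c
    if (c == 0) return(g1)
    g2 <- mu_protein_kernel(psi, phi, ia$chi, ia$chi_cr, ia$v_bar) - mu_c
    c(g1, g2)
  }
  if (c == 0) {
    pol <- mf_newton(function(x) stat_resid(exp(x[1]), 0), log(h_bar),
                     tol = ctl$tol)
    if (pol$converged) h_bar <- exp(pol$x[1])
    phi <- 0
  } else {
    pol <- mf_newton(function(x) stat_resid(exp(x[1]), exp(x[2])),
                     c(log(h_bar), log(max(phi, 1e-250))), tol = ctl$tol)
    if (pol$converged) {
      h_bar <- exp(pol$x[1])
      phi <- exp(pol$x[2])
    }
  }
  if (!pol$converged && pol$residual > 1e-6)
    fg_solver_error(
      sprintf("layer equilibrium did not converge (residual %.3g)",
              pol$residual),
      data = list(a = params$a, c = c, h_bar = h_bar, phi = phi,
                  residual = pol$residual))
  psi <- K / h_bar
  structure(
    list(h_bar = h_bar, psi = psi, phi = phi,
         free_space = 1 - psi - phi,
         uptake_per_monomer = if (psi > 0) phi / (ia$v_bar * psi) else 0,
         h_nm = h_bar * params$L,
         objective = layer_omega_kernel(h_bar, phi, K, pref, ia$chi,
                                        ia$chi_cr, ia$v_bar, mu_c, pi_c),
         c = c,
         residuals = setNames(abs(stat_resid(h_bar, phi))[seq_len(if (c == 0) 1 else 2)],
                              c("height", "protein_mu")[seq_len(if (c == 0) 1 else 2)]),
         diagnostics = list(newton_converged = pol$converged,
                            newton_iterations = pol$iterations,
                            grid = c(n_h = ctl$n_h, n_phi = ctl$n_phi)),
         params = params),
    class = "layer_equilibrium")
}

#' @export
print.layer_equilibrium <- function(x, ...) {
  cat(sprintf(
    "Layer equilibrium (c = %.3g): h_bar = %.5f (h = %.2f nm), psi = %.5f, phi = %.5g\n",
    x$c, x$h_bar, x$h_nm, x$psi, x$phi))
  cat(sprintf("  free space = %.4f, uptake = %.4g proteins per monomer\n",
              x$free_space, x$uptake_per_monomer))
  invisible(x)
}

#' Layer height versus grafting distance
#'
#' Solves the protein-free (or fixed-reservoir) layer equilibrium across a
#' grid of grafting distances.
#'
#' @param interaction an [interaction_params()].
#' @param a_grid ascending vector of grafting distances (nm).
#' @param c reservoir protein fraction (default 0).
#' @param ... passed to [layer_params()].
#' @return A data frame of class `"height_curve"` with columns `a_nm`,
#'   `h_bar`, `psi`, `phi`, `free_space`, `uptake_per_monomer`; the monomer
#'   size is attached as attribute `"l"`.
#' @export
height_vs_grafting <- function(interaction, a_grid, c = 0, ...) {
  stopifnot(inherits(interaction, "interaction_params"))
  if (any(diff(a_grid) <= 0) || any(a_grid <= 0))
    fg_domain_error("`a_grid` must be positive and ascending")
  rows <- lapply(a_grid, function(a) {
    eq <- tryCatch(
      solve_layer_equilibrium(layer_params(interaction, a, ...), c = c),
      fgnupfield_error = function(e)
        fg_solver_error(sprintf("layer solve failed at a = %g nm: %s",
                                a, conditionMessage(e))))
    data.frame(a_nm = a, h_bar = eq$h_bar, psi = eq$psi, phi = eq$phi,
               free_space = eq$free_space,
               uptake_per_monomer = eq$uptake_per_monomer)
  })
  out <- do.call(rbind, rows)
  attr(out, "l") <- interaction$l
  class(out) <- c("height_curve", class(out))
  out
}

#' Height-versus-grafting scaling exponent
#'
#' Least-squares magnitude of the log-log slope of the layer height against
#' the grafting distance, `h_bar ~ a^(-g)`.  For a non-cohesive brush the
#' exponent tends to 2/3 in the dilute limit; strong cohesion drives it
#' towards 2, where the layer behaves as a constant-density melt.
#'
#' @param curve a `"height_curve"` from [height_vs_grafting()], or any data
#'   frame with columns `a_nm` and `h_bar`.
#' @param window fitting window in units of `a / l` (default `c(2, 10)`);
#'   `NULL` uses all points.  The monomer size is taken from the curve
#'   attribute `"l"` (default 1 nm).
#' @return The fitted exponent `g` (positive scalar).
#' @export
#' @examples
#' ia <- interaction_params(chi_cr = -2.5, l = 1, b = 1.52)
#' crv <- height_vs_grafting(ia, exp(seq(log(2), log(10), length.out = 9)))
#' scaling_exponent_g(crv)
scaling_exponent_g <- function(curve, window = c(2, 10)) {
  if (!all(c("a_nm", "h_bar") %in% names(curve)))
    fg_domain_error("`curve` must have columns a_nm and h_bar")
  l <- attr(curve, "l")
  if (is.null(l)) l <- 1
  keep <- rep(TRUE, nrow(curve))
  if (!is.null(window))
    keep <- curve$a_nm / l >= window[1] - 1e-9 &
      curve$a_nm / l <= window[2] + 1e-9
  loglog_slope(curve$a_nm[keep], curve$h_bar[keep])
}

#' Fitted height-scaling exponent for a parameter set
#'
#' Convenience wrapper: builds a log-spaced grafting grid across the fit
#' window, solves each layer and fits the exponent.
#'
#' @inheritParams height_vs_grafting
#' @param window fitting window in `a / l` units.
#' @param n_points number of log-spaced grafting distances.
#' @return The fitted exponent `g`.
#' @export
height_scaling_exponent <- function(interaction, window = c(2, 10),
                                    n_points = 25, c = 0) {
  a_grid <- exp(seq(log(window[1] * interaction$l),
                    log(window[2] * interaction$l), length.out = n_points))
  scaling_exponent_g(height_vs_grafting(interaction, a_grid, c = c),
                     window = window)
}

#' Layer response to reservoir concentration
#'
#' Tracks the layer equilibrium along an ascending grid of reservoir
#' protein fractions, warm-starting every solve from the previous one so a
#' continuous branch is followed (jumps between branches, when cooperative
#' transitions occur, show up as discontinuities in `h_rel`).
#'
#' @param params a [layer_params()].
#' @param c_grid ascending reservoir fractions (may start at 0).
#' @return Data frame with columns `c`, `h_bar`, `h_rel` (height over the
#'   protein-free height), `psi`, `phi`, `free_space`, `uptake_per_monomer`.
#' @export
layer_response_curve <- function(params, c_grid) {
  stopifnot(inherits(params, "layer_params"))
  if (any(diff(c_grid) <= 0) || any(c_grid < 0))
    fg_domain_error("`c_grid` must be non-negative and strictly ascending")
  h0 <- solve_layer_equilibrium(params, c = 0)$h_bar
  warm <- NULL
  rows <- lapply(c_grid, function(cv) {
    eq <- solve_layer_equilibrium(params, c = cv, warm = warm)
    warm <<- eq
    data.frame(c = cv, h_bar = eq$h_bar, h_rel = eq$h_bar / h0, psi = eq$psi,
               phi = eq$phi, free_space = eq$free_space,
               uptake_per_monomer = eq$uptake_per_monomer)
  })
  out <- do.call(rbind, rows)
  attr(out, "h_bar_0") <- h0
  out
}

#' Layer collapse/swelling phase diagram
#'
#' For every combination of grafting distance and protein--monomer
#' interaction strength, scans reservoir concentrations up to `c_max` and
#' records the deepest compaction `h_min / h0`, the concentration at which
#' it occurs, whether the layer ever swells beyond its protein-free height,
#' and the protein uptake at maximal compaction.  Cells where a solve fails
#' are marked in `status` rather than dropped.
#'
#' @param interaction base [interaction_params()]; its `chi` is overridden
#'   by `chi_grid`.
#' @param a_grid grafting distances (nm).
#' @param chi_grid interaction strengths (negative = attraction).
#' @param c_max largest reservoir volume fraction scanned (use
#'   [molar_to_volume_fraction()] to convert a molar bound).
#' @param n_c number of log-spaced concentrations per cell.
#' @param rel_tol relative height change counted as collapse/swelling.
#' @return Data frame with one row per `(a, chi)` cell: `a_nm`, `chi`,
#'   `h_bar_0`, `h_min_rel`, `c_min`, `uptake_at_min`, `collapse`,
#'   `swelling`, `region` (one of `"collapse only"`,
#'   `"collapse and swelling"`, `"swelling only"`, `"inert"`), `status`.
#' @export
layer_phase_diagram <- function(interaction, a_grid, chi_grid, c_max,
                                n_c = 14, rel_tol = 1e-3) {
  stopifnot(inherits(interaction, "interaction_params"))
  if (!is.finite(c_max) || c_max <= 0 || c_max >= 1)
    fg_domain_error("`c_max` must lie in (0, 1)")
  cs <- exp(seq(log(c_max * 1e-4), log(c_max), length.out = n_c))
  cells <- expand.grid(a_nm = a_grid, chi = chi_grid,
                       KEEP.OUT.ATTRS = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(k) {
    ia <- interaction
    ia$chi <- cells$chi[k]
    lp <- layer_params(ia, cells$a_nm[k])
    out <- tryCatch({
      h0 <- solve_layer_equilibrium(lp, c = 0)$h_bar
      warm <- NULL
      rel <- numeric(n_c)
      upt <- numeric(n_c)
      for (i in seq_len(n_c)) {
        eq <- solve_layer_equilibrium(lp, c = cs[i], warm = warm)
        warm <- eq
        rel[i] <- eq$h_bar / h0
        upt[i] <- eq$uptake_per_monomer
      }
      imin <- which.min(rel)
      collapse <- rel[imin] < 1 - rel_tol
      swelling <- any(rel > 1 + rel_tol)
      region <- if (collapse && swelling) "collapse and swelling"
      else if (collapse) "collapse only"
      else if (swelling) "swelling only"
      else "inert"
      data.frame(a_nm = cells$a_nm[k], chi = cells$chi[k], h_bar_0 = h0,
                 h_min_rel = rel[imin], c_min = cs[imin],
                 uptake_at_min = upt[imin], collapse = collapse,
                 swelling = swelling, region = region, status = "ok")
    }, fgnupfield_error = function(e) {
      data.frame(a_nm = cells$a_nm[k], chi = cells$chi[k], h_bar_0 = NA,
                 h_min_rel = NA, c_min = NA, uptake_at_min = NA,
                 collapse = NA, swelling = NA, region = NA_character_,
                 status = paste("failed:", conditionMessage(e)))
    })
    out
  })
  do.call(rbind, res)
}

#' Infer the cohesion strength from a height-versus-grafting curve
#'
#' Least-squares fit of `chi_cr` so that the model height curve
#' `h_bar(a; chi_cr)` matches a measured (or synthetic) curve.
#'
#' @param curve data frame with columns `a_nm` and `h_bar` (>= 5 points).
#' @param interaction base [interaction_params()]; all parameters except
#'   `chi_cr` are held fixed.
#' @param interval search interval for `chi_cr` (default `c(-4, 0)`).
#' @return A list of class `"cohesion_fit"`: `chi_cr`, `rss`, `status`
#'   (`"ok"` or `"non-identifiable"` when the residual landscape is flat).
#' @export
fit_cohesion <- function(curve, interaction, interval = c(-4, 0)) {
  if (!all(c("a_nm", "h_bar") %in% names(curve)) || nrow(curve) < 5)
    fg_domain_error("`curve` must have >= 5 rows with columns a_nm and h_bar")
  sse <- function(ccr) {
    ia <- interaction
    ia$chi_cr <- ccr
    pred <- vapply(curve$a_nm, function(a)
      solve_layer_equilibrium(layer_params(ia, a), c = 0)$h_bar, numeric(1))
    sum((pred - curve$h_bar)^2)
  }
  op <- stats::optimize(sse, interval, tol = 1e-6)
  # identifiability probe: a flat landscape means the data do not constrain
  # chi_cr (e.g. all points in the dilute-brush regime)
  probes <- seq(interval[1], interval[2], length.out = 5)
  pv <- vapply(probes, sse, numeric(1))
  status <- if (diff(range(pv)) < 1e-6 * (1 + max(pv))) "non-identifiable" else "ok"
  structure(list(chi_cr = op$minimum, rss = op$objective, status = status),
            class = "cohesion_fit")
}

#' @export
print.cohesion_fit <- function(x, ...) {
  cat(sprintf("fitted chi_cr = %.4f (rss = %.4g, status: %s)\n",
              x$chi_cr, x$rss, x$status))
  invisible(x)
}
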