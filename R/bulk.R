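# Bulk phase separation of free FG nup chains, alone (binary: chain +
# solvent) or mixed with one transport-protein species (ternary).
# Coexisting compositions satisfy equality of the chain chemical potential,
# the protein chemical potential and the osmotic pressure across the two
# phases; dilute-branch fractions can be exponentially small in N, so the
# solvers work in log-composition variables throughout.

# binary helpers (phi = 0): f(psi) = psi log(psi)/N + (1-psi)log(1-psi)
#                                    + chi_cr psi^2 / 2
fb_prime <- function(psi, N, chi_cr) {
  (log_safe(psi) + 1) / N - log_safe(1 - psi) - 1 + chi_cr * psi
}
fb_pp <- function(psi, N, chi_cr) 1 / (N * psi) + 1 / (1 - psi) + chi_cr
fb_ppp <- function(psi, N) -1 / (N * psi^2) + 1 / (1 - psi)^2
pi_binary <- function(psi, N, chi_cr) {
  psi * fb_prime(psi, N, chi_cr) -
    (xlogx(psi) / N + xlogx(1 - psi) + 0.5 * chi_cr * psi^2)
}

#' Critical point of the binary chain/solvent mixture
#'
#' Solves the two defining conditions of the mean-field critical point --
#' vanishing second and third density derivatives of the bulk free energy
#' at zero protein content -- numerically.  The third derivative is
#' monotone in `psi`, so its root gives the critical composition directly
#' and the curvature condition then yields the critical cohesion.  For
#' chains of `N` monomers the result coincides with the closed forms
#' `psi_c = 1 / (1 + sqrt(N))`, `|chi_cr,c| = (1 + sqrt(N))^2 / N`, which
#' approaches `1 + 2 / sqrt(N)` for long chains.
#'
#' @param N monomers per chain (>= 1).
#' @return List with `psi_c` and `chi_cr_c` (negative: critical cohesion).
#' @export
#' @examples
#' binary_critical_point(167)
binary_critical_point <- function(N) {
  if (!is.finite(N) || N < 1) fg_domain_error("`N` must be >= 1")
  root <- stats::uniroot(function(t) fb_ppp(exp(t), N),
                         c(log(1e-12), log(1 - 1e-12)), tol = 1e-16)
  psi_c <- exp(root$root)
  chi_cr_c <- -(1 / (N * psi_c) + 1 / (1 - psi_c))
  list(psi_c = psi_c, chi_cr_c = chi_cr_c)
}

#' Spinodal of the binary mixture
#'
#' Roots of the curvature `d2f/dpsi2 = 0`, bracketing the locally unstable
#' composition range.  Requires supercritical cohesion.
#'
#' @param N monomers per chain.
#' @param chi_cr cohesion strength (negative).
#' @return Named numeric vector `c(psi_lo, psi_hi)`.
#' @export
binary_spinodal <- function(N, chi_cr) {
  cp <- binary_critical_point(N)
  if (fb_pp(cp$psi_c, N, chi_cr) >= 0)
    fg_no_coexistence_error(sprintf(
      "no spinodal: |chi_cr| = %.4g does not exceed the critical value %.4g",
      abs(chi_cr), abs(cp$chi_cr_c)))
  lo <- stats::uniroot(function(t) fb_pp(exp(t), N, chi_cr),
                       c(log(1e-300), log(cp$psi_c)), tol = 1e-16)$root
  hi <- stats::uniroot(function(p) fb_pp(p, N, chi_cr),
                       c(cp$psi_c, 1 - 1e-12), tol = 1e-16)$root
  c(psi_lo = exp(lo), psi_hi = hi)
}

#' Binodal of the binary mixture
#'
#' Coexisting dilute and dense chain fractions, found from the equality of
#' the chain chemical potential and the osmotic pressure.  The solver
#' parametrizes candidate pairs by the common chemical potential: on either
#' side of the spinodal `df/dpsi` is monotone, so each admissible potential
#' picks one dilute and one dense root, and the osmotic-pressure mismatch
#' is a one-dimensional root-finding problem in the potential.  The dilute
#' branch is resolved in log composition (it decays like `exp(-O(N))`).
#'
#' @inheritParams binary_spinodal
#' @return List of class `"binodal"`: `psi_dilute`, `psi_dense`,
#'   `log_psi_dilute`, `mu`, `pi`, `residual_mu`, `residual_pi`, and the
#'   spinodal bracket `spinodal`.
#' @export
#' @examples
#' binary_binodal(N = 167, chi_cr = -1.5)
binary_binodal <- function(N, chi_cr) {
  sp <- binary_spinodal(N, chi_cr)   # raises no-coexistence when subcritical
  mu_min <- fb_prime(sp[["psi_hi"]], N, chi_cr)
  mu_max <- fb_prime(sp[["psi_lo"]], N, chi_cr)
  lo_of <- function(mu) {
    stats::uniroot(function(t) fb_prime(exp(t), N, chi_cr) - mu,
                   c(log(1e-300), log(sp[["psi_lo"]])), tol = 1e-16)$root
  }
  hi_of <- function(mu) {
    stats::uniroot(function(p) fb_prime(p, N, chi_cr) - mu,
                   c(sp[["psi_hi"]], 1 - 1e-14), tol = 1e-16)$root
  }
  gap <- function(mu) {
    pi_binary(exp(lo_of(mu)), N, chi_cr) - pi_binary(hi_of(mu), N, chi_cr)
  }
  eps <- 1e-9 * (mu_max - mu_min)
  mu <- stats::uniroot(gap, c(mu_min + eps, mu_max - eps), tol = 1e-15)$root
  lpd <- lo_of(mu)
  psi_dense <- hi_of(mu)
  psi_dilute <- exp(lpd)
  structure(
    list(psi_dilute = psi_dilute, psi_dense = psi_dense,
         log_psi_dilute = lpd, mu = mu,
         pi = pi_binary(psi_dense, N, chi_cr),
         residual_mu = abs(fb_prime(psi_dilute, N, chi_cr) -
                             fb_prime(psi_dense, N, chi_cr)),
         residual_pi = abs(pi_binary(psi_dilute, N, chi_cr) -
                             pi_binary(psi_dense, N, chi_cr)),
         spinodal = sp, N = N, chi_cr = chi_cr),
    class = "binodal")
}

#' @export
print.binodal <- function(x, ...) {
  cat(sprintf(
    "Binary coexistence (N = %g, chi_cr = %g):\n  psi_dilute = %.6g (log = %.3f), psi_dense = %.6g\n",
    x$N, x$chi_cr, x$psi_dilute, x$log_psi_dilute, x$psi_dense))
  cat(sprintf("  residuals: |d mu| = %.2e, |d Pi| = %.2e\n",
              x$residual_mu, x$residual_pi))
  invisible(x)
}

# ternary chemical potentials / pressure on raw numerics
mu_poly3 <- function(psi, phi, p) {
  dfe_dpsi_bulk(psi, phi, p$chi, p$chi_cr, p$v_bar, p$N)
}
mu_prot3 <- function(psi, phi, p) {
  mu_protein_kernel(psi, phi, p$chi, p$chi_cr, p$v_bar)
}
pi3 <- function(psi, phi, p) {
  pi_kernel(psi, phi, p$chi, p$chi_cr, p$v_bar, p$N, bulk = TRUE)
}

# 5-equation coexistence system in u = (log psi', log phi', log psi'',
# log phi'', dense_fraction); the mass balances are scaled by the overall
# composition so all residuals are O(1).
tie_system <- function(p, psi_ov, phi_ov) {
  function(u) {
    p1 <- exp(u[1]); q1 <- exp(u[2]); p2 <- exp(u[3]); q2 <- exp(u[4])
    fr <- u[5]
    if (p1 + q1 >= 1 || p2 + q2 >= 1) return(rep(NA_real_, 5))
    c(mu_poly3(p1, q1, p) - mu_poly3(p2, q2, p),
      (mu_prot3(p1, q1, p) - mu_prot3(p2, q2, p)) / p$v_bar,
      pi3(p1, q1, p) - pi3(p2, q2, p),
      (fr * p2 + (1 - fr) * p1 - psi_ov) / psi_ov,
      (fr * q2 + (1 - fr) * q1 - phi_ov) / phi_ov)
  }
}

single_phase_result <- function(p, overall, note) {
  structure(list(status = "single-phase", dilute = NULL, dense = NULL,
                 dense_fraction = NA_real_, residuals = NULL,
                 overall = overall, params = p, note = note),
            class = "tie_line")
}

#' Ternary tie-line through an overall composition
#'
#' Given chain parameters, one protein species and an overall composition
#' `(psi, phi)`, solves the five coexistence equations (equal chain
#' chemical potential, equal protein chemical potential, equal osmotic
#' pressure, plus the two lever-rule mass balances) for the dilute phase,
#' the dense phase and the dense-phase volume fraction.  The solution is
#' reached by continuation: the protein-free binary binodal seeds the
#' system, and the overall protein content is ramped up logarithmically,
#' Newton-solving at each step.  This deterministic path selects the
#' physical root and avoids the trivial identical-phases solution.
#'
#' If the overall composition lies outside the coexistence region (lever
#' fraction escaping `[0, 1]`, phases merging, or subcritical cohesion with
#' no protein-free coexistence to continue from) the result carries status
#' `"single-phase"` rather than an error.
#'
#' @param params an [interaction_params()] describing the chain
#'   (`N`, `chi_cr`, `l`) and the protein species (`v_bar`, `chi`).
#' @param overall a [composition()] with the overall (conserved) fractions.
#' @param n_steps continuation steps in overall protein content.
#' @return Object of class `"tie_line"`: `status` (`"two-phase"` or
#'   `"single-phase"`), `dilute` and `dense` named vectors `(psi, phi)`,
#'   `dense_fraction`, and `residuals` of all five equations.
#' @export
#' @examples
#' p <- interaction_params(chi = -215, chi_cr = -1.5, v_bar = 125, N = 167)
#' ternary_tie_line(p, composition(8e-4, 1e-4))
ternary_tie_line <- function(params, overall, n_steps = 30) {
  stopifnot(inherits(params, "interaction_params"))
  overall <- as_composition(overall)
  if (length(overall$psi) != 1)
    fg_domain_error("`overall` must be a single composition")
  psi_ov <- overall$psi
  phi_ov <- overall$phi
  if (psi_ov <= 0)
    fg_domain_error("overall polymer fraction must be positive")

  bb <- tryCatch(binary_binodal(params$N, params$chi_cr),
                 fgnupfield_no_coexistence_error = function(e) NULL)
  if (is.null(bb))
    return(single_phase_result(params, overall,
                               "subcritical cohesion: no protein-free coexistence to continue from"))
  fr0 <- (psi_ov - bb$psi_dilute) / (bb$psi_dense - bb$psi_dilute)
  if (fr0 <= 0 || fr0 >= 1)
    return(single_phase_result(params, overall,
                               "overall polymer content outside the protein-free coexistence interval"))
  if (phi_ov <= 0) {
    res <- c(mu = bb$residual_mu, pi = bb$residual_pi)
    return(structure(
      list(status = "two-phase",
           dilute = c(psi = bb$psi_dilute, phi = 0),
           dense = c(psi = bb$psi_dense, phi = 0),
           dense_fraction = fr0,
           residuals = c(mu_polymer = bb$residual_mu, mu_protein = 0,
                         pi = bb$residual_pi, mass_psi = 0, mass_phi = 0),
           overall = overall, params = params, note = "protein-free"),
      class = "tie_line"))
  }

  # dilute-limit partition ratio phi''/phi' seeds the protein split
  lnK <- (params$v_bar * log_safe(1 - bb$psi_dense) -
            params$chi * bb$psi_dense) -
    (params$v_bar * log_safe(1 - bb$psi_dilute) -
       params$chi * bb$psi_dilute)
  ratio <- exp(min(lnK, 500))
  steps <- exp(seq(log(phi_ov * 1e-4), log(phi_ov), length.out = n_steps))
  q1 <- steps[1] / ((1 - fr0) + fr0 * ratio)
  u <- c(log(bb$psi_dilute), log(max(q1, 1e-290)), log(bb$psi_dense),
         log(max(min(ratio * q1, steps[1] / fr0), 1e-290)), fr0)
  last_good <- u
  for (i in seq_along(steps)) {
    sys <- tie_system(params, psi_ov, steps[i])
    sol <- mf_newton(sys, u, tol = 1e-10, maxit = 80)
    if (!sol$converged) {
      # refine the continuation step once before giving a verdict
      if (i > 1) {
        mid <- sqrt(steps[i - 1] * steps[i])
        sol_mid <- mf_newton(tie_system(params, psi_ov, mid), u,
                             tol = 1e-10, maxit = 80)
        if (sol_mid$converged) {
          u <- sol_mid$x
          sol <- mf_newton(sys, u, tol = 1e-10, maxit = 80)
        }
      }
      if (!sol$converged) {
        fr_last <- last_good[5]
        near_edge <- fr_last < 0.02 || fr_last > 0.98 ||
          abs(exp(last_good[3]) - exp(last_good[1])) < 1e-3
        if (near_edge)
          return(single_phase_result(params, overall,
                                     "continuation left the coexistence region"))
        fg_solver_error(
          sprintf("ternary coexistence continuation failed at overall phi = %.3g",
                  steps[i]),
          data = list(step = i, state = last_good, residual = sol$residual))
      }
    }
    u <- sol$x
    last_good <- u
    if (u[5] <= 0 || u[5] >= 1 || abs(exp(u[3]) - exp(u[1])) < 1e-6)
      return(single_phase_result(params, overall,
                                 "lever fraction left (0, 1): overall composition is single-phase"))
  }
  resid <- abs(tie_system(params, psi_ov, phi_ov)(u))
  structure(
    list(status = "two-phase",
         dilute = c(psi = exp(u[1]), phi = exp(u[2])),
         dense = c(psi = exp(u[3]), phi = exp(u[4])),
         dense_fraction = u[5],
         residuals = setNames(resid, c("mu_polymer", "mu_protein", "pi",
                                       "mass_psi", "mass_phi")),
         overall = overall, params = params, note = NULL),
    class = "tie_line")
}

#' @export
print.tie_line <- function(x, ...) {
  if (x$status == "single-phase") {
    cat("single phase:", x$note, "\n")
    return(invisible(x))
  }
  cat(sprintf("Tie-line (dense fraction %.4g):\n", x$dense_fraction))
  cat(sprintf("  dilute: psi = %.4e, phi = %.4e\n",
              x$dilute["psi"], x$dilute["phi"]))
  cat(sprintf("  dense:  psi = %.4e, phi = %.4e\n",
              x$dense["psi"], x$dense["phi"]))
  cat(sprintf("  max residual = %.2e\n", max(x$residuals)))
  invisible(x)
}

#' Map the two-phase region of the ternary system
#'
#' Classifies a grid of overall compositions as single- or two-phase via
#' [ternary_tie_line()] and extracts the (grid-resolution) boundary: the
#' two-phase cells adjacent to a single-phase cell.  A few representative
#' tie-lines are returned for plotting.
#'
#' @param params an [interaction_params()].
#' @param psi_grid,phi_grid overall-composition grids.
#' @param n_tie_lines how many representative tie-lines to keep.
#' @return List with `grid` (data frame: `psi`, `phi`, `two_phase`,
#'   `status`), `boundary` (subset of `grid` on the region edge) and
#'   `tie_lines`.
#' @export
ternary_phase_region <- function(params, psi_grid, phi_grid,
                                 n_tie_lines = 5) {
  cells <- expand.grid(psi = psi_grid, phi = phi_grid,
                       KEEP.OUT.ATTRS = FALSE)
  ties <- vector("list", nrow(cells))
  status <- character(nrow(cells))
  two <- logical(nrow(cells))
  for (k in seq_len(nrow(cells))) {
    r <- tryCatch(
      ternary_tie_line(params, composition(cells$psi[k], cells$phi[k])),
      fgnupfield_error = function(e) e)
    if (inherits(r, "error")) {
      status[k] <- paste("failed:", conditionMessage(r))
      two[k] <- NA
    } else {
      status[k] <- r$status
      two[k] <- r$status == "two-phase"
      ties[[k]] <- r
    }
  }
  grid <- cbind(cells, two_phase = two, status = status)
  # boundary: two-phase cells with at least one single-phase grid neighbour
  np <- length(psi_grid)
  nf <- length(phi_grid)
  idx <- function(i, j) (j - 1) * np + i
  on_edge <- rep(FALSE, nrow(grid))
  for (j in seq_len(nf)) for (i in seq_len(np)) {
    k <- idx(i, j)
    if (!isTRUE(two[k])) next
    nb <- c(if (i > 1) idx(i - 1, j), if (i < np) idx(i + 1, j),
            if (j > 1) idx(i, j - 1), if (j < nf) idx(i, j + 1))
    if (any(!two[nb], na.rm = TRUE) || anyNA(two[nb]) ||
        i == 1 || i == np || j == 1 || j == nf)
      on_edge[k] <- TRUE
  }
  keep <- which(isTRUE(two) | two)
  reps <- ties[on_edge]
  reps <- reps[!vapply(reps, is.null, logical(1))]
  if (length(reps) > n_tie_lines)
    reps <- reps[round(seq(1, length(reps), length.out = n_tie_lines))]
  list(grid = grid, boundary = grid[on_edge, , drop = FALSE],
       tie_lines = reps)
}

#' Partitioning of transport-protein species into the dense FG nup phase
#'
#' Solves one ternary tie-line per protein species against a common FG nup
#' background (one species at a time), and reports the partition
#' coefficient `phi_dense / phi_dilute` together with an in/out call.
#'
#' @param species data frame with columns `name`, `v_bar`, `chi` (one row
#'   per protein or protein--cargo complex), e.g.
#'   [partitioning_species()].
#' @param fg_params an [interaction_params()] for the chains (`N`,
#'   `chi_cr`, `l`, `z` are used; `v_bar`/`chi` are overridden per species).
#' @param polymer_uM,protein_uM overall concentrations; converted to
#'   volume fractions with the chain volume `N * l^3` and each species'
#'   volume `v_bar * l^3` via [molar_to_volume_fraction()].
#' @return Data frame with per-species compositions of both phases, the
#'   partition coefficient, `partitions_in = phi_dense > phi_dilute`,
#'   `max_residual` and `status`.
#' @export
#' @examples
#' \donttest{
#' fg <- interaction_params(chi_cr = -1.5, N = 167, l = 1)
#' partition_report(partitioning_species(), fg)
#' }
partition_report <- function(species, fg_params, polymer_uM = 5,
                             protein_uM = 1) {
  stopifnot(inherits(fg_params, "interaction_params"),
            all(c("name", "v_bar", "chi") %in% names(species)))
  v0 <- fg_params$l^3
  psi_ov <- molar_to_volume_fraction(polymer_uM, fg_params$N * v0,
                                     z = fg_params$z)
  rows <- lapply(seq_len(nrow(species)), function(k) {
    p <- fg_params
    p$v_bar <- species$v_bar[k]
    p$chi <- species$chi[k]
    phi_ov <- molar_to_volume_fraction(protein_uM, p$v_bar * v0,
                                       z = p$z)
    tl <- tryCatch(ternary_tie_line(p, composition(psi_ov, phi_ov)),
                   fgnupfield_error = function(e) e)
    if (inherits(tl, "error") || tl$status != "two-phase") {
      note <- if (inherits(tl, "error")) conditionMessage(tl) else tl$status
      return(data.frame(name = species$name[k], v_bar = p$v_bar, chi = p$chi,
                        psi_dilute = NA, psi_dense = NA, phi_dilute = NA,
                        phi_dense = NA, partition_coefficient = NA,
                        partitions_in = NA, max_residual = NA,
                        status = note))
    }
    data.frame(name = species$name[k], v_bar = p$v_bar, chi = p$chi,
               psi_dilute = tl$dilute[["psi"]], psi_dense = tl$dense[["psi"]],
               phi_dilute = tl$dilute[["phi"]], phi_dense = tl$dense[["phi"]],
               partition_coefficient = tl$dense[["phi"]] / tl$dilute[["phi"]],
               partitions_in = tl$dense[["phi"]] > tl$dilute[["phi"]],
               max_residual = max(tl$residuals), status = "two-phase")
  })
  do.call(rbind, rows)
}
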