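# Implicit-solvent solvation energy: E_sol = E_polar + E_nonpolar.
#
# Polar engines:
#   * "pb" - finite-difference linear Poisson-Boltzmann on a regular grid
#     (reference engine; 7-point stencil, trilinear charge spreading,
#     face-midpoint dielectric map from the probe-inflated van der Waals
#     region, screened-Coulomb Dirichlet boundaries, red-black SOR).
#     The reaction-field energy is the difference between the solvated
#     solve and a uniform eps_in solve on the same grid, which cancels the
#     grid self-energy.
#   * "gb" - generalized Born (Still equation) with HCT pairwise
#     descreening effective radii; fast enough for per-frame matrices.
# Nonpolar: gamma * SASA + beta with Shrake-Rupley areas.

#' Solvation model configuration
#'
#' @param eps_in solute (reference) dielectric; default 1.
#' @param eps_out solvent dielectric; default 80.
#' @param grid_spacing PB grid spacing, A; default 0.5.
#' @param grid_padding distance from solute extent to grid boundary, A;
#'   default 12.
#' @param probe_radius solvent probe radius, A (used for SASA and for the
#'   dielectric region); default 1.4.
#' @param gamma nonpolar surface coefficient, kcal/mol/A^2; default 0.00542.
#' @param beta nonpolar offset, kcal/mol; default 0.92.
#' @param n_sphere_points Shrake-Rupley points per atom; default 960.
#' @param engine polar engine, `"gb"` (fast, default) or `"pb"`
#'   (finite-difference reference).
#' @param ionic_strength molar salt; only 0 (pure linear PB with
#'   Coulombic boundaries) is supported.
#' @param pb_tol SOR convergence tolerance on the maximum potential
#'   update, kcal/mol/e; default 1e-4.
#' @param pb_maxiter maximum SOR sweeps; default 10000.
#' @param gb_descreen HCT descreening scale applied to the neighbour
#'   radii in the GB effective-radius integral (compensates overlap
#'   double-counting); default 0.8.
#' @return Object of class `"solvation_config"`.
#' @export
solvation_config <- function(eps_in = 1.0, eps_out = 80.0, grid_spacing = 0.5,
                             grid_padding = 12, probe_radius = 1.4,
                             gamma = 0.00542, beta = 0.92,
                             n_sphere_points = 960, engine = c("gb", "pb"),
                             ionic_strength = 0, pb_tol = 1e-4,
                             pb_maxiter = 10000, gb_descreen = 0.8) {
  engine <- match.arg(engine)
  if (eps_in < 1 || eps_out < eps_in) stop("require eps_out >= eps_in >= 1")
  if (grid_spacing <= 0) stop("grid spacing must be > 0")
  if (gamma < 0) stop("gamma must be >= 0")
  if (ionic_strength != 0) stop("only zero ionic strength is supported")
  structure(list(eps_in = eps_in, eps_out = eps_out, grid_spacing = grid_spacing,
                 grid_padding = grid_padding, probe_radius = probe_radius,
                 gamma = gamma, beta = beta, n_sphere_points = n_sphere_points,
                 engine = engine, ionic_strength = ionic_strength,
                 pb_tol = pb_tol, pb_maxiter = pb_maxiter,
                 gb_descreen = gb_descreen),
            class = "solvation_config")
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Deterministic golden-spiral point sampling on each atom's
#' probe-inflated sphere.
#'
#' @inheritParams bonded_energy
#' @param cfg a [solvation_config()].
#' @return Per-atom accessible areas in A^2 (one value per selection atom,
#'   in selection order).  `sum()` gives the total SASA.
#' @export
shrake_rupley_sasa <- function(frame, selection, ff, cfg = solvation_config()) {
  if (cfg$n_sphere_points < 10) stop("n_sphere_points must be >= 10")
  fr <- .as_frame(frame)
  idx <- .sel_indices(selection, nrow(fr$xyz))
  cpp_sasa(fr$xyz[idx, , drop = FALSE], ff$radius[idx],
           cfg$probe_radius, as.integer(cfg$n_sphere_points))
}

#' Nonpolar (cavity) solvation energy, linear in SASA
#'
#' @param total_sasa total accessible area, A^2.
#' @param cfg a [solvation_config()] supplying `gamma` and `beta`.
#' @return `gamma * SASA + beta` in kcal/mol.
#' @export
nonpolar_solvation <- function(total_sasa, cfg = solvation_config()) {
  if (total_sasa < 0) stop("negative SASA")
  cfg$gamma * total_sasa + cfg$beta
}

#' Polar solvation energy by finite-difference linear Poisson-Boltzmann
#'
#' Reaction-field energy
#' \eqn{\Delta G_{pol} = \tfrac12 \sum_i q_i (\phi_i^{solv} - \phi_i^{vac})}
#' from two solves on the same grid (heterogeneous dielectric map vs
#' uniform `eps_in`), so grid self-energy artifacts cancel.
#'
#' @inheritParams shrake_rupley_sasa
#' @return Energy in kcal/mol.
#' @export
pb_polar_solvation <- function(frame, selection, ff, cfg = solvation_config()) {
  fr <- .as_frame(frame)
  idx <- .sel_indices(selection, nrow(fr$xyz))
  xyz <- fr$xyz[idx, , drop = FALSE]
  q <- ff$charges[idx]
  if (all(q == 0)) return(0)
  if (cfg$eps_out == cfg$eps_in) return(0)
  rad <- ff$radius[idx] + cfg$probe_radius
  h <- cfg$grid_spacing
  lo <- apply(xyz - rad, 2, min) - cfg$grid_padding
  hi <- apply(xyz + rad, 2, max) + cfg$grid_padding
  n <- pmax(8L, as.integer(ceiling((hi - lo) / h)) + 1L)
  hi <- lo + (n - 1) * h
  if (any(xyz < matrix(lo, nrow(xyz), 3, byrow = TRUE) + h) ||
      any(xyz > matrix(hi, nrow(xyz), 3, byrow = TRUE) - h))
    stop("atom outside PB grid interior; increase grid_padding")
  dims <- as.integer(n)
  src <- .spread_charges(xyz, q, lo, h, dims)
  masks <- lapply(0:2, function(ax)
    cpp_face_mask(dims, lo[1], lo[2], lo[3], h, ax, xyz, rad))
  omega <- 2 / (1 + sin(pi / max(dims)))
  solve_one <- function(mask_in, eps_bc) {
    phi <- numeric(prod(dims))
    cpp_boundary_coulomb(phi, dims, lo[1], lo[2], lo[3], h, xyz, q, .KE, eps_bc)
    if (mask_in) {
      res <- cpp_pb_sor(phi, dims, masks[[1]], masks[[2]], masks[[3]], src,
                        cfg$eps_in, cfg$eps_out, h, omega, cfg$pb_tol,
                        cfg$pb_maxiter)
    } else {
      res <- cpp_pb_sor(phi, dims, masks[[1]], masks[[2]], masks[[3]], src,
                        cfg$eps_in, cfg$eps_in, h, omega, cfg$pb_tol,
                        cfg$pb_maxiter)
    }
    if (!res$converged)
      stop("PB solver did not converge in ", cfg$pb_maxiter,
           " sweeps (residual ", format(res$max_delta), ")")
    phi
  }
  phi_solv <- solve_one(TRUE, cfg$eps_out)
  phi_vac <- solve_one(FALSE, cfg$eps_in)
  0.5 * sum(q * (.trilinear(phi_solv, xyz, lo, h, dims) -
                 .trilinear(phi_vac, xyz, lo, h, dims)))
}

# spread charges to the 8 surrounding nodes; source term 4 pi k_e q / h
.spread_charges <- function(xyz, q, lo, h, dims) {
  src <- numeric(prod(dims))
  for (a in seq_along(q)) {
    if (q[a] == 0) next
    g <- (xyz[a, ] - lo) / h
    i0 <- floor(g); f <- g - i0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) f[1] else 1 - f[1]) *
           (if (dy) f[2] else 1 - f[2]) *
           (if (dz) f[3] else 1 - f[3])
      if (w == 0) next
      node <- (i0[1] + dx) + dims[1] * ((i0[2] + dy) + dims[2] * (i0[3] + dz)) + 1
      src[node] <- src[node] + 4 * pi * .KE * q[a] * w / h
    }
  }
  src
}

.trilinear <- function(phi, xyz, lo, h, dims) {
  vapply(seq_len(nrow(xyz)), function(a) {
    g <- (xyz[a, ] - lo) / h
    i0 <- floor(g); f <- g - i0
    v <- 0
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      w <- (if (dx) f[1] else 1 - f[1]) *
           (if (dy) f[2] else 1 - f[2]) *
           (if (dz) f[3] else 1 - f[3])
      if (w == 0) next
      node <- (i0[1] + dx) + dims[1] * ((i0[2] + dy) + dims[2] * (i0[3] + dz)) + 1
      v <- v + w * phi[node]
    }
    v
  }, numeric(1))
}

#' Polar solvation energy by generalized Born (Still / HCT)
#'
#' Still's pairwise formula with effective radii from
#' Hawkins-Cramer-Truhlar pairwise descreening of the intrinsic radii.
#' A single isolated atom reduces exactly to the Born formula.
#'
#' @inheritParams shrake_rupley_sasa
#' @return Energy in kcal/mol.
#' @export
gb_polar_solvation <- function(frame, selection, ff, cfg = solvation_config()) {
  fr <- .as_frame(frame)
  idx <- .sel_indices(selection, nrow(fr$xyz))
  xyz <- fr$xyz[idx, , drop = FALSE]
  q <- ff$charges[idx]
  if (all(q == 0)) return(0)
  if (cfg$eps_out == cfg$eps_in) return(0)
  a <- .gb_effective_radii(xyz, ff$radius[idx], cfg$gb_descreen)
  n <- length(q)
  pref <- -0.5 * .KE * (1 / cfg$eps_in - 1 / cfg$eps_out)
  e <- sum(pref * q^2 / a)  # self (Born) terms
  if (n > 1) {
    cmb <- utils::combn(n, 2)
    i <- cmb[1, ]; j <- cmb[2, ]
    r2 <- rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2)
    aa <- a[i] * a[j]
    fgb <- sqrt(r2 + aa * exp(-r2 / (4 * aa)))
    e <- e + sum(2 * pref * q[i] * q[j] / fgb)
  }
  e
}

.gb_effective_radii <- function(xyz, rho, descreen = 0.8) {
  n <- nrow(xyz)
  inv <- 1 / rho
  if (n > 1) {
    for (i in seq_len(n)) {
      r <- sqrt(rowSums((xyz[-i, , drop = FALSE] -
                         matrix(xyz[i, ], n - 1, 3, byrow = TRUE))^2))
      s <- descreen * rho[-i]
      U <- r + s
      keep <- U > rho[i]
      if (!any(keep)) next
      r <- r[keep]; s <- s[keep]; U <- U[keep]
      L <- pmax(rho[i], abs(r - s))
      I <- 0.5 * (1 / L - 1 / U +
                  0.25 * (r - s^2 / r) * (1 / U^2 - 1 / L^2) +
                  log(L / U) / (2 * r))
      inv[i] <- inv[i] - sum(I)
    }
  }
  if (any(inv <= 0))
    stop("non-positive GB effective radius; intrinsic radii too overlapped")
  1 / inv
}

#' Total solvation energy (polar + nonpolar)
#'
#' @inheritParams shrake_rupley_sasa
#' @return Energy in kcal/mol: polar term from the configured engine plus
#'   `gamma * SASA + beta`.
#' @export
solvation_energy <- function(frame, selection, ff, cfg = solvation_config()) {
  polar <- switch(cfg$engine,
                  pb = pb_polar_solvation(frame, selection, ff, cfg),
                  gb = gb_polar_solvation(frame, selection, ff, cfg))
  sasa <- sum(shrake_rupley_sasa(frame, selection, ff, cfg))
  polar + nonpolar_solvation(sasa, cfg)
}
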