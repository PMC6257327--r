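# Per-frame MMPBSA binding-energy decomposition and trajectory summaries.
#
# Single-trajectory protocol: monomer energies are evaluated on the
# coordinates excised from the complex frame, so every bonded term cancels
# in the binding difference and the internal component of dE_MM is
# identically zero.

.EM_COLS <- c("e_mm_C", "e_int_C", "e_ele_C", "e_vdw_C", "e_sol_C",
              "e_mm_A", "e_int_A", "e_ele_A", "e_vdw_A", "e_sol_A",
              "e_mm_B", "e_int_B", "e_ele_B", "e_vdw_B", "e_sol_B",
              "de_bind", "de_mm", "de_sol")

#' Per-frame binding energy decomposition (18 components)
#'
#' Evaluates E_MM (internal, electrostatic, van der Waals) and E_sol for
#' the complex and both monomers on one frame, plus the binding
#' differences dE_bind = E_C - E_A - E_B, dE_MM and dE_sol.  By the
#' single-trajectory protocol dE_bind = dE_MM + dE_sol exactly.
#'
#' @inheritParams shrake_rupley_sasa
#' @param selections list with elements `complex`, `A`, `B` (from
#'   [select_chain()]).
#' @param pairs optional precomputed [nonbonded_pairs()] table.
#' @return Named numeric vector over the 18 documented components
#'   (kcal/mol) with attribute `time` (ps).
#' @export
frame_binding_energy <- function(frame, selections, ff,
                                 cfg = solvation_config(), pairs = NULL) {
  fr <- .as_frame(frame)
  pairs <- pairs %||% nonbonded_pairs(ff, nrow(fr$xyz))
  comp <- function(sel) {
    mm <- mm_energy(fr, sel, ff, pairs)
    sol <- solvation_energy(fr, sel, ff, cfg)
    c(mm$e_mm, mm$e_int, mm$e_ele, mm$e_vdw, sol)
  }
  eC <- comp(selections$complex)
  eA <- comp(selections$A)
  eB <- comp(selections$B)
  de_mm <- eC[1] - eA[1] - eB[1]
  de_sol <- eC[5] - eA[5] - eB[5]
  row <- c(eC, eA, eB, de_mm + de_sol, de_mm, de_sol)
  names(row) <- .EM_COLS
  attr(row, "time") <- fr$time
  row
}

#' Binding energy matrix along a trajectory
#'
#' One [frame_binding_energy()] row per frame: `n_frames` x 18 components
#' in the fixed documented column order (complex block, monomer A block,
#' monomer B block, then dE_bind, dE_MM, dE_sol).
#'
#' @param traj a [trajectory()].
#' @param ff a [forcefield()].
#' @param cfg a [solvation_config()].
#' @return Numeric matrix of class `"energy_matrix"` with column names and
#'   attribute `time` (ps per frame).
#' @export
energy_matrix <- function(traj, ff, cfg = solvation_config()) {
  top <- traj$topology
  sels <- list(complex = select_chain(top, "complex"),
               A = select_chain(top, "A"), B = select_chain(top, "B"))
  pairs <- nonbonded_pairs(ff, n_atoms(top))
  nf <- n_frames(traj)
  m <- matrix(NA_real_, nf, length(.EM_COLS), dimnames = list(NULL, .EM_COLS))
  for (t in seq_len(nf))
    m[t, ] <- frame_binding_energy(get_frame(traj, t), sels, ff, cfg, pairs)
  structure(m, time = traj$time, class = c("energy_matrix", "matrix", "array"))
}

#' Write an energy matrix as CSV (time column + 18 named components)
#'
#' @param em an [energy_matrix()].
#' @param file output path.
#' @export
write_energy_matrix <- function(em, file) {
  df <- data.frame(time_ps = attr(em, "time"), unclass(em)[, , drop = FALSE])
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Combine species free energies into the binding free energy
#'
#' `G_C - G_A - G_B`: the species form of the end-state decomposition.
#'
#' @param g_complex,g_a,g_b mean free energies of complex and monomers,
#'   kcal/mol.
#' @return Binding free energy, kcal/mol.
#' @export
binding_from_species <- function(g_complex, g_a, g_b) g_complex - g_a - g_b

#' Combine MM and solvation changes into the binding free energy
#'
#' `dE_MM + dG_sol`: the component form of the end-state decomposition.
#'
#' @param de_mm,dg_sol mean molecular-mechanics and solvation changes on
#'   binding, kcal/mol.
#' @return Binding free energy, kcal/mol.
#' @export
binding_from_components <- function(de_mm, dg_sol) de_mm + dg_sol

.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Summary statistics of a binding energy matrix
#'
#' Means and population standard deviations of the binding free energy and
#' its decomposition: dG_bind, the per-species totals G_C/G_A/G_B
#' (E_MM + E_sol per frame), and the component changes dE_MM and dG_sol.
#' The two bookkeeping identities
#' `mean(dG_bind) = mean(G_C) - mean(G_A) - mean(G_B)
#'                = mean(dE_MM) + mean(dG_sol)` hold exactly.
#'
#' @param em an [energy_matrix()] (>= 2 rows).
#' @param temperature analysis temperature, K (metadata).
#' @return Object of class `"energy_summary"`: a data frame with columns
#'   `quantity`, `mean`, `sd`, plus attributes `n_frames` and
#'   `temperature`.
#' @export
trajectory_summary <- function(em, temperature = 305) {
  if (is.null(dim(em)) || nrow(em) < 2) stop("need an energy matrix with >= 2 rows")
  g <- cbind(dG_bind = em[, "de_bind"],
             G_C = em[, "e_mm_C"] + em[, "e_sol_C"],
             G_A = em[, "e_mm_A"] + em[, "e_sol_A"],
             G_B = em[, "e_mm_B"] + em[, "e_sol_B"],
             dE_MM = em[, "de_mm"],
             dG_sol = em[, "de_sol"])
  out <- data.frame(quantity = colnames(g),
                    mean = colMeans(g),
                    sd = apply(g, 2, .pop_sd),
                    row.names = NULL)
  structure(out, n_frames = nrow(em), temperature = temperature,
            class = c("energy_summary", "data.frame"))
}

#' @export
print.energy_summary <- function(x, ...) {
  cat("Binding free energy decomposition over", attr(x, "n_frames"),
      "frames at", attr(x, "temperature"), "K (kcal/mol):\n")
  df <- data.frame(quantity = x$quantity,
                   value = sprintf("%.1f (%.1f)", x$mean, x$sd))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Schlitter configurational entropy from a trajectory
#'
#' Quasi-harmonic upper bound from the mass-weighted Cartesian covariance
#' of (optionally superposed) selection coordinates:
#' \deqn{S = \frac{k_B}{2}\,\ln\det\left(I + \frac{k_B T e^2}{\hbar^2}
#'   M^{1/2} C M^{1/2}\right).}
#' Frames are rigid-body superposed onto their mean structure before the
#' covariance is formed (`fit = TRUE`), as the internal-motion entropy
#' requires.  When the covariance cannot be full rank (fewer than
#' `3 n_atoms + 1` frames) a warning is issued and the pseudo-determinant
#' over the positive eigenvalues is used; zero modes contribute nothing.
#'
#' @param traj a [trajectory()] (>= 2 frames).
#' @param selection a [select_chain()] selection or integer indices.
#' @param temperature temperature, K.
#' @param masses per-atom masses, amu; defaults to the topology masses.
#' @param fit superpose frames onto the mean structure first (default
#'   TRUE).
#' @return Object of class `"entropy_result"`: list with `s`
#'   (kcal/(mol K)), `minus_t_s` (kcal/mol), `temperature`, `n_frames`.
#' @export
schlitter_entropy <- function(traj, selection = NULL, temperature = 305,
                              masses = NULL, fit = TRUE) {
  if (n_frames(traj) < 2) stop("need at least 2 frames")
  idx <- .sel_indices(selection %||% select_chain(traj$topology, "complex"),
                      n_atoms(traj$topology))
  masses <- masses %||% traj$topology$atoms$mass[idx]
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  x <- traj$xyz[, cols, drop = FALSE]
  if (fit) {
    ref <- x[1, ]
    for (it in 1:2) {
      x <- t(apply(x, 1, .superpose_onto, ref = ref))
      ref <- colMeans(x)
    }
  }
  n <- nrow(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  C <- crossprod(xc) / n  # population covariance
  if (n - 1 < ncol(x))
    warning("fewer frames (", n, ") than degrees of freedom (", ncol(x),
            "); covariance is rank-deficient, using the pseudo-determinant")
  msqrt <- sqrt(rep(masses, each = 3))
  A <- C * tcrossprod(msqrt)
  lam <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  lam[lam < 0] <- 0
  s <- 0.5 * .KB * sum(log1p(.SCHLITTER_C * temperature * lam))
  structure(list(s = s, minus_t_s = -temperature * s,
                 temperature = temperature, n_frames = n),
            class = "entropy_result")
}

#' @export
print.entropy_result <- function(x, ...) {
  cat(sprintf("Schlitter entropy: S = %.6f kcal/(mol K), -TS = %.3f kcal/mol at %g K (%d frames)\n",
              x$s, x$minus_t_s, x$temperature, x$n_frames))
  invisible(x)
}

# Kabsch superposition of one flattened frame onto a flattened reference
.superpose_onto <- function(row, ref) {
  a <- matrix(row, ncol = 3, byrow = TRUE)
  b <- matrix(ref, ncol = 3, byrow = TRUE)
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  s <- svd(crossprod(a0, b0))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  out <- sweep(a0 %*% t(R), 2, cb, `+`)
  as.numeric(t(out))
}

#' Entropy correction to the binding free energy
#'
#' Combines the -TS terms of complex and monomers:
#' `(-T dS) = (-T S_C) - (-T S_A) - (-T S_B)`.
#'
#' @param minus_ts_complex,minus_ts_a,minus_ts_b -TS values, kcal/mol, at
#'   a common temperature.
#' @return The -T dS correction, kcal/mol.
#' @export
entropy_correction <- function(minus_ts_complex, minus_ts_a, minus_ts_b) {
  minus_ts_complex - minus_ts_a - minus_ts_b
}
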