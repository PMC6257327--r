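# Gas-phase molecular-mechanics energies under Amber conventions:
#   E_MM = E_int + E_ele + E_vdw
# E_int: sum k_b (b - b0)^2 + sum k_theta (theta - theta0)^2 +
#        sum (V_n/2)(1 + cos(n phi - gamma))        (no 1/2 on harmonics)
# E_ele: k_e sum_{i<j} q_i q_j / r_ij, 1-2/1-3 excluded, 1-4 / scee
# E_vdw: sum eps_ij [ (rmin_ij/r)^12 - 2 (rmin_ij/r)^6 ],
#        Lorentz-Berthelot rmin_ij = rmin_half_i + rmin_half_j,
#        eps_ij = sqrt(eps_i eps_j), 1-2/1-3 excluded, 1-4 / scnb
# No distance cutoff: post-processing energies are evaluated in full.

.sel_indices <- function(selection, n) {
  if (inherits(selection, "selection")) selection$indices
  else if (is.numeric(selection)) as.integer(selection)
  else seq_len(n)
}

#' Bonded (internal) energy of a selection
#'
#' Harmonic bonds and angles (Amber convention, no 1/2 factor) plus cosine
#' dihedrals, restricted to terms whose atoms all lie in the selection.
#'
#' @param frame a [frame()] (or plain n x 3 matrix).
#' @param selection a [select_chain()] selection or integer atom indices.
#' @param ff a [forcefield()].
#' @return Energy in kcal/mol.
#' @export
bonded_energy <- function(frame, selection, ff) {
  fr <- .as_frame(frame); xyz <- fr$xyz
  idx <- .sel_indices(selection, nrow(xyz))
  inset <- logical(nrow(xyz)); inset[idx] <- TRUE
  e <- 0
  b <- ff$bonds
  if (nrow(b)) {
    use <- inset[b$i] & inset[b$j]
    part <- inset[b$i] != inset[b$j]
    if (any(part)) stop("bond term references an atom outside the selection")
    if (any(use)) {
      d <- sqrt(rowSums((xyz[b$i[use], , drop = FALSE] -
                         xyz[b$j[use], , drop = FALSE])^2))
      e <- e + sum(b$kb[use] * (d - b$b0[use])^2)
    }
  }
  a <- ff$angles
  if (nrow(a)) {
    use <- inset[a$i] & inset[a$j] & inset[a$k]
    part <- (inset[a$i] | inset[a$j] | inset[a$k]) & !use
    if (any(part)) stop("angle term references an atom outside the selection")
    if (any(use)) {
      v1 <- xyz[a$i[use], , drop = FALSE] - xyz[a$j[use], , drop = FALSE]
      v2 <- xyz[a$k[use], , drop = FALSE] - xyz[a$j[use], , drop = FALSE]
      cth <- rowSums(v1 * v2) / (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2)))
      th <- acos(pmin(1, pmax(-1, cth)))
      e <- e + sum(a$ktheta[use] * (th - a$theta0[use])^2)
    }
  }
  d <- ff$dihedrals
  if (nrow(d)) {
    use <- inset[d$i] & inset[d$j] & inset[d$k] & inset[d$l]
    part <- (inset[d$i] | inset[d$j] | inset[d$k] | inset[d$l]) & !use
    if (any(part)) stop("dihedral term references an atom outside the selection")
    if (any(use)) {
      phi <- .dihedral_angle(xyz, d$i[use], d$j[use], d$k[use], d$l[use])
      e <- e + sum(d$vn2[use] * (1 + cos(d$n[use] * phi - d$gamma[use])))
    }
  }
  e
}

.dihedral_angle <- function(xyz, i, j, k, l) {
  b1 <- xyz[j, , drop = FALSE] - xyz[i, , drop = FALSE]
  b2 <- xyz[k, , drop = FALSE] - xyz[j, , drop = FALSE]
  b3 <- xyz[l, , drop = FALSE] - xyz[k, , drop = FALSE]
  cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                             u[, 3] * v[, 1] - u[, 1] * v[, 3],
                             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n1 <- cr(b1, b2); n2 <- cr(b2, b3)
  m1 <- cr(n1, b2 / sqrt(rowSums(b2^2)))
  atan2(rowSums(m1 * n2), rowSums(n1 * n2))
}

.pair_geometry <- function(xyz, pairs, idx) {
  inset <- logical(nrow(xyz)); inset[idx] <- TRUE
  keep <- inset[pairs$i] & inset[pairs$j]
  i <- pairs$i[keep]; j <- pairs$j[keep]
  r <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
  if (length(r) && min(r) < 0.1)
    stop("overlapping atoms: pair distance ", format(min(r)), " A < 0.1 A")
  list(i = i, j = j, r = r, w_ee = pairs$w_ee[keep], w_vdw = pairs$w_vdw[keep])
}

#' Coulomb energy of a selection
#'
#' Pairwise `k_e q_i q_j / r` with `k_e = 332.0636` kcal A / (mol e^2),
#' Amber exclusions (1-2, 1-3 skipped; 1-4 divided by `scee`), no cutoff.
#'
#' @inheritParams bonded_energy
#' @param pairs optional precomputed [nonbonded_pairs()] table (hoist out
#'   of per-frame loops).
#' @return Energy in kcal/mol.
#' @export
coulomb_energy <- function(frame, selection, ff, pairs = NULL) {
  fr <- .as_frame(frame); xyz <- fr$xyz
  idx <- .sel_indices(selection, nrow(xyz))
  if (length(idx) < 2) return(0)
  pairs <- pairs %||% nonbonded_pairs(ff, nrow(xyz))
  g <- .pair_geometry(xyz, pairs, idx)
  if (!length(g$r)) return(0)
  .KE * sum(g$w_ee * ff$charges[g$i] * ff$charges[g$j] / g$r)
}

#' Lennard-Jones energy of a selection
#'
#' 12-6 potential in rmin/epsilon form with Lorentz-Berthelot combining,
#' Amber exclusions (1-2, 1-3 skipped; 1-4 divided by `scnb`), no cutoff.
#'
#' @inheritParams coulomb_energy
#' @return Energy in kcal/mol.
#' @export
lennard_jones_energy <- function(frame, selection, ff, pairs = NULL) {
  fr <- .as_frame(frame); xyz <- fr$xyz
  idx <- .sel_indices(selection, nrow(xyz))
  if (length(idx) < 2) return(0)
  pairs <- pairs %||% nonbonded_pairs(ff, nrow(xyz))
  g <- .pair_geometry(xyz, pairs, idx)
  if (!length(g$r)) return(0)
  rmin <- ff$rmin_half[g$i] + ff$rmin_half[g$j]
  eps <- sqrt(ff$epsilon[g$i] * ff$epsilon[g$j])
  s6 <- (rmin / g$r)^6
  sum(g$w_vdw * eps * (s6^2 - 2 * s6))
}

#' Full molecular-mechanics energy breakdown of a selection
#'
#' @inheritParams coulomb_energy
#' @return A list of class `"mm_breakdown"` with `e_int`, `e_ele`, `e_vdw`
#'   and their sum `e_mm` (kcal/mol).  `e_mm == e_int + e_ele + e_vdw` by
#'   construction.
#' @export
mm_energy <- function(frame, selection, ff, pairs = NULL) {
  fr <- .as_frame(frame)
  pairs <- pairs %||% nonbonded_pairs(ff, nrow(fr$xyz))
  e_int <- bonded_energy(fr, selection, ff)
  e_ele <- coulomb_energy(fr, selection, ff, pairs)
  e_vdw <- lennard_jones_energy(fr, selection, ff, pairs)
  structure(list(e_int = e_int, e_ele = e_ele, e_vdw = e_vdw,
                 e_mm = e_int + e_ele + e_vdw),
            class = "mm_breakdown")
}

#' @export
print.mm_breakdown <- function(x, ...) {
  cat(sprintf("E_MM = %.4f  (E_int %.4f + E_ele %.4f + E_vdw %.4f) kcal/mol\n",
              x$e_mm, x$e_int, x$e_ele, x$e_vdw))
  invisible(x)
}
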