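# Synthetic two-chain systems and staged trajectories.
#
# The generator emulates the statistical structure the analysis assumes:
# a dimer trajectory sampled every 4 ps over a 19 ns window whose
# molecular-mechanics and solvation components of the binding energy are
# anti-correlated, with four planted energetic stages delimited by
# closest-approach events; plus a multi-temperature replica set with one
# designated best-bound replica.  Trajectories are constructed
# geometrically (rigid-body placement + planted contacts + Gaussian noise);
# there is no dynamics engine, because the analysis, not the simulation,
# is what the package implements.

# Local-frame template for one simplified residue (A): backbone N,H,CA,C,O
# and one side-chain pseudo-atom SC.  Residues are spaced 3.6 A along x.
.RES_TEMPLATE <- rbind(
  N  = c(0.00,  0.00, 0.00),
  H  = c(-0.25, 0.95, 0.00),
  CA = c(1.45,  0.25, 0.00),
  C  = c(2.45, -0.60, 0.00),
  O  = c(2.35, -1.82, 0.00),
  SC = c(1.60,  1.55, 0.75))
.RES_SPACING <- 3.6

# residue types: side-chain element and charge
.RES_TYPES <- list(
  ALA = list(sc_element = "C", sc_charge = 0),
  SER = list(sc_element = "O", sc_charge = 0),
  LYS = list(sc_element = "N", sc_charge = +1),
  GLU = list(sc_element = "O", sc_charge = -1))

.ATOM_PARAMS <- list(  # rmin/2 (A), epsilon (kcal/mol), intrinsic radius (A)
  H = c(rmin_half = 0.6000, epsilon = 0.0157, radius = 1.20),
  C = c(rmin_half = 1.9080, epsilon = 0.1094, radius = 1.70),
  N = c(rmin_half = 1.8240, epsilon = 0.1700, radius = 1.55),
  O = c(rmin_half = 1.6612, epsilon = 0.2100, radius = 1.50))

# The SC pseudo-atom stands for a whole side-chain group (several heavy
# atoms), so it gets coarse-grained parameters: a larger LJ sphere with a
# deeper well, and a larger intrinsic radius (charge spread over a group,
# not a bare ion).
.SC_PARAMS <- c(rmin_half = 2.3, epsilon = 0.55, radius = 2.3)

.BACKBONE_CHARGE <- c(N = -0.35, H = 0.25, CA = 0.10, C = 0.45, O = -0.45)

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  force(expr)
}

#' Build a toy two-chain peptide dimer with full parameters
#'
#' Two identical chains of simplified residues, each residue six atoms
#' (backbone N, H, CA, C, O and one side-chain pseudo-atom SC carrying the
#' residue charge: acidic -1, basic +1, polar/hydrophobic 0).  Every chain
#' contains at least one acid-base pair (basic residue first, acidic
#' residue last) so salt-bridge-like contacts can form; the remaining
#' residue types are drawn reproducibly from the polar/hydrophobic pool.
#' Chain B is chain A rotated 180 degrees about the z axis and offset in z.
#'
#' @param n_residues_per_chain residues per chain, between 3 and 30.
#' @param seed integer RNG seed; the same seed reproduces the system
#'   bit-for-bit.
#' @param separation reference chain-centroid separation, A (z offset of
#'   chain B in the returned reference coordinates).
#' @return A list of class `"dimer_system"` with elements `topology`
#'   ([topology()]), `forcefield` ([forcefield()]), and `xyz` (reference
#'   frame coordinates, n x 3).
#' @export
build_toy_dimer <- function(n_residues_per_chain, seed = 1, separation = 12) {
  n <- n_residues_per_chain
  if (n < 3 || n > 30) stop("n_residues_per_chain must be in [3, 30]")
  seq_types <- .with_seed(seed, {
    s <- sample(c("ALA", "SER"), n, replace = TRUE)
    s[1] <- "LYS"; s[n] <- "GLU"
    s
  })
  one_chain <- function(chain, resid_offset = 0) {
    at <- do.call(rbind, lapply(seq_len(n), function(i) {
      tp <- .RES_TYPES[[seq_types[i]]]
      data.frame(name = rownames(.RES_TEMPLATE), resname = seq_types[i],
                 resid = i, chain = chain,
                 element = c("N", "H", "C", "C", "O", tp$sc_element),
                 charge = c(unname(.BACKBONE_CHARGE), tp$sc_charge),
                 stringsAsFactors = FALSE)
    }))
    xyz <- do.call(rbind, lapply(seq_len(n), function(i)
      sweep(.RES_TEMPLATE, 2, c((i - 1) * .RES_SPACING, 0, 0), `+`)))
    list(atoms = at, xyz = xyz)
  }
  a <- one_chain("A"); b <- one_chain("B")
  atoms <- rbind(a$atoms, b$atoms)
  atoms$serial <- seq_len(nrow(atoms))
  atoms$mass <- unname(.ELEMENT_MASS[atoms$element])
  top <- topology(atoms[c("serial", "name", "resname", "resid", "chain",
                          "element", "mass")],
                  bonds = .infer_bonds(atoms))
  xyz <- rbind(a$xyz, .place_chain_b(b$xyz, a$xyz, separation))
  ff <- .toy_forcefield(top, atoms$charge, xyz)
  structure(list(topology = top, forcefield = ff, xyz = unname(xyz)),
            class = "dimer_system")
}

#' @export
print.dimer_system <- function(x, ...) {
  print(x$topology)
  invisible(x)
}

# chain B = chain A rotated pi about the z axis through A's centroid,
# then shifted along z by `separation`
.place_chain_b <- function(xyz_b, xyz_a, separation) {
  c_a <- colMeans(xyz_a)
  out <- xyz_b
  out[, 1] <- 2 * c_a[1] - xyz_b[, 1]
  out[, 2] <- 2 * c_a[2] - xyz_b[, 2]
  out[, 3] <- xyz_b[, 3] + separation
  out
}

# bonded parameters with equilibrium values read off the reference
# geometry, so the rigid template is (near) the bonded-energy minimum
.toy_forcefield <- function(top, charges, ref_xyz) {
  at <- top$atoms
  b <- top$bonds
  d <- sqrt(rowSums((ref_xyz[b[, 1], , drop = FALSE] -
                     ref_xyz[b[, 2], , drop = FALSE])^2))
  kb <- ifelse(at$element[b[, 1]] == "H" | at$element[b[, 2]] == "H", 400, 300)
  bonds <- data.frame(i = b[, 1], j = b[, 2], kb = kb, b0 = d)
  # angle terms: every path i-j-k in the bond graph
  adj <- vector("list", nrow(at))
  for (r in seq_len(nrow(b))) {
    adj[[b[r, 1]]] <- c(adj[[b[r, 1]]], b[r, 2])
    adj[[b[r, 2]]] <- c(adj[[b[r, 2]]], b[r, 1])
  }
  ang <- list()
  for (j in seq_len(nrow(at))) {
    nb <- adj[[j]]
    if (length(nb) < 2) next
    for (p in utils::combn(sort(nb), 2, simplify = FALSE))
      ang[[length(ang) + 1L]] <- c(p[1], j, p[2])
  }
  angles <- NULL
  if (length(ang)) {
    am <- do.call(rbind, ang)
    v1 <- ref_xyz[am[, 1], , drop = FALSE] - ref_xyz[am[, 2], , drop = FALSE]
    v2 <- ref_xyz[am[, 3], , drop = FALSE] - ref_xyz[am[, 2], , drop = FALSE]
    th <- acos(pmin(1, pmax(-1, rowSums(v1 * v2) /
                            (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2))))))
    angles <- data.frame(i = am[, 1], j = am[, 2], k = am[, 3],
                         ktheta = 50, theta0 = th)
  }
  # backbone dihedrals N-CA-C-N' and CA-C-N'-CA' along each chain
  dih <- list()
  for (ch in unique(at$chain)) {
    rid <- sort(unique(at$resid[at$chain == ch]))
    aidx <- function(res, nm) which(at$chain == ch & at$resid == res & at$name == nm)
    for (k in seq_len(length(rid) - 1L)) {
      dih[[length(dih) + 1L]] <- c(aidx(rid[k], "N"), aidx(rid[k], "CA"),
                                   aidx(rid[k], "C"), aidx(rid[k + 1], "N"))
      dih[[length(dih) + 1L]] <- c(aidx(rid[k], "CA"), aidx(rid[k], "C"),
                                   aidx(rid[k + 1], "N"), aidx(rid[k + 1], "CA"))
    }
  }
  dihedrals <- NULL
  if (length(dih)) {
    dm <- do.call(rbind, dih)
    dihedrals <- data.frame(i = dm[, 1], j = dm[, 2], k = dm[, 3], l = dm[, 4],
                            vn2 = 0.5, n = 2, gamma = pi)
  }
  pp <- do.call(rbind, .ATOM_PARAMS[at$element])
  sc <- at$name == "SC"
  pp[sc, ] <- matrix(.SC_PARAMS, sum(sc), 3, byrow = TRUE)
  forcefield(charges = charges, rmin_half = pp[, "rmin_half"],
             epsilon = pp[, "epsilon"], radius = pp[, "radius"],
             mass = at$mass, bonds = bonds, angles = angles,
             dihedrals = dihedrals)
}

#' Plan for a staged synthetic trajectory
#'
#' The plan plants the energetic anatomy the stage-segmentation analysis
#' looks for: the chains approach most closely at the stage boundaries, so
#' the molecular-mechanics component of the binding energy has local
#' minima there while the solvation component peaks (the two series are
#' anti-correlated).  Hydrogen bonds are planted by an explicit per-bond
#' occupancy schedule.
#'
#' @param n_frames number of frames to generate.
#' @param boundaries frame indices of the planted stage boundaries
#'   (strictly increasing, interior).  Default: the four stage delimiters
#'   at fractions 2.8/19, 6.8/19, 11.7/19 and 18.2/19 of the trajectory.
#' @param stage_sep mean chain separation per segment between boundaries,
#'   A (length `length(boundaries) + 1`).
#' @param boundary_sep closest-approach separation at each boundary, A.
#' @param noise Gaussian coordinate noise s.d., A.
#' @param hbond_schedule list of planted bonds; each element a list with
#'   `donor_chain`, `donor_res` (backbone N-H donor), `acceptor_chain`,
#'   `acceptor_res` (side-chain SC acceptor) and `occupancy` (fraction of
#'   frames, realized by an exact deterministic on/off pattern).
#' @param dt frame spacing, ps.
#' @param seed integer RNG seed.
#' @return Object of class `"stage_plan"`.
#' @export
stage_plan <- function(n_frames,
                       boundaries = round(c(2.8, 6.8, 11.7, 18.2) / 19 * n_frames),
                       stage_sep = c(10, 8.5, 11, 8, 9.5)[seq_len(length(boundaries) + 1)],
                       boundary_sep = 4.8, noise = 0.08,
                       hbond_schedule = list(), dt = 4, seed = 1) {
  boundaries <- as.integer(boundaries)
  if (any(diff(boundaries) <= 0)) stop("boundaries must be strictly increasing")
  if (any(boundaries < 2L) || any(boundaries > n_frames - 1L))
    stop("boundaries must lie strictly inside the frame range")
  if (noise < 0) stop("noise must be >= 0")
  if (length(stage_sep) != length(boundaries) + 1L)
    stop("need one stage separation per segment (boundaries + 1)")
  structure(list(n_frames = as.integer(n_frames), boundaries = boundaries,
                 stage_sep = stage_sep, boundary_sep = boundary_sep,
                 noise = noise, hbond_schedule = hbond_schedule,
                 dt = dt, seed = seed),
            class = "stage_plan")
}

# piecewise-linear separation profile: stage plateaus with dips to
# boundary_sep at each planted boundary
.separation_profile <- function(plan) {
  n <- plan$n_frames
  b <- plan$boundaries
  seg_edges <- c(1L, b, n)
  mids <- floor((head(seg_edges, -1) + tail(seg_edges, -1)) / 2)
  xk <- c(1, rbind(mids[-length(mids)], b)[TRUE], mids[length(mids)], n)
  yk <- c(plan$stage_sep[1],
          rbind(plan$stage_sep[-length(plan$stage_sep)],
                rep(plan$boundary_sep, length(b)))[TRUE],
          plan$stage_sep[length(plan$stage_sep)],
          plan$stage_sep[length(plan$stage_sep)])
  kp <- !duplicated(xk)
  stats::approx(xk[kp], yk[kp], xout = seq_len(n), rule = 2)$y
}

# exact deterministic on/off pattern hitting round(n * frac) active frames
.occupancy_pattern <- function(n, frac) {
  k <- floor(seq_len(n) * frac + 1e-9)
  c(k[1] > 0, diff(k) > 0)
}

#' Generate a staged synthetic dimer trajectory
#'
#' Rigid-body approach/retreat of chain B according to the plan's
#' separation profile, planted hydrogen-bond geometry per the occupancy
#' schedule, and Gaussian coordinate noise.  Deterministic for a fixed
#' plan seed.
#'
#' @param system a [build_toy_dimer()] result.
#' @param plan a [stage_plan()].
#' @return A [trajectory()] with `plan$n_frames` frames spaced `plan$dt` ps.
#' @export
generate_staged_trajectory <- function(system, plan) {
  top <- system$topology
  at <- top$atoms
  na <- n_atoms(top)
  a_idx <- which(at$chain == top$chains[1])
  b_idx <- which(at$chain == top$chains[2])
  xyz_a <- system$xyz[a_idx, , drop = FALSE]
  # chain B local template (undo reference placement): regenerate from A
  sep <- .separation_profile(plan)
  sched <- plan$hbond_schedule
  patterns <- lapply(sched, function(s) .occupancy_pattern(plan$n_frames, s$occupancy))
  atom_of <- function(chain, res, name) {
    ch <- if (chain == "A") top$chains[1] else top$chains[2]
    which(at$chain == ch & at$resid == res & at$name == name)
  }
  out <- matrix(NA_real_, plan$n_frames, 3 * na)
  .with_seed(plan$seed, {
    for (t in seq_len(plan$n_frames)) {
      fr <- matrix(NA_real_, na, 3)
      fr[a_idx, ] <- xyz_a
      fr[b_idx, ] <- .place_chain_b(xyz_a, xyz_a, sep[t])
      for (s in seq_along(sched)) {
        if (!patterns[[s]][t]) next
        sc <- sched[[s]]
        dn <- atom_of(sc$donor_chain, sc$donor_res, "N")
        dh <- atom_of(sc$donor_chain, sc$donor_res, "H")
        ac <- atom_of(sc$acceptor_chain, sc$acceptor_res, "SC")
        u <- fr[dh, ] - fr[dn, ]
        u <- u / sqrt(sum(u^2))
        fr[ac, ] <- fr[dh, ] + 1.95 * u
      }
      for (try in seq_len(20)) {
        cand <- fr + matrix(rnorm(3 * na, sd = plan$noise), na, 3)
        if (plan$noise == 0 || min(stats::dist(cand)) >= 0.5) break
        if (try == 20) stop("could not place frame ", t, " without atom overlap")
      }
      out[t, ] <- as.numeric(t(cand))
    }
  })
  trajectory(top, out, dt = plan$dt)
}

#' Generate a multi-temperature replica set
#'
#' One trajectory per temperature.  Coordinate noise grows with
#' temperature (amplitude proportional to sqrt(T/305)); the replica at the
#' temperature closest to `best_temp` is planted as the best-bound one
#' (tightest inter-chain contact), so the replica-selection criterion has
#' a known answer.
#'
#' @param system a [build_toy_dimer()] result.
#' @param temperatures numeric vector of replica temperatures, K (>= 2).
#' @param seed integer RNG seed.
#' @param n_frames frames per replica.
#' @param dt frame spacing, ps.
#' @param best_temp temperature of the planted best replica, K.
#' @return List of [trajectory()] objects, one per temperature, with a
#'   `temperatures` attribute.
#' @export
generate_replica_set <- function(system, temperatures, seed = 1,
                                 n_frames = 40, dt = 4, best_temp = 305) {
  if (length(temperatures) < 2) stop("need at least 2 temperatures")
  dist_rank <- abs(temperatures - best_temp)
  seps <- 5.0 + 0.35 * dist_rank^0.8
  out <- vector("list", length(temperatures))
  for (r in seq_along(temperatures)) {
    plan <- stage_plan(n_frames = n_frames,
                       boundaries = c(2L, as.integer(n_frames - 1L)),
                       stage_sep = rep(seps[r], 3),
                       boundary_sep = seps[r],
                       noise = 0.05 * sqrt(temperatures[r] / 305),
                       dt = dt, seed = seed + r)
    out[[r]] <- generate_staged_trajectory(system, plan)
  }
  attr(out, "temperatures") <- temperatures
  out
}
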