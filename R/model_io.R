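# Topology / trajectory / force-field I/O and the frame-sampling convention.
#
# Internal conventions: atom indices are 1-based R indices into the atom
# table; PDB files keep their native serial numbers.  Coordinates are in
# Angstrom, times in ps, energies in kcal/mol.

.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)

# Bond templates for the simplified residues used throughout: each residue
# carries backbone N, H, CA, C, O and one side-chain pseudo-atom SC.
.RESIDUE_BONDS <- list(c("N", "H"), c("N", "CA"), c("CA", "C"),
                       c("C", "O"), c("CA", "SC"))

#' Construct a two-chain topology
#'
#' Low-level constructor; most users obtain topologies from
#' [read_topology()] or [build_toy_dimer()].
#'
#' @param atoms data frame with columns `serial` (file serial), `name`,
#'   `resname`, `resid` (residue index), `chain` (single character),
#'   `element`, `mass` (amu).
#' @param bonds two-column integer matrix of 1-based atom indices (rows are
#'   unordered pairs).  Bonds may not cross chains.
#' @param chains character vector of chain identifiers in order of first
#'   appearance.  Dimer analyses require exactly two.
#' @return An object of class `"topology"`.
#' @export
topology <- function(atoms, bonds, chains = unique(atoms$chain)) {
  stopifnot(is.data.frame(atoms))
  need <- c("serial", "name", "resname", "resid", "chain", "element", "mass")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms table lacks columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(atoms$serial)) stop("duplicate atom serials in topology")
  if (any(!atoms$chain %in% chains)) stop("atom chain id outside declared chains")
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0)) stop("atom masses must be > 0")
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (nrow(bonds)) {
    if (any(bonds < 1L | bonds > nrow(atoms))) stop("bond index out of range")
    if (any(atoms$chain[bonds[, 1]] != atoms$chain[bonds[, 2]]))
      stop("bonds may not cross chains (two separate peptides)")
  }
  structure(list(atoms = atoms, bonds = bonds, chains = chains),
            class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat("topology: ", nrow(x$atoms), " atoms, ",
      length(unique(paste(x$atoms$chain, x$atoms$resid))), " residues, chains {",
      paste(x$chains, collapse = ","), "}, ", nrow(x$bonds), " bonds\n", sep = "")
  invisible(x)
}

#' Number of atoms in a topology
#' @param top a [topology()].
#' @return Integer count.
#' @export
n_atoms <- function(top) nrow(top$atoms)

.guess_element <- function(name) {
  el <- sub("^[0-9]*", "", name)
  el <- substr(el, 1, 1)
  el[!el %in% names(.ELEMENT_MASS)] <- "C"
  el
}

#' Read a two-chain topology from a PDB file
#'
#' Parses ATOM records (via bio3d), discovers chains, and infers covalent
#' bonds from the built-in simplified-residue template (backbone
#' N-H/N-CA/CA-C/C-O/CA-SC plus the peptide bond C(i)-N(i+1) within each
#' chain).  CONECT records, when present, are honoured in addition.
#' Bonds are never created across chains.
#'
#' @param file path to a PDB file, or a character vector of PDB lines.
#' @param dimer logical; when `TRUE` (default) exactly two chains are
#'   required.
#' @return A [topology()] object.
#' @export
read_topology <- function(file, dimer = TRUE) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file))
    readLines(file) else unlist(strsplit(file, "\n", fixed = TRUE))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, multi = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records found")
  bad <- which(is.na(at$chain) | !nzchar(trimws(at$chain)))
  if (length(bad))
    stop("missing chain identifier at ATOM record with serial ", at$eleno[bad[1]])
  chains <- unique(at$chain)
  if (dimer && length(chains) != 2L)
    stop("dimer mode requires exactly 2 chains, found ", length(chains),
         " (", paste(chains, collapse = ","), ")")
  element <- if (!is.null(at$elesy) && any(nzchar(trimws(at$elesy))))
    ifelse(nzchar(trimws(at$elesy)), trimws(at$elesy), .guess_element(at$elety))
  else .guess_element(at$elety)
  atoms <- data.frame(serial = at$eleno, name = trimws(at$elety),
                      resname = trimws(at$resid), resid = at$resno,
                      chain = at$chain, element = element,
                      mass = unname(.ELEMENT_MASS[element]),
                      stringsAsFactors = FALSE)
  atoms$mass[is.na(atoms$mass)] <- 12.011
  bonds <- .infer_bonds(atoms)
  conect <- .parse_conect(lines, atoms$serial)
  if (nrow(conect)) bonds <- unique(rbind(bonds, conect))
  # drop any CONECT-derived cross-chain record rather than erroring: the
  # topology contract is two covalently separate peptides
  if (nrow(bonds)) {
    keep <- atoms$chain[bonds[, 1]] == atoms$chain[bonds[, 2]]
    bonds <- bonds[keep, , drop = FALSE]
  }
  topology(atoms, bonds, chains)
}

.infer_bonds <- function(atoms) {
  out <- list()
  key <- paste(atoms$chain, atoms$resid)
  for (res in unique(key)) {
    idx <- which(key == res)
    nm <- atoms$name[idx]
    for (bp in .RESIDUE_BONDS) {
      i <- idx[match(bp[1], nm)]; j <- idx[match(bp[2], nm)]
      if (!is.na(i) && !is.na(j)) out[[length(out) + 1L]] <- c(i, j)
    }
  }
  # peptide bonds C(i) -> N(i+1) along each chain
  for (ch in unique(atoms$chain)) {
    rid <- sort(unique(atoms$resid[atoms$chain == ch]))
    for (k in seq_len(length(rid) - 1L)) {
      i <- which(atoms$chain == ch & atoms$resid == rid[k] & atoms$name == "C")
      j <- which(atoms$chain == ch & atoms$resid == rid[k + 1L] & atoms$name == "N")
      if (length(i) == 1L && length(j) == 1L) out[[length(out) + 1L]] <- c(i, j)
    }
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2))
  m <- do.call(rbind, out)
  m <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  unique(m)
}

.parse_conect <- function(lines, serials) {
  cl <- grep("^CONECT", lines, value = TRUE)
  if (!length(cl)) return(matrix(integer(0), ncol = 2))
  out <- list()
  for (ln in cl) {
    f <- suppressWarnings(as.integer(strsplit(trimws(substring(ln, 7)), "\\s+")[[1]]))
    f <- f[!is.na(f)]
    if (length(f) < 2) next
    i <- match(f[1], serials)
    for (s in f[-1]) {
      j <- match(s, serials)
      if (!is.na(i) && !is.na(j)) out[[length(out) + 1L]] <- c(min(i, j), max(i, j))
    }
  }
  if (!length(out)) return(matrix(integer(0), ncol = 2))
  unique(do.call(rbind, out))
}

#' Construct a trajectory
#'
#' @param top a [topology()].
#' @param xyz numeric matrix, one row per frame, `3 * n_atoms` columns in
#'   bio3d order (x1,y1,z1,x2,...), Angstrom.
#' @param dt time between stored frames, ps.
#' @param time optional explicit frame times (ps); defaults to
#'   `(0:(n-1)) * dt`.
#' @return Object of class `"trajectory"`.
#' @export
trajectory <- function(top, xyz, dt, time = NULL) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L * n_atoms(top))
    stop("xyz has ", ncol(xyz) / 3, " atoms per frame but topology has ", n_atoms(top))
  if (!nrow(xyz)) stop("trajectory has zero frames")
  if (any(!is.finite(xyz))) stop("non-finite coordinates in trajectory")
  if (is.null(time)) time <- (seq_len(nrow(xyz)) - 1) * dt
  if (nrow(xyz) > 1L) {
    dts <- diff(time)
    if (any(dts <= 0)) stop("frame times must be strictly increasing")
    if (any(abs(dts - dt) > 1e-6 * dt)) stop("frame spacing is not uniform at dt")
  }
  structure(list(topology = top, xyz = xyz, time = time, dt = dt),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory: ", nrow(x$xyz), " frames x ", n_atoms(x$topology),
      " atoms, dt = ", x$dt, " ps, span = ",
      round((x$time[length(x$time)] - x$time[1]) / 1000, 3), " ns\n", sep = "")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()].
#' @return Integer count.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Extract one frame as an n x 3 coordinate matrix
#'
#' @param traj a [trajectory()].
#' @param i frame index.
#' @return Object of class `"frame"`: a list with `xyz` (n x 3 matrix) and
#'   `time` (ps).
#' @export
get_frame <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  frame(matrix(traj$xyz[i, ], ncol = 3, byrow = TRUE), traj$time[i])
}

#' @rdname get_frame
#' @param xyz n x 3 coordinate matrix (Angstrom).
#' @param time frame time in ps.
#' @export
frame <- function(xyz, time = 0) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3, all(is.finite(xyz)))
  structure(list(xyz = xyz, time = time), class = "frame")
}

.as_frame <- function(x) {
  if (inherits(x, "frame")) x else frame(as.matrix(x))
}

#' Read a multi-model PDB trajectory
#'
#' One frame per MODEL block; the atom count of every model must match the
#' topology.
#'
#' @param file path to a multi-model PDB file.
#' @param top the matching [topology()].
#' @param dt frame spacing in ps (PDB carries no time axis).
#' @return A [trajectory()].
#' @export
read_trajectory <- function(file, top, dt = 4) {
  pdb <- bio3d::read.pdb(file, multi = TRUE, verbose = FALSE)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (!nrow(xyz)) stop("trajectory file contains zero frames")
  if (ncol(xyz) != 3L * n_atoms(top))
    stop("atom count mismatch: file has ", ncol(xyz) / 3,
         " atoms per frame, topology has ", n_atoms(top))
  trajectory(top, xyz, dt = dt)
}

#' Write a trajectory (or a topology with reference coordinates) as PDB
#'
#' Multi-frame trajectories are written as MODEL/ENDMDL blocks.
#'
#' @param traj a [trajectory()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_trajectory <- function(traj, file) {
  at <- traj$topology$atoms
  bio3d::write.pdb(file = file, xyz = traj$xyz, resno = at$resid,
                   resid = at$resname, eleno = at$serial, elety = at$name,
                   chain = at$chain, elesy = at$element)
  # append CONECT records so bond topology survives the round trip
  b <- traj$topology$bonds
  if (nrow(b)) {
    con <- sprintf("CONECT%5d%5d", at$serial[b[, 1]], at$serial[b[, 2]])
    lines <- readLines(file)
    endl <- grep("^END", lines)
    ins <- if (length(endl)) endl[length(endl)] - 1L else length(lines)
    writeLines(c(lines[seq_len(ins)], con, "END"), file)
  }
  invisible(file)
}

#' Select a chain (or the whole complex) from a topology
#'
#' @param top a [topology()].
#' @param which `"complex"`, `"A"`, or `"B"`; `"A"`/`"B"` refer to the
#'   first/second declared chain.
#' @return Object of class `"selection"` with `label` and ascending
#'   `indices`.
#' @export
select_chain <- function(top, which = c("complex", "A", "B")) {
  if (!is.character(which) || length(which) != 1L ||
      !which %in% c("complex", "A", "B"))
    stop("unknown selection label: ", paste(which, collapse = ","))
  if (length(top$chains) != 2L) stop("chain selection requires a two-chain topology")
  idx <- switch(which,
    complex = seq_len(n_atoms(top)),
    A = which(top$atoms$chain == top$chains[1]),
    B = which(top$atoms$chain == top$chains[2]))
  structure(list(label = which, indices = sort(idx)), class = "selection")
}

#' @export
print.selection <- function(x, ...) {
  cat("selection \"", x$label, "\": ", length(x$indices), " atoms\n", sep = "")
  invisible(x)
}

#' Sample frames at a fixed interval from the final window of a trajectory
#'
#' Keeps every `(interval/dt)`-th stored frame from the last `window` ns,
#' under a half-open window convention: the final frame is included, the
#' frame at the window start is excluded.  A 19 ns window at 4 ps spacing
#' therefore yields exactly 4750 frames.
#'
#' @param traj a [trajectory()].
#' @param interval sampling interval, ps; must be a multiple of `traj$dt`.
#' @param window window length, ns; must not exceed the trajectory span.
#' @return A [trajectory()] with `dt = interval`.
#' @export
sample_frames <- function(traj, interval, window) {
  dt <- traj$dt
  stride <- interval / dt
  if (abs(stride - round(stride)) > 1e-6)
    stop("interval (", interval, " ps) is not a multiple of dt (", dt, " ps)")
  stride <- as.integer(round(stride))
  span <- traj$time[n_frames(traj)] - traj$time[1]
  if (window * 1000 > span + 1e-6)
    stop("window (", window, " ns) exceeds trajectory span (", span / 1000, " ns)")
  k <- floor(window * 1000 / interval + 1e-9)
  if (k < 1L) stop("window shorter than one sampling interval")
  n <- n_frames(traj)
  idx <- n - stride * (rev(seq_len(k)) - 1L)
  if (idx[1] < 1L) stop("window (", window, " ns) exceeds trajectory span")
  trajectory(traj$topology, traj$xyz[idx, , drop = FALSE], dt = interval,
             time = traj$time[idx])
}
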