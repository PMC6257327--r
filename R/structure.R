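# Structural analyses of dimer trajectories: Kabsch RMSD dissimilarity,
# hydrogen-bond detection / presence / density / occupancy, side-chain
# contact maps, and the ten-class dimer-conformation taxonomy.

#' Minimal RMSD between two frames after Kabsch superposition
#'
#' @param frame_a,frame_b frames (or n x 3 matrices) with identical atom
#'   counts.
#' @param selection a [select_chain()] selection or integer indices
#'   (>= 3 atoms).
#' @return RMSD in Angstrom (>= 0, symmetric in its arguments).
#' @export
kabsch_rmsd <- function(frame_a, frame_b, selection = NULL) {
  a <- .as_frame(frame_a)$xyz
  b <- .as_frame(frame_b)$xyz
  idx <- .sel_indices(selection %||% seq_len(nrow(a)), nrow(a))
  if (length(idx) < 3) stop("RMSD superposition needs at least 3 atoms")
  va <- as.numeric(t(a[idx, , drop = FALSE]))
  vb <- as.numeric(t(b[idx, , drop = FALSE]))
  as.numeric(bio3d::rmsd(va, vb, fit = TRUE))
}

#' Pairwise RMSD dissimilarity matrix of a trajectory
#'
#' `M[i, j]` is the Kabsch RMSD between frames i and j over the selection
#' (typically one monomer: A and B are analysed separately).
#'
#' @param traj a [trajectory()] (>= 2 frames).
#' @param selection selection to superpose on (default: whole complex).
#' @return Symmetric matrix with zero diagonal, Angstrom.
#' @export
rmsd_dissimilarity_matrix <- function(traj, selection = NULL) {
  nf <- n_frames(traj)
  if (nf < 2) stop("need at least 2 frames")
  idx <- .sel_indices(selection %||% select_chain(traj$topology, "complex"),
                      n_atoms(traj$topology))
  cols <- as.vector(rbind(3 * idx - 2, 3 * idx - 1, 3 * idx))
  x <- traj$xyz[, cols, drop = FALSE]
  m <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) {
    for (j in (i + 1L):nf) {
      r <- as.numeric(bio3d::rmsd(x[i, ], x[j, ], fit = TRUE))
      m[i, j] <- r; m[j, i] <- r
    }
  }
  m
}

# pairs of atoms within `k` bonds in the covalent graph, as an n x n
# logical matrix (used to exclude covalent neighbours from H-bonds)
.graph_near <- function(bonds, n, k = 3) {
  A <- matrix(FALSE, n, n)
  if (nrow(bonds)) {
    A[cbind(bonds[, 1], bonds[, 2])] <- TRUE
    A[cbind(bonds[, 2], bonds[, 1])] <- TRUE
  }
  near <- A
  step <- A
  for (d in seq_len(k - 1L)) {
    step <- (step %*% A) > 0
    near <- near | step
  }
  diag(near) <- TRUE
  near
}

#' Detect hydrogen bonds in one frame
#'
#' Geometric criterion: donor (N or O covalently bound to the hydrogen)
#' to acceptor (N or O) distance at most `dist_cutoff` and
#' donor-H-acceptor angle at least `angle_cutoff`.  Donor-acceptor pairs
#' within three covalent bonds are skipped.  Bonds are categorized as
#' `inter`, `intra_A` or `intra_B` by the chain membership of donor and
#' acceptor.
#'
#' @param frame a [frame()] (or n x 3 matrix).
#' @param top a [topology()].
#' @param dist_cutoff donor-acceptor distance cutoff, A (default 3.5).
#' @param angle_cutoff donor-H-acceptor angle cutoff, degrees
#'   (default 120).
#' @return Data frame with columns `donor`, `hydrogen`, `acceptor`
#'   (atom indices), `category`, `label`; zero rows when no bond is found.
#' @export
detect_hbonds <- function(frame, top, dist_cutoff = 3.5, angle_cutoff = 120) {
  fr <- .as_frame(frame)
  xyz <- fr$xyz
  at <- top$atoms
  n <- nrow(at)
  near <- .graph_near(top$bonds, n, 3)
  is_h <- at$element == "H"
  is_no <- at$element %in% c("N", "O")
  # donor-H pairs from the bond list
  b <- top$bonds
  dh <- b[(is_no[b[, 1]] & is_h[b[, 2]]) | (is_h[b[, 1]] & is_no[b[, 2]]), ,
          drop = FALSE]
  if (nrow(dh)) {
    flip <- is_h[dh[, 1]]
    dh[flip, ] <- dh[flip, 2:1]
  }
  acc <- which(is_no)
  out <- list()
  for (r in seq_len(nrow(dh))) {
    dn <- dh[r, 1]; hy <- dh[r, 2]
    cand <- acc[!near[dn, acc]]
    if (!length(cand)) next
    d <- sqrt(colSums((t(xyz[cand, , drop = FALSE]) - xyz[dn, ])^2))
    cand <- cand[d <= dist_cutoff]
    if (!length(cand)) next
    v1 <- xyz[dn, ] - xyz[hy, ]
    va <- t(xyz[cand, , drop = FALSE]) - xyz[hy, ]
    cosang <- colSums(va * v1) / (sqrt(colSums(va^2)) * sqrt(sum(v1^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    cand <- cand[ang >= angle_cutoff]
    for (ac in cand) out[[length(out) + 1L]] <- c(dn, hy, ac)
  }
  if (!length(out))
    return(data.frame(donor = integer(0), hydrogen = integer(0),
                      acceptor = integer(0), category = character(0),
                      label = character(0)))
  m <- do.call(rbind, out)
  dch <- at$chain[m[, 1]]; ach <- at$chain[m[, 3]]
  category <- ifelse(dch != ach, "inter",
                     ifelse(dch == top$chains[1], "intra_A", "intra_B"))
  atom_tag <- function(i) paste0(at$chain[i], ":", at$resname[i], at$resid[i],
                                 "@", at$name[i])
  data.frame(donor = m[, 1], hydrogen = m[, 2], acceptor = m[, 3],
             category = category,
             label = paste0(atom_tag(m[, 1]), "->", atom_tag(m[, 3])),
             stringsAsFactors = FALSE)
}

#' Hydrogen-bond presence matrix along a trajectory
#'
#' Columns are every donor-H-acceptor triple observed in at least one
#' frame; entries are 1 (present) or 0 (absent).  No occupancy threshold
#' is applied.  Row sums equal the per-frame bond counts.
#'
#' @inheritParams detect_hbonds
#' @param traj a [trajectory()].
#' @return Binary matrix `n_frames x n_bonds` of class
#'   `"hbond_matrix"` with bond labels as column names and a `categories`
#'   attribute (per column).
#' @export
hbond_presence_matrix <- function(traj, dist_cutoff = 3.5, angle_cutoff = 120) {
  top <- traj$topology
  per_frame <- lapply(seq_len(n_frames(traj)), function(t)
    detect_hbonds(get_frame(traj, t), top, dist_cutoff, angle_cutoff))
  keys <- unique(do.call(rbind, lapply(per_frame, function(d)
    d[c("label", "category")])))
  if (is.null(keys) || !nrow(keys)) {
    m <- matrix(0L, n_frames(traj), 0)
    return(structure(m, categories = character(0),
                     class = c("hbond_matrix", "matrix", "array")))
  }
  m <- matrix(0L, n_frames(traj), nrow(keys),
              dimnames = list(NULL, keys$label))
  for (t in seq_along(per_frame)) {
    hit <- match(per_frame[[t]]$label, keys$label)
    if (length(hit)) m[t, hit] <- 1L
  }
  structure(m, categories = keys$category,
            class = c("hbond_matrix", "matrix", "array"))
}

#' Hydrogen-bond density time series per category
#'
#' Moving-window mean bond count per frame for the `inter`, `intra_A` and
#' `intra_B` categories (the three sum to the total-density series).
#'
#' @param pm an [hbond_presence_matrix()].
#' @param window odd moving-average window, frames.
#' @return Matrix `n_frames x 3` with columns `inter`, `intra_A`,
#'   `intra_B`.
#' @export
hbond_density <- function(pm, window = 101) {
  if (window > nrow(pm)) stop("window exceeds the number of frames")
  cats <- attr(pm, "categories")
  out <- sapply(c("inter", "intra_A", "intra_B"), function(cat) {
    cols <- which(cats == cat)
    counts <- if (length(cols)) rowSums(pm[, cols, drop = FALSE]) else
      numeric(nrow(pm))
    moving_average(counts, window)
  })
  rownames(out) <- NULL
  out
}

#' Hydrogen-bond occupancy table
#'
#' Occupation of each bond as the percentage of frames in which it is
#' present, sorted descending (ties broken by column order).
#'
#' @param pm an [hbond_presence_matrix()].
#' @param top_n number of bonds to report (default 5).
#' @return Data frame `bond`, `category`, `occupation` (percent).
#' @export
hbond_occupancy <- function(pm, top_n = 5) {
  if (!nrow(pm)) stop("presence matrix has zero frames")
  occ <- 100 * colMeans(pm)
  ord <- order(-occ, seq_along(occ))
  ord <- ord[seq_len(min(top_n, length(ord)))]
  data.frame(bond = colnames(pm)[ord],
             category = attr(pm, "categories")[ord],
             occupation = unname(occ[ord]),
             stringsAsFactors = FALSE)
}

# geometric centres of residue side chains (SC pseudo-atom set; CA
# fallback for residues without side-chain atoms), with residue metadata
.sidechain_centres <- function(xyz, top) {
  at <- top$atoms
  key <- paste(at$chain, at$resid)
  resk <- unique(key)
  ctr <- t(vapply(resk, function(k) {
    idx <- which(key == k & at$name == "SC")
    if (!length(idx)) idx <- which(key == k & at$name == "CA")
    colMeans(xyz[idx, , drop = FALSE])
  }, numeric(3)))
  info <- at[match(resk, key), c("chain", "resid", "resname")]
  list(xyz = ctr, chain = info$chain, resid = info$resid,
       label = paste0(info$chain, ":", info$resname, info$resid))
}

#' Side-chain contact map
#'
#' Two residues are in contact when the geometric centres of their side
#' chains are closer than `cutoff` (default 6.5 A).  Applied to a single
#' frame the map is binary; applied to a trajectory it holds the fraction
#' of frames in contact, with `threshold` available to binarize it.
#'
#' @param x a [frame()] (or n x 3 matrix) or a [trajectory()].
#' @param top a [topology()] (taken from `x` when it is a trajectory).
#' @param cutoff contact distance cutoff, A.
#' @param threshold fraction-of-frames threshold for binarizing a
#'   trajectory map; `NULL` (default) returns the fractions.
#' @return Symmetric residue x residue matrix with residue labels as
#'   dimnames; zero diagonal.
#' @export
sidechain_contact_map <- function(x, top = NULL, cutoff = 6.5, threshold = NULL) {
  if (inherits(x, "trajectory")) {
    top <- x$topology
    maps <- lapply(seq_len(n_frames(x)), function(t)
      sidechain_contact_map(get_frame(x, t), top, cutoff))
    m <- Reduce(`+`, maps) / length(maps)
    if (!is.null(threshold)) m <- (m >= threshold) + 0
    return(m)
  }
  fr <- .as_frame(x)
  sc <- .sidechain_centres(fr$xyz, top)
  d <- as.matrix(stats::dist(sc$xyz))
  m <- (d < cutoff) + 0
  diag(m) <- 0
  dimnames(m) <- list(sc$label, sc$label)
  m
}

#' Classifier thresholds for the dimer-conformation taxonomy
#'
#' @param turn_window residues on each side of a candidate turn used to
#'   form the incoming/outgoing chain directions.
#' @param turn_angle minimum direction-reversal angle at the turn,
#'   degrees.
#' @param ext_frac minimum straightness (end-to-end over contour length)
#'   for a flank to count as an extended strand.
#' @param min_flank minimum residues per flanking strand.
#' @param contact_cutoff side-chain contact cutoff for interface-strand
#'   identification, A.
#' @return List of thresholds.
#' @export
classifier_control <- function(turn_window = 2, turn_angle = 100,
                               ext_frac = 0.75, min_flank = 2,
                               contact_cutoff = 6.5) {
  list(turn_window = turn_window, turn_angle = turn_angle,
       ext_frac = ext_frac, min_flank = min_flank,
       contact_cutoff = contact_cutoff)
}

# hairpin detection on a CA trace; returns NULL or a description
.find_hairpin <- function(ca, ctl) {
  n <- nrow(ca)
  w <- ctl$turn_window
  if (n < 2 * w + 2) return(NULL)
  best <- NULL
  for (k in (w + 1):(n - w)) {
    v_in <- ca[k, ] - ca[k - w, ]
    v_out <- ca[k + w, ] - ca[k, ]
    cosang <- sum(v_in * v_out) / (sqrt(sum(v_in^2)) * sqrt(sum(v_out^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    if (ang >= ctl$turn_angle && (is.null(best) || ang > best$angle))
      best <- list(turn = k, angle = ang)
  }
  if (is.null(best)) return(NULL)
  k <- best$turn
  straightness <- function(idx) {
    if (length(idx) < 2) return(0)
    ee <- sqrt(sum((ca[idx[length(idx)], ] - ca[idx[1], ])^2))
    contour <- sum(sqrt(rowSums(diff(ca[idx, , drop = FALSE])^2)))
    ee / contour
  }
  fl_n <- seq_len(k - 1)           # N-terminal flank
  fl_c <- seq(k + 1, n)            # C-terminal flank
  if (length(fl_n) < ctl$min_flank || length(fl_c) < ctl$min_flank) return(NULL)
  if (straightness(fl_n) < ctl$ext_frac || straightness(fl_c) < ctl$ext_frac)
    return(NULL)
  list(turn = k, n_strand = fl_n, c_strand = fl_c,
       centroid = colMeans(ca),
       opening = (ca[1, ] + ca[n, ]) / 2 - ca[k, ])
}

#' Classify the dimer conformation of a frame
#'
#' Ten-class taxonomy of dimer geometries built on beta-hairpin detection:
#' when both monomers form hairpins the class is `NN`/`NC`/`CC` (by which
#' terminus each monomer's interface strand contains) crossed with
#' `parallel`/`antiparallel` (sign of the dot product of the interface
#' strands' end-to-end vectors); when exactly one monomer forms a hairpin
#' and the other wraps around it the class is `nested`/`antinested`
#' (by which side of the hairpin opening the outer chain's termini lie)
#' crossed with the same orientation test; anything else is
#' `unclassified`.
#'
#' @inheritParams detect_hbonds
#' @param ctl a [classifier_control()].
#' @return A single label, one of the ten classes or `"unclassified"`.
#' @export
classify_dimer_conformation <- function(frame, top, ctl = classifier_control()) {
  fr <- .as_frame(frame)
  at <- top$atoms
  chA <- top$chains[1]; chB <- top$chains[2]
  ca_of <- function(ch) {
    idx <- which(at$chain == ch & at$name == "CA")
    fr$xyz[idx[order(at$resid[idx])], , drop = FALSE]
  }
  caA <- ca_of(chA); caB <- ca_of(chB)
  if (nrow(caA) < 6 || nrow(caB) < 6) return("unclassified")
  hpA <- .find_hairpin(caA, ctl)
  hpB <- .find_hairpin(caB, ctl)
  ee <- function(ca) ca[nrow(ca), ] - ca[1, ]
  orient <- function(v1, v2) if (sum(v1 * v2) > 0) "parallel" else "antiparallel"
  if (!is.null(hpA) && !is.null(hpB)) {
    cm <- sidechain_contact_map(fr, top, cutoff = ctl$contact_cutoff)
    sc <- .sidechain_centres(fr$xyz, top)
    inter_contacts <- function(ch, res_idx) {
      rows <- which(sc$chain == ch & sc$resid %in% res_idx)
      cols <- which(sc$chain != ch)
      sum(cm[rows, cols, drop = FALSE])
    }
    iface <- function(ch, hp) {
      nn <- inter_contacts(ch, hp$n_strand)
      nc <- inter_contacts(ch, hp$c_strand)
      if (nn >= nc) list(term = "N", idx = hp$n_strand)
      else list(term = "C", idx = hp$c_strand)
    }
    ia <- iface(chA, hpA); ib <- iface(chB, hpB)
    pair <- paste0(sort(c(ia$term, ib$term)), collapse = "")
    strand_vec <- function(ca, idx) ca[idx[length(idx)], ] - ca[idx[1], ]
    o <- orient(strand_vec(caA, ia$idx), strand_vec(caB, ib$idx))
    return(paste0(pair, "-", o))
  }
  one <- if (!is.null(hpA)) list(hp = hpA, inner = caA, outer = caB)
         else if (!is.null(hpB)) list(hp = hpB, inner = caB, outer = caA)
         else return("unclassified")
  extent <- max(stats::dist(one$outer))
  wraps <- sqrt(sum((one$hp$centroid - colMeans(one$outer))^2)) < 0.5 * extent
  if (!wraps) return("unclassified")
  term_mid <- (one$outer[1, ] + one$outer[nrow(one$outer), ]) / 2
  side <- sum((term_mid - one$hp$centroid) * one$hp$opening)
  nest <- if (side > 0) "nested" else "antinested"
  paste0(nest, "-", orient(ee(one$inner), ee(one$outer)))
}
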