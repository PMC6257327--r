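# RMSD, hydrogen bonds, contact maps, conformation classifier.

test_that("Kabsch RMSD: zero on rigid copies, symmetric, oracle-checked", {
  sys <- toy_system(4, seed = 1)
  fr <- frame(sys$xyz)
  expect_equal(kabsch_rmsd(fr, fr), 0, tolerance = 1e-10)
  fr2 <- frame(rigid_transform(sys$xyz))
  expect_lt(kabsch_rmsd(fr, fr2), 1e-8)

  set.seed(17)
  a <- matrix(rnorm(12, sd = 3), 4, 3)
  b <- matrix(rnorm(12, sd = 3), 4, 3)
  mine <- kabsch_rmsd(frame(a), frame(b))
  expect_equal(kabsch_rmsd(frame(b), frame(a)), mine, tolerance = 1e-10)
  expect_equal(mine, oracle_min_rmsd(a, b), tolerance = 1e-4)
  expect_error(kabsch_rmsd(frame(a[1:2, ]), frame(b[1:2, ])), "at least 3")
})

test_that("RMSD dissimilarity matrix is symmetric, zero-diagonal, spot-correct", {
  sys <- toy_system(4, seed = 3)
  plan <- stage_plan(12, boundaries = c(4, 8), stage_sep = c(9, 7, 9),
                     seed = 2)
  traj <- generate_staged_trajectory(sys, plan)
  selA <- select_chain(sys$topology, "A")
  m <- rmsd_dissimilarity_matrix(traj, selA)
  expect_equal(dim(m), c(12, 12))
  expect_equal(max(abs(m - t(m))), 0, tolerance = 1e-10)
  expect_equal(max(abs(diag(m))), 0, tolerance = 1e-10)
  for (p in list(c(1, 5), c(3, 11), c(2, 12)))
    expect_equal(m[p[1], p[2]],
                 kabsch_rmsd(get_frame(traj, p[1]), get_frame(traj, p[2]),
                             selA),
                 tolerance = 1e-10)
  # rigid transform of every frame leaves the matrix unchanged
  rot <- t(apply(traj$xyz, 1, function(row)
    as.numeric(t(rigid_transform(matrix(row, ncol = 3, byrow = TRUE))))))
  m2 <- rmsd_dissimilarity_matrix(trajectory(sys$topology, rot, dt = 4), selA)
  expect_equal(m, m2, tolerance = 1e-7)
  # a static trajectory gives all zeros
  base <- traj$xyz[1, ]
  st <- trajectory(sys$topology, rbind(base, base, base), dt = 4)
  expect_equal(max(rmsd_dissimilarity_matrix(st, selA)), 0, tolerance = 1e-10)
})

test_that("hydrogen-bond geometry criteria accept and reject correctly", {
  sys <- toy_system(5, seed = 2)
  top <- sys$topology
  at <- top$atoms
  # plant one inter bond: move chain B residue 3 SC (an N/O acceptor in
  # SER/GLU/LYS residues) onto the N-H axis of chain A residue 3
  polar_res <- at$resid[at$chain == "B" & at$name == "SC" &
                          at$element %in% c("N", "O")]
  stopifnot(length(polar_res) > 0)
  res_b <- polar_res[1]
  xyz <- sys$xyz
  dn <- which(at$chain == "A" & at$resid == 3 & at$name == "N")
  hy <- which(at$chain == "A" & at$resid == 3 & at$name == "H")
  ac <- which(at$chain == "B" & at$resid == res_b & at$name == "SC")
  u <- (xyz[hy, ] - xyz[dn, ]) / sqrt(sum((xyz[hy, ] - xyz[dn, ])^2))
  xyz[ac, ] <- xyz[hy, ] + 1.9 * u  # 180 degrees, D-A about 2.9 A
  hb <- detect_hbonds(frame(xyz), top)
  hit <- hb[hb$donor == dn & hb$acceptor == ac, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$category, "inter")

  # same geometry bent to about 100 degrees is rejected
  xyz2 <- sys$xyz
  v <- xyz2[hy, ] - xyz2[dn, ]
  perp <- c(-v[2], v[1], 0); perp <- perp / sqrt(sum(perp^2))
  ang <- 100 * pi / 180
  dirv <- cos(pi - ang) * (v / sqrt(sum(v^2))) + sin(pi - ang) * perp
  xyz2[ac, ] <- xyz2[hy, ] + 1.9 * dirv
  hb2 <- detect_hbonds(frame(xyz2), top)
  expect_equal(nrow(hb2[hb2$donor == dn & hb2$acceptor == ac, ]), 0)
})

test_that("three planted bonds are found and categorized exactly", {
  sys <- toy_system(6, seed = 2)
  top <- sys$topology
  at <- top$atoms
  xyz <- sys$xyz
  plant <- function(d_ch, d_res, a_ch, a_res) {
    dn <- which(at$chain == d_ch & at$resid == d_res & at$name == "N")
    hy <- which(at$chain == d_ch & at$resid == d_res & at$name == "H")
    ac <- which(at$chain == a_ch & at$resid == a_res & at$name == "SC")
    u <- (xyz[hy, ] - xyz[dn, ]) / sqrt(sum((xyz[hy, ] - xyz[dn, ])^2))
    xyz[ac, ] <<- xyz[hy, ] + 1.9 * u
    c(dn, ac)
  }
  # acceptors must be polar side chains: residue 1 is basic (N tip) and
  # residue 6 acidic (O tip) by construction
  b1 <- plant("A", 3, "B", 6)   # inter
  b2 <- plant("A", 5, "A", 1)   # intra A
  b3 <- plant("B", 3, "B", 1)   # intra B
  hb <- detect_hbonds(frame(xyz), top)
  expect_equal(nrow(hb), 3)
  expect_equal(hb$category[hb$donor == b1[1] & hb$acceptor == b1[2]], "inter")
  expect_equal(hb$category[hb$donor == b2[1] & hb$acceptor == b2[2]], "intra_A")
  expect_equal(hb$category[hb$donor == b3[1] & hb$acceptor == b3[2]], "intra_B")
})

test_that("presence matrix recovers a planted on/off schedule exactly", {
  sys <- toy_system(6, seed = 2)
  sched <- list(
    list(donor_chain = "A", donor_res = 3, acceptor_chain = "B",
         acceptor_res = 6, occupancy = 0.4),
    list(donor_chain = "A", donor_res = 5, acceptor_chain = "A",
         acceptor_res = 1, occupancy = 1.0))
  plan <- stage_plan(10, boundaries = 5, stage_sep = c(12, 12),
                     boundary_sep = 12, noise = 0.02,
                     hbond_schedule = sched, seed = 4)
  traj <- generate_staged_trajectory(sys, plan)
  pm <- hbond_presence_matrix(traj)
  expect_true(all(pm %in% c(0L, 1L)))
  cats <- attr(pm, "categories")
  # persistent bond: a column of ones
  expect_true(any(colSums(pm) == 10 & cats == "intra_A"))
  # 0.4 occupancy bond: exactly 4 of 10 frames
  expect_true(any(colSums(pm) == 4 & cats == "inter"))
  # row sums equal per-frame detection counts
  counts <- vapply(seq_len(10), function(t)
    nrow(detect_hbonds(get_frame(traj, t), sys$topology)), integer(1))
  expect_equal(unname(rowSums(pm)), as.numeric(counts))
})

test_that("density series are windowed means that sum over categories", {
  sys <- toy_system(6, seed = 2)
  sched <- list(
    list(donor_chain = "A", donor_res = 3, acceptor_chain = "B",
         acceptor_res = 6, occupancy = 1.0),
    list(donor_chain = "B", donor_res = 3, acceptor_chain = "B",
         acceptor_res = 1, occupancy = 1.0))
  plan <- stage_plan(20, boundaries = 10, stage_sep = c(12, 12),
                     boundary_sep = 12, noise = 0.02,
                     hbond_schedule = sched, seed = 9)
  pm <- hbond_presence_matrix(generate_staged_trajectory(sys, plan))
  dens <- hbond_density(pm, window = 5)
  expect_equal(unname(dens[, "inter"]), rep(1, 20))
  expect_equal(unname(dens[, "intra_B"]), rep(1, 20))
  total <- moving_average(rowSums(pm), 5)
  expect_equal(unname(rowSums(dens)), total, tolerance = 1e-12)
  expect_error(hbond_density(pm, window = 21), "exceeds")
})

test_that("occupancy table is a sorted percentage of frames", {
  pm <- structure(cbind(b1 = c(1, 1, 0, 1, 0, 0, 0, 0, 1, 0),
                        b2 = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1),
                        b3 = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1)),
                  categories = c("inter", "intra_A", "intra_B"),
                  class = c("hbond_matrix", "matrix", "array"))
  occ <- hbond_occupancy(pm, top_n = 2)
  expect_equal(occ$bond, c("b2", "b1"))
  expect_equal(occ$occupation, c(100, 40))
  expect_equal(nrow(hbond_occupancy(pm, top_n = 10)), 3)
})

test_that("contact map thresholds at the side-chain centre distance", {
  sys <- toy_system(4, seed = 1)
  at <- sys$topology$atoms
  xyz <- sys$xyz
  scA2 <- which(at$chain == "A" & at$resid == 2 & at$name == "SC")
  scB2 <- which(at$chain == "B" & at$resid == 2 & at$name == "SC")
  place <- function(d) {
    xyz[scB2, ] <- xyz[scA2, ] + c(0, 0, d)
    sidechain_contact_map(frame(xyz), sys$topology)
  }
  m_in <- place(6.4); m_out <- place(6.6)
  la <- paste0("A:", at$resname[scA2], "2")
  lb <- paste0("B:", at$resname[scB2], "2")
  expect_equal(m_in[la, lb], 1)
  expect_equal(m_out[la, lb], 0)
  # full map equals hand-computed centroid distances
  sc_idx <- which(at$name == "SC")
  d <- as.matrix(dist(sys$xyz[sc_idx, ]))
  hand <- (d < 6.5) + 0; diag(hand) <- 0
  m <- sidechain_contact_map(frame(sys$xyz), sys$topology)
  expect_equal(unname(unclass(m)), unname(hand))
})

test_that("chain swap maps intra categories and transposes contact blocks", {
  sys <- toy_system(5, seed = 3)
  at <- sys$topology$atoms
  # swap chains by relabelling: build the swapped topology
  at2 <- at
  at2$chain <- ifelse(at$chain == "A", "B", "A")
  ord <- order(match(at2$chain, c("A", "B")), seq_len(nrow(at2)))
  perm <- match(seq_len(nrow(at)), ord)  # new position of each old atom
  b <- sys$topology$bonds
  top2 <- topology(at2[ord, ], bonds = cbind(perm[b[, 1]], perm[b[, 2]]))
  xyz2 <- sys$xyz[ord, ]
  hb1 <- detect_hbonds(frame(sys$xyz), sys$topology)
  hb2 <- detect_hbonds(frame(xyz2), top2)
  tab1 <- table(factor(hb1$category, c("inter", "intra_A", "intra_B")))
  tab2 <- table(factor(hb2$category, c("inter", "intra_A", "intra_B")))
  expect_equal(unname(tab1["inter"]), unname(tab2["inter"]))
  expect_equal(unname(tab1["intra_A"]), unname(tab2["intra_B"]))
  expect_equal(unname(tab1["intra_B"]), unname(tab2["intra_A"]))
})

test_that("classifier recognizes constructed two-hairpin geometries", {
  sys <- toy_system(8, seed = 1)
  top <- sys$topology
  # both hairpins, C strands facing, antiparallel
  caA <- hairpin_ca(origin = c(0, 0, 0), dx = 1, dy = 5)
  caB <- hairpin_ca(origin = c(11.4, 15, 0), dx = -1, dy = -5)
  expect_equal(classify_dimer_conformation(frame_from_ca(top, caA, caB), top),
               "CC-antiparallel")
  # parallel variant: same handedness
  caB2 <- hairpin_ca(origin = c(0, 15, 0), dx = 1, dy = -5)
  cls2 <- classify_dimer_conformation(frame_from_ca(top, caA, caB2), top)
  expect_equal(cls2, "CC-parallel")
})

test_that("classifier finds nested variants and falls back to unclassified", {
  sys <- toy_system(8, seed = 1)
  top <- sys$topology
  caA <- hairpin_ca(origin = c(0, 0, 0), dx = 1, dy = 5)
  centroid <- colMeans(caA)
  angles <- seq(140, -140, length.out = 8) * pi / 180
  caB <- t(sapply(angles, function(th)
    centroid + 9 * c(cos(pi - th), sin(pi - th), 0)))
  cls <- classify_dimer_conformation(frame_from_ca(top, caA, caB), top)
  expect_match(cls, "^(nested|antinested)-")

  # two extended chains: no turn anywhere
  e1 <- extended_ca(c(0, 0, 0)); e2 <- extended_ca(c(0, 6, 0))
  expect_equal(classify_dimer_conformation(frame_from_ca(top, e1, e2), top),
               "unclassified")
  # classifier is total and deterministic
  expect_equal(classify_dimer_conformation(frame_from_ca(top, e1, e2), top),
               classify_dimer_conformation(frame_from_ca(top, e1, e2), top))
})
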