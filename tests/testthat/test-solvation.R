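# Implicit solvation: SASA, nonpolar term, PB and GB polar engines.

test_that("SASA of an isolated atom matches the analytic sphere", {
  ff <- forcefield(charges = 0, rmin_half = 1.5, epsilon = 0.1,
                   radius = 1.5, mass = 12)
  cfg <- solvation_config()
  a <- shrake_rupley_sasa(frame(matrix(c(3, -2, 7), 1)), 1, ff, cfg)
  expect_equal(sum(a), 4 * pi * 2.9^2, tolerance = 0.01)
  expect_error(shrake_rupley_sasa(frame(matrix(0, 1, 3)), 1, ff,
                                  solvation_config(n_sphere_points = 5)),
               "n_sphere_points")
})

test_that("SASA of two overlapping spheres matches the spherical-cap formula", {
  ff <- forcefield(charges = c(0, 0), rmin_half = c(1, 1), epsilon = c(0, 0),
                   radius = c(1.6, 1.2), mass = c(12, 12))
  cfg <- solvation_config()
  d <- 2.4
  a <- shrake_rupley_sasa(frame(rbind(c(0, 0, 0), c(d, 0, 0))), 1:2, ff, cfg)
  exact <- oracle_two_sphere_sasa(1.6 + 1.4, 1.2 + 1.4, d)
  expect_equal(a[1], exact[1], tolerance = 0.01)
  expect_equal(a[2], exact[2], tolerance = 0.01)
})

test_that("a caged atom has zero accessible area", {
  # tight octahedral cage of large spheres around a small atom
  shell <- rbind(c(3, 0, 0), c(-3, 0, 0), c(0, 3, 0), c(0, -3, 0),
                 c(0, 0, 3), c(0, 0, -3),
                 c(2, 2, 2), c(-2, 2, 2), c(2, -2, 2), c(2, 2, -2),
                 c(-2, -2, 2), c(-2, 2, -2), c(2, -2, -2), c(-2, -2, -2))
  xyz <- rbind(c(0, 0, 0), shell)
  n <- nrow(xyz)
  ff <- forcefield(charges = numeric(n), rmin_half = rep(1, n),
                   epsilon = rep(0, n), radius = c(1.0, rep(3.0, n - 1)),
                   mass = rep(12, n))
  a <- shrake_rupley_sasa(frame(xyz), 1:n, ff, solvation_config())
  expect_equal(a[1], 0)
})

test_that("SASA is invariant under rigid transforms", {
  sys <- toy_system(4, seed = 2)
  sel <- select_chain(sys$topology, "complex")
  cfg <- solvation_config()
  a1 <- sum(shrake_rupley_sasa(frame(sys$xyz), sel, sys$forcefield, cfg))
  a2 <- sum(shrake_rupley_sasa(frame(rigid_transform(sys$xyz)), sel,
                               sys$forcefield, cfg))
  expect_equal(a1, a2, tolerance = 0.005)
})

test_that("nonpolar term is linear in SASA with the classic parameters", {
  cfg <- solvation_config()
  expect_equal(nonpolar_solvation(0, cfg), 0.92)
  expect_equal(nonpolar_solvation(1000, cfg), 6.34)
  s <- 731.5
  expect_equal(nonpolar_solvation(2 * s, cfg) - nonpolar_solvation(s, cfg),
               cfg$gamma * s, tolerance = 1e-12)
  expect_error(nonpolar_solvation(-1, cfg), "negative")
})

test_that("PB reproduces the Born ion within 2% at 0.25 A spacing", {
  ff <- two_atom_ff()
  fr <- frame(matrix(c(0.13, -0.07, 0.055), 1))
  cfg <- solvation_config(grid_spacing = 0.25, grid_padding = 6,
                          probe_radius = 0, engine = "pb")
  e <- pb_polar_solvation(fr, 1, ff, cfg)
  expect_equal(e, born_energy(1, 2, 80), tolerance = 0.02)
})

test_that("PB trivial cases vanish", {
  ff0 <- two_atom_ff(q = c(0, 0))
  fr <- frame(rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_equal(pb_polar_solvation(fr, 1:2, ff0, solvation_config(engine = "pb")), 0)
  ff1 <- two_atom_ff()
  cfg_same <- solvation_config(eps_in = 80, eps_out = 80, engine = "pb")
  expect_equal(pb_polar_solvation(fr, 1:2, ff1, cfg_same), 0)
})

test_that("PB error on the Born ion shrinks monotonically with grid spacing", {
  ff <- two_atom_ff()
  fr <- frame(matrix(c(0.13, -0.07, 0.055), 1))
  exact <- born_energy(1, 2, 80)
  errs <- vapply(c(0.5, 0.25, 0.125), function(h) {
    cfg <- solvation_config(grid_spacing = h, grid_padding = 4,
                            probe_radius = 0, engine = "pb")
    abs(pb_polar_solvation(fr, 1, ff, cfg) - exact)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("PB energy is stable under translation of the solute in the grid", {
  # the grid origin follows the solute bounding box, so a sub-lattice
  # offset between solute and grid is imposed by perturbing the padding:
  # this is exactly what a rigid translation inside a fixed grid does
  ff <- two_atom_ff(q = c(1, -1), radius = c(1.8, 1.6))
  x0 <- rbind(c(0, 0, 0), c(3, 0.5, 0.2))
  energies <- vapply(c(8, 8.13, 8.27), function(pad) {
    cfg <- solvation_config(grid_spacing = 0.4, grid_padding = pad,
                            probe_radius = 0, engine = "pb")
    pb_polar_solvation(frame(x0), 1:2, ff, cfg)
  }, numeric(1))
  expect_lt(diff(range(energies)) / abs(energies[1]), 0.005)
})

test_that("GB degenerates to the Born formula for a single atom", {
  ff <- two_atom_ff()
  fr <- frame(matrix(c(5, 1, -2), 1))
  expect_equal(gb_polar_solvation(fr, 1, ff, solvation_config()),
               born_energy(1, 2, 80), tolerance = 1e-12)
  ff0 <- two_atom_ff(q = c(0, 0))
  expect_equal(gb_polar_solvation(frame(rbind(c(0, 0, 0), c(4, 0, 0))),
                                  1:2, ff0, solvation_config()), 0)
})

test_that("GB of far-separated atoms approaches independent Born terms", {
  ff <- two_atom_ff(q = c(1, 0), radius = c(2, 1.5))
  fr <- frame(rbind(c(0, 0, 0), c(500, 0, 0)))
  e <- gb_polar_solvation(fr, 1:2, ff, solvation_config())
  expect_equal(e, born_energy(1, 2, 80), tolerance = 1e-3)
  # both charged: the residual cross term is the screened Coulomb limit
  ff2 <- two_atom_ff(q = c(1, -1), radius = c(2, 2))
  e2 <- gb_polar_solvation(frame(rbind(c(0, 0, 0), c(500, 0, 0))),
                           1:2, ff2, solvation_config())
  expected <- 2 * born_energy(1, 2, 80) + KE * (1 - 1 / 80) / 500
  expect_equal(e2, expected, tolerance = 1e-3)
})

test_that("PB and GB agree on the Born ion within 2%", {
  ff <- two_atom_ff()
  fr <- frame(matrix(c(0.1, 0, 0), 1))
  cfg_pb <- solvation_config(grid_spacing = 0.25, grid_padding = 6,
                             probe_radius = 0, engine = "pb")
  e_pb <- pb_polar_solvation(fr, 1, ff, cfg_pb)
  e_gb <- gb_polar_solvation(fr, 1, ff, solvation_config())
  expect_equal(e_pb, e_gb, tolerance = 0.02)
})

test_that("burying opposite charges lowers the total electrostatic energy", {
  # Coulomb + polar solvation along an approach series of a +/- pair:
  # the screened net attraction must be monotone in separation
  ff <- two_atom_ff(q = c(1, -1), radius = c(2, 2))
  cfg <- solvation_config()
  rr <- c(12, 10, 8, 6, 5)
  etot <- vapply(rr, function(r) {
    fr <- frame(rbind(c(0, 0, 0), c(r, 0, 0)))
    coulomb_energy(fr, 1:2, ff) + gb_polar_solvation(fr, 1:2, ff, cfg)
  }, numeric(1))
  expect_true(all(diff(etot) < 0))
})

test_that("uncharged solutes pay only the nonpolar (cavity) price", {
  sys <- toy_system(4, seed = 7)
  ff0 <- sys$forcefield
  ff0$charges[] <- 0
  sel <- select_chain(sys$topology, "complex")
  cfg <- solvation_config()
  fr <- frame(sys$xyz)
  expect_equal(solvation_energy(fr, sel, ff0, cfg),
               nonpolar_solvation(sum(shrake_rupley_sasa(fr, sel, ff0, cfg)),
                                  cfg),
               tolerance = 1e-12)
})
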