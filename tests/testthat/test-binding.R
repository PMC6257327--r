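# Binding-energy decomposition, summaries, and Schlitter entropy.

test_that("per-frame bookkeeping identities hold on synthetic frames", {
  sys <- toy_system(4, seed = 1)
  plan <- stage_plan(30, boundaries = c(10, 20), stage_sep = c(9, 6.5, 9),
                     seed = 2)
  traj <- generate_staged_trajectory(sys, plan)
  em <- energy_matrix(traj, sys$forcefield, solvation_config())
  expect_equal(dim(unclass(em)), c(30, 18))
  for (sp in c("C", "A", "B"))
    expect_equal(em[, paste0("e_mm_", sp)],
                 em[, paste0("e_int_", sp)] + em[, paste0("e_ele_", sp)] +
                   em[, paste0("e_vdw_", sp)],
                 tolerance = 1e-8)
  expect_equal(em[, "de_mm"],
               em[, "e_mm_C"] - em[, "e_mm_A"] - em[, "e_mm_B"],
               tolerance = 1e-8)
  expect_equal(em[, "de_sol"],
               em[, "e_sol_C"] - em[, "e_sol_A"] - em[, "e_sol_B"],
               tolerance = 1e-8)
  expect_equal(em[, "de_bind"], em[, "de_mm"] + em[, "de_sol"],
               tolerance = 1e-8)
  # single-trajectory protocol: the internal component cancels identically
  expect_equal(max(abs(em[, "e_int_C"] - em[, "e_int_A"] - em[, "e_int_B"])),
               0, tolerance = 1e-8)
})

test_that("binding energy vanishes for far-separated neutral chains", {
  sys <- build_toy_dimer(4, seed = 1, separation = 500)
  sels <- list(complex = select_chain(sys$topology, "complex"),
               A = select_chain(sys$topology, "A"),
               B = select_chain(sys$topology, "B"))
  # drop the charges so only short-range terms could contribute; beta = 0
  # removes the constant cavity offset that would otherwise survive the
  # C - A - B difference (one beta per species)
  ff0 <- sys$forcefield
  ff0$charges[] <- 0
  cfg <- solvation_config(beta = 0)
  row <- frame_binding_energy(frame(sys$xyz), sels, ff0, cfg)
  expect_lt(abs(row["de_bind"]), 0.1)
})

test_that("the Table-style combiners are exact arithmetic", {
  expect_equal(binding_from_species(-904.7, -445.8, -443.0), -15.9)
  expect_equal(binding_from_components(-277.8, 261.9), -15.9)
  set.seed(4)
  for (k in 1:20) {
    v <- rnorm(3, sd = 100)
    expect_equal(binding_from_species(v[1], v[2], v[3]), v[1] - v[2] - v[3])
  }
})

test_that("trajectory summary matches independent recomputation", {
  sys <- toy_system(4, seed = 3)
  plan <- stage_plan(25, boundaries = c(8, 17), stage_sep = c(9, 7, 9),
                     seed = 6)
  em <- energy_matrix(generate_staged_trajectory(sys, plan),
                      sys$forcefield, solvation_config())
  s <- trajectory_summary(em, temperature = 305)
  g_c <- em[, "e_mm_C"] + em[, "e_sol_C"]
  g_a <- em[, "e_mm_A"] + em[, "e_sol_A"]
  g_b <- em[, "e_mm_B"] + em[, "e_sol_B"]
  get <- function(q, f) s[[f]][s$quantity == q]
  expect_equal(get("G_C", "mean"), mean(g_c), tolerance = 1e-10)
  expect_equal(get("dG_bind", "mean"),
               get("G_C", "mean") - get("G_A", "mean") - get("G_B", "mean"),
               tolerance = 1e-8)
  expect_equal(get("dG_bind", "mean"),
               get("dE_MM", "mean") + get("dG_sol", "mean"),
               tolerance = 1e-8)
  # population standard deviation, not the sample one
  expect_equal(get("G_B", "sd"), sqrt(mean((g_b - mean(g_b))^2)),
               tolerance = 1e-10)
  expect_error(trajectory_summary(em[1, , drop = FALSE]), ">= 2 rows")
})

test_that("a constant energy column has zero spread in the summary", {
  sys <- toy_system(4, seed = 2)
  plan <- stage_plan(6, boundaries = 3, stage_sep = c(9, 9),
                     boundary_sep = 9, noise = 0, seed = 1)
  em <- energy_matrix(generate_staged_trajectory(sys, plan),
                      sys$forcefield, solvation_config())
  s <- trajectory_summary(em)
  expect_equal(max(s$sd), 0, tolerance = 1e-10)
})

test_that("Schlitter entropy: zero for static, closed form for one DOF", {
  sys <- toy_system(4, seed = 1)
  na <- n_atoms(sys$topology)
  base <- as.numeric(t(sys$xyz))
  static <- trajectory(sys$topology, matrix(rep(base, 5), 5, byrow = TRUE),
                       dt = 4)
  suppressWarnings(expect_equal(schlitter_entropy(static, temperature = 305)$s, 0))

  nf <- 2000
  set.seed(31)
  xyz <- matrix(rep(base, nf), nf, byrow = TRUE)
  xyz[, 1] <- xyz[, 1] + rnorm(nf, sd = 0.4)
  tr <- trajectory(sys$topology, xyz, dt = 4)
  suppressWarnings(er <- schlitter_entropy(tr, seq_len(na), temperature = 305,
                                           fit = FALSE))
  v <- mean((xyz[, 1] - mean(xyz[, 1]))^2)  # exact realized variance
  closed <- schlitter_1dof(sys$topology$atoms$mass[1], v, 305)
  expect_equal(er$s, closed, tolerance = 1e-6)
})

test_that("two uncorrelated identical DOFs double the 1-DOF entropy", {
  sys <- toy_system(4, seed = 1)
  base <- as.numeric(t(sys$xyz))
  nf <- 400
  set.seed(8)
  d1 <- rnorm(nf, sd = 0.3)
  # same displacement pattern on two x-coordinates of same-mass atoms of
  # different frames order -> identical variance, zero correlation
  d2 <- sample(d1)
  while (abs(cor(d1, d2)) > 1e-3) d2 <- sample(d1)
  xyz <- matrix(rep(base, nf), nf, byrow = TRUE)
  i1 <- 1; i2 <- 3 * 6 + 1  # x of backbone N in residues 1 and 2 (same mass)
  xyz[, i1] <- xyz[, i1] + d1
  xyz[, i2] <- xyz[, i2] + d2
  tr <- trajectory(sys$topology, xyz, dt = 4)
  suppressWarnings({
    s2 <- schlitter_entropy(tr, temperature = 305, fit = FALSE)$s
    xyz1 <- matrix(rep(base, nf), nf, byrow = TRUE)
    xyz1[, i1] <- xyz1[, i1] + d1
    s1a <- schlitter_entropy(trajectory(sys$topology, xyz1, dt = 4),
                             temperature = 305, fit = FALSE)$s
    xyz1b <- matrix(rep(base, nf), nf, byrow = TRUE)
    xyz1b[, i2] <- xyz1b[, i2] + d2
    s1b <- schlitter_entropy(trajectory(sys$topology, xyz1b, dt = 4),
                             temperature = 305, fit = FALSE)$s
  })
  expect_equal(s2, s1a + s1b, tolerance = 1e-4)
})

test_that("Schlitter entropy is invariant under rigid rotation of all frames", {
  sys <- toy_system(4, seed = 5)
  plan <- stage_plan(40, boundaries = c(15, 30), stage_sep = c(9, 7, 9),
                     seed = 3)
  traj <- generate_staged_trajectory(sys, plan)
  suppressWarnings(s1 <- schlitter_entropy(traj, temperature = 305)$s)
  rot <- t(apply(traj$xyz, 1, function(row)
    as.numeric(t(rigid_transform(matrix(row, ncol = 3, byrow = TRUE))))))
  suppressWarnings(
    s2 <- schlitter_entropy(trajectory(sys$topology, rot, dt = 4),
                            temperature = 305)$s)
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("appending an uncorrelated DOF never lowers the entropy", {
  sys <- toy_system(4, seed = 5)
  base <- as.numeric(t(sys$xyz))
  nf <- 300
  set.seed(13)
  xyz <- matrix(rep(base, nf), nf, byrow = TRUE)
  xyz[, 2] <- xyz[, 2] + rnorm(nf, sd = 0.25)
  t1 <- trajectory(sys$topology, xyz, dt = 4)
  suppressWarnings(s1 <- schlitter_entropy(t1, temperature = 305, fit = FALSE)$s)
  xyz2 <- xyz
  xyz2[, 8] <- xyz2[, 8] + rnorm(nf, sd = 0.25)
  suppressWarnings(
    s2 <- schlitter_entropy(trajectory(sys$topology, xyz2, dt = 4),
                            temperature = 305, fit = FALSE)$s)
  expect_gte(s2, s1)
})

test_that("entropy correction combines -TS terms and reproduces the marginal value", {
  expect_equal(entropy_correction(-1.716, -0.842, -0.844), -0.03,
               tolerance = 1e-9)
  expect_equal(entropy_correction(-3, -2, -1), 0)
  set.seed(2)
  v <- rnorm(3)
  expect_equal(entropy_correction(v[1], v[2], v[3]), v[1] - v[2] - v[3])
})
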