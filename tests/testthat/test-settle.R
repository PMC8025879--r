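two_atom_fixture <- function(d = 7) {
  restraintr:::new_structure(
    chain = "A", resno = c(1L, 2L), icode = "", resname = "UNK",
    atom = "X1", x = c(0, d), y = 0, z = 0
  )
}

two_atom_restraint <- function(r0 = 4) {
  out <- tibble::tibble(
    atom1 = "A|1||X1", atom2 = "A|2||X1", group = 1L, r0 = r0, k = 5,
    tau = 0.025 * r0, c = 0.05 * r0, alpha = -2 - 4 * log(r0), enabled = TRUE
  )
  class(out) <- c("distance_restraints", class(out))
  out
}

test_that("an empty restraint list gives zero energy and zero forces", {
  h <- toy_helix(5)
  e <- total_energy_and_forces(h, list())
  expect_equal(e$energy, 0)
  expect_equal(e$forces, matrix(0, nrow(h), 3))
})

test_that("a satisfied single restraint exerts no force", {
  s <- two_atom_fixture(d = 4)
  e <- total_energy_and_forces(s, two_atom_restraint(r0 = 4))
  expect_equal(e$energy, 0)
  expect_equal(max(abs(e$forces)), 0)
})

test_that("forces are the exact negative gradient of the total energy", {
  h <- toy_helix(8)
  p <- perturb_structure(h, 0.4, seed = 6)
  dr <- generate_distance_restraints(p, h)
  tr <- generate_torsion_restraints(p, h)
  e <- total_energy_and_forces(p, list(dr, tr))
  xyz <- as.matrix(p[, c("x", "y", "z")])
  ev <- restraintr:::prepare_energy(p, list(dr, tr))
  set.seed(8)
  for (i in 1:6) {
    dirn <- matrix(rnorm(length(xyz)), nrow(xyz))
    dirn <- dirn / sqrt(sum(dirn^2))
    h_ <- 1e-5
    fd <- (ev(xyz + h_ * dirn)$energy - ev(xyz - h_ * dirn)$energy) / (2 * h_)
    expect_equal(-sum(e$forces * dirn), fd, tolerance = 1e-5)
  }
})

test_that("the stereochemistry and clash terms also have exact gradients", {
  h <- toy_helix(6)
  p <- perturb_structure(h, 0.3, seed = 2)
  ev <- restraintr:::prepare_energy(p, list(), clash = TRUE, clash_scale = 1.2,
                                    stereo = TRUE)
  xyz <- as.matrix(p[, c("x", "y", "z")])
  st <- ev(xyz)
  expect_gt(st$energy, 0)
  set.seed(3)
  for (i in 1:4) {
    dirn <- matrix(rnorm(length(xyz)), nrow(xyz))
    dirn <- dirn / sqrt(sum(dirn^2))
    h_ <- 1e-6
    fd <- (ev(xyz + h_ * dirn)$energy - ev(xyz - h_ * dirn)$energy) / (2 * h_)
    expect_equal(sum(st$grad * dirn), fd, tolerance = 1e-5)
  }
})

test_that("missing restrained atoms are reported by name", {
  h <- toy_helix(5)
  bad <- two_atom_restraint()
  expect_error(total_energy_and_forces(h, bad), "A\\|1\\|\\|X1")
})

test_that("two free atoms settle into the flat bottom of their restraint", {
  s <- two_atom_fixture(d = 7)
  r <- two_atom_restraint(r0 = 4)
  res <- settle(s, r, settle_options(ftol = 1e-6))
  d_final <- measure_distance(
    as.numeric(res$structure[1, c("x", "y", "z")]),
    as.numeric(res$structure[2, c("x", "y", "z")])
  )
  expect_gte(d_final, 4 - 0.1)
  expect_lte(d_final, 4 + 0.1)
  expect_true(res$converged)
})

test_that("an already-converged input returns immediately and unchanged", {
  h <- toy_helix(8)
  dr <- generate_distance_restraints(h)
  tr <- generate_torsion_restraints(h)
  res <- settle(h, list(dr, tr))
  expect_true(res$converged)
  expect_equal(res$iterations, 0L)
  expect_identical(res$structure$x, h$x)
  # the input object is never mutated
  expect_equal(h$x, toy_helix(8)$x)
})

test_that("trajectory energies are monotone and the final energy is consistent", {
  h <- toy_helix(12)
  p <- perturb_structure(h, 0.5, seed = 3)
  dr <- generate_distance_restraints(p, h)
  tr <- generate_torsion_restraints(p, h)
  res <- settle(p, list(dr, tr))
  expect_true(all(diff(res$trajectory$energy) <= 1e-12))
  recomputed <- total_energy_and_forces(res$structure, list(dr, tr))
  ev <- restraintr:::prepare_energy(res$structure, list(dr, tr), stereo = TRUE)
  full <- ev(as.matrix(res$structure[, c("x", "y", "z")]))$energy
  expect_equal(res$final_energy, full, tolerance = 1e-9)
  expect_lte(recomputed$energy, full + 1e-9)
  expect_identical(glance(res)$converged, res$converged)
  expect_identical(tidy(res), res$trajectory)
})

test_that("settling a perturbed helix under default restraints recovers the template", {
  h <- toy_helix(20)
  p <- perturb_structure(h, 0.5, seed = 1)
  dr <- generate_distance_restraints(p, h)
  tr <- generate_torsion_restraints(p, h)
  res <- settle(p, list(dr, tr), settle_options(max_iter = 4000))
  expect_lt(rmsd_structures(res$structure, h), 0.3)
  st <- classify_restraints(dr, res$structure)
  expect_gte(mean(st$state == "satisfied"), 0.95)
})

test_that("stronger distance restraints pull the settled model closer (median over seeds)", {
  h <- toy_helix(20)
  final_rmsd <- function(kappa, seed) {
    p <- perturb_structure(h, 0.5, seed = seed)
    dr <- generate_distance_restraints(p, h,
                                       options = restraint_options(kappa = kappa))
    tr <- generate_torsion_restraints(p, h)
    res <- settle(p, list(dr, tr), settle_options(max_iter = 3000))
    rmsd_structures(res$structure, h)
  }
  seeds <- 1:10
  weak <- vapply(seeds, function(s) final_rmsd(1, s), numeric(1))
  strong <- vapply(seeds, function(s) final_rmsd(5, s), numeric(1))
  expect_lt(median(strong), median(weak))
})
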