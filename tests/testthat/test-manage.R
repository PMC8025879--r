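make_distance_set <- function(...) {
  out <- tibble::tibble(...)
  class(out) <- c("distance_restraints", class(out))
  out
}

test_that("distance classification thresholds follow the documented bands", {
  h <- toy_helix(8)
  keys <- paste(h$chain, h$resno, h$icode, h$atom, sep = "|")
  ca1 <- keys[h$atom == "CA"][1]
  ca5 <- keys[h$atom == "CA"][5]
  d <- measure_distance(
    as.matrix(h[match(ca1, keys), c("x", "y", "z")]),
    as.matrix(h[match(ca5, keys), c("x", "y", "z")])
  )
  mk <- function(r0) make_distance_set(
    atom1 = ca1, atom2 = ca5, group = 1L, r0 = r0, k = 5,
    tau = 0.025 * r0, c = 0.05 * r0, alpha = -2 - 4 * log(r0), enabled = TRUE
  )
  expect_equal(classify_restraints(mk(d), h)$state, "satisfied")
  expect_equal(classify_restraints(mk(d / (1 + 0.03)), h)$state, "strained")
  # deviation of tau + 10c is far beyond the harmonic region
  r0 <- d / (1 + 0.025 + 10 * 0.05)
  expect_equal(classify_restraints(mk(r0), h)$state, "beyond_well")
  missing <- make_distance_set(
    atom1 = "Z|99||CA", atom2 = ca1, group = 1L, r0 = 4, k = 5,
    tau = 0.1, c = 0.2, alpha = -7.5, enabled = TRUE
  )
  expect_equal(classify_restraints(missing, h)$state, "error")
})

test_that("torsion classification bands scale with the well width", {
  h <- toy_helix(10)
  tr <- generate_torsion_restraints(h)
  width <- well_width_from_kappa(tr$kappa[tr$form == "adaptive"][1])
  shift <- function(delta) {
    t2 <- tr
    t2$theta0 <- ifelse(t2$form == "adaptive", t2$theta0 - delta, t2$theta0)
    t2
  }
  half <- classify_restraints(shift(width / 2), h)
  expect_true(all(half$state[half$form == "adaptive"] == "strained"))
  expect_true(all(half$force[half$form == "adaptive"] > 0))
  outside <- classify_restraints(shift(width * 1.5), h)
  expect_true(all(outside$state[outside$form == "adaptive"] == "beyond_well"))
})

test_that("release disables matching restraints and is idempotent", {
  h <- toy_helix(10)
  dr <- generate_distance_restraints(h)
  all_off <- release_restraints(dr)
  expect_equal(sum(all_off$enabled), 0)
  expect_identical(release_restraints(all_off), all_off)
  # releasing by a deviation bound nothing exceeds changes nothing
  same <- release_restraints(dr, deviation_above = 10, struct = h)
  expect_identical(as.data.frame(same), as.data.frame(dr))
  # atom-wise release touches only restraints involving those atoms
  target <- dr$atom1[1]
  off <- release_restraints(dr, atoms = target)
  hit <- off$atom1 == target | off$atom2 == target
  expect_true(all(!off$enabled[hit]))
  expect_true(all(off$enabled[!hit]))
  expect_error(release_restraints(dr, atoms = 42), "character")
})

test_that("releasing beyond-well restraints keeps the intact ones after a hinge break", {
  h <- toy_helix(16)
  dr <- generate_distance_restraints(h)
  # displace the last 5 residues rigidly, breaking cross-boundary restraints
  moved <- h
  sel <- moved$resno > 11
  moved$x[sel] <- moved$x[sel] + 15
  st <- classify_restraints(dr, moved)
  released <- release_restraints(dr, states = "beyond_well", struct = moved)
  expect_identical(released$enabled, st$state != "beyond_well")
  expect_gt(sum(!released$enabled), 0)
  expect_gt(sum(released$enabled), 0)
})

test_that("adjust recomputes derived parameters and never touches targets", {
  h <- toy_helix(10)
  dr <- generate_distance_restraints(h)
  doubled <- adjust_restraints(dr, kappa = 10)
  expect_equal(doubled$k, dr$k * 2)
  expect_identical(doubled$r0, dr$r0)
  expect_identical(doubled$tau, dr$tau)
  expect_identical(doubled$alpha, dr$alpha)
  refall <- adjust_restraints(dr, fall_off = 6)
  expect_equal(refall$alpha, -2 - 6 * log(dr$r0), tolerance = 1e-12)
  none <- adjust_restraints(dr, atoms = character(0), kappa = 10)
  expect_identical(as.data.frame(none), as.data.frame(dr))
  expect_error(adjust_restraints(dr, well_half_width = -1), "positive")
  tr <- generate_torsion_restraints(h)
  retors <- adjust_restraints(tr, spring_constant = 100, angle_range = 120, alpha = 0)
  expect_true(all(retors$k == 100))
  adaptive <- retors$form == "adaptive"
  expect_lt(max(abs(retors$kappa[adaptive] - kappa_from_well_width(120))), 1e-12)
  expect_true(all(retors$alpha[adaptive] == 0))
  expect_identical(retors$theta0, tr$theta0)
})

test_that("chord score is zero for identical models and one at maximal deviation", {
  h <- toy_helix(8)
  sc <- chord_score(h, h)
  expect_lt(max(sc$score, na.rm = TRUE), 1e-12)
  flipped <- build_toy_structure("helix", length = 8, phi = -57 + 180,
                                 psi = -47 + 180, omega = 0)
  sc2 <- chord_score(flipped, toy_helix(8))
  mid <- sc2[!is.na(sc2$score) & sc2$n_torsions == 3, ]
  expect_equal(mid$score, rep(1, nrow(mid)), tolerance = 1e-9)
})

test_that("the 0.15 threshold sits between uniform 45- and 47-degree deviations", {
  h <- toy_helix(10)
  shift45 <- build_toy_structure("helix", length = 10, phi = -57 + 45,
                                 psi = -47 + 45, omega = 180 + 45)
  sc45 <- chord_score(shift45, h)
  full <- sc45$score[!is.na(sc45$score) & sc45$n_torsions == 3]
  expect_equal(full, rep(sin(pi / 8)^2, length(full)), tolerance = 1e-6)
  expect_true(all(full < 0.15))
  shift47 <- build_toy_structure("helix", length = 10, phi = -57 + 47,
                                 psi = -47 + 47, omega = 180 + 47)
  sc47 <- chord_score(shift47, h)
  full47 <- sc47$score[!is.na(sc47$score) & sc47$n_torsions == 3]
  expect_true(all(full47 > 0.15))
  expect_true(all(sc47$incorrect[!is.na(sc47$score) & sc47$n_torsions == 3]))
})

test_that("chord score is symmetric and ignores torsions missing on either side", {
  h <- toy_helix(10)
  m <- build_toy_structure("helix", length = 10, torsion_jitter = 20, seed = 4)
  a <- chord_score(m, h)
  b <- chord_score(h, m)
  expect_equal(a$score, b$score, tolerance = 1e-12)
  # terminal residues average over fewer torsions but still score
  expect_lt(a$n_torsions[1], 3)
  # the raw-chord variant is larger everywhere it is nonzero
  raw <- chord_score(m, h, form = "chord")
  nz <- !is.na(a$score) & a$score > 1e-12
  expect_true(all(raw$score[nz] > a$score[nz]))
})

test_that("side-chain mode compares chi torsions with optional weights", {
  h <- build_toy_structure("helix", length = 6, sequence = "LLLLLL", chi1 = -65)
  m <- build_toy_structure("helix", length = 6, sequence = "LLLLLL", chi1 = -65 + 60)
  sc <- chord_score(m, h, mode = "sidechain")
  expect_equal(sc$score, rep(sin(pi / 6)^2, 6), tolerance = 1e-9)
  w <- chord_score(m, h, mode = "sidechain", weights = c(chi1 = 2, chi2 = 1))
  expect_equal(w$score, sc$score, tolerance = 1e-9) # only chi1 present
})
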