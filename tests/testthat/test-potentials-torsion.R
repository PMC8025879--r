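test_that("von Mises density is normalised, centred and symmetric", {
  expect_equal(vonmises_density(c(-170, 0, 33), 0, 0), rep(1 / (2 * pi), 3))
  dens <- function(th) vonmises_density(th, 20, 3.46)
  q <- stats::integrate(function(t) dens(t * 180 / pi), -pi, pi,
                        rel.tol = 1e-10)
  expect_equal(q$value, 1, tolerance = 1e-6)
  grid <- seq(-180, 180, 0.5)
  expect_equal(which.max(dens(grid)), which(grid == 20))
  for (x in c(10, 90, 170)) {
    expect_equal(vonmises_density(30 + x, 30, 2.5), vonmises_density(30 - x, 30, 2.5))
  }
  expect_error(vonmises_density(0, 0, -1), "non-negative")
})

test_that("peak-force deviation matches a dense numeric maximisation", {
  # independent oracle: maximise the unnormalised von Mises gradient
  oracle <- function(kappa) {
    g <- function(th) kappa * sin(th * pi / 180) * exp(kappa * cos(th * pi / 180))
    stats::optimize(g, c(0, 90), maximum = TRUE, tol = 1e-10)$maximum
  }
  expect_equal(max_gradient_angle(3.46), 30, tolerance = 0.05 / 30)
  expect_equal(max_gradient_angle(0.67), 60, tolerance = 0.1 / 60)
  for (kap in c(0.2, 0.67, 3.46, 12)) {
    expect_equal(max_gradient_angle(kap), oracle(kap), tolerance = 1e-7)
    # inflection of the well function at the returned angle
    g <- function(th) -exp(kap * cos(th))
    th0 <- max_gradient_angle(kap) * pi / 180
    h <- 1e-4
    d2 <- (g(th0 + h) - 2 * g(th0) + g(th0 - h)) / h^2
    expect_lt(abs(d2), 1e-4 * abs(g(th0)))
  }
  kaps <- c(0.1, 0.5, 1, 2, 5, 20, 50)
  expect_true(all(diff(max_gradient_angle(kaps)) < 0))
  expect_error(max_gradient_angle(0), "positive")
})

test_that("well-width conversion reproduces the printed calibration and round-trips", {
  expect_equal(kappa_from_well_width(60), 3.46, tolerance = 0.005 / 3.46)
  expect_equal(kappa_from_well_width(120), 0.67, tolerance = 0.005 / 0.67)
  for (w in c(30, 90, 150)) {
    expect_equal(2 * max_gradient_angle(kappa_from_well_width(w)), w,
                 tolerance = 1e-6)
  }
  for (kap in c(0.3, 1, 7)) {
    expect_equal(kappa_from_well_width(well_width_from_kappa(kap)), kap,
                 tolerance = 1e-9)
  }
  expect_error(kappa_from_well_width(0), "strictly between")
  expect_error(kappa_from_well_width(180), "strictly between")
})

test_that("top-out potential is renormalised: peak gradient equals k", {
  for (kap in c(0.67, 3.46, 10)) {
    for (k in c(1, 250)) {
      pk <- peak_gradient(function(th) torsion_energy_topout(th, 0, kap, k))
      expect_equal(pk, k, tolerance = 1e-6)
    }
  }
})

test_that("top-out potential is periodic, even, and zero at the target", {
  kap <- 3.46
  expect_equal(torsion_energy_topout(25, 25, kap, 7), 0)
  expect_equal(torsion_energy_topout(35, 25, kap, 7),
               torsion_energy_topout(15, 25, kap, 7))
  th <- seq(-180, 180, 7)
  expect_equal(torsion_energy_topout(th, 10, kap, 2),
               torsion_energy_topout(th + 360, 10, kap, 2), tolerance = 1e-12)
  e <- torsion_energy_topout(th, 10, kap, 2)
  expect_true(all(e >= 0))
})

test_that("adaptive potential reduces to top-out at alpha 0 and bends with alpha", {
  th <- seq(-180, 180, 3)
  for (kap in c(0.67, 3.46)) {
    expect_equal(torsion_energy_adaptive(th, 12, kap, 5, alpha = 0),
                 torsion_energy_topout(th, 12, kap, 5), tolerance = 1e-12)
  }
  kap <- 3.46
  # outside the well (deviation 150 deg): alpha > 0 restrains, alpha < 0 repels
  g_pos <- torsion_force_adaptive(150, 0, kap, 1, alpha = 0.3)
  g_zero <- torsion_force_adaptive(150, 0, kap, 1, alpha = 0)
  g_neg <- torsion_force_adaptive(150, 0, kap, 1, alpha = -0.3)
  expect_gt(g_pos, 0.1)
  expect_lt(abs(g_zero), 0.01)
  expect_gt(g_pos, 10 * abs(g_zero))
  expect_lt(g_neg, -0.1)
})

test_that("adaptive torsion gradient matches finite differences and is antisymmetric", {
  th <- seq(-179.75, 180, 0.5)
  h <- 1e-5
  for (kap in c(0.67, 3.46)) {
    for (a in c(0, 0.3, 0.5)) {
      an <- torsion_force_adaptive(th, 0, kap, 1, a)
      fd <- (torsion_energy_adaptive(th + h, 0, kap, 1, a) -
             torsion_energy_adaptive(th - h, 0, kap, 1, a)) / (2 * h * pi / 180)
      expect_lt(max(abs(an - fd)) / max(abs(an)), 1e-6)
      x <- c(13, 55, 120, 179)
      expect_equal(torsion_force_adaptive(x, 0, kap, 1, a),
                   -torsion_force_adaptive(-x, 0, kap, 1, a), tolerance = 1e-12)
    }
  }
  expect_equal(torsion_force_adaptive(40, 40, 3.46, 9, 0.3), 0)
})

test_that("omega restraint has a 30-degree flat bottom and a smooth cosine wall", {
  expect_equal(omega_energy(180, "trans", 10), 0)
  expect_equal(omega_energy(160, "trans", 10), 0)
  expect_equal(omega_energy(-155, "trans", 10), 0)
  expect_gt(omega_energy(140, "trans", 10), 0)
  # maximum penalty at the opposite isomer, equal by cis/trans symmetry
  expect_equal(omega_energy(0, "trans", 10), 10)
  expect_equal(omega_energy(0, "trans", 10), omega_energy(180, "cis", 10))
  # C1 at the flat-bottom boundary
  h <- 1e-6
  slope <- (omega_energy(150 - h, "trans", 10) - omega_energy(150, "trans", 10)) / h
  expect_lt(abs(slope), 1e-4)
  # gradient matches finite differences away from the target
  th <- seq(-175, 175, 2.5)
  an <- omega_force(th, "trans", 3)
  fd <- (omega_energy(th + h, "trans", 3) - omega_energy(th - h, "trans", 3)) /
    (2 * h * pi / 180)
  expect_lt(max(abs(an - fd)) / max(abs(an)), 1e-5)
  expect_error(omega_energy(10, "sideways"), "cis")
})

test_that("torsion energies are even and forces odd across parameter space", {
  x <- seq(1, 179, 8)
  for (kap in c(0.3, 2, 15)) {
    for (a in c(-0.3, 0, 0.4)) {
      expect_equal(torsion_energy_adaptive(50 + x, 50, kap, 2, a),
                   torsion_energy_adaptive(50 - x, 50, kap, 2, a),
                   tolerance = 1e-12)
      expect_equal(torsion_force_adaptive(50 + x, 50, kap, 2, a),
                   -torsion_force_adaptive(50 - x, 50, kap, 2, a),
                   tolerance = 1e-12)
    }
  }
})
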