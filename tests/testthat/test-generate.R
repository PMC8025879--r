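test_that("self-restraint produces zero-deviation, zero-energy restraints", {
  h <- toy_helix(12)
  dr <- generate_distance_restraints(h)
  expect_gt(nrow(dr), 50)
  st <- classify_restraints(dr, h)
  expect_true(all(st$state == "satisfied"))
  expect_lt(max(abs(st$deviation)), 1e-9)
  e <- total_energy_and_forces(h, dr)
  expect_equal(e$energy, 0)
  expect_equal(max(abs(e$forces)), 0)
})

test_that("distance-restraint parameters follow the r0-dependent formulas", {
  h <- toy_helix(15)
  dr <- generate_distance_restraints(h)
  expect_lt(max(abs(dr$tau / dr$r0 - 0.025)), 1e-9)
  expect_lt(max(abs(dr$c / dr$r0 - 0.05)), 1e-9)
  expect_lt(max(abs(dr$alpha + 2 + 4 * log(dr$r0))), 1e-9)
  expect_true(all(dr$k == 5))
  # worked value: a 4 Angstrom template distance under defaults
  expect_equal(0.025 * 4, 0.1)
  near4 <- dr[which.min(abs(dr$r0 - 4)), ]
  expect_equal(near4$alpha, -2 - 4 * log(near4$r0))
  expect_true(all(dr$r0 <= 8))
})

test_that("emitted restraints equal a brute-force enumeration oracle", {
  # glycine-rich sequence: glycines contribute only CA
  s <- build_toy_structure("helix", length = 24,
                           sequence = "AGLGVGKGDGSGTGIGFGEGQGNG")
  dr <- generate_distance_restraints(s)
  oracle <- brute_force_self_restraints(s)
  expect_equal(nrow(dr), nrow(oracle))
  expect_identical(dr$atom1, oracle$atom1)
  expect_identical(dr$atom2, oracle$atom2)
  expect_equal(dr$r0, oracle$r0, tolerance = 1e-12)
  expect_equal(dr$tau, oracle$tau, tolerance = 1e-12)
  expect_equal(dr$c, oracle$c, tolerance = 1e-12)
  expect_equal(dr$alpha, oracle$alpha, tolerance = 1e-12)
  # per-residue participation counts match the oracle's
  count_by_res <- function(a1, a2) {
    res <- sub("^(([^|]*\\|){2}[^|]*)\\|.*$", "\\1", c(a1, a2))
    table(res)
  }
  expect_equal(count_by_res(dr$atom1, dr$atom2),
               count_by_res(oracle$atom1, oracle$atom2))
})

test_that("restraint generation is deterministic and monotone in the cutoff", {
  h <- toy_helix(15)
  a <- generate_distance_restraints(h)
  b <- generate_distance_restraints(h)
  expect_identical(as.data.frame(a), as.data.frame(b))
  narrow <- generate_distance_restraints(h, options = restraint_options(distance_cutoff = 6))
  key <- function(x) paste(x$atom1, x$atom2)
  expect_true(all(key(narrow) %in% key(a)))
  expect_gt(nrow(a), nrow(narrow))
})

test_that("custom atom names extend the eligible set", {
  h <- toy_helix(10)
  base <- generate_distance_restraints(h)
  extra <- generate_distance_restraints(
    h, options = restraint_options(custom_atom_names = c("N", "C"))
  )
  expect_gt(nrow(extra), nrow(base))
  expect_true(any(grepl("\\|N$", c(extra$atom1, extra$atom2))))
  expect_false(any(grepl("\\|N$", c(base$atom1, base$atom2))))
})

test_that("self torsion restraints cover backbone and rotameric side chains", {
  h <- toy_helix(12)
  tr <- generate_torsion_restraints(h)
  st <- classify_restraints(tr, h)
  expect_true(all(st$state == "satisfied"))
  expect_lt(max(abs(st$deviation)), 1e-9)
  labels <- split(tr$label, tr$res_key)
  # non-terminal residues carry phi, psi and omega
  mid_keys <- restraintr:::residue_key("A", 2:11, "")
  for (k in mid_keys) {
    expect_true(all(c("phi", "psi", "omega") %in% labels[[k]]))
  }
  expect_true(any(grepl("^chi", tr$label)))
  expect_true(all(tr$k == 250))
  adaptive <- tr[tr$form == "adaptive", ]
  expect_lt(max(abs(adaptive$kappa - kappa_from_well_width(60))), 1e-12)
  expect_true(all(adaptive$alpha == 0.3))
  # omega restraints never carry the adaptive form
  expect_true(all(tr$form[tr$label == "omega"] == "omega"))
})

test_that("side chains are restrained only for identical residues", {
  model <- build_toy_structure("helix", length = 8, sequence = "AALAAAAA")
  template <- build_toy_structure("helix", length = 8, sequence = "AAVAAAAA")
  tr <- generate_torsion_restraints(model, template)
  at3 <- tr[grepl("^A\\|3\\|", tr$res_key), ]
  expect_true(all(c("phi", "psi", "omega") %in% at3$label))
  expect_false(any(grepl("^chi", at3$label)))
  self_tr <- generate_torsion_restraints(model, model)
  expect_true(any(grepl("^chi", self_tr$label[grepl("^A\\|3\\|", self_tr$res_key)])))
})

test_that("a template cis-proline facing a non-proline keeps the model's isomer", {
  template <- build_toy_structure("helix", length = 8, sequence = "AAAAPAAA",
                                  omega = c(180, 180, 180, 180, 0, 180, 180, 180))
  model_nonpro <- build_toy_structure("helix", length = 8, sequence = "AAAALAAA")
  tr <- generate_torsion_restraints(model_nonpro, template)
  om5 <- tr[tr$label == "omega" & grepl("^A\\|5\\|", tr$res_key), ]
  expect_equal(om5$target, "trans")
  # a proline in the model does adopt the template's cis state
  model_pro <- build_toy_structure("helix", length = 8, sequence = "AAAAPAAA")
  tr2 <- generate_torsion_restraints(model_pro, template)
  om5b <- tr2[tr2$label == "omega" & grepl("^A\\|5\\|", tr2$res_key), ]
  expect_equal(om5b$target, "cis")
})

test_that("backbone and side-chain restraints can be disabled independently", {
  h <- toy_helix(10)
  no_bb <- generate_torsion_restraints(
    h, options = restraint_options(restrain_backbone = FALSE))
  expect_false(any(no_bb$label %in% c("phi", "psi", "omega")))
  no_sc <- generate_torsion_restraints(
    h, options = restraint_options(restrain_sidechain = FALSE))
  expect_false(any(grepl("^chi", no_sc$label)))
})

test_that("nucleic selections are rejected for torsion restraints", {
  nuc <- restraintr:::new_structure(
    chain = "B", resno = 1:5, icode = "", resname = "A",
    atom = "C4'", x = seq(0, 20, 5), y = 0, z = 0
  )
  expect_error(generate_torsion_restraints(nuc, nuc), "nucleic")
})

test_that("generation options validate their domains", {
  expect_error(restraint_options(kappa = -1), "non-negative")
  expect_error(restraint_options(angle_range = 200), "strictly between")
  expect_error(restraint_options(distance_cutoff = 0), "positive")
})
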