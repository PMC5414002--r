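test_that("sasa matches closed forms: isolated atom, buried atom, two spheres", {
  one <- fts_structure(data.frame(chain = "A", res_seq = 1, res_name = "GLY",
                                  atom_name = "CA", x = 0, y = 0, z = 0), id = "one")
  a1 <- sasa(one, probe = 1.4, uniform_radius = 1.9)
  expect_equal(as.numeric(a1), 4 * pi * 3.3^2, tolerance = 1e-12)
  # two partially overlapping spheres vs the spherical-cap closed form
  d <- 3; R <- 3.3
  two <- fts_structure(data.frame(chain = "A", res_seq = 1:2, res_name = "GLY",
                                  atom_name = "CA", x = c(0, d), y = 0, z = 0), id = "two")
  a2 <- sasa(two, probe = 1.4, uniform_radius = 1.9, n_points = 1920)
  analytic <- 4 * pi * R^2 - 2 * pi * R * (R - d / 2)
  expect_equal(as.numeric(a2[1]), analytic, tolerance = 0.02 * analytic)
  expect_equal(as.numeric(a2[2]), analytic, tolerance = 0.02 * analytic)
  # an atom enclosed by a shell of neighbours has zero accessible area
  shell <- as.matrix(expand.grid(x = c(-2, 0, 2), y = c(-2, 0, 2), z = c(-2, 0, 2)))
  shell <- shell[rowSums(shell != 0) > 0, ]
  enc <- fts_structure(data.frame(chain = "A", res_seq = seq_len(nrow(shell) + 1),
                                  res_name = "GLY", atom_name = "CA",
                                  x = c(0, shell[, 1]), y = c(0, shell[, 2]),
                                  z = c(0, shell[, 3])), id = "shell")
  ae <- sasa(enc, probe = 1.4, uniform_radius = 1.9)
  expect_equal(as.numeric(ae[1]), 0)
})

test_that("sasa is deterministic and converges when the point count doubles", {
  s <- random_ca_structure(60, seed = 2)
  a <- sasa(s, uniform_radius = 3)
  b <- sasa(s, uniform_radius = 3)
  expect_identical(a, b)
  tot1 <- attr(sasa(s, uniform_radius = 3, n_points = 960), "total")
  tot2 <- attr(sasa(s, uniform_radius = 3, n_points = 1920), "total")
  expect_lt(abs(tot1 - tot2) / tot2, 0.01)
})

test_that("interface BSA is symmetric, zero for distant subunits, monotone in separation", {
  parent <- synth_parent()$structure
  fil <- make_filament_crystal(parent, repeat_length = 44, n = 2)
  a <- select_atoms(fil, chain = "A"); b <- select_atoms(fil, chain = "B")
  rab <- interface_bsa(a, b, uniform_radius = 3)
  rba <- interface_bsa(b, a, uniform_radius = 3)
  expect_gt(rab$bsa, 0)
  expect_equal(rab$bsa, rba$bsa, tolerance = 1e-9)
  expect_lte(rab$sasa_complex, rab$sasa_a + rab$sasa_b)
  expect_equal(rab$bsa_half, rab$bsa_total / 2, tolerance = 1e-12)
  expect_equal(interface_bsa(a, b, convention = "total", uniform_radius = 3)$bsa,
               rab$bsa_total, tolerance = 1e-12)
  expect_gt(rab$n_contact_residues, 0)
  # beyond the maximum-overlap separation, translating apart can only lower
  # burial; far apart it vanishes
  seps <- c(66, 88, 110, 200)
  bsas <- vapply(seps, function(dz) {
    b2 <- apply_transform(a, rigid_transform(translation = c(0, 0, dz)))
    b2$atoms$chain <- "B"
    interface_bsa(a, b2, uniform_radius = 3)$bsa
  }, numeric(1))
  expect_true(all(diff(bsas) <= 1e-9))
  expect_equal(bsas[length(bsas)], 0)
})

test_that("filament repeat equals the applied lattice translation and screw component", {
  parent <- synth_parent()$structure
  up <- apply_transform(parent, rigid_transform(translation = c(0, 0, 44)))
  fr <- filament_repeat(parent, up)
  expect_equal(fr$repeat_length, 44, tolerance = 1e-9)
  # 45 angstrom variant
  up45 <- apply_transform(parent, rigid_transform(translation = c(0, 0, 45)))
  expect_equal(filament_repeat(parent, up45)$repeat_length, 45, tolerance = 1e-9)
  # screw operator: repeat is the axial component only
  op <- rigid_transform(rotation_about_axis(c(0, 0, 1), 30), c(0, 0, 44))
  tw <- apply_transform(parent, op)
  fr2 <- filament_repeat(parent, tw)
  expect_equal(fr2$repeat_length, 44, tolerance = 1e-6)
  expect_gte(abs(fr2$axis[3]), 0.999)
  # sequence mismatch is an error
  other <- random_ca_structure(50, seed = 99)
  expect_error(filament_repeat(parent, other), "sequence")
})

test_that("build_filament places operator powers with a consistent repeat", {
  parent <- synth_parent()$structure
  op <- rigid_transform(translation = c(0, 0, 44))
  fil <- build_filament(parent, op, 5)
  expect_length(fil$subunits, 5L)
  expect_equal(fil$repeat_length, 44, tolerance = 1e-9)
  expect_equal(vapply(fil$subunits, function(s) unique(s$atoms$chain), ""),
               c("A", "B", "C", "D", "E"))
  pair <- filament_repeat(fil$subunits[[2]], fil$subunits[[3]])
  expect_equal(pair$repeat_length, 44, tolerance = 1e-9)
  # helical operator: every adjacent transform identical along the model
  oph <- rigid_transform(rotation_about_axis(c(0, 0, 1), 360 / 6), c(0, 0, 20))
  filh <- build_filament(parent, oph, 6)
  reps <- vapply(1:5, function(k)
    filament_repeat(filh$subunits[[k]], filh$subunits[[k + 1]])$repeat_length,
    numeric(1))
  expect_lt(max(reps) - min(reps), 1e-6)
  expect_error(build_filament(parent, op, 1), "n >= 2")
  expect_error(build_filament(parent, list(rotation = diag(c(-1, 1, 1))), 3),
               "rigid_transform")
})
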