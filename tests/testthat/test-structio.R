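test_that("hand-written PDB parses with coordinates bit-equal to the file fields", {
  f <- two_residue_pdb(tempfile(fileext = ".pdb"))
  s <- read_structure(f)
  expect_equal(n_residues(s), 2L)
  expect_identical(s$atoms$x, c(11.104, 12.560, 14.851))
  expect_identical(s$atoms$y, c(13.207, 13.400, 16.033))
  expect_identical(s$atoms$z, c(9.500, 9.278, 10.002))
  expect_identical(s$atoms$res_seq, c(12L, 12L, 13L))
  expect_identical(s$cell, c(50, 60, 70, 90, 90, 90))
})

test_that("PDB write/read round trip preserves atoms to format precision", {
  s <- synth_parent()$structure
  s$cell <- c(80, 80, 132, 90, 90, 90)
  f <- tempfile(fileext = ".pdb")
  write_structure(s, f)
  s2 <- read_structure(f)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_identical(s2$atoms$res_seq, s$atoms$res_seq)
  expect_identical(s2$atoms$atom_name, s$atoms$atom_name)
  expect_lt(max(abs(coords(s2) - coords(s))), 5e-4 + 1e-9)  # 3-decimal format
  expect_equal(s2$cell, s$cell)
  # second round trip is exact (coordinates already quantized)
  f3 <- tempfile(fileext = ".pdb")
  write_structure(s2, f3)
  s3 <- read_structure(f3)
  expect_identical(coords(s3), coords(s2))
})

test_that("the same model read from PDB and mmCIF agrees to field precision", {
  s <- synth_parent()$structure
  fp <- tempfile(fileext = ".pdb"); fc <- tempfile(fileext = ".cif")
  write_structure(s, fp)
  write_minimal_cif(s, fc)
  sp <- read_structure(fp); sc <- read_structure(fc)
  expect_identical(sp$atoms$res_seq, sc$atoms$res_seq)
  expect_identical(sp$atoms$res_name, sc$atoms$res_name)
  expect_identical(sp$atoms$chain, sc$atoms$chain)
  expect_lt(max(abs(coords(sp) - coords(sc))), 1e-9)
})

test_that("altloc records resolve to highest occupancy, ties to A", {
  f <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A  10       1.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A  10       2.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CA AGLY A  11       3.000   0.000   0.000  0.50 10.00           C",
    "ATOM      4  CA BGLY A  11       4.000   0.000   0.000  0.50 10.00           C",
    "END"), f)
  s <- read_structure(f)
  expect_equal(nrow(s$atoms), 2L)
  expect_equal(s$atoms$x, c(2, 3))  # B wins on occupancy; A wins the tie
})

test_that("unreadable inputs give informative errors", {
  expect_error(read_structure(tempfile()), "not found")
  f <- tempfile(fileext = ".pdb")
  writeLines(c("REMARK nothing here", "END"), f)
  expect_error(read_structure(f), "parse|empty")
})

test_that("selection is count-exact, order-preserving, idempotent and composable", {
  s <- synth_parent()$structure  # 302 residues numbered 12..316 with gaps
  all_ca <- select_atoms(s, chain = "A", residues = c(12, 316), atom_names = "CA")
  expect_equal(nrow(all_ca$atoms), 302L)
  expect_equal(nrow(select_atoms(s, chain = "Z")$atoms), 0L)
  # composition: chained chain/residue selection equals the joint selection
  a <- select_atoms(select_atoms(s, chain = "A"), residues = c(12, 165))
  b <- select_atoms(s, chain = "A", residues = c(12, 165))
  expect_identical(a$atoms, b$atoms)
  # idempotence
  expect_identical(select_atoms(b, chain = "A", residues = c(12, 165))$atoms, b$atoms)
  # order preserved
  expect_identical(b$atoms$res_seq, sort(b$atoms$res_seq))
})

test_that("apply_transform is exact, rigid, and associative", {
  s <- synth_parent()$structure
  expect_identical(coords(apply_transform(s, rigid_transform())), coords(s))
  up44 <- apply_transform(s, rigid_transform(translation = c(0, 0, 44)))
  expect_equal(up44$atoms$z, s$atoms$z + 44)
  expect_identical(up44$atoms$x, s$atoms$x)
  t1 <- rigid_transform(rotation_about_axis(c(1, 2, 3), 37), c(1, -2, 3))
  t2 <- rigid_transform(rotation_about_axis(c(-1, 0, 1), 112), c(-5, 0, 8))
  lhs <- apply_transform(apply_transform(s, t1), t2)
  rhs <- apply_transform(s, compose_transform(t2, t1))
  expect_lt(max(abs(coords(lhs) - coords(rhs))), 1e-9)
  # pairwise distances preserved
  i <- c(1, 10, 50); j <- c(5, 200, 300)
  d0 <- sqrt(rowSums((coords(s)[i, ] - coords(s)[j, ])^2))
  d1 <- sqrt(rowSums((coords(lhs)[i, ] - coords(lhs)[j, ])^2))
  expect_lt(max(abs(d0 - d1)), 1e-9)
  # improper matrices are refused
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl), "rotation")
})

test_that("hetero records are retained, selectable and excluded from Calpha ops", {
  s <- synth_parent()$structure
  het <- data.frame(chain = "A", res_seq = 400L, ins = "", res_name = "GDP",
                    atom_name = "PA", element = "P", x = 0, y = 0, z = 0,
                    occupancy = 1, b = 0, is_hetero = TRUE)
  s2 <- fts_structure(rbind(s$atoms, het), id = "with_ligand")
  expect_equal(sum(select_atoms(s2, hetero = TRUE)$atoms$is_hetero), 1L)
  expect_equal(nrow(ca_records(s2)), 302L)  # ligand not a Calpha record
  expect_equal(nchar(ca_sequence(s2)), 302L)
})
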