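test_that("read_pdb parses a minimal structure and applies the record rules", {
  f <- write_pdb_lines(pdb_atom_line(1, "CA", "GLY", 1, 0, 0, 0))
  m <- read_pdb(f)
  expect_s3_class(m, "pdb_model")
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$resid, "GLY")

  # highest-occupancy altloc wins
  f <- write_pdb_lines(c(
    pdb_atom_line(1, "CA", "SER", 1, 0, 0, 0, occ = 0.6, alt = "A"),
    pdb_atom_line(2, "CA", "SER", 1, 9, 0, 0, occ = 0.4, alt = "B")))
  m <- read_pdb(f)
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$x, 0)

  # only MODEL 1 is kept
  f <- write_pdb_lines(c(
    "MODEL     1",
    pdb_atom_line(1, "CA", "ALA", 1, 0, 0, 0),
    "ENDMDL",
    "MODEL     2",
    pdb_atom_line(2, "CA", "ALA", 2, 5, 0, 0),
    "ENDMDL"))
  m <- read_pdb(f)
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$resno, 1L)

  f <- write_pdb_lines("REMARK nothing here")
  expect_error(read_pdb(f), class = "petasetyper_empty_structure")
  expect_error(read_pdb(tempfile()), class = "petasetyper_io_error")
})

test_that("disulfide detection applies the SG-SG distance rule", {
  two_cys <- function(d) write_pdb_lines(c(
    pdb_atom_line(1, "CA", "CYS", 10, 0, 0, 0),
    pdb_atom_line(2, "SG", "CYS", 10, 0, 1, 0),
    pdb_atom_line(3, "CA", "CYS", 50, 5, 0, 0),
    pdb_atom_line(4, "SG", "CYS", 50, d, 1, 0)))
  ds <- detect_disulfides(read_pdb(two_cys(2.05)))
  expect_equal(nrow(ds), 1L)
  expect_equal(ds$res_a, 10L)
  expect_equal(ds$res_b, 50L)
  expect_equal(ds$sg_distance, 2.05, tolerance = 1e-6)

  expect_equal(nrow(detect_disulfides(read_pdb(two_cys(4.0)))), 0L)
  # no cysteines at all -> empty, no error
  f <- write_pdb_lines(pdb_atom_line(1, "CA", "GLY", 1, 0, 0, 0))
  expect_equal(nrow(detect_disulfides(read_pdb(f))), 0L)
})

test_that("each cysteine joins at most one bond, greedily by distance", {
  # three SG atoms in a row: 10-20 at 2.0 A, 20-30 at 2.2 A
  f <- write_pdb_lines(c(
    pdb_atom_line(1, "SG", "CYS", 10, 0, 0, 0),
    pdb_atom_line(2, "SG", "CYS", 20, 2.0, 0, 0),
    pdb_atom_line(3, "SG", "CYS", 30, 4.2, 0, 0)))
  ds <- detect_disulfides(read_pdb(f))
  expect_equal(nrow(ds), 1L)
  expect_equal(c(ds$res_a, ds$res_b), c(10L, 20L))
})

test_that("disulfide output is stable under atom order reversal", {
  lines <- c(
    pdb_atom_line(1, "SG", "CYS", 64, 0, 0, 0),
    pdb_atom_line(2, "SG", "CYS", 126, 2.05, 0, 0),
    pdb_atom_line(3, "SG", "CYS", 273, 0, 10, 0),
    pdb_atom_line(4, "SG", "CYS", 276, 2.05, 10, 0))
  a <- detect_disulfides(read_pdb(write_pdb_lines(lines)))
  b <- detect_disulfides(read_pdb(write_pdb_lines(rev(lines))))
  expect_equal(a[c("res_a", "res_b")], b[c("res_a", "res_b")],
               ignore_attr = TRUE)
})

test_that("triad detection returns the constructed minimal-sum triple", {
  triad_lines <- function(d1 = 3.0, d2 = 2.8) c(
    pdb_atom_line(1, "CA", "SER", 156, 0, 0, 0),
    pdb_atom_line(2, "OG", "SER", 156, 0, 50, 0),
    pdb_atom_line(3, "CA", "HIS", 236, 5, 0, 0),
    pdb_atom_line(4, "NE2", "HIS", 236, d1, 50, 0),
    pdb_atom_line(5, "ND1", "HIS", 236, d1 + 2.2, 50, 0),
    pdb_atom_line(6, "CA", "ASP", 206, 9, 0, 0),
    pdb_atom_line(7, "OD2", "ASP", 206, d1 + 2.2 + d2, 50, 0))
  tc <- detect_triad(read_pdb(write_pdb_lines(triad_lines())))
  expect_equal(tc$ser, 156L)
  expect_equal(tc$his, 236L)
  expect_equal(tc$asp, 206L)
  expect_equal(tc$ser_his_dist, 3.0, tolerance = 1e-6)
  expect_equal(tc$his_asp_dist, 2.8, tolerance = 1e-6)
  expect_false(tc$acid_is_glu)

  # no His -> no triad
  f <- write_pdb_lines(c(
    pdb_atom_line(1, "OG", "SER", 1, 0, 0, 0),
    pdb_atom_line(2, "OD2", "ASP", 2, 3, 0, 0)))
  expect_error(detect_triad(read_pdb(f)), class = "petasetyper_no_triad")

  # out-of-range geometry -> no triad
  f <- write_pdb_lines(triad_lines(d1 = 5.0))
  expect_error(detect_triad(read_pdb(f)), class = "petasetyper_no_triad")
})

test_that("a glutamate acid member is accepted and flagged", {
  f <- write_pdb_lines(c(
    pdb_atom_line(1, "OG", "SER", 10, 0, 0, 0),
    pdb_atom_line(2, "NE2", "HIS", 20, 3.0, 0, 0),
    pdb_atom_line(3, "ND1", "HIS", 20, 5.2, 0, 0),
    pdb_atom_line(4, "OE1", "GLU", 30, 8.0, 0, 0)))
  tc <- detect_triad(read_pdb(f))
  expect_true(tc$acid_is_glu)
  expect_equal(tc$asp, 30L)
})

test_that("competing triples resolve by minimal distance sum", {
  # two complete triads; the second has the smaller OG-NE2 + ND1-OD2 sum
  f <- write_pdb_lines(c(
    pdb_atom_line(1, "OG", "SER", 1, 0, 0, 0),
    pdb_atom_line(2, "NE2", "HIS", 2, 3.4, 0, 0),
    pdb_atom_line(3, "ND1", "HIS", 2, 5.6, 0, 0),
    pdb_atom_line(4, "OD2", "ASP", 3, 9.0, 0, 0),
    pdb_atom_line(5, "OG", "SER", 11, 0, 30, 0),
    pdb_atom_line(6, "NE2", "HIS", 12, 2.8, 30, 0),
    pdb_atom_line(7, "ND1", "HIS", 12, 5.0, 30, 0),
    pdb_atom_line(8, "OD2", "ASP", 13, 7.6, 30, 0)))
  tc <- detect_triad(read_pdb(f))
  expect_equal(tc$ser, 11L)
})

test_that("superposition recovers identity and planted rotations", {
  set.seed(21)
  x <- matrix(rnorm(30), 10, 3)
  fit <- superpose(x, x)
  expect_equal(fit$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-9)
  expect_equal(fit$retained_pairs, 10L)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)

  for (r in 1:10) {
    R <- random_rotation()
    tr <- rnorm(3, sd = 5)
    y <- x %*% t(R) + matrix(tr, 10, 3, byrow = TRUE)
    fit <- superpose(x, y)
    expect_equal(fit$rmsd, 0, tolerance = 1e-6)
    expect_equal(fit$rotation, t(R), tolerance = 1e-6)
    expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  }
})

test_that("planted outliers are rejected and the remainder fits exactly", {
  set.seed(22)
  x <- matrix(rnorm(45), 15, 3)
  y <- x
  y[4, ] <- y[4, ] + c(10, 0, 0)
  fit <- superpose(x, y)
  expect_false(fit$retained[4])
  expect_equal(fit$retained_pairs, 14L)
  expect_equal(fit$rmsd, 0, tolerance = 1e-6)
  expect_gte(fit$cycles_run, 2L)
})

test_that("superposition is invariant to rigid motion of the mobile set", {
  set.seed(23)
  x <- matrix(rnorm(36), 12, 3)
  y <- x + matrix(rnorm(36, sd = 0.3), 12, 3)
  base <- superpose(x, y)$rmsd
  for (r in 1:5) {
    R <- random_rotation()
    xm <- x %*% t(R) + matrix(rnorm(3, sd = 10), 12, 3, byrow = TRUE)
    expect_equal(superpose(xm, y)$rmsd, base, tolerance = 1e-6)
  }
})

test_that("degenerate fits are rejected", {
  x <- matrix(rnorm(6), 2, 3)
  expect_error(superpose(x, x), class = "petasetyper_degenerate_fit")
})

test_that("pdb_chain_seq extracts the chain sequence with author numbering", {
  f <- write_pdb_lines(c(
    pdb_atom_line(1, "CA", "SER", 5, 0, 0, 0),
    pdb_atom_line(2, "CA", "GLY", 6, 3.8, 0, 0),
    pdb_atom_line(3, "CA", "TRP", 7, 7.6, 0, 0)))
  s <- pdb_chain_seq(read_pdb(f))
  expect_equal(s$residues, "SGW")
  expect_equal(s$numbering_offset, 5L)
  expect_equal(residue_at(s, 7), "W")
})
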