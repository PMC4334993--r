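test_that("PDB write/read round-trips atoms, numbering and model count", {
  pep <- make_toy_peptide(n_models = 3)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_structure(pep, path)
  back <- read_structure(path)
  expect_equal(n_models(back), 3L)
  for (mi in 1:3) {
    a <- model_atoms(pep, mi); b <- model_atoms(back, mi)
    expect_equal(b$name, a$name)
    expect_equal(b$resname, a$resname)
    expect_equal(b$resseq, a$resseq)
    expect_equal(b$chain, a$chain)
    expect_equal(atom_coords(b), atom_coords(a), tolerance = 1e-3)
  }
  # single-model file has no MODEL records and reads as one model
  tc <- toy_channel_neg()
  write_structure(tc$subunit, path)
  expect_false(any(grepl("^MODEL", readLines(path))))
  expect_equal(n_models(read_structure(path)), 1L)
})

test_that("read_structure rejects junk and empty files", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c("this is not", "a pdb file"), path)
  expect_error(read_structure(path), "parse")
  writeLines(c("REMARK nothing here", "END"), path)
  expect_error(read_structure(path), "empty structure")
  expect_error(read_structure(file.path(tempdir(), "no_such.pdb")), "not found")
  expect_error(write_structure(structure_bundle(list(empty_atom_table())),
                               "x.pdb"),
               "empty")
})

test_that("altlocs keep the highest occupancy and hydrogens are dropped", {
  lines <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA AALA A   1       1.000   0.000   0.000  0.40  0.00           C",
    "ATOM      3  CA BALA A   1       2.000   0.000   0.000  0.60  0.00           C",
    "ATOM      4  H   ALA A   1       9.000   0.000   0.000  1.00  0.00           H",
    "END")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(lines, path)
  a <- model_atoms(read_structure(path))
  expect_equal(nrow(a), 2L)                       # H dropped, one CA kept
  expect_equal(a$x[a$name == "CA"], 2.0)          # occupancy 0.60 wins
})

test_that("segment sequences respect inclusive author-numbered spans", {
  tc <- toy_channel_neg()
  full <- extract_segment_sequence(tc$subunit)
  n <- nrow(residue_table(model_atoms(tc$subunit)))
  expect_equal(nchar(full), n)
  s <- extract_segment_sequence(tc$subunit, segment_span("A", 3, 9))
  expect_equal(nchar(s), 7L)
  expect_equal(s, substr(full, 3, 9))
  expect_error(extract_segment_sequence(tc$subunit, segment_span("A", 9, 3)),
               "after")
  expect_error(extract_segment_sequence(tc$subunit, segment_span("Z", 1, 5)),
               "not found")
  # the classic toxin sequence from an all-atom rebuild
  tox <- structure_bundle(list(seq_structure(TPN_SEQ)))
  expect_equal(extract_segment_sequence(tox), TPN_SEQ)
})

test_that("superpose recovers exact transforms and matches the oracle", {
  set.seed(7)
  x <- matrix(rnorm(30), ncol = 3)
  fit <- superpose(x, x)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-10)

  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  y <- x %*% t(R); y <- sweep(y, 2, c(3, -2, 5), `+`)
  fit <- superpose(x, y)
  expect_equal(fit$rotation, R, tolerance = 1e-8)
  expect_lt(fit$rmsd, 1e-8)

  # 4-point asymmetric set against the standalone least-squares oracle
  a <- matrix(c(0, 0, 0, 2, 0, 0, 0, 3, 0, 1, 1, 2), ncol = 3, byrow = TRUE)
  b <- matrix(c(0.1, 0, 0, 2, 0.2, 0, 0, 3.1, 0.3, 1, 1.2, 2), ncol = 3,
              byrow = TRUE)
  expect_equal(superpose(a, b)$rmsd, oracle_kabsch(a, b)$rmsd,
               tolerance = 1e-6)
  expect_equal(superpose(a, b)$rotation, oracle_kabsch(a, b)$rotation,
               tolerance = 1e-6)

  expect_error(superpose(x, x[1:5, ]), "mismatch")
  line <- cbind(1:5, 0, 0)
  expect_warning(superpose(line, line), "degenerate")
})

test_that("superpose rmsd is invariant to common rigid motions", {
  set.seed(11)
  x <- matrix(rnorm(24), ncol = 3)
  y <- x + matrix(rnorm(24, 0, 0.3), ncol = 3)
  base <- superpose(x, y)$rmsd
  for (i in 1:5) {
    R <- oracle_kabsch(matrix(rnorm(24), ncol = 3),
                       matrix(rnorm(24), ncol = 3))$rotation
    t <- rnorm(3, 0, 10)
    xr <- sweep(x %*% t(R), 2, t, `+`)
    yr <- sweep(y %*% t(R), 2, t, `+`)
    expect_equal(superpose(xr, yr)$rmsd, base, tolerance = 1e-9)
  }
})

test_that("FASTA round-trips", {
  path <- withr::local_tempfile(fileext = ".fasta")
  seqs <- c(tox = TPN_SEQ, other = "GGGGKK")
  write_fasta(seqs, path)
  expect_equal(read_fasta(path), seqs)
})
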