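# Structure I/O and the annotated rigid-body data model.

test_that("PQR files parse, round-trip, and expose charges and radii", {
  path <- system.file("extdata", "dipeptide.pqr", package = "chromadock")
  sol <- read_pqr(path)
  expect_equal(nrow(sol$atoms), length(readLines(path)))
  expect_equal(sol$atoms$atom_name[1], "N")
  expect_equal(sol$atoms$charge[10], 0.9)
  expect_equal(sol$atoms$radius[1], 1.824)

  # hand-written two-atom file: net charge zero
  tmp <- tempfile(fileext = ".pqr")
  writeLines(c("ATOM 1 NZ LYS 1 0.0 0.0 0.0 1.0 1.8",
               "ATOM 2 OE1 GLU 2 3.0 0.0 0.0 -1.0 1.7"), tmp)
  two <- read_pqr(tmp)
  expect_equal(nrow(two$atoms), 2)
  expect_equal(as.integer(net_formal_charge(two)), 0L)

  # round-trip identity at the written precision
  out <- tempfile(fileext = ".pqr")
  write_pqr(sol, out)
  back <- read_pqr(out)
  for (col in c("atom_id", "atom_name", "residue_name", "residue_index")) {
    expect_identical(back$atoms[[col]], sol$atoms[[col]])
  }
  for (col in c("x", "y", "z", "charge", "radius")) {
    expect_equal(back$atoms[[col]], sol$atoms[[col]], tolerance = 1e-8)
  }

  # malformed line errors with its line number; empty file errors
  bad <- tempfile(fileext = ".pqr")
  writeLines(c("ATOM 1 N ALA 1 0 0 0 0 1.5", "ATOM oops"), bad)
  expect_error(read_pqr(bad), "line 2")
  writeLines(character(0), bad)
  expect_error(read_pqr(bad), "no ATOM")
})

test_that("frame-transformed solutes write transformed coordinates", {
  sol <- read_pqr(system.file("extdata", "dipeptide.pqr", package = "chromadock"))
  p <- pose(quat_from_axis_angle(c(0, 0, 1), pi / 3), c(10, -4, 2))
  sol$frame <- p
  out <- tempfile(fileext = ".pqr")
  write_pqr(sol, out)
  back <- read_pqr(out)
  # independent transform of the original coordinates
  expected <- atoms_at_pose(sol, p)
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]), expected,
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("rigid transforms preserve distances and net charge", {
  sol <- fx_lh()$solute
  p <- pose(quat_random(), c(30, -12, 7))
  moved <- transform_solute(sol, p)
  d0 <- dist(as.matrix(sol$atoms[, c("x", "y", "z")]))
  d1 <- dist(as.matrix(moved$atoms[, c("x", "y", "z")]))
  expect_equal(as.numeric(d1), as.numeric(d0), tolerance = 1e-9)
  expect_identical(net_formal_charge(moved), net_formal_charge(sol))
})

test_that("net_formal_charge rounds the charge sum and keeps the raw value", {
  lh <- fx_lh()
  nf <- net_formal_charge(lh$solute)
  expect_identical(as.integer(nf), 11L)
  expect_equal(attr(nf, "sum"), 11, tolerance = 1e-9)
  zero <- point_solute(rbind(c(0, 0, 0), c(1, 0, 0)), c(0, 0))
  expect_identical(as.integer(net_formal_charge(zero)), 0L)
})

test_that("LH element annotation enforces its invariants", {
  sol <- fx_lh()$solute
  expect_error(annotate_lh_elements(sol, list(alpha3 = c(95, 109),
                                              beta1 = c(100, 105))),
               "overlap")
  expect_error(annotate_lh_elements(sol, list(alpha3 = c(95, 300))),
               "outside")
  expect_error(annotate_lh_elements(sol, list(alpha3 = c(95, 109)),
                                    alpha3_c_terminus = 120),
               "inside the alpha3 range")
  ok <- annotate_lh_elements(sol, list(alpha3 = c(95, 109), beta1 = c(80, 90)))
  expect_s3_class(ok, "lh_model")
  expect_equal(ok$alpha3_n_terminus, 95)
})

test_that("nucleosome annotation derives dyad geometry and checks coverage", {
  nuc <- fx_nucleosome()
  # built symmetric: dyad point on the symmetry (x) axis
  expect_lt(abs(nuc$dyad_point[2]), 1e-6)
  expect_lt(abs(nuc$dyad_point[3]), 1e-6)
  expect_equal(sqrt(sum(nuc$dyad_axis^2)), 1, tolerance = 1e-9)
  expect_equal(sum(nuc$bp_table$bp == 0), 1)

  # omitting a base pair from the map is an error
  bad_map <- nuc$bp_table[-5, ]
  expect_error(annotate_nucleosome(nuc$solute, bad_map, dyad_bp = 0,
                                   core_atom_ids = nuc$core_atom_ids),
               "does not cover")
  expect_error(annotate_nucleosome(nuc$solute, nuc$bp_table, dyad_bp = 999,
                                   core_atom_ids = nuc$core_atom_ids),
               "missing")
})

test_that("relabeling the linker arms flips groove signs downstream", {
  nuc <- fx_nucleosome()
  swapped <- nuc
  seg <- swapped$bp_table$segment
  seg[seg == "L-DNA1"] <- "tmp"
  seg[seg == "L-DNA2"] <- "L-DNA1"
  seg[seg == "tmp"] <- "L-DNA2"
  swapped$bp_table$segment <- seg
  s1 <- enumerate_groove_sites(nuc)
  s2 <- enumerate_groove_sites(swapped)
  i1 <- vapply(s1, `[[`, numeric(1), "index")
  i2 <- vapply(s2, `[[`, numeric(1), "index")
  # same physical sites, negated labels
  c1 <- t(vapply(s1, `[[`, numeric(3), "center"))
  c2 <- t(vapply(s2, `[[`, numeric(3), "center"))
  m <- match(-i1, i2)
  expect_false(any(is.na(m)))
  expect_equal(c2[m, ], c1, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("minimal PDB reader extracts ATOM records", {
  tmp <- tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "HETATM    3  O   HOH A   2       2.000   3.000   4.000  1.00  0.00           O",
    "REMARK ignored"), tmp)
  sol <- read_pdb_atoms(tmp)
  expect_equal(nrow(sol$atoms), 3)
  expect_equal(sol$atoms$atom_name, c("N", "CA", "O"))
  expect_equal(sol$atoms$x[2], 11.639)
  expect_true(all(sol$atoms$charge == 0))
})
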