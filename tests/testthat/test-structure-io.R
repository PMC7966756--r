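test_that("synthetic structures round-trip through PDB within 1e-3 Angstrom", {
  for (n_res in c(1, 7)) {
    w <- water_set(matrix(runif(9, 5, 25), 3))
    s <- gen_toy_structure(n_res, planted_waters = w, cell = c(30, 35, 40))
    p <- withr::local_tempfile(fileext = ".pdb")
    write_structure(s, p)
    s2 <- read_structure(p)
    expect_equal(nrow(s2$atoms), nrow(s$atoms))
    expect_equal(s2$atoms$elety, s$atoms$elety)
    expect_equal(s2$atoms$resno, s$atoms$resno)
    expect_equal(as.matrix(s2$atoms[, c("x", "y", "z")]),
                 as.matrix(s$atoms[, c("x", "y", "z")]),
                 tolerance = 1e-3, ignore_attr = TRUE)
    expect_equal(unname(s2$cell), c(30, 35, 40, 90, 90, 90))
    expect_equal(s2$space_group, "P 21 21 21")
  }
  # one-residue scaffold has exactly 5 atoms
  s1 <- gen_toy_structure(1)
  expect_equal(nrow(s1$atoms), 5L)
})

test_that("altloc conformers collapse to the highest-occupancy copy", {
  p <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   30.000   30.000   30.000  90.00  90.00  90.00 P 1",
    "ATOM      1  N  AALA A   1       1.000   1.000   1.000  0.40 10.00           N",
    "ATOM      2  N  BALA A   1       2.000   1.000   1.000  0.60 10.00           N",
    "ATOM      3  CA  ALA A   1       3.000   1.000   1.000  1.00 10.00           C",
    "END"
  ), p)
  s <- read_structure(p)
  expect_equal(nrow(s$atoms), 2L)
  n_atom <- s$atoms[s$atoms$elety == "N", ]
  expect_equal(n_atom$x, 2.0)  # the 0.60-occupancy B conformer wins
})

test_that("water residue name synonyms are all flagged as water", {
  atoms <- data.frame(
    elety = "O", resid = c("HOH", "WAT", "H2O", "ALA"), chain = "A",
    resno = 1:4, x = 1:4, y = 0, z = 0, elesy = "O"
  )
  s <- crystal_structure(atoms)
  expect_equal(s$atoms$water, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("select_waters_near applies the any-atom cutoff and stays monotone", {
  # three waters planted at 2.5 / 3.9 / 6.0 Angstrom from the residue-1 CB
  s0 <- gen_toy_structure(1)
  cb <- as.numeric(s0$atoms[s0$atoms$elety == "CB", c("x", "y", "z")])
  w <- water_set(rbind(cb + c(2.5, 0, 0), cb + c(0, 3.9, 0), cb + c(0, 0, 6.0)))
  s <- gen_toy_structure(1, planted_waters = w)
  reg <- region_definition(probe = c(1, 1))
  expect_equal(nrow(select_waters_near(s, reg, cutoff = 4.0)), 2L)
  expect_warning(empty <- select_waters_near(s, reg, cutoff = 0), "no waters")
  expect_equal(nrow(empty), 0L)
  # monotone: larger cutoff can only add waters
  prev <- character(0)
  for (cutoff in c(1, 2.6, 4.0, 6.5)) {
    ids <- suppressWarnings(select_waters_near(s, reg, cutoff = cutoff)$water_id)
    expect_true(all(prev %in% ids))
    prev <- ids
  }
})

test_that("symmetry expansion is exact on a one-image P212121 construction", {
  # place one water so exactly one symmetry image lands within 5 Angstrom of
  # the probe: image of (x,y,z) under (x+1/2, -y+1/2, -z) in a 20-cube
  cell <- c(20, 20, 20, 90, 90, 90)
  water <- matrix(c(2, 9, 1), 1)   # op 2 image: (12, 1, -1) -> shifted (12, 1, 19)
  s <- gen_toy_structure(1, planted_waters = water_set(water), cell = cell,
                         scaffold_origin = c(3, 15, 10))
  probe <- matrix(c(12, 1, 19), 1)
  ex <- expand_symmetry(s, probe, radius = 5)
  added <- ex$atoms[ex$atoms$sym != "1_555", , drop = FALSE]
  expect_equal(nrow(added), 1L)
  expect_equal(as.numeric(added[, c("x", "y", "z")]), c(12, 1, 19))
  # oracle agreement on the same construction
  n_oracle <- oracle_symmetry_images(
    water, cell, sym_ops("P 21 21 21"), probe, 5,
    existing = as.matrix(s$atoms[, c("x", "y", "z")])
  )
  expect_equal(nrow(added), n_oracle)
})

test_that("symmetry expansion matches the brute-force oracle on random cells", {
  for (seed in 1:3) {
    set.seed(seed)
    cell <- c(18 + seed, 22, 26, 90, 90, 90)
    wxyz <- cbind(runif(6, 0, cell[1]), runif(6, 0, cell[2]), runif(6, 0, cell[3]))
    s <- gen_toy_structure(3, planted_waters = water_set(wxyz), cell = cell,
                           scaffold_origin = c(3, 5, 6))
    probe <- matrix(c(cell[1], cell[2], cell[3]) / 2, 1)
    ex <- expand_symmetry(s, probe, radius = 7)
    n_added <- nrow(ex$atoms) - nrow(s$atoms)
    n_oracle <- oracle_symmetry_images(
      wxyz, cell, sym_ops("P 21 21 21"), probe, 7,
      existing = as.matrix(s$atoms[, c("x", "y", "z")])
    )
    expect_equal(n_added, n_oracle)
  }
})

test_that("every symmetry copy inverse-maps onto an input water", {
  set.seed(4)
  cell <- c(21, 23, 25, 90, 90, 90)
  wxyz <- cbind(runif(5, 0, 21), runif(5, 0, 23), runif(5, 0, 25))
  s <- gen_toy_structure(3, planted_waters = water_set(wxyz), cell = cell)
  ex <- expand_symmetry(s, matrix(c(10, 11, 12), 1), radius = 9)
  added <- ex$atoms[ex$atoms$sym != "1_555", , drop = FALSE]
  expect_gt(nrow(added), 0)
  ops <- sym_ops("P 21 21 21")
  M <- icebound:::orth_matrix(s$cell)
  Minv <- solve(M)
  for (r in seq_len(nrow(added))) {
    tag <- strsplit(added$sym[r], "_")[[1]]
    op <- ops[[as.integer(tag[1])]]
    shift <- as.integer(strsplit(tag[2], "")[[1]]) - 5L
    img_frac <- as.numeric(Minv %*% as.numeric(added[r, c("x", "y", "z")]))
    orig_frac <- as.numeric(solve(op$R, img_frac - op$t - shift))
    orig <- as.numeric(M %*% orig_frac)
    dmin <- min(sqrt(rowSums(sweep(wxyz, 2, orig)^2)))
    expect_lt(dmin, 1e-6)
  }
})

test_that("identity-only expansion leaves a well-separated P1 cell unchanged", {
  w <- water_set(matrix(c(50, 50, 50), 1))
  s <- gen_toy_structure(2, planted_waters = w, cell = c(100, 100, 100),
                         space_group = "P 1", scaffold_origin = c(45, 50, 50))
  ex <- expand_symmetry(s, matrix(c(50, 50, 50), 1), radius = 10)
  expect_equal(nrow(ex$atoms), nrow(s$atoms))
})

test_that("missing cell or unsupported space group fail with clear errors", {
  s <- gen_toy_structure(2, planted_waters = water_set(matrix(1:3, 1)), cell = NULL)
  expect_error(expand_symmetry(s, matrix(0, 1, 3), 5), "unit cell")
  s2 <- gen_toy_structure(2, planted_waters = water_set(matrix(1:3, 1)),
                          cell = c(30, 30, 30, 90, 90, 90), space_group = "C 2")
  expect_error(expand_symmetry(s2, matrix(0, 1, 3), 5), "P 21 21 21")
})

test_that("structure invariants are enforced", {
  atoms <- data.frame(elety = "CA", resid = "ALA", chain = "A", resno = 1,
                      x = 1, y = 1, z = 1)
  expect_error(crystal_structure(rbind(atoms, atoms)), "unique")
  expect_error(crystal_structure(atoms, cell = c(-1, 2, 3, 90, 90, 90)), "positive")
  expect_error(crystal_structure(atoms, cell = c(1, 2, 3, 90, 90, 181)), "angles")
  bad <- atoms; bad$x <- NA_real_
  expect_error(crystal_structure(bad), "non-finite")
})
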