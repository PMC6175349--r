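test_that("XYZ files round-trip losslessly to the written precision", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "", "C 0.0 0.0 0.0"), f)
  m <- read_xyz(f)
  expect_equal(m$elements, "C")
  expect_equal(m$coords, matrix(0, 1, 3))

  for (id in c("co2_like", "ch4_like", "chiral_probe", "aminoethanol")) {
    mol <- generate_fixture(id)
    g <- withr::local_tempfile(fileext = ".xyz")
    write_xyz(mol, g)
    back <- read_xyz(g)
    expect_identical(back$elements, mol$elements)
    expect_lt(max(abs(back$coords - mol$coords)), 1e-6)
    expect_identical(readLines(g)[1], as.character(n_atoms(mol)))
  }
})

test_that("malformed XYZ input is rejected with the offending line", {
  f <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("x", "", "C 0 0 0"), f)
  expect_error(read_xyz(f), "line 1")
  writeLines(c("1", "", "Xx 0 0 0"), f)
  expect_error(read_xyz(f), "line 3")
  writeLines(c("1", "", "C 0 zero 0"), f)
  expect_error(read_xyz(f), "line 3")
  writeLines(c("3", "", "C 0 0 0"), f)
  expect_error(read_xyz(f), "declares")
})

test_that("CH4-like fixture file has tetrahedral geometry with r(C-H) = 1.09", {
  f <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(generate_fixture("ch4_like"), f)
  m <- read_xyz(f)
  expect_equal(n_atoms(m), 5)
  d <- sqrt(rowSums(sweep(m$coords[2:5, ], 2, m$coords[1, ])^2))
  expect_lt(max(abs(d - 1.09)), 1e-6)
})

test_that("rigid transforms preserve the full distance matrix", {
  mol <- generate_fixture("aminoethanol")
  expect_equal(apply_transform(mol, rigid_transform())$coords, mol$coords)

  tz <- apply_transform(mol, rigid_transform(translation = c(0, 0, 5)))
  expect_equal(tz$coords[, 3], mol$coords[, 3] + 5)
  expect_lt(max(abs(dist(tz$coords) - dist(mol$coords))), 1e-9)

  for (seed in 1:5) {
    tr <- random_rigid(seed)
    moved <- apply_transform(mol, tr)
    expect_lt(max(abs(dist(moved$coords) - dist(mol$coords))), 1e-9)
    expect_identical(moved$elements, mol$elements)
  }
})

test_that("improper rotations are rejected by the transform constructor", {
  expect_error(rigid_transform(diag(c(1, 1, -1))), "proper")
  expect_error(rigid_transform(matrix(runif(9), 3)), "orthogonal")
})

test_that("mirror is an involution and preserves distances", {
  mol <- generate_fixture("chiral_probe")
  mm <- mirror(mol, point = c(0.3, -0.2, 1), normal = c(1, 2, -1))
  expect_lt(max(abs(dist(mm$coords) - dist(mol$coords))), 1e-12)
  back <- mirror(mm, point = c(0.3, -0.2, 1), normal = c(1, 2, -1))
  expect_lt(max(abs(back$coords - mol$coords)), 1e-12)
  expect_error(mirror(mol, normal = c(0, 0, 0)), "zero-length")
})

test_that("mirroring a planar molecule through its own plane is the identity", {
  planar <- molecule(c("C", "O", "O"), rbind(c(0, 0, 0), c(1.2, 0, 0),
                                             c(-0.6, 1.0, 0)))
  expect_lt(max(abs(mirror(planar)$coords - planar$coords)), 1e-12)
})

test_that("Kabsch alignment recovers rigid motions and detects chirality", {
  A <- asym4()
  expect_lt(kabsch_align(A, A)$rmsd, 1e-10)
  B <- A; B$coords <- sweep(A$coords, 2, c(1, 2, 3), "+")
  expect_lt(kabsch_align(A, B)$rmsd, 1e-10)
  C <- apply_transform(A, random_rigid(42))
  fit <- kabsch_align(A, C)
  expect_lt(fit$rmsd, 1e-8)
  refit <- apply_transform(C, fit$transform)
  expect_lt(max(abs(refit$coords - A$coords)), 1e-7)

  # against the mirror image, the proper-rotation minimum is nonzero and
  # matches a dense rotation-grid brute force
  M <- mirror(A)
  r_kabsch <- kabsch_align(A, M)$rmsd
  r_grid <- rmsd_rotation_oracle(A, M)
  expect_gt(r_kabsch, 0.1)
  expect_lt(abs(r_kabsch - r_grid), 1e-3)

  expect_error(kabsch_align(A, generate_fixture("co2_like")), "mismatch")
})

test_that("max_extent matches a brute-force double loop and is rigid-invariant", {
  two <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(max_extent(two), 5)

  mol <- build_pore("graphene3")$structure
  brute <- 0
  for (i in seq_len(n_atoms(mol) - 1)) for (j in (i + 1):n_atoms(mol))
    brute <- max(brute, sqrt(sum((mol$coords[i, ] - mol$coords[j, ])^2)))
  expect_equal(max_extent(mol), brute)

  probe <- generate_fixture("chiral_probe")
  expect_lt(abs(max_extent(probe) - max_extent(mirror(probe))), 1e-12)
  expect_lt(abs(max_extent(probe) -
                  max_extent(apply_transform(probe, random_rigid(3)))), 1e-9)
  expect_error(max_extent(molecule("C", matrix(0, 1, 3))), "2 atoms")
})

test_that("center of mass is the mass-weighted mean", {
  h2 <- molecule(c("H", "H"), rbind(c(0, 0, 1), c(0, 0, -1)))
  expect_equal(center_of_mass(h2), c(0, 0, 0))
  one <- molecule("N", matrix(c(1, 2, 3), 1))
  expect_equal(center_of_mass(one), c(1, 2, 3))
  co2 <- generate_fixture("co2_like")
  expect_lt(max(abs(center_of_mass(co2))), 1e-12)
})

test_that("the chirality witness separates chiral from achiral structures", {
  expect_true(chirality_check(generate_fixture("co2_like"))$achiral)
  expect_true(chirality_check(generate_fixture("ch4_like"))$achiral)
  planar <- molecule(c("C", "O", "N"), rbind(c(0, 0, 0), c(1.3, 0, 0),
                                             c(0.4, 1.2, 0)))
  expect_true(chirality_check(planar)$achiral)
  expect_false(chirality_check(generate_fixture("chiral_probe"))$achiral)
  expect_false(chirality_check(generate_fixture("aminoethanol"))$achiral)
})

test_that("molecule constructor enforces its invariants", {
  expect_error(molecule(character(0), matrix(0, 0, 3)), "at least one")
  expect_error(molecule("C", matrix(c(0, 0, NA), 1)), "finite")
  expect_error(molecule("Zz", matrix(0, 1, 3)), "unsupported element")
  expect_error(molecule(c("C", "C"), matrix(0, 2, 3), charges = 1), "length")
  m <- molecule("cl", matrix(0, 1, 3))
  expect_identical(m$elements, "Cl")
})
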