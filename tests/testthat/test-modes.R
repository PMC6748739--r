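test_that("mode 0 produces SASA only", {
  ts <- make_two_spheres(1.6, 1.6, 3)
  r <- run_mode(ts, 0)
  expect_s3_class(r, "surface_result")
  expect_null(r$atom_matrix)
  expect_null(r$res_matrix)
  expect_null(r$bsa)
  expect_equal(unname(r$sasa), unname(compute_sasa(ts$atoms)),
               tolerance = 0)
})

test_that("mode 1 reports intermolecular matrices and BSA under all-atom scope", {
  tri <- make_fig1_triple()
  r <- run_mode(tri, 1)
  cc <- compute_contacts(tri$atoms, generate_sphere_points(2000L))
  cross <- outer(tri$atoms$object, tri$atoms$object, "!=")
  expect_equal(r$atom_matrix, cc$csa * cross, tolerance = 0)
  expect_equal(r$res_matrix,
               aggregate_to_residues(cc$csa * cross, tri$atoms),
               tolerance = 0)
  expect_equal(unname(r$bsa), unname(rowSums(cc$csa * cross)),
               tolerance = 0)
  # intramolecular entries are masked out
  expect_identical(r$atom_matrix[2, 3], 0)
})

test_that("mode 2 equals mode 3 aggregated by residue", {
  cl <- make_random_cluster(24, box = 9, seed = 31)
  m2 <- run_mode(cl, 2)
  m3 <- run_mode(cl, 3)
  expect_null(m2$atom_matrix)
  expect_null(m3$res_matrix)
  expect_equal(m2$res_matrix, aggregate_to_residues(m3$atom_matrix, cl$atoms),
               tolerance = 0)
})

test_that("mode 4 keeps contact surfaces that are not solvent accessible", {
  cage <- make_buried_cage()
  m1 <- run_mode(cage, 1)
  m4 <- run_mode(cage, 4)
  lig <- 1L  # the buried ligand atom
  expect_equal(unname(m4$sasa[lig]), 0, tolerance = 1e-12)
  expect_gt(sum(m4$atom_matrix[, lig]), 0)
  # cross-object scope never attributes less to the partner than all-atom
  # scope, and strictly more where cage atoms shield each other
  expect_true(all(m4$atom_matrix - m1$atom_matrix >= -1e-12))
  expect_gt(sum(m4$atom_matrix[, lig]), sum(m1$atom_matrix[, lig]))
})

test_that("invalid modes and missing objects are rejected", {
  ts <- make_two_spheres()
  expect_error(run_mode(ts, 7), "mode")
  one <- make_random_cluster(3, seed = 2)
  one$atoms$object <- NULL
  one$objects <- NULL
  one$atoms$resname <- "UNK"   # single auto-detected class
  expect_error(run_mode(one, 1), "two molecular objects")
})
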