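lat <- generate_sphere_points(2000L)

test_that("residue aggregation preserves totals exactly", {
  cl <- make_random_cluster(30, box = 9, seed = 21)
  cc <- compute_contacts(cl$atoms, lat)
  rm_ <- aggregate_to_residues(cc$csa, cl$atoms)
  expect_equal(sum(rm_), sum(cc$csa), tolerance = 1e-12)
  # block sums match entry by entry
  rl <- residue_label(cl$atoms)
  for (r1 in unique(rl)[1:3]) for (r2 in unique(rl)[4:6])
    expect_equal(rm_[r1, r2], sum(cc$csa[rl == r1, rl == r2]),
                 tolerance = 1e-12)
})

test_that("single-atom residues leave the matrix unchanged", {
  ts <- make_two_spheres(1.6, 1.6, 3)
  cc <- compute_contacts(ts$atoms, lat)
  rm_ <- aggregate_to_residues(cc$csa, ts$atoms)
  expect_equal(unname(rm_), unname(cc$csa), tolerance = 0)
})

test_that("multi-atom residue entries sum their atoms' contacts", {
  tri <- make_fig1_triple()           # B and C share one residue
  cc <- compute_contacts(tri$atoms, lat)
  rm_ <- aggregate_to_residues(cc$csa, tri$atoms)
  expect_identical(dim(rm_), c(2L, 2L))
  expect_equal(rm_[1, 2], cc$csa[1, 2] + cc$csa[1, 3], tolerance = 1e-12)
})

test_that("BSA column sums follow the selection contract", {
  ts <- make_two_spheres(1.6, 1.6, 3)
  cc <- compute_contacts(ts$atoms, lat)
  expect_equal(unname(derive_bsa(cc$csa)[1]), cc$csa[1, 2],
               tolerance = 0)
  expect_equal(unname(derive_bsa(cc$csa, integer(0))),
               c(0, 0), tolerance = 0)
  iso <- make_random_cluster(1, seed = 2)
  ci <- compute_contacts(iso$atoms, lat)
  expect_identical(unname(derive_bsa(ci$csa)), 0)
})

test_that("cross-object-only geometry: BSA equals differential SASA", {
  atoms <- make_cross_only_rows()
  cc <- compute_contacts(atoms, lat)
  bsa <- derive_bsa(cc$csa * outer(atoms$object, atoms$object, "!="))
  ds <- delta_sasa_csa(atoms, lat)
  # with no intra-object overlap the same buried points are counted twice
  expect_equal(unname(bsa), unname(ds$per_atom), tolerance = 1e-12)
  expect_gt(sum(bsa), 0)
})
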