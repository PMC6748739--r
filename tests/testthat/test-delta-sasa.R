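lat <- generate_sphere_points(2000L)

test_that("distant objects have zero differential-SASA interface area", {
  ts <- make_two_spheres(1.6, 1.6, 50)
  ds <- delta_sasa_csa(ts$atoms, lat)
  expect_equal(ds$total, 0, tolerance = 1e-12)
  expect_true(all(abs(ds$per_atom) < 1e-12))
})

test_that("single-occluder interfaces: delta-SASA coincides with direct CSA", {
  ts <- make_two_spheres(1.6, 1.76, 3.2)
  ds <- delta_sasa_csa(ts$atoms, lat)
  cc <- compute_contacts(ts$atoms, lat)
  # with one occluder per atom the two definitions count the same points
  expect_equal(unname(ds$per_atom), c(cc$csa[1, 2], cc$csa[2, 1]),
               tolerance = 1e-12)
  expect_equal(ds$total, sum(cc$csa), tolerance = 1e-12)
})

test_that("crowded interface: delta-SASA strictly underestimates direct CSA", {
  cr <- make_crowding_pair()
  ds <- delta_sasa_csa(cr$atoms, lat)
  m1 <- run_mode(cr, 1, n_points = 2000L)
  m4 <- run_mode(cr, 4, n_points = 2000L)
  direct1 <- sum(m1$atom_matrix)
  direct4 <- sum(m4$atom_matrix)
  expect_lt(ds$total, direct1)
  expect_lt(ds$total, direct4)
  # cross-object-only scope credits shielded patches fully, so it is the
  # larger of the two direct readings
  expect_gte(direct4, direct1)
  # removing the shielding atom restores agreement
  pair <- cr$atoms[1:2, , drop = FALSE]
  attr(pair, "probe") <- 1.4
  ds2 <- delta_sasa_csa(pair, lat)
  cc2 <- compute_contacts(pair, lat)
  expect_equal(ds2$total, sum(cc2$csa), tolerance = 1e-12)
})

test_that("delta-SASA requires exactly two objects", {
  one <- make_random_cluster(4, seed = 1)
  one$atoms$object <- 1L
  expect_error(delta_sasa_csa(one$atoms, lat), "two")
})
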