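lat2000 <- generate_sphere_points(2000L)

test_that("isolated atom: full expanded sphere, no groups", {
  one <- make_random_cluster(1, seed = 3)
  g <- classify_points(one$atoms, 1L, lattice = lat2000)
  expect_identical(g$accessible_points, g$total_points)
  expect_length(g$members, 0L)
  sasa <- compute_sasa(one$atoms, lat2000)
  expect_equal(unname(sasa[1]), full_sphere_area(one$atoms, 1),
               tolerance = 1e-12)
})

test_that("two overlapping spheres match the analytic cap oracle", {
  ts <- make_two_spheres(1.6, 1.6, 3.0)
  cc <- compute_contacts(ts$atoms, lat2000)
  # single occluder: exactly one group {B}, buried fraction = cap fraction
  g <- cc$groups[[1]]
  expect_length(g$members, 1L)
  expect_identical(g$members[[1]], 2L)
  cap_frac <- ts$expected$cap_on_a / full_sphere_area(ts$atoms, 1)
  expect_equal(sum(g$counts) / g$total_points, cap_frac, tolerance = 0.01)
  expect_equal(unname(cc$sasa[1]), ts$expected$sasa_a, tolerance = 0.01)
  expect_equal(cc$csa[1, 2], ts$expected$cap_on_a, tolerance = 0.01)
  # separated pair: exactly zero
  far <- make_two_spheres(1.6, 1.6, 10)
  ccf <- compute_contacts(far$atoms, lat2000)
  expect_identical(max(ccf$csa), 0)
  expect_equal(as.numeric(ccf$sasa), c(full_sphere_area(far$atoms, 1),
                                   full_sphere_area(far$atoms, 2)),
               tolerance = 1e-12)
})

test_that("group tables satisfy the counting identities on crowded clusters", {
  for (seed in c(11, 12)) {
    atoms <- make_random_cluster(30, box = 9, seed = seed)$atoms
    cc <- compute_contacts(atoms, lat2000)
    for (i in seq_len(nrow(atoms))) {
      g <- cc$groups[[i]]
      expect_identical(g$accessible_points + sum(g$counts), g$total_points)
      if (length(g$members)) {
        expect_true(all(lengths(g$members) >= 1L))
        expect_false(any(vapply(g$members, function(m)
          g$owner %in% m, TRUE)))
      }
    }
    # conservation: SASA + sum of attributed contacts = full sphere
    full <- 4 * pi * (atoms$radius + 1.4)^2
    resid <- abs(cc$sasa + rowSums(cc$csa) - full) / full
    expect_lt(max(resid), 1e-9)
    expect_true(all(cc$csa >= 0))
    expect_identical(unname(diag(cc$csa)), rep(0, nrow(atoms)))
  }
})

test_that("shared patches are attributed fractionally (three-atom geometry)", {
  tri <- make_fig1_triple()
  cc <- compute_contacts(tri$atoms, lat2000)
  g <- cc$groups[[1]]
  keys <- vapply(g$members, paste, "", collapse = ",")
  expect_setequal(keys, c("2", "3", "2,3"))
  # CSA(A,B) = area({B}) + area({B,C}) / 2, recomputed from the raw table
  cnt <- setNames(g$counts, keys)
  expect_equal(cc$csa[1, 2],
               (cnt[["2"]] + cnt[["2,3"]] / 2) * g$point_area,
               tolerance = 1e-12)
  expect_equal(cc$csa[1, 3],
               (cnt[["3"]] + cnt[["2,3"]] / 2) * g$point_area,
               tolerance = 1e-12)
  # conservation on the shared-patch system
  expect_equal(cc$sasa[[1]] + cc$csa[1, 2] + cc$csa[1, 3],
               full_sphere_area(tri$atoms, 1), tolerance = 1e-12)
})

test_that("mirror-symmetric occluders get equal contact areas", {
  mp <- make_mirror_pair()
  cc <- compute_contacts(mp$atoms, lat2000)
  one_point <- lat2000$point_weight * (mp$atoms$radius[1] + 1.4)^2
  expect_lte(abs(cc$csa[1, 2] - cc$csa[1, 3]), one_point)
})

test_that("sampled contact areas never exceed the analytic cap by more than granularity", {
  lat <- lat2000
  set.seed(42)
  for (k in 1:25) {
    ra <- runif(1, 1.3, 1.9)
    rb <- runif(1, 1.3, 1.9)
    d <- runif(1, 0.5, 1.05) * (ra + rb + 2.8)
    ts <- make_two_spheres(ra, rb, d)
    cc <- compute_contacts(ts$atoms, lat)
    cap <- analytic_cap_area(ra, rb, d)
    gran <- 6 * lat$point_weight * (ra + 1.4)^2
    expect_lte(cc$csa[1, 2], cap[["a"]] + gran)
    expect_lte(cc$csa[2, 1], cap[["b"]] + 6 * lat$point_weight * (rb + 1.4)^2)
  }
})

test_that("identical inputs give identical results (engine determinism)", {
  atoms <- make_random_cluster(20, seed = 5)$atoms
  a <- compute_contacts(atoms, lat2000)
  b <- compute_contacts(atoms, lat2000)
  expect_identical(a$csa, b$csa)
  expect_identical(a$sasa, b$sasa)
})
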