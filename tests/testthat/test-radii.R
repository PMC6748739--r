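test_that("shipped radius tables load with sane values and a fallback", {
  for (nm in c("pdb-united", "mol2-typed")) {
    tab <- radii_table(nm)
    expect_s3_class(tab, "radii_table")
    expect_true(all(tab$entries > 0.2 & tab$entries < 3.5))
    expect_true(tab$fallback_radius > 0.2 && tab$fallback_radius < 3.5)
  }
  pdb <- radii_table("pdb-united")
  expect_equal(unname(pdb$entries[c("ALA N", "ALA CA", "ALA C", "ALA O")]),
               c(1.65, 1.87, 1.76, 1.40))
  expect_equal(unname(radii_table("mol2-typed")$entries["C.3"]), 1.88)
})

test_that("united-atom lookup keys on (residue, atom) with element fallback", {
  atoms <- data.frame(
    serial = 1:4, name = c("CA", "CG", "XX", "OD1"),
    element = c("C", "C", "ZZ", "O"),
    resname = c("ALA", "PHE", "UNQ", "ASP"),
    chain = "A", resno = 1:4, inscode = "",
    x = 0, y = 0, z = 0, occupancy = 1, altloc = "", hetero = FALSE,
    stringsAsFactors = FALSE)
  tab <- radii_table("pdb-united")
  expect_warning(out <- assign_radii(atoms, tab), "fallback")
  expect_equal(out$radius, c(1.87, 1.76, tab$fallback_radius, 1.40))
  # probe is run configuration, never folded into the stored radii
  expect_equal(attr(out, "probe"), 1.4)
  expect_identical(suppressWarnings(assign_radii(atoms, tab))$radius,
                   out$radius)
})

test_that("mol2 lookup keys on SYBYL type; probe is validated", {
  atoms <- data.frame(
    serial = 1:3, name = c("C1", "O1", "Q1"), element = c("C", "O", "QQ"),
    resname = "LIG", chain = "A", resno = 1, inscode = "",
    x = 0, y = 0, z = 0, occupancy = 1, altloc = "", hetero = TRUE,
    sybyl = c("C.ar", "O.co2", "Unk.9"), stringsAsFactors = FALSE)
  tab <- radii_table("mol2-typed")
  expect_warning(out <- assign_radii(atoms, tab, probe = 1.2), "fallback")
  expect_equal(out$radius, c(1.77, 1.42, tab$fallback_radius))
  expect_equal(attr(out, "probe"), 1.2)
  expect_error(assign_radii(atoms, tab, probe = -1), "probe")
})
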