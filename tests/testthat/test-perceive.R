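cif_crystal <- function(spec) {
  read_cif(write_cif_text(make_toy_crystal(spec)))
}

test_that("point lattice perception and cluster geometry", {
  cr <- cif_crystal(fixture_spec("point_lattice", element = "He", a = 5))
  mols <- perceive_molecules(cr)
  expect_length(mols, 1)
  expect_equal(nrow(mols[[1]]$atoms), 1)
  expect_equal(attr(mols[[1]], "count"), 1L)

  nbs <- build_cluster(cr, mols[[1]], contact_radius = 5.1)
  expect_length(nbs, 6) # simple cubic first shell
  up <- unique_pairs(mols[[1]], nbs)
  expect_equal(nrow(up), 1)
  expect_equal(up$multiplicity_count, 6L)
  expect_equal(up$centroid_distance, 5)
  # sum of multiplicities equals the raw neighbor count
  expect_equal(sum(up$multiplicity_count), length(nbs))

  # wider shell: 6 + 12 = 18 neighbors
  nbs2 <- build_cluster(cr, mols[[1]], contact_radius = 7.2)
  expect_length(nbs2, 18)
  up2 <- unique_pairs(mols[[1]], nbs2)
  expect_equal(sum(up2$multiplicity_count), 18L)

  # radius 0 gives an empty cluster
  expect_length(build_cluster(cr, mols[[1]], contact_radius = 0), 0)
  expect_equal(nrow(unique_pairs(mols[[1]], list())), 0)
})

test_that("two neighbors with distinct fingerprints stay distinct", {
  central <- ce_molecule(tibble::tibble(element = "He", x = 0, y = 0, z = 0),
                         label = "c")
  nb1 <- ce_molecule(tibble::tibble(element = "He", x = 3, y = 0, z = 0),
                     label = "n1")
  nb2 <- ce_molecule(tibble::tibble(element = "He", x = 4.5, y = 0, z = 0),
                     label = "n2")
  up <- unique_pairs(central, list(nb1, nb2))
  expect_equal(nrow(up), 2)
  expect_equal(up$multiplicity_count, c(1L, 1L))
})

test_that("molecular lattice perception recovers whole molecules", {
  cr <- cif_crystal(fixture_spec("molecular_lattice", template = "water"))
  mols <- perceive_molecules(cr)
  expect_length(mols, 1)
  expect_equal(sort(mols[[1]]$atoms$element), c("H", "H", "O"))
})

test_that("ion lattice gives two single-atom species", {
  cr <- cif_crystal(fixture_spec("ion_pair_lattice"))
  mols <- assign_species(perceive_molecules(cr),
                         list(mol1_Na = list(charge = 1),
                              mol2_Cl = list(charge = -1)))
  expect_length(mols, 2)
  expect_true(all(vapply(mols, function(m) nrow(m$atoms) == 1, logical(1))))
  expect_setequal(vapply(mols, function(m) m$charge, integer(1)), c(1L, -1L))
  expect_true(all(vapply(mols, function(m) m$is_monatomic_ion, logical(1))))
})

test_that("boundary-split glycine is completed across the cell", {
  cr <- cif_crystal(fixture_spec("molecular_lattice", template = "glycine",
                                 spacegroup = "P 21/c", a = 16, b = 16,
                                 c = 16, frac_origin = c(0.95, 0.92, 0.97)))
  mols <- perceive_molecules(cr)
  expect_length(mols, 1)
  expect_equal(nrow(mols[[1]]$atoms), 10)
  expect_equal(attr(mols[[1]], "count"), 4L) # Z = 4 in P 21/c
  # fingerprint matches the unsplit template placement
  cr0 <- cif_crystal(fixture_spec("molecular_lattice", template = "glycine",
                                  spacegroup = "P 21/c", a = 16, b = 16,
                                  c = 16, frac_origin = c(0.3, 0.3, 0.3)))
  m0 <- perceive_molecules(cr0)[[1]]
  fp <- crystalce:::mol_fingerprint(crystalce:::mol_coords(mols[[1]]))
  fp0 <- crystalce:::mol_fingerprint(crystalce:::mol_coords(m0))
  expect_lt(max(abs(fp - fp0)), 1e-6)
})

test_that("perceived molecules are translation invariant", {
  spec <- fixture_spec("molecular_lattice", template = "water")
  cr <- cif_crystal(spec)
  shifted <- cr
  shifted$sites$fx <- (shifted$sites$fx + 1) %% 1 # lattice translation
  m1 <- perceive_molecules(cr)[[1]]
  m2 <- perceive_molecules(shifted)[[1]]
  fp1 <- crystalce:::mol_fingerprint(crystalce:::mol_coords(m1))
  fp2 <- crystalce:::mol_fingerprint(crystalce:::mol_coords(m2))
  expect_lt(max(abs(fp1 - fp2)), 1e-8)
})

test_that("polymeric connectivity is refused", {
  # chain of carbons 1.5 A apart along a: infinite component
  cr <- ce_crystal(unit_cell(1.5, 10, 10),
                   tibble::tibble(element = "C", fx = 0, fy = 0, fz = 0))
  expect_error(perceive_molecules(cr), "molecular crystals")
})

test_that("normalize_xh sets X-H to the table value exactly", {
  cr <- cif_crystal(fixture_spec("molecular_lattice", template = "water"))
  out <- normalize_xh(cr)
  # heavy atoms untouched bit-for-bit
  hv <- cr$sites$element != "H"
  expect_identical(out$sites[hv, ], cr$sites[hv, ])
  # both O-H distances now exactly 0.983
  m <- perceive_molecules(out)[[1]]
  xyz <- crystalce:::mol_coords(m)
  o <- which(m$atoms$element == "O")
  for (h in which(m$atoms$element == "H")) {
    expect_equal(sqrt(sum((xyz[h, ] - xyz[o, ])^2)), 0.983,
                 tolerance = 1e-10)
  }
  # fixed point: renormalizing changes nothing beyond 1e-12
  again <- normalize_xh(out)
  expect_lt(max(abs(as.matrix(again$sites[, c("fx", "fy", "fz")]) -
                      as.matrix(out$sites[, c("fx", "fy", "fz")]))), 1e-12)
})

test_that("normalize_xh edge cases", {
  # no hydrogens: unchanged
  cr <- cif_crystal(fixture_spec("point_lattice", element = "He", a = 5))
  expect_identical(normalize_xh(cr)$sites, cr$sites)
  # lone H with no bonded heavy atom: warning, unchanged
  crh <- ce_crystal(unit_cell(10, 10, 10),
                    tibble::tibble(element = c("H", "O"),
                                   fx = c(0.1, 0.6), fy = c(0.1, 0.6),
                                   fz = c(0.1, 0.6)))
  expect_warning(out <- normalize_xh(crh), "no bonded heavy atom")
  expect_equal(out$sites$fx, crh$sites$fx)
  # element not in the bond table: warning, unchanged
  crf <- ce_crystal(unit_cell(10, 10, 10),
                    tibble::tibble(element = c("F", "H"),
                                   fx = c(0.1, 0.192), fy = 0.1, fz = 0.1))
  expect_warning(normalize_xh(crf), "bond_table")
})

test_that("molecule origins carry the generating operation", {
  cr <- cif_crystal(fixture_spec("molecular_lattice", template = "water",
                                 spacegroup = "P 21/c"))
  mols <- perceive_molecules(cr)
  expect_length(mols, 1)
  expect_match(mols[[1]]$origin, "\\(")
  nbs <- build_cluster(cr, mols[[1]], 3.8)
  expect_true(all(grepl(",", vapply(nbs, function(m) m$origin,
                                    character(1)))))
})
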