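test_that("unit_cell validates and computes volume", {
  cl <- unit_cell(5, 6, 7)
  expect_equal(cl$volume, 210)
  expect_equal(cl$M, diag(c(5, 6, 7)))
  mono <- unit_cell(5, 6, 7, 90, 100, 90)
  expect_equal(mono$volume, 5 * 6 * 7 * sin(100 * pi / 180))
  expect_error(unit_cell(-1, 1, 1), "not TRUE")
  expect_error(unit_cell(1, 1, 1, gamma = 180), "not TRUE")
})

test_that("frac/cart conversions are mutual inverses", {
  cl <- unit_cell(5.2, 6.1, 7.3, 81, 95, 103)
  f <- matrix(runif(30), 10, 3)
  expect_equal(cart_to_frac(cl, frac_to_cart(cl, f)), f)
})

test_that("symmetry operator parsing, formatting and application", {
  op <- parse_symop("-x, y+1/2, 1/2-z")
  expect_equal(op$rotation, diag(c(-1, 1, -1)))
  expect_equal(op$translation, c(0, 0.5, 0.5))
  # round trip through the formatter
  expect_equal(parse_symop(format_symop(op)), op)
  # application
  out <- apply_symop(op, matrix(c(0.1, 0.2, 0.3), 1))
  expect_equal(drop(out), c(-0.1, 0.7, 0.2))
  # singular rotation rejected
  expect_error(parse_symop("x,x,z"), "det")
  expect_error(parse_symop("x,y"), "malformed")
})

test_that("builtin space-group table has the documented groups", {
  expect_length(builtin_spacegroup_ops("P1"), 1)
  expect_length(builtin_spacegroup_ops("P -1"), 2)
  expect_length(builtin_spacegroup_ops("P 21/c"), 4)
  expect_length(builtin_spacegroup_ops("14"), 4)
  expect_length(builtin_spacegroup_ops("P212121"), 4)
  expect_length(builtin_spacegroup_ops("Pm-3m"), 48)
  expect_length(builtin_spacegroup_ops("Fm-3m"), 192)
  expect_null(builtin_spacegroup_ops("P 63/mmc"))
})

test_that("ce_crystal wraps coordinates and adds identity", {
  cr <- ce_crystal(unit_cell(5, 5, 5),
                   tibble::tibble(element = "C", fx = 1.2, fy = -0.3,
                                  fz = 0.5),
                   symmetry_ops = "-x,-y,-z")
  expect_equal(cr$sites$fx, 0.2)
  expect_equal(cr$sites$fy, 0.7)
  expect_length(cr$symmetry_ops, 2) # identity prepended
  expect_error(ce_crystal(unit_cell(5, 5, 5),
                          tibble::tibble(element = "Zz", fx = 0, fy = 0,
                                         fz = 0)), "unknown element")
})

test_that("symmetry expansion is idempotent and counts images", {
  cr <- ce_crystal(unit_cell(8, 8, 8, 90, 95, 90),
                   tibble::tibble(element = c("O", "H", "H"),
                                  fx = c(0.20, 0.30, 0.18),
                                  fy = c(0.10, 0.10, 0.21),
                                  fz = c(0.15, 0.15, 0.15)),
                   builtin_spacegroup_ops("P 21/c"), "P 21/c")
  ex <- expand_symmetry(cr)
  expect_equal(nrow(ex$sites), 12) # 3 atoms x 4 operations, general positions
  ex2 <- expand_symmetry(ex)
  expect_equal(ex2$sites[, c("element", "fx", "fy", "fz")],
               ex$sites[, c("element", "fx", "fy", "fz")])
})

test_that("minimal P1 CIF reads to one site and one operation", {
  path <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_min",
    "_cell_length_a 5", "_cell_length_b 5", "_cell_length_c 5",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "loop_", "_symmetry_equiv_pos_as_xyz", "'x,y,z'",
    "loop_", "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "C1 C 0 0 0"), path)
  cr <- read_cif(path)
  expect_equal(nrow(cr$sites), 1)
  expect_length(cr$symmetry_ops, 1)
  expect_equal(cr$sites$element, "C")
})

test_that("CIF errors name the missing block", {
  path <- tempfile(fileext = ".cif")
  writeLines(c("data_x", "_cell_length_b 5", "_cell_length_c 5",
               "_cell_angle_alpha 90", "_cell_angle_beta 90",
               "_cell_angle_gamma 90"), path)
  expect_error(read_cif(path), "_cell_length_a")

  writeLines(c("data_x",
               "_cell_length_a 5", "_cell_length_b 5", "_cell_length_c 5",
               "_cell_angle_alpha 90", "_cell_angle_beta 90",
               "_cell_angle_gamma 90"), path)
  expect_error(read_cif(path), "atom-site loop")
  expect_error(read_cif("/nonexistent.cif"), "no such file")
})

test_that("CIF with unknown element symbol errors", {
  path <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_x",
    "_cell_length_a 5", "_cell_length_b 5", "_cell_length_c 5",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "loop_", "_symmetry_equiv_pos_as_xyz", "'x,y,z'",
    "loop_", "_atom_site_label", "_atom_site_fract_x",
    "_atom_site_fract_y", "_atom_site_fract_z",
    "Qq1 0 0 0"), path)
  expect_error(read_cif(path), "unknown element")
})

test_that("symmetry falls back to the built-in table by number", {
  path <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_x",
    "_cell_length_a 8", "_cell_length_b 8", "_cell_length_c 8",
    "_cell_angle_alpha 90", "_cell_angle_beta 95", "_cell_angle_gamma 90",
    "_space_group_IT_number 14",
    "loop_", "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "O1 O 0.2 0.1 0.15"), path)
  cr <- read_cif(path)
  expect_length(cr$symmetry_ops, 4)
  # no operators and no recognizable group -> clear error
  writeLines(c(
    "data_x",
    "_cell_length_a 8", "_cell_length_b 8", "_cell_length_c 8",
    "_cell_angle_alpha 90", "_cell_angle_beta 95", "_cell_angle_gamma 90",
    "loop_", "_atom_site_label", "_atom_site_type_symbol",
    "_atom_site_fract_x", "_atom_site_fract_y", "_atom_site_fract_z",
    "O1 O 0.2 0.1 0.15"), path)
  expect_error(read_cif(path), "no symmetry operator loop")
})

test_that("CIF write/read round trip preserves sites and symmetry", {
  cr <- ce_crystal(unit_cell(8.1, 7.9, 9.3, 90, 96.5, 90),
                   tibble::tibble(element = c("N", "C", "O", "H"),
                                  fx = c(0.123456, 0.2, 0.33, 0.41),
                                  fy = c(0.5, 0.61, 0.7, 0.82),
                                  fz = c(0.9, 0.05, 0.15, 0.27)),
                   builtin_spacegroup_ops("P 21/c"), "P 21/c")
  path <- tempfile(fileext = ".cif")
  write_cif(cr, path)
  back <- read_cif(path)
  expect_equal(back$sites$element, cr$sites$element)
  expect_lt(max(abs(as.matrix(back$sites[, c("fx", "fy", "fz")]) -
                      as.matrix(cr$sites[, c("fx", "fy", "fz")]))), 1e-6)
  expect_length(back$symmetry_ops, length(cr$symmetry_ops))
  expect_equal(back$space_group, "P 21/c")
})

test_that("ragged CIF loops are rejected", {
  path <- tempfile(fileext = ".cif")
  writeLines(c(
    "data_x",
    "_cell_length_a 5", "_cell_length_b 5", "_cell_length_c 5",
    "_cell_angle_alpha 90", "_cell_angle_beta 90", "_cell_angle_gamma 90",
    "loop_", "_atom_site_label", "_atom_site_fract_x",
    "_atom_site_fract_y", "_atom_site_fract_z",
    "C1 0 0"), path)
  expect_error(read_cif(path), "ragged loop")
})
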