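# Synthetic inputs: toy CIFs, dimers and benchmark tables, so every module
# is testable offline.  Identical spec + seed always yields identical bytes.

#' Describe a synthetic fixture
#'
#' @param kind One of `"point_lattice"`, `"molecular_lattice"`,
#'   `"ion_pair_lattice"`, `"radical_dimer"`, `"benchmark_table"`.
#' @param ... Geometric parameters interpreted by the generator (see
#'   [make_toy_crystal()]).
#' @param seed Integer seed; identical spec + seed gives identical output
#'   bytes.
#' @return A `ce_fixture_spec`.
#' @export
fixture_spec <- function(kind = c("point_lattice", "molecular_lattice",
                                  "ion_pair_lattice", "radical_dimer",
                                  "benchmark_table"),
                         ..., seed = 1L) {
  kind <- match.arg(kind)
  structure(list(kind = kind, params = list(...), seed = as.integer(seed)),
            class = "ce_fixture_spec")
}

# fixed literature-standard template geometries (Angstrom)
molecule_templates <- function() {
  water <- tibble::tibble(
    element = c("O", "H", "H"),
    x = c(0, 0.9572, 0.9572 * cos(104.52 * pi / 180)),
    y = c(0, 0, 0.9572 * sin(104.52 * pi / 180)),
    z = 0)
  glycine <- tibble::tibble(
    # zwitterion-like 10-atom geometry (idealized bond lengths/angles)
    element = c("N", "H", "H", "H", "C", "H", "H", "C", "O", "O"),
    x = c(1.430, 1.780, 1.780, 1.780, 0.000, -0.360, -0.360, -0.720,
          -0.130, -1.970),
    y = c(0.000, -0.480, -0.480, 0.960, 0.000, 0.520, 0.520, -1.310,
          -2.390, -1.280),
    z = c(0.000, 0.830, -0.830, 0.000, 0.000, 0.890, -0.890, 0.000,
          0.000, 0.000))
  list(
    h2 = tibble::tibble(element = c("H", "H"), x = c(0, 0.7414), y = 0, z = 0),
    he = tibble::tibble(element = "He", x = 0, y = 0, z = 0),
    h2o = water,
    hf = tibble::tibble(element = c("F", "H"), x = c(0, 0.9168), y = 0, z = 0),
    `li+` = tibble::tibble(element = "Li", x = 0, y = 0, z = 0),
    `f-` = tibble::tibble(element = "F", x = 0, y = 0, z = 0),
    no = tibble::tibble(element = c("N", "O"), x = c(0, 1.1508), y = 0, z = 0),
    water = water, glycine = glycine)
}

#' Generate a toy crystal as CIF text
#'
#' Deterministic small crystals whose molecule perception recovers the
#' declared units:
#' \describe{
#'   \item{point_lattice}{simple-cubic lattice of one atom; params
#'     `element` (default `"He"`), `a` (default 5).}
#'   \item{ion_pair_lattice}{CsCl-type two-site ionic lattice; params
#'     `elements` (default `c("Na", "Cl")`), `a` (default 4).}
#'   \item{molecular_lattice}{one template molecule per asymmetric unit;
#'     params `template` (`"water"` default or `"glycine"`), `spacegroup`
#'     (`"P 1"` default or `"P 21/c"`), `a`, `b`, `c`, `beta`, and
#'     `frac_origin` placing the molecule (use values near 1 to split it
#'     across a cell boundary).}
#'   \item{radical_dimer}{an NO radical in a large P 1 cell; param `a`.}
#' }
#'
#' @param spec A [fixture_spec()].
#' @return CIF text as a single character scalar.
#' @export
make_toy_crystal <- function(spec) {
  stopifnot(inherits(spec, "ce_fixture_spec"))
  p <- spec$params
  crystal <- switch(spec$kind,
    point_lattice = {
      el <- p$element %||% "He"
      a <- p$a %||% 5
      ce_crystal(unit_cell(a, a, a),
                 tibble::tibble(element = el, fx = 0, fy = 0, fz = 0,
                                label = paste0(el, "1")),
                 builtin_spacegroup_ops("Pm-3m"), space_group = "P m -3 m")
    },
    ion_pair_lattice = {
      els <- p$elements %||% c("Na", "Cl")
      a <- p$a %||% 4
      ce_crystal(unit_cell(a, a, a),
                 tibble::tibble(element = els, fx = c(0, 0.5), fy = c(0, 0.5),
                                fz = c(0, 0.5),
                                label = paste0(els, "1")),
                 builtin_spacegroup_ops("Pm-3m"), space_group = "P m -3 m")
    },
    molecular_lattice = {
      tmpl <- p$template %||% "water"
      xyz <- molecule_templates()[[tmpl]]
      if (is.null(xyz)) stop("unknown molecular_lattice template: ", tmpl)
      sg <- p$spacegroup %||% "P 1"
      a <- p$a %||% 8; b <- p$b %||% 8; cc <- p$c %||% 8
      beta <- p$beta %||% if (identical(sg, "P 21/c")) 95 else 90
      cell <- unit_cell(a, b, cc, 90, beta, 90)
      fo <- p$frac_origin %||% c(0.20, 0.10, 0.15)
      frac <- sweep(cart_to_frac(cell, as.matrix(xyz[, c("x", "y", "z")])),
                    2, fo, "+")
      ops <- builtin_spacegroup_ops(sg)
      if (is.null(ops)) stop("unsupported space group for fixtures: ", sg)
      ce_crystal(cell,
                 tibble::tibble(element = xyz$element, fx = frac[, 1],
                                fy = frac[, 2], fz = frac[, 3],
                                label = paste0(xyz$element,
                                               seq_len(nrow(xyz)))),
                 ops, space_group = sg)
    },
    radical_dimer = {
      a <- p$a %||% 10
      cell <- unit_cell(a, a, a)
      xyz <- molecule_templates()$no
      frac <- sweep(cart_to_frac(cell, as.matrix(xyz[, c("x", "y", "z")])),
                    2, c(0.25, 0.25, 0.25), "+")
      ce_crystal(cell,
                 tibble::tibble(element = xyz$element, fx = frac[, 1],
                                fy = frac[, 2], fz = frac[, 3],
                                label = c("N1", "O1")),
                 "x,y,z", space_group = "P 1")
    },
    benchmark_table = stop("benchmark_table specs are consumed by ",
                           "make_benchmark_table(), not make_toy_crystal()")
  )
  tmp <- tempfile(fileext = ".cif")
  on.exit(unlink(tmp))
  write_cif(crystal, tmp)
  paste0(paste(readLines(tmp), collapse = "\n"), "\n")
}

#' Generate a rigid dimer from a packaged template
#'
#' Copy A sits in the template's canonical orientation; copy B is rotated
#' by intrinsic x-y-z Euler angles about its centroid and translated so the
#' centroid separation is exactly `separation` Angstrom along +x.
#'
#' @param template One of `"h2"`, `"he"`, `"h2o"`, `"hf"`, `"li+"`,
#'   `"f-"`, `"no"`.
#' @param separation Centroid-centroid distance in Angstrom (> 0).
#' @param orientation Euler angles (radians), length 3.
#' @return List of two `ce_molecule` objects `a` and `b`.
#' @export
make_dimer <- function(template, separation, orientation = c(0, 0, 0)) {
  tmpl <- molecule_templates()[[tolower(template)]]
  if (is.null(tmpl) || !tolower(template) %in%
      c("h2", "he", "h2o", "hf", "li+", "f-", "no")) {
    stop("unknown dimer template: ", template)
  }
  if (!is.numeric(separation) || separation <= 0) {
    stop("separation must be a positive distance in Angstrom")
  }
  charge <- switch(tolower(template), "li+" = 1L, "f-" = -1L, 0L)
  mk <- function(lab) ce_molecule(tmpl, charge = charge, label = lab)
  a <- mk(paste0(template, "_a"))
  b <- mk(paste0(template, "_b"))
  ang <- orientation
  rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]),
                 0, -sin(ang[1]), cos(ang[1])), 3, 3)
  ry <- matrix(c(cos(ang[2]), 0, -sin(ang[2]), 0, 1, 0,
                 sin(ang[2]), 0, cos(ang[2])), 3, 3)
  rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0, -sin(ang[3]), cos(ang[3]), 0,
                 0, 0, 1), 3, 3)
  cb <- centroid(b)
  b <- transform_molecule(b, shift = -cb)
  b <- transform_molecule(b, rot = rz %*% ry %*% rx)
  b <- transform_molecule(b, shift = centroid(a) + c(separation, 0, 0))
  list(a = a, b = b)
}

#' Generate a synthetic benchmark table with known scale factors
#'
#' Component columns are drawn uniformly from documented ranges mimicking
#' the four training subsets; the organic-salt block spans reference
#' energies up to about +/-2000 kJ/mol (ion-ion Coulomb dominance), an
#' order of magnitude beyond the neutral block.  The reference energy is
#' `E_ref = k_true . components + N(0, noise_sd)`.
#'
#' Ranges (kJ/mol): neutral E_ele U(-120, 10), E_pol U(-30, 0), E_dis
#' U(-60, 0), E_rep U(0, 80); organic-salt E_ele +/-U(300, 1900), E_pol
#' U(-80, 0), E_dis U(-40, 0), E_rep U(0, 100); metal-organic E_ele
#' U(-250, 20), E_pol U(-60, 0), E_dis U(-80, 0), E_rep U(0, 150);
#' open-shell same as neutral.  Subset shares 60/20/10/10 percent.
#'
#' @param k_true Length-4 numeric `(k_ele, k_pol, k_dis, k_rep)`.
#' @param n Number of rows (>= 4).
#' @param noise_sd Gaussian noise standard deviation (kJ/mol).
#' @param seed Integer seed (fully determines the table).
#' @return Tibble of benchmark rows: `label`, `subset`, `E_ele`, `E_pol`,
#'   `E_dis`, `E_rep`, `E_ref`, `source_tag`.
#' @export
make_benchmark_table <- function(k_true, n, noise_sd = 0, seed = 1L) {
  stopifnot(length(k_true) == 4)
  if (n < 4) stop("need at least 4 benchmark rows to determine 4 factors")
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  n_salt <- floor(0.2 * n); n_metal <- floor(0.1 * n)
  n_open <- floor(0.1 * n)
  n_neutral <- n - n_salt - n_metal - n_open
  subset <- c(rep("neutral", n_neutral), rep("organic-salt", n_salt),
              rep("metal-organic", n_metal), rep("open-shell", n_open))
  draw <- function(lo, hi, m) stats::runif(m, lo, hi)
  blocks <- list(
    neutral = function(m) cbind(draw(-120, 10, m), draw(-30, 0, m),
                                draw(-60, 0, m), draw(0, 80, m)),
    `organic-salt` = function(m) cbind(
      sample(c(-1, 1), m, replace = TRUE) * draw(300, 1900, m),
      draw(-80, 0, m), draw(-40, 0, m), draw(0, 100, m)),
    `metal-organic` = function(m) cbind(draw(-250, 20, m), draw(-60, 0, m),
                                        draw(-80, 0, m), draw(0, 150, m)),
    `open-shell` = function(m) cbind(draw(-120, 10, m), draw(-30, 0, m),
                                     draw(-60, 0, m), draw(0, 80, m))
  )
  comp <- matrix(0, n, 4)
  for (tag in unique(subset)) {
    idx <- which(subset == tag)
    if (length(idx) > 0) comp[idx, ] <- blocks[[tag]](length(idx))
  }
  e_ref <- drop(comp %*% as.numeric(k_true)) +
    stats::rnorm(n, 0, noise_sd)
  tibble::tibble(
    label = sprintf("pair_%04d", seq_len(n)),
    subset = subset,
    E_ele = comp[, 1], E_pol = comp[, 2], E_dis = comp[, 3],
    E_rep = comp[, 4], E_ref = e_ref,
    source_tag = "synthetic-B3LYP-D2"
  )
}
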