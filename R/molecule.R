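#' Construct a molecule
#'
#' The monomer unit of every energy term: a set of atoms with Cartesian
#' coordinates, a net formal charge and a spin multiplicity.  Geometry is
#' taken as given; no optimization is ever performed.
#'
#' @param atoms Data frame with columns `element`, `x`, `y`, `z`
#'   (Cartesian coordinates in Angstrom), or a matrix of coordinates with
#'   `element` supplied separately.
#' @param element Optional character vector of element symbols when `atoms`
#'   is a plain coordinate matrix.
#' @param charge Integer net charge (electron units).
#' @param multiplicity Positive integer spin multiplicity; default `NULL`
#'   means singlet for even electron counts and doublet for odd ones.
#' @param label Molecule label used in pair tables and config files.
#' @param origin Text descriptor of the generating symmetry operation.
#' @return An object of class `ce_molecule`.
#' @export
ce_molecule <- function(atoms, element = NULL, charge = 0L,
                        multiplicity = NULL, label = "mol",
                        origin = "x,y,z") {
  if (is.matrix(atoms)) {
    stopifnot(ncol(atoms) == 3, !is.null(element))
    atoms <- tibble::tibble(element = element, x = atoms[, 1],
                            y = atoms[, 2], z = atoms[, 3])
  }
  atoms <- tibble::as_tibble(atoms)
  keep <- intersect(c("element", "x", "y", "z", "ghost"), names(atoms))
  atoms <- atoms[, keep]
  z <- atomic_number(atoms$element)
  if ("ghost" %in% names(atoms)) z[atoms$ghost] <- 0L # basis only, no charge
  nel <- sum(z) - charge
  if (nel < 0) stop("charge ", charge, " exceeds total nuclear charge")
  if (is.null(multiplicity)) multiplicity <- if (nel %% 2L == 0L) 1L else 2L
  check_parity(nel, multiplicity)
  structure(
    list(
      atoms = atoms,
      charge = as.integer(charge),
      multiplicity = as.integer(multiplicity),
      is_monatomic_ion = nrow(atoms) == 1L && charge != 0L,
      label = label,
      origin = origin
    ),
    class = "ce_molecule"
  )
}

check_parity <- function(nel, multiplicity) {
  if (multiplicity < 1) stop("multiplicity must be >= 1")
  if ((nel - (multiplicity - 1L)) %% 2L != 0L || multiplicity - 1L > nel) {
    stop("multiplicity ", multiplicity,
         " inconsistent with electron count ", nel)
  }
  invisible(TRUE)
}

#' @export
print.ce_molecule <- function(x, ...) {
  cat(sprintf("<ce_molecule '%s': %d atoms, charge %+d, multiplicity %d%s>\n",
              x$label, nrow(x$atoms), x$charge, x$multiplicity,
              if (x$is_monatomic_ion) ", monatomic ion" else ""))
  invisible(x)
}

n_electrons <- function(mol) {
  z <- atomic_number(mol$atoms$element)
  if ("ghost" %in% names(mol$atoms)) z[mol$atoms$ghost] <- 0L
  sum(z) - mol$charge
}

mol_coords <- function(mol) {
  as.matrix(mol$atoms[, c("x", "y", "z")])
}

#' Centre of mass of a molecule (Angstrom)
#' @param mol A `ce_molecule`.
#' @return Numeric length-3 vector.
#' @export
centroid <- function(mol) {
  m <- atomic_masses(mol$atoms$element)
  unname(colSums(mol_coords(mol) * m) / sum(m))
}

# coarse atomic masses; only used for centres of mass of framework nodes
atomic_masses <- function(element) {
  masses <- c(1.008, 4.003, 6.94, 9.012, 10.81, 12.011, 14.007, 15.999,
              18.998, 20.18, 22.99, 24.305, 26.982, 28.085, 30.974, 32.06,
              35.45, 39.948, 39.098, 40.078, 44.956, 47.867, 50.942, 51.996,
              54.938, 55.845, 58.933, 58.693, 63.546, 65.38, 69.723, 72.63,
              74.922, 78.971, 79.904, 83.798, 85.468, 87.62, 88.906, 91.224,
              92.906, 95.95, 98, 101.07, 102.906, 106.42, 107.868, 112.414,
              114.818, 118.71, 121.76, 127.6, 126.904, 131.293, 132.905,
              137.327)
  masses[atomic_number(element)]
}

#' Translate / transform a molecule rigidly
#'
#' @param mol A `ce_molecule`.
#' @param rot 3x3 rotation matrix applied about the origin (Cartesian).
#' @param shift Length-3 translation in Angstrom.
#' @return The transformed `ce_molecule`.
#' @export
transform_molecule <- function(mol, rot = diag(3), shift = c(0, 0, 0)) {
  xyz <- mol_coords(mol) %*% t(rot)
  xyz <- sweep(xyz, 2, -shift)
  mol$atoms$x <- xyz[, 1]
  mol$atoms$y <- xyz[, 2]
  mol$atoms$z <- xyz[, 3]
  mol
}

#' Assign charges, multiplicities and monatomic-ion flags
#'
#' Applies a user configuration to a list of perceived molecules.  Molecules
#' not covered by the config keep charge 0; odd-electron species with no
#' stated multiplicity default to doublets, and single-atom charged species
#' are flagged as monatomic ions (which switches their polarizability to the
#' ionic value in the polarization term).
#'
#' @param molecules List of `ce_molecule`.
#' @param config Named list mapping molecule labels to
#'   `list(charge =, multiplicity =)`, or a path to a YAML/JSON file with
#'   that structure.
#' @return List of updated `ce_molecule` objects.
#' @export
assign_species <- function(molecules, config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_species_config(config)
  }
  lapply(molecules, function(mol) {
    cfg <- config[[mol$label]]
    charge <- if (!is.null(cfg$charge)) as.integer(cfg$charge) else mol$charge
    nel <- sum(atomic_number(mol$atoms$element)) - charge
    mult <- if (!is.null(cfg$multiplicity)) {
      as.integer(cfg$multiplicity)
    } else if (nel %% 2L == 1L) {
      2L # odd-electron species default to doublet
    } else {
      1L
    }
    check_parity(nel, mult)
    mol$charge <- charge
    mol$multiplicity <- mult
    mol$is_monatomic_ion <- nrow(mol$atoms) == 1L && charge != 0L
    mol
  })
}

read_species_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required to read YAML config files")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}
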