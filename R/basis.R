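# Gaussian basis handling: file parsing, shell construction, normalization.
#
# Shells are contracted Cartesian Gaussians; coefficients handed to the C++
# integral engine refer to unnormalized (l,0,0) primitives, scaled so that
# the contracted (l,0,0) component has unit self-overlap.

basis_cache <- new.env(parent = emptyenv())

#' Load a basis-set definition
#'
#' Packaged sets: `"3-21g"` (all elements of the fast model) and
#' `"6-31gdp"` (6-31G(d,p)).  A path to an external file in the same format
#' may be given to extend element coverage (e.g. a DZVP-type set for heavy
#' elements).
#'
#' @param name Basis-set name or path to a basis file.
#' @return Named list (by element symbol) of shell definitions.
#' @export
load_basis_set <- function(name) {
  key <- tolower(name)
  if (!is.null(basis_cache[[key]])) return(basis_cache[[key]])
  path <- if (file.exists(name)) {
    name
  } else {
    system.file("extdata", "basis", paste0(key, ".txt"),
                package = "crystalce")
  }
  if (!nzchar(path) || !file.exists(path)) {
    stop("unknown basis set '", name, "' (no packaged file and no such path)")
  }
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "!")]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    hdr <- strsplit(lines[i], "\\s+")[[1]]
    if (tolower(hdr[1]) != "element") stop("malformed basis file near: ", lines[i])
    elem <- hdr[2]
    i <- i + 1L
    shells <- list()
    while (tolower(lines[i]) != "end") {
      sh <- strsplit(lines[i], "\\s+")[[1]]
      type <- toupper(sh[1])
      nprim <- as.integer(sh[2])
      rows <- do.call(rbind, lapply(lines[i + seq_len(nprim)], function(l) {
        as.numeric(strsplit(l, "\\s+")[[1]])
      }))
      i <- i + nprim + 1L
      if (type == "SP") {
        shells <- c(shells,
                    list(list(l = 0L, exps = rows[, 1], coefs = rows[, 2]),
                         list(l = 1L, exps = rows[, 1], coefs = rows[, 3])))
      } else {
        l <- match(type, c("S", "P", "D", "F")) - 1L
        if (is.na(l)) stop("unknown shell type: ", type)
        shells <- c(shells, list(list(l = l, exps = rows[, 1],
                                      coefs = rows[, 2])))
      }
    }
    i <- i + 1L
    out[[elem]] <- shells
  }
  basis_cache[[key]] <- out
  out
}

dfact_r <- function(n) if (n <= 1) 1 else prod(seq(n, 1, by = -2))

prim_norm <- function(a, l) {
  (2 * a / pi)^0.75 * sqrt((4 * a)^l / dfact_r(2 * l - 1))
}

# final coefficients for unnormalized (l,0,0) primitives with contracted
# self-overlap exactly 1
normalize_shell <- function(l, exps, coefs) {
  cp <- coefs * prim_norm(exps, l)
  p <- outer(exps, exps, "+")
  s <- dfact_r(2 * l - 1) / (2 * p)^l * (pi / p)^1.5
  norm2 <- drop(crossprod(cp, s %*% cp))
  cp / sqrt(norm2)
}

#' Build the shell list for a molecule under a basis rule
#'
#' @param mol A `ce_molecule`; atoms may carry a logical `ghost` column, in
#'   which case ghost atoms contribute basis functions but no nuclear charge
#'   or electrons (counterpoise corrections).
#' @param basis_rule Named character vector or function mapping element
#'   symbol to basis-set name, or a single basis name for all elements.
#' @return List with `shells` (for the integral engine; centres in bohr),
#'   `pos` (3 x natom matrix, bohr), `Z` (effective nuclear charges, ghosts
#'   zeroed) and `atom_of_shell`.
#' @keywords internal
build_shells <- function(mol, basis_rule) {
  elems <- mol$atoms$element
  ghost <- if ("ghost" %in% names(mol$atoms)) mol$atoms$ghost else rep(FALSE, length(elems))
  pos <- t(mol_coords(mol)) / BOHR_ANGSTROM
  pick <- if (is.function(basis_rule)) {
    vapply(elems, basis_rule, character(1))
  } else if (length(basis_rule) == 1L && is.null(names(basis_rule))) {
    rep(basis_rule, length(elems))
  } else {
    unname(basis_rule[elems])
  }
  shells <- list()
  atom_of_shell <- integer(0)
  for (i in seq_along(elems)) {
    bs <- load_basis_set(pick[i])
    def <- bs[[elems[i]]]
    if (is.null(def)) {
      stop("basis set '", pick[i], "' has no entry for element ", elems[i],
           "; supply a basis file covering it")
    }
    for (sh in def) {
      shells[[length(shells) + 1L]] <- list(
        l = sh$l,
        center = pos[, i],
        exps = sh$exps,
        coefs = normalize_shell(sh$l, sh$exps, sh$coefs)
      )
      atom_of_shell <- c(atom_of_shell, i)
    }
  }
  Z <- atomic_number(elems)
  Z[ghost] <- 0L
  list(shells = shells, pos = pos, Z = as.numeric(Z),
       atom_of_shell = atom_of_shell)
}

n_basis <- function(shells) {
  sum(vapply(shells, function(s) (s$l + 1L) * (s$l + 2L) / 2L, numeric(1)))
}
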