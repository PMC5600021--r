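# One-electron properties of monomer wavefunctions and the shared integral
# context for a dimer.

#' Electrostatic potential and field of a monomer at arbitrary points
#'
#' Total (nuclear + electronic) electrostatic potential and electric field
#' of the monomer charge distribution, in atomic units, at Cartesian points
#' given in Angstrom.
#'
#' @param wfn A `ce_wavefunction`.
#' @param points Numeric matrix (n x 3) or length-3 vector of Cartesian
#'   positions in Angstrom.
#' @return Tibble with one row per point: `x`, `y`, `z` (Angstrom),
#'   `potential` (au), `fx`, `fy`, `fz` (au).
#' @export
field_and_potential_at_points <- function(wfn, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(ncol(points) == 3, all(is.finite(points)))
  pts <- t(points) / BOHR_ANGSTROM # 3 x n, bohr
  n <- ncol(pts)
  for (k in seq_len(n)) {
    d2 <- colSums((wfn$pos - pts[, k])^2)
    if (any(d2 < 1e-10 & wfn$Z > 0)) {
      stop("point ", k, " coincides with a nucleus of the monomer ",
           "(singular potential)")
    }
  }
  D <- wfn$Da + wfn$Db
  pot <- numeric(n); fld <- matrix(0, n, 3)
  # nuclear contribution
  for (k in seq_len(n)) {
    dr <- pts[, k] - wfn$pos # 3 x natom, vector from nucleus to point
    r <- sqrt(colSums(dr^2))
    pot[k] <- sum(wfn$Z / r)
    fld[k, ] <- rowSums(sweep(dr / rep(r^3, each = 3), 2, wfn$Z, "*"))
  }
  # electronic contribution
  if (sum(D) > 0 && length(wfn$shells) > 0) {
    Vc <- cpp_point_potential(wfn$shells, pts)
    Fc <- cpp_point_field(wfn$shells, pts)
    for (k in seq_len(n)) {
      pot[k] <- pot[k] - sum(D * Vc[, , k])
      fld[k, ] <- fld[k, ] + c(sum(D * Fc[, , 3 * k - 2]),
                               sum(D * Fc[, , 3 * k - 1]),
                               sum(D * Fc[, , 3 * k]))
    }
  }
  tibble::tibble(x = points[, 1], y = points[, 2], z = points[, 3],
                 potential = pot, fx = fld[, 1], fy = fld[, 2],
                 fz = fld[, 3])
}

#' Dipole moment of a monomer (atomic units)
#' @param wfn A `ce_wavefunction`.
#' @return Length-3 numeric vector (au), origin at the centre of nuclear
#'   charge.
#' @export
dipole_moment <- function(wfn) {
  origin <- if (sum(wfn$Z) > 0) {
    drop(wfn$pos %*% wfn$Z) / sum(wfn$Z)
  } else {
    rowMeans(wfn$pos)
  }
  mu_nuc <- drop((wfn$pos - origin) %*% wfn$Z)
  D <- wfn$Da + wfn$Db
  dip <- cpp_dipole(wfn$shells, origin)
  mu_el <- -c(sum(D * dip[, , 1]), sum(D * dip[, , 2]), sum(D * dip[, , 3]))
  mu_nuc + mu_el
}

#' Shared integral context for a molecule pair
#'
#' Exposes, on the union basis of two monomer wavefunctions: overlap,
#' kinetic and total nuclear-attraction matrices, and Coulomb/exchange
#' contractions of arbitrary one-particle densities (all atomic units).
#' This is the machinery behind the classical-Coulomb and
#' exchange-repulsion terms.
#'
#' @param wfn_a,wfn_b `ce_wavefunction` objects at the dimer geometry.
#' @return A `ce_dimer_context`.
#' @export
dimer_integral_context <- function(wfn_a, wfn_b) {
  shells <- c(wfn_a$shells, wfn_b$shells)
  pos <- cbind(wfn_a$pos, wfn_b$pos)
  Z <- c(wfn_a$Z, wfn_b$Z)
  mind <- min(as.matrix(stats::dist(t(pos)))[seq_along(wfn_a$Z),
                                             -seq_along(wfn_a$Z), drop = FALSE])
  if (mind < 1e-6) stop("coincident nuclei across the two monomers")
  nbf <- n_basis(shells)
  one <- cpp_one_ints(shells)
  V <- cpp_nuclear(shells, pos, Z)
  jk <- make_jk(cpp_eri(shells), nbf)
  na_bf <- wfn_a$nbf
  e_nn_ab <- 0
  for (i in seq_along(wfn_a$Z)) for (j in seq_along(wfn_b$Z)) {
    e_nn_ab <- e_nn_ab + wfn_a$Z[i] * wfn_b$Z[j] /
      sqrt(sum((wfn_a$pos[, i] - wfn_b$pos[, j])^2))
  }
  structure(list(
    S = one$S, T = one$T, V = V, hcore = one$T + V,
    J = jk$J, K = jk$K,
    nbf = nbf, nbf_a = na_bf, nbf_b = wfn_b$nbf,
    pos = pos, Z = Z,
    e_nn_total = nuclear_repulsion(pos, Z),
    e_nn_ab = e_nn_ab,
    wfn_a = wfn_a, wfn_b = wfn_b
  ), class = "ce_dimer_context")
}

# embed a monomer matrix (density) into the union basis
embed_block <- function(M, nbf, offset) {
  out <- matrix(0, nbf, nbf)
  idx <- offset + seq_len(nrow(M))
  out[idx, idx] <- M
  out
}
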