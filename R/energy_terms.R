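# The four-term interaction-energy model:
#   E_tot = k_ele E_ele + k_pol E_pol + k_dis E_dis + k_rep E_rep
# with components computed from unperturbed monomer wavefunctions.

#' Packaged energy models and their calibrated scale factors
#'
#' The two packaged models carry the scale factors obtained by fitting to
#' counterpoise-corrected B3LYP-D2 benchmark energies over a large training
#' set of molecule/ion pairs: CE-B3LYP (1.057, 0.740, 0.871, 0.618) and
#' CE-HF (1.019, 0.651, 0.901, 0.811).
#'
#' @param model_id `"ce-b3lyp"` or `"ce-hf"`.
#' @param k Optional length-4 numeric vector `(k_ele, k_pol, k_dis, k_rep)`
#'   overriding the packaged factors (e.g. from a new calibration fit).
#' @return A `ce_energy_model`.
#' @export
energy_model <- function(model_id = c("ce-b3lyp", "ce-hf"), k = NULL) {
  model_id <- match.arg(model_id)
  if (is.null(k)) {
    k <- switch(model_id,
      "ce-b3lyp" = c(k_ele = 1.057, k_pol = 0.740, k_dis = 0.871, k_rep = 0.618),
      "ce-hf"    = c(k_ele = 1.019, k_pol = 0.651, k_dis = 0.901, k_rep = 0.811)
    )
  } else {
    stopifnot(length(k) == 4)
    k <- stats::setNames(as.numeric(k), c("k_ele", "k_pol", "k_dis", "k_rep"))
  }
  structure(list(model_id = model_id, k = k, theory = theory_spec(model_id)),
            class = "ce_energy_model")
}

#' @export
print.ce_energy_model <- function(x, ...) {
  cat(sprintf("<ce_energy_model %s: k_ele %.3f, k_pol %.3f, k_dis %.3f, k_rep %.3f>\n",
              x$model_id, x$k[1], x$k[2], x$k[3], x$k[4]))
  invisible(x)
}

#' Isotropic polarizabilities for the polarization term
#'
#' Neutral-atom values with separate, much smaller values for monatomic
#' cations (and slightly larger ones for halide anions); the ionic value is
#' used only when a species is unambiguously a bare monatomic ion.
#'
#' @return Tibble with columns `element`, `class`
#'   (`neutral`/`cation`/`anion`) and `alpha` (atomic units).
#' @export
polarizability_table <- function() {
  dplyr::bind_rows(
    tibble::tibble(element = names(POLARIZABILITY_NEUTRAL),
                   class = "neutral",
                   alpha = unname(POLARIZABILITY_NEUTRAL)),
    tibble::tibble(element = names(POLARIZABILITY_CATION),
                   class = "cation",
                   alpha = unname(POLARIZABILITY_CATION)),
    tibble::tibble(element = names(POLARIZABILITY_ANION),
                   class = "anion",
                   alpha = unname(POLARIZABILITY_ANION))
  )
}

lookup_alpha <- function(element, class, table) {
  hit <- table$alpha[table$element == element & table$class == class]
  if (length(hit) != 1L) {
    stop("no polarizability for element ", element, " as ", class)
  }
  hit
}

#' D2 pairwise dispersion parameters
#'
#' Per-element C6 coefficients (J nm^6 mol^-1) and van der Waals radii
#' (Angstrom) with the global damping steepness d = 20.  The global
#' prefactor defaults to s6 = 1: any constant factor is absorbed by the
#' fitted k_dis scale factor.
#'
#' @param s6 Global prefactor.
#' @param d Damping steepness.
#' @return A `ce_dispersion_params` list.
#' @export
dispersion_params <- function(s6 = 1.0, d = 20.0) {
  structure(list(C6 = D2_C6, Rvdw = D2_RVDW, s6 = s6, d = d),
            class = "ce_dispersion_params")
}

# ------------------------------------------------------------- components

#' Classical electrostatic (Coulomb) energy between monomer distributions
#'
#' Nuclear-nuclear, nuclear-electron (both directions) and
#' electron-electron Coulomb energy between the two unperturbed monomer
#' charge distributions.
#'
#' @param wfn_a,wfn_b `ce_wavefunction` objects at the dimer geometry.
#' @param context Optional [dimer_integral_context()] (built if missing).
#' @return Energy in kJ/mol.
#' @export
e_electrostatic <- function(wfn_a, wfn_b, context = NULL) {
  if (is.null(context)) context <- dimer_integral_context(wfn_a, wfn_b)
  e_electrostatic_hartree(context) * HARTREE_KJMOL
}

e_electrostatic_hartree <- function(ctx) {
  DA <- embed_block(ctx$wfn_a$Da + ctx$wfn_a$Db, ctx$nbf, 0L)
  DB <- embed_block(ctx$wfn_b$Da + ctx$wfn_b$Db, ctx$nbf, ctx$nbf_a)
  VA <- cpp_nuclear(c(ctx$wfn_a$shells, ctx$wfn_b$shells), ctx$wfn_a$pos,
                    ctx$wfn_a$Z)
  VB <- cpp_nuclear(c(ctx$wfn_a$shells, ctx$wfn_b$shells), ctx$wfn_b$pos,
                    ctx$wfn_b$Z)
  ctx$e_nn_ab + sum(DA * VB) + sum(DB * VA) + sum(DA * ctx$J(DB))
}

#' Polarization energy from monomer electric fields
#'
#' The electric field of each monomer's total charge distribution is
#' evaluated at every nucleus of the partner, and the energy is
#' `-1/2 sum alpha |F|^2` over the atoms of both monomers.  Monatomic ions
#' use the ionic polarizability; all other atoms the neutral-atom value.
#'
#' @param wfn_a,wfn_b `ce_wavefunction` objects.
#' @param table Polarizability table, see [polarizability_table()].
#' @return Energy in kJ/mol (always <= 0).
#' @export
e_polarization <- function(wfn_a, wfn_b, table = polarizability_table()) {
  half <- function(wfn_at, wfn_src) {
    mol <- wfn_at$molecule
    cls <- if (mol$is_monatomic_ion) {
      if (mol$charge > 0) "cation" else "anion"
    } else {
      "neutral"
    }
    pts <- mol_coords(mol)
    fp <- field_and_potential_at_points(wfn_src, pts)
    f2 <- fp$fx^2 + fp$fy^2 + fp$fz^2
    alpha <- vapply(mol$atoms$element, lookup_alpha, numeric(1),
                    class = cls, table = table)
    -0.5 * sum(alpha * f2)
  }
  (half(wfn_a, wfn_b) + half(wfn_b, wfn_a)) * HARTREE_KJMOL
}

#' D2 pairwise dispersion energy between two molecules
#'
#' `-s6 sum_ij f_dmp(R_ij) C6_ij / R_ij^6` over all intermolecular atom
#' pairs, with `f_dmp(R) = 1/(1 + exp(-d (R/R_r - 1)))` and
#' `C6_ij = sqrt(C6_i C6_j)`.
#'
#' @param mol_a,mol_b `ce_molecule` objects.
#' @param params [dispersion_params()].
#' @return Energy in kJ/mol (always <= 0).
#' @export
e_dispersion <- function(mol_a, mol_b, params = dispersion_params()) {
  ea <- mol_a$atoms$element; eb <- mol_b$atoms$element
  missing <- setdiff(c(ea, eb), names(params$C6))
  if (length(missing) > 0) {
    stop("no D2 parameters for element(s): ", paste(missing, collapse = ", "))
  }
  xa <- mol_coords(mol_a); xb <- mol_coords(mol_b)
  r <- sqrt(outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb))
  r_nm <- r / 10 # Angstrom -> nm for the C6 units
  c6 <- sqrt(outer(params$C6[ea], params$C6[eb])) # J nm^6 / mol
  rr <- outer(params$Rvdw[ea], params$Rvdw[eb], "+")
  fdmp <- 1 / (1 + exp(-params$d * (r / rr - 1)))
  -params$s6 * sum(fdmp * c6 / r_nm^6) / 1000 # J/mol -> kJ/mol
}

#' Exchange-repulsion from the antisymmetrized product of monomer orbitals
#'
#' The pooled occupied spin orbitals of the two monomers are symmetrically
#' (Lowdin) orthonormalized and the resulting single determinant is
#' evaluated with the dimer Hamiltonian in a Hartree-Fock-like expression;
#' the exchange-repulsion is that energy minus the two monomer energies
#' (same expression, own orbitals) minus the classical Coulomb energy.
#' Two open-shell monomers are combined high spin (their unpaired spins
#' parallel, e.g. two doublets couple to a triplet).
#'
#' @param wfn_a,wfn_b `ce_wavefunction` objects at the dimer geometry.
#' @param context Optional [dimer_integral_context()].
#' @return Energy in kJ/mol.
#' @export
e_exchange_repulsion <- function(wfn_a, wfn_b, context = NULL) {
  if (is.null(context)) context <- dimer_integral_context(wfn_a, wfn_b)
  ctx <- context
  occ_a <- occupied_coefs(wfn_a); occ_b <- occupied_coefs(wfn_b)
  pool <- function(Ma, Mb) {
    C <- matrix(0, ctx$nbf, ncol(Ma) + ncol(Mb))
    if (ncol(Ma) > 0) C[seq_len(ctx$nbf_a), seq_len(ncol(Ma))] <- Ma
    if (ncol(Mb) > 0) C[ctx$nbf_a + seq_len(ctx$nbf_b),
                        ncol(Ma) + seq_len(ncol(Mb))] <- Mb
    C
  }
  lowdin_density <- function(C) {
    if (ncol(C) == 0) return(matrix(0, ctx$nbf, ctx$nbf))
    So <- t(C) %*% ctx$S %*% C
    e <- eigen((So + t(So)) / 2, symmetric = TRUE)
    if (min(e$values) < 1e-8) {
      stop("pooled occupied orbitals are (near-)linearly dependent; ",
           "check the pair geometry for overlapping molecules")
    }
    Sih <- e$vectors %*% diag(1 / sqrt(e$values), ncol(C)) %*% t(e$vectors)
    Co <- C %*% Sih
    tcrossprod(Co)
  }
  # high-spin combination: each monomer's excess spin is alpha, so pooling
  # alpha with alpha aligns the unpaired electrons
  Pa <- lowdin_density(pool(occ_a$Ca, occ_b$Ca))
  Pb <- lowdin_density(pool(occ_a$Cb, occ_b$Cb))
  hf_like <- function(Pa, Pb, h, e_nn) {
    Pt <- Pa + Pb
    sum(Pt * h) + 0.5 * sum(Pt * ctx$J(Pt)) -
      0.5 * (sum(Pa * ctx$K(Pa)) + sum(Pb * ctx$K(Pb))) + e_nn
  }
  e_det <- hf_like(Pa, Pb, ctx$hcore, ctx$e_nn_total)
  # monomer energies with the same HF-like expression and their own nuclei
  shells_u <- c(wfn_a$shells, wfn_b$shells)
  VA <- cpp_nuclear(shells_u, wfn_a$pos, wfn_a$Z)
  VB <- cpp_nuclear(shells_u, wfn_b$pos, wfn_b$Z)
  DAa <- embed_block(tcrossprod_safe(occ_a$Ca), ctx$nbf, 0L)
  DAb <- embed_block(tcrossprod_safe(occ_a$Cb), ctx$nbf, 0L)
  DBa <- embed_block(tcrossprod_safe(occ_b$Ca), ctx$nbf, ctx$nbf_a)
  DBb <- embed_block(tcrossprod_safe(occ_b$Cb), ctx$nbf, ctx$nbf_a)
  e_a <- hf_like(DAa, DAb, ctx$T + VA, nuclear_repulsion(wfn_a$pos, wfn_a$Z))
  e_b <- hf_like(DBa, DBb, ctx$T + VB, nuclear_repulsion(wfn_b$pos, wfn_b$Z))
  e_ele <- e_electrostatic_hartree(ctx)
  (e_det - e_a - e_b - e_ele) * HARTREE_KJMOL
}

tcrossprod_safe <- function(M) {
  if (ncol(M) == 0) matrix(0, nrow(M), nrow(M)) else tcrossprod(M)
}

#' Combine unscaled components into the scaled model total
#'
#' @param components Named list, data frame row or numeric vector with
#'   `E_ele`, `E_pol`, `E_dis`, `E_rep` in kJ/mol (unscaled).
#' @param model A [energy_model()].
#' @return Tibble of class `ce_pair_energy` with the four unscaled
#'   components, the scaled total `E_tot` and the whole-number display
#'   value `E_tot_display` (model energies are only meaningful to about
#'   1 kJ/mol, so totals are reported as whole numbers).
#' @export
e_total <- function(components, model = energy_model("ce-b3lyp")) {
  cmp <- as.list(components)
  need <- c("E_ele", "E_pol", "E_dis", "E_rep")
  if (!all(need %in% names(cmp))) {
    stop("components must provide ", paste(need, collapse = ", "))
  }
  k <- model$k
  tot <- k["k_ele"] * cmp$E_ele + k["k_pol"] * cmp$E_pol +
    k["k_dis"] * cmp$E_dis + k["k_rep"] * cmp$E_rep
  out <- tibble::tibble(
    model_id = model$model_id,
    E_ele = cmp$E_ele, E_pol = cmp$E_pol,
    E_dis = cmp$E_dis, E_rep = cmp$E_rep,
    E_tot = unname(tot),
    E_tot_display = round(unname(tot))
  )
  class(out) <- c("ce_pair_energy", class(out))
  out
}

#' Rescale the component columns of a pair-energy table for display
#'
#' Components are stored unscaled; some published tables print pre-scaled
#' components (k times E) so that rows sum to the total.  This helper
#' converts between the two conventions.
#'
#' @param pairs A tibble with `E_ele`, `E_pol`, `E_dis`, `E_rep` columns.
#' @param model The [energy_model()] whose factors to apply.
#' @return The table with scaled component columns.
#' @export
scale_components <- function(pairs, model) {
  k <- model$k
  dplyr::mutate(pairs,
                E_ele = k[["k_ele"]] * .data$E_ele,
                E_pol = k[["k_pol"]] * .data$E_pol,
                E_dis = k[["k_dis"]] * .data$E_dis,
                E_rep = k[["k_rep"]] * .data$E_rep)
}

#' Full four-component interaction energy for one molecule pair
#'
#' Computes monomer wavefunctions at the pair geometry (cached), the four
#' unscaled components, and the scaled total under the given model.
#'
#' @param mol_a,mol_b `ce_molecule` objects.
#' @param model A [energy_model()].
#' @param table,params Polarizability table and dispersion parameters.
#' @return A one-row `ce_pair_energy` tibble.
#' @export
pair_energy <- function(mol_a, mol_b, model = energy_model("ce-b3lyp"),
                        table = polarizability_table(),
                        params = dispersion_params()) {
  wa <- compute_wavefunction(mol_a, model$theory)
  wb <- compute_wavefunction(mol_b, model$theory)
  ctx <- dimer_integral_context(wa, wb)
  cmp <- list(
    E_ele = e_electrostatic(wa, wb, ctx),
    E_pol = e_polarization(wa, wb, table),
    E_dis = e_dispersion(mol_a, mol_b, params),
    E_rep = e_exchange_repulsion(wa, wb, ctx)
  )
  out <- e_total(cmp, model)
  out$label_a <- mol_a$label
  out$label_b <- mol_b$label
  out$centroid_distance <- sqrt(sum((centroid(mol_a) - centroid(mol_b))^2))
  out
}
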