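# Converged pairwise lattice-energy summation for neutral molecular
# crystals.

# All whole neighbor molecules with centroid distance <= r_max of central.
neighbors_by_centroid <- function(crystal, central, r_max) {
  cc <- centroid(central)
  cm <- crystal_molecules(crystal)
  diam <- max(vapply(cm$mols, function(m) {
    if (nrow(m$cart) < 2) 0 else max(stats::dist(m$cart))
  }, numeric(1)))
  t_rng <- pmax(1L, ceiling((r_max + diam) / cell_heights(crystal$cell))) + 1L
  out <- list()
  ccm <- mol_coords(central)
  for (t1 in -t_rng[1]:t_rng[1]) for (t2 in -t_rng[2]:t_rng[2])
    for (t3 in -t_rng[3]:t_rng[3]) {
      tv <- drop(frac_to_cart(crystal$cell, matrix(c(t1, t2, t3), 1)))
      for (m in cm$mols) {
        cart <- sweep(m$cart, 2, tv, "+")
        if (nrow(cart) == nrow(ccm) && max(abs(cart - ccm)) < 1e-6) next
        ms <- atomic_masses(m$element)
        ct <- colSums(cart * ms) / sum(ms)
        if (sqrt(sum((ct - cc)^2)) <= r_max + 1e-9) {
          mt <- m
          mt$cart <- cart
          mt$shift <- sweep(m$shift, 2, -c(t1, t2, t3))
          out[[length(out) + 1L]] <-
            as_ce_molecule(mt, crystal, paste0(central$label, "_nb",
                                               length(out) + 1L))
        }
      }
    }
  out
}

#' Lattice energy by converged pairwise summation
#'
#' For each symmetry-unique molecule, sums half the pairwise interaction
#' energy with every surrounding molecule, growing neighbor shells in 2
#' Angstrom increments of centroid distance until the shell increment
#' falls below `tol` (or `r_max` is reached, with a warning).  Crystals
#' containing charged species are refused: ionic lattice sums are only
#' conditionally convergent and need Ewald-type resummation, which this
#' pairwise model does not provide.
#'
#' @param crystal A `ce_crystal` of neutral molecules.
#' @param model A [energy_model()].
#' @param r_max Maximum centroid-distance radius (Angstrom).
#' @param tol Convergence tolerance on the shell increment (kJ/mol).
#' @param config Species config for [assign_species()].
#' @param pair_fn Pluggable pair-energy function
#'   `function(mol_a, mol_b, model) -> E_tot kJ/mol`; defaults to the full
#'   four-component [pair_energy()].  Useful for cheap surrogates (e.g.
#'   point-charge sums) and testing.
#' @param shell_width Shell growth increment (Angstrom).
#' @return A `ce_lattice_result`: `lattice_energy` (kJ/mol per molecule,
#'   Z'-weighted over unique molecules), `shells` (tibble of radius,
#'   increment, cumulative energy), `converged`, `tol`, `r_max`,
#'   `per_molecule`.
#' @export
lattice_energy <- function(crystal, model = energy_model("ce-b3lyp"),
                           r_max = 30, tol = 0.5, config = list(),
                           pair_fn = NULL, shell_width = 2) {
  mols <- assign_species(perceive_molecules(crystal), config)
  charges <- vapply(mols, function(m) m$charge, integer(1))
  if (any(charges != 0L)) {
    stop("lattice_energy requires all-neutral molecules: ionic pairwise ",
         "lattice sums are conditionally convergent and are refused")
  }
  if (is.null(pair_fn)) {
    pair_fn <- function(a, b, model) pair_energy(a, b, model)$E_tot
  }
  weights <- vapply(mols, function(m) attr(m, "count") %||% 1L, integer(1))
  per <- vector("list", length(mols))
  shell_list <- list()
  for (mi in seq_along(mols)) {
    central <- mols[[mi]]
    nbs <- neighbors_by_centroid(crystal, central, r_max)
    up <- unique_pairs(central, nbs)
    ord <- order(up$centroid_distance)
    up <- up[ord, ]
    energies <- rep(NA_real_, nrow(up))
    cum <- 0
    shells <- list()
    converged <- FALSE
    radii <- seq(shell_width, ceiling(r_max / shell_width) * shell_width,
                 by = shell_width)
    prev_r <- 0
    seen_any <- FALSE
    prev_inc <- Inf
    for (r in radii) {
      idx <- which(up$centroid_distance > prev_r & up$centroid_distance <= r)
      inc <- 0
      for (k in idx) {
        energies[k] <- pair_fn(central, up$molecule_b[[k]], model)
        inc <- inc + 0.5 * up$multiplicity_count[k] * energies[k]
      }
      cum <- cum + inc
      shells[[length(shells) + 1L]] <- tibble::tibble(
        radius = r, n_pairs = length(idx), increment = inc, cumulative = cum)
      prev_r <- r
      # converged once two consecutive shells beyond the first occupied
      # shell each contribute less than tol
      if (seen_any && abs(inc) <= tol && abs(prev_inc) <= tol) {
        converged <- TRUE
        break
      }
      if (length(idx) > 0) seen_any <- TRUE
      prev_inc <- inc
    }
    if (!seen_any) converged <- TRUE # nothing within r_max interacts
    if (!converged && abs(shells[[length(shells)]]$increment) <= tol) {
      converged <- TRUE # ran to r_max with a sub-tol final shell
    }
    if (!converged) {
      warning("lattice sum for ", central$label, " not converged at r_max = ",
              r_max, " Angstrom (last increment ",
              signif(shells[[length(shells)]]$increment, 3), " kJ/mol)")
    }
    st <- dplyr::bind_rows(shells)
    st$central_label <- central$label
    shell_list[[mi]] <- st
    per[[mi]] <- tibble::tibble(central_label = central$label,
                                weight = weights[mi], energy = cum,
                                converged = converged)
  }
  per <- dplyr::bind_rows(per)
  structure(list(
    lattice_energy = sum(per$weight * per$energy) / sum(per$weight),
    shells = dplyr::bind_rows(shell_list),
    per_molecule = per,
    converged = all(per$converged), tol = tol, r_max = r_max,
    model_id = model$model_id), class = "ce_lattice_result")
}

#' @export
print.ce_lattice_result <- function(x, ...) {
  cat(sprintf("<ce_lattice_result %s: E_lat = %.2f kJ/mol per molecule (%s, tol %g)>\n",
              x$model_id, x$lattice_energy,
              if (x$converged) "converged" else "NOT converged",
              x$tol))
  invisible(x)
}
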