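# Molecule perception in crystals: connectivity across cell boundaries,
# X-H normalization, neighbor clusters and symmetry-unique pairs.

bond_cutoff <- function(el_a, el_b) {
  # atoms bonded when closer than r_cov(A) + r_cov(B) + 0.4 Angstrom
  COVALENT_RADII[el_a] + COVALENT_RADII[el_b] + 0.4
}

cell_heights <- function(cell) {
  # perpendicular distances between opposite cell faces
  M <- cell$M
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  a <- M[, 1]; b <- M[, 2]; c_ <- M[, 3]
  V <- abs(sum(a * cr(b, c_)))
  c(V / sqrt(sum(cr(b, c_)^2)), V / sqrt(sum(cr(a, c_)^2)),
    V / sqrt(sum(cr(a, b)^2)))
}

# All whole molecules anchored in the home cell, with symmetry bookkeeping.
# Returns list(mols = per-molecule list, expanded = expanded crystal).
# Each mols[[m]] has: site (expanded-site index), shift (n x 3 integer
# lattice offsets), element, label, parent, op, cart (n x 3 Angstrom).
crystal_molecules <- function(crystal, max_shift = 6L) {
  ex <- expand_symmetry(crystal)
  s <- ex$sites
  n <- nrow(s)
  frac <- as.matrix(s[, c("fx", "fy", "fz")])
  maxbond <- 2 * max(COVALENT_RADII[unique(s$element)]) + 0.4
  dt_rng <- pmax(1L, ceiling(maxbond / cell_heights(crystal$cell)))
  # bond table: for each lattice offset dt, which (i, j) are bonded
  cut <- outer(COVALENT_RADII[s$element], COVALENT_RADII[s$element], "+") + 0.4
  bonds <- list()
  for (t1 in -dt_rng[1]:dt_rng[1]) for (t2 in -dt_rng[2]:dt_rng[2])
    for (t3 in -dt_rng[3]:dt_rng[3]) {
      dt <- c(t1, t2, t3)
      ci <- frac_to_cart(crystal$cell, frac)
      cj <- frac_to_cart(crystal$cell, sweep(frac, 2, dt, "+"))
      d2 <- outer(rowSums(ci^2), rowSums(cj^2), "+") - 2 * ci %*% t(cj)
      hit <- which(d2 < cut^2 & d2 > 1e-8, arr.ind = TRUE)
      if (nrow(hit) > 0) {
        bonds[[length(bonds) + 1L]] <-
          cbind(hit, matrix(dt, nrow(hit), 3, byrow = TRUE))
      }
    }
  bonds <- if (length(bonds) > 0) do.call(rbind, bonds) else
    matrix(0L, 0, 5)
  adj <- split.data.frame(bonds[, 2:5, drop = FALSE], bonds[, 1])
  assigned <- rep(FALSE, n)
  mols <- list()
  for (seed in seq_len(n)) {
    if (assigned[seed]) next
    # BFS over (site, lattice shift); a site reappearing at a different
    # shift means the component is infinite (polymeric)
    shift_of <- vector("list", n)
    shift_of[[seed]] <- c(0L, 0L, 0L)
    queue <- list(c(seed, 0L, 0L, 0L))
    members <- list(c(seed, 0L, 0L, 0L))
    while (length(queue) > 0) {
      cur <- queue[[1]]; queue <- queue[-1]
      i <- cur[1]; ti <- cur[2:4]
      nb <- adj[[as.character(i)]]
      if (is.null(nb)) next
      for (r in seq_len(nrow(nb))) {
        j <- nb[r, 1]; tj <- ti + nb[r, 2:4]
        if (any(abs(tj) > max_shift)) {
          stop("molecule perception: component extends beyond ", max_shift,
               " cells; this model applies to molecular crystals, not ",
               "polymeric/framework solids")
        }
        prev <- shift_of[[j]]
        if (is.null(prev)) {
          shift_of[[j]] <- tj
          queue[[length(queue) + 1L]] <- c(j, tj)
          members[[length(members) + 1L]] <- c(j, tj)
        } else if (any(prev != tj)) {
          stop("molecule perception: infinite (polymeric/framework) ",
               "connectivity detected; this model applies to molecular ",
               "crystals only")
        }
      }
    }
    mem <- do.call(rbind, members)
    idx <- mem[, 1]
    assigned[idx] <- TRUE
    cart <- frac_to_cart(crystal$cell,
                         frac[idx, , drop = FALSE] + mem[, 2:4, drop = FALSE])
    ord <- order(idx)
    mols[[length(mols) + 1L]] <- list(
      site = idx[ord], shift = mem[ord, 2:4, drop = FALSE],
      element = s$element[idx][ord], label = s$label[idx][ord],
      parent = s$parent[idx][ord], op = s$op[idx][ord],
      cart = cart[ord, , drop = FALSE])
  }
  list(mols = mols, expanded = ex)
}

mol_fingerprint <- function(cart) {
  if (nrow(cart) < 2) return(numeric(0))
  sort(as.vector(stats::dist(cart)))
}

as_ce_molecule <- function(m, crystal, label) {
  op <- crystal$symmetry_ops[[m$op[1]]]
  # exact lattice translation for the first atom under its generating op
  asu <- as.matrix(crystal$sites[m$parent[1], c("fx", "fy", "fz")])
  tshift <- round(cart_to_frac(crystal$cell, m$cart[1, , drop = FALSE]) -
                    apply_symop(op, asu))
  mol <- ce_molecule(
    tibble::tibble(element = m$element, x = m$cart[, 1], y = m$cart[, 2],
                   z = m$cart[, 3]),
    label = label,
    origin = sprintf("%s + (%d,%d,%d)", format_symop(op),
                     tshift[1], tshift[2], tshift[3]))
  mol$site_labels <- m$label
  mol
}

#' Perceive whole molecules in a crystal
#'
#' Expands symmetry, builds the bond graph under the covalent-radius
#' criterion (bonded when closer than `r_cov(A) + r_cov(B) + 0.4` Angstrom)
#' and completes connected components across cell boundaries, returning one
#' representative per symmetry-unique molecule.
#'
#' @param crystal A `ce_crystal`.
#' @param tol Geometric tolerance (Angstrom) for grouping symmetry-related
#'   molecules by their internal distance fingerprint.
#' @return List of `ce_molecule` (charges/multiplicities unset; see
#'   [assign_species()]).  Each molecule carries `origin` (generating
#'   operation plus lattice translation) and attribute `count` (number of
#'   copies per unit cell).
#' @export
perceive_molecules <- function(crystal, tol = 1e-3) {
  cm <- crystal_molecules(crystal)
  groups <- list() # each: list(key_elements, fp, first, count)
  for (m in cm$mols) {
    key <- paste(sort(paste(m$element, m$parent)), collapse = "|")
    fp <- mol_fingerprint(m$cart)
    hit <- 0L
    for (g in seq_along(groups)) {
      gr <- groups[[g]]
      if (identical(gr$key, key) && length(gr$fp) == length(fp) &&
          (length(fp) == 0 || max(abs(gr$fp - fp)) < tol)) {
        hit <- g; break
      }
    }
    if (hit > 0L) {
      groups[[hit]]$count <- groups[[hit]]$count + 1L
    } else {
      groups[[length(groups) + 1L]] <- list(key = key, fp = fp, first = m,
                                            count = 1L)
    }
  }
  out <- vector("list", length(groups))
  for (g in seq_along(groups)) {
    m <- groups[[g]]$first
    lab <- paste0("mol", g, "_", paste0(unique(m$element), collapse = ""))
    mol <- as_ce_molecule(m, crystal, lab)
    attr(mol, "count") <- groups[[g]]$count
    out[[g]] <- mol
  }
  out
}

#' Normalize X-H bond lengths to standard neutron-diffraction values
#'
#' Every hydrogen bonded to a heavy atom with an entry in `bond_table` is
#' moved along the existing bond vector so the X-H distance equals the
#' table value exactly; heavy-atom coordinates are untouched.
#'
#' @param crystal A `ce_crystal`.
#' @param bond_table Named map element -> target X-H distance (Angstrom).
#'   The default carries the standard neutron values C-H 1.083, N-H 1.009,
#'   O-H 0.983, B-H 1.185.
#' @return The crystal with updated hydrogen sites.
#' @export
normalize_xh <- function(crystal, bond_table = XH_NEUTRON_TABLE) {
  s <- crystal$sites
  h_idx <- which(s$element == "H")
  if (length(h_idx) == 0) return(crystal)
  ex <- expand_symmetry(crystal)
  efrac <- as.matrix(ex$sites[, c("fx", "fy", "fz")])
  heavy <- which(ex$sites$element != "H")
  if (length(heavy) == 0) {
    warning("no heavy atoms; X-H normalization skipped")
    return(crystal)
  }
  dt_rng <- pmax(1L, ceiling((2 * max(COVALENT_RADII) + 0.4) /
                               cell_heights(crystal$cell)))
  shifts <- as.matrix(expand.grid(-dt_rng[1]:dt_rng[1], -dt_rng[2]:dt_rng[2],
                                  -dt_rng[3]:dt_rng[3]))
  for (ih in h_idx) {
    hf <- as.numeric(s[ih, c("fx", "fy", "fz")])
    hc <- drop(frac_to_cart(crystal$cell, matrix(hf, 1)))
    best <- NULL
    nbond <- 0L
    for (k in heavy) {
      for (r in seq_len(nrow(shifts))) {
        pc <- drop(frac_to_cart(crystal$cell,
                                matrix(efrac[k, ] + shifts[r, ], 1)))
        d <- sqrt(sum((pc - hc)^2))
        if (d > 1e-6 && d < bond_cutoff("H", ex$sites$element[k])) {
          nbond <- nbond + 1L
          if (is.null(best) || d < best$d) {
            best <- list(d = d, pos = pc, element = ex$sites$element[k])
          }
        }
      }
    }
    if (is.null(best)) {
      warning("hydrogen site ", s$label[ih], " has no bonded heavy atom; ",
              "left unchanged")
      next
    }
    if (nbond > 1L) {
      warning("hydrogen site ", s$label[ih], " bonded to ", nbond,
              " heavy atoms; nearest neighbor used")
    }
    target <- bond_table[best$element]
    if (is.na(target)) {
      warning("no standard ", best$element, "-H distance in bond_table; ",
              "site ", s$label[ih], " left unchanged")
      next
    }
    newc <- best$pos + (hc - best$pos) * target / best$d
    newf <- drop(cart_to_frac(crystal$cell, matrix(newc, 1))) %% 1
    s$fx[ih] <- newf[1]; s$fy[ih] <- newf[2]; s$fz[ih] <- newf[3]
  }
  crystal$sites <- s
  crystal
}

#' Cluster of whole neighbor molecules around a central molecule
#'
#' Returns every whole molecule with any atom within `contact_radius` of
#' any atom of the central molecule, each carrying its generating symmetry
#' operation and lattice translation; the central molecule itself is
#' excluded.
#'
#' @param crystal A `ce_crystal`.
#' @param central A `ce_molecule` from [perceive_molecules()] on the same
#'   crystal (Cartesian frame must match).
#' @param contact_radius Atom-atom contact radius in Angstrom (default
#'   3.8, a conventional nearest-neighbor shell).
#' @return List of `ce_molecule` neighbors.
#' @export
build_cluster <- function(crystal, central, contact_radius = 3.8) {
  stopifnot(contact_radius >= 0)
  cc <- mol_coords(central)
  cm <- crystal_molecules(crystal)
  diam <- max(vapply(cm$mols, function(m) {
    if (nrow(m$cart) < 2) 0 else max(stats::dist(m$cart))
  }, numeric(1)), if (nrow(cc) > 1) max(stats::dist(cc)) else 0)
  reach <- contact_radius + diam + 1e-6
  t_rng <- pmax(1L, ceiling(reach / cell_heights(crystal$cell))) + 1L
  out <- list()
  nn <- 0L
  for (t1 in -t_rng[1]:t_rng[1]) for (t2 in -t_rng[2]:t_rng[2])
    for (t3 in -t_rng[3]:t_rng[3]) {
      tv <- drop(frac_to_cart(crystal$cell, matrix(c(t1, t2, t3), 1)))
      for (m in cm$mols) {
        cart <- sweep(m$cart, 2, tv, "+")
        if (nrow(cart) == nrow(cc) &&
            max(abs(cart - cc)) < 1e-6) next # the central molecule itself
        d2 <- outer(rowSums(cc^2), rowSums(cart^2), "+") - 2 * cc %*% t(cart)
        if (min(d2) <= contact_radius^2 + 1e-9) {
          nn <- nn + 1L
          mt <- m
          mt$cart <- cart
          mt$shift <- sweep(m$shift, 2, -c(t1, t2, t3))
          out[[nn]] <- as_ce_molecule(mt, crystal,
                                      paste0(central$label, "_nb", nn))
        }
      }
    }
  out
}

#' Group cluster neighbors into symmetry-unique molecule pairs
#'
#' Neighbors whose intermolecular distance fingerprints (sorted list of all
#' central-neighbor atom-pair distances) agree within `tol` are merged into
#' one pair with a multiplicity count.  Enantiomeric contacts with
#' identical fingerprints merge; all four energy terms are identical for
#' mirror-related rigid pairs.
#'
#' @param central A `ce_molecule`.
#' @param neighbors List of `ce_molecule`, e.g. from [build_cluster()].
#' @param tol Fingerprint tolerance in Angstrom.
#' @return A `ce_dimer_pairs` tibble: `molecule_a`, `molecule_b`
#'   (list-columns), `centroid_distance`, `closest_contact`,
#'   `multiplicity_count`, `fingerprint` (list-column), `origin`.
#' @export
unique_pairs <- function(central, neighbors, tol = 1e-3) {
  stopifnot(tol > 0)
  cc <- mol_coords(central)
  rows <- list()
  for (nb in neighbors) {
    nc <- mol_coords(nb)
    d <- sqrt(outer(rowSums(cc^2), rowSums(nc^2), "+") - 2 * cc %*% t(nc))
    fp <- sort(as.vector(d))
    hit <- 0L
    for (g in seq_along(rows)) {
      gfp <- rows[[g]]$fingerprint
      if (length(gfp) == length(fp) && max(abs(gfp - fp)) < tol) {
        hit <- g; break
      }
    }
    if (hit > 0L) {
      rows[[hit]]$multiplicity_count <- rows[[hit]]$multiplicity_count + 1L
    } else {
      rows[[length(rows) + 1L]] <- list(
        molecule_b = nb, fingerprint = fp,
        centroid_distance = sqrt(sum((centroid(central) - centroid(nb))^2)),
        closest_contact = min(d), multiplicity_count = 1L,
        origin = nb$origin)
    }
  }
  out <- tibble::tibble(
    molecule_a = rep(list(central), length(rows)),
    molecule_b = lapply(rows, `[[`, "molecule_b"),
    centroid_distance = vapply(rows, `[[`, numeric(1), "centroid_distance"),
    closest_contact = vapply(rows, `[[`, numeric(1), "closest_contact"),
    multiplicity_count = vapply(rows, `[[`, integer(1), "multiplicity_count"),
    fingerprint = lapply(rows, `[[`, "fingerprint"),
    origin = vapply(rows, `[[`, character(1), "origin")
  )
  class(out) <- c("ce_dimer_pairs", class(out))
  out
}
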