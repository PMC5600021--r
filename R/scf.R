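# Self-consistent-field engine for monomer wavefunctions (restricted and
# unrestricted HF, and hybrid B3LYP on a Becke-partitioned numerical grid).

#' Define a level of theory for monomer wavefunctions
#'
#' Two packaged models: `"ce-b3lyp"` (B3LYP with 6-31G(d,p) for H-Kr and a
#' DZVP-type set for heavier elements) and `"ce-hf"` (HF/3-21G everywhere).
#' The B3LYP dialect is the mainstream Gaussian-type one: 20% exact
#' exchange, 80% Slater + 72% B88 gradient-corrected exchange, and
#' 19% VWN(RPA) + 81% LYP correlation.
#'
#' @param model_id `"ce-b3lyp"` or `"ce-hf"`.
#' @param heavy_basis Basis name or file used for elements beyond Kr under
#'   `"ce-b3lyp"`.
#' @return A `ce_theory` object.
#' @export
theory_spec <- function(model_id = c("ce-b3lyp", "ce-hf"),
                        heavy_basis = "dgdzvp") {
  model_id <- match.arg(model_id)
  if (model_id == "ce-hf") {
    basis_rule <- function(element) "3-21g"
    method <- "hf"
    xc <- NULL
    c_hf <- 1.0
  } else {
    basis_rule <- function(element) {
      if (atomic_number(element) <= 36L) "6-31gdp" else heavy_basis
    }
    method <- "b3lyp"
    xc <- c(slater = 0.80, b88 = 0.72, vwn = 0.19, lyp = 0.81)
    c_hf <- 0.2
  }
  structure(list(model_id = model_id, method = method,
                 basis_rule = basis_rule, xc = xc, c_hf = c_hf),
            class = "ce_theory")
}

#' @export
print.ce_theory <- function(x, ...) {
  cat(sprintf("<ce_theory %s (%s)>\n", x$model_id, x$method))
  invisible(x)
}

# ------------------------------------------------------------------ grid
# Atom-centred grid: Murray-Handy-Laming radial points, Gauss-Legendre x
# uniform-phi angular product grid, Becke fuzzy-cell weights.
build_dft_grid <- function(pos, elements, nrad = 70L, ntheta = 16L,
                           nphi = 32L) {
  gl <- gauss_legendre(ntheta)
  cost <- gl$nodes
  sint <- sqrt(pmax(0, 1 - cost^2))
  phis <- 2 * pi * (seq_len(nphi) - 0.5) / nphi
  ang <- cbind(
    x = as.vector(outer(sint, cos(phis))),
    y = as.vector(outer(sint, sin(phis))),
    z = rep(cost, nphi)
  )
  wang <- rep(gl$weights, nphi) * (2 * pi / nphi) # sums to 4*pi
  pts <- NULL; w0 <- NULL; parent <- NULL
  for (a in seq_along(elements)) {
    rm <- bragg_radius(elements[a]) / BOHR_ANGSTROM
    i <- seq_len(nrad)
    q <- i / (nrad + 1)
    r <- rm * q^2 / (1 - q)^2
    wr <- 2 * rm^3 * q^5 / (1 - q)^7 / (nrad + 1)
    p <- ang[rep(seq_len(nrow(ang)), each = nrad), ] * r
    p <- sweep(p, 2, -pos[, a])
    pts <- rbind(pts, p)
    w0 <- c(w0, rep(wang, each = nrad) * wr)
    parent <- c(parent, rep(a, nrad * nrow(ang)))
  }
  wb <- cpp_becke_weights(pos, as.integer(parent), t(pts))
  keep <- w0 * wb > 1e-14
  list(pts = t(pts[keep, , drop = FALSE]), w = (w0 * wb)[keep])
}

gauss_legendre <- function(n) {
  # Golub-Welsch via symmetric tridiagonal eigenproblem on [-1, 1]
  k <- seq_len(n - 1)
  b <- k / sqrt(4 * k^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(k, k + 1)] <- b
  J[cbind(k + 1, k)] <- b
  e <- eigen(J, symmetric = TRUE)
  list(nodes = rev(e$values), weights = rev(2 * e$vectors[1, ]^2))
}

# XC energy and matrices on the grid, chunked to bound memory
xc_on_grid <- function(grid, shells, Da, Db, coefs, chunk = 25000L) {
  nbf <- nrow(Da)
  Va <- matrix(0, nbf, nbf); Vb <- matrix(0, nbf, nbf)
  exc <- 0; nele <- 0
  np <- ncol(grid$pts)
  for (start in seq(1L, np, by = chunk)) {
    idx <- start:min(start + chunk - 1L, np)
    be <- cpp_basis_eval(shells, grid$pts[, idx, drop = FALSE], TRUE)
    phi <- be$phi
    w <- grid$w[idx]
    pa <- phi %*% Da; pb <- phi %*% Db
    ra <- rowSums(pa * phi); rb <- rowSums(pb * phi)
    gax <- 2 * rowSums(pa * be$gx); gay <- 2 * rowSums(pa * be$gy)
    gaz <- 2 * rowSums(pa * be$gz)
    gbx <- 2 * rowSums(pb * be$gx); gby <- 2 * rowSums(pb * be$gy)
    gbz <- 2 * rowSums(pb * be$gz)
    saa <- gax^2 + gay^2 + gaz^2
    sbb <- gbx^2 + gby^2 + gbz^2
    sab <- gax * gbx + gay * gby + gaz * gbz
    xc <- cpp_xc_eval(ra, rb, saa, sab, sbb, coefs)
    exc <- exc + sum(w * xc$exc)
    nele <- nele + sum(w * (ra + rb))
    Va <- Va + crossprod(phi, (w * xc$vrho_a) * phi)
    Vb <- Vb + crossprod(phi, (w * xc$vrho_b) * phi)
    for (cmp in list(list(ga = gax, gb = gbx, g = be$gx),
                     list(ga = gay, gb = gby, g = be$gy),
                     list(ga = gaz, gb = gbz, g = be$gz))) {
      Wa <- w * (2 * xc$vsigma_aa * cmp$ga + xc$vsigma_ab * cmp$gb)
      Wb <- w * (2 * xc$vsigma_bb * cmp$gb + xc$vsigma_ab * cmp$ga)
      Ma <- crossprod(phi, Wa * cmp$g)
      Mb <- crossprod(phi, Wb * cmp$g)
      Va <- Va + Ma + t(Ma)
      Vb <- Vb + Mb + t(Mb)
    }
  }
  list(exc = exc, Va = Va, Vb = Vb, nele = nele)
}

# ------------------------------------------------------- J/K from the ERIs
make_jk <- function(eri, nbf) {
  n2 <- nbf * nbf
  Jm <- matrix(eri, n2, n2)
  Km <- matrix(aperm(array(eri, c(nbf, nbf, nbf, nbf)), c(1, 3, 2, 4)),
               n2, n2)
  list(
    J = function(D) matrix(Jm %*% as.vector(D), nbf, nbf),
    K = function(D) matrix(Km %*% as.vector(D), nbf, nbf)
  )
}

nuclear_repulsion <- function(pos, Z) {
  n <- length(Z)
  if (n < 2) return(0)
  e <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((pos[, i] - pos[, j])^2))
    e <- e + Z[i] * Z[j] / r
  }
  e
}

#' Compute a converged monomer wavefunction
#'
#' Self-consistent field at the given geometry (never optimized).
#' Closed-shell singlets use the restricted formalism; open-shell species
#' the unrestricted one.  Convergence thresholds default to 1e-10 hartree
#' in the energy and 1e-8 in the density, tight enough that component
#' energies quoted to 0.1 kJ/mol are unaffected by the SCF.
#'
#' @param mol A `ce_molecule`.
#' @param theory A `ce_theory` from [theory_spec()].
#' @param restricted Override the restricted/unrestricted choice; an error
#'   is raised if a restricted calculation is requested for an open shell.
#' @param conv_energy,conv_density SCF convergence thresholds (hartree /
#'   density rms).
#' @param max_iter Maximum SCF iterations.
#' @param grid_params Optional list(nrad, ntheta, nphi) for the DFT grid.
#' @param cache Reuse cached wavefunctions for identical (geometry, charge,
#'   multiplicity, theory) inputs.
#' @return A `ce_wavefunction`.
#' @export
compute_wavefunction <- function(mol, theory = theory_spec("ce-hf"),
                                 restricted = NULL,
                                 conv_energy = 1e-10, conv_density = 1e-8,
                                 max_iter = 200L, grid_params = list(),
                                 cache = TRUE) {
  nel <- n_electrons(mol)
  check_parity(nel, mol$multiplicity)
  if (isTRUE(restricted) && mol$multiplicity != 1L) {
    stop("restricted calculation requested for multiplicity ",
         mol$multiplicity, "; use the unrestricted formalism")
  }
  restricted <- if (is.null(restricted)) mol$multiplicity == 1L else restricted
  key <- wfn_cache_key(mol, theory, restricted)
  if (cache && !is.null(wfn_cache[[key]])) return(wfn_cache[[key]])

  bs <- build_shells(mol, theory$basis_rule)
  nbf <- n_basis(bs$shells)
  one <- cpp_one_ints(bs$shells)
  S <- one$S
  hcore <- one$T + cpp_nuclear(bs$shells, bs$pos, bs$Z)
  jk <- make_jk(cpp_eri(bs$shells), nbf)
  e_nn <- nuclear_repulsion(bs$pos, bs$Z)
  na <- (nel + mol$multiplicity - 1L) %/% 2L
  nb <- nel - na

  es <- eigen(S, symmetric = TRUE)
  if (min(es$values) < 1e-9) {
    stop("near-linear dependence in the basis (min overlap eigenvalue ",
         signif(min(es$values), 3), ")")
  }
  X <- es$vectors %*% diag(1 / sqrt(es$values), nbf) %*% t(es$vectors)

  is_ks <- !is.null(theory$xc)
  grid <- NULL
  if (is_ks) {
    gp <- utils::modifyList(list(nrad = 70L, ntheta = 16L, nphi = 32L),
                            grid_params)
    grid <- build_dft_grid(bs$pos, mol$atoms$element, gp$nrad, gp$ntheta,
                           gp$nphi)
  }

  occ_density <- function(C, nocc) {
    if (nocc == 0L) return(matrix(0, nbf, nbf))
    tcrossprod(C[, seq_len(nocc), drop = FALSE])
  }
  diag_fock <- function(F) {
    Fp <- t(X) %*% F %*% X
    e <- eigen((Fp + t(Fp)) / 2, symmetric = TRUE)
    ord <- order(e$values) # eigen() sorts decreasing; occupy lowest first
    list(C = X %*% e$vectors[, ord, drop = FALSE], eps = e$values[ord])
  }

  # core guess
  g0 <- diag_fock(hcore)
  Ca <- g0$C; Cb <- g0$C
  Da <- occ_density(Ca, na); Db <- occ_density(Cb, nb)
  e_old <- Inf
  diis <- list(F = list(), e = list())
  energy <- NA_real_
  converged <- FALSE
  niter <- 0L

  for (it in seq_len(max_iter)) {
    niter <- it
    Dt <- Da + Db
    J <- jk$J(Dt)
    Ka <- jk$K(Da); Kb <- if (restricted) Ka else jk$K(Db)
    exc <- 0
    Va <- 0; Vb <- 0
    if (is_ks) {
      xc <- xc_on_grid(grid, bs$shells, Da, Db, theory$xc)
      exc <- xc$exc; Va <- xc$Va; Vb <- xc$Vb
    }
    Fa <- hcore + J - theory$c_hf * Ka + Va
    Fb <- hcore + J - theory$c_hf * Kb + Vb
    energy <- sum(Dt * hcore) + 0.5 * sum(Dt * J) -
      0.5 * theory$c_hf * (sum(Da * Ka) + sum(Db * Kb)) + exc + e_nn

    err_a <- t(X) %*% (Fa %*% Da %*% S - S %*% Da %*% Fa) %*% X
    err_b <- t(X) %*% (Fb %*% Db %*% S - S %*% Db %*% Fb) %*% X
    err <- rbind(err_a, err_b)
    diis$F[[length(diis$F) + 1L]] <- list(Fa = Fa, Fb = Fb)
    diis$e[[length(diis$e) + 1L]] <- err
    if (length(diis$F) > 8L) {
      diis$F <- diis$F[-1L]; diis$e <- diis$e[-1L]
    }
    m <- length(diis$F)
    if (m >= 2L) {
      B <- matrix(-1, m + 1L, m + 1L); B[m + 1L, m + 1L] <- 0
      for (i in 1:m) for (j in 1:m) {
        B[i, j] <- sum(diis$e[[i]] * diis$e[[j]])
      }
      rhs <- c(rep(0, m), -1)
      cf <- tryCatch(solve(B, rhs)[1:m], error = function(e) NULL)
      if (!is.null(cf)) {
        Fa <- Reduce(`+`, Map(function(f, c) c * f$Fa, diis$F, cf))
        Fb <- Reduce(`+`, Map(function(f, c) c * f$Fb, diis$F, cf))
      }
    }

    ga <- diag_fock(Fa)
    Ca <- ga$C; eps_a <- ga$eps
    if (restricted) {
      Cb <- Ca; eps_b <- eps_a
    } else {
      gb <- diag_fock(Fb)
      Cb <- gb$C; eps_b <- gb$eps
    }
    Da_new <- occ_density(Ca, na); Db_new <- occ_density(Cb, nb)
    d_rms <- sqrt(mean((Da_new - Da)^2 + (Db_new - Db)^2))
    dE <- abs(energy - e_old)
    Da <- Da_new; Db <- Db_new
    e_old <- energy
    if (it > 2L && dE < conv_energy && d_rms < conv_density) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    stop(sprintf(
      "SCF failed to converge in %d iterations (last dE = %.3e, molecule '%s')",
      max_iter, abs(energy - e_old), mol$label))
  }

  wfn <- structure(list(
    molecule = mol, theory = theory,
    method = paste0(if (restricted) "r" else "u", theory$method),
    restricted = restricted,
    shells = bs$shells, pos = bs$pos, Z = bs$Z, nbf = nbf,
    na = na, nb = nb,
    Ca = Ca, Cb = Cb, eps_a = eps_a, eps_b = eps_b,
    Da = Da, Db = Db, S = S,
    energy = energy, e_nn = e_nn, niter = niter, converged = converged
  ), class = "ce_wavefunction")
  if (cache) wfn_cache[[key]] <- wfn
  wfn
}

wfn_cache <- new.env(parent = emptyenv())

#' Clear the monomer wavefunction cache
#' @export
clear_wavefunction_cache <- function() {
  rm(list = ls(wfn_cache), envir = wfn_cache)
  invisible(NULL)
}

wfn_cache_key <- function(mol, theory, restricted) {
  paste(theory$model_id, restricted, mol$charge, mol$multiplicity,
        paste(mol$atoms$element, collapse = ""),
        paste(sprintf("%.10f", as.vector(mol_coords(mol))), collapse = ","),
        paste(if ("ghost" %in% names(mol$atoms)) mol$atoms$ghost else "",
              collapse = ""),
        sep = "|")
}

#' @export
print.ce_wavefunction <- function(x, ...) {
  cat(sprintf("<ce_wavefunction %s: %d basis functions, E = %.8f hartree (%d iterations)>\n",
              x$method, x$nbf, x$energy, x$niter))
  invisible(x)
}

occupied_coefs <- function(wfn) {
  list(
    Ca = wfn$Ca[, seq_len(wfn$na), drop = FALSE],
    Cb = wfn$Cb[, seq_len(wfn$nb), drop = FALSE]
  )
}
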