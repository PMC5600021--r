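# Independent oracles implemented from scratch (pure R, s-type Gaussian
# closed forms and numerical quadrature) against which package results are
# tested.  Nothing here calls the package's C++ integral engine.

HARTREE <- 2625.499
BOHR <- 0.529177

boys0 <- function(x) {
  ifelse(x < 1e-12, 1 - x / 3, 0.5 * sqrt(pi / pmax(x, 1e-300)) *
           erf_(sqrt(pmax(x, 0))))
}
erf_ <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

# closed forms for primitive s Gaussians exp(-a|r-A|^2)
s_overlap <- function(a, A, b, B) {
  p <- a + b
  (pi / p)^1.5 * exp(-a * b / p * sum((A - B)^2))
}
s_kinetic <- function(a, A, b, B) {
  p <- a + b
  mu <- a * b / p
  mu * (3 - 2 * mu * sum((A - B)^2)) * s_overlap(a, A, b, B)
}
s_nuclear <- function(a, A, b, B, C) {
  p <- a + b
  P <- (a * A + b * B) / p
  -2 * pi / p * exp(-a * b / p * sum((A - B)^2)) * boys0(p * sum((P - C)^2))
}
s_eri <- function(a, A, b, B, c, C, d, D) {
  p <- a + b; q <- c + d
  P <- (a * A + b * B) / p; Q <- (c * C + d * D) / q
  2 * pi^2.5 / (p * q * sqrt(p + q)) *
    exp(-a * b / p * sum((A - B)^2) - c * d / q * sum((C - D)^2)) *
    boys0(p * q / (p + q) * sum((P - Q)^2))
}

# contracted s basis: list of shells, each list(center, exps, coefs)
# (coefs include all normalization, as stored in a ce_wavefunction)
oracle_s_integrals <- function(shells, pos, Z) {
  n <- length(shells)
  S <- T <- V <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    si <- shells[[i]]; sj <- shells[[j]]
    for (ki in seq_along(si$exps)) for (kj in seq_along(sj$exps)) {
      cc <- si$coefs[ki] * sj$coefs[kj]
      S[i, j] <- S[i, j] + cc * s_overlap(si$exps[ki], si$center,
                                          sj$exps[kj], sj$center)
      T[i, j] <- T[i, j] + cc * s_kinetic(si$exps[ki], si$center,
                                          sj$exps[kj], sj$center)
      for (at in seq_len(ncol(pos))) {
        V[i, j] <- V[i, j] + cc * Z[at] *
          s_nuclear(si$exps[ki], si$center, sj$exps[kj], sj$center, pos[, at])
      }
    }
  }
  eri <- array(0, c(n, n, n, n))
  for (i in 1:n) for (j in 1:n) for (k in 1:n) for (l in 1:n) {
    si <- shells[[i]]; sj <- shells[[j]]; sk <- shells[[k]]; sl <- shells[[l]]
    acc <- 0
    for (a in seq_along(si$exps)) for (b in seq_along(sj$exps))
      for (cc in seq_along(sk$exps)) for (dd in seq_along(sl$exps)) {
        acc <- acc + si$coefs[a] * sj$coefs[b] * sk$coefs[cc] * sl$coefs[dd] *
          s_eri(si$exps[a], si$center, sj$exps[b], sj$center,
                sk$exps[cc], sk$center, sl$exps[dd], sl$center)
      }
    eri[i, j, k, l] <- acc
  }
  e_nn <- 0
  nat <- ncol(pos)
  if (nat > 1) for (i in 1:(nat - 1)) for (j in (i + 1):nat) {
    e_nn <- e_nn + Z[i] * Z[j] / sqrt(sum((pos[, i] - pos[, j])^2))
  }
  list(S = S, T = T, V = V, eri = eri, e_nn = e_nn)
}

oracle_jk <- function(eri, D) {
  n <- nrow(D)
  J <- K <- matrix(0, n, n)
  for (p in 1:n) for (q in 1:n) {
    J[p, q] <- sum(eri[p, q, , ] * D)
    K[p, q] <- sum(eri[p, , , q] * t(D))
  }
  list(J = J, K = K)
}

# independent closed-shell RHF for s-only systems
oracle_rhf <- function(shells, pos, Z, nocc, maxit = 200) {
  ints <- oracle_s_integrals(shells, pos, Z)
  es <- eigen(ints$S, symmetric = TRUE)
  X <- es$vectors %*% diag(1 / sqrt(es$values), length(es$values)) %*%
    t(es$vectors)
  h <- ints$T + ints$V
  D <- matrix(0, nrow(h), ncol(h))
  e_old <- Inf
  for (it in 1:maxit) {
    jk <- oracle_jk(ints$eri, D)
    F <- h + jk$J - 0.5 * jk$K
    e <- sum(D * (h + F)) / 2 + ints$e_nn
    Fp <- t(X) %*% F %*% X
    ev <- eigen((Fp + t(Fp)) / 2, symmetric = TRUE)
    ord <- order(ev$values)
    C <- X %*% ev$vectors[, ord, drop = FALSE]
    Cocc <- C[, seq_len(nocc), drop = FALSE]
    D <- 2 * tcrossprod(Cocc)
    if (abs(e - e_old) < 1e-12 && it > 2) break
    e_old <- e
  }
  e
}

# independent antisymmetrized-product (Lowdin) dimer energy for s-only
# monomer wavefunctions; spins may be pooled arbitrarily via occ lists
oracle_exchrep <- function(wfn_a, wfn_b) {
  shells <- c(wfn_a$shells, wfn_b$shells)
  pos <- cbind(wfn_a$pos, wfn_b$pos)
  Z <- c(wfn_a$Z, wfn_b$Z)
  stopifnot(all(vapply(shells, function(s) s$l == 0L, logical(1))))
  ints <- oracle_s_integrals(shells, pos, Z)
  na <- length(wfn_a$Z)
  nb <- length(wfn_b$Z)
  nbf_a <- wfn_a$nbf
  n <- length(shells)
  embed <- function(M, off) {
    out <- matrix(0, n, ncol(M))
    out[off + seq_len(nrow(M)), ] <- M
    out
  }
  Ca <- cbind(embed(wfn_a$Ca[, seq_len(wfn_a$na), drop = FALSE], 0),
              embed(wfn_b$Ca[, seq_len(wfn_b$na), drop = FALSE], nbf_a))
  Cb_list <- list()
  if (wfn_a$nb > 0) Cb_list <- c(Cb_list, list(
    embed(wfn_a$Cb[, seq_len(wfn_a$nb), drop = FALSE], 0)))
  if (wfn_b$nb > 0) Cb_list <- c(Cb_list, list(
    embed(wfn_b$Cb[, seq_len(wfn_b$nb), drop = FALSE], nbf_a)))
  Cb <- if (length(Cb_list) > 0) do.call(cbind, Cb_list) else
    matrix(0, n, 0)
  lowdin <- function(C) {
    if (ncol(C) == 0) return(matrix(0, n, n))
    So <- t(C) %*% ints$S %*% C
    e <- eigen((So + t(So)) / 2, symmetric = TRUE)
    Co <- C %*% (e$vectors %*% diag(1 / sqrt(e$values), ncol(C)) %*%
                   t(e$vectors))
    tcrossprod(Co)
  }
  Pa <- lowdin(Ca); Pb <- lowdin(Cb)
  h <- ints$T + ints$V
  hf_like <- function(Pa, Pb, h, e_nn) {
    Pt <- Pa + Pb
    jk_t <- oracle_jk(ints$eri, Pt)
    ka <- oracle_jk(ints$eri, Pa)$K
    kb <- oracle_jk(ints$eri, Pb)$K
    sum(Pt * h) + 0.5 * sum(Pt * jk_t$J) -
      0.5 * (sum(Pa * ka) + sum(Pb * kb)) + e_nn
  }
  e_det <- hf_like(Pa, Pb, h, ints$e_nn)
  # monomer energies, own nuclei only
  VA <- VB <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    si <- shells[[i]]; sj <- shells[[j]]
    for (ki in seq_along(si$exps)) for (kj in seq_along(sj$exps)) {
      cc <- si$coefs[ki] * sj$coefs[kj]
      for (at in seq_len(na)) {
        VA[i, j] <- VA[i, j] + cc * Z[at] *
          s_nuclear(si$exps[ki], si$center, sj$exps[kj], sj$center, pos[, at])
      }
      for (at in na + seq_len(nb)) {
        VB[i, j] <- VB[i, j] + cc * Z[at] *
          s_nuclear(si$exps[ki], si$center, sj$exps[kj], sj$center, pos[, at])
      }
    }
  }
  enn_of <- function(p, z) {
    e <- 0
    if (ncol(p) > 1) for (i in 1:(ncol(p) - 1)) for (j in (i + 1):ncol(p)) {
      e <- e + z[i] * z[j] / sqrt(sum((p[, i] - p[, j])^2))
    }
    e
  }
  DAa <- lowdin(embed(wfn_a$Ca[, seq_len(wfn_a$na), drop = FALSE], 0))
  DAb <- lowdin(if (wfn_a$nb > 0) {
    embed(wfn_a$Cb[, seq_len(wfn_a$nb), drop = FALSE], 0)
  } else matrix(0, n, 0))
  DBa <- lowdin(embed(wfn_b$Ca[, seq_len(wfn_b$na), drop = FALSE], nbf_a))
  DBb <- lowdin(if (wfn_b$nb > 0) {
    embed(wfn_b$Cb[, seq_len(wfn_b$nb), drop = FALSE], nbf_a)
  } else matrix(0, n, 0))
  e_a <- hf_like(DAa, DAb, ints$T + VA, enn_of(wfn_a$pos, wfn_a$Z))
  e_b <- hf_like(DBa, DBb, ints$T + VB, enn_of(wfn_b$pos, wfn_b$Z))
  # classical Coulomb between the unperturbed monomer densities
  DA <- DAa + DAb; DB <- DBa + DBb
  e_nn_ab <- 0
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    e_nn_ab <- e_nn_ab + wfn_a$Z[i] * wfn_b$Z[j] /
      sqrt(sum((wfn_a$pos[, i] - wfn_b$pos[, j])^2))
  }
  e_ele <- e_nn_ab + sum(DA * VB) + sum(DB * VA) +
    sum(DA * oracle_jk(ints$eri, DB)$J)
  list(e_rep = (e_det - e_a - e_b - e_ele) * HARTREE,
       e_ele = e_ele * HARTREE)
}

# radial electron density of an s-only monomer wavefunction at distances r
# (bohr) from its single atomic center
oracle_radial_density <- function(wfn, r) {
  D <- wfn$Da + wfn$Db
  n <- wfn$nbf
  phi <- vapply(seq_len(n), function(i) {
    s <- wfn$shells[[i]]
    colSums(s$coefs * exp(-outer(s$exps, r^2)))
  }, numeric(length(r)))
  rho <- numeric(length(r))
  for (p in 1:n) for (q in 1:n) rho <- rho + D[p, q] * phi[, p] * phi[, q]
  rho
}

# Gauss-Legendre nodes/weights on [lo, hi] (Golub-Welsch)
oracle_gl <- function(nn, lo, hi) {
  i <- seq_len(nn - 1)
  b <- i / sqrt(4 * i^2 - 1)
  A <- matrix(0, nn, nn)
  A[cbind(i, i + 1)] <- b; A[cbind(i + 1, i)] <- b
  ev <- eigen(A, symmetric = TRUE)
  list(x = (hi - lo) / 2 * ev$values + (hi + lo) / 2,
       w = (hi - lo) / 2 * 2 * ev$vectors[1, ]^2)
}

# numerical-quadrature classical Coulomb energy (kJ/mol) between two
# one-center spherical monomers (e.g. H atoms) separated by R_ang.
# Cloud potentials tabulated on a dense radial grid and splined; the
# two-center electron-electron integral is a 2D quadrature over that.
oracle_coulomb_spherical <- function(wfn_a, wfn_b, R_ang) {
  R <- R_ang / BOHR
  rmax <- 25
  # dense grid for cumulative-integral potentials
  rg <- seq(1e-5, rmax, length.out = 8000)
  cumtrap <- function(x, y) {
    c(0, cumsum(diff(x) * (head(y, -1) + tail(y, -1)) / 2))
  }
  cloud_potential <- function(wfn) {
    rho <- oracle_radial_density(wfn, rg)
    qin <- cumtrap(rg, 4 * pi * rg^2 * rho)     # charge inside r
    qout_tot <- cumtrap(rg, 4 * pi * rg * rho)  # int_0^r 4 pi s rho ds
    phi <- qin / rg + (qout_tot[length(rg)] - qout_tot)
    stats::splinefun(rg, phi)
  }
  phi_a <- cloud_potential(wfn_a)
  phi_b <- cloud_potential(wfn_b)
  Za <- sum(wfn_a$Z); Zb <- sum(wfn_b$Z)
  e_nn <- Za * Zb / R
  e_ne <- -Za * phi_b(R) - Zb * phi_a(R)
  # e-e: 2 pi int r^2 rho_a(r) int_-1^1 phi_b(sqrt(r^2+R^2-2rRu)) du dr
  ra <- oracle_gl(400, 0, rmax)
  u <- oracle_gl(96, -1, 1)
  rho_a <- oracle_radial_density(wfn_a, ra$x)
  e_ee <- 0
  for (k in seq_along(ra$x)) {
    s <- sqrt(pmax(ra$x[k]^2 + R^2 - 2 * ra$x[k] * R * u$x, 1e-12))
    e_ee <- e_ee + ra$w[k] * 2 * pi * ra$x[k]^2 * rho_a[k] *
      sum(u$w * phi_b(s))
  }
  (e_nn + e_ne + e_ee) * HARTREE
}

# direct closed-form D2 pair sum (kJ/mol)
oracle_d2 <- function(el_a, xyz_a, el_b, xyz_b, C6, Rvdw, s6 = 1, d = 20) {
  e <- 0
  for (i in seq_along(el_a)) for (j in seq_along(el_b)) {
    r <- sqrt(sum((xyz_a[i, ] - xyz_b[j, ])^2))
    rr <- Rvdw[el_a[i]] + Rvdw[el_b[j]]
    f <- 1 / (1 + exp(-d * (r / rr - 1)))
    e <- e - s6 * f * sqrt(C6[el_a[i]] * C6[el_b[j]]) / (r / 10)^6
  }
  unname(e / 1000)
}

# helper: write CIF text to a temp file and return the path
write_cif_text <- function(txt) {
  p <- tempfile(fileext = ".cif")
  writeLines(txt, p)
  p
}
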