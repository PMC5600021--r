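# Unit cells and crystallographic symmetry operations.

#' Construct a unit cell
#'
#' @param a,b,c Cell lengths in Angstrom.
#' @param alpha,beta,gamma Cell angles in degrees.
#' @return A `ce_unit_cell` with the fractional-to-Cartesian matrix `M`
#'   (columns are the lattice vectors in Angstrom) and `volume`.
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  stopifnot(a > 0, b > 0, c > 0,
            alpha > 0, alpha < 180, beta > 0, beta < 180,
            gamma > 0, gamma < 180)
  ca <- cos(alpha * pi / 180); cb <- cos(beta * pi / 180)
  cg <- cos(gamma * pi / 180); sg <- sin(gamma * pi / 180)
  vfac <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (vfac <= 0) stop("cell angles give non-positive volume")
  M <- matrix(c(a, 0, 0,
                b * cg, b * sg, 0,
                c * cb, c * (ca - cb * cg) / sg,
                c * sqrt(vfac) / sg), 3, 3)
  structure(list(a = a, b = b, c = c, alpha = alpha, beta = beta,
                 gamma = gamma, M = M, volume = a * b * c * sqrt(vfac)),
            class = "ce_unit_cell")
}

#' @export
print.ce_unit_cell <- function(x, ...) {
  cat(sprintf("<ce_unit_cell a=%.4f b=%.4f c=%.4f alpha=%.2f beta=%.2f gamma=%.2f V=%.2f>\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

frac_to_cart <- function(cell, frac) {
  # frac: n x 3 -> n x 3 Cartesian Angstrom
  frac %*% t(cell$M)
}

cart_to_frac <- function(cell, cart) {
  cart %*% t(solve(cell$M))
}

# ---------------------------------------------------- symmetry operations

#' Parse a symmetry operator string like "-x, y+1/2, 1/2-z"
#'
#' @param s Operator string in xyz notation.
#' @return A `ce_symop` with integer-valued `rotation` (3 x 3, fractional
#'   coordinates) and `translation` (length-3).
#' @export
parse_symop <- function(s) {
  parts <- strsplit(gsub("\\s", "", tolower(s)), ",")[[1]]
  if (length(parts) != 3L) stop("malformed symmetry operator: ", s)
  rot <- matrix(0, 3, 3)
  trn <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    # split into signed terms
    terms <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
    for (tm in terms) {
      sign <- if (startsWith(tm, "-")) -1 else 1
      body <- sub("^[+-]", "", tm)
      if (body %in% c("x", "y", "z")) {
        rot[i, match(body, c("x", "y", "z"))] <- sign
      } else if (grepl("^[0-9]+/[0-9]+$", body)) {
        nm <- as.numeric(strsplit(body, "/")[[1]])
        trn[i] <- trn[i] + sign * nm[1] / nm[2]
      } else if (grepl("^[0-9.]+$", body)) {
        trn[i] <- trn[i] + sign * as.numeric(body)
      } else {
        stop("cannot parse symmetry term '", tm, "' in: ", s)
      }
    }
  }
  if (abs(abs(det(rot)) - 1) > 1e-9) {
    stop("symmetry rotation has |det| != 1 in: ", s)
  }
  structure(list(rotation = rot, translation = trn %% 1), class = "ce_symop")
}

#' Format a symmetry operation as an xyz operator string
#' @param op A `ce_symop`.
#' @return Character scalar like `"-x,y+1/2,-z+1/2"`.
#' @export
format_symop <- function(op) {
  axis <- c("x", "y", "z")
  frac_str <- function(t) {
    # translations in crystallographic settings are small rationals
    for (den in c(1L, 2L, 3L, 4L, 6L)) {
      num <- t * den
      if (abs(num - round(num)) < 1e-9) {
        num <- round(num)
        if (num == 0) return("")
        return(paste0("+", if (den == 1L) num else paste0(num, "/", den)))
      }
    }
    sprintf("%+.6f", t)
  }
  vapply(1:3, function(i) {
    out <- ""
    for (j in 1:3) {
      r <- op$rotation[i, j]
      if (r == 0) next
      out <- paste0(out, if (r > 0 && nzchar(out)) "+" else if (r < 0) "-" else "",
                    axis[j])
    }
    paste0(out, frac_str(op$translation[i] %% 1))
  }, character(1)) |> paste(collapse = ",")
}

#' @export
print.ce_symop <- function(x, ...) {
  cat("<ce_symop ", format_symop(x), ">\n", sep = "")
  invisible(x)
}

apply_symop <- function(op, frac) {
  # frac: n x 3 fractional -> n x 3
  sweep(frac %*% t(op$rotation), 2, op$translation, "+")
}

# Minimal built-in space-group table for structures that give only a name
# or number.  Most inputs (and all packaged fixtures that need more) list
# their operators explicitly via _symmetry_equiv_pos_as_xyz.
builtin_spacegroup_ops <- function(key) {
  norm <- tolower(gsub("[[:space:]_]", "", as.character(key)))
  signed_perms <- function() {
    # the 48 signed permutation matrices (full cubic point group m-3m)
    out <- list()
    for (p in list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                   c(3, 1, 2), c(3, 2, 1))) {
      for (s1 in c(1, -1)) for (s2 in c(1, -1)) for (s3 in c(1, -1)) {
        R <- matrix(0, 3, 3)
        R[1, p[1]] <- s1; R[2, p[2]] <- s2; R[3, p[3]] <- s3
        out[[length(out) + 1L]] <- structure(
          list(rotation = R, translation = c(0, 0, 0)), class = "ce_symop")
      }
    }
    out
  }
  add_centering <- function(ops, centers) {
    out <- list()
    for (cc in centers) for (op in ops) {
      out[[length(out) + 1L]] <- structure(
        list(rotation = op$rotation,
             translation = (op$translation + cc) %% 1), class = "ce_symop")
    }
    out
  }
  switch(norm,
    "1" = , "p1" = list(parse_symop("x,y,z")),
    "2" = , "p-1" = lapply(c("x,y,z", "-x,-y,-z"), parse_symop),
    "14" = , "p21/c" = lapply(c("x,y,z", "-x,y+1/2,-z+1/2",
                                "-x,-y,-z", "x,-y+1/2,z+1/2"), parse_symop),
    "19" = , "p212121" = lapply(c("x,y,z", "x+1/2,-y+1/2,-z",
                                  "-x,y+1/2,-z+1/2", "-x+1/2,-y,z+1/2"),
                                parse_symop),
    "221" = , "pm-3m" = signed_perms(),
    "225" = , "fm-3m" = add_centering(
      signed_perms(),
      list(c(0, 0, 0), c(0, 0.5, 0.5), c(0.5, 0, 0.5), c(0.5, 0.5, 0))),
    NULL
  )
}

# ------------------------------------------------------------- Crystal

#' Construct a crystal structure
#'
#' @param cell A [unit_cell()].
#' @param sites Tibble with columns `element`, `fx`, `fy`, `fz` (fractional
#'   coordinates) and optionally `label`.
#' @param symmetry_ops List of `ce_symop` (identity added if missing), or
#'   character vector of xyz operator strings.
#' @param space_group Space-group label (text), for bookkeeping only.
#' @return A `ce_crystal`.  Fractional coordinates are stored wrapped into
#'   `[0, 1)`.
#' @export
ce_crystal <- function(cell, sites, symmetry_ops = list(), space_group = "P 1") {
  stopifnot(inherits(cell, "ce_unit_cell"))
  sites <- tibble::as_tibble(sites)
  need <- c("element", "fx", "fy", "fz")
  if (!all(need %in% names(sites))) {
    stop("sites must have columns ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(sites$element), ELEMENTS)
  if (length(bad) > 0) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  if (!"label" %in% names(sites)) {
    sites$label <- paste0(sites$element, seq_len(nrow(sites)))
  }
  sites$fx <- sites$fx %% 1; sites$fy <- sites$fy %% 1; sites$fz <- sites$fz %% 1
  if (is.character(symmetry_ops)) symmetry_ops <- lapply(symmetry_ops, parse_symop)
  if (length(symmetry_ops) == 0) symmetry_ops <- list(parse_symop("x,y,z"))
  has_identity <- any(vapply(symmetry_ops, function(op) {
    all(op$rotation == diag(3)) && all(abs(op$translation %% 1) < 1e-9)
  }, logical(1)))
  if (!has_identity) symmetry_ops <- c(list(parse_symop("x,y,z")), symmetry_ops)
  structure(list(cell = cell, sites = sites, symmetry_ops = symmetry_ops,
                 space_group = space_group), class = "ce_crystal")
}

#' @export
print.ce_crystal <- function(x, ...) {
  cat(sprintf("<ce_crystal %s: %d site(s), %d symmetry op(s), a=%.3f b=%.3f c=%.3f>\n",
              x$space_group, nrow(x$sites), length(x$symmetry_ops),
              x$cell$a, x$cell$b, x$cell$c))
  invisible(x)
}

#' Expand a crystal's sites by its symmetry operations
#'
#' Applies every symmetry operation to every site, wraps into `[0, 1)` and
#' removes duplicates (within `tol` fractional units).  Expanding an
#' already-expanded crystal changes nothing.
#'
#' @param crystal A `ce_crystal`.
#' @param tol Fractional-coordinate tolerance for duplicate detection.
#' @return A `ce_crystal` whose `sites` contain the full cell contents;
#'   each site gains `parent` (index of the generating stored site) and
#'   `op` (index of the generating symmetry operation).
#' @export
expand_symmetry <- function(crystal, tol = 1e-4) {
  s <- crystal$sites
  frac <- as.matrix(s[, c("fx", "fy", "fz")])
  out <- list()
  for (k in seq_along(crystal$symmetry_ops)) {
    f <- apply_symop(crystal$symmetry_ops[[k]], frac) %% 1
    out[[k]] <- tibble::tibble(element = s$element, fx = f[, 1], fy = f[, 2],
                               fz = f[, 3], label = s$label,
                               parent = if ("parent" %in% names(s)) s$parent else seq_len(nrow(s)),
                               op = k)
  }
  all <- dplyr::bind_rows(out)
  # dedupe under the minimum-image metric
  keep <- rep(TRUE, nrow(all))
  f <- as.matrix(all[, c("fx", "fy", "fz")])
  for (i in seq_len(nrow(all))) {
    if (!keep[i]) next
    if (i < nrow(all)) {
      d <- sweep(f[(i + 1):nrow(all), , drop = FALSE], 2, f[i, ])
      d <- abs(d - round(d))
      dup <- which(rowSums(d < tol) == 3L)
      keep[i + dup] <- FALSE
    }
  }
  res <- crystal
  res$sites <- all[keep, ]
  res
}
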