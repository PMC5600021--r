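# Calibration of the four scale factors against benchmark pair energies,
# fit statistics and (optionally) counterpoise-corrected reference
# energies.

component_matrix <- function(rows) {
  rows <- tibble::as_tibble(rows)
  need <- c("E_ele", "E_pol", "E_dis", "E_rep")
  if (!all(need %in% names(rows))) {
    stop("benchmark rows must have columns ", paste(need, collapse = ", "))
  }
  X <- as.matrix(rows[, need])
  if (!all(is.finite(X))) stop("non-finite component energies in rows")
  X
}

check_rank <- function(X) {
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[(qrx$rank + 1):ncol(X)]]
    stop("component columns are collinear (rank ", qrx$rank,
         "); offending column(s): ", paste(dropped, collapse = ", "))
  }
  invisible(qrx)
}

#' Deviation statistics: MAD, MD, RMSD, min, max
#'
#' @param deviations Numeric vector of model-minus-reference deviations
#'   (kJ/mol).
#' @return Tibble with `n`, `MAD` (mean absolute), `MD` (mean), `RMSD`
#'   (root mean square), `min`, `max`.
#' @export
fit_statistics <- function(deviations) {
  if (length(deviations) == 0) stop("empty deviation vector")
  if (!all(is.finite(deviations))) stop("non-finite deviations")
  tibble::tibble(
    n = length(deviations),
    MAD = mean(abs(deviations)),
    MD = mean(deviations),
    RMSD = sqrt(mean(deviations^2)),
    min = min(deviations),
    max = max(deviations))
}

#' Fit the four scale factors to benchmark pair energies
#'
#' Unweighted ordinary least squares of the reference energy on the four
#' unscaled components with no intercept (the model has no constant term).
#' Deviations are model minus reference; statistics are reported overall
#' and per subset tag.
#'
#' @param rows Benchmark rows: tibble with `E_ele`, `E_pol`, `E_dis`,
#'   `E_rep`, `E_ref` and optionally `subset` (see
#'   [make_benchmark_table()]).
#' @return A `ce_fit_result`: `k` (named factors), `statistics` (per
#'   subset plus `"all"`), `correlation` (4 x 4 parameter correlation
#'   matrix), `std_error`, `residual_sd`, `deviations`, `n`.
#' @export
fit_scale_factors <- function(rows) {
  rows <- tibble::as_tibble(rows)
  X <- component_matrix(rows)
  if (nrow(X) < 4) stop("need at least 4 benchmark rows")
  if (!"E_ref" %in% names(rows)) stop("benchmark rows must have E_ref")
  y <- rows$E_ref
  check_rank(X)
  XtX <- crossprod(X)
  k <- drop(solve(XtX, crossprod(X, y)))
  names(k) <- c("k_ele", "k_pol", "k_dis", "k_rep")
  dev <- drop(X %*% k) - y # model - reference
  dof <- max(nrow(X) - 4L, 1L)
  s2 <- sum(dev^2) / dof
  covk <- s2 * solve(XtX)
  stats_all <- fit_statistics(dev)
  stats_all$subset <- "all"
  per <- if ("subset" %in% names(rows)) {
    dplyr::bind_rows(lapply(split(dev, rows$subset), function(d) {
      fit_statistics(d)
    }), .id = "subset")
  } else NULL
  statistics <- dplyr::bind_rows(stats_all, per)
  statistics <- statistics[, c("subset", "n", "MAD", "MD", "RMSD",
                               "min", "max")]
  structure(list(
    k = k,
    statistics = tibble::as_tibble(statistics),
    correlation = stats::cov2cor(covk),
    std_error = sqrt(diag(covk)),
    residual_sd = sqrt(s2),
    deviations = dev,
    n = nrow(X)), class = "ce_fit_result")
}

#' @export
print.ce_fit_result <- function(x, ...) {
  cat(sprintf("<ce_fit_result n=%d: k_ele %.3f, k_pol %.3f, k_dis %.3f, k_rep %.3f; RMSD %.2f kJ/mol>\n",
              x$n, x$k[1], x$k[2], x$k[3], x$k[4],
              x$statistics$RMSD[x$statistics$subset == "all"]))
  invisible(x)
}

#' Tidy a scale-factor fit (broom-style)
#' @param x A `ce_fit_result`.
#' @param ... Ignored.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @exportS3Method generics::tidy
tidy.ce_fit_result <- function(x, ...) {
  tibble::tibble(term = names(x$k), estimate = unname(x$k),
                 std.error = unname(x$std_error))
}

#' One-row fit summary (broom-style)
#' @param x A `ce_fit_result`.
#' @param ... Ignored.
#' @return One-row tibble with `nobs`, `MAD`, `MD`, `RMSD`, `sigma`.
#' @exportS3Method generics::glance
glance.ce_fit_result <- function(x, ...) {
  all <- x$statistics[x$statistics$subset == "all", ]
  tibble::tibble(nobs = x$n, MAD = all$MAD, MD = all$MD, RMSD = all$RMSD,
                 sigma = x$residual_sd)
}

#' Correlation matrix of the fitted scale factors
#'
#' Correlation of the OLS parameter estimates from the scaled inverse
#' normal-equations matrix.
#'
#' @param rows Benchmark rows as for [fit_scale_factors()].
#' @return Symmetric 4 x 4 matrix with unit diagonal.
#' @export
parameter_correlation <- function(rows) {
  X <- component_matrix(tibble::as_tibble(rows))
  check_rank(X)
  m <- stats::cov2cor(solve(crossprod(X)))
  dimnames(m) <- list(c("k_ele", "k_pol", "k_dis", "k_rep"),
                      c("k_ele", "k_pol", "k_dis", "k_rep"))
  m
}

#' Box-plot statistics with mean +/- one standard deviation whiskers
#'
#' Quartiles use the linear-interpolation convention
#' ([stats::quantile()] type 7); whiskers extend one standard deviation
#' from the mean, and every deviation beyond the whiskers is listed
#' individually as an outlier.
#'
#' @param deviations Numeric vector, or data frame with columns
#'   `deviation` and `group`.
#' @param group Optional grouping vector parallel to `deviations`.
#' @return Tibble with one row per group: `group`, `n`, `q1`, `median`,
#'   `q3`, `mean`, `sd`, `whisker_lo`, `whisker_hi` and list-column
#'   `outliers`.
#' @export
boxplot_stats <- function(deviations, group = NULL) {
  if (is.data.frame(deviations)) {
    group <- deviations$group
    deviations <- deviations$deviation
  }
  if (is.null(group)) group <- rep("all", length(deviations))
  if (length(deviations) == 0) stop("empty deviation vector")
  parts <- split(deviations, group)
  if (any(vapply(parts, length, integer(1)) == 0)) stop("empty group")
  rows <- lapply(names(parts), function(g) {
    d <- parts[[g]]
    q <- stats::quantile(d, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    m <- mean(d)
    s <- stats::sd(d)
    if (is.na(s)) s <- 0
    tibble::tibble(group = g, n = length(d), q1 = q[1], median = q[2],
                   q3 = q[3], mean = m, sd = s,
                   whisker_lo = m - s, whisker_hi = m + s,
                   outliers = list(sort(d[d < m - s | d > m + s])))
  })
  dplyr::bind_rows(rows)
}

#' Counterpoise-corrected supermolecule benchmark energy
#'
#' Reference interaction energy in the style used to calibrate the model:
#' `E(AB, dimer basis) - E(A, dimer basis with ghosts on B) - E(B, dimer
#' basis with ghosts on A)` plus the intermolecular D2 dispersion term.
#' Two open-shell monomers are combined high-spin.
#'
#' @param mol_a,mol_b `ce_molecule` objects at the dimer geometry.
#' @param theory A [theory_spec()] (the packaged calibration used
#'   `theory_spec("ce-b3lyp")`).
#' @param dispersion [dispersion_params()] added to the supermolecule
#'   electronic interaction energy.
#' @return Energy in kJ/mol.
#' @export
benchmark_pair_energy <- function(mol_a, mol_b,
                                  theory = theory_spec("ce-b3lyp"),
                                  dispersion = dispersion_params()) {
  with_ghosts <- function(real, ghosted) {
    atoms <- dplyr::bind_rows(
      dplyr::mutate(real$atoms[, c("element", "x", "y", "z")], ghost = FALSE),
      dplyr::mutate(ghosted$atoms[, c("element", "x", "y", "z")], ghost = TRUE))
    ce_molecule(atoms, charge = real$charge,
                multiplicity = real$multiplicity,
                label = paste0(real$label, "+ghost"))
  }
  ua <- mol_a$multiplicity - 1L
  ub <- mol_b$multiplicity - 1L
  dimer <- ce_molecule(
    dplyr::bind_rows(mol_a$atoms[, c("element", "x", "y", "z")],
                     mol_b$atoms[, c("element", "x", "y", "z")]),
    charge = mol_a$charge + mol_b$charge,
    multiplicity = ua + ub + 1L, # high-spin combination
    label = paste0(mol_a$label, "+", mol_b$label))
  e_ab <- compute_wavefunction(dimer, theory)$energy
  e_a <- compute_wavefunction(with_ghosts(mol_a, mol_b), theory)$energy
  e_b <- compute_wavefunction(with_ghosts(mol_b, mol_a), theory)$energy
  (e_ab - e_a - e_b) * HARTREE_KJMOL + e_dispersion(mol_a, mol_b, dispersion)
}
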