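test_that("zero-noise fit recovers the true factors exactly", {
  k_true <- c(1.0, 0.5, 0.9, 0.6)
  rows <- make_benchmark_table(k_true, n = 100, noise_sd = 0, seed = 7)
  fit <- fit_scale_factors(rows)
  expect_lt(max(abs(fit$k - k_true)), 1e-10)
  expect_lt(max(abs(fit$deviations)), 1e-8)
})

test_that("noisy fit recovers factors within 3 standard errors", {
  k_true <- c(1.057, 0.740, 0.871, 0.618)
  rows <- make_benchmark_table(k_true, n = 500, noise_sd = 2, seed = 42)
  fit <- fit_scale_factors(rows)
  expect_true(all(abs(fit$k - k_true) <= 3 * fit$std_error))
  # residual scale near the injected noise
  expect_lt(abs(fit$residual_sd - 2), 0.5)
})

test_that("fit statistics match their definitions", {
  k_true <- c(1, 1, 1, 1)
  rows <- make_benchmark_table(k_true, n = 200, noise_sd = 3, seed = 3)
  fit <- fit_scale_factors(rows)
  d <- fit$deviations
  s_all <- fit$statistics[fit$statistics$subset == "all", ]
  expect_equal(s_all$MAD, mean(abs(d)))
  expect_equal(s_all$MD, mean(d))
  expect_equal(s_all$RMSD, sqrt(mean(d^2)))
  expect_equal(s_all$min, min(d))
  expect_equal(s_all$max, max(d))
  # inequalities that hold for any deviation set
  expect_gte(s_all$RMSD, abs(s_all$MD))
  expect_gte(s_all$MAD, abs(s_all$MD))
  # per-subset rows cover the four generator subsets
  expect_setequal(setdiff(fit$statistics$subset, "all"),
                  c("neutral", "organic-salt", "metal-organic",
                    "open-shell"))
  # deviations are model minus reference
  X <- as.matrix(rows[, c("E_ele", "E_pol", "E_dis", "E_rep")])
  expect_equal(d, drop(X %*% fit$k) - rows$E_ref)
  # MD equals the analytic OLS residual mean for this design
  expect_equal(s_all$MD, mean(drop(X %*% fit$k) - rows$E_ref))
})

test_that("fit_statistics handles the documented examples and errors", {
  s <- fit_statistics(c(1, -1))
  expect_equal(c(s$MAD, s$MD, s$RMSD), c(1, 0, 1))
  s2 <- fit_statistics(c(2, 2, 2))
  expect_equal(c(s2$MAD, s2$MD, s2$RMSD), c(2, 2, 2))
  set.seed(11)
  s3 <- fit_statistics(stats::rnorm(1e4, 0, 5))
  expect_lt(abs(s3$RMSD - 5) / 5, 0.02)
  expect_error(fit_statistics(numeric(0)), "empty")
  expect_error(fit_statistics(c(1, NA)), "non-finite")
})

test_that("fitting is scale-consistent in each component column", {
  k_true <- c(1.0, 0.5, 0.9, 0.6)
  rows <- make_benchmark_table(k_true, n = 100, noise_sd = 1, seed = 5)
  fit <- fit_scale_factors(rows)
  rows2 <- rows
  rows2$E_pol <- rows2$E_pol * 4
  fit2 <- fit_scale_factors(rows2)
  expect_equal(fit2$k[["k_pol"]], fit$k[["k_pol"]] / 4, tolerance = 1e-10)
  expect_equal(fit2$k[["k_ele"]], fit$k[["k_ele"]], tolerance = 1e-10)
})

test_that("rank deficiency errors name the collinear column", {
  rows <- make_benchmark_table(c(1, 1, 1, 1), n = 50, seed = 2)
  rows$E_pol <- 2 * rows$E_ele
  expect_error(fit_scale_factors(rows), "collinear")
  expect_error(parameter_correlation(rows), "collinear")
  expect_error(fit_scale_factors(rows[0, ]), "at least 4")
  rows2 <- make_benchmark_table(c(1, 1, 1, 1), n = 50, seed = 2)
  rows2$E_ref <- NULL
  expect_error(fit_scale_factors(rows2), "E_ref")
})

test_that("parameter correlation matrix properties", {
  rows <- make_benchmark_table(c(1, 1, 1, 1), n = 200, seed = 9)
  m <- parameter_correlation(rows)
  expect_equal(dim(m), c(4, 4))
  expect_equal(diag(m), rep(1, 4), ignore_attr = TRUE)
  expect_equal(m, t(m))
  # orthogonal regressors -> vanishing off-diagonals
  X <- diag(4)[rep(1:4, 25), ]
  rows_orth <- tibble::tibble(E_ele = X[, 1], E_pol = X[, 2],
                              E_dis = X[, 3], E_rep = X[, 4],
                              E_ref = rowSums(X))
  m2 <- parameter_correlation(rows_orth)
  expect_lt(max(abs(m2[upper.tri(m2)])), 1e-12)
})

test_that("boxplot statistics use mean +/- one SD whiskers", {
  s <- boxplot_stats(c(-2, -1, 0, 1, 2))
  expect_equal(s$median, 0)
  expect_equal(s$mean, 0)
  expect_equal(s$whisker_hi, stats::sd(c(-2, -1, 0, 1, 2)))
  # quartiles by linear interpolation (type 7)
  q <- boxplot_stats(1:8)
  expect_equal(c(q$q1, q$median, q$q3), c(2.75, 4.5, 6.25))
  # a single extreme value beyond mean + SD appears as an outlier
  d <- c(rep(0, 20), 30)
  s2 <- boxplot_stats(d)
  expect_equal(s2$outliers[[1]], 30)
  # outliers are exactly the points beyond the whiskers
  set.seed(4)
  dv <- stats::rnorm(500)
  s3 <- boxplot_stats(dv)
  expect_setequal(s3$outliers[[1]],
                  dv[dv < s3$mean - s3$sd | dv > s3$mean + s3$sd])
  # grouped input as a data frame
  g <- boxplot_stats(data.frame(deviation = c(1, 2, 3, 10, 20, 30),
                                group = rep(c("a", "b"), each = 3)))
  expect_equal(nrow(g), 2)
  expect_equal(g$median, c(2, 20))
  expect_error(boxplot_stats(numeric(0)), "empty")
})

test_that("tidy and glance summarize a fit", {
  rows <- make_benchmark_table(c(1, 0.5, 0.9, 0.6), n = 80, noise_sd = 1,
                               seed = 6)
  fit <- fit_scale_factors(rows)
  td <- generics::tidy(fit)
  expect_equal(td$term, c("k_ele", "k_pol", "k_dis", "k_rep"))
  expect_equal(td$estimate, unname(fit$k))
  expect_true(all(td$std.error > 0))
  gl <- generics::glance(fit)
  expect_equal(gl$nobs, 80)
  expect_equal(gl$RMSD,
               fit$statistics$RMSD[fit$statistics$subset == "all"])
  expect_output(print(fit), "ce_fit_result")
})

test_that("counterpoise benchmark energy matches an independent oracle", {
  d <- make_dimer("he", 3.0)
  e_pkg <- benchmark_pair_energy(d$a, d$b, theory_spec("ce-hf"))
  # independent pure-R counterpoise computation on the same basis
  wa <- compute_wavefunction(d$a, theory_spec("ce-hf"))
  wb <- compute_wavefunction(d$b, theory_spec("ce-hf"))
  sh <- c(wa$shells, wb$shells)
  pos <- cbind(wa$pos, wb$pos)
  e_ab <- oracle_rhf(sh, pos, c(2, 2), nocc = 2)
  e_a <- oracle_rhf(sh, pos, c(2, 0), nocc = 1) # ghosts on B
  e_b <- oracle_rhf(sh, pos, c(0, 2), nocc = 1) # ghosts on A
  p <- dispersion_params()
  e_oracle <- (e_ab - e_a - e_b) * HARTREE +
    oracle_d2("He", matrix(c(0, 0, 0), 1), "He", matrix(c(3, 0, 0), 1),
              p$C6, p$Rvdw)
  expect_lt(abs(e_pkg - e_oracle), 0.01)
})

test_that("counterpoise energy is swap-symmetric and vanishes far away", {
  d <- make_dimer("h2", 4.0)
  e1 <- benchmark_pair_energy(d$a, d$b, theory_spec("ce-hf"))
  e2 <- benchmark_pair_energy(d$b, d$a, theory_spec("ce-hf"))
  expect_equal(e1, e2, tolerance = 1e-8)
  dfar <- make_dimer("he", 200)
  expect_lt(abs(benchmark_pair_energy(dfar$a, dfar$b,
                                      theory_spec("ce-hf"))), 0.01)
})
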