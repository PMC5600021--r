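hf_wfn <- function(mol) compute_wavefunction(mol, theory_spec("ce-hf"))

mono <- function(el, x, charge = 0L) {
  ce_molecule(tibble::tibble(element = el, x = x, y = 0, z = 0),
              charge = charge)
}

test_that("packaged energy models carry the calibrated factors", {
  b3 <- energy_model("ce-b3lyp")
  expect_equal(unname(b3$k), c(1.057, 0.740, 0.871, 0.618))
  hf <- energy_model("ce-hf")
  expect_equal(unname(hf$k), c(1.019, 0.651, 0.901, 0.811))
  custom <- energy_model("ce-hf", k = c(1, 0.5, 0.9, 0.6))
  expect_equal(unname(custom$k), c(1, 0.5, 0.9, 0.6))
  expect_error(energy_model("ce-hf", k = c(1, 2)))
})

test_that("polarizability table reproduces the packaged ion values", {
  tb <- polarizability_table()
  val <- function(el, cl) tb$alpha[tb$element == el & tb$class == cl]
  expect_equal(val("Li", "cation"), 0.190)
  expect_equal(val("Na", "cation"), 0.986)
  expect_equal(val("Ca", "cation"), 3.2)
  expect_equal(val("F", "anion"), 7.25)
  expect_equal(val("Cl", "anion"), 21.2)
  expect_equal(val("Br", "anion"), 27.9)
  expect_equal(val("I", "anion"), 39.6)
  expect_equal(val("Li", "neutral"), 164.0)
  expect_equal(val("F", "neutral"), 3.70)
  # every cation alpha is far below the neutral-atom alpha
  cats <- tb[tb$class == "cation" & tb$element != "H", ]
  for (i in seq_len(nrow(cats))) {
    expect_lt(cats$alpha[i], val(cats$element[i], "neutral"))
  }
})

test_that("point-charge electrostatics reproduces Coulomb's law", {
  wa <- hf_wfn(mono("H", 0, 1L))
  wb <- hf_wfn(mono("H", 8.175, 1L))
  e <- e_electrostatic(wa, wb)
  expect_equal(e, 2625.499 * 0.529177 / 8.175, tolerance = 1e-10)
})

test_that("all four terms are symmetric under monomer swap", {
  d <- make_dimer("he", 2.5)
  wa <- hf_wfn(d$a); wb <- hf_wfn(d$b)
  expect_equal(e_electrostatic(wa, wb), e_electrostatic(wb, wa),
               tolerance = 1e-10)
  expect_equal(e_polarization(wa, wb), e_polarization(wb, wa),
               tolerance = 1e-10)
  expect_equal(e_dispersion(d$a, d$b), e_dispersion(d$b, d$a))
  expect_equal(e_exchange_repulsion(wa, wb), e_exchange_repulsion(wb, wa),
               tolerance = 1e-8)
})

test_that("terms are invariant under rigid motion of the whole dimer", {
  sep <- 3.0
  d <- make_dimer("h2o", sep)
  th <- 0.6
  rot <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  move <- function(m) transform_molecule(m, rot = rot, shift = c(0.7, -1, 2))
  cmp <- function(a, b) {
    wa <- hf_wfn(a); wb <- hf_wfn(b)
    ctx <- dimer_integral_context(wa, wb)
    c(e_electrostatic(wa, wb, ctx), e_polarization(wa, wb),
      e_dispersion(a, b), e_exchange_repulsion(wa, wb, ctx))
  }
  c1 <- cmp(d$a, d$b)
  c2 <- cmp(move(d$a), move(d$b))
  expect_lt(max(abs(c1 - c2)), 0.01)
})

test_that("dispersion equals the closed-form pair sum", {
  p <- dispersion_params()
  a <- mono("C", 0); b <- mono("C", 4)
  expect_equal(e_dispersion(a, b, p),
               oracle_d2("C", matrix(c(0, 0, 0), 1), "C",
                         matrix(c(4, 0, 0), 1), p$C6, p$Rvdw),
               tolerance = 1e-12)
  # multi-atom case
  d <- make_dimer("h2o", 3.4, orientation = c(0.3, 0.2, 0.1))
  expect_equal(e_dispersion(d$a, d$b, p),
               oracle_d2(d$a$atoms$element, crystalce:::mol_coords(d$a),
                         d$b$atoms$element, crystalce:::mol_coords(d$b),
                         p$C6, p$Rvdw),
               tolerance = 1e-12)
  # R^-6 decay and strict negativity
  expect_lt(abs(e_dispersion(mono("C", 0), mono("C", 1000), p)), 1e-10)
  expect_lt(e_dispersion(a, b, p), 0)
  # missing element
  cs <- mono("Cs", 0)
  expect_error(e_dispersion(cs, b, p), "no D2 parameters")
})

test_that("polarization matches the analytic Coulomb-field closed form", {
  wl <- hf_wfn(mono("Li", 0, 1L))   # Li+ probe
  wp <- hf_wfn(mono("H", 5, 1L))    # bare +1 point charge
  f_au <- 1 / (5 / 0.529177)^2      # Coulomb field at the Li nucleus
  expect_equal(e_polarization(wl, wp),
               -0.5 * 0.190 * f_au^2 * 2625.499, tolerance = 1e-9)
})

test_that("neutral-atom alpha scales polarization by the table ratio", {
  wl_ion <- hf_wfn(mono("Li", 0, 1L))
  wl_neu <- hf_wfn(mono("Li", 0, 0L))
  wp <- hf_wfn(mono("H", 5, 1L))
  e_ion <- e_polarization(wl_ion, wp)
  e_neu <- e_polarization(wl_neu, wp)
  expect_equal(e_neu / e_ion, 164.0 / 0.190, tolerance = 1e-9)
  # the monatomic-ion override strictly reduces |E_pol|
  expect_lt(abs(e_ion), abs(e_neu))
  # and feeding the ion a neutral-alpha table restores the larger value
  tb <- polarizability_table()
  tb$alpha[tb$element == "Li" & tb$class == "cation"] <- 164.0
  expect_equal(e_polarization(wl_ion, wp, tb), e_neu, tolerance = 1e-9)
})

test_that("polarization is zero without a field and always <= 0", {
  d <- make_dimer("he", 500)
  wa <- hf_wfn(d$a); wb <- hf_wfn(d$b)
  expect_lt(abs(e_polarization(wa, wb)), 1e-6)
  d2 <- make_dimer("h2o", 3.0)
  expect_lte(e_polarization(hf_wfn(d2$a), hf_wfn(d2$b)), 0)
  # missing table entry errors with the element named
  tb <- polarizability_table()
  tb <- tb[!(tb$element == "He" & tb$class == "neutral"), ]
  expect_error(e_polarization(wa, wb, tb), "He")
})

test_that("ion-ion electrostatics approaches q_a q_b / R at long range", {
  wl <- hf_wfn(mono("Li", 0, 1L))
  wf <- hf_wfn(mono("F", 10, -1L))
  e <- e_electrostatic(wl, wf)
  point <- -1389.35 / 10
  expect_lt(abs(e - point) / abs(point), 0.01)
})

test_that("electrostatics matches the quadrature oracle for H densities", {
  wa <- hf_wfn(mono("H", 0))
  wb <- hf_wfn(mono("H", 10))
  expect_lt(abs(e_electrostatic(wa, wb) -
                  oracle_coulomb_spherical(wa, wb, 10)), 0.01)
  # neutral monomers at 200 A: essentially zero
  d <- make_dimer("he", 200)
  expect_lt(abs(e_electrostatic(hf_wfn(d$a), hf_wfn(d$b))), 0.001)
})

test_that("exchange-repulsion matches the independent Lowdin oracle", {
  d <- make_dimer("he", 2.5)
  wa <- hf_wfn(d$a); wb <- hf_wfn(d$b)
  orc <- oracle_exchrep(wa, wb)
  e <- e_exchange_repulsion(wa, wb)
  expect_lt(abs(e - orc$e_rep), 0.01)
  expect_gt(e, 0) # repulsive at contact
  # the same oracle's classical Coulomb agrees too
  expect_lt(abs(e_electrostatic(wa, wb) - orc$e_ele), 1e-6)
  # vanishes at 100 A
  d2 <- make_dimer("he", 100)
  expect_lt(abs(e_exchange_repulsion(hf_wfn(d2$a), hf_wfn(d2$b))), 0.001)
})

test_that("overlapping monomers raise a linear-dependence error", {
  d <- make_dimer("he", 1e-5)
  wa <- hf_wfn(d$a); wb <- hf_wfn(d$b)
  expect_error(e_exchange_repulsion(wa, wb), "linearly dependent")
})

test_that("open-shell monomers are pooled high-spin", {
  wa <- hf_wfn(mono("H", 0))
  wb <- hf_wfn(mono("H", 1.2))
  e <- e_exchange_repulsion(wa, wb)
  # oracle pools the two alpha spin orbitals -> explicit triplet coupling
  orc <- oracle_exchrep(wa, wb)
  expect_lt(abs(e - orc$e_rep), 1e-6)
  expect_gt(e, 0)
})

test_that("e_total combines components with the model factors", {
  z <- list(E_ele = 0, E_pol = 0, E_dis = 0, E_rep = 0)
  expect_equal(e_total(z, energy_model("ce-b3lyp"))$E_tot, 0)
  ones <- list(E_ele = 1, E_pol = 1, E_dis = 1, E_rep = 1)
  expect_equal(e_total(ones, energy_model("ce-b3lyp"))$E_tot, 3.286)
  expect_equal(e_total(ones, energy_model("ce-hf"))$E_tot, 3.382)
  # display value is whole kJ/mol
  out <- e_total(list(E_ele = -20.4, E_pol = -3.1, E_dis = -8.7,
                      E_rep = 12.2), energy_model("ce-b3lyp"))
  expect_equal(out$E_tot_display, round(out$E_tot))
  expect_error(e_total(list(E_ele = 1), energy_model("ce-hf")),
               "components must provide")
})

test_that("scale_components multiplies each column by its factor", {
  tbl <- tibble::tibble(E_ele = 2, E_pol = 3, E_dis = 5, E_rep = 7)
  m <- energy_model("ce-hf")
  out <- scale_components(tbl, m)
  expect_equal(out$E_ele, 2 * 1.019)
  expect_equal(out$E_pol, 3 * 0.651)
  expect_equal(out$E_dis, 5 * 0.901)
  expect_equal(out$E_rep, 7 * 0.811)
  # scaled components sum to E_tot of the unscaled set
  expect_equal(sum(unlist(out)),
               e_total(as.list(tbl), m)$E_tot)
})

test_that("pair_energy assembles a full record", {
  d <- make_dimer("he", 3.0)
  pe <- pair_energy(d$a, d$b, energy_model("ce-hf"))
  expect_s3_class(pe, "ce_pair_energy")
  expect_equal(pe$centroid_distance, 3)
  expect_equal(pe$E_tot,
               sum(energy_model("ce-hf")$k *
                     c(pe$E_ele, pe$E_pol, pe$E_dis, pe$E_rep)))
  expect_lte(pe$E_pol, 0)
  expect_lt(pe$E_dis, 0)
  expect_gt(pe$E_rep, 0)
})
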