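# crystalce

Pairwise intermolecular interaction energies for molecular crystals from
monomer wavefunctions, with energy-framework visualization, lattice-energy
summation and scale-factor calibration.

## The problem

What holds a molecular crystal together is a network of pairwise
molecule–molecule interactions: hydrogen bonds, electrostatic contacts,
dispersion and short-range repulsion. Counterpoise-corrected supermolecule
calculations give accurate pair energies but are far too expensive to
evaluate for every pair in a crystal. `crystalce` implements a model-energy
scheme in which each symmetry-unique molecule gets a single cheap SCF
wavefunction and every pair energy is assembled from those *unperturbed*
monomer wavefunctions — no dimer SCF ever runs.

The model is a calibrated four-term combination

```
E_tot = k_ele * E_ele + k_pol * E_pol + k_dis * E_dis + k_rep * E_rep
```

where

- `E_ele` — exact classical Coulomb energy between the two monomer charge
  distributions (nuclei + SCF density), via analytic integrals;
- `E_pol` — `-1/2 * sum_i alpha_i |F_i|^2` over atoms, with the partner's
  electric field at each nucleus; monatomic ions use ion-specific
  polarizabilities (Li+ 0.190 a.u. vs 164 a.u. for neutral Li);
- `E_dis` — Grimme D2 pairwise damped `-C6/R^6` dispersion;
- `E_rep` — energy of the antisymmetrized (Löwdin-orthonormalized) product
  of both monomers' occupied spin orbitals, relative to the monomers and
  with the classical Coulomb part removed; open-shell monomers are pooled
  high-spin.

Two packaged parameterizations:

| model    | monomer theory            | k_ele | k_pol | k_dis | k_rep |
|----------|---------------------------|-------|-------|-------|-------|
| ce-b3lyp | B3LYP/6-31G(d,p) (DGDZVP for heavy elements) | 1.057 | 0.740 | 0.871 | 0.618 |
| ce-hf    | HF/3-21G                  | 1.019 | 0.651 | 0.901 | 0.811 |

Everything needed is self-contained: a CIF reader with symmetry expansion,
molecule perception, X–H bond-length normalization, a compact
McMurchie–Davidson RHF/UHF/B3LYP engine (C++ via Rcpp/RcppArmadillo),
energy-framework graphs, converged lattice sums and OLS calibration
machinery, plus deterministic synthetic fixtures for offline testing.

## Worked example

A water dimer at 3.0 Å centroid separation under both models:

```r
library(crystalce)

d <- make_dimer("h2o", 3.0)
th <- theory_spec("ce-hf")
wa <- compute_wavefunction(d$a, th)
wb <- compute_wavefunction(d$b, th)

e_electrostatic(wa, wb)            # -9.708 kJ/mol
e_polarization(wa, wb)             # -5.294 kJ/mol
e_dispersion(d$a, d$b)             # -3.532 kJ/mol
e_exchange_repulsion(wa, wb)       # 12.044 kJ/mol

pair_energy(d$a, d$b, energy_model("ce-hf"))$E_tot     # -6.753 kJ/mol
```

The same dimer under `ce-b3lyp` gives `E_ele = -9.248`, `E_pol = -3.868`,
`E_rep = 14.938` and `E_tot = -6.482` kJ/mol. Two +1 point charges at
8.175 Å give exactly `1389.354/8.175 = 169.95 kJ/mol`, the closed-form
Coulomb value.

A full crystal pipeline on a packaged deterministic fixture:

```r
cif  <- make_toy_crystal(fixture_spec("molecular_lattice",
                                      template = "water", a = 6, b = 6, c = 6))
path <- tempfile(fileext = ".cif"); writeLines(cif, path)
crystal <- normalize_xh(read_cif(path))

pairs <- pair_energy_table(crystal, energy_model("ce-hf"), contact_radius = 5)
pairs$E_tot                 # -0.481 kJ/mol (nearest-neighbour pair, x2)

fw <- build_framework(pairs, "tot", cutoff = 0)   # cylinder graph
export_scene(fw, "framework.json", "json")        # or "obj"

lattice_energy(crystal, energy_model("ce-hf"), r_max = 14, tol = 0.5)
# lattice energy -0.573 kJ/mol, converged
```

Calibration machinery on a synthetic benchmark with known factors:

```r
rows <- make_benchmark_table(c(1.057, 0.740, 0.871, 0.618),
                             n = 500, noise_sd = 2, seed = 42)
fit <- fit_scale_factors(rows)
fit$k        # 1.0571 0.7400 0.8668 0.6141  (recovered within 3 SE)
fit$statistics[fit$statistics$subset == "all", c("MAD", "MD", "RMSD")]
#   MAD 1.52, MD 0.014, RMSD 1.93 kJ/mol
```

## Scope and limitations

- Basis sets are packaged for light main-group elements; heavier elements
  require user-supplied basis JSON files.
- Lattice sums are refused for ionic crystals (conditionally convergent).
- Polymeric/infinite covalent networks are refused by molecule perception.
- The model is calibrated for intermolecular pairs near packing distances;
  it is not a general potential energy surface.

See the vignette (`vignettes/crystalce-methods.Rmd`) for the model,
numerics and fixture-generator details.
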