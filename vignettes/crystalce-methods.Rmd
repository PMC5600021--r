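---
title: "Model interaction energies in molecular crystals with crystalce"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model interaction energies in molecular crystals with crystalce}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crystalce)
```

## The scientific problem

The cohesion of a molecular crystal is set by the pairwise interactions
between whole molecules: hydrogen bonds, ion--ion attraction, dispersion
contacts and short-range repulsion.  Fully first-principles interaction
energies (counterpoise-corrected supermolecule calculations) are accurate
but far too slow to scan every molecular pair in a crystal, let alone
whole families of structures.  `crystalce` implements a model-energy
scheme that keeps quantum-mechanical monomer information but avoids any
dimer self-consistent-field work: each symmetry-unique molecule gets one
cheap wavefunction, and every pairwise interaction energy is assembled
from those *unperturbed* monomer wavefunctions.

The model energy is a fixed linear combination of four physically
motivated terms,

$$E_\mathrm{tot} \;=\; k_\mathrm{ele}\,E_\mathrm{ele}
  \;+\; k_\mathrm{pol}\,E_\mathrm{pol}
  \;+\; k_\mathrm{dis}\,E_\mathrm{dis}
  \;+\; k_\mathrm{rep}\,E_\mathrm{rep},$$

with scale factors $k$ calibrated once against counterpoise-corrected
benchmark energies.  Two parameterizations are packaged:

* **ce-b3lyp** -- monomer wavefunctions at B3LYP/6-31G(d,p) (DGDZVP for
  heavy elements), $k = (1.057, 0.740, 0.871, 0.618)$;
* **ce-hf** -- monomer wavefunctions at HF/3-21G,
  $k = (1.019, 0.651, 0.901, 0.811)$.

## The four terms

**Electrostatics** $E_\mathrm{ele}$ is the exact classical Coulomb energy
between the two monomer charge distributions (nuclei plus SCF electron
density), evaluated analytically with two-electron integrals over the
union basis — no multipole truncation.

**Polarization** $E_\mathrm{pol} = -\tfrac12 \sum_i \alpha_i
\lvert F_i\rvert^2$ sums over atoms $i$ of each molecule, where $F_i$ is
the electric field of the *partner* monomer at nucleus $i$ and
$\alpha_i$ an isotropic atomic polarizability.  Monatomic ions use
ion-specific polarizabilities (e.g. Li$^+$ 0.190 a.u. versus 164 a.u. for
neutral lithium): a bare cation is far stiffer than the neutral atom, and
using the neutral value would wildly overestimate the term.

**Dispersion** $E_\mathrm{dis}$ is Grimme's D2 pairwise sum
$-s_6 \sum_{ij} f_\mathrm{dmp}(R_{ij})\, C_{6,ij} / R_{ij}^6$ over
intermolecular atom pairs with $C_{6,ij} = \sqrt{C_{6,i} C_{6,j}}$ and a
sigmoidal damping $f_\mathrm{dmp}(R) = (1 + e^{-d(R/R_r - 1)})^{-1}$.

**Exchange--repulsion** $E_\mathrm{rep}$ is the energy of the
antisymmetrized product of the two monomers' occupied spin orbitals,
relative to the separated monomers and with the classical Coulomb part
removed.  The pooled occupied orbitals are symmetrically (Löwdin)
orthonormalized and a single determinant energy is evaluated with the
dimer Hamiltonian.  Two open-shell monomers are pooled *high-spin*: the
unpaired spins are aligned, so two doublets are treated as a triplet
pair.  If the pooled occupied orbitals become numerically linearly
dependent (overlapping monomers), the term refuses to produce a number
rather than returning a huge ill-conditioned value.

## Numerical design

* Integrals are McMurchie--Davidson Hermite Gaussians (Cartesian
  functions, 6 d-components), implemented in C++ with Armadillo.
* The SCF is a conventional closed-shell RHF / open-shell UHF with DIIS
  acceleration.  The B3LYP exchange-correlation energy is integrated on
  an atom-centered Becke-partitioned grid (Murray--Handy--Laming radial
  points, Gauss--Legendre angular product grid).
* Wavefunctions are cached by geometry, so a crystal with one unique
  molecule costs one SCF regardless of how many pairs are evaluated.
* All energies are reported in kJ/mol; totals also carry a rounded
  display value, since the model's calibrated accuracy (a few kJ/mol)
  makes sub-kJ digits noise for interpretation.

## From CIF to energies

The crystal pipeline is:

1. `read_cif()` parses cell, symmetry operators and atom sites (P1
   expansion via `expand_symmetry()`);
2. `perceive_molecules()` builds covalent connectivity (sum of covalent
   radii + 0.4 Å), completes molecules across cell boundaries and merges
   symmetry-equivalent copies by distance fingerprint; infinite
   (polymeric) networks are refused;
3. `normalize_xh()` moves hydrogens along their X--H bond vectors to
   standard neutron distances (X-ray positions systematically
   underestimate them);
4. `pair_energy_table()` builds the neighbor cluster of each unique
   molecule, merges symmetry-equivalent pairs (recording multiplicities)
   and computes the four terms per unique pair;
5. `build_framework()` turns the table into an energy-framework graph:
   cylinders join molecular centroids with radius
   $\lvert E \rvert / \texttt{cylinder\_scale}$, colored red
   (electrostatic), green (dispersion) or blue (total), and yellow for
   destabilizing (positive) electrostatic or total energies; pairs with
   $\lvert E\rvert$ below the cutoff (default 15 kJ/mol) are omitted.
   Scenes export to JSON or Wavefront OBJ;
6. `lattice_energy()` performs the pairwise lattice sum in radial shells
   until two consecutive shell increments fall below tolerance.  Ionic
   crystals are refused: a pairwise sum over bare ions is conditionally
   convergent and its value depends on summation order.

## A worked example

```{r example, eval = FALSE}
library(crystalce)

# a deterministic water crystal fixture (P1, 6 Angstrom cubic cell)
cif <- make_toy_crystal(fixture_spec("molecular_lattice",
                                     template = "water",
                                     a = 6, b = 6, c = 6))
path <- tempfile(fileext = ".cif")
writeLines(cif, path)
crystal <- normalize_xh(read_cif(path))

# symmetry-unique pair energies under the HF parameterization
pairs <- pair_energy_table(crystal, energy_model("ce-hf"),
                           contact_radius = 5)
pairs[, c("E_ele", "E_pol", "E_dis", "E_rep", "E_tot",
          "multiplicity_count", "centroid_distance")]

# an energy framework and a converged lattice sum
fw <- build_framework(pairs, "tot", cutoff = 0)
ggplot2::autoplot(fw)
lattice_energy(crystal, energy_model("ce-hf"), r_max = 14, tol = 0.5)
```

## Calibration machinery

`fit_scale_factors()` reproduces the calibration protocol on any
benchmark table with columns `E_ele`, `E_pol`, `E_dis`, `E_rep` and a
reference energy `E_ref`: an unweighted, no-intercept ordinary least
squares fit (the model has no constant term), with deviation statistics
(MAD, MD, RMSD) reported overall and per subset, a parameter correlation
matrix, and boxplot summaries using mean ± one standard deviation
whiskers.  `benchmark_pair_energy()` computes counterpoise-corrected
supermolecule reference energies (ghost-atom monomer calculations in the
dimer basis plus the intermolecular D2 term) so users can regenerate
references at the packaged levels of theory.

## Synthetic fixtures and their realism

The package generates its own test inputs instead of shipping third-party
crystal structures:

* toy crystals (`make_toy_crystal()`): cubic point lattices, CsCl-type
  ion lattices, water/glycine molecular lattices in P 1 or P 21/c, and an
  NO radical cell — small enough for desk-scale SCF but exercising
  symmetry expansion, boundary-split molecules and charge assignment;
* rigid dimers (`make_dimer()`) from fixed literature-standard geometries
  (e.g. water r(OH) = 0.9572 Å, HOH angle 104.52°);
* benchmark tables (`make_benchmark_table()`) with component columns
  drawn from documented ranges mimicking the four calibration subsets —
  including an organic-salt block whose reference energies reach
  ±1900 kJ/mol, an order of magnitude beyond the neutral block — and
  `E_ref` constructed from known factors plus Gaussian noise, so the
  fitting machinery can be validated against ground truth.

Identical fixture spec and seed always produce byte-identical output,
and generators save and restore the global RNG state.

## Limitations

* Basis sets are packaged for the light main-group elements; heavier
  elements need user-supplied basis files in the same JSON layout.
* The lattice sum is for neutral molecules only (no Ewald machinery).
* Single-determinant monomer wavefunctions only; no symmetry beyond the
  supplied operators is inferred; disorder and partial occupancies in
  CIFs are not handled.
* The model energy is calibrated for intermolecular pairs near
  equilibrium packing distances; it is not a potential energy surface
  for arbitrary geometries, and the scaled terms have no meaning for
  covalently bonded fragments.
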