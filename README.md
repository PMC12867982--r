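# lidfold

Ensemble-thermodynamics analysis of ligand-induced folding of a disordered
protein segment, for structural biophysicists who want the full chain —
biased sampling, free-energy surfaces, structural observables, entropy
estimates, calorimetry models and NMR profiles — as one tested R package.

The motivating system is an intrinsically disordered "lid" flanking a
structured, druggable domain (the MDM2 N-terminal lid is the archetype):
some ligands order the lid into a helical motif on binding, and a single
non-polar residue–ligand contact can decide whether that disorder-to-order
transition happens at all. The package ships a coarse-grained lid-peptide
model that encodes exactly this mechanism with known ground truth, and the
analysis layers that turn conformational ensembles and titration data into
thermodynamic statements.

## What is inside

**Synthetic lid system.** A CA-trace chain (fixed 3.8 Å pseudo-bonds, 91°
pseudo-angles) with a two-basin torsion potential
(helix θ_H = 50°, coil θ_C = 180°), nearest-neighbour cooperative coupling
−J Σ cos(θᵢ−θᵢ₊₁), and an optional rigid three-particle ligand in a
flat-bottom binding box whose contact site rewards proximity to one lid
residue: U = Σ V_tor(θᵢ) − J Σ cos(θᵢ−θᵢ₊₁) − ε·S(d_contact) + U_box.
Setting ε = 0 is the "contact-deleted mutant". Metropolis sampling
(`sample_ensemble()`), umbrella windows (`generate_bias_windows()`),
synthetic ITC isotherms and NMR shift tables all derive from it.

**Free-energy surfaces** over (lid extension, lid–core dihedral):
`wham2d()` (periodic-aware histogram reweighting), `mbar_weights()`
(binless multistate reweighting), `spline_fes()` (variational
tensor-product spline likelihood), `basin_free_energies()`
(ΔG_region = −k_BT log Σ e^{−F/k_BT} relative to the lowest region).

**Observables.** Kabsch–Sander-style H-bond secondary structure and a
torsion-window assigner (`assign_secondary_structure()`), helix propensity
with block-averaged σ_E (`helix_propensity()`), Kabsch-superposed RMSF
(`rmsf()`), Shrake–Rupley SASA (`sasa()`) and hydrophobic-SASA changes
with bootstrap uncertainties.

**Entropy.** Kozachenko–Leonenko k-NN differential entropy with periodic
angular metrics (`knn_entropy()`), free-vs-bound conformational entropy
differences with a MIST-style adjacent-pair mutual-information correction
(`conformational_entropy_difference()`), and ligand roto-translational
entropy losses against the 1 M standard state (1661 Å³) and the uniform
SO(3) measure (`ligand_rototranslational_entropy()`).

**ITC.** Exact one-site and competitive-displacement forward models with
perfusion dilution bookkeeping, Levenberg–Marquardt fitting, Wiseman-c
diagnostics, and the exact signature decomposition
ΔG = RT ln K_D = ΔH − TΔS (`one_site_heats()`, `fit_one_site()`,
`fit_competitive()`, `thermodynamic_signature()`).

**NMR.** Combined ¹H/¹⁵N CSPs (α = 0.14), secondary ¹³Cα/¹³CO shifts
against a shipped random-coil reference, ΔhetNOE profiles, sign-test trend
classification, and NMR-STAR import of assigned shifts.

**Pipeline.** `run_config()` + `run_pipeline()` run the four conditions
{apo, holo} × {wild-type analog, contact-deleted analog} from one seeded
configuration and summarise the orderings; results are deterministic and
stamped with a configuration hash.

## Worked example

Fit a synthetic isotherm generated at the standard protocol
(10 µM protein in the cell, 150 µM ligand in the syringe, 0.5 % heat
noise; truth: K_D = 50 nM, ΔH = −12 kcal/mol, n = 1):

```r
library(lidfold)
truth <- list(n = 1, kd_M = 5e-8, dh_kcal = -12)
titr  <- simulate_itc_isotherm(truth, noise_frac = 0.005, seed = 7)
fit   <- fit_one_site(titr)
fit
#> <binding_fit> one_site: n = 1, K_D = 46.7 nM, dH = -12 kcal/mol, dG = -10, -TdS = 2
thermodynamic_signature(fit)
#> # A tibble: 3 × 2
#>   quantity kcal_per_mol
#> 1 dG             -10.0
#> 2 dH             -12.0
#> 3 -TdS             2.00
```

The fitted K_D (46.7 nM) recovers the 50 nM truth within the noise, and
ΔG = ΔH + (−TΔS) holds exactly: binding is enthalpy-driven with a
2 kcal/mol entropic penalty.

Sample the bound lid with and without the stabilising contact and compare
helix propensity at the base of the lid (residues 21–25):

```r
wt  <- sample_ensemble(lid_system(ligand_present = TRUE),
                       60000, seed = 11, stride = 30)
mut <- sample_ensemble(lid_system(ligand_present = TRUE,
                                  contact_epsilon = 0),
                       60000, seed = 12, stride = 30)
prop <- function(e)
  helix_propensity(assign_secondary_structure(e, "torsion_window"),
                   residue_range = 21:25)
prop(wt)
#>   residue propensity sigma_e
#> 1      21     0.0965  0.0130
#> 2      22     0.130   0.0453
#> 3      23     0.137   0.0431
#> 4      24     0.318   0.144
#> 5      25     0.294   0.150
prop(mut)
#>   residue propensity sigma_e
#> 1      21     0.0195 0.00255
#> 2      22     0.0155 0.00330
#> 3      23     0.0135 0.00302
#> 4      24     0.0155 0.00278
#> 5      25     0.0115 0.00257
```

With the contact present the base of the lid is an order of magnitude more
helical than with the contact deleted — the folding-upon-binding mechanism
in one comparison. `run_pipeline(run_config(seed = 1))` runs the full
four-condition analysis (surfaces, SASA, entropies, shift tables) and
`compare_conditions()` tabulates the differences; the methods vignette
(`vignettes/lid-folding-thermodynamics.Rmd`) documents the model,
estimators and their numerical choices.

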