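# npcorona

Quantitative analysis of protein adsorption onto functionalised
nanoparticles (the "protein corona"), for researchers characterising
nanoparticle–protein interactions with structural models, isothermal
titration calorimetry (ITC) and circular dichroism (CD). The package
provides three tested, reusable pipelines:

1. **Structural simulation** — load a protein crystal structure under an
   explicit atom-selection policy, build a chemistry-free nanoparticle
   model (random atoms in a 20 nm cube), and compute replicated
   structural observables under Gaussian coordinate perturbation
   (σ = 0.1 nm by default):
   * unaligned RMSD, `sqrt(mean_i |r_i − r'_i|²)`, whose expectation
     under i.i.d. per-coordinate noise is `σ√3`;
   * radius of gyration, `R_g = sqrt(Σ w_i |r_i − r̄|² / Σ w_i)`;
   * minimum protein–nanoparticle interatomic distance (exact spatial
     index).
2. **One-site ITC isotherm fitting** — forward-model the single-site
   (Wiseman) isotherm with perfusion-cell displacement correction,
   `Q_i = (N·M_i·ΔH·V₀/2)·(b_i − sqrt(b_i² − 4·X_i/(N·M_i)))` with
   `b_i = 1 + X_i/(N·M_i) + 1/(N·K·M_i)`, subtract blank titrations, fit
   `(N, K, ΔH)` by Levenberg–Marquardt least squares with standard
   errors, and derive the entropic term
   `ΔS = (ΔH + R·T·ln K)/T` (R = 1.9872 cal mol⁻¹ K⁻¹).
3. **CD secondary-structure estimation** — synthesize far-UV
   (190–240 nm) mean-residue-ellipticity spectra from (α-helix, β-sheet,
   random-coil) fractions and estimate composition from a spectrum by
   exact least squares constrained to the 2-simplex, against a packaged
   reference basis — a transparent alternative to neural-network
   deconvolution.

Seeded synthetic-data generators (geometric clouds with analytic `R_g`,
thermograms with ground truth attached, CD titration series) make every
estimator testable end to end. See `vignettes/npcorona-methods.Rmd` for
the models, defaults and design rationale.

## Worked example

```r
library(npcorona)

## structural simulation on a synthetic globular decoy
prot <- generate_cloud("uniform-ball", 2000, size = 1.8, seed = 42)
protein_np_report(prot, np_atoms = 1000, gap = 0.1, sigma = 0.1,
                  n_replicates = 10, seed = 7)
#> <interaction_report> 10 replicates, sigma = 0.1 nm
#>   rmsd          0.1740 nm (sd 0.0023)
#>   rg            1.4101 nm (sd 0.0021)
#>   min_distance  0.1928 nm (sd 0.0600)
```

The mean RMSD sits at the analytic `σ√3 = 0.1732` nm for σ = 0.1 nm;
`rg` is the perturbed-protein radius of gyration (the unperturbed ball
of radius 1.8 nm has `R_g ≈ 1.8·√(3/5) ≈ 1.394` nm, inflated slightly
by the added noise), and the minimum distance fluctuates around the
constructed 0.1 nm surface gap.

```r
## simulate an albumin-design titration at 1% noise and refit it
sc <- itc_scenario("albumin")   # 28 x 10 uL, 1.42 mL cell, 310.15 K
g <- generate_itc(sc$params, sc$schedule, noise_sd = 0.01, seed = 3)
fit_one_site(g$thermogram)
#> <binding_parameters> one-site model at 310.15 K
#>   N  = 0.2462 +/- 0.000183 (g/g)
#>   K  = 8.722e+04 +/- 1.8e+04 (L/g)
#>   dH = -163.7 +/- 0.344 cal/g
#>   dS = 22.08 cal g-1 K-1 (derived)
```

The generating values were N = 0.246, K = 7.55e4, ΔH = −163.4 cal/g:
stoichiometry and enthalpy are recovered to a fraction of a percent,
while K carries the large standard error intrinsic to a very steep
(high-c) isotherm — see the methods vignette.

```r
## round-trip a known secondary-structure composition
sp <- synthesize_spectrum(ss_fractions(0.8759, 0.0048, 0.1193))
deconvolve(sp)$fractions
#> <ss_fractions> alpha 87.59%  beta 0.48%  coil 11.93%
```

A command-line wrapper over the same functions ships in
`inst/cli/npcorona-cli.R`
(`Rscript npcorona-cli.R perturb-analyze --pdb file.pdb --seed 7 --out report.json`).

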