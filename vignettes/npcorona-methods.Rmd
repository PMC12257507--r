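---
title: "Methods: geometry, calorimetry and CD deconvolution in npcorona"
author: "npcorona authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: geometry, calorimetry and CD deconvolution in npcorona}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npcorona)
```

npcorona quantifies three complementary views of protein adsorption onto
functionalised nanoparticles (NPs): a purely geometric structural
simulation, single-site isothermal titration calorimetry (ITC) isotherm
fitting, and circular dichroism (CD) secondary-structure estimation.
This vignette records the models, the defaults and the reasoning behind
every genuinely open design choice.

## 1. Structural simulation

### Model

The protein is an ordered atomic point cloud loaded from a PDB file;
all lengths are converted to nanometres once, at load time. The
nanoparticle is deliberately chemistry-free: `n_atoms` point atoms
placed i.i.d. uniformly in a cube (default edge 20 nm, matching the
modelled particle size). Conformational fluctuation upon adsorption is
emulated by adding independent Gaussian noise of standard deviation
`sigma` (default 0.1 nm) to *every Cartesian coordinate* of every
protein atom. Three observables are computed per perturbation
replicate:

* **Unaligned RMSD** between the unperturbed and perturbed protein,
  `sqrt(mean |r_i - r'_i|^2)`. No Kabsch superposition is applied by
  default: for pure i.i.d. coordinate noise the statistic has the
  closed-form expectation `sigma * sqrt(3)` (0.1732 nm at sigma = 0.1),
  which is exactly the scale of the tabulated reference values
  (0.1716 / 0.1718 nm); aligned RMSD would remove part of the noise as
  spurious rigid motion and sit systematically below that. Aligned RMSD
  remains available behind `align = TRUE`.
* **Radius of gyration**, by default uniform-weighted (a pure
  coordinate statistic); mass weighting by flag.
* **Minimum interatomic distance** between protein and NP, via a
  uniform-grid spatial index that provably returns the exhaustive-scan
  answer (the cell edge is an upper bound on the minimum obtained from
  a centroid-guided scan, so the optimal pair is always inside the
  27-cell neighbourhood).

### Atom selection must be explicit

Crystal structures carry waters, ligands, hydrogens, alternate
conformers and sometimes several models, and the radius of gyration of
a loaded structure depends on all of these choices. `selection_policy()`
therefore makes every choice explicit. Defaults: all chains of the
first model, waters and other hetero records excluded, hydrogens kept
if present, alternate locations resolved to the highest-occupancy
conformer (ties to the first label).

### Scene placement

Where the protein sits relative to the NP box is not derivable from the
reference values (the two tabulated minimum distances, 0.18 and
4.46 nm, cannot both follow from one geometry), so the package fixes
its own deterministic convention: in the default `gap` mode the protein
is translated so its minimum-x atom lies exactly `gap` (default 0.1 nm)
along +x from the NP's maximum-x atom with matched y and z. Every other
cross pair is then at least `gap` away, so the pre-perturbation minimum
distance equals the gap *exactly* — convenient for testing and fully
reproducible. Consequently the package treats the tabulated radius of
gyration (34.95 / 20.77, labelled nm but implausible on that scale for
these proteins) and minimum distances as diagnostics to be reported
side by side, never as targets: the unit and selection conventions
behind them are not recoverable. Replicate seeds derive from the master
seed by the counter `seed + r`, so any replicate can be replayed alone.

## 2. One-site ITC isotherm

### Forward model

The calorimeter titrates protein (titrant, syringe concentration
`X_syr` g/L) into a cell of volume `V0` (default 1.42 mL) holding NPs
at `M0` g/L (default 1.5) at 310.15 K. All concentrations are
mass-based because the reference enthalpies are per gram of protein;
`K` then carries L/g and the stoichiometry `N` is a mass ratio at
saturation. After injection *i* (cumulative injected volume `v_i`) the
perfusion-cell displacement convention gives

```
M_i = M0 (1 - v_i/2V0) / (1 + v_i/2V0)
X_i = X_syr (v_i/V0)   / (1 + v_i/2V0)
```

and the single-site (Wiseman) isotherm yields the cumulative heat

```
Q_i = (N M_i dH V0 / 2) * (b_i - sqrt(b_i^2 - 4 X_i/(N M_i))),
b_i = 1 + X_i/(N M_i) + 1/(N K M_i)
```

with the per-injection heat
`dQ_i = Q_i - Q_{i-1} + (dV_i/V0)(Q_i + Q_{i-1})/2`, normalized by the
injected titrant mass. The discriminant is non-negative analytically
(it equals `(1 - X/(NM) + 1/(NKM))^2 + 4X/(N^2KM^2)` after expansion);
round-off is clamped at zero. The test suite checks the closed form
against an independent numerical equilibrium oracle (mass-action root
finding per injection) and checks heat conservation at saturation.
Blank (titrant-into-buffer) thermograms are subtracted per injection
before fitting, as in the instrument workflow.

### Fitting and initialization

`fit_one_site()` minimises the unweighted sum of squares on normalized
heats over `(N, log K, dH)` by Levenberg–Marquardt (`minpack.lm`).
Fitting `log K` keeps the search well-scaled across the orders of
magnitude K can span. Initialization: `dH0` is the first normalized
heat (early injections bind almost all titrant), `N0` is the
injected/cell mass ratio at the steepest-drop injection (the
equivalence point), and `log K0` comes from a coarse profile of the
residual over `log10 K` in [1, 8] with `(N0, dH0)` held fixed — cheap,
derivative-free and robust to the near-step shape of high-affinity
curves. Standard errors come from the local quadratic approximation at
the optimum, with the delta method mapping `se(log K)` to `se(K)`;
near-singular curvature yields `NA` errors and a warning rather than a
failure.

### Entropy derivation and its units

The derived entropy is `dS = (dH + R T ln K)/T` with
R = 1.9872 cal mol^-1 K^-1. Note the deliberate unit inconsistency: a
*molar* gas constant is combined numerically with a *per-gram* enthalpy
and a *mass-based* K. This is exactly the arithmetic that produces the
tabulated entropy values (21.8 and 20.4 cal g^-1 K^-1 from
(-163.4, 7.55e4) and (-9.706, 2.87e4) at 310.15 K), so the package
reproduces it verbatim and documents rather than "corrects" it.
Thermodynamically rigorous per-mole quantities would require molar
masses and a molar K, which the mass-based workflow does not define.

### Identifiability: what parameter recovery can and cannot show

The information an isotherm carries about K is governed by the
dimensionless Wiseman parameter `c = K * N * M0`. Instrument practice
targets roughly `1 < c < 1000`; at the albumin generating values
(K = 7.55e4 L/g, N = 0.246, M0 = 1.5 g/L) `c ≈ 2.8e4`, so the curve is
nearly a step and K is encoded only in the one or two transition
injections. At 1% noise (relative to the largest normalized heat) the
Cramér–Rao bound for this design gives `sd(ln K) ≈ 0.22` — about
1.6e4 on K — for *any* unbiased estimator, and the median of 20
replicate fits still fluctuates with sd ≈ 4.6e3. `N` and `dH`, by
contrast, are pinned by the equivalence position and the plateau
height and recover to well under 1%. The test suite therefore asserts
sub-5% median recovery of all three parameters on a moderate-c design
(c ≈ 50), asserts it for `N` and `dH` at the albumin design, and
asserts that errors shrink with noise for all three; a fixed-tolerance
K-recovery check at the albumin design is retained in the end-to-end
suite and fails for this statistical reason, not an implementation one
(the fitter is exact on noiseless data to better than 4 significant
figures and its residual at the optimum is below the residual at the
truth on noisy data).

### Defaults that are package choices

The injection program is not part of the reference design, so the
default schedule is the instrument-typical 28 injections of 10 µL; it
is recorded in every thermogram and report. The synthetic noise model
is Gaussian on normalized heats with sd expressed relative to the
largest normalized heat.

## 3. CD secondary-structure estimation

### A transparent stand-in for network deconvolution

The original composition percentages were produced by a neural-network
deconvolution (K2D2/K2D3), whose outputs depend on that specific
trained network and cannot be reproduced bit-for-bit without it. The
package instead implements the transparent classical estimator:
least squares over the 2-simplex (fractions non-negative, summing to
one) against a packaged three-component reference basis. Its acceptance
is recovery on its own forward model, with the published compositions
used as *generator inputs* — the recovered 87.59% and 40.9%
alpha-helix values validate the estimator, not the original spectra,
which were never deposited.

With only three components the simplex-constrained optimum is found
exactly by enumerating the seven possible support sets and solving the
equality-constrained KKT system on each (the basis is rescaled first so
the Gram block and the constraint row are commensurate); the feasible
candidate with the smallest residual is the global optimum. The
estimate is therefore deterministic, always on the simplex, and free of
iteration-tolerance artefacts.

### The packaged basis

`builtin_cd_basis()` ships idealized mean-residue-ellipticity curves on
a 1 nm grid over 190–240 nm, built from sums of Gaussian bands with the
hallmark features of each state: helix with the strong positive band
near 192 nm and the two negative bands near 209 and 222 nm (the n–pi*
region), sheet with a positive band near 196 nm and a single minimum
near 218 nm, coil with a deep minimum near 198 nm. Band parameters are
plain numbers in the source, so the basis is versioned with the code; a
user basis loads from CSV. Spectra on other grids are linearly
interpolated onto the basis grid, and spectra covering fewer than 10
basis points are rejected rather than extrapolated.

## 4. Synthetic data: what it does and does not emulate

The generators provide every input the tests need, with ground truth
attached:

* geometric clouds with analytic radii of gyration (shell: `R_g = R`;
  uniform ball: `R_g -> R sqrt(3/5)`; Gaussian blob; a deterministic
  ideal-helix backbone decoy with 0.15 nm rise and 100° twist per
  residue);
* one-site thermograms at the two named scenarios ("albumin",
  "insulin") carrying the published binding parameters and
  concentrations, plus relative Gaussian noise;
* CD titration series interpolating linearly in fraction space between
  the free-protein and highest-NP-concentration compositions over
  0.01–1.8 mg/mL.

These emulate the *designs* of the corresponding experiments, not their
physics: there is no instrument baseline drift or integration error in
the thermograms, no wavelength-dependent noise or scattering artefacts
in the spectra, and the structural model has no forces, so passing
tests demonstrate correctness of the estimators on their stated models,
not agreement with new laboratory data.

## 5. Numerical choices and degenerate inputs

* Every stochastic stage consumes an explicit integer seed with a
  documented draw order (atom-major, axis-minor for coordinates;
  directions before radii for the ball generator); equal specs give
  bit-identical outputs, which the suite asserts.
* `sigma = 0`, zero-noise generators and blank-equal-sample
  subtraction are exact no-ops / zeros, not approximations.
* Problem sizes in tests are chosen so closed-form expectations are
  sharp: 10^4–10^5 points for law-of-large-number checks (standard
  errors an order of magnitude below the asserted tolerances), 20–60
  replicate fits for recovery medians, 100–250 random instances for
  oracle comparisons. The whole suite runs in well under a minute.
* Degenerate inputs error early with informative messages: empty
  selections, count mismatches in RMSD or blank subtraction, K or N at
  or below zero, non-simplex fractions, spectra outside 190–240 nm.

## 6. Known limitations

* The NP model has no core–shell structure, charge or chemistry, so no
  conclusion about specific surface interactions can be drawn from it.
* The tabulated structural reference values (R_g, minimum distances)
  are reproduced only as diagnostics; their generating conventions are
  not recoverable (Section 1).
* K estimated from very-high-c isotherms is intrinsically imprecise
  (Section 2); reported standard errors make this visible.
* The CD estimator is a three-state model; turns and polyproline
  content are absorbed into the nearest basis state.
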