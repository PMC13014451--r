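---
title: "Membrane permeation analysis: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane permeation analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(permeakit)
```

## The problem

Passive membrane permeation of a small molecule — here motivated by
cisplatin and its Pt(IV) prodrugs crossing a phospholipid bilayer — is
commonly quantified by the inhomogeneous solubility-diffusion model. The
permeant's position along the membrane normal, `z`, is the reaction
coordinate; two position-dependent functions govern transport:

* the potential of mean force `G(z)` (kcal/mol), the free energy of holding
  the permeant at depth `z`, and
* the local diffusivity `D(z)` (cm²/s), how fast it moves once there.

The permeability coefficient is

    P = ( ∫_{z_in}^{z_out} exp(β G(z)) / D(z) dz )⁻¹,   β = 1/(kB T)

and the integrand `R(z) = exp(β G(z))/D(z)` is the local resistance, whose
integral is the effective resistance `R_eff = 1/P`. Because `G` enters
exponentially, a ~16 kcal/mol core barrier suppresses `P` by ten orders of
magnitude regardless of modest changes in `D`; the PMF dominates.

`permeakit` implements the full estimation chain from umbrella-sampling
window trajectories: WHAM reconstruction of `G(z)` with moving-block
bootstrap errors, restrained-window diffusivity estimation, the resistance
integral, plus the surrounding structural analyses (contacts, hydration,
hydrogen bonds, `g(r)`, electron density) and an MM-GBSA-style
interaction-energy ledger for labeled snapshots.

## Coordinate conventions and units

All internal energies are kcal/mol, lengths Å, times ps, with
`kB = 0.0019872041` kcal mol⁻¹ K⁻¹; conversion to cm-based units
(`1 Å²/ps = 1e-4 cm²/s`) happens only at reporting time. The membrane
coordinate follows the double-interface convention of a symmetric
double-bilayer box: bulk water near z ≈ 70 Å (and below ~20 Å), headgroup
interfaces near 58 and 23 Å, and the bilayer core at 40 Å, all measured
from the system center of mass. The temperature default is 310 K
(kT ≈ 0.616 kcal/mol).

## WHAM

Each umbrella window `i` is restrained by `w_i(z) = k_i/2 (z − z0_i)²`.
With per-bin counts `n_i(z_b)` and retained sample counts `N_i`, WHAM
iterates

    p(z_b) = Σ_i n_i(z_b) / Σ_i N_i exp(β(f_i − w_i(z_b)))
    f_i    = −kT ln Σ_b p(z_b) exp(−β w_i(z_b))

until the largest change in any `f_i` drops below the tolerance (default
1e-7 kcal/mol, iteration cap 1e5; non-convergence is flagged on the result,
not fatal). `G = −kT ln p`, shifted so its minimum over the bulk reference
region (default 66–72 Å) is zero. Numerical choices:

* bin width 0.2 Å by default — fine enough that binning bias
  (`G'' Δ²/24`) is ≲ 0.002 kcal/mol for the curvatures seen here;
* empty bins are masked, never interpolated: the estimator does not invent
  free energy where no window placed samples;
* no symmetrization is applied to the profile; any symmetry must emerge
  from the data;
* adjacent windows whose histograms share no bin with ≥ 10 counts trigger
  a warning naming the window pair.

Uncertainties come from a moving-block bootstrap (default block length 200
samples) within each window, because window samples are strongly
autocorrelated and a plain bootstrap would understate the error. Each
replicate re-solves WHAM on the full-data bin grid, warm-started from the
full-data shift constants.

A free-energy profile is defined only up to an additive constant. The
reporting convention pins the minimum over the reference region to zero;
when comparing two profiles (reconstruction vs. ground truth, replicate vs.
replicate) the package's tests remove the mean offset first, since the
min-of-a-noisy-curve pinning itself carries a small positive bias that is a
property of the convention, not of the estimator.

## Landmarks

`extract_landmarks()` reports the interfacial minima (`Min_right`,
`Min_left`), the core maximum (`Max`), and the two barrier heights
`ΔG_right = G(Max) − G(Min_right)` and `ΔG_left = G(Max) − G(Min_left)`,
computed exactly as differences of the located values. Region defaults
(right interface 50–65 Å, core 30–50 Å, left interface 15–30 Å) follow the
headgroup positions of the membrane convention above and are configurable.
Ties are broken toward the region center. Published landmark tables
occasionally print barrier heights that differ in the last digit from the
printed max-minus-min difference (rounding of unrounded internals);
`permeakit` always reports the exact difference.

## Position-dependent diffusivity

For a harmonically restrained window the diffusivity estimator is

    D = var(z)² / ∫₀^{τ_c} C_zz(t) dt,

with the position autocorrelation `C_zz(t) = (1/n) Σ_i δz(i) δz(i+t)`
(biased normalization, fixed 1/n at every lag) and the integral truncated
at the first zero crossing `τ_c` of `C_zz`. Equivalently `D = var/τ_int`
with `τ_int = ∫C/var`. This form is exact for an Ornstein–Uhlenbeck
process — which a harmonically restrained overdamped particle is, locally —
and that exactness is what the test suite checks. Two numerical choices
matter:

* the truncation at the first zero crossing discards the noise-dominated
  tail, which would otherwise inflate the integral and bias `D` downward;
  the maximum lag defaults to 5% of the window length;
* an alternative reading of the estimator, `var/(2∫C)`, fails the OU
  self-consistency check by a factor of two and is rejected.

One `(mean z, D)` point is produced per window; windows with zero variance
or a non-positive ACF integral are excluded with a warning. The profile is
interpolated linearly between window positions and extrapolated as a
constant beyond the outermost windows. At study-scale window lengths
(2×10⁵ samples at 0.1 ps spacing) a single window's estimate carries
roughly 5–10% stochastic spread; averages over windows are correspondingly
tighter.

## Permeability integration

`permeability()` evaluates the resistance integral by the trapezoidal rule
on a 0.05 Å grid (halving the spacing moves log₁₀P by < 0.01 on smooth
profiles), with `z` in cm and `D` in cm²/s. The exponential is accumulated
in log space (`log R = βG − ln D`, combined with log-sum-exp), so large
barriers cannot overflow; `G` is never clipped. `P` and `R_eff` are exact
reciprocals by construction, and the suite asserts `P·R_eff = 1` to
machine precision.

## The synthetic window generator

The generator stands in for the all-atom molecular dynamics that real
umbrella windows come from. Its defining contract is the overdamped Itô
Euler–Maruyama update

    z ← z + [ −β D(z) (G'(z) + U'_bias(z)) + D'(z) ] dt + sqrt(2 D(z) dt) ξ

with reflecting boundaries at the domain edges. The spurious-drift term
`D'(z)` is required for the correct stationary density when `D` varies
with position: without it the equilibrium histogram would follow `1/D(z)`
rather than `exp(−βG)`, and a dedicated χ² test would fail. The stability
precondition `β D max|force| dt < 0.1 Å` is checked before every run.
Defaults: `dt = 0.01` ps, stride 10, 2×10⁶ steps → 2×10⁵ retained samples
per window, chosen so a 71-window set generates in about a minute on one
CPU. Windows start at the minimum of `G + U_bias`, so no equilibration
discard is needed for synthetic data (file readers still apply a
configurable discard, default 0.5, for externally produced windows whose
first half is treated as equilibration).

The default landscape mimics a cisplatin-like permeant: Gaussian
interfacial wells of depth 0.8 kcal/mol at 57.3 and 22.4 Å (width 3 Å), a
core barrier of 16.0 kcal/mol at 40.0 Å (width 4.5 Å, giving a ~10 Å
half-height width), bulk diffusivity 0.1 Å²/ps (1e-5 cm²/s) with
interfacial minima (×0.4) and a partial core recovery (×0.6) — the shape
restrained-window analyses of polar permeants typically recover. Gaussian
widths are the one free choice the landmark table does not fix; the values
above keep each feature's tail below 0.01 kcal/mol at the other landmarks,
so the landscape's own landmarks equal the table entries to better than
0.02 kcal/mol.

Steered seeding (`seed_windows()`) emulates constant-velocity pulling with
a moving harmonic center (default 0.972 Å/ns, spring 2.5 kcal mol⁻¹ Å⁻²)
and records the instantaneous position at every 1 Å crossing of the
center, reproducing the 71-seed extraction schedule.

What the generator deliberately does not model: lipid dynamics, leaflet
asymmetry, surface-tension (NPγT) coupling — which has no 1-D analogue —
ionic gradients, or any 3-D membrane mechanics. Passing recovery tests
therefore demonstrates the correctness of the estimators under the 1-D
diffusive model, not the fidelity of that model to atomistic membranes.

## Structural analyses

All spatial queries use per-pair minimum-image distances when a frame
carries an orthorhombic box, plain Euclidean distances otherwise, and every
operation is verified against a brute-force all-pairs oracle on small
instances.

* **Contacts** (default cutoff 7.0 Å, configurable): a probe–partner pair
  within the cutoff in the designated reference frame is *native*;
  contacting pairs outside that set are *non-native*. The reference frame
  is an explicit argument — whether the appropriate reference is the first
  frame of a window or a global structure is an analysis decision, not a
  package default. Counts are frame-averaged and rounded to integers for
  reporting; distances are means over contacting pair instances (not modal
  RDF peaks), and are labeled as such.
* **Hydration** counts water molecules by their oxygen atoms within 3 Å
  (default) of any probe atom, reported per window as mean ± 1σ of the
  frame-by-frame population (population standard deviation, matching a
  shaded-band presentation).
* **Hydrogen bonds** use a geometric criterion: heavy–acceptor distance
  ≤ 3.5 Å and donor–H···acceptor angle (at the hydrogen) ≥ 135°. These are
  declared defaults of the common geometric convention, configurable.
* **g(r)** is normalized so an ideal gas gives 1; with a box the partner
  density is N/V and `r_max` must not exceed half the smallest box length,
  without one the density comes from an explicit argument or the partner
  bounding box.
* **Electron density** assigns each atom its element's electron count in
  1 Å z-bins over the lateral area; per-component profiles partition the
  total exactly, and the profile integral equals the per-frame electron
  count — a conservation identity the suite checks to 1e-6.

## MM-GBSA

The interaction ledger evaluates, for complex, receptor and ligand with
identical parameters: pairwise Coulomb (`k_e = 332.0637` kcal Å mol⁻¹ e⁻²),
12-6 Lennard-Jones with Lorentz–Berthelot combining, the Still pairwise
generalized Born term with `f_GB = sqrt(r² + R_i R_j exp(−r²/4R_iR_j))`
including self terms (a single ion reduces exactly to the Born formula),
and Shrake–Rupley SASA (960 deterministic golden-spiral points per atom,
probe 1.4 Å) feeding `G_SA = γ·SASA` with γ = 0.0072 kcal mol⁻¹ Å⁻².
Design choices:

* Born radii are *inputs* (default: half the LJ σ); no self-consistent
  GB-OBC radius machinery is attempted, as production MD packages own that
  step and the ledger targets toy systems;
* the single-trajectory convention is used — component geometries are
  extracted from the complex — so `ΔE_int ≡ 0` by construction;
* the conformational entropy term `−TΔS` is carried as an explicit
  `"omitted"` marker, never a silent zero;
* dielectric constants default to 1 (interior) and 80 (water); γ and all
  of the above are declared defaults, since end-state methods differ in
  these conventions.

The additivity identities `ΔE_MM = ΔE_int + ΔE_ele + ΔE_vdW`,
`ΔG_sol = ΔG_GB + ΔG_SA`, `ΔG_total = ΔE_MM + ΔG_sol` hold to 1e-9 and are
property-tested, as is agreement of the decomposition with a monolithic
direct evaluation of the cross-group interaction.

## Problem sizes used by the test suite

The end-to-end recovery experiment uses the full study geometry: 71
windows at 1 Å spacing, spring constant 2.5 kcal mol⁻¹ Å⁻², 310 K, 2×10⁵
retained samples per window, and checks that the reconstructed core
barrier equals the landscape's 16.0 kcal/mol ground truth within 0.5
kcal/mol, that the profile RMSD to ground truth is below 0.3 kcal/mol
(after gauge alignment), and that permeability computed from the estimated
`G` and `D` lands within a factor of two of the ground-truth value — the
exponential `exp(βG)` amplifies PMF noise, which dominates that factor.
Estimator-exactness checks run on analytically solvable fixtures:
exactly-sampled (inverse-CDF) harmonic windows for WHAM, discrete OU
series for the ACF, flat and square-barrier profiles for the integrator,
the Born ion and isolated spheres for the energetics.

## Known limitations

* The dynamics are strictly overdamped and one-dimensional; inertial or
  memory effects, and any coupling between `z` and orthogonal degrees of
  freedom, are outside the model.
* `D(z)` estimation assumes each window is locally harmonic; strongly
  anharmonic windows bias the OU-based estimator.
* The WHAM bootstrap resamples blocks within windows only; it does not
  capture between-window seeding variability.
* MM-GBSA values depend on declared parameter conventions (Born radii,
  dielectrics, γ); the ledger is a bookkeeping and consistency tool for
  toy systems, not a reproduction of any production force-field pipeline.
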