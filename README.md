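# permeakit

Membrane permeation analysis from umbrella-sampling windows, in R.

`permeakit` is for computational chemists and structural bioinformaticians
who study how small molecules — the motivating case is cisplatin and its
Pt(IV) prodrugs — cross phospholipid bilayers, and who need the estimation
chain that turns biased window trajectories into thermodynamic and kinetic
observables:

* **PMF reconstruction**: the weighted histogram analysis method (WHAM)
  over harmonically restrained windows, with moving-block bootstrap
  uncertainties and extraction of the interfacial minima / core barrier
  landmarks (Min_right, Max, Min_left, ΔG_right, ΔG_left);
* **position-dependent diffusivity**: the restrained-window estimator
  `D = var(z)² / ∫₀^∞ C_zz(t) dt` from each window's positional variance
  and position autocorrelation function;
* **permeability by inhomogeneous solubility-diffusion theory**:
  `P = (∫ e^{βG(z)}/D(z) dz)⁻¹`, with the local resistance profile
  `R(z) = e^{βG(z)}/D(z)` and the effective resistance `R_eff = 1/P`;
* **structural profiles** over labeled membrane snapshots
  (WAT/PC/PE/PS/PG/OL/CHL/DRG components): native/non-native contacts,
  hydration-shell populations with ±1σ bands, geometric hydrogen bonds,
  radial distribution functions, per-component electron-density profiles;
* **MM-GBSA energy decomposition** (ΔE_ele, ΔE_vdW, ΔG_GB, ΔG_SA →
  ΔG_total, with −TΔS explicitly marked omitted) backed by a minimal
  Coulomb / Lennard-Jones / generalized-Born / Shrake–Rupley evaluator for
  toy systems;
* a **synthetic data generator**: a biased 1-D overdamped Langevin
  simulator (Itô Euler–Maruyama with the D′(z) spurious-drift term,
  reflecting boundaries) on configurable free-energy/diffusivity
  landscapes, plus steered-pull window seeding and labeled toy membrane
  frames — so every estimator can be exercised against known ground truth
  at desk scale.

## Worked example

Simulate a study-shaped umbrella set (here thinned to 36 windows at 2 Å
spacing for speed) on the default cisplatin-like landscape — interfacial
wells of −0.8 kcal/mol at 57.3/22.4 Å, a 16.0 kcal/mol core barrier at
40.0 Å — then run the full chain:

```r
library(permeakit)
th <- thermo_state(310)
ls <- default_landscape()
wins <- simulate_window_set(ls, centers = seq(0, 70, by = 2), spring_k = 2.5,
                            thermo = th, n_steps = 5e5, seed = 42)
fit <- permeation(wins, th, z_in = 18, z_out = 62)
print(fit)
#> WHAM PMF: 36 windows, 371 bins of 0.2 A, converged after 33260 iterations
#>   G range [-0.681, 16.246] kcal/mol; reference region [66, 72] A
#> PMF landmarks (kcal/mol, positions in A):
#>   Min_right  -0.68 ( 58.9 A)   Max  16.25 ( 40.1 A)   Min_left  -0.58 ( 23.1 A)
#>   dG_right  16.93   dG_left  16.83
#> Diffusivity profile: 36 windows (0 excluded), D in [0.0351, 0.115] A^2/ps (3.51e-06-1.15e-05 cm^2/s)
#> Permeability over [18, 62] A: P = 9.46e-10 cm/s, R_eff = 1.06e+09 s/cm
```

Reading the output: WHAM recovers the generating landscape's barrier
(16.25 vs. a true 16.0 kcal/mol at this reduced sampling; the landmark
columns mirror the usual PMF landmark tables), the diffusivity profile
spans ~0.35–1.15 × 10⁻⁵ cm²/s with its minima at the headgroup interfaces,
and the 16 kcal/mol core barrier drives the permeability down to
~10⁻⁹ cm/s (R_eff ≈ 10⁹ s/cm) — the order of magnitude expected for a
polar permeant facing such a barrier. `plot(fit)` draws G(z) and D(z);
`bootstrap_pmf()` attaches per-bin standard errors.

File-based workflows use `read_window_manifest()` (TSV manifest + two-column
time/z series), `read_frames()` (extended XYZ with a component-label column,
or PDB via bio3d), and a thin command-line front end in `inst/cli/permeakit`
with `synth`, `pmf`, `kinetics`, `profiles` and `run` subcommands.

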