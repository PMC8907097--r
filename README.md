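# saltgist

Spatially resolved solvation thermodynamics of a rigid solute in a
salt–water mixture, computed on a voxel grid from MD-style trajectories.

Grid-based inhomogeneous solvation theory decomposes the solvation free
energy into per-voxel energy and entropy contributions,

ΔA_solv = ΔE^uv + ΔE^vv − TΔS_solv,

accumulated over an equilibrium ensemble of solvent configurations around a
rigid solute. `saltgist` extends the machinery to mixed solvents of water
plus one monoatomic cation and one anion species — the salt is solvent, not
solute — which requires three things beyond the pure-water case:

* **per-species bulk-energy referencing**: the voxel reference energy is
  `N_wat⟨E_wat⟩ + N_+⟨E_+⟩ + N_−⟨E_−⟩`, with the per-species bulk energies
  determined by an ordinary least-squares fit (no intercept) over voxels far
  from the solute;
* **first-order nearest-neighbor entropies per species**, with the
  Euler–Mascheroni bias correction and a cell-list neighbor search that
  stays exact at ionic concentrations far below one sample per voxel
  (translational for ions; translational, orientational, and joint
  six-dimensional for water);
* **second-order (three-body) entropies** from one-dimensional conditional
  radial distribution functions per voxel, both exact and under the
  Kirkwood superposition approximation (KSA), for all nine ordered species
  pairs, plus finite-sampling debiasing that makes the estimates usable at
  desk-scale trajectory lengths.

Reference densities ρ∞ are recomputed from the bulk-like region of each
analyzed box, and salting-out (Setschenow) constants are fitted from a
ΔG_solv-versus-concentration series as `K_S = slope / (RT ln 10)` in L/mol.

The package is self-contained: deterministic generators (ideal gas,
Metropolis Monte-Carlo fluid with an optional hard-sphere solute, Gaussian
clouds) produce trajectories with known statistical structure, so every
stage is testable without external data. Intended users are molecular
modellers studying hydration, salting-out, and ion-specific solvation
effects.

## Worked example

A structured Monte-Carlo fluid (120 water stand-ins, 8 + 8 neutral ion-like
species) around a 2.5 Å hard-sphere solute, analyzed end to end:

```r
library(saltgist)
fx <- gen_mc_fluid(n_wat = 120, n_cation = 8, n_anion = 8,
                   box = c(16, 16, 16), solute_radius = 2.5,
                   wat = list(charge = 0, sigma = 3.0, epsilon = 0.25),
                   cation = list(charge = 0, sigma = 2.3, epsilon = 0.1),
                   anion = list(charge = 0, sigma = 3.8, epsilon = 0.1),
                   cutoff = 7, n_equil_sweeps = 150, n_frames = 120,
                   stride_sweeps = 6, seed = 27)
cfg <- run_config(
  grid = list(dims = c(28L, 28L, 28L), spacing = 0.5),
  energy = list(cutoff = 7.0, bulk_cutoff = 4.0),
  reference = list(cutoff = 4.0, n_mc = 2e4),
  second_order = list(grid_dims = c(10L, 10L, 10L), bin_width = 0.25,
                      cutoff = 6.0, bulk_cutoff = 4.0),
  integration = list(cutoff = 4.0, second_order_cutoff = 6.0),
  seed = 2L)
run <- run_pipeline(cfg, topology = fx$topology, frames = fx$frames)
print(run)
```

```
gist_run over 120 frames
  grid: 28x28x28 at 0.5 A
  dE_uv                  0.0000 kcal/mol
  dE_vv                  0.2651 kcal/mol
  TdS_six_wat           -5.7808 kcal/mol
  TdS_trans_cation       0.0000 kcal/mol
  TdS_trans_anion        0.0000 kcal/mol
  TdS_second: wat:wat=0.6228, wat:cation=0.2247, wat:anion=-0.1462, ...
  dA_solv = 5.6295 kcal/mol
```

The solute here is a pure excluded-volume sphere (no attractive
parameters), so the solute–solvent energy is zero and the positive ΔA is
carried by the water-ordering entropy near the cavity; the referenced
solvent–solvent energy is small, as the bulk fit absorbs the per-molecule
baseline:

```r
print(run$bulk_model)
#> bulk_energy_model (19776 bulk voxels, cutoff 4 A):
#>   <E_wat> = -0.930026 +/- 0.0021 kcal/mol
#>   <E_cation> = -0.370061 +/- 0.0114 kcal/mol
#>   <E_anion> = -0.506813 +/- 0.00675 kcal/mol
```

Per-voxel fields (`voxels.csv`, OpenDX grids) and a per-pair KSA validity
report are written when `paths$out_dir` is set. A Setschenow fit from a
synthetic concentration series:

```r
fit <- setschenow_fit(seq(0, 1, 0.1),
                      gen_dg_series(0.6864, intercept = -7,
                                    noise_sd = 0.05, seed = 3)$dG)
print(fit)
#> Setschenow fit (n = 11, T = 300 K):
#>   K_S  = 0.5243 +/- 0.0299 L/mol
#>   dG0  = -7.0231 kcal/mol, slope = 0.7197 kcal/(mol*M)
```

A thin command-line front end (`inst/scripts/saltgist`) exposes `run`,
`integrate`, `ks-fit`, `fixtures`, and `ksa-report` subcommands over the
same functions.

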