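---
title: "Voxelized solvation thermodynamics of salt-water mixtures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Voxelized solvation thermodynamics of salt-water mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

`saltgist` computes spatially resolved contributions to the solvation free
energy of a rigid solute in a mixed solvent — water plus one monoatomic
cation and one monoatomic anion species — from an equilibrium ensemble of
solvent configurations.  All quantities are accumulated on a cubic voxel
lattice centered on the solute, and the free energy is assembled as

$$\Delta A_\mathrm{solv} = \Delta E^{uv} + \Delta E^{vv}
  - T\,\Delta S_\mathrm{solv},$$

with a solute–solvent and a solvent–solvent energy term and an entropy term
that is expanded in correlation order.  Every Δ is taken relative to the
bulk solvent mixture far from the solute.

## Energies and per-species bulk referencing

Pairwise nonbonded energies (Lennard-Jones with Lorentz–Berthelot
combination plus truncated minimum-image Coulomb,
$C = 332.0637\,\mathrm{kcal\,\AA\,mol^{-1}e^{-2}}$) are accumulated per
frame.  Solute–solvent energy is assigned wholly to the voxel currently
holding the solvent molecule; solvent–solvent energy is split half/half
between the two partners.  Ions are solvent: ion–solute energy is part of
$E^{uv}$, water–ion and ion–ion energy of $E^{vv}$.

$E^{vv}$ tends to a nonzero bulk value that must be subtracted.  In a
mixture the per-molecule bulk energy differs by species, so the reference
is a linear model in the per-frame voxel occupancies,

$$E^{vv}_{\mathrm{ref},k} = N_{k,\mathrm{wat}}\langle E_\mathrm{wat}\rangle
 + N_{k,+}\langle E_{+}\rangle + N_{k,-}\langle E_{-}\rangle,$$

whose coefficients are determined by an ordinary least-squares fit (no
intercept — an empty voxel has zero reference energy) over voxels at least
`energy$bulk_cutoff` (default 16 Å) from every solute heavy atom.  The fit
is redone for every solvent composition.

A deliberate simplification: electrostatics are cut off at
`energy$cutoff` (default 10 Å) with the minimum image, not Ewald-summed.
The voxel decomposition requires pair-decomposable energies, which
reciprocal-space sums are not.  Referencing against the bulk fit removes
most of the truncation artifact from $\Delta E^{vv}$, but absolute energies
near strongly charged solutes will differ from mesh-Ewald results.

## First-order entropies

Translational, orientational, and six-dimensional entropies per voxel $k$
use nearest-neighbor estimators over samples pooled across all $N_f$
frames,

$$S^\mathrm{trans}_k = R\left(\gamma + \frac{1}{N_k}\sum_i
   \ln \frac{N_f \rho^0\, 4\pi d_i^3}{3}\right),\qquad
  S^\mathrm{orient}_k = R\left(\gamma + \frac{1}{N_k}\sum_i
   \ln \frac{N_k\, \Delta\omega_i^3}{6\pi}\right),$$
$$S^\mathrm{six}_k = R\left(\gamma + \frac{1}{N_k}\sum_i
   \ln \frac{N_f \rho^0\, \pi(\Delta\omega_i^2 + d_i^2)^3}{48}\right),$$

where $d_i$ is the minimum-image distance to the nearest other sample of
the same species (the same molecule in another frame counts; only the
identical sample is excluded), $\Delta\omega_i = 2\arccos|q_1\!\cdot\!q_2|$
the geodesic rotation angle between water orientation quaternions, and
$\gamma$ the Euler–Mascheroni constant correcting the asymptotic estimator
bias.  Each species uses its own reference density $\rho^0$; monoatomic
ions have no orientational term.  These estimators converge to zero in
homogeneous bulk, so no entropy reference is needed in principle; a
constant `reference_offset_six` (default 0) can absorb the small residual
that finite sampling leaves in the bulk.

The neighbor search is a cell list with a growing search radius, exact for
all three metrics (the joint metric is bounded below by its translational
part, which makes the same stopping rule exact).  Unlike a voxel-local
search it remains correct for dilute species with far less than one sample
per voxel, which is what makes ion entropies computable at all.

Per-voxel fields are reported both per molecule (`*_norm`, after
multiplying by $T$) and occupancy-weighted
($T\Delta S_k \cdot N_k/N_f$, kcal/mol per voxel); region integrals sum
the weighted field.  Voxels with one sample or fewer carry a flagged zero.

Orientations themselves are defined as the best-fit rotation (Horn's
quaternion method) mapping a fixed reference water geometry onto the
observed geometry about the oxygen; the q/−q double cover is canonicalized
by sign and never affects $\Delta\omega$.

## Second-order entropies and the superposition approximation

The pair-correlation (three-body) contribution is computed from
one-dimensional conditional radial distribution functions on a coarser
lattice (default 1 Å).  For each ordered species pair $(\nu,\nu')$ a
per-voxel histogram of minimum-image distances is normalized by
$N_{\nu k} V_l\, \rho^\infty_{\nu'} G_{s\nu',kl}$, where $V_l$ is the
radial bin volume and $G_{s\nu',kl}$ the shell-averaged relative density
of $\nu'$ around the voxel center, computed from a fine occupancy grid
(default 0.25 Å) and re-binned into the radial bins.  The per-voxel
entropy is

$$\frac{\Delta S^{2nd}_k}{k_B} = -\tfrac12 \sum_{\nu}\sum_{\nu'}
  \rho^\infty_\nu \rho^\infty_{\nu'} V_\mathrm{vox} G_{s\nu,k} \sum_l
  4\pi d_l^2\,\Delta d\,
  \left[G_{s\nu',kl}\, f(g^\mathrm{inh}_{kl}) - f(g^0_l)\right],
  \qquad f(g) = g\ln g - g + 1,$$

with $f(0) = 1$ (the $g\ln g$ limit vanishes).  The Kirkwood superposition
approximation (KSA) replaces $g^\mathrm{inh}$ by the bulk $g^0$, which
collapses the bracket to $(G_{s\nu',kl}-1)f(g^0_l)$; the two forms agree
bin by bin to machine precision under that substitution, which is tested.
Radial bins with no shell density are skipped in both forms and counted in
a coverage diagnostic, keeping the identity exact.

Several estimator details matter at realistic sampling:

* **Self-pair partner density.**  For $\nu = \nu'$ a molecule is excluded
  from its own histogram, so the partner density available to a reference
  molecule is $(N-1)/N$ of the species density.  Irrelevant for hundreds
  of waters, a 10 % effect for ten ions — and amplified by the logarithm
  in sparsely populated bins.
* **Null referencing of the convex integrand.**  $f$ is convex, so a
  histogram bin with expected count $\mu$ reads, on average, above its
  true value; at low $\mu$ the excess approaches $-\ln\mu$.  In full mode
  the package subtracts the exact null expectation
  $E[f(n/\mu)] - f(1)$ under $n \sim \mathrm{Poisson}(\mu)$ per bin
  (series evaluation below $\mu = 25$, asymptotic $1/2\mu + 1/12\mu^2$
  beyond).  For self pairs the two ordered directions of one close pair
  can land in the same voxel-bin, making the null counts compound
  ($n = a + 2b$); the correction uses that distribution, with the
  shared-voxel probability computed by deterministic sphere quadrature.
  The KSA form is linear in the histogrammed quantities and needs no
  correction.
* **Shell-density variance.**  $G_{s\nu',kl}$ is itself a histogram; its
  variance enters the divisor with weight $1/2\mu_G$, reduced by the
  fraction $q_l$ of shell cells shared between the pair histogram and the
  shell count (computed geometrically).  Shells narrower than the fine
  spacing are pooled adaptively with neighbors until a minimum occupancy
  supports them (`shell_min_support`, default 25 expected counts), trading
  negligible radial resolution for a large variance reduction.

These corrections are what make the ideal-gas null model integrate to zero
within sampling noise at 2000 frames; without them the full-mode fields
carry a systematic negative offset that in the literature is usually
suppressed only by orders-of-magnitude longer trajectories.  They vanish
as sampling grows ($O(1/\mu)$).

The radial (1-D) representation of $g^\mathrm{inh}$ is exact for
monoatomic ion pairs but ignores orientational correlations; the
water–water second-order output is therefore flagged "radial-only" and
excluded from the default free-energy assembly, which can instead scale
the first-order water entropy by $1 - 0.4 = 0.6$ as an empirical estimate
of all higher orders (`water_scaling`).  Requesting both at once is
refused as double counting.

## Reference densities and Setschenow constants

Reference densities $\rho^\infty$ are recomputed per run from the region
at least `reference$cutoff` (default 12 Å) from the solute, with the
region volume obtained by seeded Monte-Carlo integration.  This ties the
entropy normalization to the actual composition around the solute rather
than to tabulated bulk values, and removes the box-size dependence that a
fixed $\rho^0$ would introduce.  Concentrations follow from
$c = \rho\,10^{27}/N_A$; the salt concentration is the mean of the cation
and anion values, which differ in any finite box.

The salting-out (Setschenow) constant is the slope of
$\Delta G_\mathrm{solv}(c)$, fitted by ordinary least squares over a
concentration series, divided by $RT\ln 10$ (decadic convention, L/mol);
its standard error is the slope's standard error scaled identically.

# The synthetic generators

No external data is required; three seeded, deterministic generators
exercise every stage.

* `gen_ideal_gas()` is the null model: uniform independent positions each
  frame, uniform random water orientations, zero charges and epsilons.
  Every pair correlation is 1 and every referenced field is 0 in
  expectation.  The defaults — 500 waters in a 24.66 Å box
  (0.0334 Å⁻³, ambient water density) with 10 + 10 ions (about 1.1 M
  salt) over 2000 frames — are the conditions used for the null-model
  acceptance checks.
* `gen_mc_fluid()` is a Metropolis Monte-Carlo point-particle fluid
  (single-particle moves, minimum-image LJ + truncated Coulomb,
  optionally a hard-sphere solute at the origin).  It provides genuinely
  structured $g^0$ and $g^\mathrm{inh}$ — an equilibrium ensemble is all
  the analysis consumes, so no integrator or thermostat is needed.  Water
  stand-ins are dressed with reference-geometry hydrogens at
  independently uniform orientations when frames are emitted, so the
  topology invariants hold and orientation statistics are known.
* `gen_entropy_samples()` draws i.i.d. uniform, Gaussian, or
  uniform-rotation samples for direct estimator calibration, and
  `gen_dg_series()` synthesizes $\Delta G(c)$ lines for Setschenow
  round trips.

What the fixtures do **not** emulate: hydrogen-bond networks, real water
dielectrics, polarization, or long-range Ewald electrostatics.  Passing
the null and calibration tests therefore validates the estimators and
bookkeeping, not force-field realism.

# Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `grid$dims`, `grid$spacing` | 81³, 0.5 | —, Å | first-order lattice around the solute |
| `energy$cutoff` | 10 | Å | atom-pair LJ/Coulomb truncation |
| `energy$bulk_cutoff` | 16 | Å | bulk region for the per-species energy fit |
| `reference$cutoff` | 12 | Å | bulk region for ρ∞ |
| `entropy$temperature` | 300 | K | converts S to TΔS |
| `entropy$reference_offset_six` | 0 | kcal/mol | residual bulk entropy offset |
| `second_order$grid_spacing` | 1.0 | Å | coarse lattice for conditional rdfs |
| `second_order$bin_width` | 0.125 | Å | radial bin Δd |
| `second_order$cutoff` | 10 | Å | local integral range |
| `second_order$fine_spacing` | 0.25 | Å | shell-density fine grid |
| `second_order$shell_min_support` | 25 | counts | adaptive shell pooling threshold |
| `integration$cutoff` | 6 | Å | region integral for energies/first order |
| `integration$second_order_cutoff` | 10 | Å | region integral for second order |

# Numerical choices

* Voxels are half-open (lower edge inclusive), making assignment
  deterministic; region membership is by voxel-center distance.
* The molecule-pair minimum image is applied once per pair from the
  molecule centers, so a molecule's atoms never straddle images.
* Radial Jacobians use bin centers $d_l = (l - \tfrac12)\Delta d$
  (midpoint rule, $O(\Delta d^2)$).
* Degenerate inputs: overlapping atoms (< 1e−6 Å) are an error; voxels
  with ≤ 1 sample carry flagged zeros; collinear water geometries are
  refused.
* All randomized steps (generators, bulk-volume Monte Carlo) are seeded
  from the configuration; identical config and inputs give bit-identical
  outputs.

The test suite and the acceptance script run the null model at 500 + 10 +
10 molecules × 2000 frames on a 24³ × 0.5 Å analysis grid with a 12³ × 1 Å
second-order lattice, the Monte-Carlo fluid at 320 particles × 600
decorrelated frames, and estimator calibrations at 10⁵ samples; these
sizes give per-check sampling errors well below the asserted tolerances
while keeping a full run in the minutes range on one core.  Bin-width
robustness is asserted on the production (KSA) second-order estimate: the
conditional-histogram variant at these trajectory lengths is dominated by
its residual sampling bias, which scales with the number of radial bins
and therefore cannot discriminate discretization effects (production
studies of that variant use orders of magnitude more frames).

# Known limitations

* Truncated Coulomb instead of mesh Ewald (see above): absolute energy
  maps near highly charged solutes are approximate.
* The 1-D conditional rdf misses orientational pair correlations; the
  water–water second-order integral is reported but not assembled by
  default.
* One rigid solute, orthorhombic boxes, monoatomic ions only.
* The sampling-bias corrections reference the homogeneous null exactly
  but treat structured systems to first order in the local pair density;
  strongly structured, severely undersampled bins retain residual bias.
* Orientational curvature of SO(3) is neglected by the estimators
  (volume elements assume small angles); at typical voxel populations
  this is a percent-level effect on per-molecule values and far smaller
  after occupancy weighting.
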