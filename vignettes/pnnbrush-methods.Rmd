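---
title: "Methods: a coarse-grained charged-brush model of the perineuronal net"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a coarse-grained charged-brush model of the perineuronal net}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical model

Perineuronal nets are mesh-like assemblies of glycosaminoglycans (GAGs)
around neurons. `pnnbrush` models them as the simplest structure that
retains their two defining physical features — high grafting density and
high negative charge density: a planar polyelectrolyte brush. Each
coarse-grained bead represents one disaccharide unit (1 nm, charge −e);
chains of N = 101 beads are tethered through two immobile beads to a
neutral wall of immobile beads on a 1 σ lattice, dense enough that
Lennard-Jones repulsion blocks passage. The tether points form a quadratic
grid whose spacing d is the control parameter of the study: small d gives
a dense brush, large d isolated "mushrooms". A single tracer of radius a
and charge q probes transport. The box is periodic in x and y
(L = grid_n · d) and open above, so the tracer can leave the brush — which
the analysis must (and does) account for.

The potential energy is the sum of four terms: truncated 12–6
Lennard-Jones between all beads, cut at its minimum 2^(1/6) σ_LJ
(good-solvent conditions; we keep the energy-shifted WCA form so the
potential is continuous at the cutoff — forces are identical, only
absolute energy bookkeeping shifts by a constant per contact); harmonic
stretching K_bond (r − r0)²; harmonic bending K_bend (θ − π)²; and
Debye–Hückel screened electrostatics between charged beads with screening
length 1/κ = 1 nm and a 3 σ cutoff. First- and second-neighbour intrachain
pairs are excluded from the nonbonded terms (they are governed by the bond
and angle potentials).

Dynamics follow the underdamped Langevin equation
m dv/dt = F − γ v + B(t) with the fluctuation–dissipation noise amplitude,
integrated by a BAOAB splitting of velocity-Verlet type: it reduces
exactly to NVE velocity Verlet at γ = 0 (the test suite verifies energy
conservation there) and samples the free-particle velocity distribution
exactly at any γ.

Four system types are implemented: *dynamic* (chains and tracer
integrated together), *static* (chains equilibrated, then frozen — same
seed gives bit-identical frozen coordinates), *no stiffness* (bending term
removed) and *straight* (frozen vertical rods).

## Parameters, units and defaults

| quantity | value | why |
|---|---|---|
| σ = r0 | 1 nm | disaccharide length; sets the length unit |
| ε_LJ | 0.73 ε_E | from the 0.15 kJ/mol carbon–carbon coarse-graining value |
| K_bond | 140.2 ε_E/σ² | stiff, near-fixed bond length |
| K_bend | 14.02 ε_E/rad² | calibrated for l_p = 10 nm |
| kT | 2.804 ε_E | see below |
| γ (chain bead) | 1 m/τ | Stokes drag; tracer γ scales ∝ a, mass ∝ a³ |
| dt | 0.005 τ | ≥ 50 steps per bond-vibration period |
| 1/κ | 1 nm | physiological screening |
| l_B | 0.7 nm | water at ~300 K; sets the Debye prefactor l_B·kT |

**The temperature choice.** The model never prints kT directly; it is
pinned by the persistence-length calibration. For a discrete worm-like
chain, l_p ≈ 2 K_bend r0 / kT, so kT = 2.804 ε_E makes
β K_bend = 5 and l_p = 10 nm exactly as calibrated. The alternative route
— mapping physical kT through ε_LJ = 0.73 ↔ 0.15 kJ/mol — would give
kT ≈ 12.5 ε_E and a ~2 nm persistence length, contradicting the stated
calibration; we therefore follow the calibration and expose kT in the
configuration.

**Physical time.** Reduced time is τ = σ √(m/ε_E). Assigning a
disaccharide mass of 400 g/mol and ε_E = 0.15/0.73 kJ/mol gives
τ ≈ 44 ps; `unit_system()` holds this mapping and every SI-facing
endpoint (traversal times, conductivities, resistances) goes through it.
Absolute SI values inherit the uncertainty of this assignment; reduced
results do not.

## Measurement chain

**Dual MSD and the fit window.** The ensemble MSD from the production
origin is computed twice: over all realizations, and over realizations
whose tracer has remained inside the brush (z at or below the
instantaneous maximum chain-bead z — our operational reading of "still
inside") at every frame so far. Fits of 4 D∥ t and 2 D⊥ t use the
earliest decade-wide window, after the first 20 frames (past the inertial
transient), on which the two curves' log-log slopes agree within 10%; the
Ornstein–Uhlenbeck fixture verifies that this rule excludes the ballistic
regime. Errors come from splitting the ensemble into ten groups and
reporting mean ± sd of the group-wise slopes, whatever the ensemble size.

**Structure.** Radius of gyration (per chain, final frame, averaged over
chains and realizations), brush height L_z (mean of the maximal chain
z-coordinate), correlation length ξ (mean distance to the nearest bead on
another chain, minimum image), and the brush/mushroom classification
d < 2⟨Rg⟩. The persistence-length estimator fits log⟨cos θ(s)⟩ over
s ∈ [1, 3 l̂_p] with inverse-variance weights (unweighted log fits are
dragged by the noisy tail).

**Persistence-length sampling.** The slowest bending modes of a
semiflexible chain relax over times scaling as the fourth power of the
chain length — far beyond any reasonable run. Free-chain ensembles are
therefore initialized from the exact discrete worm-like-chain sampler
(`sample_discrete_wlc`, inverse-CDF sampling of
p(γ) ∝ e^{−βKγ²} sin γ), equilibrated 50k steps so that all wavelengths
entering the fit window are genuinely re-thermalized by the MD, and pooled
over independent chains. The quadrature oracle `wlc_quadrature()` provides
the independent expected value (l_p = 10.17 σ at βK = 5).

**Brush-chain initialization** is near-vertical with a small seeded
perturbation; at large spacings equilibration is extended (the
acceptance suite uses 60k steps at d ≥ 25) because coiling from a
straight start is slow.

**Energy bookkeeping.** Per production frame the tracer's full interaction
energy and the chains' per-bead potential energy are recorded; the
summary statistics are the mean tracer energy per frame, the mean over
interacting frames (any pair within a cutoff, |u| > 1e−12), and the
interacting fraction — the identity (mean per frame) = (mean when
interacting) × (fraction) holds by construction and is the consistency
check behind this reading of the columns.

## Transport models

Porosity maps a spacing to φ = 1 − (4/3)π a_f³ N_bead/(d² L_z), using the
simulated L_z(d) of the same system type (the height couples into the
porosity, so a single global height would be wrong). Tortuosity families
relate D_eff/D_bulk = 1/τ²: hyperbola of revolution (τ² = 2 − φ), ordered
packings ((3 − φ)/2), heterogeneous catalyst (φ/[1 − (1−φ)^{1/3}]), the
Mackie–Meares cation-exchange resin (τ = (2 − φ)/φ), and the generalized
random-walk model τ = 1 + p_first/(1 − p_next), whose custom
parameterization p_first = 1 − φ, p_next = k + (k − 1)(1 − φ) reduces
identically to Mackie–Meares when p_next = (2 − φ)/2 (a test verifies the
algebra symbolically on a φ grid).

Fitting conventions: the bead radius a_f is the free parameter for the
classical families (Levenberg–Marquardt); the custom family fixes a_f at
the physical bead radius 0.5 σ and fits k by bounded trust-region least
squares in (0, 1); the d power law is taken in the form
D/D_bulk = 1 − d^{−n}/c (the typeset source form is ambiguous; the
prefactor variant 1 − c·d^{−n} is available via `power_form`), and the
anisotropy ratio is fitted as D⊥/D∥ = A d^{−l} + 1 with ratio points ≤ 1
retained (they only vanish from log-log diagnostics). Degenerate inputs
(exactly isotropic ratios, exactly bulk-valued D) return the zero-strength
model directly instead of an unidentifiable nonlinear fit.

The electrical endpoint combines simulated charged-tracer diffusion
constants with a cerebrospinal-fluid-like ion composition. The source the
model follows cites concentrations without printing them, so
`csf_ion_mixture()` uses standard literature CSF values grouped by
valency (Na⁺ 147, K⁺ 3, Cl⁻ 113, HCO₃⁻ 23; Ca²⁺ 1.2, Mg²⁺ 1.1 mmol/L),
i.e. 286 mol/m³ monovalent and 2.3 mol/m³ divalent carriers, with the
simulated D per valency group supplied by the caller. Conductivity uses
the Nernst–Einstein relation; the shell resistance is the exact radial
integral ρ_e h/(4π r (r + h)).

## Synthetic data

Three generators emit the same trajectory type as the simulator, so the
analysis cannot distinguish sources: anisotropic Brownian walkers
(Gaussian increments with Var = 2 D dt per axis, optional exponential
exit hazard emulating brush escape), a velocity Ornstein–Uhlenbeck process
with a known ballistic-to-diffusive crossover, and the discrete worm-like
chain sampler. They emulate exactly the statistical structure the
estimators assume — linear MSD growth after a transient, exponential
bond decorrelation, exponential survival — and none of the structure they
do not (no trapping, no spatial heterogeneity, no charge effects), so
green fixture tests certify the estimators, not the physics; the physics
is checked by the simulation-level tests.

## Numerical choices

- Neighbor handling: a Verlet list with 0.3 σ skin built through a cell
  grid, rebuilt when any mobile bead has moved more than half the skin;
  for boxes narrower than three cells a z-sorted sweep enumerates
  candidates. Both paths are exact, and the test suite checks the kernels
  against a brute-force O(N²) R reference.
- Immobile–immobile pairs are skipped while stepping (their forces are
  never used); full-system energy evaluations include every pair
  ("interactions between all particles, static or dynamic").
- The bend force uses the standard sin θ-guarded harmonic-angle form; the
  θ → π limit is regular.
- Randomness comes from R's RNG (one stream per realization,
  base_seed + index), so every result is reproducible from seeds and the
  NVE limit is untouched by thermostat draws.
- dt = 0.005 τ resolves the bond vibration (ω ≈ 23.7/τ) with ~53 steps
  per period; the configuration rejects dt > 0.02 τ.
- Equilibration defaults to 20k steps with a warning when the running
  mean of ⟨Rg⟩ still moves by more than 1% between the two halves; the
  chain-coiling time at large spacing is much longer than any affordable
  equilibration, which is why sparse-brush cells use extended
  equilibration and the brush/mushroom boundary is assessed at the
  simulated spacings rather than by interpolating a crossover point.

## Study sizes used by the test suite

The reference analysis runs 1,000 realizations per condition over a fine
spacing grid — hours of CPU per cell. The package's own test suite runs
the same pipeline at sizes chosen to certify correctness rather than to
minimize statistical error: 8 realizations × 14k production steps per
dense-brush cell over d ∈ {2, 3, 4, 5, 7, 10} σ (neutral) and
{3, 5, 10} σ (q = −e), 4 realizations with 60k-step equilibration at
d ∈ {25, 50} σ for the phase assignment, 500 free-particle realizations
× 100k steps for the bulk check, and 16 chains × 40 decorrelated
worm-like-chain-initialized configurations for the persistence length. At these sizes the
directional diffusion constants carry ~10–20% statistical error; fitted
quantities that are sharp functions of the small-d end of D(d) (the
custom-model k, the fitted bead size a_f) inherit that error and can fall
outside reference bands that were derived from 1,000-realization data —
the corresponding checks document this rather than relax the bands.

## Known limitations

- Linear chains only: no CSPG side chains, cross-links, or hexagonal
  tether grids; a single tracer, so no ion–ion correlations (real CSF is
  ~150 mM) — both push toward overestimating diffusion and
  underestimating resistance.
- No position-resolved D(z); estimates are brush-averaged by design.
- The long-time hopping-diffusion regime at d < 2 σ is not reached;
  dense-brush tracers appear trapped on these time scales.
- Electrostatics are screened and pairwise (Debye–Hückel), appropriate at
  1 nm screening length but not for unscreened or strongly correlated
  regimes; the wall is neutral.
- SI-facing numbers (traversal times, resistances) depend on the
  documented mass/energy assignment in `unit_system()`; reduced-unit
  results do not.
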