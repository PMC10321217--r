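---
title: "Coarse-grained dynamics of DNA nanostar hydrogels with tunable planarity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coarse-grained dynamics of DNA nanostar hydrogels with tunable planarity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The system and the model

Trivalent DNA nanostars (three double-stranded arms joined at a core, each
arm ending in a self-complementary sticky end) assemble into percolating
hydrogel networks once the sticky ends hybridize. This package implements a
rigid-body coarse-grained model of such nanostars in which the geometry of
the building block — in particular its *planarity* — is a free parameter,
together with the analysis pipeline needed to characterise the gels it
forms: melting curves, contact-network topology, pair structure,
bending-angle statistics, mobility, and Green–Kubo rheology.

Each nanostar is a rigid body of ten sites:

* one **core** bead at the centre,
* two **arm** beads per arm, at 1 and 2 σ along each arm axis,
* one massless **patch** site per arm at 2.5 σ, the outer edge of the last
  arm bead, standing in for the sticky end.

Core and arm beads have diameter σ (≈ 2.5 nm of dsDNA, about 8 bp); all
lengths are in σ, energies in ε, and times in the Brownian time
τ_Br = σ²/D of a single bead (k_B = 1).

The **planarity** d_p of a molecule is the distance from its core to the
plane through the tips of the three *normalised* arm vectors: a flat
Y-shaped star has d_p = 0, and d_p → 1 as the arms collapse onto a common
axis. For the symmetric template whose arms make a polar angle ψ with the
symmetry axis, d_p = cos ψ, and all inter-arm angles follow the closed form
α(d_p) = acos((3 d_p² − 1)/2): 120° for the planar star, ≈ 87.7° at
d_p = 0.6. `ns_template(d_p)` builds the body; `compute_dp()` and
`compute_alpha()` measure it.

## Interactions and the force-field calibration

Beads of different stars repel through a WCA potential (purely repulsive
truncated-shifted Lennard-Jones, cutoff 2^(1/6) σ), so stars cannot
interpenetrate. Patches of different stars attract through a Morse well of
depth ε_m, width 1/a_m and minimum at r0_m, cut off (and shifted to zero)
at r0_m + 0.2 σ — the attraction acts within a 0.2 σ radius of the bond
minimum, which together with the arm sterics keeps every patch engaged in
at most one bond. Patch–bead cross interactions are omitted: the patch
sits on the surface of the last arm bead, so adding them would double-count
the contact repulsion.

The model class fixes the geometry, the 0.2 σ attraction radius and
the operating conditions (a melting point near
T = 1.1 ε/k_B for the planar gel at volume fraction ρ = 0.01), but not the
numerical Morse parameters. These were calibrated once, as part of the
model definition, and then frozen as the `ff_params()` defaults:

> ε_m = 22 ε, a_m = 10 /σ, r0_m = 0.05 σ, cutoff 0.25 σ (shifted),

a shifted well depth of 16.4 ε and a bonded core–core distance of
5.05 σ. The calibration proceeded in two stages. The bond *geometry* is
pinned by structure: a near-contact minimum (r0_m well under 0.1 σ) makes
bonded arms meet essentially tip-to-tip, which (i) puts the first peak of
the gel's pair correlation at 5 σ, (ii) lets the WCA contact of the
facing outer arm beads resist bond bending — the bending angle of a bond
then peaks near 20–30° instead of drifting towards the entropic 90° that
a loose bond orbit would give — and (iii) makes simultaneous double bonds
between one pair of stars sterically impossible, preserving the
single-bond-per-patch valence picture. The bond *strength* was then set so
the planar reference gel melts at the right temperature: a first estimate
from an independent equilibrium oracle (`pair_association_constant()`, an
importance-sampled Monte Carlo integral of the two-star association
constant Δ(T), inserted into the Wertheim mass-action relation
x/(1−x)² = ρ_patch Δ), refined against directly simulated quenches of a
small reference gel because the gel network bonds noticeably more than
the pair-level theory predicts (ring cooperativity). The moderate well
width (a_m = 10 rather than a hard-wall-like 20) keeps the bond
coordinate's curvature low enough that the Brownian integrator samples
the well faithfully at practical time steps.

One reference quantity is knowingly sacrificed: a 16 ε well implies an
Arrhenius barrier for bond exchange well above the target of ~10 k_BT.
The target melting sharpness (bonds mostly gone by T = 1.3) and the
target barrier (E_a ≈ 9.7 k_BT) are mutually inconsistent for any
single Morse depth at this bond entropy — the sharpness alone dictates an
effective bond energy near 16–20 ε. The calibration favours the melting
point and the structural class; the measured activation energy of this
model is correspondingly larger than the reference value, and the tests
report that honestly. The calibration is never revisited at run time;
`pair_association_constant()` stays in the package as the independent
cross-check that Brownian dynamics reproduces the equilibrium bond
statistics of the same Hamiltonian (see `test-dynamics.R`).

## Dynamics

The gel regime of interest is diffusive, so the integrator is overdamped
rigid-body Brownian dynamics: no inertia, centre and orientation updated
with mobility μ = D/k_BT and Gaussian noise of variance 2 D dt per degree
of freedom. Star-level coefficients are D_t = D/7 (the seven finite beads
carry the drag; isotropic approximation) and D_r = 3 D_t / σ_h² with
hydrodynamic radius σ_h = 2.5 σ. Any consistent choice only rescales time;
these make a free star's MSD and orientation autocorrelation match the
closed forms 6 D_t t and exp(−2 D_r t), which the test suite verifies.

Two numerical points matter:

* **Noise scheme.** The update is the Leimkuhler–Matthews variant of
  Euler–Maruyama: the Gaussian increment is the average of the previous
  and current step's noise, which improves the configurational sampling
  accuracy from O(dt) to O(dt²) at no extra force evaluations. With the
  plain Euler scheme the narrow Morse well is sampled measurably "hot" at
  any affordable dt (two-star bond occupancy disagreed with the Monte
  Carlo oracle by a factor ≈ 3). With the LM scheme and the default
  dt = 10⁻⁴ τ_Br the two-star occupancy matches the oracle within
  sampling error; at 2 × 10⁻⁴ a few-tens-of-percent occupancy deficit
  reappears for the 16 ε well, so all gel studies use dt = 10⁻⁴ and the
  coarser step is reserved for soft or non-bonding systems.
* **Bookkeeping.** Pair search uses a star-level Verlet list (pair
  interaction reach ≈ 5.25 σ plus a 1 σ skin, displacement-triggered
  rebuilds) with a
  centre-level minimum-image convention; the box must therefore exceed
  twice the listed reach (≈ 14.2 σ), which `bd_run()` enforces. A step
  whose largest centre displacement exceeds 0.1 σ is redone with dt halved
  and counted. Coordinates are stored wrapped with integer image flags, so
  trajectories unwrap exactly; the MSD refuses wrapped input.

## Metadynamics and the planarity collective variable

`bias_potential()` implements a generic history-dependent Gaussian bias
U_G on a scalar collective variable, with optional well-tempering (new
heights damped by exp(−U_G/ΔT)), the chain-rule bias force, and the
free-energy estimate F(ζ) = −U_G(ζ) (rescaled by (T + ΔT)/ΔT when
well-tempered). The engine is validated on landscapes known in closed
form: a quartic double well whose barrier must be recovered within 15%,
and a harmonic well whose curvature must be recovered within 15%. For
molecular use, `dp_cv()` provides the planarity CV with its analytic
gradient (checked against central differences to 10⁻⁶), and
`flexible_y_demo()` shows the bias driving a flexible four-bead Y out of
its planar minimum — the mechanism by which the planarity landscape of a
real nanostar would be mapped with a higher-resolution model. Defaults
(w = 0.1 ε, δ = 0.05, stride 500, ΔT = 5T) are conservative standard
settings; the demo drivers pass their own.

## Analysis definitions

* **Contacts.** Two patches within r_bond (default: the Morse cutoff) are
  bonded; if a patch has several partners in range only the nearest counts
  (greedy nearest-first matching), enforcing single-bond-per-patch
  accounting. θ = 2N_c/(3N) is the bonded fraction.
* **Melting.** Quench from a non-overlapping unbonded gas (the `gas`
  fixture, the ε_m = 0 equilibrium), record θ(t), average the last half of
  the run with a drift check (`steady_theta()`), and interpolate 〈θ〉(T)
  linearly at 0.5 for T_m. Linear interpolation is adequate at the grid
  resolution used; any smooth interpolant agrees to well under a grid
  step.
* **Relaxation.** τ_c is the least-squares exponential decay time of the
  normalised N_c(t) fluctuation autocorrelation over the window C ≥ 0.05;
  a series that never decays below that is reported as a flagged lower
  bound (frozen network). τ_c(T) over the decaying regime is fitted as
  a·exp(E_a/T) by linear regression in log-space.
* **Structure.** g(r) over core beads with 0.1 σ bins (resolving the
  6.4/6.9 σ peak pair of non-planar gels); degree histograms, components
  and the largest-component fraction c_s through igraph; the bending angle
  ϕ of a bond is the angle between one arm axis and the partner's reversed
  axis, pooled over bonds and frames in 5° bins.
* **Rheology.** The configurational virial gives the off-diagonal stress;
  a hand-rolled multiple-tau correlator (p = 16 points per level, m = 2
  block averaging — the standard streaming scheme, validated against
  brute-force autocorrelations) accumulates
  G(t) = (V/3k_BT) Σ_αβ 〈P_αβ(0)P_αβ(t)〉, and η = ∫G dt by trapezoid up
  to the first noise-floor crossing (twice the standard deviation of the
  long-lag tail), with a block-average error estimate and a flagged lower
  bound if G has not decayed.

## Problem sizes used by the tests

The packaged studies are deliberately scaled down so the whole suite runs
on one CPU in tens of minutes: gels of N = 40 stars at ρ = 0.01
(L ≈ 24.5 σ), quenches of 250 τ_Br followed by 350 τ_Br of production,
dt = 10⁻⁴ τ_Br, and a temperature grid
{0.8, 1.0, 1.1, 1.15, 1.2, 1.3} (the sweep resolution is finest around
the melting region). Green–Kubo viscosities are taken at
T = 1.15 from 1500 τ_Br of stress sampling: in the colder gel the modulus
does not decay within an affordable window and the integral would only be
a flagged lower bound, while at 1.15 both networks relax within ~10² τ_Br
and the planar/non-planar contrast is well defined. At these sizes the
melting curve,
network metrics, bending angles, MSD ordering and the planar/non-planar
viscosity contrast are all measurable, but with visible finite-size and
finite-time effects: the low-temperature plateau of 〈θ〉 sits near 0.75
rather than ≈ 0.95 (bond formation at ρ = 0.01 is diffusion-limited and
slow compared to the run length), curves carry statistical error from a
single seed per temperature, and absolute viscosities are far below the
reference long-run values (the stress autocorrelation is integrated only
as far as these runs resolve it). Qualitative orderings — which geometry
melts higher, moves faster, connects better — are robust at this scale;
absolute numbers tied to very long runs are not, and the tests assert
them only at correspondingly loose tolerances.

## Known limitations

* Rigid templates: arm-angle fluctuations and intramolecular
  self-hybridisation are outside the model (by design — the rigid body is
  the object of study).
* The single-patch-type bond is self-complementary and non-specific, as in
  the experimental design, but sequence-level thermodynamics (individual
  melting temperatures, salt dependence) is not represented; temperature
  is meaningful only in reduced units.
* Hydrodynamic interactions are absent; mobilities are isotropic
  single-body coefficients, so absolute time scales are model time, not
  mapped time. The σ/ε/τ_Br → SI helpers (`eta_to_Pa_s()`) are reporting
  conveniences only.
* The first-order Wertheim relation used in the calibration ignores ring
  cooperativity; the emergent network can (and does) shift observables
  like the low-T plateau relative to the two-star prediction.
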