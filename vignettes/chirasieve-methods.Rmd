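---
title: "Methods: pore models, complex screening and propagation profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pore models, complex screening and propagation profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`chirasieve` is a screening toolkit for chiral separation by molecular
sieving through single-atom-thick membranes. This vignette documents the
scientific model, the tunable parameters and the numerical and design
choices, so that every number the package produces can be traced to a
stated convention.

## The separation model

A chiral gatekeeper molecule bonded to a pore rim forms a temporary
bimolecular complex with a chiral target arriving from solution. Because
the complex must swing through the pore in a single barrier-crossing event,
the *size* of the complex — not the binding strength — controls the
propagation rate. For a complex geometry we use the size descriptor

$$R = \max_{i,j} \lVert \mathbf{r}_i - \mathbf{r}_j \rVert,$$

the distance between its two most distant atoms (`max_extent()`). For a
target/partner combination the screen compares the lowest-energy complex
of the opposite-chirality pairing (RS) with that of the same-chirality
pairing (SS):

$$\Delta E = E_{RS} - E_{SS}, \qquad \Delta R = R_{RS} - R_{SS}.$$

A combination with large $|\Delta R|$ is a good candidate for size-based
enantioselective sieving, since the size difference translates into a
barrier-height difference when the pore diameter lies between the two
complex sizes.

## Internal energy model

The package's own engine is a rigid-fragment nonbonded model,

$$E = \sum_{i \in A}\sum_{j \in B} 4\varepsilon_{ij}
\left[\left(\tfrac{\sigma_{ij}}{r_{ij}}\right)^{12} -
\left(\tfrac{\sigma_{ij}}{r_{ij}}\right)^{6}\right]
+ \frac{k_e\, q_i q_j}{r_{ij}},$$

with $k_e = 332.0636$ kcal·Å/(mol·e²), Lorentz–Berthelot mixing by default,
and a 12 Å cutoff (hard truncation, energies unshifted; `cutoff = "none"`
disables truncation). The per-element $\sigma/\varepsilon$ table is
UFF-derived ($\sigma = x_\mathrm{vdW}/2^{1/6}$) and is a deliberately
generic stand-in: the package's conclusions are engine-agnostic by design,
and production-quality energetics are expected to come from an external
backend implementing the engine contract (`external_engine()`, XYZ-in /
energy-out). Units are fixed throughout: kcal/mol, Å, elementary charges,
Kelvin.

Two consequences of hard truncation are handled explicitly:

* **Cutoff-edge artifacts.** With partial charges, truncating atom pairs at
  12 Å places only part of a neutral fragment's charge cloud inside the
  sphere, creating artificial wells of up to several kcal/mol at ~12 Å
  separation. The complex search therefore returns only *bound* candidates:
  poses whose closest inter-fragment contact exceeds 5 Å are discarded.
* **Hard-core overlaps.** Rigid scans reach strongly repulsive geometries;
  energies above a cap (default $10^4$ kcal/mol) are clamped and flagged so
  splines stay finite while the barrier ordering is preserved.

The engine is exactly translation-, rotation- and mirror-invariant (it
depends only on interatomic distances), which is what makes $E_{RR} =
E_{SS}$ testable; `mirror_invariance_check()` verifies this for any engine.

## Pore models and the diameter convention

Graphene flakes are built on the ideal honeycomb lattice with aromatic
C–C = 1.42 Å and C–H = 1.09 Å (`lattice_spec()`); pores are cut by removing
rings and passivating every exposed carbon with an in-plane hydrogen along
the former bond direction. The graphdiyne unit is a single triangular pore:
three benzene corners joined by diacetylene links (bond lengths 1.40 /
1.24 / 1.33 Å). Geometries are idealized and unrelaxed — reproducible counts
and diameters are the point; relaxation belongs to an external engine and
is never implicit.

The pore diameter is reported as the **geometric** opening: twice the
radius of the largest circle, centered in the membrane plane (Chebyshev
center near the pore center), that touches no rim atom center. A `"vdw"`
convention (subtracting van der Waals radii of the limiting atoms) is also
implemented. The geometric convention is the calibrated default: with the
shipped presets it reproduces the reference openings 6.0 / 5.6 / 5.6 Å for
the 4-ring graphene, 3-ring graphene and graphdiyne models (measured:
6.037 / 5.500 / 5.616 Å), whereas the vdW-corrected convention cannot
reproduce any of them. The convention is fixed once and recorded in the
model metadata.

The ring layouts were a genuinely open choice (reference figures show but
do not enumerate the removed rings). For the 4-ring pore a compact rhombus
of fused hexagons measures only ~5.76 Å geometrically; the shipped
`graphene4` preset instead removes a central ring plus three alternating
neighbours (a triphenylene-shaped, three-fold-symmetric hole), which gives
6.037 Å and matches the reference opening. `graphene3` is the compact
triangle; `graphene5` extends the 4-ring layout by one adjacent ring and is
the preset meant for gatekeeper functionalization. Layouts are overridable
(`build_graphene_flake()` + `cut_pore()` accept arbitrary axial ring sets).

Nitrogen substitution (`substitute_nitrogen()`) replaces a rim C–H unit by
bare N — the minimal pore enlargement — with site pickers for the two
scenarios of interest: `"opposite"` the gatekeeper (enlarges the opening)
and `"adjacent"` to it (frees the gatekeeper's swinging motion).

## Complex search

`find_complex_minima()` performs a rigid 6-DOF search (molecule B's
rotation vector + translation relative to fixed molecule A): starting poses
on a prefix-stable low-discrepancy sphere around A with seeded random
orientations, each locally minimized by a derivative-free compass/pattern
search (steps halved on failure; convergence when the largest step falls
below `tol`, default $10^{-5}$). The search is two-stage — every start is
polished coarsely, then the distinct low-energy candidates are refined
fully — and candidates within 0.25 Å aligned RMSD are merged. The seed is
mandatory and makes runs bit-reproducible; enlarging `n_starts` only
appends starts, so the best energy is non-increasing in `n_starts`.
Monomers stay internally rigid: the internal engine has no intramolecular
terms, and flexible-monomer optimization is delegated to external engines.

`best_complex()` takes the lowest energy, with ties broken by smaller
$R$, then by start id. Self-pairings use two copies of the same monomer
with independent chirality assignment.

## Propagation scans, extrema and pathways

`rigid_scan()` pushes the rigid molecule along the membrane normal through
the pore center on a 0.25 Å grid (default range $[-8, 8]$ Å), with a fixed
orientation and no rotation — a well-defined Cartesian reaction coordinate
that allows point-wise comparison between engines. The zero of energy is
the infinitely separated pair, realized deterministically by an evaluation
at $3\times(\text{cutoff} + \text{extents})$ along the normal, where the
internal engine is exactly zero. Note that at the default range ends the
energy is small but not zero (the 12 Å cutoff sphere still reaches the
pore); the exact-zero region starts beyond the cutoff plus extents.

Profiles are interpolated with the classic cubic spline
(Forsythe–Malcolm–Moler end conditions). FMM was chosen over natural end
conditions because it reproduces cubic polynomials exactly, which anchors
the interpolation tests; on the 0.25 Å grids the two differ only near the
range ends. Extrema are located by root-finding on the spline derivative
(exact zeros at grid points are treated as crossings), classified by the
second derivative, and mapped in z-order onto the five-slot pathway schema
*left minimum → 1st transition state → intermediate → 2nd transition state
→ right minimum*, with absent slots left empty and the rate-determining
step defined as the highest transition state.

`neb_band()` implements improved-tangent NEB with finite-difference
gradients and a projected-velocity (quick-min) integrator; the climbing
image is optional and off by default (no variant was prescribed).
For a molecule in a pore (`neb_path()`) the band runs over 6-DOF rigid
poses — a documented simplification; a flexible treatment belongs to an
engine with internal degrees of freedom. The saddle estimate is the
maximum of a cubic spline of energy over normalized arc length, and the
band maximum can only lie at or below the rigid-scan maximum for the same
endpoints, since the band relaxes the lateral and rotational constraints.

Barrier heights are reported in both conventions — from the global zero
(separated species) and from the preceding minimum — because both appear in
selectivity reasoning. `selectivity_estimate()` maps a barrier difference
onto a Boltzmann ratio $\exp(-\Delta\Delta E / k_B T)$ and
`permeance_indicator()` maps a single barrier onto
$\exp(-\max(0, E^\ddagger)/k_B T)$, with $k_B = 0.0019872$ kcal/(mol·K) and
a default temperature of 298.15 K. These are order-of-magnitude indicators
on the electronic surface, not rate predictions: no zero-point energy,
thermochemistry or entropic corrections are applied.

## Fixtures: what they emulate and what they do not

All inputs are generated deterministically in code with idealized
literature bond lengths (not optimized geometries):

* `co2_like`, `ch4_like`, `ethane_like` — prototypes of an elongated
  cigar-shaped, an almost spherical, and a corrugated electron density.
  The CH4-like probe is oriented tip-first (one C–H bond on +z), which
  produces the characteristic asymmetric profile with the global minimum
  on the entry side.
* `chiral_probe` — a *synthetic* tetrahedral probe: four distinct arms
  (H, F, Cl and an elongated 2.30 Å heavy arm) with a ±0.3 e charge lock
  on the H/F arms. It is deliberately size-mismatched so that the lowest
  RS and SS dimers dock in distinctly sized geometries
  ($\Delta R \approx +0.58$ Å under the internal engine, sign confirmed by
  an independent grid search); a plain halomethane geometry gives nearly
  congruent dimers under a pairwise LJ model and would be useless as a
  witness fixture.
* `aminoethanol` — idealized 1-aminoethanol, the classic gatekeeper/target,
  both enantiomers.
* the 5-template library — acid, aldehyde, alcohol, olefinic alcohol and
  ether templates, each a stereocenter with four distinct substituents,
  with simple stand-in partial charges (roughly electronegativity-ordered,
  neutral overall; not derived from any published charge model).

Passing tests on these fixtures demonstrate the machinery — search
convergence, symmetry and invariance properties, barrier ordering — under
a pairwise additive model on rigid idealized geometries. They do not
demonstrate chemical accuracy for real complexes: monomer flexibility,
polarization, charge transfer and relaxed pore geometries all require an
external engine, and the screening numbers for the template library are
not comparable to quantum-chemical results.

## Problem sizes and determinism

The default study conditions are: 64 starting poses per pairing (seed 7)
for the 15-combination template screen; 0.25 Å scan steps over
$[-8, 8]$ Å for the 3 pores × 3 probes propagation matrix; 11–15 NEB
images. The full default test matrix runs in a few minutes on one CPU.
Every stochastic operation takes a mandatory seed, and identical
configurations are bit-reproducible.

## Known limitations

* The internal engine is a screening device, not a force field; absolute
  energies and barrier heights from it should only be compared with each
  other.
* Rigid monomers and rigid pores overestimate barriers at tight fits (the
  familiar failure mode of pairwise models under strong steric hindrance);
  the overlap cap keeps these finite but they should be read as "blocked",
  not as quantitative heights.
* The 3-ring preset's geometric opening (5.500 Å) sits at the edge of the
  0.1 Å band around the 5.6 Å reference value; the exact removed-ring
  topology of the reference models is not enumerable from the source
  figures.
* Periodic membranes, multilayer stacks, solvent, dynamics and transport
  statistics are out of scope.
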