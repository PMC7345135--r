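---
title: "Simulating beta-dispersion with a thin-shell equivalent-membrane FEM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating beta-dispersion with a thin-shell equivalent-membrane FEM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betadisp)
```

## The physical problem

A biological cell in suspension is, electrically, a blob of conductive
cytoplasm wrapped in a ~5 nm lipid membrane that barely conducts
(σ ≈ 10⁻⁷ S/m), floating in a conductive medium. Under an alternating
field, charge piles up on either side of the membrane — Maxwell–Wagner
interfacial polarization. As frequency rises the membrane capacitance
progressively short-circuits: the suspension's apparent relative
permittivity falls from a large low-frequency value to that of the bare
fluids, and its conductivity rises. This is the **β-dispersion**,
occupying roughly the 100 kHz–10 MHz band for mammalian-sized cells, and
it is the signal that bio-impedance spectroscopy instruments read.

`betadisp` provides three routes to this spectrum and the machinery to
compare them:

1. an **analytical** single-shell + mixture model,
2. a **2D finite-element** forward solver on a meshed suspension domain,
3. the same FEM after a **thin-shell equivalence transform** that
   replaces the 5 nm membrane by a thicker layer of equivalent complex
   conductivity, cutting the number of mesh elements.

The package's purpose is the third route: quantifying how cheaply and
how faithfully the thickened membrane reproduces the full model.

## Models

### Dielectric bookkeeping

Every phase is a `material(conductivity, rel_permittivity)` with
frequency-independent σ and εr. At angular frequency ω its complex
relative permittivity and complex conductivity are

ε\* = εr + σ/(jωε₀),  σ\* = σ + jωε₀εr,  σ\* = jωε₀ε\*,

with the e^{+jωt} time convention (lossy ⇒ negative imaginary ε\*) and
ε₀ fixed at 8.8541878128×10⁻¹² F/m. The two representations are
interchangeable (`eps_to_sigma()`, `sigma_to_eps()`); spectra store σ\*
and expose σ_r = Re σ\* and ε_r = Im σ\*/(ωε₀).

### Single-shell cell and mixture

The membrane+cytoplasm inclusion is collapsed into one equivalent
permittivity

ε_p\* = ε_m\* · [2(1−v)ε_m\* + (1+2v)ε_c\*] / [(2+v)ε_m\* + (1−v)ε_c\*],
v = (1 − d_m/R)ⁿ,

with n = 2 for the planar (cylinder cross-section) model and n = 3 for
the sphere — the same printed algebraic form is used for both, only the
shell factor v changes. The suspension then follows from Wagner's dilute
mixture formula at volume fraction P:

ε\* = ε_a\* · [2(1−P)ε_a\* + (1+2P)ε_p\*] / [(2+P)ε_a\* + (1−P)ε_p\*].

Both formulas interpolate exactly at their endpoints (v → 1 gives the
cytoplasm, P ∈ {0, 1} gives medium/inclusion), which the test suite
asserts.

A deliberate convention note: the mixture formula above is the
**three-dimensional** dilute form, and the package applies it as written
for both n = 2 and n = 3 cell models, because that is how the workflow
it implements is defined. The true 2D dilute limit for an insulating
cylinder is σ/σ_a = (1−P)/(1+P) = 0.9324 at P = 0.035, whereas the 3D
form gives 2(1−P)/(2+P) = 0.9484. The FEM (which solves honest 2D
physics) is therefore *expected* to deviate from the analytical route by
O(P) at low frequency; `run_analytical_overlay()` reports this gap
rather than hiding it, and the 2D closed form is kept as an independent
oracle for the solver, never silently substituted into the analytical
route.

### Debye relaxation

For thin membranes and a poorly conducting shell the suspension spectrum
is a single-time-constant Debye relaxation plus a conduction term,

ε\* = ε_h + (ε_l − ε_h)/(1 + jωτ) + k_l/(jωε₀),

with characteristic frequency f_c = 1/(2πτ). `fit_debye()` fits
(ε_l, ε_h, τ, k_l) jointly to σ_r(f) and ε_r(f) by bounded
Levenberg–Marquardt (minpack.lm) on *relative* residuals, since the two
channels differ by orders of magnitude in units. τ is fitted on a log
scale; initial values are taken from the spectrum itself (first/last
ε_r, first σ_r, steepest ε_r descent for τ). On noiseless Debye data the
fit is a parameter-recovery identity to better than 10⁻⁶ relative; on
the analytical suspension spectrum of the canonical cell it returns
f_c ≈ 1.6 MHz — inside the 100 kHz–10 MHz dispersion band — with
residuals at the 10⁻¹² level, confirming that the dilute single-shell
suspension is itself essentially a perfect single relaxation.

### Thin-shell equivalence

The acceleration replaces the true membrane (thickness l₁, σ₁\*) plus a
slab of thickness l₂ carved from the cytoplasm (σ₂\*) by a single layer
of thickness l₁+l₂ with

σ_e\* = (l₁+l₂)·σ₁\*σ₂\* / (l₁σ₂\* + l₂σ₁\*),

i.e. the series-impedance-preserving conductivity of the two layers at
equal cross-section. For a flat stack the substitution is exact at every
frequency (asserted against direct series-impedance arithmetic); on a
curved shell the error is O((l₁+l₂)/R) — 0.4% geometric ratio for the
canonical 1:3 case. Two limits are identities: l₂ = 0, and σ₁\* = σ₂\*.
When the added layer conducts well and the membrane does not, σ_e\*
reduces to the membrane capacitance spread over the thicker layer:
ε_e(l₁+l₂) ≈ ε₁/l₁ per unit area, so the membrane capacitance
C_m = ε₁ε₀/l₁ ≈ 8.85 mF/m² is preserved (asserted within 1% at 1 MHz).

`equivalent_cell(cell, l2)` packages this: the returned model has
membrane thickness l₁+l₂, shell factor v = (1−(l₁+l₂)/R)ⁿ, and a
frequency-dependent membrane dielectric σ_e\*(f). Because σ_e\* mixes
conduction and displacement terms that scale differently with ω, it is
re-evaluated at every frequency rather than cached as a fixed material.
Thickening is applied **inward** (outer membrane surface stays at R, the
added layer replaces cytoplasm, whose electrical parameters it shares);
the geometric alternative — thickening outward into the medium — would
change the inclusion's outer radius and hence the volume fraction, which
is why the inward convention was adopted.

## The finite-element forward model

The quasi-static potential obeys ∇·((σ+jωε)∇U) = 0 on a square
suspension domain: top edge at 10 V, bottom at 0 V, side walls
insulating (the parallel-plate reading of the electrode cell; the side
condition is a modelling convention, stated here because the physical
set-up leaves it open). Discretisation is standard P1 (3-node
triangle) Galerkin with element-constant complex conductivity, giving a
complex-symmetric sparse system.

R's sparse-matrix stack has no complex factorization, so the system
K = K_r + iK_i is solved through the real block embedding
[[K_r, −K_i], [K_i, K_r]] with Matrix's sparse LU plus a few steps of
iterative refinement (relative residuals ~10⁻¹⁴, electrode-flux balance
~10⁻¹³). This direct path is the default. A complex,
Jacobi-preconditioned BiCGSTAB with warm starting from the previous
frequency in a sweep is provided as the iterative path; it falls back to
the direct solver (with a message) when it does not reach tolerance, and
the two paths agree to solver precision.

The suspension's effective property comes from the electrode current:
the reactions of the eliminated Dirichlet rows give
I = −Σ_bottom (K u), which is exactly conservative in the discrete sense
(top and bottom fluxes balance to the solver residual), and

σ\* = (L/S) · (I/U),

with L the electrode spacing and S the electrode width × 1 m — the 2D
per-unit-depth reading of "electrode area", which keeps the formula
dimensionally consistent. A plane-sum diagnostic, `cut_line_current()`,
integrates σ\*∂U/∂y across any horizontal cut; it agrees with the
reaction current to ~10⁻⁴ relative on default meshes and is exposed for
verification, while the reaction estimator (being exactly conservative
and free of cut-placement ambiguity) is the one used for reported
spectra.

Verification, all in the test suite: exact reproduction of linear
potentials on homogeneous media (P1 exactness, machine precision);
agreement with a dense-matrix brute-force assembly+solve on small
hand-built meshes to 10⁻¹²; the Wiener (series/parallel) bounds at DC;
and the dilute insulating-disc closed form σ/σ_a = (1−P)/(1+P) within
0.5% — the oracle is evaluated at the *meshed polygon's* area fraction,
so the check isolates field error from geometric approximation.

## Meshing

A 5 nm band on a 5 µm cell inside a ~47 µm box spans four orders of
magnitude, which rules out a generic Delaunay mesher at acceptable
aspect ratios (and no constrained-triangulation library is available to
this package). `generate_mesh()` therefore builds a deterministic
structured **O-grid**:

* the cell outline is sampled uniformly in arc length with spacing set
  by `max_element_size`; the four samples whose centre-rays pass through
  the domain corners are placed exactly, so the outermost ring of nodes
  tiles the square boundary exactly (region areas sum to W·L to ~10⁻¹²
  relative);
* the membrane band is a structured annulus of `membrane_layers`
  (default 3) quadrilateral rings split into triangles — the analogue of
  a commercial mesher's "narrow factor";
* radial node layers grow geometrically (rate `max_growth_rate`,
  default 1.20) from the band thickness, clamped to
  [`min_element_size`, `max_element_size`] (defaults 0.01 µm, 0.5 µm),
  inward to a centre fan and outward to the square.

Because the radial ladder starts at the membrane-band thickness, a
thicker (equivalent) membrane yields strictly fewer elements — the
economy the acceleration exists to exploit — while identical inputs
always produce byte-identical meshes. Meshes carry region tags
(medium/membrane/cytoplasm) and boundary tags (electrodes/sides), can be
validated (`validate_mesh()`: conformity, positive CCW areas, exact area
tiling, hanging-node detection on boundary edges), and round-trip
through a documented plain-text `.tmesh` format (0-based indices on
disk) and Gmsh MSH v2 with regions as physical groups.

The default `max_element_size` of 0.5 µm was fixed by a mesh-convergence
study of the quantities the package reports: over maximum sizes of
1/0.5/0.25 µm the full-vs-reduced spherical 1:3 deviation is
0.139/0.138/0.136%, the 1:1 deviation 0.048/0.046/0.045%, and the
insulating-disc oracle error 7.9×10⁻⁴/2.2×10⁻⁴/5.8×10⁻⁵ — i.e. the
reported deviations are mesh-converged at 0.5 µm with a factor-two
margin each way, at ~14 k elements and well under a minute for a
15-frequency spherical comparison on one core. (A commercial mesher's
"0.1 µm maximum" control is not comparable: its unstructured growth
coarsens far from the membrane, whereas the O-grid keeps its angular
count everywhere, so a global 0.1 µm here would cost ~20× more elements
for no change in the reported numbers.)

## The comparison experiment

`run_comparison()` orchestrates the headline experiment: mesh and sweep
the full model (d_m = 5 nm), then for each thickness ratio l₂:l₁
(presets 1:1 and 1:3) mesh and sweep the equivalent model, and report
per-frequency relative deviations of σ_r and ε_r plus their maximum.
"Error" is operationalised as the **maximum over the 15 sampled
frequencies and both channels** — the most conservative reading of a
scalar error for a pair of spectra; both per-frequency curves are
emitted so any alternative metric can be recomputed from the output.
Wall-clock times per sweep are logged in the human-readable summary for
interest but never asserted, since they are hardware- and
library-specific.

At the canonical study conditions (P = 0.035, 15 log-spaced points,
1 kHz–100 MHz) the package obtains a maximum deviation of ~0.14% for the
spherical 1:3 case (1:1 is ~3× smaller), and ~0.03% for the 12×2 µm
elliptical cell, with the reduced meshes 15–13% smaller in elements —
the element economy is milder than a narrow-band-driven unstructured
mesher would show, because the structured annulus already tames most of
the narrow-band cost in the full model. The purely analytical version of
the same comparison (shell factor rewritten with l₁+l₂, σ_e\* membrane)
gives 0.07%/0.22%/0.66% at ratios 1:1/1:3/1:9, monotone in l₂, bounding
the same physics from the formula side.

## Degenerate inputs and numerical choices

* Frequencies must be positive and strictly increasing; f = 0 is
  rejected (the conduction term of ε\* diverges) — DC behaviour is probed
  at, e.g., 1 mHz.
* Shell and mixture denominators are checked against machine-epsilon
  collapse and report which parameters are degenerate.
* `fit_debye()` refuses flat spectra ("no relaxation detected") and
  non-convergence carries the initial guess and residual.
* Membrane bands thinner than the coordinate resolution of the domain
  (64 ulp of the side length) are rejected with advice to rescale.
* The Debye fit's only tie-break — a swapped (ε_l, ε_h) optimum — is
  relabelled rather than rejected, the model being symmetric under the
  swap.
* The cut-line diagnostic nudges its line off mesh node rows (by ~10⁻¹⁰
  of the domain height) so a cut through a structured node row cannot
  double-count element strips.

## What the built-in conditions do and do not show

The canonical parameter set (σ_membrane = 10⁻⁷ S/m, σ_fluids = 1 S/m,
ε_r 5/80/80, R = 5 µm, d_m = 5 nm, P = 0.035) is a textbook idealised
mammalian cell: three homogeneous phases, one cell per periodic-like
box, no α-dispersion (surface conductance), no γ-dispersion (fluid
dipolar relaxation), no electrode polarization, no cell–cell
interaction. Passing the package's checks under these conditions
validates the *numerics* — the equivalence transform, the solver and the
meshing — not the biological fidelity of the single-shell picture.
Multi-shell organelles, membrane anisotropy and concentrated suspensions
are out of scope; so is the 3D eddy-current (induction-coil)
formulation, of which only the 2D contact-electrode problem is
implemented here.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run the spherical comparison at
the default 0.5 µm mesh (~14 k elements, 15 frequencies) and the
elliptical one at ~25 k elements; property tests use 2 µm meshes
(~4 k elements) where the property being checked is
resolution-independent. These sizes are the convergence-study choice
described above: the reported deviations change by less than 2% of
themselves when every element is halved.
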