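---
title: "Methods: temporally weighted geometry fusion and reduced-order FFR"
author: "dynffr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: temporally weighted geometry fusion and reduced-order FFR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynffr)
```

# Overview

`dynffr` estimates fractional flow reserve (FFR) from a *dynamic*
description of a coronary vessel: one surface mesh, centerline and lumen
profile per cardiac phase, eleven phases covering 0–100 % of the R–R
interval. The chain is

1. per-phase differential geometry (arc length, radius, area, curvature,
   torsion);
2. a biphasic coronary inlet velocity model, personalized from
   contrast-enhancement ratios;
3. hemodynamically weighted fusion of the phases into one effective
   geometry;
4. cardiac functional metrics (LV volumes, regurgitation-corrected
   cardiac output, aortic pressure from root-area pulsation) that feed
   Windkessel boundary conditions;
5. a quasi-static distributed-resistance network solve yielding
   time-averaged pressures and `FFR = P̄_d/P̄_a`.

This vignette documents the model assumptions, the tunable parameters,
the numerical choices, and what the synthetic-data generator does and
does not emulate.

# The flow model and its personalization

Resting coronary flow is diastole-dominant. The inlet velocity is the
sum of two Gaussians in phase fraction `x = t/T`,
peak 1.0 at `x = 0.7` (diastole, width `σ_d = 0.15`) and peak 0.4 at
`x = 0.3` (systole, width `σ_s = 0.1`). The Gaussians are evaluated on
the single cycle without periodic images: the neglected tails at the
cycle edges are below `exp(−8)` of the peak, which is smaller than any
other modelling error in the chain.

The diastolic-to-systolic velocity ratio (DSVR) is reported as the ratio
of the waveform maximum over the diastolic window to the maximum over
the systolic window, with the split at 40 % of the cycle — the clinical
convention for resting coronary traces. Note that the systolic-window
maximum of the *summed* waveform (`r round(dsvr(flow_profile_params()), 4)`
for the defaults) sits slightly above the systolic component peak, so
this window-based DSVR is a little below the ratio of component peaks;
both conventions are defensible, the window split is configurable.

Personalization multiplies the baseline profile by the per-phase
contrast-enhancement ratio `R_i = (HU_i − HU_base)/(HU_peak − HU_base)`
and a global calibration factor α. No formula for α is standard; the
package ties it to an absolute flow scale by requiring that the mean
personalized inlet flow `A_inlet · mean(α R_i V(t_i))` equal the
coronary allocation `Q_cor = f_cor · CO_eff` (`calibrate_alpha()`).
Ratios above 1 (enhancement overshoot) are passed through with a
warning rather than clamped, so calibration sees the measurement.

# Fusion weights

The per-phase, per-arc weight has a flow factor and a geometric factor.
The flow factor is the phase's share of inlet velocity. The geometric
factor sums three dimensionless terms:

* **flow acceleration** `α·|dA/ds|/A · Re/Re_ref` — the absolute value
  is deliberate: accelerations and decelerations must both raise the
  score, a signed term would cancel them along the lesion;
* **secondary flow** `β·κD_h²·Re/Re_ref·(1 + τD_h/(κ+ε))` — the Dean
  analogy for curvature-induced vortices with a torsional enhancement
  for helical segments;
* **stenotic narrowing** `γ·((A_ref−A)/A_ref)^1.5` against the
  across-phase maximum area `A_ref(s)`.

Parameter defaults and rationale:

| parameter | default | units | role |
|---|---|---|---|
| α, β, γ | 1 each | — | term coefficients; no canonical values exist, so they are equal by default, exposed in `fusion_config()` and echoed in every run manifest |
| ε | 1e-8 | 1/mm | guards the κ denominator of the torsion factor on straight segments |
| δ (`weight_floor`) | 1e-6 | — | added to every geometric weight so a featureless straight tube degrades to flow-only weighting instead of 0/0 at normalization |
| `Re_ref` | 500 | — | typical coronary Reynolds number used to non-dimensionalize |

Weights are normalized across phases at every arc position
(`Σ_i w_i^norm(s) = 1`, asserted to 1e-9 in the tests), making the fused
vertex positions, effective radius and effective curvature convex
combinations of the per-phase values — the bounds
`min_i ≤ fused ≤ max_i` are tested properties.

Phases may differ slightly in total centerline length (bending), so all
per-phase quantities are resampled onto a common *normalized* arc grid
`s/L` before weighting; otherwise sections would misalign between
phases. Each phase's mesh vertices look up weights at their own
normalized arc position, which makes the fusion exactly equivariant
under phase permutation.

Torsion on straight or locally planar segments is defined as 0: the
Frenet frame is undefined there, 0 is the planar-curve limit, and it
keeps the torsion factor finite. Curvature and torsion are computed by
central finite differences on the arc-length grid (one-sided,
three-point stencils at the ends); against closed forms (circle, helix)
the interior error at 200-point sampling is below 1 %.

# Cardiac function

LV volume is the divergence-theorem surface integral over the closed
endocardial mesh, computed as a sum of signed tetrahedra; open,
non-manifold or inward-oriented meshes are rejected with a defect
report. EDV/ESV are the curve extrema, `SV = EDV − ESV`.

Regurgitant volume uses the area-based surrogate
`RV = ∫(A(z,t_dia) − A(z,t_AVC))dz` over the aortic root (trapezoid
rule), because root areas are what multi-phase CT actually measures; a
directly measured retrograde flow series `Q_retro(t)` is accepted as an
alternative input and integrated in time. RV is clamped to `[0, SV]`:
a negative raw integral signals measurement noise, not antegrade gain.

Aortic pressures come from the linearized area–compliance relation
`ΔP/P0 = (1/β)·ΔA/A0`. The compliance coefficient β is dimensionless
here (some literature forms use `ρ·PWV²`); it has no agreed value, so
it defaults to 0.5 and should be tuned when cuff pressures are
available — `P0` itself should be the measured diastolic pressure. The
diastolic outlet waveform `P = P_sys·exp(−t/τ) + P_dia` is taken at
face value as a monotone decay; no systolic upstroke is synthesized,
and τ defaults to the `Rd·C` of the attached Windkessel.

# Boundary conditions

The printed two-harmonic aortic inflow shape
`f(t) = 0.8 sin(ωt+π/4) + 0.3 sin(2ωt+π/6) + 0.1` has cycle mean 0.1,
so scaling it by `CO_eff` directly would deliver a mean flow of only
10 % of the cardiac output. The default mode therefore renormalizes the
shape so the cycle-average flow equals `CO_eff`; the literal "raw" mode
is retained for fidelity, and the mode in force is recorded in exported
metadata. The renormalized shape has large negative excursions (it is a
shape convention, not a measured waveform); these are reported in logs.

The aorta carries the 3-element Windkessel (`Rp = 3.31e7 Pa·s/m³`,
`C = 1e-9 m³/Pa`, `Rd` scaled inversely with effective output from
`Rd_ref = 3.35e8` at `CO_ref = 5 L/min`); coronary branch outlets carry
2-element models computed from the fused geometry: the systemic bed
behind the aorta needs the characteristic-impedance element, while the
coronary microvascular beds are adequately lumped as R–C pairs. The wall
modulus E has no universal formula — it rises with age and
cardiovascular risk — so the package ships a coarse age-band lookup
(`elastic_modulus_by_age()`, 0.8–1.6 MPa), overridable everywhere.

The Womersley velocity profile is implemented as the standard
per-harmonic oscillatory solution (mean flow as Poiseuille plus the
first five Fourier harmonics of `Q(t)` with complex Bessel functions,
evaluated by power series — accurate to machine precision for
physiological Womersley numbers). The simplified time-independent
shape-factor form is available as a mode. Both renormalize the discrete
profile at every instant so its cross-section integral carries exactly
`Q(t)`, which also enforces no-slip.

# Reduced-order pressure solve

The full 3D incompressible Navier–Stokes solve is deliberately out of
scope; the package's contract is the pressure-ratio pipeline, with the
boundary bundle exporter (`export_boundary_config()`) providing the
hand-off to an external CFD code. The surrogate is a quasi-static
distributed-resistance network:

* each branch contributes `R = ∫ 8μ/(π r_eff(s)⁴) ds` (composite
  trapezoid on the arc grid);
* a focal stenosis adds the irreversible expansion loss
  `ΔP = K_t (ρ/2)(Q/A_min − Q/A_ref)²` with the classical
  sudden-expansion coefficient `K_t = 1.52`, attached at the
  minimal-area position when narrowing exceeds 2 %;
* junction flows satisfy conservation and the affine outlet
  pressure–flow relations exactly (the tree is collapsed bottom-up into
  per-node affine relations, then flows are distributed top-down);
* the quadratic stenosis term is resolved by damped fixed-point
  iteration (damping 0.7) to residual < 1e-8, with the residual history
  reported on failure;
* stateful 3-element outlets advance their distal pressure between
  instants with an exponential integrator (exact for piecewise-constant
  flow) and cycles repeat until the field is periodic to 0.1 %.

Flow inertia (Womersley effects, ∂u/∂t) is neglected in this solve:
FFR uses time-averaged pressures, which at desk scale are dominated by
resistive losses. The same exponential integrator drives
`windkessel3_solve()`, where it reproduces the analytic RC decay and
the `P = Q(Rp+Rd)` fixed point to rounding error — an ordinary ODE
library would add a dependency without adding accuracy for this scalar
linear equation.

FFR is evaluated by default one lumen diameter beyond the
minimal-radius point — a reporting convention (where a pressure wire
would sit), overridable by arc position. Because fused `r_eff` is a
convex combination of phase radii, the FFR on the fused geometry lies
between the per-phase extremes; this and the strict decrease of FFR
with stenosis severity are tested properties.

FFR is defined at maximal (adenosine) hyperemia. The pipeline scales
the resting personalized coronary waveform by `hyperemia_factor`
(default 4, the conventional several-fold hyperemic flow reserve of a
healthy microvascular bed) and calibrates the outlet resistance so that
the time-averaged ostial pressure matches the aortic estimate from
root-area pulsation. Prescribing hyperemic *flow* ignores the
flow-limiting effect of severe lesions; for severities far above the
default the assumption becomes optimistic (see Limitations).

# The synthetic-dynamics generator

The generator exists so that every downstream stage has inputs with
known ground truth. It emulates:

* 11-phase tube sequences with shared topology; elliptical
  cross-sections obeying `πab = A₀(1+ε_r)` exactly at every phase, with
  radial strain bounded by the physiological ±5 %;
* periodic motion (radial strain, ovalization, bending, bulk
  translation, all ∝ sin(2πt/T)) so phases 0 and 100 % coincide; both
  are retained because downstream sums run over all 11 indices;
* Gaussian stenoses whose minimal resting area is exactly
  `(1−severity)·A_ref` at a grid point;
* prolate-spheroid LV surfaces whose *mesh* volume is calibrated to the
  requested curve, so EDV/ESV/SV recovery is exact up to rounding, and
  sphere-volume convergence can be tested against `4/3πR³`
  independently;
* aortic-root area fields whose diastolic excess integrates to a known
  regurgitant volume.

Defaults are a 40 mm vessel of 2 mm radius (a proximal coronary
segment), 81 axial stations (a node exactly at mid-vessel), 24
circumferential vertices (section-area faceting error < 0.1 %), heart
rate 60 bpm, EDV/ESV 120/50 mL, coronary fraction 0.035, and 60 % area
stenosis severity for the demonstration lesion. All randomness (bending
azimuth, a ~1 % smooth radius modulation) flows through one explicit
seed; the same seed gives byte-identical pipeline outputs.

What the generator does **not** emulate: imaging noise and segmentation
error, inter-phase registration error (phase transforms are prescribed
analytically, since how they would be estimated from images is an
acquisition question), plaque eccentricity, vessel tapering with
branches, and fluid–structure-consistent wall mechanics. Passing tests
therefore certify the computational chain — geometry handling, weights,
conservation laws, solver accuracy, determinism — not the accuracy of
any clinical measurement.

# Skinning weights

Dynamic sequences built from a reference mesh use linear blend skinning
with biharmonic weights: minimize `tr(WᵀQW)` with `Q = L M⁻¹ L`, the
square of the area-normalized cotangent Laplacian, under anchor
constraints. The constraints encode anatomical boundary conditions;
concretely, the package anchors, for each centerline segment, the ring
of vertices nearest the segment midpoint (weight 1 for that segment). Unconstrained biharmonic weights can dip
negative; negative intermediates are clamped to 0 and rows renormalized
to sum to 1, since rigidity-preserving blending needs convex weights.
The constrained solve is by elimination of the anchored rows (sparse
Cholesky); its KKT residual is checked below 1e-8 and the result is
verified in tests against a dense Lagrange-multiplier solve.

# Numerical conventions

* Lengths are mm, areas mm², curvature/torsion 1/mm — imaging-native
  units; conversion to SI happens once, inside the Reynolds, resistance
  and compliance computations.
* Pressures are Pa internally, mmHg in reports (1 mmHg = 133.322 Pa).
* CSV/JSON/YAML outputs print doubles at 17 significant digits so that
  re-runs are byte-comparable and round trips are lossless.
* Degenerate inputs fail loudly: duplicate polyline points, open or
  inverted meshes, all-zero velocity profiles, outlet-less leaves,
  strain beyond ±5 %, severity beyond 0.95.

Problem sizes used in the shipped tests and demonstration: tubes of
41–81 axial × 16–24 circumferential vertices, icospheres of 5120 faces,
101-point arc grids, 101–201 time samples per cycle, Windkessel steps
of T/2000. At these sizes the full pipeline completes in roughly two
seconds; the sizes are chosen so the discretization errors they incur
(all below 0.5 %) sit well under the tolerances being asserted.

# Known limitations

* The quasi-static network ignores inertia and wave propagation; it is
  a surrogate for, not a replacement of, transient 3D CFD.
* Prescribed hyperemic inflow overestimates flow (and thus
  underestimates FFR) for very severe lesions where the lesion itself
  limits flow.
* The fusion treats a single unbranched vessel per call; trees are
  supported in the network solver (with Murray-exponent flow splits
  available for branch flows), but fusion weights are computed per
  branch independently.
* Rigid walls: no fluid–structure interaction; wall motion enters only
  through the phase geometries themselves.
* β (area–compliance) and the fusion coefficients α, β, γ are exposed
  but uncalibrated; conclusions sensitive to them should carry a
  sensitivity analysis.
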