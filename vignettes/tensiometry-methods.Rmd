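---
title: "Methods: magnetic tensiometry of multicellular spheroids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: magnetic tensiometry of multicellular spheroids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magtensio)
```

## The measurement principle

A cohesive multicellular spheroid whose cells carry superparamagnetic
nanoparticles behaves, near a strong permanent magnet, like a liquid drop in
an enhanced gravity: every volume element feels the body-force density
`f = Mv·grad(B)` (N/m³), where `Mv` is the magnetization per unit volume
(typically 150–500 A/m for labelled myoblast aggregates) and `grad(B)` the
field gradient (170 T/m for the reference magnet). With `Mv = 250` A/m this
gives `f = 4.25e4` N/m³, in the middle of the accessible 2.5e4–8.5e4 N/m³
range. Competing against this force, the tissue's surface tension `γ` sets
the equilibrium flattened shape, while the tissue's elasticity sets the size
of the contact zone against the substrate. Both material properties are
therefore readable from a single side-profile image at equilibrium.

Only the equilibrium shape is modelled here. The transient flattening
dynamics (an initial elastic response followed by slower viscous flow) carry
additional rheological information but require time-resolved profiles and a
viscoelastic model, and are out of scope.

## Forward model: Young–Laplace with a volumetric force

At equilibrium the pressure jump across the tissue–medium interface equals
`γ` times the mean curvature. With a uniform body force the internal
pressure grows linearly with depth, so along the profile

`γ·(dφ/ds + sin φ / x) = ΔP₀ + f·z`,

which in arc-length (Bashforth–Adams) variables becomes the first-order
system

- `dx/ds = cos φ`
- `dz/ds = sin φ`
- `dφ/ds = (2b + c·z) − sin φ / x`

with `c = f/γ` the capillary parameter (the inverse squared capillary
length) and `b` the apex mean curvature (`ΔP₀ = 2γb`). Orientation: `z` runs
from the apex downward toward the magnet, so the profile is a heavy sessile
drop. At the apex, `sin φ / x → dφ/ds`, giving the analytic limit
`dφ/ds|₀ = b`.

**Boundary condition.** The substrate is treated with a non-adhesive coating,
so the drop is non-wetting; we integrate until the tangent angle reaches
φ = 180°, the contact condition consistent with complete non-wetting. Whether
the original landmark-fitting software assumed exactly 180° or fitted the
contact region is not documented anywhere we could check; 180° is the unique
boundary condition implied by non-wetting, and the inverse fit below depends
on it only weakly because `h`, `w` and `V` are dominated by the free surface.

**Numerics.** The system is nondimensionalized by
`Ls = min(1/b, 1/√c)` — the apex radius or the capillary length, whichever
is smaller — so that a single dimensionless step (default `1e-3`) resolves
both sphere-like (`c → 0`) and puddle-like (`c·R₀² ≫ 1`) regimes. A
fixed-step classical Runge–Kutta (order 4) scheme starts from the apex
series `φ = bs`, `x = s − b²s³/6`, `z = bs²/2` at `s₀ ≤ 1e-4·Ls` and locates
the φ = 90° (width) and φ = 180° (contact) events by bisection inside the
crossing step, so height, width and contact radius are all free of
grid-sampling error. The volume of revolution is accumulated as a fourth
state `dV/ds = π x² sin φ` rather than by post-hoc quadrature of the stored
path; this keeps every reported metric converging at the integrator's fourth
order (step-halving ratios ≈ 16, verified in the tests) and leaves the
metrics converged to ~1e-12 relative at the default step. The integrator is
written in C++ (Rcpp) because the inverse fit evaluates it thousands of
times. An independent integration of the same ODE with `deSolve::lsodar`
cross-checks one reference solution in the test suite.

The field gradient is treated as spatially constant. In reality it is an
average over the 250 µm–1.75 mm working range above the magnet; the residual
inhomogeneity enters `f` directly and is not corrected here.

## Inverse problem: surface tension from landmarks

The measured inputs are three landmarks pointed on the initial and flattened
profile images: height `h`, width `w`, and the initial radius `R`, which
fixes the conserved volume `V = 4/3 π R³` (direct volume input is also
accepted; whether one should use the deformed-profile volume instead is
undecidable from the available description, and conservation of the initial
volume is the physically motivated choice for a tissue on a 10-minute
timescale). The fit minimizes

`Σ over {h, w, V} of ((model − measured)/measured)²`

over `(log b, log c)`. Relative errors are the only scale-free weighting for
quantities of different dimensions, and the log parameterization enforces
positivity without constraints. A 13-point log-grid pre-scan in `c`
(spanning γ from 0.5 to 500 mN/m, each at volume-matched `b`) seeds a
Nelder–Mead refinement (convergence at relative objective change < 1e-8 or
500 iterations, both reported in the diagnostics). Finally `γ = f/c`,
reported in mN/m.

Noise-free forward-generated landmarks round-trip γ across 1–100 mN/m to
well within 1%. With the documented 2–5 µm pointing error (modelled as
uniform on ±bound, applied independently to `h` and `w`), the coefficient of
variation of recovered γ at 20 mN/m stays below 20%, consistent with the
instrument's stated precision range. Identifiability degrades as the
spheroid stiffens: when the flattening `2R − h` falls below twice the
pointing noise the result carries a warning, and below the noise bound
itself the fit is refused as out of measurable range (γ is unbounded for an
undeformed sphere). High-tension spheroids flatten only slightly, so this is
the instrument's intrinsic sensitivity limit.

## Elasticity from the contact zone

The Young's modulus comes from the contact radius `L` via the Hertz-theory
closed form

`E = (1 − σ²) π f R⁴ / L³`,

with the Poisson ratio fixed at σ = 1/2 (incompressible tissue) but exposed
as a parameter. `L` is always a direct measurement (half the contact-zone
chord on the image); the model contact radius of the Laplace fit is reported
separately and never substituted, mirroring the deliberate separation of the
capillary and elastic analyses. The algebraic inverse
`L = [(1 − σ²) π f R⁴ / E]^(1/3)` generates fixtures with known moduli; at
the reference geometry (R = 530 µm, E = 100 Pa, f = 4.25e4 N/m³) it gives
L ≈ 429 µm, and independent 5 µm errors on `R` and `L` propagate to at most
`4·5/530 + 3·5/429 ≈ 7%` of `E`, within the stated 5–10% precision. The
modulus is meaningful for spheroids near the critical radius separating
elastic- and capillary-dominated contact; that radius's formula is outside
the available material, so the package notes the caveat rather than
enforcing a gate.

## Cell-scale tensions from contact angles

Tissue surface tension reflects a balance of cell-scale tensions
(differential interfacial tension picture): comparing interface and bulk
cell energies gives `γ = T_CM − (2T_CC − J_CC)/2`, and force balance at the
cell/cell/medium contact line gives `2 T_CM cos(α/2) = 2T_CC − J_CC`, where
`T_CM`, `T_CC` are cortical tensions at the cell–medium and cell–cell
interfaces, `J_CC > 0` the intercellular adhesion energy, and `α` the
contact angle between the free surfaces of neighbouring cells (180° = fully
spread, flat cells). Jointly:

`T_CM = γ / (1 − cos(α/2))`, `2T_CC − J_CC = 2γ cos(α/2) / (1 − cos(α/2))`.

Only the combination `2T_CC − J_CC` is identifiable from (γ, α), so the
package never reports `T_CC` or `J_CC` separately. For every physical angle
the effective cell–cell tension is strictly smaller than `2 T_CM`, and
`T_CM → γ` as cells flatten (α → 180°); both are verified as properties.
Angles are accepted in degrees (as measured in Fiji-style tools) and
aggregated as mean ± sd per condition before decomposition; angle dispersion
is reported but not propagated into tension uncertainties by default, since
the provenance of such error bars in practice (fit vs biological spread) is
ambiguous.

## Contour roughness

Cryosection contours are compared against a least-squares circular arc: a
Kåsa algebraic fit initializes a Levenberg–Marquardt refinement of the
geometric distance objective `Σ(‖pᵢ − center‖ − r)²`
(`minpack.lm::nls.lm`), which is exact on noiseless data. The roughness is
the RMS of the point-to-arc distances, `Rq = √(Σ zᵢ²/N)`. Signed residuals
are kept for diagnostics (the sign is irrelevant to `Rq`). The fit uses
whatever angular span the contour provides and never extrapolates beyond
the supplied points. `Rq` as defined is sampling-weighted: contours pointed
with non-uniform density weight dense regions more. The midpoint-refinement
stability test bounds this effect at < 5% for smooth contours, but no
resampling correction is applied.

## Dose–response

Inhibition curves are fitted with the four-parameter Hill model

`Y(X) = Bottom + (Top − Bottom) / (1 + (IC50/X)^HillSlope)`

by unconstrained nonlinear least squares on linear concentration (the model
is fitted as written, not on log-dose). The printed form is undefined at
X = 0; the analytic limit (Top for negative slopes, Bottom for positive) is
used so zero-dose controls enter the fit. The gauge freedom
`(Top, Bottom, HillSlope) ↔ (Bottom, Top, −HillSlope)` describes the same
curve; output is canonicalized to `Top ≥ Bottom`. Start values come from the
data (plateaus from the extreme-dose means, IC50 from the dose nearest the
half response, slope sign from the response direction). Standard errors come
from the Jacobian at the optimum. A racemic compound containing a fraction
`a` of active enantiomer has an active-compound IC50 of `a × IC50`
(blebbistatin: a ≈ 0.5–0.6).

## Synthetic fixtures and what they do (not) show

The generators are first-class, seeded, and default to the reference study
conditions: R = 530 µm spheroids, `Mv = 250` A/m, `grad(B) = 170` T/m,
γ = 21 mN/m and E = 100 Pa (the reference flattened-profile condition),
pointing noise uniform on ±5 µm (the upper end of the documented 2–5 µm
pointing error — the conservative choice for precision claims), dose design
{0, 1, 3, 10, 30, 80, 160} µM with 8 replicates per dose and 10% relative
Gaussian response noise, Hill truth (Top = 21, Bottom = 2, IC50 = 10,
HillSlope = −1). Every generating parameter is embedded in the fixture
manifest, and identical seeds give byte-identical fixtures.

The fixtures emulate landmark/contour geometry and measurement noise only.
They do not emulate optical segmentation artefacts, aggregate-to-aggregate
biological variability (which in practice exceeds the instrumental error),
deviations from axisymmetry, or partial wetting. Passing the round-trip and
precision tests therefore validates the estimators under the stated noise
model, not the imaging chain.

## Problem sizes and numerical defaults

Defaults chosen for the analyses and the test/acceptance suites: integrator
step 1e-3 (dimensionless), volume solve to 1e-9 relative, Nelder–Mead
tolerance 1e-8 / 500 iterations, 100 simulated assays for the IC50
recovery, 200 noisy refits for the tension-precision check, 40–60 seed
Monte-Carlo loops for the circle-fit and Rq oracles. These sizes make every
statistical check stable at the asserted tolerances while keeping the whole
suite around a minute of CPU.

## Known limitations

- Equilibrium-only: no flattening dynamics, no viscosity.
- Constant `f`: field-gradient inhomogeneity across the working distance is
  averaged, not modelled.
- The landmark objective uses exactly three scalars; full-contour
  least-squares fitting would use more of the image but is deliberately not
  implemented, matching the landmark-based measurement protocol.
- `Rq` depends on pointing density (see above).
- The Hill fit reports fit standard errors; replicate-level bootstrap is
  available only when replicates are present in the input table.
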