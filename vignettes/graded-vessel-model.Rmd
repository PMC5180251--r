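---
title: "Modelling a functionally graded artificial aorta: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling a functionally graded artificial aorta: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fgmvessel)
```

## The problem

Replacing a diseased segment of the ascending aorta with a synthetic graft
raises a materials question: a homogeneous graft (Dacron, polyurethane)
never matches the compliance of the living wall, and a layered composite
introduces abrupt property jumps that concentrate stress at the interfaces.
A functionally graded material (FGM) — a wall whose stiffness, Poisson's
ratio and density vary *continuously* from one constituent at the lumen to
another at the outer surface — is a candidate compromise. `fgmvessel`
simulates the mechanics of such a graft as a thick-walled axisymmetric
cylinder under pulsatile lumen pressure, couples it to a reduced-order
blood model, and compares its response (radial displacement, hoop stress,
von Mises stress) against a three-layer natural-wall reference.

## Wall material models

Four radial property models are supported, all evaluated through
`radial_property_field()` on the normalized thickness coordinate
$\xi = (r - r_{in})/(r_{out} - r_{in})$:

* **Homogeneous** — constants through the wall.
* **Graded (FGM)** — every property follows
  $p(\xi) = p_{in} + (p_{out} - p_{in})\,\xi^n$ between the inner and
  outer constituents. The heterogeneous index $n > 0$ controls the
  steepness of the transition: small $n$ pulls the interior toward the
  outer material, $n = 2$ is the literal parabola, and the one-parameter
  power family is the only form that supports a continuous sweep of the
  index, which is why "parabolic grading" is implemented this way. The
  endpoints are exact for every $n$ ($0^n = 0$, $1^n = 1$).
* **Layered** — piecewise-constant layers; the default thickness fractions
  0.1/0.6/0.3 encode the 1:6:3 intima/media/adventitia ratio of the
  natural wall. Layer $k$ owns the half-open span
  $[\mathrm{cum}_{k-1}, \mathrm{cum}_k)$, with the last layer closed at 1,
  so every $\xi$ maps to exactly one layer.
* **Power law** — properties as $a\,r^b + c$ of the *physical* radius;
  the graded validation cylinder uses
  $\rho(r) = 8900\,r^{0.08} - 5.93$ kg/m³ and
  $E(r) = 223\times10^9\,r^{0.082}$ Pa with $\nu = 0.3$.

The default graft constituents are Dacron at the lumen
($E = 1.9$ MPa, $\nu = 0.37$, $\rho = 1380$ kg/m³) grading outward to
polyurethane ($E = 25$ MPa, $\nu = 0.49$, $\rho = 1200$ kg/m³). The
grading direction is configurable; inner-Dacron is the default because it
is the convention under which the density-versus-thickness trend is
decreasing for most indexes.

Exact incompressibility ($\nu = 0.5$, as quoted for the natural wall)
makes the linear-elastic constitutive matrix singular; `material()` caps
$\nu$ at 0.4995 with a warning. This reproduces the near-incompressible
limit without resorting to a mixed displacement–pressure formulation, at
the cost of a slightly stiffer volumetric response — acceptable because
the natural-wall runs are qualitative references, not validation targets.

The per-layer moduli of a real intima/media/adventitia are not part of any
shipped data: `natural_wall_synthetic()` provides placeholders in the
physiological MPa range (stiffening outward), clearly named synthetic, and
quantitative natural-vessel work must override them.

## Structural model

The wall obeys the axisymmetric Navier equations with radially varying
$E(r)$, $\nu(r)$, $\rho(r)$:

$$\frac{\partial \sigma_{rr}}{\partial r} +
  \frac{\partial \sigma_{rz}}{\partial z} +
  \frac{\sigma_{rr}-\sigma_{\theta\theta}}{r} = \rho\,\ddot u_r, \qquad
  \frac{\partial \sigma_{rz}}{\partial r} +
  \frac{\partial \sigma_{zz}}{\partial z} +
  \frac{\sigma_{rz}}{r} = \rho\,\ddot u_z + \rho g,$$

with isotropic Hooke's law and small strains
($\varepsilon_{\theta\theta} = u_r/r$, etc.). A full 2D $(r,z)$
elasticity description was chosen over shell kinematics because it
supports every reported output — displacement along the length *and*
stress through the thickness — within one formulation. Boundary
conditions: $\sigma_{rr} = -P(z,t)$ and $\sigma_{rz} = 0$ on the inner
surface, traction-free outer surface, and clamped ends
($u_r = u_z = 0$ at $z = 0, L$). Gravity acts along $-z$ when enabled.

### Conservative-form collocation

Both discretizations collocate the *divergence of the discrete traction
fields* rather than the chain-rule-expanded equations. This matters for
steep gradings: with index $n < 1$ the modulus gradient
$dE/d\xi \propto n\,\xi^{n-1}$ is unbounded at the inner surface, so any
scheme that differentiates the material coefficients explicitly loses
accuracy exactly where the graft grading is most interesting (measured:
~30% cross-solver disagreement for $n = 0.2$ in expanded form, ~1% in
conservative form). The tractions themselves are smooth across the
grading, so differentiating them is well posed.

### The two discretizations

* **DQM** (`grid1d(method = "dqm")`): differential quadrature on
  Chebyshev–Gauss–Lobatto nodes, $x_i = (1-\cos(i\pi/(n-1)))/2$. The
  weighting matrices are barycentric-Lagrange derivative operators, exact
  for polynomials of degree $n-1$; second derivatives use the standard
  recurrence (the product $D_1 D_1$ is available as a cross-check). CGL
  clustering resolves the end boundary layers without extra nodes.
  Uniform nodes are available but not default: equispaced high-order
  interpolation is unstable (Runge).
* **FD** (`grid1d(method = "fd")`): second-order central differences on a
  uniform grid, one-sided second-order stencils on boundary rows. The two
  code paths share nothing beyond base arithmetic, which is what makes
  their agreement a meaningful verification.

Default grids: DQM $13 \times 21$ ($r \times z$); FD $41 \times 161$ for
the validation cylinder and $33 \times 101$ for the short aorta segment.
These sizes put both solvers' discretization errors well below the
acceptance thresholds while keeping the paired validation run under ten
seconds and the paired coupled run under a minute on one CPU.

### Time integration

Newmark-$\beta$ with average acceleration ($\beta = 1/4$,
$\gamma = 1/2$): implicit, unconditionally stable, no algorithmic
dissipation. The mass operator is the diagonal nodal density on momentum
rows and zero on boundary rows, so constraints are enforced algebraically
at every step; the effective matrix is factorized once (sparse LU) and
each step costs two triangular solves. Default $dt = 0.01$ s resolves the
2 s loading period to 1% under step halving; the structural ring
frequencies (kHz) are deliberately unresolved — the response regime is
quasi-static tracking of the pulse, and both solvers share the identical
time discretization so temporal error cancels from cross-solver
comparisons. Rayleigh damping is off by default and available for
static-limit experiments. Clamped-end rows are scaled to the stiffness
magnitude so the assembled operator stays well conditioned.

Stress recovery differentiates the displacement at the collocation points
and applies Hooke's law — no superconvergent patching, so exported
stresses are exactly what the discrete operators see.

### Comparing the two solvers

The spectral solution is resampled onto the FD nodes through its exact
polynomial representation (tensor barycentric interpolation,
`lagrange_interp_matrix()`), so no resampling error enters a discrepancy.
Discrepancies are reported as
$\max|q_{fd} - q_{dqm}| / \max|q_{fd}|$ in percent.

One norm decision deserves emphasis. At a clamped end the wall wants to
expand radially but cannot; linear elasticity makes the clamp reaction
*singular* at the wall-end corners. Pointwise near-corner stresses
therefore grow under grid refinement and differ between any two
discretizations no matter how fine — a full-grid max-norm of the stress
fields never converges (measured: 8% → 23% as the FD grid is refined
2×), and the corner also degrades the global polynomial's convergence.
The validation and coupling discrepancies are therefore evaluated on the
**mid-thickness surface** (all $z$, all $t$), where the comparison
converges cleanly and which is also where the reported physical results
live. The full-grid norm remains available
(`solution_discrepancy(r_at = NULL)`) for displacement fields, which stay
regular. Relatedly, the "static solve equals the Lamé closed form at
mid-length" check needs slenderness $L/h \approx 40$: the clamped-end
bending boundary layer has length $\sim\sqrt{r h}$, which for this thick
wall still contributes ~9% at mid-length when $L/h = 10$.

### Validation scenario

Graded cylinder with $r \in [0.8, 1.0]$ m, $\nu = 0.3$, the power-law
properties above, and inner pressure $P_0 \sin(\pi t)$ with
$P_0 = 16$ kPa over one 2 s period. The length is not part of the
reference configuration; the package uses $L = 2$ m ($L/h = 10$), long
enough that the mid-span state is bulk-like while keeping the clamped-end
layers inside the domain.

## Reduced-order blood model

The lumen is not discretized. The pressure field $P(x,t)$ is built by
marching the laminar Poiseuille gradient downstream from the inlet
waveform:

$$\frac{dP}{dx} = -\frac{8 \mu Q}{\pi r(x)^4},$$

with a classical fourth-order Runge–Kutta step (default 200 substeps per
length; self-converged to well under 0.1%). The local radius $r(x)$
closes the system: either from the static thin-wall distension balance
$P r / t = E_{in} (r - r_{in}) / r_{in}$, which is linear in $r$ with
root $r = E_{in} t\, r_{in} / (E_{in} t - P r_{in})$ (valid while
$P < E_{in} t / r_{in}$; beyond that the model is flagged invalid), or —
inside the coupled loop — from the structural solution itself. An
exponential-decay closed form
$P = P_0(t)\exp(-2\tau x/(E_{in} t))$ is available as a *reconstructed*
comparison mode; it is a surrogate, not the integrated model.

Two flow quantities with different units coexist and are never
interchanged: `Q_shear` (11.91 s⁻¹, the velocity-to-distance ratio that
feeds the wall shear $\tau = \mu Q$) and `Q_vol` (m³/s, the volumetric
rate in the Poiseuille gradient). `Q_vol` defaults to a mean inlet
velocity times the lumen area; the default $U = 0.2$ m/s is a typical
time-averaged ascending-aorta velocity and yields a (realistically) tiny
~1 Pa axial drop over the 5 cm segment. Inlet waveforms are either the
half-sine systolic surrogate $P_0\sin(\pi t)$ ($P_0 = 16$ kPa, period
2 s) or a user-tabulated trace (linear interpolation, periodic extension,
seam-continuity check); no physiological waveform samples are shipped
because none are available as data, only as figures elsewhere.

## Two-way coupling

`fsi_couple()` alternates, within each time step: (a) the pressure march
with the wall shape $r(z) = r_{in} + u_r(\text{inner}, z)$; (b) a
re-solved structural Newmark step under the updated $P(z,t)$. The
fixed-point loop stops when the relative change between successive
iterates of both the interface displacement norm and the mean lumen
pressure falls below $10^{-3}$. The threshold is implemented as a
dimensionless relative change because a mixed velocity/displacement
criterion in SI units would depend on arbitrary scales; $10^{-3}$ is the
conventional partitioned-coupling setting of this regime. The interface
displacement update is under-relaxed with a constant factor 0.7 —
Aitken acceleration is unnecessary in this compliance regime, where the
pressure field is nearly insensitive to the wall motion and the loop
converges in two iterations per step. A rigid wall converges in ≤ 2
iterations to the uncoupled profile; tightening the tolerance to
$10^{-5}$ changes the peak displacement by < 0.5%.

The fluid side is deliberately reduced-order rather than a discretized
Navier–Stokes lumen: the regime is incompressible, laminar and Newtonian,
and the desk-scale model keeps the coupled experiment fast and fully
reproducible. This is a fidelity deviation from a full CFD coupling:
inertial and secondary-flow effects in the lumen, Womersley profiles and
wave propagation are absent.

## Post-processing conventions

* Nondimensionalization: $T = t/t_e$, $Z = z/L$, $R = r/r_i$,
  $U_r = u_r K/(P_0 h)$ with the fixed stress scale $K = 10$ GPa, and
  $S_i = \sigma_i/P_0$. The $U_r$ grouping is chosen so the dimensionless
  displacement is order unity for the validation case; `redim()` is its
  exact inverse.
* von Mises:
  $\sigma_{vM} = \sqrt{\frac12[(\sigma_{rr}-\sigma_{\theta\theta})^2 +
  (\sigma_{\theta\theta}-\sigma_{zz})^2 +
  (\sigma_{zz}-\sigma_{rr})^2] + 3\sigma_{rz}^2}$.
* Profiles are extracted at the *nearest node*, never interpolated, so
  exported numbers match the stored fields bit for bit; mid-thickness is
  the node closest to $(r_{in}+r_{out})/2$.
* Peak detection is the discrete argmax with plateau ties broken to the
  earliest time; a constant series is reported as having no unique peak.

## What the shipped experiments do and do not show

The experiments ship their own inputs (geometry, constituent tables,
loading law); nothing is fitted to data. Passing the cross-solver checks
demonstrates that two independent discretizations of the same continuum
model agree — a verification statement. It does **not** validate the
model against a living aorta: the geometry is a straight cylinder (no
arch curvature), the wall is linear elastic (no collagen recruitment,
no anisotropy, no prestress), the fluid is the reduced-order chain above,
and the natural-wall layer moduli are synthetic placeholders. Problem
sizes used throughout (grids above, 2–3 s windows at $dt = 10$ ms) were
chosen so that discretization error is demonstrably below the comparison
thresholds while a full paired experiment completes in well under a
minute.
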