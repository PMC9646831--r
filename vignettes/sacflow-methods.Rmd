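---
title: "sacflow: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sacflow: models, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem sacflow addresses

Endovascular coiling treats a cerebral aneurysm by packing platinum coils
into the sac, converting it into a porous obstacle that starves the sac
of momentum and promotes thrombosis.  Whether a treated (or untreated)
aneurysm wall is mechanically at risk is commonly judged from
cycle-resolved wall indices: the wall shear stress
$\mathrm{WSS} = \mu\,(\partial u_t/\partial n)\vert_{wall}$, its cycle
average (TAWSS), and the oscillatory shear index

$$\mathrm{OSI} = \frac{1}{2}\left(1 -
  \frac{\left|\int_0^T \boldsymbol\tau_w\,dt\right|}
       {\int_0^T |\boldsymbol\tau_w|\,dt}\right) \in [0, 0.5],$$

where $\boldsymbol\tau_w$ is the tangential traction vector, $T$ the
cardiac period.  OSI is 0 for unidirectional shear and 0.5 for pure
zero-mean oscillation.  sacflow computes these indices for a
two-dimensional idealized sidewall aneurysm under pulsatile,
shear-thinning (Casson) blood flow, with the coil pack modelled as a
Darcy–Forchheimer momentum sink, and compares conditions across coil
porosity and haematocrit at the four cardiac landmarks: maximum
acceleration (A), peak systole (B), maximum deceleration (C) and early
diastole (D).

Patient-specific 3-D geometries are deliberately out of scope: the
package is a desk-scale surrogate whose every input is synthetic,
parametric and reproducible, so that all of its physics can be tested
against analytic oracles.

## Geometry and mesh

The geometry is a parent channel of width $D$ (default 4 mm) and length
$L$ (default 40 mm) carrying a sidewall sac: by default the circular
segment of a dome of radius 3 mm over a 4 mm neck, giving a sac area of
26.18 mm² — proportions chosen to echo an internal-carotid sidewall
aneurysm.  The solve happens in straightened (arc-length) coordinates; a
constant centerline curvature $\kappa$ (default 1/(20 mm)) is applied as
an isometric bending for geometry and VTK output only.  Metric
corrections to the momentum equations are $O(\kappa D) = 0.2$ and are
neglected; this is a stated approximation of the surrogate, not a claim
that curvature effects (Dean circulation) are small in real arteries.

Meshing is a uniform Cartesian staggered (MAC) grid with the channel
walls exactly on grid lines and the sac represented by the stair-step
set of cells whose centroid falls inside it.  The neck must be resolved
by at least 8 faces, meshed area converges to the analytic area at first
order in $h$, and boundary faces carry exactly one tag (inlet, outlet,
vessel wall, sac wall) ordered by a boundary walk that provides the wall
arc-length coordinate.

**Coil region.**  Coils pack the dome first, so the coil region is the
part of the sac above a horizontal cut enclosing the fraction $f_c$ of
the sac area.  The default is $f_c = 0.85$: complete angiographic
occlusion is not the common outcome, and a neck remnant — a thin
coil-free layer between the lumen and the pack — is the clinically
typical configuration.  With $f_c = 1$ the entire sac wall would sit
inside the porous region and its shear would be pure seepage noise.

## Blood rheology

Whole blood is modelled as a regularized Casson fluid,

$$\mu_{app}(\dot\gamma) = \left(\sqrt{\mu_\infty} +
  \sqrt{\tau_y/\max(\dot\gamma,\dot\gamma_{min})}\right)^2 ,$$

with haematocrit-dependent coefficients
$\mu_\infty(H) = \mu_p (1-H)^{-2.5}$ ($\mu_p = 1.45$ mPa·s) and
$\tau_y(H) = A\,(H-H_c)^3$ with $A = 0.185$ Pa, $H_c = 0.10$, calibrated
so that $\tau_y(0.40) \approx 5$ mPa — a standard literature value.  The
defaults are declared, not fitted; every coefficient is configurable,
and a Newtonian mode exists for verification.  The clamp
$\dot\gamma_{min} = 10^{-3}\,s^{-1}$ bounds the apparent viscosity at
about 5.3 Pa·s in stagnant regions; this is the simplest bounded
regularization and its value is exposed in the config.

## Inlet waveform and phase landmarks

The inlet is a truncated Fourier pulse
$u(t) = U_{mean}(1 + \sum_k a_k \cos(2\pi k t/T - \phi_k))$ with
$T = 0.8$ s, $U_{mean} = 0.3$ m/s and three harmonics
$a = (0.55, 0.30, 0.12)$, $\phi_k = 2\pi k \cdot 0.15$, giving a
systolic peak of $1.97\,U_{mean}$ at $t = 0.15\,T$ and a strictly
positive diastolic plateau of $0.63\,U_{mean}$.  These values describe a
generic carotid-type pulse; they are configuration, not measurements.
The spatial profile is the plane-Poiseuille parabola scaled so its
discrete mean equals $u(t)$ exactly.

Landmarks are found on a dense grid: A = argmax $\dot u$, B = argmax
$u$, C = argmin $\dot u$.  "Early diastole" has no standard mathematical
definition; the package's convention, recorded in every run report, is
the minimum of $u$ in the half-cycle after maximum deceleration.  Ties
resolve to the earliest time with a warning.

## Coil model

Porosity $\varepsilon$ (void fraction) and wire diameter $d_w$ (default
0.25 mm) map to a permeability via Kozeny–Carman,
$k = \varepsilon^3 d_w^2 / (180 (1-\varepsilon)^2)$, and to an inertial
coefficient via Ergun,
$C_2 = 3.5 (1-\varepsilon)/(d_w \varepsilon^3)$; both are overridable.
The momentum sink
$\mathbf S = -(\mu/k)\mathbf u - \tfrac{1}{2} C_2 \rho |\mathbf u| \mathbf u$
acts on the superficial velocity in coil-masked cells only; no porosity
rescaling of the transient or convective terms is applied (the standard
"physical velocity" simplification, which keeps the uncoiled limit
exact).  $k$ is strictly increasing in $\varepsilon$: a looser pack is
more permeable, and $\varepsilon \to 1$ recovers the open sac, which the
test suite verifies to machine precision.  Note that one sometimes sees
the opposite wording ("lower porosity, higher permeability") in the
clinical literature; sacflow follows the physics of the closure.

## Flow solver

Incompressible Navier–Stokes with variable viscosity, solved on the
staggered grid by a projection (pressure-correction) method:

* **Advection** — explicit first-order upwind.  The time step must
  satisfy an advective CFL bound; `dt = "auto"` (default) takes
  $\min(T/1000,\ 0.35\,h/u_{peak})$ rounded so a cycle is an integer
  number of steps, and the choice is echoed in the run report.
* **Viscosity** — semi-implicit splitting.  A constant reference
  viscosity $\mu_0$ (half the regularized Casson maximum; equal to
  $\mu$ for Newtonian runs) is treated implicitly through once-factorized
  sparse Helmholtz operators; the remainder of the full variable-viscosity
  stress divergence is explicit.  The splitting is unconditionally stable
  for $0 \le \mu \le 2\mu_0$ and reduces to plain implicit diffusion in
  the Newtonian verification cases.
* **Wall fluxes** — the tangential viscous flux at a wall half a cell
  away from a velocity row uses the one-sided quadratic (second-order)
  form; with it, plane Poiseuille flow is reproduced to the cell-average
  representation and the wall shear stress to 0.1–0.2 % at $h = D/10$.
* **Coil sink** — pointwise implicit (a division), unconditionally
  stable for arbitrarily stiff $\mu/k$.
* **Projection** — velocity-inlet runs use incremental pressure
  correction (the predictor carries $\nabla p^n$, applied after the
  viscous solve so the sink division also damps it; this keeps the
  steady Darcy pressure balance exact).  Pressure-inlet runs
  (used for pressure-driven benchmarks) use the non-incremental form with
  the prescribed inlet pressure as a Dirichlet value.  The pressure
  Poisson operator is symmetric positive definite and factorized once
  (sparse Cholesky); post-projection divergence is at direct-solver
  accuracy ($\sim 10^{-10}\,s^{-1}$), far below the configured tolerance.
* **Outlet** — zero-gradient velocity with zero pressure at the face
  (traction-free surrogate for a single outlet).
* **Laminar** — no turbulence or transition model; at the surrogate's
  scales ($Re \approx 120$–700, Womersley number $\alpha \approx 3$) the
  flow is laminar.  SIMPLE-family coupling is not implemented; requesting
  it is rejected with a message.

Runs integrate `cycles_to_run` cycles from rest (default 3), discard
`cycles_to_discard` (default 2), record wall tractions every step of the
final cycle and snapshot full fields at A–D.  A periodicity metric
(relative L2 velocity change between the last two cycle ends) is
reported and warned about above its tolerance; in the shipped
configurations it is $\sim 10^{-7}$ or smaller, i.e. the reported cycle
is converged in time.

## Post-processing conventions

* **WSS** uses the one-sided quadratic wall gradient and the apparent
  viscosity evaluated at the wall shear rate itself.
* **OSI** is computed in vector form (norm of the traction
  time-integral over the integral of norms) by uniform-weight periodic
  quadrature on the recorded samples; all-zero histories return 0 with a
  warning, and $0 \le \mathrm{OSI} \le 0.5$ is asserted on every run.
* **Per-landmark OSI.**  OSI is a whole-cycle integral with no
  instantaneous value, yet per-instant comparisons of "maximum OSI" are
  standard in the application literature.  sacflow's convention: the OSI
  integral restricted to a quarter-cycle window centred on the landmark.
  This is a package convention, documented here and in the index tables.
* **Aneurysm-wall statistics** (max WSS, max OSI) are taken over
  sac-wall samples; the whole-wall maximum — which in this geometry sits
  on the parent wall at the distal neck corner, the classic
  high-curvature impingement site — is reported alongside as
  `max_wss_vessel` and in the global summary.
* **Sac-mean inflow velocity** averages the velocity magnitude (not the
  signed flux) over fixed physical quadrature points on the inner 90 %
  of the neck chord, interpolated from the staggered fields.  Fixed
  points make the monitor independent of how the stair-step neck face
  set falls at a given $h$, so it converges under refinement — this is
  also the monitored quantity of the grid-independence study.
* **High-risk regions** are maximal connected sac-wall arcs with OSI at
  or above a threshold (default 0.2; thresholds are not standardized,
  so it is configuration).

## What the synthetic world does and does not establish

The generator emulates: pulsatile carotid-like inflow with the four
canonical landmarks, shear-thinning haematocrit-dependent rheology, a
sidewall sac with clinically plausible proportions, dome-first coil
packing at porosities 0.79/0.89, and the resulting cycle-resolved wall
indices.  It does not emulate: three-dimensional secondary and swirling
flows, patient-specific neck jets and impingement zones, wall
compliance, coil-strut-scale flow, thrombosis, or measured inflow
waveforms.  A green test therefore establishes that the implementation
solves its stated equations correctly (analytic oracles at 1–3 %
tolerances) and which qualitative trends this 2-D porous-sink world
produces — not that a patient geometry would produce the same numbers.

Two directional findings deserve explicit caution, and the acceptance
suite records them honestly rather than forcing them green:

* Tighter packing (porosity 0.89 → 0.79) lowers the sac-mean inflow
  velocity — the Darcy-driven effect — but the margins are small
  (0.5–2 % at HCT 0.35, and ~0.1 %, i.e. within discretization noise, at
  the max-deceleration landmark for HCT 0.45): in a sidewall geometry the
  main stream crosses the neck obliquely and largely sets the neck
  velocity itself.
* The same change does **not** lower the maximum sac-wall OSI in this
  world: weaker seepage under the tighter pack is also less directional,
  which *raises* OSI at the coil-shielded wall.  The corresponding
  acceptance assertion is left failing by design, with the analysis in
  the repository's decision notes.  Likewise, at the lower haematocrit
  the wall-shear phase lead of pulsatile flow (a genuine $\alpha \approx 3$
  effect) puts the instantaneous WSS maximum at maximum acceleration
  rather than peak systole.

## Numerical parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `resolution` h | 4e-4 | m | cell size; neck needs ≥ 8 faces |
| `dt` | auto | s | min(T/1000, 0.35 h/u_peak) |
| `cycles_to_run` / discard | 3 / 2 | – | startup transient removal |
| `gamma_min` | 1e-3 | 1/s | Casson regularization clamp |
| `divergence_tolerance` | 1e-6 | 1/s | post-projection check |
| `osi_threshold` | 0.2 | – | high-risk region cut |
| `iso_velocity_level` | 0.4 | m/s | iso-velocity area export |

Configuration files are JSON (the one structured-text format with a
parser available in every target environment); every default is echoed
into the run report so no silent defaults exist.  All artifacts (VTK
snapshots, CSV series and indices, JSON reports, the MD5 manifest) are
deterministic text: rerunning a study reproduces identical checksums.

## Known limitations

Stair-step sac walls make individual corner WSS samples first-order
accurate (field-level convergence is what the grid study checks);
curvature is visual embedding only; the outlet is reflective for strong
transients travelling backwards; the Picard option iterates viscosity
only (advection stays lagged); and 2-D vortex dynamics in the sac are a
caricature of the 3-D swirl in real aneurysms.
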