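# sacflow

Desk-scale computational hemodynamics of **coiled cerebral aneurysms** in R.

Cerebral aneurysms rupture where the flow chronically mistreats the wall,
and endovascular coiling changes that environment by turning the sac into
a porous obstacle. `sacflow` is for researchers and students who want a
fully reproducible, testable sandbox for the quantities this field argues
about — wall shear stress (WSS), its cycle average (TAWSS), the
oscillatory shear index (OSI), wall pressure and sac inflow — and for how
they respond to **coil porosity** (how tightly the sac is packed) and
**blood haematocrit** (how viscous the blood is), evaluated at the four
cardiac landmarks: maximum acceleration (A), peak systole (B), maximum
deceleration (C), early diastole (D).

Everything is synthetic and parametric by design: a 2-D idealized
sidewall aneurysm on a curved parent vessel stands in for patient
geometry, and an analytic three-harmonic pulse stands in for a measured
inflow. That makes every piece of physics verifiable against closed
forms, at the price of 3-D realism (see the methods vignette for exactly
what a green test does and does not establish).

## The model in brief

* **Flow** — transient incompressible Navier–Stokes on a staggered
  Cartesian grid; projection (pressure-correction) method with implicit
  reference-viscosity diffusion and explicit upwind advection.
* **Blood** — regularized Casson rheology
  `mu_app = (sqrt(mu_inf) + sqrt(tau_y / max(gd, gd_min)))^2` with
  haematocrit-dependent `mu_inf(H) = mu_p (1-H)^-2.5` and
  `tau_y(H) = 0.185 (H - 0.10)^3` Pa (≈ 5 mPa at H = 0.40).
* **Coil** — Darcy–Forchheimer momentum sink in the coil-packed part of
  the sac; Kozeny–Carman permeability
  `k = eps^3 d_w^2 / (180 (1-eps)^2)` and Ergun inertial coefficient from
  porosity `eps` and wire diameter `d_w`.
* **Indices** — `WSS = mu (du_t/dn)|wall` (Eq. of tangential viscous
  traction), `OSI = (1 - |∫ tau dt| / ∫ |tau| dt) / 2 ∈ [0, 0.5]`
  computed in vector form over the final, cycle-periodic cardiac cycle.

## Worked example

One coiled condition: porosity 0.79, haematocrit 0.45.

```r
library(sacflow)

geom  <- build_idealized_aneurysm(parent_length = 24e-3, sac_center_arc = 12e-3)
mesh  <- generate_mesh(geom, h = 4e-4)
blood <- blood_properties(hct = 0.45)        # male-range haematocrit
coil  <- coil_properties(porosity = 0.79)    # tightly packed coil
wave  <- pulsatile_waveform()                # 0.8 s carotid-type pulse
cfg   <- solver_config(cycles_to_run = 2, cycles_to_discard = 1)

res <- run_pulsatile(mesh, blood, coil, wave, cfg)   # ~1 min on one core
ind <- hemodynamic_indices(res)
print(ind)
```

which prints (numbers produced by this exact code):

```
<hemodynamic_indices>
 landmark     time max_wss_sac max_wss_vessel max_osi_sac max_pressure_sac
        A 0.029032    7.448188      16.730485   0.4991629         1714.543
        B 0.120000    5.053183      17.435655   0.3929080         2121.399
        C 0.210968    1.975871       6.585125   0.4321919         1988.867
        D 0.520000    2.064360       6.056522   0.1864650         2021.986
 sac_mean_velocity
        0.19639856
        0.21128866
        0.09072496
        0.06923103
  global: max WSS 19.66 Pa (vessel_wall wall), cycle max OSI 0.4594
```

Reading it: the wall-wide WSS maximum (19.7 Pa) sits on the parent wall
at the distal neck corner — the high-curvature impingement site — and
among the four landmarks it is largest at peak systole (B). The sac
wall behind the coil sees an order of magnitude less shear. The
sac-mean inflow velocity (~0.21 m/s at systole across the neck) is the
quantity the coil most directly suppresses. `high_risk_regions(ind)`
returns the connected sac-wall arcs whose whole-cycle OSI exceeds 0.2 —
here a ~2.4 mm arc near the neck with peak OSI 0.45:

```
   start    end extent n_samples  peak_osi peak_arclength
1 0.0382 0.0402 0.0024         6 0.4543533         0.0386
```

For the full porosity-by-haematocrit study (four runs, comparison
tables, VTK/CSV/JSON artifacts and an MD5 manifest):

```r
study <- run_study(default_config(), out_dir = "sacflow_out")
```

or from the command line via the installed script
(`system.file("cli", "sacflow", package = "sacflow")`):

```sh
Rscript inst/cli/sacflow study --config my_config.json --out sacflow_out
Rscript inst/cli/sacflow grid  --out sacflow_out      # grid-independence table
Rscript inst/cli/sacflow report --out sacflow_out     # rebuild tables from artifacts
```

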