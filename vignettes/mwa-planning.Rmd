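---
title: "Microwave ablation planning: model, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microwave ablation planning: model, numerics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Microwave ablation (MWA) destroys liver tumors by heating them with an
interstitial antenna until coagulative necrosis. Planning a treatment means
choosing an input power and a duration such that *every* part of the tumor is
necrosed, with a safety margin, while as little surrounding healthy tissue as
possible is damaged. Because tumors are irregular three-dimensional bodies,
the power/time combination that just ablates one tumor under-treats a larger
one and over-treats a smaller one; `mwaplan` simulates the coupled
electromagnetic–thermal–damage problem on patient-shaped (or synthetic)
tumor geometries and searches the power axis for the minimal sufficient dose.

## Model

Three coupled pieces, solved on a uniform voxel grid that labels each cell
healthy tissue, tumor, antenna metal or antenna dielectric.

**Electromagnetics.** The antenna is a thin coaxial line whose outer
conductor carries ten radiating ring slots (0.6 mm wide, 0.8 mm apart) near
the tip, driven at f = 2.45 GHz. The time-harmonic field obeys the vector
Helmholtz equation with complex permittivity
$\tilde\varepsilon = \varepsilon_r - j\,\sigma/(\omega\varepsilon_0)$.
Because the antenna is rotationally symmetric we solve its dominant
azimuthal-magnetic (TM$_0$) mode on an $(r,z)$ half-plane: with
$v = r H_\phi$ and $s = 1/\tilde\varepsilon$,

$$\partial_r\!\left(\tfrac{s}{r}\,\partial_r v\right) +
  \partial_z\!\left(\tfrac{s}{r}\,\partial_z v\right) + \tfrac{k_0^2}{r}v = 0,$$

discretized with a conservative cell-centred finite-volume scheme on a
radially graded grid (0.03 mm cells through the coax bore, geometric growth
outside). Conductors are perfect electric conductors (natural zero-flux
faces in this formulation); the outer boundary carries a first-order
absorbing condition; the coax port is driven through a matched Robin
condition that injects the analytic TEM mode ($H_\phi \propto 1/r$) and
absorbs the reflection. The tissue heat source is
$Q_{\mathrm{ext}} = \tfrac12\sigma|\mathbf E|^2$, rotated onto the 3D grid
and renormalized so its volume integral equals $\eta P_{\mathrm{in}}$
exactly.

Since tissue maps are fully 3D while the solve is axisymmetric, the EM
solver sees the azimuthal average of the voxel dielectric properties; the
thermal solve keeps full 3D heterogeneity. A second, analytic backend
(`slot_source_model()`) superposes per-slot kernels
$e^{-2\alpha d}/(d^2+d_0^2)$ with the local plane-wave attenuation constant
$\alpha$, under the same normalization and symmetry contracts; the two
backends are interchangeable through one configuration switch. The
full-wave backend is the physics reference and drives the packaged
reproduction runs; the slot backend is the default for interactive
planning because it is two orders of magnitude faster per source update.
Both backends are held to the same normalization and symmetry contracts
by the test suite, and after per-backend efficiency calibration they
produce closely agreeing planning outputs on the study phantoms.

**Bioheat.** Tissue temperature follows the Pennes equation

$$\rho c_{\mathrm{eff}}\,\partial_t T = \nabla\!\cdot\!(k\nabla T) +
  \rho_b W_b c_b (T_b - T) + Q_{\mathrm{ext}} + Q_m,$$

with zero-flux outer boundaries and an insulated antenna surface, initial
temperature 37 °C, and metabolic heat $Q_m = 0$ by default. Evaporation of
tissue water enters through the effective heat capacity

$$c_{\mathrm{eff}}(T) = c - \alpha_w \frac{dW}{dT},$$

where $\alpha_w = 2.26\times10^6$ J/kg is the latent heat and $W(T)$ the
water mass fraction. The exact $W(T)$ used by full clinical models is not
standardized; we adopt a logistic desiccation curve
$W(T) = W_0/(1+\exp((T-T_w)/s_w))$ with $W_0 = 0.78$, $T_w = 102$ °C,
$s_w = 1.5$ °C — smooth, anchored at 78% water at body temperature, and
collapsing just above boiling so its latent-heat peak caps simulated
temperatures near 100 °C without an explicit phase-change model. All three
numbers are configuration keys. The printed form of the effective-heat
correction is ambiguous about a density factor; dimensional analysis
($\alpha_w$ in J/kg, $W$ a mass fraction) fixes the form above, and the
density-scaled variant is retained as a configuration flag for sensitivity
runs.

Dielectric properties decline with desiccation: $(\varepsilon_r,\sigma)$
are scaled by $\max(W(T)/W_0, 0.1)$, the floor representing the residual
response of dry tissue. Blood perfusion is the classical heat sink
$\rho_b W_b c_b (T_b - T)$ with a damage gate: it stays at the baseline
rate $W_b = 0.0064\ \mathrm{s^{-1}}$ (a standard liver value; not printed
in the reference study) while the local damage fraction is at or below
0.8 and ceases above it, modelling coagulation of the capillary bed. Ties
sit on the perfused side.

**Damage.** Thermal injury accumulates as the Arrhenius integral
$\Omega(t) = \int_0^t A e^{-\Delta E/(R T_K)}\,dt'$ with the standard liver
coagulation kinetics $A = 7.39\times10^{39}\ \mathrm{s^{-1}}$,
$\Delta E = 2.577\times10^5$ J/mol (configuration keys; the study does not
print its values). The damage fraction is $\theta = 1-e^{-\Omega}$. A voxel
counts as necrotic when $\theta \ge 0.99$ ($\Omega \ge 4.6$); the 60 °C
isotherm is available as the alternative lesion criterion. "Complete
ablation" means every tumor voxel necrotic. Note that these kinetics, fit
in the 50–60 °C range, predict a small but non-negligible baseline rate at
37 °C (Ω ≈ 0.18 over 600 s, θ ≈ 16%) — far below both the necrosis
threshold and the perfusion gate, but visible if you inspect raw Ω fields.

## Planning metrics and calibration

`coverage_metrics()` reports the necrotic fraction of tumor voxels, the
necrosed healthy volume (cm³), and the minimal signed distance from the
tumor surface vertices to the necrosis boundary (negative as soon as any
surface point is outside the lesion). `ablation_time()` reports the first
time at which coverage reaches 1 — monitored at every time step, i.e. to
±dt. `optimal_power()` walks an ascending 1 W power grid and returns the
smallest power achieving complete ablation within the time budget, flagging
powers whose lesion is elongated (axial/transverse extent > 1.6), the
failure mode of high-power settings.

The single bridge between this reduced model and an absolute operating
point is the efficiency factor $\eta \in (0, 1.5]$, which absorbs
everything not modelled geometrically: the antenna's π-matching network,
reflection and cable losses, and the unprinted conductor radii.
`calibrate_efficiency()` bisects on $\eta$ until the anchor phantom
(the smaller study tumor) is just completely ablated at 10 W in 600 ± 5 s.
Every other reported number is then an out-of-sample prediction; nothing
else is fitted.

## Synthetic phantoms

The study geometries are two expert-segmented liver tumors from the public
3D-IRCADb-01 database, which this package does not redistribute. The
generator emulates them through their published bounding boxes
(1.74 × 1.53 × 2.10 cm and 1.78 × 1.97 × 2.27 cm) as triangulated
ellipsoids (subdivided icosahedra), optionally modulated radially by a
seeded low-order spherical-harmonic field (degree 2–3) and rescaled so the
bounding box is preserved. This reproduces the size, aspect ratio and
smooth irregularity of real tumors, but not their true lobulated shapes,
surface concavities, or the anatomical context (vessels, capsule,
neighbouring organs). Results on phantoms therefore validate the pipeline
and the size-dependence of the dose, not patient-specific predictions.

The antenna is inserted vertically with the slot-array midpoint at the
tumor volume centroid (the study does not state its insertion trajectories;
this is our convention, with an explicit-placement option).

## Numerics

* Voxel grid: uniform spacing, default 0.5 mm (unit tests and the
  reproduction runs use 0.8–1 mm), 15 mm healthy margin on all sides.
  A labeled voxel grid replaces the body-fitted finite elements of full
  clinical solvers — simpler, fully testable, and adequate at these scales
  (the voxelized phantom volume converges to the analytic ellipsoid volume
  within 2% between 1 and 0.5 mm).
* Time stepping: implicit Lie-split diffusion (one backward-Euler
  tridiagonal solve per axis per step; unconditionally stable and
  monotone), explicit perfusion and sources, dt = 0.25 s default. The
  Arrhenius integral is accumulated trapezoidally each step from exact-rate
  lookup tables (0.05 °C resolution).
* EM re-solve cadence: the source is recomputed whenever any voxel has
  drifted more than 10 °C since the last solve (dielectric properties are
  temperature-dependent).
* Temperatures are not capped at 100 °C; the latent-heat peak in
  $c_{\mathrm{eff}}$ is the heat sink that throttles super-boiling
  excursions.
* Degenerate inputs: zero thermal conductivity and zero perfusion are
  permitted (they are the adiabatic and conduction-only oracle limits);
  non-finite temperatures abort with a diagnostic; under-resolved EM grids
  (fewer than 3 axial cells per slot) are rejected with the required
  resolution; non-watertight meshes are rejected naming the defect.
* Determinism: identical configuration and seed give identical outputs;
  phantom generation restores the caller's RNG state.

Problem sizes: the packaged tests exercise the full pipeline on small
ellipsoid phantoms at 1 mm spacing and the study phantoms at 0.8–1 mm;
the reproduction script uses 0.8 mm grids (≈ 220–250k voxels, ≈ 5.6k and
8.1k tumor voxels) with dt = 0.25 s — our chosen desk-scale operating
point for a single-CPU run.

## Known limitations

* Constant delivered power: the deposition is renormalized to
  $\eta P_{\mathrm{in}}$ at every property update. Real antennas mismatch
  as the near field desiccates, and boiling consumes additional energy, so
  at high powers (≳ 20 W) this model ablates somewhat faster than a full
  circuit-coupled FEM treatment; the relative high-power time reductions
  are the least transferable outputs.
* The axisymmetric EM solve sees angle-averaged tissue; strongly
  asymmetric tumors interact with the field only through the thermal
  solve.
* No vasculature (the perfusion sink is homogeneous), no tissue shrinkage,
  no vapor transport, single-antenna scenes only.
* The raw dissipated power of the full-wave solve converges only
  first-order under grid refinement (slot-edge field singularities); the
  efficiency-normalized deposition shape, which is what the pipeline
  consumes, is stable to < 3% under 2× refinement.
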