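# mwaplan

Treatment-planning simulator for **microwave ablation (MWA) of liver
tumors**. Given a tumor surface mesh (or a synthetic phantom emulating the
two study tumors of the public 3D-IRCADb-01 liver database) and a multi-slot
coaxial antenna driven at 2.45 GHz, `mwaplan` predicts the necrotic zone
over time and selects the minimal input power that completely ablates the
tumor within a time budget while sparing healthy tissue. It is aimed at
researchers in computational biomedical physics and thermal-therapy
modelling who need a fully scriptable, testable pipeline rather than a
commercial FEM environment.

## The model

Three coupled components on a labeled voxel grid (healthy / tumor /
antenna):

1. **Electromagnetics** — the antenna's azimuthally symmetric TM₀ mode of
   the frequency-domain Helmholtz equation
   ∇²**E** − μᵣk₀²(εᵣ − jσ/(ωε₀))**E** = 0, solved by a conservative
   finite-volume scheme in (r, z) with PEC conductors, first-order
   absorbing outer boundaries and a matched TEM coax port; the heat source
   Q_ext = ½σ|**E**|² is rotated onto the 3D grid and normalized to
   η·P_in. A fast analytic slot-superposition backend with identical
   contracts is available behind one switch.
2. **Bioheat** — the Pennes equation
   ρc_eff ∂T/∂t = ∇·(k∇T) + ρ_b W_b c_b (T_b − T) + Q_ext + Q_m with
   evaporation-corrected effective heat capacity
   c_eff = c − α·dW/dT (logistic tissue-water curve W(T), 78% at body
   temperature), temperature-dependent dielectric decline, and blood
   perfusion that ceases once local damage passes the coagulation
   threshold. Implicit operator-split integration (unconditionally
   stable), insulated boundaries, 37 °C start.
3. **Damage** — the Arrhenius integral Ω(t) = ∫ A·exp(−ΔE/(R·T_K)) dt with
   standard liver kinetics; damage fraction θ = 1 − e^(−Ω); a voxel is
   necrotic at θ ≥ 0.99 (60 °C isotherm available as alternative).

Planning metrics: tumor coverage, necrosed healthy volume, minimal signed
safety margin, ablation time t_abl(P) (earliest complete necrosis),
optimal power (smallest P achieving complete ablation in the budget), and
a single-scalar efficiency calibration η anchored at the study's
10 W / 600 s operating point for the smaller tumor.

## Worked example

```r
library(mwaplan)

# synthetic phantom of the larger study tumor (printed bounding box
# 1.78 x 1.97 x 2.27 cm), voxelized with the antenna through its centroid
mesh <- generate_tumor_phantom("ircad-1.03")
grid <- voxelize(mesh, spacing = 1e-3, antenna = antenna_spec())
print(grid)
#> <mwa_grid> 48 x 50 x 53 voxels @ 1 mm (127200 total)
#>   tumor 4.09 cm^3 (4093 voxels), antenna 140 voxels

# simulate a 600 s treatment at 12 W (efficiency from the anchor
# calibration at this grid scale)
ant <- antenna_spec(power = 12, efficiency = 0.39)
run <- run_simulation(grid, ant, duration = 600, backend = "slot")
coverage_metrics(run$state, grid)
#>    coverage healthy_damage_cm3 margin_mm
#> 1 0.9953579              0.463 -1.422146

plot_temperature_series(run)     # heating-centre temperature vs time
```

At 12 W this tumor is 99.5% necrosed after 600 s but the margin is
negative: a patch of the tumor surface (about 1.4 mm deep) is still
viable, so 12 W/600 s is *not* a complete treatment at this grid scale —
the sweep locates the smallest sufficient power instead
(`optimal_power(grid, ant, duration = 600, powers = 9:15)`), and
`power_sweep()` tabulates the full t_abl(P) trade-off. The healthy-damage
column is the collaterally necrosed volume outside the tumor (here
0.46 cm³). `calibrate_efficiency()` sets η from the anchor scenario.

A command-line front end wrapping the same functions ships in
`inst/cli/mwaplan.R`:

```sh
Rscript inst/cli/mwaplan.R phantom --preset ircad-1.07 --out tumor.stl
Rscript inst/cli/mwaplan.R run --config plan.yaml --outdir out/
Rscript inst/cli/mwaplan.R sweep --config plan.yaml --powers 9,10,11,12
```

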