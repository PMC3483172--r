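# valveform

Single-cell kinetics and morphometry of diatom valve formation under
external pH change.

Diatoms polymerize silica inside an acidic compartment, the silica
deposition vesicle (SDV), to build each new valve of their cell wall.
`valveform` is an R implementation of the full analysis chain used to ask
how the environmental pH shapes this process in the centric diatom
*Thalassiosira weissflogii*:

* **Time-lapse kinetics** — track drifting cells in fluorescence stacks,
  extract each cell's boundary as the iso-intensity line of sharpest
  contrast (giving area *A(L)* and width *W(L)*, hence biovolume
  *A·W*), integrate a silica-affine reporter dye (HCK-123 type) over the
  local background, and fit the two initial phases of valve formation:
  exponential accumulation *F(t) = F₀·e^(kt)* up to the maximum *F₁*,
  then decay to a minimum *F₂*. Fits are accepted under the study's
  rules (Pearson *r* of the log-linear fit > 0.95, ≥ 45 min of data
  before *F₁*), and the pH dependence of *k*, *F₁−F₀* and *F₁−F₂* is
  fitted as *y = a·e^(b·pH)* over pH 6.4–8.2.
* **The three-fraction SDV model** — dye partitioning into free,
  protonation-trapped, and silica-entrapped fractions
  (*F_total = F_free + F_bound + F_fixed*, no dissolution), with
  weak-base equilibrium
  *(1 + 10^(pKa−pH_sdv))/(1 + 10^(pKa−pH_out))* and fixation flux
  *d(F_fixed·V)/dt = κ·F_bound·V*; a pH step reproduces the decay-phase
  signature, and a ΔpH maps to a *10^ΔpH* fold-change in accumulated dye.
* **Valve morphometry** — Otsu binarization of TEM valve images, circular
  pore detection, Voronoi/Delaunay pore spacing *d₁*, cribrum width *D*
  and rib width *d₂* from finger clustering, pore radius *R* and valve
  porosity *r*, plus the annotated macro traits (*W*, *N*, *cp*, *rp*).
* **Physiology** — exponential growth rates and doubling times, Si quotas
  per cell, incorporation rate (BSi/µ), and ratiometric BCECF
  intracellular pH calibration with analytic inverse.
* **Synthetic data with ground truth** — generators for time-lapse
  stacks, TEM-like pore arrays, dilution series and ratiometric pairs
  emulate the study conditions (5-min frames, 90 ± 39 min accumulation,
  47 ± 20 min decay in 75% of cells) so that every stage is validated by
  parameter recovery.

## Worked example

Generate a three-pH synthetic cohort, run the full chain (detect → track
→ level-line photometry → phase segmentation → exponential fits → pH
response), and inspect the result:

```r
library(valveform)

cfg <- default_run_config()
cfg$seed <- 11
cfg$cohort <- list(
  ph_levels = c(6.4, 7.3, 8.2), n_cells = 8,
  k_response = kinetics_reference$k_response,   # k(pH) = 1.1e-3 e^(0.32 pH)
  timelapse  = list(n_frames = 40, width = 220, height = 220, noise_sd = 3))
run <- run_timelapse(cfg)

head(run$fits[, c("pHe", "track_id", "k", "F0", "t_exp", "t_dec",
                  "fit_r", "accepted")], 5)
#>   pHe track_id       k   F0 t_exp t_dec fit_r accepted
#> 1 6.4        1 0.01034 1584    30    15 0.993    FALSE
#> 2 6.4        4 0.00960 1981    60    45 0.998     TRUE
#> 3 6.4        5 0.00793 1277   110    65 0.998     TRUE
#> 4 6.4        6 0.00928 1232    70    30 0.996     TRUE
#> 5 6.4        7 0.00775 1215    40    30 0.996    FALSE

sum(run$fits$accepted)          # 16 of 20 tracked cells pass the filters
r <- run$responses$k
sprintf("k(pH) = %.2e * exp(%.3f * pH), r2 = %.3f", r$a, r$b, r$r2)
#> "k(pH) = 1.69e-03 * exp(0.262 * pH), r2 = 1.000"
```

Each row is one tracked cell: `k` (min⁻¹) is the accumulation rate of the
reporter during SDV expansion, `t_exp`/`t_dec` the durations (min) of the
accumulation and decay phases, and `accepted` applies the inclusion rules
(cell 1 is rejected because its peak arrives before 45 min of recording).
The fitted exponent *b* ≈ 0.26–0.32 recovers the generating pH dependence
of the morphogenesis speed; at the study's cohort size (30 cells per pH,
6 levels, see `scripts/acceptance.R`) it lands within a few percent of
the generating value 0.32.

Morphometry works the same way:

```r
cfg <- default_run_config()
cfg$synthetic <- list(n = 5, porosity = c(0.05, 0.15))
run <- run_morphometry(cfg)
run$traits[, c("R_nm", "d1_nm", "porosity")]
```

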