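# p53cycle

Deterministic simulation and dynamical analysis of a coupled
**p53–Mdm2–p21–cell-cycle** kinetic model, for systems biologists studying
how DNA-damage signalling throttles the mitotic oscillator.

Ionising radiation creates DNA damage; damage stabilises p53 through
ARF-mediated Mdm2 degradation; p53 transactivates p21; and p21 sequesters
active MPF (the cyclin–Cdk complex driving the G2→M transition), stalling
the cell cycle until the damage is repaired. The package implements this
loop as 13 coupled ODEs over 25 reaction channels — a p53–Mdm2 negative
feedback network joined to a Goldbeter-type minimal mitotic cascade — and
the full downstream analysis of what an irradiation dose does to the
dynamics.

The cell-cycle core is the minimal cascade

```
dC/dt = k1 − k2·C·X/(k3 + C) − k4·C
dM/dt = k5·(1−M)/(k6 + (1−M)) − k7·M/(k8 + M) − k31·p21·M,   k5 = k14·C/(k13 + C)
dX/dt = k9·(1−X)/(k10 + (1−X)) − k11·X/(k12 + X),            k9 = k15·M
```

(C cyclin, M active MPF fraction, X active protease fraction), driven by
the p53 side through the mass-action p21 terms; the dose enters as the
initial amount of the irradiation species, converted at 40 damage units
per Gy (the standard double-strand-break yield). See the methods
vignette (`vignettes/dose-response-analysis.Rmd`) for the full equation
block, the documented resolutions of printed-parameter ambiguities, and
every detector's tolerances.

What the package provides, per module:

* `default_parameters()`, `ccm_rhs()`, `validate_state()` — the model
  itself, with a typo-resolution policy carried in the parameter object;
* `integrate_model()` — compiled fixed-step RK4 (bitwise reproducible,
  restartable, dense output), `baseline_state()` /
  `make_initial_state()` — equilibrated initial conditions per dose;
* `find_maxima()`, `collapse_interval()`, `classify_regime()`,
  `segment_regimes()`, `maxima_dispersion()` — oscillation features:
  maxima after transient removal, quiescence intervals, and
  period-k / chaotic / damped / oscillation-death labels;
* `run_dose_scan()`, `phase_boundary()`, `collapse_curve()`,
  `fit_collapse_model()`, `saturation()`, `time_resolved_bifurcation()`,
  `maxima_vs_dose()` — the dose-response analyses;
* `synth_signal()`, `generate_collapse_family()`,
  `perturb_parameters()` — synthetic fixtures with ground truth, so every
  detector and fitter is testable without the model;
* `render_panels()`, `write_run_record()` — figure-style outputs with CSV
  twins and hashed run provenance; a thin CLI lives in
  `inst/cli/p53cycle`.

## Worked example

```r
library(p53cycle)
p <- default_parameters()

# one irradiated trajectory: 5 Gy, 250 h
tr <- integrate_model(p, make_initial_state(5), t_end_h = 250)
find_maxima(tr, "p53")          # 11 ringing peaks, the first near 27.7 h

# dose scan and the headline analyses
scan <- run_dose_scan(seq(0, 12, by = 0.5), horizon_h = 250)
phase_boundary(scan)
#> phase diagram (p53, window [70, 120] h): boundary 3.352 Gy
cc <- collapse_curve(scan)
fit_collapse_model(cc)
#> collapse-law fit (dt in s): A = 94917.6, B = 0.360636 (A/B = 263195 s)
#>   n = 25, residual norm = 1.053e+05
saturation(cc)
#> saturation: R_c = 9.5 Gy, dt_c = 77.68 h (6 plateau points)

# time-resolved regime structure of cyclin at 5 Gy
time_resolved_bifurcation(5, "cyclin", horizon_h = 250)$segments
#>   t_start t_end    label  k
#> 1       0    75  chaotic NA
#> 2      75   250 period_1  1
```

Reading the output: below ~3.35 Gy the late-time p53 dynamics has settled
(oscillation-death phase); above it, ringing persists into the late
window (oscillating phase). The collapse time — when the p53 oscillation
dies out — grows with dose and plateaus near 78 h from ~9.5 Gy; the
saturating law `Δt = A/(B + e^−IR)` fitted in seconds summarises the
curve. On the cell-cycle side, a 5 Gy dose drives cyclin through a ~75 h
chaotic epoch before the limit cycle (`period_1`, sustained oscillation)
re-establishes.

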