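# pbrflash

Flashing-light (light/dark cycle) analysis for a flat-panel airlift
photobioreactor with horizontal tube baffles.

## The problem

In a dense microalgal culture, usable light penetrates only a centimetre or
two from the illuminated face; the rest of the panel is dark. Growth improves
when circulation shuttles cells rapidly between the light and dark zones
(the *flashing light effect*). A vertical stack of horizontal tube baffles
changes the panel's hydrodynamics — it raises mid-height horizontal velocity
and breaks the single circulation loop into baffle-scale vortices — and
thereby shortens the light/dark (L/D) cycle period experienced by the cells.

`pbrflash` is a desk-scale, fully seeded pipeline for quantifying that
effect. It is aimed at bioprocess modellers who want a reproducible,
CFD-free stand-in for the full chain:

1. **Geometry** — 160 x 900 mm panel mid-plane, six 70 mm baffle circles at
   z = 90 + 120k mm, two injection ports (`build_geometry()`).
2. **Synthetic flow** — divergence-free streamfunction fields for both
   regimes, calibrated so the standard sampling-line averages match reported
   velocities per aeration rate (`calibrate_field()`).
3. **Lagrangian tracking** — 5 um tracer cells, Stokes drag +
   pressure-gradient force, discrete-random-walk dispersion, specular
   reflection; `dt = 0.004 s`, positions every 0.1 s for 60 s (`track()`).
4. **Light model** — Beer-Lambert attenuation `I(d) = I0 e^(-sigma_a C d)`
   with critical depth `d_crit = ln(I0/I_crit)/(sigma_a C)`
   (`fit_attenuation()`, `classify_position()`).
5. **L/D statistics** — per-cell average cycle period `T_av_i`, flashing
   frequency `f = 1/T_av_i`, light-time fraction, population average
   `T_av_p`, 5 s cycle-period histogram (`population_summary()`).
6. **Tracer estimators** — volumetric mass-transfer coefficient from
   `dC_L/dt = kLa (C* - C_L)` (dynamic gassing-out, `estimate_kla()`) and
   tracer-pulse mixing time at the 5% settling criterion
   (`estimate_mixing_time()`), each with a matching synthetic probe-trace
   generator.

See `vignettes/flashing-light-methods.Rmd` for the model details and the
design rationale.

## Worked example

```r
library(pbrflash)

geom <- build_geometry()
fb <- calibrate_field(geom, rate = 0.02, baffled = TRUE)
fu <- calibrate_field(geom, rate = 0.02, baffled = FALSE)
c(vertical_velocity(fb), horizontal_velocity(fb))
#> [1] 9.6 1.0
c(vertical_velocity(fu), horizontal_velocity(fu))
#> [1] 10.20 0.52

# light model fitted to two calibration pairs predicts the third
model <- fit_attenuation(data.frame(concentration_g_per_L = c(0.28, 1.7),
                                    critical_depth_cm = c(5, 1)))
critical_depth(model, 0.85)
#> [1] 1.81497

# kLa recovery from a synthetic noiseless re-aeration trace
tr <- simulate_do_trace(0.208, c_star = 8, c0 = 0,
                        duration_s = 20 * 3600, dt = 10)
estimate_kla(tr, c_star = 8)$kla_h
#> [1] 0.208

# mixing time from a two-probe pH pulse with true settling time 22.5 s
p <- mixing_params_for_settling(22.5, noise_sd = 0.01, seed = 43)
estimate_mixing_time(simulate_ph_trace(p, duration_s = 60))
#> [1] 22.5
```

The vertical/horizontal pairs are the calibrated line averages in cm/s: with
baffles the vertical velocity drops slightly (9.6 vs 10.2) while the
horizontal velocity nearly doubles (1.0 vs 0.52) — the hydrodynamic signature
of the baffles. The 1.81 cm critical depth says the light zone at 0.85 g/L is
about 2 cm deep; the estimator calls return the generating parameters of the
synthetic traces.

The full end-to-end comparison (two 1000-particle, 60 s tracking runs) takes
a couple of minutes on one CPU:

```r
res <- run_pipeline(default_run_config(), out_dir = "pbr_out")
res$comparison[1, c("metric", "baffled", "unbaffled", "pct_change_unbaffled")]
#>     metric  baffled unbaffled pct_change_unbaffled
#> 1 t_av_p_s 20.56389  28.21286             37.19613
```

With the default seeds the baffled population L/D cycle period is about 21 s
against 28 s without baffles — removing the baffles lengthens the cycle
period by ~37% (equivalently, adding them shortens it by ~27%) — and the
probability of a 5-10 s cycle period rises from 0.043 to 0.151. The
directions mirror the physical expectation; magnitudes depend on the flow
emulator, as discussed in the vignette.

A command-line interface wraps the same stages:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "pbr.R", package = "pbrflash"))') \
    run --config config.json --seed 1 --out-dir pbr_out
```

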