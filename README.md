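# circawave

Spatiotemporal analysis of circadian recordings: SCN slice imaging,
electrophysiology and wheel-running behaviour.

## What this package is for

The suprachiasmatic nucleus (SCN) welds ~20,000 cell-autonomous circadian
clocks into one ensemble oscillation whose emergent properties — period,
phase, amplitude, synchrony and a stereotypical spatiotemporal wave of
activation — are the readouts of interest when circuit components are
imaged, recorded or perturbed. circawave implements the quantitative
pipeline for those readouts, for researchers analysing:

* **bioluminescence/fluorescence time-lapse movies** (Per2::Luciferase,
  Cry1-driven luciferase, GCaMP, ArcLight) — slice masking, grid-ROI
  extraction, per-cycle **phase maps** in circadian time (CT12 anchored to
  the ensemble reference peak), categorical CT-bin cluster maps,
  fluorescence-region overlays and baseline-normalised change maps;
* **the spatiotemporal wave** — centre-of-luminescence (CoL) trajectories
  and the per-cycle convex-hull **excursion area** as a percentage of slice
  area;
* **oscillator synchrony** — Rayleigh mean-vector length
  `R = |mean(e^{i*theta})|` with the standard uniformity test;
* **rhythm metrics** — FFT-seeded nonlinear least-squares fitting of damped
  cosines giving period, amplitude, acrophase, relative amplitude error
  (RAE = amplitude CI half-width / amplitude) and goodness of fit;
* **spike trains** — the revised local-variation regularity statistic
  `LvR = 3/(n-1) * sum (1 - 4 I_i I_{i+1}/(I_i+I_{i+1})^2)(1 + 4R/(I_i+I_{i+1}))`
  (refractoriness constant R = 5 ms), spontaneous firing rate, firing index
  and input resistance;
* **optogenetic phase-response curves** — baseline peak extrapolation,
  predicted-minus-actual shifts normalised to CT (advances positive) and
  CT-binned PRC tables;
* **behaviour** — Sokolove–Bushell chi-square periodogram, nonparametric
  relative amplitude `(M10 - L5)/(M10 + L5)`, onset detection,
  onset-aligned activity profiles and the subjective day/night split.

Seeded synthetic generators (`make_movie()`, `make_pmt_trace()`,
`make_spike_train()`, `make_actogram()`) emulate every modality with exact
ground truth, so each stage is validated by recovery rather than by
fixture files.

## Worked example

Simulate a shot-noise-limited slice movie carrying a 3 h dorsal-to-ventral
phase gradient, then recover the wave:

```r
library(circawave)

p <- movie_params(height = 64, width = 64, frame_interval = 0.5, n_cycles = 6,
                  period = 24, phase_gradient_span = 3, amplitude = 50,
                  baseline = 100, noise = list(type = "poisson", gain = 16),
                  mask_shape = "bilateral-ellipse", seed = 11)
sim  <- make_movie(p)
mask <- mask_scn(sim$movie)
grid <- grid_rois(sim$movie, mask, cell_size = 4)
pm   <- compute_phase_map(grid)
pm
#> <circa_phasemap> 106 ROIs (106 phased), 4 cycles, ensemble period 24.00 h

rayleigh_summary(pm)
#>     n         R mean_angle_rad mean_phase_ct      p_value
#> 1 106 0.9799033       3.141656      12.00024 5.279753e-66

phase_span(pm$phase_ct)        # recovered wave span, imposed 3 h
#> [1] 3.01

area <- col_trajectory_area(col_series(sim$movie, mask), sim$movie, mask)
area$mean_pct                  # CoL excursion, % of slice area
#> [1] 0.110

fftnlls_fit(grid_mean_ts(grid))
#>   period amplitude acrophase damping_rate      rae    gof n_components converged
#> 1     24     48.97     11.99     0.004987 0.002748 0.9998            1      TRUE

tr <- make_spike_train(10, "poisson", refractory = 0.005, duration = 600, seed = 1)
c(lvr = lvr(tr), sfr_hz = sfr(tr))
#>    lvr sfr_hz
#>  0.970  9.99
```

Reading the output: all 106 ROIs are phased around CT12 with tight synchrony
(R = 0.98, Rayleigh p ≈ 1e-66); the recovered phase span matches the imposed
3 h wave; the CoL excursion covers ~0.1% of slice area (a shallow
one-dimensional wave); the ensemble rhythm fits a 24.0 h damped cosine with
near-zero RAE; and an irregular (Poisson-like) spike train scores LvR ≈ 1 at
its nominal 10 Hz rate.

An end-to-end run (simulate → phase map → CoL → Rayleigh → fits, with CSV
outputs and a checksummed manifest) is one call:

```r
run_pipeline(list(seed = 7, out_dir = "demo-run"))
```

or from a shell via `Rscript inst/cli/circawave.R --config run.cfg`.

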