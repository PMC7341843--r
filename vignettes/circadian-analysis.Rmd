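---
title: "Methods: spatiotemporal analysis of circadian recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatiotemporal analysis of circadian recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circawave)
```

circawave analyses the recording modalities used to characterise the
suprachiasmatic nucleus (SCN) circadian circuit and its behavioural output:
bioluminescence/fluorescence time-lapse movies of organotypic slices
(Per2::Luciferase, Cry1-driven luciferase, GCaMP calcium and ArcLight voltage
reporters), whole-slice photomultiplier (PMT) photon-count traces,
cell-attached spike recordings, and wheel-running actograms. This vignette
explains each method, its assumptions and tunable parameters, the numerical
choices made where the procedures were genuinely open, and what the
synthetic-data generators do and do not emulate.

## Trace conditioning and peak extraction

All rhythm analyses start from a uniformly sampled trace (`circa_ts`, time in
hours). Conditioning is a two-step moving-average scheme:

* `detrend_ts()` subtracts a centred moving average with a default window of
  24 h, removing baseline drift while passing the circadian component. When
  the window is an even number of samples the two endpoint samples receive
  half weight, so the window spans exactly 24 h: a cosine whose period equals
  the window is then annihilated by the average (and returned unchanged), and
  any linear ramp is removed exactly. Samples whose full window does not fit
  are flagged missing rather than extrapolated — peak search near recording
  edges is unreliable and is simply not attempted.
* `smooth_ts()` applies a short centred moving average (default 2.5 h,
  rounded to the nearest odd sample count) to suppress sample-to-sample
  noise. Its gain on a 24 h cosine is the discrete Dirichlet factor
  `sin(n*pi*dt/24) / (n*sin(pi*dt/24))`, about 0.98 at 0.5 h sampling — a
  2% amplitude cost accepted for stable peak detection.

`find_peaks()` locates local maxima separated by at least `min_separation`
(default 16 h, which rejects sub-circadian maxima but admits any rhythm in
the 18–34 h range) with a prominence of at least 10% of the signal range.
Peak times are refined below the sampling interval by the parabola through
the three samples around each maximum. On densely sampled traces (6-min PMT
bins) that three-point parabola is noise-limited — its jitter is roughly
0.3 h at 5% noise — so an alternative refinement fits a least-squares
quadratic over all samples within `refine_window` hours of the maximum; the
phase-response module uses ±3 h by default, which cuts the jitter several
fold while remaining unbiased for a locally symmetric peak.

`peak_to_peak_periods()` reports each interval between successive peaks as
the period of that cycle, the readout used to follow transient period
changes (e.g. progressive lengthening during genetic complementation).

## Phase mapping of movies

`mask_scn()` thresholds the temporal-mean image at a fraction (default 0.2)
of its robust maximum — the 99th-percentile intensity, so isolated hot pixels
cannot set the scale — and keeps up to two connected components, one per
nucleus of a bilateral slice. `grid_rois()` then tiles the frame with square
cells (default 8 px; the acceptance analyses use 4 px on 64 px frames) and
keeps, for each cell at least half inside the mask, the mean masked-pixel
trace.

`compute_phase_map()` expresses each ROI's peak times in circadian time (CT)
with the convention that CT12 coincides with the peak of the ensemble
reference signal. For reference peak `k` at time `t_ref(k)` with peak-to-peak
period `tau(k)`, an ROI peaking at `t_roi` within half a cycle of `t_ref(k)`
receives phase `(12 + 24*(t_roi - t_ref(k))/tau(k)) mod 24`. The reference
defaults to the whole-field mean of the grid, with an override for an
externally recorded reference; matching each ROI to its nearest reference
peak within ±tau/2 makes the assignment unique per cycle. Per-cycle phases
are combined by circular (vector) averaging — CT is a circular variable and
arithmetic means would fail at the wrap. ROIs with fewer than two detected
peaks are left unphased rather than guessed.

`classify_phase_clusters()` bins phases into the six ordered categories
below CT10, CT10–11, …, above CT14 (edges configurable).
`region_overlay()` labels ROIs inside a fluorescence-delineated territory
when their normalised intensity (ROI mean divided by the mean over all ROIs)
strictly exceeds 1; exact equality — e.g. a uniform image — is labelled
outside, because membership is defined by strict inequalities on both sides.
`normalized_change_map()` reports per-ROI relative change from that ROI's
own pre-event baseline mean.

## Centre-of-luminescence wave statistics

The travelling wave of circadian activation is summarised by the
centre of luminescence (CoL): per frame, the intensity-weighted centroid over
masked pixels. `col_series()` by default weights each pixel by its
mean-subtracted, rectified intensity, so the centroid tracks the currently
active region rather than static anatomy; a raw-intensity option is
provided. Two numerical safeguards matter in practice:

* centroid coordinates are smoothed with the standard 2.5 h moving average;
* frames whose total weight falls below 10% of the maximum frame weight are
  flagged and excluded — near the oscillation trough the rectified signal
  vanishes and the centroid would otherwise be set by noise alone.

`col_trajectory_area()` segments the recording into cycles at the peaks of
the conditioned masked-mean trace, takes the convex hull of each cycle's
centroid cloud as the perimeter of the excursion, and expresses the hull
area as a percentage of the area of the temporally integrated signal (the
thresholded temporal-mean image). Per-cycle areas are averaged; a
whole-recording hull is available by flag. Collinear centroid paths have
exactly zero hull area — with the generator's strictly one-dimensional phase
gradient the noiseless centroid oscillates along a line, and it is the
shot-noise width of real (or realistically simulated) recordings that gives
the excursion its finite area, growing with the gradient span. Both the
centroid and the area percentage are exactly invariant to intensity scaling
and equivariant to translation, because every threshold in the chain is
relative.

## Rayleigh circular statistics

Oscillator synchrony is summarised by the Rayleigh mean resultant vector of
the per-ROI phases (one unweighted unit vector per oscillator): length
`R = 1` for perfect synchrony, `R = 0` for balanced dispersion.
`rayleigh_test()` uses the standard approximation
`p = exp(sqrt(1 + 4n + 4(n^2 - Z^2)) - (1 + 2n))`, `Z = nR^2`. Phases
entering the summary are each ROI's circular-mean phase over the analysis
window; a per-cycle option is retained. Note one statistical fact relied on
in validation: for `n = 100` uniform phases, `P(R < 0.15) ≈ 0.895`, so the
fraction of uniform populations below 0.15 in 100 draws hovers at ~0.9.

## FFT-seeded nonlinear least-squares rhythm fitting

`fftnlls_fit()` estimates period, amplitude, relative amplitude error (RAE)
and goodness of fit (GOF) of the circadian component of a trace:

1. the trace is linearly detrended by least squares;
2. the FFT of the residual ranks candidate frequencies by spectral power;
3. a sum of exponentially damped cosines
   `sum_j exp(-d_j t) (a_j cos(2*pi*t/tau_j) + b_j sin(2*pi*t/tau_j))`
   is fitted by Levenberg–Marquardt least squares, adding candidates in
   power order while each newly added component remains significant — its
   amplitude's linearised 95% confidence interval (delta method on the
   Jacobian at the optimum) must exclude zero — up to 4 components;
4. the retained component with period inside the search window (default
   18–34 h) is the circadian component. RAE is the half-width of the
   amplitude CI divided by the amplitude (clipped to [0, 1]; ~0 means a
   robust rhythm, values above ~0.5 an unreliable one) and GOF is
   `1 - SS_res/SS_tot` of the full model on the detrended trace.

Damping is bounded to [-0.05, 0.2] per hour so the envelope stays
sign-definite and mild over a recording; period bounds keep each component
within a factor of 3 of its FFT seed. A trace with no significant in-window
component is flagged arrhythmic (`converged = FALSE`), never an error, so
batch runs (`batch_fit()`) propagate per-trace failures as rows. The
component-retention rule and the R²-style GOF are this package's documented
choices; no numerical identity with any external FFT-NLLS service is
claimed. `ablation_windows()` reproduces the standard pre/post analysis
windows around a treatment (4 days each, excluding the first 36 h after
application).

## Spike-train statistics

`lvr()` evaluates the revised local-variation measure over consecutive ISI
pairs,

$$\mathrm{LvR} = \frac{3}{n-1}\sum_{i=1}^{n-1}
  \Big(1 - \frac{4 I_i I_{i+1}}{(I_i+I_{i+1})^2}\Big)
  \Big(1 + \frac{4R}{I_i+I_{i+1}}\Big),$$

with the refractoriness constant `R` defaulting to 5 ms. LvR is ~0 for
clock-like firing, ~1 for Poisson-like discharge, and is invariant to time
rescaling when `R` is rescaled identically (fully scale-free at `R = 0`).
Companions: `sfr()` (count/duration), `firing_index()` (evoked spikes per
60 light pulses; below 1 flags entrainment failure), `input_resistance()`
(least-squares slope of steady-state voltage deflection vs injected current,
mV/pA × 1000 = MΩ), and `ct_bin()` for the 4-h circadian grouping of timed
recordings.

## Phase-response curves

A stimulation experiment is a trace with at least four pre-stimulation
cycles. `phase_shift()` conditions the pre- and post-stimulation segments
separately — detrending across the stimulation step would drag the last
baseline peak by several tenths of an hour — fits an ordinary least-squares
line through (cycle index, baseline peak time) whose slope is the baseline
period (lower variance than averaging the peak-to-peak intervals of only
four peaks), and converts each of the first three measurable
post-stimulation peaks into a shift: predicted minus actual peak time,
normalised to circadian time by the baseline period and wrapped into
(-12, 12] h. Advances are positive, delays negative. Because shifts are
defined modulo one cycle, the wrapped computation is independent of which
cycle index each post peak is matched to — robust to a first post peak lost
in a conditioning edge. The stimulation phase is the CT of the stimulation
time under the baseline fit (CT12 at the rhythm peak). `build_prc()` bins
points into CT bins (default 4 h) with per-bin mean ± SEM and flags bins
with fewer than 5 points.

## Wheel-running behaviour

`chi_square_periodogram()` implements the Sokolove–Bushell statistic: for
each candidate period (an integer number of bins) the record is folded and
`Qp = SS_between / (SS_total/n)` computed, approximately chi-square with
(columns − 1) degrees of freedom under the no-rhythm null. Two consequences
shape the defaults. First, the null df grows with the candidate period, so
the best period is the maximiser of Qp *minus* the significance line, not of
raw Qp. Second, scanning ~100 candidate periods at a per-period 5% line
would flag rhythm-free records in well over a third of runs, so the default
line is Bonferroni-corrected across the candidates (per-period line available
via `correct = FALSE`); the reported amplitude is the Qp excess over that
line at the best period, in periodogram-power units.

`relative_amplitude()` is the standard nonparametric contrast
`RA = (M10 - L5)/(M10 + L5)` between the most-active 10 h and least-active
5 h windows of the folded mean profile, with window lengths scaled as 10/24
and 5/24 of non-24 h profile periods. For a square-wave (block) activity
pattern carrying a fraction `f` of activity in the active half-cycle,
`RA = 2f - 1` in closed form — the oracle used in validation.

`detect_onset()` smooths the folded profile (3 bins, circular), thresholds
it at a fraction of the smoothed *range above the minimum* (default 0.5, the
midrange crossing), and returns the first bin of the longest circular run of
supra-threshold bins lasting at least 6 bins. Range-referencing matters:
nocturnal animals with substantial subjective-day activity (e.g. a 64/36
night/day split leaves day rates at ~56% of night rates) never drop below a
threshold referenced to the profile maximum, while the midrange crossing
separates the two plateaus whenever night rates exceed day rates. When every
bin is supra-threshold (constant activity) the onset defaults to bin 1.

`aligned_profile()` folds the last 7 days of each animal's record at the
profile period (default 27 h, 12-min bins), peak-normalises, rotates each
profile so its onset sits at the profile mid-point, and averages across
animals with SEM. `day_night_split()` integrates the profile over the half
cycle starting at the onset (subjective night, nocturnal convention) versus
the complement; a bin straddling the half-cycle boundary contributes
proportionally, so a uniform profile splits exactly 50/50 regardless of bin
parity.

## Synthetic-data generators

Every analysis stage is validated against seeded generators with exact
ground truth (`make_movie()`, `make_pmt_trace()`, `make_spike_train()`,
`make_actogram()`). Design choices:

* **Movies** impose per-pixel damped cosines with a *linear* phase gradient
  along one image axis (default vertical, emulating the dorsal-to-ventral
  wave) on a bilateral-ellipse, disc or full-frame mask; the ground truth
  records each pixel's CT phase under the same CT12 convention the analysis
  uses, the amplitude, and the exact period. Phases are imposed, not evolved:
  there is no oscillator coupling, no mechanistic feedback-loop model, and
  the wave is one-dimensional — passing tests therefore demonstrate correct
  *measurement*, not realism of SCN network dynamics. Shot noise is Poisson
  on the photon count after scaling by a gain (bioluminescence is
  shot-noise limited); with baseline 100, amplitude 50 and gain 16 the
  amplitude SNR is ~20, the regime used in validation. Real recordings'
  noise levels are not published for these modalities, so the default noise
  is a free parameter, not a calibration.
* **PMT traces** are damped cosines with optional drift, gaussian noise and
  a step phase change at a stimulation time (advance positive), sampled at
  6-min bins.
* **Spike trains** are renewal processes (regular, Poisson, or gamma with
  shape controlling regularity); refractoriness is dead-time shifting of
  each ISI with the stochastic part's mean reduced to preserve the requested
  rate, matching the refractoriness interpretation of the LvR statistic.
  Requesting `rate * refractory >= 1` is rejected as infeasible.
* **Actograms** are Poisson counts with a block-rate profile: the first half
  of each cycle (subjective night) carries the stated fraction of total
  activity at 1 count/min overall by default, so onsets fall at exact
  period multiples and RA has the closed form above.

## Problem sizes and reproducibility

Validation uses 64×64 px, 6-cycle movies at 0.5 h frames (288 frames,
~100 ROIs at 4 px cells), 144–230 h PMT traces at 6-min bins, spike trains
of 10³–10⁵ ISIs, and 10-day actograms at 12-min bins — sizes chosen so the
whole suite and the acceptance script run in minutes on a single core while
keeping Monte-Carlo standard errors well inside the asserted tolerances.
Every generator takes an explicit integer seed and returns bit-identical
output for identical parameters; `run_pipeline()` threads one seed through
all stages and writes a manifest with MD5 checksums, so a fixed
configuration reproduces byte-identical CSVs.

## Known limitations

* The movie generator's wave is a linear one-dimensional gradient; curved or
  rotating waves, regional amplitude structure and oscillator coupling are
  out of scope.
* Movies are assumed motion-free (slice recordings); there is no
  registration step, and no single-cell segmentation — the analysis unit is
  the grid ROI.
* `fftnlls_fit()` reports linearised confidence intervals; for heavily
  damped, short records they understate the true uncertainty.
* The periodogram's amplitude is reported in Qp units relative to the
  significance line; it is not comparable across records of different
  lengths or bin widths.
* Phase maps require at least two detected peaks per ROI; very noisy or
  strongly damped ROIs drop out rather than contribute degraded phases.
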