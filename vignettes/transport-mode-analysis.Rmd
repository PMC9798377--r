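---
title: "Transport-mode analysis of intracellular single-particle trajectories"
author: "trajmodes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transport-mode analysis of intracellular single-particle trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajmodes)
```

## The problem

Nanoparticles and extracellular vesicles taken up by cells do not move in a
single way. The same cargo alternates between free (Brownian) diffusion,
motor-driven directed transport along cytoskeletal filaments, anomalous
subdiffusion in the crowded cytoplasm, and confinement inside organelles or
membrane domains. Video particle tracking yields 2D trajectories
$(x_j, y_j)$ sampled at a frame interval $\Delta t = 1/\mathrm{fps}$, and
the shape of the mean squared displacement (MSD) as a function of the time
lag $\tau = k\,\Delta t$ is the standard readout for telling these modes
apart.

`trajmodes` implements the full chain: MSD computation, transport-mode
model fitting, whole-trajectory ("nonsegmented") population analysis,
rolling-window segmentation of individual trajectories into transport-mode
segments, and the derived mobility statistics. Because suitable public
tracking data with ground truth do not exist, the package ships a labelled
trajectory simulator, and every stage is validated by parameter recovery
against it.

## Models

For a single trajectory the time-averaged MSD at lag $\tau = k\Delta t$ is
the mean over start frames $j$ of
$(x_{j+k}-x_j)^2 + (y_{j+k}-y_j)^2$; the ensemble-averaged MSD is the
unweighted mean of the per-trajectory curves. Four 2D models are fitted to
MSD curves:

* **normal diffusion** $\mathrm{MSD}(\tau) = 4D\tau$,
* **active transport** $\mathrm{MSD}(\tau) = 4D\tau + (v\tau)^2$,
* **anomalous diffusion** $\mathrm{MSD}(\tau) = 4D\tau^{\alpha}$,
* **confined diffusion**
  $\mathrm{MSD}(\tau) = r_c^2\bigl(1 - A_1 e^{-4A_2 D \tau / r_c^2}\bigr)$,

with $D$ the diffusion coefficient (µm²/s), $v$ the active speed (µm/s),
$\alpha$ the anomalous exponent ($\alpha = 1$ normal, $<1$ subdiffusion,
$>1$ superdiffusion), $r_c$ the confinement radius (µm) and $A_1, A_2$
dimensionless shape constants. The prefactor 4 is the 2D convention; the
analysis operates on 2D projections of the particle positions.

### Numerical strategy for the fits

All fits are least squares on the linear MSD values. The normal and active
models are linear in their coefficients and solved in closed form with
non-negativity clamps. The anomalous and confined models are solved by
one-dimensional *profiled* least squares: for a fixed exponent $\alpha$
(resp. a fixed exponential rate $c$) the remaining parameters are linear
and have closed-form solutions, so a single bounded 1D minimisation
(`stats::optimize`) over $\alpha \in [0.1, 2]$ (resp. over $\log c$, after
a coarse grid) finds the optimum. This is deterministic, has no
starting-value failures, and is fast enough to run thousands of times
inside a rolling window. Degenerate input (an all-zero MSD from a
stationary trajectory) yields a flagged, non-converged fit rather than an
error.

The confined model deserves a note: $A_2$ and $D$ enter only through their
product, so only three parameter combinations are identifiable — the
plateau $P = r_c^2$, the amplitude $Q = P A_1$, and the rate $c$. The
package fits those three and defines $D$ through the short-lag slope
$\mathrm{MSD}'(0) = Q c = 4D$, which is the physically meaningful
short-time diffusion coefficient inside the confinement and implies
$A_2 = 1/A_1$. $A_1$ is constrained to $(0, 2]$.

### Default lag range

A time-averaged MSD is an average over fewer and fewer displacement pairs
as the lag grows, and its fluctuations are strongly correlated across
lags. Fits that include a fixed *fraction* of the lags therefore become
dominated by those fluctuations on long trajectories: on 1000-step
simulated Brownian trajectories, fitting the power law over the first
quarter of all lags gives exponents centred near 0.95 with a spread of
0.24, while restricting the fit to the first 10 lags re-centres them at
1.00 with a spread of 0.05. The default lag range of `fit_msd()` is
therefore $k = 1 \ldots \max(3, \min(10, \lfloor 0.25\,n_{\mathrm{lags}}
\rfloor))$ — the field-standard short-lag fit. Two deliberate exceptions:

* window classification inside `rolling_classify()` uses the first quarter
  of the *window's* lags uncapped (windows are short, and the active and
  confined signatures only become visible at the window's longest lags),
  down-weighted by $1/\tau^2$ to counter the steeply growing MSD variance;
* segment parameter refits use the first quarter of the *segment's* lags
  uncapped, so the lag span in seconds — and with it the extracted active
  velocity — is comparable across frame rates.

## The simulator

`simulate_trajectory()` draws one trajectory per `sim_config()`:

* *normal*: independent Gaussian steps per axis, variance $2D\Delta t$;
* *active*: the same steps plus a constant displacement $v\Delta t$ along
  a heading drawn once per segment from a seeded uniform angle (the active
  model assumes a persistent velocity over the fitted window);
* *anomalous*: fractional Brownian motion per axis with Hurst exponent
  $H = \alpha/2$, sampled by exact Davies–Harte circulant embedding (with
  a Cholesky fallback if the embedding is not non-negative definite) and
  scaled so the MSD is $4D\tau^{\alpha}$. fBm reproduces the power-law MSD
  without committing to an obstacle or binding mechanism;
* *confined*: Brownian steps radially reflected at a circle of radius
  $r_c$ centred on the segment start — the simplest mechanism producing a
  plateau; note the plateau of the resulting time-averaged MSD is
  $\approx r_c^2$.

Localization noise — the camera's per-frame position error — is added
after path generation as i.i.d. zero-mean Gaussian noise per axis
(`sigma_loc`). `simulate_switching()` concatenates segments continuously
in position with instantaneous parameter switches, emulating the
"stop-and-go" motion of intracellular cargo, and records per-position
ground-truth labels. `matched_brownian_ensemble()` reproduces the standard
control for finite-trajectory-length broadening: pure Brownian
trajectories with one common $D$ but the observed trajectory lengths.

What the simulator does **not** emulate: spot detection and linking (the
pipeline starts from linked trajectories), photobleaching-driven intensity
loss (length censoring is emulated directly through trajectory lengths),
anisotropic or time-varying localization error, and motion blur. Passing
recovery tests on these synthetic data therefore demonstrates the
correctness of the estimators under the stated models, not robustness to
every artefact of real microscopy.

## Nonsegmented analysis

For population-level screening each whole trajectory contributes one
power-law fit (`per_trajectory_anomaly()`), one scaled relative
displacement $\Delta x_{\max}/\sqrt{T}$ (`relative_displacement()`), and
pooled axis displacements at a chosen lag (`displacement_pdf()`).
Fast, freely diffusing particles in the medium separate from slow
cell-associated particles by relative displacement
(`classify_mobility()`; the automatic threshold sits at the density
minimum between the two modes of the pooled distribution, in log space,
and refuses unimodal distributions). Gaussianity of the displacement PDF
is scored as the excess kurtosis of the pooled sample (0 for a Gaussian),
since visual PDF comparison does not automate. The ensemble diffusion
coefficient of the fast group converts to a medium viscosity through the
Stokes–Einstein relation $\eta = k_B T / (3\pi D d)$
(`stokes_einstein_viscosity()`, default $T = 293.15$ K); for
$D = 3\ \mu\mathrm{m}^2/\mathrm{s}$ and $d = 100$ nm this gives
$\approx 1.4$ mPa·s, close to water, which is the expected sanity check
for particles diffusing in cell-culture medium.

## Rolling-window segmentation

`rolling_classify()` slides an analysis window (`window_s` seconds) along
the trajectory one frame at a time, classifies each window from its MSD,
and labels each position by majority vote over the windows covering it
(ties broken toward the previous position, favouring temporal
continuity). Runs shorter than the minimum segment length are merged into
the flanking run whose fitted model describes the run's own MSD better
(ties toward the earlier segment). The minimum segment length defaults to
60% of the window, the standard ratio across all analysis settings
(`analysis_settings()`).

The window decision rule is this package's own construction (the
published per-position classifiers it emulates do not document a simple
closed rule): fit the power law; windows with $\hat\alpha >$
`alpha_super` (default 1.3) are *active* if the active model improves the
relative fit error by at least `margin` (default 10%) over pure
diffusion, otherwise normal; windows with $\hat\alpha <$ `alpha_sub`
(default 0.7) are *confined* if the exponent has collapsed to the
saturation regime ($\hat\alpha \le$ `alpha_plateau`, default 0.25 — a
plateau resolved inside the window drives the fitted exponent toward its
lower bound) and the confined model fits at least as well as the power
law, otherwise *anomalous*; everything else is *normal*. A window with no
measurable displacement is confined below resolution. All thresholds are
config-exposed (`segmentation_config()`). On well-separated four-mode
switching ensembles (active displacement at least three diffusion lengths
per window, $\alpha \le 0.5$, confinement radius far below the free
diffusion span) this rule labels over 90% of positions correctly and
locates switch points within one window length; accuracy degrades
gracefully as the modes' effect sizes shrink.

Per-segment parameters are refit from each segment's own MSD with its
mode's model ($D$ for all modes, $v$ for active, $\alpha$ for anomalous).
`mode_proportions()` weights by positions, not segments; unclassified
end-positions of too-short trajectories are excluded from the denominator
and reported as a count. Among active segments,
`rapid_transport_fraction()` reports the fraction with $D \ge 0.01\
\mu\mathrm{m}^2/\mathrm{s}$, the conventional cutoff separating rapid
microtubule-directed transport from slower microfilament-associated
movement.

## Frame rate and window effects

`framerate_window_sweep()` simulates one ensemble at a high frame rate,
subsamples it to each requested rate, and segments it at each window.
Three robust qualitative behaviours, verified in the test suite on a
fixed mode-switching ensemble (ten 122 s trajectories alternating 30 s
normal diffusion, 8 s active bursts at 0.5 µm/s and 15 s subdiffusion,
simulated at 100 fps and analysed at the six standard settings):

* the apparent median active velocity falls from the fast-sampled small
  window to the slow-sampled large window (large windows average active
  bursts with flanking slow motion; two settings that resolve the bursts
  equally well have statistically tied medians);
* the detected anomalous proportion collapses at 2 fps even at the same
  15 s window — subdiffusion looks normal on coarse time grids;
* median per-mode diffusion coefficients stay comparable (within 25%)
  across all settings.

Drift is handled before any analysis: `subtract_drift()` estimates a
single constant-velocity stage drift per ensemble (per video) as the
ensemble-mean displacement per unit time and removes it cumulatively. A
per-frame nonparametric drift estimate was rejected as over-fit at
typical track counts (tens of trajectories); a constant velocity is the
stated concern (stage drift) and is what the simulator's `apply_drift()`
inverts exactly.

## Choices made where the design was open

* **Drift scope**: per-ensemble (per video), not per cell; recordings
  share one stage.
* **Gap policy**: tracking gaps are preserved, never interpolated; MSD
  pairs use true frame differences. Linking-induced gaps of up to two
  frames are the expected case.
* **Frame indexing**: 0-based; time of frame $j$ is $j\Delta t$; duration
  is $(N-1)\Delta t$; the duration filter is boundary-inclusive.
* **Units**: µm and s internally everywhere; pixel-to-µm conversion only
  in the reader (`pixel_size`, e.g. 0.092 µm/px for a typical 60×
  camera setup).
* **Ensemble pooling**: segment statistics pool segments across
  trajectories and videos; per-trajectory provenance stays in the segment
  table.
* **Subsampling**: keeps every factor-th frame by frame index, so gaps
  stay aligned with real time, and composes multiplicatively.
* **Simulation scale in the tests**: recovery suites use 100 trajectories
  of 1000 steps per mode; the segmentation accuracy suite uses six
  80 s four-mode trajectories at 20 fps; the sweep uses ten 122 s
  trajectories at 100 fps. These sizes give medians whose sampling error
  is well below the asserted tolerances.

## Known limitations

* The window classifier is a transparent rule-based stand-in, not a
  trained classifier; its thresholds (0.7/1.3, plateau 0.25, 10% margin)
  are package defaults, validated on synthetic data only.
* Anomalous versus confined discrimination inside a single short window
  is intrinsically hard when the confinement plateau is not resolved;
  expect confusion between those two labels near that regime.
* The confined model's $A_2$ is not independently identifiable (see
  above); reported $A_2$ equals $1/A_1$ by construction.
* Localization noise inflates short-lag MSDs and makes short-lag Brownian
  motion look subdiffusive; the package reproduces (and tests) this bias
  but does not correct for it.
* No 3D MSD, no frequency-domain microrheology, no Bayesian model
  comparison.
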