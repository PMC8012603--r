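---
title: "Separating spectrally identical FRET pairs by donor photochromism"
author: "pcfret authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating spectrally identical FRET pairs by donor photochromism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcfret)
```

## The measurement and its model

A sensitized-emission FRET acquisition records three channels: the
donor-excited donor emission $S_{DD}$, the donor-excited acceptor emission
$S_{DA}$, and the directly excited acceptor emission $S_{AA}$ (a control
for photodestruction, acquired at reduced cadence because it varies
slowly; `fill_saa()` interpolates the gaps linearly with flat ends). The
acceptor channel is contaminated by donor bleed-through $\alpha$ and
direct acceptor excitation $\delta$, measured once on single-fluorophore
controls (`estimate_crosstalk()`). The corrected sensitized emission and
the absolute FRET efficiency are

$$F_c = S_{DA} - \alpha S_{DD} - \delta S_{AA}, \qquad
  \Theta = \frac{1}{\gamma S_{DD}/F_c + 1},$$

where $\gamma$ accounts for the relative brightness of donor and acceptor
and the instrument's collection efficiencies. $\gamma$ cannot be inferred
from the acquisitions themselves; it is a required user input (default 1,
giving an *apparent* efficiency). Photon noise can push $F_c$ below zero;
we deliberately keep negative values in the intensity domain — clipping
them would bias every downstream fit — and clip only at the efficiency
boundary, where $\Theta$ is forced into $[0, 1]$ and the sample is
flagged.

## Photochromism as a second contrast axis

A photochromic donor loses fluorescence under off-switching light and
recovers it under violet light. Inserting an off-switching dose between
FRET acquisitions turns every timepoint into an on/off pair, summarised by
the photoswitching ratios $\rho_D = S_{DD,\mathrm{off}}/S_{DD,\mathrm{on}}$
and $\rho_A$, the latter computed on $F_c$ when correction factors are
available and on raw $S_{DA}$ otherwise (`photoswitching_ratios()`
records which; the two conventions must not be mixed downstream).

Energy transfer drains the donor's excited state and thereby competes with
off-switching, so $\rho$ rises with $\Theta$. For a single species whose
off-switching is governed by an intrinsic quantum yield,

$$\rho(\Theta) = \rho_0^{\,1-\Theta},$$

with $\rho_0$ the ratio measured in the absence of FRET under identical
illumination: $\rho(0) = \rho_0$, $\rho(1) = 1$, strictly increasing for
$\rho_0 < 1$. Biosensors, which interconvert between active and inactive
conformations, do not follow this single-species law, and cyan
fluorescent proteins add their own spectroscopic complications; for those
the $\rho(\Theta)$ dependence is measured empirically and fitted
(`fit_calibration()`) with either a straight line or a double exponential
$a_1 e^{-k_1\Theta} + a_2 e^{-k_2\Theta}$. The published description of
the empirical curves names the functional forms but not their
parameterisation; we chose the two-amplitude/two-rate form with
$a_1, a_2 \ge 0$ because it is smooth, positive, and can represent both
decreasing and increasing curves (rates may be negative). Calibration
curves may equally be expressed against the sensitized emission ratio
rather than $\Theta$; the model records its abscissa and the solver
iterates on the same metric.

Both coordinates of a calibration point are measured, so the fits minimise
*orthogonal* rather than vertical residuals, assuming equal error scales
on the two axes (no per-point weights are given in practice). The linear
kind has the closed-form total-least-squares solution (principal axis of
the centred cloud); the nonlinear kinds minimise the summed squared
point-to-curve distances with an inner one-dimensional projection per
point. The double-exponential objective is multimodal, so the optimiser
runs from five deterministic starts derived from a log-linear
single-exponential fit and keeps the best optimum; ratios up to 1.05 are
tolerated as noise and larger ones flagged. Evaluation outside the fitted
range clamps to the nearest endpoint and flags, rather than trusting an
empirical curve to extrapolate.

## The unmixing solver

For two pairs with overlapping spectra the measured channels are sums of
per-pair contributions; the off-state signals weight each contribution by
its pair's photoswitching ratio. With all four ratios known, each channel
is an exactly solvable 2×2 linear system (`solve_two_component()`; no
least squares). The ratios depend on the unknown efficiencies, so
`iterative_unmix()` runs a fixed-point loop:

1. evaluate each pair's $\rho_D, \rho_A$ from its calibration at the
   current metric;
2. solve both channel systems exactly;
3. recompute each pair's metric from its recovered signals;
4. repeat until the largest update falls below `tol`.

Numerical choices, all exposed as arguments:

* **Initialisation**: the midpoint of each calibration's valid range; time
  series are warm-started from the previous timepoint's solution
  (`unmix_timeseries()`).
* **Convergence**: `tol = 1e-6` on the largest metric update,
  `max_iter = 100`. Convergence is typically reached in under ten
  iterations; non-convergence is reported as a flag in the result, not an
  error, because in a time series a single noisy cycle should not abort
  the trace.
* **Damping**: when a pair's update changes sign twice in a row the next
  update is halved, guarding against the oscillations a strong
  noise-driven feedback between steps 1 and 3 can produce.
* **Singularity**: channels with $|\rho_1 - \rho_2| < 0.02$ are refused
  (`pcfret_unresolvable`): below that contrast the algebraic solution is
  dominated by noise amplification.
* **Working range**: the efficiency is capped at 0.95 inside the loop so
  the $\Theta \to F_c$ inversion stays finite.
* **Negative components**: clipped to zero and flagged, with the
  complement assigned to the other pair, so recovered per-channel sums
  always equal the measured mixture (a conservation invariant the test
  suite checks to 1e-9 relative).
* **Dark acceptors**: a pair may carry a non-fluorescent acceptor
  (`acceptor_cal = NULL`); its acceptor-channel contribution is
  identically zero and the whole acceptor signal is assigned to the
  fluorescent pair, bypassing the 2×2 solve in that channel.

More than two pairs are handled by `solve_n_component()`: each switching
cycle then records one on-state read plus $n-1$ progressively off-switched
reads per channel, giving an $n \times n$ retention matrix solved exactly,
with its condition number reported and a configurable rejection threshold.

As an independent cross-check, `unmix_grid_search()` estimates the same
efficiencies by brute force: for every candidate $(\Theta_1, \Theta_2)$ on
a grid it solves for the two on-state amplitudes by linear least squares
over all four forward-model equations and returns the residual-minimising
candidate. The test suite requires the fixed-point solution to agree with
this oracle to within one grid cell over the whole plane.

## The simulation study

`simulate_acquisition()` implements the forward model used for
validation: per pair, a brightness $N$ — defined as the expected
photon count in the on-state *donor channel at zero FRET* — with energy
transfer moving a $\gamma$-scaled share into the acceptor channel,
$E[S_{DD}] = N(1-\Theta)$, $E[S_{DA}] = \gamma N \Theta$. This bookkeeping
was a genuinely open choice (the channel split at nonzero FRET is not
dictated by the method); we chose it because it conserves total expected
photons at $\gamma = 1$. Off-state expectations scale by
$\rho_0^{1-\Theta}$ in both channels; the four observed values are
independent Poisson draws around the summed expectations. Detection is
pure photon (shot) noise — no camera read noise, gain or offset — and
cross-talk is zero in simulation, so the study isolates the intrinsic
noise behaviour of the unmixing itself. An optional `n_reads` argument
averages several Poisson reads per switching state, reflecting the
accuracy gain available from extra acquisitions during off-switching.

`run_study()` draws ground-truth efficiency pairs uniformly from
$[0, 0.6]$ — the range over which cyan/yellow biosensor pairs plausibly
operate and the range the method was validated on — simulates one on/off
cycle, unmixes it with the exact power-law calibrations, and scores the
mean absolute deviation
$\mathrm{MAD} = (|\Theta_1-\hat\Theta_1| + |\Theta_2-\hat\Theta_2|)/2$.
The default conditions are one photochromic donor at $\rho_0 = 0.3$
(readily achievable with switchable fluorescent proteins) and one
photostatic donor at $\rho_0 = 1.0$. The photon-budget grid
$\{250, 1000, 4000, 16000\}$ spans the printed low-light anchors (250 and
1000 photons) with two brighter decades; the acceptance checks use 500
simulations per condition — a desk-scale study size whose medians are
stable to well within the margins being tested — while the negative
control (`random_guess_control()`, MAD between independent uniform draws,
mean $\to (b-a)/3 = 0.2$) uses 5000. Solver failures are recorded and
counted, never silently dropped, and every study is reproducible from a
single integer seed.

## Time-lapse analysis

Long acquisitions photobleach, so responses are measured against a
per-trace baseline. FRET-efficiency traces are fitted with

$$\Theta(t) = e^{-t/\tau}\left(b + \frac{A}{1 + e^{(t_0 - t)/r}}\right),$$

an exponential decay times a standard sigmoidal response; the baseline is
the decay-only factor $b\,e^{-t/\tau}$, with $\tau$ typically much longer
than the experiment. Internally the fit is parametrised by the decay
*rate* $k = 1/\tau$ so that a non-decaying trace ($k = 0$) lies in the
parameter space, with $k \le 10/\mathrm{duration}$ (i.e.
$\tau \ge \mathrm{duration}/10$) excluding degenerate fast decays.
Degenerate traces — flat, or with no response — can make the sigmoid block
of the Jacobian rank-deficient; the fit then falls back to the decay-only
model with $A = 0$. Intensity-based calcium traces are instead fitted with
a bi-exponential restricted to user-supplied *quiet intervals* (segments
without elevated signal), because calcium transients are not sigmoidal.
All nonlinear fits use bounded Levenberg–Marquardt.

Responses are expressed as
$\%\,\mathrm{Increase}(t) = 100\,(s(t) - b(t))/b(t)$, which is invariant
under joint rescaling of signal and baseline. Response metrics follow the
conventions: stimulation intervals are half-open $[t_\mathrm{start},
t_\mathrm{end})$ in seconds; the maximal response keeps its sign (an
all-negative response yields a negative maximum). Onset times use the
sensor-appropriate definition: for FRET sensors, the time at which a
fitted sigmoid reaches 7.6% of its maximum — the threshold is stored to
three decimals exactly as published, not re-derived — which inverts
analytically to $t_0 - r\ln(1/0.076 - 1)$; for intensity sensors, the
argmax of the smoothed second derivative, smoothed with a Savitzky–Golay
local quadratic window of 5 samples (configurable; the filter's edge
samples are excluded from the argmax).

`cluster_responses()` classifies cells by k-means on their maximal
responses over the designated intervals. Features are z-scored first (the
intervals have very different dynamic ranges, and the published procedure
does not specify a scaling), with 25 restarts under a fixed seed, and
labels are canonicalised by descending cluster size so runs are
comparable.

## What the synthetic data does and does not show

The fixture generator (`generate_fixture()`) renders disc-shaped cells of
uniform intensity on a uniform background, with planted per-cell
$(\Theta_1(t), \Theta_2(t))$ trajectories, optional global bleaching and
per-pixel Poisson noise, written as 32-bit-float TIFF stacks plus label
masks and a ground-truth table. It emulates the statistical structure the
method assumes — two-component additive mixing, power-law switching,
shot-noise-limited detection — and deliberately not the nuisances of real
microscopy: spatial heterogeneity within cells, focus drift and
registration error, autofluorescence, switching fatigue, incomplete
off-switching plateaus, or read noise. Passing the end-to-end tests
therefore demonstrates correctness of the analysis chain under its own
model, not robustness to those effects; on real data the empirical
calibration (which absorbs several of them, e.g. residual cross-talk) is
the main line of defence.

## Known limitations

* The power-law switching model applies to single well-behaved species;
  biosensors require the empirical calibration kinds, measured per pair
  and per light dose.
* Photoswitching ratios slightly above 1 are tolerated to 1.05 before
  flagging; systematically larger values indicate a cross-talk
  correction problem the package cannot fix on its own.
* Unmixing is per-ROI/per-pixel independent; no spatial regularisation is
  attempted.
* $\alpha$, $\delta$, $\gamma$ are inputs; the package does not compute
  them from fluorophore spectra.
* Incomplete off-switching (plateau) donors are handled only through the
  empirical calibration kinds, not by an extended analytic model.

## Problem sizes used in the checks

The validation quantities recomputed by `scripts/acceptance.R` use: a
50×50 noiseless grid over $[0, 0.6]^2$ (inversion accuracy and oracle
agreement), 500 Monte-Carlo simulations per photon-budget or contrast
condition, a 5000-draw random-guess control, 50-point noiseless and
300-point noisy calibration sets (the noisy sets carry 2% errors on both
coordinates, the regime orthogonal regression is designed for, at the
scale pooled multi-cell calibration data reaches), a 241-point time-lapse
trace at 15 s cadence over one hour, and a two-cell, eight-cycle
zero-noise imaging fixture. These sizes were chosen so each quantity's
sampling variability is small compared to the margin being checked while
the whole script completes in well under a minute.
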