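---
title: "Counting subunits in chaperone-client complexes from photobleaching trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting subunits in chaperone-client complexes from photobleaching trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(smstoich)
```

## The measurement

Small heat-shock proteins (sHsps) such as alphaB-crystallin trap misfolded
client proteins in polydisperse complexes. In a two-color TIRF experiment,
client and chaperone carry spectrally separate fluorophores, complexes are
immobilized on a coverslip, and each diffraction-limited focus is imaged at
5 Hz until every fluorophore has photobleached. Because a fluorophore
bleaches in a single discrete event, the intensity trajectory of a focus is
a descending staircase, and counting its steps counts its labeled subunits.

`smstoich` implements this measurement end to end:

1. **Image pipeline** — offset/flat-field correction, focus detection,
   aperture photometry with local background, and two-channel
   colocalization.
2. **Step analysis** — change-point segmentation of trajectories,
   calibration of the single-step intensity distribution, and conversion of
   initial intensities to subunit counts (FPP, fluorescently labeled
   proteins per point).
3. **Stoichiometry summaries** — paired (client, chaperone) counts,
   abundance heatmaps, one-phase colocalization kinetics, and rank-based
   group comparisons.
4. **Ensemble assays** — percent inhibition of aggregation from light-
   scatter curves.
5. **A synthetic-data generator** for all of the above, embodying a
   two-step binding mechanism, so every stage can be validated by parameter
   recovery against ground truth. No experimental data ships with the
   package; the generator *is* the test bed.

## Core quantities

For each focus, the initial intensity $I_0$ is the mean of the first 20
frames of its trajectory. Pooled over many trajectories, the intensity of a
single photobleaching event $I_s$ has an approximately Gaussian
distribution whose fitted mean $\bar I_s$ calibrates the brightness of one
fluorophore. The subunit count follows from

$$\mathrm{FPP} = I_0 / \bar I_s,$$

rounded half-up and clamped to a minimum of 1 (a detected focus implies at
least one fluorophore). Counts above 20 are retained but flagged excluded:
at high local fluorophore density self-quenching makes intensities
unreliable, so such complexes are reported only as an excluded fraction.
Colocalized foci from the two channels are paired into per-complex
stoichiometries $(n_\mathrm{client}, n_\mathrm{chaperone})$.

The fraction of clients colocalized with chaperone over incubation time is
fitted with the one-phase association model
$y(t) = y_0 + (P - y_0)(1 - e^{-kt})$, and size distributions across
conditions are compared with Kruskal-Wallis omnibus tests followed by
Dunn's pairwise z-tests (Bonferroni-adjusted by default — the common
convention for Dunn's procedure; the adjustment method is configurable).

## Change-point engine

`detect_steps()` fits a piecewise-constant model by *optimal partitioning*:
an exact dynamic program (implemented in C++) over least-squares segment
costs with penalty $\beta = \lambda\,\hat\sigma^2 \log n$ per change point,
where $\hat\sigma$ is a robust noise estimate from the median absolute
first difference of the trace (divided by $0.6745\sqrt2$) and $\lambda$
(default 2) sets the model-selection strength. A small penalty floor makes
the segmentation minimal on exactly piecewise-constant traces, where the
fit reproduces change points and step heights with zero residual. Two
post-processing rules are exposed: plateaus shorter than `min_dwell`
(default 3 frames) are disallowed, and level changes smaller than
`min_step` (default $0.5\hat\sigma$) are merged.

Ties in the dynamic program are resolved toward fewer segments, so
degenerate inputs (constant traces) return zero change points rather than
an error.

## Calibrating the single-step intensity

The single-step pool is built by `pool_single_steps()` as a programmatic
surrogate for manual trace curation. A trajectory contributes only if its
final plateau has returned to background (all fluorophores bleached) and it
contains no upward step beyond the blinking threshold; a step contributes
only if it is downward, larger than a floor (default twice the median
per-trace noise), and flanked by plateaus of at least `min_dwell` frames.
Inside `calibrate_single_step()` the change-point detector runs at
`min_dwell = 1` and the dwell rule is applied at pooling instead: merging
short plateaus at detection time would silently *sum* near-coincident
bleach events into double-height steps and bias the pool upward, whereas
discarding the ambiguous steps leaves the pool unbiased.

Two properties of this pool matter for fitting:

* it is **left-censored** — steps below the acceptance floor (and below the
  detection limit) never enter;
* it carries a small contamination of **unresolved doubles** — two
  fluorophores bleaching in the same frame produce one step of roughly
  twice the height. With exponential bleach times the early gaps between
  events are short, so a few percent of pooled events are doubles.

`fit_single_step_distribution()` therefore fits, by maximum likelihood, a
Gaussian $N(\mu, \sigma^2)$ left-censored at the known pool floor, with an
optional second component pinned at $N(2\mu, 2\sigma^2)$ (shared
parameters, free weight) for the doubles. With censoring bound 0 and the
doubles component off — the defaults — the fit reduces to the plain
Gaussian MLE. The censoring-aware form matters because the per-fluorophore
intensity model is a normal distribution truncated at zero: when
$\sigma/\mu$ is large (both channels here are in the 0.6-0.7 range), the
mean of the *realized* positive draws sits 5-12% above the generative
$\mu$, and an estimator that ignores truncation and censoring inherits that
bias. Parameter-recovery tests in the suite hold the censoring-aware fit to
within 5% of the generative mean on both channels' published distribution
parameters.

## Initial intensity and the averaging window

$I_0$ uses frame averaging, not the change-point plateau, because
change-point fitting degrades for large complexes (many small steps in
quick succession) while the first-frames mean does not. One refinement is
available: when a step fit is supplied, the averaging window is capped at
the first detected change point. A fluorophore that bleaches *inside* the
20-frame window otherwise drags $I_0$ down by up to one full step; capping
the window removes this censoring at no cost in the common case where the
first bleach comes later.

## Image pipeline choices

* **Coordinates** are 1-based (row, col) with pixel centers at integers,
  matching R array indexing so positions round-trip with the rendered
  arrays without off-by-one bookkeeping.
* **Offset/flat-field correction** computes
  $(\mathrm{frame} - \mathrm{offset})/\mathrm{flatfield}$ and by default
  does *not* clip negative residuals. Background pixels carry symmetric
  read noise; clipping at zero censors that distribution with a bias that
  depends on the local signal level, and in rendered-movie round trips this
  measurably attenuated fitted step heights (tens of a.u.). A `clip`
  argument exists for display.
* **Detection** projects the mean of the first 10 frames (before bleaching
  erodes signal), estimates the background level by a sigma-clipped spatial
  mean and the background spread from per-pixel *temporal* variance (a
  spatial MAD is biased low by clipping and bright foci), and keeps local
  maxima above 6 background sd. Genuine diffraction-limited foci sit far
  above this (tens of sd) while the expected number of noise peaks per
  field stays well below one. Peaks closer than 4 px (about 3 PSF sigma)
  merge into the brighter one so that threshold-crossing PSF tail pixels do
  not register as foci; centroid refinement then gives sub-pixel positions.
* **Photometry** sums a 3 px aperture minus the annulus (5-7 px) median
  background, scaled by aperture area. When the PSF width is known, the
  trace is divided by the PSF mass inside the aperture at the fitted
  position (aperture correction): the captured fraction varies by a few
  percent with sub-pixel position, which otherwise propagates directly into
  FPP errors for large complexes.
* **Colocalization** uses greedy matching within a radius (default 2 px,
  near the diffraction limit) in order of increasing distance, ties broken
  by lower row then column — deterministic and order-independent, and
  equal to the exhaustive minimum-distance assignment on the instances the
  test suite enumerates. The chance-colocalization rate of unrelated point
  sets is bounded with a permutation oracle in the tests.
* Channel registration is assumed identity (dual-view already mapped); no
  drift correction is applied, matching a surface-tethered assay.

## The synthetic-data generator

`simulate_trajectory()` draws each fluorophore's emission once from
$N(\mu_s, \sigma_s^2)$ truncated at zero and holds it constant until a
geometric bleach frame derived from a continuous exponential rate — frames
are the observable unit at 5 Hz. Blinking (a two-state on/off Markov chain)
is off by default, emulating the oxygen scavenger system used in the
experiments this models. Additive Gaussian noise stands in for the EMCCD
read chain; a photon-level gain-register model is deliberately out of
scope.

`simulate_complex_population()` is an exact event-driven (Gillespie)
simulation of a two-step binding mechanism: free sHsp seed species (sizes
1-3, configurable) capture capture-competent free clients at rate
$k_\mathrm{bind}$; captured complexes accrete single subunits from a
well-mixed, depletable free pool at $k_\mathrm{accrete}$ (scaled by the
free-pool fraction) and lose excess subunits at $k_\mathrm{off}$. Each
client is independently capture-competent with probability equal to the
equilibrium bound fraction, so the expected bound-client fraction follows
exactly the one-phase association form that the kinetics fit assumes —
which is what makes plateau recovery a clean closed loop. The stochastic
means are cross-checked against an independently integrated mean-field ODE
in the test suite. Client oligomer sizes are drawn at capture and frozen
(chaperone action arrests client growth); the size distribution of free
sHsp species is exposed as configuration because no single-subunit-level
measurement of it exists to fix it.

Defaults: $k_\mathrm{bind} = 1.5\,\mathrm{h^{-1}}$ (bound fraction rises
steeply within the first hour and is at plateau by 4 h),
$k_\mathrm{accrete} = 1\,\mathrm{h^{-1}}$, $k_\mathrm{off} =
0.2\,\mathrm{h^{-1}}$, sHsp:client subunit ratio 2, plateau bound fraction
0.5, client sizes geometric with decay 0.55 over 1-12 (mostly monomers and
small oligomers, rare 12-mers). Reference timepoints are 0, 0.25, 0.5,
0.75, 1, 4, 8, 10 h.

`render_two_color_movie()` renders immobilized foci as pixel-integrated 2-D
Gaussian PSFs scaled by their instantaneous trajectory value, then applies
flat-field gain, electronic offset and Gaussian read noise
($\mathrm{recorded} = \mathrm{offset} + \mathrm{flatfield}\times
\mathrm{signal} + \varepsilon$). Positions are sampled uniformly with a
minimum separation of $4\sigma_\mathrm{PSF}$ (overlap can be allowed
explicitly). Ground truth — positions, per-fluorophore step heights and
bleach frames, and noise-free traces — travels with the movie.

`simulate_aggregation()` produces matched light-scatter curves
$A(t) = A_\mathrm{max}\,t^h/(t_{50}^h + t^h)$ for client alone and with
chaperone; suppression $s$ (a function of the molar ratio by default)
scales the whole chaperone curve by $1-s$. Scaling the curve reduces both
the absolute aggregation rate and the plateau, and makes the endpoint
statistic $100\,(\Delta I_c - \Delta I_s)/\Delta I_c$ equal $100\,s$
exactly on noise-free curves — a closed-form identity the tests assert. A
rate-only reduction cannot produce that exactness, which is why suppression
acts on amplitude.

### What the generator does not emulate

Real data add dye photophysics beyond single-exponential bleaching
(spectral fluctuation, partial quenching in large complexes), camera gain
noise that is not Gaussian, stage drift, and the surface-selection bias by
which small species immobilize preferentially. Passing the recovery tests
therefore demonstrates that the *analysis* is correct and well calibrated
under the stated generative assumptions, not that those assumptions
exhaust real microscope data.

## Worked example

```{r example}
phot <- photophysics(step_mu = 170.5, step_sigma = 99, bleach_rate = 1 / 30)
counts <- withr::with_seed(1, sample(2:8, 400, replace = TRUE))
traces <- simulate_trajectories(counts, phot, n_frames = 200,
                                noise_sd = 25, seed = 2)
calib <- calibrate_single_step(traces, label = "client")
glance(calib)

compute_fpp(c(852.5, 170.5, 3600), calib)
```

```{r kinetics}
cfg <- binding_kinetics(plateau_bound_fraction = 0.5)
pop <- simulate_complex_population(cfg, c(0, 0.25, 0.5, 0.75, 1, 4, 8, 10),
                                   n_clients = 500, seed = 3)
obs <- sample_colocalized_fraction(pop, n_molecules = 500, seed = 4)
fit <- colocalized_fraction_kinetics(obs)
glance(fit)
```

## Problem sizes and numerical choices

The reference analyses (test suite and `scripts/acceptance.R`) use 2500
calibration trajectories per channel — the pooled single-step fit under
censoring is weakly identified when $\sigma/\mu \approx 0.7$, and this size
brings its Monte-Carlo standard deviation to roughly 1%; 50 replicates of
the 500-client population simulation for kinetics; and one rendered
two-channel movie of 50 complexes (counts capped at 8, per-fluorophore
intensity CV ~9%, trace-level step signal-to-noise ~5) for the end-to-end
round trip. The rendered-movie fixture keeps dye dispersion moderate
because FPP rounding, not detection, is the binding accuracy constraint at
8 subunits; the broad published step-intensity distributions are exercised
in the dedicated calibration recovery analyses, where no integer rounding
is involved.

Other numerical details: Gaussian fits run Nelder-Mead from three starts
and keep the best; the kinetics fit uses Levenberg-Marquardt
(`minpack.lm::nlsLM`) with $k \ge 0$; kernel densities for violin
summaries use Silverman's bandwidth with reflection at the lower support
bound (counts cannot fall below 1) and are renormalized on their evaluation
grid; rounding of FPP is half-up with a clamp at 1, since a detected focus
implies at least one fluorophore (the rounding rule is the package's
choice; published analyses do not state one).

## Known limitations

* Exactly simultaneous bleach events within one frame are unresolvable in
  principle; the calibration absorbs them via the mixture component, but
  per-focus step *counting* still undercounts such pairs. FPP counting via
  $I_0$ is immune, which is one reason the pipeline counts by intensity
  ratio rather than by detected steps.
* FRET traces are proximity ratios only (donor-leakage corrected, clipped
  to [0, 1]); no gamma correction or distance calibration is attempted.
* The exclusion threshold (20 subunits) flags records rather than dropping
  them, and `abundance_heatmap()` reports the excluded fraction; analyses
  of the excluded tail itself are out of scope.
* The change-point engine matches the piecewise-constant contract
  (exactness on noise-free staircases, penalized selection under noise); it
  does not reproduce any particular published change-point software.
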