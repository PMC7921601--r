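# smstoich

Subunit stoichiometry of chaperone–client complexes from single-molecule
photobleaching.

Small heat-shock proteins (sHsps) such as alphaB-crystallin prevent protein
aggregation by trapping misfolded clients in polydisperse complexes. In a
two-color TIRF experiment, fluorescently labeled client and chaperone are
immobilized on a coverslip and each diffraction-limited focus is imaged at
5 Hz until all fluorophores photobleach. Each fluorophore bleaches in one
discrete step, so a focus's intensity trajectory is a descending staircase
and its steps count its labeled subunits. `smstoich` is for microscopists
and biophysicists who want that analysis as tested, scriptable R rather
than ad hoc image-processing macros.

The core computation:

* **I₀** — initial intensity of a focus, the mean of its first 20 frames;
* **I_s** — the intensity of a single photobleaching event, detected by
  penalized change-point segmentation of the trajectory; pooled I_s values
  are fitted with a (censoring-aware) Gaussian to give the mean single-step
  intensity **Ī_s**;
* **FPP = I₀ / Ī_s** — fluorescently labeled proteins per point, rounded to
  an integer subunit count (counts above 20 are flagged excluded because of
  self-quenching);
* colocalized foci across the two channels are paired into per-complex
  stoichiometries (n_client, n_chaperone), summarised as abundance heatmaps
  and size distributions, compared across conditions with Kruskal–Wallis +
  Dunn tests, and colocalization kinetics are fitted with the one-phase
  association model *y(t) = y₀ + (P − y₀)(1 − e^(−kt))*;
* bulk aggregation assays are scored with
  *% inhibition = 100 (ΔI_c − ΔI_s)/ΔI_c* from light-scatter endpoints.

A first-class synthetic-data module generates photobleaching trajectories,
complex populations evolving under a two-step binding mechanism (small sHsp
species first capture misfolded clients, then complexes accrete further
subunits from the free pool), rendered two-channel TIFF movies with ground
truth, and aggregation curves — so the entire pipeline is verifiable by
parameter recovery without any experimental data.

## Worked example

Calibrate the single-step intensity from simulated client-channel
trajectories (per-fluorophore intensities drawn from N(170.5, 99²)
truncated at 0, mean bleach time 30 frames, noise sd 25 a.u.), then convert
initial intensities to subunit counts:

```r
library(smstoich)

phot   <- photophysics(step_mu = 170.5, step_sigma = 99, bleach_rate = 1/30)
counts <- withr::with_seed(1, sample(2:8, 400, replace = TRUE))
traces <- simulate_trajectories(counts, phot, n_frames = 200,
                                noise_sd = 25, seed = 2)
calib  <- calibrate_single_step(traces, label = "client")
glance(calib)
#> # A tibble: 1 × 6
#>   I_s_mean I_s_sigma     n single_weight lower_bound label
#>      <dbl>     <dbl> <int>         <dbl>       <dbl> <chr>
#> 1     169.      110.  1189         0.974        51.3 client

compute_fpp(c(852.5, 170.5, 3600), calib)
#> # A tibble: 3 × 4
#>     I_0   fpp subunit_count excluded
#>   <dbl> <dbl>         <int> <lgl>
#> 1  852.  5.03             5 FALSE
#> 2  170.  1.01             1 FALSE
#> 3 3600  21.3             21 TRUE
```

The fitted `I_s_mean` of 169 a.u. recovers the generative 170.5 a.u. to
within 1%, so an initial intensity of 852.5 a.u. reads out as a 5-mer; the
21-mer is kept but flagged excluded.

Colocalization kinetics from the two-step binding simulator (equilibrium
bound fraction 0.5, 500 molecules scored per timepoint):

```r
cfg <- binding_kinetics(plateau_bound_fraction = 0.5)
pop <- simulate_complex_population(cfg, c(0, 0.25, 0.5, 0.75, 1, 4, 8, 10),
                                   n_clients = 500, seed = 3)
obs <- sample_colocalized_fraction(pop, n_molecules = 500, seed = 4)
fit <- colocalized_fraction_kinetics(obs)
glance(fit)
#> # A tibble: 1 × 5
#>      y0 plateau     k residual_sd     n
#>   <dbl>   <dbl> <dbl>       <dbl> <int>
#> 1 0.408    48.0  1.64        3.10     8
```

One replicate fits a plateau of 48% against the generative 50%; averaging
over replicates (as `scripts/acceptance.R` does) centers on the generative
value. `autoplot()` methods exist for step fits, step distributions,
kinetics fits and abundance heatmaps, and `tidy()`/`glance()` return
broom-style tibbles throughout.

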