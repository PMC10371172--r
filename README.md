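# chancluster

Ion-channel cluster self-assembly, cluster morphometry, coupled sparklet
gating, and delayed-rectifier current simulation.

Voltage-gated channels such as KV2.1 and CaV1.2 organize into
surface-membrane clusters — micro-clusters near the resolution limit of
localization microscopy, and macro-clusters visible by confocal imaging.
Cluster organization can matter independently of conduction: a channel can
be a structural organizer even when it barely conducts. `chancluster` is for
researchers quantifying that separation. It provides:

* **Self-assembly modeling** — a stochastic lattice model of cluster
  formation (per-step nucleation *P<sub>n</sub>*, per-cluster growth
  *P<sub>g</sub>*, per-channel removal *P<sub>R</sub>*), steady-state
  detection, single-exponential size-distribution fitting (the signature of
  Poisson-like cluster formation), and KS-distance grid fitting of the
  parameters to observed distributions.
* **Cluster morphometry** — segmentation of 2D localization renders
  (8-connected) and 3D confocal stacks (26-connected, ≥2 voxels, minimum
  puncta diameters), membrane-mask restriction, macro/micro classification
  against a volume threshold (default 0.03 µm³; sphere-equivalent diameter
  *d* = (6V/π)^⅓), resolution-matching Gaussian blur, per-cell summaries,
  and PLA-style puncta density.
* **Sparklet analysis** — coupled Markov-chain simulation of *N* two-state
  channels with coupling coefficient κ ∈ [0, 1] (0 = independent, 1 =
  all-or-none), quantal-amplitude estimation, nearest-integer idealization,
  site activity *nP<sub>s</sub>* = Σ<sub>t</sub> k(t)/T with a 0.2 low/high
  cutoff, and maximum-likelihood κ with bootstrap intervals.
* **In silico KV2.1 currents** — a Hodgkin–Huxley-type conductance
  *I/C<sub>m</sub>* = *f* · *g<sub>max</sub>* · *x(t)* · (V − E<sub>K</sub>),
  where *f* is the fraction of channels that actually conduct; conductance
  calibration to a measured density and functional-fraction scaling,
  plus RY785-style blocker subtraction.
* **Synthetic ground truth** — seeded generators for localization fields,
  confocal stacks with membrane masks, sparklet traces, and exponential
  size samples, so every analysis stage is testable without any raw data.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` on fitted objects, `autoplot()` on results, and a seeded
`run_pipeline()` that writes a checksummed manifest.

## Worked example

Predicted whole-cell KV2.1 current densities when only a fraction of
membrane channels conduct. Calibrate the 100%-functional model to a male
myocyte density of 7,006 pA/pF at +50 mV, then scale:

```r
library(chancluster)

functional_fraction_scan(7006, fractions = c(1, 0.5, 0.1, 0.01))
#> # A tibble: 4 × 2
#>   f_functional i_pA_pF
#>          <dbl>   <dbl>
#> 1         1     7006
#> 2         0.5   3503
#> 3         0.1    701.
#> 4         0.01    70.1
```

Halving the functional fraction exactly halves the density (the model is
strictly linear in *f*); 1% functional channels leaves ~70 pA/pF, the order
of magnitude actually measured in native myocytes — the basis for concluding
that the vast majority of membrane KV2.1 channels do not conduct.

Macro-cluster geometry: a mean cluster volume of 0.09 µm³ corresponds to a
sphere diameter of

```r
sphere_diameter_from_volume(0.09, round_to_nm = 10)
#> [1] 560
```

Self-assembly at steady state produces exponential size distributions:

```r
res <- reach_steady_state(
  assembly_params(p_n = 0.5, p_g = 0.2, p_r = 0.05,
                  grid_w = 192, grid_h = 192, n_steps = 8000, seed = 1),
  window = 400, tol = 0.02)
fit_exponential(res$sizes)
#> Exponential size-distribution fit: scale = 2.744 (shift 1),
#>   R2(log-counts) = 0.953, n = 2360
```

The log-linear histogram (R² ≈ 0.95) is the stochastic-assembly signature.
And a full sparklet record analysis — quantal amplitude, activity class, and
coupling — from a simulated site of 3 channels with κ = 0.5:

```r
tr <- gen_sparklet_trace(
  coupled_gating_params(n_channels = 3, p_open = 0.15, kappa = 0.5,
                        n_frames = 10000, seed = 2),
  quantal_df = 1, noise_sd = 0.15)
analyze_sparklet(tr)
#> # A tibble: 1 × 7
#>   quantal_df   nps activity_class n_quantal_levels kappa kappa_low kappa_high
#>        <dbl> <dbl> <fct>                     <int> <dbl>     <dbl>      <dbl>
#> 1      0.996 0.448 high                          3 0.504     0.488      0.524
```

The generating κ = 0.5 and quantal amplitude 1.0 are recovered; nPs ≥ 0.2
classifies the site as high-activity.

## Documentation

The methods vignette (`vignettes/channel-cluster-analysis.Rmd`) describes
the models, their assumptions, the numerical choices (integrators,
estimators, bin handling, resolution floors), and known limitations.
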