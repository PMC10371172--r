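---
title: "Models and methods: channel clustering, coupled gating, and conductance scaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: channel clustering, coupled gating, and conductance scaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chancluster)
```

Voltage-gated channels such as KV2.1 and CaV1.2 do not sit uniformly in the
surface membrane of excitable cells: they assemble into clusters spanning two
orders of magnitude in size, from micro-clusters at the resolution limit of
localization microscopy up to confocally visible macro-clusters. The size of
those clusters, not the number of channels, can carry the physiology — a
structural (organizing) role that is separable from the conductive role.
`chancluster` implements the quantitative machinery this kind of study runs
on: a stochastic model of how clusters form, morphometry of clusters in
images, analysis of coordinated channel gating in fluorescence records, and a
conductance model that translates "what fraction of channels actually
conduct" into whole-cell current densities. Everything downstream of raw data
is covered by seeded synthetic generators so each stage can be validated
against known ground truth.

## Stochastic self-assembly of clusters

The assembly model (`simulate_assembly()`) is a lattice birth/growth/death
process. On a square grid with periodic boundaries, one step applies, in this
fixed order:

1. **Nucleation** — with probability $P_n$, one channel is inserted at a
   uniformly random empty site;
2. **Growth** — every 4-connected cluster, with probability $P_g$, gains one
   channel at a uniformly random empty perimeter site (at most one site per
   cluster per step);
3. **Removal** — every channel is independently removed with probability
   $P_R$.

Clusters are 4-connected components; merging happens implicitly when growth
or nucleation makes components adjacent. At steady state the balance of
random insertion and removal yields cluster sizes whose frequency histogram
decays as a single exponential — the hallmark of a Poisson-like stochastic
process — and that is precisely the signature observed in localization and
confocal data. Larger $P_n$ and $P_g$ shift the distribution towards larger
clusters; stronger removal truncates it.

Design points that the underlying literature leaves open, fixed here once
and tested: the lattice is periodic (avoids edge artifacts), the within-step
event order is nucleation → growth → removal (pinned by a dedicated test:
with $P_R = 1$ every step ends empty), and growth adds at most one site per
cluster per step. The bundled default parameters are a plausible wild-type
regime, not values traceable to a published table, and are flagged as such in
`?assembly_params`.

`reach_steady_state()` advances the simulation in windows (default 200
steps) and stops when the windowed mean occupancy changes by less than a
relative tolerance between consecutive windows; a run that hits the step cap
returns with `converged = FALSE` rather than an error, because monotone
regimes ($P_R = 0$) legitimately never stabilize.

`fit_assembly_params()` inverts the model by simulation: each candidate
$(P_n, P_g, P_R)$ on a user grid is simulated with at least three replicate
seeds and scored by the mean Kolmogorov–Smirnov distance to the observed
size distribution; ties prefer smaller $P_n$, then $P_g$. This is a
deliberately plain grid search — the loss surface from a stochastic
simulator is noisy, and with three parameters a gridded KS fit is both
transparent and reproducible.

## Exponential size-distribution fitting

`fit_exponential()` estimates the scale of a (possibly shifted) exponential
as the maximum-likelihood value $\hat\beta = \overline{x - x_\min}$, and
reports goodness of fit as the $R^2$ of a straight line through the
log-transformed histogram counts. Two numerical choices matter:

* **The shift.** For clean samples, $x_\min$ defaults to the sample minimum
  (the MLE of the shift). For *measured* sizes the sample minimum is an
  extreme-value statistic of the measurement noise — biased low by roughly
  $\sigma\sqrt{2\ln n}$ — so analyses of segmented data should pass the known
  resolution floor via `min_size` instead. The segmentation examples in this
  package do exactly that.
* **The regression.** Histogram counts are Poisson, so
  $\mathrm{Var}(\log c) \approx 1/c$: the log-count regression is weighted by
  count, which stops near-empty tail bins from dominating $R^2$. For
  integer-valued (lattice) sizes, bin widths snap to whole numbers so that
  every bin spans equally many attainable sizes; fractional widths alias the
  counts into a sawtooth that has nothing to do with the distribution.

## Synthetic imaging data and what it does (not) emulate

`gen_localization_field()` emulates a super-resolution localization render:
non-overlapping disks at uniformly random positions, areas drawn from a
shifted exponential, rendered as unit-intensity anti-aliased footprints with
additive Gaussian noise (`noise_sd = 0.1` corresponds to SNR 10). Two
defaults encode the physics of a localization render rather than free
choices:

* the default PSF is zero because rendered localization maps are typically
  exported as near-binary footprint images; optical blur is available via
  `psf_sigma_nm` when wanted;
* areas are drawn as `min_area_nm2 + Exp(mean - min_area_nm2)` with a
  1200 nm² floor, the footprint of a point source at ~40 nm resolution. A
  render cannot contain sub-resolution footprints, and at 20 nm/px an
  unshifted exponential with a 2500 nm² mean would put a large fraction of
  clusters below a single pixel — making any count-recovery claim about the
  segmenter meaningless. The floor is the generator's statement of the
  instrument's resolution, not a tuning knob.

Each rendered patch is rescaled so its integrated intensity equals the drawn
size exactly; the linear edge ramp otherwise adds $\pi/12$ px² of mass per
disk (2D) or $(\pi/3) r w^2$ per sphere (3D) — small, but systematic, and
large enough to show up in a 10% round-trip bound.

`gen_confocal_stack()` does the same in 3D (0.13 µm z-steps by default) with
spheres whose volumes have a 0.02 µm³ floor (sphere diameter ≈ 340 nm, about
the confocal lateral resolution), and returns a binary membrane mask: either
the whole volume or an ellipsoidal shell mimicking a membrane stain, with
centroids placed inside the mask (optionally whole spheres, via
`contain = "full"`).

Not emulated, deliberately: single-emitter photophysics (blinking,
localization-precision maps), drift, chromatic aberration, and Poisson shot
noise. The downstream analyses consume sizes of thresholded, binarized
structures; these effects would add realism but not change what the tests
can establish. Consequently, passing round-trips here demonstrate that the
segmentation and fitting machinery is unbiased on well-calibrated renders —
not that it is robust to every acquisition artifact of real microscopes.

## Segmentation and morphometry

`segment_2d()` / `segment_3d()` threshold at a single fixed intensity (the
field's standard practice for these data) and take 8-connected (2D) or
26-connected (3D) components. 3D components must span at least two voxels
and exceed 100 nm (x/y) and 150 nm (z) bounding-box diameters — the usual
spot-detection floor. Each cluster's size is reported two ways:

* `n_px`: supra-threshold pixel/voxel count. Raising the threshold can only
  shrink this total — the monotonicity guarantee lives here.
* the primary size (`area_nm2` / `volume_um3`): integrated raw intensity
  over the component dilated by one pixel, scaled by pixel/voxel size and
  floored at `threshold * n_px`. For anti-aliased footprints this
  partial-volume-corrected integral is unbiased where pixel counting
  quantizes small clusters by ±1 px², and because the noise is zero-mean the
  ring contributes nothing in expectation. (Clamping negative noise before
  summing would add half the folded-normal mean per ring pixel — a ~4% bias
  at SNR 10 — which is why the sum is unclamped.)

`restrict_to_membrane()` keeps clusters with at least one voxel inside a
binary mask (or centroid-inside, configurable), mirroring the restriction of
cluster analysis to a membrane stain. `summarize_clusters()` produces the
per-cell numbers (count, mean/total size, % membrane occupied, density), and
`puncta_density()` is the count-per-area metric used for proximity-ligation
puncta.

Macro/micro classification: a cluster is a **macro-cluster** when its volume
strictly exceeds the threshold, default 0.03 µm³ (`macro_threshold()`;
0.025 µm³ is also in circulation and can be passed instead). The
sphere-equivalent diameter is always the closed form
$d = (6V/\pi)^{1/3}$ — for 0.09 µm³ that is 560 nm to the nearest 10 nm, and
for 0.03 µm³ it is 385 nm. Diameters sometimes quoted alongside volume
thresholds do not always satisfy this identity; this package never
back-derives a volume from a quoted diameter.

`gaussian_blur_match()` degrades a ~40 nm render to confocal-like
resolution: the kernel radius in pixels is `kernel_radius_nm / pixel_nm`
(default 200 nm) and the Gaussian sigma is half that radius, so the kernel
covers ±2σ of the stated neighborhood. With sigma = 100 nm, two points
150 nm apart merge into one supra-threshold component while points 400 nm
apart stay separate — the behavior that makes blurred super-resolution data
reproduce confocal cluster counts. Sigma equal to the full radius would
merge at 400 nm too, which is why radius/2 was chosen. Reflect padding keeps
total intensity conserved to better than 1e-6 away from the border.

## Sparklet records: quantal idealization, nPs, and coupling

A sparklet site with $N$ two-state channels is simulated
(`simulate_coupled_gating()`) by a frame-wise mixture: with probability
$\kappa$ a coordination event forces all channels into one common state
(open with probability $p$); otherwise channels gate independently. This
generative form was chosen because it realizes exactly the two definitional
endpoints — $\kappa = 0$ independent binomial gating, $\kappa = 1$
all-or-none gating — while keeping the per-channel marginal open probability
equal to $p$ for every $\kappa$ and admitting a closed-form likelihood.
Frames are exchangeable; dwell-time kinetics are not modeled because the
quantities of interest (nPs, $\kappa$) are per-site summaries, not kinetic
ones. The fitted object records the model name so downstream consumers know
which coupling definition produced a given $\hat\kappa$.

* **Idealization** (`idealize_trace()`): nearest-integer quantization of
  $\Delta F / q$ into $[0, N_{max}]$. At noise levels up to ~20% of the
  quantal amplitude the misclassification rate stays below 2% (Gaussian tail
  at half a quantal step); a hidden-Markov idealizer would gain little at
  this SNR and is out of scope.
* **Quantal amplitude** (`estimate_quantal_amplitude()`): the all-points
  histogram is reduced to a baseline (leftmost substantial density peak,
  refined by the median of nearby points) plus events; candidate spacings
  are the top event level divided by $1..N_{max}$, scored by the mean squared
  quantization residual, with ties broken towards the *fewest* levels —
  the least-squares form of an equal-spacing mixture fit. The discrete
  candidate set plus smallest-$m$ tie-break suppresses the subharmonic
  spacings ($q/2, q/3, \dots$) that defeat naive continuous optimization of
  any quantization objective. A flat record raises an error asking for a
  manual quantal amplitude.
* **Activity**: $nP_s = \sum_t k(t) / T$, the time-averaged open-channel
  count (the number of levels reached times the probability of occurrence).
  It depends only on the idealized levels — rescaling the quantal amplitude
  cannot move it. Sites split at an nPs cutoff of 0.2; the boundary itself
  classifies as high, a convention the code documents because the cutoff is
  conventionally quoted without a tie rule.
* **Coupling** (`estimate_kappa()`): maximum likelihood under the mixture,
  with $p$ estimated as $\bar k / N$ (marginal-preserving for every
  $\kappa$) and $\hat\kappa$ the maximizer on $[0,1]$ with endpoints checked
  explicitly. The mixture log-likelihood is concave in the mixing weight, so
  a 1D optimizer suffices; tests verify agreement with a 0.001-step grid
  search to one grid step. Confidence intervals come from a percentile
  bootstrap over frames (category counts are sufficient, so resampling is a
  multinomial draw). At 20,000 frames and $p = 0.1$ the estimator recovers
  $\kappa$ to well within 0.05 across $N = 2..4$.

## The delayed-rectifier current model

`simulate_kv_step()` implements a Hodgkin–Huxley-type KV2.1 conductance:

$$ I/C_m = f \cdot g_{max} \cdot x(t) \cdot (V - E_K), \qquad
   x_\infty(V) = \frac{1}{1 + e^{-(V - V_{1/2})/k}} $$

with a bell-shaped activation time constant and an optional inactivation
gate. $f$ is the **functional fraction** — the proportion of membrane
channels that conduct at all, the central dial when the great majority of
channels are structural. Within a voltage step the gate ODE is linear, so
the integrator uses the exact exponential update
$x(t+\Delta t) = x_\infty + (x - x_\infty)e^{-\Delta t/\tau}$: reported
densities are invariant to the sample interval to machine precision, which
the suite checks. The late current is the mean over the final 10% of the
500 ms step; by then a $\tau \le 50$ ms gate has converged to well under
0.1%.

The Boltzmann defaults ($V_{1/2} = +9$ mV, $k = 9$ mV) are placeholder
delayed-rectifier values. They are deliberately irrelevant to the headline
predictions: `calibrate_gmax()` rescales $g_{max}$ in closed form (the
density is strictly linear in $g_{max}$) so that the 100%-functional density
at +50 mV matches a measured value, after which every density at that
voltage scales exactly with $f$ — halving $f$ halves the density. Published
scaling tables are linear between 100% and 1% but sub-linear between 1% and
0.1%; the package makes no attempt to reproduce the 0.1% figures, which
plainly involve an additional (likely integer channel-count) effect outside
this model.

$E_K$ defaults to the Nernst potential at 295 K for 5 mM external /
107 mM internal K⁺ — about −78 mV, computed by `nernst_potential()` rather
than hard-coded, and configurable. `ry785_subtract()` isolates a
blocker-sensitive component as a pointwise trace difference, preserving
negative excursions.

## Reproducibility plumbing

`run_pipeline()` chains the stages (size sampling, field rendering,
segmentation, assembly simulation, sparklet analysis, current scan) with
per-stage seeds derived from one global seed by a fixed string hash
(`derive_seed()`), writes every output with its MD5 checksum into a
manifest, and is bit-reproducible: same configuration + seed, same bytes.
Requesting `segment` without a field (in the run or on disk) errors naming
the stage to run first. Images travel as TIFF with a JSON sidecar carrying
the physical calibration; the sidecar is authoritative, since TIFF
resolution tags are not reliably round-tripped by the available writer.

## Problem sizes and limitations

The shipped tests and examples run at desk scale, chosen so the full suite
completes in well under a minute of simulation-heavy work: assembly
steady-state distributions on 128²–192² lattices with a few thousand steps
(pooling replicate seeds for histograms), localization fields of ~600
clusters at 20 nm/px, stacks of 150–200 spheres at 100 nm/0.13 µm voxels,
and 20,000-frame gating records. All scale monotonically: nothing in the
code depends on these sizes.

Known limitations, stated rather than hidden: the assembly update rules are
a faithful reconstruction of a modeling approach whose exact published
parameterization is not available here; the coupling estimator is tied to
the frame-wise mixture definition of $\kappa$ (a transition-based coupled
Markov formulation would need dwell-time data the per-site summaries do not
require); the quantal estimator assumes a dominant baseline and equally
spaced levels; and the synthetic images are calibrated stand-ins, so
round-trip results bound algorithmic bias, not robustness to real
acquisition artifacts.
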