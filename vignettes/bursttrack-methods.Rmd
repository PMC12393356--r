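---
title: "Linking transcriptional bursting to chromatin locus mobility: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking transcriptional bursting to chromatin locus mobility: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bursttrack)
library(dplyr)
```

## The problem this package addresses

Estrogen-responsive genes such as *NRIP1* transcribe in bursts: intervals of
high polymerase activity, visible in live cells as a bright MS2/MCP focus,
separated by silent periods. The same locus can be tagged on its DNA and
followed over hours, and the receptor that drives it (ERα) can be tracked
molecule-by-molecule at 200 frames per second under HILO illumination. The
scientific question is how these three layers connect: does a locus move
differently while its gene is bursting, do receptor molecules partition into
distinct mobility states under acute versus chronic hormone stimulation, and
does any of this correlate with proximity to nuclear bodies (interchromatin
granules, the Matrin3 meshwork)?

`bursttrack` implements the full quantitative pipeline for these questions —
burst calling, locus tracking with drift correction, per-track diffusion
biophysics, mixture-model state clustering, and organelle-proximity
statistics — together with a synthetic-data module that generates movies and
track ensembles with known ground truth, so every stage can be validated
end-to-end without any raw microscopy data.

## The synthetic-data module

The generator is a first-class part of the package: its defaults define the
conditions under which the pipeline is tested.

**Walkers.** Three motion models cover the regimes the biophysics stage must
distinguish. Brownian walkers take independent Gaussian steps with per-axis
variance $2D\,\Delta t$. Confined walkers take the same steps but are
reflected radially at a disc of radius $R_c$ about their start point; the
field fits a confinement model to such loci but never states a generative
model, so disc reflection is our choice (documented here, validated only up
to the stated tolerance). Fractional Brownian walkers have exactly
stationary correlated increments with $\mathbb{E}[\mathrm{MSD}(\Delta t)] =
4 D \Delta t^\alpha$, generated by Cholesky factorisation of the fractional
Gaussian noise covariance (exact, cached per track length and $\alpha$).
Localization error is Gaussian, independent per frame and axis, and is added
*after* reflection: it models the camera, not the motion. Photobleaching is
modelled as a fixed deterministic lifetime rather than an exponential one —
simpler ground truth, and the downstream statistics never use the lifetime
distribution.

**Movies.** Nuclei are rendered as textured ellipses (10% low-frequency
modulation) at a background level of 100 counts, with extranuclear signal at
20% of that. Point emitters become Gaussian spots (default $\sigma$ = 1.5 px)
with a peak amplitude of four times the nuclear background — MS2 foci are
several-fold brighter than the nucleoplasm — and the `snr` parameter sets
the Gaussian read noise as peak/snr, on top of Poisson shot noise. Burst foci
are visible only during their scheduled on-intervals; schedules come from a
two-state telegraph process with exponential switching times, discretised to
frames. Typical calibrations mirror the imaging regimes: 5 ms frames for
single-molecule movies, 15–30 s for locus-tracking movies, 0.1 µm pixels.

What the generator does **not** emulate: z-extent and defocus (everything is
a single plane, as the analysed data are maximum projections or HILO
sections), spectral bleed-through, uneven illumination, cell movement other
than rigid drift, and density-dependent detection failures. Passing tests
therefore demonstrate correctness of the algorithms under the stated noise
model, not robustness to every artefact of real microscopes.

## Segmentation and burst calling

Nucleus detection for burst movies follows a fixed recipe: Gaussian blur
(σ = 10 px at the reference magnification), rolling-ball background
subtraction (radius 500 px), mean auto-threshold, watershed separation, and
size selection (40–200 px² at the reference magnification; the bounds scale
by the squared pixel-size ratio via `area_scale`). Two implementation
choices deserve note. The rolling-ball step is implemented as a grayscale
top-hat with a disc structuring element — at radii of hundreds of pixels the
difference from a true rolling ball is far below the burst threshold's
sensitivity, and the top-hat is deterministic and dependency-light. And the
difference-of-Gaussians band-pass uses the quoted radii (6 and 12 for burst
calling) directly as Gaussian σ values; whether the original macro meant σ
or diameter is unknowable, so both radii are plain function arguments and
the convention is stated here rather than hidden.

Burst calling is deliberately per-nucleus: all pixels outside the target
nucleus are set to 90% of that nucleus' median intensity
(`suppress_extranuclear()`), which removes edge artefacts before the
band-pass, and a spot is accepted where the DoG response exceeds

$$T = 5 + 0.55 \times \text{median nuclear intensity},$$

an affine statistic that ties detection to each cell's own brightness. The
threshold is applied strictly-greater; spot positions are intensity-weighted
centroids of the above-threshold DoG patch (sub-pixel), with strict
8-connected maxima as seeds. When a movie is processed frame by frame
(`run_burst_pipeline()`), the per-frame watershed numbering is arbitrary, so
every frame's labels are harmonized against the first frame by maximal
overlap — a nucleus keeps one identity for the whole movie.

FISH images use the same vocabulary with different constants (rolling
radius 200, blur σ = 4, Huang threshold, minimum size 20 px², hole filling,
watershed tolerance 6). The three auto-threshold methods (mean, isodata,
Huang's fuzzy entropy) are implemented from their published definitions on
256-bin histograms.

## Linking, burst assembly, drift correction

Spot linking is frame-to-frame optimal bipartite assignment (Hungarian
algorithm) on squared displacements with links beyond `max_link_um`
forbidden, followed by a gap-closing pass over (track end, track start)
pairs ordered by time difference then distance. The single-molecule defaults
are the standard tracker settings for this kind of data: 0.4 µm link
distance, 0.6 µm closing distance, frame gap 3, minimum 5 spots per track,
and a frame filter that discards detections before frame 500 (the
photobleaching settle-in period at 200 fps); locus movies use the same
machinery with movie-appropriate distances. There is no track splitting or
merging. Optimal assignment is deterministic, and linking is invariant to
input row order.

Each linked RNA-focus track becomes one burst event spanning its first to
last frame; off-durations are measured between consecutive events within a
nucleus, and burst rates are normalised per nucleus-hour observed. Empty
phases report missing values, never zeros.

Drift correction estimates one rigid transform per frame (rotation about
the image centre plus translation) against a reference frame. The template
is the nucleus itself, prepared as the original protocol prescribes: blur,
Huang threshold, dilation of the bounds, and moderation of outlier pixels
toward the region medians so bright foci cannot bias the registration. The
estimator is phase correlation with parabolic sub-pixel peak interpolation,
wrapped in a 1D angular search (±2° in 0.05° steps by default); the contract
is the residual bound, not the estimator. Transforms are applied to spot
*coordinates* for all kinetic quantities — resampling pixels would blur
displacements — and corrected movies are also emitted for visualization.

## Per-track biophysics

For each track, `compute_msd()` averages squared displacements over every
ordered spot pair at each integer frame lag; pairs spanning missing frames
simply do not exist, so gaps contribute to longer lags but never fabricate
displacements, and lags averaging fewer than 3 displacements are dropped.
The implementation is vectorized over a gap-aware position array and is
tested against an $O(n^2)$ brute-force pair enumeration to $10^{-12}$.

Six features feed the state clustering:

* $\alpha$ and $D$ from ordinary least squares of $\log \mathrm{MSD}$ on
  $\log \Delta t$ over all retained lags, with the 2D convention
  $\mathrm{MSD} = 4 D \Delta t^\alpha$ (single-plane imaging), so
  $D = e^{\text{intercept}}/4$;
* $R_c$ and $D_r$ from nonlinear least squares of
  $\mathrm{MSD}(\Delta t) = R_c^2\,(1 - e^{-4 D_r \Delta t / R_c^2})$,
  whose plateau is $R_c^2$. Although the source describes feeding
  log-converted values to the nonlinear fit, fitting the stated formula to
  log values is ill-defined at the plateau, so the default fits in linear
  MSD space weighted by the per-lag pair counts; a `fit_space = "log"`
  switch is provided. Initialisation is $R_{c,0} = \sqrt{\max \mathrm{MSD}}$
  and $D_{r,0}$ from the first two lags; non-convergence yields flagged
  missing values, never errors;
* MSD at one frame interval, and the residence duration within 0.25 µm of
  the track start (0.5 µm travels along as QC). Residence is the frame
  offset of the first excursion beyond the radius times the frame interval,
  or the full observed duration if never exceeded.

Tracks with any missing feature are excluded from clustering and counted
(complete-case behaviour).

**Known limitation — estimator bias.** The all-lag log–log fit is the
field's convention and is reproduced exactly, but it is not an unbiased
estimator on short tracks: large-lag MSD values are averaged over very few,
strongly correlated displacements, and their logarithms are biased downward
(Jensen), pulling per-track $\alpha$ and $D$ below truth. Static
localization noise adds a floor of $4\sigma_{loc}^2$ to every lag, which
further flattens the curve when $4 D \Delta t$ is comparable to it (e.g.
$D = 0.1$ µm²/s at 5 ms with 20 nm noise). The acceptance script reports
the recovered medians under exactly these conditions so the bias is
measured, not hidden; on the long tracks typical of real 200 fps
acquisitions the bias is much smaller. Lag truncation and pair-count
weighting were evaluated and do not remove it, so the package keeps the
convention unchanged.

## State clustering

Tracks are clustered in the six-feature space after balancing the training
set evenly across conditions. Because $D$, $R_c$, and MSD(1) span orders of
magnitude, they are log-transformed before clustering by default
(`log_transform = TRUE`, switchable); the source is silent on transforms,
so this is a documented choice made for mixture normality.

Two solutions are provided. `fit_gmm()` fits a full-covariance Gaussian
mixture with $k = 6$ components by default, initialised from seeded
random-subset k-means (several candidate subsets, best within-SS kept, at
most 20 k-means iterations) followed by at most 20 EM iterations; the
log-likelihood trace is retained (EM is monotone) and singular covariances
are ridge-regularised with a warning. `fit_ward_svm()` cuts a Ward
agglomerative tree of z-scored features at $k$ clusters and trains a
multi-class Laplacian-kernel support-vector classifier (spoc-svc, $C = 8$,
kernel width estimated from the data) on the labels so later experiments
can be classified consistently. In both models, components are
canonicalised by *decreasing* mean diffusion coefficient: the last cluster
is always the slowest, most confined state, making "the condensate-like
cluster" a stable name across runs.

$k$ is never chosen silently: `cluster_selection_report()` emits average
silhouette width and the between-condition fraction divergence across a
range of $k$, mirroring the criterion that six clusters maximise the
acute-versus-chronic difference.

Per-cluster condition fractions, fold changes with a percentile bootstrap
over tracks, and (when per-cell labels exist) two-tailed t-tests on
per-cell fractions come from `cluster_fold_changes()`. A cluster empty in
the denominator reports a missing fold change rather than infinity.

## Burst-state mobility and phases

`segment_by_bursts()` labels every locus-track frame burst or non-burst by
containment in a same-nucleus event interval — frame-level containment, not
whole-track majority, because the interesting signal is the within-track
transition — and maximal runs become segments; segments shorter than 3
frames are kept but flagged unusable for displacement statistics.
`segment_by_phase()` maps frames to pre / acute / chronic windows relative
to stimulation; the default windows are acute = 0–120 min and chronic
beyond 160 min, with a named `"bursting"` preset (acute 24–132 min) for the
empirically observed high-bursting window — the source uses both, and
neither is silently preferred. Frames in the 120–160 min transition remain
unlabeled.

`compare_mobility()` aggregates single-frame displacement (or segment
$\alpha$) per cell and state and runs a paired two-tailed t-test across
cells when both states are observed in the same cells, unpaired otherwise,
with the conventional significance markers. The normalized displacement
time course divides binned mean displacements by the pre-stimulation mean;
bins fed by fewer than 3 loci are flagged.

## Organelle proximity

Signed distance to an organelle boundary is the external minus the internal
Euclidean distance transform, evaluated at the pixel nearest the spot
centroid: positive outside, negative inside. Sub-pixel interpolation would
add less than half a pixel of accuracy and would complicate the exhaustive
oracle, so the nearest-pixel convention is kept; note its one inherent
discontinuity — crossing the boundary jumps from −1 px to +1 px, since no
pixel centre lies exactly on the ring. Periphery association is expressed
as enrichment in a thin shell just outside the boundary (default 0–0.3 µm).

The burst–proximity association is tested per cell with Pearson, Spearman,
and point-biserial correlations, and its null is calibrated by *circular*
permutation of the series within each cell: both the distance and the burst
series are autocorrelated in time, and i.i.d. shuffling would wildly
overstate significance. Under independence the permutation p-values are
uniform, which the test suite verifies by a KS check.

## Numerical and reproducibility choices

All randomness flows through R's RNG, so a single `set.seed()` reproduces
any simulation bit-for-bit; fitted GMMs are bit-identical under fixed seeds.
Thresholds are strictly-greater everywhere. The confined fit converges to
$10^{-8}$ on parameters; assignment ties in linking break toward the lower
spot index via the deterministic Hungarian solver. Tables written by
`run_burst_pipeline()` carry a configuration hash so outputs are auditable.

The validation suite runs on deliberately modest problem sizes — ensembles
of 500–1000 tracks of 50–200 frames, movies of 5–20 nuclei at 160–288 px
and 60 frames, 200 bootstrap or permutation replicates — chosen so the
full suite completes in minutes while Monte-Carlo error stays well inside
the asserted tolerances; the acceptance script states the `n` it used next
to every reported number.

## Interfaces

The package is a library, not a shell tool: tibble-in/tibble-out functions
compose with the pipe, `tidy()`/`glance()` summarise fitted objects,
`autoplot()`/`plot_*()` draw the standard figures, and
`run_burst_pipeline()` ties the burst-movie stages into one reproducible
call. Spot/track tables round-trip through plain CSV (extra columns
preserved, so tables from other trackers drop in), masks through 16-bit
TIFF, movies through per-channel multi-page TIFF with a YAML sidecar.
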