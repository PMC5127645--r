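---
title: "Methods: quantifying organoid drug response, death and recovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying organoid drug response, death and recovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organoidr)
```

This vignette is the package's account of its science: the models it
implements, the conventions it fixes where the underlying laboratory
procedures leave room, and what its synthetic-data-based validation does and
does not establish.

## The experimental designs being modelled

The package targets pharmacology experiments on patient-derived tumor
organoids carrying an H2B fluorescent nuclear reporter. Three readout
families recur in such studies:

1. **ATP-based plate screens**: organoids in 384-well plates, treated with
   one or two drugs over a log-spaced concentration grid, read out as a raw
   luminescence/fluorescence signal after ~72 h.
2. **Confocal imaging**: 3D stacks (optionally over time) of the nuclear
   reporter, sometimes with a propidium-iodide (PI) co-stain that labels
   only dead cells, and sometimes with manually marked mitosis/apoptosis
   events from depth-coded projection movies.
3. **Recovery assays**: alamarBlue (resazurin) kinetics after drug washout,
   caliper measurements of xenografted tumors, and EdU × DNA flow cytometry
   for cell-cycle state.

## Dose-response analytics

### Normalization

`normalize_viability()` maps raw signals to percent viability using two
anchors: the mean of the vehicle (DMSO) wells as 100 % and the multi-drug
signal plateau at high concentrations as 0 %. The plateau is a property of
the assay floor (dead wells still emit some signal), so it must be estimated
or supplied. The default rule — mean of the `k = 3` wells with the highest
total concentration — is this package's concrete estimator for a quantity
that is otherwise determined by eye per plate. It is deliberately simple and
slightly *biased* when the dose range does not reach a true plateau (the 4PL
never reaches exactly zero); when the plateau signal is known (as it is for
simulated plates) it can be passed as a number, which makes the round-trip
normalization exact. Replicate wells at the same concentration pair are
averaged *after* normalization; values are not clipped, so normalized
viability can stray slightly outside [0, 100] under noise.

### Curve model and fitting

`fit_dose_response()` fits the normalized "log(inhibitor) vs. response
(variable slope)" model with asymptotes fixed at 100 %/0 %:

$$y(x) = \frac{100}{1 + 10^{(x - \log_{10}\mathrm{IC}_{50})\,h}},$$

with $x$ the log10 molar concentration and Hill slope $h > 0$ giving a
descending curve. The sign convention is fixed so that the no-drug limit is
100 %; resistance differences are reported as
$\Delta \mathrm{IC}_{50} = \log_{10}\mathrm{IC}_{50}(\text{line}) -
\log_{10}\mathrm{IC}_{50}(\text{reference})$, positive meaning more
resistant.

Fitting is Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) from a
3 × 3 multi-start grid (log IC50 at the 20th/50th/80th percentiles of the
observed range; slopes 0.5, 1, 2), keeping the best start by residual sum of
squares. Box constraints keep the midpoint within six decades of the data
and the slope in [0.001, 50]. At least four distinct positive
concentrations are required; an all-identical response is refused rather
than fitted. The test suite cross-checks the optimizer against an exhaustive
(log IC50, slope) grid search refined over three passes.

Combination curves on a full matrix are extracted by `extract_curve()`:
monotherapies are the zero-concentration row/column; fixed-ratio
combinations are the diagonal cells with
$\log_{10} c_B = \log_{10} c_A + \text{offset}$. A combination IC50 fitted
on a diagonal is reported on the reference (drug A) axis with the offset
recorded — the convention needed when one drug runs some decades below the
other (e.g. trametinib combinations two decades lower).

Concentration-grid presets mirror published designs: 14 points 5 nM–5 µM
(`"fig3b"`), and 9 points 5 nM–20 µM (`"fig9d"`). The `"fig4"` preset reads
"5 nM–20 µM in 22 logarithmic intervals" as 22 log-spaced concentrations
spanning the range; the alternative fencepost reading (23 points) would
shift each concentration by under 5 %, well below assay noise.

### Bliss independence

The synergy null model is Bliss independence on fractional inhibitions:
expected combined inhibition $f_A + f_B - f_A f_B$. The score of a cell is
observed minus expected inhibition; fractional inhibitions are clamped to
[0, 1] before combining so that noise-induced negative inhibitions cannot
produce spurious synergy, and monotherapy rows/columns are zero by
construction. The Bliss formula itself is the standard one — the package
adopts it as the definition wherever a study cites it indirectly.
Heat-map smoothing (`smooth_matrix()`, default window 3) is a moving average
with edge-shrinking windows, applied *after* Bliss scoring when both are
used (configurable); smoothing is idempotent on constants and bounded by the
input range, but deliberately makes no mean-conservation claim at the edges.

## Image quantification

### Conventions fixed by this package

* Foreground is intensity **≥ T** (inclusive). Indices are 1-based (R
  convention) and z index 1 is the bottom plane, closest to the vessel
  floor.
* Connected components default to 8-connectivity per slice in 2D mode and
  26-connectivity in 3D mode; 4 and 6 are available.
* A particle is *dead* iff its pixel count is strictly below the size
  cutoff (a particle exactly at the cutoff is alive). The default cutoff —
  half the median particle size of a vehicle field
  (`default_size_cutoff()`) — encodes the observation that apoptotic
  fragments are several-fold smaller than intact nuclei; it replaces the
  manual curation step of the original microscopy workflows, which is out
  of scope here.
* The "lower half of the organoid volume" is resolved slice-wise:
  `max(1, floor(n/2))` slices counted from the bottom of the organoid's own
  z-extent (by default the z-support of its mask). The analyzed range is
  recorded in the output. Alive + dead pixel counts equal total foreground
  in the analyzed slices by construction, and this partition identity is
  asserted on every input.
* Depth-coded projections take the per-pixel maximum over z and color it by
  the arg-max plane; ties go to the lowest z. With a transmitted-light
  channel, a four-quadrant montage (depth-coded, transmitted, grayscale
  projection, blend) is assembled.

### The ramped-threshold optimum

For PI-stained endpoint stacks the package derives the threshold
automatically: scan a threshold grid, record per threshold the foreground
surface `area(T)` and its `mean(T)` intensity, min–max normalize both
curves, and maximize `score(T) = norm_mean(T) − norm_area(T)` — the highest
mean signal combined with the most confined surface, with ties resolved to
the lowest threshold and empty-foreground thresholds excluded. "Most
confined" is read as *smallest area*; a shape-compactness reading would
require a segmentation notion the procedure does not otherwise need. A
constant image has a degenerate area curve and is refused.

This score is designed for near-two-level images — exactly what
high-laser-power endpoint acquisitions produce. On images with a long
continuous intensity tail the normalized mean keeps rising with T and the
optimum drifts toward the top of the range; `midpoint_threshold()` (median
to maximum midpoint) is the package's default for such data, e.g. in the
drug-and-release pipeline.

### The PI/H2B death ratio

Cell death in PI-stained stacks is the ratio of PI-positive to H2B-positive
pixel counts over the whole field, pooled across the 15–20 organoids a
field typically contains *before* division — a ratio of summed counts, not
a mean of per-organoid ratios (hence no error bars in that design). The PI
mask is deliberately not intersected with the H2B mask, matching the
literal "PI-positive pixels / H2B-positive pixels"; on pathological input
the ratio can therefore marginally exceed 1. A zero H2B count is an
explicit failure, not a silent NaN.

## Event analytics

Marked mitosis/apoptosis logs are converted to relative cell-count
trajectories by chronological ranking: +1 per mitosis, −1 per apoptosis,
starting from `n0` (the count visible at movie start, supplied by the user
or by the generator's ground truth). Events at identical times are ordered
apoptosis-first — an arbitrary but fixed convention, since simultaneity
handling is not defined by the marking procedure; the choice is
conservative in that it can only *lower* the intermediate count, and any
count below zero is rejected as an inconsistent log. Trajectories are
invariant to input record order.

Event rates bin events into half-open windows `[k·w, (k+1)·w)` (boundary
events belong to the later window) and divide by the number of organoids
scored — per-organoid normalization, chosen over per-starting-cell because
starting cell counts are not generally available from marked logs.

Growth speeds are ordinary least-squares slopes of count versus time,
fitted on the trajectory sampled at its change points plus window
endpoints, reported in cells/hour with a standard error.
`growth_speed_halves()` fits the first and second half of the recording —
the design used to detect arrest-then-regrow behavior, where the first-half
slope is ≈ 0 and the second-half slope returns to the untreated rate.

## Recovery analytics

* **alamarBlue**: viability is RFUmax within the linear range of the assay
  minus the background read at t = 0, normalized to vehicle. "Within the
  linear range" is made concrete as the longest contiguous read window
  (≥ 3 reads) whose least-squares fit reaches R² ≥ 0.99, ties to the
  earliest window and zero-variance windows counting as perfectly linear.
  On simulated saturating kinetics this window provably ends at the last
  pre-saturation read. The statistic is invariant to a shared additive
  background and linear in the treated slope.
* **Xenograft volumes**: `V = D·d²/2` from the two caliper axes, with the
  pair canonicalized by swap so field-entry order cannot corrupt volumes;
  percent change is anchored at each animal's day-0 baseline (which must
  exist). Group comparisons expose both a per-day Student's t test against
  the reference group and a two-way (group × day) ANOVA, labelling which
  test produced each p value, because study-level statistics sections often
  leave the per-figure assignment open.
* **Cell cycle**: EdU incorporation takes precedence — any cell at or above
  the EdU threshold is S phase regardless of DNA content (an EdU-positive
  4N cell is late-S, not G2); remaining cells are G1 at or below the 2N
  gate and G2 at or above the 4N gate. Cells with intermediate DNA are
  reported as unassigned rather than forced into a phase. Default gates
  come from the DNA density mode (2N peak; gates at 1.25× and 1.75× the
  peak) and a 2-means split of log EdU. Distributions are compared by
  Pearson chi-square without continuity correction on the G1/S/G2 count
  table.

## The synthetic-data generator

Every downstream stage is validated against simulations with exact ground
truth. The generator emulates:

* **Stacks** (`make_organoid_stack()`): live nuclei as compact blobs of
  radius ~5 px (sd 0.5), dead cells as clusters of 4 fragments of radius
  ~1.5 px scattered within one nucleus diameter of the death site —
  the morphology of histone-reporter nuclei before and after apoptosis.
  Blobs are isotropic in xy and compressed in z by the plane-spacing
  anisotropy, with a Gaussian radial intensity profile (σ = radius) over a
  flat background (100 AU, additive Gaussian noise of sd 5). Because the
  profile value at the blob edge (≈ 0.61 of peak) exceeds the midpoint
  between background and peak for any snr > 1, the midpoint threshold
  recovers the ground-truth voxel set exactly in the noiseless limit — this
  makes mask-level assertions well-defined. Placement is rejection sampling
  (1000 retries, loud failure when overcrowded) with a separation margin
  exceeding the 26-connectivity diagonal reach, so distinct objects can
  never merge into one particle and truth labels stay disjoint. Nucleus and
  fragment sizes are free parameters of the simulation, not calibrated to
  any particular optics.
* **Time-lapses** (`make_timelapse()`): an event schedule replaces a parent
  blob by two daughters (mitosis) or by a fragment cluster (apoptosis);
  daughters may drift to a free position when the local neighborhood is
  crowded. Frame truth satisfies the conservation law
  alive(t) = initial + mitoses(≤t) − apoptoses(≤t) by construction.
* **Plates** (`make_plate_reads()`): raw signal
  `plateau + v·(vehicle − plateau)` with `v` the 4PL viability for
  monotherapy wells and the Bliss-independent product minus an injected
  excess for combination wells, under mean-one multiplicative lognormal
  noise of a chosen CV. Note that an injected excess δ is only recoverable
  at combination cells whose independent viability is at least δ
  (inhibition saturates at 1); recovery assertions are restricted
  accordingly.
* **Kinetics** (`make_ab_kinetics()`): linear rise at
  `viability × slope` until a saturation time, then flat, plus additive
  read noise.
* **Flow samples** (`make_cellcycle_sample()`): G1/S/G2 mixture with 2N/4N
  DNA positions, S spanning the interval with high EdU, multiplicative
  noise of 5 % CV by default.

Every generator is a pure function of its parameters and a single integer
seed — identical inputs reproduce outputs bit for bit, which the pipelines
exploit to guarantee byte-identical reruns.

**What the simulations do not emulate** — and what passing tests therefore
do not establish: optical point-spread blur and depth-dependent signal
attenuation, organoid lumen/crypt morphology and touching nuclei, stage
drift, plate edge/drift effects, and cytometry spillover. The validation
shows the *analysis chain* is correct (formulas, conventions, oracles,
determinism) under a data model whose difficulty is controlled by snr and
noise parameters; it does not certify segmentation performance on real
microscopy, where nucleus contact and attenuation dominate.

## Problem sizes and tolerances used in validation

The shipped test-suite and acceptance script use: 80 × 80 × 10-voxel stacks
(12 nuclei + 4 dead cells) across snr ∈ {3, 5, 10}, 21 stacks per
run; 100 simulated plates at 5 % CV for IC50-recovery statistics; 100
random masks/arrays for the flood-fill and projection oracles; and 5000
cells for flow mixtures. These sizes were chosen as the smallest at which
the relevant statistics stabilize (classification F1 and median IC50 error
change by < 0.01 when doubled), keeping the whole validation quick while
still exercising every code path.

Numerical tolerances in the tests mirror the structure of each computation:
identities that are exact in exact arithmetic (normalization anchors,
Bliss on noiseless surfaces, volume formulas, count conservation) are
asserted to 1e-9 or to machine identity; optimizer-dependent quantities to
1e-6; statistics under injected noise at tolerances derived from their
sampling variability (e.g. median |log10 IC50 error| ≤ 0.05 at 5 % CV).

## Known limitations

* The size-based alive/dead rule misclassifies unusually small intact
  nuclei (a nucleus at ~79 % of the median radius falls under the
  half-median-volume cutoff); at the simulated 10 % radius spread this
  affects ~2 % of nuclei, consistent with the ≥ 0.95 F1 the validation
  requires.
* The ramped-threshold score is only meaningful for near-two-level images
  (see above); it is self-consistently defined and tested, but it is not a
  general-purpose auto-thresholder.
* The plateau-wells baseline estimator is biased on ranges that do not
  plateau; prefer an explicit baseline when one is known.
* Manual event marking and manual dead-particle curation are not
  reproduced; the package starts from event logs and exposes the size
  cutoff instead.
* Instance segmentation and tracking of organoids across fields are out of
  scope; per-organoid analyses assume the caller supplies per-organoid
  stacks or masks.
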