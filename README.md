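# organoidr

Quantitative analysis of drug-response experiments in patient-derived tumor
organoids. The package implements, as tested and reusable R functions, the
analysis stack used in organoid pharmacology studies built around
H2B-fluorescent nuclear reporters:

* **3D live/dead image quantification** — channel thresholding (including an
  automatic ramped-threshold optimum), 2D/3D particle detection, size-based
  alive/dead nuclear classification, integration over the lower half of each
  organoid's volume, depth-coded maximum-intensity projections, and the
  propidium-iodide/H2B surface ratio as a pooled cell-death measure.
* **Mitosis/apoptosis event analytics** — chronological ranking of marked
  events into relative cell-count trajectories, per-window event rates, and
  growth speeds by linear fitting of trajectory halves.
* **Dose-response and synergy analytics** — vehicle/plateau normalization of
  plate signals, log(inhibitor)-vs-normalized-response (variable slope)
  IC50 fitting, ΔIC50 tables on the log10 scale, Bliss-independence excess
  matrices, moving-average heat-map smoothing, and monotherapy / fixed-ratio
  diagonal curve extraction from full dose matrices.
* **Recovery analytics** — alamarBlue kinetic viability with automatic
  linear-range detection, caliper tumor-volume series (`V = D·d²/2`) with
  percent change from baseline, and EdU × DNA cell-cycle classification with
  chi-square comparisons.
* **A ground-truthed synthetic-data generator** — simulated confocal organoid
  stacks (live nuclei as bright blobs, dead cells as scattered fragment
  clusters, optional PI channel), time-lapses driven by event schedules,
  plate reads drawn from known 4PL surfaces with optional Bliss excess, and
  saturating fluorescence kinetics — so the entire pipeline is testable
  end-to-end without any imaging data.

All tabular results are tibbles, functions compose with the pipe, fitted
dose-response objects have broom-style `tidy()`/`glance()` methods, and the
main result types have `autoplot()` methods.

## The models at the core

**Dose response.** Normalized viability is
`v = 100·(raw − B)/(V − B)` with `V` the vehicle (DMSO) mean and `B` the
multi-drug signal plateau. Curves are fitted with the normalized
four-parameter logistic (asymptotes fixed at 100 %/0 %):

    y(x) = 100 / (1 + 10^((x − log10 IC50) · h)),   x = log10 concentration (M)

with Hill slope `h > 0` for a descending response. Differential sensitivity
between two lines is `ΔIC50 = log10 IC50(line) − log10 IC50(reference)`.

**Bliss independence.** With monotherapy fractional inhibitions
`fA = 1 − v(a,0)/100` and `fB = 1 − v(0,b)/100`, the expected independent
combination inhibition is `fA + fB − fA·fB`; the Bliss score of a
combination cell is observed minus expected inhibition. Positive scores mark
synergy.

**Live/dead imaging.** Nuclei are thresholded (foreground = intensity ≥ T),
connected components are labelled (8-connectivity per slice or
26-connectivity in 3D), and a particle is *dead* iff its pixel count falls
below the size cutoff (default: half the median particle size of a vehicle
field). Alive/dead pixel areas are integrated over the slices forming the
lower half of the organoid's z-extent, where image quality is best. For
PI-stained endpoint stacks, cell death is the ratio of PI-positive to
H2B-positive pixel counts, pooled over all organoids in the field.

## Worked example

Simulate a two-drug 14 × 14 plate (5 nM–5 µM, log-spaced) from a known
surface, normalize it, and fit the drug-A monotherapy:

```r
library(organoidr)

reads <- make_plate_reads(drug_truth(-7.5, 1), drug_truth(-7, 1.2),
                          conc_a_nM = conc_preset("fig3b"),
                          conc_b_nM = conc_preset("fig3b"),
                          noise_cv = 0.05, seed = 1)
dm   <- normalize_viability(reads)
mono <- extract_curve(dm, "row_a_mono")
fit  <- fit_dose_response(mono$conc_nM, mono$viability_pct)
fit
#> <drc_fit> log10 IC50 = -7.4601 (IC50 = 34.7 nM), Hill slope = 1.011
#>   n = 14 points, RSS = 42.59
```

The generating truth was log10 IC50 = −7.5 (31.6 nM) with slope 1; at 5 %
multiplicative read noise the fit recovers it to 0.04 decades. The Bliss
matrix of the same (independently acting) pair stays at zero up to noise:

```r
summary(bliss_excess(dm)$bliss_score)
#>    Min.  1st Qu.   Median     Mean  3rd Qu.     Max.
#> -0.1111  -0.0035   0.0000  -0.0002   0.0031   0.0826
```

Quantify live and dead nuclei in a synthetic organoid stack with a PI
channel (15 live nuclei; 5 dead cells shattered into 4 fragments each):

```r
p    <- organoid_sim_params(n_alive = 15, n_dead = 5, seed = 3)
sim  <- make_organoid_stack(p)
thr  <- midpoint_threshold(stack_channel(sim$stack, "H2B"))
mask <- binarize_channel(sim$stack, "H2B", thr)
cls  <- classify_particles(find_particles(mask, "volume"), 60)
dplyr::count(cls, class)
#>   class     n
#> 1 alive    15
#> 2 dead     20

pi_h2b_death_ratio(sim$stack, t_h2b = thr, t_pi = thr)
#>   pi_px h2b_px  ratio t_h2b  t_pi
#> 1   137   4256 0.0322  302.  302.
```

All 20 fragments and all 15 nuclei are recovered, and the PI/H2B ratio
(0.0322) equals the true dead-voxel fraction of the simulation.

## Documentation

The methods vignette (`vignettes/organoid-drug-response.Rmd`) describes the
models and their assumptions, what the synthetic generator does and does not
emulate, all numerical conventions (threshold inclusivity, tie-breaks,
boundary rules), and known limitations.
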