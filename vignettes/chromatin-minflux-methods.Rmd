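---
title: "Quantifying chromatin fibers and nucleosomes in 3D MINFLUX localization data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromatin fibers and nucleosomes in 3D MINFLUX localization data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromaflux)
```

## The measurement problem

MINFLUX nanoscopy localizes single fluorophores with roughly nanometer
precision (per-axis FWHM near 1.08 / 0.96 / 0.63 nm for x / y / z with a
spontaneously blinking minor-groove DNA dye). Applied to nuclear DNA, it
yields a 3D point cloud in which condensed chromatin appears as
fiber-like clouds tens of nanometers wide, and — at favorable probe
occupancy — the DNA path around single nucleosomes becomes visible as
rings of 5–10 probe positions. **chromaflux** turns such localization
tables into quantitative structure: cluster inventories, per-segment fiber
diameters and DNA densities, nucleosome-scale model fits, image-resolution
and precision estimates, dual-color channel assignment, and
group-comparison statistics for perturbation experiments.

The probe chemistry fixes the unit bookkeeping used throughout: one dye
molecule occupies a 12-bp footprint on AT-rich DNA, and such probes can
cover at most ~80% of nucleosomal DNA. Ten probes therefore stand for
120 bp; on the ~140 bp of accessible nucleosomal DNA, five probes cover
~43%. The per-nucleosome probe cap is
`floor(147 * 0.8 / 12) = 9`.

## Pipeline

1. **I/O** (`read_localizations()`, `write_localizations()`,
   `filter_roi()`): a canonical delimited-text dialect with a mandatory
   header and a `# units=` comment line. Coordinates are continuous nm in
   a right-handed frame with z along the optic axis; there is no pixel
   indexing anywhere because MINFLUX is scan-free. ROI boxes are half-open
   `[min, max)` per axis so that tilings partition exactly.
2. **Clustering** (`cluster_localizations()`): standard DBSCAN on 3D
   Euclidean coordinates. Defaults `eps = 20` nm, `min_pts = 5` were
   chosen so a ~30-nm fiber at realistic localization density forms one
   cluster while sparse background does not; both are configuration
   parameters. Border points take the label of their lowest-uid core
   neighbor, making labels bit-reproducible and permutation-stable on the
   core partition. An optional second pass (cluster, drop noise,
   re-cluster) is available but off by default.
3. **Fiber quantification** (`segment_fiber()`, `dna_density()`): cluster
   length is the full projection range along the first principal axis.
   Fibers are partitioned into 25-nm axial windows, a cylinder is fitted
   per window, adjacent windows merging when diameters differ by less
   than 20% relative. Diameter is defined as twice the least-squares
   cylinder radius (the point-cloud RMS convention), not a FWHM of the
   radial profile.
4. **Nucleosome models** (`fit_ring()`, `fit_nucleosome()`,
   `fit_dimer()`): circle and constrained-cylinder fits at the 11-nm
   scale, with probe attachment counted at a radial tolerance.
5. **Resolution and precision** (`compute_frc()`,
   `estimate_precision()`): Fourier ring correlation between odd/even
   half-sets and pooled within-emitter standard deviations.
6. **Dual color** (`split_channels()`, `channel_proximity()`): spectral
   ratio `ch1/(ch1+ch2)` with a strict `> 0.415` threshold for the DNA
   channel.
7. **Statistics** (`one_way_anova()`, `dunnett_test()`): per-cell
   fractions compared across treatment groups.

## Geometric fitting choices

**Cylinder fit.** The axis direction is optimized by Nelder–Mead over its
spherical angles; for each candidate direction the axis position and
radius are profiled out by a 2D circle fit (algebraic solve, then
geometric refinement of the center with the radius equal to the mean
radial distance). Because the axis of an elongated fiber window is the
*leading* principal direction while the axis of a disk-like nucleosome
stack is the *smallest* one, the optimizer multi-starts from all three
eigenvectors. Exact surface geometries are recovered to 1e-6 relative
radius; the fit is equivariant under rigid motions. Segment windows
narrower than the fiber diameter are orientation-degenerate, so window
fits share the whole-cluster principal axis; a cluster shorter than one
window falls back to a single free-axis fit. Strongly curved clusters
that fold back along their principal axis are outside the segmentation's
regime (the generator's default curvature keeps projections monotonic);
they would need centerline tracing, which is not implemented.

**Fit quality.** `r_squared` on radial distances is computed in
uncentered form, `1 - sum((d - r)^2) / sum(d^2)`. The centered version is
degenerate for this model class: the least-squares radius *is* the mean
radial distance, so centered residual and total sums of squares coincide
and the statistic is identically ~0 for any input. The uncentered form is
1 for exact geometry, ~0.99 at acquisition noise, and degrades as the
radial spread grows relative to the radius — a fit with ~2.5-nm radial
spread on a 5.8-nm ring scores ~0.8, the regime reported for real
nucleosome rings. Because even unstructured clouds have bounded relative
radial spread, this statistic never reaches zero; comparisons should be
made against the exact-geometry value of 1, and `rms_radial_residual`
carries the absolute scale.

**Nucleosome acceptance.** A fit is accepted when at least 5 probes
attach (radial residual within `attach_tol = 1.5` nm, about three times
the localization sigma, which separates on-cylinder probes from linker
and neighbor probes) inside the densest 8-nm axial window, with fitted
diameter inside the 9–14 nm band and height below diameter (disk-like,
not rod-like). Rejections return a "no-nucleosome" result, not an error.
Dimer fits share one axis, split points by an exact 1D two-means
partition of axial coordinates, and additionally require at least 4.5 nm
of axial center separation: two stacked disks cannot interpenetrate, and
without this constraint splitting a single nucleosome's own points in
half always yields two acceptable sub-fits ~2.9 nm apart.

**Orientation-angle inflation.** The default ring fit projects onto the
plane of the two leading principal axes. That plane is rotation-
equivariant, so fitted diameters cannot depend on how the nucleosome is
oriented in the microscope frame. Orientation dependence — invoked to
explain secondary high-side peaks in nucleosome diameter histograms —
only arises when the fitting plane is tied to the instrument frame, so
`fit_ring(plane = "imaging")` provides exactly that uncorrected variant:
points are projected along the optic axis with no correction for the
disk's orientation. For isotropically oriented nucleosomes this produces
a diameter mixture whose high-side component comes from steeply inclined
disks, where the superhelical rise (comparable to the ring radius)
smears the projection outward; `diameter_histogram()` on such fits shows
a secondary peak above the primary. A `plane = "refined"` mode minimizes
the full 3D geometric residual instead.

## The synthetic-scene generator

Real MINFLUX chromatin data are not publicly deposited, so every stage is
validated against generated scenes with exact ground-truth bookkeeping
(`make_nucleosome()`, `make_fiber()`, `make_scene()`,
`simulate_localizations()`, `apply_tsa()`; each localization carries a
truth link or a background flag).

* **Nucleosome**: probe sites at 12-bp spacing along a left-handed
  superhelix of 1.65 turns, path radius 4.2 nm, 5.7-nm rise over 147 bp.
  Each site binds with probability `at_fraction` (a per-footprint
  Bernoulli draw standing in for AT-sequence structure, since only the
  resulting 5–10 probe count is constrained), truncated at the 9-probe
  coverage cap. Probe radial positions are drawn uniformly from
  [5.0, 6.5] nm: the band is calibrated so its 5.75-nm mean reproduces
  the ~11.5-nm diameters that least-squares fits measure on real probe
  clouds, with the outer edge at the 11-nm disk envelope plus the 1-nm
  margin for the dye on the DNA cross-section. The fluorophore's true
  radial position is not known independently; this band is the
  generator's single most influential modeling choice and is exposed for
  sensitivity analysis through the fit recovery tests.
* **Fiber**: a smoothed random walk centerline with bounded curvature,
  partitioned into segments of given diameters. Nucleosomes sit on the
  shell of radius diameter/2 with random disk orientation — a
  solenoid-like arrangement with a hollower core, chosen so that the
  least-squares cylinder radius of the probe cloud equals the nominal
  fiber radius (a volume-filled fiber would fit ~2/3 of it). The linear
  nucleosome density is computed from the target DNA density
  (default 34 Mbp/um^3, configurable across 8.87–69.87) by inverting the
  probe-count density estimator, so a perfect analysis recovers the
  target in expectation.
* **Acquisition**: each bound probe is seen with `detection_prob`,
  displaced by per-axis Gaussian error with
  `sigma = FWHM / (2 sqrt(2 log 2))` (FWHM defaults 1.08/0.96/0.63 nm),
  and by default is never re-localized (`relocalization_rate = 0`),
  matching probe-exchange blinking where a molecule is rarely seen twice
  at the same position; background false positives are uniform in the
  box; timestamps advance at 93.7 us per localization in randomized
  order.
* **Decompaction** (`apply_tsa()`): a fraction `severity` of fibers is
  dissolved, their nucleosomes dispersed (half re-scattered as free
  probes by default), survivors truncated below 50 nm with diameters
  untouched — the fiber-collapse phenotype of histone-deacetylase
  inhibition.

What the generator does **not** emulate: sequence-specific AT structure,
chromatin motion (only the fixed/live contrast via `detection_prob`),
iterative beam-positioning physics and photon statistics, linker DNA and
linker histones, and inter-fiber contact geometry. Passing recovery tests
therefore demonstrate correctness of the estimators under the stated
geometric and noise model, not performance on the full complexity of
nuclear chromatin.

## Region classification

`classify_region()` reproduces the scattered / 1–2 nucleosome / >=3
nucleosome decomposition: noise-labeled localizations are scattered;
within each cluster nucleosomes are extracted greedily (densest unclaimed
18-nm window first, claimed points removed on acceptance, deterministic
given uid order), and each cluster's localizations are assigned by its
accepted-fit count. Fractions are localization-weighted, matching the
phrasing "fraction of localizations"; a per-cluster weighting is
available by summarizing `fits_per_cluster` instead. The greedy scheme
guarantees each localization is claimed by at most one fit.

## Statistics

`one_way_anova()` delegates to `stats::aov()` and reports the classical
F with (groups-1, N-groups) degrees of freedom — (3, 45) for the
4-group, 49-cell design used in decompaction time courses.
`dunnett_test()` computes pooled-variance many-to-one t statistics and
evaluates the equicoordinate multivariate-t probability of the max-|t|
null by seeded quasi-Monte-Carlo (`mvtnorm::pmvt`), which handles
unbalanced designs exactly and reports its Monte-Carlo standard error;
with a single comparison it reduces to the two-sample t test. Fractions
are analyzed untransformed, as is conventional for box-plot summaries of
per-cell fractions in this range; an arcsine-square-root transform can be
applied to the input column by the caller if desired.

## Numerical and scale choices

* FRC renders 2-nm pixels (about a tenth of the expected ~27-nm
  resolution scale), splits by odd/even uid (deterministic,
  acquisition-interleaved, robust to density gradients; a seeded random
  split is available), smooths with a centered 3-bin moving average, and
  interpolates the first downward 1/7 crossing; an uncrossed curve
  returns the Nyquist limit with a flag. 3D input is projected to xy.
* The FWHM/sigma constant `2*sqrt(2*log(2))` is defined once and shared
  by the simulator and the precision estimator.
* Test and acceptance problem sizes (hundreds of fits, a few thousand
  localizations per scene, 5 density targets, 49 simulated cells) were
  chosen as the smallest populations whose sampling noise sits well
  inside the tolerances being asserted.
* Degenerate inputs follow a uniform policy: genuinely unanswerable
  requests (collinear points, singleton precision groups, zero-volume
  cylinders) raise classed errors; structurally valid but unproductive
  inputs (no acceptable nucleosome, unsegmentable cluster, empty region)
  return flagged results.

## Known limitations

* Localization counts are used as probe counts; if re-localization is
  enabled in the simulator (or present in real data), densities
  double-count unless sightings are first collapsed (< 1 nm, < 1 ms) by
  the caller. Deduplication is deliberately not applied by default.
* Curved fibers are ordered along a single principal axis; hairpin
  clusters are not split.
* The 0.415 dual-color ratio threshold is treated as a given calibration
  constant; which physical detector is `ch1` is a dialect decision.
* FRC is 2D only (no Fourier shell correlation), and the fixed-1/7
  threshold is the only convention offered.
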