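---
title: "Quantifying polar fluorescence and motility in rod-shaped bacteria"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying polar fluorescence and motility in rod-shaped bacteria}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodpol)
```

## The measurement problem

Polarly localized proteins control where rod-shaped bacteria assemble their
motility machinery. A snapshot experiment produces, per strain, hundreds of
segmented cells in fluorescence images; the analysis must reduce each cell to
a small set of comparable numbers: how much of the tagged protein sits at
each pole, how asymmetric that distribution is, and which qualitative
localization pattern the cell shows. A time-lapse experiment produces
trajectories; the analysis reduces each to a mean speed and a reversal count.
`rodpol` implements both reductions, plus a synthetic generator that provides
exact ground truth for every intermediate quantity.

## Per-cell model and procedure

The pipeline assumes separated (non-touching), roughly rod-shaped cells whose
fluorescence is a sum of three components: a uniform camera background, a
diffuse cytoplasmic signal, and zero to two compact polar clusters.

1. **Background.** The median intensity over all non-cell pixels. Median
   rather than mean, so stray bright debris does not shift the estimate.
   Subtracting it first makes all later percentages offset-independent (and
   the whole analysis invariant to linear rescaling of the signal — a tested
   property).
2. **Geometry.** Each labeled region becomes a cell with a medial axis: the
   major principal axis of its pixel set, refined by centroids of ~1.5 px
   slices so mildly bent cells are followed; the pole tips are the extreme
   pixels along this backbone, and every pixel gets an arc coordinate (its
   position along the axis, in px). Cells touching the image border are
   excluded by default — their truncated signal would bias the asymmetry
   index — as are regions with fewer than 9 pixels or with an axis extent
   shorter than twice their width, for which "poles" are not meaningful.
   Coordinates are 1-based (row, col) from the top-left, R's native matrix
   convention.
3. **Polar caps.** Cap A and cap B are the pixels within `cap_extent` of the
   axis ends (arc ≤ `cap_extent`·L and arc ≥ (1 − `cap_extent`)·L). The rest
   is mid-cell. The default `cap_extent = 1/6` approximates the hemispherical
   end caps of a rod about six times longer than wide. Published pipelines
   rarely state where "polar" ends — a fixed-radius disc at the tip would be
   an equally defensible choice — so the extent is a first-class parameter
   rather than a constant.
4. **Cytoplasmic statistics.** Mean and SD of the background-subtracted
   mid-cell pixels. Defining "cytoplasm" as the mid-cell region (rather than
   "whatever is not in a cluster") avoids a circular definition and needs a
   single pass; it is unbiased precisely when clusters are polar, which is
   the regime this analysis targets. The SD uses the population convention
   (divisor n); `sd_type = "sample"` switches it.
5. **Cluster detection.** Within each cap, pixels strictly above
   `mean + k_sd·SD` seed candidate clusters; 8-connected components of seeds
   are kept if they have at least `min_size` pixels and a component mean at
   or above the same threshold. Defaults `k_sd = 2`, `min_size = 3`. The
   threshold is applied both per pixel (to find candidates) and to the
   component mean (the acceptance rule), because the published criterion —
   an *average* signal 2 SD above cytoplasm over 3+ pixels — specifies the
   component test but not how candidates are found. 8-connectivity is the
   standard choice for thin diagonal structures. With a perfectly uniform
   cell (SD = 0) the strict inequality means no pixel seeds, so no cluster —
   the intended degenerate behaviour.
6. **Poles, ω, category.** Cluster fluorescence is summed per cap; the
   brighter cap is pole 1, with exact ties broken deterministically toward
   cap A. For cells with any cluster,
   ω = (F₁ − F₂)/(F₁ + F₂) ∈ [0, 1], and the category follows the printed
   bins (unipolar ω > 0.9; bipolar asymmetric 0.9 ≥ ω ≥ 0.2; bipolar
   symmetric ω < 0.2; boundary values land in the middle bin). Cells without
   clusters are diffuse; ω is undefined for them, not zero. "No polar
   signal" is implemented as "no accepted component of ≥ `min_size` pixels",
   not "no pixel above threshold".
7. **Percentages.** Total cell fluorescence is the background-subtracted sum
   over all cell pixels; pole percentages are cluster totals relative to it;
   the cytoplasmic percentage is the remainder, so the three sum to 100 by
   construction. By default, polar totals are raw background-subtracted sums
   — the natural reading of "total fluorescence at a pole". The
   `subtract_cytoplasm = TRUE` flag removes the diffuse level under the
   cluster footprint instead, which is the right estimator when the target
   quantity is the spot mass itself (as when validating against the
   generator's ground-truth fractions; the raw estimator is biased upward by
   roughly the cluster area times the diffuse per-pixel level — about 3–7
   percentage points at the default settings).

Population summaries report category percentages and mean polar/cytoplasmic
percentages over **all** cells, diffuse ones included (they contribute 0%
polar). Pooling across replicates uses the mean of replicate means — equal
weight per experiment, as multi-experiment means are conventionally reported
— with cell-weighted pooling as an option. The provided significance test is
the two-tailed pooled-variance t-test; both units of analysis (replicate
means, n = number of replicates, or single cells) are legitimate and the
package deliberately leaves that choice to the caller.

## Motility metrics

Speeds are per-interval Euclidean displacements converted to µm/min; the
frame interval is validated against the recording (20 s and 30 s are the
common settings). Reversal detection needs an operational rule, since "a
reversal" is not a pixel-level concept: the package counts a reversal when
the direction of a significant step (length ≥ `min_step`, default 0.03 µm)
turns by at least `angle_threshold` (default 120°) from the current heading
*and* the next significant step confirms the new direction — i.e. the new
heading persists for at least two intervals. Unconfirmed turns are treated
as positional jitter. The 120°/2-interval/`min_step` triple is chosen to be
robust to realistic positional noise while never missing a true 180° flip;
all three are configurable, and with `angle_threshold = 180`, `min_step = 0`
the count on noise-free tracks equals the programmed flip count exactly (a
tested invariant; the 180° comparison carries a 1e-9 cosine tolerance so an
exactly antiparallel step is not lost to rounding). The inclusion rule
"moved for the entire recording" is read frame-locally: every interval
displacement must reach `min_step`; one paused frame excludes the cell.
Reversal counts are normalized to a 15-min observation window by linear
scaling when a track is shorter or longer.

## The synthetic generator

Scenes emulate snapshot fields: spherocylinders (default 0.5 µm wide,
5–7 µm long, at 0.06 µm/px — a typical 100× sCMOS sampling; the true camera
geometry of any given microscope should be configured, not assumed) placed
by rejection sampling so that no two cells touch, each rendered as

* a uniform diffuse component: `(1 − p₁ − p₂)·T` spread evenly over the
  cell's pixels,
* up to two Gaussian spots (σ default 1.8 px ≈ a 250 nm FWHM PSF) centred on
  the medial axis at the centres of the two hemispherical end caps. Each
  spot is renormalized over the cell's own pixels so its integrated in-cell
  mass is *exactly* `pᵢ·T` — truth fractions are exact by construction
  rather than approximate under boundary truncation,
* camera background (default 100 counts), then optional Poisson shot noise
  on expected counts and additive Gaussian read noise (default SD 2 counts).

The truth table records the exact fractions and the category they imply,
computed with the same binning function the pipeline uses, so truth and
pipeline disagreements isolate detection/geometry errors rather than binning
discrepancies. Default `total_intensity = 5e4` counts puts the diffuse level
around 60 counts/px over background — comfortably shot-noise-limited, as
typical fluorescent-fusion imaging is.

Trajectories are constant-speed runs (default 2 µm/min, a realistic gliding
speed) with 180° flips at programmed times, integrated exactly between frame
times, plus optional Gaussian positional noise. The reversal-time helper
draws flips on the frame grid, at least 2 intervals from the ends and 3
intervals apart — the spacing at which a 2-interval-persistence detector can
score every flip unambiguously, and a realistic cadence for cells reversing
a few times per 15 min.

**What the generator does not emulate:** optical blur of the diffuse
component (noise is pixel-independent; real camera noise is, but the signal
itself would be PSF-correlated), curved or dividing cells, uneven
illumination, photobleaching, segmentation errors, out-of-focus clusters,
and cell-body orientation in trajectories. Passing the synthetic benchmarks
therefore demonstrates the correctness of the measurement chain — geometry,
thresholding, component analysis, arithmetic, classification — not the
field robustness of segmentation or detection on degraded real images.

One consequence worth knowing: under any pixel-independent noise, a 2 SD
threshold leaves ~2.3% of cap pixels above it by chance, and occasionally
three of them are 8-adjacent — so a few percent of genuinely cluster-free
cells acquire a small spurious "cluster". This false-positive rate is
scale-invariant (the threshold adapts to the noise amplitude) and is an
intrinsic property of the published rule, not of this implementation; raising
`k_sd` or `min_size` trades it against sensitivity.

## Numerical choices and degenerate inputs

* Percentage conservation holds to 1e-6 by construction; tests assert it.
* Exact pole ties → pole 1 = cap A (determinism over arbitrariness).
* `cap_extent = 0` yields empty caps (no polar pixels), although the tip
  pixel's arc coordinate is exactly 0; `cap_extent ≥ 0.5` is rejected
  because the caps would overlap.
* A label split into several 8-connected islands is rejected with a
  diagnostic rather than silently measured as one cell.
* Cells with non-positive background-subtracted totals, or an empty mid-cell
  region, are excluded with a warning.
* Zero pooled variance in the t-test: p = 1 when the means agree, an error
  when they do not (the statistic is undefined, and silently returning
  infinity would invite misuse).
* All simulation sizes used by the test-suite and the acceptance script
  (50–500 cells per scene, 100 tracks) were chosen so each check exercises
  population-level behaviour while the whole suite runs in about a minute;
  they are stated in the scripts themselves.

## Known limitations

* The medial axis is a PCA-plus-slice-centroid backbone: adequate for
  straight or mildly curved rods, not for strongly bent or branched cells
  (use a dedicated segmentation/backbone tool and feed its masks in).
* Cap-based "polar" scoring means a cluster sitting just inside the mid-cell
  boundary is counted as cytoplasm; the cap extent parameter is the knob,
  and the right value depends on cell geometry.
* Raw polar totals include diffuse signal under the cluster (see above);
  choose the estimator to match the question.
* Reversal detection assumes approximately straight runs between flips;
  strongly meandering motion would need a different operationalization.
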