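# rodpol

Quantification of polar fluorescent protein localization and single-cell
motility in rod-shaped bacteria.

Many rod-shaped bacteria — *Myxococcus xanthus* being the classic example —
regulate motility through proteins that accumulate at one or both cell poles.
Fluorescence snapshots of such strains are summarized per cell by how the
tagged protein distributes between the two poles and the cytoplasm, and
time-lapse tracking summarizes behaviour as speeds and reversal frequencies.
`rodpol` implements that analysis as a tested, scriptable pipeline for people
who have segmentation masks (e.g. from Oufti or MicrobeJ) plus fluorescence
images, or single-cell trajectories, and want reproducible per-cell tables
instead of one-off scripts.

## The measurement

For each segmented cell the pipeline builds a medial axis with two pole tips,
defines polar caps (default: the outer 1/6 of the axis length at each end),
and detects **polar clusters**: 8-connected groups of at least 3 pixels whose
average background-subtracted fluorescence is at least 2 SD above the mean
cytoplasmic fluorescence (measured over the mid-cell region). Pole 1 is by
definition the pole with the higher cluster fluorescence. For every cell with
at least one cluster an **asymmetry index**

    ω = (F_pole1 − F_pole2) / (F_pole1 + F_pole2)

is computed from the polar fluorescence totals, and cells are binned as

| category            | rule        |
|---------------------|-------------|
| unipolar            | ω > 0.9     |
| bipolar asymmetric  | 0.9 ≥ ω ≥ 0.2 |
| bipolar symmetric   | ω < 0.2     |
| diffuse             | no polar cluster detected |

Per-cell output also includes the percentage of total cellular fluorescence
at each pole and in the cytoplasm (always summing to 100). Population
summaries average over all cells — including cluster-free ones — and pool
replicates by the mean of replicate means. Motility metrics are per-interval
speeds (µm/min), reversal counts per observation window (default 15 min),
and the inclusion filter that keeps only cells moving through the entire
recording. Strain comparisons use the two-tailed Student's t-test for samples
with equal variances.

Because public deposits of this kind of imaging data are rare, the package
ships a ground-truthed synthetic generator: spherocylindrical rod cells
(~0.5 × 5–7 µm) rendered with diffuse cytoplasmic signal, zero/one/two polar
Gaussian clusters of exactly known intensity fractions, camera background,
Poisson shot noise and Gaussian read noise — plus constant-speed trajectories
with programmed 180° reversals. Every stage of the pipeline is tested against
this ground truth.

## Worked example

```r
library(rodpol)

# a synthetic field of 40 cells, 35% / 15% of fluorescence at the two poles
spec  <- scene_spec(n_cells = 40, image_shape = c(800, 800), seed = 7)
loc   <- localization_spec(total_intensity = 5e4,
                           pole1_fraction = 0.35, pole2_fraction = 0.15)
scene <- generate_scene(spec, loc)

cells <- quantify_cells(scene$image, scene$mask)
head(cells[, c("label", "pole1_pct", "pole2_pct", "cytoplasmic_pct",
               "omega", "category")], 4)
#>   label pole1_pct pole2_pct cytoplasmic_pct omega category
#> 1     1      38.4      18.1            43.6 0.360 bipolar_asymmetric
#> 2     2      38.0      18.7            43.3 0.341 bipolar_asymmetric
#> 3     3      39.3      19.0            41.7 0.347 bipolar_asymmetric
#> 4     4      39.3      18.9            41.7 0.350 bipolar_asymmetric
```

Every cell is recovered as bipolar asymmetric, as the true fractions imply
(true ω = (0.35 − 0.15)/(0.35 + 0.15) = 0.4). The per-cell pole percentages
(~38/18 instead of 35/15) include the diffuse signal lying under the cluster
footprint; pass `subtract_cytoplasm = TRUE` to estimate pure spot mass.

```r
pop <- aggregate_population(cells)
pop[pop$replicate == "pooled",
    c("n_cells", "pct_bipolar_asymmetric", "mean_polar_pct", "mean_cytoplasmic_pct")]
#>   n_cells pct_bipolar_asymmetric mean_polar_pct mean_cytoplasmic_pct
#> 1      40                    100           56.9                 43.1

autoplot(cells)   # pole 2 % vs pole 1 % scatter with the symmetry line
autoplot(pop)     # category bar diagram

# motility: 20 tracks at 2 µm/min with programmed reversals at 5 and 10 min
tr <- generate_tracks(track_spec(n_tracks = 20, speed = 2,
                                 reversal_times = c(5, 10), seed = 8))
head(summarize_motility(filter_moving(tr$tracks)), 3)
#>   cell mean_speed_um_min n_reversals reversals_per_window moved_throughout
#> 1    1                 2           2                    2 TRUE
#> 2    2                 2           2                    2 TRUE
#> 3    3                 2           2                    2 TRUE

tidy(t_test_equal_var(c(2.1, 2.4, 2.2), c(1.1, 1.3, 1.2)))
#>   estimate statistic  p.value parameter
#> 1     1.03      9.80 0.000607         4
```

Both the speed (2 µm/min) and the programmed reversal count (2 per 15 min)
are recovered exactly on noise-free tracks.

## Command line

A thin CLI wraps the same functions:

```sh
Rscript inst/scripts/rodpol simulate --out runs/sim --seed 7
Rscript inst/scripts/rodpol quantify --mask runs/sim/mask.tif \
        --image runs/sim/fluorescence.tif --out runs/quant
Rscript inst/scripts/rodpol tracks --tracks runs/sim/tracks.csv --out runs/mot
```

Each run writes its outputs as CSV plus a `run_manifest.yaml` echoing the
full configuration, seed and input checksums. Fixed config + seed gives
byte-identical outputs.

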