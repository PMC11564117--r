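# beadrim

Quantification of microscopy-based bead recruitment assays in R.

In these assays, glutathione-agarose beads are coated with a GST-tagged bait
protein and incubated with fluorescently labelled prey proteins (for example
GFP–TBK1 or FIP200–GFP). Prey recruited to the bead surface appears on a
confocal equatorial section as a bright **rim** around each bead. The
biological readout — how strongly a condition recruits the prey, and how a
competitor titration suppresses it — is the amplitude of that rim signal,
measured per bead, quality-filtered, normalized to a control condition, and
compared statistically.

`beadrim` implements that measurement end to end, plus a synthetic
bead-scene generator with full ground truth so that every stage is testable
by parameter recovery.

## The measurement model

For each bead the pipeline:

1. **segments** the bead field (default backend: Otsu threshold → hole
   filling → Euclidean distance transform → peak-seeded watershed, with
   labels snapped to the circle at the rim-intensity peak; any external
   segmenter, e.g. a learned model, can be plugged in through a backend
   seam);
2. **fits a circular ROI**: center = label centroid, radius =
   `sqrt(area / pi)`;
3. draws **20 radial line profiles** at evenly spaced angles from the bead
   center to 1.5× its radius, sampling by bilinear interpolation at 0.5 px
   steps, truncating any line that enters the combined (margin-dilated)
   mask of the *other* beads or leaves the image;
4. scores each line by its **amplitude** `max(I) − min(I)` — the rim peak
   against the darkest point along the line — and each bead by the mean
   `m_b` and sample SD `s_b` of its valid line amplitudes;
5. applies the **QC rule**: a bead is excluded when `s_b ≥ m_b / 2`
   (uneven or artifactual rims; boundary inclusive);
6. **normalizes**: every bead mean is divided by the average bead mean of
   the control condition, so the control's normalized mean is exactly 1;
7. **tests**: one-way ANOVA with Dunnett's many-to-one comparison of each
   condition against the control (multivariate-t adjusted, two-sided), or
   Welch's t-test for two groups, with significance coded
   `*` p < 0.05, `**` p < 0.005, `***` p < 0.001, `****` p < 0.0001.

## Worked example

Simulate a four-condition competitor titration (control plus competitor at
0.1, 1 and 10 µM, IC50 1 µM, 40 beads per condition) and quantify it:

```r
library(beadrim)

base   <- scene_config(image_shape = c(512L, 512L), n_beads = 40L,
                       interior_level = 0, rim_amplitude = 100, seed = 1)
doses  <- c(0.1, 1, 10)
series <- generate_dose_series(base, doses, max_amplitude = 100, ic50 = 1)

dir <- tempfile(); dir.create(dir)
write_scene(generate_scene(base), dir, "control")
for (i in seq_along(series))
  write_scene(series[[i]]$scene, dir, sprintf("dose_%d", i))

manifest <- list(
  channels = list("GFP"),
  conditions = c(
    list(list(name = "control", control = TRUE, channel = "GFP",
              images = list(file.path(dir, "control.tif")))),
    lapply(seq_along(series), function(i)
      list(name = sprintf("dose_%g", doses[i]), channel = "GFP",
           images = list(file.path(dir, sprintf("dose_%d.tif", i)))))))

res <- run_pipeline(run_config(manifest, output_dir = file.path(dir, "out")))
res$conditions
#>  condition n_beads_pass n_beads_excluded mean_normalized sd_normalized
#>    control           40                0      1.00000000   0.020995470
#>   dose_0.1           40                0      0.90504321   0.014859950
#>     dose_1           40                0      0.49926101   0.010047514
#>    dose_10           40                0      0.09167735   0.002928964
res$stats
#> one-way ANOVA + Dunnett
#> groups (n): control=40, dose_0.1=40, dose_1=40, dose_10=40
#> statistic = 3.591e+04, df = 3, 156
#>     group    estimate          t p_adj stars
#>  dose_0.1 -0.09495679  -30.58433     0  ****
#>    dose_1 -0.50073899 -161.28143     0  ****
#>   dose_10 -0.90832265 -292.55875     0  ****
```

The recovered normalized means track the generating dose–response
`1 / (1 + dose/ic50)` — 0.909, 0.500, 0.091 at these doses — within ~1%,
and every dose is called significantly different from the control.

A thin command-line front-end with `simulate`, `quantify` and `all`
subcommands is installed at `inst/cli/beadassay.R`.

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch:
it simulates the four-condition titration above under the given seed, runs
the full segment → profile → QC → normalize → Dunnett pipeline on the
written TIFFs, prints the condition summary and statistics, and writes a
JSON result file.

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
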