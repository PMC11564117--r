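---
title: "Quantifying bead recruitment assays from rim intensity profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bead recruitment assays from rim intensity profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beadrim)
```

## The assay and its readout

Microscopy-based bead assays reconstitute protein recruitment on a surface:
glutathione beads are coated with a GST-tagged bait, incubated with
fluorescent prey proteins, and imaged on a confocal microscope. Because the
prey binds the bead surface, an equatorial optical section shows each bead
as a bright ring ("rim") over a dimmer interior and a flat background. The
quantity of interest is the rim signal per bead: how much prey a condition
recruits, relative to a control condition run in the same experiment.

`beadrim` measures this as follows. Beads are segmented and fitted with
circular ROIs. From each bead center, 20 radial lines are drawn to 1.5
times the fitted radius, each sampled by bilinear interpolation at 0.5 px
steps. Each line is scored by its amplitude, the difference between its
maximum and minimum gray value: the maximum sits on the rim, the minimum in
the bead interior or the inter-bead space, so the amplitude is the rim
signal referenced to the darkest point the line crosses. A bead is then
summarized by the mean and sample SD of its valid line amplitudes.

This composition — per-line max − min first, then the per-bead mean — is a
deliberate reading of the assay's procedure: it is the only one in which
both the per-line amplitude and the per-bead mean/SD are defined, and the
SD it produces is exactly what the downstream QC rule consumes.

## Quality control, normalization, statistics

**QC rule.** A bead is excluded when the SD of its line amplitudes is at
least half their mean. A uniform rim gives 20 nearly identical amplitudes
(low SD); an unevenly coated or artifactual bead gives a bimodal set of
amplitudes whose SD is comparable to the mean. The boundary is inclusive
(`sd == mean/2` excludes), a zero-signal bead (`0 >= 0`) is excluded with
its own reason code, and excluded beads are flagged for optional human
review rather than corrected automatically. QC uses only each bead's raw
mean and SD, so it commutes with normalization and is order-independent.

**Normalization.** Each bead mean is divided by the arithmetic mean of the
control condition's QC-passing bead means. Only passing beads feed the
control average — the self-consistent choice, since excluded beads
contribute nothing else downstream either. Normalization removes
inter-experiment gain differences exactly: a global multiplicative factor
cancels, and the control's normalized mean is 1 by construction. Bead
values are pooled across replicate images of a condition; a per-replicate
summary remains available from the per-bead table.

**Statistics.** Conditions are compared to the control with one-way ANOVA
followed by Dunnett's many-to-one procedure: statistics
$t_i = (\bar x_i - \bar x_0)/(s\sqrt{1/n_i + 1/n_0})$ with the pooled error
variance, adjusted two-sided through the multivariate t distribution with
correlation $\rho_{ij} = \lambda_i \lambda_j$,
$\lambda_i = \sqrt{n_i/(n_i + n_0)}$ (implemented on `mvtnorm::pmvt`; with
a single comparison this reduces exactly to the pooled t-test). Welch's
t-test is provided for two-group designs. Significance is coded
`*` < 0.05, `**` < 0.005, `***` < 0.001, `****` < 0.0001. `pmvt`'s
quasi-Monte-Carlo integration runs under a fixed internal RNG state, so
repeated runs produce byte-identical p-values.

## The synthetic scene generator

Every stage is validated against scenes with known ground truth. A bead is
rendered as an interior disk (`interior_level` above background) plus a
ring with Gaussian radial cross-section: at distance $d$ from the center
the ring adds $A\,e^{-(d-r)^2/2\sigma^2}$, peaking on the circle of radius
$r$. A contiguous arc of the ring can be zeroed (`defect_fraction`) to
model unevenly coated beads — the failure mode the QC rule exists for.
Noise follows a standard detector model: Poisson shot noise on the
noiseless signal first (`poisson_scale` photons per gray value), then
additive Gaussian read noise. Scenes are bit-reproducible from their
config, and `truth_labels` records each bead's true disk.

Defaults state a realistic field at 20x magnification: 256 × 256 tiles,
bead radius 20 ± 3 px (the bead diameter in pixels is not a published
quantity; this is a configurable choice), background 100 gray values, rim
amplitude 100, rim width $\sigma = 2$ px. Dose series follow a hyperbolic
competition curve $A(c) = A_{\max}/(1 + c/\mathrm{IC_{50}})$ — a
demonstration surrogate for competitor titrations (design range 0.1–10 µM),
not a fitted binding model.

What the generator does **not** emulate: point-spread-function blur, 3D
sectioning effects, autofluorescence gradients, bead clumping beyond
pairwise touching, or debris. A green parameter-recovery test therefore
establishes correctness of the measurement chain on idealized rims, not
robustness to every real-world artifact — which is why the assay retains a
manual-inspection step that this package deliberately leaves to humans.

## Numerical choices and edge cases

- **Pixel convention**: pixel $(i, j)$ has its center at continuous
  coordinate $(i, j)$, 1-based, `(row, col)` — the native R matrix
  convention.
- **Bilinear sampling** uses the incremental form
  $v_{00} + f_r\Delta_r + f_c\Delta_c + f_rf_c\Delta_{rc}$, which is exact
  on constant patches (a flat image yields amplitude exactly 0) and makes a
  global additive offset shift every sample exactly, so amplitudes are
  exactly offset-invariant and exactly linear in gain.
- **Truncation**: a sample is blocked when its rasterized pixel lies inside
  the combined exclusion mask *and* beyond the bead's own fitted radius
  plus the mask margin. Using the bare fitted radius would let a bead's own
  dilated disk cut its lines at the rim peak; both tests use the same
  rasterized pixel, so the boundary is consistent. Lines with fewer than 5
  retained samples are discarded; beads with no valid line are excluded as
  unmeasurable.
- **SD convention**: sample SD (ddof = 1); a single-line bead gets SD 0 and
  a low-n flag.
- **Segmentation**: any level-set threshold places the object boundary on
  the ring's outer Gaussian skirt, ~2–3 px beyond the bead radius, so the
  default backend snaps each label to the circle at the peak of its radial
  mean-intensity profile (skipped for objects without a rim-like profile,
  e.g. filled disks). External segmenters plug in through the
  `backend` seam of `segment_beads()` and are trusted as-is. Beads whose
  fitted circle crosses the image edge are excluded from quantification by
  default. Degenerate inputs are defined: constant images give an empty
  label map; an ROI smaller than two sampling steps is a degeneracy error.

## Known limitations

Two properties of the stated measurement are worth knowing before trusting
small effects:

1. **Sampling-density gap at the rim peak.** A 0.5 px line sampler
   undershoots the interpolated ring peak relative to a 10×-denser
   resampling of the same surface by up to ~3% of the amplitude on the
   worst line (mean agreement ~0.7%). This is intrinsic to sampling a
   curved peak on a fixed grid, not an implementation defect.
2. **Extreme-value bias under noise.** `max − min` is upward-biased: at an
   amplitude-to-noise ratio of 10 (rim 100, Gaussian SD 10, radius 20), the
   per-bead mean amplitude overestimates the true rim height by ~15%
   (median over seeded beads). The bias is shared by all conditions at
   equal noise and largely cancels under control normalization, but
   absolute amplitudes at low SNR should not be read as unbiased rim
   heights. Smoothing before min/max would reduce it, and is deliberately
   not applied: raw gray values are the stated measurement.

Also out of scope: background/flat-field correction, anisotropic pixels,
3D stacks, hierarchical modeling of replicate structure, and any bundled
learned segmentation model.
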