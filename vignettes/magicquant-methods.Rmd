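---
title: "Methods: quantifying mitochondrial import reporters in yeast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying mitochondrial import reporters in yeast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The assays and their statistics

Misfolded cytosolic proteins can be imported into mitochondria for
degradation (the MAGIC pathway, "mitochondria as guardian in cytosol"). The
workhorse readout is the split-GFP assay: GFP strands 1–10 are targeted to
the mitochondrial matrix, strand 11 is fused to a substrate such as the
destabilized luciferase FlucSM, and fluorescence reconstitutes only after
import. Mitochondrial GFP intensity per cell therefore reports import flux.
`magicquant` implements the quantification chain for this assay and its
three companions — nucleocytoplasmic (N/C) reporter distribution,
aggregate-positive cell fractions, and cycloheximide (CHX) chase
degradation kinetics — together with a synthetic-scene generator that gives
every stage a recoverable ground truth.

The spGFP chain is:

1. **z-sum projection.** Both channels of the 3D confocal stack (0.5 µm z
   step, 12 slices ≈ 6 µm, covering the yeast cell) are summed along z
   (`sum_project()`). No rescaling or clipping; intensities are carried as
   doubles from the moment of reading so that sums and medians are exact.
2. **Background/foreground separation** by random-walker segmentation
   (`segment_foreground()`). We solve the combinatorial Dirichlet problem on
   the 4-neighbor pixel graph with edge weights
   $w_{ij} = \exp(-\beta (g_i - g_j)^2)$ on the min–max-normalized image
   ($\beta = 130$ by default). Seeds are set by intensity quantiles: pixels
   at or below the 0.20 quantile seed the background class, at or above the
   0.90 quantile the foreground. Quantile seeding has two virtues: it is
   scale-free (multiplying the image by any $k > 0$ changes nothing), and it
   needs no absolute threshold. Its cost is an assumption that cells cover
   roughly 10–25% of the field — at much sparser densities the top decile
   of intensities includes background and foreground seeds become
   unreliable. The synthetic fields are generated near 18% fill to match.
3. **Watershed separation of adjoining cells** (`split_cells()`). Markers
   are local maxima of the lightly smoothed Euclidean distance transform,
   greedily suppressed within `min_marker_separation_px` (default: the
   expected cell radius, 9 px) in order of decreasing distance value with
   raster-order tie-breaks; the mask is then flooded in decreasing distance
   order from the markers — watershed on the negative distance transform
   confined to the mask. Components under `min_cell_area_px` (80 px) are
   removed; border-touching cells are kept in the map but flagged and
   excluded from statistics, since their compartments are truncated by the
   field of view. Labels are dense, 1..n in raster order of centroid, which
   makes the labeling a pure function of the mask.
4. **Mitochondrial masking** (`mito_mask()`): within each cell the marker
   (mCherry) projection is thresholded at 5% of its maximal value. We read
   "maximal" as the *per-cell* maximum (a per-image option exists). The
   threshold acts on the background-subtracted marker (below).
5. **The per-cell statistic** (`spgfp_per_cell()`): the *median* GFP
   intensity over the mitochondrial mask. Medians of even-sized pixel sets
   are the mean of the two central order statistics. Cells with an empty
   mask propagate as excluded rows with a reason, never as silent zeros.
6. **Replicate-level statistics** (`summarize_groups()`): the biological
   replicate — an independently grown culture — is the unit of inference.
   Replicate means of included cells feed grand means, SEM over replicates,
   and two-tailed t-tests (paired across matched replicate ids, or
   unpaired). Welch's unequal-variance form is the unpaired default; the
   pooled Student form is a flag. No multiplicity correction is applied:
   comparisons are reported one at a time, as is conventional for these
   assays. Relative quantities divide grand means by a reference group's.

The N/C assay shares steps 1–3, then builds a per-cell nucleoplasmic mask
from the RFP marker (per-cell Otsu threshold, largest connected component),
defines cytoplasm as the nuclear mask dilated by a 3 px disc, clipped to the
cell, minus the nucleus — an annulus, the literal reading of "defined by a
dilated nuclear mask"; a whole-cell mode is available behind a flag. The
ratio is mean nuclear over mean cytoplasmic GFP.

Aggregate scoring replaces manual counting of Hsp104-GFP foci with a
deterministic detector: scale-normalized Laplacian-of-Gaussian filtering
(σ = 2 px, matched to the generator's punctum radius), local maxima
deduplicated within 2σ, and a punctum call when the GFP intensity at the
peak exceeds `prominence_ratio` (default 2.0) times the cell's median GFP.
A cell is positive at ≥ 1 punctum; the per-image readout is the positive
fraction, compared across groups on replicate fractions.

Chase kinetics (`build_curve()`, `fit_decay()`, `compare_timepoints()`)
follow the flow-cytometry protocol arithmetic exactly: the pre-induction
background is subtracted from every mean intensity, curves are normalized
to the first time point (so relative[t₀] = 1 identically), and groups are
compared per time point with unpaired two-tailed t-tests on replicate-level
relative intensities. The optional decay fit is origin-constrained least
squares of $\log R = -kt$ over points with $R > 0$, clipped at $k \ge 0$ —
a log-linear fit rather than nonlinear least squares because it is exactly
testable against closed forms and adequate at these noise levels.

Hydropathy profiling (`kd_profile()`) is the ProtScale parameterization:
Kyte–Doolittle scale, window 5, relative edge weight 100%, linear weight
variation, no normalization. At 100% edge weight all weights are equal and
the score is the plain window mean; the linear edge-to-center weighting is
implemented generally and collapses to uniform in that limit.

## Background handling

Whether the original per-cell medians used raw or background-subtracted
projections is not recorded anywhere we could consult, so the package makes
its own choice and exposes it (`background_subtract`, default `TRUE`).
Additive camera background biases both readouts toward 1: with cytosolic
signal $c$, background $b$ and true fold change $f$, the raw relative spGFP
is $(b + cf)/(b + c) < f$, and the raw N/C ratio is compressed the same
way. The scene background is estimated as the median projection intensity
over non-cell pixels and subtracted from per-cell statistics; for the
mitochondrial mask the same subtraction is applied to the marker channel
before the 5%-of-maximum rule, because a fractional threshold is only
meaningful on signal, not on a common offset (with a z-sum background of
~20 a.u. and marker peak of ~400 a.u., 5% of the raw maximum sits exactly
at the background level and the "mitochondrial" mask would swallow the
whole cell).

## What the generator emulates — and what it does not

`generate_scene()` renders budding-yeast-sized elliptical cells (radius
9 ± 1 px at 0.2 µm/px, i.e. ~3.6 µm diameter, elongation up to 1.25×)
placed without overlap at ~18% field coverage, with one designed touching
pair of circular cells whose centers sit closer than the sum of their radii
— the neck that watershed must split. Mitochondria are persistent random
walks dilated to ~2–3 px width until they cover `mito_fraction` (0.15) of
the cell; nuclei are 3 px disks; aggregates are Gaussian puncta (σ = 1.5 px,
amplitude 500 a.u.) in an exact count `round(fraction × n_cells)` of cells,
so the realized truth is the designed fraction. The reporter channel is
background (20 a.u.) + cytosol (100 a.u.) with the designed enrichment in
the target compartment; the marker channel carries the organelle at
400 a.u. All levels are z-sum arbitrary units; signal is spread over slices
by a mid-stack Gaussian whose weights sum to one, so only the z-sum is
contractually meaningful — matching the pipeline's first step. Noise is the
standard camera model: Poisson on expected photon counts (gain 1) followed
by additive Gaussian read noise (SD 2 a.u.), then clipping at zero.

The generator deliberately omits: optics (no PSF, no defocus blur across z,
no bleed-through — the original acquisitions avoided it with alternating
excitation), vacuoles and other dark organelles, uneven illumination,
autofluorescence texture, cell-cycle shape variation (buds), and 3D truth
(the pipeline is 2D after projection). Passing the recovery suite therefore
shows the *quantification chain* is correct and unbiased under a realistic
noise model; it does not certify performance on real micrographs, where
segmentation is the fragile step.

`generate_chase()` draws per-cell initial intensities lognormally
(CV 0.2), decays them exponentially at a common rate over the 0–40 min
grid sampled every 10 min, and adds multiplicative lognormal instrument
noise (CV 0.05, mean-preserving) to every measurement, including the
per-cell pre-induction background row. The instrument-noise term is what
gives replicate-level curves nonzero variance; without it every replicate's
relative curve is exactly $e^{-kt}$ and replicate t-tests degenerate.

## Numerical choices

- All randomness flows from one explicit seed per spec through a local RNG
  scope that saves and restores the caller's `.Random.seed`; identical
  spec + seed gives bit-identical output, and generation never perturbs the
  session stream. Derived stream seeds stay below 2³¹.
- Degenerate inputs are contracts, not crashes: constant projections raise
  a degenerate-input error (quantile seeds collapse); an image with no
  foreground seeds returns "no cells detected"; an empty mask yields a
  zero-cell label map with a message; empty mitochondrial/nuclear masks
  propagate as excluded rows with reasons.
- Ties are resolved deterministically everywhere: marker suppression and
  punctum deduplication process candidates by decreasing score with
  raster-order tie-breaks; flood assignment prefers the highest-distance
  labeled neighbor in a fixed neighbor order; contradictory random-walker
  seeds resolve to foreground.
- Zero-variance t-tests (possible on synthetic data) return t = 0, p = 1
  for identical groups and p = 0 for separated constant groups instead of
  erroring.
- The vector Otsu threshold maximizes between-class variance over 256 bins
  of the per-cell intensity range and returns the smallest maximizing
  threshold; across an empty intensity gap the criterion is flat, so only
  the induced classification (which matches `EBImage::otsu`) is meaningful.
- 16-bit integer TIFF is the default on-disk representation (native EMCCD
  ADU); float TIFF writing scales by the maximum recorded in a JSON
  sidecar, since baseline TIFF writers carry no description tag.

## Problem sizes

The validation suite runs at the design sizes of the assays it emulates:
segmentation on five 20-cell scenes; spGFP recovery at designed enrichment
2.0 vs 1.0 with 3 biological replicates × 100 cells per group, plus a
20-repeat null (1.0 vs 1.0) for type-I calibration; N/C recovery at true
ratios {1, 1.5, 2, 3} with 3 × 80 cells; aggregate fractions {0.2, 0.5,
0.8} with 3 × 100 cells; chase kinetics at k = 0.06 vs 0.02 min⁻¹ with 4
replicates × 2000 cells. These sizes were chosen to match the cited
experimental designs (3–4 biological replicates; tens to hundreds of cells
per condition; flow cytometry at thousands of cells) while keeping a full
benchmark run around a minute of compute per panel.

## Known limitations

- Quantile seeding assumes a roughly known cell density; very sparse or
  very crowded fields need adjusted seed quantiles.
- The watershed marker radius equals the expected cell radius; strongly
  elongated or budding cells can merge (bud absorbed into mother) or split.
- The annulus cytoplasm definition measures peri-nuclear cytoplasm only; if
  the reporter is compartmentalized elsewhere (vacuole exclusion, plasma
  membrane) the annulus mean is not the whole-cytosol mean.
- The punctum detector's prominence ratio is calibrated on synthetic
  puncta; equivalence to human counting of real Hsp104-GFP foci cannot be
  asserted and is not claimed.
- The log-linear decay fit weights late (low-signal) time points more than
  nonlinear least squares would; with the chase noise model used here the
  difference is negligible, but for strongly heteroscedastic real data a
  weighted or nonlinear fit may be preferable.
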