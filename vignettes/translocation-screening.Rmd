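---
title: "Quantifying nucleocytoplasmic translocation in high-content screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nucleocytoplasmic translocation in high-content screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mk2screen)
```

## The assay and its readout

Stress-activated p38 MAPK signalling can be read out in living cells through
the localization of its substrate MK2: in resting cells an MK2-EGFP fusion is
nuclear-enriched, and pathway activation (e.g. hyperosmotic stress) exposes
MK2's nuclear export signal so the reporter relocates to the cytoplasm.
A p38 inhibitor blocks that export, retaining the reporter in the nucleus.
The quantitative readout per cell is the **nucleocytoplasmic ratio**

$$ r = \frac{\bar I_\text{nuc}}{\bar I_\text{ring}}, $$

the mean background-subtracted reporter intensity over an inner nuclear
region divided by the mean over a perinuclear ring that proxies the
cytoplasm. Wells average this ratio over all cells of all imaged sites
(mean of ratios, not ratio of means). An activated well sits around 0.65;
full inhibition sits near 1.2. A well is called *activated* when its mean
ratio is strictly below 0.7.

This package implements the full desk-scale pipeline around that statistic:
a synthetic plate-image generator with known ground truth, DAPI-based
nuclear segmentation, measurement-region construction, per-cell and
per-well quantification, and the screening statistics used to run and
validate a primary inhibitor screen (plate normalization, Z′, log-Z-scores,
replicate rank concordance, hit calling, benchmark normalization and a
three-concentration validation cascade).

## Segmentation and measurement regions

Nuclei are segmented from the DAPI channel by thresholding at the estimated
constant background plus 656 gray-levels (up to the 16-bit maximum), filling
holes, and separating touching objects with a distance-transform watershed
whose seed spacing derives from the only scale parameter in the protocol,
the approximate object width of 13 µm. Objects outside a 60–355 µm² area
window are removed. These defaults mirror a standard commercial
"translocation-enhanced" application module; the area window is interpreted
in µm² (the module convention) and converted through the pixel size, with a
pixel-unit mode available for other dialects.

Background estimation is a single per-image constant (the histogram mode),
matching the protocol's "auto-constant" method; a fixed value can be
supplied instead. The mode is robust as long as background pixels form the
largest single-intensity class, which holds at the default simulated
confluence (~50–60 % cytoplasm coverage whose intensities spread over many
gray-levels).

Measurement regions per nucleus: the inner region erodes the nucleus by
0.5 µm; the ring is the annulus between dilations by 0.5 µm and 2.5 µm.
Distances are converted to pixel radii rounding to the nearest pixel, never
below 1 px for positive distances (at 0.65 µm/px the defaults become 1 px
erosion and a 1→4 px annulus). Ring pixels falling on any nucleus, or off
the image, are excluded; pixels claimed by several rings go to the nucleus
with the nearest boundary (exact Euclidean distances, computed only over
the contested set). Objects whose inner region erodes below 5 px are
dropped and counted. Nuclei touching the image border are kept but flagged,
and flagged cells are excluded from well means by default: a clipped
nucleus biases both the area filter and the ring geometry.

Two further numerical choices are deliberate:

* **Background subtraction before ratios.** An additive camera offset
  biases every ratio toward 1, shrinking the assay window, so the reporter
  channel's auto-constant background is subtracted (floored at zero) by
  default; it can be disabled.
* **Undefined ratios are dropped, never zeroed.** A cell whose ring is
  empty after collision exclusion, or whose ring mean is zero, is removed
  with a logged count.

## The synthetic plate generator

The generator is first-class, tested code: it emulates adherent
U2OS-like monolayers at high confluence and provides exact per-cell ground
truth, so recovery of a known contrast through the full image pipeline is a
meaningful test of the measurement chain.

Cells are ellipses (nuclear semi-axes uniform on 4.5–7 µm, random
orientation) with a cytoplasm apron extending 5 µm beyond the nuclear
boundary, placed by dart throwing with minimum center separation 0.8 × the
sum of effective nuclear radii — touching nuclei are allowed, which
exercises watershed separation downstream. The semi-axis floor of 4.5 µm
keeps every simulated nuclear area (πab ≥ 63.6 µm²) inside the default
segmentation window. Where cytoplasm aprons overlap, each pixel belongs to
the nearest cell center, so cells tile the field like a confluent monolayer
and each cell's nuclear:cytoplasmic intensity ratio equals its requested
contrast exactly before noise. The default density of 1500 cells/mm² gives
~100 cells per 400×400 px field at 0.65 µm/px, hence ~400 cells over the
4 sites of a well — the throughput regime the assay reports.

Photometry: the reporter's cytoplasmic level is `signal_gain` × a
lognormal per-cell expression factor (log-sd 0.2); the nuclear level is the
cell's contrast times that. The DAPI channel has signal only in nuclei
(mean 5000 gray-levels). The camera adds a constant background of 600
gray-levels, Gaussian read noise of sd 30, and optional Poisson shot noise,
then clamps to 16 bits. The background default sits just below the 656
gray-level threshold offset so the default segmentation parameters remain
meaningful. Per-well phenotypes: negative controls at ratio 0.65,
positive controls at 1.19 (the two printed reference phenotypes of the
assay), compound wells on a Hill dose-response between those anchors; each
well's expected ratio is perturbed by an additive Normal(0, 0.03) well
effect, and per-cell contrasts vary lognormally (mean-one, log-sd 0.1)
around the well value. The truth table records every placed cell, and the
per-well expected ratio is defined as the mean of the per-cell contrasts
actually placed.

What the generator does **not** model: illumination gradients,
photobleaching, time-lapse kinetics, 3D structure, debris and imaging
artifacts, mitotic/apoptotic morphologies, or intensity-dependent
segmentation failures. Passing tests therefore demonstrate correctness of
the measurement and statistics chain under a faithful geometric/photometric
model — not robustness to every pathology of real microscopy.

### Screen-level simulation

For screen-scale statistics a tabular fast path draws one true ratio per
compound and two noisy replicate observations. Its defaults emulate a
combinatorial library deliberately enriched for inhibitors of the target:
40 % of compounds carry some true activity with potencies spanning orders
of magnitude (IC50 lognormal around 50 µM, log-sd 2.5), screened at 15 µM;
inactive compounds keep a reproducible compound-level spread of sd 0.06
around the activated baseline (autofluorescence, mild toxicity, weak
off-target effects), and biological-duplicate noise is sd 0.02 on a well
mean. These values were calibrated once against the assay's two printed
screen-level facts — roughly a tenth of the library above a raw ratio of 1,
and duplicate rank concordance R² above 0.85 — and then frozen; a
two-point active/inactive mixture cannot reproduce the observed graded
continuum of sorted well ratios, which is why potency dispersion, not a
tight potent cluster, is the default.

## Screening statistics

* **Plate normalization** divides each valid well's mean ratio by the
  plate mean, so normalized ratios average exactly 1; it is idempotent.
* **Z′** = 1 − 3(σ_pos + σ_neg)/|µ_pos − µ_neg| with sample SDs over
  control wells; > 0.5 indicates a robust assay window. Equal control
  means return an `NA` sentinel with a warning rather than a value.
* **Log-Z-score**: the protocol names the statistic without a formula; it
  is implemented here as the z-score of log(normalized ratio) against the
  negative-control wells, i.e.
  (log r − mean log r_neg)/sd(log r_neg) — an interpretation, documented
  as such.
* **Rank–rank R²**: squared Pearson correlation of within-replicate ranks,
  ties mid-ranked; invariant under monotone transforms and sign-blind.
* **Hit calling**: compounds whose replicate-mean normalized ratio exceeds
  1 strictly, sorted descending. The threshold applies to normalized
  ratios by default (the screen normalizes before analysis); a raw-ratio
  mode is available.
* **Validation cascade**: hits are re-tested in duplicate at 1500, 150 and
  15 nM; a compound passes a concentration when its replicate-mean ratio
  exceeds 0.95. The validation rate is the passing fraction at the highest
  concentration; the shortlist contains those passers ranked by their
  ratio at the lowest concentration, where only the most potent compounds
  remain elevated. Compounds missing from a concentration's tables are
  flagged and excluded from that denominator; compounds missing one
  replicate are excluded from the replicate mean.
* **Benchmark normalization** expresses ratios relative to a reference
  inhibitor at the same concentration (the benchmark becomes 1), skipping
  concentrations where the benchmark is absent.

## Worked example

```{r example, eval = FALSE}
library(mk2screen)

# one control plate, images rendered for 2 wells to keep this quick
map <- plate_map("P1", c("A01", "A02", "B01", "B02"),
                 c("neg_ctrl", "neg_ctrl", "pos_ctrl", "pos_ctrl"))
cfg <- run_config(min_cells = 20, n_sites = 2)
plate <- simulate_plate(map, seed = cfg$seed, n_sites = 2, dim = c(200, 200))
run <- run_screen(cfg, plate = plate)
run$wells[, c("well", "n_cells", "mean_ratio", "normalized_ratio", "activated")]
run$zprime

# screen-level statistics on the tabular path
sc <- simulate_screen(3362, seed = 1)
rank_rank_r2(sc$replicates[[1]], sc$replicates[[2]])
hits <- call_primary_hits(sc$replicates[[1]], sc$replicates[[2]],
                          value = "mean_ratio")
nrow(hits)
```

## Problem sizes and reproducibility

The package's own validation (the test suite and `scripts/acceptance.R`)
uses 400×400 px fields (~100 cells each), four sites per well for
well-level claims, 100 seeded control plates for the Z′ summary, and a
3362-compound duplicate screen for concordance — sizes chosen to match the
assay's reported throughput while remaining comfortable on a laptop CPU
(the full image pipeline runs at roughly a second per field). Every
stochastic step accepts an integer seed, and identical seeds reproduce
images and tables bit-for-bit.

## Known limitations

* The ring proxies the cytoplasm; there is no whole-cell segmentation, so
  in very sparse fields the ring can sample background if cells shrink
  below the ring's reach (not the case at default geometry).
* The watershed uses a single scale parameter; strongly size-heterogeneous
  nuclei populations may over- or under-split.
* The incubation-time course of the assay is metadata only; the simulator
  renders the fixed endpoint state.
* No dose-response curve fitting is provided: the validation cascade
  reports ratios at three concentrations, as the assay does.
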