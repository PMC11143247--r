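---
title: "Methods: colony-array riboswitch screens and reporter kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colony-array riboswitch screens and reporter kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riboscreen)
```

## Overview

`riboscreen` analyzes fluorescent-reporter screens on high-density
pinned colony arrays, where the reporter is a riboswitch-controlled
transcriptional fusion: an OFF switch whose fluorescence falls when the
sensed ligand (here TPP, thiamin pyrophosphate) is abundant. The
pipeline runs

image pair → per-colony integrated intensities → fluorescence/biomass
ratio → spatial correction → replicate combination → control
normalization → expression index → hit calls,

with a parallel module for plate-reader fluorescence/OD kinetics. A
synthetic-data generator with planted ground truth backs every stage's
tests. This vignette records the models, the defaults and why they were
chosen, and what the synthetic validation does and does not show.

## The observable: integrated intensity and the ratio

Each colony is measured as the **sum** of background-subtracted pixel
values in a square ROI centred on its grid node (side 0.8 × pitch). A
sum — not a mean — scales with both per-pixel brightness and colony
area, so it tracks total reporter output and total biomass. The screen's
base observable is the per-colony ratio

$$r_{ij} = \frac{\text{fluorescence sum}_{ij}}{\text{biomass sum}_{ij}},$$

which cancels colony-size variation: pinning and growth fluctuations
move both sums together, and dividing removes the shared part. Empty
positions are removed, and colonies with biomass below 10% of the plate
median (`growth_floor = 0.1`) are excluded as failed pinnings — low
enough to keep genuinely slow growers, high enough to drop positions
where the ratio would be dominated by background noise. Excluded
colonies propagate as missing values with a reason, never as zeros.

## Background estimation

On a 1536-density array, colonies and their tails cover most of the
image, so a plain large-window median filter sits partly on colony
light and over-subtracts in a spatially varying way — measured against
planted truth, it degraded the zero-noise biomass/planted correlation
to ~0.95. The default estimator instead takes the **10th percentile of
overlapping window-sized blocks** (window = 3 × colony diameter) and
interpolates the block grid bilinearly: the low quantile lands on the
inter-colony floor even where colonies dominate a block. The EBImage
median filter remains available (`method = "median"`) for sparser
arrays. On planted planar backgrounds the default recovers the plane
within 2% on colony-free pixels.

## Grid fitting

Robot-pinned arrays are rigid, so rather than segmenting colonies
individually the grid is fitted globally: row/column projection
profiles of the background-subtracted white-light image are matched
against a comb of node positions by a two-stage search over origin and
pitch around the configured geometry. On synthetic plates the fitted
pitch is within 0.2 px and a planted translation is recovered within
1 px. If fewer than 25% of the fitted nodes show signal above the
background level, grid detection fails loudly rather than returning
garbage measurements.

## Spatial (edge-effect) correction

Border and incubator gradients inflate or deflate colonies near plate
edges. The correction divides each ratio by a robust low-frequency
trend surface and rescales so the per-plate median of corrected ratios
is exactly 1. The default surface is a **robust local-quadratic loess**
on log-ratios (`family = "symmetric"`, neighbourhood ≈ `smooth_window`²
= 81 grid cells):

* the bisquare reweighting keeps isolated biological outliers (hits)
  out of the trend — a planted 3× outlier on a flat plate survives the
  correction essentially unchanged;
* the local polynomial tracks the steep monotone ramp at the plate
  border. A 2D running median (kept as `method = "median"`) is equally
  robust to hits but its shrinking one-sided window under-corrects the
  outermost rings: against a planted 1.5× border gradient it left a
  residual border/centre contrast of ~1.2 and a corrected-ratio vs.
  edge-distance |Spearman| of ~0.12, versus ~0.005 for the loess
  surface.

Applying the correction twice changes the typical (median) corrected
ratio by under 1%; worst-case changes of a few percent at plate corners
are inherent to any local estimator at 10% measurement CV.

## Control normalization and hit calling

Fluorescence variation unrelated to ligand sensing — plasmid copy
number, strain-specific expression, reporter artifacts — is removed by
running the identical screen with a binding-site point mutant (G31C)
that cannot sense the ligand, and forming the per-strain ratio of
replicate means, recentred at a median of 1:

$$\text{index}_s = \frac{\overline{WT}_s / \overline{G31C}_s}
{\mathrm{median}_s\left(\overline{WT}_s / \overline{G31C}_s\right)}.$$

The per-strain (not plate-wide) ratio is used because it is the only
reading that cancels strain-specific artifacts: a mutant that halves
reporter-plasmid replication halves both screens and lands at index 1.
Duplicated positions are averaged within each replicate before any
cross-replicate statistics; the duplicate pairs themselves are reported
unaveraged as an internal concordance control. Strains missing on
either side are reported as unscored, never silently dropped. The
median (not mean) recentring keeps heavy one-sided hit tails from
shifting the centre.

Hits are strains with index beyond $1 \pm k \cdot SD_{pop}$, default
$k = 5$, ties included. Because the sensor is an OFF switch the
direction map is fixed: `HIGH_FLUOR` ⇒ low ligand, `LOW_FLUOR` ⇒ high
ligand. $SD_{pop}$ is estimated **robustly** (median/MAD of the full
index distribution). A classical SD with hits included is available
(`sd_method = "sd"`) but is not the default: two dozen planted hits at
3–6× inflate the plain SD about 2.5-fold, pushing the lower threshold
$1 - 5\,SD$ negative so that no fluorescence-down hit could ever be
called — the robust scale estimates the null width the threshold is
meant to refer to. Under the null the expected false-positive count at
$k = 5$ over 3800 strains is $3800 \cdot 2\Phi(-5) \approx 0.002$.

## The synthetic screen generator

`screen_truth()` + `simulate_screen()` emulate the screen's statistical
structure; defaults are the study conditions:

| parameter | default | meaning |
|---|---|---|
| grid | 32 × 48 × 3 plates | 1536-density, ~3800 strains + 402 duplicates |
| replicates | 3 | biological replicates per reporter |
| `n_high`, `n_low`, `n_artifact` | 22, 4, 10 | planted fluorescence-up (≥3×), -down (≤0.4×), and shared-artifact strains |
| `edge_amplitude` | 1.5 | border gradient of the fluorescence/biomass ratio |
| `gradient_amplitude_biomass` | 1.2 | border gradient of biomass alone |
| `noise_cv` | 0.10 | per-colony lognormal technical noise |
| `strain_cv` | 0.35 | strain-to-strain baseline expression spread |

Three generator choices deserve explanation:

* **Shared colony-size noise.** The pinning/size fluctuation is drawn
  once per colony and applied to both channels (a colony's integrated
  fluorescence physically scales with its biomass); an independent
  expression-noise factor (same CV) applies to fluorescence only. The
  ratio therefore carries one noise CV, which is the entire point of
  the fluorescence/biomass observable. With three replicates this gives
  per-strain CVs of ~0.1/√3 per reporter and an index MAD of ~0.08 —
  so 0.4× planted LOW hits sit ~7 robust SDs below centre and are
  reliably callable.
* **Gradient structure.** The biomass channel carries its own growth
  gradient (1.2× at the border); the fluorescence channel carries that
  same gradient times the `edge_amplitude` factor. The biomass part
  cancels in the ratio, leaving a ratio gradient of exactly
  `edge_amplitude` — had the identical gradient been applied to both
  channels it would cancel completely and there would be nothing for
  the spatial correction to do. The gradient is a half-cosine ramp of
  the Chebyshev distance to the nearest edge, decaying to 1 four
  rows/columns inward; the true empirical shape of real incubator
  effects is unpublished, so this profile is a declared stand-in.
* **Strain baseline spread** (`strain_cv = 0.35`) models reporter
  expression heterogeneity across deletion strains (copy number,
  growth-coupled expression). It is shared between reporters, so it
  cancels in the index but dominates the replicate-to-replicate Pearson
  correlation within a reporter (~0.9 at these settings), as a real
  reproducible screen shows.

Colonies are rendered as Gaussian disks whose integrated intensity
equals the planted total exactly and whose radius scales with √biomass,
on a flat or planar background with additive read noise, quantized to
the bit depth. The profile is kept inside the half-pitch so neighbouring
ROIs see essentially no cross-talk. Screen-scale simulations skip pixel
rendering by default (`render = FALSE`) and emit the planted totals as
measurements directly — the statistical structure downstream is
identical, and the image route is exercised end-to-end on single plates
in the tests.

What the generator does **not** emulate: colony morphology variation,
agar texture, merged/overlapping colonies, pinning failures beyond the
biomass floor, plate-to-plate batch effects, or competition between
neighbours. Passing tests demonstrate the pipeline's correctness under
the declared noise model, not robustness to those phenomena.

## Kinetics

Growth is logistic, $OD(t) = K/(1 + ((K - od_0)/od_0)e^{-rt})$, and
reporter fluorescence accumulates proportionally to instantaneous
biomass under Hill-type ligand repression:

$$\frac{dF}{dt} = \alpha \, OD(t)\left[\ell + (1-\ell)\left(1 -
E_{max}\frac{c^{n}}{K_{1/2}^{n} + c^{n}}\right)\right].$$

Because the repression factor is constant in time at fixed ligand, the
fold regulation (reference over condition) of $F/OD$ equals
$1/(1 - E_{max}(1-\ell)\,h(c))$ at every time point — 2.0 at saturating
ligand for the defaults $E_{max} = 0.5$, $\ell = 0$, matching a ~2-fold
OFF switch. Defaults: $od_0 = 0.02$, $K = 0.8$, $r = 0.9\,h^{-1}$
(inflection near 4 h, derived — not free — from $od_0, K, r$),
$K_{1/2} = 100$ nM, 10-min sampling to 16 h, OD noise SD 0.005.

Analysis choices:

* **Blank correction** subtracts the time-matched median of blank
  wells from every reading, clipping at 0; it errors when no blanks are
  present rather than guessing an offset.
* **Exponential midpoint** is the first time blank-corrected OD crosses
  half of its amplitude, linearly interpolated — for a symmetric
  logistic started near zero this is the inflection time. "Amplitude"
  is measured robustly (5–95% spread) so a flat well raises a
  phase-detection error instead of returning a noise crossing. The
  readout is a single interpolated point, not a window average
  (a ±2-sample smoothing option exists but defaults off).
* **F/OD** is undefined below an OD floor of 0.02 to avoid blank-noise
  blow-up; the stationary readout is at 16 h.
* **Fold regulation** normalizes to the no-ligand reference (reference
  row exactly 1); the dose–response summary reports maximal repression,
  the lowest concentration reaching 90% of it, a log-interpolated
  half-repression concentration, and a count of isotonic violations.
  A response with maximal repression under 5% is reported as flat, with
  the saturation and half-repression fields undefined.

## Problem sizes and determinism

All randomness flows from a single integer seed per generator call
(sub-seeds derived per plate/replicate), so identical seeds reproduce
maps, images, curves and output bundles byte for byte; run manifests
record parameters and MD5 hashes of every artifact. The test and
acceptance workloads use three-plate, 3800-strain screens at
measurement level (seconds per seed) and single rendered 1536-position
plates for the image path (~15 s each) — sizes chosen so the complete
validation runs comfortably on one CPU while exercising the full-scale
geometry.

## Known limitations

* Channel registration is assumed (same imaging session); only the ROI
  margin absorbs small misalignments, and there is no cross-timepoint
  registration.
* The loess trend cannot separate a *biological* spatial pattern (e.g.
  a whole border row of true hits) from a technical gradient; the
  duplicate-concordance and heatmap QC outputs exist to catch such
  patterns by eye.
* The robust SD assumes the null bulk dominates the index distribution;
  a screen where most strains respond would need an external null.
* Saturated colonies are flagged (>5% full-scale pixels) but not
  corrected; quantification above saturation is censored, not modelled.
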