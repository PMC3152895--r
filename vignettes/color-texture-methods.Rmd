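---
title: "Color-space texture analysis of liver fibrosis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Color-space texture analysis of liver fibrosis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

Histological texture analysis is conventionally performed on grey-scale
images, i.e. on a luminance projection of the acquired RGB micrograph. For
trichrome-stained liver, however, the pathological component — collagen
deposited in the extracellular matrix during fibrosis — is selectively
colored by the stain, so projecting to luminance mixes the collagen-specific
channel with the others. `fibrotex` quantifies what that projection costs:
it classifies normal (C) versus fibrotic (F) liver ROIs from texture
features computed in three schemes — `greylevel`, `RGB` (channels pooled),
`HSI` (channels pooled) — at three resolutions, and reports per-group
percentage error for every scheme × resolution × texture-method cell.

## Pipeline model and assumptions

**Geometry.** Native images are 680 columns × 512 rows, 24-bit RGB. Half and
quarter resolution are produced by 2×2 and 4×4 block-mean averaging with
half-up rounding. Block averaging (rather than decimation) was chosen
because it emulates optical resolution loss without aliasing; the
composition invariant (half∘half = quarter to within 1 grey level) is
tested. Each image is split into four equal non-overlapping ROIs on a 2×2
grid after trimming a configurable border margin (default 0.05 per side,
honoring "avoid boundaries"); odd leftover rows/columns are dropped at the
far edge. Coordinates are row-major, origin top-left.

**Color spaces.** Luminance uses the BT.601 weights (0.299, 0.587, 0.114);
the source text does not print its formula, only that the most common
technique was used, which is this one — the weights are an argument of
`rgb_to_grey()` should a different convention be needed. HSI follows the
standard conversion: I = (r+g+b)/3, S = 1 − 3·min(r,g,b)/(r+g+b), H the
arccos form with the b ≤ g branch, H ≔ 0 for achromatic pixels, and the
arccos argument clamped to [−1, 1]. Texture engines need integer grey
levels, so H is mapped linearly from [0, 360) and S, I from [0, 1] onto
[0, 255] before normalization; this makes all seven channel views
commensurate. How the original analysis scaled H is unknown — this mapping
is this package's choice.

**Normalization.** Every channel ROI is normalized independently: clip to
μ ± 3σ (σ the population standard deviation over the ROI), map linearly to
[1, 128], round half-up; a constant ROI maps to 64. This gives exact
invariance under affine intensity changes v → a·v + b (a > 0) when the clip
is not engaged, which is the point: illumination differences between slides
must not masquerade as texture. Whether the original study normalized before
or after channel separation is unstated; per-channel normalization is the
only order consistent with treating each channel as an independent
grey-scale layer.

**Co-occurrence features.** The matrix counts ordered horizontal neighbor
pairs (d = 1, θ = 0°) and is symmetrized — the classical convention, which
makes the marginal means equal and the correlation statistic well defined.
Whether the original software symmetrized is not documented; this is our
choice, not a claim about that software. All 11 statistics use natural
logarithms (the log base rescales entropies monotonically and cannot change
a Fisher ranking). Correlation of a single-level ROI is defined as 0. The
full 128-level support is kept; absent levels contribute zero rows/columns.

**Run-length features.** Runs are maximal constant segments along the scan
lines of each direction (0°, 45°, 90°, 135°); every diagonal line is
scanned, single-pixel corners contributing runs of length 1. The five
statistics per direction are pooled with direction-prefixed names
("Horizontal Greylevel Non-uniformity", "45° Fraction", …), so each
direction contributes its own five parameters, matching the naming of the
reported feature tables.

**Wavelet energies.** The decomposition is separable orthonormal Haar — the
family is not documented in the source, and Haar was chosen because it is
the convention of the software lineage involved and is exactly testable by
Parseval's identity (verified to 1e-8 in the tests). E_n pools the three
detail subbands of level n and divides by the coefficient count, so energies
are comparable across scales; one E_n per scale matches the reported feature
tables (which never show per-subband values). Odd dimensions are truncated,
never padded, because padding injects artificial edges into texture energy.
Depth defaults to floor(log2(min(rows, cols))) − 1, capped at 5 — consistent
with scale-5 features being reportable at full resolution and only E_1..E_3
at quarter resolution.

**Feature selection.** The Fisher coefficient is computed as
F = (m_C − m_F)² / (v_C + v_F) with unbiased sample variances — the exact
form used originally is not printed; this is the standard two-class
reduction of between- over within-class variance. Zero pooled variance with
distinct means yields an infinite-separability sentinel that sorts first.
Ties break by column order, making selection deterministic. Selection is per
(scheme, resolution, method) cell, k = 3, and k is hard-limited to the
smaller class size (the over-fitting precaution stated with the design).

**Classification.** The original "unsupervised" raw-data procedure is not
named; k-means with k = 2 on per-column standardized features (10 restarts,
fixed seed) is the minimal procedure consistent with points clustering
independently without class knowledge. Standardization matters because the
three selected features can differ by orders of magnitude (entropies vs.
variances). Clusters are mapped to classes by minimizing total
misclassification — labels enter only at scoring. A leave-one-out 1-NN mode
(`classifier = "1nn-loo"`) is provided for sensitivity analysis only. With
all points identical, the partition degenerates to one cluster and the
minority group scores 100% error.

## The synthetic world

No image from the source study is deposited, so the generator fabricates
what the pipeline needs: Masson's-trichrome-like liver fields with a
controllable fibrosis severity.

* Background: per-channel Gaussian noise (sd 18) around a pinkish cytoplasm
  palette RGB (190, 150, 170), blurred to a correlation length of σ = 2.5 px
  and rescaled to keep the stated contrast — stationary correlated noise
  rather than explicit cell rendering, because texture statistics, not
  morphology, are what the pipeline consumes.
* Nuclei: 160 filled disks per image, radius 2–5 px, dark blue-purple
  (70, 55, 110), present identically in both classes.
* Collagen (fibrosis only): λ = 20 random-walk strands (step 2 px, angular
  jitter sd 0.22 rad, width 4 px, 150–450 steps), blended at α = 0.8 with a
  light-green palette (175, 215, 170).

The collagen palette deserves a note, because it determines *which channel
carries the class signal*. After per-channel normalization, a channel
discriminates to the extent that collagen structures stand out against the
background relative to that channel's noise. We model the light-green
counterstain variant of the trichrome stain: collagen's red and blue
reflectance is close to the pink cytoplasm's (shifts of −15 and 0 after
blending) while green differs strongly (+65, ≈3.6 noise sd). This is the
physical mechanism by which green-channel features dominate the Fisher
rankings — and mirrors why the green channel dominates on real trichrome
sections, where collagen is the only structure whose green reflectance
departs from its surroundings. With a blue-aniline trichrome variant the
signal would move to the B channel; the palette is a config field precisely
because it is a property of the staining protocol, not of the method.

Image i of a dataset uses seed `master + i`, so any image is regenerable in
isolation; generation restores the caller's RNG state.

**What a green test does and does not establish.** The synthetic world
reproduces the *structure* of the study (image sizes, group sizes 5 + 7, ROI
counts 20/28, resolution chain) and the *qualitative* findings (RGB-scheme
error ≤ greylevel-scheme error at quarter resolution; green-channel majority
among selected RGB features, 10/10 seeds at the measured defaults). It does
not reproduce — and the tests do not claim — the absolute error percentages
of the original figure, which depend on real histology: collagen
heterogeneity across animals, nonstationary illumination, vessels and
artifacts are all absent here. Absolute errors on synthetic data (roughly
0–30% per cell at quarter resolution) are properties of the generator's
noise settings, nothing more.

## Numerical choices and degenerate inputs

* Rounding is half-up (`floor(x + 0.5)`) everywhere integers are produced,
  so results do not depend on banker's-rounding platform quirks.
* 0·log 0 ≡ 0 in all entropy sums.
* Normalization of a constant ROI → all 64; correlation of a single-level
  COM → 0; Fisher of a constant feature → 0, and → Inf when classes are
  exactly separated with zero variance.
* k-means ties in cluster-to-class mapping resolve to the first (C-first)
  mapping; Fisher ties resolve by column order.
* The BMP codec covers exactly the uncompressed 24-bit BI_RGB layout of the
  acquisition format (no pre-installed R package reads BMP); PNG I/O uses
  the png package. Anything else is rejected with an error naming the
  offending property.

## Known limitations

* Only d = 1, θ = 0° co-occurrence, as studied; no multi-distance or
  direction-averaged variants.
* No color spaces beyond the three compared; no stain deconvolution.
* The HSI hue channel is an angle; its linear [0, 255] quantization tears
  the circular topology at 0°/360°. For the pinkish/green palettes used the
  hues cluster away from the tear, but images dominated by reds near the
  wrap-around would alias hue texture.
* The unsupervised error is a property of one k-means solution under a fixed
  seed with 10 restarts; it is reproducible, but not a cross-validated
  generalization estimate.
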