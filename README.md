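# fibrotex

Texture analysis of liver histology compares **color spaces** — conventional
grey-scale luminance, the separated R/G/B channels, and H/S/I — for
automated classification of normal versus fibrotic tissue, and asks how the
comparison changes as image **resolution** drops. In trichrome-stained liver,
fibrosis appears as strands of collagen deposited in the extracellular
matrix; because the stain renders collagen green, the texture that separates
the two classes is expected to live chiefly in the green channel, and a
color-aware scheme should degrade more gracefully at low resolution than the
luminance projection. `fibrotex` implements that comparison as a reusable,
tested pipeline, with a synthetic generator of trichrome-like liver images
standing in for undeposited microscope data.

## The pipeline

For each image (native 680×512, 24-bit RGB) and each resolution (full, half
= 340×256, quarter = 170×128, by block-mean reduction):

1. **ROIs** — the image is split, after trimming a border margin, into four
   equal non-overlapping regions of interest (so 5 control + 7 fibrosis
   images give 20 C and 28 F ROIs per resolution).
2. **Channels** — each ROI is viewed in one of three schemes: `greylevel`
   (Y = 0.299 R + 0.587 G + 0.114 B), `RGB` (R, G, B as separate grey-scale
   layers), or `HSI` (hue/saturation/intensity, re-quantized to 0–255).
3. **Normalization** — every channel ROI is clipped to μ ± 3σ and quantized
   to 7 bits (grey levels 1–128), removing brightness dependence.
4. **Texture parameters** — three families per channel:
   - *COM*: grey-level co-occurrence matrix at d = 1, θ = 0°, with the 11
     classical Haralick statistics (angular second moment, contrast,
     correlation, entropy, sum of squares, inverse difference moment, sum
     average, sum variance, sum entropy, difference variance, difference
     entropy);
   - *RLM*: run-length matrices in the four directions 0°/45°/90°/135°,
     each contributing short/long run emphasis, grey-level and run-length
     non-uniformity, and run fraction;
   - *WT*: orthonormal Haar wavelet energies E_n (mean squared detail
     coefficient over the LH/HL/HH subbands at scale n).
5. **Feature selection** — parameters of one method are pooled per scheme
   (channel-prefixed names such as `G_Sum Variance`), ranked by the Fisher
   coefficient F = (m_C − m_F)² / (v_C + v_F), and the top 3 become the
   features of that (scheme, resolution, method) cell.
6. **Classification** — ROIs are clustered unsupervised (k-means, k = 2, on
   standardized features) in the 3-D feature space; clusters are mapped to
   classes by minimum total misclassification and the per-group
   **percentage error** (100 × misclassified / group size) is reported.

## Worked example

```r
library(fibrotex)
ds  <- generate_dataset(synthetic_config(seed = 1))   # 5 C + 7 F images, 512x680
res <- run_experiment(ds$images, schemes = c("greylevel", "RGB"),
                      resolutions = "quarter", seed = 1)
print(res)
#> <experiment_result>
#>     scheme resolution method % error C % error F
#>  greylevel    quarter    COM         0 14.285714
#>  greylevel    quarter    RLM         0 17.857143
#>  greylevel    quarter     WT        30 14.285714
#>        RGB    quarter    COM         0 10.714286
#>        RGB    quarter    RLM         0  7.142857
#>        RGB    quarter     WT        20  7.142857
subset(res$features, scheme == "RGB" & method == "RLM")
#>    scheme resolution method rank                               feature        F
#> 13    RGB    quarter    RLM    1       G_135° Greylevel Non-uniformity 7.835639
#> 14    RGB    quarter    RLM    2 G_Horizontal Greylevel Non-uniformity 7.143877
#> 15    RGB    quarter    RLM    3   G_Vertical Greylevel Non-uniformity 7.097604
```

Reading this: at quarter resolution the RGB scheme misclassifies 2/28
fibrosis ROIs with the run-length method (7.1% F-group error, 0% C-group)
versus 5/28 (17.9%) for grey scale, and all three selected RLM features come
from the green channel — collagen texture drives the separation. Each
`% error` row is a Figure-3-style bar; `res$features` is the analogue of the
selected-feature tables.

The same grid is scriptable:

```sh
inst/exec/fibrotex generate --out data/ --seed 1
inst/exec/fibrotex run --input data/ --out-errors errors.csv --out-features features.csv
inst/exec/fibrotex plot --errors errors.csv --out figure.png
```

## Limitations

The synthetic generator produces stationary correlated-noise cytoplasm with
dark nuclei and green-dominant collagen strands; it emulates the texture
statistics the pipeline consumes, not real histology. Absolute error
percentages are therefore not comparable with values measured on microscope
images — only the structural results and the qualitative scheme ordering
are. See `vignettes/color-texture-methods.Rmd` for the full methods account.
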