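# fiborient

Quantitative fiber-organization analysis for grayscale micrographs, built
around intensity-gradient orientation statistics. The motivating application
is label-free second-harmonic-generation (SHG) imaging of collagen in the
corneal stroma, where the degree of lamellar order carries diagnostic
information (keratoconus, cross-linking treatment, wound healing), but the
method applies to any image of quasi-parallel fibrous texture.

## The method

For an image `I(i, j)` normalized to unit maximum, the pipeline has four
stages:

1. **Gradient field.** The intensity gradient is estimated at resolution
   `R`: each component is the centered intensity change over a span of `R`
   pixels on either side, divided by the span, averaged over `R` adjacent
   parallel lines. `R = 1` is the plain pixel-to-pixel difference; larger
   `R` averages more single-pixel changes, suppressing the spurious
   0/45/90/135° orientation ties that integer photon-count noise produces.
2. **Folding.** A bright fiber produces antiparallel gradients on its two
   flanks (a fiber at 45° yields gradients at 135° and −45°). Directions are
   folded onto the half-plane `(0, 180]` so both flanks reinforce one
   orientation, perpendicular to the fiber axis.
3. **Orientation PDF.** Vectors with magnitude below a threshold `T`
   (typically 10% of the maximum magnitude) are discarded; surviving folded
   orientations are binned into `180/B` half-open bins of width `B` degrees
   and converted to a per-degree probability density with exact unit area.
4. **Model fit.** The density is fitted by bounded nonlinear least squares
   to a sum of `k` Gaussians over a constant pedestal,

   ```
   PDF(θ) = Σₖ aₖ · exp( −(θ − bₖ)² / (2 cₖ²) ) + d
   ```

   where `bₖ` is a dominant fiber-normal orientation, `cₖ` its angular
   spread, `aₖ` its height above the pedestal `d` (the structureless /
   noise fraction). The model order `k` is the smallest one whose R² is
   within a tolerance of the best attained (`select_k()`).

Derived order metrics: per-component Gaussian areas `aₖ·cₖ·√(2π)`, pedestal
area `d·180`, their ratio (structure vs. noise), pairwise peak separations
`|bⱼ − bᵢ|`, and for time series the composite peak-height-to-width ratio
`(a + d)/c` with an R² threshold flag — rising R² and falling width signal
recovery of fiber order.

Because real SHG data are rarely public, the package ships deterministic
phantom generators with exact ground truth: oriented (optionally wavy)
sinusoidal fiber gratings, patch-composed multi-family textures,
integer-valued photon-count noise fields, and a direct sampler from the
Gaussian-plus-pedestal density.

## Worked example

Analyze a wavy 45° fiber phantom with photon-count noise:

```r
library(fiborient)

spec <- phantom_spec(
  size = c(256, 256),
  families = list(list(orientation = 45, period = 12, amplitude = 1,
                       waviness = 8)),
  noise = "poisson", noise_mean = 30, background = 0.1, seed = 7)
img <- make_fiber_image(spec)

res <- analyze_image(img, R = 2, t_fraction = 0.10, B = 5)
print(res)
#> <fiber_analysis> R = 2, T = 0.01976, B = 5
#> <gauss_pedestal_fit> k = 1, R^2 = 0.9930
#>               a     b     c
#>   comp1 0.02116 135.2 13.99
#>   pedestal d = 0.001435, shift applied = -45 deg
#> <order_metrics> k = 1 | Gaussian area 0.7418 | pedestal 0.2582 | ratio 2.873 | R^2 0.993
```

Reading the output: order selection chose a single Gaussian (`k = 1`); the
fitted center `b = 135.2°` is the fiber normal — perpendicular to the 45°
fiber axis, as folding dictates; the width `c ≈ 14°` reflects the 8° angle
waviness plus noise broadening; the Gaussian area 0.74 vs. pedestal area
0.26 says about three quarters of the gradient vectors belong to oriented
structure (`ratio 2.87`), and `R² = 0.993` marks a well-ordered texture.

The same pipeline runs from the shell:

```sh
Rscript inst/cli/fiborient.R simulate --spec my_phantoms.json --out phantoms/
Rscript inst/cli/fiborient.R analyze --input phantoms/ --out results/ \
    --resolution 2 --t-fraction 0.1 --binning 5 --k-max 3
Rscript inst/cli/fiborient.R analyze --input series_dir/ --out series_out/ --series
```

`analyze` writes, per image: a color-mapped orientation PNG, a per-pixel
orientation CSV, the PDF CSV with a JSON parameter sidecar, the fitted model
JSON, and a metrics CSV; `--series` adds a longitudinal panel CSV with the
R², height, width and composite metrics per time point.

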