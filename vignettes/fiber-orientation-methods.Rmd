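---
title: "Quantifying fiber organization from gradient-orientation distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying fiber organization from gradient-orientation distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiborient)
```

## The model

An elongated bright fiber in a grayscale micrograph produces intensity
gradients perpendicular to its axis, on both flanks and with opposite signs.
Folding every gradient direction onto the half-plane $(0, 180]$ makes the
two flanks reinforce a single *orientation*, so the distribution of folded
gradient orientations is a direct statistical readout of how the fibrous
texture is organized. `fiborient` summarizes that distribution with a
parametric model: the binned, unit-area orientation probability density is
fitted to a sum of $k$ Gaussian components over a constant pedestal,

$$\mathrm{PDF}(\theta) \;=\; \sum_{k} a_k
  \exp\!\left(-\frac{(\theta-b_k)^2}{2c_k^2}\right) + d .$$

Each component is one family of quasi-parallel fibers: $b_k$ its dominant
gradient orientation (the fiber normal), $c_k$ its angular spread, $a_k$ its
density height above the pedestal. The pedestal $d$ absorbs the fraction of
gradient vectors with no preferred orientation — noise and structureless
image regions. The assumptions are mild but worth stating: fibers are
locally linear at the gradient scale, families are few (the package caps
order selection at $k_{\max} = 3$ by default), and angular spreads are
narrow enough that an untruncated Gaussian on the line is an adequate stand-in
for a circular distribution (see *Limitations*).

## The gradient operator

The resolution parameter $R$ controls how many pixels the derivative
estimate averages over. The package computes, at each interior pixel,

$$g_x(i,j) = \frac{1}{R}\sum_{m}
   \frac{I(i+m,\,j+R) - I(i+m,\,j-R)}{2R},$$

and symmetrically for $g_y$, with the $R$ transverse offsets $m$ centered on
zero. Two design choices deserve explanation.

*Centered, not one-sided, spans.* The centered span difference divided by
$2R$ telescopes into the mean of the $2R$ one-pixel differences across the
span, so it is literally the per-pixel intensity change averaged along the
span. A one-sided (forward) difference would share the anchor pixel
$I(i,j)$ between $g_x$ and $g_y$, positively correlating the two components
on noise; on iid noise that correlation visibly inflates the $45°$
orientation bin and suppresses $135°$. The centered stencil keeps $g_x$ and
$g_y$ disjoint and the noise response symmetric in all four tie
orientations.

*Transverse averaging.* Averaging the span difference over $R$ adjacent
parallel lines is what makes $R$ effective against quantization ties: for
iid noise a bare span difference has the same value distribution at every
$R$, so the spurious spikes at $0/45/90/135°$ (exact integer ratios of
$g_y/g_x$ in photon-count images) would never fade. With transverse
averaging each component becomes a mean of $R$ independent differences, the
exact-tie probability drops roughly as $1/R$, and the spike bins regress to
their surroundings by $R = 3$ — the behavior the package's acceptance tests
lock in.

The valid region excludes the $R$-pixel border on all sides. Zero-magnitude
pixels carry no orientation (`atan2(0, 0)` is undefined) and are excluded
before thresholding.

## Parameters

| Parameter | Meaning | Default | Rationale |
|---|---|---|---|
| `R` (px) | gradient averaging span | 2 | suppresses integer-noise ties while keeping locality |
| `T` | minimum gradient magnitude | 10% of max magnitude | scale-free across images once intensities are max-normalized |
| `B` (deg) | angular bin width | 5 | 36 bins: smooth enough to fit, fine enough to resolve ~10° spreads |
| `k` / `k_max` | Gaussian components | selected, up to 3 | one per fiber family; more rarely identifiable |
| `epsilon` | R² tolerance in `select_k()` | 0.02 | an extra component must buy a visible R² gain |

`T` can be given as an absolute value on the normalized-gradient scale or
via `t_fraction` (the 10%-of-max rule). Raising `T` discards weak, noisy
vectors and lowers the fitted pedestal; it never increases the surviving
vector count (a tested invariant).

## Binning and framing conventions

Bins are half-open on the left, $(0,B], (B,2B], \dots, (180-B, 180]$; the
angle $0$ folds to $180$ and lands in the last bin. Density is per degree
(`counts / (n · B)`), so the area $\sum_i \mathrm{density}_i \cdot B$ is
exactly 1 (unit-area invariant, asserted to $10^{-9}$).

Because orientation is circular with period 180°, a peak near the $0/180$
seam would have its tails split by a non-circular Gaussian fit. Before
fitting, the PDF is therefore circularly rotated. Two rules are available:

* `"gap"` (default): rotate the least-populated bin to the seam, so the
  seam falls inside the orientation gap and *every* peak stays interior.
* `"peak"`: the classic rule — rotate the maximum bin to the center of the
  scale (90° by default). Identical in effect for unimodal PDFs, but when
  two peaks sit ~90° apart it parks the secondary peak on the seam; in
  package simulations this inflated width errors from under 1% to ~25%,
  which is why `"gap"` is the default.

Ties (equal-density bins) break toward the smallest angle, making every
rotation deterministic. The applied shift is recorded and composed, and all
fitted centers $b_k$ are mapped back to the original $(0, 180]$ frame.

## Fitting and model order

The fit is bounded Levenberg–Marquardt least squares (`minpack.lm::nls.lm`)
on the (bin center, density) pairs, with $a_k \ge 0$, $b_k \in [-90, 270]$
(near-edge peaks on the rotated axis remain representable),
$c_k \in [B/2, 180]$, $d \ge 0$. Initialization takes the $k$ highest local
maxima of a circular 3-bin moving average; widths start from the
half-maximum crossing. Up to four additional restarts perturb the initial
widths (×0.5, ×2, ×1.5) and centers (±B) — a fixed, deterministic table, so
identical inputs always produce bit-identical fits. The best converged
solution by residual norm is kept.

Goodness of fit is the coefficient of determination
$R^2 = 1 - SS_{res}/SS_{tot}$, which for a least-squares fit with the
pedestal acting as intercept coincides with the squared Pearson correlation
between data and model. 95% confidence half-widths come from linearization
(numeric Jacobian, $t$-quantile at $n - p$ degrees of freedom); parameters
lying in a null direction of $J^\top J$ — e.g. the center of a component
whose height collapsed to zero — are reported with infinite half-widths
rather than misleading finite ones.

`select_k()` fits $k = 1, \dots, k_{\max}$ and returns the smallest $k$
whose $R^2$ is within `epsilon` of the best attained. A fit whose dominant
height is statistically indistinguishable from zero
($a < 2\,\mathrm{ci}_{95}(a)$, or unidentifiable) is flagged
`no_dominant_orientation`: the image is pedestal-only.

## Order metrics

Component areas use the exact full-line Gaussian integral
$a_k c_k \sqrt{2\pi}$ — the constant matters so that areas are commensurate
with the unit PDF area (any fixed constant cancels in the ratio); the
pedestal area is $d \cdot 180$ over the full angular range. Their ratio
separates structured from structureless image content. Peak separations are
plain absolute differences $|b_j - b_i|$. For longitudinal series fitted
with $k = 1$, `healing_panel()` tabulates $R^2$ (with a 0.75 "very good
fit" threshold flag), height, width, and the composite
$(a + d)/c$ — the total model peak height over the Gaussian width —
normalized to the first (control) time point. Width and $R^2$ move
oppositely as order degrades and recovers, which is the trend the
acceptance suite reproduces on a disorder-then-recovery phantom series.

## What the phantoms emulate — and what they don't

`make_fiber_image()` renders fiber families as sinusoidal gratings: the
gradient of a grating is analytically perpendicular to the fiber axis,
giving exact ground truth. Waviness is implemented as phase modulation of
the perpendicular coordinate with slope amplitude $\tan(w)$, so the local
fiber angle oscillates by up to $w$ degrees — fitted widths grow
monotonically with $w$ (tested). With several families the image is tiled
into patches, one family per patch: a *transparent sum* of two gratings
concentrates gradient orientations at the bisectors of the two normals
(where the two slope fields add constructively), which is not how stacked
fiber sheets appear in tissue; patch composition restores two clean,
recoverable normals. Photon-count noise is Poisson on the scene intensity;
`make_noise_image()` provides pure integer-count fields in which the
$R = 1$ tie spikes appear at 0/45/90/135° and fade at $R = 3$. For that
spike phenomenology to be isolable with a global outlier rule, the noise
field needs a mean count high enough (tens of photons) that all 180
one-degree bins are populated; at very low counts only a lattice of
rational-ratio angles is occupied at all.

Not emulated: optical point-spread blur, SHG speckle and coherence effects,
depth-dependent signal loss, fiber crossings inside a single patch, and
non-Gaussian angular spreads. Passing tests therefore demonstrate that the
*pipeline arithmetic and statistics* behave as documented on textures with
known orientation content — not that any particular biological claim holds
for real micrographs, whose quality must still be judged per image (the
$R^2$ and area-ratio metrics exist for exactly that purpose).

## Numerical choices and degenerate inputs

* All-zero or constant images are rejected (no structure to analyze); a
  threshold above the maximum magnitude leaves an empty PDF and errors
  rather than returning a silent zero-density object.
* Normalization forces the maximum to exactly 1 and is idempotent; an
  optional quantile normalizer (`probs`) guards against photon-count
  outliers compressing the scale, clipping values above the quantile.
* Multichannel images require an explicit channel index — no silent
  luminance conversion.
* Fit non-convergence across all restarts raises an error carrying the
  restart count; order selection tolerates individual $k$ failing as long
  as one order converges.
* Problem sizes in the test suite — 128–384 px phantoms, $10^5$-angle
  samplers, 20-seed recovery studies — were chosen as the smallest sizes at
  which sampling noise is clearly below the tested tolerances (e.g. median
  center recovery error ~0.05° against a 2° bound).

## Limitations

The Gaussians are fitted on the line, not wrapped on the orientation
circle; the framing rotation removes the practical consequences for well
separated peaks, but heavily overlapping families wider than ~45° will
trade mass with the pedestal. $R^2$ is computed on the binned density, so
very coarse binning (large `B`) flatters the fit. The distribution of
gradient *magnitudes* is deliberately not analyzed — only orientations
enter the PDF. Orientation values are relative to the image frame; absolute
anatomical angles require controlled acquisition geometry.
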