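---
title: "Stain normalization methods in stainkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stain normalization methods in stainkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stainkit)
```

## The problem

Hematoxylin and eosin (H&E) slides vary in color: staining protocol,
reagent batch, section thickness and scanner all shift the hues an image
shows for the same tissue. Downstream analysis — visual review and machine
learning alike — is more reliable when every image is projected to one
reference appearance. `stainkit` implements Macenko-style stain
normalization: it estimates, per image, the two stain vectors and their
robust maximum concentrations, then re-renders the image as if it had been
stained and scanned like a reference template.

## The physical model

Beer–Lambert absorption makes stains additive in optical density (OD)
space. For channel intensity $I \in \{0,\dots,255\}$,

$$\mathrm{OD} = -\log_{10}(I / 255),$$

and a pixel's OD 3-vector is modeled as a non-negative mixture of two unit
stain vectors $h$ (hematoxylin) and $e$ (eosin):

$$\mathrm{od}(p) \approx C_h(p)\, h + C_e(p)\, e.$$

The estimation problem is to recover $h$, $e$ and the per-stain
concentration scales from tissue pixels alone. The classical geometry: all
tissue pixels lie (noisily) in the plane spanned by $h$ and $e$; that
plane is the span of the two leading principal directions of the OD cloud;
and within the plane, the angular extremes of the pixel distribution
identify the two stains, because real tissue contains nearly pure-H
structures (nuclei) and nearly pure-E structures (stroma). Robust
percentiles stand in for the extremes so isolated pixels cannot hijack
the estimate.

The pipeline per image:

1. **Background threshold** (`auto_threshold()`): the image is box-averaged
   to a low resolution (default factor 4), converted to BT.601 grayscale,
   Gaussian-blurred (default $\sigma = 2$ px, kernel truncated at
   $\lceil 3\sigma \rceil$, reflected borders), and Otsu's method picks the
   threshold maximizing between-class variance on the 256-bin histogram.
   The threshold is per-image because background brightness varies between
   slides; a fixed dataset-wide value removes too few or too many pixels on
   some slides and corrupts the robust extremes downstream.
2. **Tissue mask** (`tissue_mask()`): a pixel is tissue iff its luminance is
   strictly below the threshold, applied at the working resolution.
3. **OD conversion** (`rgb_to_od()`): tissue pixels only, through a
   256-entry look-up table $-\log_{10}(\max(v, 1)/255)$; the clamp floor of
   1 keeps OD finite at true channel zeros (8-bit images contain them).
4. **Stain plane** (`covariance_from_sums()`, `principal_plane()`): the
   $3\times3$ OD covariance is assembled in one pass from component sums;
   its two leading eigenvectors span the same plane the SVD of the pixel
   matrix would give, at $O(1)$ memory. Eigenvector signs are fixed so
   component sums are non-negative (stains absorb, they do not emit).
5. **Angular extremes** (`project_and_angles()`,
   `robust_angle_extremes()`): pixels are projected into the plane,
   unit-normalized, and summarized by $\varphi = \mathrm{atan2}(v, u)$;
   the $\alpha$-th and $(100-\alpha)$-th percentiles of $\varphi$
   (default $\alpha = 1$) map back to OD space, negative components are
   clamped to zero and the vectors renormalized. The vector with the larger
   red OD component is labelled hematoxylin.
6. **Concentrations** (`concentrations()`,
   `robust_max_concentrations()`): least-squares unmixing against the
   $3\times2$ stain matrix; the per-stain 99th percentiles are the robust
   maxima $\max C_h$, $\max C_e$.
7. **Template projection** (`normalize_image()`): concentrations are
   rescaled by $\max C^{\mathrm{ref}} / \max C$, clamped at zero, remixed
   with the template's stain vectors, and mapped back to 8-bit RGB.
   Background pixels pass through untouched.

## Performance-oriented primitives and their contracts

Each optimization is exact or carries an explicit tolerance, so speed
never changes semantics:

- **LUT OD conversion** equals the direct logarithm bit-for-bit (256
  precomputed entries).
- **Covariance from sums** equals two-pass covariance within $10^{-10}$
  relative (tested against the textbook formula).
- **Percentiles by selection** use nearest-rank semantics
  ($k = \lceil qn/100 \rceil$) computed by partial sorting; the result is
  defined to equal the full-sort percentile exactly, which makes the
  optimization testable rather than approximate.
- **Monte Carlo sampling** (`sample_pixels()`): a seeded uniform sample
  without replacement of the tissue pixels (default rate 1%) drives the
  covariance, the angle percentiles and the concentration percentiles —
  the estimation stages whose sorting dominates runtime. Sampling quality
  is quantified by `sampling_error()`: the Euclidean distance between the
  six stain-vector components of the sampled and full estimates, and the
  relative errors of the two robust maxima. Rate 1 reproduces the
  unsampled estimate bit-for-bit, and the whole pipeline is deterministic
  given the seed.

## Robust QC across a dataset (fast_rsn / fast_rsn_all)

Artifacts — staining spots, dirt, ink — bias the estimated vectors toward
the artifact color, and a single bad estimate ruins that slide's
normalization. `run_fast_rsn()` cross-checks the eight estimated
parameters ($H_R, H_G, H_B, E_R, E_G, E_B, \max C_h, \max C_e$) across all
images of a dataset: each parameter gets an acceptable range, an image
with at least one out-of-range parameter is flagged poor-quality, and
flagged images are normalized with the representative parameter set — the
component-wise mean over good images, H and E renormalized to unit length
(the mean of unit vectors is shorter than unit). `run_fast_rsn_all()`
applies the representative set to every image, trading per-image fidelity
for a perfectly uniform stain basis across the dataset.

Where the choice of bound rule was open, the default is Tukey fences
($Q_1 - 1.5\,\mathrm{IQR}$, $Q_3 + 1.5\,\mathrm{IQR}$, nearest-rank
quartiles) because quartiles are themselves robust to the outliers being
hunted; `median ± k·MAD` and fully manual bounds (the "chosen by eye"
workflow) are selectable. Flagging is single-pass: bounds are not refitted
after excluding outliers, since refitting can cascade on small datasets
(an iteration count could be exposed later; one pass matched every design
target). Note that on datasets where good images are nearly identical the
fences become very tight and occasionally flag a clean image; that false
positive is benign by construction, because the replacement parameters are
the mean of images like itself.

## The synthetic generator

`synthesize_image()` builds images from exactly the model the estimator
inverts, so ground truth is known by construction:

- a smooth random tissue blob covers 30–60% of the frame; the rest is
  background drawn uniformly in [245, 255] per channel — bright but noisy,
  so Otsu faces a realistic bimodal histogram rather than a spike;
- concentration fields come from low-pass-filtered Gaussian noise: a
  *mixing* field (with ~10% of tissue nearly pure H and ~10% nearly pure E,
  emulating nuclei and stroma — without such regions the angular extremes
  of real H&E would not exist) times an *amplitude* field with a positive
  floor, each rescaled so its nearest-rank 99th percentile over tissue
  equals the stated true maximum (defaults 1.9705 and 1.0308, the scale of
  the shipped reference template);
- correlation lengths are capped (smoothing $\sigma \le 8$ px for fields,
  $\le 32$ px for the tissue blob): structure has a fixed physical scale,
  so a larger frame shows more structure, not bigger blobs;
- artifacts are random discs overwriting tissue with a saturated color
  plus per-pixel jitter; the disc radius grows until the requested tissue
  coverage is met. The default artifact color is saturated blue
  (40, 40, 230). For detection-power experiments a saturated red
  (230, 40, 40) is used instead, because in OD space saturated blue lies
  only ~15° from the hematoxylin direction — a blue artifact partially
  mimics extra hematoxylin — while red is >30° from both stains;
- `generate_dataset()` jitters the true stain pair per image by a random
  rotation bounded by a jitter angle (default 10°), emulating
  protocol-level stain variability.

What the generator does *not* emulate: real histology texture (glands,
nuclei shapes), scanner noise and chromatic aberration, out-of-focus
regions, and annotation-level pathology. Passing tests therefore
demonstrate correctness of the algorithm under its own physical model and
robustness of the QC logic — not clinical performance on real slides.

## Numerical choices

- Rounding is half-away-from-zero everywhere (R's `round()` is banker's
  rounding and platform-stable determinism matters for byte-identical
  reruns); outputs are clipped to [0, 255].
- Otsu ties break toward the smallest maximizing threshold; a single-valued
  histogram returns that value with a warning.
- Pixels whose in-plane projection norm falls below $10^{-12}$ are dropped
  from the angle distribution and counted.
- Negative least-squares concentrations (pixels outside the stain cone)
  are kept for percentile statistics but clamped to zero before template
  projection — negative stain amounts would render brighter than white.
- Near-collinear stain estimates (condition number $> 10^8$) raise an
  error rather than producing meaningless unmixing.
- Degenerate inputs (all-background images, single-stain images with a
  rank-1 OD cloud) raise classed errors that the batch drivers record per
  image without aborting the dataset.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `sampling_rate` | 0.01 | fraction of tissue pixels used for estimation |
| `alpha` | 1 | robust percentile margin (angles and concentrations, in %) |
| `background.downsample` | 4 | resolution factor for threshold detection |
| `background.sigma` | 2 px | Gaussian blur before Otsu |
| `clamp_floor` | 1 | channel floor in the OD look-up table |
| `bounds_method`, `k` | tukey, 1.5 | QC bound rule and fence multiplier |

The reference template is configuration, not a constant: the default
(`inst/extdata/default_template.yaml`) carries the stain matrix and
maximum concentrations of the public reference Macenko implementation, and
any YAML/JSON file with `H`, `E`, `maxCh`, `maxCe` can replace it.

## Verification scale

The test suite exercises: exact oracle equivalence of the optimized
primitives (selection percentiles vs full sort, single-pass vs two-pass
covariance, Otsu vs an exhaustive 256-threshold scan); ground-truth
recovery on twenty 512×512 artifact-free images with 10° stain jitter;
sampling fidelity at 1% on a 2048×2048 image over ten seeds; 5-fold color
standardization of two differently stained renderings of one tissue; QC
detection power on twenty 10-image datasets of 96×96 images with one
20%-coverage red artifact each; and byte-identical reruns. These sizes
were chosen so the whole suite runs comfortably on a laptop-class single
core while keeping every statistic at the scale stated above;
`scripts/acceptance.R` recomputes the same quantities from scratch.

## Known limitations

- Single-stain images (or any rank-deficient OD cloud) have no stain plane
  and are rejected, not guessed.
- The H-vs-E label uses the red-OD rule; exotic stain pairs with inverted
  red absorbance would swap labels.
- Gigapixel streaming is out of scope: an image (not the whole pyramid)
  must fit in memory; multi-level TIFFs are supported at the level of
  standard TIFF directories, not proprietary scanner metadata.
- The QC bounds assume the dataset is mostly good-quality; a dataset where
  most slides carry artifacts defeats fence-based flagging (and raises an
  all-outliers error when no good subset remains).
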