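---
title: "Counting grains per panicle by density-map regression: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting grains per panicle by density-map regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The counting model and its assumptions

`paniclecount` estimates the number of grains on a single rice panicle
photographed spread-out on a dark background. Counting is cast as density
estimation: the model predicts a non-negative field over the image whose
integral is the count. This is the standard formulation for crowded, mutually
occluding objects, where per-instance detection becomes unreliable exactly in
the regions that matter most (grain clusters on primary branches).

The assumptions the pipeline inherits from this formulation:

* one panicle per image, bright grains on a near-black background;
* every grain is annotated by a single point placed at (or near) its center,
  in pixel coordinates of the native image resolution;
* local grain density varies smoothly enough that a Gaussian surrogate per
  grain is a usable regression target;
* the count is the only quantity of interest — the density map is a training
  device and diagnostic, not a segmentation.

### From points to density maps

For an annotation set $\{x_i\}_{i=1}^N$ the target map is

$$F = \sum_{i=1}^{N} \delta(\cdot - x_i) * G_{\sigma_i}, \qquad
  \sigma_i = \beta \, \bar d_i,$$

where $\bar d_i$ is the mean Euclidean distance from point $i$ to its $k$
nearest other points. Tightly packed grains get tighter kernels, so mass
stays local and neighboring grains remain separable in the target.

### The regression network

The full variant uses the first 10 convolutional layers of VGG-16 (three
2×2 max pools, stride 8) as feature extractor, then six 3×3 convolutions
with dilation 2 (channels 512-512-512-256-128-64) and a 1×1 projection to a
single channel. Dilated convolutions enlarge the receptive field without
further resolution loss, which matters for long thin branch structures. The
ground-truth map is brought to the output stride by mass-preserving block
summation, so target mass still equals $N$.

Because no deep-learning framework is available as an R dependency, the
package carries its own small engine: im2col/col2im kernels in C++ turn
stride-1 dilated convolution into BLAS matrix products; backpropagation and
Adam are written out in R. The backward pass is verified against central
finite differences in the test suite — gradient checking is the oracle that
keeps the engine honest.

## Tunable parameters

| Parameter | Default | Units | Notes |
|---|---|---|---|
| `kernel_params(k)` | 3 | neighbors | Never specified by the originating method; 3 is the convention in geometry-adaptive density pipelines. Clamped to $N-1$. |
| `kernel_params(beta)` | 0.3 | – | Bandwidth factor $\sigma_i = \beta \bar d_i$; the value reported to perform best for this family of counting problems. |
| `kernel_params(fallback_sigma)` | 15 | px | Used when an image has < 2 points and no neighbor distance exists. |
| `kernel_params(truncation_radius)` | 4 | $\sigma$ | Kernel support; with renormalization (below) the choice only affects smoothness, not mass. |
| `kernel_params(sigma_floor)` | 0.5 | px | Guards duplicate points ($\bar d_i = 0$). |
| `loss_config(alpha)` | 0.1 | – | Weight of the relative (squared-ratio) term. |
| `loss_config(beta)` | 0.01 | – | Weight of the absolute term. A distinct quantity from the kernel `beta`; the two live in different objects on purpose. |
| `loss_config(euclidean_mode)` | `"map"` | – | See "open design choices". |
| `network_config(variant)` | `"tiny"` | – | `"full"` is the production architecture; `"tiny"` (< 100k parameters) exists so training is feasible on one CPU in minutes, and is never substituted silently. |
| `network_config(output_stride)` | 8 (full), 4 (tiny) | – | Density-output downsampling factor. |
| training `lr` | 1e-3 | – | Adam, single-image batches. The lineage convention for the full, ImageNet-initialized variant is 1e-5; a randomly initialized tiny model trains far better at 1e-3, which is therefore the package default. |
| training `epochs` | 100 | – | The published training schedule; desk-scale runs use fewer. |
| `split_spec(ratios)` | 0.8/0.1/0.1 | – | Train/test/validation. |
| calibration default | $y = 1.0294x + 0.6069$ | counts | Fitted on real photograph annotate-vs-manual counts; see below. |
| `panicle_default_stats()` | mean (0.301, 0.294, 0.274), std (0.189, 0.182, 0.163) | [0,1] | Channel statistics of the real photographic dataset; for inference on comparable photos only. Synthetic work recomputes its own with `compute_channel_stats()`. |

## Numerical choices

**Kernel renormalization.** A truncated, discretized Gaussian does not sum
to 1, and near image borders part of its support is cut off. Each kernel is
therefore renormalized over its discrete in-image support so every grain
contributes mass exactly 1: `sum(render_density_map(ann)) == N` to 1e−6 for
any layout, including border-adjacent and duplicate points. This is the
invariant that makes "count = integral" exact at the ground-truth level, and
the test suite asserts it property-style.

**Mass-preserving pooling.** `downsample_density()` pads with zeros to a
multiple of the factor and block-sums, conserving mass to machine precision.
The alternative (interpolation) silently changes counts and is not offered.

**Negative activations.** The network output is unconstrained; at inference
the map is clamped at 0 before integration so counts are well defined. During
training the raw output is used, keeping gradients intact.

**Population standard deviation** for channel statistics, computed by
streaming count/sum/sum-of-squares accumulation (memory independent of
dataset size); images of different resolutions contribute per pixel. The std
is floored at 1e−6 against constant channels.

**RMSE is `sqrt(MSE)` by construction**, and the per-image relative errors
are formatted round-half-up to 2 decimals for tabular output (matching the
usual printed style; R's `round()` is banker's rounding, so the package
carries its own `round_half_up`). Published tables in this problem domain
occasionally print MSE/RMSE pairs that violate RMSE² = MSE; the package
computes them consistently and makes no attempt to reverse-engineer such
values.

**Split remainders** go train-first (floor allocation, leftover items to
train, then test, then validation). Any fixed rule works; this one is
documented and tested.

**File formats.** Annotations are single-sheet XLSX (header `x`, `y`) or an
equivalent CSV, auto-detected by extension, paired with images by shared
basename. Stored coordinates always refer to the native image resolution;
rescaling happens in memory. Since no spreadsheet writer nor `zip` binary is
available in the deployment environment, the package writes XLSX through a
minimal stored-entry ZIP container of its own; `readxl` — an independent
implementation — reads it back in the round-trip tests, and CRCs are
validated externally. Density maps persist as HDF5 (dataset `density`,
attributes `scale`, `image_id`) with a minimal NPY writer/reader as the
secondary format. Model checkpoints use R's native serialization.

## Open design choices, and why they were decided this way

**Map-level vs count-level Euclidean loss.** The loss prose in the
originating method defines the Euclidean term on scalar counts, while the
architecture lineage it builds on trains pixel-wise on density maps.
Count-only supervision of a dense regressor is severely under-constrained
(any map with the right integral is optimal), so `"map"` is the training
default; `"count"` is implemented for literal fidelity and is what the
hand-computed loss oracles exercise. Both are first-class `loss_config`
options, and the relative/absolute terms operate on counts (map masses) in
either mode.

**"First 10 layers" of VGG-16** is read as the first 10 *convolutional*
layers (through conv4_3, three pools, stride 8) — the convention of the
architecture family. The dilated back end follows that family's
configuration B (all dilation 2). Neither is enumerated in the original
description; both are assumptions, recorded here, and pinned by a
closed-form parameter-count test (16,263,489 parameters).

**Pretrained front end.** The flag exists (`pretrained_frontend`) but
raises an error: ImageNet weights require a download this offline build does
not perform. Random initialization (He-scaled, seeded) is the supported
path; the 1×1 head uses sd 0.01.

**Calibration fitting data.** The published procedure fits annotated counts
against manual counts, then applies the line to model outputs — conflating
annotation error with model error. `fit_linear_correction()` accepts either
pairing; the shipped default reproduces the published coefficients, and the
documentation of `cmd_count()`/`cmd_evaluate()` points out the choice.

**Annotation coordinate convention.** 0-based pixels, x = column,
y = row, origin top-left, bounds $0 \le x <$ width. The originating tool's
convention is unrecorded; this one matches raster indexing everywhere
downstream and is applied consistently on read, write and rescale.

## The synthetic generator: what it emulates, what it does not

`generate_panicle_image()` reproduces the *statistical structure* the
counting problem cares about:

* near-black background with additive Gaussian pixel noise;
* 80–350 bright, elongated, slightly hue-jittered ellipses ("grains")
  strung along a curved main axis with primary and secondary branches;
* partial overlap: a configurable fraction of grains is placed in contact
  with a neighbor (rejection sampling keeps the rest clear; the realized
  fraction is measured by actual ellipse-intersection tests and reported);
* an exact point annotation at every grain centroid.

Defaults: 384×384 canvas, 98–343 grains (the span of manual counts observed
on real panicles), 6–12 primary branches, semi-axes 4–7 × 2–3.5 px,
overlap target 0.3, background 0.04, noise sd 0.01.

It deliberately does **not** emulate photorealism: no specular husks, awns,
stems with texture, variety-specific morphology, lighting gradients, or
camera-specific noise. One labeling-policy difference is intentional: real
annotation skips grains so occluded that a human cannot resolve them,
whereas the generator annotates *every* drawn grain, however hidden — ground
truth stays exact, at the price of not modeling annotation undercount. (That
undercount is precisely what the calibration line corrects on real data,
so the synthetic world is used to test calibration *mechanics*, not its
default coefficients.)

Consequently, a green end-to-end test establishes that the pipeline can
learn to count dense elongated blobs under occlusion from the data it is
given — it does not establish real-photograph accuracy, which requires real
images and annotations.

### The desk-scale learnability world

The end-to-end acceptance run trains the tiny variant for 30 epochs on 200
synthetic images and requires held-out MAPE < 0.15 on 50 more, with the
composite loss doing no meaningfully worse than the Euclidean baseline.
The image size is not dictated anywhere, so it was fixed once at a 64×64
canvas with 15–40 grains of proportionally scaled size (2.5–4 × 1.2–2 px)
and 2–4 branches — the same grain-to-canvas ratio as the full-scale default,
small enough that the whole run fits in minutes on one CPU core. Learning
rate 1e-3 as discussed above. These choices were made before measuring and
are not tuned to the criterion.

## Known limitations

* The full variant is implemented and shape/parameter-verified, but training
  it to published accuracy requires the original 4000-image dataset and GPU
  time; published metric values are therefore out of reach here and are
  replaced by property suites and the desk-scale learnability criterion.
* The training engine is single-threaded per image with batch size 1;
  it is a faithful, tested implementation, not a performance-competitive one.
* The calibration default is only meaningful for photographs comparable to
  the dataset it was fitted on; for anything else, refit.
* The generator's occlusion model (ellipse intersection) does not model
  *stacked* grains (fully hidden ones), so annotation undercount — the
  real-world motivation for calibration — is absent from synthetic data.
* `mean_knn_distance()` is exact O(N²); fine for panicle-scale N (≤ ~500),
  not for crowd-scale datasets.
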