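---
title: "Synthetic UV skin imaging: models, phantoms and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic UV skin imaging: models, phantoms and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Melanin absorbs ultraviolet light, so hyperpigmented skin — senile lentigo,
freckles, early photo-damage — appears as dark, sharply delineated blobs
under UV photography while remaining faint or invisible under visible light.
UV photography equipment is rare outside specialist clinics, which motivates
*synthesizing* the UV appearance from an ordinary color photograph. This
package implements that synthesis as conditional adversarial image-to-image
translation, together with every stage needed to train and evaluate it:
face-region detection, local registration of the color/UV exposure pair,
pigment-spot segmentation, melanin-emphasis baselines, and quantitative
metrics. Because paired clinical captures cannot be redistributed, the
package ships a parametric skin-phantom generator that produces paired
color/UV images with known ground truth; every claim the test suite makes is
made on phantoms.

# The translation model

The generator `G` is a U-net: stride-2 4x4 convolutions (leaky ReLU) halve
the resolution `depth` times, and the decoder mirrors them with nearest-
neighbour upsampling, skip concatenation and 3x3 convolutions, ending in a
sigmoid so outputs live on [0, 1]. Inverted dropout acts on the two
innermost decoder levels during training (rate 0.5 at clinical scale; the
desk preset uses 0.2, because at a few thousand iterations the heavier rate
measurably slows convergence of the local spot response without improving
held-out loss). The discriminator `D` receives
the channel-concatenated (color, candidate UV) pair, applies a stride-2
convolution stack and a dense head over the flattened conv features —
flattening rather than pooling, so the head can react to spatial texture,
not just channel averages — and returns a single probability, clamped to
(1e-6, 1 - 1e-6) before any logarithm.

Training minimizes, over generator parameters,

```
mean_i [ meanpix |Y_i - G(X_i)| + lambda * log(1 - D(X_i, G(X_i))) ]
```

and, alternately over discriminator parameters,

```
- mean_I log(1 - D(X_i, G(X_i))) - mean_J log D(X_j, Y_j),
```

with the fake index set `I` and real index set `J` drawn disjointly from
each batch (the sampler splits a double-size draw into halves). `lambda`
defaults to 0.005; `lambda = 0` is the "no discriminator" ablation and then
only the generator is trained. Training runs in three phases: (1) joint
alternating updates, (2) discriminator-only refinement selected by the
validation discriminator loss, (3) generator-only refinement against the
frozen discriminator, selected by validation mean per-pixel L1. Phase-1
early stopping snapshots generator and discriminator jointly at the best
validation iteration; the cadence is `val_every` iterations (the original
cadence being unstated, 250 at desk scale). Adam is the optimizer
throughout, and augmentation applies random vertical/horizontal flips and
90-degree rotations to each sampled patch pair. All gradients are
hand-derived and checked against central finite differences in the test
suite; adversarial gradients are taken in logit space
(`d log(1-p) / dz = -p`), which avoids the clamped-probability
discontinuity.

Two desk-scale stabilizers of the adversarial game are worth stating
explicitly. First, the discriminator's Adam learning rate is a quarter of
the generator's: with symmetric rates the discriminator wins outright at
this scale, its fake-probability collapses toward zero and the saturating
`log(1 - D)` term stops producing any generator gradient. Second, the
adversarial gradient reaching the generator's output is norm-clipped to the
reconstruction gradient's norm before backpropagation: Adam normalizes step
sizes per parameter, so without a bound the adversarial direction can
dominate regardless of `lambda` and intermittently collapse the generator
onto a discriminator exploit. Neither changes the objective being
optimized, only the robustness of the steps taken on it.

# Local alignment

The color and UV exposures of a subject are captured sequentially, so the
pair is locally misaligned by small subject motion. Directly registering a
color image to a UV image is unreliable — the modalities have different
pixel statistics — so a surrogate is used: a generator trained with
`lambda = 0` and *no* alignment produces "temporal" synthetic UV images that
live in the UV intensity domain. Large tiles of the observed UV image are
then registered to the surrogate by exhaustive integer-shift search
(`[-r, r]^2`, mean per-pixel L1 on the valid overlap, ties preferring
smaller `|dy| + |dx|` then lexicographic order), and every smaller training
patch inherits the shift of the tile whose center is nearest (row-major on
ties). The sign convention is fixed once: a tile shift is the displacement
of the UV content relative to the color side, so an aligned color window is
extracted at `origin - shift`, and windows pushed out of bounds are dropped
rather than re-sampled. Overlap-normalized scoring (dividing by the overlap
area) keeps large shifts from being favored or penalized artificially.

At clinical scale the tiles are 900 px against 256 px training patches; the
desk-scale geometry preserves that ratio's intent (tiles larger than
patches: 96 px tiles, 64 px patches, 192 px phantoms) because a patch must
lie mostly within one rigid-motion tile for a single shift to register it.

# The skin phantom

`make_phantom()` renders a paired capture from a generative model with known
ground truth:

* melanin map `M`: smooth base (mean 0.30) + fine micro-texture
  (sigma ~1.5 px, amplitude 0.04 by default) + disc-shaped spot boosts
  (+0.35 inside spots of 3-7 px radius);
* UV capture: `clip(0.9 - 1.2 M) * shading + noise` — globally darker than
  the color capture and melanin-dominated, as under UV illumination;
* color capture: per-channel Beer-Lambert attenuation
  `tone_c * exp(-M_c * abs_mel[c] - H * abs_hem[c]) * shading`, with melanin
  absorbing most strongly in blue and a smooth hemoglobin field `H`
  absorbing mostly green. In the color rendering the *spot* component of `M`
  is attenuated by `color_spot_contrast` (default 0.3): spots are much
  fainter under visible light, which is the asymmetry the whole method
  exploits. The micro-texture is part of the base melanin and therefore
  fully visible in both modalities — this matters, because it is what makes
  pixel-level misalignment costly, as on real skin;
* misalignment: a piecewise-constant integer shift field (constant on
  `misalign_tile` squares, at most `misalign_max` px per axis) displaces the
  observed UV raster relative to the color geometry. Piecewise-constant
  motion makes the correct tile shift exactly recoverable, so the alignment
  stage can be tested to the pixel;
* additive Gaussian sensor noise (sigma 0.02) on the observed rasters;
  `true_uv_oracle()` returns the noise-free, registered UV ground truth.

What the phantom deliberately does **not** model: 3D facial geometry,
specular reflectance, shadows, landmarks, hair, or photorealistic texture.
Consequences for interpretation: passing tests show the pipeline's stages
are correct and that the orderings among training variants hold under
controlled misalignment and texture; they do not certify clinical image
quality, and the shadowed-region failure modes seen on real faces have no
phantom analogue.

The magnitude of subject motion is not quantified in clinical descriptions
("subtle movement"); `misalign_max = 4` px at the 192 px desk scale was
chosen as roughly 2% of the image side and is recoverable within the +-8 px
desk search radius.

# Face region and spot segmentation

The face detector is a patch-level binary classifier. On phantoms the
training labels come from window coverage of the known face mask (>= 90%
face, exactly 0 non-face, intermediate windows dropped); on real
photographs a landmark-derived mask can be supplied through the same
interface. The backbone is a small configurable CNN (stride-2 blocks,
global average pooling, dense head) rather than a large classification
network: the pipeline stage, not the backbone, is what is under test, and
the phantom task is nearly linearly separable. Region maps are assembled by
painting per-window labels and resolving overlaps by majority vote with
ties counting as face.

The spot segmenter reuses the generator's U-net with a two-class softmax head and is
trained on `ce_weight * cross-entropy + dice_weight * soft-DICE`, weights
1:1 by default (the mixture weights being unstated in clinical use). Its
training set mixes true-UV patches and synthetic-UV patches (from the
trained translation model) 1:1 with the same ground-truth masks: without
the synthetic inputs the segmenter, tuned to full-contrast UV spots, finds
almost nothing in generator output, whose spots are reproduced at reduced
depth. Because the phantom's spot masks are registered to the color-side
geometry, the segmenter trains and evaluates on the registered UV
rendering — mirroring clinical spot labels, which are derived from (and
registered to) the UV capture itself. The
soft-DICE loss is `1 - (2 sum(p t) + eps) / (sum p + sum t + eps)` with
`eps = 1`. Probability maps are assembled patch-wise, binarized at 0.5 with
no minimum-spot-size filter, and intersected with the evaluation (cheek)
region; the spot-area percentage is `100 |mask & region| / |region|`.

# Evaluation

* **Per-pixel L1**: median (default; robust to outliers) or mean of
  `255 |a - b|` inside a mask — the 0-255 scale appears only in reporting.
* **Frechet distance**: `|mu1 - mu2|^2 + tr(S1 + S2 - 2 (S1 S2)^(1/2))` on
  feature means/covariances of face-tile sets; the matrix square root comes
  from an eigendecomposition of the symmetrized product with negative
  eigenvalues clipped at zero, and the result is clipped to be
  non-negative. The embedder is pluggable. The default desk embedder is a
  deterministic feature map — 16x16 block means plus 8x8 pools of
  horizontal/vertical gradient magnitudes, followed by a fixed-seed random
  projection to 64 dimensions — chosen so that both intensity distribution
  and sharpness move the embedding; a pretrained deep embedder can be
  plugged in through the same interface but is never required.
* **Overlap metrics**: IoU, recall, precision, F from pixel confusion
  counts, with explicit empty-mask conventions (both empty: all 1; truth
  empty, prediction non-empty: recall and F reported NA, IoU and
  precision 0).
* **Correlation and no-intercept regression** for the spot-area comparison.

The ablation report evaluates the four (discriminator x alignment) variants
and the grayscale, blue-channel, and ICA baselines on one held-out cohort.
Two referencing choices are deliberate and documented here: median L1 is
computed against the *registered* UV ground truth (`true_uv_oracle`), so a
correctly aligned model is not penalized for the test pair's own
misalignment; the Frechet distance is computed against the *observed* UV
patches, because it compares distributions (registration-insensitive) and
the observed capture — noise and texture included — is what synthetic UV
output should resemble. The headline orderings are read column-wise, as in
the clinical ablation table: the mean of the two alignment-on rows against
the mean of the two alignment-off rows (median L1), and the mean of the two
discriminator-on rows against the two discriminator-off rows (Frechet).

# ICA baselines

The comparator decomposition maps RGB to absorbance (`-log RGB`), removes
multiplicative shading by projecting out the `(1,1,1)/sqrt(3)` direction,
and runs a 2-source FastICA (tanh nonlinearity, deterministic fixed
starting vectors, deflation with Gram-Schmidt, tolerance 1e-6) on the
masked pixels' plane coordinates. The component with the stronger
normalized blue-channel absorbance is labelled melanin, and each component
is oriented so its absorbance vector sums positive. Re-synthesis applies
weights to the two sources, restores the mean and shading, and
exponentiates; unit weights reconstruct the input to floating-point
accuracy. The constrained grid search scans melanin weights 0.0-2.0 in
steps of 0.1 with the weight sum fixed at 2, minimizing pooled median
per-pixel L1 against UV references (ties to the smaller melanin weight);
1.3/0.7 — the weights selected on clinical data — ship as a configuration
preset, not as an expected value.

# Scale presets and problem sizes

The `desk` preset is the package's own study condition and what the test
suite runs: 192x192 phantoms, 20-subject cohorts split 12/2/6
(train/validation/test), 64 px patches at stride 32, 96 px alignment tiles
at stride 48 with search radius 8, generator depth 3 with base 8 channels,
discriminator base 16, batch 2, learning rate 1e-3, schedule
2000/100/300 iterations with validation every 250, the spot segmenter with base 16
channels on 32 px patches for 3500 iterations, and overlapping (half-patch
stride) whole-image conversion inside the spot pipeline. These sizes keep a
full four-variant ablation plus the spot pipeline in CPU-minutes. The `clinical` preset records the clinical-scale
hyperparameters (256 px patches, 900 px tiles, lambda 0.005, batch 80,
learning rate 1e-4, schedule 150000/5000/50000, around 30000 face patches)
for completeness; one reported schedule figure is ambiguous ("5,0000"
generator-only iterations) and is read as 50000. Nothing in the test suite
exercises the clinical preset.

# Numerical choices and degenerate inputs

* Discriminator probabilities clamped at 1e-6 before logarithms; gradients
  bypass the clamp via logit-space derivatives.
* Exhaustive shift search resolves exact score ties deterministically
  (smaller `|dy|+|dx|`, then smaller `dy`, then `dx`), so constant tiles
  return (0, 0).
* Patch grids: 0-based, row/column, half-open windows; the lattice always
  covers the image with edge windows overhanging into reflect (default) or
  zero padding; assembly averages overlaps uniformly and fills uncovered
  pixels (whole-image conversion fills with the input's grayscale).
* Empty validation set disables early stopping with a warning rather than
  failing.
* ICA refuses rank-deficient pixel clouds (constant images) and masks with
  fewer than 100 pixels.
* All stochastic stages draw from the R RNG under an explicit seed;
  identical seed and configuration reproduce training traces, checkpoints
  and metric tables bit-for-bit.

# Known limitations

The desk-scale adversarial effect is the pipeline's weakest property. A
scalar discriminator trained for a few thousand iterations does not
measurably sharpen output texture here (the adversarial model's gradient
energy is no higher than the L1-only model's), so the discriminator column
of the ablation cannot be expected to show the Frechet improvement seen at
clinical scale; the package reports whatever the seeded run produces rather
than tuning toward the clinical ordering. Relatedly, the generator at a few
thousand iterations reproduces pigment spots at roughly half their true
depth, so spot-area percentages measured on synthetic UV images track the
true-UV percentages with high correlation but a regression slope well below
one. The phantom's planted
misalignment is piecewise-constant rather than smooth; real subject motion
would also contain rotation and deformation that integer shifts cannot
correct. Sub-pixel registration is out of scope (integer shifts only), as
are CycleGAN-style unpaired training, pretrained perceptual embedders, and
any reproduction of clinical headline numbers, which would require the
undistributed clinical images.
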