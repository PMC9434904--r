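---
title: "Translating between FA frames and OCT macular thickness maps: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Translating between FA frames and OCT macular thickness maps: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retfusion)
```

## The problem

Fluorescein angiography (FA) and OCT macular thickness mapping are
complementary examinations in diabetic macular edema: FA shows perfusion
and vascular leakage, the OCT report shows where the macula is thickened,
as a false-color square over a 0–500 µm scale. The two findings are
causally linked — leakage produces thickening — so a conditional
image-to-image translator trained on co-registered pairs can synthesize a
plausible stand-in for either modality when only the other is available.
`retfusion` implements the complete apparatus of such a study — paired
data preparation, pix2pix training in both directions, checkpoint
selection, and objective quality evaluation — with a synthetic phantom
generator in place of clinical images, so every stage is testable on a
desk.

## The phantom generator: what it emulates, and what it does not

Clinical datasets of this kind are private; the phantom module is the
package's first-class stand-in and defines the study conditions for all
tests.

A phantom pair is built from one ground-truth **thickness field**: a
250 µm baseline (normal central macular thickness), a gentle foveal dip,
smooth low-frequency perturbation scaled by `noiseSd`, and Gaussian edema
bumps with amplitudes drawn from 50–250 µm — placing phantoms in the
green-to-red bands of the 0–500 µm scale. The **FA render** shows a
bright perfused background, a branching vessel tree (recursive
midpoint-displacement branching; purely cosmetic), a dark disc at the
fovea (the foveal avascular zone, FAZ), bright microaneurysm dots, and —
for `focal`/`diffuse` leakage — hyperfluorescent halos centered *exactly*
on the edema bump centers. This co-location is the learnable signal: FA
leakage predicts OCT thickening, which is precisely the dependence the
translator is supposed to extract. The **OCT render** overlays the
color-coded square (centered on the fovea, 30% of the canvas side) with
opacity 0.85 over a uniform red-free gray, with a vertical color bar at
the right margin. Nothing structured is drawn beneath the square: on real
devices the overlay destroys the underlying vasculature anyway, and a
uniform underlay keeps the color → thickness decoding exactly invertible
(`decodeThickness()` un-blends with the known constants and inverts the
scale by nearest-neighbor lookup on a 0.5 µm grid; rendered maps decode
to within 1 µm of the field).

Severity follows the ETDRS ladder: lesion load (microaneurysm count,
leakage mode, edema number/amplitude) increases from `no_DR` (clean) to
`PDR` (diffuse leakage, 150–250 µm bumps). Grades are sampled uniformly
by default so the stratified split always has material in every stratum.

The device's true colormap breakpoints are not public; the scale is a
piecewise-linear table with stops at (0 violet, 100 blue, 225 green,
300 yellow, 350 orange, 425 red, 500 white), configurable through
`thicknessColorScale()`.

What phantoms do **not** model: dye transit phases, photorealistic fundus
texture, device quality scores, acquisition artifacts, or anatomic
variability beyond fovea jitter and laterality. Passing tests therefore
demonstrate that the *pipeline machinery* is correct and that the
translator can extract a planted cross-modal dependence — not clinical
performance on real data.

## Preprocessing and co-registration

Multimodal vessel-based registration is not possible here — the color
overlay obscures the vasculature — so both modalities are anchored on the
fovea:

* **OCT**: colored pixels (chroma `max(R,G,B) − min(R,G,B)` above 30/255,
  robust against the gray red-free background) are scanned inside a
  central window of half the report dimension (keeping the color bar
  out); the tight bounding box is the thickness square and its midpoint
  the presumed fovea.
* **FA**: the frame is converted to grayscale and thresholded inside a
  window shifted 10% of the width toward the left (away from dark frame
  outlines). The FAZ is hypofluorescent, so pixels *below* the threshold
  become foreground; pixels of value exactly 0 are ignored as frame
  background. The default policy is Otsu's threshold with one refinement:
  when the dark class exceeds 20% of the window — which happens when
  broad leakage splits the histogram at background-vs-bright instead of
  FAZ-vs-background — Otsu is re-applied within the dark class (at most
  3 iterations). This is the automated analogue of manually "adjusting
  the threshold to highlight the FAZ", and it brings centroid error on
  phantoms below 1 px across all severity grades. A `fixed:<v>` policy is
  available for data where a constant works.
* The largest connected component wins (ties: scan order); its contour
  and first-order-moment centroid give the presumed fovea; the FA crop
  takes the side length of the detected OCT square, both crops are
  resized to the training canvas and concatenated FA-left / OCT-right.

Pairs whose segmentation finds nothing are routed to a manual list
(`qc_status = "manual"`) rather than aborting, mirroring the manual
correction path such a study needs. Left eyes are mirrored to right-eye
orientation first; on phantoms mirroring is exactly invertible, and the
segmentation operators are flip-equivariant (tested).

Conventions: 0-based pixel coordinates, x = column, y = row, rectangles
half-open. Crops are edge-clamped with replication when the square
exceeds the frame (whether the original study clamped or padded is not
stated; clamping keeps the crop content-preserving). The magnification
correction factor between camera and OCT images is 1.0 for phantoms
(shared coordinate frame) and must be supplied for real data.

## The translator

The translator is the original pix2pix recipe, self-contained on CPU:

* **Generator**: U-Net with `log2(imageSize)` encoder levels (4×4
  convolutions, stride 2, pad 1), channel widths `ngf·2^k` capped at
  `8·ngf`, innermost layer at 1×1, mirrored decoder of transposed
  convolutions with skip concatenation, tanh output. Because depth scales
  with image size, tiny test configurations (32/64 px) use the identical
  code path as the 512 px profile.
* **Discriminator**: patch-based — three stride-2 and one stride-1 4×4
  convolution followed by a 1-channel head, emitting a spatial grid of
  real/fake logits (30×30 for a 256 px input); each cell judges one
  70×70-px receptive field.
* **Objective**: BCE-with-logits on patch scores plus λ-weighted mean
  absolute error, `G = adv + λ·L1`, λ = 100 by default. The adversarial
  term keeps outputs sharp; L1 alone blurs, adversarial alone introduces
  artifacts. The recorded history satisfies the identity exactly at every
  epoch, and a λ = 0 ablation yields equal-or-worse L1 against targets
  (tested over three seeds).
* **Normalization**: instance normalization (batch size is 1, where it is
  the batch-norm limit) everywhere except the first encoder layer, the
  1×1 bottleneck, and the output layer. Because its statistics depend
  only on the input, inference is deterministic — repeated translations
  are bit-identical. Decoder dropout from the original recipe is omitted
  for the same reason.
* **Optimizer**: Adam, lr 2·10⁻⁴, β₁ 0.5, β₂ 0.999 — the standard
  settings for this architecture; all config-exposed.
* **Checkpointing**: a generator snapshot every `checkpointInterval`
  epochs, `floor(epochs/interval)` snapshots in total; the default
  schedule (200 epochs, every 10) yields 20 per direction. Snapshot files
  are `g_<direction>_<epoch>.rds` with a JSON sidecar manifest.

Forward and backward passes of every layer are implemented in
Rcpp/RcppArmadillo (im2col convolution and its adjoint) with R-level
orchestration, and are verified against numerical differentiation in the
test suite. Determinism is a single-threaded CPU contract: a fixed config
seed covers initialization and data order, and two runs produce identical
loss histories.

## Checkpoint selection

Each saved generator translates the held-out sources; synthesized and
real target sets are embedded, fitted with sample mean and unbiased
covariance, and compared by the Fréchet distance
`‖µ_a−µ_b‖² + Tr(Σ_a+Σ_b−2(Σ_aΣ_b)^{1/2})` (matrix square root through
the symmetrized product, eigenvalues clamped at −10⁻⁶ relative
tolerance). Lower is better; the argmin checkpoint is selected, with ties
broken toward the earliest epoch since training past the optimum
overfits. The default desk embedding — resize to 32×32 grayscale, flatten,
fixed seeded random projection to 64 dimensions — exercises every code
path without a pretrained download; an inception-style extractor plugs in
through the same function interface. Absolute FID values depend entirely
on the embedding and are not comparable across extractors; only the curve
shape and argmin matter here.

## Quality metrics

* **PSNR** `10·log₁₀(255²/MSE)`; bit-identical pairs give an `Inf`
  sentinel that is excluded (with a count) from mean ± sd aggregates.
* **SSIM** with the field-standard parameterization — 11×11 Gaussian
  window, σ = 1.5, stabilizers `(0.01·255)²`, `(0.03·255)²` — averaged
  over all positions where the full window fits. RGB converts to gray by
  luma weights (0.299, 0.587, 0.114), used consistently package-wide.
* **Hamming distance** on the 64-bit average hash: resize to 8×8 by exact
  area averaging, bit = 1 iff strictly above the mean (constant images
  hash to all zeros). Both the raw count (0 = similar, 1–10 = potential
  variation, >10 = likely different) and the normalized raw/64 (used for
  aggregation, matching the magnitude convention of reported tables) are
  emitted, labelled in the CSV headers.
* **Perceptual feature distance**: per layer of a convolutional backbone,
  channel activations are unit-normalized per position; squared
  differences are averaged over channels and positions and summed over
  layers (layer weights 1). The per-position layer maps, upsampled and
  summed, localize perceptual differences. The default backbone is a
  3-layer seeded random convolutional stack — even untrained
  convolutional features rank perceptual similarity usefully — and a
  pretrained backbone can be plugged in. The distance is a pseudo-metric
  (zero on identical inputs, symmetric, nonnegative) and increases
  monotonically with additive noise dose on phantoms.

SSIM and PSNR are cross-checked against independently coded window-loop
references to 10⁻⁶; the Fréchet distance against univariate/diagonal
closed forms.

## Study sizes used in the tests

The acceptance suite trains one FA→OCT model at 32×32 on 150 phantom
pairs (130 train / 20 test after the stratified split) for 20 epochs with
snapshots every 5 — sizes chosen so the complete suite runs in a few
minutes while leaving the learning signal unambiguous: held-out
SSIM(translated, target) ≈ 0.66 versus an identity baseline of ≈ 0.17,
and a FID curve whose argmin falls mid-training. The same trained model
feeds the virtual-FA probe: three canonical diagrams of microaneurysm
dots on equidistant concentric rings around a presumed FAZ, with no,
focal, or diffuse leakage halos, are preprocessed like any FA frame,
translated, and decoded through the color scale. Decoded mean thickness
increases monotonically with leakage load (≈ 236 → 299 → 342 µm in the
seeded run), the desk-scale analogue of progressively wider thickening
around increasing leakage.

## Known limitations

* Phantom realism is deliberately minimal (see above); results quantify
  machinery, not clinical performance.
* The desk FID embedding and the desk perceptual backbone are untrained;
  absolute values are not comparable to inception-FID or AlexNet-LPIPS
  numbers.
* Determinism holds on a single CPU thread; multi-threaded BLAS or GPU
  execution is outside the test contract.
* Edge handling of fovea-centered crops (replication clamp) is a
  convention choice; alternatives (zero padding) would change border
  pixels only.
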