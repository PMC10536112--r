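---
title: "Methods: stabilization, temporal enhancement and capillary segmentation in videocapillaroscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stabilization, temporal enhancement and capillary segmentation in videocapillaroscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Videocapillaroscopy records the microcirculation of the oral mucosa with a
contact video probe (8-bit grayscale, 640 × 480, 120 frames per second at
around 150× magnification). Two physical effects make the raw video hard to
analyze. First, the handheld probe and the patient both move, so consecutive
frames are misaligned by a rigid jitter of the image plane. Second, red
blood cells (RBCs) flow intermittently through the finest capillaries, so in
any single frame only part of a vessel is perfused and visible; a capillary
appears as a broken, stroke-like trace that differs from frame to frame.

`capiflow` implements a three-stage pipeline that turns such a video into
binary capillary masks: rigid stabilization, temporal enhancement, and
segmentation with a small encoder–decoder convolutional network, plus the
evaluation metrics and a synthetic phantom generator that makes all of it
testable without clinical data.

## Stabilization

Stabilization is feature-based. For each pair of consecutive frames:

1. **Keypoint detection.** Blob keypoints are detected as strict local
   maxima of scale-normalized determinant-of-Hessian response maps
   ($\sigma^4 (L_{xx}L_{yy} - L_{xy}^2)$ at scales $\sigma = 1.2 \cdot
   1.4^{0\ldots3}$), with quadratic subpixel refinement. The response
   threshold starts at 1000 and is lowered in steps of 20 until both frames
   yield at least 10 keypoints or the threshold reaches zero. The rationale
   for demanding many keypoints is robustness: matches on moving objects
   (unchained RBCs) must be outvoted by matches on fixed structure.
   Detection at a given threshold is a cheap filter over a cached,
   threshold-independent candidate list, so the iterative loop costs almost
   nothing beyond the first detection.
2. **Description and matching.** Each keypoint gets an upright 64-D
   descriptor: a 20 × 20 grid of sample points spaced by the detection
   scale, local gradients Gaussian-weighted and pooled over a 4 × 4 grid of
   subregions into $(\sum dx, \sum |dx|, \sum dy, \sum |dy|)$, then
   L2-normalized. No dominant-orientation assignment is performed because
   inter-frame probe rotation is at most a few degrees. Matching is exact
   one-directional nearest-neighbour search in descriptor space (Euclidean),
   with no ratio test. Fewer than 5 matches abort the pair with
   "matches are too few".
3. **Good-match cascade.** With `min_dist` the smallest matching distance,
   matches with distance below $\max(2\,\texttt{min\_dist}, 0.02)$ are kept;
   if fewer than 5 survive the threshold relaxes to
   $\max(3\,\texttt{min\_dist}, 0.03)$; if still fewer than 5, the best 4
   matches are used. The floors 0.02/0.03 guard against a vanishing
   `min_dist` on near-perfect matches.
4. **Outlier rejection.** The image-plane displacement of each surviving
   match is computed; matches deviating from the mean displacement by more
   than twice the (population) standard deviation are discarded. Population
   rather than sample standard deviation is used; the bundled test cases
   were checked to be insensitive to that choice.
5. **Motion estimation.** The rigid transform (rotation + translation, no
   scale) is estimated in closed form by centroid alignment and 2-D
   orthogonal Procrustes analysis. A single surviving match degrades to pure
   translation. The motion model is rigid throughout — for a contact probe,
   perspective effects between consecutive frames are negligible — and the
   warp applied is the rigid one.

Pairwise motions are composed into cumulative transforms with frame 0 of
each segment as the reference, and every frame is warped into that frame
with bilinear interpolation. Out-of-canvas pixels are filled with 0 and
tracked in an explicit validity mask so that downstream temporal statistics
can exclude them. Sequences are split into segments wherever the inter-frame
displacement magnitude exceeds a threshold; the probe operator periodically
sweeps between regions of interest, and those sweep intervals are not
analyzable. No threshold value is prescribed by the acquisition protocol, so
the default is 10% of the frame width per frame pair, configurable.
Motion-aligned frames can also be stitched onto a union-bounding-box canvas,
averaging overlapping pixels and copying non-overlapping pixels verbatim.

## Temporal enhancement

Perfused capillaries flicker; static tissue does not. Over a sliding window
of $2n+1$ frames centred at frame $k$ the per-pixel mean

$$B(i,j,k) = \frac{1}{2n+1} \sum_{k'=k-n}^{k+n} I(i,j,k')$$

and population standard deviation

$$\sigma(i,j,k) = \sqrt{\frac{1}{2n+1} \sum_{k'=k-n}^{k+n}
  \bigl(I(i,j,k') - B(i,j,k)\bigr)^2}$$

are computed; near the sequence ends the window is clamped to existing
frames and the divisor is the actual frame count. The enhanced image is the
subtraction $H = I - \sigma$: pixels perfused at any time in the window have
large $\sigma$ and are darkened, which reconstructs vessel segments that are
invisible in the current frame. $H$ is shifted positive, linearly scaled so
its maximum maps to 255 (a flat frame maps to 0), and median-filtered with a
3 × 3 mask before 8-bit quantization.

Defaults and choices:

* `n = 5` (an 11-frame window). At 120 fps this spans ≈ 0.09 s, on the
  order of the perfusion recovery time of the intermittent regions.
* All arithmetic is floating point; quantization happens once, at HF.
* The shift-and-normalize scope is per frame (each enhanced frame is scaled
  independently); a per-sequence scope would couple distant frames through
  a global extremum and is not what the per-frame appearance of enhanced
  capillaroscopy images suggests. Normalization is invariant to adding a
  constant to all frames, which the test suite asserts.
* The median filter uses replicate padding at the borders.
* A pixel is marked invalid in HF when it is invalid (warped-in) in at
  least half of the window frames or in the current frame; invalid pixels
  are excluded from the window statistics and set to 0, never NaN.

## Segmentation

The segmenter is a compact U-shaped encoder–decoder network: four
contracting blocks of two 3 × 3 convolutions + ReLU with 2 × 2 max pooling
between levels (filter counts 32, 64, 128, 256 by default), a mirrored
expanding path using 2 × 2 up-convolutions with skip concatenations from the
matching encoder level, and a final 1 × 1 convolution to two per-pixel class
scores; the output has the spatial size of the input. Inputs are 160 × 160
grayscale tiles scaled to [0, 1]. Forward pass, backpropagation and the
per-pixel class-weighted softmax cross-entropy are implemented in compiled
code (RcppArmadillo, im2col + GEMM); the Adam optimizer (step size $10^{-3}$,
one tile per step) runs in R.

Data preparation follows a fixed order: each source image/mask pair is
rotated about its center by angles sampled equally spaced in (0°, 360°)
(bilinear for images, nearest-neighbour + re-binarization for masks,
background fill for uncovered corners); every rotated pair is cut into
160 × 160 tiles on a top-left-anchored grid with a final row/column flush
with the border (full coverage with overlap, since 620 and 476 are not
multiples of 160; discarding border capillaries would waste scarce
annotation); finally tiles whose mask holds fewer than 200 white pixels are
removed as uninformative. The default augmentation uses a handful of angles;
the number is configurable and treated as descriptive, not contractual.

Class weights compensate the strong background/capillary imbalance with the
inverse-frequency rule $w_c = \text{total}/(2\,\text{count}_c)$, so the
minority (capillary) class receives the larger weight. A literal
"proportional to the pixel counts" weighting would up-weight the majority
class and defeat the stated purpose of the weighting, so the inverse form is
implemented.

Evaluation uses leave-one-out cross-validation over source images: one
training per image, with every tile derived from the held-out image —
augmentations included — excluded from that fold's training set and used as
the validation set. Training runs all epochs (20 by default) and the
checkpoint with minimum validation loss predicts the held-out full image:
tiles are predicted independently, overlapping foreground probabilities are
averaged, and the merged map is binarized at 0.5. Whether the validation
tiles should also pass the sparse-mask filter is not prescribed anywhere;
they do here, which keeps the fold's loss comparable to the training loss.

Agreement between predicted and ground-truth masks is quantified by the
Jaccard index (IoU), sensitivity, specificity and accuracy. Cross-validation
folds are aggregated two ways — the unweighted mean of per-fold metrics
(headline) and metrics recomputed from pooled pixel counts — because the two
differ on unequal folds and neither is canonically "the" summary. With both
masks empty the Jaccard index is defined as 1; with exactly one empty, 0.

## The phantom generator

Clinical capillaroscopy databases with expert consensus masks are small and
not freely redistributable, so the package ships a synthetic phantom that
reproduces the statistical structure the pipeline relies on, not the
biophysics:

* dark tortuous vessels: smoothed random-walk centerlines dilated to a
  sampled width (4–8 px), darkened by a configurable contrast (default 60
  gray levels) on a brighter textured background (level 180) with
  stationary high-contrast blobs that guarantee detectable keypoints;
* intermittent RBC flow: each centerline is split into arcs (default 40 px)
  that are independently visible in each frame with probability
  `flow_visibility` (default 0.6);
* rigid probe jitter: per-frame-pair translations and rotations sampled
  uniformly (defaults ±2 px and ±0.3°; at 120 fps larger per-frame motion
  would correspond to the probe sweeping between regions — the regime that
  sequence splitting removes — rather than steadied-probe tremor). A
  smooth-drift mode exists for testing the splitter. The exact sampled
  motions are returned, enabling sub-pixel accuracy claims to be tested
  against ground truth;
* additive Gaussian sensor noise (default σ = 4), applied last, followed by
  8-bit quantization.

Everything is deterministic given the seed, and the caller's RNG state is
preserved. What the phantom does **not** emulate: optical blur anisotropy,
illumination drift, RBC velocimetry, non-rigid tissue deformation, and the
low vessel/background contrast of the worst clinical frames. Passing tests
on phantoms therefore demonstrates correctness of the algorithms under the
pipeline's stated assumptions, not clinical-grade performance.

## Validation experiments and problem sizes

The package validates itself end-to-end at sizes chosen to run in minutes on
one CPU:

* **Motion recovery** — a 620 × 476, 20-frame phantom with jitter up to
  20 px / 5° per pair; every estimated pairwise motion must fall within
  0.5 px and 0.2° of the logged truth. Typical errors are an order of
  magnitude below the bound.
* **Closed forms** — windowed statistics against brute-force per-pixel
  loops (machine precision), the 0/255 alternating 11-frame window
  (σ ≈ 126.97), the good-match cascade and 2σ rejection against
  hand-evaluated sets.
* **LOOCV smoke run** — two 620 × 476 static phantoms, two augmentation
  angles (≈ 44 retained tiles), a reduced encoder (8, 16, 32, 64), 10
  epochs: mean held-out Jaccard ≥ 0.6. With vessels 4–8 px wide a ±1 px
  boundary error already costs ≈ 0.3 Jaccard, so this threshold indicates
  a correctly learning segmenter rather than a saturated one.
* **Preprocessing ablation** — for each configuration (raw frames,
  enhancement only, stabilization + enhancement) a reduced network is
  trained on tiles from one 320 × 240 jittered, intermittent-flow phantom
  video and evaluated on a second, independent one, with ground truth
  transported into each frame's coordinates via the exact motion log. Each
  configuration is trained on its own preprocessed data because that is how
  preprocessing benefits segmentation in practice; reusing one network
  across differently distributed inputs would measure domain mismatch
  instead. The expected ordering — pipeline > enhancement-only > raw, each
  by a positive margin — reflects that enhancement reconstructs invisible
  vessel segments and stabilization removes the σ-smearing that jitter
  causes.

## Numerical and degenerate-input choices

* Bilinear warps clamp their output to [0, 255] to absorb floating-point
  round-off; warped-out pixels carry an explicit validity flag.
* Featureless frames exhaust the detection threshold and yield empty
  keypoint sets; the matcher then aborts with the explicit
  "matches are too few" error naming the frame pair.
* Zero displacement spread keeps all matches (no outlier rejection).
* A flat enhanced frame maps to 0, avoiding division by zero in the
  normalization.
* Tiles are never sampled outside the image: the flush anchor guarantees
  in-bounds tiles for any image at least one tile large.
* He-normal initialization, Adam moments zeroed at start, and all
  shuffling/initialization seeds derived from one master seed make training
  runs reproducible bit-for-bit on a fixed BLAS.

## Known limitations

* The rigid motion model ignores perspective and non-rigid deformation;
  strong mucosal deformation between frames would leave residual motion.
* Exact nearest-neighbour matching is quadratic in keypoint count; it is
  exact (important for reproducibility) and fast at the few hundred
  keypoints per frame this application produces, but an approximate index
  would be needed for orders of magnitude more.
* The training loop is single-threaded and tile-at-a-time; it is sized for
  the package's validation experiments and small studies, not for training
  the full-width network on large datasets.
* Video containers are not decoded; frames are exchanged as PNG/TIFF
  directories (deterministic and codec-free).
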