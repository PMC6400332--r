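---
title: "Weak PET-derived labels for CT bladder segmentation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weak PET-derived labels for CT bladder segmentation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(suvseg)
```

## The problem

Delineating the urinary bladder in CT is clinically important (radiotherapy
planning for prostate and bladder cancer, computer-aided detection,
bladder-wall measurements) but hard to automate directly: soft-tissue
contrast around the bladder is poor, its shape and position vary widely, and
manual annotation at scale is impractical. Co-registered PET/CT offers a way
out. The glucose-analogue tracer ¹⁸F-FDG is excreted through the kidneys and
accumulates in the bladder, so the bladder is by far the brightest, highest-
contrast structure in abdominal PET. A trivial operation on PET therefore
yields a usable, fully automatic "weak" ground truth for the co-registered
CT — no human annotation at any point — and that labeled CT data can train a
semantic segmentation network that at test time needs CT only.

`suvseg` implements that complete pipeline: weak-label generation by SUV
thresholding, exact-count data augmentation with patient-level splitting,
two desk-scale segmentation network families trained from scratch, and
standard segmentation metrics. A synthetic PET/CT phantom generator stands
in for clinical data so every stage is testable end to end.

## Weak labels by SUV thresholding

For each PET dataset the threshold is a fixed fraction of the dataset-wide
maximum standardized uptake value,

$$T = \mathrm{SUV}_{max} \cdot 0.2,$$

computed once per 3D dataset (never per slice). Voxels **strictly above**
$T$ are foreground; a voxel exactly at $T$ is background. We read "above"
literally; the equal-value case has measure zero on real-valued data and is
pinned by a unit test so the convention cannot drift. The fraction (default
0.2, i.e. 20%) is exposed as `threshold_rule(fraction)` with
$0 < \mathrm{fraction} < 1$.

Because labels must align pixel-for-pixel with CT training slices, PET is
always resampled onto the CT grid — never CT onto PET — with trilinear
interpolation, and the threshold is computed on the resampled volume.
Trilinear interpolation is a convex combination of neighbours, so it can
never exceed the native maximum: resampling cannot create foreground above a
threshold derived from the native grid, and computing $T$ after resampling
keeps the whole labeling a function of a single volume. All resampling uses
one convention everywhere: axes ordered (slice, row, col), 0-based physical
indexing off voxel centres, out-of-field values 0. A single convention
avoids half-pixel drift between mask and image.

Slices carrying at least one foreground pixel are extracted as training
pairs, ordered by slice index. Whether "slices around the bladder" should
include empty-context neighbours is genuinely ambiguous; the `margin`
argument exposes both readings (default 0 = foreground-bearing slices
only). No connected-component filtering is applied: the labeling is the
threshold rule alone, so stray uptake would pass through — on clinical
abdominal data the bladder dominates, and on phantoms there is no other
uptake.

## Data augmentation with exact accounting

Augmentation is configured by explicit lists: rotation angles (degrees, each
$|\theta| \le 180$, 0 required), per-axis scale factors (each within
$[0.85, 1.15]$, 1.0 required), and noise specifications. Every slice is
expanded into the full cross-product of angles × x-scales × y-scales
(identity included), and each transformed variant is duplicated `copies`
times per noise spec, so the output count is exactly

$$N_{out} = N_{in}\cdot|\Theta|\cdot|S_x|\cdot|S_y|\cdot\Big(1 + \sum_i c_i\Big).$$

The default configuration — angles $\{-45°, 0°, +45°\}$, scales
$\{0.9, 1.0, 1.1\}$ per axis, one Gaussian copy (sd 5) per variant — gives
27 transformed variants and 54 total per slice, so 630 input slices expand
to exactly 34,020 pairs. The bounds on angle, scale, noise sd (≤ 10),
amplitude (≤ 10) and salt-and-pepper density (≤ 0.5) are enforced at
configuration time. We chose explicit lists over "number of rotations"
count parameters because counts under-determine the actual transforms;
the printed expansion factors, which are the verifiable contract, fall out
of the list lengths by construction.

Rotation and scaling are applied about the image centre with the output
canvas unchanged (networks need a fixed input size). The image is
interpolated bilinearly; the mask by nearest neighbour, so it stays binary
under every transform. Out-of-canvas regions are filled with the image
minimum (mask: 0). Noise touches images only, never masks: Gaussian
(zero-mean, given sd), uniform ($\pm$ amplitude), or salt-and-pepper (a
fraction `density` of pixels set to the image min or max, half each).

Splitting is at patient level: whole patients are shuffled (seeded) and
assigned greedily to the training side until it first reaches the target
slice fraction (default 0.8). No slice of a patient may appear on both
sides — slices of one patient are highly correlated, and splitting them
would leak test information into training. Augmentation is applied to the
training side only; the test side is never augmented.

## Network families

Both families map a 1-channel CT slice to 2-class per-pixel logits at input
resolution and are trained identically.

**FCN-8s-style.** A VGG-16-shaped backbone (13 3×3 convolutions in five
stages separated by 2×2 max pooling) whose fully connected layers are
realized as convolutions (7×7, then 1×1). The stride-32 score head is
upsampled ×2 and summed with a 1×1 score map from the fourth pooling stage;
the result is upsampled ×2 again, summed with a score map from the third
pooling stage, and upsampled ×8 to input size. Skip fusion is elementwise
addition of 2-channel score maps, and the pool3/pool4 score convolutions
are zero-initialized, so at initialization the deep head passes through
unchanged and the skips learn corrections. Input sizes must be divisible
by 32.

**Upsampled ResNet-style.** A pre-activation residual backbone of four
stages (two blocks per stage by default) with stage strides 2, 2, 2, 1.
The final stage keeps resolution and uses atrous (dilated, rate 2)
convolution instead of further striding, so the deepest feature map is
input/8 — "output stride 8", the standard trade-off between feature-map
density and cost. A 1×1 score convolution and a fixed bilinear ×8
interpolation produce the logits. Input sizes must be divisible by 8. No
batch normalization appears anywhere: training uses batch size 1, where
batch statistics are undefined.

**Fixed bilinear upsampling.** All upsampling is transposed convolution
with the separable triangular kernel of side $2f - (f \bmod 2)$; for
factor 2 the central 2×2 block is $0.75^2 = 0.5625$. These kernels are
constants, excluded from training — learned upsampling kernels add cost
without measurable benefit in this setting. On interior pixels the operator
equals direct bilinear interpolation at source positions
$(i + 0.5)/f - 0.5$; a unit test checks this to $10^{-5}$ for factors 2
and 8, and rate-1 atrous convolution is checked elementwise against plain
convolution.

**Width scaling.** `width_scale` multiplies every channel count
(minimum 2). Published backbones pre-trained on natural images are *not* a
dependency: at desk scale the networks train from scratch on phantom data.
Transfer-learning effects on clinical data are therefore outside what this
package can demonstrate.

## Training

Single-image steps (batch size 1) with Adam at a fixed learning rate of
$10^{-4}$ — Adam adapts per-parameter step sizes internally, so no external
decay schedule is used — minimizing mean per-pixel softmax cross-entropy
between the 2-class logits and the binary mask. Images are z-scored per
slice before entering the network, which keeps optimization conditioning
independent of the HU-like intensity scale. The sampling order of training
images is drawn from the spec's seed; two runs with identical inputs and
seeds produce bit-identical loss traces. Prediction is per-pixel argmax
with ties to background (the conservative choice for a screening mask).

## Evaluation metrics

Per slice pair, from the pixel confusion counts:
$\mathrm{TPR} = TP/(TP+FN)$ (sensitivity),
$\mathrm{TNR} = TN/(TN+FP)$ (specificity),
$\mathrm{DSC} = 2|S_g \cap S_p| / (|S_g| + |S_p|)$, and the symmetric
Hausdorff distance
$HD(A,B) = \max(h(A,B), h(B,A))$ with
$h(A,B) = \max_{a \in A} \min_{b \in B} \lVert a-b \rVert_2$, computed on
foreground pixel coordinate sets and reported in pixel units. Interior
points never realize the max–min, so point sets are equivalent to contours
here and exactly checkable against a brute-force oracle. TPR is undefined
without ground-truth foreground, DSC when both masks are empty, HD when
either is; undefined values are excluded from cohort means with a logged
count (zero-filling would conflate "no prediction" with "perfect
background", and the choice is deliberately explicit because conventions
differ between papers). HD is deliberately outlier-sensitive — one stray
pixel moves it arbitrarily while changing DSC by $O(1/\mathrm{area})$ —
which is why both are reported.

## The phantom

`generate_phantom()` builds paired PET/CT volumes with a known bladder
mask:

* **CT**: soft-tissue background (40) plus a small bladder offset
  (default −25; urine is mildly hypodense), a high-attenuation elliptical
  "pelvic ring" (+600), optional radial streak stripes inside the ring
  (low-amplitude sinusoid in angle — a qualitative stand-in for beam-
  hardening streaks, not a CT physics simulation), and additive Gaussian
  noise (sd 10).
* **PET**: background 0.25, bladder rim at `uptake_ratio` × background
  (default 10), and a central *hot core* at `hot_core_ratio` (default
  2.75) times the rim level. Excreted tracer concentrates towards the
  bladder centre, so the dataset SUV maximum sits well above the rim —
  as in clinical FDG data, where bladder SUV far exceeds the 20%
  threshold level. With the defaults the threshold
  $T = 0.2 \cdot \mathrm{SUV}_{max}$ lands at the midpoint of the blurred
  bladder/background edge, where it delineates the boundary without bias;
  a uniform-uptake bladder would put $T$ at ~11% of the edge ramp and
  systematically dilate every mask by 1–2 px. The PET volume is blurred
  in-plane (Gaussian, default 1.5 CT pixels, the partial-volume model) and
  block-averaged to a grid coarser in-plane by `pet_downsample_factor`
  (default 2), emulating PET's lower spatial resolution.
* **Truth**: the ellipsoid rasterized on the CT grid (voxel centre inside).
  A degenerate ellipsoid falls back to the single voxel nearest its
  centre, so the mask is never empty.

Cohorts jitter bladder size, in-plane position, contrast, uptake and noise
per patient from a seeded RNG, and size each patient's ellipsoid along z to
occupy an exact requested number of slices, so cohort totals (e.g. 29
patients, 845 bladder-bearing slices) are constructible. All randomness
flows through seeds derived from one master seed; no global RNG state is
disturbed.

What the phantom does *not* emulate: attenuation/scatter physics,
respiratory or bladder-filling motion between PET and CT, non-bladder
uptake (kidneys, ureters, tumours), irregular bladder shapes, and the
bladder–prostate interface. Passing tests on phantoms therefore
demonstrates the pipeline's mechanics and the architectures' capacity, not
clinical segmentation accuracy.

## Problem sizes and numerical choices

The reference in-plane grid is 128×128 (2 mm pixels); demonstrations and
tests use 96×96 and 64×64 (divisible by 32, as FCN-8s requires) with
`width_scale` 0.125 so the full suite runs on a single CPU in minutes.
These are the package's desk-scale study conditions; clinical 512×512
training with full-width, pre-trained backbones on GPU is out of scope.
The network-capacity check trains on ten central bladder slices (cross-
sections of ≥150 px, comfortably above the networks' output stride of 8);
pole slices whose cross-section is smaller than one deep-feature cell are
kept in the data but are a documented architectural blind spot — heavily
downsampled feature maps lose objects smaller than their stride.

Slice exports store images as 16-bit TIFF with a fixed DICOM-like
intercept of 1024 (`stored = round(x) + 1024`), masks as 8-bit {0, 255}
PNG; both round-trip bit-exactly for integer-valued images in
[−1024, 64511]. NIfTI is the volume interchange format. 16-bit integer
storage, not float, keeps exports compact and exactly reproducible.

## Known limitations

* The weak labels inherit every PET artifact: partial-volume blur makes
  them imperfect at object boundaries, and small cross-sections threshold
  poorly. This is intrinsic to the method, visible on the phantom, and
  quantified by the label-fidelity check (3D DSC ≥ 0.95 under default
  conditions).
* From-scratch desk-scale training does not reproduce clinical-scale
  accuracy figures; the package's training checks are capacity
  (memorization) and loss-decrease properties, not generalization claims.
* DICOM reading is not provided; volumes enter as NIfTI.
* Hausdorff distances are reported in pixels, not millimetres, matching
  the segmentation-evaluation convention used for slice-level reporting.
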