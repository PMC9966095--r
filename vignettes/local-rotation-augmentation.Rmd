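---
title: "Local-rotation augmentation: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local-rotation augmentation: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlraug)
```

## The operator and its assumptions

Whole-image rotation inside a fixed canvas uncovers the corners, and the
uncovered region must be invented — constant black, nearest-edge repetition,
mirror reflection or periodic wrap. All four fills inject content absent from
the original data, and for texture-dominated biomedical images (nuclei
fields, histology tiles) the injected structure can be a substantial fraction
of the canvas.

Random local rotation (RLR) instead rotates the content of a disk
`C(x, y, r)` in place:

```
Ĩ = M ⊙ rot(I; x, y, θ) + (1 − M) ⊙ I
```

with `M` the rasterised disk membership mask. The operator assumes only that
the local texture is approximately rotation-tolerant at the sampled scale —
the same assumption whole-image rotation makes globally — and in exchange it
guarantees two exact properties that the package asserts per pixel:

* **outside-disk invariance** — the disk complement is returned bit-for-bit;
* **no-fill** — under nearest interpolation every output value occurs
  somewhere in the input, so there is no boundary artefact to invent.

Random centre rotation (RCR) is the degenerate case with the centre fixed at
the continuous image centre `((H−1)/2, (W−1)/2)` and the radius fixed at the
largest value honouring containment, `(min(H, W) − 1)/2 − 1`; only the angle
is random. It is a drop-in replacement for traditional rotation.

## Coordinate and intensity conventions

One convention is stated once and used everywhere: 0-based `(row, col)`
pixel coordinates with pixel centres at integers; angles counter-clockwise in
radians, normalised to `[0, 2π)`; intensities floating in `[0, 1]`, converted
from 8- or 16-bit integers on I/O by dividing by the type maximum. The
float-`[0, 1]` domain is our choice (the augmentation literature is typically
silent on whether `[0, 255]` integers or normalised floats are transformed);
it makes 8- and 16-bit microscopy data follow identical arithmetic.

Disk membership is decided at pixel centres,
`(i − x)² + (j − y)² ≤ r²`, with no anti-aliased partial coverage. Fractional
coverage would blend the seam and look smoother, but it would destroy the
bitwise outside-disk invariance that makes the operator testable exactly;
seam blending is deliberately out of scope.

## Sampling distributions and the containment guard

The reference description of RLR says only that centre, radius and angle are
"randomly generated", so the distributions are pinned here as package
defaults:

* **radius** — uniform on `[0.10, 0.45] · min(H, W)`. The lower bound avoids
  no-op specks; the upper bound guarantees at least one legal centre exists.
* **centre** — uniform over all positions for which the disk, plus a
  one-pixel guard band, lies inside the image (`r + 1 ≤` distance to every
  border). Disks crossing the border are forbidden: the inverse rotation map
  then never leaves the grid, and the guard absorbs the ≤ 0.5 px shift that
  nearest-neighbour rounding can introduce.
* **angle** — uniform on `[0, 2π)`.

Whether partially out-of-frame disks should be allowed is genuinely open; we
forbid them because every in-disk source point is then a real pixel, keeping
the no-fill property unconditional.

Nearest-neighbour interpolation is the default for both image and mask: it is
exactly invertible at quarter-turn multiples about integer centres (the basis
of the permutation oracle tests) and can never produce a label outside the
mask's input label set. Bilinear interpolation is offered for images only.

## Traditional operators: pinned dialects

Each classical operator family is implemented with one fixed, tested
convention, since the descriptions in the augmentation literature rarely pin
them down:

* **Whole-image rotation** rotates about the continuous centre, keeps the
  input canvas, and resolves out-of-grid inverse-map indices per fill policy:
  `constant` (default black), `nearest` (index clamp), `reflect`
  (edge-inclusive "symmetric" mirroring), `wrap` (modulo). The reflect
  dialect and the centre convention are our pins, enforced by a per-pixel
  index-rule oracle on small grids.
* **Crop-resize** draws an area fraction uniformly on `[0.08, 1]` (patches as
  small as 8% of the image, the conventional lower bound) and an aspect ratio
  log-uniformly on `[3/4, 4/3]`; the crop inherits its source label
  unchanged, reproducing the well-known mislabelling caveat of aggressive
  cropping. The resize maps `src = (dst + 0.5)·scale − 0.5`, so a same-size
  resize is the identity.
* **Photometric jitter**: brightness is multiplicative (`clip01(f·I)`) —
  chosen over additive offsets for bit-depth scale invariance; contrast
  pivots about the mean luma; saturation interpolates towards per-pixel luma.
  Luma weights are pinned at ITU-601 `(0.299, 0.587, 0.114)`. The transfer
  functions themselves are our choices: the source material shows example
  images, not formulas.
* **Kernel filters**: Gaussian blur truncates at half-width `⌈3σ⌉` with
  renormalisation and reflect borders (symmetric kernel + symmetric padding
  preserves the image mean exactly); Sobel magnitude is rescaled by its
  maximum possible response `4√2` to lie in `[0, 1]`; sharpening is the
  unsharp mask `clip01(I + amount·(I − blur(I, σ)))`. Motion blur is out of
  scope.
* **Noise**: additive Gaussian, salt-and-pepper (pixels corrupted jointly
  across channels to pure white or black with equal probability — matching
  the visual definition of impulsive noise), multiplicative speckle. All are
  identity at zero parameters.
* **Random erasing** honours its realised area-fraction bounds
  (`[0.02, 0.33]` by default) after integer rounding — infeasible roundings
  are retried — and fills per-pixel uniform noise by default; one-value and
  constant fills are offered because "a random value" is ambiguous between
  one value and many.

## Paired segmentation mode

Geometric operators (RLR, RCR, the four rotation policies, flips, crops)
apply one shared draw to image and mask; the mask always uses nearest
interpolation, so its output label set is contained in its input label set.
Under the constant fill policy, uncovered mask pixels receive label 0,
treated as the universal background label — the one place where a label can
appear that the input lacked, and only if the input had no background at all.
Photometric, filter and noise operators are image-only: they move no pixels,
so equivariance is the identity, and the mask passes through untouched. Mask
semantics under erasing are genuinely undefined (the rectangle may delete the
object entirely); the package leaves the mask intact and documents the
choice.

## Dataset orchestration, seeds and replay

A pass selects `n` images (default all; without replacement for replace mode,
with replacement allowed above `|D|` for append), transforms each, and forms
the output Way-1 (`D* ∪ (D ∖ D′)`, size unchanged) or Way-2 (`D* ∪ D`, size
`|D| + n`). Class-balanced subsetting assigns `⌊n/k⌋` per class with the
remainder going deterministically to the lowest-sorting class labels.
Subset draws default to unbalanced uniform sampling — balancing belongs to
subset construction, not to the augmentation draw — with `balanced_subset()`
available where the protocol calls for it.

The plan seed drives subset selection and one derived seed per generated
item; each item seed drives that item's parameter draw. The manifest records
every sampled parameter at 17 significant digits (lossless for IEEE doubles).
Replay applies geometric and photometric draws directly from the recorded
scalars; noise-field operators (the three noise models and per-pixel-uniform
erasing) would need the whole pixel field recorded, so the manifest instead
stores the item seed and replay regenerates the field from it — equally
bit-exact, at the cost of tying replay to R's RNG stream rather than to
recorded values alone.

## Synthetic fixtures

`gen_nuclei()` emulates a fluorescence-microscopy nuclei field: rotated
ellipses with Gaussian intensity profiles (`A·exp(−2q)` on the normalised
elliptical coordinate `q ≤ 1`) over a flat background with additive Gaussian
noise; the mask is exactly the union of the support ellipses. Defaults scale
with the canvas (≈ 12 nuclei and 4–10 px semi-axes per 128 × 128). With
overlap disallowed, placement enforces a conservative centre-distance
separation, so the component count equals the blob count by construction.
The generator gives exact ground truth, deterministic under a seed, at
fixture scale — a 670-pair corpus at 128 × 128 builds in seconds. What it
does not emulate: Poisson shot noise, uneven illumination, textured
cytoplasm, touching nuclei and annotation error. Passing tests therefore
demonstrate the operators' geometric and statistical contracts, not
segmentation performance on real microscopy.

`gen_coordinate_image()` encodes each pixel's own coordinates in its value,
turning any nearest-interpolation geometric operator into a readable
permutation — the substrate for the brute-force oracle tests.

## Numerical choices and degenerate inputs

Nearest-neighbour rounding uses R's `round()` (round-half-to-even); the
brute-force oracles share the convention, the algorithm they check does not
share code. Images must be at least 2 × 2; RCR requires a positive centred
radius (min dimension ≥ 5); samplers retry bounded times on infeasible draws
(radius without a legal centre, crop/erase windows that round infeasible) and
then fail loudly rather than silently degrade. `clip01()` rejects non-finite
values instead of propagating them.

## Problem sizes in the tests

The test suite and the acceptance script run the exhaustive oracles on grids
up to 16 × 16 (disk rotation) and 8 × 8 (whole-image rotation, four policies
× four angles), locality audits over 1,000 draws at 64 × 64, and
moment-recovery checks on ~10⁵ pixels with 3-standard-error tolerances —
sizes chosen so the full suite runs in under a minute while every check
remains exhaustive or statistically calibrated rather than anecdotal.

## Known limitations

* Only circular regions; elliptical or polygonal local rotation and seam
  feathering are non-goals.
* One disk per generated image; multi-disk augmentation is explicit user
  chaining.
* PNG output is 8-bit (16-bit output goes through TIFF).
* No training loop, model zoo or accuracy evaluation: this package generates
  and replays augmented datasets; judging downstream classifier benefit is a
  separate experiment.
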