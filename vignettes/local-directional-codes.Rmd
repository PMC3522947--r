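---
title: "Local directional codes for vascular pattern matching: methods and design"
author: "veinLDC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local directional codes for vascular pattern matching}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(veinLDC)
```

## The problem

Finger-vein recognition identifies a person from the pattern of subdermal
blood vessels imaged by near-infrared transillumination: hemoglobin absorbs
NIR light, so vessels appear as dark curvilinear shadows on a brighter
tissue background. Segmenting the vessel network explicitly is fragile —
scattering blurs the images and a badly segmented network destroys
recognition — so binary-pattern descriptors that work directly on local
intensity structure are attractive. A vessel is, locally, an oriented
structure; its orientation field is the information a segmentation-free
descriptor should keep.

The Local Directional Code (LDC) does exactly that: at every interior
pixel it measures the local gradient direction from two differences in the
3×3 neighborhood and stores it as an integer code in `[0, T)` after
quantizing the angle into `T` dominant orientations. An image becomes a
code map; two images are compared by the fraction of positions carrying
the same code.

## The descriptor

With row index `i` growing downward and column index `j` rightward, the
axis-aligned variant (LDC-00) uses

* `v_v = X(i, j+1) − X(i, j−1)` (right minus left) and
* `v_h = X(i−1, j) − X(i+1, j)` (top minus bottom),

and the diagonal variant (LDC-45) the corresponding 45°-rotated
differences (top-right minus bottom-left, bottom-right minus top-left).
The angle is mapped to the full circle as `θ′ = atan2(v_h, v_v) + π ∈
[0, 2π]`, and quantized by nearest sector:

```
t = floor(θ′ / (2π/T) + 1/2) mod T
```

so sector centers sit at `t · 2π/T` — for `T = 8`, the eight half-axis and
diagonal directions `t·π/4`. Border pixels are skipped; a `W × H` image
yields a `(W−2) × (H−2)` map.

Numerical conventions, all of which matter for exact reproducibility and
are pinned by tests:

* **Two-argument arctangent, not a quotient.** `atan(v_h/v_v)` is
  undefined at `v_v = 0`; `atan2` covers the axes and reproduces the
  per-quadrant sign-case table exactly (the suite verifies the
  equivalence on all quadrants).
* **Zero-gradient pixels.** `atan2(0, 0) := 0`, so a locally flat pixel
  gets `θ′ = π` and code `T/2`. Any fixed convention preserves matching
  semantics (both maps code flat pixels identically); this one is
  deterministic and documented.
* **Quantizer reading.** The `+1/2` belongs inside the floor — nearest-
  sector rounding, as in the Weber-descriptor lineage of orientation
  coding; it is the only reading that produces integer codes `0..T−1`.
* **Rotation structure.** Rotating an image by 90° rotates the code map
  and adds `T/4 (mod T)` to every code (for `T` divisible by 4, away from
  zero-gradient pixels). The suite checks this equivariance on smooth
  fixtures; it is a strong whole-pipeline invariant because it couples
  the neighbor layout, the angle map and the quantizer.

`T` trades discriminability against statistical reliability: more sectors
discriminate orientation more finely, but each code becomes rarer and
noisier. `T = 8` is the default; `sweepT()` recomputes the verification
error over a list of `T` values.

## Preprocessing

Raw captures are 24-bit 320×240 frames with the finger as a bright band
on a dark background. The chain, each stage independently callable:

1. **Gray conversion** `Y = 0.299R + 0.587G + 0.114B`.
2. **ROI detection**: 3×3 Sobel vertical-edge mask (`[−1 0 1; −2 0 2;
   −1 0 1]`); columns containing responses above `edgeThreshold` (default
   0.25) of the maximum give the horizontal extent, the transposed mask
   gives the vertical extent; the box is their intersection. A uniform
   image has no edges and is rejected as an unusable capture.
3. **Size normalization**: bilinear interpolation to 96×64,
   align-corners convention (source corners map to destination corners).
   Bilinear interpolation cannot overshoot, so outputs stay within the
   source range.
4. **Gray normalization**: min–max stretch to `[0, 255]`. A constant
   image is an error (the stretch is undefined and downstream codes would
   be meaningless).

Every floating-point pixel value is rounded **half-up** to the nearest
integer. The convention is arbitrary but must be fixed: matching compares
codes exactly, so any rounding drift would silently change scores.

## Matching and evaluation

Two code maps with identical dimensions, variant and `T` are compared
position-wise; the score is the fraction of agreeing codes. There is no
translation or rotation search — registration is preprocessing's job —
and mismatched maps are an error, never a silent crop. Two independent
uniform random maps agree at a rate of about `1/T`, which is the floor
imposter scores approach.

**Verification** (1:1): every sample is matched against all other samples
of its class (genuine) and, to bound the quadratic cost, against the
first `k = 6` samples of every other class (imposter), each unordered
pair counted once since scores are symmetric. For `C` classes of `S`
samples this gives `C·S(S−1)/2` genuine and `C(C−1)/2·k²` imposter pairs
— 59,160 and 330,480 under the 136×30 collection design. Threshold
sweep: `FAR(τ)` = imposters at or above `τ`, `FRR(τ)` = genuines below
`τ`; EER is read at the FAR/FRR crossing with linear interpolation
between the bracketing thresholds (no procedure is canonical; linear
interpolation is the standard neutral choice). The zero-FRR operating
point is the **largest** threshold rejecting no genuine (its FAR is the
fraction of imposters scoring at least the weakest genuine); the
zero-FAR point is the smallest threshold admitting no imposter.

**Identification** (closed-set 1:N): the first 10 samples of each class
are probes; one template per class is drawn from the remaining samples by
a seeded uniform draw (the seed is recorded in the report). A probe's
rank is one plus the number of templates scoring strictly higher —
optimistic tie handling, kept as the primary definition, with a
pessimistic mode available for sensitivity analysis. CMC(r) is the
fraction of probes at rank ≤ r; headline numbers are the rank-one rate
and the lowest rank of perfect recognition.

## The synthetic database

No public finger-vein corpus matches the collection design the protocols
assume, so the package ships a seeded generator that emulates it: `C`
classes (fingers), `S` samples each, every class a fixed network of 3–7
smooth spline vessels with widths 2–6 px and contrast 60–120 below a
background of 180, every sample a perturbed capture: sub-pixel
translation up to ±2 px, brightness scale ±5 %, Gaussian blur σ = 1.5 px,
additive noise σ = 8. All draws derive from one master seed through a
deterministic per-class/per-sample chain (multiplier 69069 modulo
2³¹−1, exact in doubles on any platform), so the same configuration is
bit-identical everywhere and any subset is independently reproducible.

Two rendering choices deserve explanation:

* **Diffuse stroke profile.** Vessels are drawn with a small flat core
  plus a Gaussian skirt whose σ equals the vessel half-width. This
  emulates NIR scattering, which spreads a vessel's absorption shadow in
  proportion to its caliber, and it determines how tolerant position-wise
  code matching is to the ±2 px jitter: a knife-edge stroke concentrates
  all orientation information in a 1-px band and is destroyed by a 2-px
  shift, while a caliber-scaled shadow keeps the orientation field stable
  over exactly the spatial scale of the perturbations.
* **Smooth rasterization.** The descriptor operates on gradients, so
  strokes are anti-aliased by construction; a binary mask would create
  spurious codes along staircase edges.

Full-frame mode renders the same vessels inside a bright band over a dark
border (≈15) at 320×240, exercising the Sobel ROI stage; the default
post-ROI mode renders directly at 96×64.

What the generator does **not** emulate: tissue texture (the background
is flat, so its codes are pure noise at chance agreement — real tissue
contributes class-stable texture and real genuine scores are higher),
non-rigid finger deformation, illumination gradients, sensor artifacts,
and session effects. Passing the end-to-end benchmark therefore shows the
pipeline is internally correct and that the descriptor separates
structured patterns under the modeled perturbations; it says nothing
about absolute accuracy on real captures.

## Problem sizes and benchmark

The reference conditions are 40 classes × 12 samples at 96×64 (2,640
genuine and 28,080 imposter pairs; 400 probes against 40 templates),
chosen so a full double-variant evaluation runs in well under a minute on
one CPU while keeping score distributions tight enough for stable error
estimates. On this database, with the default master seed:

```{r benchmark, eval = FALSE}
db <- generateDatabase(syntheticConfig())
runVerification(db, "00", T = 8, k = 6)   # EER 0.0316
runVerification(db, "45", T = 8, k = 6)   # EER 0.0326
runIdentification(db, "00")               # rank-one 0.960
runIdentification(db, "45")               # rank-one 0.968
```

The full-scale emulation (136 classes × 30 samples = 4,080 images, the
collection-design total) is used to realize the protocol count
identities and runs in about a minute including identification.

## Known limitations

* Benchmark error rates vary with the master seed (EER roughly
  0.03–0.05 across seeds at the default perturbation levels): 40 classes
  is a small population and the EER sits in the tail of the genuine
  distribution. The protocol identities and descriptor properties are
  exact and seed-free.
* Exact-agreement matching has no tolerance for residual misalignment
  beyond what preprocessing removes; descriptor-level robustness (e.g.,
  best-bit masks or histogram features) is out of scope.
* The ROI detector assumes a roughly axis-aligned rectangular finger
  region, the geometry its Sobel-extent construction can bound.
* `readBMP()` supports the uncompressed 24-bit and 8-bit paletted
  encodings only.
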