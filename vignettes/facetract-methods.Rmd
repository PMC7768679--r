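---
title: "Cross-modal PCA reconstruction: models, choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modal PCA reconstruction: models, choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

During speech, the visible face and the hidden vocal tract are two views of
one underlying articulatory program: jaw, lips, tongue and velum move
together because a single motor plan drives them. `facetract` asks how much
of one view can be recovered from the other. Given a frontal face video and
a midsagittal vocal-tract MR sequence of the same utterance, temporally
aligned, it builds a joint linear appearance model of both modalities and
uses the linearity of that model to reconstruct either modality from the
other alone.

## The representation: texture plus warp

Each matched frame of each modality is serialized as a long column vector:
the RGB pixel values (channel by channel, column-major) concatenated with
the `x` and `y` components of a dense warp field — the per-pixel
displacement, in pixels, that maps the frame onto a fixed reference frame
of its sequence. Pixels carry "texture" and the warp carries "shape", in the
spirit of appearance models of faces. The two modalities' vectors are
stacked (video block first) into a hybrid array of observations by frames.

Intensities stay on their native 0–255 scale and warps in pixels. The two
unit systems are deliberately left unweighted by default; `channel_weights`
in `build_hybrid()` exposes rebalancing for exploration without changing
the default behaviour.

### Frame-rate matching

Video runs faster than MR acquisition, so the video is decimated to the MR
frame count. With scale factor `s = n_vid / n_mr`, retained video index
`i` is `round(1 + (i - 1) * s)`, `i = 1..n_mr`, with halves rounded *away
from zero*: for nine video and six MR frames the retained set is
`[1, 3, 4, 6, 7, 9]`. The closed form is a reconstruction from that worked
example; banker's rounding (R's default `round()`) would silently give a
different set, which is why the package implements the rounding by hand.

### The warp estimator

The pipeline depends only on the warp field's contract — zero field on
identical frames, accurate recovery of small translations, and residual
reduction after backward warping — not on any particular flow algorithm.
The built-in estimator is a multi-scale, dense, iteratively refined
Lucas–Kanade-style gradient scheme (inner loops in C++): at each pyramid
level the current field warps the frame onto the reference, the residual is
linearized against the warped frame's gradients, and a windowed
least-squares update is solved per pixel with light Gaussian smoothing of
the field between iterations. Updates are capped at 1 px per iteration;
bilinear interpolation with border clamping is used throughout. The
estimator is pluggable (`select_reference(estimator = ...)`).

Interpolation and boundary handling are package choices (bilinear,
replicate-clamp), made for bit-reproducibility; nothing in the method
constrains them. The hybrid's pixel block holds the *raw* frame pixels, not
reference-warped texture; both readings of the representation are coherent,
and raw pixels keep serialization a bijection on (frame, field).

### Reference-frame selection

The reference is chosen by an iterated mean-texture procedure: iteration 1
uses a seeded random frame; each iteration estimates warps of all frames
onto the current reference, warps the frames, and takes the mean warped
texture as the next reference. Successive-iteration references correlate
more and more, and the iteration count is fixed at 3 rather than governed
by a tolerance; the warp fields estimated in the final iteration are the
ones used downstream.

One subtlety is worth stating plainly. When the flow estimator aligns
frames accurately, the mean-texture map has a fixed point at the starting
frame's *geometry*: every frame warped fully onto the reference reproduces
the reference's configuration, so the mean texture keeps it. On scenes
whose variation is dominated by displacements large relative to feature
width, references started from different random frames therefore converge
to different (equally valid) geometries. What is stable across starting
seeds — and what the package asserts on articulation-like synthetic
bundles — is the *downstream reconstruction fidelity* (loading correlation
differences on the order of 0.001). Pixel-level seed-independence of the
reference itself holds in the regime where frame-to-frame variation is
small rigid motion the iteration can average out, and is tested there
(cross-seed reference correlation above 0.95 on jittered textured
sequences).

## Uncentered PCA and cross-modal reconstruction

The hybrid array `X` (observations × frames) is decomposed without mean
subtraction — a second-moment decomposition — via the economical route:
eigen-decomposition of the frame-by-frame Gram matrix `X'X`, appropriate
because observations vastly outnumber frames. All non-null components are
kept. Loadings are plain inner products of columns with components.

To reconstruct modality B from modality A, B's block is set to zero and the
partial columns are projected onto the components; the resulting
reconstructed loadings form reconstructed observation vectors, whose B
block is deserialized back into images and warp fields.

**Why uncentered?** Projection is linear in the data column, so splitting a
column into its two modality blocks splits its loadings additively: the
loadings reconstructed from video-only and from MR-only sum *exactly* to
the original loadings. This identity is an exact algebraic property only
when no mean is re-subtracted at projection time; it is the backbone of the
method's interpretation (each modality owns a share of every loading) and
is tested at `1e-8`. A centered mode exists for exploration and is
explicitly flagged as breaking the identity.

**Sign convention.** Eigenvector signs are arbitrary, but the pooled
fidelity correlation is not invariant to per-component sign flips, so signs
must be pinned. The package fixes each component's sign so that its
largest-magnitude *loading* is positive. Fixing the sign in sample space
(rather than on the observation-space component vector) costs `O(n^2)` per
fit instead of `O(p·n)`, which matters because the permutation engine
refits the PCA hundreds of times; the reproducibility rationale is the
same either way.

**Fidelity metrics.** Reconstruction fidelity is scored on loadings, not
pixels: static backgrounds make pixel correlations uninformatively high.
The loading correlation `R` is the Pearson correlation over all (frame,
component) pairs pooled; the loading SSE is the summed squared difference,
with a per-frame breakdown. Reconstructed loadings are systematically
smaller in magnitude than originals (the projected vector is shorter); an
optional mean scaling factor (mean original/reconstructed ratio over all
frames and components) can compensate, but is off by default.

## Permutation nulls

High fidelity could in principle arise from mere association of arbitrary
frame pairs rather than from a shared cause. The null is built by shuffling
the MR frame order while keeping the video order, *refitting the PCA on
each shuffled hybrid*, reconstructing MR from video, and scoring against
that shuffled fit's own loadings. Identity permutations are rejected and
redrawn; p-values use the add-one estimator `(count + 1) / (n_perm + 1)`,
so a p-value is never exactly zero. The null summary interval is the
percentile 2.5–97.5 of the null values (an interpretation; mean ± 1.96·sd
is the alternative reading).

Refitting per permutation is expensive done naively, but shuffling MR
frames only permutes MR *columns*, so the shuffled Gram matrix is
`Gv + Gm[perm, perm]` with `Gv`, `Gm` precomputed once, and both loadings
and video-only reconstructed loadings are exact algebraic functions of
these blocks. The engine is cross-checked against the explicit
fit-and-reconstruct route in the test suite (agreement to 1e-10).

### Paired-frame samples

Stacking frame `t` and `t + 1` into each sample implicitly encodes motion
direction (an open mouth opening versus closing), which single-frame
samples cannot represent. Two shuffled nulls then exist: shuffling the
(t, t+1) pairs as units (preserving within-pair order) and shuffling
frames *before* pairing (destroying it). On synthetic data the null-mean
inflation from single-frame to pairs-kept shuffling is smaller than to
shuffled-before pairing: keeping within-pair order denies the shuffled
hybrids the temporal structure they would otherwise exploit.

## Bubbles occlusion mapping

Which regions of the driving modality matter? Each iteration draws a mask
of 46 hard-edged Boolean discs of diameter 12 px with centers uniform over
the pixel grid (discs may overlap and clip at borders; membership is
Euclidean distance ≤ radius on pixel centers). The mask multiplies the
driving modality's pixel channels and both warp planes (no mean fill —
consistent with the uncentered decomposition), the other modality is
zeroed, the occluded columns are projected into the *original* PCA space,
and the iteration is scored by loading SSE. Masks of the lowest-10%-SSE
iterations are summed (CorrectPlane) and divided by the sum of all masks
(TotalPlane), giving the ProportionPlane; at an uninformative pixel its
expected value is the top fraction (0.1). Ties at the selection boundary
break by iteration index, for determinism. Per-frame planes re-rank
iterations by per-frame SSE independently for each frame.

Disc count and diameter default to 46 and 12 px, sized for 160 × 120-class
geometries. The reference iteration count is 10,000; the package default is
1,000, which already localizes a single informative region clearly at desk
scale.

## The synthetic generator

Real paired recordings are large and heavily preprocessed; the generator
emulates exactly the structure the analysis assumes, with known ground
truth:

* **Latents.** Shared and modality-private channels follow independent
  stationary AR(1) walks with unit innovation variance; `smoothness` is the
  AR coefficient (default 0.85 — smooth, articulation-like trajectories;
  lag-1 autocorrelation equals the coefficient).
* **Scenes.** Both modalities default to 120 × 160 px, three equal RGB
  channels. Each latent channel owns a disjoint disc region (radius 15 px)
  at a fixed anatomical-flavoured slot (mouth/cheeks/brows for the face;
  jaw/tongue/velum/larynx for the tract); within it a soft Gaussian blob
  (σ = 3.5 px) whose amplitude (120 ± 60) and vertical position (± 6 px)
  are affine in `tanh(z / 2)` of the latent value. Soft edges give the flow
  estimator usable gradients; the `tanh` squash keeps blobs inside their
  regions. Pixels outside all regions are a static gradient backdrop, plus
  seeded Gaussian pixel noise (default SD 1) shared across channels, and
  intensities clamp to [0, 255].
* **Defaults as study conditions.** 40 frames, two shared channels and one
  private channel per modality mirror the scale at which the reconstruction
  and permutation properties are validated; k_shared = 0 severs the common
  cause entirely and is the negative control.

What the generator does *not* emulate: photorealistic appearance, occlusion
and lighting changes, head motion, acquisition artefacts, frame-rate
jitter, or any phonetic structure. Passing tests therefore demonstrate the
*pipeline's* correctness and calibration, not performance on real
recordings.

## Numerical choices

* Eigenvalues below `max(eig) * 1e-10` are treated as null components.
* The flow estimator's regularizer is `1e-3` of the mean gradient energy
  per window, so constant regions yield exactly zero updates.
* Constant (untextured) frames produce a zero field with a warning rather
  than an error: a static sequence is degenerate but well defined.
* All stochastic stages take explicit integer seeds; the pipeline derives
  stage seeds deterministically from one master seed, so a config
  round-trips to byte-identical reports.
* Problem sizes in the validation suite: the discrimination and calibration
  checks use 40-frame 120 × 160 bundles with 100 permutations (and 20 seeds
  for the null-calibration check); the paired-frame comparison uses 10
  seeds × 50 permutations per mode; the Bubbles check uses 1,000 mask
  iterations. These sizes were chosen so the full property suite runs on a
  single CPU in minutes while leaving each effect many standard errors away
  from its decision boundary.

## Known limitations

* The flow estimator is a generic gradient scheme, not a perceptually
  motivated filter-bank model; large displacements (beyond a few pixels per
  level) and occlusions are out of contract.
* Only two modalities are supported; the block design generalizes but is
  untested beyond two.
* AVI containers are not read or written; numbered-PNG directories (8-bit)
  are the interchange format, with YAML sidecars for metadata.
* The loading correlation pools all components, so a few high-variance
  components dominate it; the per-component traces (`tidy()` on the fitted
  model) should be inspected alongside the scalar.
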