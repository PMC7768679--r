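# facetract

Cross-modal PCA reconstruction of paired face-video and vocal-tract MR
image sequences.

## The problem

During speech the visible face and the hidden vocal tract are two views of
one articulatory program. Given temporally aligned recordings of both — a
frontal face video and a midsagittal MR sequence of the same utterance —
`facetract` asks how much of one view can be recovered from the other, and
which image regions carry that shared information. It is aimed at speech
production and audiovisual perception researchers who want a fully
unsupervised, whole-image answer (no hand-placed landmarks or regions of
interest).

## The method

Each matched frame of each modality is serialized as its RGB pixel values
concatenated with a dense warp field `(dx, dy)` mapping the frame onto a
reference frame of its sequence (texture + shape). The video is decimated
to the MR frame count with scale factor `s = n_vid / n_mr`, retaining video
frames `round(1 + (i - 1) s)` (halves away from zero). The two serialized
blocks are stacked into a hybrid array `X` (observations × frames), which
is decomposed by *uncentered* PCA via the frame-space Gram matrix:

    X = U D W',   loadings L = W D

Because projection is linear and no mean is re-subtracted, zeroing one
modality's block and projecting reconstructs that modality from the other,
and the two single-modality loading sets sum **exactly** to the original
loadings. Fidelity is scored on loadings, not pixels:

* loading correlation `R` — Pearson correlation of original versus
  reconstructed loadings pooled over all frames and components;
* loading SSE — the summed squared difference, with a per-frame breakdown.

Inference on top of the reconstruction:

* **Permutation nulls** — shuffle the MR frame order, refit the PCA on each
  shuffled hybrid, reconstruct, and compare; p-values use the add-one
  estimator. Paired-frame variants stack frames (t, t+1) per sample and
  shuffle either the pairs as units or the frames before pairing.
* **Bubbles occlusion maps** — random masks of 46 hard-edged 12-px discs
  occlude the driving modality; masks from the lowest-10%-SSE iterations,
  summed and divided by the sum of all masks, give a per-pixel
  ProportionPlane of region importance.

A synthetic generator produces paired sequences driven by shared and
modality-private AR(1) latent "articulation" trajectories with known
informative regions, so every stage is validated without raw recordings.

## Worked example

```r
library(facetract)

# paired 40-frame sequences with two shared latent channels (120 x 160 px)
b <- simulate_bundle(n_frames = 40, seed = 3)

# reference frame + warp fields per modality (3 mean-texture iterations)
rsa <- select_reference(b$seq_a, n_iterations = 3, seed = 11)
rsb <- select_reference(b$seq_b, n_iterations = 3, seed = 12)
video <- list(seq = b$seq_a, fields = rsa$fields)
mr    <- list(seq = b$seq_b, fields = rsb$fields)

# hybrid array, uncentered PCA, cross-modal reconstruction
h <- build_hybrid(video, mr)
m <- fit_pca(h)
recon <- reconstruct_modality(m, h, zeroed = "mr")   # MR from video alone
loading_correlation(m$loadings, recon$recon_loadings)
#> [1] 0.9869066

# is that more than mere frame association? shuffle the MR frame order
pt <- permutation_test(video, mr, n_perm = 100, seed = 5)
pt
#> <facetract_permtest (single): observed R = 0.9869, null mean = 0.9609 [0.9589, 0.9643]
#>   p(correlation) = 0.009901, p(SSE) = 0.009901, 100 permutations>
```

The observed loading correlation (0.987) says the vocal-tract sequence is
recovered from the face almost perfectly at the level of the joint
appearance model. The shuffled null is itself high (~0.96) — shuffled
hybrids still reconstruct *something* — but the correctly ordered sequence
beats all 100 shuffles (p = 1/101), which is the signature of a common
articulatory cause rather than arbitrary frame pairing. `plot_loading_scatter()`,
`plot_null_distribution()` and `plot_proportion_plane()` visualize the
loading cloud, the null, and Bubbles importance maps; `tidy()`/`glance()`
give tibble summaries of fitted models and tests.

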