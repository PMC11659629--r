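---
title: "Two-stage mitotic figure detection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage mitotic figure detection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitodetect)
```

## The problem

Counting mitotic figures (MFs) — cells captured in division — on
haematoxylin-and-eosin (H&E) stained slides is part of grading several tumour
types, and it is slow and subject to substantial inter-observer variation.
The difficulty is not finding dark nuclei: it is telling a genuine MF, whose
condensed chromosomes can take very different shapes across the four mitotic
phases, from *mitotic-like figures* (MLFs) — pyknotic nuclei, apoptotic
bodies, neutrophils — that mimic them.

`mitodetect` implements a two-stage detection architecture that separates
the two concerns completely:

1. **Proposal.** A promptable segmenter is prompted with a dense, evenly
   spaced point grid on 1024 x 1024 tissue tiles and asked for *every*
   cell-scale object. Candidates are filtered on three intrinsic quality
   measures — the segmenter's own predicted mask quality (AI-IoU), a
   stability score, and physical area — and deduplicated by non-maximum
   suppression (NMS). No class decision is made at this stage, which keeps
   sensitivity high.
2. **Classification.** Each surviving object becomes a 64 x 64 RGB crop plus
   its aligned binary mask. A convolutional classifier fuses the mask into
   its first convolutional layer and outputs the probability that the object
   is an MF.

Decoupling proposal from classification avoids the imbalanced-loss problem
of single-stage detectors (segmentation and classification losses competing
during backpropagation), and lets the classifier train on everything the
proposer emits — MFs, MLFs, ordinary nuclei, debris — which is what drives
precision.

## Stage 1: proposal

**Point grid.** `generate_point_grid(tile_px, points_per_side)` places
`points_per_side^2` cell-centred prompts; the default 64 per side on a
1024 px tile gives 4096 prompts with 16 px spacing, the first at (8, 8).

**Quality filters** (`proposer_config()`): a candidate is kept iff

* predicted quality (AI-IoU) > 0.8 (strict),
* stability score > 0.8 (strict), and
* area within [2.25, 225] um^2 (inclusive).

The stability score is the IoU between the masks obtained by thresholding
the segmenter's logit map at +offset and -offset; the offset is not fixed by
the protocol, so we use the common symmetric default of 1.0 in logit units
(configurable). An empty union scores 0 by decision, so degenerate logit
maps are filtered rather than undefined. The area band corresponds to
objects between roughly 1.7 and 17 um across at 0.25 um/pixel — the
cell scale.

**NMS.** Candidates are ranked by predicted quality and greedily suppressed
when their bounding-box IoU with a kept candidate exceeds 0.7 (ties broken
toward the earlier candidate, for determinism). Whether the original
protocol suppressed on boxes or masks is not recorded; boxes are the
standard automatic-mask-generation default and are cheap, so they are our
default, with exact mask IoU behind a flag (`use_mask = TRUE`).

**Backends.** The segmenter is pluggable behind the `segment_tile()`
generic. The shipped `reference_backend()` is a deterministic, dependency
free segmenter intended for testing and desk-scale runs: it thresholds the
tile at 0.85 x the median grey of its non-glass pixels, labels connected
components, and returns every component within a 3 px snap radius of a
prompt. Its quality score is `1 - 0.2 * (1 - circularity)` — a boundary
roughness proxy — and its stability is 1 by construction (it produces a
binary mask, not logits). The snap radius exists because a promptable
segmenter tolerates small prompt offsets; without it, an object smaller
than the prompt spacing can sit between four grid points and be lost.
A foundation-model backend can be added by implementing `segment_tile()`
for a new class; nothing else in the pipeline changes.

**Crops.** `extract_object_crop()` cuts the 64 x 64 window centred on the
mask centroid at native resolution. RGB is reflect-padded where the window
leaves the tile; the mask channel is the candidate's own mask, zero outside
it, so the crop's mask area can never exceed the candidate's.

## Stage 2: the mask-fusion classifier

The classifier consumes 4-channel crops: RGB scaled and centred to
[-0.5, 0.5], plus the binary mask. Its defining design is the *fusion
contract*: the RGB channels pass through the first convolution (which has a
bias), the mask channel is encoded by a separate, stride-matched convolution
**without bias**, and the two outputs are summed before the activation.
Consequences:

* an all-zero mask reproduces the RGB-only network output *exactly* (a
  testable identity, `test-classifier.R`),
* zeroing the mask-encoder weights makes predictions provably independent
  of the mask (the ablation identity), and
* in a transfer setting the RGB path's pre-trained weights are preserved
  untouched while mask information is injected additively.

The backbone here is deliberately compact — one 6 x 6 stride-2 convolution
with 8 filters, ReLU, 5 x 5 average pooling, and a 2-logit softmax head —
implemented directly in R over BLAS matrix products (im2col layout), with
the backward pass verified against numerical differentiation. The reference
architecture for this role in the literature is an 18-layer residual network
pre-trained on natural images; at desk scale, on synthetic crops whose class
is a deterministic function of rendered morphology and staining, the compact
network reaches the same operating regime (held-out F1 >= 0.95) in minutes
on one CPU, and every architectural contract above is independent of depth.
Swapping in a deeper backbone changes nothing in the package's interfaces.

**Training protocol** (`train_config()`): cross-entropy, AdamW (decoupled
weight decay 1e-4 on weights only), cosine-annealed learning rate starting
at 0.001, stratified 90/10 train/validation split, decision threshold 0.5,
and five seeds (0-4) giving five models whose labels are combined by
majority vote (ties resolve to non-MF, the conservative direction for a
screening tool). Weight decay, the loss, and the threshold are not pinned by
the protocol we follow; cross-entropy, 1e-4 and 0.5 are the field's
defaults. Training is bit-deterministic for a fixed seed: the split, the
weight initialisation and the batch shuffling all draw from R's seeded
generator.

**Batch size.** The reference protocol trains with batch 8000 on a GPU over
millions of objects. At desk scale (a few thousand crops, 10 epochs, one
CPU) that leaves the optimiser with too few steps to leave the majority
class, so this package's default is 64 — enough steps for the cosine
schedule to act — with otherwise identical semantics. `batch_size = 8000`
remains a valid setting for large runs.

## Colour augmentation

H&E staining varies across laboratories and scanners. Following the
stain-deconvolution approach, RGB crops are mapped to optical density
(`OD = -log10((pixel + 1) / 255)`; the +1 guards zeros), deconvolved through
the Ruifrok–Johnston H&E stain matrix (H = (0.650, 0.704, 0.286),
E = (0.072, 0.990, 0.105), residual = their normalised cross product — the
canonical published values, configurable), and each stain channel is
perturbed as `c' = alpha * c + beta` with `alpha ~ U(1 - sigma, 1 + sigma)`,
`beta ~ U(-sigma, sigma)`, `sigma = 0.14`, before reconstruction. Only the
H and E channels are perturbed; the residual channel carries no stain and is
left alone by default. Horizontal flips with p = 0.4 are applied to RGB and
mask together, so mask area is conserved and the mask is never
colour-perturbed. With `sigma = 0` the colour pathway is the identity up to
quantisation — a property the tests assert.

## Evaluation protocol

Detections match ground truth one-to-one by centroid distance. The matching
radius is a community convention, not part of the published metric; we
default to 7.5 um (30 px at 0.25 um/px, the mitosis-benchmark convention)
and label results as convention-dependent. Matching is greedy
nearest-first — deterministic and order-independent — with an exhaustive
optimal matcher available for small instances as a test oracle; on random
<= 6-object instances greedy is within one pair of optimal. Precision,
recall and F1 follow the standard identities, with zero-denominator cases
defined as 0 and flagged `degenerate` so aggregate tables never contain
undefined entries. `summarize_runs()` reports per-metric mean and sample
standard deviation (n - 1; n = 1 reported as sd 0 with a flag) plus the
ensemble F1, per group — the shape of a multi-seed benchmark table.

## Restain registration utilities

An orthogonal labelling route stains a section with an antibody specific to
mitotic cells (pHH3), extracts chromogen-positive regions by per-channel RGB
interval thresholds (`extract_positive_mask()`; components under a minimum
area are dropped), and transfers them onto the matching H&E image via an
affine transform estimated by RANSAC over point correspondences
(`estimate_affine_ransac()`: 3-point minimal samples, inlier tolerance 3 px,
least-squares refit on the best inlier set, seeded and reproducible). The
shipped RGB thresholds are illustrative — real thresholds depend on the
chromogen, counterstain and scanner and must be calibrated. Keypoint
detection for real slides is out of scope; the estimator consumes
correspondences and leaves the detector choice to the caller. Masks are
resampled nearest-neighbour through the inverse transform (area drift < 5%
for near-rigid transforms on disc-scale objects); out-of-bounds objects are
flagged, never silently dropped.

## Whole-slide tiling

Background removal analyses a grayscale (Rec. 601 luma), block-downsampled
rendition of the slide. Assuming the slide perimeter is mostly empty glass,
the background threshold is 0.9 x the mean grey of the one-pixel border
ring; a pixel is tissue iff it is darker than the threshold. Tiles are laid
at stride `tile_px` (0-based, half-open, sorted by (y, x)), partial edge
tiles are white-padded, and tiles with tissue fraction below 0.1 are
dropped. The downsample factor (8), the perimeter statistic (mean) and the
tissue cut-off (0.1) are not pinned by the protocol; all are configurable
with these logged defaults. The perimeter assumption genuinely fails when
tissue touches every image edge — that is a limitation of the method, not of
the implementation.

At the pipeline level, detections from different tiles are deduplicated in
the slide frame: a lower-quality detection is suppressed when its box IoU
with a kept one exceeds the NMS threshold *or* its centroid lies within
6 um of it. The second clause exists because an object split by a tile
border produces two adjacent part-boxes whose IoU is near zero — box NMS
alone cannot merge them; 6 um is about one nucleus diameter, small enough
not to merge genuinely distinct neighbours.

## The synthetic scene generator

Because the real curated datasets are external and large, every stage is
tested against generated H&E-like scenes with exhaustive ground truth
(`generate_scene()`, `generate_labelled_crops()`, `generate_wsi_like()`).
Scenes are composed in stain-concentration space and rendered through the
same stain matrix the augmentation uses, so stain deconvolution on synthetic
data recovers planted concentrations exactly — the generator doubles as the
oracle for the colour pipeline, and re-rendering a scene from its records
reproduces the raster bit for bit.

Four object classes mirror the object taxonomy of curated mitosis datasets:

| class | morphology | haematoxylin | area (um^2) |
|---|---|---|---|
| `ordinary` | smooth ellipse | 0.35–0.55 | 20–60 |
| `mf` | two-lobed barbell | 0.9–1.3 | 25–80 |
| `mlf` | small dense disc | 0.9–1.3 | 4–10 |
| `clutter` | faint elongated fragment | 0.10–0.22 | 3–15 |

The barbell makes shape a learnable signal without textures; MLFs share the
MF's staining but not its size or shape; clutter sits near the segmentation
threshold by design. The background is a uniform eosin wash (0.18–0.28)
with Gaussian OD noise (sd 0.02 — visible but small against the planted
contrasts), objects are placed by rejection sampling at >= 12 um centroid
spacing (an error is raised when the packing is infeasible), and mosaics add
a white glass gutter so the perimeter assumption of the tiling stage holds.

What passing on this generator shows — and what it does not: it validates
the geometry, bookkeeping, determinism and learnability of every stage
end-to-end, but real H&E carries texture, touching and overlapping nuclei,
staining gradients and scanner artefacts that the generator deliberately
omits. Synthetic F1 values say nothing quantitative about performance on
real slides.

## Numerical choices and degenerate inputs

* OD epsilon 1 grey level; OD->RGB->OD round trips are exact to machine
  precision, RGB round trips within 1 grey level.
* Stability on an empty logit union is 0; metrics with zero denominators
  are 0 with a `degenerate` flag; an all-dark slide yields threshold 0 and a
  logged degeneracy message.
* NMS and matching break ties by input index / coordinate order, never by
  hash order, so all pipelines are reproducible.
* The training forward/backward pass is pure R over BLAS; there is no
  thread-dependent reduction, so results are bit-identical across runs on
  the same platform.

## Desk-scale problem sizes

The shipped tests and the acceptance script run the full protocol at sizes
chosen for a single CPU: 2000 training crops (500 per class), 10 epochs,
five seeds, and a 2 x 2 mosaic of 512 px scene tiles (one blank) with 12
planted MFs among ~60 objects. These sizes are the package's reference
desk conditions; scaling any of them up only changes wall time.

## Known limitations

* The reference segmenter is a threshold-and-label model: it cannot separate
  touching nuclei and underestimates boundaries on textured tissue. It is a
  test oracle and a desk backend, not a substitute for a foundation
  segmenter on real slides.
* The matching radius and the restain RGB thresholds are conventions;
  results depend on them and they must be reported alongside any score.
* Pre-training on natural images is not available in this implementation;
  on real data the classifier would need either more data or an externally
  trained backbone plugged in through the same fusion contract.
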