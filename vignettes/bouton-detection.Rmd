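---
title: "Detecting axonal boutons along traced neurons: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting axonal boutons along traced neurons: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Axonal boutons — local swellings along an axon, visible in sub-micron
fluorescence microscopy as bright varicosities — are putative presynaptic
sites. Counting and locating them along a single traced neuron turns a
morphological reconstruction into an estimate of its output connectivity.
Manual annotation does not scale to whole-neuron axonal arbors, and the
difficulty for automation is not finding swellings (they are conspicuous)
but telling *boutons* apart from the many sub-threshold width and intensity
inhomogeneities of the axon shaft. The operational annotation criterion this
package follows is the standard one: a swelling whose local width is at
least twice the neighboring average axonal width is a putative bouton;
anything weaker is a non-bouton swelling, the false-positive class.

`boutonfinder` implements a two-step strategy around that distinction:

1. **Recall-oriented initial detection.** Guided by a traced skeleton (SWC),
   tubular sub-volumes are extracted along the axon, foreground signal is
   segmented, and candidate swelling centers are located by density-peak
   clustering. This stage is tuned to contain essentially every underlying
   bouton, accepting that roughly half of its detections are not boutons.
2. **Patch classification.** A compact residual convolutional network
   classifies a 2D image patch around each candidate as bouton or
   non-bouton, restoring precision at a small cost in recall.

## Skeleton-guided extraction

The traced arbor is decomposed into unbranched paths and each path is
covered greedily by segments of `segment_length` (default 100 µm) with
stride `segment_length - overlap` (default overlap 10 µm). The overlap must
exceed one bouton diameter so no bouton straddles an uncovered seam; branch
points terminate every incident path and so belong to every touching
segment. Around each segment a tube of per-axis radius 8 × 8 × 4 voxels
(ellipsoidal cross-section; a box is available) is rasterized from the
centerline resampled at half the smallest voxel pitch, and the crop is
zeroed outside the tube. This confines detection to the traced neuron's own
signal: a brighter fiber of another cell passing 5 µm away contributes
nothing.

Per-segment candidate lists are merged by a greedy rule that keeps the
highest-density representative of any group of mutual neighbors closer than
`merge_radius`. The default is 1.2 µm — equal to the evaluation matching
tolerance and slightly above the axial voxel pitch, so duplicate candidates
one z-plane apart collapse; at exactly 1.0 µm they would not.

## Foreground segmentation

The background image `C` is the block convolved `passes` (3) times with a
uniform averaging template (21 × 21 × 5 voxels ≈ 4 × 4 × 5 µm — larger than
any bouton, so boutons do not inflate their own background). Within a tube,
the average is a normalized convolution restricted to the tube support;
otherwise the zeros outside the tube drag `C` down and the whole tube
binarizes as foreground. A voxel is foreground when
`I > C * (1 + thre_binarization)` with `thre_binarization = 0.3`, followed
by one pass of mild morphological erosion with an in-plane 4-connected
cross. Erosion is 2D per z-plane because the axial pitch of the target data
(1 µm) is five times the lateral pitch (0.2 µm); isotropic 3D erosion at
that anisotropy severs thin axons. Border values are replicated in both the
averaging and the erosion so block edges are not artificially suppressed.
The parameters are deliberately permissive: specificity is the classifier's
job, and on synthetic scenes essentially all bouton voxels survive
segmentation.

## Density-peak detection

For every foreground voxel the local density is the Gaussian-weighted mean
of foreground intensities within a spherical window of radius $R = 2\sigma$:

$$\rho_i = \frac{1}{Z_i} \sum_{\|p_i - p_j\| \le R} I(p_j)\,
  e^{-\|p_i - p_j\|^2 / 2\sigma^2},$$

with $Z_i$ the sum of the weights over the same window (an alternative
fixed-constant normalization is selectable). Distances are physical
micrometres, so the axial anisotropy is handled correctly. The kernel width
$\sigma$ is set to roughly one third of the average bouton radius: 0.17 µm
for ~0.5 µm boutons.

Each voxel's $\delta$ is its distance to the nearest *strictly denser*
voxel, normalized by the maximum pairwise distance of the block's
foreground; the global density maximum receives $\delta = 1$. Density ties
are broken by lexicographically smaller (z, y, x) index counting as denser,
so $\delta$ is well defined on saturated plateaus and exactly one voxel per
block carries $\delta = 1$. Swelling centers are simultaneously dense and
far from anything denser, so they sit isolated in the $(\hat\rho, \delta)$
plane ($\hat\rho$ is $\rho$ rescaled to $[0,1]$). The feature density
$\Lambda$ is a kernel density estimate of that scatter, max-normalized,
evaluated on a 256 × 256 grid with bilinear interpolation back to the
points (deterministic and order-independent; on small instances it tracks
the exact KDE to a few percent). The bandwidth is anisotropic,
`c(0.01, 0.02)`: narrow in $\hat\rho$ so that noise-induced maxima, which
share the bulk axon intensity, stay inside the dense cloud, and wider in
the heavily compressed normalized-$\delta$ axis.

A voxel is selected as a candidate center when

* $\Lambda \le$ `thre_search` (default 0.2),
* $\delta \ge R_\mathrm{min} / \max_{i,j}\|p_i - p_j\|$ with
  $R_\mathrm{min} = 0.4$ µm, the minimum estimated bouton radius,
* it is a local density maximum over its 26-neighborhood (a center is
  denser than its neighbors; a voxel whose axial neighbor is denser is a
  cross-section of that structure, not a center), and
* its density is at least `min_rho_frac` (0.08) of the block's density
  range, which suppresses dim noise-induced maxima along the shaft that
  satisfy the $\delta$ criterion by ordering luck.

The last two conditions refine the plain two-condition criterion; without
them, Poisson noise on the axon shaft generates spurious low-density peaks
at ~0.5–1 µm spacing. Any two selected peaks are automatically at least
$R_\mathrm{min}$ apart, because the lower-density peak's $\delta$ bounds
its distance to every denser voxel, including other peaks. The thresholds
above were fixed on a small synthetic development suite (seven blocks of
the two presets) before the benchmark runs; all are configuration
parameters.

## The patch classifier

Around each candidate a 60 × 60 × 7-voxel patch is cropped (zero-padded at
volume borders), max-projected along z — at 1 µm axial pitch depth carries
no usable bouton shape — up-sampled bilinearly 4× to 240 × 240 pixels of
0.05 µm, and min–max normalized. Per-patch normalization makes the network
insensitive to absolute brightness, which varies strongly between axons;
what remains is the *relative* contrast and width of the central structure
against its own shaft, which is exactly the annotation criterion.

The network is a reduced residual bottleneck classifier. Its stem uses only
stride-1 convolutions and a single 2 × 2 max-pooling, so the stem output is
half the input (120 × 120) rather than a quarter — at these scales a bouton
is only a few pixels wide before up-sampling and survives only so much
pooling. Four bottleneck stages of widths 16/32/64/64 (one block each,
stride 2) end in global average pooling to a 64-dimensional feature, then
dropout (0.5) and a 2-way softmax. Every convolution is followed by batch
normalization, as in the 50-layer architecture this design descends from;
at inference the normalization uses statistics recomputed from training
batches (re-estimated after each epoch from a shuffled sample), so
predictions are deterministic and independent of how patches are batched.
The whole model has ~20k weights — under 1% of the unreduced reference —
which is appropriate for a two-class task and keeps desk-scale CPU
training feasible.

Training uses mini-batch stochastic gradient descent with momentum 0.9,
batch 60 and per-iteration decay 1e-6 (the function defaults also keep the
reference learning rate 1e-2 and up to 50 epochs). The bundled synthetic
trainer uses lr 0.05 for a few epochs over 5,000 generated patches (half
positive), with per-batch random augmentation — quarter-turn rotations,
gray-level scaling in [0.7, 1.3], one-pixel shifts, additive noise — a
random-per-draw version of the five fixed augmentation families that
`augment_samples()` also implements verbatim (rotations 90/180/270;
Gaussian, salt-and-pepper, Poisson noise; diagonal one-pixel shifts;
scaling by 1.2/0.82; gray-level multiplication). Training patches plant a
labeled structure at the patch center and, crucially, additional swellings
of either class off-center (plus an occasional crossing fiber), so the
network learns that the label is carried by the central structure, not by
bright neighbors — otherwise patches from densely spaced boutons are
systematically misread. The best-validation-accuracy parameters are
returned (stratified 80/20 split) and the checkpoint embeds configuration,
training log and seed.

## Evaluation protocol

A detection and a ground-truth bouton match when they are within 1.2 µm
(inclusive). Matching is one-to-one: pairs are formed greedily in ascending
distance order (ties by ids) and then extended along augmenting paths to
maximum cardinality, so the pair count equals the optimal assignment's.
With `M` truths, `N` detections and `P` pairs, precision is `P/N`, recall
`P/M`, and F1 their harmonic mean; empty denominators give 0 with a
warning.

## The synthetic scene generator

Scenes emulate sparsely labeled axons at 0.2 × 0.2 × 1 µm³ voxel pitch:
bounded-curvature random-walk centerlines (~0.5 µm diameter) in a
300 × 300 × 40-voxel block, planted boutons (width ratio 2–3.5×) and
non-bouton swellings (1.2–1.7×) at 1:1 with ≥ 2 µm spacing, anisotropic
Gaussian blur (0.15, 0.15, 0.5 µm), a background offset of 100 counts,
Poisson shot noise on the signal and Gaussian read noise (sd 5). The local
radius follows a Gaussian arclength bump of 1 µm FWHM at each swelling, and
brightness scales with the width ratio squared — proportional to the local
cross-sectional area, so boutons are brighter as well as wider, as in real
data. Tubes are rendered by maximum blending of Gaussian cross-section
profiles, which keeps shaft brightness uniform regardless of curvature; the
only systematic intensity structure along an axon is the planted swelling
profile plus an axial-sampling modulation (below). Two presets bracket the
target regimes: `"pyramidal"` (sparse, diverse boutons, ~10 boutons and ~10
non-bouton swellings per 200 µm block) and `"basket"` (strong 2.5–3.5×
boutons at 12/100 µm on a brighter axon). Everything is seed-deterministic,
down to byte-identical written files.

What the generator does *not* emulate: a realistic point-spread function
(only separable Gaussian blur), scattering and depth-dependent attenuation,
stitching seams, vasculature or somata, tracing errors in the skeleton, and
partially *overlapping* boutons closer than 2 µm. Passing tests on these
scenes therefore demonstrate the pipeline's mechanics and its behavior
under the stated noise model, not performance on any particular real brain
volume.

## Known limitations and honest numbers

The weakest planted non-bouton swellings (ratio ≲ 1.45) sit at a
detectability floor that is a property of the imaging geometry being
emulated, not of the detector: with 1 µm axial pitch and 0.5 µm axial blur,
the plane-sampled brightness of a thin axon modulates by roughly ±20% as
the centerline drifts between z-planes, which is comparable to the contrast
of those swellings. At default parameters the initial detection recovers
100% of planted boutons and ~80–86% of all planted swellings; the missing
ones are almost exclusively the weakest non-bouton class, whose loss does
not affect bouton precision or recall. The recall-oriented design goal —
that the initial detection should contain as many underlying swellings as
possible — is met for every structure above that floor.

Problem sizes used throughout the tests and the benchmark script (18
pyramidal and 2 basket blocks of 60 × 60 × 40 µm, one axon each; a
5,000-patch training set; 5 training epochs) were chosen so the complete
benchmark runs in tens of minutes on a single CPU core while keeping
per-block bouton counts (~10) large enough for stable precision/recall
averages.

## Reproducing the benchmark

```{r}
library(boutonfinder)

tp  <- generate_training_patches(n = 5000, seed = 0)
clf <- train_classifier(tp$images, tp$labels, epochs = 4, lr = 0.05,
                        seed = 0, preprocess = training_patch_preprocess,
                        train_transform = random_patch_transform)

scene <- simulate_scene(scene_preset("pyramidal"), seed = 1001)
segs  <- divide_tree(scene$skeleton)
cands <- merge_candidates(lapply(segs, function(s)
  detect_block(extract_tube(scene$volume, s))))
dets  <- filter_candidates(cands, clf, scene$volume)
compute_metrics(scene$truth[scene$truth$class == "bouton", ], dets)
```

`scripts/acceptance.R` runs this end to end over all benchmark blocks and
writes the summary quantities as JSON.
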