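---
title: "Temporally consistent random augmentation for long videos: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporally consistent random augmentation for long videos: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trandaug)
```

## The problem

Frame-wise activity recognition in long procedure videos — surgical phase and
step recognition being the motivating application — is trained with deep
spatiotemporal models that benefit heavily from data augmentation. Still-image
augmentation policies transfer poorly to video: applying an independent random
transform to every frame destroys the temporal visual consistency that the
temporal model is supposed to exploit, while applying one transform to the
whole video wastes the temporal dimension entirely. Long videos are, however,
naturally composed of contiguous activity segments whose appearance is
internally consistent.

The augmentation policy implemented here takes that structure seriously. A
video of $\Upsilon$ frames is split into a random number $T' \in [1, T]$ of
contiguous temporal segments. Each segment $i$ independently receives a random
set of $N$ transformations $\{t_{i,1}, \dots, t_{i,N}\}$, drawn uniformly with
replacement from a transform set $\tau'$, and that composition is applied
*identically to every frame of the segment*. The strength of every transform
is a single shared integer magnitude $M \in [0, 30]$, mapped linearly onto
each transform's parameter range:

$$p(M) = p_{\min} + \frac{M}{30}\,(p_{\max} - p_{\min}).$$

The whole policy is therefore the triple $(M, N, T)$, a search space small
enough to grid by hand. Two familiar policies are exact special cases:

* $T = 1$: one consistent composition for the whole video
  (`uniform_randaugment()`);
* one segment per frame: independent per-frame augmentation
  (`randaugment()`).

```{r quick-example}
vid <- replicate(12, array(runif(3 * 16 * 16), c(16, 16, 3)), simplify = FALSE)
pol <- augment_policy(M = 30, N = 1, T = 5, seed = 7)
aug <- trandaugment(vid, pol)
attr(aug, "plan")
```

## The transform set

The exact membership of the ten-transform set is a design choice of this
package (configurable through `transform_bank()`): rotation, horizontal and
vertical translation, horizontal and vertical shear, horizontal flip,
brightness, contrast, saturation and sharpness. The selection principle is
that every transform must produce frames that could plausibly occur in
endoscopic video; histogram-warping operations (posterize, solarize, equalize)
are excluded for that reason, as are all mixing-style augmentations. The set
supersets the manually designed `flip + saturation + rotation` baseline that
`train_config(augment_mode = "custom")` reproduces.

Parameter ranges follow common automated-augmentation practice, since only
the $0$–$30$ magnitude scale itself is fixed by the method: rotation
$0\to30^\circ$, translations and shears $0\to0.3$ of the image extent,
enhancement factors $1.0\to1.9$. Direction signs (rotation sense, translation
direction, factor mirrored below $1$ as $f \mapsto 2 - f$) are sampled *per
segment*, not per frame — within-segment consistency is the entire point of
the method. The horizontal flip is parameter-free and is the one default
transform that is not an identity at $M = 0$.

Numerical choices for the image operations:

* Geometric warps use inverse-mapped bilinear interpolation with
  **edge-replicate** fill. Black borders never arise in surgical video, so
  none are introduced.
* Photometric enhancements are blends toward an anchor image (black for
  brightness, mean luminance for contrast, per-pixel luminance for
  saturation, a $3\times3$ smoothed copy for sharpness), implemented as
  `img + (f - 1) * (img - anchor)` and clipped to $[0,1]$. The blend is
  written in that algebraic form deliberately: at $f = 1$ it returns the
  input **bit-exactly**, which makes the identity-at-zero contract testable
  with `identical()` rather than with a tolerance.
* Mean-absolute-difference distortion of every photometric transform is
  non-decreasing in $M$ by construction (the blend residual is linear in
  $f$; clipping can only flatten it).

## Segment sampling and determinism

Only the *number* of segments is prescribed by the policy; their placement is
open. The default is deterministic equal-length segments (remainder frames
appended to the last segment), matching the mental picture of a video cut
into clips; `boundary_mode = "random"` draws $T' - 1$ distinct cut points
uniformly instead. $T'$ is clipped to $\min(T, \Upsilon)$ so every segment is
non-empty even for degenerate short videos.

Each augmentation call runs on a private random stream seeded from
`(policy$seed, video_id)`, with a fixed draw order: $T'$, boundaries (random
mode only), then per-segment transform indices and signs in segment order.
When the support of $T'$ is the single value $\{1\}$ no draw is consumed.
These two details make the reduction equivalences *byte-exact*, not merely
distributional — the test suite asserts `identical()` between `trandaugment()`
at $T=1$ and `uniform_randaugment()`, and between the forced per-frame plan
and `randaugment()`, across 50 seeds. During training a fresh plan is drawn
for every video at every epoch (the seed is derived from master seed, policy
seed and epoch), so the model effectively sees an extended dataset of
segment-wise re-augmented videos, while the whole run remains reproducible.

## The recognition model

The recognizer is the standard two-stage architecture of the field: a
per-frame visual feature extractor feeding a causal single-stage temporal
convolutional network (SS-TCN). The SS-TCN is a $1\times1$ input projection,
`n_layers` residual blocks of dilated causal 1-D convolutions (kernel 3,
dilations $2^l$, ReLU, $1\times1$ projection), and a $1\times1$ output layer;
the layer count, width and dilation doubling are the conventional
single-stage design, since they are not prescribed — all are configurable in
`sstcn_spec()`. Causality is structural (convolutions pad only the past), so
the prediction at frame $t$ depends on at most the $n$ previous frames with
$n + 1 = 1 + (k-1)\sum_l d_l$, making the model usable online. The test suite
verifies both directions: perturbing the future never changes past scores
(bit-identical prefixes), and history outside the receptive field is
invisible.

Class imbalance is handled with a class-weighted cross-entropy. The exact
weighting formula is open; this package uses inverse frequency
$w_c \propto \text{total}/(C \cdot \text{count}_c)$, weight $0$ for absent
classes, normalized to mean $1$ over present classes, and the per-frame loss
is normalized by the total frame weight so rescaling all weights is a no-op.
The formula is isolated in `compute_class_weights()` so a median-frequency
alternative is a drop-in.

Training follows the feature-buffer protocol: within a video, frames are
consumed in temporal order in batches (default 64); each batch's features are
appended to a per-video buffer, the TCN scores all frames buffered so far,
and the loss is taken on the current batch only. The buffer is reset at the
end of every video. Buffered features are treated as constants by the
optimizer.

**Design deviation to note.** The reference setup trains CNN backbone and TCN
end to end. This package has no automatic differentiation framework available,
so the backbone is *frozen*: the `"tiny"` variant is a deterministic, seeded
random-feature CNN (strided random convolutions, ReLU, global pooling, channel
statistics, fixed random projection to $f$), and only the SS-TCN is trained
(with hand-derived backpropagation, verified against numerical gradients, and
Adam — the optimizer is unstated in the reference protocol, Adam is the field
default). Random convolutional features preserve exactly the color and texture
statistics that both the synthetic data and the augmentations manipulate,
which is sufficient for the temporal model to learn from; a full pretrained
residual backbone can be supplied as an external function via
`feature_extractor_spec("resnet50", fun = ...)`. Model selection keeps the
epoch with the best validation F1, consistent with reporting validation F1
throughout a policy search.

## Evaluation protocol

`evaluate_predictions()` implements per-video macro averaging: for each video,
frame accuracy plus precision, recall and F1 macro-averaged over the classes
*present in that video's ground truth*; the aggregate is the unweighted mean
over videos. A class never predicted inside a video contributes precision 0.
The implementation is checked against an independent confusion-matrix oracle
on 1,000 random label/prediction pairs.

## The synthetic generator: what it does and does not establish

`synth_spec()`/`generate_dataset()` emulate the *structure* of long procedure
videos: contiguous activity segments (runs of at least `min_segment_len`
frames, consecutive runs in different classes), a persistent per-class visual
signature, and i.i.d. Gaussian pixel noise. Signatures are flat colors
(well-separated hues) modulated by a class-specific low-frequency horizontal
sinusoid, chosen so that photometric transforms (which move color statistics)
and geometric transforms (which move the texture phase) are both observable
in tests. The desk-scale defaults — 10 videos × 60 frames × 3 classes at
64×64, noise sd 0.05, split 60/20/20 by video — keep every end-to-end run in
seconds-to-minutes on one CPU.

What a green end-to-end test establishes: the full pipeline (generation,
augmentation, feature extraction, buffered causal training, weighted loss,
macro evaluation) is wired correctly, learns, and is bit-reproducible under a
seed. What it does not establish: anything about real surgical video — no
tool/anatomy appearance, no class ambiguity, no annotation noise, no long-range
dependence beyond segment structure. Reproducing published benchmark numbers
requires the restricted datasets and GPU-scale training and is explicitly out
of scope.

The desk-scale training configuration used by the smoke tests and the
acceptance script (8 epochs, Adam at $5\times10^{-3}$, batch 64, the tiny
32-feature extractor and a 6-layer, 32-channel SS-TCN) was chosen once from a
pilot run as the smallest budget that cleanly separates the synthetic classes;
the package defaults in `train_config()` remain the reference protocol's
50 epochs at $10^{-5}$.

## Known limitations

* The backbone is frozen (see above); end-to-end finetuning of a CNN is out
  of reach without an autodiff runtime.
* Video-file decoding is not supported — no decoder exists in the target
  environment; videos enter as frame directories (PNG/JPEG).
* The policy operates in input space only; feature-space augmentation is
  future work in the surrounding literature and out of scope here.
* Geometric resampling is bilinear; bit-exactness of warped output is
  guaranteed within a run, not across BLAS/platform variations (all
  determinism tests compare within-run artifacts).
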