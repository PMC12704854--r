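---
title: "In-silico controlled rearing: models, retinas, and scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico controlled rearing: models, retinas, and scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rearviews)
```

## What this package models

Newborn animals raised in strictly controlled visual worlds can develop
shape-based object recognition from experience of a single object. This
package re-creates that paradigm in software so the question can be asked of
learning algorithms: an embodied agent moves through a virtual rearing
chamber containing one rotating, two-faced object; the first-person frames
it collects are (optionally) filtered through artificial retinas; a small
self-supervised encoder is trained on the stream; and the learned
representational space is scored as colour-based or shape-based.

The package has five coupled parts — synthetic world, retinas, encoders,
training, evaluation — each usable on its own, plus `run_experiment()`,
which chains them end to end with one seed governing every source of
randomness.

## The virtual chamber and its conditions

The chamber replicates a physical controlled-rearing enclosure:
66 cm x 42 cm x 69 cm, two opposing display walls, wire-mesh floor. Floor
coordinates use 1 unit = 10 cm, so the canonical movement speed of
1.5 units/s crosses the chamber in a few seconds, consistent with
game-engine units. The imprinting object (9 cm x 7 cm) rotates about a
frontoparallel vertical axis with a 6 s period; each face carries its own
shape and colour, and within ±5° of edge-on the renderer draws a thin
two-coloured band, because the physical object's edge looks identical
during either transition.

Five movement policies ablate specific sources of view diversity:

* **dense exploration** — random targets, straight transits at 1.5 units/s
  with gaze locked on the object, then a 9.5 s dwell (95 frames at
  10 frames/s) of sinusoidal head sweeps over yaw, pitch and roll;
* **no head movements** — dwells stare at the object;
* **no transitional views** — teleports between the 49 cells of a 7 x 7
  grid (head sweeps retained, no transit frames);
* **no side-to-side** — teleports restricted to the central lateral line,
  so only viewing distance changes;
* **no depth** — teleports restricted to the central depth line, so only
  lateral position changes.

The sixth condition of the design, **shuffled views**, is deliberately not
a movement policy: it reuses dense-exploration frames and destroys temporal
continuity at training time by re-permuting frames within every batch each
epoch (`shuffle_within_batches()`, or `shuffled_condition = TRUE`).

The renderer is a flat-shaded projective rasteriser — white walls, a shaded
floor band, and the visible face's silhouette foreshortened by
`|cos(angle)|` and scaled inversely with distance. The downstream analyses
consume shape/colour/view statistics, not photorealism, and a procedural
renderer keeps an 80,000-frame stream generable on a laptop. Eye height
(5 cm) and field of view (90°) are exposed in `chamber_spec()` because no
canonical values exist for them.

Head-sweep amplitudes (8–22° yaw, 3–12° pitch/roll) were chosen once so
the object stays at least partially in frame at the default field of view;
dense-exploration targets are drawn uniformly with a 0.2-unit wall margin.

## Artificial retinas

Toy retinas keep full colour inside a circular fovea and reduce the
periphery to ITU-R BT.601 luminance, then downsample 320 → 64. The
canonical bank (`toy_retina_bank()`) varies the foveal radius over
{0, 7.5, 15, 30, 60, 120} pixels at 320 x 320 input — radii are interpreted
in input pixels before downsampling.

The realistic retina composes, in a fixed order (mosaic → peripheral
degradation → cortical magnification → blending; the order is a package
choice, as no canonical one exists):

1. a seeded rod/cone mosaic (99% cones in the fovea, 1% in the periphery
   by default; rods carry luminance only);
2. peripheral Gaussian blur plus a "visual clutter" distortion — a seeded
   smooth noise field displacing peripheral pixels radially, scaled by
   `clutter_intensity`;
3. cortical magnification — inside the fovea an output pixel at radius $r$
   samples the input at $r\,(r/R)^s$, a monotone remap that is the
   identity at $s = 0$, expands central content, and fixes both the centre
   and the foveal boundary;
4. a linear fovea–periphery blend over `transition_width` pixels.

Dynamic foveation relocates the fovea to the most salient region: dense
optical flow between the preceding frame pair (classical pyramidal
Lucas–Kanade; the estimator is a pluggable contract, so a learned network
with the same signature can be substituted), a saliency map formed by
Gaussian aggregation of flow magnitude, and the centroid of pixels within
99% of its maximum. All-zero flow falls back to the image centre. The
Lucas–Kanade default gates its update on local gradient energy and
diffuses flow from textured edges into textureless interiors; flow is only
observable where there is texture, and the diffusion gives object
interiors the motion of their edges while empty regions decay to zero.

## Encoders

Four families, all with hand-written forward and backward passes (verified
against finite differences in the test suite):

* **ViT-CoT** — patch size 8 on 64 x 64 input (64 tokens), a single shared
  linear patch projection (no convolutions, so no spatial prior beyond
  patching), learned positional embeddings, pre-LN transformer blocks with
  quick-GELU MLPs. The family convention ties heads to depth: 1H = one
  head/one layer, 3H, 6H, 9H. The embedding is the mean over last-layer
  patch tokens after the final normalisation; no class token exists, and
  published variants of this family read out either way.
* **ResNet-10** (SimCLR-CLTT) — stem convolution, two stages of two
  residual basic blocks (bridge 1 x 1 projection on the downsampling
  block), global average pooling, linear head; 10 trainable layers. The
  desk-scale variant is norm-free (small-gain residual initialisation
  instead of batch norm), which keeps evaluation purely functional and
  bit-reproducible.
* **Autoencoder** — the same ResNet-10 encoder with a mirrored
  nearest-neighbour-upsampling decoder and sigmoid output; after training
  the decoder is dropped and only encoder embeddings are evaluated.
* **GreedyInfoMax** — the ResNet-10 trunk split into two five-layer
  modules, each trained by its own local contrastive loss on augmentation
  pairs (no temporal learning), with a gradient blocker at the module
  boundary. `gradient_isolation_check()` verifies the contract — and its
  negative control (blocker off) verifies the check itself.

Default `embed_dim` is 128. Published parameter totals for this model
family (5.8M–59.4M over 1H–9H) imply hidden widths that are not mutually
consistent with any single width/MLP-ratio choice, so parameter counts are
reported on the encoder handle but not asserted against published totals.

## Training

Contrastive learning through time (CLTT): each batch of consecutive frames
is augmented into two views; for an anchor, the positives are the
other-view items within the temporal window (|Δt| < 3 frames ≈ 300 ms at
10 frames/s, plus the anchor's own augmented counterpart) and the
negatives are all items of either view outside the window. The loss is
InfoNCE on cosine similarities at temperature 0.5 (the objective family is
named in the source work, but no formula or temperature is printed; 0.5 is
the SimCLR convention), averaged over anchors in both directions.

The loss is computed on the output of a small MLP projection head
(linear–batch-norm–ReLU–linear) that is discarded at evaluation time;
embeddings are always trunk features. This is the SimCLR-family design,
and it matters mechanically: without the head, the fully collapsed
embedding (all images mapping to one point) is a fixed point of the
InfoNCE dynamics — at collapse, every candidate contributes the same
vector and the per-anchor gradient sums exactly to zero — and a
small-initialisation ViT whose pooled tokens start nearly collapsed falls
straight into it. The head's batch normalisation removes the shared
component per batch and keeps the objective away from that fixed point.

The five augmentations follow the canonical diet: random resized crop
(100%), horizontal flip (50%), colour jitter (80%), grayscale (20%),
Gaussian blur (50%). Probabilities are the canonical values; per-operation
strengths (crop scale 0.6–1.0, aspect 3/4–4/3; jitter 0.4/0.4/0.4/0.1;
blur σ 0.1–2) follow the standard contrastive-learning recipe, as only
the probabilities are published.

Optimisation is Adam. The canonical recipe trains 100 epochs on
80,000-frame streams at a constant 1e-4 for ViTs (5-epoch warmup plus
cosine decay for the contrastive CNN). The presets expose three scales:

* `full_preset()` — the canonical recipe (compute-bound, not code-bound);
* `desk_preset()` — 5,000 frames, 3-layer/64-d ViT, 10 epochs, batch 64,
  learning rate 1e-3 (the step count is ~100x smaller than the canonical
  recipe, so the constant rate is raised accordingly — chosen once as a
  scaling decision);
* `micro_preset()` — 768 frames, 12 epochs, batch 32, 48-d; the scale the
  package's own test suite runs end to end.

GreedyInfoMax trains with window 1 (augmentation pairs only, no temporal
positives), each module's local loss behind its own projection head, batch
32. The autoencoder minimises pixel MSE on `[0, 1]` intensities.

## Evaluation

The test set is the 4 shapes x 4 colours factorial (defaults: circle,
triangle, square, cross; red, green, blue, yellow — the shape vocabulary
is parameterisable and was chosen for pairwise silhouette distinctness).
One frontal view per object for RDMs; 29 views per object, sampling
rotation angles across ±75° (edge-on views excluded so every silhouette
stays identifiable), for 2-D projections.

Embeddings of the 16 single-view stimuli are centred by subtracting the
grand mean embedding, then pairwise cosine similarities form the 16 x 16
matrix. The colour score averages the 24 unordered off-diagonal cell pairs
sharing a colour; the shape score the 24 sharing a shape; diagonal cells
are excluded, which makes the two scores disjoint (same-shape-same-colour
pairs occur only on the diagonal of a complete factorial). Standard errors
are taken across the unordered contributing cells.

Statistics mirror the canonical tables: within-model paired t-tests of
shape vs colour score across seeds (df = n_seeds − 1), and Welch
two-sample t-tests of trained vs untrained per score. When per-seed
differences are constant to within 1e-9, the paired statistic is undefined
and the result carries an `na_flag` with the reason — the convention used
when near-identical seeds prevent a t-test. Two-sided p-values throughout.

`project_2d()` is a visualisation-only contract (PCA default, classical
MDS optional, custom functions accepted); t-SNE is deliberately not
re-implemented, and requesting it raises a configuration error.

## What the synthetic world does and does not show

The generator emulates the *structure* of chamber-reared visual
experience: temporal continuity, embodied view diversity (distance,
lateral angle, head rotation), a single bi-faced object, and factorial
test stimuli. It does not emulate photorealistic texture, lighting,
self-occlusion by the agent's body, or the visual complexity of
head-camera recordings of daily life. Passing qualitative tests here shows
that the pipeline reproduces the direction of the published contrasts
under matched conditions at reduced scale — not that it reproduces their
published effect sizes, which arise from ~60,000-step GPU training runs.

At the micro scale the test suite can afford (hundreds of gradient steps),
the untrained colour bias and the colour-jitter contrast replicate
cleanly: random-weight encoders score colour ≈ 0.96 vs shape ≈ −0.28, and
jitter-only training beats no-augmentation training on shape score in
every seed tested, because jitter attacks the colour cue directly. The
temporal-training contrast is slower to emerge. Early CLTT training
*amplifies* colour (it is the easiest within-window-stable discriminator);
the shape−colour gap of a dense-exploration-trained model crosses its
untrained baseline only after roughly a thousand gradient steps here, and
the within-batch-shuffled control is harder still at small scale: shuffling
leaves each anchor's augmented self-pair intact, so the control degenerates
into fast SimCLR-style instance discrimination whose jitter-driven colour
suppression outpaces the ordered model's slower temporal learning until
far more steps have elapsed. The acceptance suite asserts each contrast as
a direction-of-effect sign test over three seeds at matched steps and
leaves the temporal-training contrast failing at this scale rather than
weakening its assertion; the jitter-ablation and untrained-bias contrasts
pass.

## Numerical choices and degenerate inputs

* Images are `[0, 1]` arrays quantised to 8-bit levels at module
  boundaries; all retina filters map valid 8-bit images to valid 8-bit
  images.
* One master seed expands into per-stage streams via a splitmix-style
  integer mixer (`derive_seed()`), so stages rerun independently and all
  derived seeds stay below 2^31.
* Zero-norm stimulus embeddings raise a `degenerate_embedding` error
  naming the object rather than propagating NaN cosines.
* The saliency tie-break is the centroid of all pixels within 99% of the
  saliency-map maximum; an all-zero flow field yields the image centre.
* Paired-test degeneracy threshold: sd of differences < 1e-9 on the score
  scale.
* Finite-difference gradient checks use the median relative error across
  parameters to stay robust to ReLU-kink straddling.

## Known limitations

* Pure-R training is orders of magnitude slower than framework-based
  training; the full-scale preset is defined but impractical here.
* The Lucas–Kanade default underestimates large displacements
  (> ~8 pixels/frame at 64 x 64) and textureless motion; substitute a
  stronger estimator through the flow contract if that matters.
* No event-based retina output, photoreceptor adaptation, or
  developmental acuity schedule.
* Video ingestion accepts image-sequence directories and in-memory
  arrays; container formats (MP4/AVI) need external frame extraction
  first, as no video decoder is available to R here.
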