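---
title: "Virtual-slide diatom classification: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual-slide diatom classification: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(diatomslide)
```

## The problem

Plankton-net samples from Southern Ocean expeditions are routinely prepared
as permanent slides, scanned into gigapixel *virtual slides*, and annotated
with polygon outlines and taxon labels for thousands of objects of interest
(diatom valves and frustules, girdle bands, silicoflagellate skeletons).
`diatomslide` implements the downstream analysis pipeline for such data:
turning annotated slides into labelled cut-out data sets, training a small
image classifier on them, scoring it with micro- and macro-averaged F1, and
quantifying — through a factorial experiment design and ANOVA — how data-set
size, soft background masking and between-expedition concept drift affect
classification performance.

Because the original expedition imagery is large and external, the package
ships a first-class synthetic generator that reproduces the *statistical
structure* of such data at desk scale: bright-field-like 8-bit grayscale
slides, about ten morphologically distinct object classes at realistic
imbalance, debris, neighbouring objects inside cut-out windows,
multi-annotator label disagreement, and a two-cohort design with a
controllable appearance drift. Every stage of the pipeline is tested
against this generator; nothing requires a download.

## Synthetic virtual slides

A slide is a `height x width` integer matrix of grey values (0 = black,
255 = white) with a bright homogeneous background (default mean 200,
Gaussian noise sd 6) and darker objects. Objects are procedural, not
learned: each of the ten default families (`default_shape_families()`)
combines an analytic silhouette (lanceolate, circular, star, chain or rod
base), a size range, a stria-like periodic ornament and a contrast against
the background. The families mirror the taxa of the bundled reference
composition (`reference_composition()`): e.g. *Fragilariopsis
kerguelensis* as a striated lanceolate outline, *Rhizosolenia* as a long
thin rod, silicoflagellates as spiky rosettes. Families used together are
mutually distinguishable by at least one parameter; this is deliberate —
classes must be separable by a small classifier so that pipeline tests
measure the pipeline, not the limits of a miniature network.

Conventions fixed once and used everywhere:

* polygons are `n x 2` matrices of `(x, y)` vertices in 0-based pixel
  coordinates, implicitly closed; a pixel `(x, y)` is the matrix cell
  `[y + 1, x + 1]` and is sampled at its centre `(x + 0.5, y + 0.5)`;
* rasterisation uses the even-odd fill rule (tested against an independent
  point-in-polygon oracle);
* bounding boxes are half-open, `[x0, x1) x [y0, y1)`.

Placement is rejection sampling without bounding-box overlap; with
probability `overlap_prob` an object is instead placed adjacent to an
already placed one so that the bounding boxes (and hence the later cut-out
windows) overlap while the object bodies stay essentially separate. Fully
overlapping bodies would overwrite each other's pixels and break the
ground-truth guarantee that a record's polygon recovers the rendered
object's foreground.

Cohort ("expedition") drift is a deterministic offset of three appearance
parameters, scaled by `shift_strength` in [0, 1]: background level
(-20 grey levels at full shift), object contrast (x 0.70) and size
(x 1.25). `cohort_shift_params()` exposes the applied values so drift is
measurable from outside; at `shift_strength = 0` the two cohorts share one
generating distribution. The real phenomenon this emulates — different
years, different slide scanners and stitching software — is not
parametric, so the generator's drift should be read as a controllable
surrogate with the right sign and order of magnitude, not as a calibrated
model. Debris density and background texture are likewise fixture
choices; the source imagery offers no quantitative description of either.

## Cut-outs, gold labels and soft masking

Multi-annotator label tables are resolved to a gold standard before any
counting: unanimous labels win outright; divergent labels fall to the
senior expert's label under the default `senior_wins` policy, and to a
skip decision under `unanimous_only` (or when no senior label exists, or
when the record is flagged as distorted). Both policies are provided
because archival annotation data contains divergent records without a
senior label, and which rule a given study used is usually not
recoverable.

`extract_cutout()` expands the polygon's integer bounding box by a margin
(default 10 px) on every side, clips to the canvas, and copies pixels
verbatim — neighbouring objects inside the window remain visible. The mask
covers only the focal polygon.

`mask_background()` replaces the background by the cut-out's background
grey level with a smooth transition at the object boundary. Two numerical
choices matter here:

* **The background level `b`** is the *median* grey over background pixels
  outside the transition band, computed per cut-out. A mean over all
  non-object pixels is dragged down by darker neighbour objects, making
  the homogenised background level vary arbitrarily between cut-outs; the
  median estimates the scene background robustly. Computing it per
  cut-out (rather than per slide) keeps the operation local and robust to
  illumination gradients.
* **The transition** is built by smoothing the *hard-masked field* (object
  pixels over a constant-`b` background) with a Gaussian of
  sigma = `transition_width_px / 2` (default width 5 px), truncated at two
  sigma. Object pixels are then copied verbatim and background pixels take
  the smoothed field. This construction has three properties a naive blend
  `w * image + (1 - w) * b` lacks: background pixels beyond the transition
  width equal `b` exactly (the truncated kernel has compact support),
  neighbour objects are suppressed entirely rather than attenuated, and
  the operation is idempotent to within a grey level — re-applying it
  rebuilds the same transition from the same untouched object pixels,
  whereas a blend with interior weights contracts the transition band
  toward `b` on every application.

Data-set assembly applies the package's standard rules: records flagged as
distorted are dropped first; `filter_classes()` keeps classes with at
least 40 specimens in *every* cohort; `cap_class()` subsamples a named
over-abundant class (the bundled reference composition caps *Fragilariopsis
kerguelensis* at 660) uniformly without replacement, preserving survivor
order.

## Splits

All partitions are stratified per class and operate on item ids, never on
pixels. Wherever a percentage does not divide a class size, the package
uses largest-remainder rounding with ties broken toward the earlier-listed
role (train > validation > test): allocations are deterministic and within
one item of the target per class. The schemes are: the pooled 72/18/10
split; fourfold cross-validation where each plan tests on one fold and
splits the remainder 80/20 into train/validation; per-class fractional
subsets (the 10 % condition; at least one item per non-empty class,
redrawn per replicate with distinct seeds); and the out-of-set plan that
trains 80/20 on one cohort and tests on *all* eligible items of the
other. Out-of-set plans default to classes present in both cohorts — the
at-least-40-per-cohort filter guarantees that anyway for data assembled by
this package.

## The classifier stage

The trainable stage is a compact convolutional network written against
BLAS: three 3x3 conv blocks (8, 16, 32 filters, ReLU, 2x2 max-pool)
followed by a dense softmax head of one or two 256-unit layers. Two
desk-scale backbones share this architecture:

* `tiny_cnn` (input 32 x 32) trains everything from scratch;
* `frozen_random_conv` (input 64 x 64) freezes the conv stack at seeded
  random weights and trains only the head — the structural analogue of
  transfer learning without fine-tuning, where a fixed feature extractor
  feeds a trainable classifier module.

Pretrained ImageNet backbones (`pretrained:<name>`, inputs 224/299) are a
pluggable mode: the caller supplies the feature-extractor function, the
package trains the same dense head on its output. They are never required
by tests. The input sides of the desk-scale backbones deliberately differ
from the 224/299 of published pretrained bases: each backbone declares the
shape it needs, and synthetic shapes are fully resolvable at 32 px.

Preprocessing scales intensities to [0, 1], replicates the grey channel
to three channels, and resizes to the backbone's input side after padding
to a square with the cut-out's background level — padding rather than
anisotropic resizing, so stria periods are not distorted differently along
the two axes.

Augmentation draws one random parameterisation of exactly seven transforms
— rotation, width shift, height shift, shear, zoom, horizontal flip,
vertical flip — composed into a single affine map about the image centre
and sampled bilinearly (out-of-range regions filled with the border mean).
Defaults: rotation +-180 degrees, shifts +-10 %, shear +-10 degrees, zoom
0.9-1.1, both flips enabled; every transform can be disabled. Training
uses exclusively augmented images; validation and test images are never
augmented.

Training uses Adam (default learning rate 1e-3) on shuffled minibatches
(the running conventions are batch 32 for full data sets and 8 for 10 %
subsets), for a fixed number of epochs with no early stopping and no model
selection — the final-epoch model is reported. Two stabilisers are on by
default because a final-epoch convention is sensitive to late-training
noise in small-sample regimes: global gradient-norm clipping at 5 and a
half-cosine decay of the learning rate to a tenth of its peak. Both are
configurable (`train_config()`), as is a constant-rate schedule. All
randomness (weight initialisation, shuffling, augmentation draws) is
seeded; identical seeds give bit-identical training histories.

## Metrics

Per class, precision = TP / (TP + FP), recall = TP / (TP + FN) and
F1 = 2PR / (P + R). Micro averages pool TP/FP/FN over classes before
applying the same formulas; the macro F1 is the unweighted mean of
per-class F1 values. The degenerate-class convention — needed whenever a
class is never predicted — sets any 0/0 ratio to zero, so every class
contributes a value; this is the mathematically complete form of the
convention "precision := 0 when TP = 0" and coincides with it wherever
that rule applies. In the single-label multiclass setting the micro
precision, recall and F1 all equal plain accuracy; the test suite asserts
this identity against a brute-force oracle. Macro averaging uses
*unrounded* per-class values; rounding (default 2 decimals) happens only
in `report_table()`, which also flags classes whose F1 lies below the
class average, mirroring the bold-marking convention of per-class report
tables.

## The factorial experiment harness

`build_design()` produces the 16-cell design crossing training/test cohort
(two in-set and two out-of-set directions), portion (100 % vs 10 %) and
background masking, with the running conventions attached: fourfold CV for
in-set cells, 3 replicates for full out-of-set cells, 5 for 10 %
out-of-set cells, batch 32/8 by portion; optionally the pooled
merged-cohort cell with the 72/18/10 split. `run_design()` executes any
subset of rows against a synthetic (or user-provided) cut-out source and
emits one result row per fold or replicate; 10 % subsets are redrawn per
replicate with derived seeds. A training split that loses a class is
skipped with a diagnostic rather than failing the whole design.

`estimate_effects()` fits an ordinary least-squares linear model of F1 on
the factor *combination* of each run, with the full-data + masked + in-set
cell as the reference — the reference-cell parameterisation is forced by
the way effect tables are reported (absolute baseline row, all other rows
as deltas relative to it). Each fold/replicate enters as one observation;
p-values come from the usual t statistics and map to the significance
codes `***` (< 0.001), `**` (< 0.01), `*` (< 0.05), `.` (< 0.1). A
numerically perfect fit has no residual scale, so its p-values are
reported as missing rather than spuriously significant. F1 responses are
modelled untransformed, which is the scale on which the deltas are read.
`model_comparison()` applies the same machinery across classifier
variants, reporting the best model absolutely and the others as deltas.
`simulate_f1_rows()` generates design-shaped replicate tables with known
injected effects and noise; the parameter-recovery tests and the
acceptance script use it to verify that estimation recovers effects of the
magnitude reported for such experiments (about -0.06 micro / -0.12 macro
for data-set reduction, about -0.02 for unmasked background and for
out-of-set prediction) within two standard errors.

## Desk-scale problem sizes

The test suite and the acceptance script run the full pipeline on
generated data sized for a single CPU: four-class cohort pairs with 30-80
objects per class and cohort on 1400-1800 px canvases, tiny_cnn training
for 25-30 epochs, three seeds per condition; effect-recovery simulations
use 20 replicates per design cell and 100 repetitions. These sizes are the
package's choices for demonstrating correctness properties — count
conservation, split contracts, metric identities, effect recovery, the
direction of the masking benefit under distractor objects — not estimates
of real-data performance.

## What passing tests do and do not show

The synthetic generator emulates class imbalance, cohort drift, debris,
window-sharing neighbours and annotator disagreement, but not focus
gradients, stitching artefacts ("ghosting"), within-taxon morphological
continua, girdle-band vs valve-view ambiguity, or the long tail of rare
classes in real net samples. Passing the end-to-end tests therefore shows
that the pipeline's plumbing, conventions and statistics are correct and
that its qualitative effects (masking helps when windows contain
distractors; out-of-set prediction degrades with drift) point the right
way on controlled data. It does not certify absolute F1 levels on real
expedition imagery, which depend on pretrained backbones and data the
package does not ship.

## Known limitations

* The conv engine is deliberately minimal (3x3 kernels, stride 1, 2x2
  max-pool); it is not a general deep-learning framework.
* The masking idempotency guarantee is exact only where the window's
  transition band is free of other objects; a neighbour lying within the
  transition width of the focal boundary is suppressed on the first
  application, which changes the band once.
* `unanimous_only` resolution combined with heavy simulated disagreement
  can empty small classes; the splits then refuse to stratify and name
  the offending class.
* The ANOVA treats folds and replicates as independent observations; for
  fourfold CV this ignores the mild dependence between folds sharing
  training data, as is conventional in such comparisons.
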