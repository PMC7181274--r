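---
title: "Margin-based deep networks for open-set activity recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Margin-based deep networks for open-set activity recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(marginhar)
```

## The problem

Body-worn inertial sensors produce multichannel time series that are sliced
into fixed-length windows and classified into activities. Two properties make
this hard. First, activities have **large intra-class scatter** (the same
movement performed by different people, or caught by the window at a
different moment of its cycle) and **small inter-class separation** (opening
and closing a door produce near-identical signals that differ mainly in
temporal direction). Second, a deployed recogniser meets activities that were
absent from its training set — an **open-set** problem: such windows must be
flagged as new rather than forced into a known class.

`marginhar` addresses both with one mechanism: an **additive angular margin**
on a normalized cosine softmax head. The margin forces training to compress
each class into a tight angular cluster on the unit hypersphere and to keep
classes a geodesic gap apart, which both improves closed-set discrimination
of similar activities and yields feature vectors compact enough to support a
prototype database for novelty detection.

## The loss

For a feature vector $x$ and class-weight rows $W_j$, the usual softmax
cross-entropy works on logits $f_j = W_j^\top x + b_j$. Setting $b_j = 0$ and
L2-normalizing both factors leaves only the angle:
$f_j = s\,\cos\theta_j$, where $s$ rescales the product of unit norms. The
normalized softmax loss over a batch of size $B$ is

$$L_{norm} = -\frac{1}{B}\sum_i \log
  \frac{e^{s\cos\theta_{y_i}}}{\sum_j e^{s\cos\theta_j}}.$$

The arcmargin loss additionally penalises the true class by an angle interval
$m$:

$$L_{arc} = -\frac{1}{B}\sum_i \log
  \frac{e^{s\cos(\theta_{y_i}+m)}}
       {e^{s\cos(\theta_{y_i}+m)} + \sum_{j\ne y_i} e^{s\cos\theta_j}}.$$

To reach the same predicted probability the network must make
$\theta_{y_i}$ smaller by $m$, which is what enforces intra-class compactness
and inter-class separation. At $m = 0$ the two losses coincide exactly
(`arc_margin_loss()` reduces to `normalized_softmax_loss()` to $10^{-9}$; the
suite asserts it), so the $m = 0$ twin of a margin model is its natural
softmax counterpart on the same hypersphere geometry.

Numerical choices:

* $\cos(\theta+m)$ is computed from $\cos\theta$ via
  $\cos\theta\cos m - \sin\theta\sin m$ with
  $\sin\theta=\sqrt{1-\cos^2\theta}$; cosines are clamped to $[-1,1]$ first so
  floating-point drift cannot leave the domain.
* When $\theta + m > \pi$ the cosine would fold back and *reward* larger
  angles; the implementation switches to the linear fallback
  $\cos\theta - m\sin m$, which preserves monotone penalisation. Gradients
  use the matching branch.
* The scale defaults to $s = 30$, the established convention of cosine-margin
  heads (the method family this head belongs to); it is configurable because
  the appropriate value shrinks with the embedding dimension (see the 2-D
  experiment below).
* Default margins follow the per-architecture convention: 0.5 (MLP), 0.2
  (CNN), 0.5 (LSTM), 0.3 (hybrid); `run_margin_sweep()` annotates these rows.

## The architectures

`build_network()` assembles four bodies behind a shared interface: an MLP
(three dense layers, 2000 units each by default), a temporal CNN (three
blocks of 1-D convolution over the time axis + ReLU + max-pooling, then a
1000-unit dense layer), a 2-layer LSTM (600 hidden units, one cell per window
sample, sigmoid gates and tanh state activations), and a hybrid whose single
convolution block feeds a 2-layer LSTM via per-time-step slices (each slice
is the filter-response vector at that step, in filter order). Every model
starts with an input batch-normalisation layer (per channel, over batch and
time); hidden dense layers are followed by ReLU.

Two head variants close the network: a plain dense softmax, or the arcmargin
head (normalized cosine logits, zero bias; the margin applies during training
only — inference uses raw cosines).

**The feature layer.** The open-set machinery consumes the output of the
dense layer feeding the head. For the CNN/LSTM/hybrid models this embedding
layer is *linear* — no ReLU. This is a deliberate deviation from the
"every dense layer gets a ReLU" convention of the hidden layers: a ReLU'd
embedding is confined to the non-negative orthant, which (i) caps the
achievable angular separation (in 2-D, six classes would have to share a 90°
wedge) and (ii) inflates every raw cosine with a shared positive component,
masking the compactness the margin creates. Linear embeddings are the
standard in angular-margin metric learning for exactly this reason. The
MLP's designated feature layer is its first dense layer, which feeds further
hidden layers and therefore keeps its ReLU.

Training (`train_network()`) follows the reference recipe: all weight
matrices randomly orthogonally initialised (seeded, QR-based, Haar
sign-corrected), biases zero, ADADELTA with initial step 1
($\rho = 0.9$, $\epsilon = 10^{-6}$), batch size 100, the last partial batch
included, per-epoch mean loss recorded. Everything is deterministic given the
seed; the analytic gradients of every layer are unit-tested against central
finite differences.

## Open-set recognition

After training, the arcmargin layer is removed and features are extracted
from the feature layer for all training windows. A **feature database**
stores, per class:

* **seeds** — representative feature vectors, chosen either by the *center
  method* (the feature with the highest mean cosine similarity to the rest of
  its class, plus uniformly sampled random seeds) or the *cluster method*
  (k-means++ initialisation followed by Lloyd iterations, tolerance $10^{-6}$
  or 100 iterations, run on L2-normalized features so Euclidean clustering
  orders points as cosine similarity does; empty clusters are re-seeded at
  the farthest point);
* **an acceptance threshold** $\tau_c$, calibrated on a validation split:
  candidate thresholds $0.1, 0.2, \ldots, 0.9$ are scanned, a sample is
  accepted as class $c$ iff its similarity to the class seeds is $\ge \tau$
  (similarity to a class = max cosine over its seeds, the nearest-prototype
  reading), and the $\tau$ with the best binary accept-vs-rest F1 wins, ties
  going to the *largest* $\tau$ (stricter acceptance favours novelty
  detection).

Enrolling a new activity takes a handful of its windows, extracts features,
selects seeds by the same method, and sets the **new-activity threshold**
$\tau_{new}$ to the first quartile (25th percentile, linear interpolation) of
the pairwise cosine similarities among the enrollment features.

Classification of a window computes its similarity to every database class
and takes the argmax $c^*$ (ties to the lowest class id), with value $v$. If
$c^*$ is a predefined class and $\tau_{new} < v < \tau_{c^*}$, the window is
labelled `NEW`; otherwise it is labelled $c^*$. The case $v \le \tau_{new}$
is ambiguous — the sample matches neither the known classes nor the new
activity well; following the letter of the decision rule it falls through to
$c^*$, and the prediction record flags it (`ambiguous = TRUE`). Re-enrolling
an existing class id replaces its entry; known-class thresholds are not
re-calibrated on enrollment.

## The synthetic generator

`generate_windows()` and `generate_recording()` produce data with the
statistical structure the method assumes, so the whole pipeline is testable
without external recordings. Each class is a sum of one sinusoid per channel
with class/channel-specific frequency and phase. Per frame, amplitudes are
jittered multiplicatively per channel and a single phase offset is drawn
(shared across channels — a shifted time origin), then white Gaussian noise
is added. Classes listed in `reversed_pairs` use the *time reversal* of
their partner's template: per channel this is indistinguishable from a phase
shift, so only the cross-channel phase relations separate the pair — a
controlled analogue of activities that differ only in sequential direction,
and demonstrably the most confusable pair for a nearest-template oracle (a
suite property).

Defaults (the package's study conditions): 6 classes, one reversed pair,
3 channels, 32-sample windows at 30 Hz, 100 windows per class,
amplitude jitter SD 0.3, phase jitter SD 0.8 rad, noise SD 0.4. The jitter
levels are deliberately large: windows slice cyclic movements at arbitrary
offsets, so window phase varies strongly in real pipelines, and inter-subject
amplitude variability is substantial. With mild jitter the synthetic task
becomes trivially separable and *any* head compacts classes, which would not
emulate the intra-class-scatter challenge the margin exists for.

What the generator does **not** emulate: biomechanically realistic gait
harmonics, sensor-noise physics (bias drift, saturation), multi-sensor
synchronisation artifacts, or label noise. Passing tests on this data show
the machinery behaves as designed under the stated statistical structure,
not that any particular F1 will be reached on a real deployment.

`generate_recording()` additionally lays classes out as contiguous labelled
segments (round-robin interleaved) and inserts missing values independently
per entry, to exercise the preprocessing path.

## Preprocessing conventions

* Forward fill takes the most recent non-missing value per channel; *leading*
  missing entries become 0, which is neutral after the input batch-norm.
  The operation is idempotent.
* Downsampling averages non-overlapping groups (mild anti-aliasing rather
  than decimation), drops the trailing partial group, and majority-labels
  each group with ties broken by the group's last sample.
* Sliding windows use 0-based, half-open coordinates `[start, start + T)`
  with starts at multiples of the stride; the count is
  `floor((L - T)/stride) + 1`. Window labels are the majority per-sample
  label, ties to the last sample. An `L < T` input yields an empty window set
  with a warning, not an error.
* Channel selection ranks channels by raw per-channel variance over all
  training windows (descending, ties to the lower index) and keeps the top
  *n* in their original tensor order. A principal-component projection would
  be an alternative reading of "variance rank"; raw channel variance is used
  because it selects physical *channels* (the point of the exercise is
  reducing sensors), and the choice is documented here as genuinely open.

## Evaluation

Activity datasets are heavily imbalanced (a background NULL class can
dominate), so besides accuracy the package reports the weighted F1
$F_w = \sum_c w_c \frac{2\,P_c R_c}{P_c + R_c}$ with $w_c = n_c / N$, and the
macro (average) F1 $F_m = \frac{2}{|c|}\sum_c \frac{P_c R_c}{P_c + R_c}$,
which is independent of the class distribution. Per-class 0/0 terms are
defined as 0, and $F_m$ divides by the number of *declared* classes even if
some are absent from the test labels. Both match an independent brute-force
implementation to $10^{-12}$ in the suite.

## Experiment drivers and problem sizes

`run_margin_sweep()`, `run_open_set_experiment()`, `run_embedding_2d()` and
`cosine_similarity_heatmap()` mirror the method's diagnostic experiments on
synthetic data, writing tidy tables plus a JSON manifest (config, seeds,
package version) sufficient to re-run bit-identically. The open-set driver
splits windows per class into train/validation/enrollment/test
(50/20/15/15), withholds one class from training and validation entirely,
enrolls it from the disjoint enrollment split, and reports per-class F1
including `NEW`, next to a closed-set control run through the same database
pipeline. The heatmap diagonal uses distinct pairs only, so intra- and
inter-class entries are comparable.

The package's own experiments and acceptance checks run a scaled-down
temporal CNN — blocks (9,1,16,2) and (5,1,16,2) with a 64-dimensional
embedding — for 80 epochs on the default generator. Full-size settings
(50 epochs, 2000/1000-unit layers) remain the configuration defaults; the
small sizes are chosen so a complete study runs in seconds on one CPU, and
80 epochs because the arcmargin head saturates more slowly than plain
cross-entropy under ADADELTA. The 2-D embedding experiment uses margin 0.5
and scale 10: in two dimensions the head has so little room that
$m=0.3, s=30$ saturates before the class directions spread, while a larger
margin and smaller scale keep gradients alive until the directions separate.

## Known limitations

* Pure-R training: practical for the scaled-down study sizes, not for
  full-size models on hundreds of thousands of windows.
* Single unknown class at a time: the database holds one `NEW` entry;
  multiple simultaneous unknown activities with distinct thresholds are out
  of scope, as is online re-calibration of known-class thresholds after
  enrollment.
* File I/O covers the package's CSV layouts and JSON databases; model
  checkpoints are RDS with a JSON sidecar.
* The decision rule's $v \le \tau_{new}$ branch follows the stated rule
  (predict $c^*$) but is arguably a rejection case; it is flagged per
  prediction rather than re-interpreted.
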