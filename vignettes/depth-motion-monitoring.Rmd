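---
title: "Non-contact neonatal activity monitoring from depth video: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-contact neonatal activity monitoring from depth video: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(neomotion)
```

## The problem

Neonatal activity — gross body movement and the more localised motion of
limbs, hands and head — is a clinically meaningful parameter in intensive
care: it relates to sedation state and to disease onset, and it is a major
source of artifact on contact-based vital-sign signals. A depth camera
placed above or beside the bed returns, at every pixel, the distance (mm)
to the nearest surface, so body movement appears as coherent changes in the
depth raster over time. `neomotion` turns such a depth stream into a
per-second binary **motion / no-motion** signal and evaluates the resulting
classifier exactly the way a multi-subject clinical study would: per-subject
leave-one-out cross-validation with a training-ROC operating point
transferred to the held-out subject.

No clinical recordings ship with the package. A synthetic scene generator
(section *Synthetic scenes*) produces labelled depth video with the
geometry, motion statistics and sensor-noise behaviour the method assumes,
so every stage is testable end to end.

## From depth stream to difference frames

A clip is divided into one-second spans. Each span's state is the
per-pixel **median** of the 10 frames at its start and end (five each).
The median rejects single-frame outliers, and pooling two sub-windows
~0.8 s apart deliberately comb-averages periodic respiratory
displacement (~0.8 Hz) out of the span state — sustained surface change
passes through, breathing largely does not. (Averaging a single
contiguous 10-frame window instead passes the respiration phase straight
into the one-second differences and measurably degrades the classifier's
specificity.) A pixel invalid (no sensor return, encoded 0, or outside
the plausible 200–1000 mm range) in more than half of the contributing
frames stays invalid. A clip of $n$ spans yields $n$ averaged frames and
$n-1$ difference frames; the difference for second $t$ compares spans
$t$ and $t+1$ and is compared against the truth label for second $t$.
This alignment is applied identically to predictions and truth.

Five noise-removal stages then run in a fixed order:

1. **Percentile clipping.** Depths above the 87th or below the 3rd
   percentile of all in-range (200–1000 mm) depths are removed, per frame.
   This isolates the depth band where the neonate lies. Percentiles use
   linear interpolation between order statistics (the common type-7
   estimator) everywhere in the package.
2. **Differencing.** Consecutive clipped averages are subtracted; a
   difference is defined only where both frames are valid.
3. **Masked spatial medians.** A 5×5 then a 3×3 median filter, computed
   over *valid* pixels only. Ignoring invalid pixels (rather than
   zero-filling) keeps medians unbiased at mask borders.
4. **Large-difference removal.** $|\Delta| > 150$ mm is removed — too large
   to be neonatal motion, in either direction.
5. **Small-region removal.** Connected components (8-connectivity by
   default) of valid, nonzero difference pixels with area < 40 px are
   removed. Zero-valued valid pixels carry no motion evidence and are left
   alone; consequently both removal stages are idempotent and no stage ever
   increases the number of valid pixels.

All parameters live in `denoise_config()`, with the defaults above.

## The 16 per-second features

The classifier sees sixteen features per second, in four groups. The
literature this design follows names the groups and their intent but not
closed formulas, so the definitions below are this package's explicit,
test-covered interpretation; every threshold is exposed in
`feature_config()`.

* **Spatial scale of motion (5).** For graded thresholds
  $T \in \{1,3,6,12,25\}$ mm: the fraction of valid depth pixels whose
  $|\Delta| > T$, multiplied by $(\bar d / 500)^2$ where $\bar d$ is the
  mean valid depth (mm). Apparent pixel area shrinks quadratically with
  camera distance; the factor restores a physical spatial scale. Scaling
  all depths by $c$ scales these features by exactly $c^2$.
* **Magnitude of motion (4).** For $U \in \{1,5,15,40\}$ mm: the summed
  $|\Delta|$ over pixels exceeding $U$, per valid difference pixel —
  sensitive to strong motion over small areas.
* **Average depth (4).** Mean, median, 25th and 75th percentile of valid
  depths, letting trees condition the motion evidence on distance.
* **Skewed-placement set (3).** The standard deviation of depths at or
  below their 75th percentile (robust spread), the excess kurtosis of
  depths (Fisher convention: 0 for Gaussian; an indicator of frame noise),
  and the 75th percentile itself (a distance proxy). These help when the
  camera views the scene at a skewed angle (head's or foot's end).

Both graded groups are non-increasing across their thresholds, and all 16
features are finite on every frame the denoiser can emit, including fully
invalid ones (depth summaries fall back to 0 with a warning).

## Classifier and operating point

The classifier is a probability Random Forest: trees grown on bootstrap
samples of the training seconds, a random subset of features
(`max_features`, default 4) considered at each split, per-second
probability = mean of the trees' leaf class frequencies. Tree growing is
standard CART/Gini machinery and is delegated to the `ranger` engine with
single-threaded, seeded execution, so the whole train/predict path is
bit-reproducible; the surrounding model object records the feature ordering
and refuses to predict when columns mismatch.

The operating point comes from a **training ROC**: thresholds are swept
over every distinct probability (plus sentinels), motion is flagged when
probability is *strictly greater* than the threshold, and the selected
threshold maximizes the mean of sensitivity and specificity (ties toward
the lower threshold, favouring sensitivity). The training ROC is built from
the forest's **out-of-bag** probabilities: in-sample Random Forest
probabilities are nearly separable by construction and would put the
"training optimum" in a degenerate corner, while out-of-bag probabilities
are the standard unbiased training-set assessment and produce thresholds
that transfer to held-out subjects.

`grid_search()` sweeps forest and denoising configurations jointly and
scores each combination by the mean of $\sqrt{\mathrm{AUC}}$ over held-out
clips — penalizing both false positives and false negatives — with ties
broken toward smaller models.

## Evaluation protocol

`loocv()` implements per-subject leave-one-out: for each subject, a forest
is trained on all other subjects' pooled seconds, the training threshold is
selected as above, and the model plus threshold are applied to each of the
held-out subject's positional clips separately, producing a per-clip test
ROC-AUC and sensitivity/specificity at the transferred threshold. Clips
whose truth labels are single-class have no defined ROC; their rows are
kept with `NA` and excluded from the mean/SD summaries (sample SD,
$n-1$). `subgroup_auc()` tags per-clip AUCs by bed type, covering type,
camera location or the term/preterm boundary at 37 weeks, together with
camera distance.

## Synthetic scenes

`scene_config()` describes a clip: a neonate-like body surface in front of
a flat background, respiratory modulation, intermittent motion events, and
sensor noise. Design choices that matter:

* **Geometry.** The body is a half-ellipsoid bump toward the camera
  (apex at the configured camera-to-chest distance, default 500 mm,
  background 950 mm) with **static relief**: eight elliptical
  bumps/dips (±15–70 mm, clamped to 40 mm above the chest plane) model
  the head, knees, arms and bedding folds. Relief matters for a
  subtle reason: on a perfectly smooth dome the closest 3% of pixels form
  one contiguous apex cap, and a whole motion event can sit inside the
  band that percentile clipping removes — a degenerate geometry real,
  articulated bodies do not exhibit. Relief scatters the closest band
  across several structures.
* **Respiration.** A chest sub-ellipse oscillates toward the camera with
  2 mm amplitude at 50 breaths/min — the small-scale motion the monitor
  must *not* flag.
* **Motion events.** Poisson arrivals (default 4/min), duration 1–5 s,
  elliptical patches of 50–500 px and 5–120 mm axial amplitude. A patch
  is near-rigid (full displacement over its core, soft rim) and **both**
  displaces along the camera axis (half-cosine 0.3 s on/off ramp, a
  0.25–0.75 Hz within-event oscillation so consecutive span states
  always differ) **and** translates laterally across the body. Lateral sweep is
  how limbs actually move and is what keeps events visible to a pipeline
  that clips the closest depth band: vacated and newly covered pixels
  change depth *within* the retained band. The truth label for second $t$
  is 1 iff an event observably alters the state of span $t$ or span
  $t+1$ — the two spans its difference frame compares. "Observably"
  means the event covers a majority of the ten frames whose median
  defines the span's state; a sub-majority flicker cannot move the
  median and is equally invisible to a human comparing consecutive
  one-second frames, which is how such studies score their truth.
  Labels derive from the event schedule, an idealization of human video
  scoring.
* **Sensor noise.** Per-pixel Gaussian depth error growing linearly from
  0.5 mm at 300 mm to 2 mm at 900 mm (stereo-depth error growth; this is
  what makes far placements genuinely harder), dropout pixels written as
  0, and sporadic outlier returns. Every frame is a deterministic function
  of (seed, frame index), so clips can be rendered lazily and in any
  order, bit-identically.

What the generator does **not** model: RGB appearance, caregiver hands and
occlusions, isolette-cover optical artefacts, structured (non-Gaussian)
sensor error, and truth-label subjectivity. Passing the package's checks
therefore demonstrates that the pipeline recovers the motion structure this
scene family encodes — not clinical-grade performance on real recordings.

## Numerical and degenerate-input policy

* Percentile estimator: type 7 everywhere (implementation and tests).
* Medians of even counts: mean of the two central order statistics with
  long-double accumulation, matching `stats::median()` bit for bit.
* A frame with no in-range pixels is returned fully invalid and flagged;
  depth summaries of an empty frame are sentinel 0 with a warning;
  kurtosis needs ≥ 4 valid pixels and zero variance returns 0.
* Ties at the classification threshold are no-motion (strict `>`).
* Single-class clips: error at ROC level, carrying the clip identity;
  excluded-but-logged at evaluation level.
* All randomness flows from explicit integer seeds; leave-one-out folds
  derive per-fold seeds as `seed + fold`.

## Problem sizes used by the checks

The end-to-end checks run an 8-subject × 3-clip × 120 s study at the
default 240×320 resolution (the full clinical design — 20 subjects, up to
6 positions, ~300 s — is ~30× that volume and adds nothing
methodologically at this scene fidelity). The clip-count protocol
(17×6 + 3 + 5 + 5 = 115 positional runs) is exercised separately on
lightweight feature tables, and the distance-degradation comparison uses
60 s clips at 120×160 over five seeds. `scripts/acceptance.R` re-runs the
8×3×120 study from scratch at a caller-supplied seed and reports test and
training sensitivity/specificity/AUC (percent), the mean training
threshold, and the static-scene motion count.

## Known limitations

* The 16 feature formulas are an interpretation of a published feature
  *description*; no claim of bit-exact reproduction of the original
  monitor is made, and the package's headline numbers are properties of
  the synthetic scene family.
* Percentile clipping inherently blinds the pipeline to motion confined
  to the closest 3% band of the frame; the synthetic scenes show the same
  effect the moment geometry degenerates (see *Synthetic scenes*).
* Far camera placements degrade with the modelled noise growth; with the
  default scene family the drop becomes visible beyond ~650 mm, which the
  evaluation module's distance subgrouping is designed to expose.
* Event-level (bout) metrics, probability calibration and significance
  testing between subgroups are out of scope.
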