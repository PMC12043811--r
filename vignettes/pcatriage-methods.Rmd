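---
title: "Methods: lesion-candidate evaluation and biopsy-triage simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion-candidate evaluation and biopsy-triage simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcatriage)
```

## Scope and model

`pcatriage` evaluates voxel-probability outputs of aggressive prostate
cancer detectors (csPCa, ISUP grade group ≥ 2) at the lesion and patient
level, and simulates their use as a biopsy-triage aid. The package does
not train or run a neural detector; it consumes probability maps (any
3D volume with values in [0, 1] on the T2W grid) and annotated lesion
instance maps, and provides a synthetic phantom generator so that every
stage can be verified against known ground truth.

### The candidate pipeline

Four decisions, all with a 10% default threshold and all inclusive
(`>=`):

1. *Voxel threshold* (0.10): voxels with probability below the threshold
   are clipped; the surviving support forms "soft blobs".
2. *Connected components*: blobs are the connected components of the
   support under 26-neighbourhood connectivity (configurable 6/18/26).
   Lesion blobs are compact and grid anisotropy is carried by the voxel
   spacing, so the fullest neighbourhood is the natural default.
3. *Confidence filter* (0.10): a candidate's confidence is the maximum
   probability inside it; weaker candidates are discarded. When the
   confidence threshold equals the voxel threshold this filter is
   vacuous by construction (every component contains at least one voxel
   at or above the voxel threshold); it is kept as a separate stage so
   the two thresholds can be moved independently.
4. *Gland-overlap filter* (0.10): the fraction of the candidate's own
   volume inside the prostate gland mask; candidates below threshold are
   extra-prostatic negatives. The denominator is the **candidate**
   volume: the rule is about how much of the blob lies outside the
   prostate while still tolerating extracapsular extension.

Retained candidates are then matched one-to-one to annotated aggressive
lesions by linear sum assignment maximizing total voxel overlap
(maximum-weight bipartite matching; pairs with zero overlap are never
matched). A matched candidate is a *hit* iff its intersection with its
assigned lesion reaches 10% — the denominator here is the **lesion**
volume, anchoring the rule on the annotation. The alternative
(candidate-volume) denominator is available via
`detection_config(hit_denominator = "candidate")` since the published
description does not pin either choice down. Hit evaluation consults only
the assigned pair: a candidate that happens to graze a different lesion
gets no credit for it.

`n_detected` is the number of *retained candidates*, not the number of
hit lesions: over-detection must be expressible, because the triage
categories distinguish overestimates. The case-level probability is the
maximum retained confidence (0 when no candidate survives).

A case graded aggressive whose aggressive label map is empty is valid
input — such annotation defects occur in public datasets — and is
flagged (`empty_aggressive`) rather than rejected. Non-aggressive
(ISUP 1) annotated lesions are excluded from the ground truth entirely;
they neither count as annotations nor act as matching distractors.

### A note on threshold monotonicity

Raising the confidence, gland-overlap or hit threshold can only shrink
the detected/hit sets, and the tests assert this. The *voxel* threshold
is different: raising it can split one connected component into two,
legitimately increasing the candidate count. The support itself shrinks
monotonically, which is the property tested.

## Preprocessing

DWI and ADC are resampled onto the T2W grid (trilinear; masks always
nearest-neighbour to preserve label semantics; out-of-grid coordinates
clamp to the edge). T2W and DWI are Z-scored (sample SD); ADC is clipped
to its 0.5/99.5 percentiles and then Z-scored with the clipped volume's
statistics, in that order. Percentiles use the linear-interpolation
quantile (R type 7) — the published description names no convention, so
the most common one is documented and used. Statistics are computed over
all voxels by default; a `mask` argument restricts them (e.g. to the
gland) because whether background voxels were excluded upstream is
unstated. Constant volumes raise an explicit zero-variance error.

## Metrics

* Dice `2|A∩B|/(|A|+|B|)`; undefined (NA) when both masks are empty, and
  such cases are excluded from averages.
* Hausdorff distance and average symmetric surface distance operate on
  boundary voxels — mask voxels with at least one background 6-neighbour
  (array faces count as background) — with distances in mm. HD is the
  classical maximum; a percentile argument provides HD95. ASSD is the
  mean of the two directed average surface distances. Empty masks are
  errors.
* Relative volume difference `(|pred| − |gt|)/|gt|` is signed (positive =
  over-segmentation); `absolute = TRUE` gives the magnitude.
* Pooled recall is the annotation-count-weighted mean of per-case
  recalls, i.e. Σ hits / Σ annotations; report views round half-even to
  2 decimals to match table precision.
* The median lesion-size split sends ties to the "below" group.

## Triage

The six categories partition all `(n_annotated, n_detected)` pairs:
`(0,0)` correct + avoided biopsy, `(0,>0)` overestimate + unnecessary
biopsy, `(n,n)` correct, `(n,>n)` overestimate, `(n≥2, 1..n−1)`
underestimate, `(n≥2, 0)` dangerous underestimate. The published
definitions literally leave `(1, 0)` uncovered; a missed solitary lesion
avoids a *necessary* biopsy, so it is assigned `dangerous_underestimate`
by default, with `strict = TRUE` restoring the literal scheme (the pair
is then reported as uncategorized). "Lesions present" always means
aggressive lesions.

The CAD recommendation is `n_detected ≥ 1` — equivalently, case
probability at or above the confidence threshold; truth plays no role at
decision time. The hybrid protocol performs a biopsy iff radiologist
**and** CAD both recommend it, so hybrid biopsies are always a subset of
the radiologist's. Summaries report avoided biopsies (radiologist yes,
CAD no, truth negative), dangerous avoidances (same but truth positive),
and biopsy counts under each reader. Percentages are emitted per chosen
denominator (whole cohort or a subset) because published accounts mix
both conventions.

## Calibration arithmetic

`smooth_labels` implements `y' = y(1−α) + α/K` (default α = 0.2);
`margin_penalty` is the hinge `mean(max(0, (max_logit − logit_k) − m))`
with m = 10 — the margin form is adopted from the calibration literature
the setup derives from, and is deliberately a standalone pluggable
function because the published description states only the margin value.
The calibrated loss is `0.5·softDice + 0.5·CE(smoothed)` plus the
penalty; soft Dice uses ε = 1e−5 and averages over foreground channels
(both unstated upstream; documented here). With α = 0 and m = ∞ the loss
reduces exactly to the plain average of Dice and cross-entropy, which
the tests assert to 1e−6. `poly_lr` is
`base_lr·(1 − epoch/epoch_max)^0.9` with base 0.001.

## The phantom generator

The generator defines the study conditions; its defaults are fixed once
and are not tuned per experiment.

* **Grid**: 64×64×32 voxels at 1.5×1.5×3.0 mm — prostate-MRI-like
  anisotropy at a quarter of clinical in-plane resolution, keeping a
  case generation + evaluation cycle around 0.2 s.
* **Gland**: axis-aligned ellipsoid, semi-axes 24×20×18 mm jittered ±10%
  per case — a ~60 cm³ gland, typical of the screening population.
* **Lesions**: 0–4 per case with probabilities (0.40, 0.30, 0.15, 0.10,
  0.05); roughly half of cases carry no lesion, matching the negative
  fraction of public cohorts. Shapes are ellipsoids with per-axis ±20%
  jitter; equivalent-sphere radii are log-normal (sdlog 0.35) with
  median 7 mm for the "PNet-like" style and 5 mm for "PI-CAI-like",
  encoding the observation that one cohort's lesions run larger — the
  sources publish no quantitative size parameters, so these are free
  configuration, not calibrated values. Lesions are placed ≥ 90% inside
  the gland and pairwise ≥ 8 mm apart; the separation is chosen so that
  distinct detection blobs cannot coalesce into a single candidate at
  the default thresholds (a blob's above-threshold halo extends < 3 mm
  beyond its lesion). If rejection sampling fails, a single-voxel lesion
  is placed deterministically at the interior point farthest from the
  placed lesions, so configured lesion counts are always honoured.
* **Grades**: per-lesion ISUP drawn i.i.d. from the published
  training-cohort proportions (0.52, 0.22, 0.14, 0.07, 0.02, 0.03 for
  grades 0–5); case grade = max over lesions (0 when none), matching
  index-lesion usage.
* **Intensities**: piecewise-constant background/gland/lesion contrasts
  per sequence plus Gaussian noise; DWI/ADC are generated on a 2×
  coarser in-plane grid by default so preprocessing has real resampling
  work. No MR physics is simulated.
* **Probability maps**: each aggressive lesion is detected independently
  with probability `sensitivity`; a detected lesion's blob carries the
  sampled peak confidence (Beta(8, 2) by default, mean 0.8) over the
  central 90% of its voxels, 0.7× the peak on the rim, and a Gaussian
  tail (SD 1.5 mm) outside — so any detected lesion passes the 10% hit
  rule by construction whenever its confidence clears the voxel
  threshold. False positives appear at Poisson rates (default 0.5 inside
  + 0.5 outside the gland per case, peaks Beta(2, 5)); outside blobs are
  placed clear of the gland and clipped to its exterior, guaranteeing
  zero gland overlap.
* **Radiologist**: Bernoulli reads at sensitivity 0.91 / specificity
  0.35 — high-sensitivity, low-specificity PI-RADS-style referral, the
  regime in which a CAD veto is informative.
* **Seeds**: one master seed is split into per-case, per-stream seeds by
  a counter-based affine scheme modulo 2³¹−1; every generator is
  bit-reproducible given its seed, and geometry is unchanged whether or
  not intensity volumes are generated.

What passing phantom tests do *not* show: robustness to real MR
appearance (texture, bias fields, motion), to irregular lesion shapes or
infiltrative growth, to annotation variability between radiologists, or
to correlated detector errors — the simulated detector errs
independently per lesion, which real networks do not. The phantom
validates the *evaluation and decision logic*, not detector performance
on clinical data.

## Verification strategy and problem sizes

Every operation is checked against an independent oracle implemented in
a different style: flood-fill labeling vs the BFS labeller, exhaustive
permutation enumeration vs the weighted matching (1000 random instances
up to 6×6), all-pairs double-loop surface distances vs the vectorized
metrics (tolerance 1e−9), a two-pass mean/SD oracle for normalization,
and closed-form binomial bounds (3 SDs) for every stochastic rate. The
sensitivity-recovery experiment uses 300 cases (~90 aggressive lesions);
the false-positive-removal experiment 60 cases; protocol simulations
100–150 cases — sizes at which the binomial bands are meaningful while a
full suite run stays under two minutes.

## Known limitations

* Lesions and glands are axis-aligned ellipsoids; no rotation or
  non-convex deformation.
* The gland mask is assumed given and exact; gland segmentation error is
  not modelled.
* Reader-interaction effects (automation bias) are outside the decision
  model: radiologist and CAD errors are independent by construction.
* The matching maximizes voxel overlap counts, not physical volume; with
  anisotropic voxels these coincide up to a constant factor, but mixing
  grids across cases would not be meaningful.
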