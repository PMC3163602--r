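---
title: "Methods: automated face-frame capture and grimace-scale statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated face-frame capture and grimace-scale statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its methods: what each stage
computes, the assumptions behind it, the tunable parameters and their
defaults, what the synthetic fixtures do and do not emulate, and the design
choices made where the design was genuinely open.

## The problem

Grimace-scale scoring quantifies spontaneous pain in rodents from still
photographs of the face: four action units (orbital tightening, nose/cheek
flattening, ear changes, whisker change), each scored 0 (confidently
absent), 1 (moderate or equivocal) or 2 (obvious), by human raters who are
blind to the animal's condition. Two animals are filmed side by side in
transparent cubicles; each cage occupies a fixed zone of the frame and is
analyzed separately. The package automates the frame-capture step (finding
clear, unblurred head shots), organizes the blinded scoring session, and
computes the reliability, accuracy, difference-score and dose–response
statistics the workflow ends in.

## Streams, zones and coordinates

A video stream is an 8-bit grayscale multi-page TIFF (one page per frame)
with a JSON sidecar carrying the frame rate, frame count and a source
identifier; frames decode to intensity matrices in [0, 255] (color pages
are reduced by ITU-R 601 luma at decode, so every downstream computation is
single-channel). Indexed page reads let long streams be processed in
chunks. All rectangles — zones, detections, face regions — use one
convention: 0-based integer coordinates, top-left origin, half-open
extents. Cage zones come from a YAML config and are validated for bounds,
label uniqueness and pairwise non-overlap.

For containers with irregular timing, "previous frame" always means the
previous *decoded* frame, not a fixed time offset; timestamps are
`frame_index / fps`.

## Face finding: boosted Haar cascades

Detection follows the classic boosted-cascade design. A Haar-like feature
is a small set of ± weighted rectangles inside a square base window
(default 12×12 px); its raw value — the weighted sum of rectangle pixel
sums — is computed in constant time from an integral image and
contrast-normalized by the window's intensity standard deviation times its
area, which makes values comparable across window scales and lighting.
Candidate features (default 1500) are a seeded sample from the full
two-/three-/four-rectangle pool.

Each cascade stage is an AdaBoost ensemble of decision stumps, thresholded
to retain at least 99.5% of training positives; later stages train only on
the negatives earlier stages failed to reject. Two safeguards matter in
practice:

* a stage must boost for at least `min_rounds` (default 4) rounds, so a
  single lucky stump cannot end a stage on a separable training set;
* the stage threshold is backed off by `margin_frac` (default 0.05) of the
  stage's total vote mass, a generalization buffer for scan windows
  slightly off the training distribution (sub-pixel shifts, scale-ladder
  mismatch).

Scanning slides the window over the zone at a geometric ladder of scales
(factor 1.1), with a shift of 12.5% of the window side, skipping windows
whose intensity standard deviation is below `min_sd` (default 6 gray
levels) — featureless regions cannot contain an eye or ear, and skipping
them dominates scan cost on mostly empty zones. The value is deliberately
far below real feature contrast (≥30 levels in the fixtures) and above
sensor noise (sd 3). Raw hits are grouped by a union-find over
position/size proximity (slack 0.25 of the mean size) and groups smaller
than `min_neighbors = 3` are discarded, the standard suppression of
isolated false positives. Because training crops carry a margin around the
feature (crop side = 1.25 × the feature's larger dimension), reported boxes
are shrunk to `object_frac = 0.8` of the window, so they bound the feature
rather than the window. Detection is fully deterministic, and pixels
outside the scanned zone cannot influence its detections.

Models serialize to an XML layout patterned on the standard
cascade-classifier format (stages of weak classifiers plus a weighted
rectangle table), with full `%.17g` precision so a save→load round trip
reproduces detections exactly.

### Training data and why it is scene-based

Cascade training needs positives that look exactly like what the scanner
will evaluate. The packaged recipe (`train_default_cascades()`) therefore
cuts positives out of fully rendered face scenes — backdrop, eye and ear on
the noisy background — rather than pasting features on a clean patch; a
crop around the ear, for instance, legitimately contains the bright
background beyond the backdrop edge, exactly as a scan window does.
Negatives combine plain background/backdrop crops with near-miss
distractors: the *other* feature kind centered (so the eye cascade must
reject ears), the own kind off-center in a 2.2–3.5× context window (wrong
scale and position), and backdrop-edge crops. With this composition the
training distribution matches the scan distribution and no bootstrap
mining pass is needed by default (one can be enabled via
`bootstrap_frames`). An earlier design that trained on clean feature
patches and mined hard negatives from scans proved brittle across training
seeds — near-positive windows harvested as negatives could teach the
cascade to reject true matched-scale windows — and was replaced.

## The candidate rule and face region

A frame is flagged for scoring when at least one eye and at least one ear
are detected and some eye–ear pair has center-to-center distance `d` with
`d_min ≤ d ≤ d_max`, the bounds expressed as multiples of the mean of the
pair's box widths (defaults 0.5 and 4.0). Scale-relative bounds keep the
rule resolution-independent; the absence of a candidate is a normal
outcome, not an error. One eye suffices because side-view (one-eye) head
shots are scoreable. When several pairs qualify, the closest pair defines
the face region, ties broken by the smaller eye x-coordinate — an
arbitrary but deterministic rule. The face region is the union bounding box
of the pair, expanded by half its own width/height on each side (rounded
outward, so rounding never shrinks the stated region) and clipped to the
zone.

## Motion ranking and interval selection

The motion score of a frame is the mean absolute intensity difference to
the previous decoded frame over the whole cage zone (not just the face
region — whole-body motion predicts blur). It is exactly 0 iff the zone
pixels are identical. Candidates are bucketed into half-open intervals
`[i·w, (i+1)·w)` anchored at stream time 0 (default w = 180 s, the
3-minute scoring interval); within each interval the `k = 3` candidates
with the smallest motion score are kept, ties broken by earlier frame
index, which makes the selection equal to the head of a stable sort by
(motion score, frame index). The first decoded frame has no predecessor
and is excluded from ranking with a message. Intervals with fewer than `k`
candidates keep them all and are flagged sparse; intervals with none go to
a machine-readable gap report so the user can grab frames manually. The
final choice of the single best image per interval remains a human
judgment: the tool exports the ranked candidates and stops there.

## Blinded scoring sessions

Exported face crops are lossless 8-bit PNGs with no embedded source
metadata. `build_manifest()` assigns each image a zero-padded random token
(deliberately *not* derived from the filename, which can leak the
condition), shuffles presentation order, and writes two files: the
scorer-facing manifest (token + path only) and the unblinding key (token +
animal, condition, time point, ...). Both the tokens and the permutation
are deterministic functions of the seed. Score tables are validated
(values in {0, 1, 2, NA}, offending rows reported); an image's mean score
is the mean of its scored units, with at least one unit required — so
all-0 and all-2 images reach the 0 and 2 endpoints, and a not-scorable
unit (e.g., whiskers invisible in profile) simply drops out of the mean.

## Statistics

**Reliability.** The subjects × raters matrix of mean scores feeds a
two-way ANOVA decomposition (subjects, raters, residual; mean squares via
`stats::aov`), from which all four usual intraclass correlation variants
are computed: single- or average-measure, under consistency or absolute
agreement. The reported default is the two-way random-effects,
average-measure, absolute-agreement coefficient, because the workflow
averages action-unit scores across the coder panel. Subjects with missing
cells are dropped (complete-case) with a message; fewer than two raters or
zero total variance are errors. The test suite checks the implementation
against an independent direct-summation mean-squares oracle at 1e-10 on
random small matrices, skipping only matrices whose between-subject mean
square (or another ICC denominator) is numerically zero, where the
coefficient itself degenerates.

**Accuracy.** Dichotomous pain/no-pain judgments are scored against the
true condition as hits, misses, false alarms and correct rejections. Rates
are percentages of *all* judgments — so with a 50/50 design accuracy +
miss rate + false-alarm rate is 100% — and accuracy is the hit rate plus
the correct-rejection rate; summaries are produced pooled and per scorer.

**Difference scores.** For each animal with both conditions, each action
unit's difference score is the animal's mean unit score under pain minus
its mean at baseline; the package reports per-unit and four-unit-average
deltas with the SEM across animals, excluding (with a warning) animals
missing a condition.

**AD50.** Per-animal mean scores convert to percent of maximal possible
effect, %MPE = 100·(ȳ_vehicle − y)/(ȳ_vehicle − baseline), anchoring 0% at
the vehicle group mean and 100% at the uninjured baseline level — the
standard usage, stated here explicitly because the anchoring convention is
a genuine choice. An ordinary least-squares line of %MPE on log₁₀(dose) is
fit over the non-vehicle animals (per-animal points, not dose means, so
the residual degrees of freedom are honest), and the AD50 is the dose
where the line crosses 50%. The confidence interval comes from the delta
method on the log-dose scale — the gradient of (50 − b₀)/b₁ against the
coefficient covariance, a t quantile on the residual df, back-transformed
— with Fieller's theorem available behind a flag (the two agree to first
order on well-behaved data; Fieller can return an unbounded interval when
the slope is poorly determined, which is reported as such). A non-positive
slope yields no finite estimate, and a crossing more than 10-fold outside
the tested dose range attaches an extrapolation warning to the result
rather than failing. The estimate is exactly equivariant under dose
rescaling, and exact (zero-width interval) on noiseless collinear input.

## The synthetic fixtures: what they emulate, and what not

The generator exists so that every stage can be tested against exact
ground truth; its defaults are the package's standard study conditions.

* **Faces** are stylized geometry, not photorealism: a mid-gray backdrop
  ellipse (intensity 140) carrying a dark filled eye ellipse (60, half-axes
  6×4 px) and a darker ear annulus segment (40, radii 4.5–9 px, 240°
  extent) on a light seeded Gaussian background (200 ± 3). This reproduces
  the contrast structure a Haar detector keys on — a compact dark feature
  on a lighter surround, ≥30 gray levels of contrast — while making tight
  ground-truth boxes exact (they are computed from the rendered masks).
  Passing detection tests therefore demonstrates the machinery, not
  performance on real fur, lighting or pose; users with real footage train
  on their own crops.
* **Videos** default to 6 minutes at 10 fps, 320×180 px (the 16:9 aspect
  of 1920×1080 recordings at desk scale), two 160×180 zones. The schedule
  puts the face in the left zone for the first half and the right zone for
  the second, alternating still and moving segments, so the 3-minute
  interval logic runs over two intervals per zone, each zone has one fully
  face-free interval for the gap report, and the motion ranking sees both
  frozen and drifting spans. Within a segment the face bounces along a
  fixed diagonal inside ±8 px of the zone anchor at the scripted per-frame
  displacement; the background noise field is generated once per stream,
  so zero-displacement spans are pixel-identical and the motion noise
  floor is exactly 0.
* **Rating matrices** follow the additive two-way model
  `y = 1 + s_i + r_j + e_ij` with the requested variance components,
  scaled so 2.5 total standard deviations fit the half-range and clipped
  to [0, 2]. Because the intraclass correlation is invariant to the affine
  map, the closed-form population coefficients of the pre-clipping model
  are returned alongside; with the default calibration components
  (1, 0.1, 0.2) clipping touches about 1% of cells and its bias is well
  inside the ±0.05 recovery band the tests use.
* **Dose–response cohorts** place per-animal responses on a linear
  %MPE-vs-log-dose curve crossing 50% at a true AD50 of 0.8 mg/kg (a
  realistic morphine potency on this scale), slope 60%/decade, doses
  {1, 2, 5} mg/kg plus vehicle, n = 8 per group, Gaussian noise sd 0.2 on
  the score scale (vehicle mean 1.4, baseline 0.4), clipped to [0, 2].
  Note the true AD50 lies just below the lowest tested dose, as it did for
  the motivating use case, so every fit extrapolates mildly — a realistic
  stress on the interval.
* **Simulated scorers** draw unit scores around condition-dependent means
  (pain 1.4, no-pain 0.4, sd 0.45, discretized to 0/1/2) and call an image
  "pain" when their own mean score exceeds 0.9. This is a test bed for the
  session plumbing and statistics, not a model of human raters.

Problem sizes used by the test suite and the acceptance script — the
6-minute default video, 1000 random buckets for the selection oracle, 200
simulated 100×6 panels for ICC calibration, 500 cohorts for AD50 recovery
— were chosen as the smallest sizes at which the quantities of interest
are statistically stable.

## Numerical and engineering notes

* Integral images make every rectangle sum O(1); the multi-scale scan and
  the native-size crop evaluation share one compiled kernel, so training
  and scanning see byte-identical feature values (including the integer
  rounding of rectangle rescaling). An earlier version evaluated training
  crops after bilinear resizing to the base window; the resulting
  train/scan mismatch let boosting key on resize artifacts, and was the
  single largest source of detector failure before being replaced.
* Raw-hit grouping is quadratic in the number of hits and runs compiled;
  an R implementation of the same union-find dominated whole-pipeline
  runtime when a cascade produced hundreds of raw hits per frame.
* PNG export and the 8-bit TIFF stack round-trip integer intensities
  exactly; generated crops are rounded to integers for the same reason.
* The TIFF page count is recorded in the sidecar; counting pages without a
  sidecar requires a full decode, the only reliable method the reader
  found for multi-page stacks.
* All generators are pure functions of their seed and spec (byte-identical
  reruns); per-sample geometry jitters are drawn before any noise fields
  so that a scale flag changes geometry only.

## Known limitations

* The detector is validated on the stylized fixture domain. Real rodent
  footage has fur texture, specular eyes, occlusion and pose variation the
  fixtures do not model; expect to train on real crops and revisit
  `scan_params()` there.
* The cascade XML follows the standard layout but cross-reading with other
  cascade implementations is untested here.
* Two cameras filming the same cubicles produce two independent streams;
  reconciling duplicate intervals between them is left to the user.
* The per-interval "single most scoreable image" decision stays manual by
  design; the tool only ranks.
* Whisker change is scored by humans; no whisker detection is attempted.
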