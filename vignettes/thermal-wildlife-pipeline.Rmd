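---
title: "Detecting and recognizing wildlife in thermal imagery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and recognizing wildlife in thermal imagery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermaltrack)
```

This vignette explains the models and procedures the package implements,
the assumptions behind them, the parameters that matter, what the
synthetic generator does and does not emulate, and the design choices made
where the design was genuinely open.

## The problem

A thermal camera looking straight down over a field sees warm animals as
bright blobs — but also sun-heated molehills, machinery, lamps and bare
soil. Absolute temperature is unreliable: the apparent temperature of an
animal depends on sun load, the insulation of its coat, and its distance
from the sensor. A usable detector must therefore (a) adapt its threshold
to each frame, (b) classify objects by *structure* rather than absolute
warmth, and (c) exploit the fact that a camera descending toward an object
sees it progressively better.

## Detection: dynamic median threshold

Each frame is segmented at

$$th = \tilde t + c,$$

where $\tilde t$ is the median over all pixel temperatures and $c$ (default
5 °C) sets how much warmer than the background an object must be. The
median, unlike the mean, is an order statistic: the handful of hot object
pixels in a 240 × 320 frame cannot move it, and adding a constant to the
whole scene shifts the threshold by exactly that constant, leaving the
segmentation unchanged. Segmentation is strict (`> th`), which makes the
all-background case unambiguous. Above-threshold pixels are grouped into
8-connected components (animals are compact; a diagonal link should not
split one) and components below `min_area = 2` pixels are dropped as
single-pixel noise. Both values are exposed in `detection_params()`.

## The thermal signature

For a detected blob the signature $cm(i)$, $i = -1, 0, \dots, M$, is built
with the 4-connected cross structuring element:

* $i = -1$: the blob is dilated once; the ring of new pixels just outside
  the object records the immediate background temperature.
* $i \ge 0$: the mean temperature of the blob's perimeter (the mask minus
  its erosion) is recorded, the perimeter is peeled off, and the process
  repeats until the mask is empty after $M + 1$ peels.

Temperatures are always read from the original frame; only the mask
shrinks. Because the cross element is 4-fold symmetric, the signature is
exactly invariant to integer translation and to rotation by multiples of
90°; because contours are whole-object means it is insensitive to posture
at fixed depth ordering. Each peel strictly shrinks the mask, so the
iteration count is bounded by the blob area, and the interior contours
partition the blob exactly — both properties are asserted in the test
suite on randomized blobs.

Animals, insulated by fur or feathers, are warmest just inside their
outline relative to the adjacent ground, so their signatures rise steeply
over the first interior contours; halogen lamps are flat after the rim;
molehills rise gently everywhere. This shape contrast is what the
classifier consumes.

Two readings of "the first contour" were possible for normalization: the
$i = -1$ background ring or the $i = 0$ perimeter. The package subtracts
the $i = -1$ ring, making every feature relative to the object's immediate
background — the right behaviour when the whole scene is sun-heated — and
the first normalized sample is exactly 0. The $i = -1$ sample is kept in
the transform input, since it carries the edge step. Blobs touching the
frame border get a clipped ring (flagged on the signature); a blob with no
ring at all falls back to its first interior sample.

## DCT parameterization

Signatures have different lengths ($M$ grows with object size and shrinks
with altitude), so they are mapped to a fixed-length vector by a
discrete cosine transform. The package uses the orthonormal type-II
transform with an extra $1/\sqrt{N}$ scaling:

$$c_k = \frac{s_k}{\sqrt N}\sum_{n=0}^{N-1} x_n
  \cos\!\frac{\pi (2n+1) k}{2N}, \qquad
  s_0 = \sqrt{1/N},\; s_k = \sqrt{2/N},$$

so that $c_0$ equals the sequence mean and a constant signature of value
$v$ maps to $(v, 0, \dots)$ *regardless of its length* — without the
length compensation, coefficient magnitudes would grow as $\sqrt N$ and
the length-invariance motivation for the transform would fail. The first
`n_coeff = 7` coefficients are retained (shorter signatures are
zero-padded), a truncation that keeps at least 95% of signature energy for
effectively all synthetic animal signatures (asserted under Parseval's
identity for the orthonormal convention; `energy_fraction()` reports the
retained share). The implementation is an explicit cosine-matrix product;
the test suite checks it against an independently coded double sum, basis
orthogonality, and exact round-trips when nothing is truncated.

## kNN classification with a likelihood ratio

`fit_training_set()` validates a labeled feature table (both classes
present, a common coefficient count, duplicates kept — kNN is
multiset-based) and `knn_classify()` finds the `k = 11` nearest training
vectors by Euclidean distance. No feature scaling is applied: all
coefficients derive from °C differences and share a unit, so the metric is
left untouched (scaling can be applied upstream if wanted). Distance ties
at the k-th rank break by training insertion order, making results
reproducible to the bit across runs. With `k` odd, no vote tie is
possible. Besides the majority label the classifier returns

$$g_A = k_A / k,$$

the fraction of animal neighbours, used downstream as the likelihood that
the detection came from an animal. Before entering the belief update it is
clamped to $[0.05, 0.95]$ so that a run of extreme votes can never freeze
the posterior at 0 or 1.

## Tracking and recursive belief

Tracks link detections across frames through *guess regions*: the next
position is predicted by linear extrapolation of the last movement (a
single-member track predicts itself) and a detection may join only within
a fixed gate radius (190 px). Association is greedy: among all gated
(track, detection) pairs the globally nearest is matched first, one
detection per track per frame; unmatched detections open new tracks;
a track missing more than `max_missed = 3` consecutive frames terminates.
Greedy was chosen over optimal bipartite matching deliberately: on sparse
scenes with a gate this wide, conflicts are rare, and the greedy rule is
simple and deterministic. An exhaustive brute-force matcher is kept in the
test suite as the oracle for small sparse cases; in dense conflict
geometries greedy and minimum-total-distance matching can genuinely
differ, which is accepted.

Each accepted detection updates the track's animal belief by Bayes' rule
with the two-class evidence denominator:

$$Bel(n) = \frac{Bel(n-1)\,g_A}
  {Bel(n-1)\,g_A + (1 - Bel(n-1))(1 - g_A)}.$$

New tracks start at the indifferent prior $Bel(0) = 0.5$ and absorb their
first likelihood immediately, so after one observation the belief equals
the clamped $g_A$. In log-odds the update is additive, so the final belief
depends only on the multiset of likelihoods, not their order; $g_A > 0.5$
strictly raises the belief, $g_A < 0.5$ strictly lowers it, and missed
frames change nothing (no observation, no update). A terminated track is
an animal exactly when its final belief exceeds 0.5 — strictly, so a
belief of exactly 0.5 is a non-animal call — and every member inherits the
final label. Tracks with five or fewer members are flagged unidentified
and excluded from track-level evaluation. Numerically, a long one-sided
run converges geometrically toward 0 or 1 and would saturate in floating
point; the update therefore keeps the belief $10^{-12}$ away from the
endpoints.

## Evaluation

Animal is the positive class. Because detection loss with altitude
unbalances the data (animals drop out faster than lamps), the headline
metric is balanced accuracy, $(TPR + TNR)/2$, which is invariant to class
prevalence. `evaluate_range()` reports per-altitude-band metrics over
half-open intervals $[low, high)$ — the defaults are 3–10 m and 10–20 m,
and an object at exactly 10 m belongs to the far band only. The
inverse-square footprint `pixel_footprint()` quantifies why altitude
matters: ground sample distance grows linearly with altitude, so a
305-pixel body at 5 m covers 19 pixels at 20 m.

## The synthetic generator

The generator is the package's stand-in for field recordings and defines
the conditions under which the system checks run. Scenes are a constant
background (19 °C, within the 15–23 °C band of cool-season fields) plus
independent per-pixel Gaussian noise with sd 1.5 °C — chosen to represent
the small-scale surface-temperature clutter of vegetated ground
(sun-warmed tussocks, bare patches) on top of sensor noise, not sensor
noise alone. Objects are radially symmetric temperature profiles:

* **animal** — a steep edge ramp carrying 85% of the core offset across a
  1–3 px shell, plus a gentle dome toward the centre, so the noise-free
  signature is strictly increasing with a dominant edge step;
* **lamp** — a uniform very hot disk with a half-pixel anti-aliased rim;
* **molehill** — a shallow wide Gaussian mound.

Animal core offsets are drawn from 8–14 °C and molehills from 6–12 °C —
deliberately overlapping, because apparent temperature in the field does
not separate animals from sun-warmed soil; discrimination must come from
signature shape. Lamps are unambiguous at 20–30 °C. Footprints scale with
$(\mathrm{ref\ altitude}/\mathrm{altitude})^2$ (reference: 305 px at 5 m
for a 0.05 m² body), sub-pixel mixing is emulated by a ~0.7 px floor on
profile widths, and an optional radiative attenuation dims apparent
offsets by $e^{-(alt - ref)/L}$. The experiment-level generators default
to $L = 12$ m: with it, high-altitude objects are both smaller *and*
dimmer, only the warmest distractors survive detection up high, and the
classes genuinely crowd together with altitude — without it, amplitude
alone kept the synthetic classes separable at any height, which does not
match how thermal contrast behaves at distance. All outputs are pure
functions of spec + seed.

What the generator does **not** emulate: radiative physics proper
(emissivity, atmospheric attenuation beyond the exponential dimming),
camera motion and vibration, vegetation occlusion, animal gait or posture
change, and the real fur/feather signature shapes, which are mimicked only
qualitatively. Passing system checks therefore demonstrate that the
pipeline machinery behaves as designed under controlled phenomenology, not
that field accuracy would reach any particular level.

## System-level experiments

`loo_balanced_accuracy()` measures class separability by leave-one-out
kNN. On low-altitude training sets (4–7 m) it sits near 0.95; re-generated
across altitude bands it decays monotonically (≈ 0.91 → 0.82 → 0.71 →
0.56 from 4–7 m to 14–18 m bands on average) — the characteristic collapse
of recognition with height.

`evaluate_tracking_gain()` compares per-frame kNN labels with
track-overwritten labels on sequences whose altitude descends linearly
(default 18 → 6 m, 8 sequences × 30 frames, five objects each). The
descent is the point: early far-range detections classify little better
than chance, but the belief accumulated by the time the camera is low
relabels them through their track. On constant-altitude sequences the
per-object kNN errors are strongly correlated (the same dim object errs in
every frame) and pooling cannot help — with a descending profile the gain
is a robust 4–11 percentage points across seeds.

`detection_sweep()` renders single-animal scenes at increasing altitude
(5–26 m) with the radiative attenuation on and reports the fraction
detected — a hit requires a blob touching the animal's true center, so a
stray noise blob landing nearby does not count. The curve is flat at 1.0
up to ~11 m, falls through 0.5 near 17–20 m and is essentially 0 by
23–26 m; apart from one-scene counting noise in the near-zero tail it is
non-increasing throughout.

Problem sizes in the shipped tests and the acceptance script (training
sets of 130–499 vectors, 8 × 30-frame benchmark sequences, 16 scenes per
sweep altitude) were chosen so the complete suite runs in well under a
minute while keeping the binomial noise of each measured rate comfortably
inside its asserted margin.

## On-disk formats and numerics

Frames are stored as multi-page 16-bit unsigned TIFF plus a JSON sidecar
`{scale, offset, frame_index[], altitude[]}`; temperatures reconstruct as
`raw × scale + offset` to within half a quantization step (the scale
covers the sequence's range, so the step is ≤ (range)/65535). Plain-text
grids are accepted for small fixtures. Pixel coordinates are 1-based
`(row, col)` with row 1 at the top throughout — the natural indexing for R
matrices, stated once and used everywhere. Feature tables and training
sets are headered CSV; tracks and blobs serialize to JSON; the pipeline
configuration round-trips through YAML.

## Known limitations

* The tracker assumes an essentially stationary scene (lift-style
  recording); it does not compensate for platform motion.
* Greedy association can mis-pair in dense conflict geometries; the gate
  radius assumes sparse objects.
* kNN uses unscaled Euclidean distance; if features with heterogeneous
  units were added, scaling would need to be revisited.
* The synthetic phenomenology is deliberately simple; transferring
  conclusions to field data requires field recordings.
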