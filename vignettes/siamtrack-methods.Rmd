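---
title: "Model and methods: template-matching tracking with distractor suppression and gated detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(siamtrack)
```

## The tracking problem

Behavioral experiments routinely need the trajectory of one animal (or one
body part — a foot, a pupil, a head) through thousands of video frames.
Model-free single-object tracking solves this with a single annotation: the
user draws one bounding box on the first frame, and that box — nothing else —
defines the target. No per-dataset training, no annotation campaign. The cost
of the model-free design is that the tracker can drift when the target moves
faster than its search region, or when a visually similar object (the other
foot, a conspecific) passes close by. `siamtrack` implements the full
workflow built around those two failure modes: matching-based tracking,
suppression of look-alike distractors, injected human corrections that
replace the template, and a confidence-gated detector trained on the
tracker's own confident output.

## The matching core

Each frame is processed by a Siamese-style comparison of two image crops:

1. **Template crop.** Around the defining box $(w, h)$, a square of side
   $s = \sqrt{(w+p)(h+p)}$ with context padding $p = c\,(w+h)$, $c = 0.5$,
   resampled to `template_size` pixels (default 127). Out-of-frame regions
   are padded with the frame's mean intensity.
2. **Search crop.** The same geometry around the *previous* frame's box,
   scaled up by `search_size / template_size` (default 255/127), so that a
   target of unchanged size occupies the same number of feature cells in
   both crops.

Both crops pass through a feature extractor; the template features are slid
over the search features by valid-mode cross-correlation (computed via FFT,
verified in the tests against a triple-loop oracle to $10^{-6}$), giving a
response map whose maximum locates the target. Each response cell maps back
to the image coordinate of its template-window center, so localization is
performed in continuous image coordinates throughout.

### The pix-grad feature extractor

The extractor is pluggable through a registry (`register_extractor()`), so a
learned feature backbone can be dropped in without touching the pipeline.
The default, `"pix-grad"`, is deterministic and handcrafted: the patch is
block-averaged at `feature_stride` pixels per cell, then three channels are
computed — intensity minus its 7-cell local mean, and central-difference
horizontal and vertical gradients — each smoothed with a 3×3 box filter,
and the whole tensor scaled to unit Frobenius norm. Local mean subtraction
and the unit norm make matching invariant to additive and multiplicative
illumination changes, which is what carries the tracker through the
illumination-drift benchmark unchanged.

One property of this extractor shapes several design choices below: it is
translation-equivariant only at integer multiples of the stride. Two crops
of the same object whose sampling grids are offset by a sub-stride amount
decorrelate substantially (in our measurements, a blob's feature correlation
falls from ≈0.88 within one grid to ≈0.3 across grids). Deep backbones are
trained to be robust to exactly this; a handcrafted stand-in is not.

### Box adaptation: ratio and scale candidates

Shape adaptation is done by explicit candidate search instead of a learned
box regressor: five aspect-ratio candidates $(1/3, 1/2, 1, 2, 3)$ crossed
with three scale candidates $(0.96, 1, 1.04)$. For each candidate the
template feature grid is bilinearly resampled to the corresponding shape,
re-normalized, and correlated; the candidate with the highest windowed peak
score (under a normalization range shared across candidates, so scores are
comparable) wins. The new box blends the previous size with the winner's
size by `size_damping` (default 0.3).

Three stabilizing priors replace the implicit smoothness of a trained
network, and all are exposed in `tracker_config()`:

* **Cosine window** (`window_weight`, default 0.35): the normalized response
  is blended with a raised-cosine window centered on the previous position.
  Raw argmax alone is unstable frame to frame.
* **Size damping** (`size_damping`, default 0.3): box sizes change
  gradually.
* **Shape penalty** (`shape_penalty`, default 0.15): non-identity candidates
  are multiplied by $\exp(-p\,(|\log r| + |\log \sigma|))$. Min-max
  normalization puts every candidate's peak near 1, so without this penalty
  ratio candidates win essentially at random; when two identical blobs merge
  the drift is systematic and the box aspect diverges without bound. The
  penalty makes shape changes win only when the response is genuinely
  better.

## Output confidence

Localization is treated as a classification of the target against
background: the response map is min-max normalized (making the temperature
scale-free), softmaxed over all cells at `confidence_temperature` (default
0.1), and the confidence is the probability mass in the 3×3 neighborhood of
the argmax. On a constant map of $N$ cells this is exactly $\min(9, N)/N$;
a sharp isolated peak approaches 1; a flat or fragmented map — the target
occluded, or gone from the search region — drops low. On the synthetic
benchmarks, well-locked frames score ≈0.6–0.9 and lost frames ≈0.1–0.3, so
the detection activation threshold of 0.3 separates the two regimes with
margin. Why 0.3 specifically is the field's convention; it is exposed as
configuration, not hard-coded.

## Distractor suppression

After cross-correlation, the mean response of remembered distractors is
subtracted: $\,s' = s - \frac{\alpha}{\max(1, n)} \sum_i
\mathrm{xcorr}(d_i, \text{search})$, with $\alpha$ = `distractor_alpha`
(default 0.5). Distractors are mined from the tracker's own response maps:
secondary peaks of at least `distractor_peak_fraction` (default 0.8) of the
primary peak, at least one target-box-width away from it, that are strict
local maxima and not adjacent to the response-map border (peaks at the
border are truncation artifacts of objects only partially inside the search
span, and their crops are mis-centered). One distractor is mined per frame;
the memory holds `distractor_memory` (default 5) entries, and once full,
*newly* mined entries are discarded rather than old ones — the crops mined
while the tracker was still reliably on the target are the trusted ones,
and must not be displaced by crops mined after a possible drift, which may
be the departing target itself.

The memory stores each distractor's **image location**, and on every frame
its feature is re-extracted from the current search features at that
location before correlating. This is the consequence of the phase
sensitivity noted above: a crop stored from an earlier frame lives on a
different sampling grid and correlates as strongly with the identical
target as with the distractor it came from (zero spatial selectivity — in
our 20-seed crossing benchmark, stored-crop suppression was net *harmful*).
The refreshed crop shares the current grid, so its correlation peaks
sharply at the distractor's position and weakly elsewhere; if the object
has left that location the refreshed crop is plain background and the term
is harmless. With this design, suppression fully rescues the hard
identical-distractor crossing that captures the unsuppressed tracker.

Suppression is computed at the identity candidate's response shape (exactly
the exported `suppress_distractors()` contract) and bilinearly resampled to
the other candidates' response shapes.

## Corrections and label effort

A human correction (`apply_correction()`, or a `correction_event` list
passed to `track_sequence()`) replaces the template with the features of
the corrected box on the current frame, resets the current box, clears the
distractor memory, and sets confidence to 1; tracking resumes forward from
the breaking point. The template is *never* updated automatically — only a
correction changes it. Label effort is the percentage of frames corrected,
excluding the defining first-frame annotation (which is the "snapshot"
that starts tracking, not a correction of it). `track_with_oracle()`
emulates an attentive human on synthetic data: it corrects with the true
box whenever the overlap rate falls below threshold, which is how the
label-effort numbers in the benchmarks are produced unattended.

## Tracking with detection

`harvest_exemplars()` collects the features of boxes from records with
source `"auto"` and confidence ≥ `min_harvest_confidence` (default 0.6) —
the tracker's own confident output is the training set; corrected and
detected records are never harvested. The bank is capped (default 50) by
seeded reservoir sampling. `detect()` scans the whole frame with windows of
the bank's median box size — a coarse grid at `scan_stride` (default 8 px),
then 2 px and 1 px refinement around the top five coarse windows, because a
window half a stride off the object scores far below a centered one — and
accepts the best window only if its normalized correlation reaches
`accept_score_fraction` (default 0.7) of the bank's mean self-match score.

`gated_step()` consults the detector only when the tracking confidence
falls below `activation_threshold` (default 0.3). On success the box is
re-seeded at the detection (template untouched, distractor memory cleared)
and the record is marked `"detected"`; on no-detection the tracker's own
output is kept — the detector guides, it never blocks. The invocation count
equals, exactly, the number of frames whose pre-gate confidence fell below
the threshold while the bank was non-empty.

A consequence of confidence gating worth stating plainly: drift onto a
*visually identical* distractor keeps the match quality — and hence the
confidence — high, so the detector is never consulted and cannot help; that
failure mode belongs to human correction (or suppression). The detector's
domain is the *fast-motion* failure: the target leaves the search region,
the response collapses, confidence drops below the gate, and the
whole-frame scan re-seeds the tracker in the same frame. The `"jump"`
benchmark exercises exactly this, and the `"crossing"` benchmark exercises
the former.

## Evaluation criteria

* **Overlap rate (OR)**: intersection-over-union under half-open box
  semantics (boxes sharing only an edge do not intersect; areas are exact).
  A frame succeeds when OR ≥ 0.5, *inclusive* at the boundary.
* **Pixel error (PE)**: Euclidean distance between box centers. A frame is
  accurate when PE < 20 px, *strict* at the boundary.
* `success_rate + error_rate = 1` exactly, over the same frames and
  threshold; label effort is reported alongside.

The inclusive-OR / strict-PE boundary convention follows the usual wording
("higher than" vs. "lower than" the threshold); both thresholds are
configurable. Because OR is sensitive to how tightly the annotation
circumscribes the target, `box_size_sensitivity()` re-evaluates against
ground truth inflated or deflated by a factor sweep; the recommended
annotation is the tightest circumscribing rectangle.

## The synthetic benchmark generator

`generate_scene()` renders seeded, bit-reproducible grayscale scenes with
exact ground truth: a static textured background (smoothed uniform noise,
grain ≈ 3 px, sd 0.06 around base 0.4), an anti-aliased target blob (disc /
ellipse / rounded rectangle, ≈1 px edge ramp so sub-pixel motion changes
pixels smoothly, with internal texture that travels with the blob),
optional distractors rendered from the *identical* sprite and drawn over
the target (a crossing fully occludes it — the hardest case), multiplicative
sinusoidal illumination drift, an optional occluding patch, and linear /
sinusoidal / random-walk motion with border reflection. Truth boxes are the
circumscribed rectangles of the rendered blob, recorded after reflection,
and evaluating the truth against itself gives success 1.0 by construction.

`fixture_scene()` names the standard conditions: `easy` (200 frames,
2 px/frame), `crossing` and `crossing-easy` (a parked identical distractor
on, or 1.5 widths beside, the target's path), `drifty-light` (±25%
illumination), `occluded`, `jump` (a 73 px teleport mid-sequence), and
`long` (3000 frames of random-walk target plus random-walk identical
distractor, where errors accumulate with sequence length).

What the generator does *not* emulate: articulated or deforming bodies,
photorealistic appearance, camera motion, compression artifacts, or
cluttered scenes with many heterogeneous objects. Passing these benchmarks
therefore demonstrates the mechanisms (matching, suppression, correction,
gating) under controlled conditions, not performance on real video.

## Benchmark problem sizes and numerical choices

The package default crop geometry (127/255, stride 4) suits targets of
50–150 px. The benchmarks track 10–20 px blobs in ≈100 px frames, so they
use `fixture_tracker_config()`: `"small"` (template 48, search 160, stride
2) and, for the 3000-frame endurance runs, `"tiny"` (template 24, search
80, stride 2, single scale candidate — the blobs do not change size). The
`"small"` search/template ratio (3.3 vs. the classical 2.0) widens the
response span to ±32 px so that an approaching distractor is visible in the
response map well before it touches the target, giving mining a clean
window; with the classical ratio the minimum-separation rule and the map
radius coincide and nothing can ever be mined cleanly.

Other numerical conventions: coordinates are 0-based, origin top-left,
pixel $(i, j)$ covering the half-open unit square with center at
$(j-0.5,\, i-0.5)$; argmax ties break to the smallest row, then column; an
all-equal response map resolves to its center cell; grayscale conversion
uses fixed luma weights (0.299, 0.587, 0.114); out-of-frame crops pad with
the frame mean; bilinear sampling replicates borders. Every stochastic
component (scene generation, reservoir sampling) draws from an explicit
seed, and `track_sequence()` is a pure function of its inputs — the test
suite asserts bit-identical trajectories across repeated runs and
translation invariance of the whole pipeline under integer frame shifts.

## Known limitations

* The handcrafted extractor's sub-stride phase sensitivity limits
  appearance discrimination between identical objects; suppression
  compensates via location refreshing, but a moving distractor that
  overlaps the target for many consecutive frames can still capture the
  tracker (as it can with a human-corrected deep tracker).
* Confidence calibration (temperature 0.1 against the 0.3 gate) was
  established on the synthetic benchmarks; a different feature extractor
  would need re-calibration.
* Multi-animal identity is out of scope: several targets are several
  independent tracker instances.
* The exemplar detector assumes the target's size is roughly stationary
  (windows use the bank's median box size).
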