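---
title: "Estimating clothing insulation and metabolic rate from thermal video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating clothing insulation and metabolic rate from thermal video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermotrack)
```

## The problem

Individual thermal-comfort assessment (for example with Fanger's PMV model)
needs two *personal* factors per occupant: the clothing insulation rate
`Icl` (clo, 1 clo = 0.155 m²·K/W) and the metabolic rate `M` (W/m²).
In practice these are looked up in ISO tables, which is manual, static and
unrealistic for a multi-person office. `thermotrack` implements a
contactless alternative: both factors are estimated continuously for every
tracked person from quantities that a thermal infrared camera pipeline can
produce — per-frame person detections with a clothing/posture category,
pose keypoints, per-pixel temperatures, and dense optical-flow fields.

The heavy perception models themselves (a person detector, a pose
estimator, a flow estimator) are *inputs* to this package, not part of it:
`thermotrack` consumes their outputs in standard interchange formats and
adds everything downstream — tracking, region localization, temperature
summarization, the insulation formula, activity features, and the
metabolic-rate classifier — plus a synthetic scene generator that emulates
all four input streams so the pipeline is fully testable without hardware.

## Tracking with a clothing-and-posture taxonomy

Persons are detected per frame in one of six categories crossing sleeve
status (`Long`, `Short`, `Occluded`) with key posture (`Sit`, `Stand`).
Tracking is SORT-style tracking-by-detection: each track's box is
propagated by a constant-velocity Kalman filter on
(centre-x, centre-y, area, aspect), detections are associated by
minimum-cost assignment on `1 − IoU` (an appearance-distance hook can be
added as a weighted cost term), and the DeepSort lifecycle rules apply —
a track is *tentative* until associated in `n_init = 3` consecutive
frames and *deleted* after more than `max_age` frames without a
detection. Because single-frame sleeve classifications are unreliable
under occlusion, each track's category is *voted*: the modal category over
a short window (default 3 s), with ties broken toward the previous vote,
then toward a non-Occluded candidate.

Design choices worth noting, since the method leaves them open:

* **Kalman parameters** use the standard SORT noise settings; at office
  frame-to-frame motion the filter is far from its stability limits and
  the association is dominated by the IoU gate (default 0.3).
* **`max_age` defaults to 30 frames** (≈1.4 s at 21 fps), long enough to
  ride out detector dropouts but short enough that a vacated seat does
  not keep a ghost track.
* **Confirmation is retroactive**: a confirmed track's first two
  (tentative) boxes are part of its output history. Clutter shorter than
  `n_init` frames still never appears in output, while genuine tracks are
  not charged two false negatives at birth.
* The frame rate is fixed at **21 fps** so that the canonical 10-s
  activity window equals 210 frames; all window defaults derive from it.

`evaluate_tracking()` implements CLEAR-MOT counting (carry-over matching
at IoU ≥ 0.5, then optimal assignment) and `compute_mota()` the usual
`100·(1 − (FN+FP+IDSW)/GT)`.

## Skin and clothes temperatures, and Icl

For each tracked person, two pixel sets are accumulated from pose
keypoints (only the nose, shoulders, elbows and wrists are trusted, each
requiring confidence ≥ 0.6):

* skin `Rs`: always the nose; for short sleeves also the lower arms,
  taken as the midpoint of elbow and wrist on each side;
* clothes `Rc`: always the shoulders; for long sleeves also the elbows;
* an `Occluded` sleeve status conservatively uses only nose and
  shoulders.

Each point is rounded to the nearest pixel and its temperature read from
the thermal frame (a configurable odd-sized patch mean is available, but
the default samples the single nearest pixel, matching the definition of
the regions as pixel-coordinate sets). Samples are accumulated over a
window (default 5 min — clothing changes slowly, and accumulation
averages away sporadic keypoint errors), then

$$I_{cl} = \frac{1}{0.155\,h}\cdot\frac{T_s - T_c}{T_c - T_o},
\qquad h = 8.6\ \mathrm{W/(m^2K)},$$

with `Ts`, `Tc` the sample means and `To` the operative temperature,
estimated as the mean over the window of each frame's mean background
(outside all person boxes) temperature. Numerical edge cases: when
`|Tc − To| < 0.1 °C` the estimate is ill-conditioned and an error
condition is raised instead of a number; a *negative* `Icl` (skin cooler
than clothes) is reported as-is and flagged, because clamping would mask
region-localization failures upstream.

## Activity features and M

A sitting person's metabolic range is so narrow that a single constant,
72.5 W/m², is used. A standing person's `M` is derived from three
features over a 210-frame window:

1. **centre spread** — the per-frame box centres form a 2-D cluster; the
   feature is the product of the two eigenvalues of the cluster's sample
   covariance (the area of the fitted ellipse, and identically the
   covariance determinant);
2. **scale spread** — the same construction on the boxes' half-extents
   `(w/2, h/2)` after translating every box to the origin;
3. **flow intensity** — per frame, the mean absolute deviation from
   grayscale 127 of the horizontal and vertical 8-bit flow images over
   the box pixels, combined as `sqrt(Ix² + Iy²)` and averaged over the
   window.

The sample covariance uses the `N − 1` denominator (at `N = 210` the
alternative differs by 0.5 %, but fixing it makes results
bit-reproducible), and the eigenvalue product is taken literally — no
`π` or confidence-interval scaling, since only relative magnitudes reach
the classifier. The flow grayscale-to-displacement scale is likewise
irrelevant for the same reason.

A three-class classifier (low / moderate / high standing activity) maps
features to probabilities `(Pl, Pm, Ph)`, and

$$M = P_l\,M_l + P_m\,M_m + P_h\,M_h,
\qquad (M_l, M_m, M_h) = (75, 125, 174)\ \mathrm{W/m^2},$$

a convex combination that cannot leave `[Ml, Mh]`. The default model is a
random forest with `max_depth = 2` (the configuration that classified
standing office activity best; shallow trees also resist overfitting on
three well-separated features). k-NN and SVM are provided for comparison;
features are z-scored with training statistics for those two but not for
the forest. Training rows are sorted into a canonical order before
fitting so that, given a seed, the fit is invariant to input permutation.
Windows whose posture vote is mixed use the modal posture, and training
rows labelled `ambiguous` are dropped.

## The synthetic scene generator

Real recordings of this kind are not redistributable, so the package
ships a generator whose defaults reproduce the study conditions: a
384×288 sensor quantizing temperatures to 0.08 °C at 21 fps, a 22 °C
office background, and person surface temperatures near the measured
values (skin 34.7 °C, clothes 33.4 °C). Persons are rendered as warm
blobs — a clothes-temperature torso ellipse plus skin-temperature head
and arm discs placed at the keypoint locations — over Gaussian sensor
noise (σ = 0.1 °C), then quantized. Five behaviour scripts
(`still_sit`, `still_stand`, `gesture_stand`, `stretch_stand`, `walk`)
drive sinusoidal or drifting box kinematics whose amplitudes are drawn
per scene from disjoint-but-adjacent ranges, and analytic flow fields map
the scripted displacement to 127-offset grayscale. Detections and
keypoints are derived from ground truth and corrupted by configurable
jitter, miss/clutter rates and confidence-score noise. Everything is
driven by one seed and is bit-reproducible.

What the generator deliberately does **not** emulate: clothing texture
and emissivity variation, radiative reflections, camera vignetting,
partial occlusions that deform (rather than hide) keypoints, and the
correlated failure modes of real detectors. Green tests on synthetic
scenes therefore demonstrate the *correctness of the computations* under
the stated statistical assumptions, not field performance of the full
camera stack.

`generate_activity_dataset()` draws labelled feature sets by running the
real feature extractor on scripted scenes (low ← `still_stand`,
moderate ← `gesture_stand`, high ← `stretch_stand`/`walk` alternating).
Scenes for this purpose default to 160×120 frames with smaller persons:
the features are scale-relative, and the smaller canvas keeps dataset
generation fast. The test suite exercises the classifier at the study's
sample sizes (315 training and 68 held-out sets, obtained by shuffling a
balanced set of 128 per level) and checks held-out accuracy ≥ 0.90,
ordered level medians, and that standing stretch windows outscore still
windows in `M` across 40 seeded paired trials.

## Formats, precision and problem sizes

* Detections/tracks use the MOTChallenge CSV dialect (1-based frames on
  disk, 0-based in memory; category codes 1–6); coordinates are written
  with up to 17 significant digits so round-trips are lossless.
* Keypoints use COCO-17 JSON (indices 0, 5–10 are read; others ignored).
* Thermal stacks are multi-page 32-bit-float TIFF storing °C/100 — the
  documented scale keeps values inside the unit range that baseline TIFF
  readers clamp to; the round-trip error (< 10⁻⁴ °C) is three orders of
  magnitude below the 0.08 °C camera quantization.
* Flow fields are 8-bit PNG pairs, round-tripping exactly.
* Every CLI run writes a manifest with the resolved configuration, input
  MD5 digests, seeds and record counts.

Test and example problem sizes are chosen to exercise every code path at
meaningful statistical power while staying lightweight: temperature
recovery uses a 1000-frame scene on a 192×144 canvas (the recovered
`Ts`/`Tc`/`To` must fall within one quantization step of the scripted
values, and `Icl` within 0.003 clo of the formula applied to the script);
tracking properties use 60–80-frame scenes; windows shorter than the
configured Icl accumulation are estimated anyway once at least one second
of frames exists, flagged `partial_window` — the method's own worked
examples use ~70-s windows against the 5-min default, so suppressing
short windows would be wrong.

## Known limitations

* Appearance-based re-identification is only a hook; with IoU-only
  association, two persons crossing paths can swap identities.
* The operative-temperature proxy (background mean) assumes the camera
  sees mostly air-temperature-coloured surfaces; strong radiant sources
  in view would bias `To`.
* Nose-based skin sampling is not mask-aware; masked faces bias `Ts`
  toward clothes temperature.
* The activity classifier transfers only as far as the feature
  distributions do; a deployment should retrain it on labelled windows
  from its own camera geometry.
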