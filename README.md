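# thermotrack

Contactless estimation of two personal thermal-comfort factors — the
**clothing insulation rate** `Icl` (clo) and the **metabolic rate** `M`
(W/m²) — for every person visible in thermal infrared video of an office
scene.

Comfort models such as Fanger's PMV need `Icl` and `M` per occupant, but
both are usually looked up in ISO tables by hand. `thermotrack` estimates
them continuously from the outputs of a thermal-camera perception stack:
per-frame person detections carrying a six-way clothing × posture category
(`{Long, Short, Ocl} × {Sit, Stand}`), COCO-17 pose keypoints, per-pixel
temperature frames, and optional dense optical-flow fields. The detectors
themselves are out of scope — they are file inputs, and a fully labelled
synthetic scene generator stands in for them during development and
testing.

## What it computes

**Tracking.** SORT-style tracking-by-detection (constant-velocity Kalman
filter, Hungarian association on `1 − IoU`, DeepSort lifecycle: tentative
until 3 consecutive hits, deleted after `max_age` misses) with per-track
category voting, plus CLEAR-MOT evaluation arithmetic
(`MOTA = 100·(1 − (FN+FP+IDSW)/GT)`).

**Clothing insulation.** Skin pixels `Rs` (nose; plus lower arms — the
elbow/wrist midpoints — for short sleeves) and clothes pixels `Rc`
(shoulders; plus elbows for long sleeves) are located from keypoints with
confidence ≥ 0.6 and accumulated over a window (default 5 min). With the
mean skin, clothes and background ("operative") temperatures `Ts`, `Tc`,
`To` in °C:

    Icl = (Ts − Tc) / (0.155 · h · (Tc − To)),   h = 8.6 W/(m²·K)

**Metabolic rate.** Sitting persons get the representative constant
72.5 W/m². For standing persons, three activity-intensity features over a
10-s (210-frame) window — box-centre spread and box-scale spread (each the
eigenvalue product of a 2-D cluster covariance) and in-box optical-flow
intensity — feed a three-class classifier (default: depth-2 random
forest), and

    M = Pl·75 + Pm·125 + Ph·174   (W/m²)

## Worked example

```r
library(thermotrack)

# Insulation from measured temperatures (a subject in a light T-shirt)
compute_icl(ts = 34.73, tc = 33.48, to = 25.58, h = 8.6)
#> [1] 0.1187006

# Full pipeline on a synthetic two-person scene (no camera needed)
scene <- generate_scene(scene_script(
  persons = list(scene_person("still_sit",     sleeve = "Long"),
                 scene_person("gesture_stand", sleeve = "Short")),
  frame_shape = c(220, 160), n_frames = 230, seed = 5))

clf <- fit_activity_classifier(generate_activity_dataset(25, seed = 1),
                               seed = 0)
res <- run_pipeline(scene$detections, scene$keypoints, scene$thermal,
                    scene$flows, classifier = clf)

res$icl[, c("track_id", "n_skin", "n_clothes", "ts", "tc", "to", "icl")]
#>   track_id n_skin n_clothes    ts   tc to     icl
#> 1        1    230       920 34.71 33.4 22 0.08620
#> 2        2    690       460 34.70 33.4 22 0.08567

res$m[, c("track_id", "posture", "p_low", "p_moderate", "p_high", "m")]
#>   track_id posture p_low p_moderate p_high     m
#> 1        1     Sit    NA         NA     NA  72.5
#> 2        2   Stand 0.002       0.98 0.0179 125.8
```

Reading the output: both tracked persons' temperatures are recovered from
the rendered frames (`ts` ≈ 34.7 °C skin, `tc` ≈ 33.4 °C clothes over a
22 °C background), giving ≈ 0.086 clo against a scripted ground truth of
0.0855 clo. The long-sleeved sitter accumulates 1 skin point (nose) and 4
clothes points per frame; the short-sleeved stander 3 skin and 2 clothes.
The sitter's metabolic rate is the 72.5 W/m² constant, while the
gesturing stander is classified as moderate activity (P ≈ 0.98), giving
M ≈ 126 W/m².

A thin CLI over the same functions is at `inst/cli/thermotrack.R`
(subcommands `simulate`, `track`, `icl`, `activity`, `m`, `evaluate`,
`run`); every run writes a `manifest.json` with the resolved
configuration, input digests and record counts.

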