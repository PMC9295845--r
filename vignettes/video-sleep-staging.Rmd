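---
title: "Immobility-defined sleep staging from home-cage video"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Immobility-defined sleep staging from home-cage video}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagesleep)
```

## The problem and the method

EEG/EMG recording is the gold standard for scoring sleep in mice, but it
needs surgery, tethering and days of recovery, which makes it a poor fit for
screening many animals. Video actigraphy replaces it with an infrared camera
over the home cage and a behavioural definition of sleep: a mouse that stays
immobile long enough is asleep. `cagesleep` implements that pipeline in two
stages plus the analytics needed to validate it.

**Stage 1 — frame analysis.** Each frame is Gaussian-smoothed and converted
to the absolute deviation from its median gray, so a mouse darker than a
bright light-phase background and a mouse brighter than a dark
infrared-phase background are handled identically. Two thresholds are
applied — an adaptive local-mean threshold and a global Otsu threshold — and
the union of their foregrounds is split into 8-connected components. Every
sufficiently large component becomes a candidate region; several candidates
per frame are normal, because food, water gel and shadows also produce
blobs. A trainable patch classifier scores every candidate and the highest
score is designated the mouse (ties: larger area, then lower row). For each
frame this yields the feature vector (classifier score, mask, centroid,
mean gray).

**Stage 2 — activity judgement and staging.** For a frame $f_t$, features
are differenced against frames in a window $f_{t\pm i}$ ($i$ up to $m$
sample periods): score difference $P_i$, mask difference $M_i = 1 -
\mathrm{IoU}$, centroid displacement $A_i$ (px), and mean-gray difference
$G_i$ (gray levels). The mouse is *active* at $t$ if any window difference
satisfies

$$P_i > 0.1 \;\lor\; G_i > 3 \;\lor\; A_i > 5 \;\lor\;
  \tfrac{1}{3}\!\left(\tfrac{G_i}{255} + M_i + P_i\right) > 0.5 .$$

Per-second activity is the OR over that second's sampled frames. Sleep is
then any maximal run of inactivity lasting at least 40 s; afterwards the
*movement-merging filter* relabels every wake run of at most 15 s that is
flanked by sleep on both sides as sleep, iterating to a fixed point. The
per-second hypnogram is finally scored into 20 s epochs by majority, with
ties going to Wake.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `thr_P`, `thr_G`, `thr_A` | 0.1, 3, 5 | score, gray, px | per-difference activity cuts |
| `thr_combined` | 0.5 | – | cut on the normalised mean $(G/255 + M + P)/3$ |
| `immobility_min_s` | 40 | s | minimum immobility scored as sleep (strict: 39 s stays wake) |
| `merge_filter_s` | 15 | s | longest wake run merged between two sleep bouts |
| `epoch_s` | 20 | s | scoring epoch |
| `sample_period_s`, `window_half_width` | 1, 2 | s, samples | difference window ($t \pm 1, \pm 2$ s) |
| `max_gap_s` | 2 | s | longest detection gap still counted as inactive evidence |

The four activity thresholds, the 40 s rule, the 15 s merge and the 20 s
epoch are the method's published operating point; the window half-width is
an exposed hyperparameter, and the normalisation of the combined score is a
package decision: $P$ and $M$ already live in $[0,1]$, $G$ is divided by
255, while the individual $G$ and $A$ cuts apply to raw gray levels and
pixels. Under the default cuts the combined clause is mathematically
redundant (if $P \le 0.1$ and $G \le 3$ then the mean cannot exceed 0.37),
so the implementation computes the expensive mask IoU only when the
configured thresholds make it decisive.

Detection parameters (`vision_params()`) are engineering defaults — Gaussian
$\sigma = 2$ px, adaptive block 51 px with offset 5 gray levels, Otsu floored
at that offset, minimum component area 25 % of the expected mouse area. The
floor matters: without it, Otsu on a noise-only deviation image splits the
noise itself and empty frames sprout spurious foreground.

## What the simulator emulates — and what it does not

`simulate_state_sequence()` draws alternating wake/sleep bouts from a
shifted gamma (shape 2, minimum 20 s; means 360 s wake / 480 s sleep by
default, consolidated multi-minute bouts as in adult mice). The minimum
guarantees immobility runs on both sides of the 40 s boundary so the sleep
rule is genuinely exercised. Twitches — brief movements during sleep, the
reason the merging filter exists — arrive as a Poisson process (0.3/min of
sleep by default) with uniform 5–12 s durations and an 8 px excursion.
`render_video()` draws the mouse as a deformable ellipse oriented along its
motion (rounder when curled up asleep, with a slow 4 % breathing
deformation), over a light- or dark-phase background with static
distractors: a bright food-pellet disk, a dark water-gel rectangle and a
soft shadow gradient. Waking locomotion is a 40 px/s waypoint walk; sleeping
movement is a bounded smooth oscillation never exceeding `sleep_jitter_px`
(1 px) — breathing shifts a resting body slowly, so modelling it as white
noise at the frame rate would make the apparent displacement between
analysis samples depend on the frame rate, which is unphysical.

Passing the recovery tests on this simulator therefore shows that the
staging logic, the thresholds' interplay, the merging filter and the
validation metrics behave as specified under controlled conditions with a
known answer. It does not certify performance on real infrared video:
real mice groom in place, rear against walls, burrow under bedding and
change apparent size with posture, and real cages have reflections and
bedding texture no flat-background ellipse reproduces. The classifier
accuracies reported on synthetic patches say nothing about accuracies
achievable on hand-labelled real frames.

## Classifier

The mouse-versus-background classifier follows the published protocol —
random 80/20 train/validation split, cross-entropy loss, fixed learning
rate 0.001, 50 epochs — over a pluggable backbone. The default `"logistic"`
backbone fits a logistic regression (by IRLS, so the learning-rate and
epoch fields are recorded but inert) on six intensity/shape features of the
64×64-resized crop: mean, spread, foreground fraction, contrast, elongation
and bounding-box fill, with the foreground taken as the minority side of the
crop's Otsu split (stable even when the crop also contains part of a shadow)
and a contrast gate that zeroes shape features on featureless crops. The
`"mlp"` backbone trains a single-hidden-layer network one epoch at a time
(warm-started), so its report carries a true per-epoch loss curve. A deep
convolutional backbone would slot in behind the same two-function surface
(`train_classifier()` / `score_patch()`), but no GPU stack is assumed, and
an end-to-end test asserts that swapping logistic for MLP changes the final
epoch hypnogram of a clean recording by at most one epoch.

Training patches come from the detector's own candidates
(`harvest_training_patches()`), labelled by whether the candidate mask
covers the true position — this keeps the crop geometry identical between
training and scoring, and deliberately labels blobs where the mouse has
merged with a distractor or shadow as positives, which is what makes
selection stable when the animal sleeps inside a shadow.

## Numerical and degenerate-input choices

* Coordinates are 1-based with inclusive bounding boxes (R convention),
  sub-pixel centroids are pixel-index means.
* A uniform, empty or pure-noise frame yields an empty candidate list, not
  an error; a frame with no acceptable candidate carries the last valid
  features forward and is flagged. Carried frames count as *inactive*
  evidence only while the gap is at most `max_gap_s`; longer gaps drop out
  of staging entirely (those seconds are `NA` and never count as
  immobility).
* "At least 40 s" is strict at 1 s resolution: a 39 s immobile run stays
  wake. Merging is applied left-to-right and re-scanned to a fixed point, so
  Sleep–Wake(10)–Sleep–Wake(10)–Sleep collapses into one bout;
  `merge_filter_s = 0` is the identity.
* Epoch ties go to Wake — the conservative choice given that the method's
  known failure mode is *over*-counting sleep interruptions, not missing
  wake. Trailing partial epochs are dropped and logged.
* Masks are stored as sorted linear pixel indices; IoU is an ordered
  intersection walk. The per-frame image primitives (separable Gaussian,
  integral-image box mean, 256-bin Otsu, 8-connected labelling) are
  compiled code, validated in the tests against naive R re-implementations
  (BFS flood fill, direct convolution).
* The delta band is bins 1–4 of the thirty 1 Hz bins (inclusive), so a flat
  spectrum has delta ratio 4/30; state spectra are means over epochs of
  per-epoch percentages and sum to 100 within each state; hours without
  NREM epochs give `NA`, zero-power epochs are excluded with a note.
* Sleep is the positive class in agreement metrics: sensitivity is the
  fraction of reference sleep recovered, which is exactly what twitch
  misjudgement erodes.

## The rule-based EEG stager

`rule_based_eeg_stager()` is a deliberately simple stand-in for interactive
EEG/EMG scoring software: per-epoch delta ratio > 0.4 with EMG below its
median percentile is NREM, theta ratio > 0.45 with EMG below the 15th
percentile is REM, everything else Wake. It exists so three-state workflows
(wake-to-REM episode detection, state spectra) can be exercised end to end
on synthetic band-power tables; it claims no parity with any validated
scorer, and its cutoffs are all configurable.

## Problem sizes

The shipped tests and the acceptance script use: 3-day simulated recordings
for epoch bookkeeping (six of them), 1000 random binary traces of 100–500 s
for the staging oracle, 100 traces of 600 s for the monotonicity sweep, and
one 2 h rendered recording at 352×288 px and 5 frames/s for the full
detect-and-stage recovery run — enough cycles (8–10 bouts, ~20 twitches) for
the merge filter to matter, while a full run stays in the minutes range on
one core. The renderer streams frames chunk-free (one frame at a time) so
multi-hour recordings never materialise in memory; masks for a 2 h run take
tens of megabytes.

## Known limitations

* Video alone cannot separate NREM from REM sleep; two-state output is the
  design, and three-state hypnograms here come from EEG-style tables or the
  simulator.
* The immobility rule is blind to quiet wakefulness: a mouse sitting still
  41 s while awake is scored asleep, which is the known accuracy ceiling
  of the approach.
* Window differencing smears activity by up to `window_half_width` sample
  periods around each true movement, so twitches near the merge threshold
  can escape merging; with 5–12 s twitches and the ±2 s window, runs up to
  16 s can appear and a 15 s filter leaves the longest of them split.
* The selector is purely per-frame (arg-max of the classifier); it has no
  temporal smoothing, by design fidelity to the staged method.
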