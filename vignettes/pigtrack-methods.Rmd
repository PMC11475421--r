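---
title: "Tracking group-housed pigs: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking group-housed pigs: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigtrack)
```

`pigtrack` links per-frame pig detections into identities, accounts each
animal's time per behaviour class, and evaluates the result. This vignette
is the package's account of the method: the model and its assumptions, the
parameters that matter, what the synthetic generator does and does not
emulate, and the choices made where the design was genuinely open.

## The motion model

A track's state is the seven-vector `x = (u, v, s, r, u̇, v̇, ṡ)`: box
centre in pixels, box area in px², aspect ratio (unitless), and per-frame
rates of the first three. The filter is the standard linear-Gaussian
recursion with a constant-velocity transition; the aspect ratio carries no
rate and is held constant by the motion model, so its predicted value always
equals its prior value. Time is measured in frames: detections arrive at a
fixed rate (5 fps in the recordings this targets), the file dialect carries
no timestamps, and all rates are per-frame.

Assumptions worth stating:

* **Linear motion between observations.** Pigs turn and bump into walls;
  the filter absorbs this as process noise. Over an occlusion gap the
  assumption bites harder — see ORU below.
* **Observation noise independent across frames** with fixed covariance
  `R`. Real detector errors are correlated with pose and lighting; the
  filter does not model that.

Neither `Q` nor `R` is dictated by the method, so the package adopts the
SORT-family convention: `R = diag(1, 1, 10, 10)` on `(u, v, s, r)` —
centre coordinates trusted ten times more than area and shape — and a small
process noise `Q = diag(1, 1, 1, 0.01, 0.01, 0.01, 1e-4)`. New tracks start
with velocity variance (`p_vel = 1e4`) three orders above position variance
(`p_pos = 10`) because velocities are unobserved at birth. All four live in
`tracker_config()`; no contract in the package depends on their exact
values.

Two numerical guards: predicted covariances are symmetrised after every
propagation (the tests require asymmetry below 1e-9 across a thousand
steps), and if the area rate would drive the predicted area non-positive
(`s + ṡ ≤ 0`, which the 7-D parameterisation can produce during long
occlusions) the rate is reset to zero before propagation. The update refuses
innovation covariances with condition number above 1e12 rather than
returning garbage.

## Association

The per-frame cost between track `i` and detection `j` is

```
C[i, j] = −IoU(predicted box i, detection box j) + λ · C_v(i, j)
```

`C_v` is the angle, normalised to [0, 1] by π, between (a) the track's
motion direction measured between two real observations `delta_t` frames
apart and (b) the direction from that same reference observation to the
detection centre. Only real observations enter this history — virtual
observations created for re-update are excluded — and a track with a single
observation has no defined direction, so its `C_v` is 0. Normalising by π
keeps the two cost terms commensurate, which makes `λ` interpretable as
"how many IoU points a fully reversed direction costs".

Defaults: `λ = 0.2`, `delta_t = 3` frames, association gate `iou_gate =
0.3`. None of these is pinned by the method's definition; they are the
observation-centric tracker family's published operating points, exposed in
config. The gate applies identically to the primary and the recovery
association; nothing in the method statement suggests two gates, and one
fewer knob is one fewer interaction to tune.

The assignment itself is a rectangular Hungarian solve (shortest augmenting
path with potentials) implemented in-package, since no linear-assignment
solver is available in the dependency set. Gated cells enter the solve at a
large sentinel cost and any match made at the sentinel is discarded
afterwards, which is equivalent to maximising feasible cardinality first and
minimising cost second; the test suite pins the solver against exhaustive
enumeration on all instances up to 6×6.

## Losing and recovering tracks

A track that fails to match keeps its identity with status "untracked", and
its filter keeps predicting through the gap (so its predicted box keeps
moving — the alternative, freezing the state, would make the primary
association useless for moving animals). Untracked tracks participate in the
primary association via their predicted boxes. After `max_age = 30`
consecutive unmatched frames the track is deleted and its identity is never
reused.

Two mechanisms specifically target occlusion:

* **OCR (recovery association).** After the primary association, unmatched
  tracks get a second association against the leftover detections using
  their last *observed* box. The rationale: a pig that vanished usually
  reappears near where it was last seen (occlusions are mostly pile-ups of
  resting animals), whereas the Kalman prediction may have drifted across a
  long gap on a velocity estimated from a couple of noisy frames.
* **ORU (re-update).** When a track re-associates after a gap of `g ≥ 2`
  frames, the filter state is rebuilt from the posterior at the last real
  observation by replaying predict/update along a *virtual trajectory*
  interpolating the gap interior, finishing with the real re-associating
  observation. The interpolation is linear in each of `(u, v, s, r)` — the
  functional form of the virtual trajectory is an open choice, and linear is
  the only one consistent with the constant-velocity model. ORU touches
  only filter state, never the association itself, and the tests verify
  that disabling it changes nothing in gap-free sequences.

Both mechanisms can be disabled (`enable_ocr`, `enable_oru`) for ablation;
the acceptance suite requires the full tracker to preserve identity through
single occlusion gaps strictly more often than the ablated one.

## Behaviour accounting

Each track holds a count vector `[A1, A2, A3, A4]` over (lie, stand, eat,
other) — this category order defines the array throughout the package.
Every matched frame adds an indicator with a single 1 at the matched
detection's class; the emitted row's behaviour label is that detection's
class, unsmoothed. Unmatched (occluded) frames contribute to no category:
time spent invisible is simply unaccounted, which biases durations low by
the occlusion rate rather than guessing a class.

One boundary case was genuinely ambiguous: whether a track's birth frame
counts. The package counts it — the birth detection is a real observation
and an emitted row, and counting it preserves the invariant that a track's
counts sum exactly to its number of observed frames, which is what makes the
accounting independently checkable by recounting the output table. (A
literal reading of the procedure's pseudo-code initialises the array to zero
at creation without incrementing; that reading makes every track one frame
short of its own output.)

Durations are `counts / fps`, exact division. Herd percentages pool counts
over all tracks (frame-weighted) rather than averaging per-animal
percentages: a pig tracked for ten seconds should not weigh as much as one
tracked for ten minutes. With zero accumulated frames the percentages are
reported as undefined (`NULL` in R, `null` in JSON), never NaN.

The creation threshold (`new_track_confidence`) defaults to 0.7. The
method's prose and pseudo-code disagree on this value (0.7 vs 0.75); a
single config value defaulting to the prose's 0.7 makes the discrepancy
moot.

## Evaluation

MOTA follows the CLEAR convention: `1 − (FP + FN + IDS) / gt`, with a
switch counted when a ground-truth identity's matched prediction id differs
from its most recent previously matched id. IDF1 maximises correctly
identified boxes over a global identity bijection. HOTA is implemented in
its canonical form — `HOTA_α = sqrt(DetA · AssA)` averaged over
α ∈ {0.05, …, 0.95} — even though the method statement prints the formula
without the square root and at a single threshold: the printed per-pair
association accuracy is only consistent with the canonical geometric-mean
form, and the standard definition keeps scores comparable with the rest of
the literature. The single-threshold value is exposed alongside
(`hota_single`). The matching threshold for MOTA/IDF1 defaults to IoU 0.5,
the MOTChallenge convention.

## The synthetic pen

The generator stands in for the recordings: 6–16 pigs in an overhead view,
5 fps, behaviour-dependent motion. Its stated world:

* **Behaviour** evolves by a per-frame Markov chain whose default
  stationary distribution is a healthy, lie-dominated time budget
  (72/17/10/1% over lie/stand/eat/other) with mean dwell of 50 frames
  (10 s); `behavior_markov()` builds a chain with any prescribed budget.
* **Motion** is a heading-persistent random walk scaled by behaviour (lying
  pigs are stationary, eating pigs shuffle toward a feeder on one wall,
  standing/other pigs walk at 3–5 px/frame), reflecting at the pen walls —
  deliberate nonlinear events. Pigs are solid: centres are pushed apart
  below a minimum separation, as overlapping animals would otherwise
  produce physically impossible coincident boxes. Boxes are the
  axis-aligned hulls of oriented bodies, so area and aspect ratio change
  smoothly with heading, exercising the `s, r` dynamics.
* **Degradation**: Gaussian noise on box position and size (1 px by day,
  2.5 px at night in the presets), per-pig occlusion dropouts with
  geometric length, independent misses, Poisson false positives with
  uniform boxes, and separate confidence models for true and false boxes.
  The counts actually injected are attached to the output, so
  metric fixtures know their expected FP/FN exactly; `inject_errors()`
  provides fully deterministic surgery for the same purpose.

What the generator does **not** emulate: appearance (there are no pixels),
detector-correlated errors (misses that cluster on specific poses), box
merging during contact (occlusion is modelled as dropout, which is what the
recovery mechanisms actually consume), and camera distortion. A green test
on synthetic scenes therefore establishes the *tracking logic* — association,
lifecycle, recovery, accounting, metrics — not detector robustness or
performance on real video, whose headline scores depend on a trained
detector and are out of scope here.

The occlusion-recovery study fixes its own stated world once: a single pig
whose behaviour is drawn from the lie-dominated budget above (speeds
0/0.4/1.2/2.5 px/frame for lie/eat/stand/other), first seen 2–5 frames
before the gap — occlusions shortly after first sighting are the hard case,
since the velocity estimate is still raw — a gap uniform on 2–30 frames,
ten post-gap frames, and 1.5 px detection noise.

## Known limitations

* The tracker is single-pen, single-camera and online; no re-identification
  across pens or cameras.
* Behaviour labels are taken from the detector per frame, unsmoothed; a
  flickering detector flickers the ethogram (only the totals are robust,
  since each frame contributes exactly one count).
* `O(N·M)` dense cost construction per frame is fine for pen-sized N
  (≤ 16 animals) but is not engineered for crowd-scale MOT.
* Higher-order behaviours (aggression, social interaction) and health
  inference from time budgets are out of scope.
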