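---
title: "Tracking a fixed herd: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking a fixed herd: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(herdtrack)
```

## The tracking model

`herdtrack` is a tracking-by-detection pipeline for enclosed animal
pens. Its per-frame update follows the Deep SORT architecture and adds
two refinements that exploit the closed-pen constraint (the number of
animals is fixed for the whole video):

1. detections below `min_confidence` are dropped;
2. every live track is advanced by a constant-velocity Kalman filter
   over `(cx, cy, a, h)` and velocities, dt = 1 frame;
3. **appearance cascade**: confirmed tracks, in ascending
   time-since-update order, are matched to detections by minimum
   gallery cosine distance, with a hard Mahalanobis gate (chi-square
   0.95 quantile, 4 df = 9.4877) and a hard appearance gate
   (`max_cosine_distance = 0.2`);
4. **primary IOU matching**: tentative tracks plus confirmed tracks
   that just missed the cascade (time-since-update 1) are matched on
   cost `1 − IoU` under gate 0.7;
5. **secondary IOU matching**: the remaining unmatched tracks and
   detections are matched once more under the relaxed gate 0.9;
6. matched tracks get a Kalman update, a gallery append, and
   tentative→confirmed promotion at 3 consecutive matches; unmatched
   tentative tracks die immediately; unmatched confirmed tracks die
   after `max_age = 30` consecutive misses;
7. **admission gate**: an unmatched detection creates a new (tentative)
   track only while the candidate id does not exceed the *extreme ID
   value*, the ceiling of the mean of the last 5 frames' maximum live
   ids; otherwise no track is created;
8. the current maximum live id is pushed into the ring buffer.

Only confirmed, just-updated tracks are emitted, the standard MOT
output convention. Track ids are never reused, all orderings are
deterministic (tracks by id, detections by file order), so runs are
bit-reproducible.

### Assumptions

* The pen is enclosed and the herd size constant; animals neither
  enter nor leave. This is what justifies the admission gate at all.
* The camera is fixed; no camera-motion compensation is attempted.
* One detection per animal per frame at most (the detector does not
  split animals).
* Appearance embeddings are informative in the open and may be
  arbitrarily poor during occlusion.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `n_init` | 3 | frames | consecutive matches to confirm a track |
| `max_age` | 30 | frames | confirmed-track survival without a match |
| `max_cosine_distance` | 0.2 | — | appearance gate in the cascade |
| `primary_iou_gate` | 0.7 | cost | primary IOU admissibility (`1 − IoU`) |
| `secondary_iou_gate` | 0.9 | cost | relaxed secondary admissibility |
| `extreme_id_window` | 5 | frames | ring buffer behind the extreme ID value |
| `gallery_budget` | 100 | embeddings | appearance memory per track |
| `weight_position` | 1/20 | of box height | Kalman position/size noise scale |
| `weight_velocity` | 1/160 | of box height | Kalman velocity noise scale |
| `min_confidence` | 0.3 | — | detection floor |

The confirmation count (3) and the 5-frame extreme-ID window are the
published defaults of the method; the Kalman weights and the
chi-square gate are the Deep SORT reference parameterisation; the IOU
gates are package choices (see below) exposed in `tracker_config()`.

## Design choices where the design was open

**Extreme-ID comparison.** The admission condition is stated in the
method's description both as "must be less than" and as "does not
exceed" the extreme value. We default to the inclusive comparison
(`candidate id ≤ extreme`), because the strict one cannot even
re-register a herd of constant size after a cold start; the strict
variant remains available (`admission_strict = TRUE`).

**Rounding.** The extreme ID value is always the ceiling of the buffer
mean; the ceiling of an integer is itself, which subsumes the
two-case phrasing (integer mean kept, fractional mean rounded up).

**Cold start.** The gate is inactive until the ring buffer holds a
full window (5 frames), so the initial herd can register. Without
this, nothing could ever be tracked.

**Cascade cost.** Pure appearance (minimum gallery cosine) with the
Mahalanobis distance used only as a hard gate — the λ = 0 convention
of the original Deep SORT. The method description is silent on λ.

**Scope of the secondary pass.** Open question: does the relaxed pass
re-admit only the primary stage's own leftovers, or every track still
unmatched at that point (including cascade-rejected confirmed tracks
of any age)? We default to the broader scope
(`secondary_scope = "all_unmatched"`). The narrow reading has a
structural flaw in combination with the admission gate: once a
confirmed track has starved through an occlusion burst for more than a
few frames, its innovation covariance grows too slowly for the
chi-square gate to re-admit it (the squared distance plateaus around
12–18 against the 9.49 threshold even when the appearance cost is
essentially zero), it can never re-enter the IOU stages (those would
require time-since-update 1), and it dies at `max_age`; because the
admission gate then refuses a replacement id, the animal is lost for
the remainder of the video. Under the broad scope the relaxed IOU pass
is exactly the mechanism that lets such a track reclaim its animal,
which is the method's stated purpose — fewer identity errors at no
accuracy cost. The narrow variant is kept as
`secondary_scope = "primary_leftovers"`.

**IOU gate magnitudes.** The method prescribes "a relaxation" without
a number. Defaults 0.7 (primary) and 0.9 (secondary) make the
secondary pass admit matches with 0.1 ≤ IoU < 0.3 — overlaps that are
real but too weak for the primary stage.

**Refused detections** are dropped, not buffered: the next frame will
re-detect the animal if it is real.

**Per-frame maximum id** is recorded after the frame's creations, over
live (non-deleted) tracks.

## What the simulator emulates — and what it does not

`generate_truth()` produces an enclosed pen: every animal present in
every frame, bounded random walks with reflecting walls, and scheduled
pairwise **occlusion bursts** — the two closest free animals are
steered together at a capped chase speed (2.5× the walk scale — a
brisk walk, not a teleport), held overlapping (IoU ≥ 0.5) for a fixed
duration, then released with a refractory period before either can be
scheduled again. During the hold, the *stationary* partner — the
animal underneath in a mounting/fighting cluster — is the occluded
one: it suffers the elevated miss probability and the degraded
appearance embedding, while the mover on top stays visible. These
choices keep the ground-truth kinematics physically plausible, which
matters because an idealised teleporting ground truth would defeat any
constant-velocity tracker for reasons that say nothing about real
video.

`apply_detector_noise()` adds occlusion-dependent misses, Gaussian box
jitter, Poisson false positives with fresh-identity embeddings, and a
confidence that decays with jitter magnitude (clipped to [0.5, 1]).

**Embedding noise calibration.** Embeddings are unit vectors in 256
dimensions; per-coordinate Gaussian noise of sd σ yields an expected
within-identity cosine distance of roughly `1 − 1/√(1 + 256σ²)`. The
presets are calibrated through this mapping to the spreads a working
re-identification network produces: within-identity distance ≈ 0.05 in
the open (σ = 0.02–0.025, comfortably inside the 0.2 cascade gate) and
≈ 0.4–0.55 during occlusion (σ = 0.08–0.12, beyond the gate — the
cascade is *supposed* to distrust occluded crops). Between-identity
distances of random anchors concentrate near 1 (near-orthogonality in
high dimension), a slightly kinder separation than real cattle coats;
consequently the simulator understates appearance confusion between
look-alike animals.

Not emulated: pixel appearance of any kind (the re-ID network itself
is out of scope — embeddings enter via sidecar files or the mock
embedder), split/merged detections, camera shake, lighting change,
entry/exit, and long-term appearance drift. Passing tests on synthetic
data therefore demonstrate the *association logic* under controlled
occlusion and noise, not end-to-end performance on farm video.

### Preset regimes

* `"sparse"`: 4 animals, 1920×1080 arena, 200 px boxes, rare contact
  (0.005 events/frame, 10-frame holds), 2% base miss, light jitter.
* `"distant_dense"`: 7 animals, 1280×720 arena, 80 px boxes, frequent
  contact (0.04 events/frame, 15-frame holds), 5%/55% miss
  probabilities, 0.15 false positives per frame, heavier jitter and
  occlusion-degraded embeddings. Scale intuition: at ~32 px/m a walk
  step sd of 2 px/frame at 25 fps corresponds to sub-m/s ambling, the
  chase cap to ≈ 1.6 m/s.

## Numerical choices

* Continuous-area IoU; touching boxes overlap zero.
* The Hungarian solver (shortest augmenting path) treats non-finite
  costs as infeasible sentinels; gated demotion happens after the
  optimum is found, so a gate never changes which assignment is
  optimal, only which pairs survive it.
* Kalman updates use a Cholesky solve of the innovation covariance;
  a singular innovation raises an error rather than propagating NaNs.
  Covariances are re-symmetrised after every update.
* CLEAR-MOT correspondence carries the previous frame's pairs over
  while they still clear the IoU threshold (so two overlapping
  hypotheses cannot leapfrog an established match), then assigns the
  rest by maximum total IoU at threshold 0.5.
* IDF1 solves the identity bijection by the same assignment solver on
  the negated co-occurrence matrix.
* Ties in assignment are broken deterministically by row order; with
  continuous box coordinates exact ties are measure-zero.

## Problem sizes used by the test suite

The suite validates metrics against a brute-force enumeration oracle
on 200 random instances of ≤ 3 objects × ≤ 4 frames, the assignment
solver against exhaustive permutation search on 500 matrices up to
6×6, the Kalman filter against an independently written reference on
100 random step sequences, and the end-to-end improvement claim on 20
seeded `distant_dense` scenarios of 600 frames each — sizes chosen so
the whole suite exercises every code path at desk scale while the
enumeration oracles remain exact.

## Known limitations

* With the admission gate on and ids never reused, a confirmed track
  that dies can never be replaced once the herd has registered — the
  gate design makes track survival (via the secondary pass) the only
  recovery mechanism. The simulator shows this works under plausible
  occlusion; pathological videos (very long full occlusions) would
  lose animals permanently, where the classic baseline would at least
  re-register them under a new id.
* The extreme-ID gate assumes one pen per sequence; multi-pen footage
  must be split before tracking.
* MOTP is reported in its IoU form (higher is better); the
  distance-based variant is not provided.
* The evaluator and tracker are plain R; sequences of a few thousand
  frames and tens of animals are comfortable, hour-long videos at
  25 fps are not its design point.
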