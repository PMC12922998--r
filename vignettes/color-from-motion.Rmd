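---
title: "Color-from-motion encoding, synthetic validation and tracking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Color-from-motion encoding, synthetic validation and tracking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colormotion)
```

## The model

Behavioral video analysis usually discards the most informative cue the data
contain: movement. `colormotion` splits a video into two parallel
representations. The *static* stream keeps each frame as an ordinary still
color image. The *motion* stream re-renders temporal change as false color,
so that a single frame shows not just where an animal is but how it has been
moving.

The encoding rests on the per-frame luminance difference. With luminance
planes $L_t \in [0,1]^{H \times W}$ (Rec.601 weights by default),

$$D_t = |L_t - L_{t-1}|.$$

**Exponential strategy.** Each color channel $c \in \{B, G, R\}$ carries an
exponential moving average of $D_t$ with its own persistence weight $w_c$:

$$M_{c,t} = w_c\, M_{c,t-1} + (1 - w_c)\, D_t,
\qquad 0 \le w_B < w_G < w_R < 1,$$

composed as $O_c = \mathrm{clip}_{[0,1]}(D_t + M_{c,t})$ (or
$O_c = \mathrm{clip}_{[0,1]}(M_{c,t})$ in *chromatic-tails-only* mode, which
omits the raw white difference and preserves more of the luminance detail
under blending). Unrolling the recurrence gives
$M_{c,t} = \sum_{\tau \ge 0} (1-w_c) w_c^{\tau} D_{t-\tau}$: each channel is
a window into a different age band of motion. Since blue has the shortest
memory and red the longest, a moving object leaves a tail that fades
white → blue → green → red with increasing age. The geometry of that tail
encodes kinematics: tail length tracks speed, the red→white axis points
along the heading, and because an accelerating object covers its recent path
faster than its old one, it outruns its red tail (a blue-shifted leading
trail), while a decelerating object is caught up by it (red energy
accumulating close behind the object).

**Sequential strategy.** Discrete recent differences instead of smoothing:
with $d_j = |L_{t-j+1} - L_{t-j}|$,

$$O_B = \mathrm{clip}(d_1 + d_2), \quad
  O_G = \mathrm{clip}(d_1 + d_3), \quad
  O_R = \mathrm{clip}(d_1 + d_4),$$

so the newest difference renders white (it enters all channels) and each
older lag owns one channel, bluest = most recent. This preserves discrete
spatial structure from each recent frame (a wing silhouette stays a wing
silhouette rather than smearing into a tail) at the cost of a fixed, short
temporal range.

Either output can finally be blended with the current luminance,
$O_c' = (1-\beta) O_c + \beta L_t$, restoring spatial context. Frame
skipping (encode every $k$-th frame) stretches the temporal window for
slow-moving subjects at no extra cost.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `weights` $(w_B, w_G, w_R)$ | (0.5, 0.8, 0.95) | — | per-channel memory; mean age of channel $c$'s energy is $w_c/(1-w_c)$ frames (1, 4, 19 at the defaults) |
| `tails_only` | `FALSE` | — | drop the white current difference |
| `blend` $\beta$ | 0 | — | luminance context mixed into the output |
| `frame_skip` $k$ | 1 | frames | temporal stride of the encoder |
| `seq_depth` | 3 | lags | chromatic lags of the sequential strategy |

The default weights were chosen so the ages at which each channel dominates
the impulse response partition cleanly: blue owns ages 0–1, green 2–8, red 9
and older — well separated over the 1–60-frame horizon typical of
behavioral footage. They are fully configurable, and every compiled dataset
records a SHA-256 hash of the encoder configuration, so a settings change is
detected and only the motion images are rebuilt (labels, splits and static
images stay byte-identical).

Two points were genuinely open and are settled here as package conventions.
First, the sequential window: four colors (white, blue, green, red) over
"the previous three frames" can be read as three or four lags; we expose
`seq_depth` and default to three chromatic lags behind the white current
difference, i.e., differences over a five-frame window. Second, blending
happens after composition (motion color is formed first, then mixed with
luminance); blending first would dilute the chromatic tails that carry the
signal. The blend is a convex combination rather than additive so outputs
stay in $[0,1]$ without asymmetric clipping. Differencing uses luminance
only, not per-channel color differences — one difference plane matches the
single white "difference" image of the design and halves memory.

## What the synthetic scenes emulate — and what they do not

Every quantitative claim above is tested against generated scenes with
exact ground truth (`render_scene()`): discs, squares and triangles with
constant-velocity, accelerating, decelerating, turning or stationary
kinematics ($p(t) = p_0 + v_0 t + \tfrac12 a t^2$, with per-frame heading
rotation when requested); value-noise textured backgrounds, optionally with
sinusoidal per-row drift emulating swaying vegetation; additive Gaussian
pixel noise; and camouflaged targets whose pixels are a literal sub-sample
of the background at their starting footprint — pixel-identical to their
surrounds until the first movement, the camouflage premise made exact.
Sub-pixel positions are rendered with 4×4 supersampled anti-aliased masks so
slow motion still produces frame differences; ground-truth boxes are the
tight integer bounds of the coverage mask at threshold 0.5, and rendered
frames are snapped to the 8-bit grid, the representable values of ordinary
video (this also makes PNG round-trips bit-exact). All randomness flows
from the scene seed through keyed substreams, so adding an object never
perturbs another object's noise.

These scenes deliberately lack photorealism: no articulated bodies, no 3-D
projection, no illumination change, no compression artifacts. Passing tests
therefore demonstrate that the encoder and tracker logic is correct and that
the claimed kinematic signatures exist and are measurable; they do not
demonstrate detection performance on real footage, which depends on the CNN
detector that this package treats as an injectable interface.

## Dataset compilation

Annotations (per video, frame, stream, class, box) live in a JSON-lines
store; the YOLO darknet tree — parallel static/motion
`images,labels × train,val` directories with normalized
`class cx cy w h` label lines — is a compiled artifact, never the source of
truth. Train/validation assignment hashes `(seed, video, frame)` to a side
with validation probability 0.2 by default, so assignments are stable under
re-compilation and new videos never reshuffle old ones; an
`exclusive_videos` mode assigns whole videos to one side for independence
checks. Gray-box shields paint annotated regions mid-gray (0.5 exactly, the
midpoint, minimizing luminance edges against typical backgrounds) in the
written images only. With `motion_blocks_static`, every motion-labeled box
is shielded out of the static training image, and static labels under those
boxes are dropped with a warning, so the static model only learns truly
stationary appearances. Secondary-classifier crops are cut exactly at the
detection box — no padding; context-sensitive secondary models should
instead widen their annotation boxes. Warm-up motion frames (1 frame for
the exponential strategy, `seq_depth + 1` for the sequential) are emitted
black, flagged, ineligible for annotation, and excluded from compilation
with a warning, keeping the two streams index-aligned.

## Merging and tracking

Static and motion detectors routinely find the same animal. Detections in a
frame are linked when box IoU exceeds 0.5 or centroid distance falls below
0.5 of the pair's mean box diagonal; clusters are the connected components
of that rule, re-evaluated on the union boxes until the clustering is a
fixed point (so merging is idempotent by construction). Each cluster
becomes one detection with the union box; its class follows the
`dominant_source` rule (motion-dominant, static-dominant, or highest
confidence; ties break motion-first), and all member records are kept so
both streams survive into the output.

Tracks carry a constant-velocity Kalman state $(c_x, c_y, v_x, v_y)$ with
position-only measurements; heading and speed are derived from the velocity
components rather than tracked as separate states. Process noise follows
the discrete white-acceleration model scaled by `q` (default 0.01 px²/frame⁴
— trajectories of walking or flying animals are near-ballistic over a few
frames), measurement noise `r` (default 1 px², the scale of detector
centroid jitter). Box size is smoothed by a separate EMA rather than
entering the filter. The covariance is symmetrized after every update and
stays positive-definite over at least 10⁴ cycles in the tests. Association
is a Hungarian assignment on centroid distances with per-track gating
(adaptive by default: three posterior position standard deviations plus the
box diagonal); tracks confirm after 2 hits, are lost after 15 consecutive
misses, and IDs are never reused. Optional post-hoc filtering by minimum
track length suppresses short spurious tracks.

One measurement choice deserves a note: when two trajectories cross, there
are frames in which the objects are literally coincident and identity is
unobservable from positions alone — any assignment is equally valid and
updates both filters identically. Identity-swap counts are therefore
evaluated over frames where the objects are separated by more than one box
width; at the tested conditions (3 px/frame, 60° crossing, 1 px measurement
noise) identities persist across the crossing and the filtered positions
are smoother than the raw measurements.

## Numerical conventions and degenerate inputs

Frames are H×W×3 arrays in $[0,1]$, RGB order, 0-based frame indices,
pixel-coordinate boxes half-open with origin top-left. Accumulators are
never clipped (clipping happens once, at composition), so the EMA stays an
exact linear functional of the difference sequence — the test suite checks
it against the brute-force weighted sum at $10^{-9}$. Encoding is a pure
function of (frames, configuration): re-runs are bit-identical, which is
what makes rebuild detection by hash meaningful. Degenerate cases are
explicit: empty inputs and unreadable paths are errors; out-of-bounds
shield boxes are clipped with a warning; zero-area crops skip secondary
dispatch with a recorded reason; detector failures skip the frame, and a
run with more than 10% skipped frames is flagged degraded.

## Problem sizes

The bundled validation runs on 64×64 to 80×72 scenes of 10–50 frames, 100
random difference sequences for the smoothing oracle, 1,000 random
detection sets for the merge oracle, 10 seeds of the crossing scenario and
10,000 frames for split statistics — sizes at which every property above is
exercised in well under a minute on one CPU.

## Limitations

Video-codec containers (MP4/AVI) are not decoded; inputs are image-sequence
directories or multi-page TIFF stacks, and frame rate must be supplied when
the container carries none. The tracker has no appearance model: after
occlusions longer than `max_misses` an individual returns with a new ID,
and re-identification, pose, segmentation and multi-camera setups are out
of scope. The oracle detector bounds what the surrounding machinery can do
with perfect detections; real-world accuracy is set by the external CNN
plugged into the detector interface.
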