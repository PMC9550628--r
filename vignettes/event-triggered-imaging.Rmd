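---
title: "Event-triggered STED imaging: models, pipelines and simulation choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event-triggered STED imaging: models, pipelines and simulation choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etsted)
```

## The problem

Event-triggered STED (etSTED) couples two imaging modalities: a camera-based
widefield channel that continuously surveys a large field of view at tens of
milliseconds per frame, and a point-scanning STED channel that delivers
~30 nm resolution but only over a small region. The computational core —
what this package implements, entirely hardware-free — is the decision
machinery in between: real-time analysis pipelines that detect subcellular
events in each widefield frame, a polynomial coordinate transform that maps
a detected widefield coordinate into the scanner's coordinate system, and a
closed-loop controller that interrupts widefield acquisition, triggers a
small high-resolution scan at the event site, saves the evidence, and
resumes surveillance. Because the instrument itself is not required, a
ground-truth scene simulator stands in for the microscope, which makes every
stage testable against known truth.

Coordinates everywhere are `(x, y)` = (column, row), 0-based, continuous,
with the origin at the centre of the top-left pixel; frame indices are
0-based. All tabular results are tibbles.

## Detection pipelines

All three pipelines share one interface: `(current frame, carried state,
binary sample mask, parameters) -> (events, updated state)`. The state after
frame `k` is sufficient to process frame `k + 1`, so a stored timelapse
replayed frame by frame (`detect_events()`) produces exactly the event
stream the live controller would see. The sample mask is recorded by
averaging 10 frames and thresholding globally (`record_binary_mask()`).

**rapid_signal_spikes** targets sub-second intensity transients (calcium
indicator activity, pHluorin unquenching). Both the current and previous
frames are Gaussian-smoothed (`smoothing_sigma`, default 1.5 px) and
compared per pixel as a ratio `smooth(cur) / max(smooth(prev), epsilon)`; a
ratio makes the trigger threshold (default 1.5, unitless, > 1) independent
of local brightness. Pixels outside the mask, below a raw-intensity gate
(default 10 counts — where the denominator approaches the floor `epsilon`,
division noise would otherwise dominate), or within `border_px` of the frame
edge (so a triggered scan ROI always fits) are zeroed. Local maxima of the
map are found by comparing it with a maximum-filtered version of itself
(window 5 px); connected plateaus of equal value collapse deterministically
to their (row, column)-smallest pixel. Events are returned sorted by
descending ratio so a consumer taking the first takes the ratiometrically
brightest peak. A normalized-difference mode (`mode = "normdiff"`) is
available as a configuration alternative.

**dynamin_rise** targets slower (~1 s) local intensity rises from protein
recruitment. Each frame is smoothed and background-reduced (subtraction of a
wide Gaussian blur, sigma 10 px); peaks are gated by low and high intensity
thresholds (the high gate rejects large bright clusters); the mean
preprocessed intensity of a `(2a+1)^2` box (a = 2 px) around each peak is
appended to the carried per-track history, and peaks are linked frame to
frame. When a track has stayed detected for exactly `N` frames (default 5),
it is evaluated once: if its last box intensity is at least `rise_ratio`
(default 2) times its first, one event fires at the track's last
coordinate. The endpoint ratio deliberately does not require monotonicity —
frame-to-frame noise would otherwise veto genuine rises. The box intensity
is the box *mean* (an open choice; the mean is less noisy than the maximum
at these box sizes).

**vesicle_proximity** targets two vesicles approaching within the widefield
resolution. Vesicles are detected and linked per frame; a track unmatched
for more than `memory` frames closes ("disappears"). At each frame, every
track that disappeared within the last `lookback` frames is tested against
every surviving track with five Boolean conditions: the disappearance
itself; proximity of the survivor's current position to the disappeared
track's last position (within `r_prox`); recency of the disappearance;
consistent presence of both tracks (at least `presence_fraction` of the last
`window_frames` frames); and motion — at least one track must have moved a
net displacement (`d_net`, the magnitude of the summed step vectors, our
reading of "accumulated vectorial distance") *and* a path length (`d_path`,
the sum of step magnitudes, our reading of "absolute distance") above
threshold over the window. All five true fires one event at the disappeared
track's last position; a track pair can fire only once.

Two geometric facts shaped the vesicle defaults. First, two point emitters
become a single detected maximum when closer than roughly twice the
effective PSF sigma, so the disappeared track's last position is
systematically about that merge separation away from its partner —
`r_prox` (5 px = 0.5 µm at 100 nm pixels) must be wider than the optical
resolution itself. Second, the motion thresholds must separate genuine
transport from the jitter of a stationary noisy track: on the integer
detection grid a stationary track accumulates a path length of roughly half
a pixel per frame but a net displacement near 1 px, so `d_net = 4` px over a
15-frame window discriminates cleanly while tolerating a slow docking
approach (`d_path = 5`).

## Track linking

Linking is greedy: candidate track-detection pairs are sorted by distance
and matched one-to-one, links beyond `max_link_distance` rejected, unmatched
detections opening new tracks, with a `memory` of frames across which a
track may be resumed. Greedy matching (rather than globally optimal
assignment) is deterministic, cheap, and indistinguishable from optimal
assignment at the particle densities involved; it is also what common
particle-tracking software does by default. Sub-pixel refinement and global
assignment are deliberately out of scope.

## Coordinate transform

The widefield-to-scan mapping is a general third-order 2-D polynomial (10
coefficients per axis), fitted to manually matched control points by damped
least squares (Levenberg–Marquardt via minpack.lm). Source coordinates are
normalised to [-1, 1] before the monomial design is built — third-order
monomials on raw few-hundred-pixel coordinates produce condition numbers in
the 10^12 range and garbage coefficients. Because the model is linear in its
coefficients the damped fit must agree with the closed-form least-squares
solution; the test suite asserts agreement to 1e-8 relative against an
independent QR implementation. Fits require at least 10 well-spread pairs
(the model has 10 coefficients per axis); collinear designs are rejected
with advice rather than silently pseudo-inverted. Transforms serialise to
plain JSON and round-trip exactly, so a session's calibration is reusable,
and `accuracy_report()` produces the per-point error map (in nm) used to
check for spatial structure in the calibration error. On synthetic bead
fields with 0.5 px detection noise at 100 nm pixels the mean calibration
error lands in the tens of nanometres — sub-pixel, as a bead calibration
should be.

## The controller

`run_experiment()` consumes a frame source (a simulated scene or a stored
timelapse) and runs the chosen pipeline per frame. On a detection in a
triggering mode it takes the most salient event only (single-scanner
semantics), maps it through the transform, requests a scan stack from the
source's callback (centre, ROI size, pixel size, frame count — the same
contract a hardware backend would implement), stores the evidence bundle
(pre-event widefield buffer ending at the triggering frame, scan stack, both
coordinates, a timing entry), resets the pipeline state — the widefield
stream was interrupted, so frame-difference state across the gap would be
invalid — and either resumes (`endless`) or stops (`single_trigger`).
`validation` mode records events without scanning; `visualization` mode also
retains the preprocessed maps. Events whose scan ROI would leave the field
are logged and skipped (border exclusion normally precludes them). An
optional per-site refractory window exists but defaults to off, matching the
instrument's free re-arming.

Wall-clock per-stage timings are recorded as metadata in a separate sidecar
file; they are measurements of this machine, not results, and no timing is
asserted anywhere. The event log itself (JSON-lines, schema-versioned, one
self-contained record per line) is therefore bit-reproducible for a fixed
seed.

## The scene simulator

The simulator is the package's microscope. Its camera model is sCMOS-like:
expected photon counts, Poisson shot noise, additive Gaussian read noise
(sigma 2 counts), clamp at zero, round to integers. Defaults mirror the
acquisition geometry the method targets: 100 nm widefield pixels, 50 ms
frames.

* Calcium scenes multiply the local baseline inside a Gaussian footprint by
  `1 + A exp(-(t - t_on)/tau)` — instantaneous onset, exponential decay —
  so the scheduled `A` *is* the peak dF/F0 regardless of local brightness.
* Rising-signal scenes ramp a spot linearly from `I0` to `r * I0` over `M`
  frames, then hold.
* Vesicle scenes move point emitters by 2-D Brownian steps (per-axis sd
  `sqrt(2 D dt)`), with scripted approach-and-merge events that move one
  emitter onto another and then render them unresolvable.
* Bead fields scatter points uniformly and perturb their mapped positions
  with isotropic detection noise, for calibration benchmarks against a
  known ground-truth cubic.
* `render_scan_roi()` renders the same ground-truth emitters at scan
  sampling (25–30 nm pixels, 40 nm FWHM PSF) — a toy renderer sufficient
  for geometry and centring checks, with no STED photophysics.

**Benchmark conditions.** The spike benchmark (`calcium_benchmark_scene()`)
uses 200 × 200 px × 100 frames and ten spikes of amplitude `A = 1`,
`tau = 400` ms at a peak-increment-to-noise ratio of 5. "SNR" here is
defined as `A·B / sqrt(B + sigma_read^2)` — peak signal increment over the
per-pixel noise sd at baseline `B` — giving `B ≈ 28.5` counts; this is the
natural definition for a detector thresholding a frame-difference map. The
vesicle benchmark (`vesicle_merge_scene()`) uses a diffraction-limited spot
sigma of 0.8 px (0.21 λ/NA ≈ 78 nm at 100 nm pixels) and an axis-aligned
docking approach of 12 px over 21 frames (~0.5 px/frame): slow enough that
the mover's last resolvable detection lies within the peak-merge separation
of the merge site, fast enough that the motion conditions are met. These
scene parameters were chosen from the optics and kinetics above and then
frozen; the matched noise-only and independent-vesicle controls use the
same conditions with no scheduled events.

What passing these benchmarks shows — and does not. The simulator has
uniform backgrounds, stylized stationary structures and isolated Gaussian
events; real recordings add moving filopodia, heterogeneous labeling,
bleaching and out-of-focus light. High precision/recall here therefore
demonstrates the correctness of the detection machinery under controlled
conditions, not a performance claim for any particular biological
preparation, where thresholds must be re-tuned per experiment.

## Post-acquisition analysis

`dff0_trace()` extracts `F(t)` as a disc mean and reports
`(F(t) − F0)/F0`, with `F0` the mean of the first `k` frames (`k = 1`
reproduces the `F(t0)` convention); it is exactly invariant under global
gain. `evaluate_detection()` matches detections to manual annotations
greedily (closest in time, then space, one-to-one, within tolerances) and
reports the true-positive ratio (matched/detections) and the detected-events
ratio (matched/annotations); with zero detections the former is undefined
and flagged rather than silently zeroed.

The cluster pipeline follows a fixed recipe: histogram-matching bleach
correction, 1 px Gaussian smoothing, a timelapse-constant global threshold,
one 3 × 3 binary erosion, 8-connected labelling, and removal of objects at
or below 0.015 µm². Histogram matching maps each frame's rank-averaged
intensities into the reference frame's sorted intensities — monotone by
construction, exact when values are distinct, and unbiased on heavily tied
integer counts (a minimum-rank rule would drag tied pixels toward low
quantiles). Regions report area (pixel count × pixel area), aspect ratio
(square root of the second-moment eigenvalue ratio of the equivalent
ellipse, with the 1/12 single-pixel variance term so one-pixel-thin regions
stay finite), and the unweighted binary centroid. Centroids link across
frames by minimum distance with a hard 0.3 µm-per-frame limit, and the trace
seeded by the largest first-frame cluster carries the MSD flag.

`compute_msd()` defaults to the squared displacement (µm², the units in
which MSD results are reported and the form whose ensemble mean is `4 D Δt`
for 2-D Brownian motion); a `literal_distance` mode computes the unsquared
mean Euclidean distance instead, because the two readings of the written
recipe conflict and the choice should be explicit, recorded in the output
rather than buried in code.

## Numerical and degenerate-input choices

Convolutions and maximum filters use half-sample reflective boundaries
(edge darkening would fabricate ratiometric border peaks); kernels truncate
at 4 sigma and renormalise. Plateaus, tie-breaks and candidate orderings are
all resolved lexicographically so every operation is bit-deterministic.
`sigma = 0` smoothing is the identity. Constant frames yield a single
plateau representative, removed by any positive threshold. Empty detection
sets, empty event lists and trigger-free runs are all valid states, not
errors; malformed inputs (negative sigma, even windows, too-few control
points, mismatched shapes, out-of-range ROIs) raise classed conditions.
One top-level seed derives per-module substreams (`derive_seed()`), so a
single integer reproduces a whole workflow bit-identically.

Problem sizes in the test-suite benchmarks (ten 200 × 200 × 100 movies for
the spike benchmark, twenty 64 × 64 × 40 scenes per vesicle arm, 1,000
Monte-Carlo calibration replicates, 200 oracle images) were chosen to give
stable statistics at desk scale.

## Known limitations

Peak positions are integer pixels (no sub-pixel refinement), linking is
greedy rather than optimal, the STED renderer has no depletion photophysics
or 3-D sectioning, and scan-space coordinates share the widefield frame in
simulation (the transform machinery supports arbitrary cubics, but the
simulated scanner is not distorted by default). The detection-quality ratios
reported on synthetic scenes are not comparable to values measured on live
neurons.
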