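---
title: "From bone bases to joint drivers: the handmotion pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From bone bases to joint drivers: the handmotion pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(handmotion)
```

## The model

Optical marker-less hand trackers deliver, per frame, a position and an
orthonormal 3×3 basis per bone segment. Driving a musculoskeletal model
instead requires per-joint angle time series. `handmotion` computes these in
two matrix steps. For each bone, the rotation relative to the initial
posture t₀ is `R(t0,ti) = R(t0) · R(ti)ᵀ`, where the basis `R(t)` maps
global coordinates into the bone frame (rows are the bone's local axes in
global coordinates). For each joint the parent and child bones' t₀-relative
rotations are combined, `Q(i) = R_parent(t0,ti) · R_child(t0,ti)ᵀ`, and `Q`
is decomposed into Cardan angles under the fixed intrinsic X-Y-Z
factorization `Q = Rx(φ)·Ry(θ)·Rz(ψ)`.

Anatomical reading of the axes, per the joint coordinate conventions used
in hand biomechanics: X is the flexion/extension axis (φ), Y the
abduction/adduction axis (θ), Z the longitudinal bone axis (ψ, axial
rotation / pronation-supination). Positive φ is flexion toward the palm;
the local +Y axis points palmar at reference. All user-facing angles are
degrees, positions and lengths mm.

Key assumptions:

* **Neutral-zero reference.** All angles are measured from a flat
  outstretched hand in which every relative joint rotation is the identity.
  By default frame 0 of a recording is that reference; an explicit
  `reference_posture()` can override it, which is what you want for noisy
  recordings (otherwise reference noise becomes a constant bias on every
  frame — the same mechanism that produces the familiar ~10° "resting
  offset" of real sensors against video tracking).
* **Rigid bones, fixed segment lengths.** The skeleton is a tree rooted at
  the forearm; the upper arm is treated as the fixed global frame, so elbow
  angles are the forearm's rotation relative to the world.
* **Fixed Cardan axes,** not a floating/ISB Grood–Suntay axis triad: the
  matrix pipeline above implies fixed axes, and the factorization order
  (flexion extracted first) follows the axis-priority convention of the
  sensor-to-simulation tools this package emulates. The order is one
  documented constant (`cardan_matrix`) should it ever need switching.

### Why the round trip is exact, not circular

The generator composes bases as `B_child(i) = B_parent(i) · Rx(φ)Ry(θ)Rz(ψ)`
with identity reference bases. Substituting into the extraction formulas:
`S_p = B_p(i)ᵀ`, `S_c = (B_p(i)·J)ᵀ`, hence
`Q = S_p · S_cᵀ = B_p(i)ᵀ · B_p(i) · J = J` — the parent's own motion
cancels algebraically at any depth of the hierarchy. The extractor only
ever sees global bases (optionally serialized through the text recording
format first), so the round-trip acceptance test genuinely exercises the
full path: trajectory → global bases → relative rotations → Cardan
extraction → unwrap.

## Skeleton and joints

`default_skeleton()` builds 22 bones: forearm, hand (carpus/palm), and per
digit (1 = thumb … 5 = pinky) metacarpal → proximal → intermediate → distal
phalanx. Segment lengths are plausible adult values in mm (index proximal
phalanx 40 mm), scaled uniformly by `scale`; subject-specific anthropometry
beyond that uniform scale is out of scope.

The thumb anatomically lacks an intermediate phalanx. The package keeps the
uniform 4-bone chain with a **zero-length thumb metacarpal** — the same
modelling trick the sensor's internal hand model uses — so one traversal
serves all digits. Its joints are exposed with clinical aliases: CMC
(hand–MC, 3 DOF opposition), MCP (MC–PP, flexion), IP (PP–IP, flexion);
the chain's residual IP–DP joint is rigid. Degrees of freedom per joint
(the `dof` mask) gate only what the driver export writes; extraction always
computes all three angles:

```{r}
joints_of(default_skeleton())[, c("name", "child_bone", "parent_bone", "dof")]
```

The masks are a documented choice (elbow flexion + pronation/supination;
wrist flexion + deviation; finger MCPs flexion + abduction; PIP/DIP
flexion; non-thumb CMCs rigid): the published description says only that
"up to three" vectors are stored per joint, so the exact subset is a
package decision, flagged as such.

## The synthetic generator: what it emulates, what it does not

`forward_kinematics()` replaces the hardware sensor: it chains bases
parent-to-child and propagates positions distally along each bone's local Z
axis (bone long axis, pointing distally — offsets `(0,0,length)` in the
parent frame). It also records the five fingertip positions each frame, as
real trackers do; these give `compute_finger_lengths()` a measured distal
endpoint for every segment, keeping length extraction a measurement rather
than a copy of the skeleton table.

`fist_scenario()` is the validation motion — outstretched hand closing to a
fist. Peak angles per joint are **not published** for the original
experiment, so the defaults are labelled package choices: PIP reaches
`peak_flexion` (default 100°, the approximate closed-fist PIP angle
reported by video tracking), MCP 0.9×, DIP 0.7× — physiologically ordered
ratios — and the thumb gets a modest opposition ramp. Easing is cosine;
any smooth monotone ramp would satisfy the round-trip contracts, and the
midpoint of the cosine ramp (half the peak at the middle frame of an
odd-length ramp) is part of the test surface.

`add_noise()` models sensor error as an isotropic small rotation per bone
per frame (axis uniform on the sphere, angle `|N(0, σ)|`) plus Gaussian
position jitter, seeded and reproducible. This is explicitly synthetic —
the real sensor's dominant failure modes (finger/palm occlusion, the
saturation above ~80° flexion, the resting offset) are *systematic*, not
isotropic, and are out of scope. Hence a green noise test establishes
numerical robustness of the extraction, not field accuracy of any sensor.

Simulation sizes in the tests are kept at 100 frames or fewer so the whole
suite runs in well under a minute.

## File formats and numerical choices

* **Recording format**: plain text, header (frame rate, handedness, bone
  table) then per frame one line per bone (`name px py pz b11..b33`,
  row-major basis) and five `tip` lines. 17 significant digits → lossless
  round trip. Bases are re-orthonormalized on ingestion (polar
  decomposition via SVD) with tolerance 1e-3; matrices farther from
  orthonormal, singular or left-handed are rejected as degenerate.
* **BVH dialect**: root `forearm` with 6 channels (`Xposition Yposition
  Zposition Zrotation Xrotation Yrotation`), all other joints `Zrotation
  Xrotation Yrotation` — the dominant dialect among BVH tools; the
  channel↔angle mapping is fixed (X←φ, Y←θ, Z←ψ). Offsets mm, rotations
  degrees, 6 decimals; `write → read → write` is byte-identical.
  Interoperability with any specific third-party tool's hierarchy is
  best-effort, not a contract. BVH has no comment syntax, so BVH files are
  the one output without a provenance header.
* **Driver files**: `Finger1..5.any`, `Wrist.any`, `Elbow.any`,
  `TimeSeries.any`, `FingerLength.any`; grammar `Name = {v1, v2, ...};`
  with names like `Finger2.Joint_PP_IP.Flexion`. Angles are exported in
  **degrees** (the convention is documented here precisely because the
  original description is silent on units). `TimeSeries` is the evenly
  spaced 0…1 abscissa, regenerated (not sliced) after frame cutting so it
  always spans 0…1. Compatibility with the commercial simulation product's
  actual scripting syntax is not claimed.
* **Gimbal lock**: at |θ| → 90° only φ±ψ is determined; the package sets
  ψ = 0 and folds the residual into φ, deterministically. Physiological
  finger abduction stays far from 90°, and the generator rejects |θ| > 90°.
* **Unwrapping**: per-series 1D unwrap with a 180° threshold keeps the
  exported vectors continuous for B-spline driving. Consequence: a genuine
  frame-to-frame jump larger than 180° would be misread, which at
  physiological speeds and ≥ 30 Hz cannot occur.
* **Angle ranges**: φ, ψ ∈ (−180°, 180°], θ ∈ [−90°, 90°] before
  unwrapping.

## The 2D validation bridge

The accuracy-measurement method films the index finger side-on and tracks
three markers (MCP, PIP, fingertip); the PIP flexion angle is the angle
between the two segment vectors, in [0°, 180°), 0 = straight.
`project_recording()` replaces the camera with an orthographic projection
(no lens model); `angle_from_markers()` is invariant under rigid 2D motion
and uniform scaling. For planar PIP-only flexion viewed perpendicular to
the motion plane, the marker angle equals the 3D Cardan φ to 1e-6° — the
bridge that lets the two measurement paths check each other. The third
marker is taken at the fingertip (with DIP also flexed the marker angle is
then a *different*, composite quantity — which is exactly why the bridge
test uses PIP-only motion). `compare_trajectories()` aligns two series by
linear resampling onto the coarser series' time grid over the overlapping
span (start-time offsets supported) and reports per-frame difference, RMSE,
max |difference| and bias (`b − a`).

## Known limitations

* Fixed Cardan axes, not ISB floating axes; switching conventions would
  change θ/ψ for combined motions (φ for pure flexion is unaffected).
* The mean-over-frames length estimator cannot de-bias a zero-length
  segment: the measured length of the thumb metacarpal under position noise
  is |ε|, whose expectation is ≈ σ√2·√(8/π) rather than 0. All segments of
  nonzero length are recovered within 0.2 mm at σ = 0.5 mm over 100 frames.
* Metacarpal bases all originate at the hand bone's distal end (pure-Z
  chaining); the palm's transverse geometry is not modelled. This affects
  no angle and no per-segment length, only absolute finger positions.
* Occlusion and other systematic sensor artefacts are not simulated; the
  driving of joints inside any simulation product, and the hardware
  capture itself, are out of scope — the contract ends at correct files.
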