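---
title: "Validating multi-camera pose rigs with rigid test objects: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating multi-camera pose rigs with rigid test objects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The validation model

A markerless 3D capture rig is a set of calibrated cameras plus a 2D
keypoint detector; reconstruction triangulates per-camera detections into
world coordinates. `rigcheck` grades such a rig with a rigid object whose
geometry is known exactly. Rigidity gives two frame-invariant ground
truths: every pairwise keypoint distance, and every angle between direction
vectors within the body. The package's primary accuracy proxy is the
**inter-keypoint distance error**
$e_{ij}(t) = \lVert \hat p_i(t) - \hat p_j(t) \rVert - d_{ij}$, decomposed
per pair into *bias* (mean of $e_{ij}$ over frames: a systematic offset
between the expected and true distance) and *variance* (sample variance,
$n-1$ denominator, of the repeated distance measures: reconstruction
noise). For subjects with no ground truth, a camera subset is instead
scored by its **deviation from reference** — the per-frame Euclidean
distance between its estimate and the full-rig estimate of the same
keypoint. The deviation of the full rig from itself is identically zero,
which doubles as a pipeline self-check.

Assumptions worth stating: the object is perfectly rigid and its keypoints
are identifiable in every view (the letters on the physical object exist
precisely to give each rod a unique identity); calibration and detection
errors are the only error sources modeled; the detector's output is a
pixel location with a confidence, nothing more.

## Camera model and reconstruction

Cameras follow the standard pinhole model with a 5-coefficient
radial-tangential distortion `(k1, k2, p1, p2, k3)`. The world frame has
its origin at the arena-floor centre, +z up; extrinsics are stored
world-to-camera (`X_cam = R X + t`), serialized as Rodrigues 3-vectors in
calibration files and kept as matrices in memory; the image origin is the
top-left corner with v down, pixel coordinates continuous, no half-pixel
offset on I/O. These conventions are pinned by tests because upstream
tools disagree silently about them.

Triangulation undistorts each observation to normalized coordinates by
fixed-point inversion of the distortion polynomial (tolerance `1e-14` in
normalized units, iteration cap 200, verified through the forward map on
non-convergence), then solves the homogeneous DLT system by SVD, then
polishes the point by Gauss-Newton on the *pixel* reprojection residuals
with an analytic Jacobian and backtracking line search. Only improving
steps are accepted, so the refined reprojection RMS can never exceed the
linear solution's — an invariant the test suite asserts. Degeneracy
(coincident centres, parallel rays) is detected through the ratio of the
DLT system's singular values (`1e-10` relative).

Resectioning estimates a camera from 3D–2D correspondences (at least 6,
not coplanar — coplanarity is checked via the singular values of the
centered points). With known intrinsics the DLT runs in normalized
coordinates and only the pose is recovered (nearest orthonormal matrix by
SVD, cheirality fixed by majority positive depth), then polished by a
6-parameter Gauss-Newton. Without intrinsics the full projection matrix is
estimated with Hartley normalization on both sides and RQ-decomposed into
intrinsics and pose; distortion is taken as zero at that stage, matching
how checkerboard-style calibration separates the problems. Rig refinement
(`refine_rig()`) polishes extrinsics only, camera by camera — with fixed
world points the cameras decouple, and intrinsic re-estimation from the
same correspondences is the resectioning DLT's job, not the polisher's.

## The simulator: what it emulates, and what it does not

The simulator replaces three physical components: the arena (geometry),
the object's handling (trajectory), and the neural-network detector
(noise). The rig layout mirrors a surround-view mouse arena: `n` ring
cameras at equal azimuth spacing aimed at the arena centre plus one camera
below the transparent floor. Presets: *small* (89 mm arena) and *large*
(320 mm arena, cameras 340 mm from the centre — the latter figure is the
published layout; the small preset's 120 mm ring radius is this package's
choice: the 44.5 mm arena radius plus a realistic lens standoff). The
sensor template is a 1280 × 800 global-shutter sensor behind a 2.4 mm lens;
the focal length in pixels (800) assumes a 3 µm pixel pitch, which is
exposed as a parameter because only relative geometry matters for the
validation properties.

Trajectories rotate the object at `rotation_rate` (default 2°/frame at
30 fps — slow, smooth handling) about a slowly precessing axis while the
centre follows a bounded sum-of-harmonics excursion (default amplitude
10 mm). Both are reproducible from a seed; one global seed expands into
independent per-stage seeds so the dropout pattern does not shift when
only the noise level changes.

The detector stand-in is statistical: isotropic Gaussian pixel jitter
(default 1 px), per-(camera, keypoint, frame) dropout (default 0.02) as
the occlusion proxy, and optional gross outliers. Points projecting behind
a camera or outside the image bounds are missing by contract — never
encoded as (0, 0). The `mouse_like_preset()` captures the one asymmetry
that matters for surround rigs: ventral keypoints (paws) are poorly seen
from the side. It raises side-camera dropout on paw keypoints to 0.5
(bottom: 0.05) and gives the surviving side-view paw detections a 0.15
gross-mislocalisation probability (σ = 40 px), because occlusion makes real
detectors both miss and mis-place; these rates were fixed from the
qualitative description of the phenomenon, before any test was run against
them.

What the simulator does **not** model — and therefore what passing tests
do not show about real data: geometric self-occlusion (dropout is
independent across frames, real occlusion is temporally correlated),
detector appearance errors (left/right paw swaps, systematic biases toward
high-contrast edges), rolling-shutter and synchronization artifacts, and
calibration error itself (the simulator's rig is exact unless you perturb
it). Absolute error magnitudes from the simulator are therefore lower
bounds with respect to a real rig; the *orderings* the package tests
(more cameras better; bottom camera critical for ventral keypoints) are
the transferable findings.

## Statistics

- **Boxplot summaries** use quartiles by linear interpolation between
  order statistics (the `type = 7` definition) — no convention was
  inherited, so the choice is pinned by a brute-force sorting oracle in
  the tests. Whiskers sit at `Q1 − 1.5·IQR` and `Q3 + 1.5·IQR`, clipped to
  the most extreme data values inside the fences; values beyond are
  counted as outliers and excluded from whisker placement.
- **Error vs image centre**: each error record is paired with the pixel
  distance between the observation midpoint and the principal point,
  averaged over the views that saw the keypoint(s); a single-worst-view
  covariate is available behind a switch. Association is measured by
  Spearman rank correlation (tie-averaged ranks, large-sample normal
  p-value), and records beyond a configurable 486 px field border are
  flagged.
- **Configuration ANOVA**: absolute deviation is modeled on camera number
  and bottom-camera inclusion with interaction, type-II sums of squares
  (fitted via `car::Anova`; the type is this package's choice and is
  cross-checked in the tests against a nested-residual-sum-of-squares
  oracle). When the design has empty cells — unavoidable once the
  full-rig class is included, since four cameras always include the bottom
  one — the interaction is dropped with a warning and main effects are
  reported. Tukey HSD over symmetry classes provides the pairwise
  comparisons.

Camera subsets are grouped into **symmetry classes** keyed by
(number of ring cameras, bottom present), because equally spaced ring
cameras are geometrically interchangeable; per-instance results are kept
so asymmetric rigs degrade gracefully. A 3-ring + bottom rig yields 11
subsets of size ≥ 2 in 5 classes: `2s`, `1s+b`, `3s`, `2s+b` and the full
rig `3s+b`. (Texts sometimes describe "nine" proper sub-configurations of
such a rig; the enumeration gives ten of size 2–3, and all ten are
retained here.) Frames where a keypoint has fewer than `min_views` usable
detections are excluded from the statistics and surfaced as a coverage
fraction rather than imputed. Signed errors are kept alongside absolute
ones so bias remains estimable while boxplots use magnitudes.

## Numerical and design choices

- Confidence threshold at triangulation defaults to 0.5 — arbitrary but
  pinned, logged, and overridable.
- RANSAC over view subsets is not applied by default: robust view
  selection changes which errors the statistics see, and nothing in the
  validated workflow requires it; the refinement's backtracking already
  rejects worsening steps.
- The default XYZ object uses 40 mm rods, fully overridable via JSON —
  geometry is an input, not a result. The *unlabeled* rod-tip set retains
  a 3-fold rotational symmetry about (1, 1, 1); the letter identities
  (keypoint names) break it, which `object_symmetries()` makes explicit:
  24 axis-aligned proper rotations are enumerated and only the identity
  maps every named keypoint onto itself.
- The median temporal 2D filter (window 3) fills the filtering slot for
  before/after comparisons; it is deliberately simple, as filtering is not
  where this package's claims live.
- A rod tip may leave a single camera's field of view during rotation;
  that detection is missing by contract and the frame remains valid as
  long as two views survive.

## Problem sizes

The bundled checks run at sizes chosen to make the Monte-Carlo conclusions
stable while staying desk-sized: 200 frames for the noiseless
end-to-end identity (errors at machine precision, asserted < 1e-6 mm);
10 seeds × 60 frames for the camera-count ordering and 10 seeds × 50
frames for the bottom-camera effect (each required in ≥ 9 of 10 seeds);
100 simulations for ANOVA type-I calibration (n = 500 per cell) and for
the planted 10 mm shift power check (required detected in ≥ 95 of 100).
The acceptance script uses 100-frame sessions.

## Known limitations

Fisheye and omnidirectional lens models are out of scope (the
radial-tangential polynomial covers moderate wide-angle lenses, not
180°-class optics). ChArUco corner detection in images is out of scope —
point correspondences are the calibration entry point. The simulator's
confidence law is deliberately crude (binary by default); detector
confidence calibration is a research topic of its own. The mouse-like
preset is a rigid stand-in: articulated kinematics, and therefore
pose-dependent occlusion, are not modeled.
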