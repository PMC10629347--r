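# rigcheck

Validation of multi-camera 3D animal-pose capture rigs with rigid test
objects of known geometry.

## The problem

Markerless 3D pose estimation for laboratory animals (mice in particular)
runs a 2D keypoint detector on synchronized multi-camera video and
triangulates the detections into 3D. The usual quality figure — 2D
reprojection error — can hide real 3D failure modes: a rig can reproject
well while systematically mis-placing points in depth. A direct 3D check is
to film a rigid object whose geometry is known exactly: three perpendicular
rods of equal length meeting at an origin, one letter (X, Y, Z) at each rod
tip so every keypoint has a unique visual identity. Because the object is
rigid, two quantities are known for every frame regardless of its pose:

- **inter-keypoint distances** — for keypoints $i, j$ with reconstructed
  positions $\hat{p}_i, \hat{p}_j$ and true object-frame distance $d_{ij}$,
  the error $e_{ij} = \lVert \hat{p}_i - \hat{p}_j \rVert - d_{ij}$ should
  be zero. Its mean over frames is the **bias**, the variance of the
  repeated distance measures the **precision**;
- **inter-rod angles** — rigid motion preserves angles between direction
  vectors within the body (90° between the rods here).

For live animals, where no ground truth exists, the full-rig reconstruction
serves as the standard and each camera subset is scored by its
**deviation from reference**: the per-frame, per-keypoint Euclidean distance
to the full-rig estimate.

`rigcheck` implements this validation method end to end for a surround-view
rig (ring cameras at equal azimuths plus one camera under a transparent
floor), together with a seeded simulator that stands in for the physical
arena and the neural-network detector, so every statistic can be exercised
and calibrated against known ground truth.

## What is inside

- **Camera geometry** — pinhole model with 5-coefficient radial-tangential
  distortion, multi-view DLT triangulation on undistorted rays with
  Gauss-Newton reprojection refinement, DLT resectioning (pose-only or full
  projection-matrix with RQ decomposition), and rig refinement from 3D-2D
  correspondences.
- **Test object** — parametric perpendicular-rod XYZ object
  (`make_xyz_object()`), ground-truth distance/angle queries, JSON
  serialization.
- **Simulator** — arena presets (small: 89 mm arena, large: 320 mm arena
  with cameras 340 mm out), smooth seeded rigid trajectories, and a
  detector noise model: Gaussian pixel jitter, per-(camera, keypoint)
  dropout as the occlusion proxy, gross-outlier mislocalisation, and a
  mouse-like preset in which ventral keypoints are poorly visible from the
  ring cameras.
- **Evaluation** — camera-subset enumeration with symmetry classes
  (interchangeable ring cameras pooled), inter-keypoint/deviation/angle
  error tables, bias/variance, boxplot summaries with 1.5 IQR whiskers,
  Spearman correlation of error against distance from the image centre,
  and a two-way (camera number × bottom-camera) type-II ANOVA with Tukey
  HSD post hoc comparisons.
- **I/O and CLI** — Anipose-dialect calibration TOML, DeepLabCut-style
  detection CSV, wide 3D CSV, report JSON, and a
  `simulate / triangulate / evaluate / report` command line
  (`inst/scripts/rigcheck`).

## Worked example

```r
library(rigcheck)

sim <- simulate_session(layout = arena_preset("small"),
                        spec = make_xyz_object(),   # 40 mm rods
                        n_frames = 100,
                        noise = noise_model(pixel_sigma = 1, p_miss = 0.02),
                        seed = 1)
report <- run_validation(sim$rig, sim$detections, sim$spec)
print(report)
```

```
<validation_report> 5 symmetry classes
  2s     n=1646   median |interkeypoint error| = 0.1368 mm
  1s+b   n=573    median |interkeypoint error| = 0.1006 mm
  3s     n=600    median |interkeypoint error| = 0.1069 mm
  2s+b   n=1740   median |interkeypoint error| = 0.09699 mm
  3s+b   n=600    median |interkeypoint error| = 0.0767 mm
  Spearman error vs image centre: rho=0.087 p=0.034 (n=600)
  ANOVA: F(camera number)=192 F(configuration)=98.3 F(interaction)=115
```

Reading this: each row is a camera-configuration symmetry class — `2s` is
any two ring ("side") cameras, `1s+b` one ring camera plus the bottom
camera, and so on up to the full rig `3s+b`. The median absolute
inter-keypoint distance error falls as cameras are added
(0.13 mm for two cameras → 0.08 mm for four at 1 px detector noise), the
error is nearly flat with distance from the image centre (small rho), and
the ANOVA on deviation-from-reference confirms camera number and bottom
inclusion both matter. With the mouse-like visibility preset, dropping the
bottom camera roughly triples the median deviation relative to dropping one
ring camera — the bottom view carries the ventral keypoints.

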