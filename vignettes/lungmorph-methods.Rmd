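---
title: "Methods: segmentation, local thickness and interface curvature for 3D lung tomograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation, local thickness and interface curvature for 3D lung tomograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and data model

`lungmorph` quantifies lung parenchyma in high-resolution 3D tomograms of
intact lungs: how big the airspaces are (local air-volume thickness) and how
the air-to-tissue interface is shaped (principal-curvature statistics). It
assumes reconstructed grayscale volumes with isotropic voxel spacing in
micrometres, in which tissue is bright and air dark; typical inputs are
synchrotron phase-contrast tomograms at effective pixel sizes around 1.1 or
2.9 µm, acquired at low dose so that the thin interalveolar septa are barely
above the background. All arrays are `(z, y, x)`; all physical quantities
are micrometres. Anisotropic spacing is rejected rather than resampled.

# Segmentation

Low-dose region-of-interest tomography produces two artifacts that defeat a
single global threshold: a smooth illumination gradient across each slice
(the sample extends beyond the field of view), and septa whose contrast is
a small fraction of bulk-tissue contrast. The pipeline in `segment_volume()`
runs, in order:

1. **Background-plane correction** (`correct_background`). Each slice is
   grayscale-eroded with a disk (default radius 20 px), which replaces every
   pixel by the darkest value in its neighbourhood and so erases structures
   thinner than the disk; what survives approximates the air background plus
   the illumination plane. Pixels outside the 5th–95th percentile of the
   eroded slice are masked out as histogram extremes, the border band where
   the disk does not fit is excluded (truncated disks bias the slope), and a
   plane $a x + b y + c$ is least-squares fitted with one robust
   reweighting pass (texture contamination of the eroded image is one-sided).
   Only the gradient $a x + b y$ is subtracted; the offset $c$ is kept so
   gray values stay comparable across slices.
2. **Otsu threshold estimation** (`otsu_threshold`): one global threshold
   per volume, maximising between-class variance over a 256-bin histogram,
   ties broken toward the lower bin. The value is stored and reused after
   ridging, so ridge marking cannot shift the threshold.
3. **Ridge enhancement** (`ridge_enhance`). Line profiles are scanned along
   0°, 45°, 90° and 135° within each slice (diagonals sampled along array
   diagonals, step $\sqrt2$ px, without resampling). For each local maximum
   the flanking minima are found; the *prominence* is the peak height above
   the higher flank and the *width* is the contiguous run of samples
   exceeding that flank by at least `min_margin`. Runs with width in
   `[min_width, max_width]` (default 1–4 px) and prominence in
   `[min_margin, max_margin]` (default 50 gray units and effectively
   unbounded above) are set to the volume maximum, so detected septa always
   survive the threshold. `max_margin` exists as an upper prominence cutoff
   for very bright vessel-like lines. These two margins and widths are the
   parameters a user is expected to vary; they directly trade septal recall
   against false ridge marks.
4. **Thresholding** with the stored Otsu value; **isolated-voxel removal**
   (a tissue voxel with no tissue voxel among its 26 neighbours is always an
   artifact, because real septa are connected to surrounding tissue); and a
   **3D connected-component filter** (26-connectivity, default minimum
   27 voxels — a one-voxel cube at the smallest plausible septal-junction
   scale). Both cleanup steps are anti-extensive and idempotent.

`segmentation_ensemble()` reruns the pipeline over a list of parameter
variants; every downstream density and range fraction can then be reported
as mean ± sample standard deviation across variants, which is how
segmentation uncertainty is propagated into all quantitative results.

# Local air-volume thickness

The local thickness of a point $p$ in a phase $\Omega$ is the diameter of
the largest sphere that contains $p$ and fits entirely inside $\Omega$ —
the maximum-inscribed-sphere measure commonly used for trabecular bone,
applied here with the **air** as the measured object. The implementation
(`local_thickness`) computes an exact Euclidean distance transform, assigns
every air voxel the largest admissible sphere radius (its distance to the
nearest non-air voxel centre minus half a voxel), removes redundant sphere
centres, and stamps the surviving spheres, largest first.

Numerical conventions worth stating:

* **Voxel-sphere convention.** A sphere of radius $r$ at centre $x$ contains
  voxel $v$ iff $|c(v) - x| \le r$; the volume boundary counts as the
  opposite phase. A single isolated air voxel therefore has
  $\tau = \text{spacing}$.
* **Exactness.** A centre is removed only when its sphere is provably
  contained in another single sphere (checked first in a 5×5×5 window, then
  against already-stamped spheres through a running coverage-depth map), and
  containment is transitive with strictly increasing radii, so the surviving
  set still attains the brute-force maximum at every voxel.
  `brute_force_thickness()` evaluates the definition literally (quadratic
  cost, guarded to ~10^5 phase voxels) and the test suite asserts voxelwise
  equality on random volumes — the map is not an approximation.
* **Density estimation.** `thickness_density()` uses a Gaussian KDE with a
  Sheather–Jones plug-in bandwidth on a deterministic sorted-stride
  subsample (the selector is quadratic in n), evaluated on a fixed 512-point
  grid over the analysis band and renormalised there. Because $\tau$ values
  are quantized by the voxel lattice, the bandwidth is floored at one voxel
  spacing; without the floor the selector resolves individual lattice atoms
  and the density degenerates into spikes.
* **Analysis band.** Default floor 20 µm (below the smallest plausible
  alveolar diameter) and cap 170 µm (large airspaces drift in and out of
  small fields of view and would bias comparisons across inflation states).
  `range_fractions()` integrates the voxel population over 20–50, 50–80,
  80–110 and ≥110 µm by default.

# Interface curvature

`extract_surface()` extracts the air–tissue interface at level ½ of the air
indicator by marching over the Freudenthal (six-tetrahedra) subdivision of
the voxel lattice. This subdivision is translation-invariant, so the mesh is
edge-manifold by construction without case tables; every vertex lies at a
lattice-edge midpoint and triangles are wound so normals point from air into
tissue. The marching is restricted to cells between existing voxels: air
touching the volume border produces an open mesh there rather than an
artificial cap, and the curvature step later excludes any vertex whose
neighbourhood touches such a boundary. One consequence of tetrahedral
marching on binary data is a zigzag surface whose raw area overestimates a
sphere's analytic area by roughly a quarter; after the standard smoothing
step below the area is within a fraction of a percent, which is why area
assertions in the tests are made on smoothed meshes.

`smooth_mesh()` applies plain umbrella-operator Laplacian smoothing
(default 20 iterations, step 0.5): each vertex moves toward the centroid of
its neighbours. This removes single-voxel staircase noise; it also shrinks
closed surfaces slightly (well under 5 % enclosed volume at the defaults,
recorded in the mesh metadata rather than corrected).

`normal_cycle_curvature()` estimates the curvature tensor per vertex from
the theory of normal cycles: every mesh edge inside the geodesic ball
$B(v, R)$ contributes its signed dihedral angle times its length inside the
ball times the outer product of its direction; the sum is divided by the
barycentric area of the ball and restricted to the tangent plane, whose two
eigenvalues are reported as $\kappa_1 \le \kappa_2$. Geodesic distances are
Dijkstra shortest paths over the edge graph (not exact polyhedral
geodesics), which is standard and adequate at the neighbourhood sizes used.
The radius $R$ (micrometres; default 3.5, with 15 as the coarse preset) is
the resolution knob of the whole analysis: small radii resolve septal edges
and dimples, large radii absorb small deviations into the surrounding shape
class, which is what makes alveolar surfaces appear as coherent convex
patches. Mean and Gaussian curvature are derived as
$H = (\kappa_1+\kappa_2)/2$, $K = \kappa_1\kappa_2$;
`principal_from_HK()` inverts the pair with
$\kappa_{1,2} = H \mp \sqrt{H^2 - K}$, clamping negative discriminants
(possible only when H and K are estimated independently) to zero and
counting the clamps. Under the air-to-tissue orientation an air pocket
(alveolus surrogate) has $\kappa_1, \kappa_2 > 0$ (ISD region 1), tissue
spheres are negative (region 4), saddles split into regions 2/3 by
comparing $|\kappa_1|$ with $\kappa_2$ (ties to region 2; exact zeros are
tied to the adjacent region, flat points upward to region 1).

Interface shape distributions (`isd_density`) are 2D Gaussian KDEs of
$(\kappa_1, \kappa_2)$ over the included vertices on a 256×256 grid with a
diagonal plug-in bandwidth matrix; the unreachable half-plane above the
$\kappa_1 = \kappa_2$ diagonal is zeroed and the estimate renormalised. For
very large meshes the tensor can be computed on a regular vertex stride,
which leaves distributions unchanged at a fraction of the cost. When
densities are compared **across** segmentation variants, a common
evaluation window and a common bandwidth must be used (both exposed as
arguments); letting each variant pick its own plug-in bandwidth confounds
the comparison, especially near the flat-surface spike.

# The foam phantom

Because no reference scans ship with the package, `generate_foam()` builds
parenchyma surrogates with known ground truth, and `render_image()` adds
the imaging artifacts the segmentation must overcome (per-slice linear
background plane, Gaussian blur in micrometres, additive Gaussian noise;
all deterministic given seeds). The geometry is a Voronoi-type foam with
three deliberate departures from the textbook tessellation, each mirroring
real parenchyma:

* **Curved walls.** Seeds carry multiplicative weights drawn from
  $[1, 1.8]$; cell boundaries under the weighted distance are spherical
  caps, so septa bow like real interalveolar walls. A plane-faced foam
  pins the ISD peak at zero curvature, where it cannot respond to
  inflation.
* **Rounded junctions.** The air phase is morphologically opened with a
  ball (the *fillet radius*), rounding the wedges where several walls
  meet, as real septal junctions are. Without the fillet the voxel-weighted
  thickness density is monotone-decreasing (wedge corners contribute
  arbitrarily small inscribed spheres) and its truncated mode sits
  immovably at the analysis floor.
* **A border tissue shell** stands in for pleura/vessel-scale bulk tissue
  and anchors the Otsu threshold the way bright anatomy does in real
  slices.

Alveolar ducts are mimicked by opening the shared wall of a fraction of
adjacent cell pairs. `inflate()` rescales the seed geometry (and the
fillet) about the volume centre while keeping wall thickness and the field
of view fixed — airspaces grow, septa thin out relatively, and part of the
foam leaves the crop, exactly as a region of interest inside an inflating
lung behaves. It is a geometric surrogate, not a mechanical tissue model.

Two canned study conditions (`study_phantom_spec`) emulate the two optics
the package targets: a high-resolution condition (1.1 µm pixels, 96³
voxels, 10 cells of ≈55 µm, 2-voxel septa, 6.6 µm fillet) used for
segmentation and curvature work, and a lower-resolution condition (2.9 µm
pixels, 150 cells, single-voxel septa, 13 µm fillet) whose larger cell
count gives stable airspace statistics. Default artifact levels
(tissue/air contrast 100 gray units, plane gradient (1, 0.6, 0) per slice,
blur σ = 1.4 µm, noise σ = 5) were fixed once so that plain Otsu
thresholding of the raw render loses a substantial part of the septal
voxels — the failure mode the pipeline exists to repair — while the full
pipeline recovers them.

What passing phantom tests does **not** show: the foam has no acinar
airway tree, no phase-contrast fringe artifacts, no reconstruction rings,
and its noise is Gaussian rather than the residual texture of a
phase-retrieved low-projection reconstruction. Results on real tomograms
depend on artifact levels the phantom only approximates.

# Registration and dose

Volumes acquired at different inflation pressures are aligned with a
landmark-based rigid (Euclidean) transform: the orthogonal Procrustes
problem solved by SVD with determinant sign-correction (no scaling, no
reflection), followed by resampling into the fixed frame with trilinear
interpolation for gray data and nearest-neighbour for masks (no fractional
labels), cropped to a common output shape. `entrance_dose()` evaluates the
synchrotron entrance-dose formula
$D = 1.602\times10^{-4}\, I_0\, h\nu / (\mu^{-1} \rho)$ verbatim on its
printed unit scale (photons/µm², eV, µm, g/cm³) with no unit conversion.

# Problem sizes and determinism

All shipped tests and the acceptance script run at desk scale: 24³ volumes
for brute-force oracle equality, 52–64³ analytic shapes, 96³ phantoms for
segmentation and trend recovery, 80³ for the nine-variant ensemble, with
curvature sampled on vertex strides of 4–6 for the largest meshes. These
sizes were chosen so the full chain reruns in minutes while every statistic
keeps enough voxels/vertices to be stable; the same code runs unchanged on
full reconstructions. Every stochastic step (seed placement, weights, duct
choice, noise) is a pure function of explicit integer seeds, and ensemble
variants are deterministic given their parameters.

# Known limitations

* The thickness map is exact but the measure itself saturates at the field
  of view: airspaces cut by the crop are reported smaller, which is why the
  analysis band is capped and why whole-distribution statistics shift less
  than interior cells under inflation.
* Ridge enhancement is 2D (within slices), matching how the pipeline is
  defined; septa exactly parallel to the slice plane are found only via
  their in-plane cross-sections.
* Umbrella smoothing is not volume-preserving; the induced curvature bias
  at the defaults is below the estimator's discretisation error.
* The saddle split between ISD regions 2 and 3 and the prominence-based
  ridge acceptance rule are concrete choices where the underlying
  procedures are usually left informal; both are documented above and
  exposed as parameters.
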