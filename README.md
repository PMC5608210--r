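# lungmorph

Quantitative morphometry of high-resolution 3D lung images in R.

Modern tomographic microscopy resolves intact lung parenchyma down to the
alveolar scale, but low-dose acquisitions leave the thin interalveolar
septa (often a single voxel wide) barely above the background and overlaid
with a smooth illumination gradient from region-of-interest tomography. A
single global threshold therefore destroys exactly the structures a
morphometric analysis needs. `lungmorph` provides the full chain from such
gray volumes to quantitative descriptors of lung inflation, for
researchers analysing phase-contrast micro-CT of lungs (or any comparable
two-phase foam-like material):

* **Septa-preserving segmentation** — per-slice background-plane
  correction (grayscale erosion, histogram-extreme masking, least-squares
  plane fit), global Otsu threshold estimation, line-profile ridge
  enhancement in four directions that rescues thin bright septa,
  isolated-voxel removal and 3D connected-component cleanup; plus an
  ensemble runner that sweeps the user-facing parameters to quantify
  segmentation uncertainty.
* **Local air-volume thickness** — for every air voxel, the diameter
  τ(p) = 2·max{ r : p ∈ sph(x, r) ⊆ Ω } of the largest sphere containing
  it that fits in the airspace (maximum inscribed sphere), computed
  exactly via distance transform, ridge extraction and sphere propagation,
  with a brute-force oracle, Gaussian-KDE distributions (plug-in
  bandwidth) and volumetric range fractions over 20–50, 50–80, 80–110 and
  ≥110 µm.
* **Interface curvature** — isosurface extraction of the air–tissue
  interface, Laplacian smoothing, normal-cycle curvature tensors averaged
  over geodesic neighbourhoods giving per-vertex principal curvatures
  κ₁ ≤ κ₂ (with H = (κ₁+κ₂)/2, K = κ₁κ₂ and
  κ₁,₂ = H ∓ √(H²−K)), interface shape distributions (ISD) over
  (κ₁, κ₂), region classification (convex / saddle / concave), and
  back-mapping of vertex labels onto the voxel lattice.
* **Rigid registration** of volumes acquired at different
  peak-inspiratory pressures (landmark Procrustes, SVD with sign
  correction), an entrance-dose utility, and a **synthetic alveolar-foam
  phantom** (weighted Voronoi cells with curved walls, rounded junctions,
  duct openings, border shell, rendered with gradient/blur/noise
  artifacts) so the whole chain is testable without synchrotron data.

## Worked example

Segment a rendered phantom with known ground truth, then measure airspace
sizes and interface shapes:

```r
library(lungmorph)

truth <- generate_foam(study_phantom_spec("high"))     # 96^3, 1.1 um pixels
vol   <- render_image(truth, imaging_params(seed = 11))
mask  <- segment_volume(vol)                           # full pipeline

dice <- 2 * sum(mask$data & truth$mask$data) /
  (sum(mask$data) + sum(truth$mask$data))
cat(sprintf("Dice vs ground truth: %.3f\n", dice))
#> Dice vs ground truth: 0.980

tmap <- local_thickness(mask, phase = "air")           # tau in um
range_fractions(tmap)
#>    lo  hi fraction
#> 1  20  50      100
#> 2  50  80        0
#> 3  80 110        0
#> 4 110 Inf        0

mesh  <- smooth_mesh(extract_surface(mask), iterations = 20, step = 0.5)
field <- normal_cycle_curvature(mesh, geodesic_radius = 3.5, stride = 4)
lab   <- classify_regions(field)
cat(sprintf("median kappa1/kappa2 [1/um]: %.4f / %.4f; region-1 fraction: %.2f\n",
            median(field$kappa1[field$included]),
            median(field$kappa2[field$included]),
            mean(lab[field$included] == 1)))
#> median kappa1/kappa2 [1/um]: 0.0001 / 0.0561; region-1 fraction: 0.52
```

Reading the output: the segmentation recovers 98 % (Dice) of the phantom's
tissue despite the illumination gradient and the low septal contrast; all
airspaces of this condition fall in the 20–50 µm band (they are ≈35 µm
across, and `inflate()` shifts them toward 50–80 µm); and the interface is
dominated by flat-to-gently-convex patches — the median κ₂ of 0.056 µm⁻¹
corresponds to a radius of ≈18 µm, the curved septal caps and junction
fillets of this foam. On an inflated phantom the same statistics move
toward larger thicknesses and smaller curvatures.

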