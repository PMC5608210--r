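# Synthetic alveolar-foam phantoms.
#
# The parenchyma surrogate is a Voronoi tessellation of uniformly sampled
# seed points: cell interiors are airspaces, and voxels whose two nearest
# seeds are nearly equidistant (gap <= wall_thickness) form the thin septal
# walls shared between neighbouring cells. A fraction of adjacent cell pairs
# has the shared wall opened, mimicking alveolar ducts. The rendered image
# adds the acquisition artifacts the segmentation pipeline must overcome:
# a per-slice linear background gradient (region-of-interest tomography),
# Gaussian blur and additive Gaussian noise.

#' Phantom geometry specification
#'
#' @param shape volume dimensions `(z, y, x)` in voxels.
#' @param spacing voxel edge length, micrometres.
#' @param n_cells number of foam cells (>= 1).
#' @param wall_thickness septal wall thickness, micrometres (>= spacing).
#' @param duct_fraction fraction of adjacent cell pairs whose shared wall is
#'   opened into a duct-like channel, in `[0, 1)`.
#' @param shell_thickness thickness of the tissue shell at the volume border,
#'   micrometres; emulates pleura/vessel-like bulk tissue. Defaults to twice
#'   the wall thickness.
#' @param weight_spread spread of the multiplicative cell weights: each
#'   seed gets a weight drawn uniformly from `[1, 1 + weight_spread]`.
#'   Unequal weights bow the shared walls into spherical caps (curved,
#'   alveolus-like septa); 0 gives the classic plane-faced Voronoi foam.
#' @param fillet_radius junction-fillet radius, micrometres: the air phase
#'   is morphologically opened with a ball of this radius, rounding the
#'   sharp wedges where several walls meet (real interalveolar junctions
#'   are thickened and rounded). 0 disables. The fillet scales with
#'   [inflate()], like every other length in the geometry.
#' @param seed integer RNG seed; all phantom operations are deterministic
#'   given the spec.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape, spacing, n_cells, wall_thickness,
                         duct_fraction = 0.1,
                         shell_thickness = 2 * wall_thickness,
                         weight_spread = 0, fillet_radius = 0, seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 4L))
    stop("`shape` must be three dimensions of at least 4 voxels")
  spacing <- check_spacing(spacing)
  if (n_cells < 1) stop("`n_cells` must be >= 1")
  if (wall_thickness < spacing) stop("`wall_thickness` must be >= spacing")
  if (duct_fraction < 0 || duct_fraction >= 1)
    stop("`duct_fraction` must be in [0, 1)")
  structure(list(shape = shape, spacing = spacing, n_cells = as.integer(n_cells),
                 wall_thickness = wall_thickness,
                 duct_fraction = duct_fraction,
                 shell_thickness = shell_thickness,
                 weight_spread = weight_spread,
                 fillet_radius = fillet_radius, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Imaging-artifact parameters for phantom rendering
#'
#' @param gray_air,gray_tissue native gray values of the two phases
#'   (`gray_tissue > gray_air`).
#' @param gradient plane coefficients `(a, b, c)`: every slice receives the
#'   additive background `a*x + b*y + c` (x, y are 0-based pixel indices),
#'   emulating the local-tomography illumination gradient.
#' @param blur_sigma Gaussian blur sigma in micrometres (>= 0); converts to
#'   pixels via the voxel spacing.
#' @param noise_sigma additive Gaussian noise sigma in gray units (>= 0).
#' @param seed integer RNG seed for the noise.
#' @return An object of class `imaging_params`.
#' @export
imaging_params <- function(gray_air = 60, gray_tissue = 160,
                           gradient = c(1, 0.6, 0), blur_sigma = 1.4,
                           noise_sigma = 5, seed = 1L) {
  if (gray_tissue <= gray_air) stop("`gray_tissue` must exceed `gray_air`")
  if (blur_sigma < 0 || noise_sigma < 0)
    stop("blur_sigma and noise_sigma must be >= 0")
  if (length(gradient) != 3L) stop("`gradient` must be (a, b, c)")
  structure(list(gray_air = gray_air, gray_tissue = gray_tissue,
                 gradient = as.numeric(gradient), blur_sigma = blur_sigma,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "imaging_params")
}

# binary opening of a phase with a Euclidean ball (radius in voxels)
open_phase <- function(phase, radius_vox) {
  dims <- dim(phase)
  core <- array(.sq_edt_cpp(phase, dims, TRUE) > radius_vox^2, dims)
  if (!any(core)) return(array(FALSE, dims))
  d2 <- .sq_edt_cpp(!core, dims, FALSE)
  array(d2 <= radius_vox^2, dims)
}

foam_from_seeds <- function(spec, seeds, weights, duct_pairs,
                            fillet_um = spec$fillet_radius) {
  dims <- spec$shape
  assign <- .foam_assign_cpp(dims, spec$spacing, seeds, weights)
  # weighted gap times the local weight ~ physical wall-normal distance
  wall <- array(assign$gap * weights[assign$nearest] <= spec$wall_thickness,
                dims)
  if (length(duct_pairs) > 0) {
    for (p in duct_pairs) {
      open_p <- wall &
        ((assign$nearest == p[1] & assign$second == p[2]) |
           (assign$nearest == p[2] & assign$second == p[1]))
      wall[open_p] <- FALSE
    }
  }
  # tissue shell at the volume border
  sh <- max(1L, round(spec$shell_thickness / spec$spacing))
  shell <- array(FALSE, dims)
  idx_z <- c(seq_len(min(sh, dims[1])), dims[1] - seq_len(min(sh, dims[1])) + 1L)
  idx_y <- c(seq_len(min(sh, dims[2])), dims[2] - seq_len(min(sh, dims[2])) + 1L)
  idx_x <- c(seq_len(min(sh, dims[3])), dims[3] - seq_len(min(sh, dims[3])) + 1L)
  shell[idx_z, , ] <- TRUE
  shell[, idx_y, ] <- TRUE
  shell[, , idx_x] <- TRUE
  tissue <- wall | shell
  if (fillet_um > 0)
    tissue <- !open_phase(!tissue, fillet_um / spec$spacing) | shell
  tf <- mean(tissue)
  if (tf >= 1 - 1e-9)
    stop("degenerate phantom: walls thicker than typical cells (all tissue)")
  # per-cell equivalent-sphere diameters from assigned air voxels
  air_cells <- assign$nearest[!tissue]
  counts <- tabulate(air_cells, nbins = nrow(seeds))
  diam <- 2 * (3 * counts * spec$spacing^3 / (4 * pi))^(1 / 3)
  list(tissue = tissue, diam = diam, assign = assign)
}

#' Generate a synthetic alveolar foam with known ground truth
#'
#' Voronoi-style foam: cell interiors are air, walls of the requested
#' thickness are centred on the cell boundaries, and a fraction of adjacent
#' cell pairs has the shared wall opened (alveolar-duct surrogate). Seed
#' points are drawn uniformly with a minimum separation of twice the wall
#' thickness; everything is a pure function of the spec (including its seed).
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `phantom_truth` with fields `mask`
#'   ([binary_volume()], tissue = `TRUE`), `cell_centers` (physical points,
#'   micrometres), `nominal_diameters` (per-cell equivalent-sphere diameter,
#'   micrometres), `duct_pairs` and `spec`.
#' @export
generate_foam <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop("expected a phantom_spec")
  dims <- spec$shape
  ext <- (dims - 1) * spec$spacing # physical extent of voxel centres
  # keep seeds clear of the border shell so every cell centre lies in air
  margin <- spec$shell_thickness + spec$wall_thickness
  if (any(ext <= 2 * margin))
    stop("volume too small for the requested shell/wall thicknesses")
  sw <- withr::with_seed(spec$seed + 2L,
                         runif(spec$n_cells, 1, 1 + spec$weight_spread))
  seeds <- withr::with_seed(spec$seed, {
    pts <- matrix(NA_real_, spec$n_cells, 3)
    n_got <- 0L
    tries <- 0L
    min_sep <- 2 * spec$wall_thickness
    while (n_got < spec$n_cells && tries < 10000L * spec$n_cells) {
      cand <- margin + runif(3) * (ext - 2 * margin)
      ok <- n_got == 0L ||
        min(sqrt(colSums((t(pts[seq_len(n_got), , drop = FALSE]) - cand)^2))) >
        min_sep
      if (ok) {
        n_got <- n_got + 1L
        pts[n_got, ] <- cand
      }
      tries <- tries + 1L
    }
    if (n_got < spec$n_cells)
      stop("could not place ", spec$n_cells, " seeds with the required separation")
    pts
  })
  # adjacency from the nearest/second-nearest assignment, then open ducts
  assign0 <- .foam_assign_cpp(dims, spec$spacing, seeds, sw)
  duct_pairs <- list()
  if (spec$duct_fraction > 0 && spec$n_cells > 1) {
    at_wall <- assign0$gap * sw[assign0$nearest] <= spec$wall_thickness
    prs <- unique(data.frame(
      a = pmin(assign0$nearest[at_wall], assign0$second[at_wall]),
      b = pmax(assign0$nearest[at_wall], assign0$second[at_wall])))
    n_open <- min(nrow(prs), round(spec$duct_fraction * spec$n_cells))
    if (n_open > 0) {
      sel <- withr::with_seed(spec$seed + 1L,
                              sample(nrow(prs), n_open))
      duct_pairs <- lapply(sel, function(i) c(prs$a[i], prs$b[i]))
    }
  }
  foam <- foam_from_seeds(spec, seeds, sw, duct_pairs, spec$fillet_radius)
  mask <- binary_volume(foam$tissue, spec$spacing,
                        meta = list(history = sprintf(
                          "generate_foam(n_cells=%d, wall=%g, seed=%d)",
                          spec$n_cells, spec$wall_thickness, spec$seed)))
  structure(list(mask = mask, cell_centers = seeds, weights = sw,
                 nominal_diameters = foam$diam, duct_pairs = duct_pairs,
                 spec = spec),
            class = "phantom_truth")
}

#' Inflate a phantom
#'
#' Isotropically up-scales the airspace geometry by `factor` while keeping
#' the wall thickness unchanged (septa thin out relative to the airspaces,
#' as in inflating lungs), then crops back to the original field of view,
#' mimicking region-of-interest imaging at higher inflation pressure.
#'
#' @param truth a [generate_foam()] result.
#' @param factor dimensionless scale factor (>= 1).
#' @return A new `phantom_truth` at the same volume shape.
#' @export
inflate <- function(truth, factor) {
  if (!inherits(truth, "phantom_truth")) stop("expected a phantom_truth")
  if (factor < 1) stop("`factor` must be >= 1")
  spec <- truth$spec
  ctr <- (spec$shape - 1) * spec$spacing / 2
  seeds <- sweep(sweep(truth$cell_centers, 2, ctr) * factor, 2, ctr, "+")
  foam <- foam_from_seeds(spec, seeds, truth$weights, truth$duct_pairs,
                          spec$fillet_radius * factor)
  mask <- binary_volume(foam$tissue, spec$spacing,
                        meta = list(history = c(truth$mask$meta$history,
                                                sprintf("inflate(factor=%g)",
                                                        factor))))
  structure(list(mask = mask, cell_centers = seeds, weights = truth$weights,
                 nominal_diameters = truth$nominal_diameters * factor,
                 duct_pairs = truth$duct_pairs, spec = spec),
            class = "phantom_truth")
}

#' Render a phantom into a grayscale volume with imaging artifacts
#'
#' Assigns the phase gray values, adds the per-slice background plane, blurs
#' with an isotropic Gaussian and adds Gaussian noise, in that order.
#' Deterministic given `imaging$seed`.
#'
#' @param truth a [generate_foam()] result.
#' @param imaging an [imaging_params()] object.
#' @return A [gray_volume()].
#' @export
render_image <- function(truth, imaging) {
  if (!inherits(truth, "phantom_truth")) stop("expected a phantom_truth")
  if (!inherits(imaging, "imaging_params")) stop("expected imaging_params")
  dims <- dim(truth$mask$data)
  sp <- truth$mask$spacing
  img <- ifelse(truth$mask$data, imaging$gray_tissue, imaging$gray_air)
  g <- imaging$gradient
  if (any(g != 0)) {
    xs <- (seq_len(dims[3]) - 1)
    ys <- (seq_len(dims[2]) - 1)
    plane <- outer(ys, xs, function(y, x) g[1] * x + g[2] * y + g[3])
    img <- sweep(img, c(2, 3), plane, "+")
  }
  if (imaging$blur_sigma > 0)
    img <- .gaussian_blur3d_cpp(img, dims, imaging$blur_sigma / sp)
  if (imaging$noise_sigma > 0)
    img <- img + withr::with_seed(imaging$seed,
                                  array(rnorm(prod(dims), 0,
                                              imaging$noise_sigma), dims))
  dim(img) <- dims
  gray_volume(img, sp, meta = list(history = c(
    truth$mask$meta$history,
    sprintf("render_image(blur=%g, noise=%g, gradient=%s, seed=%d)",
            imaging$blur_sigma, imaging$noise_sigma,
            paste(g, collapse = ","), imaging$seed))))
}

#' Study-condition phantom specifications
#'
#' Canned [phantom_spec()]s emulating the two imaging conditions the
#' package targets: `"high"` is the high-resolution optics (1.1 um pixels,
#' ~50 um airspaces in a ~105 um field of view, 2-voxel septal walls) used
#' for segmentation and curvature work; `"low"` is the lower-resolution
#' optics (2.9 um pixels, ~280 um field of view, single-voxel walls) whose
#' larger cell count gives stable airspace-size statistics.
#'
#' @param optics `"high"` (1.1 um) or `"low"` (2.9 um).
#' @param seed RNG seed for the foam geometry.
#' @return A [phantom_spec()].
#' @export
study_phantom_spec <- function(optics = c("high", "low"), seed = 7L) {
  optics <- match.arg(optics)
  if (optics == "high")
    phantom_spec(shape = c(96, 96, 96), spacing = 1.1, n_cells = 10,
                 wall_thickness = 2.2, duct_fraction = 0.1,
                 shell_thickness = 4.4, weight_spread = 0.8,
                 fillet_radius = 6.6, seed = seed)
  else
    phantom_spec(shape = c(96, 96, 96), spacing = 2.9, n_cells = 150,
                 wall_thickness = 2.9, duct_fraction = 0.1,
                 shell_thickness = 5.8, weight_spread = 0.8,
                 fillet_radius = 13, seed = seed)
}
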