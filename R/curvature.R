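# Air-to-tissue interface analysis: isosurface extraction from the binary
# segmentation, Laplacian smoothing, normal-cycle curvature estimation over
# geodesic neighbourhoods, and interface shape distributions (ISD) over the
# principal curvature pair (kappa1 <= kappa2). Surface normals point from
# the air volume toward the lung tissue, so an alveolus-like air pocket has
# kappa1, kappa2 > 0.

#' Surface-mesh container
#'
#' @param vertices n x 3 matrix of `(z, y, x)` positions, micrometres.
#' @param triangles m x 3 matrix of 1-based vertex indices, consistently
#'   wound so normals point from air toward tissue.
#' @param spacing voxel spacing of the source volume, micrometres.
#' @param meta provenance list.
#' @return An object of class `surface_mesh` with per-vertex unit
#'   `vertex_normals`.
#' @export
surface_mesh <- function(vertices, triangles, spacing = NA_real_,
                         meta = list()) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  if (ncol(vertices) != 3 || ncol(triangles) != 3) stop("need n x 3 matrices")
  if (min(triangles) < 1 || max(triangles) > nrow(vertices))
    stop("triangle indices out of range")
  structure(list(vertices = vertices, triangles = triangles,
                 vertex_normals = vertex_normals(vertices, triangles),
                 spacing = spacing, meta = meta),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

# cross product in (z, y, x) component order; consistent with the
# extractor's winding test so normals point from air toward tissue
cross_zyx <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

vertex_normals <- function(V, T_) {
  e1 <- V[T_[, 2], , drop = FALSE] - V[T_[, 1], , drop = FALSE]
  e2 <- V[T_[, 3], , drop = FALSE] - V[T_[, 1], , drop = FALSE]
  fn <- cross_zyx(e1, e2) # length = 2 * face area (area weighting)
  N <- matrix(0, nrow(V), 3)
  for (k in 1:3) {
    for (c in 1:3) {
      acc <- rowsum(fn[, c], T_[, k])
      N[as.integer(rownames(acc)), c] <- N[as.integer(rownames(acc)), c] + acc
    }
  }
  len <- sqrt(rowSums(N^2))
  len[len == 0] <- 1
  N / len
}

#' Extract the air-to-tissue isosurface of a binary volume
#'
#' Marches over the simplicial (Freudenthal) subdivision of the voxel
#' lattice and extracts the interface of the air phase at level 1/2.
#' Vertices lie at lattice-edge midpoints in physical micrometre
#' coordinates; triangles are wound so normals point from air toward
#' tissue. Cells are formed between existing voxels only, so air touching
#' the volume border yields an open mesh there (no artificial caps); the
#' curvature estimator later excludes neighbourhoods touching such
#' boundaries.
#'
#' @param mask a [binary_volume()] (tissue = `TRUE`).
#' @return A [surface_mesh()].
#' @export
extract_surface <- function(mask) {
  stopifnot_volume(mask)
  air <- !mask$data
  if (!any(air) || all(air)) stop("both phases must be present")
  res <- .extract_surface_cpp(air, dim(air), mask$spacing)
  if (nrow(res$vertices) == 0) stop("no interface found")
  surface_mesh(res$vertices, res$triangles, mask$spacing,
               meta = list(history = c(mask$meta$history, "extract_surface")))
}

#' Laplacian mesh smoothing
#'
#' Iterative umbrella-operator smoothing: every vertex moves a fraction
#' `step` of the way toward the centroid of its neighbours, `iterations`
#' times. Removes the single-voxel staircase noise of meshes extracted from
#' binary data; connectivity is unchanged and `iterations = 0` is the
#' identity. Plain umbrella smoothing shrinks closed surfaces slightly; the
#' enclosed-volume change is recorded in the metadata.
#'
#' @param mesh a [surface_mesh()].
#' @param iterations number of smoothing passes (default 20).
#' @param step relaxation factor in (0, 1) (default 0.5).
#' @return Smoothed [surface_mesh()].
#' @export
smooth_mesh <- function(mesh, iterations = 20, step = 0.5) {
  if (!inherits(mesh, "surface_mesh")) stop("expected a surface_mesh")
  if (iterations < 0) stop("`iterations` must be >= 0")
  if (step <= 0 || step >= 1) stop("`step` must lie in (0, 1)")
  if (iterations == 0) return(mesh)
  V <- mesh$vertices
  T_ <- mesh$triangles
  ij <- rbind(T_[, 1:2], T_[, 2:3], T_[, c(3, 1)])
  ij <- rbind(ij, ij[, 2:1])
  ij <- unique(ij)
  A <- Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = 1,
                            dims = c(nrow(V), nrow(V)))
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  vol0 <- .mesh_volume_cpp(V, T_)
  for (it in seq_len(iterations))
    V <- V + step * (as.matrix(A %*% V) / deg - V)
  out <- surface_mesh(V, T_, mesh$spacing, mesh$meta)
  vol1 <- .mesh_volume_cpp(V, T_)
  out$meta$smoothing <- list(iterations = iterations, step = step,
                             volume_change = (vol1 - vol0) / max(vol0, 1e-12))
  lm_log("smooth_mesh: %d iterations, enclosed volume change %.2f%%",
         iterations, 100 * (vol1 - vol0) / max(vol0, 1e-12))
  out
}

#' Curvature-field container
#'
#' Per-vertex principal curvatures `kappa1 <= kappa2` (1/um), mean curvature
#' `H = (kappa1 + kappa2)/2`, Gaussian curvature `K = kappa1 * kappa2`
#' (1/um^2), the geodesic radius used, and an inclusion flag (`FALSE` for
#' vertices whose geodesic ball was truncated by a mesh boundary).
#'
#' @param mesh the source [surface_mesh()].
#' @param kappa1,kappa2 principal curvature vectors.
#' @param geodesic_radius neighbourhood radius, micrometres.
#' @param included logical vector, `FALSE` = boundary-excluded.
#' @return An object of class `curvature_field`.
#' @export
curvature_field <- function(mesh, kappa1, kappa2, geodesic_radius, included) {
  if (any(kappa1 > kappa2 + 1e-12)) stop("kappa1 must not exceed kappa2")
  structure(list(mesh = mesh, kappa1 = kappa1, kappa2 = kappa2,
                 H = (kappa1 + kappa2) / 2, K = kappa1 * kappa2,
                 geodesic_radius = geodesic_radius, included = included),
            class = "curvature_field")
}

#' Normal-cycle curvature estimation
#'
#' Accumulates, for every vertex, the normal-cycle curvature tensor over all
#' mesh edges within the geodesic ball of radius `geodesic_radius`
#' (Dijkstra distances over the edge graph): each edge contributes its
#' signed dihedral angle times its length inside the ball times the outer
#' product of its direction. The tensor, normalised by the barycentric area
#' of the ball and restricted to the tangent plane, yields the principal
#' curvatures; signs follow the air-to-tissue normal convention. Vertices
#' whose ball touches a mesh boundary are marked excluded. Larger radii
#' average curvature over larger surface patches, absorbing small dimples
#' into their surrounding shape class.
#'
#' @param mesh a [surface_mesh()].
#' @param geodesic_radius neighbourhood radius in micrometres (> 0).
#' @param stride compute the tensor at every `stride`-th vertex only
#'   (default 1 = all); unsampled vertices are marked excluded. Useful for
#'   density estimates on very large meshes, where a regular vertex
#'   subsample gives the same distributions at a fraction of the cost.
#' @return A [curvature_field()].
#' @export
normal_cycle_curvature <- function(mesh, geodesic_radius = 3.5, stride = 1L) {
  if (!inherits(mesh, "surface_mesh")) stop("expected a surface_mesh")
  if (geodesic_radius <= 0) stop("`geodesic_radius` must be > 0")
  res <- .curvature_cpp(mesh$vertices, mesh$triangles, mesh$vertex_normals,
                        geodesic_radius, as.integer(stride))
  if (all(res$excluded))
    stop("geodesic radius smaller than local edge length everywhere")
  curvature_field(mesh, res$kappa1, res$kappa2, geodesic_radius,
                  !res$excluded)
}

#' Principal curvatures from mean and Gaussian curvature
#'
#' Inverts `H = (k1 + k2)/2`, `K = k1 k2`:
#' `kappa1 = H - sqrt(H^2 - K)`, `kappa2 = H + sqrt(H^2 - K)`.
#' Negative discriminants (possible when H and K are estimated
#' independently) are clamped to zero; clamp events are counted in the
#' `"clamped"` attribute.
#'
#' @param H mean curvature (1/um), vectorised.
#' @param K Gaussian curvature (1/um^2), vectorised.
#' @return List with `kappa1` and `kappa2` (`kappa1 <= kappa2`), attribute
#'   `clamped` = number of clamped entries.
#' @export
principal_from_HK <- function(H, K) {
  disc <- H^2 - K
  clamped <- sum(disc < 0)
  if (clamped > 0) lm_log("principal_from_HK: clamped %d negative discriminants",
                          clamped)
  s <- sqrt(pmax(0, disc))
  structure(list(kappa1 = H - s, kappa2 = H + s), clamped = clamped)
}

#' Classify vertices into ISD regions
#'
#' Region 1: `kappa1, kappa2 > 0` (ellipsoidal, convex toward the tissue —
#' the alveolus-like shape); region 4: both negative (concave); regions 2
#' and 3: saddles (`kappa1 < 0 < kappa2`), split by comparing `|kappa1|`
#' with `kappa2` (region 2 when `|kappa1| <= kappa2`). Exact zeros are tied
#' to the adjacent region by the same comparisons; boundary-excluded
#' vertices are labelled 0.
#'
#' @param field a [curvature_field()].
#' @return Integer vector of per-vertex labels in `{0, 1, 2, 3, 4}`.
#' @export
classify_regions <- function(field) {
  if (!inherits(field, "curvature_field")) stop("expected a curvature_field")
  k1 <- field$kappa1
  k2 <- field$kappa2
  lab <- integer(length(k1))
  lab[k1 >= 0 & k2 > 0] <- 1L
  lab[k1 < 0 & k2 <= 0] <- 4L
  saddle <- k1 < 0 & k2 > 0
  lab[saddle & abs(k1) <= k2] <- 2L
  lab[saddle & abs(k1) > k2] <- 3L
  lab[k1 == 0 & k2 == 0] <- 1L # flat: tie upward to the convex side
  lab[!field$included] <- 0L
  lab
}

# deterministic thinning for quadratic-cost estimators
thin_rows <- function(n, max_n) {
  if (n <= max_n) return(seq_len(n))
  unique(round(seq(1, n, length.out = max_n)))
}

#' Interface shape distribution (ISD)
#'
#' 2D Gaussian kernel density of the principal curvature pairs
#' `(kappa1, kappa2)` of all included vertices, on a 256 x 256 grid, with a
#' diagonal plug-in bandwidth matrix (Sheather-Jones per axis). Density
#' above the `kappa1 = kappa2` diagonal (unreachable since
#' `kappa1 <= kappa2`) is zeroed and the estimate renormalised.
#'
#' @param field a [curvature_field()].
#' @param n_grid grid resolution per axis (default 256).
#' @param max_vertices deterministic thinning bound for the KDE input.
#' @param lims optional `c(k1_lo, k1_hi, k2_lo, k2_hi)` evaluation window;
#'   supply a common window when building ensembles.
#' @param bandwidth optional `c(h1, h2)` kernel bandwidths; supply a common
#'   bandwidth when comparing densities across segmentation variants
#'   (otherwise per-variant plug-in selection confounds the comparison).
#' @return An object of class `isd_density` with fields `grid_k1`,
#'   `grid_k2`, `density` (matrix, rows = k1), `bandwidth`, `n_vertices`.
#' @export
isd_density <- function(field, n_grid = 256, max_vertices = 20000,
                        lims = NULL, bandwidth = NULL) {
  if (!inherits(field, "curvature_field")) stop("expected a curvature_field")
  k1 <- field$kappa1[field$included]
  k2 <- field$kappa2[field$included]
  if (length(k1) < 100) stop("too few included vertices for an ISD")
  o <- order(k1)
  pick <- thin_rows(length(k1), max_vertices)
  k1s <- k1[o][pick]
  k2s <- k2[o][pick]
  if (is.null(bandwidth)) {
    h1 <- plugin_bandwidth(k1s)
    h2 <- plugin_bandwidth(k2s)
  } else {
    h1 <- bandwidth[1]
    h2 <- bandwidth[2]
  }
  pad <- 3
  if (is.null(lims))
    lims <- c(range(k1s) + c(-pad, pad) * h1, range(k2s) + c(-pad, pad) * h2)
  kd <- MASS::kde2d(k1s, k2s, h = c(4 * h1, 4 * h2), n = n_grid, lims = lims)
  dens <- kd$z
  above <- outer(kd$x, kd$y, ">") # k1 > k2: unreachable half-plane
  dens[above] <- 0
  cell <- diff(kd$x[1:2]) * diff(kd$y[1:2])
  dens <- dens / (sum(dens) * cell)
  structure(list(grid_k1 = kd$x, grid_k2 = kd$y, density = dens,
                 bandwidth = c(h1, h2), n_vertices = length(k1s)),
            class = "isd_density")
}

#' 1D densities of mean and Gaussian curvature
#'
#' Gaussian KDEs (plug-in bandwidth) of H and K over the included vertices,
#' each normalised on its evaluation grid.
#'
#' @param field a [curvature_field()].
#' @param n_grid grid size (default 512).
#' @param bandwidth optional `c(h_H, h_K)` bandwidth override; supply a
#'   common value when comparing variants.
#' @param from,to optional named lists (`H =`, `K =`) fixing the evaluation
#'   windows, for ensembles on a common grid.
#' @return List with [density_estimate()]s `H` and `K`.
#' @export
curvature_densities <- function(field, n_grid = 512, bandwidth = NULL,
                                from = NULL, to = NULL) {
  if (!inherits(field, "curvature_field")) stop("expected a curvature_field")
  one <- function(x, h, lo, hi) {
    if (is.null(h)) h <- plugin_bandwidth(x)
    if (is.null(lo)) {
      de <- density(x, bw = h, n = n_grid)
    } else {
      de <- density(x, bw = h, from = lo, to = hi, n = n_grid)
    }
    density_estimate(de$x, de$y / trapz(de$x, de$y), h, length(x))
  }
  list(H = one(field$H[field$included], bandwidth[1], from$H, to$H),
       K = one(field$K[field$included], bandwidth[2], from$K, to$K))
}

#' Map vertex region labels back onto the voxel lattice
#'
#' Rasterises every vertex to its nearest voxel; a voxel's label is the
#' majority region among its vertices, ties going to the lower region
#' index. Yields the thin shell of labelled voxels along the interface for
#' overlay on the gray slices.
#'
#' @param mesh a [surface_mesh()].
#' @param labels per-vertex integer labels (0 = unlabelled, 1-4 = region).
#' @param shape voxel dimensions `(z, y, x)` of the target volume.
#' @return A [gray_volume()] of integer labels (0 = none).
#' @export
map_to_slices <- function(mesh, labels, shape) {
  if (!inherits(mesh, "surface_mesh")) stop("expected a surface_mesh")
  shape <- as.integer(shape)
  vox <- round(mesh$vertices / mesh$spacing) + 1 # 1-based indices
  if (any(vox < 1) || any(sweep(vox, 2, shape, ">") != 0))
    stop("mesh vertices fall outside the target volume")
  lin <- vox[, 1] + shape[1] * ((vox[, 2] - 1) + shape[2] * (vox[, 3] - 1))
  lab <- array(0L, shape)
  sel <- labels > 0
  if (any(sel)) {
    tab <- table(lin = lin[sel], region = labels[sel])
    linu <- as.integer(rownames(tab))
    # first maximum along each row = lowest region index on ties
    win <- as.integer(colnames(tab))[apply(tab, 1, which.max)]
    lab[linu] <- win
  }
  gray_volume(lab, mesh$spacing, meta = list(history = "map_to_slices"))
}

#' Ensemble mean and standard deviation of ISDs
#'
#' Pointwise statistics across per-variant ISDs computed on a common grid.
#'
#' @param isds list of [isd_density()] results with identical grids.
#' @return List with `grid_k1`, `grid_k2`, `mean` and `sd` matrices.
#' @export
ensemble_isd <- function(isds) {
  if (length(isds) < 1) stop("empty ensemble")
  g1 <- isds[[1]]$grid_k1
  g2 <- isds[[1]]$grid_k2
  for (x in isds)
    if (max(abs(x$grid_k1 - g1)) > 1e-12 || max(abs(x$grid_k2 - g2)) > 1e-12)
      stop("inconsistent ISD grids")
  arr <- simplify2array(lapply(isds, function(x) x$density))
  list(grid_k1 = g1, grid_k2 = g2,
       mean = apply(arr, c(1, 2), mean),
       sd = if (length(isds) > 1) apply(arr, c(1, 2), sd)
            else array(0, dim(arr)[1:2]))
}
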