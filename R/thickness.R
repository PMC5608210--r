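# Local air-volume thickness: tau(p) is the diameter of the largest sphere
# that contains p and fits entirely inside the selected phase (maximum
# inscribed sphere). Computed from the Euclidean distance transform via
# distance-ridge extraction and sphere propagation; a literal brute-force
# evaluation serves as the testing oracle. Distributions are summarised by
# Gaussian kernel densities with plug-in bandwidths and by volumetric range
# fractions.

#' Thickness-map container
#'
#' @param tau 3D array of local thickness values in micrometres, defined on
#'   the analysed phase (0 elsewhere).
#' @param spacing voxel spacing, micrometres.
#' @param floor,cap analysis floor/ceiling in micrometres (defaults 20 and
#'   170: structures below the smallest plausible alveolar diameter are
#'   ignored, and very large airspaces move in and out of small fields of
#'   view).
#' @param meta provenance list.
#' @return An object of class `thickness_map`.
#' @export
thickness_map <- function(tau, spacing, floor = 20, cap = 170, meta = list()) {
  if (!is.array(tau) || length(dim(tau)) != 3L) stop("`tau` must be 3D")
  if (any(tau < 0)) stop("`tau` must be non-negative")
  structure(list(tau = tau, spacing = check_spacing(spacing), floor = floor,
                 cap = cap, meta = meta),
            class = "thickness_map")
}

phase_array <- function(mask, phase = c("air", "tissue")) {
  phase <- match.arg(phase)
  if (phase == "air") !mask$data else mask$data
}

#' Local thickness by maximum inscribed spheres
#'
#' For every voxel of the selected phase, returns the diameter (micrometres)
#' of the largest sphere containing that voxel and fitting entirely inside
#' the phase. The volume is treated as bounded: the space outside the
#' lattice belongs to the opposite phase. A sphere of radius r placed at a
#' voxel centre is admissible if every voxel centre within r belongs to the
#' phase; under this convention a single isolated phase voxel carries
#' `tau = spacing`.
#'
#' Implementation: exact Euclidean distance transform, removal of redundant
#' sphere centres (distance ridge), then sphere propagation from the ridge.
#' The centre-removal rule is exact (a removed sphere is always contained in
#' a kept neighbour's sphere), so the result equals the brute-force
#' maximisation of [brute_force_thickness()] voxel by voxel.
#'
#' @param mask a [binary_volume()] (tissue = `TRUE`).
#' @param phase which phase to measure (`"air"` measures the airspaces).
#' @param floor,cap analysis limits in micrometres, stored with the map.
#' @return A [thickness_map()].
#' @export
local_thickness <- function(mask, phase = c("air", "tissue"),
                            floor = 20, cap = 170) {
  stopifnot_volume(mask)
  phase <- match.arg(phase)
  ph <- phase_array(mask, phase)
  if (!any(ph)) stop("selected phase is empty")
  tau_vox <- .local_thickness_cpp(ph, dim(ph))
  thickness_map(tau_vox * mask$spacing, mask$spacing, floor, cap,
                meta = list(phase = phase,
                            source_history = mask$meta$history))
}

#' Brute-force local thickness (testing oracle)
#'
#' Literal evaluation of the maximum-inscribed-sphere definition: every
#' phase voxel is a candidate sphere centre with the largest admissible
#' radius (distance to the nearest opposite-phase voxel centre, minus half
#' a voxel), and each sphere stamps its diameter onto all phase voxels it
#' contains. Quadratic cost; guarded to small volumes.
#'
#' @inheritParams local_thickness
#' @param max_voxels guard on the phase voxel count (default 1e5).
#' @return A [thickness_map()].
#' @export
brute_force_thickness <- function(mask, phase = c("air", "tissue"),
                                  floor = 20, cap = 170, max_voxels = 1e5) {
  stopifnot_volume(mask)
  phase <- match.arg(phase)
  ph <- phase_array(mask, phase)
  if (!any(ph)) stop("selected phase is empty")
  if (sum(ph) > max_voxels)
    stop("phase too large for brute-force evaluation (", sum(ph), " voxels)")
  dims <- dim(ph)
  idx <- which(ph)
  # 0-based voxel coordinates of phase voxels
  zz <- (idx - 1) %% dims[1]
  yy <- ((idx - 1) %/% dims[1]) %% dims[2]
  xx <- (idx - 1) %/% (dims[1] * dims[2])
  P <- cbind(zz, yy, xx)
  # opposite phase, plus a one-voxel virtual border layer
  oidx <- which(!ph)
  oz <- (oidx - 1) %% dims[1]
  oy <- ((oidx - 1) %/% dims[1]) %% dims[2]
  ox <- (oidx - 1) %/% (dims[1] * dims[2])
  O <- rbind(cbind(oz, oy, ox), pad_layer_coords(dims))
  # admissible radius at every phase voxel
  r <- rep(Inf, nrow(P))
  chunk <- max(1L, floor(2e6 / max(1, nrow(O))))
  for (s in seq(1, nrow(P), by = chunk)) {
    e <- min(nrow(P), s + chunk - 1)
    d2 <- outer(rowSums(P[s:e, , drop = FALSE]^2), rowSums(O^2), "+") -
      2 * P[s:e, , drop = FALSE] %*% t(O)
    r[s:e] <- sqrt(pmax(0, apply(d2, 1, min))) - 0.5
  }
  # stamp each sphere onto the phase voxels it contains
  tau <- rep(0, nrow(P))
  chunk <- max(1L, floor(2e6 / nrow(P)))
  for (s in seq(1, nrow(P), by = chunk)) {
    e <- min(nrow(P), s + chunk - 1)
    d2 <- outer(rowSums(P[s:e, , drop = FALSE]^2), rowSums(P^2), "+") -
      2 * P[s:e, , drop = FALSE] %*% t(P)
    covered <- d2 <= (r[s:e]^2 + 1e-7)
    stamped <- covered * (2 * r[s:e])
    tau <- pmax(tau, apply(stamped, 2, max))
  }
  out <- array(0, dims)
  out[idx] <- tau * mask$spacing
  thickness_map(out, mask$spacing, floor, cap,
                meta = list(phase = phase, oracle = TRUE))
}

pad_layer_coords <- function(dims) {
  # voxel coordinates (0-based) of the one-voxel layer surrounding the
  # lattice: the nearest outside lattice point always lies in this layer
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  g <- function(z, y, x) as.matrix(expand.grid(z = z, y = y, x = x))
  rbind(g(c(-1, nz), 0:(ny - 1), 0:(nx - 1)),
        g(0:(nz - 1), c(-1, ny), 0:(nx - 1)),
        g(0:(nz - 1), 0:(ny - 1), c(-1, nx)))
}

#' Density estimate container
#'
#' @param grid evaluation abscissa.
#' @param density non-negative density values; the trapezoidal integral
#'   over `grid` must be 1 within 1e-3.
#' @param bandwidth kernel bandwidth (same units as `grid`).
#' @param n_samples number of samples behind the estimate.
#' @return An object of class `density_estimate`.
#' @export
density_estimate <- function(grid, density, bandwidth, n_samples) {
  if (any(density < 0)) stop("density must be non-negative")
  integral <- trapz(grid, density)
  if (abs(integral - 1) > 1e-3)
    stop(sprintf("density must integrate to 1 (got %.5f)", integral))
  structure(list(grid = grid, density = density, bandwidth = bandwidth,
                 n_samples = n_samples),
            class = "density_estimate")
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# Plug-in (Sheather-Jones) bandwidth on a deterministic subsample; the
# selector is quadratic in n, so large samples are thinned by sorted
# striding (order statistics), which is deterministic and seed-free.
plugin_bandwidth <- function(x, max_n = 5000) {
  if (length(x) > max_n) {
    xs <- sort(x)
    x <- xs[unique(round(seq(1, length(xs), length.out = max_n)))]
  }
  h <- tryCatch(stats::bw.SJ(x), error = function(e) NA_real_)
  if (!is.finite(h) || h <= 0)
    h <- tryCatch(stats::bw.nrd0(x), error = function(e) NA_real_)
  if (!is.finite(h) || h <= 0) h <- max(1e-3, diff(range(x)) / 100, sd(x) / 10)
  h
}

#' Kernel density of local thickness values
#'
#' Gaussian KDE of the per-voxel thickness values within `[floor, cap]`
#' (every phase voxel contributes one sample), plug-in bandwidth, evaluated
#' on a fixed 512-point grid spanning `[floor, cap]` and renormalised on the
#' truncated support.
#'
#' @param tmap a [thickness_map()].
#' @param floor,cap truncation limits, micrometres (default from the map).
#' @param n_grid grid size (default 512).
#' @return A [density_estimate()].
#' @export
thickness_density <- function(tmap, floor = tmap$floor, cap = tmap$cap,
                              n_grid = 512) {
  if (!inherits(tmap, "thickness_map")) stop("expected a thickness_map")
  x <- tmap$tau[tmap$tau >= floor & tmap$tau <= cap]
  if (length(x) == 0) stop("no phase voxels with thickness in [floor, cap]")
  # thickness values are quantized by the voxel lattice; the plug-in
  # selector would resolve individual lattice atoms, so the voxel spacing
  # acts as a lower bandwidth floor (the measurement quantum)
  h <- max(plugin_bandwidth(x), tmap$spacing)
  de <- density(x, bw = h, from = floor, to = cap, n = n_grid)
  dens <- de$y / trapz(de$x, de$y)
  density_estimate(de$x, dens, h, length(x))
}

#' Volumetric range fractions of a thickness map
#'
#' Fraction (per cent) of in-support phase voxels whose thickness falls in
#' each half-open range `[lo, hi)`; the default ranges are 20-50, 50-80,
#' 80-110 and >= 110 micrometres.
#'
#' @param tmap a [thickness_map()].
#' @param ranges matrix-like list of `c(lo, hi)` pairs in micrometres, or a
#'   vector of ascending breakpoints (last range open-ended).
#' @return Data frame with columns `lo`, `hi`, `fraction` (per cent).
#' @export
range_fractions <- function(tmap, ranges = c(20, 50, 80, 110)) {
  if (!inherits(tmap, "thickness_map")) stop("expected a thickness_map")
  if (is.numeric(ranges) && is.null(dim(ranges))) {
    lo <- ranges
    hi <- c(ranges[-1], Inf)
  } else {
    rm_ <- do.call(rbind, ranges)
    lo <- rm_[, 1]
    hi <- rm_[, 2]
  }
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]
  if (any(hi[-length(hi)] > lo[-1] + 1e-12)) stop("ranges must not overlap")
  x <- tmap$tau[tmap$tau > 0]
  insupp <- x >= lo[1] & (x < hi[length(hi)] | !is.finite(hi[length(hi)]))
  x <- x[insupp]
  n <- length(x)
  frac <- vapply(seq_along(lo), function(i) sum(x >= lo[i] & x < hi[i]) / n,
                 numeric(1))
  data.frame(lo = lo, hi = hi, fraction = 100 * frac)
}

#' Ensemble mean and standard deviation
#'
#' Pointwise mean and sample standard deviation across segmentation
#' variants, for lists of [density_estimate()]s (common grid required), of
#' numeric vectors, or of [range_fractions()] data frames.
#'
#' @param xs list with one element per segmentation variant.
#' @return List with `mean` and `sd` in the shape of the inputs.
#' @export
ensemble_stats <- function(xs) {
  if (length(xs) < 1) stop("empty ensemble")
  if (inherits(xs[[1]], "density_estimate")) {
    g <- xs[[1]]$grid
    for (x in xs)
      if (max(abs(x$grid - g)) > 1e-9) stop("inconsistent density grids")
    m <- do.call(rbind, lapply(xs, function(x) x$density))
    return(list(grid = g, mean = colMeans(m), sd = apply(m, 2, sd)))
  }
  if (is.data.frame(xs[[1]])) {
    m <- do.call(rbind, lapply(xs, function(x) x$fraction))
    return(list(lo = xs[[1]]$lo, hi = xs[[1]]$hi, mean = colMeans(m),
                sd = apply(m, 2, sd)))
  }
  m <- do.call(rbind, xs)
  list(mean = colMeans(m), sd = apply(m, 2, sd))
}

#' Colour-index overlay of a thickness map
#'
#' Quantises thickness values into `n_bins` equal-width bins for external
#' rendering on top of the gray data: index 0 is transparent (voxels outside
#' the phase), the largest thickness maps to the top index. The legend table
#' documents the micrometre interval of every index.
#'
#' @param tmap a [thickness_map()].
#' @param vol the gray volume the map belongs to (shape check only).
#' @param n_bins number of colour indices (default 64).
#' @return List with `index` (a [gray_volume()] of integer colour indices)
#'   and `legend` (data frame `index`, `lo`, `hi`, `mid` in micrometres).
#' @export
export_thickness_overlay <- function(tmap, vol, n_bins = 64) {
  if (!inherits(tmap, "thickness_map")) stop("expected a thickness_map")
  stopifnot_volume(vol)
  if (!all(dim(tmap$tau) == dim(vol$data))) stop("shape mismatch")
  pos <- tmap$tau[tmap$tau > 0]
  if (length(pos) == 0) stop("empty thickness map")
  lo <- min(pos)
  hi <- max(pos)
  width <- max(hi - lo, 1e-9)
  idx <- array(0L, dim(tmap$tau))
  sel <- tmap$tau > 0
  idx[sel] <- pmin(n_bins, 1L + as.integer(floor((tmap$tau[sel] - lo) /
                                                   width * n_bins)))
  edges <- seq(lo, hi, length.out = n_bins + 1)
  legend <- data.frame(index = seq_len(n_bins), lo = edges[-(n_bins + 1)],
                       hi = edges[-1])
  legend$mid <- (legend$lo + legend$hi) / 2
  list(index = gray_volume(idx, tmap$spacing,
                           meta = list(history = "export_thickness_overlay")),
       legend = legend)
}
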