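# Seven-step semi-automatic segmentation of low-dose lung tomograms:
# per-slice background-illumination plane correction, volume-wide Otsu
# threshold estimation, line-profile ridge enhancement that rescues thin
# interalveolar septa, thresholding, isolated-voxel removal and 3D
# connected-component cleanup — plus an ensemble runner that produces
# several segmentations per volume for uncertainty quantification.

#' Ridge-detection parameters
#'
#' Controls the line-profile septa detector: a local maximum along a profile
#' is accepted as a septum crossing when its width (contiguous run of
#' samples exceeding the flanking background by at least `min_margin`) lies
#' in `[min_width, max_width]` and its prominence above the flanking
#' background lies in `[min_margin, max_margin]`. `max_margin` acts as an
#' upper prominence cutoff that rejects very bright vessel-like lines.
#'
#' @param min_width,max_width admissible run widths in pixels.
#' @param min_margin,max_margin admissible prominences in gray units.
#' @param directions subset of `c(0, 45, 90, 135)` (degrees) of in-slice
#'   profile directions; diagonals are sampled along array diagonals.
#' @return An object of class `ridge_params`.
#' @export
ridge_params <- function(min_width = 1, max_width = 4, min_margin = 50,
                         max_margin = 1e6, directions = c(0, 45, 90, 135)) {
  if (min_width < 1 || min_width > max_width)
    stop("need 1 <= min_width <= max_width")
  if (min_margin < 0 || min_margin > max_margin)
    stop("need 0 <= min_margin <= max_margin")
  if (!all(directions %in% c(0, 45, 90, 135)))
    stop("directions must be a subset of 0, 45, 90, 135")
  structure(list(min_width = as.integer(min_width),
                 max_width = as.integer(max_width),
                 min_margin = min_margin, max_margin = max_margin,
                 directions = directions),
            class = "ridge_params")
}

#' Segmentation parameters
#'
#' @param erosion_radius radius (pixels) of the disk structuring element for
#'   the background-plane estimation (default 20).
#' @param ridge a [ridge_params()] object.
#' @param min_component minimum 26-connected tissue component size kept, in
#'   voxels (default 27, one voxel cube at the smallest plausible septal
#'   junction scale).
#' @param variant_id label used for ensemble bookkeeping.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(erosion_radius = 20, ridge = ridge_params(),
                                min_component = 27, variant_id = "default") {
  if (erosion_radius < 1) stop("`erosion_radius` must be >= 1")
  if (min_component < 1) stop("`min_component` must be >= 1")
  structure(list(erosion_radius = as.integer(erosion_radius), ridge = ridge,
                 min_component = as.integer(min_component),
                 variant_id = variant_id),
            class = "segmentation_params")
}

#' Estimate the background-illumination plane of one slice
#'
#' Grayscale erosion with a disk structuring element suppresses thin bright
#' structures (septa); pixels outside the central quantile band of the
#' eroded slice are masked out as histogram extremes, and a plane
#' `a*x + b*y + c` is least-squares fitted to the remaining pixels
#' (`x`, `y` are 0-based pixel indices along columns and rows).
#'
#' @param slice 2D numeric matrix `(y, x)`.
#' @param erosion_radius disk radius in pixels.
#' @param trim quantile band kept after erosion (default `c(0.05, 0.95)`).
#' @return An object of class `plane_model` with field `coefficients`
#'   `(a, b, c)`.
#' @export
estimate_background_plane <- function(slice, erosion_radius = 20,
                                      trim = c(0.05, 0.95)) {
  slice <- as.matrix(slice)
  if (min(dim(slice)) <= 2 * erosion_radius + 1)
    stop("slice smaller than the structuring element")
  brush <- EBImage::makeBrush(2L * as.integer(erosion_radius) + 1L, "disc")
  # EBImage grayscale morphology operates on [0, 1]; rescale around it
  lo <- min(slice)
  sc <- max(max(slice) - lo, 1e-12)
  er <- EBImage::erode((slice - lo) / sc, brush) * sc + lo
  ny <- nrow(slice)
  nx <- ncol(slice)
  # the erosion is only valid where the structuring element fits: exclude
  # the border band, where truncated disks bias the fitted slope
  valid <- matrix(FALSE, ny, nx)
  rb <- as.integer(erosion_radius)
  valid[(rb + 1):(ny - rb), (rb + 1):(nx - rb)] <- TRUE
  qs <- quantile(er[valid], trim, names = FALSE)
  keep <- valid & er >= qs[1] & er <= qs[2]
  if (!any(keep)) stop("histogram-extreme masking removed all pixels")
  xs <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  ys <- matrix(rep(0:(ny - 1), nx), ny, nx)
  X <- cbind(xs[keep], ys[keep], 1)
  cf <- stats::lm.fit(X, er[keep])$coefficients
  # one robust refinement: texture contamination of the eroded image is
  # one-sided (patches without clean background erode high), so drop
  # large-residual pixels and refit
  res <- er[keep] - X %*% cf
  ok <- abs(res - median(res)) <= 2 * stats::mad(res)
  if (sum(ok) > 10) cf <- stats::lm.fit(X[ok, , drop = FALSE],
                                        er[keep][ok])$coefficients
  structure(list(coefficients = as.numeric(cf)), class = "plane_model")
}

#' Per-slice background-illumination correction
#'
#' Estimates and subtracts the background plane of every slice, keeping each
#' slice's constant offset `c` (only the gradient `a*x + b*y` is removed) so
#' the gray scale remains comparable across slices.
#'
#' @param vol a [gray_volume()].
#' @param erosion_radius disk radius in pixels.
#' @return Corrected [gray_volume()].
#' @export
correct_background <- function(vol, erosion_radius = 20) {
  stopifnot_volume(vol)
  d <- vol$data
  dims <- dim(d)
  nx <- dims[3]
  ny <- dims[2]
  xs <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  ys <- matrix(rep(0:(ny - 1), nx), ny, nx)
  for (z in seq_len(dims[1])) {
    pm <- estimate_background_plane(d[z, , ], erosion_radius)
    cf <- pm$coefficients
    d[z, , ] <- d[z, , ] - cf[1] * xs - cf[2] * ys
  }
  out <- gray_volume(d, vol$spacing, vol$origin, vol$meta)
  add_history(out, sprintf("correct_background(erosion_radius=%d)",
                           as.integer(erosion_radius)))
}

#' Otsu threshold of a volume
#'
#' Global threshold maximising the between-class variance over a 256-bin
#' histogram of the whole volume; ties broken toward the lower bin. The
#' returned value is on the original gray scale (a bin edge).
#'
#' @param vol a [gray_volume()] or numeric array.
#' @return Threshold gray value.
#' @export
otsu_threshold <- function(vol) {
  d <- if (is_volume(vol)) vol$data else vol
  rng <- range(d)
  if (diff(rng) <= 0) stop("constant volume has no Otsu threshold")
  nb <- 256L
  h <- tabulate(pmin(nb, 1L + floor((d - rng[1]) / diff(rng) * nb)), nbins = nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * seq_len(nb))
  mu_t <- mu[nb]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b) # first maximum = lower bin on ties
  rng[1] + k / nb * diff(rng)
}

#' Ridge enhancement of thin bright lines
#'
#' Scans line profiles of every slice in the requested directions
#' (0, 45, 90, 135 degrees); local maxima whose run width and prominence
#' pass the [ridge_params()] acceptance rule are set to the volume's
#' maximum gray value, ensuring the detected septa survive the subsequent
#' global threshold. All other voxels are unchanged.
#'
#' @param vol a [gray_volume()].
#' @param params a [ridge_params()] object.
#' @return Enhanced [gray_volume()].
#' @export
ridge_enhance <- function(vol, params = ridge_params()) {
  stopifnot_volume(vol)
  dirs <- c(0, 45, 90, 135) %in% params$directions
  mark <- .ridge_mark_cpp(vol$data, dim(vol$data), params$min_width,
                          params$max_width, params$min_margin,
                          params$max_margin, dirs)
  d <- vol$data
  d[mark] <- max(d)
  out <- gray_volume(d, vol$spacing, vol$origin, vol$meta)
  add_history(out, sprintf(
    "ridge_enhance(width=[%d,%d], margin=[%g,%g], dirs=%s; %d voxels marked)",
    params$min_width, params$max_width, params$min_margin, params$max_margin,
    paste(params$directions, collapse = "/"), sum(mark)))
}

#' Threshold a gray volume
#'
#' Tissue = voxels with gray value `>= threshold`.
#'
#' @param vol a [gray_volume()].
#' @param threshold gray value.
#' @return A [binary_volume()].
#' @export
threshold_with <- function(vol, threshold) {
  stopifnot_volume(vol)
  out <- binary_volume(vol$data >= threshold, vol$spacing, vol$origin,
                       vol$meta)
  add_history(out, sprintf("threshold_with(%g)", threshold))
}

#' Remove isolated tissue voxels
#'
#' Tissue voxels with no tissue neighbour in the 26-neighbourhood are set to
#' air: a single free-standing voxel always represents an artifact, since
#' real septa are connected to surrounding tissue. Anti-extensive and
#' idempotent.
#'
#' @param mask a [binary_volume()].
#' @return Cleaned [binary_volume()].
#' @export
remove_isolated <- function(mask) {
  stopifnot_volume(mask)
  cnt <- .neighbor_count_cpp(mask$data, dim(mask$data))
  d <- mask$data & (cnt > 0L)
  out <- binary_volume(array(d, dim(mask$data)), mask$spacing, mask$origin,
                       mask$meta)
  add_history(out, sprintf("remove_isolated(%d voxels removed)",
                           sum(mask$data) - sum(d)))
}

#' Remove small tissue components
#'
#' 26-connected tissue components smaller than `min_component` voxels are
#' set to air. Anti-extensive and idempotent.
#'
#' @param mask a [binary_volume()].
#' @param min_component minimum component size kept, voxels.
#' @return Filtered [binary_volume()].
#' @export
component_filter <- function(mask, min_component = 27) {
  stopifnot_volume(mask)
  if (min_component < 1) stop("`min_component` must be >= 1")
  lab <- .label_components_cpp(mask$data, dim(mask$data), 26L)
  sizes <- tabulate(lab)
  keep <- mask$data
  if (length(sizes) > 0) {
    small <- which(sizes < min_component)
    if (length(small) > 0) keep[lab %in% small] <- FALSE
  }
  out <- binary_volume(keep, mask$spacing, mask$origin, mask$meta)
  add_history(out, sprintf("component_filter(min_component=%d)",
                           as.integer(min_component)))
}

#' Full segmentation pipeline
#'
#' Runs, in order: background correction, Otsu threshold estimation (value
#' stored), ridge enhancement, thresholding with the stored Otsu value,
#' isolated-voxel removal and connected-component filtering. All parameters
#' are recorded in the output metadata.
#'
#' @param vol a [gray_volume()].
#' @param params a [segmentation_params()] object.
#' @return A [binary_volume()] (tissue = `TRUE`).
#' @export
segment_volume <- function(vol, params = segmentation_params()) {
  stopifnot_volume(vol)
  corrected <- correct_background(vol, params$erosion_radius)
  thr <- otsu_threshold(corrected)
  ridged <- ridge_enhance(corrected, params$ridge)
  mask <- threshold_with(ridged, thr)
  mask <- remove_isolated(mask)
  mask <- component_filter(mask, params$min_component)
  mask$meta$variant_id <- params$variant_id
  mask$meta$otsu <- thr
  add_history(mask, sprintf("segment_volume(variant='%s', otsu=%.3f)",
                            params$variant_id, thr))
}

#' Segmentation ensemble
#'
#' Runs [segment_volume()] once per parameter variant; downstream statistics
#' consume the resulting list to quantify segmentation uncertainty.
#'
#' @param vol a [gray_volume()].
#' @param variants list of [segmentation_params()].
#' @return List of [binary_volume()] masks, one per variant.
#' @export
segmentation_ensemble <- function(vol, variants) {
  if (length(variants) < 1) stop("at least one variant is required")
  lapply(variants, function(p) segment_volume(vol, p))
}
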