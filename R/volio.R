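#' @useDynLib lungmorph, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats density sd var rnorm runif quantile median
#' @importFrom utils read.csv write.csv head tail
NULL

# ---- logging / provenance -------------------------------------------------

lm_log <- function(...) {
  if (isTRUE(getOption("lungmorph.verbose", FALSE)))
    message("[lungmorph] ", sprintf(...))
  invisible(NULL)
}

add_history <- function(vol, entry) {
  vol$meta$history <- c(vol$meta$history, entry)
  lm_log("%s", entry)
  vol
}

# ---- domain types ---------------------------------------------------------

#' Construct a 3D grayscale volume
#'
#' The basic image container of the package: a 3D scalar array in `(z, y, x)`
#' axis order with an isotropic voxel spacing in micrometres. All physical
#' quantities downstream (thickness, curvature) are expressed in micrometres
#' via this spacing. Anisotropic spacings are rejected.
#'
#' @param data 3D numeric array, dimensions `(z, y, x)`.
#' @param spacing voxel edge length in micrometres (single positive number,
#'   or a length-3 vector whose entries must all be equal).
#' @param origin physical coordinate of voxel `(1,1,1)` in micrometres.
#' @param meta free-form provenance list; `meta$history` is append-only.
#' @return An object of class `gray_volume` with fields `data`, `spacing`,
#'   `origin` and `meta`.
#' @export
gray_volume <- function(data, spacing, origin = c(0, 0, 0), meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z, y, x)")
  if (any(dim(data) < 1L)) stop("all dimensions must be >= 1")
  spacing <- check_spacing(spacing)
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin),
                 meta = meta),
            class = "gray_volume")
}

#' Construct a binary air/tissue volume
#'
#' Same geometry contract as [gray_volume()]; voxels are logical with
#' `TRUE` = tissue (foreground) and `FALSE` = air. The thickness analysis
#' inverts internally when measuring the air phase.
#'
#' @inheritParams gray_volume
#' @param data 3D logical array, `TRUE` = tissue.
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(data, spacing, origin = c(0, 0, 0), meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array (z, y, x)")
  if (!is.logical(data)) {
    u <- unique(as.vector(data))
    if (length(setdiff(u, c(0, 1, 255))) > 0)
      stop("binary volume data must be logical or two-valued")
    data <- array(data == max(u), dim(data))
  }
  spacing <- check_spacing(spacing)
  structure(list(data = data, spacing = spacing, origin = as.numeric(origin),
                 meta = meta),
            class = "binary_volume")
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 3L) {
    if (max(spacing) - min(spacing) > 1e-12)
      stop("anisotropic voxel spacing is not supported")
    spacing <- spacing[1]
  }
  if (length(spacing) != 1L || !is.finite(spacing) || spacing <= 0)
    stop("`spacing` must be a single positive number (micrometres)")
  spacing
}

#' @export
print.gray_volume <- function(x, ...) {
  cat(sprintf("<gray_volume> %s voxels, spacing %g um, range [%g, %g]\n",
              paste(dim(x$data), collapse = " x "), x$spacing,
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  cat(sprintf("<binary_volume> %s voxels, spacing %g um, tissue fraction %.3f\n",
              paste(dim(x$data), collapse = " x "), x$spacing,
              mean(x$data)))
  invisible(x)
}

is_volume <- function(x) inherits(x, c("gray_volume", "binary_volume"))

stopifnot_volume <- function(x) {
  if (!is_volume(x)) stop("expected a gray_volume or binary_volume")
  invisible(x)
}

# ---- I/O -------------------------------------------------------------------

#' Read a 3D volume from disk
#'
#' Supports multi-page grayscale TIFF stacks (8/16-bit integer, read
#' bit-exact, or 32-bit float) and raw binary files with a JSON sidecar
#' (`<path>.json` holding `shape`, `dtype` and `spacing_um`). TIFF pages are
#' stacked in page order as the z axis.
#'
#' @param path file path (`.tif`/`.tiff` or `.raw`).
#' @param spacing voxel spacing in micrometres; required for TIFF, taken
#'   from the sidecar for raw files when omitted.
#' @return A [gray_volume()].
#' @export
read_volume <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.(tif|tiff)$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) == 0L) stop("TIFF file has no pages: ", path)
    shp <- dim(pages[[1]])
    if (length(shp) != 2L) stop("only single-channel grayscale TIFF supported")
    ok <- vapply(pages, function(p) identical(dim(p), shp), logical(1))
    if (!all(ok)) stop("inconsistent page shapes in ", path)
    arr <- array(0, c(length(pages), shp[1], shp[2]))
    for (z in seq_along(pages)) arr[z, , ] <- pages[[z]]
    if (is.null(spacing)) stop("`spacing` is required for TIFF input")
    vol <- gray_volume(arr, spacing,
                       meta = list(source = path,
                                   history = sprintf("read_volume('%s')", path)))
    return(vol)
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) sidecar <- sub("\\.raw$", ".json", path)
  if (!file.exists(sidecar)) stop("no JSON sidecar found for raw file: ", path)
  info <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  shp <- as.integer(info$shape)
  what <- switch(info$dtype,
                 uint8 = , int8 = "integer",
                 uint16 = , int16 = , int32 = "integer",
                 float32 = , float64 = "double",
                 stop("unsupported dtype: ", info$dtype))
  size <- switch(info$dtype, uint8 = 1L, int8 = 1L, uint16 = 2L, int16 = 2L,
                 int32 = 4L, float32 = 4L, float64 = 8L)
  n <- prod(shp)
  con <- file(path, "rb")
  on.exit(close(con))
  raw_vals <- readBin(con, what = what, n = n, size = size,
                      signed = !(info$dtype %in% c("uint8", "uint16")) || size > 2)
  if (length(raw_vals) != n) stop("raw file shorter than declared shape")
  # stored x-fastest (C order of (z, y, x)); fill accordingly
  arr <- aperm(array(raw_vals, rev(shp)), c(3, 2, 1))
  sp <- if (is.null(spacing)) info$spacing_um else spacing
  gray_volume(arr, sp, meta = list(source = path,
                                   history = sprintf("read_volume('%s')", path)))
}

#' Write a volume to disk
#'
#' Grayscale volumes are written as multi-page TIFF: integer-valued data as
#' 8- or 16-bit (bit-exact round-trip), other data as 32-bit float TIFF when
#' supported, else raw + JSON sidecar. Binary volumes are written as 8-bit
#' 0/255. Volumes containing NaN are refused.
#'
#' @param vol a [gray_volume()] or [binary_volume()].
#' @param path output path (`.tif`/`.tiff`, or `.raw` for raw + sidecar).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(vol, path) {
  stopifnot_volume(vol)
  d <- vol$data
  if (anyNA(d)) stop("refusing to write volume containing NA/NaN voxels")
  if (grepl("\\.raw$", path)) {
    con <- file(path, "wb")
    writeBin(as.vector(aperm(d * 1, c(3, 2, 1))), con, size = 8)
    close(con)
    jsonlite::write_json(list(shape = dim(d), dtype = "float64",
                              spacing_um = vol$spacing),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  if (inherits(vol, "binary_volume")) {
    pages <- lapply(seq_len(dim(d)[1]), function(z) (d[z, , ] * 255) / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
    return(invisible(path))
  }
  rng <- range(d)
  int_like <- all(d == round(d)) && rng[1] >= 0
  if (int_like && rng[2] <= 255) {
    pages <- lapply(seq_len(dim(d)[1]), function(z) d[z, , ] / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else if (int_like && rng[2] <= 65535) {
    pages <- lapply(seq_len(dim(d)[1]), function(z) d[z, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else {
    # scale into [0,1] for 32-bit float storage; record scale in sidecar
    lo <- rng[1]; sc <- if (diff(rng) > 0) diff(rng) else 1
    pages <- lapply(seq_len(dim(d)[1]), function(z) (d[z, , ] - lo) / sc)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    jsonlite::write_json(list(offset = lo, scale = sc,
                              spacing_um = vol$spacing),
                         paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

# ---- entrance dose ---------------------------------------------------------

#' Entrance-dose parameters
#'
#' Bundle of the quantities entering the synchrotron entrance-dose formula:
#' photon flux at the sample (photons/um^2), photon energy (eV), attenuation
#' length (um) and mass density (g/cm^3).
#'
#' @param flux photons per square micrometre (>= 0).
#' @param photon_energy photon energy in eV (> 0).
#' @param attenuation_length attenuation length in micrometres (> 0).
#' @param density mass density in g/cm^3 (> 0).
#' @return An object of class `dose_params`.
#' @export
dose_params <- function(flux, photon_energy, attenuation_length, density) {
  if (flux < 0) stop("`flux` must be >= 0")
  if (photon_energy <= 0 || attenuation_length <= 0 || density <= 0)
    stop("photon_energy, attenuation_length and density must be > 0")
  structure(list(flux = flux, photon_energy = photon_energy,
                 attenuation_length = attenuation_length, density = density),
            class = "dose_params")
}

#' Entrance dose of a tomographic projection
#'
#' Computes the entrance dose in Gray from the photon flux `I0`
#' (photons/um^2), photon energy `h nu` (eV), attenuation length (um) and
#' density (g/cm^3):
#' `D = 1.602e-4 * I0 * h_nu / (att_length * density)`,
#' evaluated verbatim on this unit scale (no unit auto-conversion).
#'
#' @param params a [dose_params()] object.
#' @return Dose in Gy.
#' @export
entrance_dose <- function(params) {
  if (!inherits(params, "dose_params")) stop("expected dose_params")
  1.602e-4 * params$flux * params$photon_energy /
    (params$attenuation_length * params$density)
}

# ---- configuration ---------------------------------------------------------

#' Package-wide default parameters
#'
#' Defaults used by the command-line wrappers and convenient as a starting
#' point for programmatic use. Override any subset via a YAML config file
#' read with [read_config()].
#'
#' @return Nested list of defaults per processing stage.
#' @export
lungmorph_defaults <- function() {
  list(
    segment = list(erosion_radius = 20, min_component = 27,
                   ridge = list(min_width = 1, max_width = 4,
                                min_margin = 50, max_margin = 1e6,
                                directions = c(0, 45, 90, 135))),
    thickness = list(floor = 20, cap = 170,
                     ranges = c(20, 50, 80, 110)),
    curvature = list(geodesic_radius = 3.5, smooth_iterations = 20,
                     smooth_step = 0.5)
  )
}

#' Read a YAML configuration file
#'
#' Reads a YAML file of parameter overrides and merges it (recursively)
#' over [lungmorph_defaults()].
#'
#' @param path YAML file path.
#' @return Merged parameter list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_lists(lungmorph_defaults(), user)
}

merge_lists <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_lists(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}
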