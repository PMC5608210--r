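# Rigid (Euclidean) alignment of volumes acquired at different inflation
# pressures. Landmark pairs (e.g. airway branch points clicked by the user)
# define an orthogonal Procrustes problem solved with SVD sign-correction:
# no scaling, no reflection. Gray volumes are resampled with trilinear
# interpolation, binary masks with nearest-neighbour.

#' Rigid transform container
#'
#' @param rotation 3x3 orthonormal rotation matrix (acts on `(z, y, x)`
#'   physical coordinates in micrometres).
#' @param translation length-3 translation vector, micrometres.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation, translation) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3))) stop("rotation must be 3x3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation must be orthonormal")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation must be proper (det = +1, no reflection)")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' Least-squares rigid transform between landmark sets
#'
#' Solves the orthogonal Procrustes problem: finds the rotation `R` and
#' translation `t` (no scaling, no reflection) minimising the RMS distance
#' `|R p_moving + t - p_fixed|` over all landmark pairs, using the SVD of
#' the cross-covariance with determinant sign-correction.
#'
#' @param landmarks_fixed,landmarks_moving n x 3 matrices of corresponding
#'   points `(z, y, x)` in micrometres, n >= 3, non-collinear.
#' @return A [rigid_transform()] mapping moving coordinates into the fixed
#'   frame.
#' @export
estimate_rigid <- function(landmarks_fixed, landmarks_moving) {
  A <- as.matrix(landmarks_moving)
  B <- as.matrix(landmarks_fixed)
  if (!all(dim(A) == dim(B)) || ncol(A) != 3)
    stop("landmark sets must be equal-sized n x 3 matrices")
  if (nrow(A) < 3) stop("at least 3 landmark pairs are required")
  ca <- colMeans(A)
  cb <- colMeans(B)
  Ac <- sweep(A, 2, ca)
  Bc <- sweep(B, 2, cb)
  # collinearity check: centred points must span a plane
  s_pts <- svd(Ac)$d
  if (s_pts[2] < 1e-9 * max(s_pts[1], 1))
    stop("degenerate (collinear) landmark configuration")
  H <- crossprod(Ac, Bc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_vec <- cb - as.vector(R %*% ca)
  rigid_transform(R, t_vec)
}

#' Apply a rigid transform to landmarks
#'
#' @param transform a [rigid_transform()].
#' @param points n x 3 matrix of `(z, y, x)` points, micrometres.
#' @return Transformed n x 3 matrix.
#' @export
transform_points <- function(transform, points) {
  pts <- as.matrix(points)
  sweep(pts %*% t(transform$rotation), 2, transform$translation, "+")
}

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first`, then `second`.
#'
#' @param second,first [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_rigid <- function(second, first) {
  rigid_transform(second$rotation %*% first$rotation,
                  as.vector(second$rotation %*% first$translation) +
                    second$translation)
}

#' Resample a volume under a rigid transform
#'
#' Resamples `vol` (the moving volume) into the fixed frame defined by
#' `transform`, producing a volume of `out_shape` voxels at the same
#' spacing. Gray volumes use trilinear interpolation, binary volumes
#' nearest-neighbour (no fractional labels); voxels mapping outside the
#' input are set to `fill`. Voxel `(i, j, k)` (0-based) of the output sits
#' at physical position `(i, j, k) * spacing` in the fixed frame.
#'
#' @param vol a [gray_volume()] or [binary_volume()].
#' @param transform a [rigid_transform()] mapping moving -> fixed
#'   coordinates.
#' @param out_shape output dimensions `(z, y, x)`; defaults to `dim(vol)`.
#' @param fill value used outside the moving volume (default 0).
#' @return Volume of the same class as `vol`.
#' @export
apply_rigid <- function(vol, transform, out_shape = dim(vol$data), fill = 0) {
  stopifnot_volume(vol)
  out_shape <- as.integer(out_shape)
  if (length(out_shape) != 3L || any(out_shape < 1L))
    stop("`out_shape` must be three positive dimensions")
  sp <- vol$spacing
  # fixed voxel p -> moving voxel q: q = R^-1 (p*sp - t) / sp
  Rinv <- t(transform$rotation)
  A <- Rinv
  b <- -as.vector(Rinv %*% transform$translation) / sp
  nearest <- inherits(vol, "binary_volume")
  res <- .resample_affine_cpp(vol$data * 1, dim(vol$data), A, b, out_shape,
                              nearest, fill)
  hist_entry <- sprintf("apply_rigid(out_shape=%s)",
                        paste(out_shape, collapse = "x"))
  if (nearest)
    binary_volume(array(res > 0.5, out_shape), sp,
                  meta = list(history = c(vol$meta$history, hist_entry)))
  else
    gray_volume(res, sp, meta = list(history = c(vol$meta$history, hist_entry)))
}

#' Read a landmark CSV file
#'
#' Expects columns `fixed_z, fixed_y, fixed_x, moving_z, moving_y, moving_x`
#' in micrometres.
#'
#' @param path CSV file path.
#' @return List with `fixed` and `moving` n x 3 matrices.
#' @export
read_landmarks <- function(path) {
  d <- read.csv(path)
  need <- c("fixed_z", "fixed_y", "fixed_x", "moving_z", "moving_y", "moving_x")
  if (!all(need %in% names(d)))
    stop("landmark CSV must have columns: ", paste(need, collapse = ", "))
  list(fixed = as.matrix(d[, need[1:3]]), moving = as.matrix(d[, need[4:6]]))
}
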