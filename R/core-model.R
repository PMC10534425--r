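# Pinhole imaging model with radial/tangential distortion, shared by the camera
# and the projector. Pixel convention: 0-based, (u, v) = (column, row), pixel
# centers at integer coordinates. Distortion acts in normalized image
# coordinates (after the perspective divide, before the intrinsic mapping).

#' Camera/projector intrinsics
#'
#' Focal lengths and principal point in pixel units, plus the chip size.
#'
#' @param fx,fy Focal lengths in pixel units (> 0).
#' @param cx,cy Principal point in pixel units (0-based column/row).
#' @param image_size Integer vector `c(n_cols, n_rows)`.
#' @return An object of class `sfdi_intrinsics`.
#' @export
intrinsics <- function(fx, fy, cx, cy, image_size) {
  stopifnot(fx > 0, fy > 0, length(image_size) == 2, all(image_size >= 1))
  if (cx < 0 || cx >= image_size[1] || cy < 0 || cy >= image_size[2])
    warning("principal point lies outside the chip")
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy,
                 image_size = as.integer(image_size)),
            class = "sfdi_intrinsics")
}

#' Lens distortion coefficients
#'
#' Up to three radial terms and two tangential terms, applied in normalized
#' image coordinates. All-zero coefficients give an ideal pinhole.
#'
#' @param radial Numeric vector `(k1, k2, k3)`, length 0..3.
#' @param tangential Numeric vector `(p1, p2)`.
#' @return An object of class `sfdi_distortion`.
#' @export
distortion <- function(radial = numeric(0), tangential = c(0, 0)) {
  if (length(radial) > 3)
    sfdi_stop("sfdi_config_error",
              "at most 3 radial distortion terms supported, got %d", length(radial))
  stopifnot(length(tangential) == 2, all(is.finite(radial)), all(is.finite(tangential)))
  structure(list(radial = as.numeric(radial), tangential = as.numeric(tangential)),
            class = "sfdi_distortion")
}

#' Rigid pose (global to device frame)
#'
#' Transforms global coordinates into the device frame: `x_dev = R x_glob + t`.
#'
#' @param rotation 3x3 rotation matrix (orthonormal, det +1 within 1e-9).
#' @param translation 3-vector in mm.
#' @return An object of class `sfdi_pose`.
#' @export
pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    sfdi_stop("sfdi_config_error", "rotation matrix is not orthonormal")
  if (abs(det(rotation) - 1) > 1e-9)
    sfdi_stop("sfdi_config_error", "rotation matrix determinant is not +1")
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "sfdi_pose")
}

#' Pinhole device: intrinsics + distortion + pose
#'
#' @param intrinsics An [intrinsics()] object.
#' @param distortion A [distortion()] object.
#' @param pose A [pose()] object; the identity pose makes the device frame the
#'   global frame.
#' @param role `"camera"` or `"projector"`.
#' @return An object of class `sfdi_device`.
#' @export
pinhole_device <- function(intrinsics, distortion = NULL, pose = NULL,
                           role = c("camera", "projector")) {
  role <- match.arg(role)
  structure(list(intrinsics = intrinsics,
                 distortion = distortion %||% sfdical::distortion(),
                 pose = pose %||% sfdical::pose(),
                 role = role),
            class = "sfdi_device")
}

#' @export
print.sfdi_device <- function(x, ...) {
  k <- x$intrinsics
  cat(sprintf("<sfdi_device: %s>  %d x %d px, fx = %.1f, fy = %.1f, c = (%.1f, %.1f)\n",
              x$role, k$image_size[1], k$image_size[2], k$fx, k$fy, k$cx, k$cy))
  cat(sprintf("  radial: %s  tangential: %s\n",
              paste(signif(x$distortion$radial, 4), collapse = ", "),
              paste(signif(x$distortion$tangential, 4), collapse = ", ")))
  cat(sprintf("  center (global): %s mm\n",
              paste(signif(device_center(x), 5), collapse = ", ")))
  invisible(x)
}

#' Projection center of a device in global coordinates
#' @param device An [pinhole_device()] object.
#' @return 3-vector in mm.
#' @export
device_center <- function(device) {
  p <- device$pose
  as.numeric(-crossprod(p$rotation, p$translation))
}

#' Transform points between global and device frames
#' @param pose An [pose()] object.
#' @param points n x 3 matrix (mm).
#' @return n x 3 matrix.
#' @export
to_device_frame <- function(pose, points) {
  points <- as_points(points, 3)
  sweep(points %*% t(pose$rotation), 2, pose$translation, "+")
}

#' @rdname to_device_frame
#' @export
to_global_frame <- function(pose, points) {
  points <- as_points(points, 3)
  sweep(points, 2, pose$translation, "-") %*% pose$rotation
}

#' Apply lens distortion in normalized image coordinates
#'
#' Radial displacement `u (k1 r^2 + k2 r^4 + k3 r^6)` plus the tangential term
#' `(2 p1 u v + p2 (r^2 + 2 u^2), p1 (r^2 + 2 v^2) + 2 p2 u v)`.
#'
#' @param distortion A [distortion()] object.
#' @param points n x 2 matrix of normalized coordinates.
#' @return n x 2 matrix of distorted normalized coordinates.
#' @export
apply_distortion <- function(distortion, points) {
  pts <- as_points(points, 2)
  u <- pts[, 1]; v <- pts[, 2]
  r2 <- u^2 + v^2
  k <- c(distortion$radial, 0, 0, 0)[1:3]
  radial <- k[1] * r2 + k[2] * r2^2 + k[3] * r2^3
  p1 <- distortion$tangential[1]; p2 <- distortion$tangential[2]
  du <- u * radial + 2 * p1 * u * v + p2 * (r2 + 2 * u^2)
  dv <- v * radial + p1 * (r2 + 2 * v^2) + 2 * p2 * u * v
  out <- cbind(u + du, v + dv)
  if (is.null(dim(points))) out else out
}

#' Invert lens distortion by damped fixed-point iteration
#'
#' Solves `apply_distortion(x) = x_d` for `x`. Converges for the small
#' coefficients of real lenses; non-contractive coefficient sets raise a
#' numeric error reporting the residual.
#'
#' @param distortion A [distortion()] object.
#' @param points n x 2 matrix of distorted normalized coordinates.
#' @param tol Convergence tolerance on the update (default 1e-10).
#' @param max_iter Maximum iterations (default 50).
#' @return n x 2 matrix of undistorted normalized coordinates.
#' @export
undistort_points <- function(distortion, points, tol = 1e-10, max_iter = 50) {
  pts <- as_points(points, 2)
  if (length(distortion$radial) == 0 && all(distortion$tangential == 0)) return(pts)
  x <- pts
  for (i in seq_len(max_iter)) {
    d <- apply_distortion(distortion, x) - x    # pure distortion displacement
    x_new <- pts - d
    delta <- max(abs(x_new - x))
    x <- x_new
    if (!is.finite(delta)) break
    if (delta < tol) {
      resid <- max(abs(apply_distortion(distortion, x) - pts))
      if (resid < 1e-8) return(x)
    }
  }
  resid <- suppressWarnings(max(abs(apply_distortion(distortion, x) - pts)))
  sfdi_stop("sfdi_numeric_error",
            "undistortion did not converge after %d iterations (residual %.3g)",
            max_iter, resid)
}

#' Project global 3D points to pixel coordinates
#'
#' Extrinsic transform, perspective divide, distortion in normalized
#' coordinates, then intrinsic mapping. Points at or behind the projection
#' center raise a degenerate-geometry error.
#'
#' @param device A [pinhole_device()] object.
#' @param points n x 3 matrix of global coordinates (mm), or a 3-vector.
#' @return n x 2 matrix of 0-based pixel coordinates (u, v).
#' @export
project_points <- function(device, points) {
  pts <- to_device_frame(device$pose, as_points(points, 3))
  s <- pts[, 3]
  if (any(s <= 0))
    sfdi_stop("sfdi_degenerate_geometry",
              "%d point(s) at or behind the projection center (s <= 0)", sum(s <= 0))
  norm_pts <- cbind(pts[, 1] / s, pts[, 2] / s)
  d <- apply_distortion(device$distortion, norm_pts)
  k <- device$intrinsics
  cbind(k$fx * d[, 1] + k$cx, k$fy * d[, 2] + k$cy)
}

#' Back-project pixels to unit rays in the global frame
#'
#' Undistortion is applied before back-projection; rays originate at the
#' device center and have unit norm.
#'
#' @param device A [pinhole_device()] object.
#' @param pixels n x 2 matrix of 0-based (u, v) pixel coordinates.
#' @param check_bounds Raise a bounds error for out-of-chip pixels (default TRUE).
#' @return n x 3 matrix of unit direction vectors in global coordinates.
#' @export
pixel_rays <- function(device, pixels, check_bounds = TRUE) {
  px <- as_points(pixels, 2)
  k <- device$intrinsics
  if (check_bounds) {
    bad <- px[, 1] < 0 | px[, 1] > k$image_size[1] - 1 |
           px[, 2] < 0 | px[, 2] > k$image_size[2] - 1
    if (any(bad))
      sfdi_stop("sfdi_bounds_error", "%d pixel(s) outside the chip", sum(bad))
  }
  norm_pts <- cbind((px[, 1] - k$cx) / k$fx, (px[, 2] - k$cy) / k$fy)
  und <- undistort_points(device$distortion, norm_pts)
  dirs_dev <- normalize_rows(cbind(und, 1))
  dirs_dev %*% device$pose$rotation   # R^T applied row-wise
}

# --- serialization -----------------------------------------------------------

#' Read/write a pinhole device as JSON
#'
#' The calibration-file format shared by all modules: a JSON document with
#' fields `intrinsics`, `distortion`, `pose`, `role` and `image_size`.
#'
#' @param device A [pinhole_device()] object.
#' @param path File path.
#' @return `read_device_json` returns an `sfdi_device`; `write_device_json`
#'   returns `path` invisibly.
#' @export
write_device_json <- function(device, path) {
  k <- device$intrinsics
  doc <- list(
    role = device$role,
    image_size = k$image_size,
    intrinsics = list(fx = k$fx, fy = k$fy, cx = k$cx, cy = k$cy),
    distortion = list(radial = device$distortion$radial,
                      tangential = device$distortion$tangential),
    pose = list(rotation = device$pose$rotation,
                translation = device$pose$translation))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_device_json
#' @export
read_device_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  rot <- doc$pose$rotation
  if (is.list(rot)) rot <- do.call(rbind, lapply(rot, unlist))
  pinhole_device(
    intrinsics(doc$intrinsics$fx, doc$intrinsics$fy, doc$intrinsics$cx,
               doc$intrinsics$cy, doc$image_size),
    distortion(doc$distortion$radial %||% numeric(0),
               doc$distortion$tangential %||% c(0, 0)),
    pose(rot, doc$pose$translation),
    role = doc$role)
}
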