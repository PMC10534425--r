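# Step-1 geometric calibration: circle-grid detection, phase-encoded projector
# correspondences, pinhole solves for camera and projector, frame unification,
# reference plane, predistorted patterns and per-pixel ray fields.

#' Circle-grid calibration target description
#'
#' A regular grid of printed circles; the three corner markers (origin, x-axis
#' end, y-axis end) are rendered with distinct, larger diameters so they can be
#' identified by blob area and fix the origin and main axes.
#'
#' @param n_cols,n_rows Grid size (circles per row/column).
#' @param spacing Grid constant a in mm (> circle_diameter).
#' @param circle_diameter Circle diameter in mm.
#' @param marker_scale Diameter multipliers for the origin, x-end and y-end
#'   markers (decreasing, all > 1).
#' @return An object of class `sfdi_target`.
#' @export
calibration_target <- function(n_cols = 40, n_rows = 40, spacing = 2,
                               circle_diameter = 1,
                               marker_scale = c(origin = 2.0, x = 1.7, y = 1.4)) {
  stopifnot(spacing > circle_diameter, circle_diameter > 0,
            n_cols >= 3, n_rows >= 3, all(marker_scale > 1),
            diff(marker_scale) < 0)
  structure(list(n_cols = as.integer(n_cols), n_rows = as.integer(n_rows),
                 spacing = spacing, circle_diameter = circle_diameter,
                 marker_scale = marker_scale),
            class = "sfdi_target")
}

#' Planar object points of a target in mm (grid coordinates times spacing)
#'
#' @param target A [calibration_target()] object.
#' @return n x 2 matrix, ordered row-major by grid y then grid x.
#' @export
object_points <- function(target) {
  g <- expand.grid(ix = 0:(target$n_cols - 1), iy = 0:(target$n_rows - 1))
  cbind(g$ix, g$iy) * target$spacing
}

#' @noRd
marker_grid_nodes <- function(target) {
  rbind(origin = c(0, 0),
        x = c(target$n_cols - 1, 0),
        y = c(0, target$n_rows - 1))
}

#' Detect the circle grid in a DC image
#'
#' Binarizes the (dark circles on bright background) DC image, extracts blob
#' centroids with EBImage, identifies the three enlarged corner markers by
#' area, and orders all centroids by grid coordinate via an affine estimate
#' from the markers refined by a full homography.
#'
#' @param dc_image Numeric matrix (row, col), e.g. `i_dc` from [demodulate()].
#' @param target A [calibration_target()] object.
#' @return List with `image_points` (n x 2, 0-based pixels, ordered like
#'   [object_points()]), `object_points` (mm), `grid_coords`, and `markers`.
#' @export
detect_grid <- function(dc_image, target) {
  rng <- range(dc_image, na.rm = TRUE)
  thr <- mean(c(stats::quantile(dc_image, 0.05, na.rm = TRUE),
                stats::quantile(dc_image, 0.95, na.rm = TRUE)))
  binary <- dc_image < thr
  binary[is.na(binary)] <- FALSE
  # EBImage uses [x, y] = [col, row]; transpose our [row, col] maps
  lab <- EBImage::bwlabel(EBImage::Image(t(binary)))
  n_expect <- target$n_cols * target$n_rows
  n_blobs <- max(lab)
  if (n_blobs != n_expect)
    sfdi_stop("sfdi_detection_error",
              "expected %d grid circles, detected %d blobs", n_expect, n_blobs)
  # sub-pixel centroids: weight by darkness so the smooth circle edge counts
  weight <- pmax(thr - dc_image, 0)
  weight[is.na(weight)] <- 0
  mom <- EBImage::computeFeatures.moment(lab, EBImage::Image(t(weight)))
  shp <- EBImage::computeFeatures.shape(lab)
  uv <- cbind(mom[, "m.cx"] - 1, mom[, "m.cy"] - 1)   # 0-based (u, v)
  area <- shp[, "s.area"]
  ord <- order(area, decreasing = TRUE)
  if (area[ord[3]] / area[ord[4]] < 1.1)
    sfdi_stop("sfdi_detection_error",
              "axis markers ambiguous: marker/circle area ratio %.2f",
              area[ord[3]] / area[ord[4]])
  # origin = largest, x-end = second, y-end = third (by construction)
  markers_uv <- uv[ord[1:3], , drop = FALSE]
  marker_grid <- marker_grid_nodes(target)
  # affine from the 3 markers: [gx gy 1] %*% M = [u v]
  G <- cbind(marker_grid, 1)
  M <- solve(G, markers_uv)
  grid_est <- cbind(uv, 1) %*% solve(cbind(M, c(0, 0, 1)))[, 1:2]
  assign_grid <- function(est) {
    gc <- round(est)
    ok <- abs(est - gc) < 0.35 &
      gc[, 1] >= 0 & gc[, 1] < target$n_cols & gc[, 2] >= 0 & gc[, 2] < target$n_rows
    list(gc = gc, ok = ok[, 1] & ok[, 2])
  }
  a1 <- assign_grid(grid_est)
  if (sum(a1$ok) >= 8) {   # refine with a homography over confident points
    H <- homography_dlt(a1$gc[a1$ok, , drop = FALSE], uv[a1$ok, , drop = FALSE])
    Hi <- solve(H)
    ph <- cbind(uv, 1) %*% t(Hi)
    a1 <- assign_grid(ph[, 1:2] / ph[, 3])
  }
  if (!all(a1$ok))
    sfdi_stop("sfdi_detection_error",
              "%d blob(s) could not be assigned to grid nodes", sum(!a1$ok))
  key <- a1$gc[, 1] + target$n_cols * a1$gc[, 2]
  if (anyDuplicated(key))
    sfdi_stop("sfdi_detection_error", "duplicate grid assignments (ambiguous axes)")
  idx <- order(key)
  list(image_points = uv[idx, , drop = FALSE],
       object_points = a1$gc[idx, , drop = FALSE] * target$spacing,
       grid_coords = a1$gc[idx, , drop = FALSE],
       markers = markers_uv)
}

#' Projector (DMD) image points from unwrapped phase maps
#'
#' Samples the unwrapped column/row phase maps bilinearly at the detected
#' marker centroids and converts phase to DMD pixel coordinates:
#' `u_DLP = phi_u / (f_col * 4 * pi / N_col)` and analogously for rows.
#'
#' @param phase_u Unwrapped phase map of the column-encoding pattern.
#' @param phase_v Unwrapped phase map of the row-encoding pattern.
#' @param camera_points n x 2 matrix of 0-based camera pixel coordinates.
#' @param pattern_spec List with `n_col`, `n_row` (DMD size) and `f_col`,
#'   `f_row` (pixel-based pattern frequencies).
#' @return List with `dmd_points` (n x 2) and logical `ok` flagging points
#'   inside the representable range; out-of-range markers are NA with a warning.
#' @export
projector_points_from_phase <- function(phase_u, phase_v, camera_points,
                                        pattern_spec) {
  cp <- as_points(camera_points, 2)
  pu <- bilinear_sample(phase_u, cp[, 1], cp[, 2])
  pv <- bilinear_sample(phase_v, cp[, 1], cp[, 2])
  u_dlp <- pu / (pattern_spec$f_col * 4 * pi / pattern_spec$n_col)
  v_dlp <- pv / (pattern_spec$f_row * 4 * pi / pattern_spec$n_row)
  ok <- is.finite(u_dlp) & is.finite(v_dlp) &
    u_dlp >= 0 & u_dlp < pattern_spec$n_col &
    v_dlp >= 0 & v_dlp < pattern_spec$n_row
  if (!all(ok)) {
    warning(sprintf("%d marker(s) outside the representable DMD range dropped",
                    sum(!ok)))
    u_dlp[!ok] <- NA_real_; v_dlp[!ok] <- NA_real_
  }
  pts <- unname(cbind(u_dlp, v_dlp))
  dimnames(pts) <- NULL
  list(dmd_points = pts, ok = ok)
}

#' Calibrate one pinhole device from planar correspondences
#'
#' Closed-form (homography-based) initialization followed by
#' Levenberg-Marquardt refinement of intrinsics, radial distortion and
#' per-pose extrinsics, minimizing the reprojection error over all poses.
#'
#' @param object_points List (one per pose) of n x 2 planar coordinates in mm.
#' @param image_points List (one per pose) of n x 2 pixel coordinates.
#' @param image_size `c(n_cols, n_rows)` of the device chip.
#' @param n_radial Number of radial distortion terms to fit (0..3, default 2).
#' @param fit_tangential Also fit the two tangential terms (default FALSE).
#' @param role Device role for the returned object.
#' @return List with `device` (an [pinhole_device()] with identity pose),
#'   `poses` (per-pose [pose()] objects), and `rms` reprojection error in px.
#' @export
calibrate_device <- function(object_points, image_points, image_size,
                             n_radial = 2, fit_tangential = FALSE,
                             role = "camera") {
  if (length(object_points) < 3)
    sfdi_stop("sfdi_input_error",
              "at least three target poses required, got %d", length(object_points))
  if (n_radial > 3)
    sfdi_stop("sfdi_config_error", "at most 3 radial terms supported")
  stopifnot(length(object_points) == length(image_points))
  keep <- mapply(function(o, i) stats::complete.cases(o) & stats::complete.cases(i),
                 object_points, image_points, SIMPLIFY = FALSE)
  object_points <- mapply(function(p, k) p[k, , drop = FALSE], object_points, keep,
                          SIMPLIFY = FALSE)
  image_points <- mapply(function(p, k) p[k, , drop = FALSE], image_points, keep,
                         SIMPLIFY = FALSE)
  sol <- solve_planar_calibration(object_points, image_points, image_size,
                                  n_radial = n_radial, fit_tangential = fit_tangential)
  dev <- pinhole_device(
    intrinsics(sol$K$fx, sol$K$fy, sol$K$cx, sol$K$cy, image_size),
    distortion(sol$radial, sol$tangential),
    pose(), role = role)
  list(device = dev,
       poses = lapply(sol$poses, function(p) pose(p$rotation, p$translation)),
       rms = sol$rms)
}

# --- frame unification and system geometry -----------------------------------

#' @noRd
rot_to_quat <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- 0.25 * s
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  q / sqrt(sum(q^2))
}

#' @noRd
quat_to_rot <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

#' System geometry: camera, projector, reference plane and calibrated volume
#'
#' The camera pose is the identity and defines the global frame; the projector
#' pose expresses the projector-to-camera transform.
#'
#' @param camera,projector [pinhole_device()] objects.
#' @param volume List with `center` (3-vector mm) and `size` (3-vector mm).
#' @param reference_plane List with `point` and `normal`; default from
#'   [define_reference_plane()].
#' @param reprojection_rms Named numeric, px per device.
#' @param axis_tolerance Max allowed angle (deg) between the reference-plane
#'   normal and the camera optical axis.
#' @return An object of class `sfdi_geometry`.
#' @export
system_geometry <- function(camera, projector, volume,
                            reference_plane = NULL,
                            reprojection_rms = c(camera = NA_real_, projector = NA_real_),
                            axis_tolerance = 1) {
  reference_plane <- reference_plane %||% define_reference_plane(volume)
  axis <- as.numeric(camera$pose$rotation[3, ])   # camera optical axis, global
  cosang <- abs(sum(reference_plane$normal * axis)) /
    sqrt(sum(reference_plane$normal^2))
  if (acos(pmin(cosang, 1)) > axis_tolerance * pi / 180)
    sfdi_stop("sfdi_config_error",
              "reference plane normal deviates from the camera optical axis")
  half <- volume$size / 2
  inside <- all(abs(reference_plane$point - volume$center) <= half + 1e-9)
  if (!inside)
    sfdi_stop("sfdi_config_error", "reference plane lies outside the calibrated volume")
  structure(list(camera = camera, projector = projector,
                 reference_plane = reference_plane, volume = volume,
                 reprojection_rms = reprojection_rms),
            class = "sfdi_geometry")
}

#' @export
print.sfdi_geometry <- function(x, ...) {
  cat(sprintf("<sfdi_geometry> reference plane z = %.1f mm, volume %s mm\n",
              x$reference_plane$point[3],
              paste(signif(x$volume$size, 4), collapse = " x ")))
  cat(sprintf("  projector center: (%s) mm, rms: %s px\n",
              paste(signif(device_center(x$projector), 4), collapse = ", "),
              paste(signif(x$reprojection_rms, 3), collapse = "/")))
  invisible(x)
}

#' Unify camera and projector frames into one system geometry
#'
#' Expresses the projector pose in the camera frame using the shared target
#' poses: per pose, `R_rel = R_pro R_cam^T`, `t_rel = t_pro - R_rel t_cam`;
#' per-pose estimates are averaged (rotation via quaternion mean, translation
#' arithmetic) and the spread is reported. The calibrated volume defaults to
#' the bounding box of the target points across poses, in camera coordinates.
#'
#' @param camera_calib,projector_calib Results of [calibrate_device()] on the
#'   same pose set.
#' @param object_points List of per-pose planar target points (mm), used to
#'   compute the calibrated volume; optional if `volume` is given.
#' @param volume Optional explicit volume (list with `center`, `size`).
#' @param spread_tolerance Warn when the per-pose translation spread exceeds
#'   this value (mm).
#' @return An `sfdi_geometry`; attributes `rotation_spread_deg` and
#'   `translation_spread_mm` report the per-pose agreement (NA for one pose).
#' @export
unify_frames <- function(camera_calib, projector_calib, object_points = NULL,
                         volume = NULL, spread_tolerance = 1) {
  n <- length(camera_calib$poses)
  stopifnot(n == length(projector_calib$poses))
  rels <- vector("list", n)
  for (i in seq_len(n)) {
    Rc <- camera_calib$poses[[i]]$rotation; tc <- camera_calib$poses[[i]]$translation
    Rp <- projector_calib$poses[[i]]$rotation; tp <- projector_calib$poses[[i]]$translation
    Rrel <- Rp %*% t(Rc)
    rels[[i]] <- list(R = Rrel, t = tp - as.numeric(Rrel %*% tc))
  }
  if (n == 1) {
    Rm <- rels[[1]]$R; tm <- rels[[1]]$t
    rot_spread <- NA_real_; t_spread <- NA_real_
  } else {
    qs <- vapply(rels, function(r) rot_to_quat(r$R), numeric(4))
    qs <- sweep(qs, 2, sign(colSums(qs * qs[, 1])), "*")   # hemisphere align
    Rm <- quat_to_rot(rowMeans(qs))
    ts <- vapply(rels, `[[`, numeric(3), "t")
    tm <- rowMeans(ts)
    rot_spread <- max(vapply(rels, function(r) {
      ang <- acos(pmin(pmax((sum(diag(t(Rm) %*% r$R)) - 1) / 2, -1), 1))
      ang * 180 / pi
    }, numeric(1)))
    t_spread <- max(sqrt(colSums((ts - tm)^2)))
    if (t_spread > spread_tolerance)
      warning(sprintf(
        "projector pose spread across poses: %.3f mm / %.3f deg", t_spread, rot_spread))
  }
  projector <- projector_calib$device
  projector$pose <- pose(Rm, tm)
  projector$role <- "projector"
  if (is.null(volume)) {
    if (is.null(object_points))
      sfdi_stop("sfdi_input_error", "need object_points or an explicit volume")
    pts <- do.call(rbind, lapply(seq_len(n), function(i) {
      P <- cbind(as_points(object_points[[i]], 2), 0)
      ps <- camera_calib$poses[[i]]
      sweep(P %*% t(ps$rotation), 2, ps$translation, "+")
    }))
    lo <- apply(pts, 2, min); hi <- apply(pts, 2, max)
    volume <- list(center = (lo + hi) / 2, size = pmax(hi - lo, 1e-6))
  }
  geo <- system_geometry(camera_calib$device, projector, volume,
                         reprojection_rms = c(camera = camera_calib$rms,
                                              projector = projector_calib$rms))
  attr(geo, "rotation_spread_deg") <- rot_spread
  attr(geo, "translation_spread_mm") <- t_spread
  geo
}

#' Reference plane at the center of the calibrated volume
#'
#' Plane through the volume center, normal along the camera optical axis
#' (the global +z axis, since the camera defines the global frame).
#'
#' @param volume List with `center` and `size`.
#' @return List with `point` and `normal`.
#' @export
define_reference_plane <- function(volume) {
  list(point = as.numeric(volume$center), normal = c(0, 0, 1))
}

#' Intersect rays with a plane
#' @noRd
intersect_plane <- function(origin, dirs, point, normal) {
  denom <- dirs %*% normal
  tt <- as.numeric(((point - origin) %*% normal)) / as.numeric(denom)
  tt[abs(denom) < 1e-12 | tt <= 0] <- NA_real_
  tt
}

#' Generate a predistorted DMD pattern for a metric fringe frequency
#'
#' For each DMD pixel, intersects its ray with the reference plane and writes
#' the sinusoid of the target metric fringe field at the intersection, so the
#' projected pattern shows equidistant fringes of `f_target` per mm on the
#' reference plane.
#'
#' @param geometry An [system_geometry()] object.
#' @param f_target Metric spatial frequency at the reference plane, 0..1 1/mm.
#' @param orientation `"y"` (fringes constant along x, default) or `"x"`.
#' @param phase_offset Phase shift in radians.
#' @return Matrix (n_row x n_col) of intensities in 0..1; DMD pixels whose
#'   rays miss the plane are 0 and flagged in the `masked` attribute.
#' @export
generate_predistorted_patterns <- function(geometry, f_target,
                                           orientation = c("y", "x"),
                                           phase_offset = 0) {
  orientation <- match.arg(orientation)
  if (f_target < 0 || f_target > 1)
    sfdi_stop("sfdi_config_error", "f_target must lie in [0, 1] 1/mm, got %g", f_target)
  pro <- geometry$projector
  sz <- pro$intrinsics$image_size
  nr <- sz[2]; nc <- sz[1]
  u <- rep(0:(nc - 1), each = nr); v <- rep(0:(nr - 1), nc)
  dirs <- pixel_rays(pro, cbind(u, v))
  orig <- device_center(pro)
  tt <- intersect_plane(orig, dirs, geometry$reference_plane$point,
                        geometry$reference_plane$normal)
  coord <- orig[if (orientation == "y") 2 else 1] +
    tt * dirs[, if (orientation == "y") 2 else 1]
  val <- 0.5 + 0.5 * cos(2 * pi * f_target * coord + phase_offset)
  masked <- is.na(val)
  val[masked] <- 0
  out <- matrix(val, nr, nc)
  attr(out, "masked") <- matrix(masked, nr, nc)
  out
}

#' Per-pixel unit ray fields for a device
#'
#' Vectorized [pixel_rays()] over the full chip, optionally subsampled.
#'
#' @param geometry An [system_geometry()] object.
#' @param device `"camera"` or `"projector"`.
#' @return List with matrices `x`, `y`, `z` (unit ray components per pixel,
#'   row/col layout), `origin` (device center) and the pixel grid used.
#' @export
build_ray_fields <- function(geometry, device = c("camera", "projector")) {
  device <- match.arg(device)
  dev <- geometry[[device]]
  sz <- dev$intrinsics$image_size
  nr <- sz[2]; nc <- sz[1]
  u <- rep(0:(nc - 1), each = nr); v <- rep(0:(nr - 1), nc)
  dirs <- pixel_rays(dev, cbind(u, v))
  list(x = matrix(dirs[, 1], nr, nc), y = matrix(dirs[, 2], nr, nc),
       z = matrix(dirs[, 3], nr, nc), origin = device_center(dev),
       image_size = sz)
}

#' Read/write a system geometry as JSON
#'
#' @param geometry An [system_geometry()] object.
#' @param path File path.
#' @return `read_system_geometry` returns an `sfdi_geometry`.
#' @export
write_system_geometry <- function(geometry, path) {
  tmp_cam <- tempfile(fileext = ".json"); tmp_pro <- tempfile(fileext = ".json")
  on.exit(unlink(c(tmp_cam, tmp_pro)))
  write_device_json(geometry$camera, tmp_cam)
  write_device_json(geometry$projector, tmp_pro)
  doc <- list(camera = jsonlite::read_json(tmp_cam),
              projector = jsonlite::read_json(tmp_pro),
              reference_plane = geometry$reference_plane,
              volume = geometry$volume,
              reprojection_rms = as.list(geometry$reprojection_rms))
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_system_geometry
#' @export
read_system_geometry <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  dev_from <- function(d) {
    tmp <- tempfile(fileext = ".json")
    on.exit(unlink(tmp))
    jsonlite::write_json(d, tmp, digits = NA, auto_unbox = TRUE)
    read_device_json(tmp)
  }
  system_geometry(dev_from(doc$camera), dev_from(doc$projector),
                  volume = list(center = unlist(doc$volume$center),
                                size = unlist(doc$volume$size)),
                  reference_plane = list(point = unlist(doc$reference_plane$point),
                                         normal = unlist(doc$reference_plane$normal)),
                  reprojection_rms = unlist(doc$reprojection_rms))
}
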