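# Parameterized 3D point estimation: per-pixel cubic phase-distance
# polynomials fitted on virtual planes, conversion of unwrapped phase maps to
# point clouds, grid-PCA normals, local frames and projection/detection
# angles.
#
# Angle conventions (documented; the source equations are ambiguous):
#   phi_*   polar angle between the ray and the surface normal (0 = normal
#           incidence); the oblique projection geometry shows up here
#           (mean phi_pro ~ 35 deg on a flat sample).
#   theta_* azimuth of the ray's tangential component, measured from the
#           in-plane pattern propagation direction (~0 on the reference
#           geometry).

#' Pattern specification for the global phase field
#'
#' `metric` patterns are predistorted fringes with frequency `f` per mm on the
#' reference plane, varying along `orientation`; `dmd` patterns encode DMD
#' pixel columns/rows with pixel-based frequency `f_px` (phase
#' `u_DLP * 4 pi f_px / N`).
#'
#' @param type `"metric"` or `"dmd"`.
#' @param f Metric frequency (1/mm) for `metric` patterns.
#' @param orientation `"y"` or `"x"` (metric): axis along which the fringe
#'   field varies on the reference plane.
#' @param axis `"u"` or `"v"` (dmd): encoded chip axis.
#' @param f_px Pixel-based frequency (dmd).
#' @return A list of class `sfdi_pattern`.
#' @export
pattern_spec <- function(type = c("metric", "dmd"), f = 0.45,
                         orientation = c("y", "x"), axis = c("u", "v"),
                         f_px = 10) {
  type <- match.arg(type)
  structure(list(type = type, f = f, orientation = match.arg(orientation),
                 axis = match.arg(axis), f_px = f_px),
            class = "sfdi_pattern")
}

#' Global phase of the projected pattern at 3D points
#'
#' For metric (predistorted) patterns the fringe phase carried by the light
#' through a point equals the fringe field at the reference-plane piercing
#' point of the projector ray through it; for DMD patterns the phase encodes
#' the DMD pixel coordinate obtained by projecting the point through the
#' projector model.
#'
#' @param geometry An [system_geometry()] object.
#' @param points n x 3 matrix of global coordinates.
#' @param pattern A [pattern_spec()].
#' @return Numeric vector of absolute phase in radians (NA where degenerate).
#' @export
phase_of_points <- function(geometry, points, pattern) {
  pts <- as_points(points, 3)
  pro <- geometry$projector
  if (pattern$type == "metric") {
    orig <- device_center(pro)
    dirs <- sweep(pts, 2, orig)       # not normalized; plane intersection is affine
    denom <- dirs %*% geometry$reference_plane$normal
    tt <- as.numeric(((geometry$reference_plane$point - orig) %*%
                        geometry$reference_plane$normal)) / as.numeric(denom)
    j <- if (pattern$orientation == "y") 2 else 1
    coord <- orig[j] + tt * dirs[, j]
    coord[abs(denom) < 1e-12] <- NA_real_
    2 * pi * pattern$f * coord
  } else {
    uv <- project_points(pro, pts)
    n_ax <- pro$intrinsics$image_size[if (pattern$axis == "u") 1 else 2]
    uv[, if (pattern$axis == "u") 1 else 2] * (4 * pi * pattern$f_px / n_ax)
  }
}

#' Fit per-pixel cubic phase-distance polynomials on virtual planes
#'
#' Samples each camera ray at its intersections with `n_planes` virtual planes
#' spanning the calibrated volume in z, maps every sample through the
#' projector model to its global phase, and fits (per pixel, least squares) a
#' cubic polynomial distance-vs-phase relation. Phases are centered and scaled
#' per pixel before fitting for numerical conditioning. Monotonicity of the
#' fitted cubic over the sampled phase range is asserted; offending pixels are
#' invalidated.
#'
#' @param geometry An [system_geometry()] object.
#' @param n_planes Number of virtual planes (>= 4; default 10).
#' @param pattern A [pattern_spec()] describing the measurement pattern whose
#'   phase will be converted to distance.
#' @param rays Optional precomputed camera ray field from [build_ray_fields()].
#' @return An object of class `sfdi_phase_distance` with per-pixel coefficient
#'   arrays, valid phase ranges, fit residuals and a validity mask.
#' @export
fit_phase_distance <- function(geometry, n_planes = 10, pattern = pattern_spec(),
                               rays = NULL) {
  if (n_planes < 4)
    sfdi_stop("sfdi_input_error",
              "cubic phase-distance fit needs at least 4 planes, got %d", n_planes)
  rays <- rays %||% build_ray_fields(geometry, "camera")
  nr <- nrow(rays$x); nc <- ncol(rays$x); npix <- nr * nc
  dirs <- cbind(as.numeric(rays$x), as.numeric(rays$y), as.numeric(rays$z))
  orig <- rays$origin
  zc <- geometry$volume$center[3]; hz <- geometry$volume$size[3] / 2
  z_planes <- seq(zc - hz, zc + hz, length.out = n_planes)
  PHI <- matrix(NA_real_, npix, n_planes)
  L <- matrix(NA_real_, npix, n_planes)
  for (k in seq_len(n_planes)) {
    tt <- intersect_plane(orig, dirs, c(0, 0, z_planes[k]), c(0, 0, 1))
    P <- sweep(dirs * tt, 2, orig, "+")
    L[, k] <- tt
    ok <- stats::complete.cases(P)
    phi <- rep(NA_real_, npix)
    if (pattern$type == "dmd") {
      # points behind the projector frustum are flagged, not fatal
      phi[ok] <- tryCatch(phase_of_points(geometry, P[ok, , drop = FALSE], pattern),
                          error = function(e) rep(NA_real_, sum(ok)))
      n_ax <- geometry$projector$intrinsics$image_size[
        if (pattern$axis == "u") 1 else 2]
      rng <- c(0, n_ax) * (4 * pi * pattern$f_px / n_ax)
      phi[!is.na(phi) & (phi < rng[1] | phi > rng[2])] <- NA_real_
    } else {
      phi[ok] <- phase_of_points(geometry, P[ok, , drop = FALSE], pattern)
    }
    PHI[, k] <- phi
  }
  support <- rowSums(is.finite(PHI) & is.finite(L))
  valid <- support >= 4
  reduced <- valid & support < n_planes
  w <- is.finite(PHI) & is.finite(L)
  PHIw <- PHI; PHIw[!w] <- 0; Lw <- L; Lw[!w] <- 0
  mu <- rowSums(PHIw) / pmax(support, 1)
  sdv <- sqrt(rowSums((PHIw - mu * w)^2 * w) / pmax(support - 1, 1))
  sdv[sdv < 1e-12] <- 1
  X <- (PHI - mu) / sdv            # standardized phase, NA where unsupported
  # power sums for the per-pixel 4x4 normal equations
  pow <- function(p) { M <- X^p; M[!w] <- 0; rowSums(M) }
  S <- lapply(0:6, pow)
  Tm <- lapply(0:3, function(p) { M <- X^p * L; M[!w] <- 0; rowSums(M) })
  coef <- matrix(NA_real_, npix, 4)
  resid_max <- rep(NA_real_, npix)
  idx <- which(valid)
  A <- matrix(0, 4, 4); b <- numeric(4)
  for (i in idx) {
    for (r in 1:4) for (cc in 1:4) A[r, cc] <- S[[r + cc - 1]][i]
    for (r in 1:4) b[r] <- Tm[[r]][i]
    cf <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(cf)) { valid[i] <- FALSE; next }
    coef[i, ] <- cf
    xi <- X[i, w[i, ]]
    fit <- cf[1] + cf[2] * xi + cf[3] * xi^2 + cf[4] * xi^3
    resid_max[i] <- max(abs(fit - L[i, w[i, ]]))
  }
  # monotonicity of the cubic over the sampled range
  Xmin <- apply(X, 1, function(r) suppressWarnings(min(r, na.rm = TRUE)))
  Xmax <- apply(X, 1, function(r) suppressWarnings(max(r, na.rm = TRUE)))
  mono <- monotone_cubic(coef, Xmin, Xmax)
  valid <- valid & (mono | !is.finite(Xmin))
  structure(list(
    coef = coef, phi_mean = mu, phi_sd = sdv,
    phi_range = cbind(mu + Xmin * sdv, mu + Xmax * sdv),
    valid = matrix(valid, nr, nc),
    reduced_support = matrix(reduced, nr, nc),
    resid_max = matrix(resid_max, nr, nc),
    n_planes = n_planes, z_planes = z_planes, pattern = pattern,
    image_size = rays$image_size, origin = orig),
    class = "sfdi_phase_distance")
}

#' Strict monotonicity of cubics over an interval, vectorized
#' @noRd
monotone_cubic <- function(coef, lo, hi) {
  a1 <- coef[, 2]; a2 <- coef[, 3]; a3 <- coef[, 4]
  d_at <- function(x) a1 + 2 * a2 * x + 3 * a3 * x^2
  s_lo <- d_at(lo); s_hi <- d_at(hi)
  ok <- sign(s_lo) == sign(s_hi) & s_lo != 0
  # critical points of the derivative inside the range flip monotonicity
  disc <- (2 * a2)^2 - 4 * (3 * a3) * a1
  has_root <- is.finite(disc) & disc > 0 & abs(a3) > 1e-15
  r1 <- (-2 * a2 - sqrt(pmax(disc, 0))) / (2 * 3 * a3)
  r2 <- (-2 * a2 + sqrt(pmax(disc, 0))) / (2 * 3 * a3)
  inside <- has_root & ((r1 > lo & r1 < hi) | (r2 > lo & r2 < hi))
  ok & !inside
}

#' Convert an unwrapped phase map to a 3D surface map
#'
#' Evaluates the per-pixel phase-distance polynomial and multiplies by the
#' camera ray field. Phases outside the per-pixel calibrated range are masked
#' and counted.
#'
#' @param model An [fit_phase_distance()] result.
#' @param phase_map Unwrapped absolute phase map (matrix).
#' @param geometry The [system_geometry()] used to fit the model.
#' @param rays Optional camera ray field.
#' @param range_tolerance Fractional extension of the valid phase range
#'   allowed before masking (default 0.02).
#' @return An object of class `sfdi_surface` with matrices `x`, `y`, `z`
#'   (global mm), `l` (distance along the camera ray), `valid`, plus the ray
#'   field; the number of out-of-range pixels is in attribute `n_masked_range`.
#' @export
phase_to_points <- function(model, phase_map, geometry, rays = NULL,
                            range_tolerance = 0.02) {
  rays <- rays %||% build_ray_fields(geometry, "camera")
  phi <- as.numeric(phase_map)
  lo <- model$phi_range[, 1]; hi <- model$phi_range[, 2]
  pad <- (hi - lo) * range_tolerance
  in_range <- phi >= lo - pad & phi <= hi + pad
  ok <- as.numeric(model$valid) > 0 & is.finite(phi) & in_range
  n_masked <- sum(as.numeric(model$valid) > 0 & is.finite(phi) & !in_range)
  x <- (phi - model$phi_mean) / model$phi_sd
  l <- model$coef[, 1] + model$coef[, 2] * x + model$coef[, 3] * x^2 +
    model$coef[, 4] * x^3
  l[!ok] <- NA_real_
  nr <- nrow(phase_map); nc <- ncol(phase_map)
  out <- structure(list(
    x = matrix(rays$origin[1] + l * as.numeric(rays$x), nr, nc),
    y = matrix(rays$origin[2] + l * as.numeric(rays$y), nr, nc),
    z = matrix(rays$origin[3] + l * as.numeric(rays$z), nr, nc),
    l = matrix(l, nr, nc),
    valid = matrix(ok, nr, nc),
    rays = rays),
    class = "sfdi_surface")
  attr(out, "n_masked_range") <- n_masked
  out
}

#' Construct a surface map directly from known geometry
#'
#' Used by the digital twin to emit ground truth in the same container the
#' pipeline produces.
#' @noRd
surface_from_points <- function(x, y, z, rays) {
  l <- sqrt((x - rays$origin[1])^2 + (y - rays$origin[2])^2 + (z - rays$origin[3])^2)
  structure(list(x = x, y = y, z = z, l = l,
                 valid = is.finite(as.numeric(z)) &
                   matrix(TRUE, nrow(z), ncol(z)), rays = rays),
            class = "sfdi_surface")
}

#' Estimate surface normals on the pixel grid by local-plane PCA
#'
#' For each pixel, fits a plane (smallest principal component) to the valid 3D
#' points in the surrounding window covering about `k_neighbors` neighbors,
#' and orients the normal toward the camera.
#'
#' @param surface An `sfdi_surface`.
#' @param k_neighbors Target neighbor count (>= 3; default 16, i.e. a 5x5
#'   window).
#' @return The surface with matrices `nx`, `ny`, `nz` added; pixels with fewer
#'   than 3 valid neighbors are invalidated.
#' @export
estimate_normals <- function(surface, k_neighbors = 16) {
  if (k_neighbors < 3)
    sfdi_stop("sfdi_input_error",
              "normal estimation needs k_neighbors >= 3, got %d", k_neighbors)
  r <- max(1L, as.integer(ceiling((sqrt(k_neighbors + 1) - 1) / 2)))
  nr <- nrow(surface$z); nc <- ncol(surface$z)
  w <- matrix(as.numeric(surface$valid), nr, nc)
  box <- function(m) { m[is.na(m)] <- 0; box_filter(m, r) }
  n <- box(w)
  sx <- box(surface$x * w); sy <- box(surface$y * w); sz <- box(surface$z * w)
  sxx <- box(surface$x^2 * w); syy <- box(surface$y^2 * w); szz <- box(surface$z^2 * w)
  sxy <- box(surface$x * surface$y * w); sxz <- box(surface$x * surface$z * w)
  syz <- box(surface$y * surface$z * w)
  ok <- n >= 3 & surface$valid
  # covariance entries
  cxx <- sxx / n - (sx / n)^2; cyy <- syy / n - (sy / n)^2; czz <- szz / n - (sz / n)^2
  cxy <- sxy / n - sx * sy / n^2; cxz <- sxz / n - sx * sz / n^2
  cyz <- syz / n - sy * sz / n^2
  npix <- nr * nc
  nxv <- rep(NA_real_, npix); nyv <- rep(NA_real_, npix); nzv <- rep(NA_real_, npix)
  idx <- which(as.numeric(ok) > 0)
  for (i in idx) {
    C <- matrix(c(cxx[i], cxy[i], cxz[i],
                  cxy[i], cyy[i], cyz[i],
                  cxz[i], cyz[i], czz[i]), 3, 3)
    ev <- eigen(C, symmetric = TRUE)
    v <- ev$vectors[, 3]
    nxv[i] <- v[1]; nyv[i] <- v[2]; nzv[i] <- v[3]
  }
  # orient toward the camera: n . e_cam < 0
  ex <- as.numeric(surface$rays$x); ey <- as.numeric(surface$rays$y)
  ez <- as.numeric(surface$rays$z)
  dp <- nxv * ex + nyv * ey + nzv * ez
  flip <- !is.na(dp) & dp > 0
  nxv[flip] <- -nxv[flip]; nyv[flip] <- -nyv[flip]; nzv[flip] <- -nzv[flip]
  surface$nx <- matrix(nxv, nr, nc)
  surface$ny <- matrix(nyv, nr, nc)
  surface$nz <- matrix(nzv, nr, nc)
  surface$valid <- ok & !is.na(surface$nx)
  surface
}

#' Moving-window box sum via cumulative sums
#' @noRd
box_filter <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  cs <- apply(rbind(0, m), 2, cumsum)
  lo <- pmax(0:(nr - 1) - r, 0); hi <- pmin(0:(nr - 1) + r + 1, nr)
  mr <- cs[hi + 1, , drop = FALSE] - cs[lo + 1, , drop = FALSE]
  cs2 <- t(apply(cbind(0, mr), 1, cumsum))
  lo2 <- pmax(0:(nc - 1) - r, 0); hi2 <- pmin(0:(nc - 1) + r + 1, nc)
  cs2[, hi2 + 1, drop = FALSE] - cs2[, lo2 + 1, drop = FALSE]
}

#' Local surface frame from normal, projector ray and pattern direction
#'
#' `e_z = n`; `e_x` is the pattern (constant-phase) direction projected along
#' the projector ray onto the surface tangent plane; `e_y = e_z x e_x`. The
#' returned rotation maps global to local coordinates.
#'
#' @param normal Unit surface normal (3-vector).
#' @param projector_ray Unit ray direction, projector toward the surface.
#' @param pattern_direction Unit fringe (constant-phase) direction in the
#'   reference plane.
#' @return 3x3 orthonormal rotation matrix with rows `e_x`, `e_y`, `e_z`.
#' @export
local_frame <- function(normal, projector_ray, pattern_direction) {
  nd_e <- sum(normal * projector_ray)
  if (abs(nd_e) < 1e-9)
    sfdi_stop("sfdi_degenerate_geometry", "projector ray is tangent to the surface")
  ex <- pattern_direction - projector_ray * (sum(normal * pattern_direction) / nd_e)
  nx <- sqrt(sum(ex^2))
  if (nx < 1e-9)
    sfdi_stop("sfdi_degenerate_geometry",
              "pattern direction is parallel to the projector ray")
  ex <- ex / nx
  ez <- normal / sqrt(sum(normal^2))
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2], ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  rbind(ex, ey, ez, deparse.level = 0)
}

#' Convert rays to local polar/azimuth angles
#'
#' Transforms the camera and projector rays into the local frame and returns
#' polar angles (`phi_*`, from the normal) and azimuths (`theta_*`, from the
#' in-plane pattern propagation direction `e_y`). Rays reaching the point from
#' below the tangent plane (self-occlusion) yield NA.
#'
#' @param R_g Local frame rotation from [local_frame()].
#' @param camera_ray,projector_ray Unit ray directions (device toward surface).
#' @param normal Unit normal (oriented toward the camera).
#' @return Named numeric: `theta_cam`, `phi_cam`, `theta_pro`, `phi_pro` (rad).
#' @export
rays_to_angles <- function(R_g, camera_ray, projector_ray, normal) {
  ang <- function(e) {
    el <- as.numeric(R_g %*% e)
    if (el[3] >= 0) return(c(NA_real_, NA_real_))    # from below the surface
    c(atan2(el[1], el[2]), acos(pmin(-el[3], 1)))
  }
  a_cam <- ang(camera_ray); a_pro <- ang(projector_ray)
  c(theta_cam = a_cam[1], phi_cam = a_cam[2],
    theta_pro = a_pro[1], phi_pro = a_pro[2])
}

#' Per-pixel projection and detection angles for a surface map
#'
#' Vectorized local frames and ray angles over the whole map; requires normals
#' (see [estimate_normals()]); the projector ray per pixel points from the
#' projector center to the surface point.
#'
#' @param surface An `sfdi_surface` with normals.
#' @param geometry An [system_geometry()] object.
#' @param orientation Pattern fringe-field orientation (`"y"`: varies along y,
#'   fringes constant along x).
#' @return The surface with matrices `phi_pro`, `theta_pro`, `phi_cam`,
#'   `theta_cam` (radians) added; self-occluded pixels are invalidated.
#' @export
surface_angles <- function(surface, geometry, orientation = c("y", "x")) {
  orientation <- match.arg(orientation)
  if (is.null(surface$nx))
    sfdi_stop("sfdi_input_error", "surface has no normals; run estimate_normals()")
  e_pat <- if (orientation == "y") c(1, 0, 0) else c(0, 1, 0)
  nr <- nrow(surface$z); nc <- ncol(surface$z)
  P <- cbind(as.numeric(surface$x), as.numeric(surface$y), as.numeric(surface$z))
  N <- cbind(as.numeric(surface$nx), as.numeric(surface$ny), as.numeric(surface$nz))
  e_cam <- cbind(as.numeric(surface$rays$x), as.numeric(surface$rays$y),
                 as.numeric(surface$rays$z))
  pro_origin <- device_center(geometry$projector)
  e_pro <- normalize_rows(sweep(P, 2, pro_origin))
  nd_e <- rowSums(N * e_pro)
  nd_pat <- N %*% e_pat
  ex <- matrix(e_pat, nrow(P), 3, byrow = TRUE) - e_pro * as.numeric(nd_pat / nd_e)
  ex <- ex / row_norms(ex)
  ey <- cross_rows(N, ex)
  loc <- function(e) list(x = rowSums(e * ex), y = rowSums(e * ey),
                          z = rowSums(e * N))
  lp <- loc(e_pro); lc <- loc(e_cam)
  occl <- (!is.na(lp$z) & lp$z >= 0) | (!is.na(lc$z) & lc$z >= 0) |
    abs(nd_e) < 1e-9
  shape <- function(v) { v[occl] <- NA_real_; matrix(v, nr, nc) }
  surface$phi_pro <- shape(acos(pmin(-lp$z, 1)))
  surface$theta_pro <- shape(atan2(lp$x, lp$y))
  surface$phi_cam <- shape(acos(pmin(-lc$z, 1)))
  surface$theta_cam <- shape(atan2(lc$x, lc$y))
  surface$valid <- surface$valid & !matrix(occl, nr, nc)
  surface$pattern_orientation <- orientation
  surface
}

#' Reference-plane angles per camera pixel
#'
#' Angles of the flat reference configuration (plane at the reference
#' position, normal toward the camera), used to normalize the angular
#' frequency-scaling factors and as the reference pose for the Lambert model.
#'
#' @param geometry An [system_geometry()] object.
#' @param orientation Pattern orientation as in [surface_angles()].
#' @param rays Optional camera ray field.
#' @return An `sfdi_surface` for the reference plane, with angles.
#' @export
reference_surface <- function(geometry, orientation = "y", rays = NULL) {
  rays <- rays %||% build_ray_fields(geometry, "camera")
  dirs <- cbind(as.numeric(rays$x), as.numeric(rays$y), as.numeric(rays$z))
  tt <- intersect_plane(rays$origin, dirs, geometry$reference_plane$point,
                        geometry$reference_plane$normal)
  nr <- nrow(rays$x); nc <- ncol(rays$x)
  P <- sweep(dirs * tt, 2, rays$origin, "+")
  surf <- surface_from_points(matrix(P[, 1], nr, nc), matrix(P[, 2], nr, nc),
                              matrix(P[, 3], nr, nc), rays)
  nrm <- -geometry$reference_plane$normal /
    sqrt(sum(geometry$reference_plane$normal^2))
  surf$nx <- matrix(nrm[1], nr, nc)
  surf$ny <- matrix(nrm[2], nr, nc)
  surf$nz <- matrix(nrm[3], nr, nc)
  surface_angles(surf, geometry, orientation)
}

#' Export a surface map as an ASCII PLY point cloud
#'
#' @param surface An `sfdi_surface` (normals included when present).
#' @param path Output file path.
#' @param stride Keep every `stride`-th pixel in each direction.
#' @return `path`, invisibly.
#' @export
write_surface_ply <- function(surface, path, stride = 1) {
  keep <- matrix(FALSE, nrow(surface$z), ncol(surface$z))
  keep[seq(1, nrow(keep), stride), seq(1, ncol(keep), stride)] <- TRUE
  keep <- keep & surface$valid
  has_n <- !is.null(surface$nx)
  n <- sum(keep)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0", sprintf("element vertex %d", n),
               "property float x", "property float y", "property float z",
               if (has_n) c("property float nx", "property float ny",
                            "property float nz"),
               "end_header"), con)
  m <- cbind(surface$x[keep], surface$y[keep], surface$z[keep])
  if (has_n) m <- cbind(m, surface$nx[keep], surface$ny[keep], surface$nz[keep])
  utils::write.table(format(m, trim = TRUE, digits = 8), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
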