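# Digital twin: renders synthetic camera images of projected fringe patterns
# on parametric scenes (planes, spherical caps, printed calibration targets)
# from ground-truth device models, including lens distortion, oblique
# projection, defocus MTF roll-off, vignetting, Lambertian shading and noise.
# Every render also emits the ground truth the pipeline is supposed to
# recover.

#' Ground-truth camera for the digital twin
#'
#' A telephoto camera viewing a `field` mm square at `z_ref` mm: the default
#' matches a 2048 px chip over 21.6 mm at 320 mm (fx about 30341 px). The
#' narrow field makes higher-order radial and tangential distortion terms
#' unobservable, so the truth model carries a single k1 term.
#'
#' @param n_px Chip size in pixels (square chip).
#' @param field Lateral field of view at the reference distance, mm.
#' @param z_ref Reference distance, mm.
#' @param k1 Radial distortion coefficient.
#' @return An [pinhole_device()] with identity pose (defines the global frame).
#' @export
twin_camera <- function(n_px = 2048, field = 21.6, z_ref = 320, k1 = -0.2) {
  fx <- n_px * z_ref / field
  pinhole_device(intrinsics(fx, fx, (n_px - 1) / 2, (n_px - 1) / 2, c(n_px, n_px)),
                 distortion(radial = k1), pose(), role = "camera")
}

#' Ground-truth projector for the digital twin
#'
#' DMD projector on the cone of `oblique_deg` incidence toward the
#' reference-plane center, at `range_mm` distance (default 361 mm, the
#' projector-to-field-center distance implied by the printed setup geometry),
#' tilted in the y-z plane and aimed at the field center. The default
#' illuminated area is 56.8 mm x 27.9 mm at the reference plane.
#'
#' @param n_col,n_row DMD resolution.
#' @param oblique_deg Oblique incidence angle at the field center, degrees.
#' @param range_mm Distance from the projector center to the field center, mm.
#' @param z_ref Reference distance, mm.
#' @param illuminated c(width, height) of the illuminated area at z_ref, mm.
#' @param k1 Radial distortion coefficient.
#' @return An [pinhole_device()].
#' @export
twin_projector <- function(n_col = 1920, n_row = 1080, oblique_deg = 35,
                           range_mm = 361, z_ref = 320,
                           illuminated = c(56.8, 27.9), k1 = -0.1) {
  th <- oblique_deg * pi / 180
  center <- c(0, range_mm * sin(th), z_ref - range_mm * cos(th))
  ez <- (c(0, 0, z_ref) - center) / range_mm
  ex <- c(1, 0, 0)
  ey <- c(ez[2] * ex[3] - ez[3] * ex[2], ez[3] * ex[1] - ez[1] * ex[3],
          ez[1] * ex[2] - ez[2] * ex[1])
  R <- rbind(ex, ey, ez, deparse.level = 0)
  fx <- n_col * range_mm / illuminated[1]
  fy <- n_row * range_mm / illuminated[2]
  pinhole_device(intrinsics(fx, fy, (n_col - 1) / 2, (n_row - 1) / 2,
                            c(n_col, n_row)),
                 distortion(radial = k1),
                 pose(R, as.numeric(-R %*% center)), role = "projector")
}

#' Digital-twin configuration
#'
#' Ground-truth devices plus the radiometric model: defocus MTF width grows
#' linearly with the distance from the focal plane
#' (`MTF = exp(-2 pi^2 f^2 (sigma0 |l - focal|)^2)`), smooth radial
#' vignetting, Lambertian shading, sinusoidal pattern modulation, additive
#' Gaussian and multiplicative intensity noise, and optional Poisson shot
#' noise.
#'
#' @param camera,projector Ground-truth devices.
#' @param volume Calibrated volume (center/size, mm).
#' @param focal_distance Camera focal-plane distance, mm (intensity-vs-l peak).
#' @param defocus_sigma0 Blur growth, mm of Gaussian blur sd per mm defocus.
#' @param gain Overall intensity gain (keeps intensities in 0..1).
#' @param modulation Pattern modulation depth m in 0..1.
#' @param vignetting Relative intensity drop at the field corner.
#' @param noise_sigma Additive Gaussian noise sd (intensity units).
#' @param noise_mult Multiplicative Gaussian noise sd (relative).
#' @param poisson_scale Photons per intensity unit for shot noise (0 = off).
#' @param reference_props Optical properties of the reference standard
#'   (mu_a, mu_s_prime, n_refractive).
#' @return A list of class `sfdi_twin_config`.
#' @export
twin_config <- function(camera = twin_camera(), projector = twin_projector(),
                        volume = list(center = c(0, 0, 320),
                                      size = c(21.6, 21.6, 25)),
                        focal_distance = 316, defocus_sigma0 = 0.027,
                        gain = 0.5, modulation = 0.8, vignetting = 0.15,
                        noise_sigma = 0, noise_mult = 0, poisson_scale = 0,
                        reference_props = list(mu_a = 0.01, mu_s_prime = 2.5,
                                               n_refractive = 1.5)) {
  structure(list(camera = camera, projector = projector, volume = volume,
                 focal_distance = focal_distance, defocus_sigma0 = defocus_sigma0,
                 gain = gain, modulation = modulation, vignetting = vignetting,
                 noise_sigma = noise_sigma, noise_mult = noise_mult,
                 poisson_scale = poisson_scale, reference_props = reference_props),
            class = "sfdi_twin_config")
}

#' Ground-truth system geometry of a twin configuration
#'
#' @param config A [twin_config()].
#' @return An [system_geometry()] built from the truth devices.
#' @export
twin_geometry <- function(config) {
  system_geometry(config$camera, config$projector, config$volume,
                  reprojection_rms = c(camera = 0, projector = 0))
}

#' Reference-standard reflectance table of the twin
#'
#' The known `R_SFD,ref(f)` of the twin's reference standard, evaluated with
#' the forward model at the configured reference optical properties.
#'
#' @param config A [twin_config()].
#' @param f_grid Frequency grid, 1/mm.
#' @return A tibble with columns `f` and `r`.
#' @export
twin_reference_table <- function(config, f_grid = seq(0, 1.2, by = 0.005)) {
  rp <- config$reference_props
  tibble::tibble(f = f_grid,
                 r = forward_reflectance(f_grid, rp$mu_a, rp$mu_s_prime,
                                         rp$n_refractive))
}

#' Digital-twin scene
#'
#' @param surface `"plane"`, `"sphere_cap"` or `"calibration_target"`.
#' @param z Plane z position, mm (plane).
#' @param normal Plane normal (plane; default optical axis).
#' @param radius Radius of curvature, mm (sphere_cap).
#' @param apex Apex position, mm (sphere_cap; the cap bulges toward the camera).
#' @param target A [calibration_target()] (calibration_target surface).
#' @param target_pose A [pose()] mapping target-local to global coordinates.
#' @param reflectance `list(type = "lambertian", albedo = )` or
#'   `list(type = "sfd_model", mu_a = , mu_s_prime = , n_refractive = , g = )`.
#' @return A list of class `sfdi_twin_scene`.
#' @export
twin_scene <- function(surface = c("plane", "sphere_cap", "calibration_target"),
                       z = 320, normal = c(0, 0, 1), radius = 40,
                       apex = c(0, 0, 320), target = NULL, target_pose = NULL,
                       reflectance = list(type = "lambertian", albedo = 0.8)) {
  surface <- match.arg(surface)
  if (surface == "calibration_target" && (is.null(target) || is.null(target_pose)))
    sfdi_stop("sfdi_input_error", "calibration_target scenes need target and target_pose")
  structure(list(surface = surface, z = z, normal = normal / sqrt(sum(normal^2)),
                 radius = radius, apex = apex, target = target,
                 target_pose = target_pose, reflectance = reflectance),
            class = "sfdi_twin_scene")
}

#' Wavelength-analogue optical-property pairs of the twin phantom
#'
#' Nine (mu_a, mu_s') pairs standing in for the nine LED wavelengths of a
#' multispectral measurement of an epoxy/TiO2/hematite phantom: reduced
#' scattering decreasing with wavelength, absorption with a mineral-absorber
#' profile. The 521 nm analogue carries the integrating-sphere reference
#' values mu_s' = 1.98 1/mm, mu_a = 0.18 1/mm.
#'
#' @param n_refractive Phantom refractive index (default 1.52).
#' @param g Anisotropy factor carried as metadata (default 0.6).
#' @return A tibble with columns `wavelength_nm`, `mu_a`, `mu_s_prime`,
#'   `n_refractive`, `g`.
#' @export
twin_phantom_pairs <- function(n_refractive = 1.52, g = 0.6) {
  tibble::tibble(
    wavelength_nm = c(447, 470, 521, 595, 630, 660, 730, 850, 945),
    mu_a = c(0.30, 0.24, 0.18, 0.14, 0.10, 0.08, 0.10, 0.16, 0.26),
    mu_s_prime = c(2.40, 2.28, 1.98, 1.88, 1.80, 1.74, 1.66, 1.56, 1.48),
    n_refractive = n_refractive, g = g)
}

#' Pose placing a calibration target in the scene
#'
#' Builds the [pose()] (global to target-local) that puts the target center at
#' `center` with the given intrinsic rotations about the target axes.
#'
#' @param target A [calibration_target()].
#' @param center Global position of the grid center, mm.
#' @param rot_deg Rotations about the target x, y, z axes, degrees.
#' @return A [pose()] usable as `target_pose` in [twin_scene()].
#' @export
target_pose_at <- function(target, center = c(0, 0, 320), rot_deg = c(0, 0, 0)) {
  r <- rot_deg * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(r[1]), sin(r[1]), 0, -sin(r[1]), cos(r[1])), 3, 3)
  Ry <- matrix(c(cos(r[2]), 0, -sin(r[2]), 0, 1, 0, sin(r[2]), 0, cos(r[2])), 3, 3)
  Rz <- matrix(c(cos(r[3]), sin(r[3]), 0, -sin(r[3]), cos(r[3]), 0, 0, 0, 1), 3, 3)
  R <- Rx %*% Ry %*% Rz
  lc <- c((target$n_cols - 1) * target$spacing / 2,
          (target$n_rows - 1) * target$spacing / 2, 0)
  pose(R, as.numeric(lc - R %*% center))
}

#' Intersect camera rays with the scene surface
#' @noRd
intersect_scene <- function(scene, origin, dirs) {
  if (scene$surface == "plane") {
    tt <- intersect_plane(origin, dirs, c(0, 0, scene$z), scene$normal)
    P <- sweep(dirs * tt, 2, origin, "+")
    n <- matrix(scene$normal, nrow(dirs), 3, byrow = TRUE)
  } else if (scene$surface == "sphere_cap") {
    C <- scene$apex + c(0, 0, scene$radius)
    oc <- matrix(origin - C, nrow(dirs), 3, byrow = TRUE)
    b <- 2 * rowSums(dirs * oc)
    cc <- sum((origin - C)^2) - scene$radius^2
    disc <- b^2 / 4 - cc
    tt <- -b / 2 - sqrt(pmax(disc, 0))  # near-side root
    tt[disc <= 0 | tt <= 0] <- NA_real_
    P <- sweep(dirs * tt, 2, origin, "+")
    n <- (P - matrix(C, nrow(dirs), 3, byrow = TRUE)) / scene$radius
  } else {
    pt <- as.numeric(scene$target_pose$rotation[3, ])  # plane normal (local z)
    p0 <- to_global_frame(scene$target_pose, matrix(0, 1, 3))
    # local z axis in global coordinates is the third column of R^T = row of R
    tt <- intersect_plane(origin, dirs, as.numeric(p0), pt)
    P <- sweep(dirs * tt, 2, origin, "+")
    n <- matrix(pt, nrow(dirs), 3, byrow = TRUE)
  }
  # orient normals toward the camera
  flip <- rowSums(n * dirs) > 0
  flip[is.na(flip)] <- FALSE
  n[flip, ] <- -n[flip, , drop = FALSE]
  list(points = P, t = tt, normals = n)
}

#' Local albedo of a scene at global points
#' @noRd
scene_albedo <- function(scene, points, edge_width = 0.1) {
  if (scene$surface != "calibration_target")
    return(rep(scene$reflectance$albedo %||% 0.8, nrow(points)))
  loc <- to_device_frame(scene$target_pose, points)
  tg <- scene$target
  gx <- pmin(pmax(round(loc[, 1] / tg$spacing), 0), tg$n_cols - 1)
  gy <- pmin(pmax(round(loc[, 2] / tg$spacing), 0), tg$n_rows - 1)
  d <- sqrt((loc[, 1] - gx * tg$spacing)^2 + (loc[, 2] - gy * tg$spacing)^2)
  radius <- rep(tg$circle_diameter / 2, nrow(points))
  mk <- marker_grid_nodes(tg)
  for (m in seq_len(3)) {
    sel <- gx == mk[m, 1] & gy == mk[m, 2]
    radius[sel] <- tg$circle_diameter / 2 * tg$marker_scale[m]
  }
  # smooth edge: 1 inside the circle, 0 outside, linear ramp of edge_width
  inside <- pmin(pmax((radius - d) / edge_width + 0.5, 0), 1)
  bg <- 0.9; fg <- 0.15
  bg + (fg - bg) * inside
}

#' Render fringe stacks of a scene seen by the twin camera
#'
#' For each camera pixel the ray is intersected with the surface; the pattern
#' phase at the hit point follows from the ground-truth projector model; the
#' pixel intensity is
#' `gain * V * S_Lambert * (R_dc + m * MTF_defocus * R_ac * cos(phase + shift))`
#' with the sample reflectance evaluated at the local corrected frequency for
#' `sfd_model` scenes. Gaussian (additive and multiplicative) and optional
#' Poisson noise are applied per frame.
#'
#' @param scene A [twin_scene()].
#' @param config A [twin_config()].
#' @param f_list Nominal reference-plane frequencies, 1/mm (0 allowed).
#' @param n_phases Number of equally spaced phase shifts (>= 3).
#' @param orientation Fringe-field orientation (see [pattern_spec()]).
#' @param patterns Optional list of [pattern_spec()]s overriding the metric
#'   patterns (e.g. DMD axis encodings for calibration).
#' @param seed Random seed for the noise (NULL = leave RNG untouched).
#' @return List with `stacks` (list of [fringe_stack()], one per pattern),
#'   `truth` (ground-truth `sfdi_surface` with analytic normals and angles,
#'   per-frequency local corrected frequency and model reflectance,
#'   `s_lambert`, `mtf`, phase maps) and `geometry` (truth
#'   [system_geometry()]).
#' @export
render_measurement <- function(scene, config, f_list, n_phases = 3,
                               orientation = "y", patterns = NULL,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  geometry <- twin_geometry(config)
  rays <- build_ray_fields(geometry, "camera")
  nr <- nrow(rays$x); nc <- ncol(rays$x)
  dirs <- cbind(as.numeric(rays$x), as.numeric(rays$y), as.numeric(rays$z))
  hit <- intersect_scene(scene, rays$origin, dirs)
  frac <- mean(is.finite(hit$t))
  if (frac < 0.9)
    warning(sprintf("surface visible over only %.0f%% of the image", 100 * frac))
  surf <- surface_from_points(matrix(hit$points[, 1], nr, nc),
                              matrix(hit$points[, 2], nr, nc),
                              matrix(hit$points[, 3], nr, nc), rays)
  surf$nx <- matrix(hit$normals[, 1], nr, nc)
  surf$ny <- matrix(hit$normals[, 2], nr, nc)
  surf$nz <- matrix(hit$normals[, 3], nr, nc)
  surf$valid <- surf$valid & is.finite(surf$z)
  surf <- surface_angles(surf, geometry, orientation)
  reference <- reference_surface(geometry, orientation, rays)
  s_lam <- surface_lambert(surf)
  # vignetting: radial over the chip
  k <- geometry$camera$intrinsics
  u <- rep(0:(nc - 1), each = nr); v <- rep(0:(nr - 1), nc)
  rho2 <- ((u - k$cx)^2 + (v - k$cy)^2) / ((k$cx)^2 + (k$cy)^2)
  vig <- matrix(1 - config$vignetting * rho2, nr, nc)
  sigma_l <- config$defocus_sigma0 * abs(surf$l - config$focal_distance)
  if (is.null(patterns))
    patterns <- lapply(f_list, function(f)
      pattern_spec("metric", f = f, orientation = orientation))
  shifts <- 2 * pi * (seq_len(n_phases) - 1) / n_phases
  alb <- scene_albedo(scene, hit$points,
                      edge_width = surf$l[ceiling(nr / 2), ceiling(nc / 2)] / k$fx)
  stacks <- vector("list", length(patterns))
  truth_f <- vector("list", length(patterns))
  truth_r <- vector("list", length(patterns))
  truth_phase <- vector("list", length(patterns))
  for (j in seq_along(patterns)) {
    pat <- patterns[[j]]
    if (pat$type == "metric") {
      fm <- correct_frequency(pat$f, surf, geometry, reference = reference)
      f_local <- fm$f_corr
    } else {
      f_local <- matrix(0, nr, nc)     # chip-encoding pattern: no metric frequency
    }
    if (scene$reflectance$type == "sfd_model") {
      rp <- scene$reflectance
      r_ac <- matrix(forward_reflectance(pmax(as.numeric(f_local), 0),
                                         rp$mu_a, rp$mu_s_prime, rp$n_refractive),
                     nr, nc)
      r_dc <- forward_reflectance(0, rp$mu_a, rp$mu_s_prime, rp$n_refractive)
      r_dc <- matrix(r_dc, nr, nc)
    } else {
      r_ac <- matrix(alb, nr, nc); r_dc <- matrix(alb, nr, nc)
    }
    mtf <- exp(-2 * pi^2 * f_local^2 * sigma_l^2)
    if (pat$type != "metric") mtf <- matrix(1, nr, nc)
    phi <- matrix(phase_of_points(geometry, hit$points, pat), nr, nc)
    frames <- vector("list", n_phases)
    for (i in seq_len(n_phases)) {
      I <- config$gain * vig * s_lam *
        (r_dc + config$modulation * mtf * r_ac * cos(phi + shifts[i]))
      I[!surf$valid | is.na(I)] <- 0
      if (config$noise_mult > 0)
        I <- I * (1 + config$noise_mult * matrix(stats::rnorm(nr * nc), nr, nc))
      if (config$noise_sigma > 0)
        I <- I + config$noise_sigma * matrix(stats::rnorm(nr * nc), nr, nc)
      if (config$poisson_scale > 0)
        I <- matrix(stats::rpois(nr * nc, pmax(I, 0) * config$poisson_scale) /
                      config$poisson_scale, nr, nc)
      frames[[i]] <- I
    }
    stacks[[j]] <- fringe_stack(frames, shifts,
                                nominal_frequency = if (pat$type == "metric") pat$f
                                else NA_real_,
                                pattern_direction = if ((pat$orientation %||% "y") == "y")
                                  "rows" else "columns")
    truth_f[[j]] <- f_local
    truth_r[[j]] <- r_ac
    truth_phase[[j]] <- phi
  }
  list(stacks = stacks,
       truth = list(surface = surf, s_lambert = s_lam, f_local = truth_f,
                    r_model = truth_r, phase = truth_phase, albedo = alb,
                    vignetting = vig),
       geometry = geometry,
       f_list = if (is.null(patterns)) f_list else
         vapply(patterns, function(p) if (p$type == "metric") p$f else NA_real_,
                numeric(1)))
}

#' Render a calibration-target pose
#'
#' Renders the DC-capable fringe stacks of DMD row/column encodings over the
#' printed circle grid, plus ground-truth marker correspondences (camera image
#' points via the truth camera, DMD points via the truth projector).
#'
#' @param target A [calibration_target()].
#' @param target_pose A [pose()] mapping target coordinates to global.
#' @param config A [twin_config()].
#' @param pattern_freqs Pixel-based frequency chain used per axis (absolute
#'   first; each entry must stay within a half period of the unwrap chain).
#' @param n_phases Phase shifts per pattern.
#' @param seed Noise seed.
#' @return List with `stacks_u`, `stacks_v` (lists over `pattern_freqs`),
#'   `pattern_freqs`, `truth` (object/image/DMD points) and the scene.
#' @export
render_calibration_pose <- function(target, target_pose, config,
                                    pattern_freqs = c(0.25, 2, 10),
                                    n_phases = 3, seed = NULL) {
  scene <- twin_scene("calibration_target", target = target,
                      target_pose = target_pose,
                      reflectance = list(type = "lambertian", albedo = NA))
  obj <- object_points(target)
  P <- to_global_frame(target_pose, cbind(obj, 0))
  cam_uv <- project_points(config$camera, P)
  sz <- config$camera$intrinsics$image_size
  if (any(cam_uv[, 1] < 0 | cam_uv[, 1] > sz[1] - 1 |
          cam_uv[, 2] < 0 | cam_uv[, 2] > sz[2] - 1))
    sfdi_stop("sfdi_input_error", "target pose places markers outside the camera frustum")
  dmd_uv <- project_points(config$projector, P)
  pats <- c(lapply(pattern_freqs, function(f) pattern_spec("dmd", axis = "u", f_px = f)),
            lapply(pattern_freqs, function(f) pattern_spec("dmd", axis = "v", f_px = f)))
  rend <- render_measurement(scene, config, f_list = NULL, n_phases = n_phases,
                             patterns = pats, seed = seed)
  nf <- length(pattern_freqs)
  list(stacks_u = rend$stacks[seq_len(nf)],
       stacks_v = rend$stacks[nf + seq_len(nf)],
       pattern_freqs = pattern_freqs,
       truth = list(object_points = obj, camera_points = cam_uv,
                    dmd_points = dmd_uv, surface = rend$truth$surface),
       scene = scene, geometry = rend$geometry)
}

#' Render the intensity-calibration reference measurements
#'
#' The reference standard (a flat Lambertian-like turbid plate with known
#' reflectance) is rendered at `n_positions` z positions evenly distributed
#' over the calibrated volume, at the given frequencies (plus the absolute
#' phase anchor), with the defocus MTF applied.
#'
#' @param config A [twin_config()].
#' @param n_positions Number of positions (default 6).
#' @param f_list Nominal frequencies, 1/mm (default 9 values 0..1).
#' @param anchor_frequency Low-frequency absolute-phase pattern, 1/mm.
#' @param n_phases Phase shifts per pattern.
#' @param seed Noise seed.
#' @return List with `positions` (each: `z`, `render`), `f_list` (including
#'   the anchor as its first nonzero entry), `anchor_frequency`.
#' @export
render_reference_stack <- function(config, n_positions = 6,
                                   f_list = seq(0, 1, length.out = 9),
                                   anchor_frequency = 0.01, n_phases = 3,
                                   seed = NULL) {
  zc <- config$volume$center[3]; hz <- config$volume$size[3] / 2
  z_list <- seq(zc - hz, zc + hz, length.out = n_positions)
  rp <- config$reference_props
  f_all <- c(anchor_frequency, f_list)
  out <- vector("list", n_positions)
  for (i in seq_len(n_positions)) {
    scene <- twin_scene("plane", z = z_list[i],
                        reflectance = list(type = "sfd_model", mu_a = rp$mu_a,
                                           mu_s_prime = rp$mu_s_prime,
                                           n_refractive = rp$n_refractive))
    out[[i]] <- list(z = z_list[i],
                     render = render_measurement(
                       scene, config, f_all, n_phases = n_phases,
                       seed = if (is.null(seed)) NULL else seed + i))
  }
  list(positions = out, f_list = f_all, anchor_frequency = anchor_frequency,
       z_list = z_list)
}
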