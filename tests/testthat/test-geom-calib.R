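# Geometric calibration: grid detection, phase-encoded projector
# correspondences, planar calibration solves, frame unification, reference
# plane, predistorted patterns and ray fields.

calib_renders <- function() {
  cached("calib_renders", {
    cfg <- tiny_config(256)
    target <- small_target()
    poses <- calibration_pose_set(target)
    renders <- lapply(poses, function(p) render_calibration_pose(target, p, cfg))
    list(cfg = cfg, target = target, poses = poses, renders = renders)
  })
}

detected_correspondences <- function() {
  cached("calib_detected", {
    cr <- calib_renders()
    out <- list(object = list(), camera = list(), dmd = list(),
                centroid_err = numeric(0), dmd_err = numeric(0))
    for (k in seq_along(cr$renders)) {
      rp <- cr$renders[[k]]
      du <- lapply(rp$stacks_u, demodulate)
      dv <- lapply(rp$stacks_v, demodulate)
      det <- detect_grid(du[[1]]$i_dc, cr$target)
      pu <- unwrap_chain(du, rp$pattern_freqs)
      pv <- unwrap_chain(dv, rp$pattern_freqs)
      pp <- projector_points_from_phase(
        pu, pv, det$image_points,
        list(n_col = 1920, n_row = 1080,
             f_col = max(rp$pattern_freqs), f_row = max(rp$pattern_freqs)))
      out$object[[k]] <- det$object_points
      out$camera[[k]] <- det$image_points
      out$dmd[[k]] <- pp$dmd_points
      out$centroid_err[k] <- max(abs(det$image_points - rp$truth$camera_points))
      out$dmd_err[k] <- max(abs(pp$dmd_points - rp$truth$dmd_points), na.rm = TRUE)
    }
    out
  })
}

test_that("grid detection recovers ordered sub-pixel centroids on twin renders", {
  det <- detected_correspondences()
  expect_length(det$camera, 6)
  expect_true(all(vapply(det$camera, nrow, 1L) == 169))
  expect_lt(max(det$centroid_err), 0.12)
  # ordering matches the truth ordering exactly (object points in mm)
  expect_equal(det$object[[1]], unname(object_points(small_target())),
               ignore_attr = TRUE)
})

test_that("half-occluded grids and ambiguous markers raise detection errors", {
  cr <- calib_renders()
  dc <- demodulate(cr$renders[[1]]$stacks_u[[1]])$i_dc
  occluded <- dc
  occluded[, 1:(ncol(dc) / 2)] <- max(dc, na.rm = TRUE)  # wash out half the grid
  expect_error(detect_grid(occluded, cr$target), class = "sfdi_detection_error")
  # a grid of identical disks offers no identifiable axis markers
  n <- 200
  img <- matrix(1, n, n)
  centers <- as.matrix(expand.grid(seq(30, 170, by = 14), seq(30, 170, by = 14)))
  xs <- matrix(rep(1:n, each = n), n, n)   # column index per entry
  ys <- matrix(rep(1:n, n), n, n)
  for (i in seq_len(nrow(centers)))
    img[(xs - centers[i, 1])^2 + (ys - centers[i, 2])^2 < 16] <- 0
  uniform <- calibration_target(n_cols = 11, n_rows = 11, spacing = 1.4,
                                circle_diameter = 0.7)
  expect_error(detect_grid(img, uniform), class = "sfdi_detection_error")
})

test_that("rotated targets are still assigned consistently via the axis markers", {
  cr <- calib_renders()
  rp <- cr$renders[[6]]   # includes an in-plane rotation
  det <- detect_grid(demodulate(rp$stacks_u[[1]])$i_dc, cr$target)
  expect_lt(max(abs(det$image_points - rp$truth$camera_points)), 0.12)
  # quarter-turn rotation: axes must be resolved purely from the markers
  rot <- render_calibration_pose(cr$target,
                                 target_pose_at(cr$target, c(0, 0, 318),
                                                c(0, 0, 90)),
                                 cr$cfg, pattern_freqs = 0.25)
  det90 <- detect_grid(demodulate(rot$stacks_u[[1]])$i_dc, cr$target)
  expect_lt(max(abs(det90$image_points - rot$truth$camera_points)), 0.12)
})

test_that("phase decoding maps DMD pixels per the encoding equation", {
  # u_DLP = phi / (f_col * 4 pi / N_col): phi = 20 pi, f = 10, N = 1920 -> 960
  ph <- matrix(20 * pi, 4, 4)
  pp <- projector_points_from_phase(ph, ph, cbind(1.5, 1.5),
                                    list(n_col = 1920, n_row = 1080,
                                         f_col = 10, f_row = 10))
  expect_equal(pp$dmd_points[1, 1], 960)
  pp0 <- projector_points_from_phase(matrix(0, 4, 4), matrix(0, 4, 4),
                                     cbind(1.5, 1.5),
                                     list(n_col = 1920, n_row = 1080,
                                          f_col = 10, f_row = 10))
  expect_equal(pp0$dmd_points[1, 1], 0)
  expect_warning(
    projector_points_from_phase(matrix(-4 * pi, 4, 4), ph, cbind(1.5, 1.5),
                                list(n_col = 1920, n_row = 1080,
                                     f_col = 10, f_row = 10)),
    "outside the representable")
})

test_that("twin-rendered phase encoding recovers DMD coordinates sub-pixel", {
  det <- detected_correspondences()
  expect_lt(max(det$dmd_err), 0.3)
  expect_lt(det$dmd_err[1], 0.2)   # fronto-parallel pose
})

test_that("planar calibration recovers the truth devices from exact correspondences", {
  cfg <- tiny_config(256)
  corr <- exact_correspondences(cfg)
  cam <- suppressWarnings(
    calibrate_device(corr$object, corr$camera, cfg$camera$intrinsics$image_size,
                     n_radial = 1))
  pro <- suppressWarnings(
    calibrate_device(corr$object, corr$dmd, cfg$projector$intrinsics$image_size,
                     n_radial = 1, role = "projector"))
  expect_lt(cam$rms, 0.05)
  expect_lt(pro$rms, 0.05)
  for (fld in c("fx", "fy", "cx", "cy")) {
    expect_lt(abs(cam$device$intrinsics[[fld]] / cfg$camera$intrinsics[[fld]] - 1),
              0.01)
    expect_lt(abs(pro$device$intrinsics[[fld]] / cfg$projector$intrinsics[[fld]] - 1),
              0.01)
  }
  expect_lt(abs(cam$device$distortion$radial[1] - (-0.2)), 0.01 * 0.2)
  expect_lt(abs(pro$device$distortion$radial[1] - (-0.1)), 0.01 * 0.1)
  geo <- unify_frames(cam, pro, corr$object)
  expect_lt(sqrt(sum((device_center(geo$projector) -
                        device_center(cfg$projector))^2)), 0.5)
  # per-pose extrinsics: the solved pose maps target-local into camera
  # coordinates, the inverse of the scene pose (global/camera to target-local)
  R_exp <- t(corr$poses[[1]]$rotation)
  t_exp <- -as.numeric(R_exp %*% corr$poses[[1]]$translation)
  expect_lt(max(abs(cam$poses[[1]]$rotation - R_exp)), 1e-4)
  expect_lt(max(abs(cam$poses[[1]]$translation - t_exp)), 0.01)
  assign("exact_geo", geo, envir = fixture_env)
})

test_that("calibration degrades gracefully to the centroid noise floor", {
  cfg <- tiny_config(256)
  corr <- exact_correspondences(cfg)
  set.seed(8)
  noisy <- lapply(corr$camera, function(m) m + matrix(rnorm(length(m), sd = 0.1),
                                                      nrow(m)))
  cam <- suppressWarnings(
    calibrate_device(corr$object, noisy, cfg$camera$intrinsics$image_size,
                     n_radial = 1))
  expect_lt(cam$rms, 0.15)
  expect_gt(cam$rms, 0.05)
  expect_lt(abs(cam$device$intrinsics$fx / cfg$camera$intrinsics$fx - 1), 0.02)
  expect_lt(abs(cam$device$intrinsics$fy / cfg$camera$intrinsics$fy - 1), 0.02)
})

test_that("full rendered calibration chain reaches the expected accuracy", {
  cfg <- tiny_config(256)
  det <- detected_correspondences()
  cam <- suppressWarnings(
    calibrate_device(det$object, det$camera, cfg$camera$intrinsics$image_size,
                     n_radial = 1))
  pro <- suppressWarnings(
    calibrate_device(det$object, det$dmd, cfg$projector$intrinsics$image_size,
                     n_radial = 1, role = "projector"))
  expect_lt(cam$rms, 0.05)
  expect_lt(abs(cam$device$intrinsics$fx / cfg$camera$intrinsics$fx - 1), 0.02)
  expect_lt(abs(pro$device$intrinsics$fx / cfg$projector$intrinsics$fx - 1), 0.02)
  geo <- suppressWarnings(unify_frames(cam, pro, det$object))
  expect_lt(sqrt(sum((device_center(geo$projector) -
                        device_center(cfg$projector))^2)), 5)
})

test_that("two poses violate the minimum-pose precondition", {
  corr <- exact_correspondences()
  expect_error(calibrate_device(corr$object[1:2], corr$camera[1:2],
                                c(256, 256)),
               class = "sfdi_input_error")
})

test_that("frame unification handles identical and single pose sets", {
  corr <- exact_correspondences()
  cfg <- tiny_config(256)
  cam <- suppressWarnings(
    calibrate_device(corr$object, corr$camera, cfg$camera$intrinsics$image_size,
                     n_radial = 1))
  same <- unify_frames(cam, cam, corr$object)
  expect_equal(same$projector$pose$rotation, diag(3), tolerance = 1e-9)
  expect_lt(max(abs(same$projector$pose$translation)), 1e-9)
  one <- list(device = cam$device, poses = cam$poses[1], rms = cam$rms)
  g1 <- unify_frames(one, one, corr$object[1])
  expect_true(is.na(attr(g1, "rotation_spread_deg")))
})

test_that("the reference plane sits at the volume center along the optical axis", {
  vol <- list(center = c(0, 0, 320), size = c(21.6, 21.6, 25))
  pl <- define_reference_plane(vol)
  expect_equal(pl$point, c(0, 0, 320))
  expect_equal(pl$normal, c(0, 0, 1))
  vol0 <- list(center = c(1, 2, 315), size = c(20, 20, 0))
  expect_equal(define_reference_plane(vol0)$point[3], 315)
})

test_that("system geometry invariants are enforced", {
  cfg <- tiny_config(64)
  vol <- list(center = c(0, 0, 320), size = c(21.6, 21.6, 25))
  expect_error(
    system_geometry(cfg$camera, cfg$projector, vol,
                    reference_plane = list(point = c(0, 0, 340),
                                           normal = c(0, 0, 1))),
    class = "sfdi_config_error")
  expect_error(
    system_geometry(cfg$camera, cfg$projector, vol,
                    reference_plane = list(point = c(0, 0, 320),
                                           normal = c(0.2, 0, 1))),
    class = "sfdi_config_error")
})

test_that("predistorted patterns produce metric fringes on the reference plane", {
  geo <- twin_geometry(tiny_config(64))
  flat <- generate_predistorted_patterns(geo, 0)
  expect_lt(diff(range(flat)), 1e-12)
  pat <- generate_predistorted_patterns(geo, 0.45)
  expect_true(all(pat >= 0 & pat <= 1))
  # the stored intensity at each DMD pixel equals the fringe field at its
  # reference-plane intersection
  pro <- geo$projector
  u <- c(400, 960, 1500); v <- c(300, 540, 800)
  rays <- pixel_rays(pro, cbind(u, v))
  orig <- device_center(pro)
  tt <- (320 - orig[3]) / rays[, 3]
  ystar <- orig[2] + tt * rays[, 2]
  expect_equal(pat[cbind(v + 1, u + 1)], 0.5 + 0.5 * cos(2 * pi * 0.45 * ystar),
               tolerance = 1e-9)
  expect_error(generate_predistorted_patterns(geo, 1.5),
               class = "sfdi_config_error")
})

test_that("rendered fringes hit the target metric frequency on the reference plane", {
  cfg <- tiny_config(96)
  rend <- render_measurement(twin_scene("plane", z = 320), cfg, f_list = 0.45)
  d <- demodulate(rend$stacks[[1]])
  unw <- unwrap_phase(d$phase_wrapped, d$validity, quality = d$i_ac)
  # regression of phase against the true metric coordinate along the pattern axis
  y <- rend$truth$surface$y
  fit <- stats::lm(as.numeric(unw) ~ as.numeric(y))
  f_obs <- abs(stats::coef(fit)[2]) / (2 * pi)
  expect_lt(abs(f_obs - 0.45) / 0.45, 0.005)
})

test_that("frequency scales with the plane offset via the magnification factor", {
  cfg <- tiny_config(96)
  rend <- render_measurement(twin_scene("plane", z = 330), cfg, f_list = 0.45)
  d <- demodulate(rend$stacks[[1]])
  unw <- unwrap_phase(d$phase_wrapped, d$validity, quality = d$i_ac)
  fit <- stats::lm(as.numeric(unw) ~ as.numeric(rend$truth$surface$y))
  f_obs <- abs(stats::coef(fit)[2]) / (2 * pi)
  s_z_true <- (330 - device_center(cfg$projector)[3]) /
    (320 - device_center(cfg$projector)[3])
  expect_lt(abs(f_obs - 0.45 / s_z_true) / 0.45, 0.005)
})

test_that("ray fields are unit norm and consistent with the field of view", {
  geo <- twin_geometry(tiny_config(128))
  rf <- build_ray_fields(geo, "camera")
  norms <- sqrt(rf$x^2 + rf$y^2 + rf$z^2)
  expect_lt(max(abs(norms - 1)), 1e-12)
  k <- geo$camera$intrinsics
  ctr <- c(rf$x[65, 65], rf$y[65, 65], rf$z[65, 65])
  expect_lt(acos(ctr[3]), 0.01)
  hit_x <- rf$x / rf$z * 320
  expect_equal(max(hit_x) - min(hit_x), 21.6 * 127 / 128, tolerance = 0.02)
})

test_that("system geometry JSON round trips", {
  geo <- twin_geometry(tiny_config(64))
  path <- withr::local_tempfile(fileext = ".json")
  write_system_geometry(geo, path)
  geo2 <- read_system_geometry(path)
  expect_equal(device_center(geo2$projector), device_center(geo$projector),
               tolerance = 1e-10)
  expect_equal(geo2$reference_plane$point, geo$reference_plane$point)
  expect_equal(geo2$volume$size, geo$volume$size)
})
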