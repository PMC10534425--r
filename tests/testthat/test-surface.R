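# Phase-distance conversion, 3D reconstruction, normals, local frames and
# projection/detection angles.

test_that("phase-distance polynomials reproduce the virtual-plane distances", {
  art <- noise_free_artifacts()
  pd <- art$art$pd_model
  expect_true(all(pd$valid))
  expect_lt(max(pd$resid_max, na.rm = TRUE), 1e-3)   # < 1 um over the volume
  expect_error(fit_phase_distance(art$art$geometry, n_planes = 3),
               class = "sfdi_input_error")
})

test_that("a noise-free flat target reconstructs to sub-micrometer residuals", {
  art <- noise_free_artifacts()
  cfg <- art$cfg; cfg$noise_mult <- 0
  rend <- render_measurement(twin_scene("plane", z = 320), cfg,
                             f_list = c(0.01, 0.45))
  demods <- demodulate_series(rend$stacks, c(0.01, 0.45), 0.01)
  rc <- run_config(c(0.01, 0.45), anchor_frequency = 0.01)
  surf <- reconstruct_surface(demods, rc, art$art$geometry, art$art$pd_model,
                              art$art$rays)
  fit <- stats::lm(as.numeric(surf$z) ~ as.numeric(surf$x) + as.numeric(surf$y))
  expect_lt(mean(abs(stats::residuals(fit))) * 1e3, 1)       # um
  expect_lt(abs(mean(surf$z, na.rm = TRUE) - 320) * 1e3, 1)  # um
})

test_that("a sphere cap reconstructs with sub-10-um radial residuals", {
  art <- noise_free_artifacts()
  rend <- render_measurement(twin_scene("sphere_cap", radius = 40,
                                        apex = c(0, 0, 320)),
                             art$cfg, f_list = c(0.01, 0.45))
  demods <- demodulate_series(rend$stacks, c(0.01, 0.45), 0.01)
  rc <- run_config(c(0.01, 0.45), anchor_frequency = 0.01)
  surf <- reconstruct_surface(demods, rc, art$art$geometry, art$art$pd_model,
                              art$art$rays)
  r <- sqrt(surf$x^2 + surf$y^2 + (surf$z - 360)^2)
  expect_lt(sqrt(mean((r - 40)^2, na.rm = TRUE)) * 1e3, 10)
})

test_that("out-of-range phases are masked and counted", {
  art <- noise_free_artifacts()
  pd <- art$art$pd_model
  phase <- matrix(pd$phi_range[, 2] + 10, 64, 64)   # beyond the fitted range
  surf <- phase_to_points(pd, phase, art$art$geometry, art$art$rays)
  expect_false(any(surf$valid))
  expect_equal(attr(surf, "n_masked_range"), 64 * 64)
})

test_that("grid-PCA normals are exact on planes and sub-degree on spheres", {
  art <- noise_free_artifacts()
  surf_p <- truth_surface(twin_scene("plane", z = 320), art$cfg)
  est <- estimate_normals(surf_p, 16)
  expect_lt(max(abs(est$nz + 1), na.rm = TRUE), 1e-10)
  expect_lt(max(abs(est$nx), na.rm = TRUE), 1e-10)
  surf_s <- truth_surface(twin_scene("sphere_cap", radius = 40,
                                     apex = c(0, 0, 320)), art$cfg)
  est_s <- estimate_normals(surf_s, 16)
  inner <- 6:59
  dots <- (est_s$nx * surf_s$nx + est_s$ny * surf_s$ny +
             est_s$nz * surf_s$nz)[inner, inner]
  ang <- acos(pmin(abs(dots), 1)) * 180 / pi
  expect_lt(max(ang, na.rm = TRUE), 0.5)
  expect_error(estimate_normals(surf_p, 1), class = "sfdi_input_error")
})

test_that("local frames are orthonormal and map the normal to local +z", {
  set.seed(21)
  for (i in 1:25) {
    n <- rnorm(3); n <- n / sqrt(sum(n^2)); if (n[3] > 0) n <- -n
    e <- rnorm(3); e <- e / sqrt(sum(e^2)); if (sum(e * n) > 0) e <- -e
    Rg <- local_frame(n, e, c(1, 0, 0))
    expect_lt(max(abs(Rg %*% t(Rg) - diag(3))), 1e-12)
    expect_equal(as.numeric(Rg %*% n), c(0, 0, 1), tolerance = 1e-12)
  }
  expect_error(local_frame(c(0, 0, -1), c(1, 0, 0), c(1, 0, 0)),
               class = "sfdi_degenerate_geometry")
})

test_that("ray angles follow the documented polar/azimuth convention", {
  n <- c(0, 0, -1)
  Rg <- local_frame(n, c(0, -sin(0.5), cos(0.5)), c(1, 0, 0))
  a <- rays_to_angles(Rg, c(0, 0, 1), c(0, -sin(0.5), cos(0.5)), n)
  expect_equal(unname(a["phi_cam"]), 0, tolerance = 1e-12)
  expect_equal(unname(a["phi_pro"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(a["theta_pro"]), 0, tolerance = 1e-12)
  # 45 degrees in the e_x--e_z plane: tangential component along the fringe
  # direction, i.e. a quarter turn of azimuth from the propagation direction
  e45 <- c(sin(pi / 4), 0, cos(pi / 4))   # arriving from the camera side
  a45 <- rays_to_angles(Rg, e45, e45, n)
  expect_equal(unname(a45["phi_pro"]), pi / 4, tolerance = 1e-12)
  expect_equal(abs(unname(a45["theta_pro"])), pi / 2, tolerance = 1e-12)
  # a ray arriving from below the tangent plane is self-occluded
  below <- c(0, 0, -1)
  expect_true(is.na(rays_to_angles(Rg, below, below, n)["phi_cam"]))
})

test_that("twin angle maps agree with analytic ray-surface angles", {
  art <- noise_free_artifacts()
  scene <- twin_scene("sphere_cap", radius = 40, apex = c(0, 0, 320))
  surf <- truth_surface(scene, art$cfg)   # analytic normals, package angles
  est <- estimate_normals(surf, 16)       # PCA normals
  est <- surface_angles(est, art$art$geometry)
  inner <- 6:59
  dphi <- abs(est$phi_pro - surf$phi_pro)[inner, inner] * 180 / pi
  expect_lt(stats::quantile(dphi, 0.99, na.rm = TRUE), 0.5)
  # flat phantom: mean projection incidence equals the oblique angle
  flat <- truth_surface(twin_scene("plane", z = 320), art$cfg)
  expect_equal(mean(flat$phi_pro, na.rm = TRUE) * 180 / pi, 35, tolerance = 0.1)
  expect_lt(mean(flat$phi_cam, na.rm = TRUE) * 180 / pi, 4)
  expect_lt(abs(mean(flat$theta_pro, na.rm = TRUE)), 0.05)
})

test_that("surface maps export as PLY point clouds", {
  art <- noise_free_artifacts()
  surf <- estimate_normals(truth_surface(twin_scene("plane", z = 320), art$cfg), 16)
  path <- withr::local_tempfile(fileext = ".ply")
  write_surface_ply(surf, path, stride = 8)
  lines <- readLines(path)
  expect_equal(lines[1], "ply")
  n_vertex <- as.integer(sub("element vertex ", "",
                             grep("element vertex", lines, value = TRUE)))
  expect_equal(n_vertex, 64L)
  expect_length(lines, n_vertex + which(lines == "end_header"))
})
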