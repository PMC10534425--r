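# Digital-twin rendering: radiometry, determinism and ground-truth closure.

test_that("a zero-frequency pattern renders a smooth DC-like image", {
  cfg <- tiny_config(48)
  rend <- render_measurement(twin_scene("plane", z = 320), cfg, f_list = 0)
  d <- demodulate(rend$stacks[[1]], ac_threshold_rel = 0)
  # modulation present (f = 0 still phase-shifts globally), no spatial fringes
  expect_lt(stats::sd(d$i_ac) / mean(d$i_ac), 0.2)
  # DC image varies only through vignetting and Lambert shading
  expect_lt(diff(range(d$i_dc)) / mean(d$i_dc), 0.35)
})

test_that("identical seeds give bit-identical fixtures", {
  cfg <- tiny_config(32, noise_sigma = 0.005, noise_mult = 0.01)
  scene <- twin_scene("sphere_cap", radius = 40, apex = c(0, 0, 320))
  a <- render_measurement(scene, cfg, f_list = 0.45, seed = 77)
  b <- render_measurement(scene, cfg, f_list = 0.45, seed = 77)
  expect_identical(a$stacks[[1]]$images, b$stacks[[1]]$images)
  c <- render_measurement(scene, cfg, f_list = 0.45, seed = 78)
  expect_false(identical(a$stacks[[1]]$images, c$stacks[[1]]$images))
})

test_that("poisson shot noise is applied when configured", {
  cfg <- tiny_config(32, poisson_scale = 5e4)
  rend <- render_measurement(twin_scene("plane", z = 320), cfg,
                             f_list = 0.2, seed = 5)
  img <- rend$stacks[[1]]$images[[1]]
  expect_gt(length(unique(round(img * 5e4))), 100)
  expect_true(all(img >= 0))
})

test_that("scenes invisible to the camera warn at render time", {
  cfg <- tiny_config(32)
  scene <- twin_scene("sphere_cap", radius = 5, apex = c(40, 40, 320))
  expect_warning(render_measurement(scene, cfg, f_list = 0.2),
                 "visible over only")
})

test_that("defocus suppresses modulation away from the focal plane", {
  cfg <- tiny_config(48)
  m_at <- function(z) {
    rend <- render_measurement(twin_scene("plane", z = z), cfg, f_list = 0.8)
    d <- demodulate(rend$stacks[[1]])
    stats::median(d$i_ac / d$i_dc, na.rm = TRUE)
  }
  expect_gt(m_at(316), m_at(328))
  expect_gt(m_at(316), m_at(308))
  # with zero defocus growth the modulation is flat in distance
  cfg0 <- tiny_config(48, defocus_sigma0 = 0)
  m0 <- function(z) {
    rend <- render_measurement(twin_scene("plane", z = z), cfg0, f_list = 0.8)
    d <- demodulate(rend$stacks[[1]])
    stats::median(d$i_ac / d$i_dc, na.rm = TRUE)
  }
  expect_equal(m0(316), m0(328), tolerance = 0.02)
})

test_that("calibration-pose renders expose consistent ground truth", {
  cr <- cached("calib_renders", {
    cfg <- tiny_config(256)
    target <- small_target()
    poses <- calibration_pose_set(target)
    renders <- lapply(poses, function(p) render_calibration_pose(target, p, cfg))
    list(cfg = cfg, target = target, poses = poses, renders = renders)
  })
  rp <- cr$renders[[2]]
  expect_equal(nrow(rp$truth$camera_points), 169)
  # truth camera points equal the projection of the posed grid nodes
  P <- to_global_frame(cr$poses[[2]], cbind(object_points(cr$target), 0))
  expect_equal(rp$truth$camera_points, project_points(cr$cfg$camera, P),
               tolerance = 1e-12)
  expect_error(
    render_calibration_pose(cr$target,
                            target_pose_at(cr$target, c(40, 0, 320)), cr$cfg),
    class = "sfdi_input_error")
})

test_that("the reference stack covers the volume with the defocus peak at 316 mm", {
  art <- noise_free_artifacts()
  expect_length(art$ref$positions, 6)
  expect_equal(art$ref$z_list, seq(307.5, 332.5, length.out = 6))
  # per-pixel corrected AC intensity along l peaks near the focal distance
  lut <- art$art$lut
  i <- 32 + 31 * 64
  k_hi <- lut$n_f   # highest stored frequency is most defocus-sensitive
  prof <- lut$ac_nodes[i, , k_hi]
  peak_l <- lut$l_nodes[i, which.max(prof)]
  expect_lt(abs(peak_l - 316), 5.1)   # node spacing limits localization
})

test_that("twin reflectance closes the loop with the forward model", {
  cfg <- tiny_config(48)
  scene <- twin_scene("plane", z = 320,
                      reflectance = list(type = "sfd_model", mu_a = 0.18,
                                         mu_s_prime = 1.98, n_refractive = 1.52,
                                         g = 0.6))
  rend <- render_measurement(scene, cfg, f_list = 0.45)
  d <- demodulate(rend$stacks[[1]])
  # AC/DC ratio equals m * MTF * R(f_local) / R(0) exactly (noise-free)
  r0 <- forward_reflectance(0, 0.18, 1.98, 1.52)
  rf <- rend$truth$r_model[[1]]
  sigma_l <- cfg$defocus_sigma0 * abs(rend$truth$surface$l - cfg$focal_distance)
  mtf <- exp(-2 * pi^2 * rend$truth$f_local[[1]]^2 * sigma_l^2)
  expect_equal(d$i_ac / d$i_dc, cfg$modulation * mtf * rf / r0,
               tolerance = 1e-9, ignore_attr = TRUE)
})
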