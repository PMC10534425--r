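# Frequency scaling, Lambert correction, MTF look-up table and diffuse
# reflectance.

test_that("angular scaling factors match hand-evaluated cases and symmetries", {
  d35 <- 35 * pi / 180
  expect_equal(scaling_parallel(0, 1.2), 1)
  expect_equal(scaling_parallel(d35, pi / 2), 1, tolerance = 1e-12)
  expect_equal(scaling_parallel(d35, 0), cos(d35), tolerance = 1e-12)
  expect_equal(scaling_perpendicular(0, 0.3), 1)
  expect_equal(scaling_perpendicular(d35, 0), 1, tolerance = 1e-12)
  expect_equal(scaling_perpendicular(d35, pi / 2), cos(d35), tolerance = 1e-12)
  set.seed(4)
  tilt <- runif(50, 0, pi / 2 - 0.01); az <- runif(50, -pi, pi)
  expect_equal(scaling_parallel(tilt, az),
               scaling_perpendicular(tilt, pi / 2 - az), tolerance = 1e-12)
  expect_true(all(scaling_parallel(tilt, az) > 0 & scaling_parallel(tilt, az) <= 1))
})

test_that("the magnification factor is the reference/sample distance ratio", {
  expect_equal(magnification(c(0, 0, 320), c(0, 0, 320)), 1)
  expect_equal(magnification(c(0, 0, 320), c(0, 0, 310)), 320 / 310,
               tolerance = 1e-12)
  ds <- seq(300, 340, by = 5)
  s <- vapply(ds, function(z) magnification(c(0, 0, 320), c(0, 0, z)), numeric(1))
  expect_true(all(diff(s) < 0))
  expect_error(magnification(c(0, 0, 320), c(0, 0, 0)),
               class = "sfdi_degenerate_geometry")
})

test_that("the Lambert factor composes the three cosine terms", {
  expect_equal(lambert_factor(0, 0, 0), 1)
  d <- pi / 180
  expect_equal(lambert_factor(4 * d, 35 * d, 0), cos(4 * d) * cos(35 * d),
               tolerance = 1e-12)
  phis <- seq(0, 80, by = 10) * d
  expect_true(all(diff(lambert_factor(phis, 35 * d, 0.3)) < 0))
})

test_that("a flat sample at the reference plane has unit correction factors", {
  art <- noise_free_artifacts()
  surf <- truth_surface(twin_scene("plane", z = 320), art$cfg)
  fm <- correct_frequency(0.45, surf, art$art$geometry)
  expect_lt(max(abs(fm$f_corr - 0.45), na.rm = TRUE), 1e-6 * 0.45)
  expect_lt(max(abs(fm$s_z - 1), na.rm = TRUE), 1e-6)
  expect_lt(max(abs(fm$s_ang_par - 1), na.rm = TRUE), 1e-6)
  s_lam <- lambert_factor(surf$phi_cam, surf$phi_pro, surf$theta_pro)
  ref <- reference_surface(art$art$geometry, rays = surf$rays)
  s_lam_ref <- lambert_factor(ref$phi_cam, ref$phi_pro, ref$theta_pro)
  expect_lt(max(abs(s_lam / s_lam_ref - 1), na.rm = TRUE), 1e-9)
})

test_that("a height-shifted flat sample scales purely by the magnification factor", {
  art <- noise_free_artifacts()
  surf <- truth_surface(twin_scene("plane", z = 310), art$cfg)
  fm <- correct_frequency(0.45, surf, art$art$geometry)
  expect_lt(max(abs(fm$f_corr - 0.45 * 320 / 310), na.rm = TRUE), 1e-6)
  expect_lt(max(abs(fm$s_ang_par - 1), na.rm = TRUE), 1e-6)
})

test_that("the corrected-frequency map obeys its factor decomposition on the cap", {
  art <- noise_free_artifacts()
  surf <- truth_surface(twin_scene("sphere_cap", radius = 40,
                                   apex = c(0, 0, 320)), art$cfg)
  fm <- correct_frequency(0.45, surf, art$art$geometry)
  expect_equal(fm$f_corr, 0.45 * fm$s_z * fm$s_ang_par, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(fm$s_z > 0 & fm$s_ang_par > 0, na.rm = TRUE))
  # literal printed composition reproduces the published hemisphere gradient
  maps <- lapply(c(310, 320, 330), function(z) {
    s <- truth_surface(twin_scene("sphere_cap", radius = 40, apex = c(0, 0, z)),
                       art$cfg)
    correct_frequency(0.45, s, art$art$geometry, normalize = FALSE)$f_corr
  })
  expect_equal(min(unlist(maps), na.rm = TRUE), 0.28, tolerance = 0.05)
  expect_lt(max(unlist(maps), na.rm = TRUE), 0.45)
  # the perpendicular-inclusion flag changes the map
  fm2 <- correct_frequency(0.45, surf, art$art$geometry,
                           include_perpendicular = TRUE)
  expect_gt(max(abs(fm2$f_corr - fm$f_corr), na.rm = TRUE), 1e-4)
})

test_that("MTF LUT queries reproduce stored nodes exactly and blend between them", {
  art <- noise_free_artifacts()
  lut <- art$art$lut
  # query at the node grid of one position: both DC and AC rows
  pos <- 3
  l_node <- matrix(lut$l_nodes[, pos], lut$dims[1], lut$dims[2])
  got_dc <- mtf_lookup(lut, l_node, 0)
  expect_equal(as.numeric(got_dc), lut$dc_nodes[, pos], tolerance = 1e-9)
  for (k in c(1, 4)) {
    fq <- matrix(lut$f_nodes[, pos, k], lut$dims[1], lut$dims[2])
    got <- mtf_lookup(lut, l_node, fq)
    expect_equal(as.numeric(got), lut$ac_nodes[, pos, k], tolerance = 1e-9)
  }
  # midway in l between two positions: value between the two node values
  l_mid <- matrix((lut$l_nodes[, 2] + lut$l_nodes[, 3]) / 2,
                  lut$dims[1], lut$dims[2])
  fq <- matrix(lut$f_nodes[, 2, 4], lut$dims[1], lut$dims[2])
  got_mid <- as.numeric(mtf_lookup(lut, l_mid, fq))
  lo <- pmin(lut$ac_nodes[, 2, 4], lut$ac_nodes[, 3, 4]) - 1e-9
  hi <- pmax(lut$ac_nodes[, 2, 4], lut$ac_nodes[, 3, 4]) + 1e-9
  ok <- !is.na(got_mid)
  expect_true(all(got_mid[ok] >= lo[ok] * 0.98 & got_mid[ok] <= hi[ok] * 1.02))
  # outside the node hull: masked by default, finite under clamping
  l_out <- matrix(lut$l_nodes[, lut$n_pos] + 5, lut$dims[1], lut$dims[2])
  expect_true(all(is.na(mtf_lookup(lut, l_out, 0))))
  expect_true(all(is.finite(mtf_lookup(lut, l_out, 0, policy = "clamp"))))
})

test_that("the per-pixel intensity profile peaks at the focal distance", {
  art <- noise_free_artifacts()
  lut <- art$art$lut
  # densely query the DC profile of the central pixel across the volume
  ls <- seq(308, 332, by = 0.25)
  i <- 32 + 31 * 64
  prof <- vapply(ls, function(l) {
    lq <- matrix(NA_real_, 64, 64); lq[32, 32] <- l
    mtf_lookup(lut, lq, matrix(0.45 * l / 320, 64, 64))[32, 32]
  }, numeric(1))
  expect_equal(ls[which.max(prof)], 316, tolerance = 3)
})

test_that("measuring the reference standard reproduces its reflectance table", {
  art <- noise_free_artifacts()
  rp <- art$cfg$reference_props
  pos <- art$art$lut   # LUT built from these measurements
  ref_run <- art$ref$positions[[4]]
  demods <- demodulate_series(ref_run$render$stacks, art$ref$f_list, 0.01)
  rc <- run_config(art$ref$f_list, anchor_frequency = 0.01, f_geometry = 0.5,
                   n_refractive = rp$n_refractive, binning = 8)
  surf <- reconstruct_surface(demods, rc, art$art$geometry, art$art$pd_model,
                              art$art$rays)
  keep <- which(art$ref$f_list > 0 & abs(art$ref$f_list - 0.01) > 1e-12)
  fmaps <- lapply(art$ref$f_list[keep], correct_frequency, surface = surf,
                  geometry = art$art$geometry)
  refl <- compute_reflectance(demods[keep], art$ref$f_list[keep], surf, fmaps,
                              art$art$lut, art$art$geometry)
  r_true <- function(f) forward_reflectance(f, rp$mu_a, rp$mu_s_prime,
                                            rp$n_refractive)
  for (k in seq_along(keep)) {
    rel <- refl$r_ac[, , k] / r_true(refl$f_corr[, , k]) - 1
    expect_lt(stats::median(abs(rel), na.rm = TRUE), 1e-3)
  }
  expect_lt(stats::median(abs(refl$r_dc / r_true(0) - 1), na.rm = TRUE), 1e-6)
})
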