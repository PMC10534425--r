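# Shared fixtures, built once per test run and cached.

fixture_env <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = fixture_env))
    assign(name, force(expr), envir = fixture_env)
  get(name, envir = fixture_env)
}

tiny_config <- function(n_px = 64, ...) {
  twin_config(camera = twin_camera(n_px = n_px), ...)
}

small_target <- function() {
  calibration_target(n_cols = 13, n_rows = 13, spacing = 1.4,
                     circle_diameter = 0.7)
}

# Six target poses spanning the calibrated volume with tilt diversity,
# chosen so every circle stays safely inside the camera field.
calibration_pose_set <- function(target = small_target()) {
  list(target_pose_at(target, c(0, 0, 312), c(0, 0, 0)),
       target_pose_at(target, c(0.4, -0.4, 316), c(12, 5, 3)),
       target_pose_at(target, c(-0.4, 0.4, 320), c(-10, 8, -5)),
       target_pose_at(target, c(0.3, 0.3, 324), c(5, -12, 8)),
       target_pose_at(target, c(-0.3, -0.2, 328), c(-6, -8, -10)),
       target_pose_at(target, c(0, 0.2, 318), c(14, 10, 12)))
}

# Exact 3D-2D correspondences from the truth devices (solver-level oracle).
exact_correspondences <- function(cfg = tiny_config(256),
                                  target = small_target(),
                                  poses = calibration_pose_set(target)) {
  obj <- object_points(target)
  out <- list(object = list(), camera = list(), dmd = list(), poses = poses)
  for (k in seq_along(poses)) {
    P <- to_global_frame(poses[[k]], cbind(obj, 0))
    out$object[[k]] <- obj
    out$camera[[k]] <- project_points(cfg$camera, P)
    out$dmd[[k]] <- project_points(cfg$projector, P)
  }
  out
}

# Ascending temporal unwrap of a demodulated frequency chain.
unwrap_chain <- function(demods, freqs) {
  prev <- demods[[1]]$phase_wrapped
  pf <- freqs[1]
  for (q in seq_along(demods)[-1]) {
    prev <- unwrap_phase(demods[[q]]$phase_wrapped, demods[[q]]$validity,
                         anchor = prev, anchor_scale = freqs[q] / pf)
    pf <- freqs[q]
  }
  prev
}

# Noise-free 64 px calibration artifacts shared across correction and
# inversion tests (reference stack, phase-distance model, MTF LUT).
noise_free_artifacts <- function() {
  cached("art64", {
    cfg <- tiny_config(64)
    ref <- render_reference_stack(cfg, seed = 7)
    art <- twin_calibration_artifacts(cfg, ref, f_model = 0.45)
    list(cfg = cfg, ref = ref, art = art)
  })
}

# Ground-truth surface (with angles) of a scene, noise-free, via the twin.
truth_surface <- function(scene, cfg) {
  cfg$noise_sigma <- 0; cfg$noise_mult <- 0; cfg$poisson_scale <- 0
  render_measurement(scene, cfg, f_list = numeric(0),
                     patterns = list(pattern_spec("metric", f = 0)))$truth$surface
}
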