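# End-to-end orchestration: demodulate -> unwrap (temporal anchor chain) ->
# phase-distance reconstruction -> normals/angles -> frequency correction ->
# reflectance -> binning -> inversion, with correction toggles and a
# reproducible run manifest.

#' Pipeline run configuration
#'
#' @param f_list Nominal measurement frequencies, 1/mm, including the
#'   low-frequency absolute-phase anchor as its smallest nonzero entry.
#' @param anchor_frequency The absolute-phase anchor frequency (must appear in
#'   `f_list`); its phase map seeds the temporal unwrapping chain and it is
#'   excluded from the reflectance fit.
#' @param f_geometry Frequency whose phase map drives the 3D reconstruction
#'   (default: the largest entry of `f_list`).
#' @param n_phases Phase shifts per frequency.
#' @param orientation Pattern orientation (see [pattern_spec()]).
#' @param corrections List of toggles: `frequency` and `intensity` (Lambert).
#' @param binning Binning factor before inversion (default 16).
#' @param n_refractive Sample refractive index for the inversion.
#' @param k_neighbors Neighbors for normal estimation.
#' @param n_planes Virtual planes for the phase-distance fit.
#' @param policy LUT extrapolation policy.
#' @param include_dc Use the DC channel as an f = 0 point in the inversion.
#' @param seed Seed recorded in the manifest.
#' @return A validated list of class `sfdi_run_config`.
#' @export
run_config <- function(f_list, anchor_frequency = 0.01, f_geometry = NULL,
                       n_phases = 3, orientation = "y",
                       corrections = list(frequency = TRUE, intensity = TRUE),
                       binning = 16, n_refractive = 1.4, k_neighbors = 16,
                       n_planes = 10, policy = "mask", include_dc = TRUE,
                       seed = NULL) {
  if (length(f_list) == 0)
    sfdi_stop("sfdi_config_error", "f_list must not be empty")
  if (!anchor_frequency %in% f_list)
    sfdi_stop("sfdi_config_error", "anchor_frequency must be one of f_list")
  f_geometry <- f_geometry %||% max(f_list)
  if (!f_geometry %in% f_list)
    sfdi_stop("sfdi_config_error", "f_geometry must be one of f_list")
  stopifnot(isTRUE(corrections$frequency) || isFALSE(corrections$frequency),
            isTRUE(corrections$intensity) || isFALSE(corrections$intensity))
  structure(list(f_list = f_list, anchor_frequency = anchor_frequency,
                 f_geometry = f_geometry, n_phases = n_phases,
                 orientation = orientation, corrections = corrections,
                 binning = binning, n_refractive = n_refractive,
                 k_neighbors = k_neighbors, n_planes = n_planes,
                 policy = policy, include_dc = include_dc, seed = seed),
            class = "sfdi_run_config")
}

#' Demodulate and temporally unwrap a frequency series of fringe stacks
#'
#' Demodulates every stack and unwraps the phase maps in ascending frequency
#' order: the anchor frequency (absolute phase, less than a half period over
#' the field) seeds the chain; each subsequent map takes the 2 pi branch
#' closest to the frequency-scaled previous map.
#'
#' @param stacks List of [fringe_stack()]s aligned with `f_list`.
#' @param f_list Nominal frequencies.
#' @param anchor_frequency The chain seed frequency.
#' @return List of [demodulate()] results with `phase_unwrapped` filled for
#'   all nonzero frequencies.
#' @export
demodulate_series <- function(stacks, f_list, anchor_frequency) {
  demods <- lapply(stacks, demodulate)
  nz <- which(f_list > 0)
  ord <- nz[order(f_list[nz])]
  if (abs(f_list[ord[1]] - anchor_frequency) > 1e-12)
    sfdi_stop("sfdi_config_error",
              "anchor frequency %.4g is not the smallest nonzero frequency",
              anchor_frequency)
  prev_phase <- NULL; prev_f <- NULL
  for (j in ord) {
    d <- demods[[j]]
    if (is.null(prev_phase)) {
      d$phase_unwrapped <- d$phase_wrapped       # absolute by design
    } else {
      d$phase_unwrapped <- unwrap_phase(d$phase_wrapped, d$validity,
                                        anchor = prev_phase,
                                        anchor_scale = f_list[j] / prev_f)
    }
    demods[[j]] <- d
    prev_phase <- d$phase_unwrapped; prev_f <- f_list[j]
  }
  demods
}

#' Reconstruct the sample surface from a demodulated series
#'
#' Uses the phase map at `f_geometry` (scaled to the phase-distance model's
#' pattern frequency if they differ), converts it to 3D points, estimates
#' normals and angles.
#'
#' @param demods Output of [demodulate_series()].
#' @param config An [run_config()].
#' @param geometry An [system_geometry()].
#' @param pd_model An [fit_phase_distance()] result.
#' @param rays Optional camera ray field.
#' @return An `sfdi_surface` with normals and angles.
#' @export
reconstruct_surface <- function(demods, config, geometry, pd_model, rays = NULL) {
  j <- which(abs(config$f_list - config$f_geometry) < 1e-12)[1]
  phase <- demods[[j]]$phase_unwrapped
  if (is.null(phase))
    sfdi_stop("sfdi_input_error", "geometry frequency has no unwrapped phase")
  scale <- pd_model$pattern$f / config$f_geometry
  surf <- phase_to_points(pd_model, phase * scale, geometry, rays = rays)
  surf <- estimate_normals(surf, config$k_neighbors)
  surface_angles(surf, geometry, config$orientation)
}

#' Run the full measurement pipeline
#'
#' @param stacks List of [fringe_stack()]s, one per entry of `config$f_list`.
#' @param config An [run_config()].
#' @param geometry An [system_geometry()].
#' @param pd_model An [fit_phase_distance()] result for the measurement
#'   pattern.
#' @param lut An [build_mtf_lut()] result.
#' @param rays Optional precomputed camera ray field.
#' @return A list of class `sfdi_run`: `demods`, `surface`, `freq_maps`,
#'   `reflectance`, `properties`, and `manifest` (stage statistics, applied
#'   corrections, seeds and output checksums).
#' @export
run_pipeline <- function(stacks, config, geometry, pd_model, lut, rays = NULL) {
  stopifnot(inherits(config, "sfdi_run_config"))
  if (length(stacks) != length(config$f_list))
    sfdi_stop("sfdi_config_error", "got %d stacks for %d frequencies",
              length(stacks), length(config$f_list))
  stage <- function(name, expr) {
    out <- tryCatch(force(expr), error = function(e)
      sfdi_stop("sfdi_stage_error", "stage '%s' failed: %s", name,
                conditionMessage(e)))
    out
  }
  rays <- rays %||% build_ray_fields(geometry, "camera")
  demods <- stage("demodulate", demodulate_series(stacks, config$f_list,
                                                  config$anchor_frequency))
  surf <- stage("reconstruct",
                reconstruct_surface(demods, config, geometry, pd_model, rays))
  reference <- reference_surface(geometry, config$orientation, rays)
  # reflectance frequencies: nonzero, excluding the unwrapping anchor
  refl_sel <- which(config$f_list > 0 &
                      abs(config$f_list - config$anchor_frequency) > 1e-12)
  f_refl <- config$f_list[refl_sel]
  freq_maps <- stage("correct_frequency", lapply(f_refl, function(f) {
    if (config$corrections$frequency)
      correct_frequency(f, surf, geometry, reference = reference)
    else {
      fc <- matrix(f, nrow(surf$l), ncol(surf$l))
      fc[!surf$valid] <- NA_real_
      structure(list(f_ref = f, f_corr = fc,
                     s_z = matrix(1, nrow(surf$l), ncol(surf$l)),
                     s_ang_par = matrix(1, nrow(surf$l), ncol(surf$l)),
                     s_ang_perp = matrix(1, nrow(surf$l), ncol(surf$l)),
                     normalized = NA), class = "sfdi_freq_map")
    }
  }))
  refl <- stage("reflectance",
                compute_reflectance(demods[refl_sel], f_refl, surf, freq_maps,
                                    lut, geometry,
                                    lambert = config$corrections$intensity,
                                    policy = config$policy))
  props <- stage("invert", invert_map(refl, bin = config$binning,
                                      n_refractive = config$n_refractive,
                                      include_dc = config$include_dc))
  manifest <- list(
    f_list = config$f_list, anchor_frequency = config$anchor_frequency,
    f_geometry = config$f_geometry, corrections = config$corrections,
    binning = config$binning, n_refractive = config$n_refractive,
    seed = config$seed,
    stages = list(
      demodulate = list(valid_fraction =
                          vapply(demods, function(d) mean(d$validity), numeric(1))),
      reconstruct = list(valid_fraction = mean(surf$valid),
                         masked_out_of_range = attr(surf, "n_masked_range")),
      reflectance = list(valid_fraction = valid_fraction(refl$r_ac)),
      invert = list(cells = length(props$mu_a),
                    converged_fraction = mean(props$converged[!is.na(props$mu_a)]))),
    checksums = list(mu_a = checksum_of(props$mu_a),
                     mu_s_prime = checksum_of(props$mu_s_prime),
                     r_ac = checksum_of(refl$r_ac)))
  structure(list(demods = demods, surface = surf, freq_maps = freq_maps,
                 reflectance = refl, properties = props, manifest = manifest),
            class = "sfdi_run")
}

#' MD5 checksum of a serialized R object
#' @noRd
checksum_of <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Fit the calibration-time artifacts of a twin setup
#'
#' Convenience wrapper producing everything a measurement run needs from a
#' twin configuration and its reference stack: the (ground-truth) system
#' geometry, camera ray field, phase-distance model and MTF look-up table.
#'
#' @param config A [twin_config()].
#' @param reference Output of [render_reference_stack()].
#' @param f_model Pattern frequency for the phase-distance model, 1/mm.
#' @param n_planes Virtual planes for the fit.
#' @param orientation Pattern orientation.
#' @param f_geometry Frequency used to reconstruct the reference surfaces;
#'   defaults to the acquired frequency closest to `f_model`. High frequencies
#'   lose modulation to defocus at the volume edges and make poor geometry
#'   sources.
#' @return List with `geometry`, `rays`, `pd_model`, `lut`, `r_ref_table`.
#' @export
twin_calibration_artifacts <- function(config, reference, f_model = 0.45,
                                       n_planes = 10, orientation = "y",
                                       f_geometry = NULL) {
  geometry <- twin_geometry(config)
  rays <- build_ray_fields(geometry, "camera")
  pd_model <- fit_phase_distance(geometry, n_planes = n_planes,
                                 pattern = pattern_spec("metric", f = f_model,
                                                        orientation = orientation),
                                 rays = rays)
  r_ref_table <- twin_reference_table(config)
  f_all <- reference$f_list
  f_geometry <- f_geometry %||%
    f_all[f_all > 0][which.min(abs(f_all[f_all > 0] - f_model))]
  positions <- lapply(reference$positions, function(pos) {
    demods <- demodulate_series(pos$render$stacks, f_all,
                                reference$anchor_frequency)
    cfg <- run_config(f_list = f_all,
                      anchor_frequency = reference$anchor_frequency,
                      f_geometry = f_geometry, orientation = orientation,
                      n_planes = n_planes)
    surf <- reconstruct_surface(demods, cfg, geometry, pd_model, rays)
    # LUT nodes: all frequencies except the unwrapping anchor
    keep <- which(abs(f_all - reference$anchor_frequency) > 1e-12)
    list(surface = surf, demods = demods[keep], f_nominal = f_all[keep])
  })
  lut <- build_mtf_lut(positions, geometry, r_ref_table)
  list(geometry = geometry, rays = rays, pd_model = pd_model, lut = lut,
       r_ref_table = r_ref_table)
}
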