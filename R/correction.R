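# Position- and orientation-dependent corrections: angular and magnification
# scaling of the local spatial frequency, Lambert intensity correction, the
# per-pixel MTF look-up hypersurface over (distance, frequency), and diffuse
# reflectance against a reference standard.

#' Angular frequency-scaling factors
#'
#' Geometric scaling of the projected fringe frequency for a surface patch
#' illuminated at polar angle `tilt` with the ray azimuth `azimuth`:
#' `scaling_parallel = sqrt(cos^2 tilt + sin^2 azimuth * sin^2 tilt)` (scaling
#' along the fringe direction) and
#' `scaling_perpendicular = sqrt(cos^2 tilt + cos^2 azimuth * sin^2 tilt)`.
#' The two coincide under the exchange `azimuth -> 90 deg - azimuth`; both are
#' 1 at normal incidence and fall to `cos(tilt)` at the respective degenerate
#' azimuth.
#'
#' @param tilt Polar angle in radians (angle between ray and surface normal).
#' @param azimuth Azimuth of the ray's tangential component in radians.
#' @return Scaling factor(s) in (0, 1].
#' @export
scaling_parallel <- function(tilt, azimuth) {
  sqrt(cos(tilt)^2 + sin(azimuth)^2 * sin(tilt)^2)
}

#' @rdname scaling_parallel
#' @export
scaling_perpendicular <- function(tilt, azimuth) {
  sqrt(cos(tilt)^2 + cos(azimuth)^2 * sin(tilt)^2)
}

#' Magnification factor between a reference point and a sample point
#'
#' `S_z = |p_ref| / |p|`: the fringe field diverges from the projection
#' center, so a surface closer to the device sees a proportionally higher
#' metric frequency.
#'
#' @param p_ref,p 3-vectors (or n x 3 matrices) of global coordinates, mm.
#' @return Scalar or vector of magnification factors.
#' @export
magnification <- function(p_ref, p) {
  p_ref <- as_points(p_ref, 3); p <- as_points(p, 3)
  np <- row_norms(p)
  if (any(np <= 0, na.rm = TRUE))
    sfdi_stop("sfdi_degenerate_geometry", "sample point at the origin")
  row_norms(p_ref) / np
}

#' Lambert intensity-correction factor
#'
#' `cos(phi_cam) * scaling_perpendicular(phi_pro, theta_pro) *
#' scaling_parallel(phi_pro, theta_pro)`: the cosine-law signal attenuation of
#' a Lambertian surface patch relative to normal incidence and detection.
#' Measured intensities are divided by this factor (relative orientation
#' correction); the same division is applied to the reference standard when
#' building the MTF look-up table, so the reference ratio of the reflectance
#' computation cancels the model exactly for Lambertian samples.
#'
#' @param phi_cam Detection polar angle (rad).
#' @param phi_pro Projection polar angle (rad).
#' @param theta_pro Projection azimuth (rad).
#' @return Factor(s) in (0, 1].
#' @export
lambert_factor <- function(phi_cam, phi_pro, theta_pro) {
  abs(cos(phi_cam)) * scaling_perpendicular(phi_pro, theta_pro) *
    scaling_parallel(phi_pro, theta_pro)
}

#' @noRd
surface_lambert <- function(surface) {
  lambert_factor(surface$phi_cam, surface$phi_pro, surface$theta_pro)
}

#' Per-pixel corrected spatial frequency
#'
#' `f_corr = f_ref * s_z * s_ang` with `s_z` the magnification factor of the
#' surface point against the reference-plane point on the same camera ray and
#' `s_ang` the angular scaling from the projection angles. With
#' `normalize = TRUE` (default) the angular factor is taken relative to its
#' reference-plane value at the same pixel, so a flat sample at the reference
#' plane has all factors identically 1 and the corrected map tracks the true
#' local fringe frequency; `normalize = FALSE` uses the raw composition of the
#' angular factor. `include_perpendicular` additionally applies the
#' perpendicular scaling ratio (off by default; the angular factor along the
#' fringe normal direction dominates for oblique projection).
#'
#' @param f_ref Nominal frequency at the reference plane, 1/mm.
#' @param surface An `sfdi_surface` with angles (see [surface_angles()]).
#' @param geometry An [system_geometry()] object.
#' @param reference Optional precomputed [reference_surface()] (used for the
#'   per-pixel reference points of the magnification factor).
#' @param normalize Normalize the angular factors to isolate the orientation
#'   effect: each factor is divided by its value for a reference-oriented
#'   (flat, camera-facing) patch at the same surface position, so a pure
#'   height shift is carried entirely by `s_z` and a flat sample at the
#'   reference plane has all factors identically 1.
#' @param include_perpendicular Also apply the perpendicular scaling ratio.
#' @return An object of class `sfdi_freq_map`: matrices `f_corr`, `s_z`,
#'   `s_ang_par`, `s_ang_perp` and the scalar `f_ref`. `s_ang_par` is the
#'   angular factor actually applied, so `f_corr = f_ref * s_z * s_ang_par`
#'   holds exactly.
#' @export
correct_frequency <- function(f_ref, surface, geometry, reference = NULL,
                              normalize = TRUE, include_perpendicular = FALSE) {
  if (is.null(surface$phi_pro))
    sfdi_stop("sfdi_input_error", "surface has no angles; run surface_angles()")
  orientation <- surface$pattern_orientation %||% "y"
  reference <- reference %||%
    reference_surface(geometry, orientation, rays = surface$rays)
  s_par <- scaling_parallel(surface$phi_pro, surface$theta_pro)
  s_perp <- scaling_perpendicular(surface$phi_pro, surface$theta_pro)
  if (normalize) {
    flat <- surface
    nrm <- -geometry$reference_plane$normal /
      sqrt(sum(geometry$reference_plane$normal^2))
    nr <- nrow(surface$z); nc <- ncol(surface$z)
    flat$nx <- matrix(nrm[1], nr, nc)
    flat$ny <- matrix(nrm[2], nr, nc)
    flat$nz <- matrix(nrm[3], nr, nc)
    flat <- surface_angles(flat, geometry, orientation)
    s_par <- s_par / scaling_parallel(flat$phi_pro, flat$theta_pro)
    s_perp <- s_perp / scaling_perpendicular(flat$phi_pro, flat$theta_pro)
  }
  s_ang <- if (include_perpendicular) s_par * s_perp else s_par
  np <- sqrt(surface$x^2 + surface$y^2 + surface$z^2)
  npr <- sqrt(reference$x^2 + reference$y^2 + reference$z^2)
  s_z <- npr / np
  f_corr <- f_ref * s_z * s_ang
  f_corr[!surface$valid] <- NA_real_
  structure(list(f_ref = f_ref, f_corr = f_corr, s_z = s_z,
                 s_ang_par = s_ang, s_ang_perp = s_perp,
                 normalized = normalize),
            class = "sfdi_freq_map")
}

# --- MTF look-up hypersurface -------------------------------------------------

#' Build the per-pixel MTF look-up table from reference measurements
#'
#' For each reference position the Lambert-corrected DC and AC intensities are
#' placed per pixel on a (distance l, corrected frequency f) node grid; the DC
#' row sits at f = 0. Nodes are sorted per pixel by l (duplicates averaged and
#' flagged); queries interpolate bilinearly inside the node hull and return NA
#' outside.
#'
#' @param positions List, one entry per reference position, each a list with
#'   `surface` (an `sfdi_surface` with angles), `demods` (list of
#'   [demodulate()] results, one per nominal frequency), `f_nominal` (numeric
#'   vector, 1/mm; entries equal to 0 contribute to the DC row only), and
#'   optionally `freq_maps` (list of [correct_frequency()] results; computed
#'   when missing).
#' @param geometry An [system_geometry()] object.
#' @param r_ref_table Data frame with columns `f` and `r`: the known diffuse
#'   reflectance of the reference standard (linear interpolation in f).
#' @return An object of class `sfdi_mtf_lut`.
#' @export
build_mtf_lut <- function(positions, geometry, r_ref_table) {
  stopifnot(length(positions) >= 2)
  reference <- reference_surface(geometry, rays = positions[[1]]$surface$rays)
  n_pos <- length(positions)
  dims <- dim(positions[[1]]$surface$l)
  npix <- prod(dims)
  f_ac <- positions[[1]]$f_nominal[positions[[1]]$f_nominal > 0]
  n_f <- length(f_ac)
  l_nodes <- matrix(NA_real_, npix, n_pos)
  dc_nodes <- matrix(NA_real_, npix, n_pos)
  f_nodes <- array(NA_real_, c(npix, n_pos, n_f))
  ac_nodes <- array(NA_real_, c(npix, n_pos, n_f))
  for (p in seq_len(n_pos)) {
    pos <- positions[[p]]
    stopifnot(identical(dim(pos$surface$l), dims))
    s_lam <- surface_lambert(pos$surface)
    l_nodes[, p] <- as.numeric(pos$surface$l)
    dc <- 0; n_dc <- 0
    ac_j <- 0L
    for (j in seq_along(pos$f_nominal)) {
      dm <- pos$demods[[j]]
      dc <- dc + as.numeric(dm$i_dc / s_lam); n_dc <- n_dc + 1
      if (pos$f_nominal[j] > 0) {
        ac_j <- ac_j + 1L
        fm <- if (!is.null(pos$freq_maps)) pos$freq_maps[[ac_j]] else
          correct_frequency(pos$f_nominal[j], pos$surface, geometry,
                            reference = reference)
        f_nodes[, p, ac_j] <- as.numeric(fm$f_corr)
        ac_nodes[, p, ac_j] <- as.numeric(dm$i_ac / s_lam)
      }
    }
    dc_nodes[, p] <- dc / n_dc
  }
  # per-pixel sort by l; average duplicate-l nodes
  ord <- t(apply(l_nodes, 1, order, na.last = TRUE))
  n_dup <- 0L
  for (i in seq_len(npix)) {
    o <- ord[i, ]
    if (is.unsorted(l_nodes[i, ], na.rm = TRUE)) {
      l_nodes[i, ] <- l_nodes[i, o]
      dc_nodes[i, ] <- dc_nodes[i, o]
      f_nodes[i, , ] <- f_nodes[i, o, ]
      ac_nodes[i, , ] <- ac_nodes[i, o, ]
    }
    d <- which(diff(l_nodes[i, ]) < 1e-9)
    if (length(d) > 0) {
      n_dup <- n_dup + 1L
      for (k in d) {
        m <- (dc_nodes[i, k] + dc_nodes[i, k + 1]) / 2
        dc_nodes[i, k] <- m; dc_nodes[i, k + 1] <- m
        ma <- (ac_nodes[i, k, ] + ac_nodes[i, k + 1, ]) / 2
        ac_nodes[i, k, ] <- ma; ac_nodes[i, k + 1, ] <- ma
        l_nodes[i, k + 1] <- l_nodes[i, k] + 1e-9
      }
    }
  }
  if (n_dup > 0)
    warning(sprintf("%d pixel(s) had duplicate distance nodes (averaged)", n_dup))
  structure(list(l_nodes = l_nodes, dc_nodes = dc_nodes, f_nodes = f_nodes,
                 ac_nodes = ac_nodes, dims = dims, n_pos = n_pos, n_f = n_f,
                 f_nominal_ac = f_ac, r_ref_table = r_ref_table),
            class = "sfdi_mtf_lut")
}

#' Interpolate a value along the frequency axis of one LUT position row
#' @noRd
interp_f_row <- function(lut, pos_idx, fq, pix) {
  fn <- lut$f_nodes[cbind(rep(pix, lut$n_f), rep(pos_idx, lut$n_f),
                          rep(seq_len(lut$n_f), each = length(pix)))]
  dim(fn) <- c(length(pix), lut$n_f)
  an <- lut$ac_nodes[cbind(rep(pix, lut$n_f), rep(pos_idx, lut$n_f),
                           rep(seq_len(lut$n_f), each = length(pix)))]
  dim(an) <- c(length(pix), lut$n_f)
  out <- rep(NA_real_, length(pix))
  # assume f_nodes increasing in the frequency index (corrected f follows nominal f)
  j_hi <- rowSums(fq > fn) + 1L
  ok <- !is.na(fq) & !is.na(j_hi) & j_hi >= 2L & j_hi <= lut$n_f
  ok[ok] <- fq[ok] >= fn[cbind(which(ok), j_hi[ok] - 1L)]
  exact1 <- !is.na(fq) & !is.na(fn[, 1]) & abs(fq - fn[, 1]) < 1e-12
  out[exact1] <- an[exact1, 1]
  idx <- which(ok)
  if (length(idx) > 0) {
    jl <- j_hi[idx] - 1L; jh <- j_hi[idx]
    fl <- fn[cbind(idx, jl)]; fh <- fn[cbind(idx, jh)]
    w <- (fq[idx] - fl) / (fh - fl)
    out[idx] <- (1 - w) * an[cbind(idx, jl)] + w * an[cbind(idx, jh)]
  }
  out
}

#' Query the MTF look-up hypersurface
#'
#' Bilinear interpolation over the per-pixel (l, f) node grid; `f = 0` queries
#' the DC row. Queries outside the node hull return NA (`policy = "mask"`) or
#' are clamped to the hull (`policy = "clamp"`).
#'
#' @param lut An [build_mtf_lut()] result.
#' @param l_query Matrix (or vector) of distances, mm.
#' @param f_query Matrix/vector of corrected frequencies (1/mm), or the scalar
#'   0 for the DC row.
#' @param policy `"mask"` or `"clamp"`.
#' @return Matrix of interpolated corrected reference intensities.
#' @export
mtf_lookup <- function(lut, l_query, f_query = 0, policy = c("mask", "clamp")) {
  policy <- match.arg(policy)
  lq <- as.numeric(l_query)
  npix <- length(lq)
  stopifnot(npix == prod(lut$dims))
  if (policy == "clamp") {
    lq <- pmin(pmax(lq, lut$l_nodes[, 1]), lut$l_nodes[, lut$n_pos])
  }
  p_hi <- rowSums(lq > lut$l_nodes) + 1L
  exact_last <- !is.na(lq) & !is.na(lut$l_nodes[, lut$n_pos]) &
    abs(lq - lut$l_nodes[, lut$n_pos]) < 1e-12
  p_hi[exact_last] <- lut$n_pos
  exact_first <- !is.na(lq) & !is.na(lut$l_nodes[, 1]) &
    abs(lq - lut$l_nodes[, 1]) < 1e-12
  p_hi[exact_first] <- 2L
  ok <- !is.na(lq) & !is.na(p_hi) & p_hi >= 2L & p_hi <= lut$n_pos
  dc_mode <- length(f_query) == 1 && all(f_query == 0)
  fq <- if (dc_mode) NULL else as.numeric(f_query)
  if (!dc_mode && policy == "clamp") {
    fmin <- apply(lut$f_nodes[, , 1, drop = FALSE], 1, max)
    fmax <- apply(lut$f_nodes[, , lut$n_f, drop = FALSE], 1, min)
    fq <- pmin(pmax(fq, fmin), fmax)
  }
  out <- rep(NA_real_, npix)
  idx <- which(ok)
  if (length(idx) > 0) {
    pl <- p_hi[idx] - 1L; ph <- p_hi[idx]
    ll <- lut$l_nodes[cbind(idx, pl)]; lh <- lut$l_nodes[cbind(idx, ph)]
    w <- (lq[idx] - ll) / (lh - ll)
    if (dc_mode) {
      vlo <- lut$dc_nodes[cbind(idx, pl)]; vhi <- lut$dc_nodes[cbind(idx, ph)]
    } else {
      vlo <- rep(NA_real_, npix); vhi <- rep(NA_real_, npix)
      for (p in sort(unique(pl))) {
        sel <- idx[pl == p]
        vlo[sel] <- interp_f_row(lut, p, fq[sel], sel)
      }
      for (p in sort(unique(ph))) {
        sel <- idx[ph == p]
        vhi[sel] <- interp_f_row(lut, p, fq[sel], sel)
      }
      vlo <- vlo[idx]; vhi <- vhi[idx]
    }
    val <- (1 - w) * vlo + w * vhi
    # exactly on a node row: the other row carries zero weight even if it
    # does not cover the query frequency
    eps <- 1e-12
    val[w >= 1 - eps] <- vhi[w >= 1 - eps]
    val[w <= eps] <- vlo[w <= eps]
    out[idx] <- val
  }
  matrix(out, lut$dims[1], lut$dims[2])
}

#' Known reference reflectance at given frequencies
#' @noRd
r_ref_at <- function(r_ref_table, f) {
  stats::approx(r_ref_table$f, r_ref_table$r, xout = f, rule = 2)$y
}

#' Diffuse reflectance of a sample measurement
#'
#' Implements the reference-ratio reflectance: per frequency,
#' `R = (I_AC / S_Lambert) / MTF_ref(l, f_corr) * R_ref(f_corr)`; the DC
#' channel averages `(I_DC / S_Lambert) / MTF_ref(l, 0) * R_ref(0)` over the
#' acquired frequencies.
#'
#' @param demods List of [demodulate()] results, one per nominal frequency.
#' @param f_nominal Nominal reference-plane frequencies (1/mm) of `demods`.
#' @param surface The reconstructed sample `sfdi_surface` with angles.
#' @param freq_maps List of [correct_frequency()] results aligned with the
#'   entries of `f_nominal` that are > 0.
#' @param lut An [build_mtf_lut()] result.
#' @param geometry An [system_geometry()] object.
#' @param lambert Apply the Lambert correction (disable to reproduce
#'   uncorrected processing).
#' @param policy Extrapolation policy for LUT queries.
#' @return An object of class `sfdi_reflectance`: array `r_ac`
#'   (rows x cols x n_f over the AC frequencies), matrix `r_dc`, arrays of the
#'   corrected frequencies used, and provenance flags.
#' @export
compute_reflectance <- function(demods, f_nominal, surface, freq_maps, lut,
                                geometry, lambert = TRUE,
                                policy = c("mask", "clamp")) {
  policy <- match.arg(policy)
  s_lam <- if (lambert) surface_lambert(surface) else
    matrix(1, nrow(surface$l), ncol(surface$l))
  ac_sel <- which(f_nominal > 0)
  n_f <- length(ac_sel)
  dims <- dim(surface$l)
  r_ac <- array(NA_real_, c(dims, n_f))
  f_used <- array(NA_real_, c(dims, n_f))
  dc_acc <- matrix(0, dims[1], dims[2]); dc_n <- 0
  mtf_dc <- mtf_lookup(lut, surface$l, 0, policy = policy)
  r0 <- r_ref_at(lut$r_ref_table, 0)
  for (j in seq_along(f_nominal)) {
    dm <- demods[[j]]
    dc_acc <- dc_acc + (dm$i_dc / s_lam) / mtf_dc * r0
    dc_n <- dc_n + 1
    if (f_nominal[j] > 0) {
      k <- match(j, ac_sel)
      fm <- freq_maps[[k]]
      mtf <- mtf_lookup(lut, surface$l, fm$f_corr, policy = policy)
      r_ac[, , k] <- (dm$i_ac / s_lam) / mtf * r_ref_at(lut$r_ref_table, fm$f_corr)
      f_used[, , k] <- fm$f_corr
    }
  }
  structure(list(r_ac = r_ac, r_dc = dc_acc / dc_n, f_corr = f_used,
                 f_nominal = f_nominal[ac_sel],
                 corrections = c(lambert = lambert),
                 policy = policy),
            class = "sfdi_reflectance")
}
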