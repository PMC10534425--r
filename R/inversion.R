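# Diffusion-approximation forward reflectance model for semi-infinite turbid
# media in the spatial frequency domain, map binning, and bounded nonlinear
# least-squares inversion for (mu_a, mu_s') with a coarse-grid multi-start.
# The forward model is deliberately pluggable: any function R(f, mu_a, mu_s')
# can replace it in fit_optical_properties().

#' Effective internal-reflection parameter from the refractive index
#'
#' `r_eff` follows the Groenhuis/Egan-Hilgeman polynomial
#' `-1.440 n^-2 + 0.710 n^-1 + 0.668 + 0.0636 n`; the boundary parameter is
#' `A = (1 + r_eff) / (1 - r_eff)`.
#'
#' @param n_refractive Sample refractive index.
#' @return `internal_reflection_A` returns A; `r_eff_polynomial` returns r_eff.
#' @export
internal_reflection_A <- function(n_refractive) {
  r_eff <- r_eff_polynomial(n_refractive)
  (1 + r_eff) / (1 - r_eff)
}

#' @rdname internal_reflection_A
#' @export
r_eff_polynomial <- function(n_refractive) {
  -1.440 / n_refractive^2 + 0.710 / n_refractive + 0.668 + 0.0636 * n_refractive
}

#' Diffusion-approximation SFD diffuse reflectance
#'
#' `mu_tr = mu_a + mu_s'`, `mu_eff'(f) = sqrt(3 mu_a mu_tr + (2 pi f)^2)`,
#' `a' = mu_s' / mu_tr`, and
#' `R = 3 A a' / ((mu_eff'/mu_tr + 1) (mu_eff'/mu_tr + 3 A))`.
#' Strictly decreasing in f and in mu_a, with `R -> 1` as `mu_a -> 0, f -> 0`.
#'
#' @param f Spatial frequency, 1/mm (scalar or vector).
#' @param mu_a Absorption coefficient, 1/mm (>= 0).
#' @param mu_s_prime Reduced scattering coefficient, 1/mm (> 0).
#' @param n_refractive Refractive index (default 1.4).
#' @return Diffuse reflectance in (0, 1).
#' @export
forward_reflectance <- function(f, mu_a, mu_s_prime, n_refractive = 1.4) {
  stopifnot(all(f >= 0, na.rm = TRUE), all(mu_a >= 0, na.rm = TRUE),
            all(mu_s_prime > 0, na.rm = TRUE))
  A <- internal_reflection_A(n_refractive)
  mu_tr <- mu_a + mu_s_prime
  mu_eff <- sqrt(3 * mu_a * mu_tr + (2 * pi * f)^2)
  a_prime <- mu_s_prime / mu_tr
  ratio <- mu_eff / mu_tr
  3 * A * a_prime / ((ratio + 1) * (ratio + 3 * A))
}

#' Mask-aware map binning
#'
#' Reduces a map by `factor` in each direction, averaging valid pixels per
#' cell; cells with less than half their pixels valid are masked. Trailing
#' rows/columns that do not fill a complete cell are trimmed.
#'
#' @param map Numeric matrix (NA = invalid).
#' @param factor Integer binning factor (default 16).
#' @param min_valid Minimum valid fraction per cell (default 0.5).
#' @return Binned matrix.
#' @export
bin_map <- function(map, factor = 16, min_valid = 0.5) {
  stopifnot(factor >= 1)
  nr <- (nrow(map) %/% factor) * factor
  nc <- (ncol(map) %/% factor) * factor
  if (nr < factor || nc < factor)
    sfdi_stop("sfdi_input_error", "map smaller than one bin")
  m <- map[seq_len(nr), seq_len(nc), drop = FALSE]
  v <- !is.na(m)
  mm <- m; mm[!v] <- 0
  g1 <- rep(seq_len(nr / factor), each = factor)
  sum_rows <- rowsum(mm, g1); cnt_rows <- rowsum(v + 0, g1)
  g2 <- rep(seq_len(nc / factor), each = factor)
  sums <- t(rowsum(t(sum_rows), g2)); cnts <- t(rowsum(t(cnt_rows), g2))
  out <- sums / cnts
  out[cnts < min_valid * factor^2] <- NA_real_
  dimnames(out) <- NULL
  out
}

#' Fit optical properties to measured diffuse reflectance
#'
#' Bounded Levenberg-Marquardt least squares of the forward model against
#' `R(f)` data, started from the best cell of a coarse log-spaced
#' (mu_a, mu_s') grid to avoid local minima.
#'
#' @param r_values Measured diffuse reflectance per frequency (NA allowed).
#' @param f_values Spatial frequencies, 1/mm (same length).
#' @param n_refractive Sample refractive index.
#' @param forward Forward model `function(f, mu_a, mu_s_prime, n_refractive)`.
#' @param bounds List with `mu_a` and `mu_s_prime` ranges, 1/mm.
#' @param grid_n Multi-start grid resolution per parameter (default 8).
#' @return An object of class `sfdi_opt_fit`: `mu_a`, `mu_s_prime`,
#'   `fit_residual` (RMS), `converged`, `n_points`, `n_refractive`.
#' @export
fit_optical_properties <- function(r_values, f_values, n_refractive = 1.4,
                                   forward = forward_reflectance,
                                   bounds = list(mu_a = c(1e-5, 10),
                                                 mu_s_prime = c(1e-3, 20)),
                                   grid_n = 8) {
  keep <- is.finite(r_values) & is.finite(f_values)
  r <- r_values[keep]; f <- f_values[keep]
  dup <- !duplicated(signif(f, 12)) | TRUE   # duplicated points are legitimate data
  if (length(unique(signif(f, 12))) < 2 || all(r == 0))
    return(structure(list(mu_a = NA_real_, mu_s_prime = NA_real_,
                          fit_residual = NA_real_, converged = FALSE,
                          n_points = sum(keep), n_refractive = n_refractive),
                     class = "sfdi_opt_fit"))
  ga <- exp(seq(log(max(bounds$mu_a[1], 1e-4)), log(min(bounds$mu_a[2], 5)),
                length.out = grid_n))
  gs <- exp(seq(log(max(bounds$mu_s_prime[1], 0.05)), log(min(bounds$mu_s_prime[2], 10)),
                length.out = grid_n))
  grid <- expand.grid(mu_a = ga, mu_s = gs)
  sse <- vapply(seq_len(nrow(grid)), function(i) {
    sum((forward(f, grid$mu_a[i], grid$mu_s[i], n_refractive) - r)^2)
  }, numeric(1))
  best <- grid[which.min(sse), ]
  resid_fn <- function(p) forward(f, p[1], p[2], n_refractive) - r
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(best$mu_a, best$mu_s), fn = resid_fn,
                       lower = c(bounds$mu_a[1], bounds$mu_s_prime[1]),
                       upper = c(bounds$mu_a[2], bounds$mu_s_prime[2]),
                       control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(mu_a = best$mu_a, mu_s_prime = best$mu_s,
                          fit_residual = sqrt(min(sse) / length(r)),
                          converged = FALSE, n_points = length(r),
                          n_refractive = n_refractive),
                     class = "sfdi_opt_fit"))
  }
  structure(list(mu_a = fit$par[1], mu_s_prime = fit$par[2],
                 fit_residual = sqrt(mean(fit$fvec^2)),
                 converged = fit$info %in% 1:4,
                 n_points = length(r), n_refractive = n_refractive),
            class = "sfdi_opt_fit")
}

#' @export
print.sfdi_opt_fit <- function(x, ...) {
  cat(sprintf("<sfdi_opt_fit> mu_a = %.4g 1/mm, mu_s' = %.4g 1/mm (RMS %.3g, %s)\n",
              x$mu_a, x$mu_s_prime, x$fit_residual,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' Tidy an optical-property fit
#'
#' @param x An `sfdi_opt_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.sfdi_opt_fit <- function(x, ...) {
  tibble::tibble(term = c("mu_a", "mu_s_prime"),
                 estimate = c(x$mu_a, x$mu_s_prime),
                 unit = "1/mm")
}

#' Glance at an optical-property fit
#'
#' @param x An `sfdi_opt_fit`.
#' @param ... Unused.
#' @return A one-row tibble with fit diagnostics.
#' @export
glance.sfdi_opt_fit <- function(x, ...) {
  tibble::tibble(fit_residual = x$fit_residual, converged = x$converged,
                 n_points = x$n_points, n_refractive = x$n_refractive)
}

#' Invert a binned reflectance map to optical-property maps
#'
#' Bins the per-frequency reflectance and corrected-frequency maps, then fits
#' (mu_a, mu_s') per cell.
#'
#' @param reflectance An [compute_reflectance()] result.
#' @param bin Binning factor (default 16).
#' @param n_refractive Sample refractive index.
#' @param include_dc Include the DC channel as an f = 0 data point.
#' @param forward Forward model (see [fit_optical_properties()]).
#' @return A list of class `sfdi_property_map`: matrices `mu_a`, `mu_s_prime`,
#'   `fit_residual`, `converged`, and a tibble `summary`.
#' @export
invert_map <- function(reflectance, bin = 16, n_refractive = 1.4,
                       include_dc = TRUE, forward = forward_reflectance) {
  n_f <- dim(reflectance$r_ac)[3]
  rb <- lapply(seq_len(n_f), function(k) bin_map(reflectance$r_ac[, , k], bin))
  fb <- lapply(seq_len(n_f), function(k) bin_map(reflectance$f_corr[, , k], bin))
  dcb <- if (include_dc) bin_map(reflectance$r_dc, bin) else NULL
  dims <- dim(rb[[1]])
  mu_a <- matrix(NA_real_, dims[1], dims[2])
  mu_s <- matrix(NA_real_, dims[1], dims[2])
  rms <- matrix(NA_real_, dims[1], dims[2])
  conv <- matrix(FALSE, dims[1], dims[2])
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    r <- vapply(rb, function(m) m[i, j], numeric(1))
    f <- vapply(fb, function(m) m[i, j], numeric(1))
    if (include_dc) { r <- c(dcb[i, j], r); f <- c(0, f) }
    if (sum(is.finite(r) & is.finite(f)) < 2) next
    fit <- fit_optical_properties(r, f, n_refractive, forward = forward)
    mu_a[i, j] <- fit$mu_a; mu_s[i, j] <- fit$mu_s_prime
    rms[i, j] <- fit$fit_residual; conv[i, j] <- fit$converged
  }
  summary <- tibble::tibble(
    parameter = c("mu_a", "mu_s_prime"),
    mean = c(mean(mu_a, na.rm = TRUE), mean(mu_s, na.rm = TRUE)),
    median = c(stats::median(mu_a, na.rm = TRUE), stats::median(mu_s, na.rm = TRUE)),
    sd = c(stats::sd(mu_a, na.rm = TRUE), stats::sd(mu_s, na.rm = TRUE)))
  structure(list(mu_a = mu_a, mu_s_prime = mu_s, fit_residual = rms,
                 converged = conv, summary = summary, bin = bin,
                 n_refractive = n_refractive),
            class = "sfdi_property_map")
}
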