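# Per-pixel phase-shift demodulation of fringe image stacks into offset (DC),
# modulation amplitude (AC) and phase, plus spatial and temporal (anchored)
# phase unwrapping. Image maps are numeric matrices indexed [row, col]; invalid
# pixels are NA.

#' Fringe image stack
#'
#' A set of phase-shifted frames of one sinusoidal pattern at one nominal
#' spatial frequency.
#'
#' @param images List of at least 3 numeric matrices of equal dimension,
#'   non-negative intensities.
#' @param phase_shifts Nominal phase shifts in radians, distinct modulo 2*pi.
#' @param nominal_frequency Spatial frequency at the reference plane, 1/mm.
#' @param pattern_direction `"rows"` or `"columns"`: along which chip axis the
#'   projected pattern varies.
#' @return An object of class `sfdi_fringe_stack`.
#' @export
fringe_stack <- function(images, phase_shifts, nominal_frequency = NA_real_,
                         pattern_direction = c("rows", "columns")) {
  pattern_direction <- match.arg(pattern_direction)
  if (length(images) < 3)
    sfdi_stop("sfdi_input_error", "at least 3 phase-shifted frames required, got %d",
              length(images))
  if (length(phase_shifts) != length(images))
    sfdi_stop("sfdi_input_error", "got %d images but %d phase shifts",
              length(images), length(phase_shifts))
  dims <- vapply(images, dim, integer(2))
  if (any(dims != dims[, 1]))
    sfdi_stop("sfdi_input_error", "all frames must have the same shape")
  d <- abs(outer(phase_shifts, phase_shifts, "-")) %% (2 * pi)
  d <- pmin(d, 2 * pi - d)
  if (min(d[upper.tri(d)]) < 1e-9)
    sfdi_stop("sfdi_input_error", "phase shifts must be distinct modulo 2*pi")
  structure(list(images = images, phase_shifts = as.numeric(phase_shifts),
                 nominal_frequency = nominal_frequency,
                 pattern_direction = pattern_direction),
            class = "sfdi_fringe_stack")
}

#' Demodulate a fringe stack into DC, AC and wrapped phase
#'
#' Models each pixel as `I_i = DC + AC * cos(phase + delta_i)` and solves the
#' linear least-squares system over the shift set; for >= 3 distinct shifts the
#' design is full rank and the estimate is exact on noise-free sinusoids. For
#' the canonical shift set \{0, 2*pi/3, 4*pi/3\} this reduces to the classic
#' three-step closed form.
#'
#' @param stack An [fringe_stack()] object.
#' @param ac_threshold_abs,ac_threshold_rel A pixel is masked invalid (phase
#'   undefined) when `i_ac <= max(abs, rel * median(i_ac))`.
#' @return An object of class `sfdi_demod` with elements `i_dc`, `i_ac`,
#'   `phase_wrapped` (in (-pi, pi], NA where invalid), `phase_unwrapped`
#'   (NULL until [unwrap_phase()] is applied), `validity` (logical matrix) and
#'   `nominal_frequency`.
#' @export
demodulate <- function(stack, ac_threshold_abs = 1e-6, ac_threshold_rel = 0.01) {
  stopifnot(inherits(stack, "sfdi_fringe_stack"))
  delta <- stack$phase_shifts
  n <- length(delta)
  dims <- dim(stack$images[[1]])
  # design: I = DC + a cos(delta) - b sin(delta), a = AC cos(phase), b = AC sin(phase)
  X <- cbind(1, cos(delta), -sin(delta))
  # solve via pseudo-inverse once; apply to all pixels at once
  pinv <- solve(crossprod(X), t(X))            # 3 x n
  Y <- vapply(stack$images, as.numeric, numeric(prod(dims)))  # npix x n
  theta <- Y %*% t(pinv)                       # npix x 3
  i_dc <- matrix(theta[, 1], dims[1], dims[2])
  a <- theta[, 2]; b <- theta[, 3]
  i_ac <- matrix(sqrt(a^2 + b^2), dims[1], dims[2])
  phase <- matrix(atan2(b, a), dims[1], dims[2])
  thr <- max(ac_threshold_abs, ac_threshold_rel * stats::median(i_ac, na.rm = TRUE))
  validity <- i_ac > thr
  phase[!validity] <- NA_real_
  if (any(i_dc < i_ac - 1e-9 & validity, na.rm = TRUE))
    warning("i_dc < i_ac on some pixels: signal is not a non-negative sinusoid")
  structure(list(i_dc = i_dc, i_ac = i_ac, phase_wrapped = phase,
                 phase_unwrapped = NULL, validity = validity,
                 nominal_frequency = stack$nominal_frequency,
                 pattern_direction = stack$pattern_direction),
            class = "sfdi_demod")
}

#' @export
print.sfdi_demod <- function(x, ...) {
  cat(sprintf("<sfdi_demod> %d x %d px, f = %s 1/mm, %.1f%% valid, median AC/DC = %.3f\n",
              nrow(x$i_dc), ncol(x$i_dc),
              format(x$nominal_frequency), 100 * mean(x$validity),
              stats::median(x$i_ac / pmax(x$i_dc, .Machine$double.eps), na.rm = TRUE)))
  invisible(x)
}

#' Unwrap a wrapped phase map
#'
#' With an `anchor` map (temporal unwrapping), picks per pixel the 2*pi branch
#' of the wrapped phase closest to `anchor * anchor_scale`; this is exact when
#' the anchor is an absolute phase measured at a lower frequency and
#' `anchor_scale` is the frequency ratio. Without an anchor, performs
#' quality-guided flood-fill spatial unwrapping (quality defaults to the AC
#' amplitude); disconnected valid regions are unwrapped independently and
#' their count is reported in the `n_components` attribute.
#'
#' @param phase_wrapped Matrix of wrapped phase in (-pi, pi] (NA = invalid).
#' @param validity Logical matrix; defaults to `!is.na(phase_wrapped)`.
#' @param anchor Absolute phase map at a lower frequency, or NULL.
#' @param anchor_scale Ratio (this frequency) / (anchor frequency).
#' @param quality Matrix guiding the flood fill (larger = earlier), e.g. `i_ac`.
#' @return Matrix of continuous phase, congruent to the input modulo 2*pi on
#'   valid pixels; attribute `n_components` gives the number of independently
#'   unwrapped regions (spatial mode only).
#' @export
unwrap_phase <- function(phase_wrapped, validity = NULL, anchor = NULL,
                         anchor_scale = 1, quality = NULL) {
  validity <- validity %||% !is.na(phase_wrapped)
  if (!is.null(anchor)) {
    target <- anchor * anchor_scale
    k <- round((target - phase_wrapped) / (2 * pi))
    out <- phase_wrapped + 2 * pi * k
    out[!validity] <- NA_real_
    return(out)
  }
  unwrap_flood_fill(phase_wrapped, validity, quality)
}

# Quality-guided flood fill. Seeds at the highest-quality pixel of each
# connected component; neighbors enter a max-heap keyed by quality and are
# unwrapped relative to the already-unwrapped pixel that enqueued them.
#' @noRd
unwrap_flood_fill <- function(phase, validity, quality = NULL) {
  nr <- nrow(phase); nc <- ncol(phase)
  quality <- quality %||% matrix(1, nr, nc)
  q <- as.numeric(quality); ph <- as.numeric(phase)
  valid <- as.logical(validity) & !is.na(ph)
  out <- rep(NA_real_, nr * nc)
  state <- integer(nr * nc)            # 0 = untouched, 1 = queued, 2 = done
  # simple binary max-heap over (quality, index, reference value)
  heap_idx <- integer(0); heap_ref <- numeric(0)
  heap_push <- function(i, ref) {
    heap_idx <<- c(heap_idx, i); heap_ref <<- c(heap_ref, ref)
    k <- length(heap_idx)
    while (k > 1) {
      p <- k %/% 2
      if (q[heap_idx[p]] >= q[heap_idx[k]]) break
      tmp <- heap_idx[p]; heap_idx[p] <<- heap_idx[k]; heap_idx[k] <<- tmp
      tmp <- heap_ref[p]; heap_ref[p] <<- heap_ref[k]; heap_ref[k] <<- tmp
      k <- p
    }
  }
  heap_pop <- function() {
    top <- c(heap_idx[1], heap_ref[1])
    n <- length(heap_idx)
    heap_idx[1] <<- heap_idx[n]; heap_ref[1] <<- heap_ref[n]
    heap_idx <<- heap_idx[-n]; heap_ref <<- heap_ref[-n]
    k <- 1; n <- n - 1
    while (TRUE) {
      l <- 2 * k; r <- l + 1; big <- k
      if (l <= n && q[heap_idx[l]] > q[heap_idx[big]]) big <- l
      if (r <= n && q[heap_idx[r]] > q[heap_idx[big]]) big <- r
      if (big == k) break
      tmp <- heap_idx[big]; heap_idx[big] <<- heap_idx[k]; heap_idx[k] <<- tmp
      tmp <- heap_ref[big]; heap_ref[big] <<- heap_ref[k]; heap_ref[k] <<- tmp
      k <- big
    }
    top
  }
  neighbors <- function(i) {
    r <- (i - 1) %% nr + 1; cc <- (i - 1) %/% nr + 1
    nb <- integer(0)
    if (r > 1) nb <- c(nb, i - 1)
    if (r < nr) nb <- c(nb, i + 1)
    if (cc > 1) nb <- c(nb, i - nr)
    if (cc < nc) nb <- c(nb, i + nr)
    nb
  }
  n_components <- 0L
  remaining <- which(valid)
  while (length(remaining) > 0) {
    n_components <- n_components + 1L
    seed <- remaining[which.max(q[remaining])]
    out[seed] <- ph[seed]; state[seed] <- 2L
    for (nb in neighbors(seed)) if (valid[nb] && state[nb] == 0L) {
      state[nb] <- 1L; heap_push(nb, out[seed])
    }
    while (length(heap_idx) > 0) {
      top <- heap_pop()
      i <- as.integer(top[1]); ref <- top[2]
      if (state[i] == 2L) next
      out[i] <- ph[i] + 2 * pi * round((ref - ph[i]) / (2 * pi))
      state[i] <- 2L
      for (nb in neighbors(i)) if (valid[nb] && state[nb] == 0L) {
        state[nb] <- 1L; heap_push(nb, out[i])
      }
    }
    remaining <- which(valid & state == 0L)
  }
  res <- matrix(out, nr, nc)
  attr(res, "n_components") <- n_components
  res
}

#' Read a fringe stack from TIFF files
#'
#' Accepts either a single multi-page TIFF or a vector of single-frame TIFF
#' paths, in phase-shift order.
#'
#' @param paths Character vector of file paths.
#' @param phase_shifts,nominal_frequency,pattern_direction Passed to
#'   [fringe_stack()].
#' @return An `sfdi_fringe_stack`.
#' @export
read_fringe_stack <- function(paths, phase_shifts, nominal_frequency = NA_real_,
                              pattern_direction = "rows") {
  imgs <- list()
  for (p in paths) {
    frames <- tiff::readTIFF(p, all = TRUE)
    if (!is.list(frames)) frames <- list(frames)
    imgs <- c(imgs, frames)
  }
  fringe_stack(imgs, phase_shifts, nominal_frequency, pattern_direction)
}

#' Write a fringe stack to single-frame TIFF files
#'
#' Intensities are stored as 32-bit float TIFF, one file per phase shift.
#'
#' @param stack An [fringe_stack()] object.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_fringe_stack <- function(stack, dir, prefix = "frame") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(stack$images))
  for (i in seq_along(stack$images)) {
    paths[i] <- file.path(dir, sprintf("%s_%02d.tiff", prefix, i))
    tiff::writeTIFF(stack$images[[i]], paths[i], bits.per.sample = 32)
  }
  invisible(paths)
}
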