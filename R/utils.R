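#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Row-wise Euclidean norms of an n x 3 matrix
#' @noRd
row_norms <- function(m) sqrt(rowSums(m^2))

#' Normalize rows to unit length
#' @noRd
normalize_rows <- function(m) m / row_norms(m)

#' Row-wise cross product of two n x 3 matrices
#' @noRd
cross_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

#' Coerce points to an n x k numeric matrix
#' @noRd
as_points <- function(p, k) {
  if (is.null(dim(p))) {
    stopifnot(length(p) %% k == 0)
    p <- matrix(p, ncol = k, byrow = length(p) > k)
  }
  storage.mode(p) <- "double"
  p
}

#' Stop with a classed condition
#' @noRd
sfdi_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "sfdical_error", "error", "condition"),
                 list(message = sprintf(msg, ...), call = sys.call(-1))))
}

#' Fraction of valid (non-NA) pixels in a map
#' @noRd
valid_fraction <- function(m) mean(!is.na(m))

#' Bilinear sampling of a matrix at fractional 0-based (u, v) = (col, row)
#'
#' Used to read demodulated phase maps at sub-pixel marker centroids.
#' @noRd
bilinear_sample <- function(m, u, v) {
  nr <- nrow(m); nc <- ncol(m)
  u0 <- pmax(0L, pmin(nc - 2L, floor(u))); v0 <- pmax(0L, pmin(nr - 2L, floor(v)))
  du <- u - u0; dv <- v - v0
  i <- v0 + 1L; j <- u0 + 1L
  m[cbind(i, j)] * (1 - du) * (1 - dv) +
    m[cbind(i, j + 1L)] * du * (1 - dv) +
    m[cbind(i + 1L, j)] * (1 - du) * dv +
    m[cbind(i + 1L, j + 1L)] * du * dv
}
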