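# Planar-target calibration: homography-based closed-form initialization
# (Zhang's method) followed by Levenberg-Marquardt bundle refinement of
# intrinsics, distortion and per-pose extrinsics minimizing the reprojection
# error. Internal; the user-facing surface is calibrate_device().

#' Rotation matrix <-> axis-angle (Rodrigues) vector
#' @noRd
rot_to_rodrigues <- function(R) {
  ang <- acos(pmin(pmax((sum(diag(R)) - 1) / 2, -1), 1))
  if (ang < 1e-12) return(c(0, 0, 0))
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(ang))
  ax * ang
}

#' @noRd
rodrigues_to_rot <- function(v) {
  ang <- sqrt(sum(v^2))
  if (ang < 1e-12) return(diag(3))
  k <- v / ang
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
}

#' Normalized DLT homography from planar object coords to image pixels
#' @noRd
homography_dlt <- function(xy, uv) {
  n <- nrow(xy)
  norm_T <- function(p) {
    ctr <- colMeans(p)
    s <- sqrt(2) / mean(sqrt(rowSums(sweep(p, 2, ctr)^2)))
    matrix(c(s, 0, 0, 0, s, 0, -s * ctr[1], -s * ctr[2], 1), 3, 3)
  }
  T1 <- norm_T(xy); T2 <- norm_T(uv)
  hom <- function(p, TT) {
    ph <- cbind(p, 1) %*% t(TT)
    ph[, 1:2] / ph[, 3]
  }
  a <- hom(xy, T1); b <- hom(uv, T2)
  A <- matrix(0, 2 * n, 9)
  A[seq(1, 2 * n, 2), ] <- cbind(-a[, 1], -a[, 2], -1, 0, 0, 0,
                                 a[, 1] * b[, 1], a[, 2] * b[, 1], b[, 1])
  A[seq(2, 2 * n, 2), ] <- cbind(0, 0, 0, -a[, 1], -a[, 2], -1,
                                 a[, 1] * b[, 2], a[, 2] * b[, 2], b[, 2])
  h <- svd(A, nu = 0)$v[, 9]
  H <- solve(T2) %*% matrix(h, 3, 3, byrow = TRUE) %*% T1
  H / H[3, 3]
}

#' Closed-form intrinsics from >= 3 homographies (Zhang)
#' @noRd
zhang_intrinsics <- function(H_list, image_size) {
  v_ij <- function(H, i, j) {
    c(H[1, i] * H[1, j],
      H[1, i] * H[2, j] + H[2, i] * H[1, j],
      H[2, i] * H[2, j],
      H[3, i] * H[1, j] + H[1, i] * H[3, j],
      H[3, i] * H[2, j] + H[2, i] * H[3, j],
      H[3, i] * H[3, j])
  }
  V <- do.call(rbind, lapply(H_list, function(H)
    rbind(v_ij(H, 1, 2), v_ij(H, 1, 1) - v_ij(H, 2, 2))))
  b <- svd(V, nu = 0)$v[, 6]
  B11 <- b[1]; B12 <- b[2]; B22 <- b[3]; B13 <- b[4]; B23 <- b[5]; B33 <- b[6]
  cy <- (B12 * B13 - B11 * B23) / (B11 * B22 - B12^2)
  lambda <- B33 - (B13^2 + cy * (B12 * B13 - B11 * B23)) / B11
  fx2 <- lambda / B11
  fy2 <- lambda * B11 / (B11 * B22 - B12^2)
  if (!is.finite(fx2) || !is.finite(fy2) || fx2 <= 0 || fy2 <= 0)
    sfdi_stop("sfdi_solver_error",
              "closed-form intrinsics failed (degenerate pose set): fx^2 = %.3g, fy^2 = %.3g",
              fx2, fy2)
  fx <- sqrt(fx2); fy <- sqrt(fy2)
  cx <- -B13 * fx2 / lambda
  list(fx = fx, fy = fy, cx = cx, cy = cy)
}

#' Extrinsics from a homography given intrinsics
#' @noRd
extrinsics_from_h <- function(K, H) {
  Ainv <- solve(K)
  h1 <- H[, 1]; h2 <- H[, 2]; h3 <- H[, 3]
  lam <- 1 / sqrt(sum((Ainv %*% h1)^2))
  r1 <- lam * (Ainv %*% h1)
  r2 <- lam * (Ainv %*% h2)
  r3 <- pracma_cross(as.numeric(r1), as.numeric(r2))
  t <- lam * (Ainv %*% h3)
  if (t[3] < 0) { r1 <- -r1; r2 <- -r2; t <- -t; r3 <- pracma_cross(as.numeric(r1), as.numeric(r2)) }
  R0 <- cbind(r1, r2, r3)
  # nearest rotation matrix
  s <- svd(R0)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  list(rotation = R, translation = as.numeric(t))
}

#' @noRd
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Pack/unpack the bundle parameter vector
#' @noRd
pack_params <- function(K, kr, kt, poses, n_radial, fit_tangential) {
  p <- c(K$fx, K$fy, K$cx, K$cy)
  if (n_radial > 0) p <- c(p, kr[seq_len(n_radial)])
  if (fit_tangential) p <- c(p, kt)
  for (ps in poses) p <- c(p, rot_to_rodrigues(ps$rotation), ps$translation)
  p
}

#' @noRd
unpack_params <- function(p, n_poses, n_radial, fit_tangential) {
  K <- list(fx = p[1], fy = p[2], cx = p[3], cy = p[4])
  i <- 4
  kr <- numeric(0)
  if (n_radial > 0) { kr <- p[i + seq_len(n_radial)]; i <- i + n_radial }
  kt <- c(0, 0)
  if (fit_tangential) { kt <- p[i + 1:2]; i <- i + 2 }
  poses <- vector("list", n_poses)
  for (j in seq_len(n_poses)) {
    rv <- p[i + 1:3]; tv <- p[i + 4:6]; i <- i + 6
    poses[[j]] <- list(rotation = rodrigues_to_rot(rv), translation = tv)
  }
  list(K = K, radial = kr, tangential = kt, poses = poses)
}

#' Reprojection residuals for all poses, vectorized
#' @noRd
bundle_residuals <- function(p, object_xy, image_uv, n_radial, fit_tangential) {
  n_poses <- length(object_xy)
  par <- unpack_params(p, n_poses, n_radial, fit_tangential)
  dist_obj <- distortion(par$radial, par$tangential)
  res <- vector("list", n_poses)
  for (j in seq_len(n_poses)) {
    P <- cbind(object_xy[[j]], 0)
    pd <- sweep(P %*% t(par$poses[[j]]$rotation), 2, par$poses[[j]]$translation, "+")
    z <- pd[, 3]
    if (any(z <= 0)) return(rep(1e6, 2 * sum(vapply(object_xy, nrow, 1L))))
    d <- apply_distortion(dist_obj, cbind(pd[, 1] / z, pd[, 2] / z))
    uv <- cbind(par$K$fx * d[, 1] + par$K$cx, par$K$fy * d[, 2] + par$K$cy)
    res[[j]] <- as.numeric(uv - image_uv[[j]])
  }
  unlist(res)
}

#' Full planar calibration: closed-form init + LM refinement
#' @noRd
solve_planar_calibration <- function(object_xy, image_uv, image_size,
                                     n_radial = 2, fit_tangential = FALSE) {
  n_poses <- length(object_xy)
  H_list <- mapply(homography_dlt, object_xy, image_uv, SIMPLIFY = FALSE)
  K0 <- zhang_intrinsics(H_list, image_size)
  Kmat <- matrix(c(K0$fx, 0, 0, 0, K0$fy, 0, K0$cx, K0$cy, 1), 3, 3)
  poses0 <- lapply(H_list, extrinsics_from_h, K = Kmat)
  p0 <- pack_params(K0, rep(0, 3), c(0, 0), poses0, n_radial, fit_tangential)
  fit <- minpack.lm::nls.lm(
    par = p0, fn = bundle_residuals,
    object_xy = object_xy, image_uv = image_uv,
    n_radial = n_radial, fit_tangential = fit_tangential,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-13,
                                         ptol = 1e-13, factor = 10))
  if (fit$info == 0)
    sfdi_stop("sfdi_solver_error", "bundle refinement failed (info = %d)", fit$info)
  if (fit$info == 5)
    warning(sprintf("bundle refinement hit the iteration cap (rms %.3g px)",
                    sqrt(mean(fit$fvec^2))))
  par <- unpack_params(fit$par, n_poses, n_radial, fit_tangential)
  rms <- sqrt(mean(fit$fvec^2))
  list(K = par$K, radial = par$radial, tangential = par$tangential,
       poses = par$poses, rms = rms)
}
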