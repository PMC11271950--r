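#' 6-parameter rigid pose
#'
#' Translations in mm, rotations in degrees. Rotations act about the volume
#' center in a right-handed mm frame and are applied in the fixed order
#' rx -> ry -> rz (so the matrix rotation block is `Rz %*% Ry %*% Rx`).
#'
#' @param tx,ty,tz translations (mm).
#' @param rx,ry,rz rotations (degrees).
#' @return named numeric vector of class `rigid_pose`.
#' @export
rigid_pose <- function(tx = 0, ty = 0, tz = 0, rx = 0, ry = 0, rz = 0) {
  p <- c(tx = tx, ty = ty, tz = tz, rx = rx, ry = ry, rz = rz)
  stopifnot(all(is.finite(p)))
  structure(p, class = "rigid_pose")
}

rot_block <- function(rx, ry, rz) {
  a <- rx * pi / 180; b <- ry * pi / 180; c <- rz * pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rz <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Homogeneous matrix of a rigid pose
#'
#' Maps world mm coordinates (origin at the rotation center): `w' = R (w) + t`
#' where `R = Rz Ry Rx`. `pose_to_matrix` builds the full voxel-aware mapping
#' when voxel size and center are supplied: the matrix then maps mm world
#' points measured from the volume center.
#'
#' @param pose a [rigid_pose()].
#' @return 4x4 homogeneous matrix (world mm frame, origin at rotation center).
#' @export
pose_to_matrix <- function(pose) {
  M <- diag(4)
  M[1:3, 1:3] <- rot_block(pose["rx"], pose["ry"], pose["rz"])
  M[1:3, 4] <- pose[c("tx", "ty", "tz")]
  M
}

#' @rdname pose_to_matrix
#' @param M 4x4 homogeneous rigid matrix.
#' @return `matrix_to_pose`: the [rigid_pose()] with `Rz Ry Rx` Euler angles.
#' @export
matrix_to_pose <- function(M) {
  R <- M[1:3, 1:3]
  ry <- -asin(max(-1, min(1, R[3, 1])))
  rx <- atan2(R[3, 2], R[3, 3])
  rz <- atan2(R[2, 1], R[1, 1])
  rigid_pose(M[1, 4], M[2, 4], M[3, 4],
             rx * 180 / pi, ry * 180 / pi, rz * 180 / pi)
}

#' @rdname pose_to_matrix
#' @export
invert_pose <- function(pose) matrix_to_pose(solve(pose_to_matrix(pose)))

#' @rdname pose_to_matrix
#' @param p,q poses; the composition applies `q` first, then `p`.
#' @export
compose_poses <- function(p, q) matrix_to_pose(pose_to_matrix(p) %*% pose_to_matrix(q))

# voxel->voxel (0-based) affine of the *inverse* pose mapping: output voxel
# coordinates -> input sampling coordinates, for resampling
pose_sampling_affine <- function(pose, dims, voxel_mm) {
  cmm <- (dims - 1) / 2 * voxel_mm
  V <- diag(c(voxel_mm, 1)); Vi <- diag(c(1 / voxel_mm, 1))
  C <- diag(4); C[1:3, 4] <- -cmm
  Ci <- diag(4); Ci[1:3, 4] <- cmm
  Tw <- pose_to_matrix(pose)
  # world(v) = V v - cmm ; sample input at world^-1( T^-1 world(v_out) )
  Vi %*% Ci %*% solve(Tw) %*% C %*% V
}

#' Apply a rigid transform to a volume
#'
#' Resamples the volume under the pose (image content moves with the pose;
#' `apply_rigid(vol, p)` evaluates the input at `T_p^{-1} x`). Out-of-field
#' voxels are set to 0; real and imaginary parts of complex input are
#' interpolated separately. A zero pose returns the input unchanged.
#'
#' @param volume 3D numeric or complex array.
#' @param pose a [rigid_pose()].
#' @param voxel_mm voxel size triple (mm).
#' @param interp `"cubic"` (default, Catmull-Rom) or `"trilinear"`.
#' @return transformed array of the same shape.
#' @export
apply_rigid <- function(volume, pose, voxel_mm = c(1, 1, 1),
                        interp = c("cubic", "trilinear")) {
  interp <- match.arg(interp)
  if (all(pose == 0)) return(volume)
  d <- dim(volume)
  A <- pose_sampling_affine(pose, d, voxel_mm)
  code <- if (interp == "trilinear") 0L else 1L
  if (is.complex(volume)) {
    re <- resample_affine(Re(volume), as.integer(d), A, code)
    im <- resample_affine(Im(volume), as.integer(d), A, code)
    out <- complex(real = re, imaginary = im)
    dim(out) <- d
    out
  } else {
    resample_affine(volume, as.integer(d), A, code)
  }
}

# image gradient in world mm units by central differences (zero-padded edges)
grad3 <- function(vol, voxel_mm) {
  d <- dim(vol)
  g <- vector("list", 3)
  for (ax in 1:3) {
    p <- vol; m <- vol
    idx_p <- pmin(seq_len(d[ax]) + 1, d[ax])
    idx_m <- pmax(seq_len(d[ax]) - 1, 1)
    if (ax == 1) { p <- vol[idx_p, , , drop = FALSE]; m <- vol[idx_m, , , drop = FALSE] }
    if (ax == 2) { p <- vol[, idx_p, , drop = FALSE]; m <- vol[, idx_m, , drop = FALSE] }
    if (ax == 3) { p <- vol[, , idx_p, drop = FALSE]; m <- vol[, , idx_m, drop = FALSE] }
    g[[ax]] <- (p - m) / (2 * voxel_mm[ax])
  }
  g
}

# derivative of the rotation block w.r.t. each angle (degrees)
drot_blocks <- function(rx, ry, rz) {
  a <- rx * pi / 180; b <- ry * pi / 180; c <- rz * pi / 180
  s <- pi / 180
  Rx <- matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
  Ry <- matrix(c(cos(b), 0, -sin(b), 0, 1, 0, sin(b), 0, cos(b)), 3, 3)
  Rz <- matrix(c(cos(c), sin(c), 0, -sin(c), cos(c), 0, 0, 0, 1), 3, 3)
  dRx <- s * matrix(c(0, 0, 0, 0, -sin(a), cos(a), 0, -cos(a), -sin(a)), 3, 3)
  dRy <- s * matrix(c(-sin(b), 0, -cos(b), 0, 0, 0, cos(b), 0, -sin(b)), 3, 3)
  dRz <- s * matrix(c(-sin(c), cos(c), 0, -cos(c), -sin(c), 0, 0, 0, 0), 3, 3)
  list(dx = Rz %*% Ry %*% dRx, dy = Rz %*% dRy %*% Rx, dz = dRz %*% Ry %*% Rx)
}

#' Rigid registration by Gauss-Newton on sum-of-squared differences
#'
#' Coarse-to-fine (Gaussian smoothing, FWHM 16, 8, then 4 mm) Gauss-Newton
#' minimization of the SSD between `moving` and the rigidly transformed
#' `fixed`, over the 6 pose parameters. Convergence when every parameter
#' update falls below `tol` (mm or deg); at most `max_iter` iterations per
#' level. Returns the pose mapping `fixed` to `moving` (i.e.
#' `apply_rigid(fixed, pose) ~ moving`).
#'
#' @param moving,fixed 3D volumes on the same grid (complex input is reduced
#'   to magnitude).
#' @param voxel_mm voxel size triple (mm).
#' @param fwhm_mm smoothing levels in mm (coarse to fine).
#' @param max_iter maximum Gauss-Newton iterations per level.
#' @param tol convergence threshold on the parameter update.
#' @param init optional initial [rigid_pose()].
#' @return a [rigid_pose()] with attributes `converged` (logical) and
#'   `n_iter`. A warning is issued when the last level failed to converge.
#' @export
register_rigid <- function(moving, fixed, voxel_mm = c(1, 1, 1),
                           fwhm_mm = c(16, 8, 4), max_iter = 64, tol = 1e-3,
                           init = rigid_pose()) {
  if (is.complex(moving)) moving <- Mod(moving)
  if (is.complex(fixed)) fixed <- Mod(fixed)
  if (!all(is.finite(moving)) || !all(is.finite(fixed)))
    stop("non-finite values in input volumes")
  d <- dim(moving)
  stopifnot(all(d == dim(fixed)))
  # estimate q with moving ~ fixed(T_q x); the returned pose is its inverse
  q <- as.numeric(invert_pose(init))
  converged <- FALSE
  total_iter <- 0L
  cmm <- (d - 1) / 2 * voxel_mm
  ax_mm <- lapply(1:3, function(a) ((seq_len(d[a]) - 1) * voxel_mm[a]) - cmm[a])
  X1 <- rep(ax_mm[[1]], times = d[2] * d[3])
  X2 <- rep(rep(ax_mm[[2]], each = d[1]), times = d[3])
  X3 <- rep(ax_mm[[3]], each = d[1] * d[2])
  ssd_at <- function(Fs, mv, qv) {
    A <- pose_sampling_affine(
      invert_pose(rigid_pose(qv[1], qv[2], qv[3], qv[4], qv[5], qv[6])),
      d, voxel_mm)
    fw <- resample_affine(Fs, as.integer(d), A, 0L)
    sum((as.vector(fw) - mv)^2)
  }
  for (lev in seq_along(fwhm_mm)) {
    Fs <- gauss_smooth(fixed, fwhm_mm[lev], voxel_mm)
    Ms <- gauss_smooth(moving, fwhm_mm[lev], voxel_mm)
    gF <- grad3(Fs, voxel_mm)
    mv <- as.vector(Ms)
    converged <- FALSE
    cost <- ssd_at(Fs, mv, q)
    for (it in seq_len(max_iter)) {
      total_iter <- total_iter + 1L
      pose_q <- rigid_pose(q[1], q[2], q[3], q[4], q[5], q[6])
      # fixed evaluated at T_q x: sample fixed at the voxel coords of T_q
      A <- pose_sampling_affine(invert_pose(pose_q), d, voxel_mm)
      code <- 0L
      fw <- resample_affine(Fs, as.integer(d), A, code)
      g1 <- resample_affine(gF[[1]], as.integer(d), A, code)
      g2 <- resample_affine(gF[[2]], as.integer(d), A, code)
      g3 <- resample_affine(gF[[3]], as.integer(d), A, code)
      r <- as.vector(fw) - mv
      dR <- drot_blocks(q[4], q[5], q[6])
      # Jacobian columns: translations then rotations
      J <- cbind(as.vector(g1), as.vector(g2), as.vector(g3),
                 as.vector(g1) * (dR$dx[1, 1] * X1 + dR$dx[1, 2] * X2 + dR$dx[1, 3] * X3) +
                 as.vector(g2) * (dR$dx[2, 1] * X1 + dR$dx[2, 2] * X2 + dR$dx[2, 3] * X3) +
                 as.vector(g3) * (dR$dx[3, 1] * X1 + dR$dx[3, 2] * X2 + dR$dx[3, 3] * X3),
                 as.vector(g1) * (dR$dy[1, 1] * X1 + dR$dy[1, 2] * X2 + dR$dy[1, 3] * X3) +
                 as.vector(g2) * (dR$dy[2, 1] * X1 + dR$dy[2, 2] * X2 + dR$dy[2, 3] * X3) +
                 as.vector(g3) * (dR$dy[3, 1] * X1 + dR$dy[3, 2] * X2 + dR$dy[3, 3] * X3),
                 as.vector(g1) * (dR$dz[1, 1] * X1 + dR$dz[1, 2] * X2 + dR$dz[1, 3] * X3) +
                 as.vector(g2) * (dR$dz[2, 1] * X1 + dR$dz[2, 2] * X2 + dR$dz[2, 3] * X3) +
                 as.vector(g3) * (dR$dz[3, 1] * X1 + dR$dz[3, 2] * X2 + dR$dz[3, 3] * X3))
      JtJ <- crossprod(J)
      delta <- tryCatch(solve(JtJ + diag(1e-8 * max(diag(JtJ)), 6), crossprod(J, r)),
                        error = function(e) rep(0, 6))
      # backtracking line search: accept only SSD-decreasing steps so the
      # iterate cannot run away on flat or garbage cost landscapes
      delta <- as.numeric(delta)
      accepted <- FALSE
      for (sc in c(1, 0.5, 0.25, 0.125)) {
        q_try <- q - sc * delta
        cost_try <- ssd_at(Fs, mv, q_try)
        if (cost_try < cost) {
          q <- q_try; cost <- cost_try; accepted <- TRUE
          delta <- sc * delta
          break
        }
      }
      if (!accepted) { converged <- TRUE; break }  # local minimum at step scale
      if (max(abs(delta)) < tol) { converged <- TRUE; break }
    }
  }
  # q maps moving-domain points into the fixed image; the fixed->moving pose
  # under this module's conventions is its inverse
  out <- invert_pose(rigid_pose(q[1], q[2], q[3], q[4], q[5], q[6]))
  if (!converged)
    warning("register_rigid: final level did not converge; returning best iterate")
  attr(out, "converged") <- converged
  attr(out, "n_iter") <- total_iter
  out
}
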