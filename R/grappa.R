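#' GRAPPA kernel geometry
#'
#' A "2x2 kernel" means 2x2 blocks of sampled source lines in the two
#' undersampled phase-encode dimensions; `kx_taps` readout taps are added
#' along the fully sampled axis. Tikhonov regularization is scaled to the
#' calibration matrix (relative lambda).
#'
#' @param src_blocks_y,src_blocks_z integer >= 2: source blocks along y and z.
#' @param kx_taps odd integer: readout taps.
#' @param tikhonov_lambda nonnegative relative regularization.
#' @return object of class `grappa_kernel_spec`.
#' @export
grappa_kernel_spec <- function(src_blocks_y = 2, src_blocks_z = 2,
                               kx_taps = 3, tikhonov_lambda = 1e-4) {
  stopifnot(src_blocks_y >= 2, src_blocks_z >= 2,
            kx_taps %% 2 == 1, tikhonov_lambda >= 0)
  structure(list(src_blocks_y = as.integer(src_blocks_y),
                 src_blocks_z = as.integer(src_blocks_z),
                 kx_taps = as.integer(kx_taps),
                 tikhonov_lambda = tikhonov_lambda),
            class = "grappa_kernel_spec")
}

# source offsets for one missing-offset class (dy, dz); block offsets chosen
# so the sampled source lines bracket the target
grappa_offsets <- function(dy, dz, scheme, kernel) {
  oy <- (0:(kernel$src_blocks_y - 1)) * scheme$accel_y - dy
  oz <- (0:(kernel$src_blocks_z - 1)) * scheme$accel_z - dz
  h <- (kernel$kx_taps - 1) / 2
  ox <- -h:h
  list(ox = ox, oy = oy, oz = oz)
}

# gather the source matrix for targets on the cartesian grid xs x ys x zs
# (1-based indices into `ksp`, wrapped circularly); columns ordered
# (coil, ox, oy, oz) with coil fastest
gather_sources <- function(ksp, xs, ys, zs, off) {
  d <- dim(ksp)
  nc <- d[4]
  ntap <- length(off$ox) * length(off$oy) * length(off$oz)
  S <- matrix(0 + 0i, length(xs) * length(ys) * length(zs), nc * ntap)
  col <- 1L
  for (oz in off$oz) for (oy in off$oy) for (ox in off$ox) {
    xi <- wrap_index(xs + ox, d[1])
    yi <- wrap_index(ys + oy, d[2])
    zi <- wrap_index(zs + oz, d[3])
    for (c_i in seq_len(nc)) {
      S[, col] <- as.vector(ksp[xi, yi, zi, c_i])
      col <- col + 1L
    }
  }
  S
}

#' Calibrate GRAPPA weights from ACS data
#'
#' For each missing-offset class within the acceleration cell, solves the
#' Tikhonov-regularized least-squares fit of ACS target samples from their
#' R-spaced sampled source neighborhood across all coils. Deterministic.
#'
#' @param acs_kspace complex 4D ACS block (x, y, z, coil), centered on DC.
#' @param scheme a [sampling_scheme()].
#' @param kernel a [grappa_kernel_spec()].
#' @return object of class `grappa_weights`: per-class complex weight
#'   matrices with the scheme/kernel that produced them and per-class
#'   normalized calibration residuals.
#' @export
calibrate_grappa <- function(acs_kspace, scheme, kernel = grappa_kernel_spec()) {
  d <- dim(acs_kspace)
  if (length(d) != 4) stop("acs_kspace must be 4D (x, y, z, coil)")
  nc <- d[4]
  classes <- expand.grid(dy = 0:(scheme$accel_y - 1), dz = 0:(scheme$accel_z - 1))
  classes <- classes[!(classes$dy == 0 & classes$dz == 0), , drop = FALSE]
  weights <- list()
  residuals <- numeric(0)
  for (i in seq_len(nrow(classes))) {
    dy <- classes$dy[i]; dz <- classes$dz[i]
    off <- grappa_offsets(dy, dz, scheme, kernel)
    h <- (kernel$kx_taps - 1) / 2
    x_lo <- 1 + h; x_hi <- d[1] - h
    y_lo <- max(1, 1 - min(off$oy)); y_hi <- min(d[2], d[2] - max(off$oy))
    z_lo <- max(1, 1 - min(off$oz)); z_hi <- min(d[3], d[3] - max(off$oz))
    if (x_hi < x_lo || y_hi < y_lo || z_hi < z_lo)
      stop(sprintf(paste0("ACS block (%dx%dx%d) too small for kernel span ",
                          "(x %d, y %d..%d, z %d..%d) at R=%dx%d"),
                   d[1], d[2], d[3], kernel$kx_taps,
                   min(off$oy), max(off$oy), min(off$oz), max(off$oz),
                   scheme$accel_y, scheme$accel_z))
    xs <- x_lo:x_hi; ys <- y_lo:y_hi; zs <- z_lo:z_hi
    A <- gather_sources(acs_kspace, xs, ys, zs, off)
    B <- matrix(0 + 0i, nrow(A), nc)
    for (c_i in seq_len(nc)) B[, c_i] <- as.vector(acs_kspace[xs, ys, zs, c_i])
    AhA <- Conj(t(A)) %*% A
    AhB <- Conj(t(A)) %*% B
    if (kernel$tikhonov_lambda > 0) {
      lam <- kernel$tikhonov_lambda * mean(Re(diag(AhA)))
      AhA <- AhA + diag(lam, ncol(A))
    }
    W <- solve(AhA, AhB)
    res <- sqrt(sum(Mod(A %*% W - B)^2)) / sqrt(sum(Mod(B)^2))
    key <- sprintf("%d_%d", dy, dz)
    weights[[key]] <- W
    residuals[key] <- res
  }
  structure(list(weights = weights, scheme = scheme, kernel = kernel,
                 n_coils = nc, residuals = residuals),
            class = "grappa_weights")
}

#' Synthesize missing k-space lines with GRAPPA weights
#'
#' Acquired samples pass through unchanged; every missing sample is
#' synthesized from its R-spaced source neighborhood (circular boundary
#' handling). If the input contains a fully sampled ACS block
#' (`acs_present = TRUE`), that block is re-inserted verbatim afterwards.
#'
#' @param undersampled_kspace complex 4D (x, y, z, coil) with zeros at
#'   unsampled positions.
#' @param weights a `grappa_weights` object.
#' @param scheme a [sampling_scheme()]; must match the calibration scheme.
#' @param acs_present logical; re-insert the centered ACS block from input.
#' @return complex 4D fully populated k-space.
#' @export
apply_grappa <- function(undersampled_kspace, weights, scheme = weights$scheme,
                         acs_present = FALSE) {
  d <- dim(undersampled_kspace)
  if (d[4] != weights$n_coils) stop("coil count mismatch between data and weights")
  if (scheme$accel_y != weights$scheme$accel_y ||
      scheme$accel_z != weights$scheme$accel_z)
    stop("scheme/weights acceleration mismatch")
  if (scheme$accel_y == 1 && scheme$accel_z == 1) return(undersampled_kspace)
  out <- undersampled_kspace
  dcy <- dc_index0(d[2]); dcz <- dc_index0(d[3])
  for (key in names(weights$weights)) {
    dd <- as.integer(strsplit(key, "_")[[1]])
    dy <- dd[1]; dz <- dd[2]
    off <- grappa_offsets(dy, dz, scheme, weights$kernel)
    ys <- which((((seq_len(d[2]) - 1) - dcy) %% scheme$accel_y) == dy)
    zs <- which((((seq_len(d[3]) - 1) - dcz) %% scheme$accel_z) == dz)
    if (length(ys) == 0 || length(zs) == 0) next
    xs <- seq_len(d[1])
    S <- gather_sources(undersampled_kspace, xs, ys, zs, off)
    synth <- S %*% weights$weights[[key]]
    for (c_i in seq_len(d[4])) {
      blk <- synth[, c_i]
      dim(blk) <- c(length(xs), length(ys), length(zs))
      out[xs, ys, zs, c_i] <- blk
    }
  }
  if (acs_present) {
    iy <- centered_range(d[2], scheme$acs_size[1])
    iz <- centered_range(d[3], scheme$acs_size[2])
    out[, iy, iz, ] <- undersampled_kspace[, iy, iz, ]
  }
  out
}

#' Root-sum-of-squares coil combination
#'
#' @param imgs complex 4D (x, y, z, coil) per-coil image volumes, or a 3D
#'   single-coil image.
#' @return real 3D magnitude volume.
#' @export
rss_combine <- function(imgs) {
  d <- dim(imgs)
  if (length(d) == 3) return(Mod(imgs))
  sqrt(apply(Mod(imgs)^2, 1:3, sum))
}

#' Reconstruct an RSS image from undersampled multi-coil k-space
#'
#' Convenience wrapper: GRAPPA-fill the missing lines, inverse FFT per coil,
#' RSS-combine.
#'
#' @inheritParams apply_grappa
#' @return real 3D magnitude volume.
#' @export
grappa_reconstruct <- function(undersampled_kspace, weights,
                               scheme = weights$scheme, acs_present = FALSE) {
  full <- apply_grappa(undersampled_kspace, weights, scheme, acs_present)
  d <- dim(full)
  imgs <- array(0 + 0i, dim = d)
  for (c_i in seq_len(d[4])) imgs[, , , c_i] <- centered_ifft3(full[, , , c_i])
  rss_combine(imgs)
}

#' Serialize GRAPPA weights
#'
#' Writes the complex weight matrices to an RDS container next to a JSON
#' header recording the sampling scheme and kernel geometry.
#'
#' @param weights a `grappa_weights` object.
#' @param path output path (`.rds`); the header is written to `<path>.json`.
#' @export
write_grappa_weights <- function(weights, path) {
  saveRDS(weights, path)
  hdr <- list(scheme = unclass(weights$scheme), kernel = unclass(weights$kernel),
              n_coils = weights$n_coils, classes = names(weights$weights))
  jsonlite::write_json(hdr, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_grappa_weights
#' @export
read_grappa_weights <- function(path) readRDS(path)
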