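#' Assign phase-encode lines to acquisition shots
#'
#' Partitions the partition-encode (z) axis into contiguous blocks of nearly
#' equal size, one block per shot (readout train); every (y, z) line belongs
#' to exactly one shot. Deterministic.
#'
#' @param shape integer triple (x, y, z array shape).
#' @param n_shots number of shots (1 <= n_shots <= shape\[3\]).
#' @param ordering `"linear_partition"` (blocks along z) or `"linear_phase"`
#'   (blocks along y).
#' @return object of class `shot_segmentation`: list with `shot_of_line`
#'   (integer matrix y x z), `n_shots`, `ordering`.
#' @export
segment_kspace <- function(shape, n_shots, ordering = c("linear_partition", "linear_phase")) {
  ordering <- match.arg(ordering)
  if (n_shots <= 0) stop("n_shots must be positive")
  ax <- if (ordering == "linear_partition") shape[3] else shape[2]
  if (n_shots > ax) stop("more shots than phase-encode lines")
  # contiguous blocks differing in size by at most 1
  block <- rep(seq_len(n_shots), times = diff(round(seq(0, ax, length.out = n_shots + 1))))
  shot_of_line <- if (ordering == "linear_partition")
    matrix(rep(block, each = shape[2]), shape[2], ax)
  else
    matrix(rep(block, times = shape[3]), shape[2], shape[3])
  structure(list(shot_of_line = shot_of_line, n_shots = as.integer(n_shots),
                 ordering = ordering, shape = as.integer(shape)),
            class = "shot_segmentation")
}

#' Corrupt a volume with shot-wise rigid motion
#'
#' Assembles a composite k-space: for each shot, the volume is rigidly
#' transformed to that shot's pose, Fourier transformed, and the shot's
#' phase-encode lines are copied into the composite; the magnitude of the
#' inverse transform is returned. Exact for piecewise-constant pose per
#' shot. A zero trace returns `|volume|` (to floating tolerance); repeated
#' poses are computed once.
#'
#' @param volume 3D (complex) image.
#' @param trace `motion_trace` with one row per shot.
#' @param seg a [segment_kspace()] segmentation with matching shot count.
#' @param voxel_mm voxel size (mm).
#' @param interp interpolation for the rigid resampling.
#' @return real 3D magnitude volume.
#' @export
corrupt_image_with_motion <- function(volume, trace, seg, voxel_mm = c(1, 1, 1),
                                      interp = "cubic") {
  if (nrow(trace) != seg$n_shots)
    stop("trace length does not match shot count")
  d <- dim(volume)
  ksp <- array(0 + 0i, dim = d)
  prev_pose <- NULL
  prev_k <- NULL
  for (s in seq_len(seg$n_shots)) {
    pose <- rigid_pose(trace$tx[s], trace$ty[s], trace$tz[s],
                       trace$rx[s], trace$ry[s], trace$rz[s])
    if (!is.null(prev_pose) && all(pose == prev_pose)) {
      ks <- prev_k
    } else {
      mv <- apply_rigid(volume, pose, voxel_mm, interp)
      ks <- centered_fft3(mv)
      prev_pose <- pose; prev_k <- ks
    }
    if (seg$ordering == "linear_partition") {
      zs <- which(seg$shot_of_line[1, ] == s)
      ksp[, , zs] <- ks[, , zs]
    } else {
      ys <- which(seg$shot_of_line[, 1] == s)
      ksp[, ys, ] <- ks[, ys, ]
    }
  }
  Mod(centered_ifft3(ksp))
}

# edge-replicated shift of a 3D array by integer voxels along one axis
shift_rep <- function(x, ax, by) {
  d <- dim(x)
  n <- d[ax]
  src <- pmin(pmax(seq_len(n) - by, 1L), n)
  if (ax == 1) return(x[src, , , drop = FALSE])
  if (ax == 2) return(x[, src, , drop = FALSE])
  x[, , src, drop = FALSE]
}

#' Gradient entropy of a volume
#'
#' Per axial slice, 2D Prewitt gradients along x and y (edge-replicated
#' convolution); the gradient magnitude `sqrt(gx^2 + gy^2)` is max-normalized
#' to \[0, 1\], quantized into `n_bins` equal bins over the whole volume, and
#' the base-2 Shannon entropy of the bin histogram is returned
#' (zero-probability bins excluded). Lower values mean a sharper image. The
#' z-gradient is deliberately excluded. Invariant to global intensity
#' scaling; an all-constant volume has entropy 0.
#'
#' @param volume real 3D array (complex input is reduced to magnitude).
#' @param n_bins histogram bins (default 256).
#' @return nonnegative scalar entropy (bits).
#' @export
gradient_entropy <- function(volume, n_bins = 256) {
  if (is.complex(volume)) volume <- Mod(volume)
  if (length(volume) == 0) stop("empty volume")
  # Prewitt: derivative along one axis, uniform smoothing along the other
  # (x-y in-plane only), via edge-replicated shifts
  dxp <- shift_rep(volume, 1, 1) - shift_rep(volume, 1, -1)
  gx <- dxp + shift_rep(dxp, 2, 1) + shift_rep(dxp, 2, -1)
  dyp <- shift_rep(volume, 2, 1) - shift_rep(volume, 2, -1)
  gy <- dyp + shift_rep(dyp, 1, 1) + shift_rep(dyp, 1, -1)
  gmag <- sqrt(gx^2 + gy^2)
  m <- max(gmag)
  if (m == 0) return(0)
  g <- gmag / m
  bins <- pmin(n_bins - 1L, floor(g * n_bins))  # n_bins equal bins on [0,1]
  counts <- tabulate(bins + 1L, nbins = n_bins)
  p <- counts[counts > 0] / length(g)
  -sum(p * log2(p))
}
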