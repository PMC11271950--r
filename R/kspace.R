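#' Centered unitary 3D Fourier transforms
#'
#' DC is located at 0-based index `floor(N/2)` on every axis (the repo-wide
#' centering convention). Transforms are unitary, so Parseval's identity holds
#' exactly and `centered_ifft3(centered_fft3(x))` returns `x` to floating
#' tolerance.
#'
#' @param x 3D numeric or complex array (image for `centered_fft3`, k-space for
#'   `centered_ifft3`).
#' @return 3D complex array of the same shape.
#' @export
centered_fft3 <- function(x) {
  if (length(dim(x)) != 3) stop("input must be a 3D array")
  fftshift3(fft(ifftshift3(x))) / sqrt(length(x))
}

#' @rdname centered_fft3
#' @export
centered_ifft3 <- function(x) {
  if (length(dim(x)) != 3) stop("input must be a 3D array")
  fftshift3(fft(ifftshift3(x), inverse = TRUE)) / sqrt(length(x))
}

# circular shifts putting DC at floor(N/2) (fftshift) and back (ifftshift)
shift3 <- function(x, s) {
  d <- dim(x)
  idx <- lapply(1:3, function(ax) wrap_index(seq_len(d[ax]) - s[ax], d[ax]))
  x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}
fftshift3 <- function(x) shift3(x, floor(dim(x) / 2))
ifftshift3 <- function(x) shift3(x, -floor(dim(x) / 2))

#' Cartesian 3D sampling scheme
#'
#' Describes regular undersampling of the two phase-encode axes (y, z) with a
#' fully sampled readout (x) and an optional fully sampled auto-calibration
#' (ACS) block centered on DC. An acceleration of 4x4 corresponds to a nominal
#' undersampling factor R = 16.
#'
#' @param accel_y,accel_z integer acceleration factors (>= 1) along y and z.
#' @param acs_size integer pair: ACS extent in y and z (lines).
#' @param shape integer triple: full k-space array shape.
#' @return object of class `sampling_scheme`.
#' @export
sampling_scheme <- function(accel_y, accel_z, acs_size, shape) {
  stopifnot(accel_y >= 1, accel_z >= 1, length(acs_size) == 2, length(shape) == 3)
  if (acs_size[1] > shape[2] || acs_size[2] > shape[3])
    stop("acs_size exceeds k-space shape in y/z")
  structure(list(accel_y = as.integer(accel_y), accel_z = as.integer(accel_z),
                 acs_size = as.integer(acs_size), shape = as.integer(shape)),
            class = "sampling_scheme")
}

#' Binary undersampling mask for a Cartesian scheme
#'
#' The readout axis is always fully sampled. Along y and z every
#' `accel`-th line is kept, phased so that the line containing DC is always
#' sampled. With `include_acs` the centered ACS block is added.
#'
#' @param scheme a [sampling_scheme()].
#' @param include_acs logical; add the fully sampled ACS block.
#' @return 3D 0/1 array of `scheme$shape`.
#' @export
make_sampling_mask <- function(scheme, include_acs = FALSE) {
  d <- scheme$shape
  my <- ((seq_len(d[2]) - 1) - dc_index0(d[2])) %% scheme$accel_y == 0
  mz <- ((seq_len(d[3]) - 1) - dc_index0(d[3])) %% scheme$accel_z == 0
  mask_yz <- outer(my, mz)
  if (include_acs) {
    iy <- centered_range(d[2], scheme$acs_size[1])
    iz <- centered_range(d[3], scheme$acs_size[2])
    mask_yz[iy, iz] <- TRUE
  }
  mask <- array(rep(as.numeric(mask_yz), each = d[1]), dim = d)
  mask
}

#' Extract the centered ACS block from k-space
#'
#' @param kspace 3D k-space array (or 4D with coils on the 4th axis).
#' @param acs_size integer pair (y, z extent); the readout axis is kept whole.
#' @return array of shape (nx, acs_y, acs_z\[, ncoil\]).
#' @export
extract_acs <- function(kspace, acs_size) {
  d <- dim(kspace)
  if (acs_size[1] > d[2] || acs_size[2] > d[3]) stop("acs_size exceeds k-space shape")
  iy <- centered_range(d[2], acs_size[1])
  iz <- centered_range(d[3], acs_size[2])
  if (length(d) == 3) kspace[, iy, iz, drop = FALSE]
  else kspace[, iy, iz, , drop = FALSE]
}

#' Separable apodization windows
#'
#' `tukey_window` and `hamming_window` return length-`n` symmetric windows;
#' `apply_window` multiplies a k-space block by the separable product over the
#' chosen axes (default: the two phase-encode axes, matching a readout that is
#' always fully sampled; set `axes = 1:3` for 3D apodization).
#'
#' @param n window length.
#' @param alpha Tukey taper fraction in \[0, 1\]; 0 gives a rectangular window.
#' @return numeric window with maximum 1.
#' @export
tukey_window <- function(n, alpha = 0.5) {
  stopifnot(n >= 1, alpha >= 0, alpha <= 1)
  if (n == 1) return(1)
  # centered on the DC convention (peak at 0-based floor(n/2)) so that
  # windowing a spectrum introduces no linear phase
  u <- abs((0:(n - 1)) - dc_index0(n)) / (n / 2)
  w <- rep(1, n)
  if (alpha > 0) {
    taper <- u > 1 - alpha
    w[taper] <- 0.5 * (1 + cos(pi * (u[taper] - (1 - alpha)) / alpha))
  }
  w
}

#' @rdname tukey_window
#' @export
hamming_window <- function(n) {
  stopifnot(n >= 1)
  if (n == 1) return(1)
  u <- ((0:(n - 1)) - dc_index0(n)) / (n / 2)
  0.54 + 0.46 * cos(pi * u)
}

#' @rdname tukey_window
#' @param data array (3D, or 4D with coils last) to window.
#' @param kind "tukey" or "hamming".
#' @param params list of window parameters (`alpha` for Tukey).
#' @param axes which of the three spatial axes to window.
#' @export
apply_window <- function(data, kind = c("tukey", "hamming"), params = list(),
                         axes = c(2, 3)) {
  kind <- match.arg(kind)
  d <- dim(data)
  spat <- d[1:3]
  wlist <- lapply(1:3, function(ax) {
    if (!(ax %in% axes)) return(rep(1, spat[ax]))
    switch(kind,
           tukey = tukey_window(spat[ax], if (is.null(params$alpha)) 0.5 else params$alpha),
           hamming = hamming_window(spat[ax]))
  })
  w3 <- outer(outer(wlist[[1]], wlist[[2]]), wlist[[3]])
  dim(w3) <- spat
  if (length(d) == 3) data * w3
  else data * array(rep(w3, d[4]), dim = d)
}

#' Zero-fill a centered k-space block to a larger grid
#'
#' Places the block so that its DC sample lands on the target grid's DC;
#' all other entries are zero. `extract_acs(zero_fill(b, s), dim(b)[2:3])`
#' returns `b` exactly.
#'
#' @param block 3D (or 4D, coils last) centered k-space block.
#' @param target_shape integer triple for the spatial output shape.
#' @return zero-filled array.
#' @export
zero_fill <- function(block, target_shape) {
  d <- dim(block)
  if (any(d[1:3] > target_shape)) stop("block larger than target shape")
  ix <- centered_range(target_shape[1], d[1])
  iy <- centered_range(target_shape[2], d[2])
  iz <- centered_range(target_shape[3], d[3])
  if (length(d) == 3) {
    out <- array(0 + 0i, dim = target_shape)
    out[ix, iy, iz] <- block
  } else {
    out <- array(0 + 0i, dim = c(target_shape, d[4]))
    out[ix, iy, iz, ] <- block
  }
  out
}

#' Write a sampling mask as NIfTI for inspection
#'
#' @param mask 3D 0/1 array.
#' @param path output file path (.nii or .nii.gz).
#' @param voxel_mm voxel size triple in mm.
#' @export
write_mask_nifti <- function(mask, path, voxel_mm = c(1, 1, 1)) {
  img <- RNifti::asNifti(array(as.integer(mask), dim = dim(mask)))
  RNifti::pixdim(img) <- voxel_mm
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}
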