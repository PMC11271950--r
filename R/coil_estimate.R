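#' Estimate smooth complex coil sensitivity maps from ACS data
#'
#' Pipeline: Tukey-window the centered ACS block (phase-encode axes),
#' Hamming-apodize it to suppress ringing, zero-fill to the target grid,
#' centered inverse FFT per coil, divide each coil image by the
#' root-sum-of-squares over coils, then smooth the real and imaginary parts
#' with a penalized-least-squares (DCT) smoother. Outside the support (RSS
#' below 5% of its maximum) the maps are extrapolated by the smoother.
#' Deterministic.
#'
#' @param acs_kspace complex 4D array (x, y_acs, z_acs, coil), centered on DC.
#' @param target_shape integer triple: output grid.
#' @param tukey_param Tukey taper fraction (default 0.5).
#' @param smooth_strength smoothing parameter, or `NULL` for GCV selection.
#' @param support_frac support threshold as a fraction of max RSS.
#' @param smooth_parts `"reim"` (default) smooths real/imaginary parts;
#'   `"magphase"` smooths magnitude and unwrapped-phase factors instead.
#' @param window_3d logical; window the readout axis too (default windows the
#'   two phase-encode axes only).
#' @return object of class `coil_maps`: list with `maps` (complex 4D),
#'   `support` (logical 3D), `source = "estimated"`, and `smooth_s`.
#' @export
estimate_coil_maps <- function(acs_kspace, target_shape, tukey_param = 0.5,
                               smooth_strength = NULL, support_frac = 0.05,
                               smooth_parts = c("reim", "magphase"),
                               window_3d = FALSE) {
  smooth_parts <- match.arg(smooth_parts)
  d <- dim(acs_kspace)
  if (length(d) != 4) stop("acs_kspace must be 4D (x, y, z, coil)")
  if (all(Mod(acs_kspace) == 0)) stop("no calibration signal")
  nc <- d[4]
  if (nc < 2 && smooth_parts == "reim") {
    # single-channel self-ratio still well defined; proceed
  }
  axes <- if (window_3d) 1:3 else c(2, 3)
  blk <- apply_window(acs_kspace, "tukey", list(alpha = tukey_param), axes = axes)
  blk <- apply_window(blk, "hamming", axes = axes)
  ksp <- zero_fill(blk, target_shape)
  imgs <- array(0 + 0i, dim = c(target_shape, nc))
  for (c_i in seq_len(nc)) imgs[, , , c_i] <- centered_ifft3(ksp[, , , c_i])
  rss <- sqrt(apply(Mod(imgs)^2, 1:3, sum))
  support <- rss >= support_frac * max(rss)
  w <- array(as.numeric(support), dim = target_shape)
  maps <- array(0 + 0i, dim = c(target_shape, nc))
  s_used <- NA_real_
  for (c_i in seq_len(nc)) {
    ratio <- imgs[, , , c_i] / ifelse(rss > 0, rss, 1)
    ratio[!support] <- 0
    if (smooth_parts == "reim") {
      sr <- smooth_pls(Re(ratio), s = smooth_strength, weights = w)
      si <- smooth_pls(Im(ratio), s = sr$s, weights = w)
      maps[, , , c_i] <- complex(real = sr$z, imaginary = si$z)
      s_used <- sr$s
    } else {
      sm <- smooth_pls(Mod(ratio), s = smooth_strength, weights = w)
      sp_r <- smooth_pls(cos(Arg(ratio)), s = sm$s, weights = w)
      sp_i <- smooth_pls(sin(Arg(ratio)), s = sm$s, weights = w)
      ph <- atan2(sp_i$z, sp_r$z)
      maps[, , , c_i] <- sm$z * exp(1i * ph)
      s_used <- sm$s
    }
  }
  dim(maps) <- c(target_shape, nc)
  structure(list(maps = maps, support = support, source = "estimated",
                 smooth_s = s_used),
            class = "coil_maps")
}
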