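#' Normalized root-mean-square error
#'
#' RMS difference between an image and a reference, normalized by the L2 norm
#' of the reference. Complex input is compared in the complex plane.
#'
#' @param x array to evaluate.
#' @param ref reference array of the same shape.
#' @return nonnegative scalar; 0 means identical arrays.
#' @export
nrmse <- function(x, ref) {
  stopifnot(all(dim(x) == dim(ref)))
  den <- sqrt(sum(Mod(ref)^2))
  if (den == 0) stop("reference has zero norm")
  sqrt(sum(Mod(x - ref)^2)) / den
}

#' Spearman rank correlation
#'
#' Thin wrapper kept for a stable call site in the degradation-trend checks.
#' @param x,y numeric vectors.
#' @return rank correlation in \[-1, 1\].
#' @export
rank_correlation <- function(x, y) {
  stats::cor(x, y, method = "spearman")
}

# index vector with circular wrap (1-based)
wrap_index <- function(i, n) ((i - 1L) %% n) + 1L

# 0-based index of the DC sample under the repo-wide centering convention
dc_index0 <- function(n) floor(n / 2)

# centered index range (0-based start) of a block of size m on an axis of size n
centered_range <- function(n, m) {
  if (m > n) stop("block larger than axis")
  start0 <- dc_index0(n) - floor(m / 2)
  start0 + seq_len(m)  # 1-based indices
}

# Gaussian low-pass filtering via the FFT (periodic boundaries); fwhm in mm
gauss_smooth <- function(vol, fwhm_mm, voxel_mm) {
  if (fwhm_mm <= 0) return(vol)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d <- dim(vol)
  gk <- lapply(seq_along(d), function(ax) {
    f <- c(0:(ceiling(d[ax] / 2) - 1), -(floor(d[ax] / 2):1)) / (d[ax] * voxel_mm[ax])
    exp(-2 * pi^2 * sigma^2 * f^2)
  })
  g3 <- outer(outer(gk[[1]], gk[[2]]), gk[[3]])
  dim(g3) <- d
  out <- fft(fft(vol) * g3, inverse = TRUE) / prod(d)
  if (is.complex(vol)) out else Re(out)
}
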