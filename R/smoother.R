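# Penalized least-squares smoothing on a regular grid via the DCT, in the
# style of discrete-spline smoothers for gridded data of arbitrary dimension:
# minimize ||W^(1/2)(y - z)||^2 + s ||D z||^2 with D the discrete Laplacian;
# the minimizer is diagonal in the DCT basis, z = IDCT(Gamma .* DCT(y)) with
# Gamma = 1 / (1 + s * Lambda^2).

# orthonormal DCT-II along the first dimension of a matrix (columns
# transformed independently), via the half-sample FFT reordering
dct_mat <- function(x) {
  n <- nrow(x)
  if (n == 1) return(x)
  idx <- c(seq(1, n, by = 2), seq(if (n %% 2 == 0) n else n - 1, 2, by = -2))
  v <- x[idx, , drop = FALSE]
  V <- mvfft(v)
  ph <- exp(-1i * pi * (0:(n - 1)) / (2 * n))
  y <- Re(ph * V) * sqrt(2 / n)
  y[1, ] <- y[1, ] / sqrt(2)
  y
}

idct_mat <- function(y) {
  n <- nrow(y)
  if (n == 1) return(y)
  # rebuild the half-sample FFT spectrum: Z_k = y_k - i*y_{n-k} (up to scale)
  Z <- matrix(0 + 0i, n, ncol(y))
  Z[1, ] <- y[1, ] * sqrt(n)
  Z[2:n, ] <- (y[2:n, , drop = FALSE] - 1i * y[n:2, , drop = FALSE]) / sqrt(2 / n)
  ph <- exp(1i * pi * (0:(n - 1)) / (2 * n))
  v <- Re(mvfft(Z * ph, inverse = TRUE)) / n
  x <- matrix(0, n, ncol(y))
  idx <- c(seq(1, n, by = 2), seq(if (n %% 2 == 0) n else n - 1, 2, by = -2))
  x[idx, ] <- v
  x
}

# apply f (a matrix operator on the first dim) along dimension `ax` of a 3D array
apply_along <- function(x, ax, f) {
  d <- dim(x)
  perm <- c(ax, setdiff(1:3, ax))
  xp <- aperm(x, perm)
  m <- f(matrix(xp, nrow = d[ax]))
  dim(m) <- d[perm]
  aperm(m, order(perm))
}

dct3 <- function(x) {
  for (ax in 1:3) x <- apply_along(x, ax, dct_mat)
  x
}
idct3 <- function(x) {
  for (ax in 1:3) x <- apply_along(x, ax, idct_mat)
  x
}

# eigenvalues of the 3D discrete Laplacian in the DCT basis
laplacian_eigs <- function(shape) {
  lam <- lapply(shape, function(n) 2 - 2 * cos(pi * (0:(n - 1)) / n))
  l3 <- outer(lam[[1]], lam[[2]], "+")
  l3 <- outer(l3, lam[[3]], "+")
  dim(l3) <- shape
  l3
}

#' Smooth gridded data by penalized least squares (DCT-diagonal)
#'
#' Discrete smoothing-spline for 3D gridded data: a Laplacian-squared
#' roughness penalty solved exactly in the DCT basis. Supports a 0/1 (or
#' fractional) weight field: unweighted voxels are filled in by the smoother
#' (extrapolation), using an iterated weighted scheme. The smoothing
#' parameter is chosen by generalized cross-validation when `s = NULL`.
#'
#' @param y real 3D array.
#' @param s smoothing parameter (>= 0), or `NULL` for GCV selection.
#' @param weights array of weights in \[0, 1\], same shape as `y`.
#' @param n_iter iterations of the weighted scheme (ignored for unit weights).
#' @return list with `z` (smoothed array) and `s` (parameter used).
#' @export
smooth_pls <- function(y, s = NULL, weights = NULL, n_iter = 8) {
  d <- dim(y)
  stopifnot(length(d) == 3)
  lam2 <- laplacian_eigs(d)^2
  n <- length(y)
  uniform_w <- is.null(weights) || all(weights == 1)
  if (uniform_w) weights <- array(1, d)

  gcv_score <- function(log10s, yy) {
    s_ <- 10^log10s
    gamma <- 1 / (1 + s_ * lam2)
    dy <- dct3(yy)
    rss <- sum(((gamma - 1) * dy)^2)
    trh <- sum(gamma)
    (rss / n) / (1 - trh / n)^2
  }

  run <- function(s_) {
    gamma <- 1 / (1 + s_ * lam2)
    if (uniform_w) return(idct3(gamma * dct3(y)))
    z <- array(mean(y[weights > 0]), d)
    for (i in seq_len(n_iter))
      z <- idct3(gamma * dct3(weights * (y - z) + z))
    z
  }

  if (is.null(s)) {
    yy <- if (uniform_w) y else {
      # GCV on the filled field: a cheap fill keeps the criterion stable
      z0 <- y; z0[weights == 0] <- mean(y[weights > 0]); z0
    }
    opt <- stats::optimize(gcv_score, interval = c(-6, 5), yy = yy)
    s <- 10^opt$minimum
  }
  list(z = run(s), s = s)
}
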