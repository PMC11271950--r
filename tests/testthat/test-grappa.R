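test_that("unaccelerated schemes produce empty weights and identity reconstruction", {
  sch <- sampling_scheme(1, 1, c(8, 8), c(16, 16, 16))
  acs <- array(complex(real = rnorm(16 * 8 * 8 * 2),
                       imaginary = rnorm(16 * 8 * 8 * 2)), c(16, 8, 8, 2))
  w <- calibrate_grappa(acs, sch)
  expect_length(w$weights, 0)
  ksp <- array(complex(real = rnorm(16^3 * 2), imaginary = rnorm(16^3 * 2)),
               c(16, 16, 16, 2))
  expect_identical(apply_grappa(ksp, w), ksp)
})

test_that("calibration reproduces an exact shift-invariant model with zero residual", {
  # single coil, R = 2x1: data with geometric structure in every axis is an
  # exact linear combination of its R-spaced neighbors
  nx <- 12; ny <- 16; nz <- 6
  ax <- exp(1i * 0.31 * (0:(nx - 1)))
  ay <- exp(1i * 0.17 * (0:(ny - 1)))
  az <- exp(1i * 0.23 * (0:(nz - 1)))
  dat <- array(0 + 0i, c(nx, ny, nz, 1))
  dat[, , , 1] <- outer(outer(ax, ay), az)
  sch <- sampling_scheme(2, 1, c(ny, nz), c(nx, ny, nz))
  # rank-deficient consistent system: a whisper of regularization keeps
  # the normal equations solvable without perturbing the exact fit
  kern <- grappa_kernel_spec(2, 2, 3, tikhonov_lambda = 1e-10)
  w <- calibrate_grappa(dat, sch, kern)
  expect_lt(max(w$residuals), 1e-8)
})

test_that("calibration solves the regularized least squares (independent solver cross-check)", {
  ksp <- fx_ksp8()
  sch <- sampling_scheme(2, 2, c(24, 24), dim(ksp)[1:3])
  acs <- extract_acs(ksp, c(24, 24))
  kern <- grappa_kernel_spec()
  w <- calibrate_grappa(acs, sch, kern)
  expect_lt(max(w$residuals), 0.05)
  # independent dense refit of one class: augmented-matrix least squares
  off <- fatnavsim:::grappa_offsets(1, 0, sch, kern)
  xs <- seq(2, dim(acs)[1] - 1)
  ys <- seq(max(1, 1 - min(off$oy)), min(24, 24 - max(off$oy)))
  zs <- seq(max(1, 1 - min(off$oz)), min(24, 24 - max(off$oz)))
  A <- fatnavsim:::gather_sources(acs, xs, ys, zs, off)
  B <- sapply(seq_len(dim(acs)[4]), function(c_i) as.vector(acs[xs, ys, zs, c_i]))
  lam <- kern$tikhonov_lambda * mean(Re(diag(Conj(t(A)) %*% A)))
  Aaug <- rbind(A, sqrt(lam) * diag(1 + 0i, ncol(A)))
  Baug <- rbind(B, matrix(0 + 0i, ncol(A), ncol(B)))
  W_qr <- qr.solve(Aaug, Baug)
  expect_lt(max(Mod(W_qr - w$weights[["1_0"]])), 1e-6 * max(Mod(W_qr)))
})

test_that("GRAPPA reconstruction preserves acquired samples and recovers the phantom", {
  ksp <- fx_ksp8()
  d <- dim(ksp)
  sch <- sampling_scheme(2, 2, c(20, 32), d[1:3])
  w <- fx("w8_r2", calibrate_grappa(extract_acs(ksp, c(20, 32)), sch))
  mask <- make_sampling_mask(sch)
  us <- ksp * array(rep(mask, d[4]), dim = d)
  full <- apply_grappa(us, w)
  # acquired entries pass through bit-identically
  sel <- array(rep(mask == 1, d[4]), dim = d)
  expect_identical(full[sel], us[sel])
  # end-to-end oracle: RSS image vs the fully sampled reconstruction
  rec <- grappa_reconstruct(us, w)
  expect_lt(nrmse(rec, fx_ref_rss8()), 0.05)
  expect_error(apply_grappa(us[, , , 1:3, drop = FALSE], w), "coil count")
})

test_that("ACS too small for the kernel geometry raises a sized error", {
  ksp <- fx_ksp8()
  sch <- sampling_scheme(4, 4, c(4, 4), dim(ksp)[1:3])
  expect_error(calibrate_grappa(extract_acs(ksp, c(4, 4)), sch), "too small")
})

test_that("root-sum-of-squares combination matches the per-voxel formula", {
  set.seed(5)
  img <- array(complex(real = rnorm(4^3), imaginary = rnorm(4^3)), c(4, 4, 4))
  expect_equal(rss_combine(img), Mod(img))
  two <- array(0 + 0i, c(4, 4, 4, 2)); two[, , , 1] <- img; two[, , , 2] <- img
  expect_equal(rss_combine(two), sqrt(2) * Mod(img), tolerance = 1e-12)
  three <- array(complex(real = rnorm(4^3 * 3), imaginary = rnorm(4^3 * 3)),
                 c(4, 4, 4, 3))
  direct <- array(0, c(4, 4, 4))
  for (i in 1:4) for (j in 1:4) for (k in 1:4)
    direct[i, j, k] <- sqrt(sum(Mod(three[i, j, k, ])^2))
  expect_equal(rss_combine(three), direct, tolerance = 1e-12)
})
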