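test_that("degenerate phantom geometry is rejected", {
  expect_error(make_head_phantom(phantom_spec(fat_shell_thickness_mm = 0)),
               "unresolvable")
  expect_error(make_head_phantom(phantom_spec(skull_gap_mm = 2)), "gap")
})

test_that("fat shell and brain interior have disjoint supports and are deterministic", {
  ph <- fx_nav8()
  expect_equal(max(Mod(ph$fat) * Mod(ph$t1)), 0)
  ph2 <- make_head_phantom(fx_spec8(), "nav")
  expect_identical(ph$fat, ph2$fat)
  expect_identical(ph$t1, ph2$t1)
  # labels: fat label only where fat is nonzero
  expect_true(all((ph$labels == 4) == (Mod(ph$fat) > 0)))
})

test_that("fat voxel count matches the analytic ellipsoid-shell membership oracle", {
  spec <- fx_spec8()
  ph <- fx_nav8()
  # independent voxel-membership count from the analytic geometry
  semi <- spec$brain_semiaxes_mm
  sbar <- mean(semi)
  rho_in <- 1 + spec$skull_gap_mm / sbar
  rho_out <- rho_in + spec$fat_shell_thickness_mm / sbar
  w <- max(spec$nav_voxel_mm) / sbar
  shp <- spec$nav_shape
  cnt <- 0L
  for (k in seq_len(shp[3])) for (j in seq_len(shp[2])) {
    x <- ((seq_len(shp[1]) - 1) - (shp[1] - 1) / 2) * spec$nav_voxel_mm[1]
    y <- ((j - 1) - (shp[2] - 1) / 2) * spec$nav_voxel_mm[2]
    z <- ((k - 1) - (shp[3] - 1) / 2) * spec$nav_voxel_mm[3]
    rho <- sqrt((x / semi[1])^2 + (y / semi[2])^2 + (z / semi[3])^2)
    cnt <- cnt + sum(rho > rho_in - w / 2 & rho < rho_out + w / 2)
  }
  expect_identical(sum(Mod(ph$fat) > 0), as.integer(cnt))
})

test_that("coil maps are smooth, positive in RSS, and share the ring symmetry", {
  spec <- fx_spec8()
  maps <- fx_maps8()
  ph <- fx_nav8()
  rss <- sqrt(apply(Mod(maps)^2, 1:3, sum))
  supp <- Mod(ph$fat) + Mod(ph$t1) > 0
  expect_gt(min(rss[supp]), 0)
  # 4-coil symmetric ring: RSS invariant under the y-flip that maps the
  # ring onto itself
  m4 <- make_coil_maps(phantom_spec(n_coils = 4), "nav")
  r4 <- sqrt(apply(Mod(m4)^2, 1:3, sum))
  flipped <- r4[, rev(seq_len(dim(r4)[2])), ]
  expect_lt(max(abs(r4 - flipped)) / max(r4), 1e-10)
  # smoothness oracle: projection onto a 3rd-order polynomial basis leaves
  # a small relative residual
  shp <- dim(rss)
  co <- expand.grid(x = seq_len(shp[1]), y = seq_len(shp[2]), z = seq_len(shp[3]))
  co <- scale(as.matrix(co))
  basis <- cbind(1, co, co^2, co^3, co[, 1] * co[, 2], co[, 1] * co[, 3],
                 co[, 2] * co[, 3], co[, 1] * co[, 2] * co[, 3],
                 co[, 1]^2 * co[, 2], co[, 1]^2 * co[, 3],
                 co[, 2]^2 * co[, 1], co[, 2]^2 * co[, 3],
                 co[, 3]^2 * co[, 1], co[, 3]^2 * co[, 2])
  for (c_i in c(1, 4)) {
    for (part in list(Re, Im)) {
      v <- as.vector(part(maps[, , , c_i]))
      fit <- lm.fit(basis, v)
      expect_lt(sqrt(sum(fit$residuals^2)) / sqrt(sum(v^2)), 0.15)
    }
  }
})

test_that("multi-coil k-space simulation is seeded, exact for impulses, and noise-calibrated", {
  # impulse at the convention center with unit map -> flat magnitude
  im <- array(0 + 0i, dim = c(8, 8, 8)); im[5, 5, 5] <- 1
  unit_map <- array(1 + 0i, dim = c(8, 8, 8, 1))
  k <- simulate_multicoil_kspace(im, unit_map, 0)
  expect_equal(sd(Mod(k)), 0)
  # determinism
  maps <- fx_maps8()
  vol <- fx_nav8()$fat
  k1 <- simulate_multicoil_kspace(vol, maps, 0.05, seed = 9)
  k2 <- simulate_multicoil_kspace(vol, maps, 0.05, seed = 9)
  expect_identical(k1, k2)
  expect_error(simulate_multicoil_kspace(vol[1:10, , ], maps), "disagree")
  # Monte-Carlo noise check: subtract the noiseless spectrum to isolate the
  # injected noise; max|volume| = 1 so sigma is absolute. Pooled std of the
  # real and imaginary parts must sit within 5% of the requested 0.01.
  kk <- simulate_multicoil_kspace(vol, maps, 0.01, seed = 1)
  nz <- kk - fx_ksp8()
  pooled <- c(Re(nz), Im(nz))
  expect_lt(abs(sd(pooled) - 0.01) / 0.01, 0.05)
  # round-trip invariant: noiseless per-coil k-space inverts to coil images
  ksp <- fx_ksp8()
  img1 <- centered_ifft3(ksp[, , , 3])
  expect_lt(nrmse(img1, vol * maps[, , , 3]), 1e-10)
})

test_that("simulated observers reduce to a step function without noise and match the latent model", {
  osp <- observer_spec(2, c(1, 2, 3), noise_scale = 1e-9, seed = 4)
  sc <- simulate_observer_scores(c(0.5, 1.5, 2.5, 3.5), osp)
  expect_identical(sc, matrix(c(4L, 3L, 2L, 1L, 4L, 3L, 2L, 1L), 4, 2))
  # metric below the first threshold -> everyone scores 4
  expect_true(all(simulate_observer_scores(rep(0.2, 5), osp) == 4L))
  # perfect agreement in the noiseless limit
  ge <- seq(0.2, 3.8, length.out = 16)
  sc2 <- simulate_observer_scores(ge, observer_spec(2, c(1, 2, 3), 1e-9, seed = 1))
  expect_equal(krippendorff_alpha(sc2), 1)
  # latent-model oracle: empirical P(score = 4 | metric) vs the logistic
  # closed form, monotone nonincreasing over 5 metric values
  osp3 <- observer_spec(2, c(1, 2, 3), noise_scale = 0.5, seed = 21)
  ms <- c(0.2, 0.8, 1.4, 2.0, 2.6)
  emp <- sapply(ms, function(m) {
    s <- simulate_observer_scores(rep(m, 2000),
                                  observer_spec(2, c(1, 2, 3), 0.5,
                                                seed = round(1000 * m)))
    mean(s == 4L)
  })
  expect_true(all(diff(emp) < 0))
  theo <- sapply(ms, function(m) observer_score_probs(m, osp3)[4])
  expect_lt(max(abs(emp - theo)), 0.05)
  # exact probabilities sum to 1
  expect_equal(sum(observer_score_probs(1.7, osp3)), 1)
})
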