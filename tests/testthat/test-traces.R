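test_that("single-octave fractal noise interpolates its control points", {
  # one octave, weight 1: the curve is the cubic interpolant of the drawn
  # controls (up to the demeaning constant)
  # octave 1 has 2^1 + 1 = 3 controls; with 5 samples they land on the lattice
  tr1 <- fractal_noise(5, weight = 1, n_octaves = 1, seed = 42)
  set.seed(42)
  ctrl <- runif(3, -1, 1)
  at_knots <- tr1[c(1, 3, 5)]
  expect_equal(diff(at_knots), diff(ctrl), tolerance = 1e-12)
  expect_equal(mean(tr1), 0, tolerance = 1e-12)
  # determinism
  expect_identical(fractal_noise(64, 0.65, 3, seed = 7),
                   fractal_noise(64, 0.65, 3, seed = 7))
})

test_that("more octaves shift spectral energy to high frequencies", {
  hf <- function(noct) mean(sapply(1:50, function(s) {
    x <- fractal_noise(128, 0.65, noct, seed = s)
    p <- Mod(fft(x))^2
    mean(p[33:64])  # upper half of the positive-frequency band
  }))
  expect_gt(hf(8), hf(3))
})

test_that("generated traces hit their RMS targets exactly", {
  sp <- trace_spec(64, "smooth", target_rms_rot_deg = 2.5,
                   target_rms_trans_mm = 4, seed = 3)
  tr <- make_motion_trace(sp)
  r <- rms_motion(tr)
  expect_equal(unname(r["rms_rot_deg"]), 2.5, tolerance = 1e-9)
  expect_equal(unname(r["rms_trans_mm"]), 4, tolerance = 1e-9)
  # zero targets give the identically zero trace with zero FD
  z <- make_motion_trace(trace_spec(16, "rough", 0, 0, seed = 1))
  expect_true(all(as.matrix(z) == 0))
  expect_equal(framewise_displacement(z)$mean_fd, 0)
})

test_that("RMS magnitude follows the per-channel-then-average definition", {
  mk <- function(m) { df <- as.data.frame(m); names(df) <- c("tx","ty","tz","rx","ry","rz"); df }
  const <- mk(matrix(rep(c(3, 3, 3, 0, 0, 0), each = 8), 8, 6))
  expect_equal(unname(rms_motion(const)["rms_trans_mm"]), 3)
  # single-channel square wave +-a: per-channel RMS a, averaged over 3 -> a/3
  sq <- mk(cbind(rep(c(2, -2), 8), 0, 0, 0, 0, 0))
  expect_equal(unname(rms_motion(sq)["rms_trans_mm"]), 2 / 3)
  zero <- mk(matrix(0, 4, 6))
  expect_equal(unname(rms_motion(zero)), c(0, 0))
})

test_that("framewise displacement matches its closed forms and invariances", {
  mk <- function(m) { df <- as.data.frame(m); names(df) <- c("tx","ty","tz","rx","ry","rz"); df }
  # single +1 deg step in rx: arc length on the 50 mm sphere
  tr <- mk(matrix(0, 3, 6)); tr$rx[2:3] <- 1
  fd <- framewise_displacement(tr)
  expect_equal(fd$fd_series, c(50 * pi / 180, 0), tolerance = 1e-12)
  # single (1,1,1) mm step: sum of absolute translations
  tr2 <- mk(matrix(0, 2, 6)); tr2[2, 1:3] <- 1
  expect_equal(framewise_displacement(tr2)$fd_series, 3)
  # constant trace -> 0
  expect_equal(framewise_displacement(mk(matrix(2, 5, 6)))$mean_fd, 0)
  expect_error(framewise_displacement(mk(matrix(0, 1, 6))), "length >= 2")
  # offset invariance for FD (not for RMS) and linear amplitude scaling
  tr3 <- make_motion_trace(trace_spec(32, "rough", 2, 2, seed = 9))
  tr3b <- tr3; tr3b$ty <- tr3b$ty + 5
  expect_equal(framewise_displacement(tr3b)$mean_fd,
               framewise_displacement(tr3)$mean_fd, tolerance = 1e-12)
  expect_gt(rms_motion(tr3b)["rms_trans_mm"], rms_motion(tr3)["rms_trans_mm"])
  tr3c <- tr3; tr3c[] <- 3 * as.matrix(tr3)
  expect_equal(framewise_displacement(tr3c)$mean_fd,
               3 * framewise_displacement(tr3)$mean_fd, tolerance = 1e-12)
})

test_that("rough traces carry more framewise displacement than smooth at matched RMS", {
  wins <- sapply(1:20, function(s) {
    a <- framewise_displacement(make_motion_trace(trace_spec(64, "smooth", 2, 2, seed = s)))$mean_fd
    b <- framewise_displacement(make_motion_trace(trace_spec(64, "rough", 2, 2, seed = s)))$mean_fd
    b > a
  })
  expect_gte(sum(wins), 19)
})

test_that("the default trace set reproduces the study counts", {
  specs <- make_trace_specs()
  expect_length(specs, 192)
  expect_equal(sum(sapply(specs, function(s) s$kind == "smooth")), 96)
  expect_equal(sum(sapply(specs, function(s) s$kind == "rough")), 96)
  # 3 datasets -> 576 total
  expect_equal(3 * length(specs), 576)
})
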