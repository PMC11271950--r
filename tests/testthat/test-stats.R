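test_that("Krippendorff's alpha matches a hand-computed coincidence-matrix oracle", {
  expect_equal(krippendorff_alpha(cbind(c(1, 2, 3, 4, 2), c(1, 2, 3, 4, 2))), 1)
  expect_error(krippendorff_alpha(cbind(rep(2, 4), rep(2, 4))), "no variance")

  # 4-image 2-observer toy table, ordinal metric, computed independently here
  toy <- cbind(c(1, 2, 3, 3), c(2, 2, 3, 4))
  vals <- 1:4
  co <- matrix(0, 4, 4)
  for (u in 1:4) {
    r <- toy[u, ]
    for (a in 1:2) for (b in 1:2) if (a != b)
      co[r[a], r[b]] <- co[r[a], r[b]] + 1  # m_u - 1 = 1
  }
  ncv <- rowSums(co)
  n <- sum(ncv)
  d2 <- matrix(0, 4, 4)
  for (a in 1:4) for (b in 1:4) if (a != b) {
    lo <- min(a, b); hi <- max(a, b)
    d2[a, b] <- (sum(ncv[lo:hi]) - (ncv[a] + ncv[b]) / 2)^2
  }
  alpha_hand <- 1 - (sum(co * d2) / n) / (sum(outer(ncv, ncv) * d2) / (n * (n - 1)))
  expect_equal(krippendorff_alpha(toy), alpha_hand, tolerance = 1e-12)
  # strong agreement on a larger simulated panel rates as highly reliable
  sc <- simulate_observer_scores(seq(0, 4, length.out = 192),
                                 observer_spec(2, c(1, 2, 3), 0.05, seed = 2))
  expect_gt(krippendorff_alpha(sc), 0.8)
})

test_that("the category model recovers known cutpoints and yields proper probabilities", {
  set.seed(31)
  ge <- runif(400, 0, 4)
  sc <- simulate_observer_scores(ge, observer_spec(2, c(1, 2, 3), 0.08, seed = 1))
  fm <- fit_category_model(ge, sc)
  # generating thresholds recovered within one grid step of the metric range
  step <- diff(range(ge)) / 100
  expect_lt(max(abs(fm$category_intercepts - c(1, 2, 3))), 5 * step)
  expect_true(all(diff(fm$category_intercepts) > 0))
  # probabilities sum to 1 across the metric axis
  pp <- fm$prob_fun(seq(0, 4, length.out = 11))
  expect_equal(rowSums(pp), rep(1, 11), tolerance = 1e-8)
  # P(category 4) monotone nonincreasing
  p4 <- fm$prob_fun(seq(0, 4, length.out = 101))[, "4"]
  expect_true(all(diff(p4) <= 1e-12))
  # the ordinal (proportional-odds) variant locates the same cutpoints
  fmo <- suppressWarnings(fit_category_model(ge, sc, model = "ordinal"))
  expect_lt(max(abs(fmo$category_intercepts - c(1, 2, 3))), 5 * step)
  # mirrored data gives mirrored curves
  fm2 <- fit_category_model(-ge, 5L - sc)
  expect_equal(unname(sort(-fm2$category_intercepts)),
               unname(sort(fm$category_intercepts)), tolerance = 5 * step)
})

test_that("one-way ANOVA agrees with the textbook formula and separates categories", {
  # two groups, hand-sized: direct F computation
  g1 <- c(1, 2, 3); g2 <- c(5, 6, 7)
  res <- one_way_anova(c(g1, g2), c(1L, 1L, 1L, 2L, 2L, 2L))
  gm <- mean(c(g1, g2))
  ssb <- 3 * (mean(g1) - gm)^2 + 3 * (mean(g2) - gm)^2
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  expect_equal(res$F, (ssb / 1) / (ssw / 4), tolerance = 1e-12)
  # identical group means -> tiny F, large p
  res2 <- one_way_anova(c(1, 2, 3, 1, 2, 3), c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_gt(res2$p, 0.5)
  # strongly separated synthetic categories -> p < 0.001
  set.seed(8)
  ge <- runif(288, 0, 4)
  sc <- simulate_observer_scores(ge, observer_spec(2, c(1, 2, 3), 0.15, seed = 3))
  expect_lt(one_way_anova(ge, sc)$p, 0.001)
})

test_that("the RMS model recovers exact coefficients and selects by BIC", {
  set.seed(12)
  rot <- runif(96, 0, 20); trans <- runif(96, 0, 40)
  y <- 1 + 0.1 * rot + 0.2 * trans
  f <- fit_rms_model(y, rot, trans)
  expect_equal(unname(coef(f$model)), c(1, 0.1, 0.2), tolerance = 1e-8)
  expect_identical(f$selected, "no_interaction")
  expect_lt(abs(f$interaction$coefficients["rot:trans"]), 1e-8)
  # R^2 equals its definition
  yn <- y + rnorm(96, 0, 0.2)
  fn <- fit_rms_model(yn, rot, trans)
  rss <- sum(resid(fn$no_interaction$fit)^2)
  expect_equal(fn$no_interaction$r_squared, 1 - rss / sum((yn - mean(yn))^2))
})

test_that("BIC detects a true interaction in most repeated draws", {
  picks <- sapply(1:50, function(s) {
    set.seed(s)
    rot <- runif(96, 0, 20); trans <- runif(96, 0, 40)
    y <- 1 + 0.1 * rot + 0.2 * trans + 0.05 * rot * trans + rnorm(96, 0, 0.3)
    fit_rms_model(y, rot, trans)$selected == "interaction"
  })
  expect_gte(mean(picks), 0.9)
})

test_that("RMS boundaries invert the fitted plane and clip unreachable categories", {
  set.seed(2)
  rot <- runif(50, 0, 20); trans <- runif(50, 0, 40)
  f <- fit_rms_model(1 + 0.5 * rot + 0.25 * trans, rot, trans)
  b <- invert_rms_boundary(f, 2)
  expect_equal(b$rot_boundary_deg, 2, tolerance = 1e-8)
  expect_equal(b$trans_boundary_mm, 4, tolerance = 1e-8)
  expect_false(b$rot_unreachable)
  # threshold below the intercept: clipped to zero and flagged
  b0 <- invert_rms_boundary(f, 0.5)
  expect_equal(b0$rot_boundary_deg, 0)
  expect_true(b0$rot_unreachable)
  # boundaries monotone across increasing thresholds
  th <- c(2, 3, 4)
  rb <- sapply(th, function(t) invert_rms_boundary(f, t)$rot_boundary_deg)
  expect_true(all(diff(rb) > 0))
})

test_that("FD models recover exact parameters and the log model wins on log-truth data", {
  set.seed(77)
  fd <- runif(96, 0.05, 2)
  ge <- 1 + 0.3 * log(fd - 0.02)
  f <- fit_fd_models(ge, fd)
  expect_equal(f$logarithmic$a, 1, tolerance = 1e-6)
  expect_equal(f$logarithmic$b, 0.3, tolerance = 1e-6)
  expect_equal(f$logarithmic$c, 0.02, tolerance = 1e-6)
  # algebraic inversion round-trips every observation
  expect_equal(invert_fd_boundary(f$logarithmic, ge[5]), fd[5], tolerance = 1e-5)
  # linear fit on linear-truth data recovers the slope exactly
  gl <- 0.5 + 0.7 * fd
  fl <- fit_fd_models(gl, fd)
  expect_equal(fl$linear$b, 0.7, tolerance = 1e-8)
  # model comparison: log-truth data favors the log model nearly always
  wins <- sapply(1:50, function(s) {
    set.seed(1000 + s)
    fd <- runif(96, 0.05, 2)
    ge <- 1 + 0.3 * log(fd - 0.02) + rnorm(96, 0, 0.02)
    ff <- fit_fd_models(ge, fd)
    ff$logarithmic$r_squared > ff$linear$r_squared
  })
  expect_gte(mean(wins), 0.95)
})

test_that("the synthetic scoring round trip closes: cutpoints to boundaries", {
  set.seed(55)
  rot <- runif(200, 0, 20); trans <- 2 * rot + runif(200, -2, 2)
  trans <- pmax(trans, 0)
  ge <- 1 + 0.1 * rot + 0.05 * trans   # known linear GE surface
  sc <- simulate_observer_scores(ge, observer_spec(2, quantile(ge, c(0.25, 0.5, 0.75)),
                                                   0.05, seed = 6))
  fm <- fit_category_model(ge, sc)
  step <- diff(range(ge)) / 50
  expect_lt(max(abs(fm$category_intercepts -
                      quantile(ge, c(0.25, 0.5, 0.75)))), step)
  f <- fit_rms_model(ge, rot, trans)
  b <- invert_rms_boundary(f, fm$category_intercepts[1])
  truth <- (quantile(ge, 0.25) - 1) / 0.1
  expect_lt(abs(b$rot_boundary_deg - truth) / truth, 0.05)
})
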