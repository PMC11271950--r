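test_that("the default motion grid reproduces the study combinatorics", {
  g <- make_motion_grid()
  rot_only <- unique(g[, c("rx", "ry", "rz")])
  expect_equal(nrow(rot_only), 125)
  expect_equal(sum(g$tz < 0), 100)
  expect_equal(nrow(g), 225)
  # first block pairs nonnegative-z translations index-to-index; the
  # negative-z block re-uses rotation sets cyclically
  expect_equal(attr(g, "pair_index")[1:125], 1:125)
  expect_equal(attr(g, "pair_index")[126:225], 1:100)
  # deterministic lexicographic ordering
  expect_identical(g, make_motion_grid())
  expect_equal(g$rx[1:25], rep(0, 25))
  # translation sets cover the full factorial including signed z
  expect_equal(nrow(unique(g[, c("tx", "ty", "tz")])), 225)
})

test_that("scaled grids keep the pairing structure", {
  g <- fx_grid_small()
  expect_equal(nrow(g), 27 + 18)
  expect_equal(sum(g$tz < 0), 18)
  expect_equal(nrow(unique(g[, c("rx", "ry", "rz")])), 27)
})

test_that("corrupting at the zero pose reproduces the reference reconstruction", {
  fat <- fx_nav16()$fat
  cm <- fx_maps16()
  sch <- sampling_scheme(4, 4, c(20, 32), dim(fat))
  w <- fx("w16_r4", calibrate_grappa(
    extract_acs(simulate_multicoil_kspace(fat, cm), c(20, 32)), sch))
  a <- corrupt_fatnav(fat, cm, rigid_pose(), w, sch)
  b <- corrupt_fatnav(fat, cm, rigid_pose(), w, sch)
  expect_identical(a, b)
  # an extreme pose degrades strictly more than no motion
  extreme <- corrupt_fatnav(fat, cm, rigid_pose(40, 0, 0, 20, 0, 0), w, sch)
  expect_gt(nrmse(extreme, a), 0)
})

test_that("residual interpolation is exact at nodes and linear between them", {
  # hand-built averaged table on a tiny factorial grid
  rl <- c(0, 10); tl <- c(0, 20); zl <- c(-20, 0, 20)
  g <- expand.grid(rx = rl, ry = rl, rz = rl)
  gt <- expand.grid(tx = tl, ty = tl, tz = zl)
  n <- max(nrow(g), nrow(gt))
  tab <- data.frame(dataset = "avg", grid_index = seq_len(n))
  gg <- g[rep(seq_len(nrow(g)), length.out = n), ]
  tt <- gt[rep(seq_len(nrow(gt)), length.out = n), ]
  tab[paste0("applied_", c("tx", "ty", "tz"))] <- tt
  tab[paste0("applied_", c("rx", "ry", "rz"))] <- gg
  # residuals defined by simple known functions of the applied pose
  tab$residual_rx <- 0.1 * tab$applied_rx
  tab$residual_ry <- 0.05 * tab$applied_ry
  tab$residual_rz <- 0
  tab$residual_tx <- 0.02 * tab$applied_tx
  tab$residual_ty <- 0
  tab$residual_tz <- 0.03 * tab$applied_tz
  for (p in c("tx", "ty", "tz", "rx", "ry", "rz"))
    tab[[paste0("estimated_", p)]] <- tab[[paste0("applied_", p)]] -
      tab[[paste0("residual_", p)]]
  tab$failed <- FALSE
  attr(tab, "rot_levels") <- rl; attr(tab, "trans_levels") <- tl
  attr(tab, "tz_levels") <- zl
  class(tab) <- c("residual_table", "data.frame")

  mk <- function(v) { df <- as.data.frame(matrix(v, 1)); names(df) <- c("tx","ty","tz","rx","ry","rz"); df }
  # node query returns the node residual exactly
  at_node <- interpolate_residual(tab, mk(c(20, 0, -20, 10, 10, 0)))
  expect_equal(as.numeric(at_node), c(0.4, 0, -0.6, 1, 0.5, 0), tolerance = 1e-12)
  # zero-motion query -> zero residual
  expect_equal(as.numeric(interpolate_residual(tab, mk(rep(0, 6)))), rep(0, 6))
  # midpoint along one axis: arithmetic mean of the two node residuals
  mid <- interpolate_residual(tab, mk(c(10, 0, 0, 0, 0, 0)))
  expect_equal(mid$tx, (0 + 0.4) / 2, tolerance = 1e-12)
  mid2 <- interpolate_residual(tab, mk(c(0, 0, 0, 5, 0, 0)))
  expect_equal(mid2$rx, (0 + 1) / 2, tolerance = 1e-12)
  # signs re-applied on symmetric axes
  neg <- interpolate_residual(tab, mk(c(-20, 0, 0, -10, 0, 0)))
  expect_equal(neg$tx, -0.4, tolerance = 1e-12)
  expect_equal(neg$rx, -1, tolerance = 1e-12)
  # outside the hull: clamped with a warning
  expect_warning(interpolate_residual(tab, mk(c(50, 0, 0, 0, 0, 0))), "clamped")
})

test_that("the averaged residual block is the mean of the per-dataset residuals", {
  tab <- fx_tab_r16()
  per <- tab[tab$dataset != "avg" & !tab$failed, ]
  avg <- tab[tab$dataset == "avg", ]
  for (g_i in c(1, 10, 30)) {
    sub <- per[per$grid_index == g_i, ]
    expect_equal(avg$residual_rx[avg$grid_index == g_i], mean(sub$residual_rx))
    expect_equal(avg$residual_tz[avg$grid_index == g_i], mean(sub$residual_tz))
  }
  # residual = applied - estimated componentwise
  expect_equal(per$residual_ty, per$applied_ty - per$estimated_ty)
})
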