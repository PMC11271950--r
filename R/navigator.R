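#' Build the motion grid of applied poses
#'
#' Rotation combinations are the full factorial of `rot_levels` over
#' (rx, ry, rz); translation combinations are the factorial of
#' `trans_levels` over (tx, ty) with tz running over `trans_levels` and,
#' when `negative_z = TRUE`, its nonzero values negated as well (movement
#' towards the feet). The nonnegative-z translation sets are paired
#' index-to-index with the rotation sets; the negative-z sets are paired by
#' cyclic index. With the default levels (0, 5, 10, 15, 20 deg and 0..40 mm
#' by 10) this yields 125 rotation sets, 125 + 100 translation sets and 225
#' paired entries. Ordering is lexicographic and deterministic.
#'
#' @param rot_levels nonnegative rotation magnitudes (deg).
#' @param trans_levels nonnegative translation magnitudes (mm).
#' @param negative_z also apply nonzero z-translations in the negative sense.
#' @return data.frame of class `motion_grid` with columns
#'   rx, ry, rz, tx, ty, tz and attributes `rot_levels`, `trans_levels`,
#'   `tz_levels`, `pair_index`.
#' @export
make_motion_grid <- function(rot_levels = c(0, 5, 10, 15, 20),
                             trans_levels = c(0, 10, 20, 30, 40),
                             negative_z = TRUE) {
  stopifnot(all(rot_levels >= 0), all(trans_levels >= 0),
            rot_levels[1] == 0, trans_levels[1] == 0)
  rot <- expand.grid(rx = rot_levels, ry = rot_levels, rz = rot_levels,
                     KEEP.OUT.ATTRS = FALSE)
  rot <- rot[order(rot$rx, rot$ry, rot$rz), ]
  pos <- expand.grid(tx = trans_levels, ty = trans_levels, tz = trans_levels,
                     KEEP.OUT.ATTRS = FALSE)
  pos <- pos[order(pos$tx, pos$ty, pos$tz), ]
  n_rot <- nrow(rot)
  grid <- cbind(rot, pos)
  pair <- seq_len(n_rot)
  if (negative_z) {
    negz <- trans_levels[trans_levels > 0]
    neg <- expand.grid(tx = trans_levels, ty = trans_levels, tz = -negz,
                       KEEP.OUT.ATTRS = FALSE)
    neg <- neg[order(neg$tx, neg$ty, neg$tz), ]
    cyc <- ((seq_len(nrow(neg)) - 1) %% n_rot) + 1
    grid <- rbind(grid, cbind(rot[cyc, ], neg))
    pair <- c(pair, cyc)
  }
  rownames(grid) <- NULL
  grid <- grid[, c("rx", "ry", "rz", "tx", "ty", "tz")]
  attr(grid, "rot_levels") <- rot_levels
  attr(grid, "trans_levels") <- trans_levels
  attr(grid, "tz_levels") <- sort(unique(grid$tz))
  attr(grid, "pair_index") <- pair
  class(grid) <- c("motion_grid", "data.frame")
  grid
}

#' Corrupt a fat-navigator volume through the fixed-calibration pipeline
#'
#' Emulates what the scanner would produce if the head moved after
#' calibration: rigid transform of the navigator, multiplication by the coil
#' maps, centered FFT, Cartesian undersampling at the scheme, GRAPPA
#' synthesis with weights calibrated once at the unmoved pose, RSS
#' combination. Deterministic.
#'
#' @param fat_volume 3D complex navigator image (unmoved reference).
#' @param coil_maps complex 4D coil sensitivities on the navigator grid.
#' @param pose applied [rigid_pose()].
#' @param weights `grappa_weights` calibrated from the unmoved reference.
#' @param scheme a [sampling_scheme()].
#' @param voxel_mm navigator voxel size (mm).
#' @return real 3D corrupted magnitude volume.
#' @export
corrupt_fatnav <- function(fat_volume, coil_maps, pose, weights, scheme,
                           voxel_mm = c(4, 4, 4)) {
  d <- dim(coil_maps)
  moved <- apply_rigid(fat_volume, pose, voxel_mm)
  ksp <- array(0 + 0i, dim = d)
  for (c_i in seq_len(d[4]))
    ksp[, , , c_i] <- centered_fft3(moved * coil_maps[, , , c_i])
  mask <- make_sampling_mask(scheme, include_acs = FALSE)
  ksp <- ksp * array(rep(mask, d[4]), dim = d)
  grappa_reconstruct(ksp, weights, scheme, acs_present = FALSE)
}

#' Tabulate navigator tracking accuracy over the motion grid
#'
#' For each grid entry and dataset: corrupt the navigator at the applied
#' pose, register the corrupted volume to the zero-pose reference
#' reconstruction, and record the residual pose (applied - estimated). An
#' averaged block (dataset `"avg"`) holds the arithmetic mean of the
#' per-dataset residuals. Failed registrations are recorded and excluded
#' from the average.
#'
#' @param datasets list of datasets, each a list with elements `fat`
#'   (3D complex navigator), `coil_maps` (4D complex), `voxel_mm`.
#' @param grid a [make_motion_grid()] grid.
#' @param scheme a [sampling_scheme()].
#' @param kernel a [grappa_kernel_spec()].
#' @param verbose print per-row progress.
#' @return data.frame of class `residual_table`: columns dataset, grid
#'   coordinates, applied/estimated/residual parameters, `failed`; averaged
#'   rows have `dataset == "avg"`. Grid attributes are carried over.
#' @export
tracking_accuracy_table <- function(datasets, grid, scheme,
                                    kernel = grappa_kernel_spec(),
                                    verbose = FALSE) {
  stopifnot(length(datasets) >= 1)
  par_names <- c("tx", "ty", "tz", "rx", "ry", "rz")
  rows <- list()
  for (ds_i in seq_along(datasets)) {
    ds <- datasets[[ds_i]]
    acs <- extract_acs(simulate_multicoil_kspace(ds$fat, ds$coil_maps),
                       scheme$acs_size)
    weights <- if (scheme$accel_y > 1 || scheme$accel_z > 1)
      calibrate_grappa(acs, scheme, kernel)
    else
      structure(list(weights = list(), scheme = scheme, kernel = kernel,
                     n_coils = dim(ds$coil_maps)[4], residuals = numeric(0)),
                class = "grappa_weights")
    reference <- corrupt_fatnav(ds$fat, ds$coil_maps, rigid_pose(), weights,
                                scheme, ds$voxel_mm)
    for (g_i in seq_len(nrow(grid))) {
      pose <- rigid_pose(grid$tx[g_i], grid$ty[g_i], grid$tz[g_i],
                         grid$rx[g_i], grid$ry[g_i], grid$rz[g_i])
      corrupted <- corrupt_fatnav(ds$fat, ds$coil_maps, pose, weights,
                                  scheme, ds$voxel_mm)
      est <- tryCatch(
        suppressWarnings(register_rigid(corrupted, reference, ds$voxel_mm)),
        error = function(e) NULL)
      failed <- is.null(est)
      if (failed) est <- rigid_pose(NA, NA, NA, NA, NA, NA)
      row <- data.frame(dataset = as.character(ds_i), grid_index = g_i)
      row[paste0("applied_", par_names)] <- as.numeric(pose)[c(1:3, 4:6)]
      row[paste0("estimated_", par_names)] <- as.numeric(est)
      row[paste0("residual_", par_names)] <- as.numeric(pose) - as.numeric(est)
      row$failed <- failed
      rows[[length(rows) + 1]] <- row
      if (verbose)
        message(sprintf("dataset %d grid %d/%d done", ds_i, g_i, nrow(grid)))
    }
  }
  tab <- do.call(rbind, rows)
  n_failed <- sum(tab$failed)
  if (n_failed > 0)
    message(sprintf("tracking_accuracy_table: %d registrations failed and were excluded from the average", n_failed))
  # average across datasets per grid entry
  avg_rows <- lapply(seq_len(nrow(grid)), function(g_i) {
    sub <- tab[tab$grid_index == g_i & !tab$failed, , drop = FALSE]
    row <- data.frame(dataset = "avg", grid_index = g_i)
    row[paste0("applied_", par_names)] <-
      as.numeric(grid[g_i, c("tx", "ty", "tz", "rx", "ry", "rz")])
    for (p in par_names) {
      row[[paste0("estimated_", p)]] <- mean(sub[[paste0("estimated_", p)]])
      row[[paste0("residual_", p)]] <- mean(sub[[paste0("residual_", p)]])
    }
    row$failed <- nrow(sub) == 0
    row
  })
  tab <- rbind(tab, do.call(rbind, avg_rows))
  attr(tab, "rot_levels") <- attr(grid, "rot_levels")
  attr(tab, "trans_levels") <- attr(grid, "trans_levels")
  attr(tab, "tz_levels") <- attr(grid, "tz_levels")
  class(tab) <- c("residual_table", "data.frame")
  tab
}

# trilinear interpolation on a regular (possibly nonuniform-level) 3D grid;
# vals is an array indexed by the three level vectors; queries outside the
# hull are clamped to the boundary
interp3_regular <- function(levels1, levels2, levels3, vals, q1, q2, q3) {
  locate <- function(lv, q) {
    q <- pmin(max(lv), pmax(min(lv), q))
    i <- findInterval(q, lv, rightmost.closed = TRUE)
    i <- pmin(pmax(i, 1L), length(lv) - 1L)
    t <- (q - lv[i]) / (lv[i + 1] - lv[i])
    list(i = i, t = t)
  }
  if (length(levels1) == 1) { l1 <- list(i = rep(1L, length(q1)), t = rep(0, length(q1))) } else l1 <- locate(levels1, q1)
  if (length(levels2) == 1) { l2 <- list(i = rep(1L, length(q2)), t = rep(0, length(q2))) } else l2 <- locate(levels2, q2)
  if (length(levels3) == 1) { l3 <- list(i = rep(1L, length(q3)), t = rep(0, length(q3))) } else l3 <- locate(levels3, q3)
  n1 <- length(levels1); n2 <- length(levels2)
  gi <- function(i1, i2, i3) vals[cbind(i1, i2, i3)]
  i1 <- l1$i; i2 <- l2$i; i3 <- l3$i
  u1 <- pmin(i1 + 1L, length(levels1)); u2 <- pmin(i2 + 1L, length(levels2))
  u3 <- pmin(i3 + 1L, length(levels3))
  t1 <- l1$t; t2 <- l2$t; t3 <- l3$t
  c00 <- gi(i1, i2, i3) * (1 - t1) + gi(u1, i2, i3) * t1
  c10 <- gi(i1, u2, i3) * (1 - t1) + gi(u1, u2, i3) * t1
  c01 <- gi(i1, i2, u3) * (1 - t1) + gi(u1, i2, u3) * t1
  c11 <- gi(i1, u2, u3) * (1 - t1) + gi(u1, u2, u3) * t1
  (c00 * (1 - t2) + c10 * t2) * (1 - t3) + (c01 * (1 - t2) + c11 * t2) * t3
}

# arrange averaged residuals on the factorial grids: rotations on the
# (rx, ry, rz) level grid, translations on the (tx, ty, tz-signed) grid
residual_lookup <- function(table) {
  avg <- table[table$dataset == "avg" & !table$failed, , drop = FALSE]
  rl <- attr(table, "rot_levels"); tl <- attr(table, "trans_levels")
  zl <- attr(table, "tz_levels")
  rot_arr <- lapply(c("rx", "ry", "rz"), function(p) {
    a <- array(NA_real_, dim = c(length(rl), length(rl), length(rl)))
    i <- cbind(match(avg$applied_rx, rl), match(avg$applied_ry, rl),
               match(avg$applied_rz, rl))
    v <- avg[[paste0("residual_", p)]]
    # average duplicates (rotation sets reused by the negative-z pairing)
    for (k in seq_len(nrow(i))) {
      prev <- a[i[k, , drop = FALSE]]
      a[i[k, , drop = FALSE]] <- if (is.na(prev)) v[k] else (prev + v[k]) / 2
    }
    a
  })
  tr_arr <- lapply(c("tx", "ty", "tz"), function(p) {
    a <- array(NA_real_, dim = c(length(tl), length(tl), length(zl)))
    i <- cbind(match(avg$applied_tx, tl), match(avg$applied_ty, tl),
               match(avg$applied_tz, zl))
    v <- avg[[paste0("residual_", p)]]
    a[i] <- v
    a
  })
  list(rot = rot_arr, trans = tr_arr, rot_levels = rl, trans_levels = tl,
       tz_levels = zl)
}

#' Interpolate expected residual motion for a query trace
#'
#' Linearly interpolates the averaged tracking-accuracy table at each query
#' pose: the rotational residual triple on the (rx, ry, rz) magnitude grid
#' and the translational triple on the (tx, ty, tz) grid (z signed, other
#' axes by magnitude with the query's signs re-applied). Queries outside the
#' grid hull are clamped to the boundary with a warning.
#'
#' @param table a `residual_table` from [tracking_accuracy_table()].
#' @param query_trace a `motion_trace` (or single-row pose data.frame).
#' @return residual `motion_trace` with the same number of rows.
#' @export
interpolate_residual <- function(table, query_trace) {
  if (nrow(table[table$dataset == "avg", ]) == 0) stop("empty residual table")
  lk <- residual_lookup(table)
  q <- as.data.frame(query_trace)
  hull_max_r <- max(lk$rot_levels)
  hull_max_t <- max(lk$trans_levels)
  if (any(abs(q[, c("rx", "ry", "rz")]) > hull_max_r) ||
      any(abs(q[, c("tx", "ty")]) > hull_max_t) ||
      any(q$tz > max(lk$tz_levels)) || any(q$tz < min(lk$tz_levels)))
    warning("query motion outside the grid hull; clamped to the boundary")
  out <- q[, c("tx", "ty", "tz", "rx", "ry", "rz")]
  for (j in 1:3) {
    p <- c("rx", "ry", "rz")[j]
    val <- interp3_regular(lk$rot_levels, lk$rot_levels, lk$rot_levels,
                           lk$rot[[j]], abs(q$rx), abs(q$ry), abs(q$rz))
    out[[p]] <- ifelse(q[[p]] == 0, val, sign(q[[p]]) * val)
  }
  for (j in 1:3) {
    p <- c("tx", "ty", "tz")[j]
    val <- interp3_regular(lk$trans_levels, lk$trans_levels, lk$tz_levels,
                           lk$trans[[j]], abs(q$tx), abs(q$ty), q$tz)
    out[[p]] <- if (p == "tz") val else ifelse(q[[p]] == 0, val, sign(q[[p]]) * val)
  }
  as_motion_trace(out)
}

#' Write/read a residual table as CSV
#'
#' @param table a `residual_table`.
#' @param path file path.
#' @export
write_residual_table_csv <- function(table, path) {
  df <- as.data.frame(table)
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(rot_levels = attr(table, "rot_levels"),
               trans_levels = attr(table, "trans_levels"),
               tz_levels = attr(table, "tz_levels"))
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname write_residual_table_csv
#' @export
read_residual_table_csv <- function(path) {
  df <- utils::read.csv(path)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  attr(df, "rot_levels") <- meta$rot_levels
  attr(df, "trans_levels") <- meta$trans_levels
  attr(df, "tz_levels") <- meta$tz_levels
  df$dataset <- as.character(df$dataset)
  class(df) <- c("residual_table", "data.frame")
  df
}
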