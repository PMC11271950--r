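#' Fractal (multi-octave) noise
#'
#' Sums `n_octaves` octaves of cubic-spline-interpolated random control
#' points: octave k has `2^k + 1` control points drawn uniformly in
#' \[-1, 1\] and amplitude `weight^k`. The result is demeaned. Seeded and
#' reproducible.
#'
#' @param n_points output length (>= 2).
#' @param weight octave amplitude decay, in (0, 1\].
#' @param n_octaves number of octaves (>= 1).
#' @param seed integer seed.
#' @return numeric vector of length `n_points` with zero mean.
#' @export
fractal_noise <- function(n_points, weight = 0.65, n_octaves = 3, seed = 1L) {
  stopifnot(n_points >= 2, weight > 0, weight <= 1, n_octaves >= 1)
  set.seed(seed)
  t_out <- seq(0, 1, length.out = n_points)
  out <- numeric(n_points)
  for (k in seq_len(n_octaves)) {
    n_ctrl <- 2^k + 1
    ctrl <- runif(n_ctrl, -1, 1)
    t_ctrl <- seq(0, 1, length.out = n_ctrl)
    f <- splinefun(t_ctrl, ctrl, method = "natural")
    out <- out + weight^k * f(t_out)
  }
  out - mean(out)
}

#' Specification of a fractal-noise motion trace
#'
#' @param n_points number of shots/navigators (>= 2).
#' @param kind `"smooth"` (slow drifts, 3 octaves) or `"rough"` (rapid abrupt
#'   changes, 8 octaves).
#' @param target_rms_rot_deg,target_rms_trans_mm nonnegative RMS targets for
#'   the rotation and translation channel groups.
#' @param weight octave decay in (0, 1).
#' @param n_octaves octave count; `NULL` uses the kind's default (3 or 8).
#' @param seed integer seed.
#' @return object of class `trace_spec`.
#' @export
trace_spec <- function(n_points, kind = c("smooth", "rough"),
                       target_rms_rot_deg = 2, target_rms_trans_mm = 2,
                       weight = 0.65, n_octaves = NULL, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n_points >= 2, weight > 0, weight < 1,
            target_rms_rot_deg >= 0, target_rms_trans_mm >= 0)
  if (is.null(n_octaves)) n_octaves <- if (kind == "smooth") 3L else 8L
  structure(list(n_points = as.integer(n_points), kind = kind,
                 target_rms_rot_deg = target_rms_rot_deg,
                 target_rms_trans_mm = target_rms_trans_mm,
                 weight = weight, n_octaves = as.integer(n_octaves),
                 seed = as.integer(seed)),
            class = "trace_spec")
}

#' Generate a 6-channel rigid motion trace
#'
#' Six independent fractal-noise channels (tx, ty, tz in mm; rx, ry, rz in
#' deg); the three translation channels are jointly rescaled so that
#' [rms_motion()] hits `target_rms_trans_mm` exactly, and likewise the
#' rotations. Deterministic per seed.
#'
#' @param spec a [trace_spec()].
#' @return data.frame of class `motion_trace` with columns
#'   tx, ty, tz, rx, ry, rz and one row per shot.
#' @export
make_motion_trace <- function(spec) {
  ch <- sapply(1:6, function(j)
    fractal_noise(spec$n_points, spec$weight, spec$n_octaves,
                  seed = spec$seed * 131L + j))
  colnames(ch) <- c("tx", "ty", "tz", "rx", "ry", "rz")
  rms_ch <- function(m) mean(sqrt(colMeans(m^2)))
  rt <- rms_ch(ch[, 1:3, drop = FALSE])
  rr <- rms_ch(ch[, 4:6, drop = FALSE])
  ch[, 1:3] <- if (spec$target_rms_trans_mm == 0 || rt == 0) 0 else
    ch[, 1:3] * (spec$target_rms_trans_mm / rt)
  ch[, 4:6] <- if (spec$target_rms_rot_deg == 0 || rr == 0) 0 else
    ch[, 4:6] * (spec$target_rms_rot_deg / rr)
  tr <- as.data.frame(ch)
  class(tr) <- c("motion_trace", "data.frame")
  tr
}

as_motion_trace <- function(df) {
  stopifnot(all(c("tx", "ty", "tz", "rx", "ry", "rz") %in% names(df)))
  df <- df[, c("tx", "ty", "tz", "rx", "ry", "rz")]
  class(df) <- c("motion_trace", "data.frame")
  df
}

#' Scalar RMS motion magnitude of a trace
#'
#' Per-channel root-mean-square over time, then the arithmetic mean over the
#' three channels of each group.
#'
#' @param trace a `motion_trace` data.frame.
#' @return named vector `c(rms_trans_mm, rms_rot_deg)`.
#' @export
rms_motion <- function(trace) {
  stopifnot(nrow(trace) >= 1)
  m <- as.matrix(trace[, c("tx", "ty", "tz", "rx", "ry", "rz")])
  c(rms_trans_mm = mean(sqrt(colMeans(m[, 1:3, drop = FALSE]^2))),
    rms_rot_deg = mean(sqrt(colMeans(m[, 4:6, drop = FALSE]^2))))
}

#' Framewise displacement of a motion trace
#'
#' Sum of absolute first differences of the six parameters, with rotation
#' differences converted to arc length on a sphere of `sphere_radius_mm`
#' (default 50 mm).
#'
#' @param trace a `motion_trace` with at least 2 rows.
#' @param sphere_radius_mm sphere radius used for the rotation arcs.
#' @return list with `fd_series` (length `nrow - 1`, mm) and `mean_fd` (mm).
#' @export
framewise_displacement <- function(trace, sphere_radius_mm = 50) {
  if (nrow(trace) < 2) stop("framewise displacement needs a trace of length >= 2")
  m <- as.matrix(trace[, c("tx", "ty", "tz", "rx", "ry", "rz")])
  dm <- abs(diff(m))
  fd <- rowSums(dm[, 1:3, drop = FALSE]) +
    sphere_radius_mm * rowSums(dm[, 4:6, drop = FALSE] * pi / 180)
  list(fd_series = as.numeric(fd), mean_fd = mean(fd))
}

#' Build the study's default trace set
#'
#' For each motion kind (smooth, rough), RMS levels are swept over
#' `n_levels` values spanning the study ranges (rotations up to 20 deg,
#' translations up to 40 mm, the two ladders paired by a seeded permutation
#' so both magnitudes vary independently across the set) and each level is
#' generated `n_repeats` times with independent seeds, emulating repeated
#' draws with the same magnitude but different k-space timing. Defaults give
#' 96 traces per kind, 192 per dataset.
#'
#' @param n_points shots per trace.
#' @param n_levels RMS levels per kind.
#' @param n_repeats independent draws per level.
#' @param max_rms_rot_deg,max_rms_trans_mm top of the RMS ranges.
#' @param seed base seed.
#' @return list of `trace_spec` objects of length `2 * n_levels * n_repeats`.
#' @export
make_trace_specs <- function(n_points = 64, n_levels = 24, n_repeats = 4,
                             max_rms_rot_deg = 20, max_rms_trans_mm = 40,
                             seed = 1L) {
  rot_levels <- seq(max_rms_rot_deg / n_levels, max_rms_rot_deg, length.out = n_levels)
  trans_levels <- seq(max_rms_trans_mm / n_levels, max_rms_trans_mm, length.out = n_levels)
  # pair the two level ladders by a seeded permutation so that rotational and
  # translational RMS are not collinear across the set (the RMS regression
  # needs both regressors identifiable)
  set.seed(seed)
  perm <- sample.int(n_levels)
  specs <- list()
  i <- 0L
  for (kind in c("smooth", "rough"))
    for (lev in seq_len(n_levels))
      for (rep_i in seq_len(n_repeats)) {
        i <- i + 1L
        specs[[i]] <- trace_spec(n_points, kind,
                                 target_rms_rot_deg = rot_levels[lev],
                                 target_rms_trans_mm = trans_levels[perm[lev]],
                                 seed = seed + 7919L * i)
      }
  specs
}

#' Read/write motion traces as CSV
#'
#' Plain CSV with header `tx,ty,tz,rx,ry,rz`, one row per shot, full decimal
#' serialization (world units mm and degrees).
#'
#' @param trace a `motion_trace`.
#' @param path file path.
#' @export
write_trace_csv <- function(trace, path) {
  df <- as.data.frame(trace)[, c("tx", "ty", "tz", "rx", "ry", "rz")]
  df[] <- lapply(df, function(x) sprintf("%.17g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  as_motion_trace(utils::read.csv(path))
}
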