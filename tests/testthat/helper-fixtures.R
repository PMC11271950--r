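# Shared fixtures, built lazily and cached for the whole test run. All data
# is generated in code; the heavier objects (navigator phantom, multi-coil
# k-space, scaled tracking tables) are computed once and reused across files.

.fx_cache <- new.env(parent = emptyenv())

fx <- function(name, expr) {
  if (!exists(name, envir = .fx_cache, inherits = FALSE))
    assign(name, expr, envir = .fx_cache)
  get(name, envir = .fx_cache, inherits = FALSE)
}

# default navigator phantom (48^3 at 4 mm, 8 coils)
fx_spec8 <- function() fx("spec8", phantom_spec())
fx_nav8 <- function() fx("nav8", make_head_phantom(fx_spec8(), "nav"))
fx_maps8 <- function() fx("maps8", make_coil_maps(fx_spec8(), "nav"))
fx_ksp8 <- function() fx("ksp8",
  simulate_multicoil_kspace(fx_nav8()$fat, fx_maps8()))
fx_ref_rss8 <- function() fx("ref_rss8", {
  ksp <- fx_ksp8()
  d <- dim(ksp)
  imgs <- array(0 + 0i, dim = d)
  for (c_i in seq_len(d[4])) imgs[, , , c_i] <- centered_ifft3(ksp[, , , c_i])
  rss_combine(imgs)
})

# 16-coil variant for the R = 4x4 navigator experiment
fx_spec16 <- function() fx("spec16", phantom_spec(n_coils = 16))
fx_nav16 <- function() fx("nav16", make_head_phantom(fx_spec16(), "nav"))
fx_maps16 <- function() fx("maps16", make_coil_maps(fx_spec16(), "nav"))

# scaled-down motion grid shared by the residual-pipeline checks
fx_grid_small <- function() fx("grid_small",
  make_motion_grid(c(0, 10, 20), c(0, 20, 40), negative_z = TRUE))

fx_dataset16 <- function() fx("dataset16",
  list(list(fat = fx_nav16()$fat, coil_maps = fx_maps16(),
            voxel_mm = fx_spec16()$nav_voxel_mm)))

# tracking-accuracy tables on the scaled grid: accelerated (R = 4x4,
# 16 coils, ACS 20x32) and unaccelerated baseline
fx_tab_r16 <- function() fx("tab_r16", {
  sch <- sampling_scheme(4, 4, c(20, 32), dim(fx_nav16()$fat))
  tracking_accuracy_table(fx_dataset16(), fx_grid_small(), sch)
})
fx_tab_r1 <- function() fx("tab_r1", {
  sch <- sampling_scheme(1, 1, c(20, 32), dim(fx_nav16()$fat))
  tracking_accuracy_table(fx_dataset16(), fx_grid_small(), sch)
})

residual_cols <- paste0("residual_", c("tx", "ty", "tz", "rx", "ry", "rz"))

# smaller target phantom for the corruption-arm comparisons
fx_spec_target <- function() fx("spec_target",
  phantom_spec(target_shape = c(64, 64, 64), target_voxel_mm = c(3, 3, 3),
               n_coils = 16))
fx_t1_small <- function() fx("t1_small",
  Re(make_head_phantom(fx_spec_target(), "target")$t1))
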