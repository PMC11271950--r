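#' Specification of the synthetic head phantom
#'
#' An analytic head: an ellipsoidal brain with CSF/GM/WM compartments (the
#' T1-weighted target) surrounded, after a skull gap, by a bright ellipsoidal
#' subcutaneous fat shell (the fat-navigator contrast). Two grids are carried:
#' a coarse navigator grid (default 48^3 at 4 mm) and a fine target grid
#' (default 96^3 at 2 mm; use 192^3 at 1 mm for full-scale runs).
#'
#' @param nav_shape integer triple, navigator grid.
#' @param target_shape integer triple, target grid.
#' @param nav_voxel_mm,target_voxel_mm positive voxel sizes (mm) per grid.
#' @param brain_semiaxes_mm positive triple, brain ellipsoid semiaxes (mm).
#' @param skull_gap_mm gap between brain surface and inner fat shell (mm).
#' @param fat_shell_thickness_mm fat shell thickness (mm).
#' @param intensity_fat,intensity_gm,intensity_wm,intensity_csf nonnegative
#'   tissue intensities (arbitrary units; defaults give T1-weighted contrast).
#' @param noise_sigma complex Gaussian noise std per channel, relative to the
#'   maximum signal (applied in k-space).
#' @param n_coils number of receive channels (>= 4).
#' @param seed integer seed for the stochastic pieces (noise).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(nav_shape = c(48, 48, 48),
                         target_shape = c(96, 96, 96),
                         nav_voxel_mm = c(4, 4, 4),
                         target_voxel_mm = c(2, 2, 2),
                         brain_semiaxes_mm = c(60, 72, 64),
                         skull_gap_mm = 10,
                         fat_shell_thickness_mm = 9,
                         intensity_fat = 1, intensity_gm = 0.65,
                         intensity_wm = 1, intensity_csf = 0.15,
                         noise_sigma = 0, n_coils = 8, seed = 1L) {
  stopifnot(length(nav_shape) == 3, length(target_shape) == 3,
            all(nav_voxel_mm > 0), all(target_voxel_mm > 0),
            all(brain_semiaxes_mm > 0), skull_gap_mm >= 0,
            fat_shell_thickness_mm >= 0,
            intensity_fat >= 0, intensity_gm >= 0, intensity_wm >= 0,
            intensity_csf >= 0, noise_sigma >= 0, n_coils >= 4)
  structure(list(nav_shape = as.integer(nav_shape),
                 target_shape = as.integer(target_shape),
                 nav_voxel_mm = nav_voxel_mm, target_voxel_mm = target_voxel_mm,
                 brain_semiaxes_mm = brain_semiaxes_mm,
                 skull_gap_mm = skull_gap_mm,
                 fat_shell_thickness_mm = fat_shell_thickness_mm,
                 intensity_fat = intensity_fat, intensity_gm = intensity_gm,
                 intensity_wm = intensity_wm, intensity_csf = intensity_csf,
                 noise_sigma = noise_sigma, n_coils = as.integer(n_coils),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# normalized ellipsoid radius (1 on the surface with semiaxes `semi`) at world
# mm coordinates; coords is a 3-column matrix
ellipsoid_rho <- function(coords, semi) {
  sqrt((coords[, 1] / semi[1])^2 + (coords[, 2] / semi[2])^2 + (coords[, 3] / semi[3])^2)
}

# world mm coordinates of every voxel center, origin at the volume center
grid_coords_mm <- function(shape, voxel_mm) {
  ax <- lapply(1:3, function(a) ((seq_len(shape[a]) - 1) - (shape[a] - 1) / 2) * voxel_mm[a])
  cbind(rep(ax[[1]], times = shape[2] * shape[3]),
        rep(rep(ax[[2]], each = shape[1]), times = shape[3]),
        rep(ax[[3]], each = shape[1] * shape[2]))
}

# linear edge ramp: 1 well inside [lo, hi] in rho units, 0 outside, with a
# transition of width w on each edge
edge_ramp <- function(rho, lo, hi, w) {
  up <- pmin(1, pmax(0, (rho - (lo - w / 2)) / w))
  dn <- pmin(1, pmax(0, ((hi + w / 2) - rho) / w))
  up * dn
}

#' Build the fat-navigator and T1-weighted head phantoms
#'
#' Voxelizes the analytic head on the requested grid. The fat volume is
#' nonzero only on the subcutaneous shell; the T1 volume is nonzero only
#' inside the brain ellipsoid; the two supports are disjoint by construction
#' (skull gap > one ramp width is enforced). Edges carry a 1-voxel
#' anti-aliasing ramp. Deterministic given the spec.
#'
#' @param spec a [phantom_spec()].
#' @param grid `"nav"` or `"target"`.
#' @return list with `fat` (complex 3D), `t1` (complex 3D), `labels` (integer
#'   3D: 0 background, 1 CSF, 2 GM, 3 WM, 4 fat), and `voxel_mm`.
#' @export
make_head_phantom <- function(spec, grid = c("nav", "target")) {
  grid <- match.arg(grid)
  shape <- if (grid == "nav") spec$nav_shape else spec$target_shape
  vox <- if (grid == "nav") spec$nav_voxel_mm else spec$target_voxel_mm
  if (spec$fat_shell_thickness_mm < max(vox))
    stop("fat shell unresolvable at this voxel size")
  semi <- spec$brain_semiaxes_mm
  co <- grid_coords_mm(shape, vox)
  rho <- ellipsoid_rho(co, semi)
  # shell bounds in rho units of the *brain* ellipsoid (additive mm offsets
  # along each semiaxis -> divide by the mean semiaxis for an isotropic ramp)
  sbar <- mean(semi)
  rho_in <- 1 + spec$skull_gap_mm / sbar
  rho_out <- rho_in + spec$fat_shell_thickness_mm / sbar
  w <- max(vox) / sbar  # 1-voxel ramp in rho units
  if (spec$skull_gap_mm < 2 * max(vox))
    stop("skull gap too small: fat and brain supports would overlap")

  fat <- spec$intensity_fat * edge_ramp(rho, rho_in, rho_out, w)

  # brain interior: WM core (rho < .55), GM (.55..,.88), CSF rim (.88..1)
  t1 <- numeric(length(rho))
  inside <- pmin(1, pmax(0, (1 - rho) / w + 0.5))
  wm <- pmin(1, pmax(0, (0.55 - rho) / w + 0.5))
  gm <- pmin(1, pmax(0, (0.88 - rho) / w + 0.5)) - wm
  csf <- inside - wm - gm
  t1 <- spec$intensity_wm * wm + spec$intensity_gm * gm + spec$intensity_csf * csf

  labels <- integer(length(rho))
  labels[rho < 1] <- 1L
  labels[rho < 0.88] <- 2L
  labels[rho < 0.55] <- 3L
  labels[fat > 0] <- 4L

  dim(fat) <- shape; dim(t1) <- shape; dim(labels) <- shape
  list(fat = fat + 0i, t1 = t1 + 0i, labels = labels, voxel_mm = vox)
}

#' Simulate smooth complex coil sensitivity maps
#'
#' Each channel has a Gaussian magnitude profile centered on one point of a
#' ring around the head in the x-y plane (alternating slightly above/below
#' the z midplane) and a linear phase pointing at the coil. The
#' root-sum-of-squares over coils is strictly positive everywhere.
#' Deterministic given the spec.
#'
#' @param spec a [phantom_spec()].
#' @param grid `"nav"` or `"target"`.
#' @param normalize logical; divide by the RSS over coils so that the maps are
#'   directly comparable to ratio-estimated maps.
#' @return complex 4D array (x, y, z, coil) with attribute `voxel_mm`.
#' @export
make_coil_maps <- function(spec, grid = c("nav", "target"), normalize = FALSE) {
  grid <- match.arg(grid)
  shape <- if (grid == "nav") spec$nav_shape else spec$target_shape
  vox <- if (grid == "nav") spec$nav_voxel_mm else spec$target_voxel_mm
  nc <- spec$n_coils
  co <- grid_coords_mm(shape, vox)
  ring_r <- 1.25 * max(spec$brain_semiaxes_mm + spec$skull_gap_mm +
                         spec$fat_shell_thickness_mm)
  sigma <- 0.9 * ring_r
  maps <- array(0 + 0i, dim = c(shape, nc))
  for (c_i in seq_len(nc)) {
    th <- 2 * pi * (c_i - 1) / nc
    pc <- c(ring_r * cos(th), ring_r * sin(th),
            if (c_i %% 2 == 0) 0.15 * ring_r else -0.15 * ring_r)
    d2 <- (co[, 1] - pc[1])^2 + (co[, 2] - pc[2])^2 + (co[, 3] - pc[3])^2
    mag <- exp(-d2 / (2 * sigma^2))
    # linear phase along the coil direction, ~0.4 cycle across the FOV (kept
    # gentle so the fields stay low-order smooth)
    khat <- pc / sqrt(sum(pc^2))
    ph <- 2 * pi * 0.4 * (co %*% khat) / (shape[1] * vox[1]) + 2 * pi * (c_i - 1) / nc
    maps[, , , c_i] <- array(mag * exp(1i * ph), dim = shape)
  }
  if (normalize) {
    rss <- sqrt(apply(Mod(maps)^2, 1:3, sum))
    maps <- maps / array(rep(rss, nc), dim = dim(maps))
  }
  attr(maps, "voxel_mm") <- vox
  maps
}

#' Simulate noisy multi-coil k-space
#'
#' For each coil the image is multiplied by its sensitivity map in the complex
#' domain and Fourier transformed (centered, unitary); i.i.d. complex Gaussian
#' noise is then added in k-space. `noise_sigma` is relative to the maximum
#' image magnitude; real and imaginary parts each have that standard
#' deviation. Reproducible given `seed`.
#'
#' @param volume 3D complex image.
#' @param coil_maps complex 4D array (x, y, z, coil).
#' @param noise_sigma nonnegative noise level.
#' @param seed integer seed.
#' @return complex 4D k-space array (x, y, z, coil).
#' @export
simulate_multicoil_kspace <- function(volume, coil_maps, noise_sigma = 0, seed = 1L) {
  d <- dim(coil_maps)
  if (!all(dim(volume) == d[1:3])) stop("volume and coil map shapes disagree")
  nc <- d[4]
  out <- array(0 + 0i, dim = d)
  for (c_i in seq_len(nc))
    out[, , , c_i] <- centered_fft3(volume * coil_maps[, , , c_i])
  if (noise_sigma > 0) {
    sig <- noise_sigma * max(Mod(volume))
    set.seed(seed)
    n <- length(out)
    out <- out + complex(real = rnorm(n, 0, sig), imaginary = rnorm(n, 0, sig))
    dim(out) <- d
  }
  out
}
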