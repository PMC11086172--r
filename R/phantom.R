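# Helmet array geometry, voxel grid, and differential target scenarios.
#
# Coordinate convention (used everywhere): right-handed, z up, origin at the
# center of the helmet cap sphere. Voxels are indexed 0-based, x-fastest;
# voxel (0,0,0) has its center at origin + spacing/2.

#' Build a helmet antenna array
#'
#' Places `n_antennas` on rings of a spherical cap of radius `cap_radius`
#' (z up, cap centered on the +z axis). The default reproduces a 16-element
#' helmet as three rings of 6/6/4 antennas from rim to crown. The layout is
#' deterministic: ring k (from the rim) sits at polar angle
#' `theta_max * (R - k + 1) / R` with `theta_max = cap_extent / 2`, and rings
#' are azimuthally staggered by half a step to avoid aligned columns.
#' Transmit and receive response factors default to unity.
#'
#' @param n_antennas Number of antennas (>= 3; default 16).
#' @param cap_radius Cap sphere radius in meters (default 0.10 m).
#' @param cap_extent Full opening angle of the cap in degrees (default 120).
#' @param ring_counts Optional integer vector of per-ring antenna counts
#'   (rim to crown) summing to `n_antennas`; default 6/6/4 for 16 antennas,
#'   otherwise rings of at most 6.
#' @return An object of class `helmet_array` with fields `positions`
#'   (n x 3 matrix, meters), `tx_response`, `rx_response` (complex vectors),
#'   `cap_radius`, `cap_extent`.
#' @export
make_helmet <- function(n_antennas = 16, cap_radius = 0.10, cap_extent = 120,
                        ring_counts = NULL) {
  if (n_antennas < 3) stop("need at least 3 antennas")
  if (!is.numeric(cap_radius) || cap_radius <= 0 || cap_radius > 1)
    stop("cap_radius must be a physical helmet radius in meters (0, 1]")
  if (cap_extent <= 0 || cap_extent > 180)
    stop("cap_extent must lie in (0, 180] degrees")
  if (is.null(ring_counts)) {
    ring_counts <- if (n_antennas == 16) c(6L, 6L, 4L) else {
      r <- ceiling(n_antennas / 6)
      base <- rep(n_antennas %/% r, r)
      extra <- n_antennas %% r
      if (extra > 0) base[seq_len(extra)] <- base[seq_len(extra)] + 1L
      base
    }
  }
  if (sum(ring_counts) != n_antennas)
    stop("ring_counts must sum to n_antennas")
  theta_max <- cap_extent / 2 * pi / 180
  nr <- length(ring_counts)
  pos <- matrix(NA_real_, n_antennas, 3,
                dimnames = list(NULL, c("x", "y", "z")))
  i <- 1L
  for (k in seq_len(nr)) {
    theta <- theta_max * (nr - k + 1) / nr
    m <- ring_counts[k]
    phi <- 2 * pi * (seq_len(m) - 1) / m + (k - 1) * pi / m
    idx <- i:(i + m - 1L)
    pos[idx, ] <- cbind(cap_radius * sin(theta) * cos(phi),
                        cap_radius * sin(theta) * sin(phi),
                        cap_radius * cos(theta))
    i <- i + m
  }
  structure(
    list(positions = pos,
         tx_response = rep(1 + 0i, n_antennas),
         rx_response = rep(1 + 0i, n_antennas),
         cap_radius = cap_radius, cap_extent = cap_extent),
    class = "helmet_array")
}

#' @export
print.helmet_array <- function(x, ...) {
  cat(sprintf("<helmet_array> %d antennas on a %.0f mm cap (extent %g deg)\n",
              nrow(x$positions), 1000 * x$cap_radius, x$cap_extent))
  invisible(x)
}

#' Build the imaging voxel grid
#'
#' Regular grid over the region under test, organised as `n_slices`
#' horizontal slices (the 3D image is assembled slice by slice). The default
#' covers a 140 x 140 x 88 mm head region under the helmet crown with 10 mm
#' in-plane spacing and 11 slices (8 mm apart).
#'
#' @param extent List with numeric ranges `x`, `y`, `z` (meters).
#' @param spacing In-plane (x, y) voxel spacing in meters.
#' @param n_slices Number of z slices (default 11).
#' @return An object of class `voxel_grid` with fields `origin`, `spacing`
#'   (dx, dy, dz), `shape` (nx, ny, nz) and `slice_heights`.
#' @export
make_grid <- function(extent = list(x = c(-0.07, 0.07),
                                    y = c(-0.07, 0.07),
                                    z = c(0, 0.088)),
                      spacing = 0.01, n_slices = 11) {
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be > 0")
  if (n_slices < 1) stop("need at least one slice")
  span <- vapply(extent, diff, numeric(1))
  if (any(span <= 0)) stop("extent ranges must be increasing")
  nx <- round(span[["x"]] / spacing)
  ny <- round(span[["y"]] / spacing)
  nz <- as.integer(n_slices)
  if (nx < 1 || ny < 1) stop("grid is empty: extent smaller than spacing")
  dz <- span[["z"]] / nz
  origin <- c(extent$x[1], extent$y[1], extent$z[1])
  g <- structure(
    list(origin = origin,
         spacing = c(dx = spacing, dy = spacing, dz = dz),
         shape = c(nx = as.integer(nx), ny = as.integer(ny), nz = nz),
         slice_heights = origin[3] + dz / 2 + dz * (seq_len(nz) - 1)),
    class = "voxel_grid")
  g
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels (%g x %g x %g mm), %d voxels total\n",
              x$shape[1], x$shape[2], x$shape[3],
              1000 * x$spacing[1], 1000 * x$spacing[2], 1000 * x$spacing[3],
              n_voxels(x)))
  invisible(x)
}

#' Number of voxels in a grid
#' @param grid A [make_grid()] object.
#' @export
n_voxels <- function(grid) prod(grid$shape)

#' Voxel center coordinates
#'
#' Centers in the package ordering: 0-based indices, x-fastest, then y,
#' then z (slices last). Center of voxel (i,j,k) is
#' `origin + spacing * (i + 1/2, j + 1/2, k + 1/2)`.
#'
#' @param grid A [make_grid()] object.
#' @return An Ns x 3 matrix of coordinates in meters.
#' @export
voxel_centers <- function(grid) {
  s <- grid$shape
  ix <- seq_len(s[1]) - 1L
  iy <- seq_len(s[2]) - 1L
  iz <- seq_len(s[3]) - 1L
  idx <- as.matrix(expand.grid(x = ix, y = iy, z = iz))
  sweep(sweep(idx + 0.5, 2, grid$spacing, "*"), 2, grid$origin, "+")
}

#' Convert a flat voxel index to 0-based (i, j, k) indices
#' @param grid A [make_grid()] object.
#' @param flat 1-based flat index in x-fastest order.
#' @return Integer matrix with columns i, j, k (0-based).
#' @export
voxel_index <- function(grid, flat) {
  s <- grid$shape
  f <- flat - 1L
  i <- f %% s[1]
  j <- (f %/% s[1]) %% s[2]
  k <- f %/% (s[1] * s[2])
  cbind(i = i, j = j, k = k)
}

#' Nearest voxel (flat index) to a point
#' @param grid A [make_grid()] object.
#' @param point Numeric length-3 coordinate (m).
#' @export
nearest_voxel <- function(grid, point) {
  idx <- pmin(pmax(floor((point - grid$origin) / grid$spacing), 0),
              grid$shape - 1L)
  as.integer(1 + idx[1] + grid$shape[1] * (idx[2] + grid$shape[2] * idx[3]))
}

#' Define a spherical target inclusion
#'
#' @param center Length-3 center coordinate in meters.
#' @param volume_ml Volume in milliliters (> 0); the equivalent radius is
#'   `(3 V / 4 pi)^(1/3)`.
#' @param tissue [tissue_spec()] of the inclusion material (e.g. blood for a
#'   hemorrhage, a vacuum-like spec for an air-filled balloon).
#' @param contrast_amplitude Optional complex differential scattering
#'   amplitude at the reference frequency; when `NULL` it is derived from
#'   `tissue` against the scene background at imaging time.
#' @return An object of class `target_inclusion`.
#' @export
target_inclusion <- function(center, volume_ml, tissue,
                             contrast_amplitude = NULL) {
  stopifnot(length(center) == 3, is.numeric(center))
  if (!is.numeric(volume_ml) || volume_ml <= 0)
    stop("volume_ml must be > 0")
  structure(
    list(center = as.numeric(center), volume_ml = volume_ml,
         radius = (3 * volume_ml * 1e-6 / (4 * pi))^(1 / 3),
         tissue = tissue, contrast_amplitude = contrast_amplitude,
         shape = "sphere"),
    class = "target_inclusion")
}

#' Define a two-snapshot differential scattering scene
#'
#' A scene is the background medium plus the target inclusions present at
#' the two measurement instants t1 and t2. Differential imaging works on
#' the change between the snapshots, so only voxels whose contrast differs
#' between t1 and t2 scatter.
#'
#' @param background [tissue_spec()] of the effective homogeneous background
#'   (default: the 75/25 white/gray brain blend from the numerical table).
#' @param snapshot_t1,snapshot_t2 Lists of [target_inclusion()]s (either may
#'   be empty; an empty t1 is the background-measurement case).
#' @return An object of class `scattering_scene`.
#' @export
scattering_scene <- function(background = NULL,
                             snapshot_t1 = list(), snapshot_t2 = list()) {
  if (is.null(background))
    background <- brain_blend(tissue("white_matter", "numerical"),
                              tissue("gray_matter", "numerical"))
  ok <- function(l) all(vapply(l, inherits, logical(1), "target_inclusion"))
  if (!ok(snapshot_t1) || !ok(snapshot_t2))
    stop("snapshots must be lists of target_inclusion objects")
  structure(list(background = background,
                 snapshot_t1 = snapshot_t1, snapshot_t2 = snapshot_t2),
            class = "scattering_scene")
}

#' Hemorrhage-growth scenario
#'
#' A blood-filled spherical inclusion growing from 10 mL at the first
#' measurement to 26 mL at the second (a 16 mL differential volume),
#' centered at `position`, in a brain-blend background. The dielectric
#' contrast (blood vs brain) has positive real part.
#'
#' @param position Length-3 target center in meters.
#' @param v1_ml,v2_ml Snapshot volumes in mL (defaults 10 and 26).
#' @param blood,background Optional [tissue_spec()]s; defaults are the
#'   measured blood mixture and the white/gray brain blend.
#' @return A [scattering_scene()].
#' @export
hemorrhage_growth_scenario <- function(position, v1_ml = 10, v2_ml = 26,
                                       blood = NULL, background = NULL) {
  if (is.null(blood)) blood <- tissue("blood", "physical")
  if (is.null(background))
    background <- brain_blend(tissue("white_matter", "numerical"),
                              tissue("gray_matter", "numerical"))
  scattering_scene(
    background = background,
    snapshot_t1 = list(target_inclusion(position, v1_ml, blood)),
    snapshot_t2 = list(target_inclusion(position, v2_ml, blood)))
}

#' Negative-contrast (air-filled balloon) scenario
#'
#' Same geometry as the hemorrhage-growth scenario but with an air-filled
#' inclusion, so the dielectric contrast against brain is opposite in sign
#' (real-negative). With `differential = "background"` the first snapshot is
#' empty (background measurement vs target present) and the single `v2_ml`
#' inclusion is the full differential target.
#'
#' @inheritParams hemorrhage_growth_scenario
#' @param differential `"growth"` (10 -> 26 mL air inclusion) or
#'   `"background"` (empty t1 vs a `v2_ml` inclusion at t2).
#' @return A [scattering_scene()].
#' @export
negative_contrast_scenario <- function(position, v1_ml = 10, v2_ml = 26,
                                       differential = c("growth", "background"),
                                       background = NULL) {
  differential <- match.arg(differential)
  air <- tissue_spec("air", eps_r = 1, sigma = 0)
  if (is.null(background))
    background <- brain_blend(tissue("white_matter", "numerical"),
                              tissue("gray_matter", "numerical"))
  t1 <- if (differential == "growth")
    list(target_inclusion(position, v1_ml, air)) else list()
  scattering_scene(
    background = background,
    snapshot_t1 = t1,
    snapshot_t2 = list(target_inclusion(position, v2_ml, air)))
}

# Membership of voxel centers in an inclusion list; returns the complex
# contrast (target eps_c - background eps_c at `freq`) per voxel, 0 outside.
.snapshot_contrast <- function(inclusions, centers, background, freq) {
  v <- complex(length.out = nrow(centers))
  eps_bg <- complex_permittivity(background, freq)
  for (inc in inclusions) {
    d2 <- (centers[, 1] - inc$center[1])^2 +
          (centers[, 2] - inc$center[2])^2 +
          (centers[, 3] - inc$center[3])^2
    inside <- d2 <= inc$radius^2
    amp <- if (!is.null(inc$contrast_amplitude)) inc$contrast_amplitude
           else complex_permittivity(inc$tissue, freq) - eps_bg
    v[inside] <- amp
  }
  v
}

#' Rasterize a scene's differential contrast onto a grid
#'
#' Returns the per-voxel differential scattering contrast, i.e. the change
#' in complex permittivity contrast between the two snapshots, evaluated at
#' voxel centers. For a growing inclusion this is nonzero exactly on the
#' shell of voxels gained (or lost) between t1 and t2, plus any overlap
#' voxels whose amplitude changed; identical snapshots give the zero vector.
#'
#' @param scene A [scattering_scene()].
#' @param grid A [make_grid()] object covering all inclusions.
#' @param freq Frequency in Hz at which the contrast is evaluated
#'   (default: the background's reference frequency).
#' @return Complex vector of length `n_voxels(grid)` in x-fastest order.
#' @export
rasterize_targets <- function(scene, grid, freq = NULL) {
  stopifnot(inherits(scene, "scattering_scene"), inherits(grid, "voxel_grid"))
  if (is.null(freq)) freq <- scene$background$ref_freq
  lo <- grid$origin
  hi <- grid$origin + grid$shape * grid$spacing
  for (inc in c(scene$snapshot_t1, scene$snapshot_t2)) {
    if (any(inc$center - inc$radius < lo) || any(inc$center + inc$radius > hi))
      stop(sprintf("inclusion at (%g, %g, %g) m extends outside the grid",
                   inc$center[1], inc$center[2], inc$center[3]))
  }
  centers <- voxel_centers(grid)
  c2 <- .snapshot_contrast(scene$snapshot_t2, centers, scene$background, freq)
  c1 <- .snapshot_contrast(scene$snapshot_t1, centers, scene$background, freq)
  c2 - c1
}
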