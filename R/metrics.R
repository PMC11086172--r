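# Reconstruction quality metrics: signal-to-clutter ratio (SCR),
# signal-to-mean ratio (SMR), spatial displacement (SD).
#
# Convention: amplitude dB (20 log10). The imaging volumes are pseudospectra
# (amplitude-like, non-negative); a power convention (10 log10) is a single
# switch via the `db_factor` argument. All three metrics are invariant under
# positive global rescaling of the volume.

#' Build a ground-truth mask for metric evaluation
#'
#' The target region is the differential support of the scene (voxels whose
#' contrast changes between the snapshots), dilated by `dilate` voxels in
#' Chebyshev distance to absorb partial-volume effects; the clutter region
#' is its complement within the grid.
#'
#' @param scene A [scattering_scene()] (used for support and true center),
#'   or `NULL` if `target_flat` is supplied directly.
#' @param grid A [make_grid()] grid.
#' @param dilate Dilation radius in voxels (default 1).
#' @param target_flat Optional explicit 1-based flat voxel indices of the
#'   (undilated) target support.
#' @param true_center Optional true target center (m); default: the center
#'   of the first t2 inclusion (or the support centroid).
#' @return An object of class `truth_mask`: list with `target_region`,
#'   `clutter_region` (flat indices), `true_center`, `grid`.
#' @export
truth_mask <- function(scene = NULL, grid, dilate = 1, target_flat = NULL,
                       true_center = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  if (is.null(target_flat)) {
    if (is.null(scene)) stop("need a scene or explicit target_flat indices")
    dc <- rasterize_targets(scene, grid)
    target_flat <- which(dc != 0)
  }
  if (length(target_flat) == 0) stop("target region is empty")
  if (is.null(true_center)) {
    true_center <- if (!is.null(scene) && length(scene$snapshot_t2) > 0)
      scene$snapshot_t2[[1]]$center
    else colMeans(voxel_centers(grid)[target_flat, , drop = FALSE])
  }
  region <- target_flat
  if (dilate > 0) {
    s <- grid$shape
    idx <- voxel_index(grid, target_flat)
    off <- as.matrix(expand.grid(di = -dilate:dilate, dj = -dilate:dilate,
                                 dk = -dilate:dilate))
    all_idx <- do.call(rbind, lapply(seq_len(nrow(off)), function(r)
      sweep(idx, 2, off[r, ], "+")))
    keep <- all_idx[, 1] >= 0 & all_idx[, 1] < s[1] &
            all_idx[, 2] >= 0 & all_idx[, 2] < s[2] &
            all_idx[, 3] >= 0 & all_idx[, 3] < s[3]
    all_idx <- all_idx[keep, , drop = FALSE]
    region <- sort(unique(as.integer(
      1 + all_idx[, 1] + s[1] * (all_idx[, 2] + s[2] * all_idx[, 3]))))
  }
  structure(list(target_region = region,
                 clutter_region = setdiff(seq_len(n_voxels(grid)), region),
                 true_center = as.numeric(true_center), grid = grid),
            class = "truth_mask")
}

# Log10 view of a volume (exact even when linear values over/underflowed).
.log10_volume <- function(volume) {
  if (inherits(volume, "pseudospectrum_volume")) {
    if (!is.null(volume$log10)) as.numeric(volume$log10)
    else log10(as.numeric(volume$values))
  } else log10(as.numeric(volume))
}

.linear_volume <- function(volume) {
  if (inherits(volume, "pseudospectrum_volume")) as.numeric(volume$values)
  else as.numeric(volume)
}

#' Signal-to-clutter ratio (dB)
#'
#' `SCR = db_factor * log10(max over target region / max over clutter)`.
#' Computed in the log domain so that extreme pseudospectrum dynamic ranges
#' stay exact. A zero clutter maximum is reported as the capped sentinel
#' `cap_db`.
#'
#' @param volume A `pseudospectrum_volume` or non-negative numeric array.
#' @param mask A [truth_mask()].
#' @param db_factor 20 for amplitude dB (default) or 10 for power dB.
#' @param cap_db Sentinel for infinite ratios (default 300 dB).
#' @return SCR in dB.
#' @export
scr <- function(volume, mask, db_factor = 20, cap_db = 300) {
  stopifnot(inherits(mask, "truth_mask"))
  lg <- .log10_volume(volume)
  mt <- max(lg[mask$target_region])
  mc <- max(lg[mask$clutter_region])
  if (!is.finite(mc)) return(cap_db)
  min(db_factor * (mt - mc), cap_db)
}

#' Signal-to-mean ratio (dB)
#'
#' `SMR = db_factor * log10(max over target region / mean over clutter)`.
#' The clutter mean is computed by a log-sum-exp so volumes whose linear
#' values overflow or underflow double precision are still scored exactly.
#'
#' @inheritParams scr
#' @return SMR in dB.
#' @export
smr <- function(volume, mask, db_factor = 20, cap_db = 6000) {
  stopifnot(inherits(mask, "truth_mask"))
  lg <- .log10_volume(volume)
  mt <- max(lg[mask$target_region])
  lc <- lg[mask$clutter_region]
  m0 <- max(lc)
  if (!is.finite(m0)) return(cap_db)
  log_mean <- m0 + log10(mean(10^(lc - m0)))
  min(db_factor * (mt - log_mean), cap_db)
}

#' Spatial displacement (mm)
#'
#' Euclidean distance between the volume's peak voxel center and the true
#' target center, in millimeters. Peak ties are broken by the lowest flat
#' index.
#'
#' @param volume A `pseudospectrum_volume` or numeric array on the mask's
#'   grid.
#' @param mask A [truth_mask()].
#' @return SD in mm.
#' @export
sd_mm <- function(volume, mask) {
  stopifnot(inherits(mask, "truth_mask"))
  grid <- mask$grid
  lg <- .log10_volume(volume)
  flat <- which.max(lg)
  idx <- voxel_index(grid, flat)
  loc <- grid$origin + grid$spacing * (as.numeric(idx) + 0.5)
  1000 * sqrt(sum((loc - mask$true_center)^2))
}

#' Peak displacement in voxel index units
#'
#' Euclidean distance, in voxel index space, between the volume peak and
#' the voxel containing the true center. Useful when slices are thinner
#' than the in-plane spacing.
#'
#' @inheritParams sd_mm
#' @return Non-negative numeric (0 when the peak voxel contains the true
#'   center).
#' @export
sd_voxels <- function(volume, mask) {
  stopifnot(inherits(mask, "truth_mask"))
  grid <- mask$grid
  lg <- .log10_volume(volume)
  pk <- voxel_index(grid, which.max(lg))
  tr <- voxel_index(grid, nearest_voxel(grid, mask$true_center))
  sqrt(sum((as.numeric(pk) - as.numeric(tr))^2))
}

#' Peak displacement from the true differential support, in voxels
#'
#' Euclidean distance in voxel index space between the volume peak and the
#' nearest voxel of the true differential support (the region that actually
#' changed between the snapshots). For a growing inclusion the support is a
#' shell around the inclusion center: a reconstruction that peaks anywhere
#' on the changed region scores 0 here even though its center displacement
#' [sd_mm()] is the shell radius.
#'
#' @inheritParams sd_mm
#' @param support_flat Optional explicit 1-based flat indices of the true
#'   (undilated) support; default: the mask's target region.
#' @return Non-negative numeric (0 when the peak lies on the support).
#' @export
sd_support_voxels <- function(volume, mask, support_flat = NULL) {
  stopifnot(inherits(mask, "truth_mask"))
  grid <- mask$grid
  if (is.null(support_flat)) support_flat <- mask$target_region
  lg <- .log10_volume(volume)
  pk <- as.numeric(voxel_index(grid, which.max(lg)))
  si <- voxel_index(grid, support_flat)
  min(sqrt(rowSums(sweep(si, 2, pk)^2)))
}

#' Score a reconstruction against ground truth
#'
#' Computes SCR, SMR and SD for a volume and attaches them to a
#' [detect()]-style report.
#'
#' @param volume A `pseudospectrum_volume`.
#' @param mask A [truth_mask()].
#' @param report Optional `reconstruction_report` to attach metrics to.
#' @param db_factor 20 (amplitude, default) or 10 (power).
#' @return A list with `scr_db`, `smr_db`, `sd_mm`, `sd_voxels` (or the
#'   report with `$metrics` filled).
#' @export
score_reconstruction <- function(volume, mask, report = NULL, db_factor = 20) {
  m <- list(scr_db = scr(volume, mask, db_factor = db_factor),
            smr_db = smr(volume, mask, db_factor = db_factor),
            sd_mm = sd_mm(volume, mask),
            sd_voxels = sd_voxels(volume, mask))
  if (is.null(report)) return(m)
  report$metrics <- m
  report
}

#' Write a metrics table as CSV
#'
#' One row per (experiment, method) pair with columns
#' `experiment, method, scr_db, smr_db, sd_mm`.
#'
#' @param rows A data.frame with those columns (see
#'   [score_reconstruction()]).
#' @param path Output CSV path.
#' @export
write_metrics_csv <- function(rows, path) {
  need <- c("experiment", "method", "scr_db", "smr_db", "sd_mm")
  if (!all(need %in% names(rows)))
    stop("metrics table needs columns: ", paste(need, collapse = ", "))
  utils::write.csv(rows[, need], path, row.names = FALSE)
  invisible(path)
}
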