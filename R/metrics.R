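#' Per-lesion metabolic metrics
#'
#' Six metrics characterize a lesion at one time point: `suv_max` (hottest
#' voxel), `suv_peak` (highest 1 cm^3 spherical-neighborhood mean),
#' `suv_mean` (mean over the segmented mask), `mv` (metabolic volume,
#' mL), `tlg` (total lesion glycolysis, `suv_mean * mv`), and `sam`
#' (standardized added metabolic activity: total uptake in excess of the
#' local background over an enlarged region, SUV.mL).
#'
#' @name metrics
NULL

#' @describeIn metrics Maximum voxel SUV within the mask.
#' @param volume A [pet_volume].
#' @param voi A [lesion_voi] aligned to `volume`.
#' @export
suv_max <- function(volume, voi) {
  check_voi(volume, voi)
  max(volume$values[voi$mask])
}

# sphere radius (mm) enclosing 1 cm^3
peak_sphere_radius <- function() (3 * 1000 / (4 * pi))^(1 / 3)

#' @describeIn metrics Maximum, over sphere centers within the mask, of
#'   the mean SUV in a 1 cm^3 sphere (radius 6.204 mm) rasterized by
#'   voxel-center inclusion. The sphere may extend beyond the mask but
#'   not beyond the volume; centers whose sphere would leave the volume
#'   are skipped.
#' @export
suv_peak <- function(volume, voi) {
  check_voi(volume, voi)
  d <- dim(volume$values)
  off <- sphere_offsets(peak_sphere_radius(), volume$spacing)
  omax <- apply(abs(off), 2, max)
  if (any(2 * omax + 1 > d))
    stop("1 cm^3 peak sphere does not fit inside the volume",
         call. = FALSE)
  centers <- which(voi$mask, arr.ind = TRUE) - 1L
  ok <- centers[, 1] >= omax[1] & centers[, 1] < d[1] - omax[1] &
        centers[, 2] >= omax[2] & centers[, 2] < d[2] - omax[2] &
        centers[, 3] >= omax[3] & centers[, 3] < d[3] - omax[3]
  centers <- centers[ok, , drop = FALSE]
  if (nrow(centers) == 0)
    stop("no mask voxel admits a fully interior peak sphere",
         call. = FALSE)
  lin_c <- 1 + centers[, 1] + d[1] * (centers[, 2] + d[2] * centers[, 3])
  lin_o <- off[, 1] + d[1] * (off[, 2] + d[2] * off[, 3])
  # centers are >= omax from every face, so linear offsets cannot wrap
  means <- rowMeans(matrix(volume$values[outer(lin_c, lin_o, "+")],
                           nrow = length(lin_c)))
  max(means)
}

#' @describeIn metrics Mean SUV over the mask, metabolic volume (mL), and
#'   their product TLG, returned as a named list.
#' @export
suv_mean_mv_tlg <- function(volume, voi) {
  check_voi(volume, voi)
  m <- mean(volume$values[voi$mask])
  mv <- sum(voi$mask) * voxel_volume_ml(volume)
  list(suv_mean = m, mv = mv, tlg = m * mv)
}

#' @describeIn metrics Standardized added metabolic activity over the
#'   mask dilated by `margin_mm`: total SUV.mL in the enlarged region
#'   minus the local background mean times the region volume. Being an
#'   excess integral over a generous region, SAM is insensitive to the
#'   exact delineation and to partial-volume blurring, which only
#'   redistributes activity within the enlarged region.
#' @param margin_mm Dilation margin of the enlarged region, mm.
#' @param shell_inner,shell_outer Background shell margins, mm.
#' @param bg_exclude_frac Shell voxels above this fraction of the lesion
#'   SUVmax are excluded from the background estimate.
#' @export
sam <- function(volume, voi, margin_mm = 8, shell_inner = 10,
                shell_outer = 20, bg_exclude_frac = 0.4) {
  check_voi(volume, voi)
  enlarged <- dilate_mask(voi$mask, volume$spacing, margin_mm)
  rng <- mask_bounding_box(enlarged)
  bg <- shell_background(volume, rng, shell_inner, shell_outer,
                         bg_exclude_frac * suv_max(volume, voi))
  vv <- voxel_volume_ml(volume)
  sum(volume$values[enlarged]) * vv - bg * sum(enlarged) * vv
}

#' @describeIn metrics All six metrics as a one-row data frame of class
#'   `lesion_metrics` (the TLG identity `tlg = suv_mean * mv` holds
#'   exactly).
#' @param ... Passed to [sam].
#' @export
compute_all_metrics <- function(volume, voi, ...) {
  mmt <- suv_mean_mv_tlg(volume, voi)
  out <- data.frame(
    lesion_id = voi$lesion_id, organ = voi$organ,
    frame_id = volume$frame_id,
    suv_max = suv_max(volume, voi),
    suv_peak = suv_peak(volume, voi),
    suv_mean = mmt$suv_mean, mv = mmt$mv, tlg = mmt$tlg,
    sam = sam(volume, voi, ...),
    stringsAsFactors = FALSE)
  class(out) <- c("lesion_metrics", class(out))
  out
}

metric_names <- function() {
  c("suv_max", "suv_peak", "suv_mean", "mv", "tlg", "sam")
}

check_voi <- function(volume, voi) {
  stopifnot(inherits(volume, "pet_volume"), inherits(voi, "lesion_voi"))
  if (!identical(dim(voi$mask), dim(volume$values)))
    stop("mask and volume grids differ", call. = FALSE)
  if (sum(voi$mask) == 0) stop("empty mask", call. = FALSE)
  invisible(TRUE)
}
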