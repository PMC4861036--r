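#' Contrast-oriented adaptive-threshold segmentation settings
#'
#' The lesion threshold is `T = coeff_a * mSUV70 + coeff_b * BG`, where
#' `mSUV70` is the mean SUV of the voxels at or above 70% of the local
#' maximum and `BG` is the mean SUV of a background shell around the
#' working region. The defaults (`coeff_a = 0.5`, `coeff_b = 1`) are the
#' generic contrast-oriented form; scanner-specific coefficients can be
#' obtained with [calibrate_coefficients].
#'
#' @param coeff_a Multiplier of the 70%-isocontour mean (0 < a < 1).
#' @param coeff_b Multiplier of the background mean (>= 0).
#' @param shell_inner,shell_outer Inner/outer margins (mm) of the
#'   background sampling shell around the working region.
#' @param max_region Half-width (mm) of the cubic working region grown
#'   around the seed.
#' @param bg_exclude_frac Shell voxels above this fraction of the local
#'   SUVmax are excluded from the background estimate (guards against
#'   neighboring lesions).
#' @param min_contrast Minimum `mSUV70 - BG` (SUV) below which the seed
#'   is declared to have no focal uptake.
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(coeff_a = 0.5, coeff_b = 1.0,
                                shell_inner = 10, shell_outer = 20,
                                max_region = 20, bg_exclude_frac = 0.4,
                                min_contrast = 0.5) {
  stopifnot(coeff_a > 0, coeff_a < 1, coeff_b >= 0,
            shell_inner > 0, shell_outer > shell_inner, max_region > 0)
  structure(list(coeff_a = coeff_a, coeff_b = coeff_b,
                 shell_inner = shell_inner, shell_outer = shell_outer,
                 max_region = max_region,
                 bg_exclude_frac = bg_exclude_frac,
                 min_contrast = min_contrast),
            class = "segmentation_config")
}

# clipped cubic index range around a seed, half-width in mm
cube_range <- function(dim, spacing, seed, halfwidth_mm) {
  h <- ceiling(halfwidth_mm / spacing)
  list(lo = pmax(seed - h, 0L), hi = pmin(seed + h, dim - 1L))
}

cube_values <- function(values, rng) {
  values[(rng$lo[1] + 1):(rng$hi[1] + 1),
         (rng$lo[2] + 1):(rng$hi[2] + 1),
         (rng$lo[3] + 1):(rng$hi[3] + 1), drop = FALSE]
}

# Mean SUV of the cubic shell between margins inner..outer (mm) around
# the working region, excluding voxels above exclude_above.
shell_background <- function(volume, rng, inner, outer, exclude_above) {
  d <- dim(volume$values)
  ri <- list(lo = pmax(rng$lo - ceiling(inner / volume$spacing), 0L),
             hi = pmin(rng$hi + ceiling(inner / volume$spacing), d - 1L))
  ro <- list(lo = pmax(rng$lo - ceiling(outer / volume$spacing), 0L),
             hi = pmin(rng$hi + ceiling(outer / volume$spacing), d - 1L))
  sel <- array(FALSE, dim = d)
  sel[(ro$lo[1] + 1):(ro$hi[1] + 1), (ro$lo[2] + 1):(ro$hi[2] + 1),
      (ro$lo[3] + 1):(ro$hi[3] + 1)] <- TRUE
  sel[(ri$lo[1] + 1):(ri$hi[1] + 1), (ri$lo[2] + 1):(ri$hi[2] + 1),
      (ri$lo[3] + 1):(ri$hi[3] + 1)] <- FALSE
  vals <- volume$values[sel]
  if (length(vals) == 0)
    stop_petresponse("empty_shell", "background shell empty")
  kept <- vals[vals <= exclude_above]
  # when the exclusion empties the shell there is no hot structure to
  # avoid (the local maximum is itself background-level): keep all
  if (length(kept) == 0) kept <- vals
  mean(kept)
}

stop_petresponse <- function(class, message) {
  stop(structure(class = c(paste0("petresponse_", class), "error",
                           "condition"),
                 list(message = message, call = NULL)))
}

#' Segment a lesion with the contrast-oriented adaptive threshold
#'
#' Grows a cubic working region around the seed, computes the local
#' SUVmax and the mean of the voxels at or above 70% of it (ties
#' included), estimates the local background in a shell around the
#' working region, thresholds the region at
#' `T = coeff_a * mSUV70 + coeff_b * BG`, and keeps the 26-connected
#' component of supra-threshold voxels containing the seed.
#'
#' Two failure modes are reported as typed conditions rather than
#' guessed around: `petresponse_no_focal_uptake` when the 70%-isocontour
#' mean does not exceed the background by `min_contrast` (no lesion at
#' the seed), and `petresponse_empty_mask` when the threshold lies above
#' every voxel in the region (non-measurable lesion).
#'
#' @param volume A [pet_volume].
#' @param seed 0-based voxel index triple near the lesion center.
#' @param config A [segmentation_config].
#' @param lesion_id,organ Passed through to the returned [lesion_voi].
#' @return A [lesion_voi]; its `meta` records `threshold`, `suv_max`,
#'   `msuv70`, and `bg`.
#' @export
segment_lesion <- function(volume, seed, config = segmentation_config(),
                           lesion_id = "lesion", organ = "node") {
  stopifnot(inherits(volume, "pet_volume"))
  seed <- as.integer(seed)
  d <- dim(volume$values)
  stopifnot(all(seed >= 0), all(seed < d))
  rng <- cube_range(d, volume$spacing, seed, config$max_region)
  region <- cube_values(volume$values, rng)
  suv_max <- max(region)
  iso <- region[region >= 0.7 * suv_max]
  msuv70 <- mean(iso)
  bg <- shell_background(volume, rng, config$shell_inner,
                         config$shell_outer,
                         config$bg_exclude_frac * suv_max)
  if (msuv70 - bg < config$min_contrast)
    stop_petresponse("no_focal_uptake",
                     sprintf("no focal uptake at seed (mSUV70 %.2f vs background %.2f)",
                             msuv70, bg))
  threshold <- config$coeff_a * msuv70 + config$coeff_b * bg
  mask <- array(FALSE, dim = d)
  mask[(rng$lo[1] + 1):(rng$hi[1] + 1), (rng$lo[2] + 1):(rng$hi[2] + 1),
       (rng$lo[3] + 1):(rng$hi[3] + 1)] <- region >= threshold
  if (!mask[seed[1] + 1, seed[2] + 1, seed[3] + 1]) {
    # allow the seed to sit one voxel off the supra-threshold core
    nb <- cube_range(d, volume$spacing, seed, max(volume$spacing))
    core <- which(cube_values(mask, nb), arr.ind = TRUE)
    if (nrow(core) == 0)
      stop_petresponse("empty_mask",
                       "threshold above all voxels near the seed (non-measurable lesion)")
    seed <- as.integer(core[1, ] - 1L + nb$lo)
  }
  comp <- connected_component_26(mask, seed)
  if (sum(comp) == 0)
    stop_petresponse("empty_mask", "empty segmentation mask")
  lesion_voi(lesion_id, organ, seed, comp,
             meta = list(threshold = threshold, suv_max = suv_max,
                         msuv70 = msuv70, bg = bg))
}

#' Calibrate segmentation coefficients on phantom lesions
#'
#' Scans a coefficient grid and returns the configuration minimizing the
#' mean absolute relative metabolic-volume error against known true
#' masks, the standard way scanner-specific threshold coefficients are
#' obtained from sphere phantoms.
#'
#' @param phantoms List of cases, each a list with `volume`
#'   ([pet_volume]), `seed` (0-based voxel triple), and `true_volume_ml`
#'   (or `true_mask`, from which the volume is computed).
#' @param grid Data frame with columns `coeff_a` and `coeff_b`.
#' @param ... Further arguments to [segmentation_config].
#' @return The winning [segmentation_config], with the error table in
#'   attribute `"calibration"`.
#' @export
calibrate_coefficients <- function(phantoms, grid, ...) {
  if (nrow(grid) == 0) stop("empty coefficient grid", call. = FALSE)
  errs <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cfg <- segmentation_config(coeff_a = grid$coeff_a[g],
                               coeff_b = grid$coeff_b[g], ...)
    rel <- vapply(phantoms, function(ph) {
      truth <- if (!is.null(ph$true_volume_ml)) ph$true_volume_ml
               else sum(ph$true_mask) * voxel_volume_ml(ph$volume)
      voi <- tryCatch(segment_lesion(ph$volume, ph$seed, cfg),
                      error = function(e) NULL)
      if (is.null(voi)) return(1)  # failed delineation counts in full
      abs(sum(voi$mask) * voxel_volume_ml(ph$volume) - truth) / truth
    }, numeric(1))
    errs[g] <- mean(rel)
  }
  best <- which.min(errs)
  out <- segmentation_config(coeff_a = grid$coeff_a[best],
                             coeff_b = grid$coeff_b[best], ...)
  attr(out, "calibration") <- cbind(grid, mean_abs_rel_volume_error = errs)
  out
}
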