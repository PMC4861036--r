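#' PET volume in SUV units
#'
#' A `pet_volume` is the basic container shared by every stage of the
#' pipeline: a dense 3-D voxel grid of standardized uptake values (SUV,
#' dimensionless) together with the geometric metadata needed to map voxel
#' indices to physical (world) coordinates.
#'
#' Voxel indices are 0-based and axis-aligned: the physical position of
#' voxel `(i, j, k)` is `origin + c(i, j, k) * spacing` (mm). Oblique
#' orientations are not supported.
#'
#' @param values 3-D numeric array of voxel SUVs; finite and non-negative.
#' @param spacing Numeric length-3, voxel edge lengths in mm (all > 0).
#' @param origin Numeric length-3, world coordinate (mm) of voxel (0,0,0).
#' @param frame_id Character scan identifier.
#' @param acquisition_meta Optional named list of acquisition metadata
#'   (e.g. `injected_activity_mbq`, `body_weight_kg`, `uptake_time_min`).
#'
#' @return An object of class `pet_volume`.
#' @export
pet_volume <- function(values, spacing, origin = c(0, 0, 0),
                       frame_id = "frame", acquisition_meta = NULL) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3-D array", call. = FALSE)
  if (any(dim(values) < 1L))
    stop("each axis must have at least one voxel", call. = FALSE)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 positive finite values (mm)", call. = FALSE)
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)", call. = FALSE)
  if (any(!is.finite(values)))
    stop("voxel values must be finite", call. = FALSE)
  if (any(values < 0))
    stop("SUV values must be non-negative", call. = FALSE)
  structure(
    list(values = values, spacing = spacing, origin = origin,
         frame_id = as.character(frame_id),
         acquisition_meta = acquisition_meta),
    class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<pet_volume '%s'> %d x %d x %d voxels @ (%g, %g, %g) mm\n",
              x$frame_id, d[1], d[2], d[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  SUV range [%.3g, %.3g], origin (%g, %g, %g) mm\n",
              min(x$values), max(x$values),
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' @export
dim.pet_volume <- function(x) dim(x$values)

# mL per voxel
voxel_volume_ml <- function(volume) prod(volume$spacing) / 1000

# world coordinates (n x 3, mm) of 0-based voxel index rows
voxel_to_world <- function(volume, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3)
  sweep(sweep(idx, 2, volume$spacing, "*"), 2, volume$origin, "+")
}

# continuous 0-based voxel coordinates of world points (n x 3, mm)
world_to_voxel <- function(volume, pts) {
  pts <- matrix(as.numeric(pts), ncol = 3)
  sweep(sweep(pts, 2, volume$origin, "-"), 2, volume$spacing, "/")
}

#' Convert an activity concentration to a body-weight SUV
#'
#' SUV is the tissue activity concentration normalized by the injected
#' activity per kilogram of body weight:
#' `SUV = concentration [kBq/mL] * weight [kg] / injected [MBq]`
#' (numerically consistent because 1 MBq/kg = 1 kBq/g and tissue density
#' is taken as 1 g/mL). Body-weight normalization is used throughout the
#' package; lean-body-mass SUL is deliberately not implemented.
#'
#' @param concentration Activity concentration, kBq/mL (> 0, vectorized).
#' @param weight Body weight, kg (> 0).
#' @param injected_activity Injected activity decay-corrected to scan
#'   start, MBq (> 0).
#'
#' @return Dimensionless SUV, same length as `concentration`.
#' @examples
#' to_suv(5, 70, 350)  # 1.0
#' @export
to_suv <- function(concentration, weight, injected_activity) {
  if (any(concentration <= 0) || weight <= 0 || injected_activity <= 0)
    stop("all inputs to the SUV conversion must be positive", call. = FALSE)
  concentration * weight / injected_activity
}

#' Read a 3-D PET volume from a NIfTI-1 file
#'
#' Spacing and origin are taken from the NIfTI header (the grid is assumed
#' axis-aligned). When `units = "activity_concentration"` the voxel values
#' are interpreted as kBq/mL and converted to SUV using acquisition
#' metadata, supplied either through `acquisition_meta` or through a JSON
#' sidecar file next to the image (same stem, `.json` extension) with keys
#' `body_weight_kg` and `injected_activity_mbq`.
#'
#' @param path Path to a NIfTI file.
#' @param units `"SUV"` (default) or `"activity_concentration"`.
#' @param acquisition_meta Optional named list overriding the JSON sidecar.
#' @param frame_id Scan identifier; defaults to the file stem.
#'
#' @return A [pet_volume].
#' @export
read_volume <- function(path, units = c("SUV", "activity_concentration"),
                        acquisition_meta = NULL, frame_id = NULL) {
  units <- match.arg(units)
  if (!file.exists(path))
    stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3-D image, got ", length(d), " dimensions", call. = FALSE)
  spacing <- abs(RNifti::pixdim(img))[1:3]
  if (any(spacing <= 0))
    stop("non-positive voxel spacing in header", call. = FALSE)
  origin <- as.numeric(RNifti::voxelToWorld(c(1, 1, 1), img))
  values <- array(as.numeric(img), dim = d)
  if (is.null(frame_id))
    frame_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  if (units == "activity_concentration") {
    if (is.null(acquisition_meta)) {
      sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
      if (!file.exists(sidecar))
        stop("activity-concentration input needs acquisition_meta ",
             "(argument or JSON sidecar)", call. = FALSE)
      acquisition_meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    }
    w <- acquisition_meta$body_weight_kg
    a <- acquisition_meta$injected_activity_mbq
    if (is.null(w) || is.null(a))
      stop("acquisition_meta must contain body_weight_kg and ",
           "injected_activity_mbq", call. = FALSE)
    if (w <= 0 || a <= 0)
      stop("acquisition metadata must be positive", call. = FALSE)
    values[values < 0] <- 0          # stray negative reconstruction values
    values[] <- values * (w / a)     # kBq/mL * kg / MBq -> SUV
  }
  validate_acquisition_meta(acquisition_meta)
  pet_volume(values, spacing, origin, frame_id, acquisition_meta)
}

#' Write a PET volume to a NIfTI-1 file
#'
#' Values are stored as float32 in an RAS-oriented grid whose affine is
#' diagonal in the voxel spacing with the volume origin as translation, so
#' a read/write round trip reproduces values (to float32 precision),
#' spacing, and origin.
#'
#' @param volume A [pet_volume].
#' @param path Output path (parent directory must exist).
#' @return Invisibly, `path`.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "pet_volume"))
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path), call. = FALSE)
  img <- RNifti::asNifti(structure(volume$values, pixdim = volume$spacing),
                         datatype = "float")
  affine <- diag(c(volume$spacing, 1))
  affine[1:3, 4] <- volume$origin
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# Acquisition QC per the PERCIST-style protocol constraints: uptake window
# 50-70 min, serial injected activities within +/-20%. Violations warn
# rather than error, since they are protocol quality flags, not data errors.
validate_acquisition_meta <- function(meta, reference_activity = NULL) {
  if (is.null(meta)) return(invisible(NULL))
  ut <- meta$uptake_time_min
  if (!is.null(ut) && (ut < 50 || ut > 70))
    warning("uptake time ", ut, " min outside the 50-70 min window",
            call. = FALSE)
  if (!is.null(reference_activity) && !is.null(meta$injected_activity_mbq)) {
    rel <- abs(meta$injected_activity_mbq - reference_activity) /
      reference_activity
    if (rel > 0.2)
      warning("injected activity differs from the reference scan by ",
              round(100 * rel), "% (> 20%)", call. = FALSE)
  }
  invisible(NULL)
}
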