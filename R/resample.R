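#' Resample a volume through a rigid transform onto a reference grid
#'
#' `transform` is understood as the mapping that carries `volume`'s
#' content onto the reference frame (the convention returned by
#' [register_rigid]): the output voxel at world position `x` takes the
#' trilinearly interpolated value of `volume` at `transform^-1(x)`.
#' Voxels whose source position falls outside `volume`'s grid are set to
#' 0 and marked `FALSE` in the `"validity"` attribute of the result's
#' values array.
#'
#' @param volume A [pet_volume] to resample.
#' @param transform A [rigid_transform] mapping `volume` onto `reference`.
#' @param reference A [pet_volume] supplying the output grid.
#' @return A [pet_volume] on `reference`'s grid.
#' @export
resample_through <- function(volume, transform, reference) {
  stopifnot(inherits(volume, "pet_volume"), inherits(reference, "pet_volume"))
  d <- dim(reference$values)
  inv <- invert_transform(transform)
  # affine form of the inverse map: p_src = A p_world + b
  A <- inv$matrix
  b <- inv$center + inv$translation - as.numeric(A %*% inv$center)
  out <- resample_affine_cpp(as.numeric(volume$values),
                             dim(volume$values), volume$spacing,
                             volume$origin, d, reference$spacing,
                             reference$origin, A, b)
  values <- array(pmax(out$values, 0), dim = d)
  res <- pet_volume(values, reference$spacing, reference$origin,
                    frame_id = paste0(volume$frame_id, "_resampled"),
                    acquisition_meta = volume$acquisition_meta)
  attr(res$values, "validity") <- array(out$valid, dim = d)
  res
}

# Trilinear interpolation of volume at continuous world points (n x 3).
# Returns values (0 outside) and a validity flag.
interp_trilinear <- function(volume, world_pts) {
  u <- world_to_voxel(volume, world_pts)
  d <- dim(volume$values)
  valid <- u[, 1] >= 0 & u[, 1] <= d[1] - 1 &
           u[, 2] >= 0 & u[, 2] <= d[2] - 1 &
           u[, 3] >= 0 & u[, 3] <= d[3] - 1
  u[!valid, ] <- 0
  i0 <- floor(u)
  f <- u - i0
  # clamp the upper corner so edge points interpolate within bounds
  i1 <- pmin(i0 + 1, matrix(rep(d - 1L, each = nrow(u)), ncol = 3))
  v <- volume$values
  lin <- function(x, y, z) v[1 + x + d[1] * (y + d[2] * z)]
  w000 <- (1 - f[, 1]) * (1 - f[, 2]) * (1 - f[, 3])
  w100 <- f[, 1] * (1 - f[, 2]) * (1 - f[, 3])
  w010 <- (1 - f[, 1]) * f[, 2] * (1 - f[, 3])
  w110 <- f[, 1] * f[, 2] * (1 - f[, 3])
  w001 <- (1 - f[, 1]) * (1 - f[, 2]) * f[, 3]
  w101 <- f[, 1] * (1 - f[, 2]) * f[, 3]
  w011 <- (1 - f[, 1]) * f[, 2] * f[, 3]
  w111 <- f[, 1] * f[, 2] * f[, 3]
  vals <- w000 * lin(i0[, 1], i0[, 2], i0[, 3]) +
    w100 * lin(i1[, 1], i0[, 2], i0[, 3]) +
    w010 * lin(i0[, 1], i1[, 2], i0[, 3]) +
    w110 * lin(i1[, 1], i1[, 2], i0[, 3]) +
    w001 * lin(i0[, 1], i0[, 2], i1[, 3]) +
    w101 * lin(i1[, 1], i0[, 2], i1[, 3]) +
    w011 * lin(i0[, 1], i1[, 2], i1[, 3]) +
    w111 * lin(i1[, 1], i1[, 2], i1[, 3])
  vals[!valid] <- 0
  list(values = vals, valid = valid)
}

#' Isotropic Gaussian smoothing of a voxel array
#'
#' Separable convolution with a truncated (4 sigma), edge-renormalized
#' Gaussian kernel; used to emulate the scanner point-spread function.
#'
#' @param values 3-D array.
#' @param spacing Voxel spacing, mm.
#' @param fwhm Full width at half maximum of the PSF, mm (0 = no-op).
#' @return Smoothed array of the same dimensions.
#' @export
gaussian_blur <- function(values, spacing, fwhm) {
  stopifnot(fwhm >= 0)
  if (fwhm == 0) return(values)
  sigma_mm <- fwhm / (2 * sqrt(2 * log(2)))
  d <- dim(values)
  for (ax in 1:3) {
    sig <- sigma_mm / spacing[ax]
    n <- d[ax]
    K <- gauss_band_matrix(n, sig)
    values <- apply_along_axis(values, ax, K)
  }
  values
}

gauss_band_matrix <- function(n, sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  off <- (-r):r
  k <- exp(-off^2 / (2 * sigma_vox^2))
  K <- matrix(0, n, n)
  for (j in seq_len(n)) {
    rows <- j + off
    ok <- rows >= 1 & rows <= n
    K[rows[ok], j] <- k[ok] / sum(k[ok])  # renormalize truncated edges
  }
  t(K)
}

apply_along_axis <- function(arr, ax, K) {
  d <- dim(arr)
  if (ax == 1) {
    array(K %*% matrix(arr, d[1], d[2] * d[3]), dim = d)
  } else if (ax == 2) {
    a <- aperm(arr, c(2, 1, 3))
    a <- array(K %*% matrix(a, d[2], d[1] * d[3]), dim = d[c(2, 1, 3)])
    aperm(a, c(2, 1, 3))
  } else {
    a <- aperm(arr, c(3, 1, 2))
    a <- array(K %*% matrix(a, d[3], d[1] * d[2]), dim = d[c(3, 1, 2)])
    aperm(a, c(2, 3, 1))
  }
}
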