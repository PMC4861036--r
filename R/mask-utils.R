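# Shared voxel-geometry helpers: sphere rasterization, dilation,
# connected components, bounding boxes. All voxel indices are 0-based.

# Integer voxel offsets whose centers lie within radius_mm of the origin.
sphere_offsets <- function(radius_mm, spacing) {
  r <- floor(radius_mm / spacing)
  g <- expand.grid(x = -r[1]:r[1], y = -r[2]:r[2], z = -r[3]:r[3])
  d2 <- (g$x * spacing[1])^2 + (g$y * spacing[2])^2 + (g$z * spacing[3])^2
  as.matrix(g[d2 <= radius_mm^2, , drop = FALSE])
}

# Logical array of voxels whose centers lie inside a sphere (world mm).
rasterize_sphere <- function(dim, spacing, origin, center, radius) {
  x <- origin[1] + (seq_len(dim[1]) - 1) * spacing[1]
  y <- origin[2] + (seq_len(dim[2]) - 1) * spacing[2]
  z <- origin[3] + (seq_len(dim[3]) - 1) * spacing[3]
  dx2 <- (x - center[1])^2
  dy2 <- (y - center[2])^2
  dz2 <- (z - center[3])^2
  arr <- outer(outer(dx2, dy2, "+"), dz2, "+")
  array(arr <= radius^2, dim = dim)
}

# Binary dilation of a mask by a spherical structuring element.
dilate_mask <- function(mask, spacing, radius_mm) {
  d <- dim(mask)
  vox <- which(mask, arr.ind = TRUE) - 1L
  if (nrow(vox) == 0) return(mask)
  off <- sphere_offsets(radius_mm, spacing)
  out <- array(FALSE, dim = d)
  for (i in seq_len(nrow(off))) {
    p <- sweep(vox, 2, off[i, ], "+")
    ok <- p[, 1] >= 0 & p[, 1] < d[1] & p[, 2] >= 0 & p[, 2] < d[2] &
          p[, 3] >= 0 & p[, 3] < d[3]
    if (any(ok)) {
      q <- p[ok, , drop = FALSE]
      out[1 + q[, 1] + d[1] * (q[, 2] + d[2] * q[, 3])] <- TRUE
    }
  }
  out
}

# 26-connected component of `mask` containing `seed` (0-based triple).
connected_component_26 <- function(mask, seed) {
  d <- dim(mask)
  seed <- as.integer(seed)
  if (!mask[seed[1] + 1, seed[2] + 1, seed[3] + 1])
    return(array(FALSE, dim = d))
  off <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  visited <- array(FALSE, dim = d)
  visited[seed[1] + 1, seed[2] + 1, seed[3] + 1] <- TRUE
  frontier <- matrix(seed, ncol = 3)
  while (nrow(frontier) > 0) {
    cand <- frontier[rep(seq_len(nrow(frontier)), each = nrow(off)), ,
                     drop = FALSE] +
      off[rep(seq_len(nrow(off)), nrow(frontier)), , drop = FALSE]
    ok <- cand[, 1] >= 0 & cand[, 1] < d[1] &
          cand[, 2] >= 0 & cand[, 2] < d[2] &
          cand[, 3] >= 0 & cand[, 3] < d[3]
    cand <- cand[ok, , drop = FALSE]
    if (nrow(cand) == 0) break
    lin <- 1 + cand[, 1] + d[1] * (cand[, 2] + d[2] * cand[, 3])
    keep <- mask[lin] & !visited[lin]
    lin_new <- unique(lin[keep])
    if (length(lin_new) == 0) break
    visited[lin_new] <- TRUE
    k0 <- lin_new - 1
    frontier <- cbind(k0 %% d[1],
                      (k0 %/% d[1]) %% d[2],
                      k0 %/% (d[1] * d[2]))
  }
  visited
}

mask_bounding_box <- function(mask) {
  idx <- which(mask, arr.ind = TRUE) - 1L
  if (nrow(idx) == 0) return(NULL)
  list(lo = apply(idx, 2, min), hi = apply(idx, 2, max))
}

#' Lesion volume of interest
#'
#' A seeded, organ-labeled lesion region: a boolean mask aligned to a
#' [pet_volume], required to be a single 26-connected component that
#' contains its seed voxel. The bounding box covers the mask exactly.
#'
#' @param lesion_id Identifier.
#' @param organ One of `"node"`, `"bone"`, `"liver"`, `"breast"`,
#'   `"lung"`, `"peritoneum"`.
#' @param seed 0-based voxel index triple inside the mask.
#' @param mask Logical 3-D array.
#' @param meta Optional named list of segmentation details.
#' @return An object of class `lesion_voi`.
#' @export
lesion_voi <- function(lesion_id, organ, seed, mask, meta = NULL) {
  organ <- match.arg(organ, organ_labels())
  seed <- as.integer(seed)
  stopifnot(is.array(mask), is.logical(mask), length(dim(mask)) == 3,
            length(seed) == 3)
  if (sum(mask) < 1) stop("mask must contain at least one voxel",
                          call. = FALSE)
  if (!mask[seed[1] + 1, seed[2] + 1, seed[3] + 1])
    stop("seed voxel is not inside the mask", call. = FALSE)
  comp <- connected_component_26(mask, seed)
  if (sum(comp) != sum(mask))
    stop("mask must be a single connected component containing the seed",
         call. = FALSE)
  structure(list(lesion_id = as.character(lesion_id), organ = organ,
                 seed = seed, mask = mask,
                 bounding_box = mask_bounding_box(mask), meta = meta),
            class = "lesion_voi")
}

#' @export
print.lesion_voi <- function(x, ...) {
  cat(sprintf("<lesion_voi '%s'> organ %s, %d voxels, seed (%d, %d, %d)\n",
              x$lesion_id, x$organ, sum(x$mask),
              x$seed[1], x$seed[2], x$seed[3]))
  invisible(x)
}

organ_labels <- function() {
  c("node", "bone", "liver", "breast", "lung", "peritoneum")
}
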