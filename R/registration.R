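#' Block-matching registration settings
#'
#' The similarity measure is normalized cross-correlation; block size,
#' search radius and iteration defaults are package choices (the method
#' family does not prescribe them).
#'
#' @param block_size Cubic block edge length, voxels (odd, >= 3).
#' @param search_radius Search radius around each block, voxels (>= 1).
#' @param block_stride Spacing of block centers, voxels.
#' @param trim_fraction Fraction of worst block matches discarded by the
#'   trimmed rigid fit (0 <= f < 0.5).
#' @param max_iterations Maximum match/fit/resample iterations.
#' @param convergence_tol Convergence tolerance on the incremental
#'   transform's corner displacement, mm.
#' @param min_ncc Block matches with peak NCC below this are discarded
#'   (the maximum over a full search window of pure-noise correlations
#'   reaches about 0.35, so 0.5 keeps only genuine structure).
#' @param max_blocks At most this many highest-contrast blocks are used.
#' @return An object of class `block_match_config`.
#' @export
block_match_config <- function(block_size = 5, search_radius = 5,
                               block_stride = 2, trim_fraction = 0.2,
                               max_iterations = 10, convergence_tol = 0.1,
                               min_ncc = 0.5, max_blocks = 400) {
  stopifnot(block_size >= 3, block_size %% 2 == 1, search_radius >= 1,
            trim_fraction >= 0, trim_fraction < 0.5, max_iterations >= 1,
            convergence_tol > 0, block_stride >= 1)
  structure(list(block_size = as.integer(block_size),
                 search_radius = as.integer(search_radius),
                 block_stride = as.integer(block_stride),
                 similarity = "ncc",
                 trim_fraction = trim_fraction,
                 max_iterations = as.integer(max_iterations),
                 convergence_tol = convergence_tol,
                 min_ncc = min_ncc, max_blocks = as.integer(max_blocks)),
            class = "block_match_config")
}

# Candidate block centers (0-based), restricted to an optional roi
# (list(lo, hi), 0-based inclusive) and filtered to high-contrast blocks.
select_blocks <- function(fixed, config, roi = NULL) {
  d <- dim(fixed$values)
  bh <- (config$block_size - 1L) %/% 2L
  margin <- bh + config$search_radius
  lo <- rep(margin, 3); hi <- d - 1L - margin
  if (!is.null(roi)) {
    lo <- pmax(lo, roi$lo); hi <- pmin(hi, roi$hi)
  }
  if (any(hi < lo)) stop("roi too small for the block configuration",
                         call. = FALSE)
  grids <- lapply(1:3, function(ax) seq(lo[ax], hi[ax],
                                        by = config$block_stride))
  centers <- as.matrix(expand.grid(grids[[1]], grids[[2]], grids[[3]]))
  storage.mode(centers) <- "integer"
  sds <- block_sd_cpp(as.numeric(fixed$values), d, centers, bh)
  cut <- max(1.5 * median(sds), 1e-8)
  keep <- which(sds > cut)
  if (length(keep) == 0)
    stop("no matchable blocks (image has no contrast)", call. = FALSE)
  keep <- keep[order(sds[keep], decreasing = TRUE)]
  centers[head(keep, config$max_blocks), , drop = FALSE]
}

# Least-trimmed rigid fit mapping points P onto Q (world mm) via the
# Kabsch SVD solution. Starts from the trim_fraction quantile cut, then
# iteratively re-trims residuals beyond 3x the median of the kept set,
# so a minority cluster of spurious matches (e.g. blocks on a lesion
# that resolved between scans) is rejected entirely rather than
# averaged into the fit. Never keeps fewer than half the points.
fit_rigid_trimmed <- function(P, Q, trim_fraction,
                              allow_rotation = TRUE) {
  fit <- function(P, Q) {
    pc <- colMeans(P); qc <- colMeans(Q)
    if (!allow_rotation || nrow(P) < 3)
      return(rigid_transform(translation = qc - pc, center = pc))
    H <- t(sweep(P, 2, pc)) %*% sweep(Q, 2, qc)
    sv <- svd(H)
    s <- diag(c(1, 1, sign(det(sv$v %*% t(sv$u)))))
    R <- sv$v %*% s %*% t(sv$u)
    rigid_transform(rotation = matrix_to_euler(R),
                    translation = qc - pc, center = pc)
  }
  tf <- fit(P, Q)
  n <- nrow(P)
  if (trim_fraction <= 0 || n <= 6) return(list(transform = tf,
                                                keep = rep(TRUE, n)))
  keep <- rep(TRUE, n)
  for (round in 1:4) {
    res <- sqrt(rowSums((transform_points(tf, P) - Q)^2))
    cut <- if (round == 1) quantile(res, 1 - trim_fraction)
           else max(3 * median(res[keep]), 0.2)
    keep_new <- res <= cut
    if (sum(keep_new) < max(6, n %/% 2)) {
      ord <- order(res)
      keep_new <- seq_len(n) %in% ord[seq_len(max(6, n %/% 2))]
    }
    if (identical(keep_new, keep) && round > 1) break
    keep <- keep_new
    tf <- fit(P[keep, , drop = FALSE], Q[keep, , drop = FALSE])
  }
  list(transform = tf, keep = keep)
}

#' Rigid registration of two PET volumes by iterated block matching
#'
#' Estimates the rigid transform mapping `moving` onto `fixed`. Each
#' iteration resamples `moving` through the current estimate, displaces
#' high-contrast blocks of `fixed` to maximize normalized
#' cross-correlation within the search radius (with parabolic sub-voxel
#' refinement), fits a rigid transform to the block displacement field by
#' a least-trimmed Kabsch solution, and composes it into the estimate;
#' iteration stops when the incremental transform moves the volume
#' corners by less than `convergence_tol` mm. When `roi` is given, only
#' blocks inside it contribute (local rigid registration around the
#' lesion burden).
#'
#' @param fixed,moving [pet_volume]s sharing a physical space.
#' @param config A [block_match_config].
#' @param roi Optional list `(lo, hi)` of 0-based voxel bounds in
#'   `fixed`.
#' @return A [rigid_transform] `T` such that
#'   `resample_through(moving, T, fixed)` aligns `moving` with `fixed`.
#' @export
register_rigid <- function(fixed, moving, config = block_match_config(),
                           roi = NULL) {
  stopifnot(inherits(fixed, "pet_volume"), inherits(moving, "pet_volume"))
  d <- dim(fixed$values)
  bh <- (config$block_size - 1L) %/% 2L
  centers <- select_blocks(fixed, config, roi)
  P <- voxel_to_world(fixed, centers)

  t_inv <- rigid_transform(center = voxel_to_world(
    fixed, matrix((d - 1) / 2, 1)))  # running estimate of T^-1
  corners <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1),
                                   c(0, d[3] - 1)))
  corners <- voxel_to_world(fixed, corners)

  fit_residual <- Inf
  for (it in seq_len(config$max_iterations)) {
    mov_cur <- if (is_identity_transform(t_inv))
      resample_onto(moving, fixed) else
      resample_through(moving, invert_transform(t_inv), fixed)
    bm <- block_match_cpp(as.numeric(fixed$values),
                          as.numeric(mov_cur$values),
                          d, centers, bh, config$search_radius)
    ok <- bm[, 5] > 0 & bm[, 4] >= config$min_ncc
    if (sum(ok) < 6)
      stop("insufficient block matches; volumes may not overlap",
           call. = FALSE)
    disp <- sweep(bm[ok, 1:3, drop = FALSE], 2, fixed$spacing, "*")
    Pok <- P[ok, , drop = FALSE]
    ft <- fit_rigid_trimmed(Pok, Pok + disp, config$trim_fraction)
    Pk <- Pok[ft$keep, , drop = FALSE]
    Qk <- (Pok + disp)[ft$keep, , drop = FALSE]
    # a spatially narrow surviving match field cannot constrain rotation
    spread <- max(sqrt(rowSums(sweep(Pk, 2, colMeans(Pk))^2)))
    delta <- if (spread > 30) ft$transform
             else fit_rigid_trimmed(Pk, Qk, 0,
                                    allow_rotation = FALSE)$transform
    fit_residual <- median(sqrt(rowSums((transform_points(delta, Pk) -
                                           Qk)^2)))
    # delta maps fixed coords to current-moving coords; fold into T^-1
    t_inv <- compose_transforms(t_inv, delta)
    move <- max(sqrt(rowSums((transform_points(delta, corners) -
                                corners)^2)))
    if (move < config$convergence_tol) break
  }
  # a displacement field no rigid motion can explain (median residual
  # beyond the voxel scale) means the matches were spurious
  if (fit_residual > 1.5 * mean(fixed$spacing))
    stop("block displacement field is inconsistent with a rigid motion; ",
         "registration unreliable", call. = FALSE)
  invert_transform(t_inv)
}

# Resample onto the reference grid with the identity transform (grid
# harmonization only).
resample_onto <- function(volume, reference) {
  if (identical(dim(volume$values), dim(reference$values)) &&
      isTRUE(all.equal(volume$spacing, reference$spacing)) &&
      isTRUE(all.equal(volume$origin, reference$origin)))
    return(volume)
  resample_through(volume, rigid_transform(), reference)
}
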