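#' Settings for the two-frame factor analysis
#'
#' @param k_sigma Multiple of the robust noise scale of the frame
#'   difference beyond which a voxel joins the evolving set.
#' @param tol Convergence tolerance on the evolution factor.
#' @param max_iter Maximum factor re-estimation iterations.
#' @param degeneracy_ratio If the second singular value of the centered
#'   voxel-by-frame data is below this fraction of the first, the pair is
#'   declared free of evolution (degenerate model).
#' @param min_excess The evolving set must be at least this multiple of
#'   the count expected from Gaussian noise alone at `k_sigma`, else the
#'   pair carries no evolution.
#' @param min_coherence Minimum sign coherence
#'   `|sum(d)| / sum(|d|)` of the evolving voxels' frame differences;
#'   a symmetric noise tail scores near 0, a real evolution well above.
#' @return An object of class `fads_config`.
#' @export
fads_config <- function(k_sigma = 4, tol = 1e-6, max_iter = 20,
                        degeneracy_ratio = 1e-3, min_excess = 2,
                        min_coherence = 0.15) {
  stopifnot(k_sigma > 0, tol > 0, max_iter >= 1, degeneracy_ratio > 0,
            min_excess >= 1, min_coherence >= 0, min_coherence < 1)
  structure(list(k_sigma = k_sigma, tol = tol,
                 max_iter = as.integer(max_iter),
                 degeneracy_ratio = degeneracy_ratio,
                 min_excess = min_excess, min_coherence = min_coherence),
            class = "fads_config")
}

#' Two-frame factor analysis of a registered PET pair
#'
#' Decomposes the per-voxel two-frame signal `S(v, .)` as
#' `Ib(v) * Cb + Ie(v) * Ce`, where the background factor `Cb` is
#' constrained to the constant vector `(1, 1)` (so `Ib` carries the SUV
#' of unchanged voxels) and the evolution factor `Ce` is a unit-norm
#' kinetic estimated from the data without orthogonality constraints
#' (an oblique rotation of the principal-component solution).
#'
#' The estimation alternates two steps until `Ce` is stable: (1) voxels
#' whose residual under the constant factor alone exceeds `k_sigma`
#' times a robust (MAD) noise scale - estimated on the complement - form
#' the evolving set; (2) `Ce` is re-fit as the dominant principal
#' direction (uncentered SVD) of the evolving voxels' two-frame
#' profiles, with its sign fixed so that the evolving set's summed
#' evolution image is non-negative. Given the factors, `(Ib, Ie)` solve
#' the per-voxel 2 x 2 linear system exactly, so the reconstruction is
#' exact wherever the system is nonsingular.
#'
#' Pairs with no evolution (identical frames up to noise, a rank-1
#' centered data matrix, or an evolution factor collinear with the
#' constant) yield a model flagged `degenerate` with `Ie = 0`
#' everywhere.
#'
#' @param frame1,frame2 Registered [pet_volume]s on a common grid.
#' @param roi Optional list `(lo, hi)` of 0-based voxel bounds limiting
#'   the analysis region (default: whole grid).
#' @param config A [fads_config].
#' @return An object of class `factor_model` with fields `c_b`, `c_e`,
#'   `i_b`, `i_e` (3-D arrays), `residual_rms`, `evolving_fraction`,
#'   `degenerate`, `roi`.
#' @export
fads_two_frame <- function(frame1, frame2, roi = NULL,
                           config = fads_config()) {
  stopifnot(inherits(frame1, "pet_volume"), inherits(frame2, "pet_volume"))
  if (!identical(dim(frame1$values), dim(frame2$values)))
    stop("frames must share a voxel grid", call. = FALSE)
  d <- dim(frame1$values)
  in_roi <- array(TRUE, dim = d)
  if (!is.null(roi)) {
    in_roi[] <- FALSE
    in_roi[(roi$lo[1] + 1):(roi$hi[1] + 1),
           (roi$lo[2] + 1):(roi$hi[2] + 1),
           (roi$lo[3] + 1):(roi$hi[3] + 1)] <- TRUE
  }
  s1 <- frame1$values[in_roi]
  s2 <- frame2$values[in_roi]
  delta <- s2 - s1

  degenerate_model <- function(reason) {
    i_b <- array(0, dim = d)
    i_b[in_roi] <- (s1 + s2) / 2
    model <- list(c_b = c(1, 1), c_e = c(1, -1) / sqrt(2),
                  i_b = i_b, i_e = array(0, dim = d),
                  residual_rms = 0, evolving_fraction = 0,
                  degenerate = TRUE, degenerate_reason = reason,
                  roi = roi)
    class(model) <- "factor_model"
    model
  }

  # Rank-1 centered data means all variation follows one direction;
  # that is evolution-free only when the direction is the constant
  # vector (identical frames). A noiseless two-population pair is also
  # rank 1, but along an oblique direction, and must not be flagged.
  X <- cbind(s1 - mean(s1), s2 - mean(s2))
  dec <- svd(X, nu = 0)
  if (dec$d[1] < 1e-12)
    return(degenerate_model("constant frames (no variation)"))
  if (dec$d[2] / dec$d[1] < config$degeneracy_ratio) {
    v1 <- dec$v[, 1]
    if (abs(sum(v1 * c(1, 1)) / sqrt(2)) > 0.9999)
      return(degenerate_model("identical frames (no evolution)"))
  }

  evolving <- rep(FALSE, length(delta))
  ce <- NULL
  for (it in seq_len(config$max_iter)) {
    # robust noise scale of the frame difference on quiescent voxels;
    # in the noiseless limit the MAD is 0 and any nonzero change evolves
    quiet <- if (any(!evolving)) delta[!evolving] else delta
    sigma <- max(stats::mad(quiet, center = 0), 1e-12)
    evolving_new <- abs(delta) > config$k_sigma * sigma
    if (!any(evolving_new))
      return(degenerate_model("no voxels beyond the noise level"))
    E <- cbind(s1[evolving_new], s2[evolving_new])
    ce_new <- svd(E, nu = 0)$v[, 1]
    ce_new <- ce_new / sqrt(sum(ce_new^2))
    # sign: summed evolution image over the evolving set must be >= 0
    denom <- ce_new[2] - ce_new[1]
    if (abs(denom) > 1e-12 &&
        sum((E[, 2] - E[, 1]) / denom) < 0)
      ce_new <- -ce_new
    if (!is.null(ce) && sqrt(sum((ce_new - ce)^2)) < config$tol &&
        identical(evolving_new, evolving)) {
      ce <- ce_new; evolving <- evolving_new; break
    }
    ce <- ce_new; evolving <- evolving_new
  }
  # no-evolution guards: the evolving set must outgrow the pure-noise
  # tail expectation and carry a sign-coherent frame difference
  n_expected <- 2 * stats::pnorm(-config$k_sigma) * length(delta)
  if (sum(evolving) < config$min_excess * n_expected)
    return(degenerate_model("evolving set within the noise expectation"))
  dE <- delta[evolving]
  if (abs(sum(dE)) / sum(abs(dE)) < config$min_coherence)
    return(degenerate_model("no sign-coherent evolution"))
  denom <- ce[2] - ce[1]
  if (abs(denom) < 1e-9)
    return(degenerate_model("evolution factor collinear with background"))

  # exact per-voxel solution of Ib*(1,1) + Ie*(ce1,ce2) = (s1,s2)
  ie_v <- delta / denom
  ib_v <- s1 - ie_v * ce[1]
  i_b <- array(0, dim = d); i_e <- array(0, dim = d)
  i_b[in_roi] <- ib_v
  i_e[in_roi] <- ie_v
  recon1 <- ib_v + ie_v * ce[1]
  recon2 <- ib_v + ie_v * ce[2]
  residual_rms <- sqrt(mean((recon1 - s1)^2 + (recon2 - s2)^2) / 2)
  model <- list(c_b = c(1, 1), c_e = ce, i_b = i_b, i_e = i_e,
                residual_rms = residual_rms,
                evolving_fraction = mean(evolving),
                degenerate = FALSE, degenerate_reason = NULL, roi = roi)
  class(model) <- "factor_model"
  model
}

#' @export
print.factor_model <- function(x, ...) {
  if (x$degenerate) {
    cat("<factor_model> degenerate:", x$degenerate_reason, "\n")
  } else {
    cat(sprintf(
      "<factor_model> Ce = (%.4f, %.4f) [%s], evolving fraction %.3g\n",
      x$c_e[1], x$c_e[2],
      if (x$c_e[2] < x$c_e[1]) "decreasing" else "increasing",
      x$evolving_fraction))
  }
  invisible(x)
}

#' Parametric image of significant tumour change
#'
#' Masks the evolution factor image at a significance cut: each voxel
#' equals `Ie(v)` when `|Ie(v)| > threshold` and 0 otherwise. With the
#' package's factor normalization (`Cb = (1, 1)`, unit-norm `Ce`), the
#' default cut of 1 reads as roughly one SUV of change.
#'
#' @param model A [fads_two_frame] result.
#' @param threshold Significance cut, SUV units (default 1).
#' @return An object of class `sultan_image` with fields `values`
#'   (masked 3-D image), `threshold`, `direction` (`"decreasing"` or
#'   `"increasing"` trend of the evolution factor over time), and
#'   `degenerate`.
#' @export
sultan_image <- function(model, threshold = 1) {
  stopifnot(inherits(model, "factor_model"), threshold >= 0)
  values <- model$i_e
  values[abs(values) <= threshold] <- 0
  direction <- if (model$c_e[2] < model$c_e[1]) "decreasing"
               else "increasing"
  structure(list(values = values, threshold = threshold,
                 direction = direction, degenerate = model$degenerate),
            class = "sultan_image")
}

#' Write a parametric change image as a NIfTI overlay
#'
#' The masked evolution image is signed (positive = following the main
#' factor), so it is written directly as float32 NIfTI on the reference
#' grid, suitable for overlay on the baseline scan.
#'
#' @param image A [sultan_image].
#' @param reference The baseline [pet_volume] supplying the grid.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_sultan_image <- function(image, reference, path) {
  stopifnot(inherits(image, "sultan_image"),
            inherits(reference, "pet_volume"))
  img <- RNifti::asNifti(structure(image$values,
                                   pixdim = reference$spacing),
                         datatype = "float")
  affine <- diag(c(reference$spacing, 1))
  affine[1:3, 4] <- reference$origin
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  img <- RNifti::`qform<-`(img, structure(affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Classify one lesion from the parametric change image
#'
#' The lesion's evolution sign is the sign of the sum of the masked
#' parametric image over the lesion mask (so large coherent changes
#' dominate isolated suprathreshold speckle). A lesion responds when the
#' main factor decreases over time and the lesion follows it (`Ie > 0`),
#' or increases and the lesion opposes it (`Ie < 0`). Lesions whose
#' suprathreshold support covers less than `min_fraction` of the mask
#' show no significant change and are non-responders (noise speckle
#' alone covers about 1% of a stable lesion at the default cut).
#'
#' @param image A [sultan_image].
#' @param voi A [lesion_voi] on the same grid.
#' @param min_fraction Minimum fraction of mask voxels that must exceed
#'   the significance cut for the lesion to count as changed.
#' @return `"responder"` or `"non_responder"`.
#' @export
classify_lesion_sultan <- function(image, voi, min_fraction = 0.05) {
  stopifnot(inherits(image, "sultan_image"), inherits(voi, "lesion_voi"))
  if (!identical(dim(image$values), dim(voi$mask)))
    stop("image and mask grids differ", call. = FALSE)
  vals <- image$values[voi$mask]
  if (length(vals) == 0)
    stop("lesion mask does not intersect the analysis region",
         call. = FALSE)
  if (image$degenerate || mean(vals != 0) < min_fraction)
    return("non_responder")
  s <- sum(vals)
  if (s == 0) return("non_responder")
  decreasing <- image$direction == "decreasing"
  if ((decreasing && s > 0) || (!decreasing && s < 0)) "responder"
  else "non_responder"
}

#' Patient-level classification from lesion calls
#'
#' A patient responds only if every lesion responds.
#'
#' @param lesion_labels Character vector of `"responder"` /
#'   `"non_responder"` calls (>= 1).
#' @return `"responder"` or `"non_responder"`.
#' @export
classify_patient_sultan <- function(lesion_labels) {
  if (length(lesion_labels) == 0)
    stop("at least one lesion label is required", call. = FALSE)
  stopifnot(all(lesion_labels %in% c("responder", "non_responder")))
  if (all(lesion_labels == "responder")) "responder" else "non_responder"
}
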