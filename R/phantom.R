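#' Lesion specification for the phantom generator
#'
#' Describes one spherical focal lesion of a paired-scan phantom: its
#' position, size, organ label, and SUV at the two time points. The
#' ground-truth percent change of mean SUV is
#' `100 * (suv_t2 - suv_t1) / suv_t1`.
#'
#' @param center World coordinates of the sphere center, mm.
#' @param radius Sphere radius at baseline, mm (> 0).
#' @param suv_t1,suv_t2 Lesion SUV at baseline / follow-up.
#' @param organ Organ label (see [lesion_voi]).
#' @param radius_t2 Optional follow-up radius, mm (defaults to `radius`).
#' @param lesion_id Identifier.
#' @return An object of class `lesion_spec`.
#' @export
lesion_spec <- function(center, radius, suv_t1, suv_t2, organ = "node",
                        radius_t2 = NULL, lesion_id = "lesion") {
  organ <- match.arg(organ, organ_labels())
  stopifnot(length(center) == 3, radius > 0, suv_t1 > 0, suv_t2 >= 0)
  if (is.null(radius_t2)) radius_t2 <- radius
  stopifnot(radius_t2 > 0)
  structure(list(center = as.numeric(center), radius = radius,
                 suv_t1 = suv_t1, suv_t2 = suv_t2, organ = organ,
                 radius_t2 = radius_t2, lesion_id = as.character(lesion_id)),
            class = "lesion_spec")
}

#' Paired-scan phantom specification
#'
#' Defines the synthetic study conditions for one baseline/follow-up PET
#' pair: a uniform soft-tissue background, spherical focal lesions whose
#' SUV (and optionally size) changes between time points, an isotropic
#' Gaussian point-spread function, additive Gaussian noise in SUV units,
#' and a known rigid misalignment of the follow-up scan. Defaults emulate
#' a clinical whole-body FDG acquisition at desk scale: 96^3 voxels at
#' 2 mm, liver-like background SUV 2, 6 mm FWHM PSF, noise sigma 0.15 SUV.
#'
#' @param lesions List of [lesion_spec] objects.
#' @param grid_shape Voxel counts per axis.
#' @param spacing Voxel spacing, mm.
#' @param background_suv Mean background SUV.
#' @param psf_fwhm PSF full width at half maximum, mm (>= 0).
#' @param noise_sigma Standard deviation of additive SUV noise (>= 0).
#' @param misalignment A [rigid_transform]: the transform mapping the
#'   follow-up scan onto the baseline (i.e. what registration should
#'   recover). The follow-up is generated with lesions displaced through
#'   its inverse.
#' @param seed Integer RNG seed (`NULL` = use the current RNG state).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(lesions, grid_shape = c(96, 96, 96),
                         spacing = c(2, 2, 2), background_suv = 2,
                         psf_fwhm = 6, noise_sigma = 0.15,
                         misalignment = rigid_transform(), seed = NULL) {
  stopifnot(psf_fwhm >= 0, noise_sigma >= 0, background_suv > 0,
            inherits(misalignment, "rigid_transform"))
  if (inherits(lesions, "lesion_spec")) lesions <- list(lesions)
  extent <- (grid_shape - 1) * spacing
  for (ls in lesions) {
    stopifnot(inherits(ls, "lesion_spec"))
    if (any(ls$center - ls$radius < 0) || any(ls$center + ls$radius > extent))
      stop("lesion '", ls$lesion_id, "' is clipped by the grid boundary",
           call. = FALSE)
    if (ls$suv_t1 <= background_suv)
      stop("lesion '", ls$lesion_id,
           "' has no focal uptake (suv_t1 <= background)", call. = FALSE)
  }
  if (length(lesions) > 1) {
    for (i in seq_along(lesions)) for (j in seq_len(i - 1)) {
      dmin <- lesions[[i]]$radius + lesions[[j]]$radius
      if (sqrt(sum((lesions[[i]]$center - lesions[[j]]$center)^2)) <= dmin)
        stop("lesions '", lesions[[j]]$lesion_id, "' and '",
             lesions[[i]]$lesion_id, "' overlap", call. = FALSE)
    }
  }
  structure(list(grid_shape = as.integer(grid_shape),
                 spacing = as.numeric(spacing),
                 background_suv = background_suv, lesions = lesions,
                 psf_fwhm = psf_fwhm, noise_sigma = noise_sigma,
                 misalignment = misalignment, seed = seed),
            class = "phantom_spec")
}

#' Generate a baseline/follow-up phantom pair with known ground truth
#'
#' The baseline scan is the background plus spherical lesions at their
#' baseline SUV, convolved with the Gaussian PSF, plus additive Gaussian
#' noise. The follow-up scan is built the same way at the follow-up SUV
#' and radius, with the lesion spheres displaced through the inverse of
#' the misalignment transform (so the misalignment itself maps the
#' follow-up back onto the baseline). Spheres are rasterized analytically
#' at their displaced positions, so no interpolation error enters the
#' simulated scans. Identical seeds give bit-identical output.
#'
#' @param spec A [phantom_spec].
#' @param response_threshold Percent decrease of true mean SUV at or
#'   beyond which a lesion counts as a ground-truth responder (default
#'   30, mirroring the PERCIST convention).
#' @return A list with elements `baseline` and `followup`
#'   ([pet_volume]s) and `truth`: per-lesion true percent changes and
#'   labels, the patient label (responder only if all lesions respond),
#'   and the true misalignment.
#' @export
generate_pair <- function(spec, response_threshold = 30) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  d <- spec$grid_shape; sp <- spec$spacing
  minv <- invert_transform(spec$misalignment)

  scene <- function(time) {
    arr <- array(spec$background_suv, dim = d)
    for (ls in spec$lesions) {
      ctr <- ls$center
      r <- if (time == 1) ls$radius else ls$radius_t2
      suv <- if (time == 1) ls$suv_t1 else ls$suv_t2
      if (time == 2 && !is_identity_transform(spec$misalignment))
        ctr <- as.numeric(transform_points(minv, ctr))
      sph <- rasterize_sphere(d, sp, c(0, 0, 0), ctr, r)
      arr[sph] <- suv
    }
    arr
  }
  make_frame <- function(time, id) {
    arr <- gaussian_blur(scene(time), sp, spec$psf_fwhm)
    if (spec$noise_sigma > 0)
      arr <- arr + array(rnorm(prod(d), 0, spec$noise_sigma), dim = d)
    pet_volume(pmax(arr, 0), sp, c(0, 0, 0), frame_id = id)
  }
  baseline <- make_frame(1, "t1")
  followup <- make_frame(2, "t2")

  change <- vapply(spec$lesions, function(ls)
    100 * (ls$suv_t2 - ls$suv_t1) / ls$suv_t1, numeric(1))
  labels <- ifelse(change <= -response_threshold, "responder",
                   "non_responder")
  truth <- list(
    lesions = data.frame(
      lesion_id = vapply(spec$lesions, `[[`, character(1), "lesion_id"),
      organ = vapply(spec$lesions, `[[`, character(1), "organ"),
      suv_t1 = vapply(spec$lesions, `[[`, numeric(1), "suv_t1"),
      suv_t2 = vapply(spec$lesions, `[[`, numeric(1), "suv_t2"),
      true_change_pct = change,
      label = labels,
      stringsAsFactors = FALSE),
    patient_label = if (all(labels == "responder")) "responder"
                    else "non_responder",
    misalignment = spec$misalignment,
    response_threshold = response_threshold)
  list(baseline = baseline, followup = followup, truth = truth)
}

# organ frequencies of the emulated lesion population
default_organ_weights <- function() {
  c(node = 44, bone = 43, liver = 17, breast = 10, lung = 5,
    peritoneum = 4) / 123
}

#' Generate a synthetic patient cohort with known response labels
#'
#' Builds `n_patients` paired-scan phantom specifications with randomized
#' lesion geometry, organ labels drawn from a clinically inspired
#' distribution (node : bone : liver : breast : lung : peritoneum =
#' 44 : 43 : 17 : 10 : 5 : 4), at most two lesions per organ per patient,
#' and a random rigid misalignment per pair. Per-lesion true mean-SUV
#' percent changes are drawn from a three-component mixture: clear
#' responses (-85% to -40%), boundary-straddling changes (-45% to -12%),
#' and stable/progressing disease (-5% to +5% or +30% to +80%). A lesion
#' is a ground-truth responder when its true change is at or below
#' `-response_threshold`; a patient responds only if every lesion does,
#' and every non-responding patient carries at least one clearly stable
#' or progressing lesion.
#'
#' Volumes are not generated here (a cohort of dense volumes would be
#' needlessly large); call [generate_pair] on each element of `$patients`
#' or set `materialize = TRUE` for small cohorts.
#'
#' @param n_patients Number of patients (>= 1).
#' @param response_mix Named proportions for patient labels, summing to 1
#'   (default half responders).
#' @param seed Integer RNG seed for the whole cohort.
#' @param lesions_per_patient Integer vector of candidate lesion counts.
#' @param grid_shape,spacing,background_suv,psf_fwhm,noise_sigma Passed
#'   to [phantom_spec].
#' @param max_translation_mm,max_rotation_deg Bounds of the uniform random
#'   misalignment of each follow-up scan.
#' @param response_threshold Ground-truth response rule, percent decrease.
#' @param materialize If `TRUE`, attach generated volumes to each patient.
#' @param out_dir Optional directory: writes `lesions.csv` (lesion
#'   catalog with voxel seeds) and `gold_standard.csv` (per-pair labels).
#' @return A list with `patients` (each holding `spec`, `truth`,
#'   `pair_id`, `patient_id`), `lesion_catalog`, and `gold_catalog`.
#' @export
generate_cohort <- function(n_patients,
                            response_mix = c(responder = 0.5,
                                             non_responder = 0.5),
                            seed = NULL,
                            lesions_per_patient = 2:5,
                            grid_shape = c(96, 96, 96),
                            spacing = c(2, 2, 2),
                            background_suv = 2, psf_fwhm = 6,
                            noise_sigma = 0.15,
                            max_translation_mm = 5,
                            max_rotation_deg = 2,
                            response_threshold = 30,
                            materialize = FALSE,
                            out_dir = NULL) {
  if (n_patients < 1) stop("n_patients must be >= 1", call. = FALSE)
  if (abs(sum(response_mix) - 1) > 1e-9)
    stop("response_mix proportions must sum to 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pair_seeds <- sample.int(.Machine$integer.max - 1L, n_patients)
  extent <- (grid_shape - 1) * spacing
  center_mm <- extent / 2

  draw_responder_change <- function()
    if (runif(1) < 0.7) runif(1, -85, -40) else runif(1, -45, -31)
  draw_nonresponder_change <- function(clear = FALSE) {
    type <- if (clear) sample(c("stable", "progress"), 1)
            else sample(c("near", "stable", "progress"), 1,
                        prob = c(0.3, 0.35, 0.35))
    switch(type,
           near = runif(1, -28, -12),
           stable = runif(1, -5, 5),
           progress = runif(1, 30, 80))
  }

  patients <- vector("list", n_patients)
  lesion_rows <- list()
  gold_rows <- list()
  for (p in seq_len(n_patients)) {
    patient_id <- sprintf("P%03d", p)
    label <- sample(names(response_mix), 1, prob = response_mix)
    n_les <- if (length(lesions_per_patient) == 1) lesions_per_patient
             else sample(lesions_per_patient, 1)

    organs <- character(0)
    w <- default_organ_weights()
    for (i in seq_len(n_les)) {
      repeat {
        o <- sample(names(w), 1, prob = w)
        if (sum(organs == o) < 2) break
      }
      organs <- c(organs, o)
    }

    # non-overlapping sphere placement with room for background shells
    radii <- runif(n_les, 6, 14)
    centers <- matrix(NA_real_, n_les, 3)
    for (i in seq_len(n_les)) {
      margin <- radii[i] + 24
      for (try in 1:500) {
        cand <- runif(3, margin, extent - margin)
        ok <- TRUE
        if (i > 1) {
          dists <- sqrt(rowSums(sweep(centers[seq_len(i - 1), , drop = FALSE],
                                      2, cand)^2))
          ok <- all(dists > radii[i] + radii[seq_len(i - 1)] + 24)
        }
        if (ok) { centers[i, ] <- cand; break }
      }
      if (any(is.na(centers[i, ])))
        stop("could not place ", n_les, " non-overlapping lesions; ",
             "reduce lesions_per_patient or enlarge the grid", call. = FALSE)
    }

    changes <- numeric(n_les)
    if (label == "responder") {
      for (i in seq_len(n_les)) changes[i] <- draw_responder_change()
    } else {
      changes[1] <- draw_nonresponder_change(clear = TRUE)
      for (i in seq_len(n_les)[-1]) {
        changes[i] <- if (runif(1) < 0.5) draw_responder_change()
                      else draw_nonresponder_change()
      }
    }

    suv_t1 <- runif(n_les, 5, 12)
    lesions <- lapply(seq_len(n_les), function(i)
      lesion_spec(center = centers[i, ], radius = radii[i],
                  suv_t1 = suv_t1[i],
                  suv_t2 = max(suv_t1[i] * (1 + changes[i] / 100), 0),
                  organ = organs[i],
                  lesion_id = sprintf("%s_L%d", patient_id, i)))

    mis <- rigid_transform(
      rotation = runif(3, -1, 1) * max_rotation_deg * pi / 180,
      translation = runif(3, -1, 1) * max_translation_mm,
      center = center_mm)
    spec <- phantom_spec(lesions, grid_shape = grid_shape, spacing = spacing,
                         background_suv = background_suv,
                         psf_fwhm = psf_fwhm, noise_sigma = noise_sigma,
                         misalignment = mis, seed = pair_seeds[p])

    true_change <- 100 * (vapply(lesions, `[[`, numeric(1), "suv_t2") -
                            suv_t1) / suv_t1
    lesion_labels <- ifelse(true_change <= -response_threshold,
                            "responder", "non_responder")
    patient_label <- if (all(lesion_labels == "responder")) "responder"
                     else "non_responder"
    pair_id <- sprintf("pair%03d", p)
    seeds_vox <- t(vapply(lesions, function(ls)
      as.integer(round(ls$center / spacing)), integer(3)))
    lesion_rows[[p]] <- data.frame(
      patient_id = patient_id,
      lesion_id = vapply(lesions, `[[`, character(1), "lesion_id"),
      organ = organs,
      seed_x = seeds_vox[, 1], seed_y = seeds_vox[, 2],
      seed_z = seeds_vox[, 3],
      pair_id = pair_id, gold_label = lesion_labels,
      stringsAsFactors = FALSE)
    gold_rows[[p]] <- data.frame(pair_id = pair_id, patient_id = patient_id,
                                 gold_label = patient_label,
                                 stringsAsFactors = FALSE)
    truth <- list(lesions = data.frame(
                    lesion_id = lesion_rows[[p]]$lesion_id,
                    organ = organs, suv_t1 = suv_t1,
                    suv_t2 = vapply(lesions, `[[`, numeric(1), "suv_t2"),
                    true_change_pct = true_change, label = lesion_labels,
                    stringsAsFactors = FALSE),
                  patient_label = patient_label, misalignment = mis,
                  response_threshold = response_threshold)
    patients[[p]] <- list(patient_id = patient_id, pair_id = pair_id,
                          spec = spec, truth = truth)
    if (materialize) {
      pair <- generate_pair(spec, response_threshold)
      patients[[p]]$baseline <- pair$baseline
      patients[[p]]$followup <- pair$followup
    }
  }
  lesion_catalog <- do.call(rbind, lesion_rows)
  gold_catalog <- do.call(rbind, gold_rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(lesion_catalog, file.path(out_dir, "lesions.csv"),
              row.names = FALSE)
    write.csv(gold_catalog, file.path(out_dir, "gold_standard.csv"),
              row.names = FALSE)
  }
  list(patients = patients, lesion_catalog = lesion_catalog,
       gold_catalog = gold_catalog)
}
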