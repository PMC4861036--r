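# Shared fixtures, all generated in code.

# Single centred spherical lesion on a uniform background.
single_lesion_spec <- function(suv_t1 = 10, suv_t2 = 3, radius = 10,
                               background = 2, psf_fwhm = 0,
                               noise_sigma = 0, grid = c(48, 48, 48),
                               spacing = c(2, 2, 2),
                               misalignment = rigid_transform(),
                               seed = 1) {
  ctr <- (grid - 1) * spacing / 2
  phantom_spec(list(lesion_spec(ctr, radius, suv_t1, suv_t2,
                                lesion_id = "L1")),
               grid_shape = grid, spacing = spacing,
               background_suv = background, psf_fwhm = psf_fwhm,
               noise_sigma = noise_sigma, misalignment = misalignment,
               seed = seed)
}

center_seed <- function(grid = c(48, 48, 48)) as.integer((grid - 1) %/% 2)

# True voxelized sphere membership for a centred lesion.
true_sphere_mask <- function(grid = c(48, 48, 48), spacing = c(2, 2, 2),
                             radius = 10) {
  ctr <- (grid - 1) * spacing / 2
  petresponse:::rasterize_sphere(grid, spacing, c(0, 0, 0), ctr, radius)
}

# Multi-lesion phantom with lesions spread out, good for registration.
spread_lesion_spec <- function(misalignment = rigid_transform(),
                               noise_sigma = 0.15, psf_fwhm = 6,
                               seed = 42) {
  lesions <- list(
    lesion_spec(c(60, 60, 60), 9, 8, 8, lesion_id = "a"),
    lesion_spec(c(130, 70, 110), 10, 10, 10, organ = "bone",
                lesion_id = "b"),
    lesion_spec(c(80, 130, 80), 8, 7, 7, organ = "liver",
                lesion_id = "c"),
    lesion_spec(c(120, 120, 140), 11, 9, 9, organ = "lung",
                lesion_id = "d"))
  phantom_spec(lesions, psf_fwhm = psf_fwhm, noise_sigma = noise_sigma,
               misalignment = misalignment, seed = seed)
}

# A lesion_voi wrapping an arbitrary connected mask.
voi_from_mask <- function(mask, id = "L", organ = "node") {
  idx <- which(mask, arr.ind = TRUE) - 1L
  lesion_voi(id, organ, idx[1, ], mask)
}
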