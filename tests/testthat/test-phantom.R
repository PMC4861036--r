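test_that("a no-change pair with zero noise reproduces the baseline", {
  spec <- single_lesion_spec(suv_t1 = 8, suv_t2 = 8, psf_fwhm = 6,
                             noise_sigma = 0, seed = 1)
  pair <- generate_pair(spec)
  expect_identical(pair$followup$values, pair$baseline$values)
  expect_equal(pair$truth$lesions$true_change_pct, 0)
  expect_equal(pair$truth$lesions$label, "non_responder")
})

test_that("ground truth encodes the specified mean-SUV change", {
  spec <- single_lesion_spec(suv_t1 = 10, suv_t2 = 3)
  pair <- generate_pair(spec)
  expect_equal(pair$truth$lesions$true_change_pct, -70)
  expect_equal(pair$truth$lesions$label, "responder")
  expect_equal(pair$truth$patient_label, "responder")
})

test_that("equal seeds give bit-identical volumes, different seeds differ", {
  spec <- single_lesion_spec(noise_sigma = 0.15, psf_fwhm = 6, seed = 9)
  a <- generate_pair(spec)
  b <- generate_pair(spec)
  expect_identical(a$baseline$values, b$baseline$values)
  expect_identical(a$followup$values, b$followup$values)
  spec2 <- single_lesion_spec(noise_sigma = 0.15, psf_fwhm = 6, seed = 10)
  expect_false(identical(generate_pair(spec2)$baseline$values,
                         a$baseline$values))
})

test_that("noiseless unblurred lesions hit their nominal SUV", {
  # radius 10 mm >= 3 * 2 mm spacing: voxelization error under 2%
  spec <- single_lesion_spec(suv_t1 = 10, suv_t2 = 10, psf_fwhm = 0,
                             noise_sigma = 0)
  pair <- generate_pair(spec)
  sph <- true_sphere_mask()
  expect_equal(mean(pair$baseline$values[sph]), 10, tolerance = 0.02)
  expect_equal(mean(pair$baseline$values[!sph]), 2, tolerance = 1e-12)
})

test_that("background noise matches the nominal sigma", {
  spec <- phantom_spec(
    list(lesion_spec(c(63, 63, 63), 8, 10, 10, lesion_id = "L")),
    grid_shape = c(64, 64, 64), spacing = c(2, 2, 2),
    psf_fwhm = 0, noise_sigma = 0.15, seed = 2)
  pair <- generate_pair(spec)
  bg <- !petresponse:::rasterize_sphere(c(64, 64, 64), c(2, 2, 2),
                                        c(0, 0, 0), c(63, 63, 63), 12)
  expect_equal(sd(pair$baseline$values[bg]), 0.15, tolerance = 0.05)
})

test_that("misaligned pairs place lesions where the transform says", {
  mis <- rigid_transform(translation = c(6, -4, 2))
  spec <- single_lesion_spec(suv_t1 = 10, suv_t2 = 10, psf_fwhm = 0,
                             noise_sigma = 0, misalignment = mis)
  pair <- generate_pair(spec)
  # mapping the follow-up through the misalignment restores the baseline
  realigned <- resample_through(pair$followup, mis, pair$baseline)
  sph <- true_sphere_mask(radius = 8)  # stay clear of the sphere edge
  expect_equal(realigned$values[sph], pair$baseline$values[sph],
               tolerance = 1e-6)
})

test_that("invalid lesion layouts are rejected", {
  expect_error(single_lesion_spec(suv_t1 = 1.5), "focal uptake")
  big <- lesion_spec(c(4, 40, 40), 10, 10, 3)
  expect_error(phantom_spec(list(big), grid_shape = c(48, 48, 48)),
               "clipped")
  a <- lesion_spec(c(40, 40, 40), 10, 10, 3, lesion_id = "a")
  b <- lesion_spec(c(50, 40, 40), 10, 10, 3, lesion_id = "b")
  expect_error(phantom_spec(list(a, b)), "overlap")
})

test_that("cohort generation respects the response mix and organ caps", {
  coh <- generate_cohort(12, response_mix = c(responder = 1),
                         seed = 5, lesions_per_patient = 2:4)
  expect_true(all(coh$gold_catalog$gold_label == "responder"))
  expect_true(all(coh$lesion_catalog$gold_label == "responder"))
  counts <- table(coh$lesion_catalog$patient_id,
                  coh$lesion_catalog$organ)
  expect_true(all(counts <= 2))
})

test_that("patient labels are the conjunction of lesion labels", {
  coh <- generate_cohort(25, seed = 8)
  for (pt in coh$patients) {
    expect_equal(pt$truth$patient_label,
                 if (all(pt$truth$lesions$label == "responder"))
                   "responder" else "non_responder")
  }
})

test_that("organ frequencies approximate the clinical distribution", {
  # draw enough lesions for a goodness-of-fit test at alpha = 0.01
  set.seed(3)
  w <- petresponse:::default_organ_weights()
  draws <- character(0)
  organs <- character(0)
  for (rep in 1:700) {
    organs_pt <- character(0)
    for (i in 1:3) {
      repeat {
        o <- sample(names(w), 1, prob = w)
        if (sum(organs_pt == o) < 2) break
      }
      organs_pt <- c(organs_pt, o)
    }
    draws <- c(draws, organs_pt)
  }
  coh <- generate_cohort(100, seed = 31, lesions_per_patient = 3)
  obs <- table(factor(coh$lesion_catalog$organ, levels = names(w)))
  # compare against the empirical law of the capped sampler itself
  ref <- table(factor(draws, levels = names(w))) / length(draws)
  gof <- suppressWarnings(chisq.test(obs, p = as.numeric(ref)))
  expect_gt(gof$p.value, 0.01)
  # and the rare organs stay rare, frequent ones frequent
  expect_gt(obs[["node"]], obs[["peritoneum"]])
  expect_gt(obs[["bone"]], obs[["lung"]])
})

test_that("cohorts are reproducible and write their catalogs", {
  dir <- withr::local_tempdir()
  a <- generate_cohort(4, seed = 77, out_dir = dir)
  b <- generate_cohort(4, seed = 77)
  expect_identical(a$lesion_catalog, b$lesion_catalog)
  expect_identical(a$gold_catalog, b$gold_catalog)
  les <- read.csv(file.path(dir, "lesions.csv"))
  expect_identical(nrow(les), nrow(a$lesion_catalog))
  expect_true(all(c("patient_id", "lesion_id", "organ", "seed_x",
                    "seed_y", "seed_z", "pair_id", "gold_label") %in%
                    names(les)))
  expect_true(file.exists(file.path(dir, "gold_standard.csv")))
})

test_that("degenerate cohort requests error", {
  expect_error(generate_cohort(0), "n_patients")
  expect_error(generate_cohort(2, response_mix = c(responder = 0.7,
                                                   non_responder = 0.7)),
               "sum to 1")
})
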