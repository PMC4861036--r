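test_that("suv_max equals a brute-force scan of masked voxels", {
  set.seed(1)
  for (i in 1:10) {
    vals <- array(runif(16^3, 0, 12), c(16, 16, 16))
    v <- pet_volume(vals, c(2, 2, 2))
    mask <- array(FALSE, c(16, 16, 16))
    mask[5:9, 6:10, 4:8] <- TRUE
    voi <- voi_from_mask(mask)
    expect_identical(suv_max(v, voi), max(vals[mask]))
  }
})

test_that("suv_peak matches the rasterized-sphere oracle for a hot voxel", {
  d <- c(24, 24, 24); sp <- c(2, 2, 2)
  vals <- array(0, d)
  vals[12, 12, 12] <- 100
  v <- pet_volume(vals, sp)
  mask <- array(FALSE, d); mask[12, 12, 12] <- TRUE
  # independent rasterization of the 1 cm^3 sphere (voxel centers)
  r <- (3 * 1000 / (4 * pi))^(1 / 3)
  g <- expand.grid(x = -4:4, y = -4:4, z = -4:4)
  n_sphere <- sum(2 * sqrt(g$x^2 + g$y^2 + g$z^2) <= r)
  expect_equal(suv_peak(v, voi_from_mask(mask)), 100 / n_sphere)
  expect_equal(100 / n_sphere, 0.8, tolerance = 0.15)  # ~125 voxels
})

test_that("suv_peak equals a constant field's value and respects bounds", {
  v <- pet_volume(array(5, c(20, 20, 20)), c(2, 2, 2))
  mask <- array(FALSE, c(20, 20, 20)); mask[10, 10, 10] <- TRUE
  expect_equal(suv_peak(v, voi_from_mask(mask)), 5)
  tiny <- pet_volume(array(5, c(4, 4, 4)), c(2, 2, 2))
  mask4 <- array(FALSE, c(4, 4, 4)); mask4[2, 2, 2] <- TRUE
  expect_error(suv_peak(tiny, voi_from_mask(mask4)), "sphere")
})

test_that("suv_peak never exceeds suv_max on random phantom lesions", {
  set.seed(2)
  for (i in 1:25) {
    vals <- array(runif(20^3, 0, 10), c(20, 20, 20))
    v <- pet_volume(vals, c(2, 2, 2))
    mask <- array(FALSE, c(20, 20, 20))
    lo <- sample(5:8, 3, replace = TRUE)
    mask[lo[1]:(lo[1] + 6), lo[2]:(lo[2] + 6), lo[3]:(lo[3] + 6)] <- TRUE
    voi <- voi_from_mask(mask)
    expect_lte(suv_peak(v, voi), suv_max(v, voi))
  }
})

test_that("mean, volume, and TLG follow their definitions", {
  vals <- array(2, c(12, 12, 12))
  mask <- array(FALSE, c(12, 12, 12))
  mask[which(array(TRUE, c(12, 12, 12)))[1:100]] <- TRUE
  mask[] <- FALSE; mask[1:4, 1:5, 1:5] <- TRUE  # 100 connected voxels
  vals[mask] <- 5
  v <- pet_volume(vals, c(2, 2, 2))
  out <- suv_mean_mv_tlg(v, voi_from_mask(mask))
  expect_equal(out$mv, 100 * 8 / 1000)  # 0.8 mL
  expect_equal(out$suv_mean, 5)
  expect_equal(out$tlg, 5 * 0.8)
})

test_that("SAM equals the closed-form excess on an ideal sphere", {
  pair <- generate_pair(single_lesion_spec(suv_t1 = 10, suv_t2 = 10,
                                           psf_fwhm = 0, noise_sigma = 0))
  v <- pair$baseline
  voi <- segment_lesion(v, center_seed())
  vol_ml <- sum(true_sphere_mask()) * 0.008
  expect_equal(sam(v, voi), (10 - 2) * vol_ml, tolerance = 1e-9)
})

test_that("SAM of a background-only region is near zero", {
  set.seed(3)
  vals <- array(2 + rnorm(40^3, 0, 0.15), c(40, 40, 40))
  v <- pet_volume(pmax(vals, 0), c(2, 2, 2))
  mask <- array(FALSE, c(40, 40, 40)); mask[18:22, 18:22, 18:22] <- TRUE
  s <- sam(v, voi_from_mask(mask))
  expect_lt(abs(s), 0.5)  # SUV.mL, vs ~8 SUV.mL for a real lesion
})

test_that("SAM is robust to the dilation margin where TLG is not", {
  # blurred sphere: partial-volume redistribution stays inside the
  # enlarged region, so SAM barely moves across margins 4-12 mm
  pair <- generate_pair(single_lesion_spec(suv_t1 = 10, suv_t2 = 10,
                                           psf_fwhm = 6, noise_sigma = 0))
  v <- pair$baseline
  voi <- segment_lesion(v, center_seed())
  sams <- vapply(c(4, 8, 12), function(m) sam(v, voi, margin_mm = m),
                 numeric(1))
  # the 4 mm margin loses a sliver of the blurred tail (the adaptive
  # mask sits ~1 mm inside the true sphere); spread stays under 8%
  expect_lt((max(sams) - min(sams)) / mean(sams), 0.08)
  # whereas the true excess is under-covered by the tight mask's TLG
  true_excess <- (10 - 2) * sum(true_sphere_mask()) * 0.008
  expect_equal(mean(sams), true_excess, tolerance = 0.05)
})

test_that("SUV metrics scale with intensity while MV does not", {
  pair <- generate_pair(single_lesion_spec(psf_fwhm = 6,
                                           noise_sigma = 0.1, seed = 4))
  v <- pair$baseline
  voi <- segment_lesion(v, center_seed())
  k <- 2.5
  vk <- pet_volume(k * v$values, v$spacing, v$origin)
  m <- compute_all_metrics(v, voi)
  mk <- compute_all_metrics(vk, voi)
  expect_equal(mk$suv_max, k * m$suv_max)
  expect_equal(mk$suv_peak, k * m$suv_peak)
  expect_equal(mk$suv_mean, k * m$suv_mean)
  expect_equal(mk$tlg, k * m$tlg)
  expect_equal(mk$sam, k * m$sam, tolerance = 1e-9)
  expect_equal(mk$mv, m$mv)
})

test_that("the six metrics satisfy their joint invariants on phantoms", {
  for (seed in 1:4) {
    pair <- generate_pair(single_lesion_spec(suv_t1 = 9, suv_t2 = 9,
                                             psf_fwhm = 6,
                                             noise_sigma = 0.15,
                                             seed = seed))
    v <- pair$baseline
    voi <- segment_lesion(v, center_seed())
    m <- compute_all_metrics(v, voi)
    expect_lte(m$suv_mean, m$suv_peak + 1e-9)
    expect_lte(m$suv_peak, m$suv_max + 1e-9)
    expect_equal(m$tlg, m$suv_mean * m$mv, tolerance = 1e-9)
    expect_gte(m$mv, 0)
    expect_equal(m$suv_max, suv_max(v, voi))
    expect_equal(m$suv_peak, suv_peak(v, voi))
    expect_equal(m$sam, sam(v, voi))
  }
})

test_that("partial-volume error hits SAM less than TLG on small lesions", {
  # diameter 12 mm < 2 * FWHM: blur removes a large share of the
  # excess from a tight mask but not from the enlarged region
  spec <- single_lesion_spec(suv_t1 = 10, suv_t2 = 10, radius = 5,
                             psf_fwhm = 7, noise_sigma = 0)
  pair <- generate_pair(spec)
  v <- pair$baseline
  voi <- segment_lesion(v, center_seed())
  vol <- sum(true_sphere_mask(radius = 5)) * 0.008
  true_tlg <- 10 * vol
  true_sam <- (10 - 2) * vol
  meas <- compute_all_metrics(v, voi)
  rel_tlg <- abs(meas$tlg - true_tlg) / true_tlg
  rel_sam <- abs(meas$sam - true_sam) / true_sam
  expect_lt(rel_sam, rel_tlg)
})
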