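# Independent per-voxel least-squares oracle: given factors (cb, ce),
# solve s = ib * cb + ie * ce for every voxel with base R.
ls_oracle <- function(s1, s2, cb, ce) {
  A <- cbind(cb, ce)
  coef <- t(apply(cbind(s1, s2), 1, function(s)
    solve(t(A) %*% A, t(A) %*% s)))
  list(ib = coef[, 1], ie = coef[, 2])
}

test_that("identical frames give a degenerate model with zero evolution", {
  pair <- generate_pair(single_lesion_spec(psf_fwhm = 6,
                                           noise_sigma = 0.1, seed = 1))
  m <- fads_two_frame(pair$baseline, pair$baseline)
  expect_true(m$degenerate)
  expect_true(all(m$i_e == 0))
  # the background factor alone reconstructs both frames
  expect_equal(m$i_b, pair$baseline$values, tolerance = 1e-12)
})

test_that("a two-population volume separates constant and evolving voxels", {
  d <- c(10, 10, 10)
  s1 <- array(4, d); s2 <- array(4, d)
  s1[1:5, 1:2, 1] <- 8; s2[1:5, 1:2, 1] <- 2  # 10 evolving voxels
  f1 <- pet_volume(s1, c(2, 2, 2), frame_id = "t1")
  f2 <- pet_volume(s2, c(2, 2, 2), frame_id = "t2")
  m <- fads_two_frame(f1, f2)
  expect_false(m$degenerate)
  evolving <- s1 != 4
  expect_true(all(abs(m$i_e[evolving]) > 0))
  expect_true(all(abs(m$i_e[!evolving]) < 1e-9))
  # per-voxel coefficients match the independent least-squares solution
  oracle <- ls_oracle(as.numeric(s1), as.numeric(s2), m$c_b, m$c_e)
  expect_equal(as.numeric(m$i_b), oracle$ib, tolerance = 1e-6)
  expect_equal(as.numeric(m$i_e), oracle$ie, tolerance = 1e-6)
  # and the reconstruction is exact
  r1 <- m$i_b * m$c_b[1] + m$i_e * m$c_e[1]
  r2 <- m$i_b * m$c_b[2] + m$i_e * m$c_e[2]
  expect_equal(as.numeric(r1), as.numeric(s1), tolerance = 1e-9)
  expect_equal(as.numeric(r2), as.numeric(s2), tolerance = 1e-9)
})

test_that("factor images agree with least squares across random models", {
  set.seed(42)
  for (i in 1:100) {
    d <- c(6, 6, 6)
    n <- prod(d)
    base <- runif(1, 2, 6)
    s1 <- array(base + rnorm(n, 0, 0.05), d)
    s2 <- array(s1 + rnorm(n, 0, 0.05), d)
    n_ev <- sample(10:40, 1)
    idx <- sample(n, n_ev)
    shift <- runif(1, 2, 6) * sample(c(-1, 1), 1)
    s2[idx] <- s2[idx] + shift
    f1 <- pet_volume(pmax(s1, 0), c(2, 2, 2))
    f2 <- pet_volume(pmax(s2, 0), c(2, 2, 2))
    m <- fads_two_frame(f1, f2)
    expect_false(m$degenerate)
    oracle <- ls_oracle(as.numeric(f1$values), as.numeric(f2$values),
                        m$c_b, m$c_e)
    expect_equal(as.numeric(m$i_b), oracle$ib, tolerance = 1e-6)
    expect_equal(as.numeric(m$i_e), oracle$ie, tolerance = 1e-6)
  }
})

test_that("a responding lesion dominates the evolution image support", {
  spec <- single_lesion_spec(suv_t1 = 10, suv_t2 = 3, psf_fwhm = 0,
                             noise_sigma = 0)
  pair <- generate_pair(spec)
  m <- fads_two_frame(pair$baseline, pair$followup)
  nz <- sultan_image(m)$values != 0
  truth <- true_sphere_mask()
  expect_gte(sum(nz & truth) / sum(nz), 0.8)
  expect_gte(sum(nz & truth) / sum(truth), 0.8)
})

test_that("the significance mask applies the |Ie| > threshold rule", {
  m <- structure(list(c_b = c(1, 1), c_e = c(0.9, 0.3),
                      i_e = array(c(0.5, -1.5, 2.0, rep(0, 5)),
                                  c(2, 2, 2)),
                      i_b = array(2, c(2, 2, 2)), degenerate = FALSE),
                 class = "factor_model")
  img <- sultan_image(m, threshold = 1)
  expect_equal(as.numeric(img$values)[1:3], c(0, -1.5, 2.0))
  expect_equal(img$direction, "decreasing")
  # nonzero count equals the brute-force count on a random field
  set.seed(1)
  m$i_e <- array(rnorm(64), c(4, 4, 4))
  img2 <- sultan_image(m, threshold = 0.8)
  expect_equal(sum(img2$values != 0), sum(abs(m$i_e) > 0.8))
  expect_true(all(abs(img2$values[img2$values != 0]) > 0.8))
})

test_that("lesion classification follows the direction/sign rule", {
  d <- c(8, 8, 8)
  mask <- array(FALSE, d); mask[3:5, 3:5, 3:5] <- TRUE
  voi <- voi_from_mask(mask)
  mk_img <- function(direction, ie_val) {
    vals <- array(0, d); vals[mask] <- ie_val
    structure(list(values = vals, threshold = 1, direction = direction,
                   degenerate = FALSE), class = "sultan_image")
  }
  expect_equal(classify_lesion_sultan(mk_img("decreasing", 2), voi),
               "responder")
  expect_equal(classify_lesion_sultan(mk_img("increasing", 2), voi),
               "non_responder")
  expect_equal(classify_lesion_sultan(mk_img("increasing", -2), voi),
               "responder")
  expect_equal(classify_lesion_sultan(mk_img("decreasing", -2), voi),
               "non_responder")
  expect_equal(classify_lesion_sultan(mk_img("decreasing", 0), voi),
               "non_responder")
})

test_that("patient classification is the all-responders conjunction", {
  expect_equal(classify_patient_sultan(c("responder", "responder")),
               "responder")
  expect_equal(classify_patient_sultan(c("responder", "non_responder")),
               "non_responder")
  expect_equal(classify_patient_sultan("responder"), "responder")
  expect_equal(classify_patient_sultan("non_responder"), "non_responder")
  expect_error(classify_patient_sultan(character(0)), "at least one")
})

test_that("swapping frame order flips direction and classification", {
  spec <- single_lesion_spec(suv_t1 = 10, suv_t2 = 3, psf_fwhm = 6,
                             noise_sigma = 0.1, seed = 5)
  pair <- generate_pair(spec)
  voi <- segment_lesion(pair$baseline, center_seed())
  fwd <- sultan_image(fads_two_frame(pair$baseline, pair$followup))
  rev <- sultan_image(fads_two_frame(pair$followup, pair$baseline))
  expect_equal(fwd$direction, "decreasing")
  expect_equal(rev$direction, "increasing")
  expect_equal(classify_lesion_sultan(fwd, voi), "responder")
  expect_equal(classify_lesion_sultan(rev, voi), "non_responder")
})

test_that("a stable noisy pair is recognized as evolution-free", {
  spec <- single_lesion_spec(suv_t1 = 8, suv_t2 = 8, psf_fwhm = 6,
                             noise_sigma = 0.15, seed = 6)
  pair <- generate_pair(spec)
  m <- fads_two_frame(pair$baseline, pair$followup)
  expect_true(m$degenerate)
  voi <- segment_lesion(pair$baseline, center_seed())
  expect_equal(classify_lesion_sultan(sultan_image(m), voi),
               "non_responder")
})

test_that("heterogeneous pairs classify each lesion by its own sign", {
  lesions <- list(
    lesion_spec(c(60, 60, 60), 10, 10, 3, lesion_id = "down"),
    lesion_spec(c(130, 130, 130), 10, 6, 10, organ = "bone",
                lesion_id = "up"))
  spec <- phantom_spec(lesions, psf_fwhm = 6, noise_sigma = 0.1,
                       seed = 7)
  pair <- generate_pair(spec)
  img <- sultan_image(fads_two_frame(pair$baseline, pair$followup))
  voi_down <- segment_lesion(pair$baseline, c(30, 30, 30),
                             lesion_id = "down")
  voi_up <- segment_lesion(pair$baseline, c(65, 65, 65),
                           lesion_id = "up", organ = "bone")
  expect_equal(classify_lesion_sultan(img, voi_down), "responder")
  expect_equal(classify_lesion_sultan(img, voi_up), "non_responder")
  expect_equal(classify_patient_sultan(c(
    classify_lesion_sultan(img, voi_down),
    classify_lesion_sultan(img, voi_up))), "non_responder")
})
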