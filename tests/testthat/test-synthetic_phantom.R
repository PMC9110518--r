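test_that("blur-free sphere paints exactly the analytic voxel set", {
  dims <- c(24, 24, 24)
  center <- (dims - 1) / 2 * 3.9
  gen <- make_sphere_volume(dims, 3.9, bg = 1, hot = 9, radius = 12,
                            center = center)
  supra <- sum(gen$volume$data > 1)
  expect_equal(supra, sphere_center_count(dims, 3.9, center, 12))
  expect_equal(gen$truth$lesions[[1]]$true_volume_cm3,
               supra * 3.9^3 / 1000)
})

test_that("cold cores revert to background before blurring", {
  dims <- c(24, 24, 24)
  center <- (dims - 1) / 2 * 3.9
  ph <- phantom_spec(shape = dims, spacing_mm = rep(3.9, 3),
                     background_suv = 2,
                     lesions = list(lesion_spec(center, 14, 20,
                                                cold_core_fraction = 0.5)),
                     blur_fwhm_mm = 0, seed = 1)
  gen <- generate_phantom(ph)
  vol <- image_volume(gen$volume$data, spacing = rep(3.9, 3))
  xyz <- bonespectq:::voxel_center_coords(vol)
  d2 <- rowSums(sweep(xyz, 2, center, "-")^2)
  inner <- d2 <= 7^2
  outer_shell <- d2 <= 14^2 & d2 > 7^2
  expect_true(all(gen$volume$data[inner] == 2))
  expect_true(all(gen$volume$data[outer_shell] == 20))
  expect_false(any(gen$truth$lesions[[1]]$mask[inner]))
})

test_that("phantom generation is bit-deterministic given its seed", {
  ph <- phantom_spec(shape = c(20, 20, 20), spacing_mm = rep(3.9, 3),
                     background_suv = 5,
                     lesions = list(lesion_spec(rep(9.5 * 3.9, 3), 12, 25)),
                     blur_fwhm_mm = 8,
                     noise = list(type = "poisson", scale = 50), seed = 77)
  a <- generate_phantom(ph)$volume$data
  b <- generate_phantom(ph)$volume$data
  expect_identical(a, b)
  ph2 <- ph; ph2$seed <- 78L
  expect_false(identical(a, generate_phantom(ph2)$volume$data))
})

test_that("Gaussian blur conserves total intensity away from the boundary", {
  ph <- phantom_spec(shape = c(40, 40, 40), spacing_mm = rep(3.9, 3),
                     background_suv = 3,
                     lesions = list(lesion_spec(rep(19.5 * 3.9, 3), 15, 30)),
                     blur_fwhm_mm = 8, seed = 1)
  blurred <- generate_phantom(ph)$volume$data
  ph0 <- ph; ph0$blur_fwhm_mm <- 0
  sharp <- generate_phantom(ph0)$volume$data
  expect_lt(abs(sum(blurred) / sum(sharp) - 1), 0.005)
})

test_that("lesions outside the grid are rejected", {
  ph <- phantom_spec(shape = c(10, 10, 10), spacing_mm = rep(3.9, 3),
                     lesions = list(lesion_spec(c(0, 0, 0), 20, 25)))
  expect_error(generate_phantom(ph), class = "spec_error")
})

test_that("cohort generator reproduces its specified stage structure", {
  sim <- generate_cohort(cohort_spec(seed = 5))
  expect_equal(as.vector(table(sim$truth$stage)), c(3L, 16L, 4L))
  expect_equal(nrow(sim$truth), 23L)
  expect_equal(sim$truth$rtbu, sim$truth$rsuv_mean * sim$truth$mbv_cm3)

  # degenerate sigma: every stage-2 MBV equals the stage-2 median
  sim0 <- generate_cohort(cohort_spec(mbv_sigma = 0, seed = 5))
  expect_equal(sim0$truth$mbv_cm3[sim0$truth$stage == 2], rep(15.28, 16),
               tolerance = 1e-12)
})

test_that("large cohorts recover the specified log-normal medians", {
  big <- generate_cohort(cohort_spec(counts = c(4000, 4000, 4000), seed = 9))
  med <- tapply(big$truth$mbv_cm3, big$truth$stage, median)
  expect_true(all(abs(med / c(8.28, 15.28, 34.61) - 1) < 0.05))
  medr <- tapply(big$truth$rsuv_mean, big$truth$stage, median)
  expect_true(all(abs(medr / c(4.93, 5.03, 4.89) - 1) < 0.05))
})

test_that("cohort generation is deterministic and phantom specs are coherent", {
  s1 <- generate_cohort(cohort_spec(seed = 33), make_phantoms = TRUE)
  s2 <- generate_cohort(cohort_spec(seed = 33), make_phantoms = TRUE)
  expect_identical(s1$truth, s2$truth)
  expect_length(s1$phantoms, 23)
  ph <- s1$phantoms[[1]]
  r <- ph$lesions[[1]]$semi_axes_mm[1]
  expect_equal(4 / 3 * pi * r^3 / 1000, s1$truth$mbv_cm3[1], tolerance = 1e-9)
  expect_identical(ph$control_region$role, "control")
})

test_that("blur-free phantoms recover MBV exactly through the full pipeline", {
  sim <- generate_cohort(cohort_spec(blur_fwhm_mm = 0, seed = 12),
                         make_phantoms = TRUE)
  rec <- recover_and_score(sim$phantoms[1:6], sim$truth[1:6, ])
  expect_equal(rec$recovered_mbv, rec$true_mbv, tolerance = 1e-12)
  expect_equal(rec$recovered_suv_mean, rec$true_suv_mean, tolerance = 1e-12)
})

test_that("blurred recovery stays within the frozen calibrated envelope", {
  # the histogram threshold sits low on the lesion-background contrast, so
  # blurred spheres over-segment; the calibrated regression envelope for
  # spheres >= 8 cm^3 at 8 mm FWHM is (0, 1.05] relative error
  sim <- generate_cohort(cohort_spec(seed = 20), make_phantoms = TRUE)
  keep <- sim$truth$mbv_cm3 >= 8
  rec <- recover_and_score(sim$phantoms[keep], sim$truth[keep, ])
  expect_true(all(rec$mbv_rel_error > 0))
  expect_true(all(rec$mbv_rel_error <= 1.05))
  # Poisson noise widens the recovery envelope by < 10 percentage points
  simn <- generate_cohort(cohort_spec(noise = list(type = "poisson",
                                                   scale = 100), seed = 20),
                          make_phantoms = TRUE)
  recn <- recover_and_score(simn$phantoms[keep], simn$truth[keep, ])
  expect_true(all(abs(recn$mbv_rel_error) <= 1.05 + 0.10))
})

test_that("recovered MBV preserves the ranking of true MBV", {
  sim <- generate_cohort(cohort_spec(seed = 2), make_phantoms = TRUE)
  rec <- recover_and_score(sim$phantoms, sim$truth)
  expect_gte(cor(rec$true_mbv, rec$recovered_mbv, method = "spearman"), 0.9)
})
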