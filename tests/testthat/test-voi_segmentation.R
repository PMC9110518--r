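test_that("threshold estimation matches the hand-built histogram fixture", {
  vals <- c(rep(10, 100), rep(12, 94), rep(14, 50))
  est <- estimate_threshold(vals, threshold_params(n_bins = 3))
  expect_equal(est$mode_value, 10)
  expect_equal(est$base_value, 12)      # first bin at <= 95% of modal count
  expect_equal(est$sd, sd(vals))
  expect_equal(est$threshold, 12 + 0.5 * sd(vals))

  est95 <- estimate_threshold(vals, threshold_params(n_bins = 3,
                                                     base_rule = "value95"))
  expect_equal(est95$base_value, 9.5)
  expect_equal(est95$threshold, 9.5 + 0.5 * sd(vals))
})

test_that("degenerate threshold inputs follow the contract", {
  const <- estimate_threshold(rep(5, 1000))
  expect_equal(const$mode_value, 5)
  expect_equal(const$sd, 0)
  expect_equal(const$threshold, 5)

  single <- estimate_threshold(7.5)
  expect_equal(single$threshold, 7.5)
  expect_equal(single$sd, 0)

  expect_error(estimate_threshold(numeric(0)), class = "input_error")
  expect_error(threshold_params(sd_multiplier = -1), class = "input_error")
})

test_that("threshold estimate agrees with a brute-force oracle on random lists", {
  set.seed(42)
  for (i in 1:60) {
    n <- sample(20:400, 1)
    vals <- round(runif(n, 0, 50), sample(0:2, 1))
    if (diff(range(vals)) == 0) vals[1] <- vals[1] + 1
    nb <- sample(c(8L, 32L, 128L), 1)
    rule <- sample(c("freq95", "value95"), 1)
    est <- estimate_threshold(vals, threshold_params(n_bins = nb,
                                                     base_rule = rule))
    ora <- brute_force_threshold(vals, nb, 0.5, rule)
    expect_identical(est$histogram$bins, ora$bins)
    expect_equal(est$mode_value, ora$mode_value, tolerance = 1e-12)
    expect_lt(abs(est$threshold - ora$threshold), 1e-9)
  }
})

test_that("uniform hot sphere on empty background segments to exactly its voxels", {
  gen <- make_sphere_volume(bg = 0, hot = 10, radius = 12)
  suv <- gen$volume
  center <- (dim(suv$data) - 1) / 2 * 3.9
  seed <- seed_region("box", center, half_extents_mm = rep(20, 3),
                      role = "lesion_target_range")
  voi <- segment_lesion_voi(suv, seed)
  expect_identical(voi$mask$data, gen$truth$lesions[[1]]$mask)
  # analytic enumeration of centres inside the sphere
  expect_equal(sum(voi$mask$data),
               sphere_center_count(dim(suv$data), 3.9, center, 12))
  # every VOI voxel is supra-threshold
  expect_true(all(suv$data[voi$mask$data] >= voi$threshold_used$threshold))
})

test_that("the VOI is one 26-connected component anchored at the seed maximum", {
  arr <- array(0, dim = c(30, 12, 12))
  arr[4:8, 4:8, 4:8] <- 10          # blob A
  arr[20:24, 4:8, 4:8] <- 8         # blob B, disjoint
  suv <- image_volume(arr, spacing = c(1, 1, 1), units = "suv_percent")
  seed <- seed_region("box", center_mm = c(5, 5, 5),
                      half_extents_mm = c(7, 7, 7),
                      role = "lesion_target_range")
  voi <- segment_lesion_voi(suv, seed)
  in_b <- array(FALSE, dim = dim(arr)); in_b[20:24, 4:8, 4:8] <- TRUE
  expect_equal(sum(voi$mask$data & in_b), 0)
  expect_gt(sum(voi$mask$data), 0)
})

test_that("pure-background seed regions are rejected", {
  suv <- image_volume(array(0, dim = c(10, 10, 10)), spacing = c(2, 2, 2),
                      units = "suv_percent")
  seed <- seed_region("box", c(9, 9, 9), half_extents_mm = c(5, 5, 5),
                      role = "lesion_target_range")
  expect_error(segment_lesion_voi(suv, seed), class = "segmentation_error")
})

test_that("raising the SD multiplier never grows the VOI", {
  gen <- generate_phantom(phantom_spec(
    shape = c(26, 26, 26), spacing_mm = rep(3.9, 3), background_suv = 5,
    lesions = list(lesion_spec(rep(12.5 * 3.9, 3), 14, 25)),
    blur_fwhm_mm = 8, seed = 4))
  seed <- seed_region("box", rep(12.5 * 3.9, 3),
                      half_extents_mm = rep(20, 3),
                      role = "lesion_target_range")
  sizes <- sapply(c(0, 0.25, 0.5, 1, 1.5), function(m)
    sum(segment_lesion_voi(gen$volume, seed,
                           threshold_params(sd_multiplier = m))$mask$data))
  expect_true(all(diff(sizes) <= 0))
})

test_that("re-segmentation with a frozen threshold is idempotent", {
  gen <- make_sphere_volume(bg = 1, hot = 9, radius = 10)
  center <- (dim(gen$volume$data) - 1) / 2 * 3.9
  seed <- seed_region("box", center, half_extents_mm = rep(18, 3),
                      role = "lesion_target_range")
  v1 <- segment_lesion_voi(gen$volume, seed)
  v2 <- segment_lesion_voi(gen$volume, seed,
                           frozen_threshold = v1$threshold_used)
  expect_identical(v1$mask$data, v2$mask$data)
})

test_that("control VOIs are geometric, threshold-free voxel sets", {
  suv <- image_volume(array(1, dim = c(20, 20, 20)),
                      spacing = c(3.9, 3.9, 3.9), units = "suv_percent")
  ctr <- c(9, 9, 9) * 3.9            # exactly on a voxel centre
  voi <- define_control_voi(suv, seed_region("sphere", ctr,
                                             radius_mm = 2 * 3.9,
                                             role = "control"))
  expect_equal(sum(voi$mask$data),
               sphere_center_count(c(20, 20, 20), 3.9, ctr, 2 * 3.9))
  expect_null(voi$threshold_used)
  expect_identical(voi$role, "control")

  tiny <- define_control_voi(suv, seed_region("box", ctr,
                                              half_extents_mm = rep(1, 3),
                                              role = "control"))
  expect_equal(sum(tiny$mask$data), 1)

  far <- seed_region("sphere", c(1e4, 1e4, 1e4), radius_mm = 5,
                     role = "control")
  expect_error(define_control_voi(suv, far), class = "geometry_error")
  expect_error(define_control_voi(suv, seed_region("box", ctr,
                                                   half_extents_mm = rep(1, 3),
                                                   role = "lesion_target_range")),
               class = "input_error")
})
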