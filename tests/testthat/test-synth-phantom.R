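test_that("circular untapered spec yields equal calipers and undefined orientation", {
  gt <- ground_truth_profile(circular_spec())
  expect_equal(gt$feret_max_mm, gt$feret_min_mm)
  expect_true(all(gt$circular_flag))
  expect_true(all(gt$theta_deg == 0))
  expect_equal(gt$eccentricity, rep(0, nrow(gt)))
  expect_equal(diff(range(gt$area_mm2)), 0)
})

test_that("undulation modulates the max caliper at the set wavelength but not the area", {
  spec <- whisker_spec("undulated", length_mm = 40,
                       undulation_wavelength_mm = 2,
                       undulation_amplitude = 0.2)
  gt <- ground_truth_profile(spec)
  # dominant Fourier period of the detrended caliper series equals lambda
  x <- gt$feret_max_mm - fitted(lm(gt$feret_max_mm ~ gt$arc_mm))
  spec_pow <- Mod(fft(x))[2:(nrow(gt) %/% 2)]
  period_mm <- as.numeric(nrow(gt) * 0.03 / which.max(spec_pow))
  expect_equal(period_mm, 2, tolerance = 0.1)
  # area follows only the taper: smooth and monotone decreasing
  expect_true(all(diff(gt$area_mm2) < 0))
})

test_that("over one wavelength the area CV stays under 1% while caliper CV tracks alpha/sqrt(2)", {
  spec <- whisker_spec("undulated", length_mm = 40,
                       undulation_wavelength_mm = 2,
                       undulation_amplitude = 0.2)
  gt <- ground_truth_profile(spec)
  win <- gt$arc_mm >= 19 & gt$arc_mm < 21  # one wavelength, mid-shaft
  cv <- function(v) sd(v) / mean(v)
  expect_lt(cv(gt$area_mm2[win]), 0.01)
  expect_equal(cv(gt$feret_max_mm[win]), 0.2 / sqrt(2), tolerance = 0.05)
})

test_that("voxelization is deterministic and respects the spec grid", {
  ph1 <- generate_phantom(small_undulated_spec())
  ph2 <- generate_phantom(small_undulated_spec())
  expect_identical(ph1$volume, ph2$volume)
  expect_equal(dim(ph1$volume)[3], floor(9 / 0.03))
  expect_equal(attr(ph1$volume, "voxel_size_um"), 30)
  expect_true(all(ph1$volume %in% c(0, 1)))
})

test_that("unresolvable or axis-swapping specs are rejected", {
  expect_error(generate_phantom(small_undulated_spec(voxel_size_um = 300)),
               "unresolvable")
  expect_error(
    ground_truth_profile(whisker_spec("undulated", base_eccentricity = 0.1,
                                      tip_eccentricity = 0.2,
                                      undulation_amplitude = 0.4)),
    "swaps")
  expect_error(whisker_spec("undulated", undulation_amplitude = 0.7))
  expect_error(whisker_spec("undulated", base_eccentricity = 1))
  expect_error(whisker_spec("undulated", length_mm = -2))
})

test_that("halving the voxel size roughly halves the caliper recovery error", {
  errs <- sapply(c(60, 30, 15), function(v) {
    spec <- whisker_spec("undulated", length_mm = 6,
                         undulation_wavelength_mm = 3, voxel_size_um = v)
    ph <- generate_phantom(spec)
    prof <- profile_along_shaft(ph$volume)
    max(abs(prof$feret_max_mm - ph$truth$feret_max_mm),
        abs(prof$feret_min_mm - ph$truth$feret_min_mm))
  })
  expect_true(all(diff(errs) < 0))
  expect_equal(errs[2] / errs[1], 0.5, tolerance = 0.5)
  expect_equal(errs[3] / errs[2], 0.5, tolerance = 0.5)
})

test_that("bent slide layout bows the centerline within the slide plane", {
  spec <- small_undulated_spec(curvature_radius_mm = 50)
  straight <- generate_phantom(spec)
  bent <- generate_phantom(spec, bend = "slide")
  centroid_x <- function(vol, i) {
    idx <- which(vol[, , i] > 0, arr.ind = TRUE)
    mean(idx[, 2])
  }
  n <- dim(straight$volume)[3]
  drift_straight <- centroid_x(straight$volume, n) - centroid_x(straight$volume, 1)
  drift_bent <- centroid_x(bent$volume, n) - centroid_x(bent$volume, 1)
  expect_lt(abs(drift_straight), 1)
  # expected deflection over 9 mm at R = 50 mm is ~0.82 mm = ~27 voxels
  expect_gt(drift_bent, 20)
  # y centroid unaffected: curvature confined to the slide plane
  centroid_y <- function(vol, i) {
    idx <- which(vol[, , i] > 0, arr.ind = TRUE)
    mean(idx[, 1])
  }
  expect_equal(centroid_y(bent$volume, n), centroid_y(bent$volume, 1),
               tolerance = 1)
})
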