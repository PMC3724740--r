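px <- 30  # µm, default pixel pitch used across these tests

test_that("caliper widths and theta match closed forms on random ellipses", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      # base-to-midshaft section sizes at 30 um; orientation of
      # near-circular or very small sections is quantization-limited and is
      # handled by the circular flag instead
      a <- runif(1, 18, 40)
      b <- runif(1, 9, 0.8 * a)
      th <- runif(1, -85, 85)
      m <- make_ellipse_mask(a, b, th, pixel_spacing = px)
      cal <- caliper_widths(m)
      expect_lt(abs(cal["max_caliper"] - 2 * a * px), 2 * px)
      expect_lt(abs(cal["min_caliper"] - 2 * b * px), 2 * px)
      ang <- principal_axis_theta(m)
      expect_false(ang$circular)
      expect_lt(abs(ang$theta_deg - th), 2)
    }
  })
})

test_that("a digitized disc is isotropic with undefined orientation", {
  m <- make_ellipse_mask(10, 10, 0, pixel_spacing = px)
  cal <- caliper_widths(m)
  expect_lt(abs(cal["max_caliper"] - 20 * px), 2 * px)
  expect_lt(abs(cal["min_caliper"] - 20 * px), 2 * px)
  th <- principal_axis_theta(m)
  expect_true(th$circular)
  expect_equal(th$theta_deg, 0)
})

test_that("metrics are rotation-invariant and scale-covariant", {
  m <- make_ellipse_mask(24, 11, 20, pixel_spacing = px)
  rot <- cross_section_mask(t(m$mask)[ncol(m$mask):1, ], px)  # 90 deg turn
  expect_identical(sum(m$mask), sum(rot$mask))  # area exact
  cal <- caliper_widths(m); cal_r <- caliper_widths(rot)
  expect_lt(abs(cal["max_caliper"] - cal_r["max_caliper"]), 2 * px)
  expect_lt(abs(cal["min_caliper"] - cal_r["min_caliper"]), 2 * px)
  th <- principal_axis_theta(m)$theta_deg
  th_r <- principal_axis_theta(rot)$theta_deg
  wrap <- (th_r - th + 90) %% 180
  expect_lt(min(wrap, 180 - wrap), 2)
  # doubling the pixel spacing doubles lengths exactly, shape terms unchanged
  m2 <- cross_section_mask(m$mask, 2 * px)
  expect_equal(caliper_widths(m2), 2 * cal)
  expect_equal(principal_axis_theta(m2)$theta_deg, th)
  e1 <- eccentricity(cal["max_caliper"], cal["min_caliper"])
  e2 <- eccentricity(2 * cal["max_caliper"], 2 * cal["min_caliper"])
  expect_equal(unname(e1), unname(e2))
})

test_that("eccentricity identities hold and outputs stay in [0, 1)", {
  expect_equal(eccentricity(1, 1), 0)
  expect_equal(eccentricity(2, 1), sqrt(0.75))  # 0.8660
  withr::with_seed(1, {
    mx <- runif(50, 0.5, 3)
    mn <- runif(50, 0.01, 1) * mx
    e <- eccentricity(mx, mn)
    expect_true(all(e >= 0 & e < 1))
  })
  expect_error(eccentricity(2, 0), "positive")
  expect_error(eccentricity(1, 2), "max_caliper")
})

test_that("segment_slice recovers a circular section and flags bad slices", {
  ph <- generate_phantom(circular_spec())  # radius from area 0.6 mm^2
  mid <- dim(ph$volume)[3] %/% 2
  m <- segment_slice(ph$volume, mid)
  area <- sum(m$mask) * (m$pixel_spacing / 1000)^2
  expect_equal(area, 0.6, tolerance = 0.03)
  empty <- array(0, dim = c(8, 8, 2)); attr(empty, "voxel_size_um") <- 30
  expect_error(segment_slice(empty, 1, "fixed", threshold = 0.5),
               "no whisker")
  two <- empty
  two[2:3, 2:3, 1] <- 1; two[6:7, 6:7, 1] <- 1
  expect_error(segment_slice(two, 1, "fixed", threshold = 0.5), "ambiguous")
})

test_that("areas agree across voxel resolutions", {
  a30 <- sum(segment_slice(generate_phantom(circular_spec())$volume, 50)$mask) *
    (30 / 1000)^2
  ph15 <- generate_phantom(circular_spec(voxel_size_um = 15))
  a15 <- sum(segment_slice(ph15$volume, 100)$mask) * (15 / 1000)^2
  expect_equal(a30 / a15, 1, tolerance = 0.03)
})

test_that("shaft profiles recover phantom structure base to tip", {
  ph <- generate_phantom(small_undulated_spec())
  prof <- profile_along_shaft(ph$volume)
  expect_equal(nrow(prof), nrow(ph$truth))
  # eccentricity grows toward the tip (allow voxel-level jitter)
  fit <- lm(prof$eccentricity ~ prof$arc_mm)
  expect_gt(coef(fit)[2], 0)
  # dominant caliper oscillation period equals the generator wavelength
  x <- prof$feret_max_mm - fitted(lm(prof$feret_max_mm ~ prof$arc_mm))
  spec_pow <- Mod(fft(x))[2:(nrow(prof) %/% 2)]
  period <- as.numeric(nrow(prof) * 0.03 / which.max(spec_pow))
  expect_equal(period, 3, tolerance = 0.1)
  # undulated archetype: flattening aligned with the slide plane
  expect_lt(mean(abs(prof$theta_deg)), 5)
  # base (largest area) first regardless of stack orientation
  rev_vol <- ph$volume[, , rev(seq_len(dim(ph$volume)[3]))]
  attr(rev_vol, "voxel_size_um") <- 30
  prof_rev <- profile_along_shaft(rev_vol)
  expect_gt(mean(prof_rev$area_mm2[1:10]), mean(rev(prof_rev$area_mm2)[1:10]))
  expect_equal(prof_rev$area_mm2, prof$area_mm2, tolerance = 1e-12)
})

test_that("smooth-archetype theta recovery matches the configured offset", {
  ph <- generate_phantom(small_smooth_spec())
  prof <- profile_along_shaft(ph$volume)
  expect_equal(mean(prof$theta_deg), 15, tolerance = 0.15)
  expect_length(attr(prof, "crest_indices"), 0)
})

test_that("crest/trough detection counts undulations and enforces alternation", {
  s <- sin(2 * pi * (1:100) / 20) + 2
  ext <- detect_crests_troughs(s)
  expect_length(ext$crest_indices, 5)
  both <- sort(c(ext$crest_indices, ext$trough_indices))
  kinds <- ifelse(both %in% ext$crest_indices, 1, -1)
  expect_true(all(diff(kinds) != 0))
  # smooth series: no extrema
  expect_length(detect_crests_troughs(seq(2, 1, length.out = 50))$crest_indices, 0)
  # phantom with 3 wavelengths over 9 mm
  ph <- generate_phantom(small_undulated_spec())
  prof <- profile_along_shaft(ph$volume)
  expect_gte(length(attr(prof, "crest_indices")), 2)
  expect_lte(length(attr(prof, "crest_indices")), 4)
  expect_error(detect_crests_troughs(c(1, 2, 1)), "short")
})

test_that("area stays consistent across undulations while the caliper swings", {
  ph <- generate_phantom(small_undulated_spec())
  prof <- profile_along_shaft(ph$volume)
  st <- area_consistency_stat(prof)
  expect_true(st$applicable)
  expect_lt(st$area_cv, st$caliper_cv)
  # stronger undulation, larger caliper swing
  # alpha = 0.3 needs a flatter section so the undulation never swaps axes
  ph3 <- generate_phantom(small_undulated_spec(undulation_amplitude = 0.3,
                                               base_eccentricity = 0.9))
  ph1 <- generate_phantom(small_undulated_spec(undulation_amplitude = 0.1,
                                               base_eccentricity = 0.9))
  cv3 <- area_consistency_stat(profile_along_shaft(ph3$volume))$caliper_cv
  cv1 <- area_consistency_stat(profile_along_shaft(ph1$volume))$caliper_cv
  expect_gt(cv3, cv1)
  # a smooth whisker evaluated at arbitrary sections shows ~0 for both
  smooth_prof <- profile_along_shaft(generate_phantom(small_smooth_spec())$volume)
  st0 <- area_consistency_stat(smooth_prof,
                               crest_indices = c(50, 150, 250),
                               trough_indices = c(100, 200))
  expect_lt(st0$caliper_cv, 0.02)
  expect_lt(st0$area_cv, 0.02)
  # too few extrema: not applicable
  expect_false(area_consistency_stat(smooth_prof)$applicable)
})
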