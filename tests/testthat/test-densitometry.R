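# FWHM densitometry: profile extraction, calibration, lobe detection,
# half-maximum localization and full vessel measurement.

test_that("scale calibration converts the 200 um bar and rejects nonsense", {
  expect_equal(calibrate_scale(100)$um_per_px, 2.0)
  expect_equal(calibrate_scale(80)$um_per_px, 2.5)
  expect_error(calibrate_scale(0), "> 0")
  expect_error(calibrate_scale(-5), "> 0")
})

test_that("extract_profile reproduces constant images, image columns, and ramp slopes", {
  img <- matrix(7, 20, 30)
  prof <- extract_profile(img, c(2, 5), c(18, 25))
  expect_true(all(prof$intensities == 7))

  # axis-aligned identity: a vertical line through column 12 returns that column
  img2 <- matrix(rnorm(20 * 30), 20, 30)
  img2 <- img2 + 3  # keep values arbitrary
  prof2 <- extract_profile(img2, c(1, 12), c(20, 12))
  expect_equal(prof2$intensities, img2[, 12], tolerance = 1e-12)

  # diagonal line across a linear ramp: slope per px equals the directional
  # derivative alpha*dr/len + beta*dc/len
  alpha <- 0.7; beta <- -0.3
  ramp <- outer(1:40, 1:40, function(r, c) alpha * r + beta * c)
  p0 <- c(5, 5); p1 <- c(35, 25)
  prof3 <- extract_profile(ramp, p0, p1)
  len <- sqrt(sum((p1 - p0)^2))
  slope_expected <- (alpha * (p1[1] - p0[1]) + beta * (p1[2] - p0[2])) / len
  slopes <- diff(prof3$intensities) / diff(prof3$positions)
  expect_equal(slopes, rep(slope_expected, length(slopes)), tolerance = 1e-9)

  expect_error(extract_profile(img, c(2, 5), c(2, 5)), "zero-length")
  expect_error(extract_profile(img, c(0, 5), c(18, 25)), "inside")
})

test_that("half-max crossings interpolate a triangle lobe exactly and match the Gaussian closed form", {
  # triangle lobes (0, 1, 0) on zero baseline: crossings at peak -/+ 0.5
  tri <- intensity_profile(0:9, c(0, 0, 1, 0, 0, 0, 0, 1, 0, 0))
  lobes <- detect_wall_lobes(
    tri, densitometry_config(polarity = "walls-bright", min_lumen_px = 3))
  expect_equal(half_max_crossings(tri, lobes[[1]]), c(1.5, 2.5))
  expect_equal(half_max_crossings(tri, lobes[[2]]), c(6.5, 7.5))

  # densely sampled Gaussian lobe: FWHM edges at mu +/- sigma*sqrt(2*log(2))
  sigma <- 6
  pos <- seq(0, 200, by = 0.25)
  mu1 <- 60; mu2 <- 140
  y <- exp(-(pos - mu1)^2 / (2 * sigma^2)) + exp(-(pos - mu2)^2 / (2 * sigma^2))
  prof <- intensity_profile(pos, y)
  lob <- detect_wall_lobes(prof, densitometry_config(polarity = "walls-bright"))
  hw <- sigma * sqrt(2 * log(2))
  cr1 <- half_max_crossings(prof, lob[[1]])
  cr2 <- half_max_crossings(prof, lob[[2]])
  expect_lt(abs(cr1[1] - (mu1 - hw)), 0.25)
  expect_lt(abs(cr1[2] - (mu1 + hw)), 0.25)
  expect_lt(abs(cr2[1] - (mu2 - hw)), 0.25)
  expect_lt(abs(cr2[2] - (mu2 + hw)), 0.25)
})

test_that("a lobe truncated by the profile edge raises an open-lobe error", {
  # detect on the full window, then crop the window just past the right wall's
  # peak so its outer flank never descends to the half level
  prof <- generate_vessel_profile(control_phantom(psf = 2, noise = 0),
                                  seed = 1)$profile
  lob <- detect_wall_lobes(prof, densitometry_config(polarity = "walls-bright"))
  i2 <- lob[[2]]$extremum_index
  cropped <- intensity_profile(prof$positions[1:(i2 + 1)],
                               prof$intensities[1:(i2 + 1)])
  expect_error(half_max_crossings(cropped, lob[[2]]), "open lobe")
})

test_that("lobe detection finds wall centres, is polarity-symmetric, and rejects degenerate profiles", {
  spec <- control_phantom(psf = 2, noise = 0)
  prof <- generate_vessel_profile(spec, seed = 1)$profile
  centre <- (length(prof$positions) - 1) / 2
  wall_centres <- centre + c(-1, 1) * (130.71 + 97.21) / 4  # annulus midlines
  lob <- detect_wall_lobes(prof, densitometry_config())
  expect_lt(abs(lob[[1]]$extremum_position - wall_centres[1]), 1)
  expect_lt(abs(lob[[2]]$extremum_position - wall_centres[2]), 1)

  # inverted intensities with auto polarity give the identical lobes
  inv <- intensity_profile(prof$positions, -prof$intensities)
  lob_inv <- detect_wall_lobes(inv, densitometry_config())
  expect_equal(lob_inv[[1]]$extremum_position, lob[[1]]$extremum_position)
  expect_equal(lob_inv[[2]]$extremum_position, lob[[2]]$extremum_position)

  expect_error(detect_wall_lobes(intensity_profile(0:9, 0:9), densitometry_config()),
               "no vessel found")
  expect_error(detect_wall_lobes(intensity_profile(0:9, rep(1, 10)), densitometry_config()),
               "no contrast")
})

test_that("measure_vessel recovers unblurred geometry and propagates failures", {
  prof <- generate_vessel_profile(vessel_phantom_spec(130, 97), seed = 1)$profile
  m <- measure_vessel(prof, calibrate_scale(200))
  expect_lt(abs(m$raod_um - 130), 1)
  expect_lt(abs(m$rald_um - 97), 1)
  expect_true(all(diff(m$boundaries_px) > 0))
  expect_error(measure_vessel(intensity_profile(0:19, 0:19), calibrate_scale(200)),
               "no vessel found")
})

test_that("boundary positions are invariant under affine intensity maps", {
  spec <- control_phantom()
  prof <- generate_vessel_profile(spec, seed = 9)$profile
  ref <- measure_vessel(prof, calibrate_scale(200))$boundaries_px
  set.seed(31)
  for (i in 1:50) {
    a <- runif(1, 0.05, 20)
    b <- runif(1, -100, 100)
    prof2 <- intensity_profile(prof$positions, a * prof$intensities + b)
    b2 <- measure_vessel(prof2, calibrate_scale(200))$boundaries_px
    expect_lt(max(abs(b2 - ref)), 1e-9)
  }
})

test_that("translation shifts boundaries, scale calibration rescales diameters linearly", {
  spec <- control_phantom()
  prof <- generate_vessel_profile(spec, seed = 2)$profile
  m <- measure_vessel(prof, calibrate_scale(200))
  shifted <- intensity_profile(prof$positions + 12.5, prof$intensities)
  ms <- measure_vessel(shifted, calibrate_scale(200))
  expect_equal(ms$boundaries_px, m$boundaries_px + 12.5, tolerance = 1e-9,
               ignore_attr = TRUE)
  expect_equal(coef(ms), coef(m), tolerance = 1e-12)

  mh <- measure_vessel(prof, calibrate_scale(100))
  expect_equal(coef(mh), 2 * coef(m), tolerance = 1e-12)
})

test_that("RAOD exceeds RALD on every successful measurement and blur bias stays below one step", {
  # blurred-boxcar phantoms, no noise: half-max of a blurred step sits at the
  # step, so the bias stays below one sampling step for moderate blur
  # (sigma up to AWT/4; stronger blur erodes the lobe peak and shifts the
  # half level).
  awt <- (130.71 - 97.21) / 2
  for (sigma in c(0, 1, 2, awt / 4)) {
    prof <- generate_vessel_profile(control_phantom(psf = sigma, noise = 0),
                                    seed = 1)$profile
    m <- measure_vessel(prof, calibrate_scale(200))
    expect_gt(m$raod_um, m$rald_um)
    expect_lt(abs(m$raod_um - 130.71), 1)
    expect_lt(abs(m$rald_um - 97.21), 1)
  }
})

test_that("profile CSV round-trips and validation catches malformed profiles", {
  prof <- generate_vessel_profile(control_phantom(), seed = 4)$profile
  path <- withr::local_tempfile(fileext = ".csv")
  write_profile_csv(prof, path)
  back <- read_profile_csv(path)
  expect_equal(back$positions, prof$positions)
  expect_equal(back$intensities, prof$intensities, tolerance = 1e-12)

  expect_error(intensity_profile(c(0, 1, 2, 3, 4, 5, 7), rep(1, 7)), "uniform")
  expect_error(intensity_profile(0:6, c(1, 2, NA, 4, 5, 6, 7)), "finite")
  expect_error(intensity_profile(0:4, rep(1, 5)), "7 samples")
})
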