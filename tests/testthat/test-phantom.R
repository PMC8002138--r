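# Vessel phantom generator: geometry, blur, noise, reproducibility.

test_that("noise-free unblurred phantom has wall plateaus exactly where the geometry says", {
  spec <- vessel_phantom_spec(130, 97, psf_sigma_um = 0, noise_sd = 0, um_per_px = 1)
  out <- generate_vessel_profile(spec, seed = 1)
  prof <- out$profile
  centre <- (length(prof$positions) - 1) / 2
  x <- prof$positions - centre  # um about the vessel centre
  wall <- spec$wall_intensity
  in_wall <- abs(x) > 48.5 & abs(x) < 65
  expect_true(all(prof$intensities[in_wall] == wall))
  expect_true(all(prof$intensities[!in_wall] != wall))
  # lumen and background levels fill the rest; exact-edge samples (x = +/-65
  # here) take the midway value, the sigma -> 0 limit of the blurred edge
  expect_true(all(prof$intensities[abs(x) < 48.5] == spec$lumen_intensity))
  expect_true(all(prof$intensities[abs(x) > 65] == spec$background_intensity))
  expect_true(all(prof$intensities[abs(x) == 65] ==
                    (wall + spec$background_intensity) / 2))
})

test_that("half-max crossings of the sampled noise-free profile sit at the true edges", {
  spec <- vessel_phantom_spec(130, 97)
  prof <- generate_vessel_profile(spec, seed = 1)$profile
  lobes <- detect_wall_lobes(prof, densitometry_config(polarity = "walls-bright"))
  centre <- (length(prof$positions) - 1) / 2
  cl <- half_max_crossings(prof, lobes[[1]]) - centre
  cr <- half_max_crossings(prof, lobes[[2]]) - centre
  step <- prof$step
  expect_lt(abs(cl[1] - (-65)), step)
  expect_lt(abs(cl[2] - (-48.5)), step)
  expect_lt(abs(cr[1] - 48.5), step)
  expect_lt(abs(cr[2] - 65), step)
})

test_that("identical spec and seed reproduce byte-identical profiles; noise is seed-dependent, truth is not", {
  spec <- control_phantom()
  a <- generate_vessel_profile(spec, seed = 42)
  b <- generate_vessel_profile(spec, seed = 42)
  c <- generate_vessel_profile(spec, seed = 43)
  expect_identical(a$profile$intensities, b$profile$intensities)
  expect_false(identical(a$profile$intensities, c$profile$intensities))
  expect_identical(a$truth, c$truth)
})

test_that("ground truth satisfies the morphometric identities to 1e-9 relative error", {
  set.seed(11)
  for (i in 1:25) {
    raod <- runif(1, 80, 180)
    rald <- runif(1, 0.5, 0.9) * raod
    tr <- phantom_ground_truth(vessel_phantom_spec(raod, rald))
    expect_equal(tr$wlr, 2 * tr$awt_um / tr$rald_um, tolerance = 1e-9)
    expect_equal(tr$wcsa_um2, pi * tr$awt_um * (tr$rald_um + tr$awt_um),
                 tolerance = 1e-9)
  }
})

test_that("invalid phantom specs are rejected", {
  expect_error(vessel_phantom_spec(97, 130), "smaller")
  expect_error(vessel_phantom_spec(130, 97, psf_sigma_um = 20,
                                   profile_halfwidth_um = 50),
               "profile window too small")
  expect_error(vessel_phantom_spec(130, 97, wall_intensity = 60,
                                   lumen_intensity = 60), "differ")
  expect_error(vessel_phantom_spec(130, 97, wall_intensity = 20,
                                   polarity = "walls-bright"), "polarity")
})

test_that("repeat-measurement generator: zero error duplicates columns, one repeat errors", {
  truth <- data.frame(vessel_id = 1:8,
                      raod_um = seq(120, 148, by = 4),
                      rald_um = seq(90, 111, by = 3))
  rep0 <- generate_repeat_measurements(truth, error_sd = 0, n_repeats = 2, seed = 1)
  m <- as_repeats_matrix(rep0, "raod_um")
  expect_identical(m[, 1], m[, 2])
  expect_equal(icc_absolute_agreement(m, "single")$icc, 1)
  expect_error(generate_repeat_measurements(truth, 0.5, n_repeats = 1), ">= 2")
  expect_error(generate_repeat_measurements(truth[0, ], 0.5), "non-empty")
})

test_that("near-noiseless repeats give ICC above 0.99, matching the closed-form expectation", {
  # 85 vessels, between-vessel SD 10 um, within-session error SD 0.6 um:
  # expected ICC ~ 100 / (100 + 0.36) = 0.9964.
  truth <- data.frame(
    raod_um = 130.71 + 10 * qnorm((1:85) / 86),
    rald_um = 97.21 + 8 * qnorm((1:85) / 86)
  )
  reps <- generate_repeat_measurements(truth, error_sd = 0.6, n_repeats = 2, seed = 5)
  m <- as_repeats_matrix(reps, "raod_um")
  icc <- icc_absolute_agreement(m, "single")
  expect_gt(icc$icc, 0.99)
  expect_lte(icc$ci_low, icc$icc)
  expect_gte(icc$ci_high, icc$icc)
})
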