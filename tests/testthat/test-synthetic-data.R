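test_that("empty scene gives a uniform background volume", {
  spec <- phantom_spec(c(8, 8, 4), background_intensity = 0.3,
                       smooth_sigma_vox = 0)
  ph <- generate_phantom(spec, seed = 1)
  expect_true(all(ph$magnitude == 0.3))
  expect_length(ph$masks, 0)
})

test_that("ellipsoid mask matches a brute-force inclusion count", {
  spec <- phantom_spec(c(32, 32, 32),
                       structures = list(list(name = "e", center = c(16, 17, 15),
                                              semi_axes = c(4, 4, 2),
                                              intensity = 0.9)))
  ph <- generate_phantom(spec, seed = 1)
  cnt <- 0L
  for (x in 1:32) for (y in 1:32) for (z in 1:32) {
    if (((x - 16) / 4)^2 + ((y - 17) / 4)^2 + ((z - 15) / 2)^2 <= 1) cnt <- cnt + 1L
  }
  expect_equal(sum(ph$masks$e), cnt)
})

test_that("phantom generation is deterministic and rejects out-of-grid structures", {
  spec <- default_phantom_spec(c(16, 16, 8))
  a <- generate_phantom(spec, seed = 7)
  b <- generate_phantom(spec, seed = 7)
  expect_identical(a, b)
  bad <- phantom_spec(c(8, 8, 4),
                      structures = list(list(name = "big", center = c(4, 4, 2),
                                             semi_axes = c(6, 2, 1),
                                             intensity = 0.5)))
  expect_error(generate_phantom(bad, 1), "outside the grid")
})

test_that("phase-map frequencies invert to the stated wavelengths", {
  expect_equal(1 / 1.25e-3, 800)
  expect_equal(1 / 2.50e-3, 400)
})

test_that("degenerate phase map equals the closed-form sinusoid sum", {
  f <- 2e-3
  spec <- phase_map_spec(1, c(f, f), fixed_phase_shift = 0, seed = 4)
  spacing <- c(1.5, 2, 3)
  shape <- c(9, 8, 5)
  pm <- make_phase_map(shape, spacing, spec)
  for (v in list(c(1, 1, 1), c(5, 3, 2), c(9, 8, 5))) {
    expected <- sum(sin(2 * pi * f * (v - 1) * spacing))
    expect_equal(pm[v[1], v[2], v[3]], expected, tolerance = 1e-12)
  }
  expect_identical(pm, make_phase_map(shape, spacing, spec))
  expect_error(make_phase_map(shape, c(0, 1, 1), spec))
  # bounded by amplitude * components per axis
  spec4 <- phase_map_spec(4, seed = 9)
  pm4 <- make_phase_map(c(16, 16, 8), c(1, 1, 1), spec4)
  expect_true(max(abs(pm4)) <= 3 * 4)
})

test_that("analytic motion field honours identity, bounds and centroid shift", {
  mm <- motion_model(c(2, 1, 3), 6, 4)
  shape <- c(16, 16, 8)
  expect_true(all(analytic_motion_dvf(shape, mm, 0)$data == 0))
  expect_true(all(analytic_motion_dvf(shape, motion_model(c(0, 0, 0), 6, 4), 0.7)$data == 0))
  d <- analytic_motion_dvf(shape, mm, 0.5)
  expect_true(max(abs(d$data[, , , 1])) <= 2 + 1e-12)
  expect_true(max(abs(d$data[, , , 3])) <= 3 + 1e-12)
  # warping a central mask shifts its centroid by about the mask-mean displacement
  mask <- array(0L, shape); mask[6:11, 6:11, 3:6] <- 1L
  wm <- warp_mask(mask, d)
  c0 <- colMeans(which(mask > 0, arr.ind = TRUE))
  c1 <- colMeans(which(wm > 0, arr.ind = TRUE))
  md <- vapply(1:3, function(j) mean(d$data[, , , j][mask > 0]), numeric(1))
  # backward warping pulls content against the displacement direction
  expect_equal(as.numeric(c1 - c0), -md, tolerance = 0.35)
})

test_that("complex noise has the drawn standard deviation and is reproducible", {
  vol <- complex_volume(array(0.5 + 0.2i, c(64, 64, 32)))
  spec <- noise_spec(c(4e-3, 4e-3), seed = 6)
  noisy <- add_complex_noise(vol, spec)
  expect_identical(noisy$data, add_complex_noise(vol, spec)$data)
  dr <- Re(noisy$data - vol$data)
  di <- Im(noisy$data - vol$data)
  expect_lt(abs(sd(dr) - 4e-3) / 4e-3, 0.05)
  expect_lt(abs(sd(di) - 4e-3) / 4e-3, 0.05)
  frozen <- add_complex_noise(vol, noise_spec(c(0, 0), seed = 2))
  expect_identical(frozen$data, vol$data)
})

test_that("cohort bins are the reference bin warped by the stored fields", {
  cohort <- generate_cohort(2, default_phantom_spec(c(12, 12, 8)),
                            motion = motion_model(c(0.8, 0.5, 1.5), 5, 3),
                            seed = 21)
  expect_length(cohort, 2)
  for (subj in cohort) {
    expect_true(all(subj$dvfs[[1]]$data == 0))
    for (b in 2:3) {
      rebuilt <- warp_complex(subj$bins_clean[[1]], subj$dvfs[[b]])
      expect_equal(rebuilt$data, subj$bins_clean[[b]]$data, tolerance = 1e-12)
    }
  }
  single <- generate_cohort(1, default_phantom_spec(c(12, 12, 8)),
                            motion = motion_model(c(1, 1, 1), 5, 1), seed = 2)
  expect_length(single[[1]]$bins, 1)
})

test_that("approximate unwarping recovers the reference bin on smooth phantoms", {
  spec <- default_phantom_spec(c(24, 24, 8))
  spec$smooth_sigma_vox <- 2   # a genuinely smooth scene isolates the
  subj <- generate_cohort(1, spec,  # interpolation error of the round trip
                          motion = motion_model(c(0.4, 0.25, 0.6), 8, 4),
                          seed = 33)[[1]]
  for (b in 2:3) {
    inv <- invert_dvf(subj$dvfs[[b]])
    rec <- warp_complex(subj$bins_clean[[b]], inv)
    re <- metric_re(Mod(rec$data), Mod(subj$bins_clean[[1]]$data))
    expect_lt(re, 5)
  }
})

test_that("cohort generation is a pure function of (spec, seed)", {
  a <- generate_cohort(1, default_phantom_spec(c(12, 12, 8)), seed = 5)
  b <- generate_cohort(1, default_phantom_spec(c(12, 12, 8)), seed = 5)
  expect_identical(a[[1]]$bins[[2]]$data, b[[1]]$bins[[2]]$data)
  expect_identical(a[[1]]$dvfs[[3]]$data, b[[1]]$dvfs[[3]]$data)
})
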