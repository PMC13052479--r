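test_that("carrier calibration finds the planted spectral peak", {
  cfg <- default_cfg
  sc <- scene_spec(1, carrier_freq = c(fy = 24 / 96, fx = 256 / 4096))
  acq <- synthesize_frames(sc, cfg, keep_true_phase = FALSE)
  calib <- calibrate_carrier(acq$frames[, , 1], cfg)
  expect_equal(unname(calib$carrier_freq["fy"]), 24 / 96)
  expect_equal(unname(calib$carrier_freq["fx"]), 256 / 4096)

  # shifting the carrier by +3 spectral columns shifts the crop window by +3
  sc2 <- scene_spec(1, carrier_freq = c(fy = 24 / 96, fx = 259 / 4096))
  acq2 <- synthesize_frames(sc2, cfg, keep_true_phase = FALSE)
  calib2 <- calibrate_carrier(acq2$frames[, , 1], cfg)
  expect_identical(calib2$crop_cols[1] - calib$crop_cols[1], 3L)
  expect_identical(calib2$peak_index[2] - calib$peak_index[2], 3L)
})

test_that("a DC-only frame has no off-axis carrier", {
  frame <- matrix(1, 96, 4096)
  expect_error(calibrate_carrier(frame, default_cfg),
               "no off-axis carrier")
})

test_that("demodulation produces half and full resolution fields", {
  sc <- scene_spec(1)
  acq <- synthesize_frames(sc, default_cfg, keep_true_phase = FALSE)
  calib <- calibrate_carrier(acq$frames[, , 1], default_cfg)
  dm <- demodulate(acq$frames[, , 1], calib, default_cfg)
  expect_identical(dim(dm$half$values), c(48L, 2048L))
  expect_identical(dim(dm$full$values), c(96L, 4096L))
  expect_equal(dm$half$pixel_um, 2 * default_cfg$pixel_um)
  expect_equal(dm$full$pixel_um, default_cfg$pixel_um)
})

test_that("a pure fringe frame demodulates to zero phase", {
  sc <- scene_spec(1, background_poly_coeffs = c(0, 0, 0, 0))
  acq <- synthesize_frames(sc, default_cfg, keep_true_phase = FALSE)
  calib <- calibrate_carrier(acq$frames[, , 1], default_cfg)
  dm <- demodulate(acq$frames[, , 1], calib, default_cfg)
  for (res in c("half", "full")) {
    psi <- wrapped_phase(dm[[res]])
    psi <- wrap_phase(psi - mean(psi))  # piston removal
    expect_lt(max(abs(psi)), 1e-6)
  }
  # amplitude convention: unit-contrast fringes give mean amplitude ~ 1
  expect_equal(mean(Mod(dm$full$values)), 1, tolerance = 1e-6)
})

test_that("an in-band smooth phase is recovered almost exactly", {
  # cubic background only: spatially smooth, well within the crop bandwidth
  sc <- scene_spec(1, background_poly_coeffs = c(0.5, 2, -1.5, 0.8))
  acq <- synthesize_frames(sc, default_cfg)
  calib <- calibrate_carrier(acq$frames[, , 1], default_cfg)
  dm <- demodulate(acq$frames[, , 1], calib, default_cfg)
  psi <- wrapped_phase(dm$half)
  truth <- bandlimited_truth(acq, 1, "half", include_static = TRUE)
  err <- wrap_phase(psi - truth)
  err <- wrap_phase(err - mean(err))
  expect_lt(sqrt(mean(err^2)), 0.02)
})

test_that("demodulation is linear in the input frame", {
  sc1 <- scene_spec(1, background_poly_coeffs = c(0.3, 1, 0, 0), seed = 1)
  sc2 <- scene_spec(1, background_poly_coeffs = c(0, -0.5, 1, 0), seed = 2)
  a <- synthesize_frames(sc1, default_cfg, keep_true_phase = FALSE)$frames[, , 1]
  b <- synthesize_frames(sc2, default_cfg, keep_true_phase = FALSE)$frames[, , 1]
  calib <- calibrate_carrier(a, default_cfg)
  da <- demodulate(a, calib, default_cfg)$half$values
  db <- demodulate(b, calib, default_cfg)$half$values
  dab <- demodulate(a + 2 * b, calib, default_cfg)$half$values
  expect_lt(max(Mod(dab - (da + 2 * db))), 1e-9)
})

test_that("half and full resolution phases agree after downsampling", {
  sc <- scene_spec(1, cells = list(cell_spec(1, 1200)))
  acq <- synthesize_frames(sc, default_cfg, keep_true_phase = FALSE)
  calib <- calibrate_carrier(acq$frames[, , 1], default_cfg)
  dm <- demodulate(acq$frames[, , 1], calib, default_cfg)
  ph_half <- wrapped_phase(dm$half)
  ph_full_ds <- downsample2(wrapped_phase(dm$full))
  err <- wrap_phase(ph_half - ph_full_ds)
  err <- wrap_phase(err - mean(err))
  expect_lt(sqrt(mean(err^2)), 0.05)
})

test_that("wrapped phase uses the (-pi, pi] convention", {
  f <- matrix(exp(1i * pi), 2, 2)
  expect_equal(wrapped_phase(f), matrix(pi, 2, 2))
  expect_equal(wrapped_phase(matrix(1 + 0i, 2, 2)), matrix(0, 2, 2))
  expect_equal(wrapped_phase(matrix(exp(1i * 3 * pi / 2), 1, 1)),
               matrix(-pi / 2, 1, 1))
  # zero-magnitude pixels: phase 0 and a validity mask
  f2 <- matrix(c(0 + 0i, 1i), 1, 2)
  ph <- wrapped_phase(f2)
  expect_equal(ph[1, 1], 0)
  expect_identical(attr(ph, "valid")[1, 1], FALSE)
})
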