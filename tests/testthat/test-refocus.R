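cfg <- optics_config()

test_that("propagation is unitary and invertible on the band limit", {
  cf <- make_cell_field()
  U <- cf$field
  # zero distance is the exact identity
  expect_lt(max(Mod(propagate(U, 0, cfg$wavelength_um, cfg$pixel_um) - U)),
            1e-12)
  # d then -d returns the band-limited field exactly: compare on a field
  # already stripped of its evanescent components
  Ubl <- propagate(propagate(U, 1, cfg$wavelength_um, cfg$pixel_um), -1,
                   cfg$wavelength_um, cfg$pixel_um)
  rt <- propagate(propagate(Ubl, 7, cfg$wavelength_um, cfg$pixel_um), -7,
                  cfg$wavelength_um, cfg$pixel_um)
  expect_lt(max(Mod(rt - Ubl)), 1e-10)
  # Parseval: energy conserved on propagating components
  e0 <- sum(Mod(Ubl)^2)
  e1 <- sum(Mod(propagate(Ubl, 13, cfg$wavelength_um, cfg$pixel_um))^2)
  expect_lt(abs(e1 - e0) / e0, 1e-9)
})

test_that("a Gaussian beam expands by the analytic width law", {
  n <- 96L
  w0 <- 2.0  # um
  xy <- (seq_len(n) - (n + 1) / 2) * cfg$pixel_um
  r2 <- outer(xy^2, xy^2, "+")
  U <- exp(-r2 / w0^2) + 0i
  for (d in c(10, 20)) {
    Ud <- propagate(U, d, cfg$wavelength_um, cfg$pixel_um)
    I <- Mod(Ud)^2
    # Gaussian intensity exp(-2 r^2 / w^2) has second moment w^2 / 4
    sig2 <- sum(I * r2) / sum(I) / 2  # per-axis variance
    w_meas <- 2 * sqrt(sig2)
    w_true <- w0 * sqrt(1 + (cfg$wavelength_um * d / (pi * w0^2))^2)
    expect_equal(w_meas, w_true, tolerance = 0.02)
  }
})

test_that("background division recovers the object phase exactly", {
  set.seed(4)
  bg <- matrix(complex(modulus = stats::runif(96 * 96, 0.5, 1.5),
                       argument = stats::runif(96 * 96, -pi, pi)), 96, 96)
  expect_lt(max(Mod(divide_background(bg, bg) - 1)), 1e-12)
  q <- divide_background(bg * exp(1i * 0.7), bg)
  expect_lt(max(abs(Arg(q) - 0.7)), 1e-12)

  # near-zero background pixels are floored and flagged
  bg2 <- bg
  bg2[5, 5] <- 0 + 0i
  q2 <- divide_background(bg, bg2)
  expect_true(attr(q2, "flagged")[5, 5])
  expect_true(all(is.finite(Mod(q2))))
})

test_that("amplitude variance is the population variance of |U|", {
  expect_equal(amplitude_variance(matrix(3 + 4i, 5, 5)), 0)
  f <- matrix(c(1, 1, 3, 3) + 0i, 2, 2)
  expect_equal(amplitude_variance(f), 1.0)
  expect_equal(amplitude_variance(f * exp(1i * 1.1)), 1.0)
})

test_that("autofocus recovers the correcting distance on its grid", {
  af0 <- autofocus(make_cell_field()$field, cfg$wavelength_um, cfg$pixel_um)
  step <- diff(af0$distances_um[1:2])
  expect_equal(step, 48 / 31, tolerance = 1e-12)
  expect_length(af0$distances_um, 32L)
  expect_lte(abs(af0$distance_um), step / 2 + 1e-9)  # in-focus object

  for (d0 in c(-15, 6, 10)) {
    af <- autofocus(make_cell_field(d0)$field, cfg$wavelength_um, cfg$pixel_um)
    expect_lte(abs(af$distance_um - (-d0)), step + 1e-9)
  }
})

test_that("quadratic focus calibration recovers exact and noisy curves", {
  x <- seq(100, 4000, length.out = 128)
  d_exact <- 2e-6 * x^2 - 0.005 * x + 3
  cal <- calibrate_focus(x, d_exact)
  expect_equal(unname(cal$coeffs), c(2e-6, -0.005, 3), tolerance = 1e-9)
  expect_lt(cal$residual_std_um, 1e-9)

  cal_const <- calibrate_focus(x, rep(5, 128))
  expect_equal(unname(cal_const$coeffs), c(0, 0, 5), tolerance = 1e-9)

  set.seed(17)
  d_noisy <- d_exact + stats::rnorm(128, sd = 1)
  cal2 <- calibrate_focus(x, d_noisy)
  td <- tidy(cal2)
  true_vals <- c(a = 2e-6, b = -0.005, c = 3)
  expect_true(all(abs(td$estimate - true_vals[td$term]) <=
                    3 * td$std.error))
  expect_equal(cal2$residual_std_um, 1, tolerance = 0.2)
  expect_equal(glance(cal2)$n_cells_used, 128L)

  expect_error(calibrate_focus(1:2, 1:2), "insufficient")
  expect_warning(calibrate_focus(1:5, c(1, 2, 1.5, 3, 2)), "fewer than 8")
})

test_that("three-depth refocusing selects the calibrated middle in focus", {
  # calibration with zero residual spread: all candidates identical
  x <- seq(100, 4000, length.out = 16)
  cal0 <- calibrate_focus(x, rep(-10, 16))
  cf <- make_cell_field(10)
  bg <- matrix(1 + 0i, 96, 96)
  rc <- refocus_cell(cf$field, bg, 2000, cal0, cfg$wavelength_um, cfg$pixel_um)
  expect_equal(rc$distance_um, -10, tolerance = 1e-9)
  # degenerate spread: the three candidates coincide, the middle is reported
  expect_equal(rc$candidates_um[2], rc$distance_um)
  expect_equal(min(rc$variances), rc$variances[2])

  # refocused phase matches the true focused phase closely
  expect_gt(ssim(rc$phase - corner_offset(rc$phase), cf$phase), 0.98)

  # with spread, a cell on the curve still picks the middle depth
  set.seed(30)
  cal1 <- calibrate_focus(x, rep(-10, 16) + stats::rnorm(16, sd = 0.8))
  d_mid <- predict_focus(cal1, 2000)
  cf2 <- make_cell_field(-d_mid)
  rc2 <- refocus_cell(cf2$field, bg, 2000, cal1,
                      cfg$wavelength_um, cfg$pixel_um)
  expect_identical(which.min(rc2$variances), 2L)
  # the refinement never does worse than the single calibrated depth
  expect_lte(min(rc2$variances), rc2$variances[2])
})

test_that("divide-then-propagate matches propagate-then-divide for thin cells", {
  x <- seq(100, 4000, length.out = 16)
  set.seed(31)
  cal <- calibrate_focus(x, rep(-8, 16) + stats::rnorm(16, sd = 0.5))
  cf <- make_cell_field(8)

  # uniform background (piston + amplitude): the orders commute exactly
  bg0 <- matrix(complex(modulus = 1.3, argument = 0.4), 96, 96)
  r1 <- refocus_cell(cf$field, bg0, 2000, cal, cfg$wavelength_um, cfg$pixel_um)
  r2 <- refocus_cell(cf$field, bg0, 2000, cal, cfg$wavelength_um, cfg$pixel_um,
                     propagate_before_divide = TRUE)
  expect_identical(r1$distance_um, r2$distance_um)
  expect_lt(max(abs(wrap_phase(r1$phase - r2$phase))), 1e-10)

  # background with the tilt scale a simulator crop carries (~0.02 rad
  # across 96 columns): same distance, cell phase agreement well below the
  # pipeline's phase noise floor
  xy <- seq(0, 1, length.out = 96)
  bg_phase <- 0.016 * outer(rep(1, 96), xy) + 0.002 * outer(xy, xy)
  bg <- exp(1i * bg_phase)
  r3 <- refocus_cell(cf$field, bg, 2000, cal, cfg$wavelength_um, cfg$pixel_um)
  r4 <- refocus_cell(cf$field, bg, 2000, cal, cfg$wavelength_um, cfg$pixel_um,
                     propagate_before_divide = TRUE)
  expect_identical(r3$distance_um, r4$distance_um)
  roi <- cf$phase > 0.3
  expect_lt(max(abs(wrap_phase(r3$phase - r4$phase))[roi]), 0.01)
})
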