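cfg <- optics_config()

disk_mask <- function(R, n = 96L, ratio = 1) {
  rr <- outer(seq_len(n) - (n + 1) / 2, rep(1, n))
  cc <- outer(rep(1, n), seq_len(n) - (n + 1) / 2)
  (rr / ratio)^2 + cc^2 <= R^2
}

test_that("corner offset averages the four 8x8 corner blocks", {
  expect_equal(corner_offset(matrix(2.4, 32, 32)), 2.4)
  img <- matrix(0, 32, 32)
  img[1:8, 1:8] <- 1; img[1:8, 25:32] <- 2
  img[25:32, 1:8] <- 3; img[25:32, 25:32] <- 4
  expect_equal(corner_offset(img), 2.5)
  ramp <- matrix(seq_len(40), 40, 40)  # constant along rows
  blocks <- c(mean(1:8), mean(33:40))
  expect_equal(corner_offset(ramp), mean(blocks))
})

test_that("cell masks are cleaned and restricted to the largest component", {
  img <- matrix(0, 96, 96)
  img[disk_mask(15)] <- 1
  m <- cell_mask(img)
  expect_identical(m, disk_mask(15))

  # isolated spikes are removed by the opening
  img2 <- img
  set.seed(5)
  spikes <- cbind(sample(1:10, 10, TRUE), sample(80:96, 10, TRUE))
  img2[spikes] <- 2
  expect_identical(cell_mask(img2), disk_mask(15))

  expect_null(cell_mask(matrix(0.1, 96, 96)))
})

test_that("phase converts to OPL at lambda over two pi", {
  mask <- disk_mask(20)
  img <- matrix(0, 96, 96)
  img[mask] <- 2 * pi
  m <- measure_cell(img, mask, cfg)
  expect_equal(m$mean_opl_um, cfg$wavelength_um)
  expect_equal(m$ov_um3, m$area_um2 * cfg$wavelength_um)
})

test_that("disk area and optical volume match closed forms", {
  mask <- disk_mask(20)
  img <- matrix(0, 96, 96)
  img[mask] <- 1
  m <- measure_cell(img, mask, cfg)
  expect_equal(m$area_um2, pi * (20 * cfg$pixel_um)^2, tolerance = 0.03)
  expect_equal(m$ov_um3, pi * (20 * cfg$pixel_um)^2 * cfg$wavelength_um / (2 * pi),
               tolerance = 0.03)
  expect_lt(m$eccentricity, 0.05)
  expect_gt(m$circularity, 0.95)
  expect_lt(m$circularity, 1.05)
  # Eq. 5/6 consistency: mean OPL x pixel count x dA = OV
  expect_equal(m$mean_opl_um * m$n_pixels * cfg$pixel_um^2, m$ov_um3)
})

test_that("a 2:1 ellipse has eccentricity sqrt(3)/2", {
  mask <- disk_mask(18, ratio = 2)
  img <- matrix(1, 96, 96)
  m <- measure_cell(img, mask, cfg)
  expect_equal(m$eccentricity, sqrt(3) / 2, tolerance = 0.02)
})

test_that("eccentricity is rotation invariant", {
  n <- 96L
  centre <- (n + 1) / 2
  eccs <- vapply(c(0, 30, 90) * pi / 180, function(th) {
    rr <- outer(seq_len(n) - centre, rep(1, n))
    cc <- outer(rep(1, n), seq_len(n) - centre)
    u <- cc * cos(th) + rr * sin(th)
    v <- -cc * sin(th) + rr * cos(th)
    mask <- (u / 2)^2 + v^2 <= 15^2
    measure_cell(matrix(1, n, n), mask, cfg)$eccentricity
  }, numeric(1))
  expect_lt(max(abs(eccs - eccs[1])), 0.02)
})

test_that("circularity of rasterized circles approaches 1", {
  circs <- vapply(c(10, 20, 40), function(R) {
    n <- as.integer(2 * R + 16)
    mask <- disk_mask(R, n)
    measure_cell(matrix(1, n, n), mask, cfg)$circularity
  }, numeric(1))
  expect_true(all(abs(circs - 1) < 0.05))
  # the printed (inverted) variant is available and huge for a circle
  n <- 56L
  m_inv <- measure_cell(matrix(1, n, n), disk_mask(20, n), cfg,
                        circularity_printed_form = TRUE)
  expect_gt(m_inv$circularity, 100)
})

test_that("optical volume scales linearly with phase and pixel area", {
  mask <- disk_mask(15)
  img <- matrix(0, 96, 96)
  img[mask] <- 0.8
  m1 <- measure_cell(img, mask, cfg)
  m2 <- measure_cell(2 * img, mask, cfg)
  expect_equal(m2$ov_um3, 2 * m1$ov_um3)
  cfg2 <- optics_config(pixel_um = 2 * cfg$pixel_um)
  m4 <- measure_cell(img, mask, cfg2)
  expect_equal(m4$area_um2, 4 * m1$area_um2)
  expect_equal(m4$ov_um3, 4 * m1$ov_um3)
})

test_that("the RBC filter applies closed-interval bounds", {
  f <- rbc_filter()
  mid <- tibble::tibble(area_um2 = 50, ov_um3 = 6, mean_opl_um = 0.3,
                        eccentricity = 0.4, circularity = 0.9,
                        perimeter_um = 26, n_pixels = 1200, degenerate = FALSE)
  expect_true(filter_cell(mid, f))
  hi <- mid; hi$area_um2 <- 95
  expect_false(filter_cell(hi, f))
  edge <- mid; edge$area_um2 <- 90  # exactly on the bound: accepted
  expect_true(filter_cell(edge, f))
  ecc <- mid; ecc$eccentricity <- 0.9
  expect_false(filter_cell(ecc, f))
  expect_error(rbc_filter(area_um2 = c(90, 20)))
})
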