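test_that("the detection kernel has the documented geometry", {
  k <- detection_kernel()
  expect_identical(dim(k), c(48L, 24L))
  expect_identical(sort(unique(as.numeric(k))), c(-8, 0, 1))
  expect_true(all(k[1:4, ] == -8) && all(k[45:48, ] == -8))
  expect_equal(k[24, 12], 1)  # centre is inside the disk
  # a fully centred cell scores positive, an edge-overlapping one cannot
  expect_gt(sum(k[k > 0]), 8 * 24)
})

test_that("binarization applies the 0.3 rad threshold", {
  f <- matrix(0, 10, 10)
  expect_false(any(binarize(f)))
  f[3:5, 3:5] <- 1
  expect_identical(sum(binarize(f)), 9L)
  expect_false(any(binarize(matrix(0.2, 10, 10))))
})

test_that("FFT correlation equals the brute-force sliding dot product", {
  set.seed(21)
  kern <- detection_kernel(height = 16L, width = 8L, disk_diameter = 6L,
                           edge_rows = 2L)
  masks <- lapply(1:4, function(i) matrix(stats::runif(16 * 60) > 0.7, 16, 60))
  fft_map <- correlate_batch(masks, kern)
  brute <- holocyto:::correlate_brute(masks, kern)
  expect_lt(max(abs(fft_map - brute)), 1e-6)
  expect_true(all(correlate_batch(lapply(1:3, function(i) matrix(FALSE, 16, 60)),
                                  kern) == 0))
})

test_that("a centred synthetic cell peaks at its true position", {
  masks <- lapply(1:10, function(i) matrix(FALSE, 48, 400))
  # disk mask of radius 9 centred at (24, 200) in frame 6
  rr <- outer((1:48) - 24, rep(1, 400))
  cc <- outer(rep(1, 48), (1:400) - 200)
  masks[[6]] <- rr^2 + cc^2 <= 81
  map <- correlate_batch(masks, detection_kernel())
  peak <- which(map == max(map), arr.ind = TRUE)
  expect_lte(abs(peak[1, 1] - 6), 1)
  expect_lte(abs(peak[1, 2] - 200), 1)
})

test_that("detections are unique, thresholded and edge-rejected", {
  expect_identical(nrow(detect_cells(matrix(0, 80, 500))), 0L)

  kern <- detection_kernel()
  disk_mask <- function(frames, t0, x0, r0 = 9, yc = 24) {
    m <- matrix(FALSE, 48, 500)
    rr <- outer((1:48) - yc, rep(1, 500))
    cc <- outer(rep(1, 48), (1:500) - x0)
    m <- rr^2 + cc^2 <= r0^2
    frames[[t0]] <- frames[[t0]] | m
    frames
  }
  frames <- lapply(1:80, function(i) matrix(FALSE, 48, 500))
  frames <- disk_mask(frames, 10, 80)
  frames <- disk_mask(frames, 40, 250)
  frames <- disk_mask(frames, 70, 420)
  # an edge cell: same disk but centred on the top penalty rows
  frames <- disk_mask(frames, 25, 150, yc = 3)
  map <- correlate_batch(frames, kern)
  det <- detect_cells(map)
  expect_identical(nrow(det), 3L)
  expect_true(all(abs(sort(det$x_half) - c(80, 250, 420)) <= 1))
  expect_true(all(abs(sort(det$frame) - c(10, 40, 70)) <= 1))
  # no detection at the edge cell's position
  expect_false(any(abs(det$frame - 25) <= 2 & abs(det$x_half - 150) <= 2))
})

test_that("background frames are the zero-correlation frames", {
  kern <- detection_kernel()
  empty <- lapply(1:80, function(i) matrix(FALSE, 48, 300))
  map0 <- correlate_batch(empty, kern)
  expect_identical(find_background_frames(map0), 1:80)

  frames <- empty
  rr <- outer((1:48) - 24, rep(1, 300))
  cc <- outer(rep(1, 48), (1:300) - 150)
  disk <- rr^2 + cc^2 <= 81
  for (t in 10:14) frames[[t]] <- disk
  map <- correlate_batch(frames, kern)
  bg <- find_background_frames(map)
  expect_false(any(10:14 %in% bg))
  expect_true(all(c(1:8, 16:80) %in% bg))

  det <- detect_cells(map)
  det <- assign_background_frames(det, bg)
  expect_true(all(det$background_frame %in% bg))
  expect_lte(min(abs(det$background_frame - det$frame)), 6)

  # continuous stream: no background anywhere -> warning and NA
  stream <- lapply(1:20, function(i) disk)
  maps <- correlate_batch(stream, kern)
  expect_length(find_background_frames(maps), 0)
  d2 <- detect_cells(maps)
  expect_warning(d3 <- assign_background_frames(d2, integer(0)),
                 "no background frame")
  expect_true(all(is.na(d3$background_frame)))
})

test_that("detection recall is perfect on a noise-free synthetic scene", {
  cells <- list(cell_spec(5, 800), cell_spec(12, 2000),
                cell_spec(19, 3200, profile = "disk", peak_phase_rad = 1.2))
  sc <- scene_spec(24, cells = cells)
  pr <- process_small_scene(sc)
  masks <- lapply(pr$cleaned, binarize)
  map <- correlate_batch(masks, detection_kernel())
  det <- detect_cells(map)
  truth <- pr$acq$truth$detections
  expect_identical(nrow(det), nrow(truth))
  det <- det[order(det$frame), ]
  expect_true(all(abs(det$frame - truth$frame) <= 1))
  expect_true(all(abs(det$x_half - truth$x_center / 2) <= 1))
})
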