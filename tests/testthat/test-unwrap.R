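test_that("wrapped differences map to (-pi, pi]", {
  expect_equal(wrap_diff(0, 0), 0)
  expect_equal(wrap_diff(-3 * pi / 4, 3 * pi / 4), -pi / 2)
  for (a in c(-2, 0, 1.3)) expect_equal(wrap_diff(a, a + pi), pi)
  expect_equal(wrap_phase(pi), pi)
  expect_equal(wrap_phase(-pi), pi)
})

test_that("residues detect 2 pi loop sums and only those", {
  expect_true(all(phase_residues(matrix(0.7, 8, 8)) == 0L))
  # counter-clockwise steps of pi/2 around one plaquette sum to 2 pi
  psi <- matrix(0, 2, 2)
  psi[1, 1] <- 0; psi[1, 2] <- pi / 2; psi[2, 2] <- pi; psi[2, 1] <- -pi / 2
  expect_identical(phase_residues(psi)[1, 1], 1L)
  expect_identical(phase_residues(-psi)[1, 1], -1L)
})

test_that("residues are antisymmetric under phase negation", {
  for (seed in 1:5) {
    set.seed(seed)
    psi <- wrap_phase(matrix(stats::runif(15 * 15, -4, 4), 15, 15))
    r <- phase_residues(psi)
    rn <- phase_residues(wrap_phase(-psi))
    # negation can move boundary values pi -> pi (not -pi), so compare where
    # no sample sits exactly on the branch boundary
    expect_identical(rn, -r)
  }
})

test_that("branch cuts connect dipoles and lone residues to the edge", {
  shape <- c(20L, 20L)
  expect_identical(place_branch_cuts(matrix(0L, 19, 19), shape),
                   matrix(FALSE, 20, 20))

  # single +1 residue two pixels from the top edge: vertical cut of length 2
  res <- matrix(0L, 19, 19)
  res[2, 10] <- 1L
  cuts <- place_branch_cuts(res, shape)
  expect_true(all(cuts[1:2, 10]))
  expect_identical(sum(cuts), 2L)

  # adjacent +1/-1 dipole in the interior: one short joining cut, no edge cut
  res2 <- matrix(0L, 19, 19)
  res2[10, 10] <- 1L
  res2[10, 11] <- -1L
  cuts2 <- place_branch_cuts(res2, shape)
  expect_true(cuts2[10, 10] && cuts2[10, 11])
  expect_identical(sum(cuts2), 2L)
  expect_false(any(cuts2[1, ]) || any(cuts2[20, ]) ||
                 any(cuts2[, 1]) || any(cuts2[, 20]))
})

test_that("flood fill is exact on smooth fields and wrapped ramps", {
  # already-smooth input: identity
  psi <- matrix(seq(0, 1, length.out = 50), 10, 50, byrow = TRUE)
  expect_equal(floodfill_unwrap(psi), psi)

  # 1D ramp wrapped into (-pi, pi]: recovered up to a global 2 pi multiple
  true <- matrix(0.4 * (0:199), 4, 200, byrow = TRUE)
  rec <- floodfill_unwrap(wrap_phase(true))
  off <- rec - true
  expect_lt(max(abs(off - off[1, 1])), 1e-9)
  expect_equal(off[1, 1] / (2 * pi), round(off[1, 1] / (2 * pi)),
               tolerance = 1e-9)

  # output minus input is everywhere a whole number of wraps
  set.seed(3)
  psi2 <- wrap_phase(matrix(stats::runif(30 * 40, -9, 9), 30, 40))
  rec2 <- floodfill_unwrap(psi2)
  k <- (rec2 - psi2) / (2 * pi)
  expect_lt(max(abs(k - round(k))), 1e-9)
})

test_that("an all-cut block has no seed", {
  psi <- matrix(0, 4, 4)
  cuts <- matrix(TRUE, 4, 4)
  expect_error(floodfill_unwrap(psi, cuts), "no seed")
})

test_that("the default block schedule tiles 2048 columns into 128 blocks", {
  starts <- holocyto:::block_starts(2048L, 20L, 4L)
  expect_length(starts, 128L)
  expect_identical(starts[1], 1L)
  # consecutive blocks overlap by 4 columns; the frame is fully covered
  ends <- pmin(starts + 19L, 2048L)
  expect_true(all(starts[-1] <= ends[-length(ends)] - 3L))
  expect_identical(max(ends), 2048L)
})

test_that("block unwrapping matches the whole-frame flood fill", {
  fld <- smooth_wrapped_field(c(48L, 512L), seed = 11)
  expect_true(all(phase_residues(fld$wrapped) == 0L))
  merged <- unwrap_frame(fld$wrapped)
  oracle <- floodfill_unwrap(fld$wrapped)
  diff <- merged - oracle
  expect_lt(max(abs(diff - diff[1])), 1e-9)  # one global 2 pi multiple
  expect_equal(diff[1] / (2 * pi), round(diff[1] / (2 * pi)), tolerance = 1e-9)
  # and the truth is recovered up to a global offset
  err <- merged - fld$true
  expect_lt(max(abs(err - err[1])), 1e-9)
})

test_that("block flattening restores continuity across many wraps", {
  # a steep ramp spanning ~40 wraps: each block seeds at its own branch,
  # so merging must re-align nearly every junction
  true <- matrix(0.125 * (0:2047), 48, 2048, byrow = TRUE)
  rec <- unwrap_frame(wrap_phase(true))
  err <- rec - true
  expect_lt(max(abs(err - err[1])), 1e-9)
})

test_that("unwrapping is invariant to the block width on clean fields", {
  fld <- smooth_wrapped_field(c(24L, 256L), seed = 5)
  r1 <- unwrap_frame(fld$wrapped, block_cols = 20L, overlap_cols = 4L)
  r2 <- unwrap_frame(fld$wrapped, block_cols = 64L, overlap_cols = 8L)
  d <- r1 - r2
  expect_lt(max(abs(d - d[1])), 1e-9)
})

test_that("wrap consistency holds at every pixel", {
  fld <- smooth_wrapped_field(c(48L, 256L), seed = 9)
  rec <- unwrap_frame(fld$wrapped)
  expect_lt(max(abs(wrap_phase(rec) - fld$wrapped)), 1e-9)
})

test_that("batch unwrapping equals per-frame unwrapping", {
  frames <- lapply(1:3, function(s) smooth_wrapped_field(c(24L, 128L), s)$wrapped)
  batch <- unwrap_batch(frames)
  solo <- lapply(frames, unwrap_frame)
  expect_identical(batch, solo)
  expect_identical(unwrap_batch(list()), list())
})
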