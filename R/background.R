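#' Correct temporal 2 pi unwrapping jumps in a frame batch
#'
#' Within a batch (40 frames in the pipeline), each pixel's temporal median
#' is the reference; any frame value deviating from it by more than `2 pi` is
#' shifted by the integer multiple of `2 pi` bringing it nearest the median.
#' Values are therefore only ever changed by whole wraps.
#'
#' @param frames List of unwrapped phase matrices (all the same shape),
#'   batch length >= 3.
#' @return List of corrected phase matrices.
#' @export
correct_temporal_jumps <- function(frames) {
  stopifnot(is.list(frames), length(frames) >= 3)
  med <- temporal_median(frames)
  lapply(frames, function(f) {
    dev <- f - med
    jump <- abs(dev) > 2 * pi
    if (any(jump)) {
      f[jump] <- f[jump] - 2 * pi * round(dev[jump] / (2 * pi))
    }
    f
  })
}

#' Subtract the per-row cubic phase background
#'
#' The smooth optical-path background across the long axis is removed by
#' fitting a third-order polynomial to each row by least squares and
#' subtracting it (the frame is far wider than tall, so per-row curves stand
#' in for a full 2D cubic surface). By default one robust re-fit excludes
#' pixels whose first-pass residual exceeds `mask_threshold`, so cells do not
#' pull the curve up; rows left with fewer than 4 usable pixels fall back to
#' the plain fit. Set `robust = FALSE` for the direct single-pass fit.
#'
#' @param frame Unwrapped phase matrix (width >= 4).
#' @param mask_threshold Residual threshold in radians for the re-fit.
#' @param robust Perform the masked re-fit (default `TRUE`).
#' @return Phase matrix with the fitted background removed.
#' @export
subtract_row_background <- function(frame, mask_threshold = 0.5,
                                    robust = TRUE) {
  stopifnot(is.matrix(frame), ncol(frame) >= 4)
  x <- seq_len(ncol(frame)) / ncol(frame)
  X <- cbind(1, x, x^2, x^3)
  # one QR for all rows: coefficients for every row at once
  fit <- function(Y, Xd) t(qr.coef(qr(Xd), t(Y)))
  beta <- fit(frame, X)
  bg <- beta %*% t(X)
  if (robust) {
    resid <- frame - bg
    for (r in seq_len(nrow(frame))) {
      keep <- abs(resid[r, ]) <= mask_threshold
      if (sum(keep) >= 4 && any(!keep)) {
        b <- qr.coef(qr(X[keep, , drop = FALSE]), frame[r, keep])
        bg[r, ] <- X %*% b
      }
    }
  }
  frame - bg
}

#' Static background map of a frame batch
#'
#' The channel walls, dust on the chip and any persistent residual
#' unwrapping error appear identically in (almost) every frame, while a
#' flowing cell occupies any given pixel in only a small minority of a
#' 40-frame batch. The pixel-wise temporal median over the batch therefore
#' isolates the static background.
#'
#' @param frames List of phase matrices, batch length >= 5.
#' @return Matrix of the static background (radians), to be subtracted from
#'   every frame of the batch.
#' @export
static_background <- function(frames) {
  stopifnot(is.list(frames), length(frames) >= 5)
  temporal_median(frames)
}

#' Full post-processing of an unwrapped frame batch
#'
#' Applies, in order: temporal 2 pi jump correction, per-row cubic background
#' subtraction, and static background subtraction. The output is the cleaned
#' phase video in which only flowing cells remain.
#'
#' @param frames List of unwrapped phase matrices (>= 5 for the static
#'   background step).
#' @param mask_threshold,robust Passed to [subtract_row_background()].
#' @return List of cleaned phase matrices.
#' @export
postprocess_batch <- function(frames, mask_threshold = 0.5, robust = TRUE) {
  frames <- correct_temporal_jumps(frames)
  frames <- lapply(frames, subtract_row_background,
                   mask_threshold = mask_threshold, robust = robust)
  static <- static_background(frames)
  lapply(frames, function(f) f - static)
}

# Pixel-wise median across a list of equally shaped matrices.
temporal_median <- function(frames) {
  stack <- vapply(frames, as.numeric, numeric(length(frames[[1]])))
  matrix(cpp_row_medians(stack), nrow(frames[[1]]), ncol(frames[[1]]))
}
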