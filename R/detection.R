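#' Cell identification kernel
#'
#' A 2D template the height of the half-resolution frame: a `+1` disk in the
#' centre (diameter ~ one red blood cell at half resolution) and strongly
#' negative bands along the top and bottom rows so that any cell overlapping
#' the edge of the field of view scores below threshold and is rejected.
#'
#' @param height Kernel height = frame height (48 at half resolution).
#' @param width Kernel width in columns.
#' @param disk_diameter Diameter of the `+1` interior disk, pixels.
#' @param edge_rows Number of penalized rows at the top and bottom.
#' @param edge_value Value of the penalty bands (negative).
#' @return Numeric `height x width` matrix.
#' @export
detection_kernel <- function(height = 48L, width = 24L, disk_diameter = 20L,
                             edge_rows = 4L, edge_value = -8) {
  stopifnot(height > 2 * edge_rows, width >= disk_diameter)
  k <- matrix(0, height, width)
  cy <- (height + 1) / 2
  cx <- (width + 1) / 2
  rr <- outer(seq_len(height) - cy, rep(1, width))
  cc <- outer(rep(1, height), seq_len(width) - cx)
  k[rr^2 + cc^2 <= (disk_diameter / 2)^2] <- 1
  if (edge_rows > 0) {
    k[seq_len(edge_rows), ] <- edge_value
    k[height - seq_len(edge_rows) + 1L, ] <- edge_value
  }
  k
}

#' Threshold a cleaned phase frame to a binary cell mask
#'
#' @param frame Cleaned phase matrix (radians).
#' @param threshold Phase threshold in radians (default 0.3).
#' @return Logical matrix, `TRUE` where `frame > threshold`.
#' @export
binarize <- function(frame, threshold = 0.3) {
  frame > threshold
}

#' Correlation map of a detection batch
#'
#' For each frame of the batch (80 frames in the pipeline), the binary mask
#' is cross-correlated with the kernel along the x-axis only, summing over
#' the full frame height: `map[t, x]` is the dot product of the kernel with
#' the mask around column `x` of frame `t`. Computed by FFT with zero-padding
#' (no circular wrap-around); identical to the brute-force sliding dot
#' product to numerical precision.
#'
#' @param masks List of logical/numeric mask matrices of equal shape.
#' @param kernel A [detection_kernel()] whose height equals the mask height.
#' @return Numeric `length(masks) x ncol(mask)` matrix of correlation scores
#'   (class `correlation_map`).
#' @export
correlate_batch <- function(masks, kernel) {
  stopifnot(is.list(masks), length(masks) >= 1)
  h <- nrow(masks[[1]]); nc <- ncol(masks[[1]])
  stopifnot(nrow(kernel) == h)
  kw <- ncol(kernel)
  ctr <- kw %/% 2L + 1L
  L <- nc + kw
  # FFT of the zero-padded kernel rows, once per batch
  K <- matrix(0, L, h)
  K[seq_len(kw), ] <- t(kernel)
  Kf <- Conj(stats::mvfft(K))
  map <- matrix(0, length(masks), nc)
  for (t in seq_along(masks)) {
    m <- masks[[t]]
    stopifnot(nrow(m) == h, ncol(m) == nc)
    M <- matrix(0, L, h)
    M[seq_len(nc), ] <- t(m * 1)
    prod_sum <- rowSums(stats::mvfft(M) * Kf)
    corr <- Re(stats::fft(prod_sum, inverse = TRUE)) / L
    # circular lag l = x - ctr aligns the kernel centre on column x; negative
    # lags wrap into the zero-padding region, so no contamination occurs.
    # Rounding removes FFT noise so symmetric plateaus tie exactly.
    map[t, ] <- round(corr[(seq_len(nc) - ctr) %% L + 1L], 6)
  }
  structure(map, class = c("correlation_map", "matrix", "array"))
}

# Brute-force reference correlation (used as the in-package oracle in tests
# and for tiny inputs).
correlate_brute <- function(masks, kernel) {
  h <- nrow(masks[[1]]); nc <- ncol(masks[[1]])
  kw <- ncol(kernel)
  ctr <- kw %/% 2L + 1L
  map <- matrix(0, length(masks), nc)
  for (t in seq_along(masks)) {
    m <- masks[[t]] * 1
    for (x in seq_len(nc)) {
      js <- seq_len(kw)
      cols <- x + js - ctr
      ok <- cols >= 1L & cols <= nc
      map[t, x] <- sum(m[, cols[ok], drop = FALSE] * kernel[, js[ok], drop = FALSE])
    }
  }
  structure(map, class = c("correlation_map", "matrix", "array"))
}

#' Detect cells on a correlation map
#'
#' Finds 2D local maxima (8-neighbourhood) above `peak_threshold` and accepts
#' them greedily in descending score, excluding further peaks within
#' `min_sep_x` columns and `min_sep_t` frames of an accepted one, so each
#' flowing cell (which scores highly over several consecutive frames) yields
#' exactly one detection: the frame where it is vertically centred in the
#' field of view.
#'
#' @param map A [correlate_batch()] result (frames x columns).
#' @param peak_threshold Minimum score; default half the kernel's positive
#'   mass for the default [detection_kernel()].
#' @param min_sep_x,min_sep_t Exclusion radii (columns at half resolution;
#'   frames).
#' @return A tibble with columns `frame` (row index into the batch), `x_half`
#'   (column at half resolution), `x_full` (`2 * x_half - 1`), `score`.
#' @export
detect_cells <- function(map, peak_threshold = NULL,
                         min_sep_x = 24L, min_sep_t = 5L) {
  if (is.null(peak_threshold)) {
    peak_threshold <- 0.5 * sum(detection_kernel()[detection_kernel() > 0])
  }
  nt <- nrow(map); nc <- ncol(map)
  # local maxima over the 8-neighbourhood (>= neighbours, > threshold)
  pad <- matrix(-Inf, nt + 2, nc + 2)
  pad[2:(nt + 1), 2:(nc + 1)] <- map
  is_max <- matrix(TRUE, nt, nc)
  for (dt in -1:1) for (dx in -1:1) {
    if (dt == 0 && dx == 0) next
    is_max <- is_max & (map >= pad[2:(nt + 1) + dt, 2:(nc + 1) + dx])
  }
  cand <- which(is_max & map > peak_threshold, arr.ind = TRUE)
  if (nrow(cand) == 0) {
    return(tibble::tibble(frame = integer(), x_half = integer(),
                          x_full = integer(), score = numeric()))
  }
  sc <- map[cand]
  ord <- order(-sc, cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]
  sc <- sc[ord]
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (any(keep & abs(cand[, 1] - cand[i, 1]) <= min_sep_t &
              abs(cand[, 2] - cand[i, 2]) <= min_sep_x)) next
    keep[i] <- TRUE
  }
  tibble::tibble(
    frame = as.integer(cand[keep, 1]),
    x_half = as.integer(cand[keep, 2]),
    x_full = as.integer(2L * cand[keep, 2] - 1L),
    score = sc[keep]
  )
}

#' Find empty background frames in a detection batch
#'
#' Frames whose maximum correlation score across all columns stays below
#' `zero_threshold` contain no cell anywhere in the field of view and can
#' serve as clean backgrounds for refocusing.
#'
#' @param map A [correlate_batch()] result.
#' @param zero_threshold Score ceiling for an empty frame; default one tenth
#'   of the default detection threshold.
#' @return Integer vector of frame indices (rows of `map`).
#' @export
find_background_frames <- function(map, zero_threshold = NULL) {
  if (is.null(zero_threshold)) {
    zero_threshold <- 0.05 * sum(detection_kernel()[detection_kernel() > 0])
  }
  which(apply(map, 1, max) < zero_threshold)
}

#' Assign the temporally nearest background frame to each detection
#'
#' @param detections A [detect_cells()] tibble.
#' @param background_frames Integer vector from [find_background_frames()].
#' @return The detections tibble with a `background_frame` column (`NA` when
#'   no background frame exists).
#' @export
assign_background_frames <- function(detections, background_frames) {
  if (nrow(detections) == 0) {
    detections$background_frame <- integer(0)
    return(detections)
  }
  if (length(background_frames) == 0) {
    warning("no background frame available; refocusing will be skipped")
    detections$background_frame <- NA_integer_
    return(detections)
  }
  detections$background_frame <- vapply(detections$frame, function(t) {
    background_frames[which.min(abs(background_frames - t))]
  }, integer(1))
  detections
}
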