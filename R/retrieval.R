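#' Locate the off-axis carrier in the spectrum of the first frame
#'
#' The cross-correlation (sideband) term of an off-axis interferogram sits on
#' a spatial-frequency carrier. Its position is found once per acquisition as
#' the local maximum of the Fourier magnitude of the first captured frame,
#' searched over the positive-`fx` half-plane with a rectangular exclusion
#' zone around the zero-frequency bin (so the DC term can never win). The
#' spectral crop window (`crop_shape`, default 20 x 874) is then centred on
#' the peak and clipped to stay inside the spectral support.
#'
#' @param first_frame Numeric matrix of shape `cfg$frame_shape`.
#' @param cfg An [optics_config()].
#' @param min_peak_ratio The peak magnitude must exceed this multiple of the
#'   median spectral magnitude in the search region, or the calibration fails
#'   with "no off-axis carrier found".
#' @param dc_exclude Integer `(rows, cols)` half-extent of the exclusion
#'   rectangle around DC (default +/-8 rows, +/-64 cols).
#' @return An object of class `carrier_calibration`: list with `peak_index`
#'   (1-based `(row, col)` into the centred spectrum), `carrier_freq`
#'   (cycles/pixel `(fy, fx)`), `crop_rows`, `crop_cols` (index ranges into
#'   the centred spectrum) and `centre` (the zero-frequency bin index).
#' @export
calibrate_carrier <- function(first_frame, cfg,
                              min_peak_ratio = 10,
                              dc_exclude = c(8L, 64L)) {
  validate_optics_config(cfg)
  if (!is.matrix(first_frame) || any(dim(first_frame) != cfg$frame_shape)) {
    stop("first_frame must have shape frame_shape", call. = FALSE)
  }
  S <- fftshift2(stats::fft(first_frame))
  mag <- Mod(S)
  nr <- nrow(mag); nc <- ncol(mag)
  ctr <- c(floor(nr / 2) + 1L, floor(nc / 2) + 1L)

  allowed <- matrix(FALSE, nr, nc)
  allowed[, (ctr[2] + 1L):nc] <- TRUE  # positive-fx half-plane only
  rows_dc <- pmax(1L, ctr[1] - dc_exclude[1]):pmin(nr, ctr[1] + dc_exclude[1])
  cols_dc <- pmax(1L, ctr[2] - dc_exclude[2]):pmin(nc, ctr[2] + dc_exclude[2])
  allowed[rows_dc, cols_dc] <- FALSE

  cand <- mag
  cand[!allowed] <- -Inf
  # lexicographic (row, col) tie-break: scan column-major and keep the first
  peak_lin <- which(cand == max(cand))
  peak_rc <- cbind((peak_lin - 1L) %% nr + 1L, (peak_lin - 1L) %/% nr + 1L)
  ord <- order(peak_rc[, 1], peak_rc[, 2])
  peak <- peak_rc[ord[1], ]

  floor_mag <- max(min_peak_ratio * stats::median(mag[allowed]),
                   1e-9 * mag[ctr[1], ctr[2]])
  if (!is.finite(cand[peak[1], peak[2]]) ||
      mag[peak[1], peak[2]] <= floor_mag) {
    stop("no off-axis carrier found", call. = FALSE)
  }

  ch <- cfg$crop_shape
  row_start <- min(max(peak[1] - ch[1] %/% 2L, 1L), nr - ch[1] + 1L)
  col_start <- min(max(peak[2] - ch[2] %/% 2L, 1L), nc - ch[2] + 1L)
  structure(
    list(
      peak_index = as.integer(peak),
      carrier_freq = c(fy = (peak[1] - ctr[1]) / nr,
                       fx = (peak[2] - ctr[2]) / nc),
      crop_rows = row_start:(row_start + ch[1] - 1L),
      crop_cols = col_start:(col_start + ch[2] - 1L),
      centre = ctr
    ),
    class = "carrier_calibration"
  )
}

#' @export
print.carrier_calibration <- function(x, ...) {
  cat("<carrier_calibration>\n")
  cat(sprintf("  peak at centred bin (%d, %d); carrier (fy, fx) = (%.4f, %.4f) cyc/px\n",
              x$peak_index[1], x$peak_index[2],
              x$carrier_freq[["fy"]], x$carrier_freq[["fx"]]))
  invisible(x)
}

#' Demodulate one interferogram frame
#'
#' Fourier transforms the frame, crops the calibrated sideband window,
#' recentres it on the carrier peak, embeds it in a zero spectrum of the half
#' (48 x 2048) and full (96 x 4096) output shapes, and inverse transforms
#' both. The amplitude is scaled so that a unit-contrast fringe pattern gives
#' a field of mean amplitude ~ the fringe modulation depth at either
#' resolution (the inverse FFT is scaled by the frame size, not the output
#' size, so zero-padding does not change the amplitude).
#'
#' @param frame Numeric matrix of shape `cfg$frame_shape`.
#' @param calib A [calibrate_carrier()] result for this acquisition.
#' @param cfg An [optics_config()].
#' @return A list with elements `half` and `full`, each of class
#'   `complex_field`: list with `values` (complex matrix), `resolution`
#'   (`"half"` or `"full"`) and `pixel_um`.
#' @export
demodulate <- function(frame, calib, cfg) {
  validate_optics_config(cfg)
  stopifnot(inherits(calib, "carrier_calibration"))
  if (!is.matrix(frame) || any(dim(frame) != cfg$frame_shape)) {
    stop("frame must have shape frame_shape", call. = FALSE)
  }
  S <- fftshift2(stats::fft(frame))
  crop <- S[calib$crop_rows, calib$crop_cols]
  # peak position within the crop (1-based)
  pr <- calib$peak_index[1] - calib$crop_rows[1] + 1L
  pc <- calib$peak_index[2] - calib$crop_cols[1] + 1L
  n_frame <- prod(cfg$frame_shape)
  list(
    half = complex_field(embed_ifft(crop, pr, pc, cfg$half_shape, n_frame),
                         "half", 2 * cfg$pixel_um),
    full = complex_field(embed_ifft(crop, pr, pc, cfg$full_shape, n_frame),
                         "full", cfg$pixel_um)
  )
}

# Embed `crop` into a zero spectrum of `out_shape` so that crop element
# (peak_r, peak_c) lands on the zero-frequency bin, then inverse transform.
embed_ifft <- function(crop, peak_r, peak_c, out_shape, n_frame) {
  spec <- matrix(0 + 0i, out_shape[1], out_shape[2])
  ctr <- c(floor(out_shape[1] / 2) + 1L, floor(out_shape[2] / 2) + 1L)
  r0 <- ctr[1] - peak_r + 1L
  c0 <- ctr[2] - peak_c + 1L
  rows <- r0:(r0 + nrow(crop) - 1L)
  cols <- c0:(c0 + ncol(crop) - 1L)
  keep_r <- rows >= 1L & rows <= out_shape[1]
  keep_c <- cols >= 1L & cols <= out_shape[2]
  spec[rows[keep_r], cols[keep_c]] <- crop[keep_r, keep_c]
  stats::fft(ifftshift2(spec), inverse = TRUE) / n_frame
}

complex_field <- function(values, resolution, pixel_um) {
  structure(list(values = values, resolution = resolution,
                 pixel_um = pixel_um),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %d x %d (%s resolution, %.3f um/px)\n",
              nrow(x$values), ncol(x$values), x$resolution, x$pixel_um))
  invisible(x)
}

#' Wrapped phase of a complex field
#'
#' Element-wise principal argument mapped to `(-pi, pi]` (the boundary `-pi`
#' is remapped to `+pi`). Pixels of exactly zero magnitude have undefined
#' phase; they are set to 0 and recorded in a logical `"valid"` attribute
#' (only present when such pixels exist).
#'
#' @param field A `complex_field` (from [demodulate()]) or a complex matrix.
#' @return Numeric matrix of wrapped phase in radians.
#' @export
wrapped_phase <- function(field) {
  v <- if (inherits(field, "complex_field")) field$values else field
  ph <- Arg(v)
  ph[ph <= -pi] <- pi
  zero <- Mod(v) == 0
  if (any(zero)) {
    ph[zero] <- 0
    attr(ph, "valid") <- !zero
  }
  ph
}
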