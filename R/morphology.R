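#' Background phase offset from the image corners
#'
#' Mean of the four 8 x 8 pixel corner blocks of a refocused cell image (256
#' pixels in total); subtracting it removes the residual piston left after
#' background division.
#'
#' @param img Phase matrix, at least 16 x 16.
#' @param block Corner block size (default 8).
#' @return Scalar offset in radians.
#' @export
corner_offset <- function(img, block = 8L) {
  stopifnot(is.matrix(img), nrow(img) >= 2 * block, ncol(img) >= 2 * block)
  nr <- nrow(img); nc <- ncol(img)
  ri <- c(seq_len(block), nr - block + seq_len(block))
  ci <- c(seq_len(block), nc - block + seq_len(block))
  mean(img[ri, ci])
}

#' Segment a cell from its offset-corrected phase image
#'
#' Thresholds the phase, cleans single-pixel noise by a binary opening
#' (erosion then dilation with a disk structuring element), and keeps only
#' the largest 4-connected component.
#'
#' @param img Offset-corrected phase matrix.
#' @param threshold Phase threshold in radians (default 0.3, the same value
#'   the detection stage uses).
#' @param opening_radius Radius of the disk structuring element.
#' @return Logical mask, or `NULL` when no object survives ("no object").
#' @export
cell_mask <- function(img, threshold = 0.3, opening_radius = 1L) {
  m <- img > threshold
  if (!any(m)) return(NULL)
  if (opening_radius > 0) {
    brush <- EBImage::makeBrush(2L * opening_radius + 1L, shape = "disc")
    m <- EBImage::opening(m * 1, brush) > 0.5
    if (!any(m)) return(NULL)
  }
  lab <- label_components4(m)
  sizes <- tabulate(lab[lab > 0])
  m <- lab == which.max(sizes)
  m
}

# 4-connected component labelling by scanline BFS (masks are small, 96x96).
label_components4 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  for (start in which(mask)) {
    if (lab[start] > 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue[[1]]
      queue <- queue[-1]
      r <- (p - 1L) %% nr + 1L
      c <- (p - 1L) %/% nr + 1L
      for (q in c(if (r > 1L) p - 1L, if (r < nr) p + 1L,
                  if (c > 1L) p - nr, if (c < nc) p + nr)) {
        if (mask[q] && lab[q] == 0L) {
          lab[q] <- cur
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

# Crofton 4-direction perimeter of a binary mask, in pixel units.
# Cauchy-Crofton: P = pi/2 * mean over directions of (intersections x line
# spacing); horizontal/vertical spacing 1, diagonal spacing 1/sqrt(2).
crofton_perimeter <- function(mask) {
  m <- mask * 1L
  padr <- rbind(0L, m, 0L)
  padc <- cbind(0L, m, 0L)
  n_h <- sum(abs(padc[, -1] - padc[, -ncol(padc)]))       # along rows
  n_v <- sum(abs(padr[-1, ] - padr[-nrow(padr), ]))       # along cols
  pad2 <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
  pad2[2:(nrow(m) + 1), 2:(ncol(m) + 1)] <- m
  a <- pad2[-nrow(pad2), -ncol(pad2)]
  b <- pad2[-1, -1]
  n_d1 <- sum(abs(a - b))                                  # "\" diagonal
  a2 <- pad2[-nrow(pad2), -1]
  b2 <- pad2[-1, -ncol(pad2)]
  n_d2 <- sum(abs(a2 - b2))                                # "/" diagonal
  (pi / 8) * (n_h + n_v + (n_d1 + n_d2) / sqrt(2))
}

#' Morphological parameters of a refocused cell
#'
#' From the phase image and its binary mask, computes the descriptors used
#' for red-blood-cell screening:
#' * projection area `A = (number of mask pixels) * dA`, `dA = pixel_um^2`;
#' * per-pixel optical path length `OPL = phi * lambda / (2 pi)` (um);
#' * optical volume `OV = dA * sum(OPL over the mask)` (um^3);
#' * mean OPL over the mask (um);
#' * eccentricity of the moment-equivalent ellipse,
#'   `sqrt(1 - lambda_minor / lambda_major)` from the eigenvalues of the
#'   second central moment matrix;
#' * perimeter `C` by the Crofton 4-direction estimator (um);
#' * circularity `4 pi A / C^2` (1 for a perfect circle). The printed
#'   inverted form `4 pi C^2 / A` is available via
#'   `circularity_printed_form = TRUE`.
#'
#' @param img Phase matrix (radians), offset-corrected.
#' @param mask Logical mask from [cell_mask()].
#' @param cfg An [optics_config()] (wavelength and full-resolution pixel
#'   size).
#' @param circularity_printed_form Use the dimensionally inverted circularity
#'   variant instead of `4 pi A / C^2`.
#' @return A one-row tibble: `area_um2`, `ov_um3`, `mean_opl_um`,
#'   `eccentricity`, `circularity`, `perimeter_um`, `n_pixels`, `degenerate`.
#' @export
measure_cell <- function(img, mask, cfg, circularity_printed_form = FALSE) {
  validate_optics_config(cfg)
  stopifnot(is.matrix(img), !is.null(mask), any(mask))
  dA <- cfg$pixel_um^2
  npx <- sum(mask)
  A <- npx * dA
  opl <- img * cfg$wavelength_um / (2 * pi)
  ov <- dA * sum(opl[mask])
  mean_opl <- mean(opl[mask])

  degenerate <- npx < 2
  if (degenerate) {
    ecc <- 0
    circ <- NA_real_
    perim <- crofton_perimeter(mask) * cfg$pixel_um
  } else {
    idx <- which(mask, arr.ind = TRUE)
    mu_r <- mean(idx[, 1]); mu_c <- mean(idx[, 2])
    m20 <- mean((idx[, 2] - mu_c)^2)
    m02 <- mean((idx[, 1] - mu_r)^2)
    m11 <- mean((idx[, 2] - mu_c) * (idx[, 1] - mu_r))
    tr2 <- (m20 + m02) / 2
    det_rt <- sqrt(((m20 - m02) / 2)^2 + m11^2)
    l_major <- tr2 + det_rt
    l_minor <- tr2 - det_rt
    ecc <- if (l_major <= 0) 0 else sqrt(max(0, 1 - l_minor / l_major))
    perim <- crofton_perimeter(mask) * cfg$pixel_um
    circ <- if (circularity_printed_form) {
      4 * pi * perim^2 / A
    } else {
      4 * pi * A / perim^2
    }
  }
  tibble::tibble(
    area_um2 = A, ov_um3 = ov, mean_opl_um = mean_opl,
    eccentricity = ecc, circularity = circ, perimeter_um = perim,
    n_pixels = npx, degenerate = degenerate
  )
}

#' Acceptance bounds for red-blood-cell screening
#'
#' Closed-interval bounds on each morphological parameter used to filter
#' non-RBC objects (debris, doublets, unwrapping artifacts). The defaults
#' are generous ranges around healthy-RBC values and are configuration, not
#' measurements: projection area around the ~50 um^2 of a face-on RBC, and
#' optical volume around refractive-index-contrast times cell volume
#' (~0.06 x 70-120 fL, i.e. a few um^3).
#'
#' @param area_um2,ov_um3 Length-2 `(min, max)` bounds.
#' @param eccentricity_max,circularity_min Scalar bounds.
#' @return An `rbc_filter` list.
#' @export
rbc_filter <- function(area_um2 = c(20, 90), ov_um3 = c(2, 20),
                       eccentricity_max = 0.8, circularity_min = 0.7) {
  stopifnot(area_um2[1] <= area_um2[2], ov_um3[1] <= ov_um3[2])
  structure(list(area_um2 = area_um2, ov_um3 = ov_um3,
                 eccentricity_max = eccentricity_max,
                 circularity_min = circularity_min),
            class = "rbc_filter")
}

#' Does a measured cell pass the RBC filter?
#'
#' All bounds are closed intervals: a parameter exactly on a bound passes.
#'
#' @param m A one-row tibble from [measure_cell()].
#' @param f An [rbc_filter()].
#' @return `TRUE` iff every parameter lies within its bounds.
#' @export
filter_cell <- function(m, f = rbc_filter()) {
  stopifnot(inherits(f, "rbc_filter"))
  if (isTRUE(m$degenerate) || is.na(m$circularity)) return(FALSE)
  m$area_um2 >= f$area_um2[1] && m$area_um2 <= f$area_um2[2] &&
    m$ov_um3 >= f$ov_um3[1] && m$ov_um3 <= f$ov_um3[2] &&
    m$eccentricity <= f$eccentricity_max &&
    m$circularity >= f$circularity_min
}
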