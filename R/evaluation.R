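#' Fine ("traditional") refocusing of one cell
#'
#' Exhaustive amplitude-variance minimization on a 0.1 um grid over the full
#' search range. This is the slow reference method against which the
#' three-depth real-time refocusing is evaluated.
#'
#' @param field Background-divided complex crop of the cell.
#' @param wavelength_um,pixel_um Optics constants.
#' @param d_min_um,d_max_um Search range (default -24 to 24 um).
#' @param step_um Grid step (default 0.1 um).
#' @return A list with `distance_um`, `distances_um`, `variances`.
#' @export
fine_refocus <- function(field, wavelength_um, pixel_um,
                         d_min_um = -24, d_max_um = 24, step_um = 0.1) {
  ds <- seq(d_min_um, d_max_um, by = step_um)
  v <- variance_profile(field, ds, wavelength_um, pixel_um)
  best <- which(v == min(v))
  best <- best[which.min(abs(ds[best]))]
  list(distance_um = ds[best], distances_um = ds, variances = v)
}

#' Global structural similarity index of two images
#'
#' Whole-image SSIM with population statistics:
#' `SSIM = (2 mu_x mu_y + c1)(2 sigma_xy + c2) /
#'         ((mu_x^2 + mu_y^2 + c1)(sigma_x^2 + sigma_y^2 + c2))`.
#' Images are compared on the phase (radian) scale.
#'
#' @param x,y Numeric matrices of the same shape.
#' @param c1,c2 Stabilizing constants (defaults 2.22e-3 and 2.00e-2).
#' @return SSIM scalar; 1 iff the images are identical.
#' @export
ssim <- function(x, y, c1 = 2.22e-3, c2 = 2.00e-2) {
  stopifnot(is.matrix(x), is.matrix(y), all(dim(x) == dim(y)),
            c1 > 0, c2 > 0)
  mx <- mean(x); my <- mean(y)
  vx <- pop_var(x); vy <- pop_var(y)
  cxy <- mean((x - mx) * (y - my))
  (2 * mx * my + c1) * (2 * cxy + c2) /
    ((mx^2 + my^2 + c1) * (vx + vy + c2))
}

#' Root mean square error of two phase maps, on the optical path length scale
#'
#' `sqrt(mean((x - y)^2)) * lambda / (2 pi)`: the phase RMSE converted to
#' micrometres of optical path length, so a constant offset of `2 pi` rad
#' gives an RMSE of one wavelength.
#'
#' @param x,y Phase matrices (radians) of the same shape.
#' @param wavelength_um Wavelength in micrometres.
#' @return RMSE in micrometres.
#' @export
rmse_opl <- function(x, y, wavelength_um) {
  stopifnot(all(dim(x) == dim(y)))
  sqrt(mean((x - y)^2)) * wavelength_um / (2 * pi)
}

# Per-cell comparison metrics of a candidate phase image against the fine
# reference image: morphological percent errors / absolute differences,
# OPL RMSE and SSIM, as one named numeric vector.
cell_metrics <- function(candidate, reference, cfg, mask_threshold = 0.3) {
  cand <- candidate - corner_offset(candidate)
  ref <- reference - corner_offset(reference)
  mr <- cell_mask(ref, threshold = mask_threshold)
  mc <- cell_mask(cand, threshold = mask_threshold)
  if (is.null(mr) || is.null(mc)) return(NULL)
  ref_m <- measure_cell(ref, mr, cfg)
  cand_m <- measure_cell(cand, mc, cfg)
  pe <- function(a, b) 100 * abs(a - b) / abs(b)
  c(
    ov_pct = pe(cand_m$ov_um3, ref_m$ov_um3),
    area_pct = pe(cand_m$area_um2, ref_m$area_um2),
    mean_opl_pct = pe(cand_m$mean_opl_um, ref_m$mean_opl_um),
    eccentricity_abs = abs(cand_m$eccentricity - ref_m$eccentricity),
    circularity_abs = abs(cand_m$circularity - ref_m$circularity),
    rmse_opl_um = rmse_opl(cand, ref, cfg$wavelength_um),
    ssim = ssim(cand, ref)
  )
}

#' Population comparison of refocusing quality
#'
#' For every cell, the unrefocused ("before") and three-depth real-time
#' refocused ("after") phase images are compared against the fine-refocused
#' reference: percent errors of optical volume, projection area and mean
#' OPL; absolute differences of eccentricity and circularity; RMSE of the
#' OPL map (um); and SSIM. The report gives the population mean and 95th
#' percentile (linear-interpolation quantile) of each metric before and
#' after, with the improvement factor `before / after` (not defined for
#' SSIM, where larger is better and 1 is perfect).
#'
#' @param cells List of cells; each element a list with phase matrices
#'   `before`, `after` and `fine` (the reference).
#' @param cfg An [optics_config()].
#' @param mask_threshold Segmentation threshold passed to [cell_mask()].
#' @return An `hc_evaluation` tibble with 7 metric rows and columns
#'   `metric`, `mean_before`, `mean_after`, `mean_factor`, `p95_before`,
#'   `p95_after`, `p95_factor`, plus an `n_cells` attribute.
#' @export
compare_populations <- function(cells, cfg, mask_threshold = 0.3) {
  stopifnot(length(cells) >= 2)
  before <- list(); after <- list()
  for (cl in cells) {
    mb <- cell_metrics(cl$before, cl$fine, cfg, mask_threshold)
    ma <- cell_metrics(cl$after, cl$fine, cfg, mask_threshold)
    if (is.null(mb) || is.null(ma)) next  # unsegmentable cell: skip the pair
    before[[length(before) + 1L]] <- mb
    after[[length(after) + 1L]] <- ma
  }
  if (length(before) < 2) stop("fewer than 2 comparable cells", call. = FALSE)
  B <- do.call(rbind, before)
  A <- do.call(rbind, after)
  metrics <- colnames(B)
  q95 <- function(x) unname(stats::quantile(x, 0.95, type = 7))
  out <- tibble::tibble(
    metric = metrics,
    mean_before = unname(colMeans(B)),
    mean_after = unname(colMeans(A)),
    mean_factor = unname(colMeans(B) / colMeans(A)),
    p95_before = unname(apply(B, 2, q95)),
    p95_after = unname(apply(A, 2, q95)),
    p95_factor = unname(apply(B, 2, q95) / apply(A, 2, q95))
  )
  out$mean_factor[out$metric == "ssim"] <- NA_real_
  out$p95_factor[out$metric == "ssim"] <- NA_real_
  attr(out, "n_cells") <- nrow(B)
  class(out) <- c("hc_evaluation", class(out))
  out
}

#' Object acquisition rate of an acquisition
#'
#' `n_objects / (n_frames / fps)`, rounded to two decimals: e.g. 115,695
#' objects over 50,000 frames at 300 fps is 694.17 objects/s.
#'
#' @param n_objects Number of detected objects.
#' @param n_frames Number of frames captured.
#' @param fps Frame rate, Hz.
#' @return Objects per second (2 decimals).
#' @export
acquisition_rate <- function(n_objects, n_frames, fps) {
  stopifnot(n_frames > 0, fps > 0)
  round(n_objects / (n_frames / fps), 2)
}

#' Build and evaluate a synthetic defocused cell population
#'
#' The refocusing-quality harness in one call: simulates `n_cells` thin
#' phase cells (biconcave profile) at random lateral positions whose true
#' defocus follows a quadratic curve in position plus Gaussian scatter,
#' calibrates the refocus curve on the coarse 32-point autofocus of the
#' first `n_calibration` cells, refocuses every cell at three depths, fine
#' refocuses every cell on the 0.1 um grid as the reference, and compares
#' the populations.
#'
#' @param n_cells Number of cells (>= `n_calibration` recommended).
#' @param cfg An [optics_config()].
#' @param defocus_coeffs True defocus curve `(a, b, c)` over full-resolution
#'   columns; the defaults span roughly 2 to 15 um of defocus across the
#'   field of view.
#' @param scatter_sd_um Per-cell Gaussian scatter around the curve.
#' @param n_calibration Cells used for the quadratic calibration.
#' @param seed Seed for positions, scatter and cell sizes.
#' @return A list: `report` (the [compare_populations()] tibble),
#'   `calibration` (the [calibrate_focus()] fit), `cells_um` (tibble of
#'   per-cell `x_full`, `true_defocus_um`, `coarse_um`, `realtime_um`,
#'   `fine_um`).
#' @export
evaluate_refocusing_population <- function(n_cells = 200,
                                           cfg = optics_config(),
                                           defocus_coeffs = c(7.7e-7, 0, 2),
                                           scatter_sd_um = 0.8,
                                           n_calibration = 128,
                                           seed = 1L) {
  set.seed(seed)
  xs <- sample.int(cfg$full_shape[2] - 200L, n_cells) + 100L
  d_curve <- defocus_coeffs[1] * xs^2 + defocus_coeffs[2] * xs +
    defocus_coeffs[3]
  d_true <- d_curve + stats::rnorm(n_cells, sd = scatter_sd_um)
  radii <- stats::runif(n_cells, 3.0, 3.9)
  peaks <- stats::runif(n_cells, 1.4, 2.2)

  fields <- vector("list", n_cells)
  focused <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cs <- cell_spec(1L, 48L, radius_um = radii[i],
                    peak_phase_rad = peaks[i], profile = "biconcave")
    phi <- make_cell_phase(cs, cfg$pixel_um, c(96L, 96L))
    focused[[i]] <- phi
    fields[[i]] <- propagate(exp(1i * phi), d_true[i],
                             cfg$wavelength_um, cfg$pixel_um)
  }

  n_cal <- min(n_calibration, n_cells)
  coarse <- vapply(seq_len(n_cal), function(i) {
    autofocus(fields[[i]], cfg$wavelength_um, cfg$pixel_um)$distance_um
  }, numeric(1))
  calib <- calibrate_focus(xs[seq_len(n_cal)], coarse,
                           n_target = n_calibration)

  bg <- matrix(1 + 0i, 96L, 96L)
  realtime <- numeric(n_cells)
  fine <- numeric(n_cells)
  cells <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    rc <- refocus_cell(fields[[i]], bg, xs[i], calib,
                       cfg$wavelength_um, cfg$pixel_um)
    fr <- fine_refocus(fields[[i]], cfg$wavelength_um, cfg$pixel_um)
    realtime[i] <- rc$distance_um
    fine[i] <- fr$distance_um
    cells[[i]] <- list(
      before = Arg(fields[[i]]),
      after = rc$phase,
      fine = Arg(propagate(fields[[i]], fr$distance_um,
                           cfg$wavelength_um, cfg$pixel_um))
    )
  }
  list(
    report = compare_populations(cells, cfg),
    calibration = calib,
    cells_um = tibble::tibble(x_full = xs, true_defocus_um = d_true,
                              realtime_um = realtime, fine_um = fine)
  )
}
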