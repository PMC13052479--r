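#' Angular spectrum propagation of a complex field
#'
#' Propagates a sampled complex optical field by a distance `d_um` using the
#' exact scalar angular spectrum method: the field's 2D spectrum is multiplied
#' by the transfer function
#' `H(fx, fy) = exp(i * 2 * pi * d * (sqrt(1/lambda^2 - fx^2 - fy^2) - 1/lambda))`
#' on propagating components (`fx^2 + fy^2 <= 1/lambda^2`) and zeroed on
#' evanescent ones. The constant plane-wave phase `exp(i k d)` is referenced
#' out (the `- 1/lambda` term), as usual in holographic refocusing: an
#' interferometric phase measurement is relative to the reference beam, so
#' propagation must not add a distance-dependent piston.
#'
#' The sign convention used throughout the package: the refocus distance
#' recorded for a cell is the distance passed to `propagate()` that restores
#' focus, so a field defocused by `+d` has refocus distance `-d`.
#'
#' @param field Complex matrix (the sampled field).
#' @param d_um Propagation distance in micrometres (positive or negative).
#' @param wavelength_um Wavelength in micrometres.
#' @param pixel_um Sampling pitch of `field` in micrometres.
#' @return Complex matrix of the same shape.
#' @examples
#' u <- matrix(complex(modulus = 1, argument = 0), 32, 32)
#' v <- propagate(u, 5, 0.64, 0.203)
#' @export
propagate <- function(field, d_um, wavelength_um, pixel_um) {
  stopifnot(is.matrix(field), is.finite(d_um))
  H <- propagation_kernel(dim(field), d_um, wavelength_um, pixel_um)
  ifft2(stats::fft(field) * H)
}

# Transfer function in unshifted FFT order. At d = 0 no propagation (and no
# evanescent filtering) happens: H is identically 1.
propagation_kernel <- function(shape, d_um, wavelength_um, pixel_um) {
  if (d_um == 0) return(matrix(1 + 0i, shape[1], shape[2]))
  fy <- fft_freqs(shape[1]) / pixel_um
  fx <- fft_freqs(shape[2]) / pixel_um
  fy2 <- matrix(fy^2, shape[1], shape[2])
  fx2 <- matrix(fx^2, shape[1], shape[2], byrow = TRUE)
  arg <- 1 / wavelength_um^2 - fy2 - fx2
  H <- matrix(0 + 0i, shape[1], shape[2])
  prop <- arg >= 0
  H[prop] <- exp(2i * pi * d_um * (sqrt(arg[prop]) - 1 / wavelength_um))
  H
}

#' Remove the background field by complex division
#'
#' Element-wise division of the cell crop by the background crop taken from
#' the nearest empty frame at the same columns. For thin objects (phase delay
#' below 2 pi) the argument of the quotient is the object phase directly, so
#' no unwrapping is needed at this step.
#'
#' Background pixels with near-zero amplitude (below `1e-6` times the median
#' background amplitude) are replaced by a phase-preserving value of that
#' floor amplitude; their positions are returned in the `"flagged"` attribute.
#'
#' @param cell_field,background_field Complex matrices of identical shape.
#' @return Complex matrix `cell_field / background_field` (with the guard
#'   above), carrying a logical `"flagged"` attribute if any pixel was fixed.
#' @export
divide_background <- function(cell_field, background_field) {
  stopifnot(is.matrix(cell_field), is.matrix(background_field),
            all(dim(cell_field) == dim(background_field)))
  amp <- Mod(background_field)
  eps <- 1e-6 * stats::median(amp)
  bad <- amp < eps
  if (any(bad)) {
    # keep the phase, lift the amplitude to the floor
    ph <- Arg(background_field[bad])
    background_field[bad] <- complex(modulus = pmax(eps, .Machine$double.xmin),
                                     argument = ph)
  }
  out <- cell_field / background_field
  if (any(bad)) attr(out, "flagged") <- bad
  out
}

#' Amplitude variance focus metric
#'
#' Population variance of the amplitude `|field|` over all pixels. A pure
#' phase object shows minimal amplitude contrast in focus, so refocusing
#' seeks the propagation distance minimizing this quantity.
#'
#' @param field Complex matrix.
#' @return Non-negative scalar.
#' @export
amplitude_variance <- function(field) {
  pop_var(Mod(field))
}

#' Coarse autofocus by amplitude-variance minimization
#'
#' Evaluates `amplitude_variance(propagate(field, d))` on a uniform grid of
#' `n` distances in `[d_min_um, d_max_um]` (default: 32 distances from -24 to
#' 24 um) and returns the minimizer. Ties are broken toward the smaller
#' absolute distance. The forward FFT is computed once and reused across
#' distances.
#'
#' @inheritParams propagate
#' @param d_min_um,d_max_um Search range in micrometres.
#' @param n Number of grid points (>= 2).
#' @return A list with `distance_um` (the argmin), `distances_um` (the grid)
#'   and `variances`.
#' @export
autofocus <- function(field, wavelength_um, pixel_um,
                      d_min_um = -24, d_max_um = 24, n = 32) {
  stopifnot(n >= 2, d_max_um > d_min_um)
  ds <- seq(d_min_um, d_max_um, length.out = n)
  v <- variance_profile(field, ds, wavelength_um, pixel_um)
  best <- which(v == min(v))
  best <- best[which.min(abs(ds[best]))]
  list(distance_um = ds[best], distances_um = ds, variances = v)
}

# Amplitude variance after propagation over a vector of distances,
# with the forward FFT hoisted out of the loop.
variance_profile <- function(field, distances_um, wavelength_um, pixel_um) {
  Fv <- stats::fft(field)
  fy <- fft_freqs(nrow(field)) / pixel_um
  fx <- fft_freqs(ncol(field)) / pixel_um
  arg <- outer(fy^2, fx^2, "+")
  arg <- 1 / wavelength_um^2 - arg
  prop <- arg >= 0
  rt <- sqrt(pmax(arg, 0))
  vapply(distances_um, function(d) {
    if (d == 0) return(amplitude_variance(field))
    H <- matrix(0 + 0i, nrow(field), ncol(field))
    H[prop] <- exp(2i * pi * d * (rt[prop] - 1 / wavelength_um))
    amplitude_variance(ifft2(Fv * H))
  }, numeric(1))
}

#' Fit the refocus-distance-versus-position calibration
#'
#' Least-squares quadratic fit `d(x) = a x^2 + b x + c` of coarse autofocus
#' distances against lateral (full-resolution column) position, normally
#' over the first 128 detected cells of an acquisition. The residual standard
#' deviation of the regression sets the spread of the three-depth refinement
#' in [refocus_cell()].
#'
#' @param x_full Numeric vector of full-resolution column positions.
#' @param d_um Numeric vector of coarse refocus distances (micrometres).
#' @param n_target Number of cells the calibration aims to use (informational).
#' @return An object of class `focus_calibration`: list with `coeffs`
#'   (`c(a, b, c)`), `residual_std_um`, `n_cells_used`, and the fitted `model`.
#' @export
calibrate_focus <- function(x_full, d_um, n_target = 128) {
  stopifnot(length(x_full) == length(d_um))
  n <- length(x_full)
  if (n < 3) stop("insufficient calibration cells (need >= 3)", call. = FALSE)
  if (n < 8) warning("focus calibration from fewer than 8 cells is degenerate")
  fit <- stats::lm(d_um ~ I(x_full^2) + x_full)
  co <- stats::coef(fit)
  res <- stats::residuals(fit)
  structure(
    list(
      coeffs = c(a = unname(co[2]), b = unname(co[3]), c = unname(co[1])),
      residual_std_um = stats::sd(res),
      n_cells_used = n,
      n_target = n_target,
      model = fit
    ),
    class = "focus_calibration"
  )
}

#' Predict the calibrated refocus distance at a lateral position
#'
#' @param calib A [calibrate_focus()] result.
#' @param x_full Full-resolution column position(s).
#' @return Refocus distance(s) in micrometres.
#' @export
predict_focus <- function(calib, x_full) {
  stopifnot(inherits(calib, "focus_calibration"))
  co <- calib$coeffs
  co[["a"]] * x_full^2 + co[["b"]] * x_full + co[["c"]]
}

#' @export
print.focus_calibration <- function(x, ...) {
  cat("<focus_calibration>\n")
  cat(sprintf("  d(x) = %.4g x^2 + %.4g x + %.4g um   (n = %d cells)\n",
              x$coeffs[["a"]], x$coeffs[["b"]], x$coeffs[["c"]],
              x$n_cells_used))
  cat(sprintf("  residual std: %.3f um\n", x$residual_std_um))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the focus calibration fit
#'
#' @param x A `focus_calibration` object.
#' @param ... Unused.
#' @return A tibble with one row per polynomial term (`term`, `estimate`,
#'   `std.error`).
#' @export
tidy.focus_calibration <- function(x, ...) {
  s <- summary(x$model)$coefficients
  tibble::tibble(
    term = c("c", "a", "b"),
    estimate = unname(s[, 1]),
    std.error = unname(s[, 2])
  )[c(2, 3, 1), ]
}

#' One-row summary of the focus calibration
#'
#' @inheritParams tidy.focus_calibration
#' @return A tibble with `n_cells_used`, `residual_std_um`, `r.squared`.
#' @export
glance.focus_calibration <- function(x, ...) {
  tibble::tibble(
    n_cells_used = x$n_cells_used,
    residual_std_um = x$residual_std_um,
    r.squared = summary(x$model)$r.squared
  )
}

#' Three-depth refocusing of one detected cell
#'
#' Divides the cell crop by its background crop, then propagates the quotient
#' to three candidate depths: the calibrated distance `d(x)` for the cell's
#' lateral position, and `d(x)` plus/minus one residual standard deviation of
#' the calibration regression. The candidate minimizing the amplitude
#' variance is selected. With `propagate_before_divide = TRUE` the cell and
#' background crops are each propagated and then divided (same transfer
#' function, equivalent phase for thin objects).
#'
#' @param cell_field,background_field 96 x 96 complex crops at full
#'   resolution (any equal square-ish shape is accepted).
#' @param x_full Lateral position of the cell (full-resolution column).
#' @param calib A [calibrate_focus()] result.
#' @param wavelength_um,pixel_um Optics constants for the crops.
#' @param propagate_before_divide Propagate both fields then divide, instead
#'   of dividing first.
#' @return An object of class `refocused_cell`: list with `phase` (radians,
#'   background-divided, refocused), `distance_um` (chosen), `candidates_um`,
#'   `variances`.
#' @export
refocus_cell <- function(cell_field, background_field, x_full, calib,
                         wavelength_um, pixel_um,
                         propagate_before_divide = FALSE) {
  stopifnot(inherits(calib, "focus_calibration"))
  d0 <- predict_focus(calib, x_full)
  s <- calib$residual_std_um
  cands <- c(d0 - s, d0, d0 + s)
  fields <- lapply(cands, function(d) {
    if (propagate_before_divide) {
      divide_background(propagate(cell_field, d, wavelength_um, pixel_um),
                        propagate(background_field, d, wavelength_um, pixel_um))
    } else {
      propagate(divide_background(cell_field, background_field),
                d, wavelength_um, pixel_um)
    }
  })
  v <- vapply(fields, amplitude_variance, numeric(1))
  best <- which(v == min(v))
  if (length(best) > 1) best <- if (2L %in% best) 2L else best[1]
  structure(
    list(
      phase = Arg(fields[[best]]),
      distance_um = cands[best],
      candidates_um = cands,
      variances = v
    ),
    class = "refocused_cell"
  )
}
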