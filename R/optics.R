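#' Optical and geometric configuration of a holographic cytometry acquisition
#'
#' Bundles the physical constants of the interferometer and the fixed frame
#' geometry of the line-scan acquisition so that no downstream stage carries
#' magic numbers. Defaults reproduce a 20x / 0.4 NA off-axis Mach-Zehnder
#' system with a 640 nm pulsed source and a 96 x 4096 pixel sensor read at
#' 300 frames per second.
#'
#' Frames are stored with rows = the short ("y") axis and columns = the long
#' ("x") axis; the long axis indexes lateral position across the flow channel.
#'
#' @param wavelength_um Illumination wavelength in micrometres.
#' @param pixel_um Object-plane pixel pitch at full resolution, micrometres.
#' @param numerical_aperture Objective NA, in (0, 1).
#' @param frame_rate_hz Acquisition frame rate, Hz.
#' @param frame_shape Integer `(rows, cols)` of a raw interferogram frame.
#' @param crop_shape Integer `(rows, cols)` of the spectral region of interest
#'   cropped around the off-axis carrier peak (cols along the long axis).
#'
#' @return An object of class `optics_config`: a validated list with the above
#'   fields plus `half_shape` and `full_shape` (frame shape at half and full
#'   lateral resolution).
#' @examples
#' cfg <- optics_config()
#' lateral_resolution(cfg)   # 0.976 um
#' spot_diameter_pixels(cfg) # 5 px
#' @export
optics_config <- function(wavelength_um = 0.640,
                          pixel_um = 0.203,
                          numerical_aperture = 0.4,
                          frame_rate_hz = 300,
                          frame_shape = c(96L, 4096L),
                          crop_shape = c(20L, 874L)) {
  cfg <- structure(
    list(
      wavelength_um = wavelength_um,
      pixel_um = pixel_um,
      numerical_aperture = numerical_aperture,
      frame_rate_hz = frame_rate_hz,
      frame_shape = as.integer(frame_shape),
      crop_shape = as.integer(crop_shape),
      half_shape = as.integer(frame_shape) %/% 2L,
      full_shape = as.integer(frame_shape)
    ),
    class = "optics_config"
  )
  validate_optics_config(cfg)
  cfg
}

validate_optics_config <- function(cfg) {
  stopifnot(inherits(cfg, "optics_config"))
  if (!is.numeric(cfg$wavelength_um) || length(cfg$wavelength_um) != 1L ||
      !is.finite(cfg$wavelength_um) || cfg$wavelength_um <= 0) {
    stop("wavelength_um must be a positive scalar", call. = FALSE)
  }
  if (!is.numeric(cfg$pixel_um) || length(cfg$pixel_um) != 1L ||
      !is.finite(cfg$pixel_um) || cfg$pixel_um <= 0) {
    stop("pixel_um must be a positive scalar", call. = FALSE)
  }
  na <- cfg$numerical_aperture
  if (!is.numeric(na) || length(na) != 1L || !is.finite(na) ||
      na <= 0 || na >= 1) {
    stop("numerical_aperture must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.numeric(cfg$frame_rate_hz) || cfg$frame_rate_hz <= 0) {
    stop("frame_rate_hz must be positive", call. = FALSE)
  }
  if (length(cfg$frame_shape) != 2L || any(cfg$frame_shape < 2L)) {
    stop("frame_shape must be two integers >= 2", call. = FALSE)
  }
  if (any(cfg$frame_shape %% 2L != 0L)) {
    stop("frame_shape dimensions must be even (half resolution is exact)",
         call. = FALSE)
  }
  if (length(cfg$crop_shape) != 2L || any(cfg$crop_shape < 1L)) {
    stop("crop_shape must be two positive integers", call. = FALSE)
  }
  if (any(cfg$crop_shape > cfg$frame_shape)) {
    stop("crop_shape must fit inside the spectral support of frame_shape",
         call. = FALSE)
  }
  invisible(cfg)
}

#' @export
print.optics_config <- function(x, ...) {
  cat("<optics_config>\n")
  cat(sprintf("  wavelength: %.3f um   pixel: %.3f um   NA: %.2f   %g fps\n",
              x$wavelength_um, x$pixel_um, x$numerical_aperture,
              x$frame_rate_hz))
  cat(sprintf("  frame: %d x %d   spectral crop: %d x %d   half: %d x %d\n",
              x$frame_shape[1], x$frame_shape[2],
              x$crop_shape[1], x$crop_shape[2],
              x$half_shape[1], x$half_shape[2]))
  invisible(x)
}

#' Diffraction-limited lateral resolution
#'
#' Rayleigh criterion, `0.61 * wavelength / NA`. With the default 640 nm
#' source and 0.4 NA objective this is 0.976 um.
#'
#' @param cfg An [optics_config()].
#' @return Lateral resolution in micrometres.
#' @export
lateral_resolution <- function(cfg) {
  validate_optics_config(cfg)
  0.61 * cfg$wavelength_um / cfg$numerical_aperture
}

#' Diffraction spot diameter on the detector, in pixels
#'
#' The lateral resolution divided by the full-resolution pixel pitch, rounded
#' to the nearest integer (defaults give 5 px).
#'
#' @inheritParams lateral_resolution
#' @return Integer number of pixels.
#' @export
spot_diameter_pixels <- function(cfg) {
  validate_optics_config(cfg)
  as.integer(round(lateral_resolution(cfg) / cfg$pixel_um))
}
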