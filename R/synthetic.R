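#' Specify one synthetic flowing cell
#'
#' Describes a cell-like phase object flowing through the channel: at frame
#' `center_frame` its centre crosses the middle row of the field of view,
#' moving `flow_rows_per_frame` rows per frame along the short axis.
#'
#' @param center_frame Frame index (1-based) at which the cell is vertically
#'   centred.
#' @param x_center Column of the cell centre, full-resolution pixels.
#' @param radius_um Cell radius in micrometres.
#' @param peak_phase_rad Peak phase delay in radians (must stay below `2 pi`:
#'   the thin-object assumption under which background-divided phase needs no
#'   unwrapping).
#' @param profile One of `"disk"`, `"biconcave"`, `"bead"`.
#' @param flow_rows_per_frame Vertical displacement between frames,
#'   full-resolution rows.
#' @return A `cell_spec` list.
#' @export
cell_spec <- function(center_frame, x_center, radius_um = 3.4,
                      peak_phase_rad = 1.8,
                      profile = c("biconcave", "disk", "bead"),
                      flow_rows_per_frame = 24) {
  profile <- match.arg(profile)
  stopifnot(peak_phase_rad > 0, radius_um > 0)
  if (peak_phase_rad >= 2 * pi) {
    stop("peak_phase_rad must be < 2*pi (thin-object assumption)",
         call. = FALSE)
  }
  structure(list(center_frame = as.integer(center_frame),
                 x_center = as.integer(x_center),
                 radius_um = radius_um,
                 peak_phase_rad = peak_phase_rad,
                 profile = profile,
                 flow_rows_per_frame = flow_rows_per_frame),
            class = "cell_spec")
}

#' Rasterize the phase profile of a synthetic cell
#'
#' Produces a non-negative smooth phase image of the requested profile,
#' centred at `center` (row, col) of a `shape` canvas:
#' * `disk` - uniform `phi0` inside the radius, 0 outside;
#' * `biconcave` - red-blood-cell-like dimpled profile
#'   `phi0 * (1 - 0.5 * exp(-r^2 / (0.25 R^2)))` inside the radius, smoothly
#'   tapered to 0 over the outer 15% of the radius;
#' * `bead` - spherical cap `phi0 * sqrt(1 - (r/R)^2)`.
#'
#' @param spec A [cell_spec()].
#' @param pixel_um Pixel pitch of the canvas, micrometres.
#' @param shape Integer `(rows, cols)` of the canvas.
#' @param center Numeric `(row, col)` of the cell centre (defaults to the
#'   canvas centre).
#' @return Numeric phase matrix, values in `[0, peak_phase_rad]`.
#' @export
make_cell_phase <- function(spec, pixel_um, shape,
                            center = (shape + 1) / 2) {
  stopifnot(inherits(spec, "cell_spec"))
  R <- spec$radius_um
  if (2 * R > min(shape) * pixel_um) {
    stop("cell larger than the requested canvas", call. = FALSE)
  }
  rr <- (seq_len(shape[1]) - center[1]) * pixel_um
  cc <- (seq_len(shape[2]) - center[2]) * pixel_um
  r <- sqrt(outer(rr^2, cc^2, "+"))
  phi0 <- spec$peak_phase_rad
  inside <- r < R
  ph <- matrix(0, shape[1], shape[2])
  if (spec$profile == "disk") {
    ph[inside] <- phi0
  } else if (spec$profile == "bead") {
    ph[inside] <- phi0 * sqrt(1 - (r[inside] / R)^2)
  } else {
    base <- phi0 * (1 - 0.5 * exp(-r[inside]^2 / (0.25 * R^2)))
    # cosine taper over the outer 15% of the radius, to 0 at R
    taper <- rep(1, sum(inside))
    edge <- r[inside] > 0.85 * R
    taper[edge] <- cos(pi / 2 * (r[inside][edge] - 0.85 * R) / (0.15 * R))^2
    ph[inside] <- base * taper
  }
  ph
}

#' Specify a synthetic holographic cytometry scene
#'
#' Collects everything the simulator needs to emit a raw interferogram stack
#' with known ground truth: the flowing cells, static channel-wall phase
#' steps, a smooth cubic phase background along the long axis, the off-axis
#' carrier frequency, a quadratic true-defocus-versus-position curve, and an
#' intensity noise level.
#'
#' @param n_frames Number of frames to synthesize.
#' @param cells List of [cell_spec()] objects.
#' @param wall_positions_x Full-resolution columns where channel-wall phase
#'   steps sit; consecutive positions toggle the elevated region on and off,
#'   so a pair of walls produces one raised channel band.
#' @param wall_height_rad Height of the wall phase step (default 4 rad,
#'   above `pi`, so block unwrapping genuinely mis-steps there and the
#'   temporal/static background stages have an error to remove).
#' @param background_poly_coeffs Length-4 cubic coefficients
#'   `(c0, c1, c2, c3)` in radians, evaluated on the column coordinate
#'   normalized to `[0, 1]`; applied identically to every row.
#' @param carrier_freq `(fy, fx)` carrier in cycles/pixel; must land inside
#'   the spectral crop window and outside the DC exclusion zone.
#' @param defocus_curve_coeffs `(a, b, c)` of the true defocus
#'   `d(x) = a x^2 + b x + c` in micrometres, `x` in full-resolution columns;
#'   must stay within `+/- 24 um` over the field of view.
#' @param noise_sigma Standard deviation of additive Gaussian intensity
#'   noise (the noise-free intensity has mean ~2 for unit amplitudes).
#' @param ref_amplitude,sample_amplitude Beam amplitudes (fringe contrast).
#' @param seed Integer seed; identical spec + seed gives a bit-identical
#'   stack.
#' @return A `scene_spec` list.
#' @export
scene_spec <- function(n_frames,
                       cells = list(),
                       wall_positions_x = integer(0),
                       wall_height_rad = 4,
                       background_poly_coeffs = c(0.5, 1.2, -0.9, 0.5),
                       carrier_freq = c(fy = 24 / 96, fx = 256 / 4096),
                       defocus_curve_coeffs = c(a = 0, b = 0, c = 0),
                       noise_sigma = 0,
                       ref_amplitude = 1,
                       sample_amplitude = 1,
                       seed = 1L) {
  stopifnot(n_frames >= 1)
  if (length(cells) && inherits(cells, "cell_spec")) cells <- list(cells)
  structure(list(n_frames = as.integer(n_frames), cells = cells,
                 wall_positions_x = as.integer(wall_positions_x),
                 wall_height_rad = wall_height_rad,
                 background_poly_coeffs = background_poly_coeffs,
                 carrier_freq = carrier_freq,
                 defocus_curve_coeffs = defocus_curve_coeffs,
                 noise_sigma = noise_sigma,
                 ref_amplitude = ref_amplitude,
                 sample_amplitude = sample_amplitude,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# True defocus at a full-resolution column.
scene_defocus <- function(scene, x) {
  co <- scene$defocus_curve_coeffs
  co[[1]] * x^2 + co[[2]] * x + co[[3]]
}

# Static part of the true phase: cubic background plus channel-wall steps.
scene_static_phase <- function(scene, cfg) {
  shape <- cfg$frame_shape
  xn <- seq_len(shape[2]) / shape[2]
  co <- scene$background_poly_coeffs
  row_bg <- co[1] + co[2] * xn + co[3] * xn^2 + co[4] * xn^3
  static <- matrix(row_bg, shape[1], shape[2], byrow = TRUE)
  if (length(scene$wall_positions_x)) {
    inside <- outer(rep(1L, shape[2]), scene$wall_positions_x, ">=")
    band <- rowSums(inside) %% 2 == 1
    static <- static + scene$wall_height_rad *
      matrix(band, shape[1], shape[2], byrow = TRUE)
  }
  static
}

#' Synthesize a raw interferogram stack with ground truth
#'
#' Builds, frame by frame, the true unwrapped phase (cells in their flow
#' positions + cubic background + wall steps), forms the sample beam
#' `s = A_s exp(i phi_true)`, applies the true defocus to each cell by
#' propagating the 96-column sub-field around the cell by `d(x_center)`,
#' interferes it with the tilted reference beam
#' `r = A_r exp(i 2 pi (fy y + fx x))`, and records the intensity
#' `|r + s|^2` with optional additive Gaussian noise (clipped at zero).
#' Ground truth is captured before noise.
#'
#' @param scene A [scene_spec()].
#' @param cfg An [optics_config()].
#' @param keep_true_phase Store per-frame true phase maps in the ground
#'   truth (costs memory for long stacks).
#' @return An object of class `hc_acquisition`: list with `frames` (array
#'   `rows x cols x n_frames` of intensities), `truth` (list: `detections`
#'   tibble of true `(frame, x_center, ...)` entries for cells whose centre
#'   frame lies in range, `cell_phase` list of true focused full-resolution
#'   96 x 96 phase crops, `defocus_um` true defocus per cell, `static_phase`,
#'   and optionally `true_phase` per frame), `scene`, `cfg`.
#' @export
synthesize_frames <- function(scene, cfg = optics_config(),
                              keep_true_phase = TRUE) {
  stopifnot(inherits(scene, "scene_spec"))
  validate_optics_config(cfg)
  check_carrier_in_crop(scene, cfg)
  shape <- cfg$frame_shape
  set.seed(scene$seed)

  static <- scene_static_phase(scene, cfg)
  ref_phase <- 2 * pi * (outer(seq_len(shape[1]) - 1L, rep(1, shape[2])) *
                           scene$carrier_freq[[1]] +
                         outer(rep(1, shape[1]), seq_len(shape[2]) - 1L) *
                           scene$carrier_freq[[2]])
  # negative tilt on the reference so the positive-frequency sideband
  # conj(r) * s carries +phi (matches the demodulator's half-plane choice)
  r_beam <- scene$ref_amplitude * exp(-1i * ref_phase)

  crop_half <- 48L
  frames <- array(0, c(shape[1], shape[2], scene$n_frames))
  truth_rows <- list()
  cell_phase <- list()
  defocus_um <- numeric(0)
  true_phase <- if (keep_true_phase) vector("list", scene$n_frames) else NULL

  # per-cell focused crops and true defocus (ground truth)
  for (ci in seq_along(scene$cells)) {
    cs <- scene$cells[[ci]]
    cell_phase[[ci]] <- make_cell_phase(cs, cfg$pixel_um, c(96L, 96L))
    defocus_um[ci] <- scene_defocus(scene, cs$x_center)
    if (abs(defocus_um[ci]) > 24) {
      stop("true defocus exceeds 24 um inside the field of view",
           call. = FALSE)
    }
    if (cs$center_frame >= 1L && cs$center_frame <= scene$n_frames) {
      truth_rows[[length(truth_rows) + 1L]] <- tibble::tibble(
        cell = ci, frame = cs$center_frame, x_center = cs$x_center,
        defocus_um = defocus_um[ci]
      )
    }
  }

  for (t in seq_len(scene$n_frames)) {
    phi <- static
    occupied <- list()
    for (ci in seq_along(scene$cells)) {
      cs <- scene$cells[[ci]]
      row_c <- (shape[1] + 1) / 2 + (t - cs$center_frame) * cs$flow_rows_per_frame
      extent <- cs$radius_um / cfg$pixel_um
      if (row_c + extent < 1 || row_c - extent > shape[1]) next
      phi <- phi + make_cell_phase(cs, cfg$pixel_um, shape,
                                   center = c(row_c, cs$x_center))
      occupied[[length(occupied) + 1L]] <- ci
    }
    s <- scene$sample_amplitude * exp(1i * phi)
    # apply true defocus per visible cell by propagating its sub-field
    for (ci in unlist(occupied)) {
      cs <- scene$cells[[ci]]
      d <- defocus_um[ci]
      if (d == 0) next
      c0 <- cs$x_center - crop_half + 1L
      c1 <- cs$x_center + crop_half
      if (c0 < 1L || c1 > shape[2]) next  # cell too close to the x edge
      s[, c0:c1] <- propagate(s[, c0:c1, drop = FALSE], d,
                              cfg$wavelength_um, cfg$pixel_um)
    }
    I <- Mod(r_beam + s)^2
    if (keep_true_phase) true_phase[[t]] <- phi
    if (scene$noise_sigma > 0) {
      I <- I + stats::rnorm(length(I), sd = scene$noise_sigma)
      I[I < 0] <- 0
    }
    frames[, , t] <- I
  }

  detections <- if (length(truth_rows)) {
    do.call(rbind, truth_rows)
  } else {
    tibble::tibble(cell = integer(), frame = integer(),
                   x_center = integer(), defocus_um = numeric())
  }
  structure(
    list(frames = frames,
         truth = list(detections = detections,
                      cell_phase = cell_phase,
                      defocus_um = defocus_um,
                      static_phase = static,
                      true_phase = true_phase),
         scene = scene, cfg = cfg),
    class = "hc_acquisition"
  )
}

# The carrier must sit inside the demodulation crop window and outside the
# DC exclusion zone, or demodulation is impossible.
check_carrier_in_crop <- function(scene, cfg) {
  fy_bin <- scene$carrier_freq[[1]] * cfg$frame_shape[1]
  fx_bin <- scene$carrier_freq[[2]] * cfg$frame_shape[2]
  half_r <- cfg$crop_shape[1] %/% 2L
  half_c <- cfg$crop_shape[2] %/% 2L
  if (fx_bin <= 0) {
    stop("carrier fx must be positive (search half-plane convention)",
         call. = FALSE)
  }
  if (abs(fy_bin) + half_r > cfg$frame_shape[1] %/% 2L ||
      abs(fx_bin) + half_c > cfg$frame_shape[2] %/% 2L) {
    stop("carrier outside the spectral support: crop window would clip",
         call. = FALSE)
  }
  if (abs(fy_bin) <= 8 && abs(fx_bin) <= 64) {
    stop("carrier inside the DC exclusion zone; demodulation impossible",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.hc_acquisition <- function(x, ...) {
  cat(sprintf("<hc_acquisition> %d frames of %d x %d, %d cell(s), seed %d\n",
              dim(x$frames)[3], dim(x$frames)[1], dim(x$frames)[2],
              length(x$scene$cells), x$scene$seed))
  invisible(x)
}

#' Write an acquisition to disk (multi-page TIFF + JSON sidecar)
#'
#' Frames go to a 32-bit float multi-page TIFF (one page per frame,
#' intensities normalized to `[0, 1]`; the scale factor is stored in the
#' sidecar). The scene specification and the tabular part of the ground
#' truth go to a JSON sidecar next to it.
#'
#' @param acq An [synthesize_frames()] result.
#' @param path Path of the TIFF to write; the sidecar gets `.json` appended.
#' @return `path`, invisibly.
#' @export
write_acquisition <- function(acq, path) {
  stopifnot(inherits(acq, "hc_acquisition"))
  n <- dim(acq$frames)[3]
  scale <- max(acq$frames)
  if (scale <= 0) scale <- 1
  pages <- lapply(seq_len(n), function(t) acq$frames[, , t] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  sidecar <- list(
    intensity_scale = scale,
    scene = unclass(acq$scene)[setdiff(names(acq$scene), "cells")],
    cells = lapply(acq$scene$cells, unclass),
    true_detections = acq$truth$detections
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an acquisition frame stack written by [write_acquisition()]
#'
#' @param path Path of the TIFF written by [write_acquisition()].
#' @return A list with `frames` (rows x cols x n array, intensity scale
#'   restored when the sidecar is present) and `sidecar` (parsed JSON or
#'   `NULL`).
#' @export
read_acquisition <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  sidecar_path <- paste0(path, ".json")
  sidecar <- NULL
  scale <- 1
  if (file.exists(sidecar_path)) {
    sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    if (!is.null(sidecar$intensity_scale)) scale <- sidecar$intensity_scale
  }
  frames <- array(0, c(dim(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) frames[, , t] <- pages[[t]] * scale
  list(frames = frames, sidecar = sidecar)
}

#' Ground-truth phase within the demodulation bandwidth
#'
#' The demodulator isolates a finite spectral window (`cfg$crop_shape`)
#' around the carrier, so even a perfect reconstruction can only recover the
#' true phase low-pass filtered to that window. This helper computes that
#' reachable reference directly -- by filtering `exp(i * phi_true)` with the
#' same centred spectral window, with no carrier, interference or unwrapping
#' involved -- for comparison against the demodulated and post-processed
#' output.
#'
#' @param acq An [synthesize_frames()] result with `keep_true_phase = TRUE`.
#' @param frame Frame index.
#' @param resolution `"half"` or `"full"` output sampling.
#' @param include_static Include the static background (walls + cubic) in
#'   the filtered truth; when `FALSE` (default) only the cells' phase is
#'   filtered, matching the output of the background-removal stage.
#' @return Phase matrix at the requested resolution.
#' @export
bandlimited_truth <- function(acq, frame, resolution = c("half", "full"),
                              include_static = FALSE) {
  stopifnot(inherits(acq, "hc_acquisition"))
  resolution <- match.arg(resolution)
  if (is.null(acq$truth$true_phase)) {
    stop("acquisition was synthesized with keep_true_phase = FALSE",
         call. = FALSE)
  }
  cfg <- acq$cfg
  phi <- acq$truth$true_phase[[frame]]
  if (!include_static) phi <- phi - acq$truth$static_phase
  S <- fftshift2(stats::fft(exp(1i * phi)))
  ctr <- c(floor(nrow(S) / 2) + 1L, floor(ncol(S) / 2) + 1L)
  hr <- cfg$crop_shape[1] %/% 2L
  hc <- cfg$crop_shape[2] %/% 2L
  rows <- (ctr[1] - hr):(ctr[1] + cfg$crop_shape[1] - hr - 1L)
  cols <- (ctr[2] - hc):(ctr[2] + cfg$crop_shape[2] - hc - 1L)
  crop <- S[rows, cols]
  out_shape <- if (resolution == "half") cfg$half_shape else cfg$full_shape
  # peak (DC of the object spectrum) sits at the crop centre
  u <- embed_ifft(crop, hr + 1L, hc + 1L, out_shape, prod(cfg$frame_shape))
  Arg(u)
}
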