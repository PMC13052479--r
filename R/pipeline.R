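#' Pipeline configuration
#'
#' Collects the optics constants and every tunable of the processing stages
#' in one validated list. Unknown keys are rejected. Values mirror the
#' defaults of the individual stage functions.
#'
#' @param cfg An [optics_config()].
#' @param ... Overrides for any tunable listed in Details.
#'
#' @details Tunables and defaults: `unwrap_batch = 20`, `post_batch = 40`,
#' `detect_batch = 80`, `block_cols = 20`, `overlap_cols = 4`,
#' `mask_threshold = 0.5` (row-fit robustification, rad), `robust_fit = TRUE`,
#' `detect_threshold = 0.3` (rad), `kernel_width = 24`, `kernel_disk = 20`,
#' `kernel_edge_rows = 4`, `kernel_edge_value = -8`, `peak_threshold = NULL`
#' (half the kernel's positive mass), `zero_threshold = NULL` (a tenth of the
#' peak threshold), `min_sep_x = 24`, `min_sep_t = 5`, `autofocus_n = 32`,
#' `autofocus_range = c(-24, 24)`, `n_calibration_cells = 128`,
#' `propagate_before_divide = FALSE`, `morph_threshold = 0.3`,
#' `opening_radius = 1`, `filter` = [rbc_filter()].
#'
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cfg = optics_config(), ...) {
  defaults <- list(
    unwrap_batch = 20L, post_batch = 40L, detect_batch = 80L,
    block_cols = 20L, overlap_cols = 4L,
    mask_threshold = 0.5, robust_fit = TRUE,
    detect_threshold = 0.3,
    kernel_width = 24L, kernel_disk = 20L, kernel_edge_rows = 4L,
    kernel_edge_value = -8,
    peak_threshold = NULL, zero_threshold = NULL,
    min_sep_x = 24L, min_sep_t = 5L,
    autofocus_n = 32L, autofocus_range = c(-24, 24),
    n_calibration_cells = 128L,
    propagate_before_divide = FALSE,
    morph_threshold = 0.3, opening_radius = 1L,
    filter = rbc_filter()
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown)) {
    stop("unknown pipeline option(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults[names(dots)] <- dots
  validate_optics_config(cfg)
  structure(c(list(optics = cfg), defaults), class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key-value YAML: optics keys (`wavelength_um`, `pixel_um`,
#' `numerical_aperture`, `frame_rate_hz`) plus any [pipeline_config()]
#' tunable. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @param overrides Named list applied on top of the file's values.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  vals[names(overrides)] <- overrides
  optic_keys <- c("wavelength_um", "pixel_um", "numerical_aperture",
                  "frame_rate_hz")
  cfg <- do.call(optics_config, vals[intersect(names(vals), optic_keys)])
  rest <- vals[setdiff(names(vals), optic_keys)]
  do.call(pipeline_config, c(list(cfg = cfg), rest))
}

# Split 1..n into consecutive batches of `size`; a trailing remainder
# shorter than `min_last` is merged into the previous batch.
batch_indices <- function(n, size, min_last = 1L) {
  starts <- seq(1L, n, by = size)
  idx <- lapply(starts, function(s) s:min(s + size - 1L, n))
  k <- length(idx)
  if (k > 1L && length(idx[[k]]) < min_last) {
    idx[[k - 1L]] <- c(idx[[k - 1L]], idx[[k]])
    idx[[k]] <- NULL
  }
  idx
}

#' Run the full acquisition-to-morphology pipeline
#'
#' Streams a raw interferogram stack through every stage: carrier
#' calibration on the first frame, per-frame demodulation, block Goldstein
#' unwrapping in 20-frame batches, post-processing in 40-frame batches
#' (temporal jump correction, per-row cubic background, static background),
#' detection in 80-frame batches (threshold mask, kernel correlation, local
#' maxima, background-frame search), refocus calibration on the first 128
#' cells followed by three-depth refocusing, and per-cell morphometry with
#' RBC filtering. Deterministic given the input and configuration.
#'
#' @param frames A `rows x cols x n` intensity array, an `hc_acquisition`,
#'   or a path readable by [read_acquisition()].
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory: per-cell TIFFs, `detections.csv`,
#'   `morphology.csv` and `manifest.json` are written there.
#' @return An object of class `hc_run`: list with `manifest` (stage counts,
#'   calibrations), `detections` (tibble), `morphology` (tibble with one row
#'   per refocused cell, `accepted` flag from the RBC filter), `cells` (list
#'   of `refocused_cell` objects), `cleaned` (list of cleaned half-resolution
#'   phase frames).
#' @export
run_pipeline <- function(frames, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(frames)) frames <- read_acquisition(frames)$frames
  if (inherits(frames, "hc_acquisition")) frames <- frames$frames
  stopifnot(is.array(frames), length(dim(frames)) == 3)
  cfg <- config$optics
  n <- dim(frames)[3]

  calib <- calibrate_carrier(frames[, , 1], cfg)

  # demodulate every frame; keep half-res wrapped phase + full-res fields
  wrapped <- vector("list", n)
  fields_full <- vector("list", n)
  for (t in seq_len(n)) {
    dm <- demodulate(frames[, , t], calib, cfg)
    wrapped[[t]] <- wrapped_phase(dm$half)
    fields_full[[t]] <- dm$full$values
  }

  # unwrap in batches
  unwrapped <- vector("list", n)
  for (b in batch_indices(n, config$unwrap_batch)) {
    unwrapped[b] <- unwrap_batch(wrapped[b],
                                 block_cols = config$block_cols,
                                 overlap_cols = config$overlap_cols)
  }

  # post-process in batches (static background needs >= 5 frames)
  cleaned <- vector("list", n)
  for (b in batch_indices(n, config$post_batch, min_last = 5L)) {
    cleaned[b] <- postprocess_batch(unwrapped[b],
                                    mask_threshold = config$mask_threshold,
                                    robust = config$robust_fit)
  }

  # detect in batches
  kernel <- detection_kernel(height = cfg$half_shape[1],
                             width = config$kernel_width,
                             disk_diameter = config$kernel_disk,
                             edge_rows = config$kernel_edge_rows,
                             edge_value = config$kernel_edge_value)
  pos_mass <- sum(kernel[kernel > 0])
  peak_thr <- config$peak_threshold %||% (0.5 * pos_mass)
  zero_thr <- config$zero_threshold %||% (0.1 * peak_thr)

  det_list <- list()
  bg_frames <- integer(0)
  for (b in batch_indices(n, config$detect_batch)) {
    masks <- lapply(cleaned[b], binarize, threshold = config$detect_threshold)
    map <- correlate_batch(masks, kernel)
    det <- detect_cells(map, peak_threshold = peak_thr,
                        min_sep_x = config$min_sep_x,
                        min_sep_t = config$min_sep_t)
    det$frame <- det$frame + b[1] - 1L  # batch-local -> acquisition index
    bg_frames <- c(bg_frames, find_background_frames(map, zero_thr) + b[1] - 1L)
    det_list[[length(det_list) + 1L]] <- det
  }
  detections <- do.call(rbind, det_list)
  # deduplicate across batch boundaries
  if (nrow(detections) > 1) {
    keep <- rep(TRUE, nrow(detections))
    for (i in seq_len(nrow(detections))[-1]) {
      prev <- which(keep[seq_len(i - 1L)])
      dup <- abs(detections$frame[prev] - detections$frame[i]) <= config$min_sep_t &
        abs(detections$x_half[prev] - detections$x_half[i]) <= config$min_sep_x
      if (any(dup)) keep[i] <- FALSE
    }
    detections <- detections[keep, ]
  }
  detections <- assign_background_frames(detections, bg_frames)

  # discard cells whose 96-column full-res window exceeds the frame
  half_w <- 48L
  in_fov <- detections$x_full - half_w + 1L >= 1L &
    detections$x_full + half_w <= cfg$full_shape[2]
  detections <- detections[in_fov, ]

  # refocus: coarse autofocus on the first n_calibration_cells, quadratic
  # calibration, then three-depth refocusing for the rest
  detections <- detections[order(detections$frame, detections$x_half), ]
  cells <- list()
  morph_rows <- list()
  focus_calib <- NULL
  usable <- which(!is.na(detections$background_frame))
  if (length(usable) >= 3) {
    crop_of <- function(i) {
      d <- detections[i, ]
      cols <- (d$x_full - half_w + 1L):(d$x_full + half_w)
      list(cell = fields_full[[d$frame]][, cols, drop = FALSE],
           bg = fields_full[[d$background_frame]][, cols, drop = FALSE])
    }
    n_cal <- min(config$n_calibration_cells, length(usable))
    cal_idx <- usable[seq_len(n_cal)]
    coarse <- vapply(cal_idx, function(i) {
      cr <- crop_of(i)
      q <- divide_background(cr$cell, cr$bg)
      autofocus(q, cfg$wavelength_um, cfg$pixel_um,
                d_min_um = config$autofocus_range[1],
                d_max_um = config$autofocus_range[2],
                n = config$autofocus_n)$distance_um
    }, numeric(1))
    focus_calib <- calibrate_focus(detections$x_full[cal_idx], coarse,
                                   n_target = config$n_calibration_cells)

    for (i in usable) {
      cr <- crop_of(i)
      rc <- refocus_cell(cr$cell, cr$bg, detections$x_full[i], focus_calib,
                         cfg$wavelength_um, cfg$pixel_um,
                         propagate_before_divide = config$propagate_before_divide)
      cells[[length(cells) + 1L]] <- rc
      img <- rc$phase - corner_offset(rc$phase)
      mask <- cell_mask(img, threshold = config$morph_threshold,
                        opening_radius = config$opening_radius)
      row <- if (is.null(mask)) {
        tibble::tibble(area_um2 = NA_real_, ov_um3 = NA_real_,
                       mean_opl_um = NA_real_, eccentricity = NA_real_,
                       circularity = NA_real_, perimeter_um = NA_real_,
                       n_pixels = 0L, degenerate = TRUE)
      } else {
        measure_cell(img, mask, cfg)
      }
      row$accepted <- if (is.null(mask)) FALSE else filter_cell(row, config$filter)
      row$cell_id <- length(cells)
      row$frame <- detections$frame[i]
      row$x_full <- detections$x_full[i]
      row$refocus_distance_um <- rc$distance_um
      morph_rows[[length(morph_rows) + 1L]] <- row
    }
  } else if (nrow(detections) > 0) {
    warning("too few usable detections for refocus calibration; ",
            "cells left unrefocused")
  }
  morphology <- if (length(morph_rows)) {
    m <- do.call(rbind, morph_rows)
    m[, c("cell_id", "frame", "x_full", "refocus_distance_um", "area_um2",
          "ov_um3", "mean_opl_um", "eccentricity", "circularity",
          "perimeter_um", "n_pixels", "degenerate", "accepted")]
  } else {
    tibble::tibble(cell_id = integer(), frame = integer(), x_full = integer(),
                   refocus_distance_um = numeric(), area_um2 = numeric(),
                   ov_um3 = numeric(), mean_opl_um = numeric(),
                   eccentricity = numeric(), circularity = numeric(),
                   perimeter_um = numeric(), n_pixels = integer(),
                   degenerate = logical(), accepted = logical())
  }

  manifest <- list(
    frames_read = n,
    objects_detected = nrow(detections),
    cells_refocused = length(cells),
    cells_accepted = sum(morphology$accepted),
    background_frames = length(bg_frames),
    carrier_peak = calib$peak_index,
    focus_calibration = if (!is.null(focus_calib)) {
      list(coeffs = as.list(focus_calib$coeffs),
           residual_std_um = focus_calib$residual_std_um,
           n_cells_used = focus_calib$n_cells_used)
    }
  )
  run <- structure(
    list(manifest = manifest, detections = detections,
         morphology = morphology, cells = cells, cleaned = cleaned,
         carrier = calib, focus_calibration = focus_calib),
    class = "hc_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.hc_run <- function(x, ...) {
  m <- x$manifest
  cat("<hc_run>\n")
  cat(sprintf("  frames: %d   detections: %d   refocused: %d   accepted: %d\n",
              m$frames_read, m$objects_detected, m$cells_refocused,
              m$cells_accepted))
  invisible(x)
}

# Write per-cell TIFFs, CSVs (6 significant digits) and the manifest JSON.
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) {
    df[] <- lapply(df, function(col) {
      if (is.double(col)) signif(col, 6) else col
    })
    df
  }
  utils::write.csv(fmt(run$detections),
                   file.path(out_dir, "detections.csv"), row.names = FALSE)
  utils::write.csv(fmt(run$morphology),
                   file.path(out_dir, "morphology.csv"), row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  for (i in seq_along(run$cells)) {
    ph <- run$cells[[i]]$phase
    rng <- range(ph)
    scaled <- if (diff(rng) > 0) (ph - rng[1]) / diff(rng) else ph * 0
    tiff::writeTIFF(scaled, file.path(out_dir, sprintf("cell_%05d.tif", i)),
                    bits.per.sample = 32L)
  }
  invisible(out_dir)
}

#' Subsample or duplicate a detection list
#'
#' Emulates different cell concentrations from one dataset by ignoring a
#' seeded random fraction of the detections, or by processing each detection
#' several times (cyclic duplication).
#'
#' @param detections A detections tibble.
#' @param keep_fraction Fraction in `(0, 1]` to keep (seeded sample without
#'   replacement, original order preserved).
#' @param duplicate_factor Integer >= 1; each detection appears this many
#'   times.
#' @param seed Seed for the random subset.
#' @return The subsampled/duplicated tibble.
#' @export
subsample_cells <- function(detections, keep_fraction = NULL,
                            duplicate_factor = NULL, seed = 1L) {
  if (!is.null(keep_fraction)) {
    if (keep_fraction <= 0 || keep_fraction > 1) {
      stop("keep_fraction must lie in (0, 1]", call. = FALSE)
    }
    set.seed(seed)
    k <- round(nrow(detections) * keep_fraction)
    keep <- sort(sample.int(nrow(detections), k))
    return(detections[keep, ])
  }
  if (!is.null(duplicate_factor)) {
    if (duplicate_factor < 1 || duplicate_factor != round(duplicate_factor)) {
      stop("duplicate_factor must be a positive integer", call. = FALSE)
    }
    return(detections[rep(seq_len(nrow(detections)), duplicate_factor), ])
  }
  detections
}
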