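# Shared fixture builders. Everything is generated in code, seeded.

default_cfg <- optics_config()

# 2x2 block-mean downsampling (full -> half resolution comparison).
downsample2 <- function(m) {
  (m[seq(1, nrow(m), 2), seq(1, ncol(m), 2)] +
     m[seq(2, nrow(m), 2), seq(1, ncol(m), 2)] +
     m[seq(1, nrow(m), 2), seq(2, ncol(m), 2)] +
     m[seq(2, nrow(m), 2), seq(2, ncol(m), 2)]) / 4
}

# A focused synthetic cell as a background-divided complex crop, plus the
# same field defocused by d_um (crop-level, no interferometry involved).
make_cell_field <- function(d_um = 0, profile = "biconcave",
                            peak_phase = 1.8, radius_um = 3.4,
                            cfg = default_cfg, shape = c(96L, 96L)) {
  cs <- cell_spec(1L, shape[2] %/% 2L, radius_um = radius_um,
                  peak_phase_rad = peak_phase, profile = profile)
  phi <- make_cell_phase(cs, cfg$pixel_um, shape)
  U <- exp(1i * phi)
  if (d_um != 0) U <- propagate(U, d_um, cfg$wavelength_um, cfg$pixel_um)
  list(field = U, phase = phi)
}

# Smooth residue-free wrapped field of a given shape: low-order polynomial
# plus long-wavelength sinusoids, with neighbour steps safely below pi.
smooth_wrapped_field <- function(shape, seed) {
  set.seed(seed)
  y <- seq(-1, 1, length.out = shape[1])
  x <- seq(-1, 1, length.out = shape[2])
  a <- stats::runif(6, -1, 1)
  phi <- a[1] * 20 * outer(y, rep(1, shape[2])) +
    a[2] * 60 * outer(rep(1, shape[1]), x) +
    a[3] * 30 * outer(rep(1, shape[1]), x^2) +
    a[4] * 15 * outer(y, x) +
    a[5] * 10 * sin(2 * pi * outer(rep(1, shape[1]), x)) +
    a[6] * 5 * cos(2 * pi * outer(y, rep(1, shape[2])))
  list(true = phi, wrapped = wrap_phase(phi))
}

# Synthesize, demodulate, unwrap and clean a small acquisition; returns the
# acquisition plus cleaned half-resolution frames and full-resolution fields.
process_small_scene <- function(scene, cfg = default_cfg) {
  acq <- synthesize_frames(scene, cfg)
  calib <- calibrate_carrier(acq$frames[, , 1], cfg)
  n <- dim(acq$frames)[3]
  wrapped <- vector("list", n)
  fields <- vector("list", n)
  for (t in seq_len(n)) {
    dm <- demodulate(acq$frames[, , t], calib, cfg)
    wrapped[[t]] <- wrapped_phase(dm$half)
    fields[[t]] <- dm$full$values
  }
  unwrapped <- unwrap_batch(wrapped)
  cleaned <- postprocess_batch(unwrapped)
  list(acq = acq, calib = calib, wrapped = wrapped, fields = fields,
       cleaned = cleaned)
}
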