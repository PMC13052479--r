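#' Residue map of a wrapped phase field
#'
#' For each 2 x 2 plaquette of pixels, the four wrapped phase differences are
#' summed around a counter-clockwise closed loop; the loop sum is always in
#' `{-2 pi, 0, +2 pi}` and its sign is the residue charge. Non-zero residues
#' mark points where unwrapping is path-dependent and must be isolated by
#' branch cuts.
#'
#' @param psi Numeric matrix of wrapped phase in `(-pi, pi]`.
#' @return Integer matrix of shape `(nrow - 1) x (ncol - 1)` with values in
#'   `{-1, 0, 1}`; residue `(r, c)` sits on the plaquette whose top-left
#'   pixel is `(r, c)`.
#' @export
phase_residues <- function(psi) {
  stopifnot(is.matrix(psi), nrow(psi) >= 2, ncol(psi) >= 2)
  a <- psi[-nrow(psi), -ncol(psi), drop = FALSE]  # (r, c)
  b <- psi[-nrow(psi), -1, drop = FALSE]          # (r, c+1)
  c_ <- psi[-1, -1, drop = FALSE]                 # (r+1, c+1)
  d <- psi[-1, -ncol(psi), drop = FALSE]          # (r+1, c)
  s <- wrap_diff(a, b) + wrap_diff(b, c_) + wrap_diff(c_, d) + wrap_diff(d, a)
  r <- sign(round(s / (2 * pi)))
  storage.mode(r) <- "integer"
  r
}

#' Place Goldstein branch cuts
#'
#' Classic growing-box pairing: each unbalanced residue searches square boxes
#' of increasing radius (up to `max_box_radius`) for an unbalanced residue of
#' opposite charge, or for the image edge, whichever appears at the smaller
#' radius (opposite charges are preferred at equal radius). Matched pairs are
#' joined by a Bresenham-rasterized straight cut; unmatched residues are cut
#' to the nearest image edge. Pixels on cuts may not serve as unwrapping
#' references.
#'
#' @param res Residue matrix from [phase_residues()].
#' @param shape Integer `(rows, cols)` of the phase frame the mask is for.
#' @param max_box_radius Largest search radius before falling back to the
#'   nearest edge.
#' @return Logical matrix of `shape`; `TRUE` marks branch-cut pixels.
#' @export
place_branch_cuts <- function(res, shape, max_box_radius = 8L) {
  stopifnot(is.matrix(res), length(shape) == 2)
  cuts <- matrix(FALSE, shape[1], shape[2])
  idx <- which(res != 0L, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(cuts)
  charge <- res[idx]
  balanced <- rep(FALSE, nrow(idx))
  nr <- nrow(res); nc <- ncol(res)

  for (i in seq_len(nrow(idx))) {
    if (balanced[i]) next
    r <- idx[i, 1]; c <- idx[i, 2]
    matched <- FALSE
    for (rad in seq_len(max_box_radius)) {
      # nearest edge of the *pixel* grid (frame edges at rows 1/shape[1] etc.)
      edge_dist <- min(r - 0L, c - 0L, shape[1] - r, shape[2] - c)
      cand <- which(!balanced & charge == -charge[i] &
                      abs(idx[, 1] - r) <= rad & abs(idx[, 2] - c) <= rad)
      if (length(cand)) {
        d2 <- (idx[cand, 1] - r)^2 + (idx[cand, 2] - c)^2
        j <- cand[which.min(d2)]
        cuts <- rasterize_cut(cuts, r, c, idx[j, 1], idx[j, 2])
        balanced[i] <- TRUE
        balanced[j] <- TRUE
        matched <- TRUE
        break
      }
      if (edge_dist <= rad) {
        cuts <- cut_to_edge(cuts, r, c, shape)
        balanced[i] <- TRUE
        matched <- TRUE
        break
      }
    }
    if (!matched) {
      cuts <- cut_to_edge(cuts, r, c, shape)
      balanced[i] <- TRUE
    }
  }
  cuts
}

# Bresenham segment between two residue positions (marked on the pixel grid).
rasterize_cut <- function(cuts, r1, c1, r2, c2) {
  dr <- abs(r2 - r1); dc <- abs(c2 - c1)
  sr <- sign(r2 - r1); sc <- sign(c2 - c1)
  err <- dc - dr
  r <- r1; c <- c1
  repeat {
    cuts[r, c] <- TRUE
    if (r == r2 && c == c2) break
    e2 <- 2 * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc) { err <- err + dc; r <- r + sr }
  }
  cuts
}

cut_to_edge <- function(cuts, r, c, shape) {
  dists <- c(r - 0L, shape[1] - r, c - 0L, shape[2] - c)
  side <- which.min(dists)
  target <- switch(side,
                   c(1L, c), c(shape[1], c), c(r, 1L), c(r, shape[2]))
  rasterize_cut(cuts, r, c, target[1], target[2])
}

#' Flood-fill unwrap one block
#'
#' Breadth-first region growing from the first non-cut pixel in row-major
#' order: each pixel is unwrapped from an already-unwrapped 4-neighbour by
#' adding the wrapped difference. Branch-cut pixels never serve as references
#' and are assigned last from their unwrapped neighbours.
#'
#' @param psi Wrapped phase matrix (radians).
#' @param cuts Logical branch-cut mask of the same shape (default: none).
#' @return Unwrapped phase matrix; `output - input` is everywhere an integer
#'   multiple of `2 pi`.
#' @export
floodfill_unwrap <- function(psi, cuts = NULL) {
  stopifnot(is.matrix(psi))
  if (is.null(cuts)) cuts <- matrix(FALSE, nrow(psi), ncol(psi))
  cpp_floodfill(psi, cuts)
}

#' Block-parallel unwrap of one half-resolution frame
#'
#' The frame is split along the x-axis into blocks of `block_cols` columns,
#' consecutive blocks sharing `overlap_cols` columns (for the 48 x 2048
#' half-resolution frame with the defaults this gives exactly 128 blocks of
#' 20 x 48 pixels with 4-column overlaps; the final block is clipped to the
#' frame edge). Each block is flood-filled independently against the global
#' branch-cut mask, then blocks are merged left to right: the per-pixel phase
#' difference over each overlap is rounded to the nearest multiple of `2 pi`
#' and its mode (ties toward the smallest absolute offset) is added to the
#' right block and all blocks beyond. Overlap columns keep the left block's
#' values.
#'
#' @param psi Wrapped phase matrix (radians), typically 48 x 2048.
#' @param cuts Logical branch-cut mask for the whole frame (default: computed
#'   from [phase_residues()] and [place_branch_cuts()]).
#' @param block_cols,overlap_cols Block schedule along x.
#' @return Unwrapped phase matrix of the same shape.
#' @export
unwrap_frame <- function(psi, cuts = NULL, block_cols = 20L,
                         overlap_cols = 4L) {
  stopifnot(is.matrix(psi), block_cols > overlap_cols, overlap_cols >= 1L)
  if (is.null(cuts)) {
    cuts <- place_branch_cuts(phase_residues(psi), dim(psi))
  }
  nc <- ncol(psi)
  starts <- block_starts(nc, block_cols, overlap_cols)
  out <- matrix(0, nrow(psi), nc)
  offset <- 0
  prev_end <- 0L
  for (s in starts) {
    e <- min(s + block_cols - 1L, nc)
    blk <- floodfill_unwrap(psi[, s:e, drop = FALSE],
                            cuts[, s:e, drop = FALSE])
    if (prev_end == 0L) {
      out[, s:e] <- blk
    } else {
      ov_cols <- s:prev_end
      left <- out[, ov_cols, drop = FALSE]
      right <- blk[, seq_len(length(ov_cols)), drop = FALSE]
      ov_cuts <- cuts[, ov_cols, drop = FALSE]
      k <- round((left - right) / (2 * pi))
      use <- !ov_cuts
      if (!any(use)) {
        warning("block overlap entirely on branch cuts; merge offset set to 0")
        koff <- 0L
      } else {
        koff <- int_mode(as.integer(k[use]))
      }
      blk <- blk + 2 * pi * koff
      # overlap values come from the left block
      if (e > prev_end) out[, (prev_end + 1L):e] <- blk[, (prev_end - s + 2L):ncol(blk), drop = FALSE]
    }
    prev_end <- e
    if (e == nc) break
  }
  out
}

# Column indices where unwrapping blocks start: one block every
# (block_cols - overlap_cols) columns, the final block clipped at the frame
# edge. 2048 columns with 20-column blocks and 4-column overlaps -> 128
# blocks.
block_starts <- function(nc, block_cols = 20L, overlap_cols = 4L) {
  if (nc <= block_cols) return(1L)
  seq.int(1L, nc - overlap_cols, by = block_cols - overlap_cols)
}

#' Unwrap a batch of frames
#'
#' Applies residue identification, branch-cut placement and block unwrapping
#' to each frame of a batch. The batch form mirrors the pipeline's grouping
#' of 20 frames per unwrapping pass; results are identical to processing each
#' frame alone.
#'
#' @param frames List of wrapped phase matrices.
#' @param block_cols,overlap_cols Passed to [unwrap_frame()].
#' @return List of unwrapped phase matrices.
#' @export
unwrap_batch <- function(frames, block_cols = 20L, overlap_cols = 4L) {
  lapply(frames, function(psi) {
    unwrap_frame(psi, block_cols = block_cols, overlap_cols = overlap_cols)
  })
}
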