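# Shared numeric helpers for spectral manipulation and phase arithmetic.

#' Wrap phase values into (-pi, pi]
#'
#' The principal-value convention used throughout: the branch boundary -pi is
#' remapped to +pi, so `wrap_phase(pi)` is `pi` and `wrap_phase(-pi)` is `pi`.
#'
#' @param x Numeric vector/matrix of phase values in radians.
#' @return Values wrapped into `(-pi, pi]`, same shape as `x`.
#' @export
wrap_phase <- function(x) {
  w <- x - 2 * pi * round(x / (2 * pi))
  # round() sends exact half-multiples to even, which can leave -pi; remap.
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

#' Wrapped phase difference
#'
#' `wrap_phase(psi2 - psi1)`: the smallest-magnitude phase step from `psi1`
#' to `psi2`, in `(-pi, pi]`.
#'
#' @param psi1,psi2 Phase values in radians (vectorized).
#' @return Wrapped differences.
#' @export
wrap_diff <- function(psi1, psi2) {
  wrap_phase(psi2 - psi1)
}

# Swap spectral quadrants so the zero-frequency bin moves to the "centre"
# index (floor(n/2) + 1 in 1-based terms), and its inverse.
fftshift2 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  x[c(seq_len(ceiling(nr / 2)) + floor(nr / 2), seq_len(floor(nr / 2))),
    c(seq_len(ceiling(nc / 2)) + floor(nc / 2), seq_len(floor(nc / 2)))]
}

ifftshift2 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  x[c(seq_len(floor(nr / 2)) + ceiling(nr / 2), seq_len(ceiling(nr / 2))),
    c(seq_len(floor(nc / 2)) + ceiling(nc / 2), seq_len(ceiling(nc / 2)))]
}

# DFT sample frequencies in cycles per pixel (unshifted order, like the
# output of fft()): 0, 1/n, ..., then the negative frequencies.
fft_freqs <- function(n) {
  k <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  k / n
}

# 2D inverse FFT with 1/N normalization.
ifft2 <- function(x) {
  stats::fft(x, inverse = TRUE) / length(x)
}

# Population variance (divides by N, not N-1).
pop_var <- function(x) {
  mean((x - mean(x))^2)
}

# Mode of an integer vector; ties broken toward the smallest absolute value.
int_mode <- function(k) {
  tab <- table(k)
  vals <- as.integer(names(tab))
  best <- vals[tab == max(tab)]
  best[which.min(abs(best))]
}
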