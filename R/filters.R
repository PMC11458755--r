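#' Zero-phase Gaussian low-pass filter
#'
#' Convolves the trace with a Gaussian kernel whose frequency response has
#' gain 0.5 at `cutoff_hz` (the convention recorded in provenance; a -3 dB
#' convention would use a slightly narrower kernel). By the Gaussian
#' Fourier pair this fixes the kernel's time-domain standard deviation at
#' `sigma_t = sqrt(ln 2 / 2) / (pi * f_c)`. The kernel is normalized to
#' unit sum (DC gain exactly 1) and applied symmetrically (zero phase lag,
#' peak times preserved); edges are handled by reflection.
#'
#' @param trace A [gevi_trace()].
#' @param cutoff_hz Half-gain frequency in Hz, `0 < cutoff < Nyquist`.
#' @return Filtered `gevi_trace` with `gauss_lp(<cutoff>)` appended to
#'   provenance.
#' @export
gaussian_lowpass <- function(trace, cutoff_hz) {
  stopifnot(inherits(trace, "gevi_trace"))
  dt_s <- trace$sampling_interval_ms / 1000
  nyquist <- 1 / (2 * dt_s)
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyquist) {
    stop("cutoff must lie in (0, Nyquist)", call. = FALSE)
  }
  sigma_s <- sqrt(log(2) / 2) / (pi * cutoff_hz)
  sigma_samp <- sigma_s / dt_s
  half <- max(1L, ceiling(4 * sigma_samp))
  k <- exp(-((-half:half)^2) / (2 * sigma_samp^2))
  k <- k / sum(k)
  x <- trace$samples
  n <- length(x)
  if (half >= n) {
    # short trace: pad by full reflection repeatedly
    pad <- function(v, m) {
      while (length(v) < m) v <- c(rev(v), v, rev(v))
      v
    }
    xp <- c(rev(x), x, rev(x))
    xp <- pad(xp, n + 2L * half)
  } else {
    xp <- c(rev(x[seq_len(half)]), x, rev(x[(n - half + 1L):n]))
  }
  y <- stats::filter(xp, k, method = "convolution", sides = 2)
  start <- (length(xp) - n) %/% 2L
  y <- as.numeric(y[(start + 1L):(start + n)])
  trace_update(trace, y, sprintf("gauss_lp(%g)", cutoff_hz))
}

#' Causal single-pole RC high-pass filter
#'
#' Digital equivalent (bilinear transform) of an analog RC high-pass stage
#' with -3 dB point at `cutoff_hz`, applied causally — this mimics the AC
#' coupling stage of the acquisition chain and fully rejects DC.
#'
#' @param trace A [gevi_trace()].
#' @param cutoff_hz -3 dB frequency in Hz, `0 < cutoff < Nyquist`.
#' @return Filtered `gevi_trace` with `rc_hp(<cutoff>)` appended.
#' @export
rc_highpass <- function(trace, cutoff_hz) {
  stopifnot(inherits(trace, "gevi_trace"))
  dt_s <- trace$sampling_interval_ms / 1000
  nyquist <- 1 / (2 * dt_s)
  if (!is.numeric(cutoff_hz) || cutoff_hz <= 0 || cutoff_hz >= nyquist) {
    stop("cutoff must lie in (0, Nyquist)", call. = FALSE)
  }
  wc <- 2 * pi * cutoff_hz
  K <- 2 / dt_s
  b <- c(K, -K) / (K + wc)
  a <- c(1, (wc - K) / (K + wc))
  y <- as.numeric(signal::filter(b, a, trace$samples))
  trace_update(trace, y, sprintf("rc_hp(%g)", cutoff_hz))
}
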