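#' Unit-peak evoked-response kernels
#'
#' Temporal waveforms of the two signal components mixed in the optical
#' record: `"epsp"` — a difference of exponentials (synaptic potential;
#' graded, slow, summating), normalized to unit peak; `"ap"` — a narrow
#' Gaussian-like transient of the configured full width at half maximum
#' (population action-potential component; fast, all-or-none). Both are
#' causal: identically zero before time 0.
#'
#' @param kind `"epsp"` or `"ap"`.
#' @param t_ms Time grid in ms (kernel is evaluated at `t_ms` relative to
#'   onset at 0).
#' @param rise_ms,decay_ms EPSP time constants (ms), both > 0,
#'   `rise < decay`.
#' @param width_ms AP full width at half maximum (ms), > 0.
#' @return Numeric vector, unit peak on a sufficiently fine grid.
#' @export
#' @examples
#' t <- seq(0, 200, by = 1.02)
#' max(evoked_kernel("epsp", t))  # 1
evoked_kernel <- function(kind = c("epsp", "ap"), t_ms,
                          rise_ms = 3, decay_ms = 40, width_ms = 1.5) {
  kind <- match.arg(kind)
  if (kind == "epsp") {
    if (rise_ms <= 0 || decay_ms <= 0 || rise_ms >= decay_ms) {
      stop("need 0 < rise < decay", call. = FALSE)
    }
    # analytic peak time of exp(-t/d) - exp(-t/r)
    tp <- rise_ms * decay_ms / (decay_ms - rise_ms) * log(decay_ms / rise_ms)
    peak <- exp(-tp / decay_ms) - exp(-tp / rise_ms)
    y <- ifelse(t_ms >= 0, (exp(-t_ms / decay_ms) - exp(-t_ms / rise_ms)) / peak, 0)
  } else {
    if (width_ms <= 0) stop("AP width must be positive", call. = FALSE)
    s <- width_ms / (2 * sqrt(2 * log(2)))  # FWHM -> sd
    t0 <- 3 * s                             # delay so the kernel is ~0 at onset
    y <- ifelse(t_ms >= 0, exp(-(t_ms - t0)^2 / (2 * s^2)), 0)
  }
  y
}
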