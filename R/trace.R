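#' Construct a ROI trace
#'
#' A `gevi_trace` is a one-dimensional optical signal sampled at a fixed
#' interval, together with a provenance record listing every processing step
#' that produced it. After [compute_dff()] with inversion the convention is
#' depolarization-positive dF/F.
#'
#' @param samples Numeric vector of sample values (dimensionless dF/F after
#'   preprocessing; raw camera counts before).
#' @param sampling_interval_ms Positive sampling interval in milliseconds.
#'   The default 1.020 ms matches a ~1 kHz full-frame CCD readout.
#' @param provenance Character vector of processing-step descriptors, e.g.
#'   `"dff(invert)"`, `"gauss_lp(33)"`. Append-only; see [trace_provenance()].
#'
#' @return An object of class `gevi_trace`.
#' @export
#' @examples
#' tr <- gevi_trace(sin(seq(0, 2 * pi, length.out = 100)))
#' tidy(tr)
gevi_trace <- function(samples, sampling_interval_ms = 1.020,
                       provenance = character()) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    stop("trace must contain at least one sample", call. = FALSE)
  }
  if (!all(is.finite(samples))) {
    stop("trace samples must all be finite", call. = FALSE)
  }
  if (!is.numeric(sampling_interval_ms) || length(sampling_interval_ms) != 1L ||
      !is.finite(sampling_interval_ms) || sampling_interval_ms <= 0) {
    stop("sampling_interval_ms must be a positive number", call. = FALSE)
  }
  structure(
    list(
      samples = samples,
      sampling_interval_ms = as.numeric(sampling_interval_ms),
      provenance = as.character(provenance)
    ),
    class = "gevi_trace"
  )
}

#' @export
print.gevi_trace <- function(x, ...) {
  cat(sprintf(
    "<gevi_trace> %d samples @ %.3f ms (%.1f ms)\n",
    length(x$samples), x$sampling_interval_ms,
    length(x$samples) * x$sampling_interval_ms
  ))
  if (length(x$provenance)) {
    cat("  provenance: ", paste(x$provenance, collapse = " -> "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.gevi_trace <- function(x) length(x$samples)

#' Sample times of a trace, in milliseconds
#'
#' Sample `i` is assigned time `(i - 1) * sampling_interval_ms`.
#'
#' @param trace A [gevi_trace()].
#' @return Numeric vector of times in ms, same length as the trace.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "gevi_trace"))
  (seq_along(trace$samples) - 1) * trace$sampling_interval_ms
}

#' Provenance of a trace
#'
#' @param trace A [gevi_trace()].
#' @return Character vector of processing-step descriptors, oldest first.
#' @export
trace_provenance <- function(trace) {
  stopifnot(inherits(trace, "gevi_trace"))
  trace$provenance
}

# Internal: return a copy with new samples and one more provenance entry.
trace_update <- function(trace, samples, step) {
  gevi_trace(samples, trace$sampling_interval_ms, c(trace$provenance, step))
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a trace into a tibble
#'
#' @param x A [gevi_trace()].
#' @param ... Unused.
#' @return A tibble with columns `time_ms` and `value`.
#' @export
tidy.gevi_trace <- function(x, ...) {
  tibble::tibble(time_ms = trace_times(x), value = x$samples)
}

#' Plot a trace
#'
#' @param object A [gevi_trace()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gevi_trace <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$time_ms, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Time (ms)", y = "ΔF/F") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
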