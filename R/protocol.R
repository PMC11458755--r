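#' Construct a stimulation protocol
#'
#' Describes the evoked paradigm: an optional single conditioning pulse
#' ("stim 1") followed by a train of `n_pulses` ("stim 10") at a nominal
#' frequency, delivered at a fixed current.
#'
#' @param frequency_hz Nominal train rate.
#' @param pulse_times_ms Strictly ascending onset times of the train
#'   pulses, in ms; length gives `n_pulses`.
#' @param pulse_width_ms Pulse duration in ms (default 1).
#' @param current_nA Stimulation current (default 135, the plateau point of
#'   the intensity-response curve).
#' @param pre_pulse_time_ms Optional onset of the single pulse preceding
#'   the train; must precede `pulse_times_ms[1]`.
#' @param frame_interval_ms Frame interval the times are snapped to.
#' @return An object of class `stim_protocol`.
#' @export
stim_protocol <- function(frequency_hz, pulse_times_ms, pulse_width_ms = 1,
                          current_nA = 135, pre_pulse_time_ms = NULL,
                          frame_interval_ms = 1.020) {
  if (frequency_hz <= 0) stop("frequency must be positive", call. = FALSE)
  if (any(diff(pulse_times_ms) <= 0)) {
    stop("pulse times must be strictly increasing", call. = FALSE)
  }
  if (!is.null(pre_pulse_time_ms) &&
      pre_pulse_time_ms >= pulse_times_ms[1]) {
    stop("pre-pulse must precede the train", call. = FALSE)
  }
  structure(
    list(
      frequency_hz = frequency_hz,
      n_pulses = length(pulse_times_ms),
      pulse_times_ms = pulse_times_ms,
      isi_ms = round(1000 / frequency_hz),
      pulse_width_ms = pulse_width_ms,
      current_nA = current_nA,
      pre_pulse_time_ms = pre_pulse_time_ms,
      frame_interval_ms = frame_interval_ms
    ),
    class = "stim_protocol"
  )
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("<stim_protocol> %g Hz, %d pulse(s), ISI %d ms, %g nA\n",
              x$frequency_hz, x$n_pulses, x$isi_ms, x$current_nA))
  if (!is.null(x$pre_pulse_time_ms)) {
    cat(sprintf("  pre-pulse at %g ms; train starts %g ms\n",
                x$pre_pulse_time_ms, x$pulse_times_ms[1]))
  }
  invisible(x)
}

#' Generate a stimulus train at a nominal frequency
#'
#' The nominal interstimulus interval is `round(1000 / frequency_hz)` ms
#' (50, 25 and 12 ms at 20, 40 and 83 Hz). Pulse onsets `onset + k * ISI`
#' are snapped to the frame grid, so consecutive spacings equal the
#' nominal ISI to within one frame interval.
#'
#' @param frequency_hz Train rate (> 0).
#' @param n_pulses Number of pulses (>= 1).
#' @param onset_ms Onset of the first pulse, ms.
#' @param frame_interval_ms Frame interval, ms.
#' @param pre_pulse_time_ms Optional single-pulse onset preceding the
#'   train.
#' @param ... Passed to [stim_protocol()] (`pulse_width_ms`, `current_nA`).
#' @return A [stim_protocol()].
#' @export
#' @examples
#' generate_stim_train(40, 10, onset_ms = 400)$isi_ms  # 25
generate_stim_train <- function(frequency_hz, n_pulses, onset_ms = 0,
                                frame_interval_ms = 1.020,
                                pre_pulse_time_ms = NULL, ...) {
  if (frequency_hz <= 0) stop("frequency must be positive", call. = FALSE)
  if (n_pulses < 1) stop("need at least one pulse", call. = FALSE)
  isi <- round(1000 / frequency_hz)
  if (n_pulses > 1 && isi < 2 * frame_interval_ms) {
    stop("frequency too high: ISI below two frame intervals", call. = FALSE)
  }
  snap <- function(t) round(t / frame_interval_ms) * frame_interval_ms
  times <- snap(onset_ms + (seq_len(n_pulses) - 1) * isi)
  if (!is.null(pre_pulse_time_ms)) pre_pulse_time_ms <- snap(pre_pulse_time_ms)
  stim_protocol(frequency_hz, times,
                pre_pulse_time_ms = pre_pulse_time_ms,
                frame_interval_ms = frame_interval_ms, ...)
}

# First stimulus event (pre-pulse if present, else first train pulse).
protocol_first_event_ms <- function(protocol) {
  if (!is.null(protocol$pre_pulse_time_ms)) {
    protocol$pre_pulse_time_ms
  } else {
    protocol$pulse_times_ms[1]
  }
}
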