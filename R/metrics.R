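#' Stimulus-locked per-pulse peak extraction
#'
#' For pulse `k` at time `t_k`, the search window is
#' `[t_k + min_latency, t_(k+1))` (last pulse: `t_k + ISI`). The pulse
#' amplitude is the window maximum minus the pre-stimulus baseline value
#' (amplitudes are measured from the pre-train baseline, not from the
#' preceding trough, so P2/P1 > 1 is the signature of summation). When a
#' window contains no local maximum — fused responses at high rates — the
#' endpoint-excluded window maximum is taken and the pulse is flagged
#' unresolved; P1 is always reported from the rising phase. Ties at the
#' maximum resolve to the earliest sample. `max_peak` is the global
#' maximum over the train epoch extended by three EPSP decay constants.
#'
#' @param trace A preprocessed, depolarization-positive [gevi_trace()]
#'   covering the full train plus a pre-stimulus baseline.
#' @param protocol A [stim_protocol()].
#' @param min_latency_ms Synaptic delay excluded at each window start
#'   (default 2 ms).
#' @param epsp_decay_ms Decay constant used to extend the Max-Peak search
#'   epoch (default 40 ms).
#' @return An object of class `train_response` with fields
#'   `baseline_value`, `baseline_sd`, `peak_times_ms`, `peak_amplitudes`,
#'   `resolved`, `n_resolved`, `max_peak`, and `pre_pulse` (amplitude and
#'   time of the conditioning-pulse response, when present).
#' @export
detect_train_peaks <- function(trace, protocol, min_latency_ms = 2,
                               epsp_decay_ms = 40) {
  stopifnot(inherits(trace, "gevi_trace"), inherits(protocol, "stim_protocol"))
  t_ms <- trace_times(trace)
  x <- trace$samples
  first_event <- protocol_first_event_ms(protocol)
  base_idx <- which(t_ms < first_event - 5)
  if (!length(base_idx)) stop("baseline window empty", call. = FALSE)
  baseline <- mean(x[base_idx])
  baseline_sd <- stats::sd(x[base_idx])
  if (is.na(baseline_sd)) baseline_sd <- 0

  times <- protocol$pulse_times_ms
  n <- protocol$n_pulses
  isi <- protocol$isi_ms
  if (times[n] + isi > t_ms[length(t_ms)] + 1e-9) {
    stop("train epoch extends past trace end", call. = FALSE)
  }
  win_end <- c(times[-1], times[n] + isi)

  pick_peak <- function(lo, hi) {
    idx <- which(t_ms >= lo & t_ms < hi)
    if (length(idx) < 1L) stop("empty search window", call. = FALSE)
    # a local maximum anywhere in the window means the pulse is resolved;
    # without one (fused response) the endpoint-excluded max is reported
    has_lmax <- any(vapply(idx, function(i) {
      i > 1L && i < length(x) && x[i] > x[i - 1L] && x[i] >= x[i + 1L]
    }, TRUE))
    cand <- if (has_lmax || length(idx) <= 2L) idx else idx[-c(1L, length(idx))]
    best <- cand[which.max(x[cand])]
    best <- cand[x[cand] == x[best]][1]  # earliest among ties
    list(i = best, resolved = has_lmax)
  }

  peak_t <- numeric(n); peak_a <- numeric(n); resolved <- logical(n)
  for (k in seq_len(n)) {
    pk <- pick_peak(times[k] + min_latency_ms, win_end[k])
    peak_t[k] <- t_ms[pk$i]
    peak_a[k] <- x[pk$i] - baseline
    resolved[k] <- pk$resolved
  }

  epoch <- which(t_ms >= times[1] & t_ms <= times[n] + 3 * epsp_decay_ms)
  max_peak <- max(x[epoch]) - baseline

  pre <- NULL
  if (!is.null(protocol$pre_pulse_time_ms)) {
    hi <- min(times[1] - 5, protocol$pre_pulse_time_ms + 100)
    pk <- pick_peak(protocol$pre_pulse_time_ms + min_latency_ms, hi)
    pre <- list(time_ms = t_ms[pk$i], amplitude = x[pk$i] - baseline,
                resolved = pk$resolved)
  }

  structure(
    list(
      baseline_value = baseline, baseline_sd = baseline_sd,
      peak_times_ms = peak_t, peak_amplitudes = peak_a,
      resolved = resolved, n_resolved = sum(resolved),
      max_peak = max_peak, pre_pulse = pre,
      frequency_hz = protocol$frequency_hz
    ),
    class = "train_response"
  )
}

#' @export
print.train_response <- function(x, ...) {
  cat(sprintf("<train_response> %d pulse(s) @ %g Hz, %d resolved\n",
              length(x$peak_amplitudes), x$frequency_hz, x$n_resolved))
  cat(sprintf("  P1 = %.4g, max peak = %.4g (baseline sd %.2g)\n",
              x$peak_amplitudes[1], x$max_peak, x$baseline_sd))
  invisible(x)
}

#' Tidy per-pulse peaks into a tibble
#'
#' @param x A `train_response`.
#' @param ... Unused.
#' @return A tibble with one row per pulse.
#' @export
tidy.train_response <- function(x, ...) {
  tibble::tibble(
    pulse = seq_along(x$peak_amplitudes),
    peak_time_ms = x$peak_times_ms,
    amplitude = x$peak_amplitudes,
    resolved = x$resolved
  )
}

#' Temporal summation efficacy (P2/P1)
#'
#' Ratio of the second to the first per-pulse peak amplitude within the
#' same trial; > 1 indicates temporal summation of compound EPSPs.
#' Measurements whose P1 does not exceed the validity threshold return
#' `NA` (an invalid-measurement marker excluded from group statistics),
#' never an error that aborts a run.
#'
#' @param resp A [detect_train_peaks()] result with >= 2 pulses.
#' @param min_p1 Validity threshold on P1; default 3 x the baseline-window
#'   sd of the trace.
#' @param p1_source `"train"` (default: first pulse of the train, keeping
#'   both peaks within the same trial) or `"pre_pulse"` (the response to
#'   the single conditioning pulse preceding the train).
#' @return P2/P1, or `NA_real_` when P1 is at or below threshold.
#' @export
summation_efficacy <- function(resp, min_p1 = NULL,
                               p1_source = c("train", "pre_pulse")) {
  stopifnot(inherits(resp, "train_response"))
  p1_source <- match.arg(p1_source)
  if (length(resp$peak_amplitudes) < 2L) {
    stop("need at least two pulses for P2/P1", call. = FALSE)
  }
  if (is.null(min_p1)) min_p1 <- 3 * resp$baseline_sd
  p1 <- if (p1_source == "pre_pulse") {
    if (is.null(resp$pre_pulse)) {
      stop("no conditioning pulse in this protocol", call. = FALSE)
    }
    resp$pre_pulse$amplitude
  } else {
    resp$peak_amplitudes[1]
  }
  if (!is.finite(p1) || p1 <= min_p1) {
    message(sprintf("P1 = %.3g at or below validity threshold %.3g; marked invalid",
                    p1, min_p1))
    return(NA_real_)
  }
  resp$peak_amplitudes[2] / p1
}

#' Spatial propagation efficacy (remote/reference amplitude ratio)
#'
#' Ratio of the evoked amplitude at a remote ROI to the amplitude at a
#' reference ROI (typically the stimulation site) within the same trial.
#' The default amplitude is P1 of the 10-pulse train — the time point of
#' the first-response peak used for the voltage maps; `mode = "max_peak"`
#' uses the maximal train depolarization instead.
#'
#' @param resp_remote,resp_reference [detect_train_peaks()] results from
#'   the same slice and trial.
#' @param mode `"p1"` or `"max_peak"`.
#' @param min_reference Validity threshold on the reference amplitude;
#'   default 3 x the reference trace's baseline sd.
#' @return Amplitude ratio, or `NA_real_` when the reference is at or
#'   below threshold.
#' @export
propagation_efficacy <- function(resp_remote, resp_reference,
                                 mode = c("p1", "max_peak"),
                                 min_reference = NULL) {
  stopifnot(inherits(resp_remote, "train_response"),
            inherits(resp_reference, "train_response"))
  mode <- match.arg(mode)
  pick <- function(r) {
    if (mode == "p1") r$peak_amplitudes[1] else r$max_peak
  }
  ref <- pick(resp_reference)
  if (is.null(min_reference)) min_reference <- 3 * resp_reference$baseline_sd
  if (!is.finite(ref) || ref <= min_reference) {
    message(sprintf(
      "reference amplitude %.3g at or below validity threshold %.3g; marked invalid",
      ref, min_reference))
    return(NA_real_)
  }
  pick(resp_remote) / ref
}

#' Frame-subtraction voltage map
#'
#' Per-pixel mean over a +/-1-frame window around the peak time minus the
#' per-pixel baseline mean: the spatial extent of the evoked
#' depolarization at the chosen time point.
#'
#' @param movie A dF/F-transformed [gevi_movie()] (see [dff_movie()]).
#' @param peak_frame Frame index of the reference time.
#' @param baseline_frames Frame indices of the pre-stimulus baseline.
#' @return An object of class `voltage_map` (matrix `map` plus metadata).
#' @export
voltage_map <- function(movie, peak_frame, baseline_frames) {
  stopifnot(inherits(movie, "gevi_movie"))
  n <- dim(movie$frames)[1]
  peak_frame <- as.integer(peak_frame)
  if (peak_frame < 1L || peak_frame > n) {
    stop("peak frame outside the movie", call. = FALSE)
  }
  baseline_frames <- as.integer(baseline_frames)
  if (!length(baseline_frames) ||
      any(baseline_frames < 1L | baseline_frames > n)) {
    stop("baseline window out of range", call. = FALSE)
  }
  win <- intersect((peak_frame - 1L):(peak_frame + 1L), seq_len(n))
  peak_img <- apply(movie$frames[win, , , drop = FALSE], c(2, 3), mean)
  base_img <- apply(movie$frames[baseline_frames, , , drop = FALSE], c(2, 3), mean)
  structure(
    list(map = peak_img - base_img, peak_frame = peak_frame,
         baseline_frames = range(baseline_frames),
         frame_interval_ms = movie$frame_interval_ms),
    class = "voltage_map"
  )
}

#' @export
print.voltage_map <- function(x, ...) {
  cat(sprintf("<voltage_map> %dx%d, peak frame %d, range [%.3g, %.3g]\n",
              nrow(x$map), ncol(x$map), x$peak_frame,
              min(x$map), max(x$map)))
  invisible(x)
}

#' Tidy a voltage map into pixel rows
#'
#' @param x A `voltage_map`.
#' @param ... Unused.
#' @return Tibble with `row`, `col`, `amplitude`.
#' @export
tidy.voltage_map <- function(x, ...) {
  tibble::tibble(
    row = as.vector(row(x$map)),
    col = as.vector(col(x$map)),
    amplitude = as.vector(x$map)
  )
}

#' Plot a voltage map
#'
#' @param object A [voltage_map()].
#' @param ... Unused.
#' @return A ggplot object (amplitude-coded raster, red = maximal).
#' @export
autoplot.voltage_map <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$col, .data$row, fill = .data$amplitude)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradientn(colours = c("darkblue", "cyan", "yellow", "red")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Column", y = "Row", fill = "ΔF/F") +
    ggplot2::theme_minimal()
}

#' Intensity-response curve and stimulus-intensity selection
#'
#' Fits a polynomial trendline to (current, amplitude) pairs and selects
#' the smallest tested current whose fitted amplitude reaches
#' `plateau_fraction` of the fitted maximum over the tested range —
#' the point where the response saturates and further current brings no
#' major improvement.
#'
#' @param data Data frame with columns `current_nA` and `amplitude`.
#'   Duplicate currents are all used (no deduplication).
#' @param degree Polynomial degree (default 3); needs more distinct
#'   currents than the degree.
#' @param plateau_fraction Fraction of the fitted maximum defining the
#'   plateau (default 0.9).
#' @return Object of class `intensity_response` with the sorted pairs,
#'   coefficients, fitted values and `selected_intensity`.
#' @export
intensity_response <- function(data, degree = 3, plateau_fraction = 0.9) {
  stopifnot(all(c("current_nA", "amplitude") %in% names(data)))
  data <- dplyr::arrange(tibble::as_tibble(data), .data$current_nA)
  n_distinct <- length(unique(data$current_nA))
  if (n_distinct < degree + 1) {
    stop("need at least degree + 1 distinct currents", call. = FALSE)
  }
  fit <- stats::lm(amplitude ~ poly(current_nA, degree, raw = TRUE),
                   data = data)
  grid <- seq(min(data$current_nA), max(data$current_nA), length.out = 512)
  pred <- stats::predict(fit,
                         newdata = data.frame(current_nA = grid))
  fitted_at <- function(I) {
    stats::predict(fit, newdata = data.frame(current_nA = I))
  }
  target <- plateau_fraction * max(pred)
  tested <- sort(unique(data$current_nA))
  reached <- tested[fitted_at(tested) >= target]
  selected <- if (length(reached)) reached[1] else tested[length(tested)]
  structure(
    list(
      pairs = data,
      coefficients = unname(stats::coef(fit)),
      degree = degree,
      plateau_fraction = plateau_fraction,
      fitted = tibble::tibble(current_nA = grid, amplitude = pred),
      selected_intensity = selected
    ),
    class = "intensity_response"
  )
}

#' @export
print.intensity_response <- function(x, ...) {
  cat(sprintf(
    "<intensity_response> degree-%d fit of %d points; selected %.4g nA (%.0f%% plateau)\n",
    x$degree, nrow(x$pairs), x$selected_intensity, 100 * x$plateau_fraction))
  invisible(x)
}

#' Plot an intensity-response curve
#'
#' @param object An [intensity_response()].
#' @param ... Unused.
#' @return ggplot with data points, polynomial trendline and the selected
#'   intensity as a vertical line.
#' @export
autoplot.intensity_response <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(.data$current_nA, .data$amplitude)) +
    ggplot2::geom_point(colour = "darkorange") +
    ggplot2::geom_line(data = object$fitted) +
    ggplot2::geom_vline(xintercept = object$selected_intensity,
                        linetype = 2) +
    ggplot2::labs(x = "Current (nA)", y = "Peak ΔF/F") +
    ggplot2::theme_minimal()
}
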