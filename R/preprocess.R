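#' dF/F transform of a raw intensity trace
#'
#' Fractional fluorescence change relative to the mean over a pre-stimulus
#' baseline window: `dFF_t = (F_t - Fbase) / Fbase`. Raw GEVI records are
#' negative-going with depolarization, so `invert = TRUE` (the default)
#' multiplies by -1 to make depolarization positive.
#'
#' @param trace A raw-intensity [gevi_trace()].
#' @param baseline_window Integer sample indices of the baseline window;
#'   must be non-empty and should precede the first stimulus.
#' @param invert Flip polarity so depolarization is positive.
#' @return A dF/F `gevi_trace`, provenance `dff(invert)` or `dff`.
#' @export
compute_dff <- function(trace, baseline_window, invert = TRUE) {
  stopifnot(inherits(trace, "gevi_trace"))
  baseline_window <- as.integer(baseline_window)
  if (length(baseline_window) < 1L) {
    stop("baseline window must be non-empty", call. = FALSE)
  }
  if (any(baseline_window < 1L | baseline_window > length(trace$samples))) {
    stop("baseline window out of range", call. = FALSE)
  }
  f0 <- mean(trace$samples[baseline_window])
  if (f0 <= 0) stop("baseline mean must be positive", call. = FALSE)
  y <- (trace$samples - f0) / f0
  if (invert) y <- -y
  trace_update(trace, y, if (invert) "dff(invert)" else "dff")
}

#' Photobleach correction by exponential fit and subtraction
#'
#' Fits `a * exp(-t / tau) + c` by nonlinear least squares to the samples
#' lying OUTSIDE the protected windows (stimulus/response epochs), then
#' subtracts the entire fitted curve (including its constant) from the
#' whole trace. This removes the trend and any DC offset while preserving
#' the response shape, leaving a zero pre-stimulus baseline — the
#' reference for all downstream amplitude measurements. Falls back to a
#' linear detrend with a warning if the nonlinear fit does not converge.
#'
#' @param trace A [gevi_trace()] (typically dF/F).
#' @param protect_windows List of `c(start_ms, end_ms)` intervals excluded
#'   from the fit, e.g. from just before the first stimulus to well after
#'   the train.
#' @return List with `trace` (corrected, provenance `bleach_correct`) and
#'   `fit` (named vector `a`, `tau_ms`, `c`, plus `method`).
#' @export
correct_bleach <- function(trace, protect_windows = list()) {
  stopifnot(inherits(trace, "gevi_trace"))
  t_ms <- trace_times(trace)
  y <- trace$samples
  keep <- rep(TRUE, length(y))
  for (w in protect_windows) {
    keep[t_ms >= w[1] & t_ms <= w[2]] <- FALSE
  }
  if (sum(keep) < 9L) {
    stop("too few unprotected samples for a 3-parameter fit", call. = FALSE)
  }
  tf <- t_ms[keep]; yf <- y[keep]
  # the (a, tau, c) surface is near-degenerate when the observed span is
  # short relative to tau, so seed with a coarse log-grid profile over tau
  # (a and c solved by linear least squares at each tau), then polish
  span_t <- diff(range(tf))
  taus <- exp(seq(log(span_t / 20), log(span_t * 20), length.out = 40))
  best <- NULL
  for (tau in taus) {
    basis <- cbind(1, exp(-tf / tau))
    co <- stats::lm.fit(basis, yf)$coefficients
    rss <- sum((yf - basis %*% co)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(rss = rss, a = unname(co[2]), c = unname(co[1]), tau = tau)
    }
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      yf ~ a * exp(-tf / tau) + c,
      start = list(a = best$a, tau = best$tau, c = best$c),
      lower = c(a = -Inf, tau = 1e-3, c = -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    p <- stats::coef(fit)
    method <- "exp"
  } else if (is.finite(best$rss)) {
    # LM polish can stall on the flat (a, tau, c) ridge; the profiled
    # grid optimum is itself a least-squares exponential fit
    p <- c(a = best$a, tau = best$tau, c = best$c)
    method <- "exp_grid"
  } else {
    warning("exponential bleach fit did not converge; using linear detrend",
            call. = FALSE)
    lf <- stats::lm(yf ~ tf)
    curve <- stats::predict(lf, newdata = data.frame(tf = t_ms))
    p <- c(a = NA_real_, tau = NA_real_, c = NA_real_)
    method <- "linear"
  }
  if (method != "linear") {
    curve <- p[["a"]] * exp(-t_ms / p[["tau"]]) + p[["c"]]
  }
  corrected <- y - curve
  list(
    trace = trace_update(trace, corrected, "bleach_correct"),
    fit = list(a = unname(p[1]), tau_ms = unname(p[2]), c = unname(p[3]),
               method = method)
  )
}

#' Pointwise average of repeated sweeps
#'
#' Averaging n aligned sweeps improves SNR by sqrt(n) for independent
#' noise.
#'
#' @param traces List of [gevi_trace()] of equal length and sampling
#'   interval.
#' @return A `gevi_trace`, provenance `sweep_avg(n=<n>)` appended to the
#'   first trace's provenance.
#' @export
average_sweeps <- function(traces) {
  if (!length(traces)) stop("no traces to average", call. = FALSE)
  lens <- vapply(traces, function(tr) length(tr$samples), 0L)
  dts <- vapply(traces, function(tr) tr$sampling_interval_ms, 0)
  if (length(unique(lens)) != 1L || length(unique(dts)) != 1L) {
    stop("traces must share length and sampling interval", call. = FALSE)
  }
  m <- rowMeans(vapply(traces, function(tr) tr$samples, numeric(lens[1])))
  gevi_trace(m, dts[1],
             c(traces[[1]]$provenance, sprintf("sweep_avg(n=%d)", length(traces))))
}

#' Spatial average of a movie over one ROI
#'
#' Per-frame mean over the pixels of the requested ROI label, producing a
#' single trace per ROI.
#'
#' @param movie A [gevi_movie()] (raw or dF/F-transformed).
#' @param rois A [roi_set()].
#' @param label Integer ROI label to average.
#' @return A [gevi_trace()], provenance `spatial_avg(px=<count>)`.
#' @export
spatial_average <- function(movie, rois, label) {
  stopifnot(inherits(movie, "gevi_movie"), inherits(rois, "roi_set"))
  mask <- rois$label_map == label
  npx <- sum(mask)
  if (npx == 0L) stop("ROI label ", label, " is empty", call. = FALSE)
  d <- dim(movie$frames)
  flat <- matrix(movie$frames, d[1], d[2] * d[3])
  y <- rowMeans(flat[, as.vector(mask), drop = FALSE])
  gevi_trace(y, movie$frame_interval_ms, sprintf("spatial_avg(px=%d)", npx))
}

#' Blank stimulus artifacts by linear interpolation
#'
#' Optionally removes electrical stimulus artifacts by replacing the
#' `n_frames` samples at each pulse onset with a linear interpolation of
#' their neighbours. Off by default in the pipeline: 1-ms pulses at a
#' 1 ms frame interval rarely contaminate more than a single frame.
#'
#' @param trace A [gevi_trace()].
#' @param protocol A [stim_protocol()].
#' @param n_frames Frames to blank from each pulse onset (default 2).
#' @return A `gevi_trace` with `blank_artifact(<n>)` appended.
#' @export
blank_stimulus_artifact <- function(trace, protocol, n_frames = 2) {
  stopifnot(inherits(trace, "gevi_trace"), inherits(protocol, "stim_protocol"))
  t_ms <- trace_times(trace)
  y <- trace$samples
  onsets <- c(protocol$pre_pulse_time_ms, protocol$pulse_times_ms)
  for (on in onsets) {
    i0 <- which(t_ms >= on)[1]
    if (is.na(i0)) next
    idx <- i0:min(i0 + n_frames - 1L, length(y))
    lo <- max(1L, i0 - 1L)
    hi <- min(length(y), idx[length(idx)] + 1L)
    y[idx] <- stats::approx(x = c(lo, hi), y = y[c(lo, hi)], xout = idx)$y
  }
  trace_update(trace, y, sprintf("blank_artifact(%d)", n_frames))
}

#' Branch-specific preprocessing chain
#'
#' Runs the full trace-extraction chain for one ROI of one slice:
#' per-pixel dF/F with inversion, spatial averaging over the ROI, sweep
#' averaging, exponential bleach correction (fit excluding a protected
#' window from 5 ms before the first stimulus to 300 ms after the last
#' pulse, ~7.5 EPSP decay constants), then the branch filters — temporal summation uses a 33 Hz
#' Gaussian low-pass and no high-pass; spatial propagation uses a 77 Hz
#' Gaussian low-pass plus a 0.1 Hz RC high-pass.
#'
#' @param sweeps List of [gevi_movie()] (one per sweep, raw intensities).
#' @param rois A [roi_set()].
#' @param label ROI label to extract.
#' @param protocol A [stim_protocol()].
#' @param branch `"summation"` or `"propagation"`.
#' @return A preprocessed [gevi_trace()].
#' @export
preprocess_branch <- function(sweeps, rois, label, protocol,
                              branch = c("summation", "propagation")) {
  branch <- match.arg(branch)
  dt <- sweeps[[1]]$frame_interval_ms
  first_stim <- protocol_first_event_ms(protocol)
  base_frames <- seq_len(max(2L, floor((first_stim - 5) / dt)))
  per_sweep <- lapply(sweeps, function(mv) {
    dm <- dff_movie(mv, base_frames, invert = TRUE)
    tr <- spatial_average(dm, rois, label)
    gevi_trace(tr$samples, tr$sampling_interval_ms,
               c("dff(invert)", tr$provenance))
  })
  avg <- average_sweeps(per_sweep)
  protect <- list(c(first_stim - 5, max(protocol$pulse_times_ms) + 300))
  bc <- correct_bleach(avg, protect)
  tr <- bc$trace
  if (branch == "summation") {
    gaussian_lowpass(tr, 33)
  } else {
    rc_highpass(gaussian_lowpass(tr, 77), 0.1)
  }
}
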