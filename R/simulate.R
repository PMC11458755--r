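#' Simulation configuration
#'
#' Defaults describe an 80 x 80 pixel sensor imaging a 1 mm field at
#' 12.5 um/px, a stimulation site in the layer-4 band, ROI-2 300 um above
#' it in L2/3 of the same column and ROI-3 a further 300 um laterally in
#' the adjacent column. Evoked amplitude at a pixel decays exponentially
#' with its city-block (vertical-then-horizontal path) distance from the
#' stimulation site, with a short space constant for the direct/AP
#' component and a long one for the synaptic component. No absolute
#' indicator scale is assumed: `peak_dff` and `noise_scale` are
#' order-of-magnitude choices exposed here, not measured values.
#'
#' @param h,w Frame size in pixels.
#' @param pixel_size_um Pixel pitch, um.
#' @param stim_site `c(row, col)` of the stimulation site (1-based).
#' @param roi2_offset_um Vertical (toward pia, decreasing row) offset of
#'   ROI-2 from the stimulation site, um.
#' @param roi3_lateral_um Additional lateral offset of ROI-3 from ROI-2,
#'   um (~300 in the default layout).
#' @param layer4_halfwidth_um Half-width of the darker layer-4 band in the
#'   baseline image, um.
#' @param epsp_rise_ms,epsp_decay_ms Synaptic kernel time constants, ms.
#' @param ap_width_ms FWHM of the fast direct-activation transient at the
#'   stimulation site, ms. Single-cell spikes last 1-2 ms, but the
#'   compound population volley picked up by a wide-field ROI is
#'   temporally dispersed; the default 6 ms reflects that compound width.
#' @param peak_dff Total noiseless dF/F peak of a single pulse at the
#'   stimulation site (AP + EPSP components).
#' @param ap_fraction Fraction of `peak_dff` carried by the AP component
#'   at the stimulation site.
#' @param lambda_ap_um Spatial decay length of the direct/AP component,
#'   um (short: direct activation is confined to the electrode's
#'   vicinity).
#' @param lambda_epsp_um Synaptic space constant(s), um. A scalar applies
#'   isotropically; a named length-2 vector `c(vertical = , horizontal = )`
#'   separates local (within-column, axo-dendritic) from trans-columnar
#'   (through L2/3 neuropil) propagation — the axis the AD condition
#'   weakens. The horizontal constant applies only to the lateral leg
#'   beyond `column_halfwidth_um`; lateral micro-offsets inside the home
#'   column decay with the local (vertical) constant, so measurements at
#'   the stimulation column are untouched by trans-columnar weakening.
#' @param column_halfwidth_um Half-width of a cortical column, um; the
#'   boundary between local and trans-columnar lateral spread.
#' @param weights Per-pulse synaptic weights `w_1..w_n` (facilitation), or
#'   `NULL` for the saturating default `1 + 0.6 * (1 - 0.55^(k-1))`.
#' @param n_sweeps Sweeps per trial for averaging.
#' @param epsp_success_p Per-pulse Bernoulli success probability of
#'   synaptic release, in (0, 1].
#' @param jitter_sd_ms Per-sweep Gaussian onset jitter sd, ms.
#' @param bleach_tau_ms,bleach_frac Photobleaching time constant and total
#'   fractional amplitude (fluorescence decays from 1 toward
#'   `1 - bleach_frac`).
#' @param noise_scale Multiplier on shot-noise-like Gaussian noise with sd
#'   `sqrt(F)` counts; 1 = pure shot noise.
#' @param baseline_counts Mean resting fluorescence, camera counts. The
#'   default 20000 gives, with pure shot noise, a single-sweep
#'   single-pixel peak SNR of ~3 at the stimulation site — low enough
#'   that 4-sweep and ROI averaging are visibly useful.
#' @param layer4_dim_factor Relative brightness of the layer-4 band.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(h = 80, w = 80, pixel_size_um = 12.5,
                       stim_site = c(60, 20),
                       roi2_offset_um = 300, roi3_lateral_um = 300,
                       layer4_halfwidth_um = 75,
                       epsp_rise_ms = 3, epsp_decay_ms = 40,
                       ap_width_ms = 6,
                       peak_dff = 0.02, ap_fraction = 0.6,
                       lambda_ap_um = 60, lambda_epsp_um = 600,
                       column_halfwidth_um = 150,
                       weights = NULL,
                       n_sweeps = 4, epsp_success_p = 0.9,
                       jitter_sd_ms = 1,
                       bleach_tau_ms = 8000, bleach_frac = 0.05,
                       noise_scale = 1,
                       baseline_counts = 20000, layer4_dim_factor = 0.8) {
  cfg <- as.list(environment())
  if (length(lambda_epsp_um) == 1L) {
    lambda_epsp_um <- c(vertical = unname(lambda_epsp_um),
                        horizontal = unname(lambda_epsp_um))
  }
  if (!all(c("vertical", "horizontal") %in% names(lambda_epsp_um))) {
    stop("lambda_epsp_um needs 'vertical' and 'horizontal' components",
         call. = FALSE)
  }
  cfg$lambda_epsp_um <- lambda_epsp_um[c("vertical", "horizontal")]
  if (cfg$lambda_ap_um <= 0 || any(cfg$lambda_epsp_um <= 0)) {
    stop("spatial decay lengths must be positive", call. = FALSE)
  }
  if (cfg$epsp_success_p <= 0 || cfg$epsp_success_p > 1) {
    stop("EPSP success probability must lie in (0, 1]", call. = FALSE)
  }
  if (cfg$bleach_tau_ms <= 0) stop("bleach tau must be positive", call. = FALSE)
  if (!is.null(weights) && any(weights <= 0)) {
    stop("synaptic weights must be positive", call. = FALSE)
  }
  if (stim_site[1] < 1 || stim_site[1] > h || stim_site[2] < 1 ||
      stim_site[2] > w) {
    stop("stimulation site outside the frame", call. = FALSE)
  }
  centers <- roi_centers(cfg)
  for (ct in centers) {
    if (ct[1] < 1 || ct[1] > h || ct[2] < 1 || ct[2] > w) {
      stop("ROI offsets map outside the frame at this pixel size",
           call. = FALSE)
    }
  }
  class(cfg) <- "sim_config"
  cfg
}

# Default per-pulse synaptic weights: saturating facilitation.
default_weights <- function(n) 1 + 0.6 * (1 - 0.55^(seq_len(n) - 1))

# ROI centres (row, col) implied by the configured geometry.
roi_centers <- function(cfg) {
  px <- cfg$pixel_size_um
  r1 <- cfg$stim_site
  r2 <- c(r1[1] - round(cfg$roi2_offset_um / px), r1[2])
  r3 <- c(r2[1], r2[2] + round(cfg$roi3_lateral_um / px))
  list(stim_site = r1, same_column = r2, adjacent_column = r3)
}

#' Standard ROI layout implied by a simulation config
#'
#' @param cfg A [sim_config()].
#' @param n_pixels Pixels per ROI aperture (57 summation, 37 propagation).
#' @return A [roi_set()].
#' @export
default_rois <- function(cfg, n_pixels = 37) {
  standard_rois(c(cfg$h, cfg$w), roi_centers(cfg), n_pixels)
}

# Vertical and horizontal path legs (um) of every pixel from the
# stimulation site: propagation runs vertically within the column then
# horizontally through L2/3, so path length decomposes as |dr| + |dc| in
# physical units (city-block distance).
distance_legs_um <- function(cfg) {
  rr <- matrix(rep(seq_len(cfg$h), cfg$w), cfg$h, cfg$w)
  cc <- matrix(rep(seq_len(cfg$w), each = cfg$h), cfg$h, cfg$w)
  list(vertical = abs(rr - cfg$stim_site[1]) * cfg$pixel_size_um,
       horizontal = abs(cc - cfg$stim_site[2]) * cfg$pixel_size_um)
}

# Spatial gain fields of the two response components. The lateral leg
# inside the home column decays with the local (vertical) constant; only
# the trans-columnar remainder uses the horizontal constant.
response_fields <- function(cfg) {
  d <- distance_legs_um(cfg)
  lam <- cfg$lambda_epsp_um
  chw <- cfg$column_halfwidth_um %||% 0
  h_local <- pmin(d$horizontal, chw)
  h_trans <- pmax(d$horizontal - chw, 0)
  list(
    ap = cfg$peak_dff * cfg$ap_fraction *
      exp(-(d$vertical + d$horizontal) / cfg$lambda_ap_um),
    ep = cfg$peak_dff * (1 - cfg$ap_fraction) *
      exp(-((d$vertical + h_local) / lam[["vertical"]] +
              h_trans / lam[["horizontal"]]))
  )
}

# Baseline fluorescence image with the darker layer-4 band.
baseline_image <- function(cfg) {
  b <- matrix(cfg$baseline_counts, cfg$h, cfg$w)
  halfpx <- cfg$layer4_halfwidth_um / cfg$pixel_size_um
  band <- abs(seq_len(cfg$h) - cfg$stim_site[1]) <= halfpx
  b[band, ] <- b[band, ] * cfg$layer4_dim_factor
  b
}

# All stimulus events of a protocol with their synaptic weights.
# The pre-pulse (stim 1) gets weight w_1; train pulses w_1..w_n.
protocol_events <- function(cfg, protocol) {
  w <- cfg$weights
  if (is.null(w)) w <- default_weights(protocol$n_pulses)
  if (length(w) < protocol$n_pulses) {
    stop("need one synaptic weight per pulse", call. = FALSE)
  }
  times <- protocol$pulse_times_ms
  weights <- w[seq_len(protocol$n_pulses)]
  if (!is.null(protocol$pre_pulse_time_ms)) {
    times <- c(protocol$pre_pulse_time_ms, times)
    weights <- c(w[1], weights)
  }
  list(times = times, weights = weights)
}

# Noiseless expected dF/F trace of the summed response components for a
# set of events; AP gain saturates at 1 per pulse (all-or-none), EPSP
# scales with weight * success.
component_timecourses <- function(cfg, t_ms, times, ap_gain, ep_gain) {
  ap <- numeric(length(t_ms))
  ep <- numeric(length(t_ms))
  for (i in seq_along(times)) {
    rel <- t_ms - times[i]
    ap <- ap + ap_gain[i] * evoked_kernel("ap", rel, width_ms = cfg$ap_width_ms)
    ep <- ep + ep_gain[i] *
      evoked_kernel("epsp", rel, rise_ms = cfg$epsp_rise_ms,
                    decay_ms = cfg$epsp_decay_ms)
  }
  list(ap = ap, ep = ep)
}

#' Simulate wide-field movies for one slice and one protocol
#'
#' Forward model, per pixel `p` at path distance `d` from the stimulation
#' site and frame time `t`:
#' `F(p,t) = B(p) * bleach(t) * (1 - s(p,t)) + noise`, with
#' `s(p,t) = A_ap exp(-d/lambda_ap) sum_k g_ap(t - t_k - j) +
#'  A_ep exp(-d/lambda_epsp) sum_k w_k succ_k g_epsp(t - t_k - j)`.
#' The AP per-pulse gain is capped at 1 (all-or-none; no facilitation), so
#' AP-dominated sites summate weakly, while the synaptic weights `w_k`
#' facilitate. Depolarization dims emission, so raw responses are
#' negative-going. Noise is Gaussian with sd `noise_scale * sqrt(F)`
#' (shot-noise-like) and frames are rounded to integer counts.
#'
#' @param cfg A [sim_config()].
#' @param protocol A [stim_protocol()] (see [generate_stim_train()]).
#' @param seed Optional integer seed; identical seeds give identical
#'   output.
#' @param tail_ms Recording time kept after the last pulse, ms.
#' @param quantize Round frames to integer camera counts (default TRUE).
#'   With `noise_scale = 0` quantization errors are identical across
#'   sweeps and neighbouring pixels and never average out, so fully
#'   noiseless studies should disable it.
#' @return List with `sweeps` (list of [gevi_movie()], one per sweep),
#'   `truth` (see [simulation_truth()]), and `protocol`.
#' @export
simulate_movie <- function(cfg, protocol, seed = NULL, tail_ms = 500,
                           quantize = TRUE) {
  stopifnot(inherits(cfg, "sim_config"), inherits(protocol, "stim_protocol"))
  if (!is.null(seed)) set.seed(seed)
  dt <- protocol$frame_interval_ms
  n_frames <- ceiling((max(protocol$pulse_times_ms) + tail_ms) / dt)
  t_ms <- (seq_len(n_frames) - 1) * dt
  ev <- protocol_events(cfg, protocol)

  fields <- response_fields(cfg)
  ap_field <- fields$ap
  ep_field <- fields$ep
  b_img <- baseline_image(cfg)
  bleach_t <- 1 - cfg$bleach_frac * (1 - exp(-t_ms / cfg$bleach_tau_ms))

  f_base <- bleach_t %o% as.vector(b_img)  # static baseline x bleach field
  sweeps <- vector("list", cfg$n_sweeps)
  jitters <- numeric(cfg$n_sweeps)
  successes <- matrix(NA, cfg$n_sweeps, length(ev$times))
  for (s in seq_len(cfg$n_sweeps)) {
    jit <- stats::rnorm(1, 0, cfg$jitter_sd_ms)
    succ <- stats::rbinom(length(ev$times), 1, cfg$epsp_success_p)
    jitters[s] <- jit
    successes[s, ] <- succ
    tc <- component_timecourses(cfg, t_ms, ev$times + jit,
                                ap_gain = rep(1, length(ev$times)),
                                ep_gain = ev$weights * succ)
    # rank-2 spatio-temporal response, T x (H*W)
    sig <- tcrossprod(tc$ap, as.vector(ap_field)) +
      tcrossprod(tc$ep, as.vector(ep_field))
    if (max(sig) >= 1) {
      stop("response amplitude drives fluorescence negative; reduce peak_dff",
           call. = FALSE)
    }
    f <- f_base * (1 - sig)
    if (cfg$noise_scale > 0) {
      f <- f + cfg$noise_scale * sqrt(f) * stats::rnorm(length(f))
    }
    f <- if (quantize) round(pmax(f, 0)) else pmax(f, 0)
    sweeps[[s]] <- gevi_movie(array(f, dim = c(n_frames, cfg$h, cfg$w)), dt,
                              meta = list(trial = s, signal = "raw"))
  }
  # standard-layout truth is unavailable when the geometry cannot hold
  # the three ROI apertures (e.g. tiny noise-characterization frames)
  truth <- tryCatch(simulation_truth(cfg, protocol, t_ms),
                    error = function(e) list(traces = NULL, table = NULL))
  truth$jitters_ms <- jitters
  truth$epsp_successes <- successes
  list(sweeps = sweeps, truth = truth, protocol = protocol)
}

#' Ground truth for a simulated slice
#'
#' Deterministic expectation of the model (no jitter, EPSP success at its
#' expected value, no noise, no bleaching): noiseless dF/F traces per ROI
#' and the true metrics extracted from them with [detect_train_peaks()].
#' Because the branch filters are part of the measurement definition (a
#' 33 Hz low-pass fuses 40 Hz peaks for truth and recordings alike), a
#' `branch` can be given so the noiseless traces pass through the same
#' filter chain before peak extraction; `"raw"` skips filtering and
#' reports model-level amplitudes.
#'
#' @param cfg A [sim_config()].
#' @param protocol A [stim_protocol()].
#' @param t_ms Time grid; default covers the train plus 500 ms.
#' @param roi_pixels Aperture size for the truth ROIs; defaults to the
#'   branch convention (57 summation, 37 propagation/raw).
#' @param branch `"raw"`, `"summation"` or `"propagation"`.
#' @return List with `traces` (named list of [gevi_trace()]) and `table`
#'   (one-row tibble of true metrics).
#' @export
simulation_truth <- function(cfg, protocol, t_ms = NULL, roi_pixels = NULL,
                             branch = c("raw", "summation", "propagation")) {
  branch <- match.arg(branch)
  if (is.null(roi_pixels)) {
    roi_pixels <- if (branch == "summation") 57 else 37
  }
  if (is.null(t_ms)) {
    dt <- protocol$frame_interval_ms
    t_ms <- (seq_len(ceiling((max(protocol$pulse_times_ms) + 500) / dt)) - 1) * dt
  }
  ev <- protocol_events(cfg, protocol)
  tc <- component_timecourses(cfg, t_ms, ev$times,
                              ap_gain = rep(1, length(ev$times)),
                              ep_gain = ev$weights * cfg$epsp_success_p)
  truth_from_timecourses(cfg, protocol, t_ms, tc, branch, roi_pixels)
}

# Shared back end: ROI traces and true metrics from component timecourses.
truth_from_timecourses <- function(cfg, protocol, t_ms, tc, branch,
                                   roi_pixels) {
  fields <- response_fields(cfg)
  ap_field <- fields$ap
  ep_field <- fields$ep
  rois <- default_rois(cfg, roi_pixels)
  roles <- c("stim_site", "same_column", "adjacent_column")
  names(roles) <- c("roi1", "roi2", "roi3")
  dt <- diff(t_ms[1:2])
  traces <- list()
  peaks <- list()
  for (nm in names(roles)) {
    lab <- roi_label_for_role(rois, roles[[nm]])
    mask <- rois$label_map == lab
    y <- mean(ap_field[mask]) * tc$ap + mean(ep_field[mask]) * tc$ep
    tr <- gevi_trace(y, dt, provenance = "simulated_truth")
    tr <- switch(branch,
      raw = tr,
      summation = gaussian_lowpass(tr, 33),
      propagation = rc_highpass(gaussian_lowpass(tr, 77), 0.1)
    )
    traces[[nm]] <- tr
    peaks[[nm]] <- detect_train_peaks(tr, protocol,
                                      epsp_decay_ms = cfg$epsp_decay_ms)
  }
  p1 <- vapply(peaks, function(p) p$peak_amplitudes[1], 0)
  p2 <- vapply(peaks, function(p)
    if (protocol$n_pulses >= 2) p$peak_amplitudes[2] else NA_real_, 0)
  mx <- vapply(peaks, function(p) p$max_peak, 0)
  tab <- tibble::tibble(
    frequency_hz = protocol$frequency_hz,
    p1_roi1 = p1[["roi1"]], p1_roi2 = p1[["roi2"]], p1_roi3 = p1[["roi3"]],
    p2_over_p1_roi1 = p2[["roi1"]] / p1[["roi1"]],
    p2_over_p1_roi2 = p2[["roi2"]] / p1[["roi2"]],
    p2_over_p1_roi3 = p2[["roi3"]] / p1[["roi3"]],
    max_peak_roi1 = mx[["roi1"]], max_peak_roi2 = mx[["roi2"]],
    max_peak_roi3 = mx[["roi3"]],
    roi2_over_roi1 = p1[["roi2"]] / p1[["roi1"]],
    roi3_over_roi2 = p1[["roi3"]] / p1[["roi2"]],
    roi3_over_roi1 = p1[["roi3"]] / p1[["roi1"]]
  )
  list(traces = traces, table = tab)
}

#' Realized ground truth of one simulated trial average
#'
#' The noiseless dF/F traces of the sweep average actually realized in a
#' simulated trial — using the per-sweep onset jitters and per-pulse EPSP
#' successes recorded by [simulate_movie()] — and the true metrics
#' extracted from them. This is the parameter-recovery reference: it
#' differs from [simulation_truth()] (the model expectation) by the
#' trial-to-trial sampling of jitter and synaptic failures, which a
#' 4-sweep average does not average away.
#'
#' @param cfg A [sim_config()].
#' @param protocol A [stim_protocol()].
#' @param jitters_ms Per-sweep onset jitters (from `truth$jitters_ms`).
#' @param successes Sweep x pulse 0/1 matrix (from
#'   `truth$epsp_successes`).
#' @param t_ms Time grid; default covers the train plus 500 ms.
#' @param roi_pixels Aperture size; defaults to the branch convention.
#' @param branch `"raw"`, `"summation"` or `"propagation"`.
#' @return As [simulation_truth()].
#' @export
realized_truth <- function(cfg, protocol, jitters_ms, successes,
                           t_ms = NULL, roi_pixels = NULL,
                           branch = c("raw", "summation", "propagation")) {
  branch <- match.arg(branch)
  if (is.null(roi_pixels)) {
    roi_pixels <- if (branch == "summation") 57 else 37
  }
  if (is.null(t_ms)) {
    dt <- protocol$frame_interval_ms
    t_ms <- (seq_len(ceiling((max(protocol$pulse_times_ms) + 500) / dt)) - 1) * dt
  }
  ev <- protocol_events(cfg, protocol)
  n_s <- length(jitters_ms)
  ap <- ep <- numeric(length(t_ms))
  for (s in seq_len(n_s)) {
    tc <- component_timecourses(cfg, t_ms, ev$times + jitters_ms[s],
                                ap_gain = rep(1, length(ev$times)),
                                ep_gain = ev$weights * successes[s, ])
    ap <- ap + tc$ap
    ep <- ep + tc$ep
  }
  truth_from_timecourses(cfg, protocol, t_ms,
                         list(ap = ap / n_s, ep = ep / n_s),
                         branch, roi_pixels)
}

#' Standard evoked paradigm: one conditioning pulse then a 10-pulse train
#'
#' 200 ms pre-stimulus baseline, single pulse ("stim 1") at 200 ms, train
#' ("stim 10") starting at 450 ms.
#'
#' @param frequency_hz Train rate (20, 40 or 83 in the standard paradigm).
#' @param n_pulses Train length (default 10).
#' @param frame_interval_ms Frame interval, ms.
#' @return A [stim_protocol()].
#' @export
train_paradigm <- function(frequency_hz, n_pulses = 10,
                           frame_interval_ms = 1.020) {
  generate_stim_train(frequency_hz, n_pulses, onset_ms = 450,
                      frame_interval_ms = frame_interval_ms,
                      pre_pulse_time_ms = 200)
}
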