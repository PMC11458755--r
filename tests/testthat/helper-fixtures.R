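# Reduced-geometry simulation config used across tests: 40x40 px at
# 25 um/px keeps the 300 um ROI offsets inside the frame while movies
# stay small. Overrides are passed through to sim_config().
test_config <- function(...) {
  args <- list(...)
  defaults <- list(h = 40, w = 40, pixel_size_um = 25, stim_site = c(30, 8))
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Fully deterministic variant: no noise, no jitter, no synaptic failures.
det_config <- function(...) {
  test_config(noise_scale = 0, jitter_sd_ms = 0, epsp_success_p = 1, ...)
}

# Independent per-window argmax oracle for detect_train_peaks: brute
# force over the sample grid, no local-maximum logic.
oracle_train_peaks <- function(trace, protocol, min_latency_ms = 2) {
  t <- trace_times(trace)
  x <- trace$samples
  base <- mean(x[t < protocol_first_event_ms_test(protocol) - 5])
  times <- protocol$pulse_times_ms
  ends <- c(times[-1], times[length(times)] + protocol$isi_ms)
  vapply(seq_along(times), function(k) {
    idx <- which(t >= times[k] + min_latency_ms & t < ends[k])
    max(x[idx]) - base
  }, 0)
}

protocol_first_event_ms_test <- function(protocol) {
  if (!is.null(protocol$pre_pulse_time_ms)) protocol$pre_pulse_time_ms
  else protocol$pulse_times_ms[1]
}
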