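test_that("train peaks match the per-window argmax oracle on clean traces", {
  cfg <- det_config()
  for (f in c(20, 40)) {
    pr <- train_paradigm(f)
    truth <- simulation_truth(cfg, pr, branch = "raw")
    for (tr in truth$traces) {
      got <- detect_train_peaks(tr, pr)
      expect_equal(got$peak_amplitudes, oracle_train_peaks(tr, pr),
                   tolerance = 1e-12)
      expect_true(all(diff(got$peak_times_ms) > 0))
    }
  }
})

test_that("single-pulse and degenerate traces are handled", {
  pr <- generate_stim_train(20, 1, onset_ms = 300)
  t <- (0:599) * 1.02
  y <- 0.01 * evoked_kernel("epsp", t - 300)
  r <- detect_train_peaks(gevi_trace(y, 1.02), pr)
  expect_equal(length(r$peak_amplitudes), 1L)
  expect_equal(r$max_peak, r$peak_amplitudes[1], tolerance = 1e-9)

  rz <- detect_train_peaks(gevi_trace(rep(0, 600), 1.02), pr)
  expect_equal(rz$peak_amplitudes, 0)
  expect_equal(rz$n_resolved, 0L)

  short <- gevi_trace(y[1:310], 1.02)
  expect_error(detect_train_peaks(short, pr), "past trace end")
})

test_that("fused high-rate trains flag unresolved pulses but keep P1", {
  cfg <- det_config()
  pr <- train_paradigm(83)
  tr <- simulation_truth(cfg, pr, branch = "summation")$traces$roi3
  r <- detect_train_peaks(tr, pr)
  expect_lt(r$n_resolved, 10L)
  expect_gt(r$peak_amplitudes[1], 0)
  expect_gte(r$max_peak, max(r$peak_amplitudes))
})

test_that("summation efficacy is P2/P1 with a validity threshold", {
  mk <- function(p1, p2) {
    structure(list(baseline_value = 0, baseline_sd = 1e-4,
                   peak_amplitudes = c(p1, p2), peak_times_ms = c(10, 35),
                   resolved = c(TRUE, TRUE), n_resolved = 2L,
                   max_peak = max(p1, p2), pre_pulse = NULL,
                   frequency_hz = 40),
              class = "train_response")
  }
  expect_equal(summation_efficacy(mk(0.01, 0.01)), 1.0)
  expect_equal(summation_efficacy(mk(0.01, 0.014)), 1.4)
  expect_message(out <- summation_efficacy(mk(0, 0.01)), "invalid")
  expect_true(is.na(out))
  expect_message(out2 <- summation_efficacy(mk(2e-4, 0.01)), "invalid")
  expect_true(is.na(out2))  # below 3 x baseline sd
})

test_that("propagation efficacy divides remote by reference amplitude", {
  mk <- function(p1, mx) {
    structure(list(baseline_value = 0, baseline_sd = 1e-4,
                   peak_amplitudes = c(p1, p1 * 1.2), peak_times_ms = c(10, 35),
                   resolved = c(TRUE, TRUE), n_resolved = 2L,
                   max_peak = mx, pre_pulse = NULL, frequency_hz = 40),
              class = "train_response")
  }
  a <- mk(0.01, 0.02)
  expect_equal(propagation_efficacy(a, a), 1.0)
  expect_equal(propagation_efficacy(mk(0.005, 0.01), a), 0.5)
  expect_equal(propagation_efficacy(mk(0.005, 0.01), a, mode = "max_peak"), 0.5)
  expect_message(out <- propagation_efficacy(a, mk(0, 0)), "invalid")
  expect_true(is.na(out))
})

test_that("efficacy ratios are scale- and translation-invariant", {
  cfg <- det_config()
  pr <- train_paradigm(40)
  tr <- simulation_truth(cfg, pr, branch = "summation")$traces$roi2
  r0 <- detect_train_peaks(tr, pr)
  scaled <- gevi_trace(tr$samples * 3.7, tr$sampling_interval_ms)
  shifted <- gevi_trace(tr$samples + 0.5, tr$sampling_interval_ms)
  rs <- detect_train_peaks(scaled, pr)
  rt <- detect_train_peaks(shifted, pr)
  expect_equal(summation_efficacy(rs), summation_efficacy(r0),
               tolerance = 1e-12)
  expect_equal(rt$peak_amplitudes, r0$peak_amplitudes, tolerance = 1e-9)
  expect_equal(propagation_efficacy(rs, rs), 1.0)
})

test_that("voltage maps localize the evoked response", {
  # single bright-pixel step
  frames <- array(100, c(10, 6, 6))
  frames[6:10, 3, 4] <- 130
  mv <- gevi_movie(frames, 1.02)
  vm <- voltage_map(mv, peak_frame = 8, baseline_frames = 1:4)
  expect_equal(sum(abs(vm$map) > 1e-9), 1L)
  expect_equal(vm$map[3, 4], 30)

  cfg <- det_config()
  pr <- generate_stim_train(20, 1, onset_ms = 300)
  sim <- simulate_movie(cfg, pr, seed = 1)
  dm <- dff_movie(sim$sweeps[[1]], 1:200)
  peak_frame <- round(310 / 1.02)
  vm2 <- voltage_map(dm, peak_frame, 1:200)
  hit <- which(vm2$map == max(vm2$map), arr.ind = TRUE)
  expect_lte(max(abs(hit[1, ] - cfg$stim_site)), 1)
  # a baseline time point yields a flat map
  vm3 <- voltage_map(dm, 100, 1:200)
  expect_lt(max(abs(vm3$map)), 0.003)
  expect_error(voltage_map(dm, 10^6, 1:200), "outside")
})

test_that("intensity-response fitting finds the plateau current", {
  # linear data: the cubic fit reproduces a line exactly
  lin <- tibble::tibble(current_nA = seq(20, 200, by = 15))
  lin$amplitude <- 1e-4 * lin$current_nA
  ir <- intensity_response(lin)
  expect_equal(max(abs(ir$fitted$amplitude - 1e-4 * ir$fitted$current_nA)), 0,
               tolerance = 1e-9)
  expect_equal(ir$selected_intensity,
               min(lin$current_nA[1e-4 * lin$current_nA >=
                                    0.9 * max(lin$amplitude)]))
  # saturating curve: selection within one step of the brute-force answer
  cur <- seq(18, 198, length.out = 13)
  sat <- tibble::tibble(current_nA = cur,
                        amplitude = 0.03 * (1 - exp(-cur / 60)))
  irs <- intensity_response(sat)
  brute <- min(cur[sat$amplitude >= 0.9 * max(sat$amplitude)])
  expect_lte(abs(irs$selected_intensity - brute), diff(cur[1:2]) + 1e-9)
  # duplicate currents all enter the fit
  dup <- dplyr::bind_rows(sat, tibble::tibble(current_nA = 18,
                                              amplitude = 0.001))
  expect_equal(nrow(intensity_response(dup)$pairs), 14L)
  expect_error(intensity_response(sat[1:3, ]), "distinct currents")
})

test_that("summation efficacy can reference the conditioning pulse", {
  cfg <- det_config()
  pr <- train_paradigm(20)
  tr <- simulation_truth(cfg, pr, branch = "summation")$traces$roi3
  r <- detect_train_peaks(tr, pr)
  ratio_train <- summation_efficacy(r)
  ratio_pre <- summation_efficacy(r, p1_source = "pre_pulse")
  expect_gt(ratio_pre, 0)
  # conditioning-pulse response carries no train residual, so its P1 is
  # close to (not above) the train's first peak
  expect_equal(ratio_train, r$peak_amplitudes[2] / r$peak_amplitudes[1])
  expect_equal(ratio_pre, r$peak_amplitudes[2] / r$pre_pulse$amplitude)
  pr_no <- generate_stim_train(20, 10, onset_ms = 450)
  tr2 <- gevi_trace(tr$samples, tr$sampling_interval_ms)
  r2 <- detect_train_peaks(tr2, pr_no)
  expect_error(summation_efficacy(r2, p1_source = "pre_pulse"),
               "conditioning")
})
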