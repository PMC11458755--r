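test_that("stimulus trains use the nominal rounded interstimulus interval", {
  expect_equal(generate_stim_train(20, 10)$isi_ms, 50)
  expect_equal(generate_stim_train(40, 10)$isi_ms, 25)
  expect_equal(generate_stim_train(83, 10)$isi_ms, 12)
  # onsets snap to the frame grid: spacing within one frame interval
  pr <- generate_stim_train(83, 10, onset_ms = 450, frame_interval_ms = 1.020)
  gaps <- diff(pr$pulse_times_ms)
  expect_true(all(abs(gaps - 12) <= 1.020))
  expect_true(all(diff(pr$pulse_times_ms) > 0))
  expect_equal(pr$n_pulses, 10L)
  # single pulse: no ISI constraint applies
  expect_equal(generate_stim_train(20, 1, onset_ms = 100)$n_pulses, 1L)
  expect_error(generate_stim_train(600, 10), "ISI")
})

test_that("evoked kernels are unit-peak and causal", {
  t <- seq(-20, 300, by = 0.1)
  ep <- evoked_kernel("epsp", t)
  expect_equal(max(ep), 1, tolerance = 1e-6)
  expect_true(all(ep[t < 0] == 0))
  ap <- evoked_kernel("ap", t, width_ms = 1.5)
  expect_equal(max(ap), 1, tolerance = 1e-3)
  expect_true(all(ap[t < 0] == 0))
  # support above 1% of peak spans < 5 ms for a 1.5 ms FWHM transient
  supp <- range(t[ap >= 0.01])
  expect_lt(diff(supp), 5)
  expect_error(evoked_kernel("epsp", t, rise_ms = 50, decay_ms = 40), "rise")
})

test_that("a noiseless single pulse peaks at the configured amplitude", {
  cfg <- det_config(bleach_frac = 0)
  pr <- generate_stim_train(20, 1, onset_ms = 300)
  sim <- simulate_movie(cfg, pr, seed = 1, quantize = FALSE)
  mv <- sim$sweeps[[1]]
  # stim-site pixel, dF/F with inversion
  px <- mv$frames[, cfg$stim_site[1], cfg$stim_site[2]]
  dff <- -(px - mean(px[1:200])) / mean(px[1:200])
  # closed form: at d = 0 the peak is A_ap * 1 + A_ep * w1 * p_success,
  # reduced slightly because AP and EPSP kernels peak at different times
  a_ap <- cfg$peak_dff * cfg$ap_fraction
  a_ep <- cfg$peak_dff * (1 - cfg$ap_fraction)
  expect_gt(max(dff), 0.95 * (a_ap + a_ep) - 0.01 * cfg$peak_dff)
  expect_lt(max(dff), (a_ap + a_ep) * 1.01)
})

test_that("raw polarity is negative-going and inversion restores it", {
  cfg <- det_config()
  pr <- generate_stim_train(20, 1, onset_ms = 300)
  sim <- simulate_movie(cfg, pr, seed = 1)
  px <- sim$sweeps[[1]]$frames[, cfg$stim_site[1], cfg$stim_site[2]]
  base <- mean(px[1:200])
  expect_lt(min(px) , base * (1 - 0.005))     # dips below baseline
  tr <- gevi_trace(px, 1.020)
  dff <- compute_dff(tr, 1:200, invert = TRUE)
  expect_gt(max(dff$samples), 0.005)          # depolarization-positive
})

test_that("pure synaptic amplitude decays as exp(-d/lambda) with distance", {
  # two single-pixel sites at path distances 0 and 300 um, no AP component
  cfg <- det_config(ap_fraction = 0, lambda_epsp_um = 433, bleach_frac = 0)
  pr <- generate_stim_train(20, 1, onset_ms = 300)
  sim <- simulate_movie(cfg, pr, seed = 1, quantize = FALSE)
  mv <- sim$sweeps[[1]]
  d_px <- 300 / cfg$pixel_size_um
  near <- mv$frames[, cfg$stim_site[1], cfg$stim_site[2]]
  far <- mv$frames[, cfg$stim_site[1] - d_px, cfg$stim_site[2]]
  amp <- function(v) max(-(v - mean(v[1:200])) / mean(v[1:200]))
  expect_equal(amp(far) / amp(near), exp(-300 / 433), tolerance = 0.01)
})

test_that("identical seeds reproduce identical movies", {
  cfg <- test_config()
  pr <- train_paradigm(40)
  s1 <- simulate_movie(cfg, pr, seed = 99)
  s2 <- simulate_movie(cfg, pr, seed = 99)
  expect_identical(s1$sweeps[[1]]$frames, s2$sweeps[[1]]$frames)
  expect_identical(s1$truth$jitters_ms, s2$truth$jitters_ms)
  s3 <- simulate_movie(cfg, pr, seed = 100)
  expect_false(identical(s1$sweeps[[1]]$frames, s3$sweeps[[1]]$frames))
})

test_that("evoked amplitude is non-increasing with distance from the site", {
  cfg <- det_config(bleach_frac = 0)
  fields <- gevitrain:::response_fields(cfg)
  total <- fields$ap + fields$ep
  r0 <- cfg$stim_site[1]; c0 <- cfg$stim_site[2]
  along_col <- total[seq(r0, 1), c0]
  along_row <- total[r0, seq(c0, cfg$w)]
  expect_true(all(diff(along_col) <= 1e-12))
  expect_true(all(diff(along_row) <= 1e-12))
})

test_that("cohort bookkeeping matches the requested design", {
  co <- simulate_cohort(
    n_slices = c(AD_F = 1, AD_M = 1, CTRL_F = 1, CTRL_M = 1),
    frequencies = c(20, 40, 83), config = test_config(), seed = 2
  )
  expect_equal(nrow(co), 12L)  # 4 slices x 3 frequencies
  expect_equal(length(unique(co$slice_id)), 4L)
  expect_setequal(unique(co$group), c("AD", "CTRL"))
  expect_error(simulate_cohort(n_slices = c(AD_F = 0), config = test_config()),
               "zero slices")
  expect_error(simulate_cohort(n_slices = c(XX = 3), config = test_config()),
               "group labels")
})

test_that("a shorter horizontal space constant lowers ROI 3/2 in every slice", {
  co <- simulate_cohort(
    n_slices = c(AD_F = 4, CTRL_F = 4), frequencies = 40,
    config = test_config(), lambda_epsp_um = c(AD = 433, CTRL = 600),
    slice_cv = c(amplitude = 0.2, lambda = 0.03),
    truth_branches = "propagation", seed = 8
  )
  ad <- co$true_roi3_over_roi2[co$group == "AD"]
  ctrl <- co$true_roi3_over_roi2[co$group == "CTRL"]
  expect_lt(max(ad), min(ctrl))
  # vertical ratio is group-equal by construction (same distribution)
  expect_lt(abs(mean(co$true_roi2_over_roi1[co$group == "AD"]) -
                  mean(co$true_roi2_over_roi1[co$group == "CTRL"])), 0.05)
})

test_that("over-strong responses are rejected rather than clipped", {
  cfg <- det_config(peak_dff = 0.9, ap_fraction = 0.5)
  pr <- train_paradigm(83)
  expect_error(simulate_movie(cfg, pr, seed = 1), "negative")
})
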