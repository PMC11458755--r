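test_that("dF/F maps fractional dimming onto positive depolarization", {
  const <- gevi_trace(rep(1000, 100))
  expect_equal(compute_dff(const, 1:50)$samples, rep(0, 100))
  drop1pc <- gevi_trace(c(rep(1000, 50), rep(990, 50)))
  out <- compute_dff(drop1pc, 1:50, invert = TRUE)
  expect_equal(out$samples[51], 0.01, tolerance = 1e-12)
  expect_equal(compute_dff(drop1pc, 1:50, invert = FALSE)$samples[51], -0.01,
               tolerance = 1e-12)
  expect_error(compute_dff(const, integer(0)), "non-empty")
  expect_error(compute_dff(gevi_trace(c(0, 0, 1)), 1:2), "positive")
  expect_match(tail(trace_provenance(out), 1), "dff")
})

test_that("bleach correction recovers an exponential trend exactly", {
  t <- (0:1499) * 1.02
  pure <- gevi_trace(0.05 * exp(-t / 2000) + 0.01, 1.02)
  res <- correct_bleach(pure)
  expect_lt(diff(range(res$trace$samples)), 1e-6)
  expect_equal(res$fit$tau_ms, 2000, tolerance = 0.01)

  const <- gevi_trace(rep(0.25, 600), 1.02)
  resc <- correct_bleach(const)
  expect_lt(abs(resc$fit$a), 1e-6)
  expect_equal(resc$trace$samples, rep(0, 600), tolerance = 1e-8)
})

test_that("bleach fit excludes protected windows and recovers tau to 5%", {
  set.seed(42)
  t <- (0:1999) * 1.02
  resp <- 0.02 * evoked_kernel("epsp", t - 600, rise_ms = 5, decay_ms = 60)
  y <- 0.04 * exp(-t / 2000) + resp + rnorm(length(t), 0, 2e-4)
  tr <- gevi_trace(y, 1.02)
  res <- correct_bleach(tr, protect_windows = list(c(590, 1100)))
  expect_equal(res$fit$tau_ms, 2000, tolerance = 0.05)
  # response shape preserved: corrected peak close to injected amplitude
  peak <- max(res$trace$samples[t > 600 & t < 700])
  expect_equal(peak, 0.02, tolerance = 0.1)
  expect_error(
    correct_bleach(gevi_trace(rep(1, 50), 1.02),
                   protect_windows = list(c(0, 1e6))),
    "unprotected")
})

test_that("sweep averaging obeys the sqrt(n) law", {
  tr <- function() gevi_trace(rnorm(400), 1.02)
  set.seed(1)
  # identity cases
  a <- gevi_trace(sin(1:100), 1.02)
  expect_equal(average_sweeps(list(a))$samples, a$samples)
  expect_equal(average_sweeps(rep(list(a), 4))$samples, a$samples)
  expect_error(average_sweeps(list(a, gevi_trace(1:50, 1.02))), "length")
  # 25 unit-variance traces: residual sd ~ 1/5
  avg25 <- average_sweeps(replicate(25, tr(), simplify = FALSE))
  expect_equal(sd(avg25$samples), 0.2, tolerance = 0.25)
  # log-log slope of sd vs n is -1/2
  ns <- c(1, 4, 9, 16, 25)
  sds <- vapply(ns, function(n) {
    mean(replicate(40, sd(average_sweeps(
      replicate(n, tr(), simplify = FALSE))$samples)))
  }, 0)
  slope <- coef(lm(log(sds) ~ log(ns)))[2]
  expect_equal(unname(slope), -0.5, tolerance = 0.06)
})

test_that("spatial averaging reduces an ROI to its per-frame mean", {
  frames <- array(0, c(5, 4, 4))
  frames[, , ] <- 3
  mv <- gevi_movie(frames, 1.02)
  lm_half <- matrix(0L, 4, 4); lm_half[1:2, ] <- 1L
  rois <- roi_set(lm_half, c("1" = "stim_site"))
  expect_equal(spatial_average(mv, rois, 1)$samples, rep(3, 5))

  frames2 <- frames
  frames2[, 1, 1] <- 7  # single pixel differs
  mv2 <- gevi_movie(frames2, 1.02)
  lm_px <- matrix(0L, 4, 4); lm_px[1, 1] <- 1L
  rois_px <- roi_set(lm_px, c("1" = "stim_site"))
  expect_equal(spatial_average(mv2, rois_px, 1)$samples, rep(7, 5))
  # half 0 / half 1
  frames3 <- array(rep(c(0, 1), each = 2 * 5 * 2), c(5, 4, 2))
  frames3 <- array(0, c(5, 4, 4)); frames3[, 1:2, ] <- 0; frames3[, 3:4, ] <- 1
  mv3 <- gevi_movie(frames3, 1.02)
  lm_all <- matrix(1L, 4, 4)
  rois_all <- roi_set(lm_all, c("1" = "stim_site"))
  expect_equal(spatial_average(mv3, rois_all, 1)$samples, rep(0.5, 5))
  expect_error(spatial_average(mv3, rois_all, 2), "empty")
})

test_that("the Gaussian low-pass meets its half-gain contract", {
  dt <- 1.02
  t <- (0:8191) * dt / 1000
  gain_at <- function(fc, fs) {
    x <- gevi_trace(sin(2 * pi * fs * t), dt)
    y <- gaussian_lowpass(x, fc)
    mid <- 2000:6000
    sqrt(mean(y$samples[mid]^2) / mean(x$samples[mid]^2))
  }
  expect_equal(gain_at(33, 33), 0.5, tolerance = 0.02)
  expect_equal(gain_at(77, 77), 0.5, tolerance = 0.02)
  expect_lt(gain_at(33, 83), 0.05)
  # DC gain exactly 1
  const <- gevi_trace(rep(2.5, 500), dt)
  expect_equal(gaussian_lowpass(const, 33)$samples, rep(2.5, 500))
  expect_error(gaussian_lowpass(const, 500), "Nyquist")
})

test_that("the RC high-pass meets its -3 dB contract and rejects DC", {
  dt <- 1.02
  const <- gevi_trace(rep(1, 6000), dt)
  out <- rc_highpass(const, 0.1)
  expect_lt(abs(out$samples[6000]), 0.7)  # decaying toward 0
  expect_lt(abs(out$samples[6000]), abs(out$samples[100]))
  # steady-state gain at the cutoff: long 0.1 Hz sinusoid (several cycles)
  t <- (0:59999) * dt / 1000
  x <- gevi_trace(sin(2 * pi * 0.1 * t), dt)
  y <- rc_highpass(x, 0.1)
  late <- 40000:60000
  g <- sqrt(mean(y$samples[late]^2) / mean(x$samples[late]^2))
  expect_equal(g, 1 / sqrt(2), tolerance = 0.05)
  # fast signals pass essentially untouched
  x40 <- gevi_trace(sin(2 * pi * 40 * t[1:8192]), dt)
  y40 <- rc_highpass(x40, 0.1)
  g40 <- sqrt(mean(y40$samples[4000:8000]^2) / mean(x40$samples[4000:8000]^2))
  expect_gt(g40, 0.999)
})

test_that("every trace-domain stage is linear", {
  set.seed(3)
  dt <- 1.02
  x <- gevi_trace(rnorm(600), dt)
  y <- gevi_trace(rnorm(600), dt)
  comb <- gevi_trace(2 * x$samples + 3 * y$samples, dt)
  for (stage in list(
    function(tr) gaussian_lowpass(tr, 33),
    function(tr) rc_highpass(tr, 0.1),
    function(tr) average_sweeps(list(tr, tr))
  )) {
    lhs <- stage(comb)$samples
    rhs <- 2 * stage(x)$samples + 3 * stage(y)$samples
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("sweep and spatial averaging commute", {
  set.seed(4)
  sweeps <- replicate(3, gevi_movie(array(rexp(10 * 4 * 4), c(10, 4, 4)), 1.02),
                      simplify = FALSE)
  lm <- matrix(0L, 4, 4); lm[2:3, 2:3] <- 1L
  rois <- roi_set(lm, c("1" = "stim_site"))
  # spatial average each sweep then average sweeps
  a <- average_sweeps(lapply(sweeps, spatial_average, rois = rois, label = 1))
  # average the movies framewise then spatial average
  mean_frames <- Reduce(`+`, lapply(sweeps, function(m) m$frames)) / 3
  b <- spatial_average(gevi_movie(mean_frames, 1.02), rois, 1)
  expect_equal(a$samples, b$samples, tolerance = 1e-12)
})

test_that("stimulus-artifact blanking interpolates only the onset frames", {
  pr <- generate_stim_train(20, 2, onset_ms = 100)
  y <- rep(0, 300); t <- (0:299) * 1.02
  for (on in pr$pulse_times_ms) y[which(t >= on)[1]] <- 5  # spike artifact
  tr <- gevi_trace(y, 1.02)
  out <- blank_stimulus_artifact(tr, pr, n_frames = 2)
  expect_equal(max(abs(out$samples)), 0)
  expect_match(tail(trace_provenance(out), 1), "blank_artifact\\(2\\)")
  # untouched away from pulses
  clean <- gevi_trace(sin(t / 20), 1.02)
  out2 <- blank_stimulus_artifact(clean, pr)
  far <- t < 95 | t > 160
  expect_equal(out2$samples[far], clean$samples[far])
})
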