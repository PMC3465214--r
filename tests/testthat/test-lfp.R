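# LFP chain: band-pass response, sweep averaging, amplitude extraction and
# the burst-frequency comparison. Reduced sampling rates keep the suite fast
# where the full 10 kHz chain is not the point.

test_that("band-pass keeps in-band signal and rejects out-of-band signal", {
  pr <- makeDefaultProtocol(8, 12)
  fs <- 2000
  t <- seq(0, 2, by = 1 / fs)
  mk <- function(x) new("LfpSweepSet", samples = matrix(x, ncol = 1),
                        samplingRate = fs, protocol = pr,
                        band = c(NA_real_, NA_real_))
  s50 <- bandpassSweeps(mk(sin(2 * pi * 50 * t)), 1, 100)
  expect_gt(max(abs(sweepMatrix(s50)[500:3500])), 0.95)
  s500 <- bandpassSweeps(mk(sin(2 * pi * 500 * t)), 1, 100)
  expect_lt(max(abs(sweepMatrix(s500)[500:3500])), 0.1)
  dc <- bandpassSweeps(mk(rep(1, length(t))), 1, 100)
  expect_lt(max(abs(sweepMatrix(dc)[500:3500])), 0.05)
  expect_error(bandpassSweeps(mk(t), 100, 1), "band")
})

test_that("sweep averaging is pointwise and reduces noise like sqrt(n)", {
  pr <- makeDefaultProtocol(8, 12)
  mk <- function(m) new("LfpSweepSet", samples = m, samplingRate = 1000,
                        protocol = pr, band = c(NA_real_, NA_real_))
  x <- sin(seq(0, 20, length.out = 2000))
  same <- averageSweeps(mk(cbind(x, x, x)))
  expect_equal(sweepMatrix(same)[, 1], x)
  cancel <- averageSweeps(mk(cbind(x, -x)))
  expect_equal(max(abs(sweepMatrix(cancel))), 0)
  set.seed(31)
  noisy <- matrix(rnorm(2000 * 20), 2000, 20)
  ratio <- sd(rowMeans(noisy)) / sd(noisy[, 1])
  expect_equal(ratio, 1 / sqrt(20), tolerance = 0.15)
  avg <- averageSweeps(mk(noisy))
  expect_equal(sweepMatrix(avg)[, 1], rowMeans(noisy))
})

test_that("noiseless pulse amplitudes recover the designed deflection", {
  sw <- simulateLfp(8, 12, n_sweeps = 1, gain_slope = 0, noise_sd = 0,
                    A0 = 0.4, sweep_gain_cv = 0, sampling_rate = 2000,
                    seed = 1)
  amps <- pulseAmplitudes(sw)
  expect_equal(nrow(amps), 80 + 120)
  expect_true(all(abs(amps$amplitude - 0.4) < 0.004))
  # zero trace gives zero amplitudes
  zero <- new("LfpSweepSet",
              samples = matrix(0, nrow(sweepMatrix(sw)), 1),
              samplingRate = 2000, protocol = protocol(sw),
              band = c(NA_real_, NA_real_))
  expect_true(all(pulseAmplitudes(zero)$amplitude == 0))
})

test_that("every 12 Hz pulse beats every 8 Hz pulse without noise", {
  sw <- simulateLfp(8, 12, n_sweeps = 1, gain_slope = 0.01, noise_sd = 0,
                    sweep_gain_cv = 0, sampling_rate = 2000, seed = 1)
  amps <- pulseAmplitudes(sw)
  expect_gt(min(amps$amplitude[amps$burst == 2]),
            max(amps$amplitude[amps$burst == 1]))
})

test_that("amplitudes are invariant to a constant offset before band-pass", {
  sw <- simulateLfp(8, 12, n_sweeps = 2, sampling_rate = 2000, seed = 5)
  shifted <- new("LfpSweepSet", samples = sweepMatrix(sw) + 3.7,
                 samplingRate = 2000, protocol = protocol(sw),
                 band = c(NA_real_, NA_real_))
  a1 <- pulseAmplitudes(bandpassSweeps(sw, 1, 100))
  a2 <- pulseAmplitudes(bandpassSweeps(shifted, 1, 100))
  expect_equal(a1$amplitude, a2$amplitude, tolerance = 1e-6)
})

test_that("a gain of zero leaves no systematic burst difference", {
  sw <- simulateLfp(8, 12, n_sweeps = 10, gain_slope = 0, noise_sd = 0.05,
                    sampling_rate = 2000, seed = 11)
  cmp <- compareBurstAmplitudes(pulseAmplitudes(bandpassSweeps(sw)))
  se <- sqrt(cmp$sem_burst1^2 + cmp$sem_burst2^2)
  expect_lt(abs(cmp$mean_burst2 - cmp$mean_burst1), 3 * se)
})

test_that("the designed frequency effect is detected across 20 sweeps", {
  sw <- simulateLfp(8, 12, n_sweeps = 20, seed = 3)
  cmp <- compareBurstAmplitudes(pulseAmplitudes(bandpassSweeps(sw)))
  expect_gt(cmp$mean_burst2, cmp$mean_burst1)
  expect_lt(cmp$t_test$p, 0.05)
  expect_true(cmp$t_test$paired)
})
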