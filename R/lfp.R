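# Local field potential chain: simulated sweeps, band-pass filtering, sweep
# averaging, per-pulse amplitude extraction and the 8 vs 12 Hz comparison.

# Biphasic evoked deflection template, normalized so its most negative
# excursion is exactly -1. Negative-going first lobe (cortical evoked LFPs
# at this depth), small positive rebound.
.deflectionTemplate <- function(fs, dur_s = 0.06, tau_s = 0.015) {
  t <- seq(0, dur_s, by = 1 / fs)
  s <- -sin(2 * pi * t / (2 * dur_s / 1.5)) * exp(-t / tau_s)
  s / abs(min(s))
}

#' Simulate local field potential sweeps
#'
#' Each whisker pulse evokes a biphasic deflection whose (negative) peak
#' amplitude grows linearly with the burst pulse frequency,
#' `A(f) = A0 + gain_slope * f`, on top of broadband Gaussian noise and a
#' small per-sweep multiplicative gain jitter. Sweeps are sampled at 10 kHz
#' by default and are deterministic given the seed.
#'
#' @param freq1,freq2 burst pulse frequencies (Hz).
#' @param n_sweeps number of sweeps (>= 1).
#' @param gain_slope amplitude gain per Hz; 0 gives the null (no frequency
#'   effect).
#' @param noise_sd broadband noise SD (same units as the amplitudes).
#' @param seed RNG seed.
#' @param A0 frequency-independent amplitude offset.
#' @param sweep_gain_cv per-sweep multiplicative gain coefficient of
#'   variation.
#' @param sampling_rate sampling rate (Hz).
#' @param protocol stimulus protocol; defaults to
#'   `makeDefaultProtocol(freq1, freq2)`.
#' @return an [LfpSweepSet-class] (unfiltered).
#' @export
simulateLfp <- function(freq1 = 8, freq2 = 12, n_sweeps = 20,
                        gain_slope = 0.01, noise_sd = 0.05, seed = 1,
                        A0 = 0.1, sweep_gain_cv = 0.05,
                        sampling_rate = 10000, protocol = NULL) {
  if (n_sweeps < 1) stop("n_sweeps must be >= 1")
  if (is.null(protocol)) protocol <- makeDefaultProtocol(freq1, freq2)
  set.seed(as.integer(seed))
  fs <- sampling_rate
  n <- round(totalDuration(protocol) * fs)
  tmpl <- .deflectionTemplate(fs)
  base <- numeric(n)
  for (b in seq_len(nBursts(protocol))) {
    A <- A0 + gain_slope * bursts(protocol)$pulse_freq_hz[b]
    for (tp in pulseTimes(protocol, b)) {
      i0 <- round(tp * fs) + 1L
      idx <- i0:min(n, i0 + length(tmpl) - 1L)
      base[idx] <- base[idx] + A * tmpl[seq_along(idx)]
    }
  }
  sweeps <- matrix(0, n, n_sweeps)
  for (s in seq_len(n_sweeps)) {
    gain <- if (sweep_gain_cv > 0)
      exp(stats::rnorm(1, -log(1 + sweep_gain_cv^2) / 2,
                       sqrt(log(1 + sweep_gain_cv^2)))) else 1
    sweeps[, s] <- gain * base +
      if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
  }
  new("LfpSweepSet", samples = sweeps, samplingRate = fs,
      protocol = protocol, band = c(NA_real_, NA_real_))
}

#' Band-pass filter LFP sweeps
#'
#' Zero-phase Butterworth band-pass (1-100 Hz by default), applied per
#' sweep. The band is recorded on the returned object.
#'
#' @param sweeps an [LfpSweepSet-class].
#' @param low,high band edges (Hz), `0 < low < high < Nyquist`.
#' @param order filter order (per direction).
#' @return a filtered [LfpSweepSet-class].
#' @export
bandpassSweeps <- function(sweeps, low = 1, high = 100, order = 3) {
  fs <- sweeps@samplingRate
  if (!(low > 0 && low < high && high < fs / 2))
    stop("band must satisfy 0 < low < high < Nyquist")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  m <- sweeps@samples
  pad <- min(nrow(m) - 1L, round(fs / low))
  for (s in seq_len(ncol(m))) m[, s] <- .zeroPhase(m[, s], bf, pad = pad)
  initialize(sweeps, samples = m, band = c(low, high))
}

#' Average LFP sweeps
#'
#' Pointwise mean across sweeps (all must share length and rate by
#' construction of [LfpSweepSet-class]).
#'
#' @param sweeps an [LfpSweepSet-class], or a list of single-sweep sets with
#'   equal length and rate.
#' @return an [LfpSweepSet-class] with one averaged sweep.
#' @export
averageSweeps <- function(sweeps) {
  if (is.list(sweeps) && !is(sweeps, "LfpSweepSet")) {
    lens <- vapply(sweeps, function(s) nrow(s@samples), integer(1))
    rates <- vapply(sweeps, function(s) s@samplingRate, numeric(1))
    if (length(unique(lens)) != 1 || length(unique(rates)) != 1)
      stop("sweeps must share length and sampling rate")
    m <- do.call(cbind, lapply(sweeps, function(s) s@samples))
    sweeps <- initialize(sweeps[[1]], samples = m)
  }
  initialize(sweeps,
             samples = matrix(rowMeans(sweeps@samples), ncol = 1))
}

#' Per-pulse evoked amplitudes
#'
#' For every stimulus pulse of every sweep, the amplitude is the depth of
#' the peak negative deflection within a post-pulse window (capped at 80 ms
#' and truncated at the next pulse onset) relative to the local pre-pulse
#' baseline (mean over the 5 ms before the pulse). `peak_to_peak = TRUE`
#' instead reports max - min within the window.
#'
#' @param sweeps an [LfpSweepSet-class] with an attached protocol (a
#'   single averaged sweep or a full sweep set).
#' @param window_s post-pulse search window cap (s).
#' @param peak_to_peak report peak-to-peak amplitude instead of
#'   peak-to-baseline.
#' @return data.frame with columns `sweep`, `burst`, `freq_hz`, `pulse`,
#'   `amplitude`.
#' @export
pulseAmplitudes <- function(sweeps, window_s = 0.08, peak_to_peak = FALSE) {
  pr <- sweeps@protocol
  if (is.null(pr)) stop("a protocol must be attached")
  fs <- sweeps@samplingRate
  m <- sweeps@samples
  n <- nrow(m)
  out <- list()
  for (b in seq_len(nBursts(pr))) {
    tp <- pulseTimes(pr, b)
    ipi <- 1 / bursts(pr)$pulse_freq_hz[b]
    win <- min(window_s, ipi)
    f <- bursts(pr)$pulse_freq_hz[b]
    for (p in seq_along(tp)) {
      i0 <- round(tp[p] * fs) + 1L
      i1 <- min(n, i0 + round(win * fs) - 1L)
      ib <- seq.int(max(1L, i0 - round(0.005 * fs)), max(1L, i0 - 1L))
      for (s in seq_len(ncol(m))) {
        seg <- m[i0:i1, s]
        amp <- if (peak_to_peak) max(seg) - min(seg)
               else mean(m[ib, s]) - min(seg)
        out[[length(out) + 1L]] <- data.frame(
          sweep = s, burst = b, freq_hz = f, pulse = p, amplitude = amp)
      }
    }
  }
  do.call(rbind, out)
}

#' Compare evoked amplitudes between the two bursts
#'
#' Per-sweep mean amplitudes for each burst, paired by sweep, with a
#' two-tailed paired t test (the amplitude comparison between the 8 Hz and
#' 12 Hz bursts).
#'
#' @param amps data.frame from [pulseAmplitudes()] on a multi-sweep set.
#' @return list with per-burst means +/- SEM, per-sweep means, and the
#'   paired test.
#' @export
compareBurstAmplitudes <- function(amps) {
  if (length(unique(amps$burst)) != 2) stop("exactly two bursts are required")
  bySweep <- lapply(split(amps, amps$burst), function(d)
    vapply(split(d$amplitude, d$sweep), mean, numeric(1)))
  a <- bySweep[[1]]; b <- bySweep[[2]]
  list(mean_burst1 = mean(a), sem_burst1 = meanSem(a)$sem,
       mean_burst2 = mean(b), sem_burst2 = meanSem(b)$sem,
       per_sweep = data.frame(sweep = as.integer(names(a)),
                              burst1 = unname(a), burst2 = unname(b)),
       t_test = tTest(a, b, paired = TRUE))
}
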