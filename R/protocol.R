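#' Build the canonical paired burst-stimulus protocol
#'
#' Two bursts of air-puff pulses (10 s each by default) separated by an
#' inter-burst interval, preceded by a pre-stimulus baseline window of the
#' same length. The defaults reproduce the paired 8-to-12 Hz design: baseline
#' 0-10 s, burst 1 at 10-20 s, burst 2 at 30-40 s, recording ends at 50 s.
#' `makeDefaultProtocol(8, 8)` gives the same-frequency control.
#'
#' @param freq1,freq2 pulse frequencies of the two bursts (Hz, > 0).
#' @param baseline_s pre-stimulus baseline before the first burst (s).
#' @param burst_s duration of each burst (s).
#' @param interval_s inter-burst interval (s).
#' @param post_s recording time after the second burst (s).
#' @param pulse_width_ms air-puff pulse width (ms).
#' @return a [StimulusProtocol-class].
#' @examples
#' makeDefaultProtocol(8, 12)
#' @export
makeDefaultProtocol <- function(freq1, freq2, baseline_s = 10, burst_s = 10,
                                interval_s = 10, post_s = 10,
                                pulse_width_ms = 50) {
  if (!is.numeric(freq1) || !is.numeric(freq2) || freq1 <= 0 || freq2 <= 0)
    stop("pulse frequencies must be positive")
  onsets <- c(baseline_s, baseline_s + burst_s + interval_s)
  StimulusProtocol(
    data.frame(onset_s = onsets, duration_s = burst_s,
               pulse_freq_hz = c(freq1, freq2),
               pulse_width_ms = pulse_width_ms),
    total_duration_s = onsets[2] + burst_s + post_s)
}

#' Frame window of a burst
#'
#' 1-based frame indices covering `[onset, onset + duration)` of burst `b` at
#' frame rate `fs`: frame j spans time `[(j-1)/fs, j/fs)`.
#'
#' @param protocol a [StimulusProtocol-class].
#' @param b burst index.
#' @param fs frame rate (Hz).
#' @return integer vector of frame indices.
#' @export
burstWindow <- function(protocol, b, fs) {
  stopifnot(is(protocol, "StimulusProtocol"), b >= 1, b <= nBursts(protocol))
  bu <- bursts(protocol)[b, ]
  first <- floor(bu$onset_s * fs) + 1L
  last <- floor((bu$onset_s + bu$duration_s) * fs)
  seq.int(first, last)
}

#' Frame window of the full stimulation epoch
#'
#' Frames from the onset of the first burst to the end of the last burst,
#' inter-burst gaps included.
#'
#' @inheritParams burstWindow
#' @export
stimulationEpoch <- function(protocol, fs) {
  bu <- bursts(protocol)
  first <- floor(bu$onset_s[1] * fs) + 1L
  last <- floor((bu$onset_s[nrow(bu)] + bu$duration_s[nrow(bu)]) * fs)
  seq.int(first, last)
}

#' Pre-stimulus baseline frame window
#'
#' Frames strictly before the first burst onset (the 10 s preceding burst 1
#' under the default protocol).
#'
#' @inheritParams burstWindow
#' @export
baselineFrames <- function(protocol, fs) {
  seq_len(floor(bursts(protocol)$onset_s[1] * fs))
}

#' Pulse onset times of a burst
#'
#' @inheritParams burstWindow
#' @return numeric vector of pulse onset times (s).
#' @export
pulseTimes <- function(protocol, b) {
  bu <- bursts(protocol)[b, ]
  n <- floor(bu$duration_s * bu$pulse_freq_hz)
  bu$onset_s + (seq_len(n) - 1) / bu$pulse_freq_hz
}

#' Read / write a stimulus protocol as JSON
#'
#' @param protocol a [StimulusProtocol-class].
#' @param path file path.
#' @return `readProtocol` returns a [StimulusProtocol-class].
#' @export
writeProtocol <- function(protocol, path) {
  jsonlite::write_json(
    list(bursts = bursts(protocol),
         total_duration_s = totalDuration(protocol)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeProtocol
#' @export
readProtocol <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  StimulusProtocol(as.data.frame(x$bursts), x$total_duration_s)
}
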