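# Raw-channel to dF/F processing chain: median filter, ROI extraction,
# background subtraction, SR101 normalization, dF/F, Butterworth smoothing,
# active-cell detection.

#' Per-frame 2-D median filter
#'
#' Applies a square median filter of the given radius to every frame of an
#' image stack (the photon/PMT denoising step; radius 1 gives the usual 3x3
#' neighborhood). Neighborhoods are truncated at the image border.
#'
#' @param stack 3-D array (rows x cols x frames) or a single 2-D frame.
#' @param radius_px neighborhood radius in pixels (>= 1).
#' @return filtered stack with the same dimensions.
#' @export
medianFilterStack <- function(stack, radius_px = 1) {
  if (is.matrix(stack)) return(.medianFilterFrame(stack, radius_px))
  if (!is.array(stack) || length(dim(stack)) != 3 || any(dim(stack) == 0))
    stop("stack must be a non-empty rows x cols x frames array")
  if (radius_px < 1) stop("radius_px must be >= 1")
  out <- stack
  for (f in seq_len(dim(stack)[3]))
    out[, , f] <- .medianFilterFrame(stack[, , f], radius_px)
  out
}

.medianFilterFrame <- function(fr, r) {
  nr <- nrow(fr); nc <- ncol(fr)
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  stackArr <- array(NA_real_, c(nr, nc, nrow(offs)))
  for (k in seq_len(nrow(offs))) {
    dx <- offs$dx[k]; dy <- offs$dy[k]
    sr <- seq_len(nr) + dx; sc <- seq_len(nc) + dy
    okr <- sr >= 1 & sr <= nr; okc <- sc >= 1 & sc <= nc
    stackArr[which(okr), which(okc), k] <- fr[sr[okr], sc[okc]]
  }
  apply(stackArr, c(1, 2), stats::median, na.rm = TRUE)
}

#' Extract ROI-mean traces from an image stack
#'
#' Per-ROI mean pixel intensity per frame, for each available channel,
#' assembled into a [TraceSet-class].
#'
#' @param stack list with elements `ch1` (indicator channel, rows x cols x
#'   frames array) and optionally `ch2` (SR101 channel).
#' @param masks logical array (rows x cols x cells) of pixel-true ROI masks.
#' @param cellType character vector of cell types, one per mask; by default
#'   inferred from the SR101 channel (mask-mean ch2 intensity above
#'   `sr101_cut`).
#' @param frameRate frame rate (Hz).
#' @param protocol optional [StimulusProtocol-class].
#' @param sr101_cut mean-intensity criterion used for type inference.
#' @return a [TraceSet-class].
#' @export
extractRoiTraces <- function(stack, masks, cellType = NULL, frameRate = 10,
                             protocol = NULL, sr101_cut = 20) {
  ch1 <- stack$ch1
  d <- dim(ch1)
  if (length(dim(masks)) != 3) stop("masks must be a rows x cols x cells array")
  if (any(dim(masks)[1:2] != d[1:2]))
    stop("mask extent must match the image field")
  ncell <- dim(masks)[3]
  flat1 <- matrix(ch1, d[1] * d[2], d[3])
  flat2 <- if (!is.null(stack$ch2)) matrix(stack$ch2, d[1] * d[2], d[3])
  raw <- matrix(0, ncell, d[3])
  sr <- if (!is.null(flat2)) matrix(NA_real_, ncell, d[3])
  means2 <- numeric(ncell)
  for (i in seq_len(ncell)) {
    idx <- which(masks[, , i])
    if (length(idx) == 0) stop("empty ROI mask (cell ", i, ")")
    raw[i, ] <- colMeans(flat1[idx, , drop = FALSE])
    if (!is.null(flat2)) {
      sr[i, ] <- colMeans(flat2[idx, , drop = FALSE])
      means2[i] <- mean(sr[i, ])
    }
  }
  if (is.null(cellType)) {
    cellType <- if (is.null(flat2)) rep("neuron", ncell)
                else ifelse(means2 > sr101_cut, "astrocyte", "neuron")
  }
  if (!is.null(sr)) sr[cellType == "neuron", ] <- NA_real_
  TraceSet(raw, cellType, frameRate, protocol = protocol, sr101 = sr)
}

#' Subtract the unstained-vessel background trace
#'
#' Subtracts a frame-long background (noise) trace, measured from unstained
#' blood vessels, from every cell's raw fluorescence.
#'
#' @param traces a [TraceSet-class].
#' @param background numeric vector, one value per frame; defaults to the
#'   background stored in the object's metadata.
#' @return a [TraceSet-class] with corrected raw traces.
#' @export
subtractBackground <- function(traces, background = NULL) {
  if (is.null(background)) background <- metadata(traces)$background
  if (is.null(background)) stop("no background trace supplied or stored")
  if (length(background) != ncol(traces))
    stop("background length must equal the frame count")
  raw <- sweep(rawTraces(traces), 2, background, "-")
  assays(traces)$raw <- raw
  md <- metadata(traces); md$background <- NULL; metadata(traces) <- md
  traces
}

#' Normalize an astrocyte calcium trace to its SR101 channel
#'
#' Pointwise ratio of the indicator channel to the SR101 channel, rescaled by
#' the mean SR101 intensity so units are preserved. A multiplicative motion
#' artefact common to both channels cancels exactly.
#'
#' @param ogb numeric vector, indicator-channel trace.
#' @param sr101 numeric vector of the same length, strictly positive.
#' @return normalized trace.
#' @export
normalizeAstroToSr101 <- function(ogb, sr101) {
  if (length(ogb) != length(sr101)) stop("traces must have equal length")
  if (any(sr101 <= 0)) stop("sr101 must be strictly positive")
  ogb / sr101 * mean(sr101)
}

#' Apply SR101 normalization to all astrocytes of a TraceSet
#'
#' @param traces a [TraceSet-class] with an `sr101` assay.
#' @return a [TraceSet-class] with normalized astrocyte raw traces.
#' @export
normalizeAstrocytes <- function(traces) {
  sr <- sr101Traces(traces)
  if (is.null(sr)) return(traces)
  raw <- rawTraces(traces)
  for (i in which(cellTypes(traces) == "astrocyte"))
    raw[i, ] <- normalizeAstroToSr101(raw[i, ], sr[i, ])
  assays(traces)$raw <- raw
  traces
}

#' Compute relative fluorescence changes (dF/F)
#'
#' Per cell, \eqn{dF/F(t) = (F(t) - F) / F} with the baseline fluorescence F
#' the mean of the raw trace over the baseline window (the pre-stimulus
#' frames by default). The per-cell baseline SD of dF/F over the same window
#' is stored for the downstream activation and pattern thresholds. Cells with
#' non-positive baseline fluorescence are flagged invalid (all-NA row is not
#' produced; their baseline_sd is set to NA).
#'
#' @param traces a [TraceSet-class].
#' @param baseline_window integer frame range `c(first, last)`; default the
#'   frames before the first burst onset, or the first 10 s when no protocol
#'   is attached.
#' @return a [DffTraceSet-class] (unsmoothed).
#' @export
computeDff <- function(traces, baseline_window = NULL) {
  fs <- frameRate(traces)
  pr <- protocol(traces)
  if (is.null(baseline_window)) {
    bw <- if (is.null(pr)) seq_len(min(ncol(traces), round(10 * fs)))
          else baselineFrames(pr, fs)
    baseline_window <- c(min(bw), max(bw))
  }
  bw <- seq.int(baseline_window[1], baseline_window[2])
  if (length(bw) < 10) stop("baseline window must span at least 10 frames")
  if (!is.null(pr) && baseline_window[2] > bursts(pr)$onset_s[1] * fs)
    stop("baseline window must precede the first burst onset")
  raw <- rawTraces(traces)
  F0 <- rowMeans(raw[, bw, drop = FALSE])
  bad <- F0 <= 0
  F0safe <- ifelse(bad, NA_real_, F0)
  dff <- (raw - F0safe) / F0safe
  dff[bad, ] <- 0
  bsd <- apply(dff[, bw, drop = FALSE], 1, stats::sd)
  bsd[bad] <- NA_real_
  al <- c(list(dff = dff), as.list(assays(traces)))
  se <- SummarizedExperiment(assays = al, rowData = rowData(traces))
  metadata(se) <- metadata(traces)
  rowData(se)$baseline_sd <- bsd
  rowData(se)$valid <- !bad
  new("DffTraceSet", new("TraceSet", se),
      baselineWindow = as.integer(baseline_window), smoothed = FALSE)
}

#' Smooth dF/F traces with a zero-phase low-pass Butterworth filter
#'
#' Forward-backward (zero-phase) filtering with unit DC gain, applied per
#' cell with odd-reflection padding so burst plateaus and peak delays are not
#' biased. The per-cell baseline SD is recomputed on the smoothed traces,
#' which is what the activation and pattern thresholds consume downstream.
#'
#' @param dff a [DffTraceSet-class].
#' @param cutoff_hz low-pass cutoff (Hz), strictly below Nyquist.
#' @param order filter order.
#' @return a smoothed [DffTraceSet-class].
#' @export
smoothDff <- function(dff, cutoff_hz = 2, order = 4) {
  fs <- frameRate(dff)
  lp <- .lowpassFilter(cutoff_hz, order, fs)
  m <- dffTraces(dff)
  for (i in seq_len(nrow(m))) m[i, ] <- .zeroPhase(m[i, ], lp)
  assays(dff)$dff <- m
  bw <- seq.int(dff@baselineWindow[1], dff@baselineWindow[2])
  bsd <- apply(m[, bw, drop = FALSE], 1, stats::sd)
  bsd[!rowData(dff)$valid] <- NA_real_
  rowData(dff)$baseline_sd <- bsd
  dff@smoothed <- TRUE
  dff
}

#' Detect active cells
#'
#' A cell is active when its dF/F exceeds `k_sd` times its baseline SD for at
#' least `ceiling(min_duration_s * frame_rate)` consecutive frames anywhere
#' outside the baseline window (defaults: 2.5 SD sustained for 500 ms, i.e.
#' 5 frames at 10 Hz). The run test is strict: no sub-threshold gaps are
#' tolerated.
#'
#' @param dff a [DffTraceSet-class] (normally smoothed).
#' @param k_sd threshold multiplier on the baseline SD.
#' @param min_duration_s minimum supra-threshold duration (s).
#' @return named logical vector, `NA` for invalid cells (zero or undefined
#'   baseline SD).
#' @export
detectActiveCells <- function(dff, k_sd = 2.5, min_duration_s = 0.5) {
  fs <- frameRate(dff)
  need <- ceiling(min_duration_s * fs)
  m <- dffTraces(dff)
  bsd <- baselineSd(dff)
  bw <- seq.int(dff@baselineWindow[1], dff@baselineWindow[2])
  outside <- setdiff(seq_len(ncol(m)), bw)
  res <- setNames(rep(NA, nrow(m)), cellIds(dff))
  for (i in seq_len(nrow(m))) {
    if (is.na(bsd[i]) || bsd[i] <= 0) next
    ex <- m[i, outside] > k_sd * bsd[i]
    r <- rle(ex)
    res[i] <- any(r$values & r$lengths >= need)
  }
  res
}

#' Process raw traces into smoothed dF/F
#'
#' Convenience chain: background subtraction (when a background trace is
#' stored), SR101 normalization of astrocytes, dF/F against the pre-stimulus
#' baseline, and zero-phase Butterworth smoothing.
#'
#' @param traces a [TraceSet-class].
#' @param baseline_window optional frame range passed to [computeDff()].
#' @param cutoff_hz,order smoothing parameters, see [smoothDff()].
#' @return a smoothed [DffTraceSet-class].
#' @export
processTraces <- function(traces, baseline_window = NULL, cutoff_hz = 2,
                          order = 4) {
  if (!is.null(metadata(traces)$background))
    traces <- subtractBackground(traces)
  traces <- normalizeAstrocytes(traces)
  smoothDff(computeDff(traces, baseline_window), cutoff_hz, order)
}
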