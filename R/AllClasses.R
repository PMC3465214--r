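#' @import methods
#' @importFrom stats cor sd rnorm runif t.test median setNames quantile
#' @importFrom utils head tail read.csv write.csv packageVersion
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assays<- assayNames rowData rowData<-
NULL

# ---------------------------------------------------------------------------
# StimulusProtocol
# ---------------------------------------------------------------------------

#' Timed whisker burst-stimulus protocol
#'
#' Describes a sequence of burst-pulse whisker stimuli: each burst has an
#' onset, a duration, a pulse frequency and a pulse width. The canonical
#' protocol of the analysis is two 10-s bursts (8 Hz then 12 Hz air puffs)
#' separated by a 10-s interval, preceded by a 10-s pre-stimulus baseline.
#'
#' @slot bursts data.frame with columns \code{onset_s}, \code{duration_s},
#'   \code{pulse_freq_hz}, \code{pulse_width_ms}; time-ordered and
#'   non-overlapping.
#' @slot totalDuration total recording duration in seconds; at least the end
#'   of the last burst.
#' @seealso [makeDefaultProtocol()]
#' @export
setClass("StimulusProtocol",
  slots = c(bursts = "data.frame", totalDuration = "numeric"))

setValidity("StimulusProtocol", function(object) {
  b <- object@bursts
  need <- c("onset_s", "duration_s", "pulse_freq_hz", "pulse_width_ms")
  if (!all(need %in% names(b)))
    return(paste("bursts must have columns", paste(need, collapse = ", ")))
  if (nrow(b) == 0) return("at least one burst is required")
  if (any(b$onset_s < 0)) return("onset_s must be >= 0")
  if (any(b$duration_s <= 0)) return("duration_s must be > 0")
  if (any(b$pulse_freq_hz <= 0)) return("pulse_freq_hz must be > 0")
  ends <- b$onset_s + b$duration_s
  if (nrow(b) > 1) {
    if (is.unsorted(b$onset_s, strictly = TRUE))
      return("bursts must be time-ordered")
    if (any(ends[-nrow(b)] > b$onset_s[-1]))
      return("bursts must not overlap")
  }
  if (length(object@totalDuration) != 1 || object@totalDuration < max(ends))
    return("totalDuration must be a scalar >= the end of the last burst")
  TRUE
})

#' @describeIn StimulusProtocol-class constructor.
#' @param bursts data.frame as described for the slot.
#' @param total_duration_s total recording duration (seconds).
#' @export
StimulusProtocol <- function(bursts, total_duration_s) {
  new("StimulusProtocol", bursts = as.data.frame(bursts),
      totalDuration = as.numeric(total_duration_s))
}

setMethod("show", "StimulusProtocol", function(object) {
  b <- object@bursts
  cat("StimulusProtocol:", nrow(b), "burst(s),",
      object@totalDuration, "s total\n")
  for (i in seq_len(nrow(b)))
    cat(sprintf("  burst %d: [%g, %g) s @ %g Hz (pulse %g ms)\n", i,
                b$onset_s[i], b$onset_s[i] + b$duration_s[i],
                b$pulse_freq_hz[i], b$pulse_width_ms[i]))
})

# ---------------------------------------------------------------------------
# TraceSet / DffTraceSet
# ---------------------------------------------------------------------------

#' Population fluorescence traces
#'
#' A \code{TraceSet} holds per-cell fluorescence time series for a mixed
#' population of neurons and astrocytes as a
#' \linkS4class{SummarizedExperiment}: rows are cells, columns are frames.
#' The \code{"raw"} assay is the calcium-indicator channel in arbitrary
#' fluorescence units; an optional \code{"sr101"} assay carries the red
#' astrocyte-marker channel. Metadata stores the frame rate, the stimulus
#' protocol (absent for spontaneous recordings), an optional background
#' (unstained-vessel) trace, and generator ground truth when the object was
#' simulated.
#'
#' @export
setClass("TraceSet", contains = "SummarizedExperiment")

setValidity("TraceSet", function(object) {
  if (!"raw" %in% assayNames(object)) return("assay 'raw' is required")
  raw <- assay(object, "raw")
  if (!all(is.finite(raw))) return("raw traces must be finite")
  rd <- rowData(object)
  if (!all(c("cell_id", "cell_type") %in% names(rd)))
    return("rowData must have cell_id and cell_type")
  if (!all(rd$cell_type %in% c("neuron", "astrocyte")))
    return("cell_type must be 'neuron' or 'astrocyte'")
  fr <- metadata(object)$frame_rate_hz
  if (is.null(fr) || fr <= 0) return("frame_rate_hz must be > 0")
  pr <- metadata(object)$protocol
  if (!is.null(pr)) {
    if (!is(pr, "StimulusProtocol")) return("protocol must be a StimulusProtocol")
    if (ncol(object) != round(pr@totalDuration * fr))
      return("frame count must equal total_duration_s * frame_rate_hz (rounded)")
  }
  bg <- metadata(object)$background
  if (!is.null(bg) && length(bg) != ncol(object))
    return("background must have one value per frame")
  TRUE
})

#' @describeIn TraceSet-class constructor.
#' @param raw cells x frames matrix of raw fluorescence.
#' @param cellType character vector, one of \code{"neuron"}, \code{"astrocyte"}
#'   per cell.
#' @param frameRate acquisition frame rate in Hz.
#' @param protocol \linkS4class{StimulusProtocol} or \code{NULL} (spontaneous).
#' @param sr101 optional cells x frames matrix for the SR101 channel
#'   (rows for neurons may be \code{NA}).
#' @param background optional frame-long vector with the unstained-vessel
#'   noise trace.
#' @param groundTruth optional list of generator ground truth.
#' @export
TraceSet <- function(raw, cellType, frameRate, protocol = NULL, sr101 = NULL,
                     background = NULL, groundTruth = NULL) {
  raw <- as.matrix(raw)
  ids <- rownames(raw)
  if (is.null(ids)) ids <- sprintf("cell%03d", seq_len(nrow(raw)))
  rownames(raw) <- ids
  al <- list(raw = raw)
  if (!is.null(sr101)) {
    sr101 <- as.matrix(sr101)
    rownames(sr101) <- ids
    al$sr101 <- sr101
  }
  rd <- DataFrame(cell_id = ids, cell_type = as.character(cellType),
                  row.names = ids)
  se <- SummarizedExperiment(assays = al, rowData = rd)
  metadata(se) <- list(frame_rate_hz = frameRate, protocol = protocol,
                       background = background, ground_truth = groundTruth)
  new("TraceSet", se)
}

#' Relative fluorescence-change traces
#'
#' A \linkS4class{TraceSet} whose primary assay \code{"dff"} holds
#' dimensionless dF/F values, together with the baseline frame window used
#' for the baseline fluorescence F and the per-cell baseline standard
#' deviation of dF/F over that window (\code{rowData} column
#' \code{baseline_sd}). \code{smoothed} records whether the zero-phase
#' low-pass filter has been applied.
#'
#' @export
setClass("DffTraceSet", contains = "TraceSet",
  slots = c(baselineWindow = "integer", smoothed = "logical"))

setValidity("DffTraceSet", function(object) {
  if (!"dff" %in% assayNames(object)) return("assay 'dff' is required")
  bw <- object@baselineWindow
  if (length(bw) != 2 || bw[1] < 1 || bw[2] > ncol(object) || bw[1] > bw[2])
    return("baselineWindow must be a valid [first, last] frame range")
  if (!"baseline_sd" %in% names(rowData(object)))
    return("rowData must carry baseline_sd")
  TRUE
})

setMethod("show", "TraceSet", function(object) {
  tp <- table(rowData(object)$cell_type)
  cat(class(object), "with", nrow(object), "cells (",
      paste(sprintf("%d %s", as.integer(tp), names(tp)), collapse = ", "),
      ") x", ncol(object), "frames @", metadata(object)$frame_rate_hz, "Hz\n")
  pr <- metadata(object)$protocol
  if (is.null(pr)) cat("  spontaneous (no stimulus protocol)\n") else show(pr)
})

# ---------------------------------------------------------------------------
# Correlation containers
# ---------------------------------------------------------------------------

#' Lag-resolved cross-correlation function
#'
#' The normalized cross-correlation r(d) between two trace windows evaluated
#' at integer frame delays d symmetric about zero. At each delay the
#' coefficient is the Pearson correlation over the overlapping samples, with
#' both means computed on the overlap, so that r is identically normalized to
#' the zero-lag autocorrelation.
#'
#' @slot delays integer frame delays, \code{-maxLag:maxLag}.
#' @slot r correlation coefficient at each delay, in [-1, 1].
#' @export
setClass("CorrFunction", slots = c(delays = "integer", r = "numeric"))

setValidity("CorrFunction", function(object) {
  if (length(object@delays) != length(object@r))
    return("delays and r must have equal length")
  if (any(abs(object@r) > 1 + 1e-9, na.rm = TRUE))
    return("|r| must not exceed 1")
  TRUE
})

setMethod("show", "CorrFunction", function(object) {
  pk <- peakCoefficient(object)
  cat(sprintf("CorrFunction over delays [%d, %d]; peak r = %.3f at d = %d\n",
              min(object@delays), max(object@delays), pk$r, pk$delay))
})

#' Matrix of peak cross-correlation coefficients
#'
#' Peak (central-peak) coefficients and their delays for every pair of cells
#' drawn from a row set and a column set. Square matrices (same set on both
#' axes, e.g. neuron-neuron) are symmetric with a unit diagonal; bipartite
#' matrices (e.g. astrocytes x neurons) are rectangular.
#'
#' @slot peakR matrix of peak coefficients in [-1, 1].
#' @slot peakDelay matrix of frame delays at the peak.
#' @slot window first and last frame of the analyzed window.
#' @slot maxLag largest |delay| searched (frames).
#' @slot bipartite TRUE when the row and column sets differ.
#' @export
setClass("CorrMatrix",
  slots = c(peakR = "matrix", peakDelay = "matrix", window = "integer",
            maxLag = "integer", bipartite = "logical"))

setValidity("CorrMatrix", function(object) {
  if (!identical(dim(object@peakR), dim(object@peakDelay)))
    return("peakR and peakDelay must have identical dimensions")
  if (any(abs(object@peakR) > 1 + 1e-9, na.rm = TRUE))
    return("coefficients must lie in [-1, 1]")
  if (!object@bipartite) {
    if (nrow(object@peakR) != ncol(object@peakR))
      return("non-bipartite matrix must be square")
    if (any(abs(object@peakR - t(object@peakR)) > 1e-9, na.rm = TRUE))
      return("square matrix must be symmetric")
  }
  TRUE
})

setMethod("show", "CorrMatrix", function(object) {
  cat(sprintf("CorrMatrix %dx%d (%s), window [%d, %d], max lag %d\n",
              nrow(object@peakR), ncol(object@peakR),
              if (object@bipartite) "bipartite" else "square",
              object@window[1], object@window[2], object@maxLag))
})

# ---------------------------------------------------------------------------
# FunctionalNetwork
# ---------------------------------------------------------------------------

#' Thresholded functional-connectivity graph
#'
#' Binary adjacency obtained by comparing stimulated peak correlation
#' coefficients against a threshold derived from spontaneous activity
#' (mean + 2 SD of spontaneous pair coefficients). Square networks connect
#' activated neurons (or astrocytes) among themselves; bipartite networks
#' link neurons (columns) with astrocytes (rows).
#'
#' @slot adjacency binary matrix; square case symmetric with zero diagonal.
#' @slot thresh the coefficient threshold used.
#' @slot rowType,colType cell type of the row and column node sets.
#' @slot bipartite TRUE for rectangular neuron-astrocyte networks.
#' @export
setClass("FunctionalNetwork",
  slots = c(adjacency = "matrix", thresh = "numeric",
            rowType = "character", colType = "character",
            bipartite = "logical"))

setValidity("FunctionalNetwork", function(object) {
  A <- object@adjacency
  if (!all(A %in% c(0, 1))) return("adjacency entries must be 0 or 1")
  if (!object@bipartite) {
    if (nrow(A) != ncol(A)) return("square network must be square")
    if (any(diag(A) != 0)) return("diagonal must be zero")
    if (any(A != t(A))) return("square adjacency must be symmetric")
  }
  TRUE
})

setMethod("show", "FunctionalNetwork", function(object) {
  cat(sprintf("FunctionalNetwork %dx%d (%s), thresh = %.3f, %d link(s)\n",
              nrow(object@adjacency), ncol(object@adjacency),
              if (object@bipartite) "bipartite" else "square", object@thresh,
              if (object@bipartite) sum(object@adjacency)
              else sum(object@adjacency) / 2))
})

# ---------------------------------------------------------------------------
# LfpSweepSet
# ---------------------------------------------------------------------------

#' Local field potential sweeps
#'
#' One or more LFP sweeps recorded (or simulated) under a common stimulus
#' protocol, sampled at \code{samplingRate} (10 kHz by default). \code{band}
#' records the band-pass edges once filtering has been applied.
#'
#' @slot samples samples x sweeps matrix of voltages (arbitrary units).
#' @slot samplingRate sampling rate in Hz.
#' @slot protocol the \linkS4class{StimulusProtocol} driving the sweeps.
#' @slot band numeric(2) band-pass edges in Hz, or NA before filtering.
#' @export
setClass("LfpSweepSet",
  slots = c(samples = "matrix", samplingRate = "numeric",
            protocol = "StimulusProtocol", band = "numeric"))

setValidity("LfpSweepSet", function(object) {
  if (!all(is.finite(object@samples))) return("samples must be finite")
  if (object@samplingRate <= 0) return("samplingRate must be > 0")
  if (!any(is.na(object@band)) &&
      object@samplingRate <= 2 * max(object@band))
    return("samplingRate must exceed twice the upper band edge")
  TRUE
})

setMethod("show", "LfpSweepSet", function(object) {
  cat(sprintf("LfpSweepSet: %d sweep(s) x %d samples @ %g kHz",
              ncol(object@samples), nrow(object@samples),
              object@samplingRate / 1000))
  if (!any(is.na(object@band)))
    cat(sprintf(", band-passed %g-%g Hz", object@band[1], object@band[2]))
  cat("\n")
})

# ---------------------------------------------------------------------------
# ScenarioConfig
# ---------------------------------------------------------------------------

#' Synthetic-population scenario configuration
#'
#' All knobs of the synthetic calcium-trace generator. Pattern probabilities
#' give the ground-truth fractions of increment / decrement / parallel cells;
#' pairwise Pearson targets are hit exactly in expectation through a shared
#' latent component whose loading is solved from the closed-form mixing
#' identity r = a^2 sigma_C^2 / (a^2 sigma_C^2 + sigma_eps^2), evaluated on
#' post-smoothing variances and including the evoked-kernel contribution.
#'
#' @slot nNeurons,nAstrocytes population sizes.
#' @slot patternProbsNeurons,patternProbsAstrocytes numeric(3)
#'   (increment, decrement, parallel) probabilities, each summing to 1.
#' @slot pSilent probability that a cell is unresponsive (amplitude 0).
#' @slot amplitudeMean mean evoked plateau amplitude (dF/F units).
#' @slot amplitudeCv lognormal coefficient of variation of per-cell amplitude.
#' @slot deltaRel relative step of R2 vs R1 for increment/decrement cells.
#' @slot noiseSd independent per-frame noise SD (dF/F units).
#' @slot tauNeuron,tauAstro calcium decay constants (s).
#' @slot astroLag astrocyte response onset lag (s).
#' @slot frameRate acquisition frame rate (Hz).
#' @slot f0 baseline fluorescence (arbitrary units).
#' @slot rWithinNeurons,rWithinAstrocytes,rNeuronAstro per-burst Pearson
#'   targets (length 2, burst 1 and burst 2); NA to leave the class
#'   uncalibrated.
#' @slot rEpochCross optional neuron-astrocyte target over the full
#'   stimulation epoch; when set, the evoked amplitude is solved to reach it.
#' @slot rSpontaneous Pearson target outside bursts / without stimulation.
#' @slot spontDuration duration of spontaneous recordings (s).
#' @slot calibration \code{"within"} (solve within-type targets),
#'   \code{"cross"} (solve the between-type target with equal loadings),
#'   \code{"spont"} (spontaneous latent only), \code{"manual"} (explicit
#'   loadings), or \code{"assembly"} (assembly-structured coupling for
#'   functional-connectivity scenarios).
#' @slot loadings list used when \code{calibration == "manual"}:
#'   \code{sigmaL} (log-normal SD of per-cell loading multipliers),
#'   \code{beta} (length-2 latent scale per burst), \code{astroScale}
#'   (astrocyte stimulated-loading multiplier), \code{astroRest}
#'   (astrocyte resting-loading multiplier, reflecting gap-junction
#'   coupling at rest). When \code{calibration == "assembly"}:
#'   \code{rStrong} (within-assembly Pearson target per burst),
#'   \code{rWeakBurst} (diffuse non-assembly target per burst),
#'   \code{neuronAssemblies} and \code{astroAssemblies} (per burst, a list
#'   of member index vectors; assembly g of each type shares one latent).
#' @slot seed integer RNG seed; identical config + seed gives bit-identical
#'   output.
#' @seealso [scenarioConfig()], [scenarioPreset()], [simulatePopulation()]
#' @export
setClass("ScenarioConfig",
  slots = c(nNeurons = "numeric", nAstrocytes = "numeric",
            patternProbsNeurons = "numeric", patternProbsAstrocytes = "numeric",
            pSilent = "numeric",
            amplitudeMean = "numeric", amplitudeCv = "numeric",
            deltaRel = "numeric", noiseSd = "numeric",
            tauNeuron = "numeric", tauAstro = "numeric", astroLag = "numeric",
            frameRate = "numeric", f0 = "numeric",
            rWithinNeurons = "numeric", rWithinAstrocytes = "numeric",
            rNeuronAstro = "numeric", rEpochCross = "numeric",
            rSpontaneous = "numeric", spontDuration = "numeric",
            calibration = "character", loadings = "list", seed = "numeric"))

setValidity("ScenarioConfig", function(object) {
  pp <- list(object@patternProbsNeurons, object@patternProbsAstrocytes)
  for (p in pp) {
    if (length(p) != 3 || any(p < 0) || abs(sum(p) - 1) > 1e-8)
      return("pattern probabilities must be 3 non-negative values summing to 1")
  }
  rt <- c(object@rWithinNeurons, object@rWithinAstrocytes,
          object@rNeuronAstro, object@rEpochCross, object@rSpontaneous)
  rt <- rt[!is.na(rt)]
  if (any(rt < 0 | rt >= 1)) return("r targets must lie in [0, 1)")
  if (object@noiseSd <= 0) return("noiseSd must be > 0")
  if (object@frameRate <= 0) return("frameRate must be > 0")
  if (object@pSilent < 0 || object@pSilent >= 1)
    return("pSilent must be in [0, 1)")
  if (!object@calibration %in% c("within", "cross", "spont", "manual",
                                 "assembly"))
    return(
      "calibration must be 'within', 'cross', 'spont', 'manual' or 'assembly'")
  TRUE
})

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf(
    "ScenarioConfig: %d neurons + %d astrocytes, amplitude %.2g, noise %.2g, calibration '%s', seed %d\n",
    object@nNeurons, object@nAstrocytes, object@amplitudeMean,
    object@noiseSd, object@calibration, as.integer(object@seed)))
})
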