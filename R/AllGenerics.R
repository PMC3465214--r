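# Accessor generics. Slot access from user code should go through these.

#' @rdname StimulusProtocol-class
#' @param x,object an object of the documented class.
#' @export
setGeneric("bursts", function(x) standardGeneric("bursts"))
#' @rdname StimulusProtocol-class
#' @export
setMethod("bursts", "StimulusProtocol", function(x) x@bursts)

#' @rdname StimulusProtocol-class
#' @export
setGeneric("nBursts", function(x) standardGeneric("nBursts"))
#' @rdname StimulusProtocol-class
#' @export
setMethod("nBursts", "StimulusProtocol", function(x) nrow(x@bursts))

#' @rdname StimulusProtocol-class
#' @export
setGeneric("totalDuration", function(x) standardGeneric("totalDuration"))
#' @rdname StimulusProtocol-class
#' @export
setMethod("totalDuration", "StimulusProtocol", function(x) x@totalDuration)

#' @rdname TraceSet-class
#' @export
setGeneric("rawTraces", function(x) standardGeneric("rawTraces"))
#' @rdname TraceSet-class
#' @export
setMethod("rawTraces", "TraceSet", function(x) assay(x, "raw"))

#' @rdname TraceSet-class
#' @export
setGeneric("sr101Traces", function(x) standardGeneric("sr101Traces"))
#' @rdname TraceSet-class
#' @export
setMethod("sr101Traces", "TraceSet", function(x) {
  if ("sr101" %in% assayNames(x)) assay(x, "sr101") else NULL
})

#' @rdname TraceSet-class
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))
#' @rdname TraceSet-class
#' @export
setMethod("cellIds", "TraceSet", function(x) rowData(x)$cell_id)

#' @rdname TraceSet-class
#' @export
setGeneric("cellTypes", function(x) standardGeneric("cellTypes"))
#' @rdname TraceSet-class
#' @export
setMethod("cellTypes", "TraceSet", function(x)
  setNames(rowData(x)$cell_type, rowData(x)$cell_id))

#' @rdname TraceSet-class
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname TraceSet-class
#' @export
setMethod("frameRate", "TraceSet", function(x) metadata(x)$frame_rate_hz)

#' @rdname TraceSet-class
#' @export
setGeneric("protocol", function(x) standardGeneric("protocol"))
#' @rdname TraceSet-class
#' @export
setMethod("protocol", "TraceSet", function(x) metadata(x)$protocol)
#' @rdname TraceSet-class
#' @export
setMethod("protocol", "LfpSweepSet", function(x) x@protocol)

#' @rdname TraceSet-class
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname TraceSet-class
#' @export
setMethod("groundTruth", "TraceSet", function(x) metadata(x)$ground_truth)

#' @rdname DffTraceSet-class
#' @param x a \code{DffTraceSet}.
#' @export
setGeneric("dffTraces", function(x) standardGeneric("dffTraces"))
#' @rdname DffTraceSet-class
#' @export
setMethod("dffTraces", "DffTraceSet", function(x) assay(x, "dff"))

#' @rdname DffTraceSet-class
#' @export
setGeneric("baselineSd", function(x) standardGeneric("baselineSd"))
#' @rdname DffTraceSet-class
#' @export
setMethod("baselineSd", "DffTraceSet", function(x)
  setNames(rowData(x)$baseline_sd, rowData(x)$cell_id))

#' @rdname DffTraceSet-class
#' @export
setGeneric("baselineWindow", function(x) standardGeneric("baselineWindow"))
#' @rdname DffTraceSet-class
#' @export
setMethod("baselineWindow", "DffTraceSet", function(x) x@baselineWindow)

#' @rdname CorrMatrix-class
#' @param x a \code{CorrMatrix} or \code{FunctionalNetwork}.
#' @export
setGeneric("peakR", function(x) standardGeneric("peakR"))
#' @rdname CorrMatrix-class
#' @export
setMethod("peakR", "CorrMatrix", function(x) x@peakR)

#' @rdname CorrMatrix-class
#' @export
setGeneric("peakDelay", function(x) standardGeneric("peakDelay"))
#' @rdname CorrMatrix-class
#' @export
setMethod("peakDelay", "CorrMatrix", function(x) x@peakDelay)

#' @rdname FunctionalNetwork-class
#' @param x a \code{FunctionalNetwork}.
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))
#' @rdname FunctionalNetwork-class
#' @export
setMethod("adjacencyMatrix", "FunctionalNetwork", function(x) x@adjacency)

#' @rdname FunctionalNetwork-class
#' @export
setGeneric("connectionThreshold",
           function(x) standardGeneric("connectionThreshold"))
#' @rdname FunctionalNetwork-class
#' @export
setMethod("connectionThreshold", "FunctionalNetwork", function(x) x@thresh)

#' @rdname LfpSweepSet-class
#' @param x an \code{LfpSweepSet}.
#' @export
setGeneric("sweepMatrix", function(x) standardGeneric("sweepMatrix"))
#' @rdname LfpSweepSet-class
#' @export
setMethod("sweepMatrix", "LfpSweepSet", function(x) x@samples)

#' @rdname LfpSweepSet-class
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname LfpSweepSet-class
#' @export
setMethod("samplingRate", "LfpSweepSet", function(x) x@samplingRate)
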