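# Plain-text interchange: traces CSV (frames x cells, header = cell ids),
# cells CSV (cell_id, cell_type, optional active flag), protocol JSON.

#' Write a TraceSet to a directory of plain-text files
#'
#' `traces.csv` holds the raw traces with one row per frame and one column
#' per cell (header row carries the cell ids); `sr101.csv` likewise when the
#' SR101 channel is present; `cells.csv` lists cell id and type (plus any
#' extra columns supplied); `protocol.json` the stimulus protocol. For a
#' [DffTraceSet-class] the dF/F values are written instead, with the
#' baseline window and per-cell baseline SD alongside.
#'
#' @param ts a [TraceSet-class] or [DffTraceSet-class].
#' @param dir output directory (created if missing).
#' @param extra_cell_columns optional data.frame merged into `cells.csv`
#'   (e.g. an `active` flag).
#' @return the directory, invisibly.
#' @export
writeTraceSet <- function(ts, dir, extra_cell_columns = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  isDff <- is(ts, "DffTraceSet")
  m <- if (isDff) dffTraces(ts) else rawTraces(ts)
  df <- as.data.frame(t(m))
  names(df) <- cellIds(ts)
  utils::write.csv(df, file.path(dir, "traces.csv"), row.names = FALSE)
  sr <- sr101Traces(ts)
  if (!is.null(sr)) {
    srd <- as.data.frame(t(sr)); names(srd) <- cellIds(ts)
    utils::write.csv(srd, file.path(dir, "sr101.csv"), row.names = FALSE)
  }
  cells <- data.frame(cell_id = cellIds(ts),
                      cell_type = unname(cellTypes(ts)))
  if (isDff) cells$baseline_sd <- unname(baselineSd(ts))
  if (!is.null(extra_cell_columns)) cells <- cbind(cells, extra_cell_columns)
  utils::write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  meta <- list(frame_rate_hz = frameRate(ts))
  if (isDff) meta$baseline_window <- baselineWindow(ts)
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(protocol(ts)))
    writeProtocol(protocol(ts), file.path(dir, "protocol.json"))
  invisible(dir)
}

#' Read a TraceSet from a directory written by [writeTraceSet()]
#'
#' Also accepts externally produced directories following the same dialect:
#' `traces.csv` (frames x cells), `cells.csv` (cell_id, cell_type), optional
#' `sr101.csv`, `meta.json` with `frame_rate_hz`, optional `protocol.json`.
#'
#' @param dir directory path.
#' @return a [TraceSet-class].
#' @export
readTraceSet <- function(dir) {
  tr <- utils::read.csv(file.path(dir, "traces.csv"), check.names = FALSE)
  cells <- utils::read.csv(file.path(dir, "cells.csv"))
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  raw <- t(as.matrix(tr))
  rownames(raw) <- names(tr)
  raw <- raw[cells$cell_id, , drop = FALSE]
  srPath <- file.path(dir, "sr101.csv")
  sr <- NULL
  if (file.exists(srPath)) {
    srd <- utils::read.csv(srPath, check.names = FALSE)
    sr <- t(as.matrix(srd))[cells$cell_id, , drop = FALSE]
  }
  prPath <- file.path(dir, "protocol.json")
  pr <- if (file.exists(prPath)) readProtocol(prPath) else NULL
  TraceSet(raw, cells$cell_type, meta$frame_rate_hz, protocol = pr,
           sr101 = sr)
}
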