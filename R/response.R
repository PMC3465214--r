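# Paired-response measurement (R1, R2) and the three-way pattern
# classification (increment / decrement / parallel).

#' Measure paired burst responses R1 and R2
#'
#' For each cell, R1 is the maximum smoothed dF/F within the burst-1 window
#' (baseline is ~0 by construction of dF/F). Because calcium may not return
#' to baseline between bursts, R2 is measured above the residual of response
#' one: the residual is the mean dF/F over the final second before burst-2
#' onset, and R2 = (maximum dF/F within the burst-2 window) - residual,
#' floored at 0 (a trace that only decays below its residual has no evoked
#' second response; such cells are flagged).
#'
#' @param dff a [DffTraceSet-class] (normally smoothed).
#' @param protocol a [StimulusProtocol-class] with exactly two bursts;
#'   defaults to the protocol attached to `dff`.
#' @param residual_window_s length of the pre-burst-2 residual window (s).
#' @return data.frame with columns `cell_id`, `cell_type`, `R1`, `R2`,
#'   `residual`, `baseline_sd`, `floored`, and `pattern` (unset, `NA`).
#' @export
measurePairedResponses <- function(dff, protocol = NULL,
                                   residual_window_s = 1) {
  if (is.null(protocol)) protocol <- protocol(dff)
  if (is.null(protocol) || nBursts(protocol) != 2)
    stop("a protocol with exactly 2 bursts is required")
  fs <- frameRate(dff)
  m <- dffTraces(dff)
  w1 <- burstWindow(protocol, 1, fs)
  w2 <- burstWindow(protocol, 2, fs)
  on2 <- floor(bursts(protocol)$onset_s[2] * fs)
  rw <- seq.int(max(1L, on2 - round(residual_window_s * fs) + 1L), on2)
  R1 <- apply(m[, w1, drop = FALSE], 1, max)
  resid <- rowMeans(m[, rw, drop = FALSE])
  R2raw <- apply(m[, w2, drop = FALSE], 1, max) - resid
  data.frame(cell_id = cellIds(dff), cell_type = unname(cellTypes(dff)),
             R1 = unname(R1), R2 = pmax(R2raw, 0),
             residual = unname(resid),
             baseline_sd = unname(baselineSd(dff)),
             floored = unname(R2raw < 0),
             pattern = NA_character_)
}

#' Classify the response pattern of paired responses
#'
#' The difference of the two responses is compared against `k_sd` times the
#' cell's baseline SD (the magnitudes are considered equal when their net
#' change is below that): increment when `R2 - R1 > k_sd * baseline_sd`,
#' decrement when `R1 - R2 > k_sd * baseline_sd`, parallel otherwise.
#'
#' @param resp data.frame from [measurePairedResponses()], or a one-row list
#'   with `R1`, `R2`, `baseline_sd`.
#' @param k_sd threshold multiplier (default 2).
#' @return `resp` with the `pattern` column filled.
#' @export
classifyPattern <- function(resp, k_sd = 2) {
  d <- resp$R2 - resp$R1
  th <- k_sd * resp$baseline_sd
  resp$pattern <- ifelse(d > th, "increment",
                         ifelse(-d > th, "decrement", "parallel"))
  resp
}

#' Summarize pattern portions across sessions
#'
#' Per-session percentages of decrement / increment / parallel cells, their
#' cross-session mean and SEM, and the per-session increment-to-decrement
#' ratio (averaged over sessions where the decrement portion is non-zero;
#' sessions with zero decrement are flagged). Sessions with no cells are
#' excluded with a warning.
#'
#' @param labels list with one character vector of pattern labels per
#'   session.
#' @return list with `per_session` (data.frame of percentages), `mean`,
#'   `sem` (named numeric over the three patterns), `ratio_inc_dec`
#'   (mean +/- SEM and per-session values), `n_sessions`.
#' @export
summarizePatterns <- function(labels) {
  if (!is.list(labels)) labels <- list(labels)
  keep <- vapply(labels, length, integer(1)) > 0
  if (!any(keep)) stop("at least one session with >= 1 cell is required")
  if (any(!keep))
    warning(sum(!keep), " session(s) with zero cells excluded")
  labels <- labels[keep]
  pats <- c("decrement", "increment", "parallel")
  per <- t(vapply(labels, function(l)
    100 * vapply(pats, function(p) mean(l == p), numeric(1)),
    numeric(3)))
  colnames(per) <- pats
  ratios <- vapply(labels, function(l) {
    nd <- sum(l == "decrement")
    if (nd == 0) NA_real_ else sum(l == "increment") / nd
  }, numeric(1))
  rs <- if (all(is.na(ratios))) list(mean = NA_real_, sem = NA_real_)
        else meanSem(ratios[!is.na(ratios)])
  list(per_session = as.data.frame(per),
       mean = colMeans(per),
       sem = apply(per, 2, function(x) meanSem(x)$sem),
       ratio_inc_dec = list(mean = rs$mean, sem = rs$sem,
                            per_session = ratios,
                            undefined_sessions = sum(is.na(ratios))),
       n_sessions = length(labels))
}
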