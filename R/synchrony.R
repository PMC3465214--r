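# Lag-resolved pairwise cross-correlation (the synchrony measure) and the
# correlation matrices built from it.

#' Normalized cross-correlation of two trace windows
#'
#' For each delay d in `-max_lag_frames:max_lag_frames`, the coefficient
#'
#' \deqn{r(d) = \frac{\sum_t (x(t)-m_x)(y(t-d)-m_y)}
#'   {\sqrt{\sum_t (x(t)-m_x)^2 \sum_t (y(t-d)-m_y)^2}}}
#'
#' is computed over the n - |d| overlapping samples, with both means taken on
#' the overlap (no padding). This denominator normalizes identically to the
#' zero-lag autocorrelation, so r(0) of a trace with itself is exactly 1.
#'
#' @param x,y numeric vectors of equal length (> max_lag + 2), each with
#'   non-zero variance.
#' @param max_lag_frames largest |delay| searched (frames).
#' @return a [CorrFunction-class].
#' @examples
#' x <- sin(seq(0, 6 * pi, length.out = 100))
#' peakCoefficient(crossCorrelation(x, x, 5))
#' @export
crossCorrelation <- function(x, y, max_lag_frames = 5L) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n <= max_lag_frames + 2)
    stop("windows must be longer than max_lag + 2")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero-variance window (flat or saturated cell)")
  delays <- as.integer(seq.int(-max_lag_frames, max_lag_frames))
  r <- vapply(delays, function(d) {
    if (d >= 0) {
      xs <- x[seq.int(d + 1L, n)]; ys <- y[seq_len(n - d)]
    } else {
      xs <- x[seq_len(n + d)]; ys <- y[seq.int(1L - d, n)]
    }
    stats::cor(xs, ys)
  }, numeric(1))
  new("CorrFunction", delays = delays, r = r)
}

#' Peak (central-peak) coefficient of a cross-correlation function
#'
#' The signed maximum of r(d) over the delay range, with ties broken toward
#' the smaller |d| and then toward the negative delay.
#'
#' @param cf a [CorrFunction-class].
#' @return list with elements `r` and `delay`.
#' @export
peakCoefficient <- function(cf) {
  if (length(cf@r) == 0) stop("empty correlation function")
  ord <- order(-cf@r, abs(cf@delays), cf@delays)
  i <- ord[1]
  list(r = cf@r[i], delay = cf@delays[i])
}

#' Pairwise peak cross-correlation matrix
#'
#' Peak coefficient and peak delay for every pair drawn from two cell-id
#' sets, computed on the smoothed dF/F traces restricted to a frame window.
#' With identical sets the matrix is square and symmetric with a unit
#' diagonal at zero delay (neuron-neuron or astrocyte-astrocyte case); with
#' different sets it is bipartite, rows indexing `cells_a` (e.g. astrocytes)
#' and columns `cells_b` (neurons). Zero-variance cells are dropped with a
#' warning.
#'
#' @param dff a [DffTraceSet-class].
#' @param cells_a,cells_b character vectors of cell ids (defaults: all
#'   cells).
#' @param window frame indices to analyze (default: whole trace).
#' @param max_lag largest |delay| searched (frames); the default 0.5 s at
#'   10 Hz keeps the search near the central peak.
#' @return a [CorrMatrix-class].
#' @export
pairwiseMatrix <- function(dff, cells_a = NULL, cells_b = NULL,
                           window = NULL, max_lag = 5L) {
  m <- dffTraces(dff)
  ids <- cellIds(dff)
  if (is.null(cells_a)) cells_a <- ids
  if (is.null(cells_b)) cells_b <- cells_a
  if (!all(c(cells_a, cells_b) %in% ids)) stop("unknown cell id")
  if (is.null(window)) window <- seq_len(ncol(m))
  if (min(window) < 1 || max(window) > ncol(m))
    stop("window outside the trace")
  sub <- m[, window, drop = FALSE]
  keepVar <- apply(sub, 1, stats::sd) > 0
  dropIds <- ids[!keepVar]
  if (any(c(cells_a, cells_b) %in% dropIds)) {
    warning("excluding zero-variance cell(s): ",
            paste(intersect(unique(c(cells_a, cells_b)), dropIds),
                  collapse = ", "))
    cells_a <- setdiff(cells_a, dropIds)
    cells_b <- setdiff(cells_b, dropIds)
  }
  bip <- !identical(sort(cells_a), sort(cells_b))
  pr <- matrix(NA_real_, length(cells_a), length(cells_b),
               dimnames = list(cells_a, cells_b))
  pd <- pr
  for (i in seq_along(cells_a)) {
    jset <- if (bip) seq_along(cells_b) else seq.int(i, length(cells_b))
    for (j in jset) {
      if (!bip && cells_a[i] == cells_b[j]) {
        pr[i, j] <- 1; pd[i, j] <- 0
        next
      }
      pk <- peakCoefficient(crossCorrelation(sub[cells_a[i], ],
                                             sub[cells_b[j], ], max_lag))
      pr[i, j] <- pk$r; pd[i, j] <- pk$delay
      if (!bip) { pr[j, i] <- pk$r; pd[j, i] <- -pk$delay }
    }
  }
  new("CorrMatrix", peakR = pr, peakDelay = pd,
      window = as.integer(range(window)), maxLag = as.integer(max_lag),
      bipartite = bip)
}

#' Mean pairwise synchrony of a correlation matrix
#'
#' Square case: mean over the unique unordered pairs, excluding the
#' autocorrelation diagonal. Bipartite case: mean over all entries. When a
#' list of matrices (sessions) is given, the session means are averaged and
#' their SEM reported.
#'
#' @param m a [CorrMatrix-class] or a list of them (one per session).
#' @param exclude_diagonal kept for clarity; the diagonal is always excluded
#'   in the square case.
#' @return list with `mean`, `sem` (NA for a single matrix), `n_pairs`,
#'   `per_session` when a list is supplied.
#' @export
meanSynchrony <- function(m, exclude_diagonal = TRUE) {
  one <- function(cm) {
    x <- cm@peakR
    vals <- if (cm@bipartite) as.vector(x) else x[upper.tri(x)]
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0) stop("no valid pairs")
    c(mean = mean(vals), n = length(vals))
  }
  if (is(m, "CorrMatrix")) {
    v <- one(m)
    return(list(mean = unname(v["mean"]), sem = NA_real_,
                n_pairs = unname(v["n"])))
  }
  per <- vapply(m, one, numeric(2))
  ms <- meanSem(per["mean", ])
  list(mean = ms$mean, sem = ms$sem, n_pairs = sum(per["n", ]),
       per_session = unname(per["mean", ]))
}
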