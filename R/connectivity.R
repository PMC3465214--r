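# Functional-connectivity graphs: spontaneous-activity threshold, binary
# adjacency, and the network percentages Pn, Pk, Pl.

#' Spontaneous-activity connection threshold
#'
#' The threshold above which a stimulated pair correlation counts as a
#' functional connection: the mean of the spontaneous pair coefficients plus
#' two sample standard deviations (n - 1 denominator). Rests on the
#' assumption that spontaneous activity carries no coordination, so its
#' correlation level is the no-connection null.
#'
#' @param spont_coeffs numeric vector of pair peak coefficients from a
#'   spontaneous (no-stimulus) recording, length >= 2. A
#'   [CorrMatrix-class] is also accepted (its unique pair values are used).
#' @param k_sd multiplier on the SD (default 2).
#' @return the threshold (scalar).
#' @export
spontaneousThreshold <- function(spont_coeffs, k_sd = 2) {
  if (is(spont_coeffs, "CorrMatrix")) {
    x <- spont_coeffs@peakR
    spont_coeffs <- if (spont_coeffs@bipartite) as.vector(x)
                    else x[upper.tri(x)]
  }
  spont_coeffs <- spont_coeffs[!is.na(spont_coeffs)]
  if (length(spont_coeffs) < 2)
    stop("at least 2 spontaneous coefficients are required")
  mean(spont_coeffs) + k_sd * stats::sd(spont_coeffs)
}

#' Binarize a correlation matrix into a functional network
#'
#' Adjacency rule: \eqn{A_{ij} = 1} iff \eqn{r_{ij} > thresh} (strict;
#' coefficients exactly at the threshold give 0). In the square case the
#' diagonal is forced to zero and symmetry enforced.
#'
#' @param peak_r a [CorrMatrix-class] or a plain numeric matrix of peak
#'   coefficients.
#' @param thresh the connection threshold (see [spontaneousThreshold()]).
#' @param rowType,colType node cell types recorded on the network.
#' @return a [FunctionalNetwork-class].
#' @export
binarize <- function(peak_r, thresh, rowType = "neuron",
                     colType = rowType) {
  bip <- FALSE
  if (is(peak_r, "CorrMatrix")) {
    bip <- peak_r@bipartite
    peak_r <- peak_r@peakR
  } else {
    bip <- !identical(rownames(peak_r), colnames(peak_r)) &&
      !is.null(rownames(peak_r))
    if (nrow(peak_r) != ncol(peak_r)) bip <- TRUE
  }
  if (!all(is.finite(peak_r))) stop("peak_r must be finite")
  A <- (peak_r > thresh) * 1
  if (!bip) {
    diag(A) <- 0
    A <- pmax(A, t(A)) # symmetry (input should already be symmetric)
  }
  new("FunctionalNetwork", adjacency = A, thresh = thresh,
      rowType = rowType, colType = colType, bipartite = bip)
}

#' Network percentages Pn, Pk and Pl
#'
#' Square network over N activated neurons: a neuron with at least one
#' connection is function-connected; with n such neurons and k the mean
#' number of connections over all N neurons, `P_n = n / N` and
#' `P_k = k / (N - 1)` (the complete-graph degree). Bipartite network over N
#' neurons and M astrocytes with l realized links: `P_l = l / (N * M)`. All
#' reported as percentages.
#'
#' @param net a [FunctionalNetwork-class].
#' @param connected_only when TRUE, k averages over the function-connected
#'   neurons only (alternative reading of the mean-degree definition).
#' @return list with `N`, `n`, `k`, `Pn`, `Pk` (square) or `N`, `M`, `l`,
#'   `Pl` (bipartite), percentages in [0, 100].
#' @export
networkMetrics <- function(net, connected_only = FALSE) {
  A <- net@adjacency
  if (net@bipartite) {
    M <- nrow(A); N <- ncol(A)
    if (N < 1 || M < 1) stop("N and M must be >= 1")
    l <- sum(A)
    return(list(N = N, M = M, l = l, Pl = 100 * l / (N * M)))
  }
  N <- nrow(A)
  if (N < 2) stop("P_k requires at least 2 activated neurons")
  deg <- rowSums(A)
  n <- sum(deg >= 1)
  k <- if (connected_only) {
    if (n == 0) 0 else mean(deg[deg >= 1])
  } else mean(deg)
  list(N = N, n = n, k = k, Pn = 100 * n / N, Pk = 100 * k / (N - 1))
}

#' Compare network metrics between matched conditions
#'
#' Paired comparison of a per-session metric between two conditions
#' (e.g. Pn during response one vs response two): per-session differences,
#' their mean and SEM, and a two-tailed paired t test.
#'
#' @param a,b numeric vectors of the per-session metric under the two
#'   conditions, matched by position (equal length).
#' @return list with `mean_a`, `mean_b`, `sem_a`, `sem_b`, `diff` (mean),
#'   `diff_sem`, and `t_test` (see [tTest()]).
#' @export
compareConditions <- function(a, b) {
  if (length(a) != length(b)) stop("conditions must have matched sessions")
  d <- b - a
  ds <- meanSem(d)
  list(mean_a = mean(a), sem_a = meanSem(a)$sem,
       mean_b = mean(b), sem_b = meanSem(b)$sem,
       diff = ds$mean, diff_sem = ds$sem,
       t_test = tTest(a, b, paired = TRUE))
}
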