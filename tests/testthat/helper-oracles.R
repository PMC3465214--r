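# Independent oracles, written as literal transcriptions so they stay
# independent of the vectorized implementations they check.

# Lag-resolved normalized cross-correlation as an explicit double loop:
# r(d) = sum_t (x(t)-mx)(y(t-d)-my) /
#        sqrt(sum_t (x(t)-mx)^2 * sum_t (y(t-d)-my)^2)
# over the overlapping samples, means on the overlap.
bruteCrossCor <- function(x, y, max_lag) {
  n <- length(x)
  delays <- -max_lag:max_lag
  r <- numeric(length(delays))
  for (k in seq_along(delays)) {
    d <- delays[k]
    ts <- if (d >= 0) (d + 1):n else 1:(n + d)
    xs <- ys <- c()
    for (t in ts) {
      xs <- c(xs, x[t])
      ys <- c(ys, y[t - d])
    }
    mx <- mean(xs); my <- mean(ys)
    num <- 0; dx <- 0; dy <- 0
    for (i in seq_along(xs)) {
      num <- num + (xs[i] - mx) * (ys[i] - my)
      dx <- dx + (xs[i] - mx)^2
      dy <- dy + (ys[i] - my)^2
    }
    r[k] <- num / sqrt(dx * dy)
  }
  list(delays = delays, r = r)
}

brutePeak <- function(bc) {
  best <- 1
  for (k in seq_along(bc$delays)) {
    better <- bc$r[k] > bc$r[best] + 1e-15
    tie <- abs(bc$r[k] - bc$r[best]) <= 1e-15 &&
      (abs(bc$delays[k]) < abs(bc$delays[best]) ||
         (abs(bc$delays[k]) == abs(bc$delays[best]) &&
            bc$delays[k] < bc$delays[best]))
    if (better || tie) best <- k
  }
  list(r = bc$r[best], delay = bc$delays[best])
}

# Per-pixel neighborhood median with border truncation.
bruteMedianFilter <- function(fr, radius) {
  out <- fr
  for (i in seq_len(nrow(fr))) {
    for (j in seq_len(ncol(fr))) {
      vals <- c()
      for (di in -radius:radius) {
        for (dj in -radius:radius) {
          ii <- i + di; jj <- j + dj
          if (ii >= 1 && ii <= nrow(fr) && jj >= 1 && jj <= ncol(fr))
            vals <- c(vals, fr[ii, jj])
        }
      }
      out[i, j] <- median(vals)
    }
  }
  out
}

# Build a DffTraceSet directly from given dF/F traces (bypassing computeDff)
# for tests that need exact control over trace values.
makeDff <- function(dff, frameRate = 10, protocol = NULL,
                    baseline = c(1L, 100L), cellType = NULL,
                    smoothed = TRUE) {
  dff <- as.matrix(dff)
  if (is.null(rownames(dff)))
    rownames(dff) <- sprintf("c%02d", seq_len(nrow(dff)))
  if (is.null(cellType)) cellType <- rep("neuron", nrow(dff))
  raw <- 100 * (1 + dff)
  ts <- TraceSet(raw, cellType, frameRate, protocol = protocol)
  d <- computeDff(ts, baseline_window = baseline)
  # overwrite the dff assay with the exact requested values
  SummarizedExperiment::assays(d)$dff <- dff
  bw <- seq.int(baseline[1], baseline[2])
  SummarizedExperiment::rowData(d)$baseline_sd <-
    apply(dff[, bw, drop = FALSE], 1, sd)
  d@smoothed <- smoothed
  d
}

expectWithin <- function(value, target, tol) {
  expect_lt(abs(value - target), tol,
            label = sprintf("|%.4g - %.4g|", value, target))
}
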