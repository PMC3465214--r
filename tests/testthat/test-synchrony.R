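test_that("autocorrelation at zero lag is exactly one, sign inversion gives -1", {
  set.seed(1)
  x <- rnorm(60)
  cf <- crossCorrelation(x, x, 5)
  expect_equal(cf@r[cf@delays == 0], 1)
  cf2 <- crossCorrelation(x, -x, 5)
  expect_equal(cf2@r[cf2@delays == 0], -1)
})

test_that("a delayed copy is found at its delay with unit overlap correlation", {
  # y(t) = z(t + 2): x(t) matches y(t - 2), so the peak sits at d = 2 with
  # r = 1 on the overlap; an aperiodic source avoids ties
  set.seed(5)
  z <- cumsum(rnorm(14))
  x <- z[1:12]
  y <- z[3:14]
  cf <- crossCorrelation(x, y, 3)
  pk <- peakCoefficient(cf)
  expect_equal(pk$delay, 2)
  expect_equal(pk$r, 1)
  bp <- brutePeak(bruteCrossCor(x, y, 3))
  expect_equal(bp$delay, 2)
})

test_that("the implementation equals a literal brute-force double loop", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    lag <- sample(1:6, 1)
    x <- rnorm(n); y <- rnorm(n)
    cf <- crossCorrelation(x, y, lag)
    bc <- bruteCrossCor(x, y, lag)
    expect_equal(cf@delays, bc$delays)
    expect_equal(cf@r, bc$r, tolerance = 1e-12)
    pk <- peakCoefficient(cf); bp <- brutePeak(bc)
    expect_equal(pk$r, bp$r, tolerance = 1e-12)
    expect_equal(pk$delay, bp$delay)
  }
})

test_that("coefficients are invariant under positive affine transforms", {
  set.seed(7)
  x <- rnorm(80); y <- rnorm(80)
  r0 <- crossCorrelation(x, y, 5)@r
  r1 <- crossCorrelation(3.2 * x + 10, y, 5)@r
  r2 <- crossCorrelation(x, 0.01 * y - 4, 5)@r
  expect_equal(r0, r1, tolerance = 1e-12)
  expect_equal(r0, r2, tolerance = 1e-12)
})

test_that("peak ties break toward smaller |d| and then toward negative d", {
  cf <- new("CorrFunction", delays = -2:2, r = c(0.5, 0.8, 0.2, 0.8, 0.5))
  expect_equal(peakCoefficient(cf)$delay, -1)
  cf2 <- new("CorrFunction", delays = -2:2, r = c(0.8, 0.5, 0.2, 0.5, 0.8))
  expect_equal(peakCoefficient(cf2)$delay, -2)
  cf3 <- new("CorrFunction", delays = -2:2, r = c(0.1, 0.5, 0.9, 0.5, 0.1))
  expect_equal(peakCoefficient(cf3)$delay, 0)
})

test_that("zero-variance windows are rejected and excluded from matrices", {
  expect_error(crossCorrelation(rep(1, 50), rnorm(50), 5), "zero-variance")
  set.seed(3)
  m <- rbind(a = rnorm(100), b = rnorm(100), c = rep(0, 100))
  d <- makeDff(m, baseline = c(1L, 50L))
  expect_warning(cm <- pairwiseMatrix(d), "zero-variance")
  expect_equal(dim(peakR(cm)), c(2, 2))
})

test_that("identical traces give an all-ones matrix with zero delays", {
  tr <- sin(seq(0, 10, length.out = 120))
  m <- rbind(a = tr, b = tr, c = tr)
  d <- makeDff(m + 1e-8 * 0, baseline = c(1L, 50L))
  cm <- pairwiseMatrix(d)
  expect_equal(unname(peakR(cm)), matrix(1, 3, 3))
  expect_true(all(diag(peakDelay(cm)) == 0))
})

test_that("pairwise matrices agree with the brute-force oracle on white noise", {
  set.seed(17)
  m <- matrix(rnorm(4 * 100), 4, 100,
              dimnames = list(sprintf("c%02d", 1:4), NULL))
  d <- makeDff(m, baseline = c(1L, 50L))
  cm <- pairwiseMatrix(d, max_lag = 4)
  for (i in 1:3) for (j in (i + 1):4) {
    bp <- brutePeak(bruteCrossCor(m[i, ], m[j, ], 4))
    expect_equal(unname(peakR(cm)[i, j]), bp$r, tolerance = 1e-12)
    expect_equal(unname(peakDelay(cm)[i, j]), bp$delay)
  }
  # peak picking is positively biased on independent noise
  off <- peakR(cm)[upper.tri(peakR(cm))]
  expect_gt(mean(off), 0)
})

test_that("mean synchrony averages unique pairs or all bipartite entries", {
  mk <- function(m, bip) new("CorrMatrix", peakR = m,
                             peakDelay = m * 0, window = c(1L, 10L),
                             maxLag = 5L, bipartite = bip)
  sq <- matrix(0.6, 2, 2); diag(sq) <- 1
  expect_equal(meanSynchrony(mk(sq, FALSE))$mean, 0.6)
  expect_equal(meanSynchrony(mk(matrix(1, 4, 4), FALSE))$mean, 1)
  blk <- matrix(c(1, 0.2, 0.4, 0.2, 1, 0.6, 0.4, 0.6, 1), 3, 3)
  expect_equal(meanSynchrony(mk(blk, FALSE))$mean, mean(c(0.2, 0.4, 0.6)))
  bip <- matrix(c(0.1, 0.3, 0.5, 0.7), 2, 2)
  expect_equal(meanSynchrony(mk(bip, TRUE))$mean, 0.4)
})

test_that("burst-2 synchrony exceeds burst-1 synchrony in the calibrated scenario", {
  pr <- makeDefaultProtocol(8, 12)
  wins <- list(burstWindow(pr, 1, 10), burstWindow(pr, 2, 10))
  up <- 0
  n_rep <- 12
  for (s in 1:n_rep) {
    dff <- processTraces(simulatePopulation(
      scenarioPreset("S-SYNC-N", seed = 100 + s), pr))
    r <- vapply(wins, function(w)
      meanSynchrony(pairwiseMatrix(dff, window = w))$mean, numeric(1))
    up <- up + (r[2] > r[1])
  }
  expect_gte(up / n_rep, 0.95)
})
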