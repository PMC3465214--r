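pr812 <- makeDefaultProtocol(8, 12)

# ---------------------------------------------------------------- median ----

test_that("median filter leaves constant frames unchanged and removes impulses", {
  fr <- matrix(3, 8, 8)
  expect_equal(medianFilterStack(fr, 1), fr)
  fr[4, 5] <- 100
  out <- medianFilterStack(fr, 1)
  expect_equal(out[4, 5], 3)
  expect_error(medianFilterStack(array(0, c(0, 4, 2))), "non-empty")
})

test_that("median filter equals the per-pixel neighborhood oracle", {
  set.seed(11)
  fr <- matrix(rnorm(81), 9, 9)
  expect_equal(medianFilterStack(fr, 1), bruteMedianFilter(fr, 1))
  expect_equal(medianFilterStack(fr, 2), bruteMedianFilter(fr, 2))
  # and frame-wise on a stack
  st <- array(rnorm(9 * 9 * 3), c(9, 9, 3))
  out <- medianFilterStack(st, 1)
  for (f in 1:3) expect_equal(out[, , f], bruteMedianFilter(st[, , f], 1))
})

# ------------------------------------------------------------- extraction ----

test_that("ROI extraction averages the masked pixels", {
  st <- list(ch1 = array(0, c(6, 6, 4)))
  st$ch1[1:2, 1:2, ] <- 7
  masks <- array(FALSE, c(6, 6, 1)); masks[1:2, 1:2, 1] <- TRUE
  rec <- extractRoiTraces(st, masks, cellType = "neuron")
  expect_equal(unname(rawTraces(rec)[1, ]), rep(7, 4))
  # empty mask and mismatched field are rejected
  expect_error(extractRoiTraces(st, array(FALSE, c(6, 6, 1)),
                                cellType = "neuron"), "empty")
  expect_error(extractRoiTraces(st, array(TRUE, c(8, 8, 1)),
                                cellType = "neuron"), "extent")
})

# ------------------------------------------------------------- background ----

test_that("background subtraction inverts an added drift exactly", {
  cfg <- scenarioConfig(nNeurons = 3, spontDuration = 20, seed = 3)
  ts <- simulatePopulation(cfg)
  drift <- 5 * sin(seq_len(ncol(ts)) / 20)
  drifted <- TraceSet(sweep(rawTraces(ts), 2, drift, "+"),
                      unname(cellTypes(ts)), frameRate(ts))
  rec <- subtractBackground(drifted, drift)
  expect_equal(rawTraces(rec), rawTraces(ts))
  # zero background is the identity
  expect_equal(rawTraces(subtractBackground(ts, rep(0, ncol(ts)))),
               rawTraces(ts))
  # a background equal to a cell's trace zeroes that cell
  rec2 <- subtractBackground(ts, rawTraces(ts)[2, ])
  expect_equal(unname(rawTraces(rec2)[2, ]), rep(0, ncol(ts)))
  expect_error(subtractBackground(ts, 1:3), "length")
})

# ---------------------------------------------------------------- sr101 ----

test_that("SR101 normalization preserves units and cancels shared artefacts", {
  set.seed(4)
  ogb <- 100 + rnorm(200)
  expect_equal(normalizeAstroToSr101(ogb, rep(50, 200)), ogb)
  motion <- 1 + 0.2 * sin(seq_len(200) / 10)
  motion <- motion - mean(motion) + 1  # unit-mean artefact
  expect_equal(normalizeAstroToSr101(ogb * motion, 50 * motion), ogb,
               tolerance = 1e-12)
  expect_error(normalizeAstroToSr101(ogb, rep(0, 200)), "positive")
  expect_error(normalizeAstroToSr101(ogb, rep(50, 100)), "length")
})

test_that("SR101 normalization improves recovery under motion artefacts", {
  set.seed(5)
  clean <- 100 + 20 * sin(seq_len(300) / 15)
  motion <- 1 + 0.3 * sin(seq_len(300) / 7 + 1)
  observed <- clean * motion
  sr <- 50 * motion * (1 + rnorm(300, 0, 0.002))
  fixed <- normalizeAstroToSr101(observed, sr)
  expect_gt(cor(fixed, clean), cor(observed, clean))
  expect_gt(cor(fixed, clean), 0.999)
})

# ------------------------------------------------------------------ dff ----

test_that("dF/F arithmetic matches hand computation", {
  raw <- matrix(100, 1, 120)
  raw[1, 110] <- 150
  ts <- TraceSet(raw, "neuron", 10)
  d <- computeDff(ts, baseline_window = c(1, 100))
  expect_equal(max(dffTraces(d)), 0.5)
  # flat trace gives all zeros
  flat <- computeDff(TraceSet(matrix(80, 1, 120), "neuron", 10))
  expect_equal(unname(dffTraces(flat)[1, ]), rep(0, 120))
})

test_that("dF/F matches an independent spreadsheet-style oracle", {
  raw <- matrix(c(98, 101, 100, 99, 102, 97, 101, 102, 100, 100,
                  150, 120, 95, 130, 160, 140, 110, 105, 100, 99), 1, 20)
  ts <- TraceSet(raw, "neuron", 10)
  d <- computeDff(ts, baseline_window = c(1, 10))
  F0 <- sum(raw[1, 1:10]) / 10
  oracle <- (raw[1, ] - F0) / F0
  expect_equal(unname(dffTraces(d)[1, ]), oracle, tolerance = 1e-12)
  expect_lt(abs(mean(dffTraces(d)[1, 1:10])), 1e-9)
  expect_equal(unname(baselineSd(d)[1]), sd(oracle[1:10]))
})

test_that("dF/F is invariant to positive rescaling of the raw fluorescence", {
  cfg <- scenarioConfig(nNeurons = 4, seed = 6)
  ts <- simulatePopulation(cfg, pr812)
  d1 <- dffTraces(computeDff(ts))
  scaled <- TraceSet(rawTraces(ts) * 37.5, unname(cellTypes(ts)),
                     frameRate(ts), protocol = protocol(ts))
  d2 <- dffTraces(computeDff(scaled))
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("invalid baselines are handled", {
  ts <- TraceSet(matrix(1, 1, 500), "neuron", 10, protocol = pr812)
  expect_error(computeDff(ts, baseline_window = c(1, 110)), "precede")
  expect_error(computeDff(ts, baseline_window = c(1, 5)), "at least 10")
  neg <- TraceSet(matrix(-5, 1, 500), "neuron", 10, protocol = pr812)
  d <- computeDff(neg)
  expect_true(is.na(baselineSd(d)[1]))
})

# --------------------------------------------------------------- smoothing ----

test_that("zero-phase Butterworth smoothing has unit DC gain and the right rolloff", {
  n <- 500
  const <- makeDff(matrix(0.3, 1, n))
  sm <- smoothDff(const)
  expect_equal(unname(dffTraces(sm)[1, ]), rep(0.3, n), tolerance = 1e-9)
  tt <- seq_len(n) / 10
  hi <- makeDff(matrix(sin(2 * pi * 4.5 * tt), 1, n))
  att <- max(abs(dffTraces(smoothDff(hi))[1, 100:400]))
  expect_lt(att, 0.1)   # > 90% attenuation far above the 2 Hz cutoff
  lo <- makeDff(matrix(sin(2 * pi * 0.2 * tt), 1, n))
  keep <- max(abs(dffTraces(smoothDff(lo))[1, 100:400]))
  expect_gt(keep, 0.99) # < 1% loss far below the cutoff
  expect_error(smoothDff(const, cutoff_hz = 5), "Nyquist")
})

test_that("the processing chain reproduces noiseless ground-truth dF/F", {
  cfg <- scenarioConfig(nNeurons = 3, nAstrocytes = 2, noiseSd = 1e-9,
                        rSpontaneous = 0, amplitudeMean = 0.4, seed = 8)
  ts <- simulatePopulation(cfg, pr812)
  gt <- groundTruth(ts)
  k_n <- barrelsync:::.kernelMatrix(pr812, 10, 500, 1, 0)
  k_a <- barrelsync:::.kernelMatrix(pr812, 10, 500, 3, 1)
  dff <- processTraces(ts)
  types <- unname(cellTypes(ts))
  for (i in seq_len(nrow(ts))) {
    K <- if (types[i] == "neuron") k_n else k_a
    truth <- K[, 1] * gt$a1[i] + K[, 2] * gt$a2[i]
    got <- dffTraces(dff)[i, ]
    rms <- sqrt(mean((got - truth)^2)) / max(truth)
    expect_lt(rms, 0.01)
  }
})

# --------------------------------------------------------------- activity ----

test_that("activation needs 500 ms of sustained supra-threshold signal", {
  n <- 300
  base <- matrix(rnorm(2 * n, 0, 0.01), 2, n)
  base[1, 150:153] <- 0.2   # 4 consecutive frames at 10 Hz: too short
  base[2, 150:154] <- 0.2   # 5 consecutive frames: active
  d <- makeDff(base, baseline = c(1L, 100L))
  act <- detectActiveCells(d, k_sd = 2.5, min_duration_s = 0.5)
  expect_false(unname(act[1]))
  expect_true(unname(act[2]))
})

test_that("white-noise traces are almost never called active", {
  set.seed(123)
  n_cells <- 1000
  noise <- matrix(rnorm(n_cells * 300, 0, 0.05), n_cells, 300)
  d <- makeDff(noise, baseline = c(1L, 100L), smoothed = FALSE)
  act <- detectActiveCells(d)
  expect_lt(mean(act), 0.01)  # false-positive rate below 1%
})

test_that("zero-variance cells are flagged invalid", {
  d <- makeDff(matrix(0, 1, 200))
  expect_true(is.na(detectActiveCells(d)[1]))
})

test_that("activation recovers responsive cells with high sensitivity and specificity", {
  sens <- spec <- c()
  for (s in 1:3) {
    cfg <- scenarioPreset("S-FREQ", seed = s)
    cfg@pSilent <- 0.3
    ts <- simulatePopulation(cfg, pr812)
    act <- detectActiveCells(processTraces(ts))
    silent <- groundTruth(ts)$pattern == "silent"
    sens <- c(sens, mean(act[!silent]))
    spec <- c(spec, mean(!act[silent]))
  }
  expect_gte(mean(sens), 0.95)
  expect_gte(mean(spec), 0.95)
})
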