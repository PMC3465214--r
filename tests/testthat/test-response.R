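pr812 <- makeDefaultProtocol(8, 12)

test_that("R2 is measured above the residual of response one", {
  # peak1 0.5, residual 0.1 in the last second before burst 2, peak2 0.6
  tr <- numeric(500)
  tr[101:200] <- 0.5 * sin(pi * (1:100) / 100)  # R1 peak 0.5
  tr[201:300] <- 0.1                             # residual level 0.1
  tr[301:400] <- 0.1 + 0.5 * sin(pi * (1:100) / 100)  # peak 0.6
  d <- makeDff(matrix(tr, 1, 500), protocol = pr812)
  resp <- measurePairedResponses(d)
  expect_equal(resp$R1, 0.5, tolerance = 1e-6)
  expect_equal(resp$residual, 0.1, tolerance = 1e-6)
  expect_equal(resp$R2, 0.5, tolerance = 1e-6)
})

test_that("a flat trace yields zero responses and a decaying trace floors R2 at 0", {
  d <- makeDff(matrix(0, 1, 500), protocol = pr812)
  resp <- measurePairedResponses(d)
  expect_equal(resp$R1, 0)
  expect_equal(resp$R2, 0)
  # decay below the residual in the burst-2 window
  tr <- numeric(500); tr[200:290] <- 0.4; tr[291:500] <- 0.4 * exp(-(1:210) / 20)
  d2 <- makeDff(matrix(tr, 1, 500), protocol = pr812)
  r2 <- measurePairedResponses(d2)
  expect_equal(r2$R2, 0)
  expect_true(r2$floored)
})

test_that("protocols without exactly two bursts are rejected", {
  one <- StimulusProtocol(data.frame(onset_s = 10, duration_s = 10,
                                     pulse_freq_hz = 8, pulse_width_ms = 50),
                          30)
  d <- makeDff(matrix(0, 1, 300))
  expect_error(measurePairedResponses(d, one), "exactly 2")
})

test_that("the 2-SD rule classifies increment, decrement and parallel", {
  mk <- function(R1, R2, sd) data.frame(R1 = R1, R2 = R2, baseline_sd = sd)
  expect_equal(classifyPattern(mk(0.3, 0.5, 0.05))$pattern, "increment")
  expect_equal(classifyPattern(mk(0.5, 0.3, 0.05))$pattern, "decrement")
  expect_equal(classifyPattern(mk(0.4, 0.4, 0.05))$pattern, "parallel")
  # boundary: difference 0.09 below the 2 * 0.05 threshold
  expect_equal(classifyPattern(mk(0.50, 0.41, 0.05))$pattern, "parallel")
  # exactly at the threshold is still parallel (strict inequality)
  expect_equal(classifyPattern(mk(0.50, 0.60, 0.05))$pattern, "parallel")
})

test_that("classification is antisymmetric under swapping R1 and R2", {
  set.seed(9)
  for (i in 1:200) {
    R1 <- runif(1); R2 <- runif(1); s <- runif(1, 0.01, 0.2)
    a <- classifyPattern(data.frame(R1 = R1, R2 = R2, baseline_sd = s))$pattern
    b <- classifyPattern(data.frame(R1 = R2, R2 = R1, baseline_sd = s))$pattern
    expect_equal(b, switch(a, increment = "decrement",
                           decrement = "increment", parallel = "parallel"))
  }
})

test_that("pattern portions are counted, averaged and sum to 100", {
  one <- summarizePatterns(list(c("increment", "increment", "decrement",
                                  "parallel")))
  expect_equal(unname(one$mean), c(25, 50, 25))  # dec / inc / par
  expect_equal(sum(one$per_session[1, ]), 100)
  # the same-frequency control composition: 2 inc / 18 dec / 4 par of 24
  ctrl <- summarizePatterns(list(rep(c("increment", "decrement", "parallel"),
                                     c(2, 18, 4))))
  expect_equal(unname(round(ctrl$mean, 1)), c(75.0, 8.3, 16.7))
  # identical sessions give zero SEM
  lab <- rep(c("increment", "decrement"), c(3, 1))
  two <- summarizePatterns(list(lab, lab))
  expect_equal(unname(two$sem), c(0, 0, 0))
  expect_equal(two$ratio_inc_dec$mean, 3)
  # empty sessions are excluded with a warning
  expect_warning(summarizePatterns(list(lab, character(0))), "excluded")
  expect_error(summarizePatterns(list(character(0))), "at least one")
})
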