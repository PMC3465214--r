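mkCorr <- function(m, bip = FALSE) {
  new("CorrMatrix", peakR = m, peakDelay = m * 0L,
      window = c(1L, 100L), maxLag = 5L, bipartite = bip)
}

test_that("the spontaneous threshold is mean + 2 sample SD", {
  expect_equal(spontaneousThreshold(c(0.2, 0.2, 0.2)), 0.2)
  expect_equal(spontaneousThreshold(c(0.1, 0.3)),
               0.2 + 2 * sqrt(((0.1 - 0.2)^2 + (0.3 - 0.2)^2) / 1),
               tolerance = 1e-12)
  expect_equal(round(spontaneousThreshold(c(0.1, 0.3)), 4), 0.4828)
  expect_error(spontaneousThreshold(0.5), "at least 2")
})

test_that("binarization is strict and enforces square-network structure", {
  expect_equal(sum(binarize(matrix(c(0, 0.5, 0.5, 0), 2, 2), 0.3)@adjacency),
               2)
  # exactly at the threshold gives no edge
  m <- matrix(c(0, 0.3, 0.3, 0), 2, 2)
  expect_equal(sum(binarize(m, 0.3)@adjacency), 0)
  # all-negative coefficients with a non-negative threshold: empty graph
  neg <- -abs(matrix(rnorm(16), 4, 4)); diag(neg) <- 1
  neg <- (neg + t(neg)) / 2; diag(neg) <- 1
  expect_equal(sum(binarize(neg, 0)@adjacency), 0)
  # diagonal forced to zero even though r_ii = 1 > thresh
  full <- matrix(0.9, 3, 3)
  expect_equal(diag(binarize(full, 0.5)@adjacency), c(0, 0, 0))
})

test_that("network percentages match hand enumeration", {
  cg <- matrix(1, 5, 5); diag(cg) <- 0
  m <- networkMetrics(new("FunctionalNetwork", adjacency = cg, thresh = 0.5,
                          rowType = "neuron", colType = "neuron",
                          bipartite = FALSE))
  expect_equal(m$Pn, 100); expect_equal(m$Pk, 100)
  empty <- networkMetrics(new("FunctionalNetwork",
                              adjacency = matrix(0, 4, 4), thresh = 0.5,
                              rowType = "neuron", colType = "neuron",
                              bipartite = FALSE))
  expect_equal(empty$Pn, 0); expect_equal(empty$Pk, 0)
  # path a-b-c-d: degrees 1,2,2,1, k = 1.5
  path <- matrix(0, 4, 4)
  path[cbind(c(1, 2, 2, 3, 3, 4), c(2, 1, 3, 2, 4, 3))] <- 1
  pm <- networkMetrics(new("FunctionalNetwork", adjacency = path,
                           thresh = 0.5, rowType = "neuron",
                           colType = "neuron", bipartite = FALSE))
  expect_equal(pm$n, 4); expect_equal(pm$k, 1.5)
  expect_equal(pm$Pn, 100); expect_equal(pm$Pk, 50)
  # bipartite link fraction
  bip <- matrix(c(1, 0, 0, 1, 1, 0), 2, 3)
  bm <- networkMetrics(new("FunctionalNetwork", adjacency = bip,
                           thresh = 0.5, rowType = "astrocyte",
                           colType = "neuron", bipartite = TRUE))
  expect_equal(bm$l, 3); expect_equal(bm$Pl, 50)
  expect_error(networkMetrics(new("FunctionalNetwork",
                                  adjacency = matrix(0, 1, 1), thresh = 0,
                                  rowType = "neuron", colType = "neuron",
                                  bipartite = FALSE)), "at least 2")
})

test_that("k can alternatively average over connected neurons only", {
  path <- matrix(0, 4, 4)
  path[cbind(c(1, 2), c(2, 1))] <- 1  # one edge, two isolated
  net <- new("FunctionalNetwork", adjacency = path, thresh = 0.5,
             rowType = "neuron", colType = "neuron", bipartite = FALSE)
  expect_equal(networkMetrics(net)$k, 0.5)
  expect_equal(networkMetrics(net, connected_only = TRUE)$k, 1)
})

test_that("raising the threshold never increases n, k or l", {
  set.seed(21)
  for (rep in 1:10) {
    m <- matrix(runif(64, -1, 1), 8, 8)
    m <- (m + t(m)) / 2; diag(m) <- 1
    ths <- sort(runif(5, -1, 1))
    prev <- NULL
    for (th in ths) {
      met <- networkMetrics(binarize(mkCorr(m), th))
      if (!is.null(prev)) {
        expect_lte(met$n, prev$n)
        expect_lte(met$k, prev$k)
      }
      prev <- met
    }
    # P_k = 100% iff the graph on activated neurons is complete
    met0 <- networkMetrics(binarize(mkCorr(m), min(m) - 1))
    expect_equal(met0$Pk, 100)
    A <- binarize(mkCorr(m), min(m) - 1)@adjacency
    expect_true(all(A[upper.tri(A)] == 1))
  }
})

test_that("matched-condition comparison handles regular and degenerate inputs", {
  same <- compareConditions(c(40, 50, 60), c(40, 50, 60))
  expect_equal(same$diff, 0)
  expect_equal(same$t_test$p, 1)
  expect_equal(same$t_test$flag, "zero-variance identical samples")
  expect_warning(shift <- compareConditions(c(40, 50), c(50, 60)))
  expect_equal(shift$diff, 10)
  expect_equal(shift$diff_sem, 0)
  expect_error(compareConditions(1:3, 1:4), "matched")
})

test_that("burst 2 yields more functional connectivity than burst 1 in S-CONN", {
  pr <- makeDefaultProtocol(8, 12)
  up <- 0; n_rep <- 8
  for (s in 1:n_rep) {
    cfg <- scenarioPreset("S-CONN", seed = 200 + s)
    dff <- processTraces(simulatePopulation(cfg, pr))
    types <- cellTypes(dff)
    nI <- names(types)[types == "neuron"]
    spontCfg <- scenarioPreset("S-CONN", seed = 1200 + s)
    spont <- processTraces(simulatePopulation(spontCfg, NULL))
    th <- spontaneousThreshold(pairwiseMatrix(spont, nI))
    pk <- vapply(1:2, function(b)
      networkMetrics(binarize(pairwiseMatrix(
        dff, nI, window = burstWindow(pr, b, 10)), th))$Pk, numeric(1))
    up <- up + (pk[2] > pk[1])
  }
  expect_gte(up / n_rep, 0.95)
})
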