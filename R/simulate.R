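#' Simulate a population of calcium traces
#'
#' Generates seeded raw fluorescence traces for a mixed neuron/astrocyte
#' population with known ground truth. Each cell's relative fluorescence is
#'
#' \deqn{dF/F_i(t) = \sum_b a_{i,b} K_{type}(t; b) + \lambda_i(t) C(t) +
#'   \epsilon_i(t)}
#'
#' where \eqn{K_{type}} is the burst pulse train convolved with an
#' exponential calcium kernel (unit plateau; astrocytes use a slower kernel
#' and an onset lag), \eqn{a_{i,b}} encodes the ground-truth response pattern
#' (increment: \eqn{a_2 = a_1(1+\delta)}; decrement: \eqn{a_2 =
#' a_1(1-\delta)}; parallel: \eqn{a_2 = a_1}), \eqn{C(t)} is a shared latent
#' component (standard normal per frame) whose loading \eqn{\lambda_i(t)} is
#' solved from the Pearson mixing identity to hit the scenario's correlation
#' targets, and \eqn{\epsilon} is independent noise. Raw fluorescence is
#' \eqn{F_i(t) = F_0 (1 + dF/F_i(t))}; astrocytes additionally get a nearly
#' constant SR101 channel. Output is bit-identical for identical
#' configuration and seed.
#'
#' @param cfg a [ScenarioConfig-class].
#' @param protocol a [StimulusProtocol-class], or `NULL` for a spontaneous
#'   recording of `cfg@spontDuration` seconds.
#' @param seed optional seed overriding `cfg@seed`.
#' @return a [TraceSet-class] with ground truth in its metadata.
#' @examples
#' ts <- simulatePopulation(scenarioPreset("S-SYNC-N", seed = 1),
#'                          makeDefaultProtocol(8, 12))
#' ts
#' @export
simulatePopulation <- function(cfg, protocol = NULL, seed = NULL) {
  stopifnot(is(cfg, "ScenarioConfig"))
  validObject(cfg)
  if (!is.null(seed)) cfg@seed <- seed
  set.seed(as.integer(cfg@seed))
  fs <- cfg@frameRate
  n <- if (is.null(protocol)) round(cfg@spontDuration * fs)
       else round(totalDuration(protocol) * fs)
  nN <- cfg@nNeurons; nA <- cfg@nAstrocytes
  nc <- nN + nA
  if (nc < 1) stop("at least one cell is required")
  types <- c(rep("neuron", nN), rep("astrocyte", nA))
  ids <- sprintf("%s%02d", ifelse(types == "neuron", "n", "a"),
                 c(seq_len(nN), seq_len(nA)))

  calib <- calibrateScenario(cfg, protocol)
  seg <- .segmentLabels(protocol, fs, n)
  # contiguous blocks (baseline / burst 1 / gap / burst 2 / post): variance
  # pinning and noise conditioning act per block, not per pooled segment
  blk <- with(rle(seg), rep(seq_along(lengths), lengths))

  # ground-truth pattern classes and per-burst amplitudes
  classes <- character(nc); a1 <- numeric(nc); a2 <- numeric(nc)
  for (i in seq_len(nc)) {
    pp <- if (types[i] == "neuron") cfg@patternProbsNeurons
          else cfg@patternProbsAstrocytes
    if (stats::runif(1) < cfg@pSilent) {
      classes[i] <- "silent"
    } else {
      classes[i] <- sample(c("increment", "decrement", "parallel"), 1,
                           prob = pp)
    }
    amp <- calib$amplitude
    if (cfg@amplitudeCv > 0) {
      sl <- sqrt(log(1 + cfg@amplitudeCv^2))
      amp <- amp * exp(stats::rnorm(1, -sl^2 / 2, sl))
    }
    a1[i] <- if (classes[i] == "silent") 0 else amp
    a2[i] <- switch(classes[i],
                    increment = a1[i] * (1 + cfg@deltaRel),
                    decrement = a1[i] * (1 - cfg@deltaRel),
                    a1[i])
  }

  # per-cell latent loading multipliers (manual mode: log-normal, mean 1)
  u <- rep(1, nc)
  manual <- identical(cfg@calibration, "manual")
  if (manual && !is.null(cfg@loadings$sigmaL) && cfg@loadings$sigmaL > 0) {
    sL <- cfg@loadings$sigmaL
    u <- exp(stats::rnorm(nc, -sL^2 / 2, sL))
  }

  Klist <- list()
  if (!is.null(protocol)) {
    Klist$neuron <- .kernelMatrix(protocol, fs, n, cfg@tauNeuron, 0)
    Klist$astrocyte <- .kernelMatrix(protocol, fs, n, cfg@tauAstro,
                                     cfg@astroLag)
  }

  # Shared latent component, conditioned per stimulus segment so that the
  # designed pair correlations are realized (not merely expected) in every
  # session: zero mean and unit variance in the raw domain, then (i) the
  # sample covariance with the smoothed evoked kernels inside each burst
  # window is projected out — the smoother is linear, so subtracting a
  # multiple of the raw kernel does this exactly — and (ii) the realized
  # variance after the default smoother is pinned to its nominal value.
  # Without this the evoked-latent cross-products and the sampled variance
  # of the smoothed latent dominate session-to-session dispersion of
  # short-window synchrony summaries.
  lpPin <- .lowpassFilter(2, 4, fs)
  gPin <- sqrt(calib$gain[1])
  pinSmoothed <- function(x, idx) {
    for (iter in 1:3) {
      xs <- .zeroPhase(x, lpPin)
      x[idx] <- x[idx] - mean(xs[idx])
      xs <- .zeroPhase(x, lpPin)
      x[idx] <- x[idx] * gPin / stats::sd(xs[idx])
    }
    x
  }
  C <- stats::rnorm(n)
  for (bk in unique(blk)) {
    idx <- which(blk == bk)
    if (length(idx) >= 3) C[idx] <- (C[idx] - mean(C[idx])) / stats::sd(C[idx])
  }
  if (!is.null(protocol)) {
    Kn_sm <- apply(Klist$neuron, 2, .zeroPhase, filt = lpPin)
    Ka_sm <- apply(Klist$astrocyte, 2, .zeroPhase, filt = lpPin)
    KsAll <- cbind(if (nN > 0) Kn_sm, if (nA > 0) Ka_sm)
    KrAll <- cbind(if (nN > 0) Klist$neuron, if (nA > 0) Klist$astrocyte)
    for (bk in unique(blk)) {
      w <- which(blk == bk)
      # kernel columns with appreciable variance in this block (burst
      # windows and decay tails reaching into the following block); the
      # subtraction is block-local so ill-conditioned fits on faint tails
      # cannot perturb other windows
      keep <- apply(KsAll[w, , drop = FALSE], 2, stats::sd) > 0.02
      if (!any(keep)) next
      Cs <- .zeroPhase(C, lpPin)
      beta <- stats::lm.fit(cbind(1, KsAll[w, keep, drop = FALSE]),
                            Cs[w])$coefficients[-1]
      beta[is.na(beta)] <- 0
      C[w] <- C[w] - as.vector(KrAll[w, keep, drop = FALSE] %*% beta)
    }
  }
  for (bk in unique(blk)) {
    idx <- which(blk == bk)
    if (length(idx) >= 10) C <- pinSmoothed(C, idx)
  }

  # assembly-structured coupling: each assembly shares its own latent,
  # active (and variance-pinned) within the corresponding burst window
  assemblyMode <- identical(cfg@calibration, "assembly")
  D <- NULL; memb <- NULL
  if (assemblyMode && !is.null(protocol)) {
    B <- nBursts(protocol)
    memb <- matrix(0L, nc, B)
    for (b in seq_len(B)) {
      gsN <- cfg@loadings$neuronAssemblies[[b]]
      for (gI in seq_along(gsN))
        if (length(gsN[[gI]]) > 0) memb[gsN[[gI]], b] <- gI
      gsA <- cfg@loadings$astroAssemblies[[b]]
      for (gI in seq_along(gsA))
        if (length(gsA[[gI]]) > 0) memb[nN + gsA[[gI]], b] <- gI
    }
    D <- vector("list", B)
    for (b in seq_len(B)) {
      w <- burstWindow(protocol, b, fs)
      nGb <- max(memb[, b], 1L)
      Db <- matrix(0, n, nGb)
      Xs <- cbind(Kn_sm[w, b], Ka_sm[w, b])
      Xr <- cbind(Klist$neuron[w, b], Klist$astrocyte[w, b])
      for (gI in seq_len(nGb)) {
        z <- stats::rnorm(length(w))
        Db[w, gI] <- (z - mean(z)) / stats::sd(z)
        zs <- .zeroPhase(Db[, gI], lpPin)
        beta <- stats::lm.fit(cbind(1, Xs), zs[w])$coefficients[-1]
        Db[w, gI] <- Db[w, gI] - as.vector(Xr %*% beta)
        Db[, gI] <- pinSmoothed(Db[, gI], w)
      }
      D[[b]] <- Db
    }
  }
  # Independent noise, drawn as a block and conditioned per segment: the
  # cell noise vectors are made exactly mutually uncorrelated and orthogonal
  # to the latent components and evoked kernels within each segment (QR on
  # the residualized block — the same exact-sample device as drawing
  # multivariate normals with empirical moments), then pinned to the nominal
  # SD. This removes the sampled pair-level cross-products that would
  # otherwise bias and disperse short-window peak-correlation estimates.
  eps <- matrix(stats::rnorm(nc * n), nc, n)
  for (bk in unique(blk)) {
    idx <- which(blk == bk)
    sg <- seg[idx[1]]
    X <- cbind(1, C[idx])
    if (!is.null(protocol)) {
      X <- cbind(X, Klist$neuron[idx, , drop = FALSE])
      if (nA > 0) X <- cbind(X, Klist$astrocyte[idx, , drop = FALSE])
      if (assemblyMode && sg > 0)
        X <- cbind(X, D[[sg]][idx, , drop = FALSE])
    }
    X <- X[, colSums(abs(X)) > 0, drop = FALSE]
    if (length(idx) < nc + ncol(X) + 2) next
    qx <- qr(X)
    Qx <- qr.Q(qx)[, seq_len(qx$rank), drop = FALSE]
    E <- eps[, idx, drop = FALSE]
    E <- E - (E %*% Qx) %*% t(Qx)
    Q <- qr.Q(qr(t(E)))[, seq_len(nc), drop = FALSE]
    eps[, idx] <- t(Q) / apply(Q, 2, stats::sd)
  }

  dff <- matrix(0, nc, n, dimnames = list(ids, NULL))
  for (i in seq_len(nc)) {
    # manual (heterogeneous) scenarios keep each cell's coupling multiplier
    # at rest as well, so spontaneous recordings of the same population show
    # the same across-pair dispersion that the connection threshold sees;
    # astrocytes can carry a stronger resting coupling (gap junctions)
    rest <- 1
    if (manual) {
      rest <- u[i]
      if (types[i] == "astrocyte" && !is.null(cfg@loadings$astroRest))
        rest <- rest * cfg@loadings$astroRest
    }
    lam <- rep(calib$alphaSpont * rest, n)
    if (!is.null(protocol)) {
      inb <- seg > 0
      if (manual) {
        beta <- cfg@loadings$beta
        sc <- if (types[i] == "astrocyte" &&
                  !is.null(cfg@loadings$astroScale))
          cfg@loadings$astroScale else 1
        lam[inb] <- u[i] * sc * beta[seg[inb]]
      } else {
        ab <- calib$alphaBurst[[types[i]]]
        lam[inb] <- ab[seg[inb]]
      }
    }
    ev <- 0
    if (!is.null(protocol)) {
      K <- Klist[[types[i]]]
      ev <- K[, 1] * a1[i] + if (ncol(K) >= 2) K[, 2] * a2[i] else 0
    }
    dff[i, ] <- ev + lam * C + cfg@noiseSd * eps[i, ]
    if (assemblyMode && !is.null(protocol))
      for (b in seq_len(ncol(memb)))
        if (memb[i, b] > 0)
          dff[i, ] <- dff[i, ] + calib$gammaStrong[b] * D[[b]][, memb[i, b]]
  }

  raw <- cfg@f0 * (1 + dff)
  sr101 <- NULL
  if (nA > 0) {
    sr101 <- matrix(NA_real_, nc, n, dimnames = list(ids, NULL))
    for (i in which(types == "astrocyte"))
      sr101[i, ] <- 50 * (1 + stats::rnorm(n, 0, 0.002))
  }

  gt <- list(pattern = setNames(classes, ids),
             a1 = setNames(a1, ids), a2 = setNames(a2, ids),
             loadingMultiplier = setNames(u, ids),
             assemblyMembership = memb,
             calibration = calib, seed = cfg@seed,
             config = cfg)
  TraceSet(raw, types, fs, protocol = protocol, sr101 = sr101,
           groundTruth = gt)
}
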