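#' Create a synthetic-scenario configuration
#'
#' Constructor for [ScenarioConfig-class] with defaults matching the
#' 8-to-12 Hz study conditions: 10 Hz frame rate, single-exponential calcium
#' kernels (tau 1 s neurons, 3 s astrocytes, 1 s astrocyte onset lag),
#' baseline fluorescence 100 a.u., and a spontaneous pairwise correlation of
#' 0.25.
#'
#' @param nNeurons,nAstrocytes population sizes.
#' @param patternProbsNeurons,patternProbsAstrocytes length-3 probabilities
#'   (increment, decrement, parallel).
#' @param pSilent probability of an unresponsive cell.
#' @param amplitudeMean,amplitudeCv evoked plateau amplitude (dF/F) and its
#'   lognormal coefficient of variation across cells.
#' @param deltaRel relative R2 vs R1 step for increment / decrement cells.
#' @param noiseSd independent per-frame noise SD (dF/F).
#' @param tauNeuron,tauAstro,astroLag calcium kinetics (s).
#' @param frameRate frame rate (Hz).
#' @param f0 baseline fluorescence (a.u.).
#' @param rWithinNeurons,rWithinAstrocytes,rNeuronAstro length-2 per-burst
#'   Pearson targets (NA = uncalibrated).
#' @param rEpochCross optional between-type target over the full stimulation
#'   epoch (solves the amplitude).
#' @param rSpontaneous Pearson target without stimulation.
#' @param spontDuration duration of spontaneous recordings (s).
#' @param calibration calibration mode, see [ScenarioConfig-class].
#' @param loadings manual-mode loading parameters.
#' @param seed RNG seed.
#' @return a [ScenarioConfig-class].
#' @export
scenarioConfig <- function(nNeurons = 20, nAstrocytes = 0,
                           patternProbsNeurons = c(0, 0, 1),
                           patternProbsAstrocytes = c(0, 0, 1),
                           pSilent = 0,
                           amplitudeMean = 0.3, amplitudeCv = 0,
                           deltaRel = 0.4, noiseSd = 0.05,
                           tauNeuron = 1, tauAstro = 3, astroLag = 1,
                           frameRate = 10, f0 = 100,
                           rWithinNeurons = c(NA_real_, NA_real_),
                           rWithinAstrocytes = c(NA_real_, NA_real_),
                           rNeuronAstro = c(NA_real_, NA_real_),
                           rEpochCross = NA_real_,
                           rSpontaneous = 0.25, spontDuration = 100,
                           calibration = "spont", loadings = list(),
                           seed = 1) {
  new("ScenarioConfig", nNeurons = nNeurons, nAstrocytes = nAstrocytes,
      patternProbsNeurons = patternProbsNeurons,
      patternProbsAstrocytes = patternProbsAstrocytes, pSilent = pSilent,
      amplitudeMean = amplitudeMean, amplitudeCv = amplitudeCv,
      deltaRel = deltaRel, noiseSd = noiseSd, tauNeuron = tauNeuron,
      tauAstro = tauAstro, astroLag = astroLag, frameRate = frameRate,
      f0 = f0, rWithinNeurons = rWithinNeurons,
      rWithinAstrocytes = rWithinAstrocytes, rNeuronAstro = rNeuronAstro,
      rEpochCross = rEpochCross, rSpontaneous = rSpontaneous,
      spontDuration = spontDuration, calibration = calibration,
      loadings = loadings, seed = seed)
}

#' Shipped scenario presets
#'
#' Named presets, one per figure family of the study design, each calibrated
#' via the closed-form Pearson mixing identity (see [calibrateScenario()]):
#' \describe{
#'   \item{S-FREQ}{8-to-12 Hz mixed population for response-pattern
#'     classification; ground-truth fractions 0.619/0.215/0.166
#'     (increment/decrement/parallel) for neurons and 0.634/0.22/0.146 for
#'     astrocytes.}
#'   \item{S-SYNC-N}{neuron-only synchrony scenario, within-type per-burst
#'     Pearson targets 0.75 (8 Hz) and 0.80 (12 Hz).}
#'   \item{S-SYNC-A}{astrocyte-only synchrony scenario, targets 0.92 and
#'     0.96.}
#'   \item{S-SYNC-NA}{mixed population with between-type per-burst targets
#'     0.31 and 0.37, full-stimulation-epoch target 0.40 (amplitude solved),
#'     and spontaneous target 0.25.}
#'   \item{S-CONN}{mixed population with assembly-structured coupling:
#'     per burst, fixed-size cell assemblies share a strong latent at the
#'     stimulated synchrony levels (0.75 / 0.80) while non-assembly pairs
#'     keep a diffuse sub-threshold coupling, so the functional-network
#'     edge fractions under the spontaneous mean + 2 SD threshold are
#'     designed quantities matching the connectivity percentages.}
#'   \item{S-SAME}{8-to-8 Hz control, decrement-dominant pattern fractions
#'     2/18/4 of 24.}
#' }
#' The LFP scenario is provided by [simulateLfp()] defaults.
#'
#' @param name preset name.
#' @param seed RNG seed stored in the returned config.
#' @return a [ScenarioConfig-class].
#' @export
scenarioPreset <- function(name = c("S-FREQ", "S-SYNC-N", "S-SYNC-A",
                                    "S-SYNC-NA", "S-CONN", "S-SAME"),
                           seed = 1) {
  name <- match.arg(name)
  switch(name,
    "S-FREQ" = scenarioConfig(
      nNeurons = 30, nAstrocytes = 16,
      patternProbsNeurons = c(0.619, 0.215, 0.166),
      patternProbsAstrocytes = c(0.634, 0.220, 0.146),
      amplitudeMean = 0.5, amplitudeCv = 0.2, deltaRel = 0.4,
      calibration = "spont", seed = seed),
    "S-SYNC-N" = scenarioConfig(
      nNeurons = 20, nAstrocytes = 0, amplitudeMean = 0.2,
      rWithinNeurons = c(0.75, 0.80), calibration = "within", seed = seed),
    "S-SYNC-A" = scenarioConfig(
      nNeurons = 0, nAstrocytes = 12, amplitudeMean = 0.2,
      rWithinAstrocytes = c(0.92, 0.96), calibration = "within", seed = seed),
    "S-SYNC-NA" = scenarioConfig(
      nNeurons = 12, nAstrocytes = 8, amplitudeMean = 0.2,
      rNeuronAstro = c(0.31, 0.37), rEpochCross = 0.40,
      calibration = "cross", seed = seed),
    "S-CONN" = scenarioConfig(
      nNeurons = 13, nAstrocytes = 8, amplitudeMean = 0.072,
      noiseSd = 0.03, rSpontaneous = 0.53, spontDuration = 150,
      calibration = "assembly",
      loadings = list(
        rWeakBurst = c(0.39, 0.39), rStrong = c(0.75, 0.80),
        neuronAssemblies = list(b1 = list(1:7, 8:12),
                                b2 = list(1:11, 12:13)),
        astroAssemblies = list(b1 = list(1:4, 5:6),
                               b2 = list(1:5, integer(0)))),
      seed = seed),
    "S-SAME" = scenarioConfig(
      nNeurons = 24, nAstrocytes = 0,
      patternProbsNeurons = c(2, 18, 4) / 24,
      amplitudeMean = 0.5, amplitudeCv = 0.2, deltaRel = 0.4,
      calibration = "spont", seed = seed))
}

#' Default protocol of a preset
#'
#' The paired 8-to-12 Hz protocol for all presets except the S-SAME control,
#' which uses 8-to-8 Hz.
#'
#' @param name preset name as in [scenarioPreset()].
#' @export
presetProtocol <- function(name) {
  if (identical(name, "S-SAME")) makeDefaultProtocol(8, 8)
  else makeDefaultProtocol(8, 12)
}
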