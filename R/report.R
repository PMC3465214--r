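# Descriptive and inferential statistics, and the end-to-end pipeline
# orchestrator.

#' Mean and standard error of the mean
#'
#' SEM uses the sample SD (n - 1 denominator) divided by sqrt(n). With a
#' single value the SEM is undefined and flagged as NA.
#'
#' @param values numeric vector, length >= 1.
#' @return list with `mean`, `sem`, `n`.
#' @export
meanSem <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1) stop("at least one value is required")
  list(mean = mean(values),
       sem = if (length(values) < 2) NA_real_
             else stats::sd(values) / sqrt(length(values)),
       n = length(values))
}

#' Two-tailed Student's t test
#'
#' Paired, or unpaired assuming unequal variances (Welch). Degenerate cases
#' are handled explicitly: identical paired samples give t = 0, p = 1 with a
#' zero-variance flag; paired samples whose differences are a non-zero
#' constant are flagged and reported as p -> 0 with a warning.
#'
#' @param a,b numeric samples (paired requires equal lengths >= 2).
#' @param paired logical.
#' @return list with `t`, `df`, `p`, `paired`, `flag` (NA when regular).
#' @export
tTest <- function(a, b, paired = FALSE) {
  if (paired) {
    if (length(a) != length(b)) stop("paired samples must have equal length")
    if (length(a) < 2) stop("insufficient n for a t test")
    d <- b - a
    if (stats::sd(d) == 0) {
      if (all(d == 0))
        return(list(t = 0, df = length(d) - 1L, p = 1, paired = TRUE,
                    flag = "zero-variance identical samples"))
      warning("paired differences are a non-zero constant; p reported as 0")
      return(list(t = sign(mean(d)) * Inf, df = length(d) - 1L, p = 0,
                  paired = TRUE, flag = "zero-variance constant difference"))
    }
    ht <- stats::t.test(b, a, paired = TRUE)
  } else {
    if (length(a) < 2 || length(b) < 2) stop("insufficient n for a t test")
    ht <- stats::t.test(a, b, var.equal = FALSE)
  }
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, paired = paired, flag = NA_character_)
}

# Per-session imaging analysis shared by the pipeline: process, detect,
# classify, and build per-burst correlation matrices over active cells.
.analyzeSession <- function(ts, max_lag = 5L, k_sd_active = 2.5,
                            k_sd_pattern = 2, active_only = TRUE) {
  pr <- protocol(ts)
  dff <- processTraces(ts)
  act <- detectActiveCells(dff, k_sd = k_sd_active)
  resp <- classifyPattern(measurePairedResponses(dff), k_sd = k_sd_pattern)
  keep <- if (active_only) names(act)[!is.na(act) & act] else names(act)
  types <- cellTypes(dff)
  nIds <- intersect(keep, names(types)[types == "neuron"])
  aIds <- intersect(keep, names(types)[types == "astrocyte"])
  fs <- frameRate(dff)
  mats <- list()
  for (b in 1:2) {
    w <- burstWindow(pr, b, fs)
    if (length(nIds) >= 2)
      mats[[paste0("nn_b", b)]] <- pairwiseMatrix(dff, nIds, window = w,
                                                  max_lag = max_lag)
    if (length(aIds) >= 2)
      mats[[paste0("aa_b", b)]] <- pairwiseMatrix(dff, aIds, window = w,
                                                  max_lag = max_lag)
    if (length(nIds) >= 1 && length(aIds) >= 1)
      mats[[paste0("na_b", b)]] <- pairwiseMatrix(dff, aIds, nIds,
                                                  window = w,
                                                  max_lag = max_lag)
  }
  if (length(nIds) >= 1 && length(aIds) >= 1)
    mats[["na_epoch"]] <- pairwiseMatrix(dff, aIds, nIds,
                                         window = stimulationEpoch(pr, fs),
                                         max_lag = max_lag)
  list(dff = dff, active = act, responses = resp,
       activeIds = keep, neuronIds = nIds, astroIds = aIds,
       matrices = mats)
}

#' Run the full analysis pipeline on a synthetic scenario
#'
#' Orchestrates simulate -> process -> classify -> correlate (-> network /
#' lfp) for one of the shipped scenarios and assembles a structured session
#' report: pattern portions with SEM, mean synchrony per pair class and
#' burst with a paired test between bursts, functional-network percentages
#' against matched spontaneous recordings (S-CONN), or the LFP amplitude
#' comparison (S-LFP). Fully deterministic given the seeds; spontaneous
#' companion recordings of session i use seed `seeds[i] + 1000`.
#'
#' @param scenario one of the [scenarioPreset()] names or `"S-LFP"`.
#' @param seeds integer vector, one per session.
#' @param interval_s inter-burst interval (s) of the protocol.
#' @param max_lag peak-search range (frames).
#' @param active_only restrict classification and synchrony to active cells.
#' @param out_dir optional directory; when given, the report JSON and the
#'   per-session classification CSVs are written there.
#' @return a `SessionReport` list.
#' @export
runPipeline <- function(scenario = "S-FREQ", seeds = 1:6, interval_s = 10,
                        max_lag = 5L, active_only = TRUE, out_dir = NULL) {
  report <- list(provenance = list(
    package = "barrelsync",
    version = as.character(utils::packageVersion("barrelsync")),
    scenario = scenario, seeds = seeds, interval_s = interval_s))
  if (identical(scenario, "S-LFP")) {
    sw <- bandpassSweeps(simulateLfp(seed = seeds[1]))
    amps <- pulseAmplitudes(sw)
    report$lfp <- compareBurstAmplitudes(amps)
    avg <- pulseAmplitudes(averageSweeps(sw))
    report$lfp$avg_amplitude_by_burst <-
      vapply(split(avg$amplitude, avg$burst), mean, numeric(1))
  } else {
    freqs <- if (identical(scenario, "S-SAME")) c(8, 8) else c(8, 12)
    pr <- makeDefaultProtocol(freqs[1], freqs[2], interval_s = interval_s)
    sess <- lapply(seeds, function(s) {
      cfg <- scenarioPreset(scenario, seed = s)
      .analyzeSession(simulatePopulation(cfg, pr), max_lag = max_lag,
                      active_only = active_only)
    })
    # pattern portions over active neurons / astrocytes
    lab <- function(type) lapply(sess, function(x) {
      r <- x$responses
      r$pattern[r$cell_id %in% x$activeIds & r$cell_type == type]
    })
    nlab <- lab("neuron")
    if (any(vapply(nlab, length, integer(1)) > 0))
      report$patterns_neurons <- summarizePatterns(nlab)
    alab <- lab("astrocyte")
    if (any(vapply(alab, length, integer(1)) > 0))
      report$patterns_astrocytes <- summarizePatterns(alab)
    # synchrony per pair class and burst
    syn <- list()
    for (cl in c("nn", "aa", "na")) {
      for (b in 1:2) {
        key <- paste0(cl, "_b", b)
        ms <- lapply(sess, function(x) x$matrices[[key]])
        ms <- ms[!vapply(ms, is.null, logical(1))]
        if (length(ms) > 0) syn[[key]] <- meanSynchrony(ms)
      }
      k1 <- paste0(cl, "_b1"); k2 <- paste0(cl, "_b2")
      if (!is.null(syn[[k1]]) && !is.null(syn[[k2]]) &&
          length(syn[[k1]]$per_session) == length(syn[[k2]]$per_session) &&
          length(syn[[k1]]$per_session) >= 2)
        syn[[paste0(cl, "_burst_test")]] <-
          tTest(syn[[k1]]$per_session, syn[[k2]]$per_session, paired = TRUE)
    }
    if (length(syn) > 0) report$synchrony <- syn
    # functional connectivity against matched spontaneous recordings
    if (identical(scenario, "S-CONN"))
      report$connectivity <- .connectivityStage(scenario, seeds, sess,
                                                max_lag)
    report$sessions <- lapply(sess, function(x)
      list(n_active = length(x$activeIds),
           responses = x$responses))
  }
  class(report) <- "SessionReport"
  if (!is.null(out_dir)) writeReport(report, out_dir)
  report
}

# Threshold each session's stimulated matrices with its matched spontaneous
# recording and compute Pn / Pk / Pl per burst.
.connectivityStage <- function(scenario, seeds, sess, max_lag = 5L) {
  met <- list(nn = list(b1 = list(), b2 = list()),
              na = list(b1 = list(), b2 = list()))
  thr <- list(nn = numeric(0), na = numeric(0))
  for (i in seq_along(seeds)) {
    cfg <- scenarioPreset(scenario, seed = seeds[i] + 1000)
    spont <- processTraces(simulatePopulation(cfg, NULL))
    nIds <- sess[[i]]$neuronIds; aIds <- sess[[i]]$astroIds
    thNN <- spontaneousThreshold(
      pairwiseMatrix(spont, nIds, max_lag = max_lag))
    thNA <- spontaneousThreshold(
      pairwiseMatrix(spont, aIds, nIds, max_lag = max_lag))
    thr$nn <- c(thr$nn, thNN); thr$na <- c(thr$na, thNA)
    for (b in 1:2) {
      key <- paste0("b", b)
      net <- binarize(sess[[i]]$matrices[[paste0("nn_b", b)]], thNN)
      met$nn[[key]][[i]] <- networkMetrics(net)
      netNA <- binarize(sess[[i]]$matrices[[paste0("na_b", b)]], thNA,
                        rowType = "astrocyte", colType = "neuron")
      met$na[[key]][[i]] <- networkMetrics(netNA)
    }
  }
  pull <- function(cls, b, what)
    vapply(met[[cls]][[b]], function(x) x[[what]], numeric(1))
  list(thresh_nn = thr$nn, thresh_na = thr$na,
       Pn = list(b1 = pull("nn", "b1", "Pn"), b2 = pull("nn", "b2", "Pn"),
                 compare = compareConditions(pull("nn", "b1", "Pn"),
                                             pull("nn", "b2", "Pn"))),
       Pk = list(b1 = pull("nn", "b1", "Pk"), b2 = pull("nn", "b2", "Pk"),
                 compare = compareConditions(pull("nn", "b1", "Pk"),
                                             pull("nn", "b2", "Pk"))),
       Pl = list(b1 = pull("na", "b1", "Pl"), b2 = pull("na", "b2", "Pl"),
                 compare = compareConditions(pull("na", "b1", "Pl"),
                                             pull("na", "b2", "Pl"))))
}

#' Write a session report to disk
#'
#' The report body as JSON plus one classification CSV per session.
#'
#' @param report a `SessionReport` from [runPipeline()].
#' @param out_dir output directory (created if missing).
#' @export
writeReport <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  body <- unclass(report)
  sessions <- body$sessions
  body$sessions <- NULL
  jsonlite::write_json(body, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       na = "null")
  for (i in seq_along(sessions))
    utils::write.csv(sessions[[i]]$responses,
                     file.path(out_dir, sprintf("responses_session%02d.csv",
                                                i)),
                     row.names = FALSE)
  invisible(out_dir)
}

#' @export
print.SessionReport <- function(x, ...) {
  cat("SessionReport:", x$provenance$scenario, "- seeds",
      paste(x$provenance$seeds, collapse = ","), "\n")
  if (!is.null(x$patterns_neurons)) {
    m <- x$patterns_neurons$mean; s <- x$patterns_neurons$sem
    cat(sprintf(
      "  neuron patterns (dec/inc/par %%): %.1f+/-%.1f / %.1f+/-%.1f / %.1f+/-%.1f\n",
      m[1], s[1], m[2], s[2], m[3], s[3]))
  }
  if (!is.null(x$patterns_astrocytes)) {
    m <- x$patterns_astrocytes$mean; s <- x$patterns_astrocytes$sem
    cat(sprintf(
      "  astrocyte patterns (dec/inc/par %%): %.1f+/-%.1f / %.1f+/-%.1f / %.1f+/-%.1f\n",
      m[1], s[1], m[2], s[2], m[3], s[3]))
  }
  for (key in intersect(c("nn_b1", "nn_b2", "aa_b1", "aa_b2", "na_b1",
                          "na_b2"), names(x$synchrony))) {
    v <- x$synchrony[[key]]
    cat(sprintf("  synchrony %s: %.3f +/- %.3f\n", key, v$mean, v$sem))
  }
  if (!is.null(x$connectivity)) {
    cn <- x$connectivity
    cat(sprintf("  Pn: %.1f%% -> %.1f%% (p = %.3g)\n",
                mean(cn$Pn$b1), mean(cn$Pn$b2), cn$Pn$compare$t_test$p))
    cat(sprintf("  Pk: %.1f%% -> %.1f%% (p = %.3g)\n",
                mean(cn$Pk$b1), mean(cn$Pk$b2), cn$Pk$compare$t_test$p))
    cat(sprintf("  Pl: %.1f%% -> %.1f%% (p = %.3g)\n",
                mean(cn$Pl$b1), mean(cn$Pl$b2), cn$Pl$compare$t_test$p))
  }
  if (!is.null(x$lfp))
    cat(sprintf("  LFP amplitude: %.3f -> %.3f (p = %.3g)\n",
                x$lfp$mean_burst1, x$lfp$mean_burst2, x$lfp$t_test$p))
  invisible(x)
}
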