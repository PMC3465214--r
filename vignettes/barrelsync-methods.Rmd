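---
title: "barrelsync: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{barrelsync: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(barrelsync)
```

# The scientific problem

Rodents sample their environment by whisking, and the pulse frequency of
whisker contact carries behavioral information (faster motion, faster
contact). In the barrel cortex — the whisker-representation area of the
somatosensory cortex — both neurons and astrocytes respond to whisker
deflections with somatic calcium transients. The question this package's
analysis addresses is how a *population* of neurons and astrocytes encodes a
frequency *increase*: when a 10-s burst of 8 Hz air puffs is followed, after
a 10-s interval, by a 10-s burst at 12 Hz, do the cells respond more
strongly, more synchronously, and with more functional coupling during the
second burst?

Four quantitative readouts operationalize the question:

* per-cell **paired responses** R1 and R2 and a three-way classification
  (increment / decrement / parallel);
* pairwise **synchrony**, the central peak of the lag-resolved Pearson
  cross-correlation of smoothed dF/F traces;
* **functional connectivity**, a binary graph obtained by thresholding the
  stimulated correlation matrix at the spontaneous-activity level, and the
  percentages P~n~ = n/N, P~k~ = k/(N−1), P~l~ = l/(N·M);
* evoked **LFP amplitudes** per stimulus pulse, comparing the 8 Hz and
  12 Hz bursts.

# The processing chain and its assumptions

Raw per-cell fluorescence (arbitrary units) is converted to dF/F against the
mean over a **baseline window**, by default the 10 s preceding the first
burst (the design only fixes "before stimuli"; using the full pre-stimulus
epoch is the most stable choice at a 10 Hz frame rate). dF/F makes the
pipeline invariant to any positive gain on the raw signal, which is tested
as a property.

Astrocyte traces are divided by their SR101 (red marker) channel and
rescaled by the mean SR101 intensity. Because a motion artefact multiplies
both channels, the ratio cancels it exactly; the rescale keeps the dF/F
units unchanged when SR101 is stable.

Smoothing uses a **zero-phase low-pass Butterworth filter, cutoff 2 Hz,
order 4**, applied forward–backward with odd-reflection padding. The cutoff
preserves the 10-s burst plateaus and the seconds-scale calcium kinetics
while removing frame noise; zero-phase filtering is essential because peak
*delays* feed the synchrony analysis and a causal filter would bias them.
The per-cell baseline SD — the noise yardstick for both the activation and
the pattern thresholds — is recomputed on the smoothed traces, since those
are what the thresholds are applied to (this is a deliberate resolution of
an ambiguity; `detectActiveCells` accepts any `DffTraceSet`, so the
unsmoothed variant is one call away).

A cell is **active** when its dF/F exceeds 2.5 baseline SD for at least
500 ms — `ceiling(0.5 s × 10 Hz) = 5` consecutive frames, with no gap
tolerance. On pure noise this criterion fires on well under 1% of cells
(tested by simulation); on the generator's default signal-to-noise it
recovers responsive cells with sensitivity and specificity above 0.95.

**R1** is the maximum smoothed dF/F in the burst-1 window. Calcium need not
return to baseline between bursts, so **R2** is measured *above the residual
of response one*: the residual is the mean dF/F over the final 1 s before
burst-2 onset, and R2 is the burst-2 maximum minus that residual, floored at
0 (a trace that only decays has no evoked second response; such cells are
flagged). The window maximum, not the mean, is used because the analysis is
about peak amplitudes and the smoothed maximum is robust. Classification
compares R2 − R1 against ±2 baseline SD; the rule is antisymmetric in
(R1, R2) by construction. Pattern portions are summarized over active cells
only (the portions describe responding cells; a switch exposes the
alternative).

**Synchrony** of a pair is the signed maximum over delays |d| ≤ 5 frames
(0.5 s) of the normalized cross-correlation computed on the overlapping
samples with overlap means — which normalizes identically to the zero-lag
autocorrelation. Ties break toward smaller |d|, then toward negative d. The
0.5-s search range keeps the estimate at the central peak; it spans the
neuron–astrocyte onset lag without drifting to spurious far-lag maxima. The
burst windows themselves serve as the R1/R2 analysis windows.

A caveat the package quantifies rather than hides: the peak of a
lag-resolved correlation is a *maximum of noisy estimates*, so on short
windows it is biased upward relative to the underlying population
correlation — on independent 100-frame noise pairs the mean peak is small
but positive, and at a population correlation of ~0.3 on a 100-frame window
the mean measured peak sits roughly 0.05 higher. Long windows (the full
stimulation epoch, spontaneous recordings) make the bias negligible.

**Functional connections** are defined against spontaneous activity under
the assumption that resting coordination is the no-connection null: the
threshold is the mean + 2 sample SD of the spontaneous pair coefficients,
pooled within session and separately for neuron–neuron and neuron–astrocyte
pairs (their resting synchrony differs). Binarization is strict
(coefficients exactly at the threshold give no edge); the mean degree k
averages over *all* activated neurons, isolated ones included (the
connected-only alternative is available behind a flag). No
astrocyte–astrocyte graph metric is computed: astrocytes are coupled by gap
junctions and their pairwise connection count does not vary with the
stimulus, so no designed readout exists for it.

**LFP** sweeps are band-passed 1–100 Hz with a zero-phase order-3
Butterworth (order 3 keeps the 50 Hz mid-band gain above 99% after the
forward–backward pass; order 2 would already lose 6%). Per-pulse amplitude
is the depth of the most negative deflection in a post-pulse window —
min(80 ms, inter-pulse interval) — below the local 5-ms pre-pulse baseline;
evoked LFPs at this cortical depth are negative-going. Peak-to-peak
measurement is available behind a flag. Statistics are computed on per-sweep
mean amplitudes, paired by sweep, because the figure-level comparison is a
paired significance test and the sweep is its natural unit. Under a null
simulation with no frequency effect the test's rejection rate at
alpha = 0.05 is nominal (checked over 400 seeded runs).

All summary statistics are reported as mean ± SEM (sample SD over sqrt(n));
t tests are two-tailed, paired or Welch-unpaired. No multiple-comparison
correction is applied, matching the analysis the pipeline reproduces; the
report records this. Degenerate paired tests (zero-variance differences) are
flagged rather than silently propagated.

# The synthetic-data generator

No recordings ship with the package, so the generator defines the study
conditions. Each cell's relative fluorescence is

dF/F~i~(t) = Σ~b~ a~i,b~ K~type~(t; b) + λ~i~(t) C(t) + ε~i~(t),

with raw fluorescence F~i~(t) = F~0~ (1 + dF/F~i~(t)), F~0~ = 100 a.u.
(arbitrary; everything downstream of dF/F is gain-invariant).

* **Evoked kernel** K: the burst's pulse train convolved with a
  single-exponential calcium decay, τ = 1 s for neurons and τ = 3 s with a
  1-s onset lag for astrocytes — typical OGB-1 and astrocytic kinetics; the
  design does not constrain them. Kernels are normalized to unit
  steady-state plateau and *frame-integrated* (10× oversampled and averaged
  per frame), as frame-rate imaging integrates photons; point-sampling an
  8 Hz pulse train at 10 Hz would alias in a 2 Hz beat ripple.
* **Pattern classes**: a~i,2~ = a~i,1~(1 + δ) for increments,
  a~i,1~(1 − δ) for decrements, a~i,1~ for parallel cells, with δ = 0.4 and
  per-cell lognormal amplitude spread where configured.
* **Shared latent** C(t): standard normal per frame, loaded per segment
  (burst 1, burst 2, rest). The loading is solved from the Pearson mixing
  identity r = α²σ~C~²/(α²σ~C~² + σ~ε~²) evaluated on *post-smoothing*
  variances: the smoother's white-noise variance gain g and its lagged
  autocovariances are computed numerically from the impulse response, and
  the evoked kernel's window variance — shared across cells, hence
  correlation-raising — enters the identity explicitly
  (`calibrateScenario`).

## Exact-session conditioning

A population of 10–30 cells observed for 100-frame windows is a small
sample. If C(t) and ε(t) are left as plain draws, the sampled
kernel–latent cross-products and the realized variance of the *smoothed*
latent within a window dominate the session-to-session spread of every
synchrony and connectivity summary — dispersion several times the SEM bands
of the summaries the scenarios are designed to reproduce. The generator
therefore conditions its draws, per contiguous stimulus block (baseline /
burst 1 / gap / burst 2 / post):

* C is centered and variance-pinned in the raw domain, its sample
  covariance with the smoothed kernels is projected out block-locally
  (the smoother is linear, so subtracting a multiple of the raw kernel
  does this exactly), and its smoothed-domain block mean and variance are
  pinned to the nominal values;
* the noise block is made exactly mutually uncorrelated across cells and
  orthogonal to the latent and kernels within each block (QR on the
  residualized block — the same exact-sample device as drawing
  multivariate normals with empirical moments), then pinned to the nominal
  SD.

The marginal statistics are unchanged; what changes is that the *designed*
correlations are realized in every session instead of merely in
expectation. Everything remains bit-reproducible for a given seed.

## Scenario presets and their calibration

One preset per figure family (`scenarioPreset`):

* **S-FREQ** (6 sessions, 30 neurons + 16 astrocytes): ground-truth pattern
  fractions 0.619/0.215/0.166 (increment/decrement/parallel) for neurons
  and 0.634/0.220/0.146 for astrocytes; amplitude 0.5 ± 20% lognormal,
  noise SD 0.05. The classifier recovers the ground truth with ≥95%
  accuracy at these settings, so the recovered portions track the designed
  fractions.
* **S-SYNC-N / S-SYNC-A**: single-type populations with per-burst Pearson
  targets 0.75 → 0.80 (neurons) and 0.92 → 0.96 (astrocytes), solved in
  closed form from the mixing identity including the evoked-window
  variance.
* **S-SYNC-NA**: mixed population with between-type per-burst targets
  0.31 → 0.37 and a full-stimulation-epoch target of 0.40; the evoked
  amplitude is the free parameter, solved by bisection against a
  selection-aware expected peak (the expectation of the maximum of the
  lag-correlated estimates, with the estimator noise scale measured once at
  design time, κ = 0.8). Spontaneous recordings target 0.25. The per-burst
  0.31/0.37 are population values; their short-window peak *estimates* sit
  about 0.05 higher by the selection bias quantified above.
* **S-CONN** (13 neurons + 8 astrocytes): connectivity scenario built from
  *assemblies* — per burst, fixed-size groups of cells share a strong
  latent at the stimulated synchrony levels (0.75 burst 1, 0.80 burst 2)
  while all other couplings stay at a diffuse sub-threshold level (0.39
  during bursts, 0.53 at rest; the rest level sets the connection
  threshold). The burst-1 assemblies {7 neurons + 4 astrocytes} and
  {5 n + 2 a} with one isolated neuron, growing to {11 n + 5 a} and {2 n}
  in burst 2, make the designed edge fractions explicit:
  P~n~ 92.3 → 100%, P~k~ 39.7 → 71.8%, P~l~ 36.5 → 52.9%. A first design
  with heterogeneous lognormal per-cell loadings was built and measured,
  but its edge fractions were hypersensitive to the session-realized
  threshold (per-session SDs near 20 percentage points); the assembly
  structure matches the clustered connection graphs the analysis produces
  and makes the recovered percentages stable (per-session SDs below 3
  points).
* **S-SAME**: the 8-to-8 Hz control with decrement-dominant fractions
  2/18/4 of 24.
* The **LFP** scenario lives in `simulateLfp` defaults: pulse amplitude
  A(f) = A~0~ + 0.01·f with A~0~ = 0.1, broadband noise SD 0.05, 5%
  per-sweep gain jitter, 20 sweeps at 10 kHz.

Session sizes (5–8 sessions of 20–46 cells, 500-frame stimulated traces,
100–150 s spontaneous recordings) mirror the figure-level ns of the study
design and keep the whole suite and the acceptance script fast.

## What the generator does *not* emulate

The traces are Gaussian around a deterministic evoked profile: no spiking,
no spike-to-calcium nonlinearity (the analysis deliberately avoids
deconvolution), no photobleaching, drift or motion beyond the explicit
background/SR101 artefact fixtures, no neuropil contamination, and — by
design — less session-to-session dispersion than in vivo data. Passing
recovery tests therefore shows that the *pipeline* is correct and that the
statistics are recoverable under the stated noise model; it does not show
robustness to artefacts the generator does not produce.

# Numerical choices and degenerate inputs

* `signal::filtfilt` leaves edge transients, so all zero-phase filtering
  pads by odd reflection and trims.
* Correlation of a zero-variance (flat or saturated) window is undefined
  and raises an error; `pairwiseMatrix` drops such cells with a warning.
* Peak ties break toward smaller |d|, then negative d (documented,
  deterministic).
* Cells with non-positive baseline fluorescence are flagged invalid.
* Identical paired samples give t = 0, p = 1 with a zero-variance flag;
  constant non-zero paired differences are flagged and reported as p → 0
  with a warning.
* Sessions with zero active cells are excluded from pattern summaries with
  a warning; the increment/decrement ratio is flagged when no decrement
  cells exist.
* `spontaneousThreshold` requires at least two coefficients; the 2-SD uses
  the n−1 sample SD.

# Known limitations

* The peak-selection bias of short-window synchrony estimates is inherent
  to the statistic; the package documents and measures it instead of
  correcting it, because the downstream comparisons (R1 vs R2, stimulated
  vs spontaneous) share the bias.
* The connection threshold is estimated from a single spontaneous recording
  per session, as in the original design; its sampling error propagates
  into the network percentages.
* The pattern classifier's accuracy degrades when 2 SD of baseline noise
  approaches δ·a; the presets keep a comfortable margin, and the parameter
  recovery property (portions within 5 points of the design over ≥6
  sessions) is part of the test suite.
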