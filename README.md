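# barrelsync

Analysis of how populations of barrel-cortex neurons and astrocytes encode an
increase in whisker stimulus frequency, from two-photon calcium imaging and
local field potential (LFP) recordings. The experimental design is a paired
burst stimulus: two 10-s trains of air puffs to the whiskers, the first at
8 Hz and the second at 12 Hz, separated by a 10-s interval. The package
implements the full analysis chain and a calibrated synthetic-data generator
so that every stage is testable without recorded data.

## What it computes

Given per-cell fluorescence traces (or small two-channel image stacks with
ROI masks) acquired at 10 Hz:

1. **Signal processing** — per-frame median filtering, ROI-mean extraction,
   unstained-vessel background subtraction, SR101 normalization of
   astrocytes, relative fluorescence change
   ΔF/F(t) = (F(t) − F)/F against the pre-stimulus baseline, and
   zero-phase low-pass Butterworth smoothing (2 Hz, order 4). A cell is
   *active* when ΔF/F exceeds 2.5 baseline SD for at least 500 ms.
2. **Paired-response classification** — R1 is the peak ΔF/F during burst 1;
   R2 is the burst-2 peak measured above the residual of response one
   (mean ΔF/F over the last second before burst-2 onset). A cell is an
   *increment* if R2 − R1 > 2 SD of baseline, a *decrement* if
   R1 − R2 > 2 SD, and *parallel* otherwise.
3. **Synchrony** — for each cell pair, the lag-resolved normalized
   cross-correlation

   r(d) = Σₜ (x(t) − m_x)(y(t−d) − m_y) /
          √( Σₜ (x(t) − m_x)² · Σₜ (y(t−d) − m_y)² )

   over the overlapping samples, and its central-peak coefficient over
   |d| ≤ 5 frames; matrices of peak coefficients for neuron–neuron,
   astrocyte–astrocyte and neuron–astrocyte (bipartite) pairs.
4. **Functional connectivity** — the coefficient matrix is binarized at
   *thresh* = mean + 2 SD of the spontaneous-activity pair coefficients
   (A_ij = 1 iff r_ij > thresh), and summarized as
   P_n = n/N (percentage of function-connected neurons),
   P_k = k/(N−1) (mean per-neuron connection percentage) and
   P_l = l/(N·M) (realized neuron–astrocyte link percentage).
5. **LFP** — 1–100 Hz zero-phase band-pass of 10 kHz sweeps, sweep
   averaging, per-pulse evoked amplitudes (negative-peak depth over local
   baseline), and a paired two-tailed t test of 8 Hz vs 12 Hz amplitudes.

The synthetic module (`simulatePopulation`, `simulateImageStack`,
`simulateLfp`) generates seeded populations whose pattern fractions and
pairwise Pearson correlations are calibrated analytically through the mixing
identity r = α²σ_C²/(α²σ_C² + σ_ε²); shipped presets (`scenarioPreset`)
encode the study conditions per figure family.

## Worked example

```r
library(barrelsync)

protocol <- makeDefaultProtocol(8, 12)   # bursts at 10-20 s and 30-40 s
ts  <- simulatePopulation(scenarioPreset("S-FREQ", seed = 1), protocol)
dff <- processTraces(ts)                 # background, SR101, dF/F, smoothing
table(detectActiveCells(dff))
#> TRUE
#>   46
resp <- classifyPattern(measurePairedResponses(dff))
summarizePatterns(list(resp$pattern[resp$cell_type == "neuron"]))$mean
#> decrement increment  parallel
#>  13.33333  73.33333  13.33333
m2 <- pairwiseMatrix(dff, window = burstWindow(protocol, 2, 10))
meanSynchrony(m2)$mean
#> [1] 0.8771774
```

All 46 simulated cells pass the activation criterion; the neurons split into
the three response patterns with the increment class dominant (the 8-to-12 Hz
signature), and the burst-2 neuron-pair synchrony is high because the evoked
response is shared across the population. `runPipeline("S-CONN", seeds = 1:5)`
runs the full chain through the functional-network stage and prints the
P_n/P_k/P_l comparison between the 8 Hz and 12 Hz conditions.

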