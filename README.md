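# mitonet

Dynamic functional clustering analysis of oscillating mitochondrial
networks in cardiac myocytes.

## The problem

Under oxidative or metabolic stress, the inner membrane potential
(ΔΨ<sub>m</sub>) of cardiac mitochondria enters cycles of depolarization
and repolarization. Imaged with a potentiometric dye such as TMRE, a
myocyte becomes a lattice of coupled oscillators: clusters of
mitochondria oscillate synchronously in the ~10–25 mHz band while others
stay quiescent. `mitonet` quantifies the *functional topology* of such a
network — who is dynamically connected to whom, and how strongly the
network clusters — as opposed to its anatomical lattice organization.

The package is aimed at researchers analyzing per-organelle fluorescence
time series (two-photon recordings of isolated myocytes, or any
lattice-organized oscillator network) who want a reproducible, tested
pipeline from raw intensity traces to network statistics.

## The method

Starting from an M × N intensity matrix (M mitochondria, N frames,
frame interval *dt*):

1. **Wavelet frequency tracks.** Each signal is transformed with Morlet
   continuous wavelets (ω₀ = 6) on the scale grid
   s<sub>j</sub> = s₀·2^((j−1)·dj), dj = 0.1, s₀ = 4·dt,
   j₁ = log₂(N/s₀)/dj + 1. Band-limited power between
   ν<sub>min</sub> = 1/(1.1·T) and ν<sub>max</sub> = 1/s₀ is interpolated
   at 0.1 mHz and its argmax gives the dominant frequency per
   mitochondrion per frame.
2. **Dynamic major cluster.** Per frame, a frequency histogram is peak-
   picked (peaks above 10% of the maximum peak), adjacent peaks whose
   mean signals correlate ≥ 95% over the running window
   T<sub>w</sub> = 1.1·T are merged, and remaining mitochondria whose
   signals correlate ≥ 95% with the cluster mean are recruited. The
   cluster's normalized area is its pixel count over the myocyte pixel
   count.
3. **Functional graphs.** Two mitochondria are connected at time *t* when
   the Pearson correlation of their signals in the window T<sub>w</sub>
   around *t* exceeds a cutoff θ (default 0.90). Local clustering follows
   Watts–Strogatz: C<sub>m</sub> = 2L<sub>m</sub>/(m<sub>N</sub>(m<sub>N</sub>−1)),
   with network mean C = (1/M)·ΣC<sub>m</sub>.
4. **Erdős–Rényi null.** Per frame, uniformly random graphs with exactly
   the real edge count E(t) (the G(n, m) realization of
   p(t) = Σ<sub>m</sub>D<sub>m</sub>(t)/(M(M−1))) give the chance-level
   clustering baseline.
5. **Mean-field correlation, coherence, relations.** Each mitochondrion's
   mean windowed correlation with its spatial lattice neighbours is
   averaged into c(t); Welch magnitude-squared coherence (FFT length 2¹¹,
   0–100 mHz) is averaged over lattice neighbours and cluster members;
   cluster properties (coherence, frequency, area, normalized amplitude)
   are regressed against C(t), linearly or with
   f(x) = a·exp(−x/b) + c.

A synthetic lattice-oscillator generator with planted frequency clusters,
asymmetric depolarization waveforms, non-oscillating members, amplitude
decay and noise provides ground truth for every stage, so the whole
pipeline is testable without experimental recordings.

## Worked example

```r
library(mitonet)

cfg <- syntheticConfig(gridRows = 8, gridCols = 8, nFrames = 512, seed = 42)
sim <- simulateNetwork(cfg)
sim$signals
#> MitoSignalSet: 64 mitochondria x 512 frames (dt = 0.55 s, 281.6 s total)
#>   lattice edges: 112; myocyte pixels: 1024

report <- runPipeline(sim$signals,
                      pipelineConfig(seed = 1, frameBy = 8, coherenceBy = 16))
report
#> ClusteringReport: 64 evaluated frames
#>   time-averaged mean clustering C = 0.855 (ER null 0.409 +/- 0.005)
#>   time-averaged mean-field correlation c = 0.710

head(reportSummary(report)[, c("frame", "C", "CNullMean", "meanField", "area")], 3)
#>   frame     C CNullMean meanField  area
#> 1     1 0.835     0.388     0.751 0.594
#> 2     9 0.840     0.398     0.739 0.594
#> 3    17 0.857     0.411     0.732 0.594
```

The synchronized synthetic network clusters far above its matched random
network (C ≈ 0.86 vs ≈ 0.41): the planted 15 mHz cluster spans ~59% of
the lattice and its members are nearly fully interconnected at θ = 0.9,
while the edge-matched Erdős–Rényi graphs only reach their density-level
clustering. `writeReport(report, dir)` persists the summary series,
membership, amplitude events and relation fits as CSV plus a JSON
manifest; identical configuration and seed reproduce the files
byte-for-byte.

For image-stack input rather than a signal table, see
`extractSignals()` / `estimateShifts()` (grid-template region means with
integer shift correction), and `renderStack()` for the synthetic inverse.

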