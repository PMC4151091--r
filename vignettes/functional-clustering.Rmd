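---
title: "Dynamic functional clustering of mitochondrial oscillator networks"
author: "mitonet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional clustering of mitochondrial oscillator networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitonet)
```

## The model and its assumptions

Cardiac mitochondria are packed in a quasi-square lattice. Under
oxidative stress their inner membrane potential oscillates in the tens
of millihertz, and imaging with a potentiometric dye yields one
intensity trace per mitochondrion. `mitonet` treats such a recording as
a network of coupled oscillators and asks a topological question: at
each moment, which pairs behave as *functionally connected*, and how
strongly does the resulting graph cluster compared to chance?

The analysis assumes:

* signals are raw region-mean intensities on a common frame clock
  (`MitoSignalSet`), with no detrending — every normalization happens
  at the stage that defines it;
* oscillations are non-stationary, so frequency content must be tracked
  over time (hence wavelets, not a single periodogram);
* spatial coupling is local: the "neighbours" of the mean-field and
  coherence stages are the 4-connected lattice neighbours, while the
  "neighbours" of the clustering coefficient are graph neighbours in the
  functional network. These are deliberately different notions — the
  first asks how well a mitochondrion follows its anatomical
  surroundings, the second how clique-like its dynamic partners are.

## Stages and parameters

### Wavelet frequency tracks

Each signal is transformed with an admissible Morlet wavelet
(central frequency $\omega_0 = 6$) computed in the Fourier domain with
zero-padding to the next power of two. Scales form the geometric grid
$s_j = s_0 2^{(j-1)\,dj}$ with $dj = 0.1$ (10 sub-scales per octave),
$s_0 = 4\,dt$ (the shortest period in which one oscillation is
detectable), and $j_1 = \log_2(N/s_0)/dj + 1$ scales. Scales convert to
Fourier-equivalent frequency via
$f = (\omega_0 + \sqrt{2 + \omega_0^2})/(4\pi s)$.

The analysis band runs from $\nu_{\min} = 1/(1.1\,T)$ to
$\nu_{\max} = 1/s_0$, where $T$ is the longest synchronized oscillation
period. $T$ is ideally supplied by the analyst (`pipelineConfig(T = …)`);
as an automatic fallback `estimateBand()` uses the reciprocal of the
lower quartile of the per-mitochondrion median dominant frequencies, so
the slow band edge sits just below the bulk of observed oscillations.
Per frame, band power is interpolated onto a 0.1 mHz grid with a cubic
spline (the 0.1 mHz step is the method's convention; the cubic scheme is
a package choice) and the argmax is taken, ties toward the lower
frequency.

Two flags accompany the track: frames with zero band power, and whole
mitochondria whose time-averaged band power falls below 5% of the
myocyte median (`powerFloor`) — these are treated as non-oscillating.
The 5% floor is a package convention: recordings contain clearly flat
members but the flat/oscillating boundary needs a concrete rule, and on
synthetic data this floor cleanly separates planted flat members at the
default noise level.
The cone of influence (e-folding distance $\sqrt{2}s$ from either
record edge) is reported via `coiFrames()`; edge values are kept but
annotated, not masked.

### The dynamic major cluster

Per frame: a 1 mHz-bin histogram of dominant frequencies (1 mHz resolves
the 10–25 mHz band into ~15 bins); local maxima above 10% of the maximum
peak (strict inequality) are significant; adjacent peaks merge into the
maximum peak while the windowed correlation of mean signals is at least
0.95, walking outward nearest-first and alternating sides, a side
closing at its first failure; finally all outsiders whose signals
correlate at least 0.95 with the merged core's mean are recruited in a
single pass (the core mean is *not* recomputed mid-pass, which keeps the
result independent of candidate order). Comparisons follow the
conventions "above 10%" (strict) and "95% or higher" (inclusive).

All windows are $T_w = 1.1\,T$ wide, centred on the frame, truncated at
record edges and never padded; a frame whose window retains fewer than
$\max(4, T_w/(2\,dt))$ samples is skipped.

Peak/trough amplitude events of the cluster mean signal are detected
automatically: local extrema with topographic prominence at least 20% of
the signal's interdecile range and minimum separation $s_0$. This
replaces manual identification; the prominence floor suppresses
noise-level wiggles while keeping genuine depolarization spikes, and on
synthetic data recovers planted per-cycle amplitude decay to a few
percent. Each peak is paired with the deepest following trough before
the next peak; normalized amplitudes divide by the maximum event
amplitude, so the largest event is exactly 1.

### Functional graphs, clustering, and the null

Connectivity at time $t$: windowed Pearson correlation (zero-lag, raw
segments) strictly above the cutoff $\theta$ (default 0.90 — "exceeds").
Negative correlations never create edges, and zero-variance windows
yield flagged entries that are treated as non-connected. Local
clustering is $C_m = 2L_m/(m_N(m_N-1))$; degree-0/1 vertices score 0 and
are included in $C = (1/M)\sum_m C_m$ (exclusion is available via
`meanClustering(…, excludeLowDegree = TRUE)` but changes the literal
mean).

The null model fixes, per frame, the exact edge count of the real graph:
uniform $G(n, m)$ sampling rather than independent Bernoulli
$G(n, p(t))$, because the comparison requires the number of connections
to be identical at every time point ($p(t) = \sum_m D_m(t)/(M(M-1))$ is
the corresponding density). Bernoulli mode remains available
(`erNull(mode = "gnp")`) for sensitivity checks. Null realizations are
seeded per frame (`seed + frame`) so any frame subset reproduces
identically.

### Mean-field correlation and maps

Each mitochondrion's windowed correlations with its $N_m$ lattice
neighbours average to a per-mitochondrion value, and those average again
into the network mean $c(t)$; isolated lattice vertices are excluded
with a warning. (The summation form without the outer $1/M$ would leave
the interval $[-1, 1]$ that the quantity is defined on; the mean is the
self-consistent reading.) `correlationMap()` renders per-mitochondrion
values as a spatial field by piecewise-linear barycentric interpolation
over the triangulated lattice; pixels outside the convex hull stay
masked. The map interpolates the per-mitochondrion *mean* neighbour
correlation, one value per site.

### Coherence

Magnitude-squared coherence uses Welch averaging with Hann-tapered,
mean-removed segments at 50% overlap, zero-padded onto the fixed
$2^{11}$-sample FFT grid ($2^{11}/2 + 1 = 1025$ bins), restricted to
0–100 mHz. The default segment length is one third of the running
window, giving about five averaging segments. This is the key estimator
choice: with a single segment MSC is identically 1, and with two
half-overlapping segments the independent-input bias is so large
(~0.67) that contrasts between synchronized and unsynchronized
neighbourhoods are compressed; five short segments trade frequency
resolution for a usable bias level (~1/L). The scalar "coherence" of a
pair is the band mean of the spectrum (band maximum would weight single
bins too heavily); pairs with zero windowed power score 0, since no
oscillatory synchrony is detectable in a constant signal. Per
mitochondrion, coherence averages over lattice neighbours; per frame,
over major-cluster members. `normalizeTime()` rescales any recording
onto $[0, 1]$ (101-point grid) so myocytes of unequal duration can be
averaged.

### Fits and the cutoff sweep

Relations between the mean clustering coefficient and cluster
properties use per-frame samples joined strictly by frame index.
Coherence, frequency and area relations are fitted linearly; the
amplitude relation and the cutoff sweep use
$f(x) = a\,e^{-x/b} + c$ by Levenberg–Marquardt least squares with
multi-start initialization: $c$ from the right-tail mean, $a$ from
(first − last), $b$ from the log-slope of $|y - c|$, each start jittered
by factors 0.5/1/2 with both signs of $b$, best converged fit by RSS.
Standard errors come from the covariance at the optimum. The sweep
thresholds one set of correlation matrices at every cutoff, which makes
edge-count monotonicity in $\theta$ exact by construction, and reports
where the fitted curve crosses mean clustering 0.5.

## The synthetic generator

`syntheticConfig()`/`simulateNetwork()` emulate the phenomenology of a
stressed myocyte recording: a `gridRows × gridCols` 4-connected lattice;
planted clusters occupying contiguous blocks (in raster order) with
scattered non-oscillating members; a shared per-cluster phase from an
integrated instantaneous frequency that drifts as a bounded random walk
(clipped to ±30% of the planted value — the non-stationarity the wavelet
stage exists for); per-member static phase jitter; an asymmetric
relaxation waveform (fast exponential depolarization over
`waveformAsymmetry` of the period, slower recovery over the rest) whose
fundamental dominates its spectrum; per-cycle amplitude decay; additive
Gaussian noise. Defaults — 0.55 s frames, 512 frames, 15/25 mHz clusters
with 10% non-oscillating members, noise sd 0.05 of unit amplitude —
were chosen once as plausible two-photon recording conditions (no
published amplitude or SNR figures exist for the raw traces, so the
intensity scale is arbitrary).

What the generator does *not* model: the ROS-induced-ROS-release
biophysics (no differential equations of the mitochondrial oscillator),
cluster recruitment/criticality dynamics, photobleaching trends, or
movement artifacts beyond integer translations. Passing tests therefore
demonstrate the *pipeline's* correctness on data with known structure,
not the biological fidelity of any particular parameter value.

## Numerical choices and degenerate inputs

* Windows truncate at edges; short windows skip the frame rather than
  pad.
* Histogram plateau peaks and interpolated-power ties resolve toward
  the lower frequency, making peak selection deterministic.
* Zero-variance correlation rows flag as undefined and never create
  edges; isolated lattice vertices leave the mean-field average with a
  warning; zero-power coherence pairs score 0.
* `MSC(x, x) = 1` holds exactly in floating point because auto-spectra
  are computed as $\mathrm{Re}(X\bar X)$, never via `Mod()`.
* All stochastic stages (generator, ER nulls) take explicit seeds and
  restore the caller's RNG state; a pipeline re-run with the same
  configuration writes byte-identical CSVs.

## Interpreting the null comparison

A caution for permissive cutoffs: graphs thresholded from *sample*
correlations of even completely independent signals are systematically
more transitive than Erdős–Rényi graphs of the same density, because
$\mathrm{E}[r_{jk} \mid r_{ij}, r_{ik} > \theta] \approx \theta^2 > 0$
and the estimator couples triads sharing a vertex. At the working cutoff
$\theta = 0.9$ this excess is negligible — independent-phase data
produce (near-)empty graphs whose clustering matches the matched null —
but comparisons of real vs null clustering at cutoffs near zero should
not be read as evidence of physiological coupling.

## Problem sizes

The test-suite and acceptance studies use 36–100 mitochondria over
400–512 frames, clustering evaluated every 4–8 frames, coherence every
8–16, and 5–20 null realizations per frame; the ER calibration uses 200
vertices × 100 realizations. These sizes make every stage's statistical
target (oracle equality, null calibration within ±0.01, ≥90% planted
membership accuracy) comfortably reachable in seconds to a couple of
minutes per stage on a single core, and scale linearly in frames and
quadratically in mitochondria for the correlation stages.

## Known limitations

* The merge step's "adjacent peak" order (alternating sides,
  nearest-first) and single-pass recruitment are package conventions;
  procedures that re-run recruitment to a fixed point can admit slightly
  larger clusters.
* The 1 mHz histogram bin can split a cluster whose track straddles a
  bin edge; when the split halves both fall below a competing peak the
  major cluster can briefly jump to the competitor. Wider bins or peak
  merging across the split mitigate this at the cost of frequency
  resolution.
* Correlation maps require lattice-organized positions (the
  triangulation comes from grid cells); fully irregular layouts are not
  triangulated.
* Shift correction is integer-pixel by design — the template grid moves,
  pixel intensities are never resampled.
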