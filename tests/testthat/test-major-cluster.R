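# Builds a peakList directly so the merge/recruit rules can be exercised
# on constructed signals without going through the wavelet stage.
fakePeaks <- function(freqs, counts, members, maxIdx = which.max(counts)) {
  out <- data.frame(bin = seq_along(freqs), freqMHz = freqs,
                    count = counts, isMax = seq_along(freqs) == maxIdx)
  attr(out, "members") <- members
  class(out) <- c("peakList", "data.frame")
  out
}

test_that("the 10% peak rule keeps separated maxima and drops small ones", {
  # histogram [5, 50, 3, 20]: bin 2 is the global max, bin 4 a local max
  # above 10% of 50; bin 1 is not a local maximum at all
  sim <- simulateNetwork(syntheticConfig(gridRows = 4, gridCols = 4,
                                         nFrames = 400, seed = 1))
  tr <- dominantFrequency(sim$signals, band = frequencyBand(80, 2.2))
  h <- frequencyHistogram(tr, 200)
  h$counts <- c(5L, 50L, 3L, 20L, rep(0L, length(h$counts) - 4))
  h$members <- c(list(1:5, 6:55, 56:58, 59:78),
                 rep(list(integer(0)), length(h$counts) - 4))
  pk <- significantPeaks(h)
  expect_equal(pk$bin, c(2, 4))
  expect_equal(pk$isMax, c(TRUE, FALSE))

  # a local maximum at exactly 10% is excluded (strict ">")
  h$counts <- c(0L, 5L, 0L, 50L, 0L, rep(0L, length(h$counts) - 5))
  h$members <- rep(list(integer(0)), length(h$counts))
  pk2 <- significantPeaks(h)
  expect_equal(pk2$bin, 4)
})

test_that("plateau peaks break ties toward the lower frequency", {
  sim <- simulateNetwork(syntheticConfig(gridRows = 4, gridCols = 4,
                                         nFrames = 400, seed = 1))
  tr <- dominantFrequency(sim$signals, band = frequencyBand(80, 2.2))
  h <- frequencyHistogram(tr, 200)
  h$counts <- c(10L, 10L, rep(0L, length(h$counts) - 2))
  h$members <- rep(list(integer(0)), length(h$counts))
  pk <- significantPeaks(h)
  expect_equal(pk$bin, 1)

  h$counts <- c(0L, 7L, rep(0L, length(h$counts) - 2))
  pk2 <- significantPeaks(h)
  expect_equal(pk2$bin, 2)
})

test_that("histogram counts cover exactly the unflagged mitochondria", {
  sim <- simulateNetwork(syntheticConfig(gridRows = 5, gridCols = 5,
                                         nFrames = 400,
                                         nonOscillatingFraction = 0.2,
                                         clusterSpec = list(
                                           list(fraction = 0.8, frequency = 15,
                                                phaseJitterSd = 0.1,
                                                frequencyDriftSd = 0)),
                                         seed = 6))
  tr <- dominantFrequency(sim$signals)
  h <- frequencyHistogram(tr, 150)
  expect_equal(sum(h$counts), sum(!trackFlagged(tr)[, 150]))
  expect_equal(sort(unlist(h$members)), which(!trackFlagged(tr)[, 150]))
})

test_that("identical mean signals merge; anti-phase ones do not", {
  N <- 100
  tt <- seq_len(N)
  x <- sin(2 * pi * tt / 25)
  sig <- rbind(x, x, -x)
  pk <- fakePeaks(c(10, 12, 14), c(5, 9, 3),
                  list(1L, 2L, 3L), maxIdx = 2)
  merged <- mergePeaks(sig, pk, frame = 50, Tw = 40, dt = 1)
  expect_equal(merged, c(1L, 2L))   # peak 3 is anti-phase, not merged
})

test_that("merging walks outward and stops at the first failure per side", {
  # A (max) and B correlate 1; C is noise so corr(A U B, C) ~ 0
  set.seed(4)
  N <- 200
  x <- sin(2 * pi * seq_len(N) / 40)
  sig <- rbind(x, x, rnorm(N))
  pk <- fakePeaks(c(10, 11, 12), c(9, 5, 4), list(1L, 2L, 3L), maxIdx = 1)
  expect_equal(mergePeaks(sig, pk, 100, Tw = 120, dt = 1), c(1L, 2L))

  # beyond a failed peak nothing further on that side is considered,
  # even a perfectly correlated one
  sig2 <- rbind(x, rnorm(N), x)
  expect_equal(mergePeaks(sig2, pk, 100, Tw = 120, dt = 1), 1L)
})

test_that("merging is idempotent on its own output", {
  set.seed(9)
  N <- 150
  x <- sin(2 * pi * seq_len(N) / 30)
  y <- x + rnorm(N, 0, 0.05)
  sig <- rbind(x, y, rnorm(N))
  pk <- fakePeaks(c(10, 11, 15), c(9, 4, 3), list(1L, 2L, 3L), maxIdx = 1)
  m1 <- mergePeaks(sig, pk, 75, Tw = 100, dt = 1)
  pk2 <- fakePeaks(c(10.5, 15), c(13, 3), list(m1, 3L), maxIdx = 1)
  m2 <- mergePeaks(sig, pk2, 75, Tw = 100, dt = 1)
  expect_equal(m2, m1)
})

test_that("recruitment adds only signals correlated at >= 95% with the core mean", {
  set.seed(12)
  N <- 120
  x <- sin(2 * pi * seq_len(N) / 30)
  sig <- rbind(x, x, x + rnorm(N, 0, 0.01), rnorm(N))
  out <- recruitMembers(sig, core = c(1L, 2L), frame = 60, Tw = 80, dt = 1)
  expect_true(3L %in% out)     # near-identical -> recruited
  expect_false(4L %in% out)    # independent noise -> not recruited
  expect_error(recruitMembers(sig, integer(0), 60, 80, dt = 1), "empty")
})

test_that("major cluster equals the oscillating set on clean single-cluster data", {
  cfg <- syntheticConfig(gridRows = 4, gridCols = 4, nFrames = 400,
                         clusterSpec = list(list(fraction = 0.75,
                                                 frequency = 18,
                                                 phaseJitterSd = 0,
                                                 frequencyDriftSd = 0)),
                         nonOscillatingFraction = 0.25, noiseSd = 0,
                         seed = 17)
  sim <- simulateNetwork(cfg)
  tr <- dominantFrequency(sim$signals)
  mc <- majorCluster(sim$signals, tr, frames = seq(100, 300, by = 50))
  planted <- sim$truth$labels == 1
  mem <- clusterMembership(mc)
  for (i in seq_len(ncol(mem))) {
    expect_equal(unname(mem[, i]), unname(planted))
  }
  # with equal-size regions the normalized area equals the member fraction
  expect_equal(clusterArea(mc), colSums(mem) / 16, tolerance = 1e-12)
})

test_that("cluster membership is equivariant under mitochondrion relabeling", {
  cfg <- syntheticConfig(gridRows = 4, gridCols = 4, nFrames = 400,
                         seed = 23)
  sim <- simulateNetwork(cfg)
  sig <- intensity(sim$signals)
  perm <- rev(seq_len(nrow(sig)))
  permSet <- MitoSignalSet(sig[perm, ], dt = frameInterval(sim$signals),
                           gridRow = SummarizedExperiment::rowData(sim$signals)$gridRow[perm],
                           gridCol = SummarizedExperiment::rowData(sim$signals)$gridCol[perm])
  b <- estimateBand(sim$signals)
  tr1 <- dominantFrequency(sim$signals, band = b)
  tr2 <- dominantFrequency(permSet, band = b)
  mc1 <- majorCluster(sim$signals, tr1, frames = 200)
  mc2 <- majorCluster(permSet, tr2, frames = 200)
  m1 <- which(clusterMembership(mc1)[, 1])
  m2 <- perm[which(clusterMembership(mc2)[, 1])]
  expect_equal(sort(m1), sort(m2))
})

test_that("amplitude events follow the printed normalization rule", {
  # triangle wave: every event amplitude equals 2, all normalized to 1
  x <- rep(c(0, 1, 2, 1), 8)
  ev <- amplitudeEvents(x, dt = 1, minSeparation = 2)
  expect_gt(nrow(ev), 3)
  expect_true(all(abs(ev$amplitude - 2) < 1e-12))
  expect_true(all(ev$normAmplitude == 1))

  # amplitudes [2, 4, 3] -> normalized [0.5, 1, 0.75]
  y <- c(0, 2, 0, 0, 4, 0, 0, 3, 0, 1)
  ev2 <- amplitudeEvents(y, dt = 1, minSeparation = 1,
                         minProminenceFrac = 0.05)
  expect_equal(ev2$amplitude, c(2, 4, 3))
  expect_equal(ev2$normAmplitude, c(0.5, 1, 0.75))
  expect_equal(max(ev2$normAmplitude), 1)
})

test_that("detected event amplitudes reproduce the planted per-cycle decay", {
  cfg <- syntheticConfig(gridRows = 3, gridCols = 3, nFrames = 512,
                         clusterSpec = list(list(fraction = 1, frequency = 20,
                                                 phaseJitterSd = 0,
                                                 frequencyDriftSd = 0)),
                         nonOscillatingFraction = 0, noiseSd = 0,
                         amplitudeDecayRate = 0.1, seed = 3)
  sim <- simulateNetwork(cfg)
  x <- intensity(sim$signals)[1, ]
  ev <- amplitudeEvents(x, dt = frameInterval(sim$signals))
  expect_gt(nrow(ev), 4)
  ratios <- ev$amplitude[-1] / ev$amplitude[-nrow(ev)]
  expect_equal(mean(ratios), 0.9, tolerance = 0.03)
})

test_that("degenerate amplitude inputs give an empty event list", {
  expect_equal(nrow(amplitudeEvents(rep(1, 32), dt = 1)), 0)
  expect_error(amplitudeEvents(c(1, 2, 3), dt = 1), "at least 8")
})
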