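#' Configuration for the synthetic lattice-oscillator generator
#'
#' Describes a quasi-square lattice of mitochondrial oscillators with
#' planted frequency clusters, mimicking whole-cell recordings of
#' membrane-potential (TMRE) oscillations: clusters of members sharing a
#' common slowly drifting frequency in the ~10-25 mHz band, asymmetric
#' depolarization/repolarization waveforms with per-cycle amplitude decay,
#' a fraction of non-oscillating mitochondria, and additive noise.
#'
#' @param gridRows,gridCols Lattice dimensions; M = gridRows * gridCols.
#' @param dt Frame interval, seconds (default 0.55 s, a plausible
#'   two-photon frame time).
#' @param nFrames Number of frames.
#' @param clusterSpec List of cluster descriptions, each a list with
#'   `fraction` (member fraction of M), `frequency` (mHz),
#'   `phaseJitterSd` (radians, per-member static phase offset) and
#'   `frequencyDriftSd` (mHz per frame, sd of the shared random-walk
#'   drift, clipped to +/-30\% of the planted frequency).
#' @param nonOscillatingFraction Fraction of baseline-plus-noise members.
#' @param noiseSd Additive white noise sd, intensity units (oscillation
#'   amplitude is 1).
#' @param amplitudeDecayRate Fractional amplitude loss per completed
#'   cycle.
#' @param waveformAsymmetry Fraction of the period spent depolarizing
#'   (fast drop); the remainder is the slower repolarization recovery.
#' @param baseline Baseline intensity level.
#' @param cellHeight,cellWidth Pixel footprint of each region when the
#'   set is rendered to an image stack.
#' @param seed Integer seed; generation is bit-reproducible given it.
#' @return An object of class `syntheticConfig` (a validated list).
#' @export
syntheticConfig <- function(gridRows = 10, gridCols = 10, dt = 0.55,
                            nFrames = 512,
                            clusterSpec = list(
                              list(fraction = 0.6, frequency = 15,
                                   phaseJitterSd = 0.1, frequencyDriftSd = 0.02),
                              list(fraction = 0.3, frequency = 25,
                                   phaseJitterSd = 0.1, frequencyDriftSd = 0.02)),
                            nonOscillatingFraction = 0.1,
                            noiseSd = 0.05, amplitudeDecayRate = 0.05,
                            waveformAsymmetry = 0.25, baseline = 10,
                            cellHeight = 4, cellWidth = 4, seed = 1L) {
  cfg <- list(gridRows = gridRows, gridCols = gridCols, dt = dt,
              nFrames = nFrames, clusterSpec = clusterSpec,
              nonOscillatingFraction = nonOscillatingFraction,
              noiseSd = noiseSd, amplitudeDecayRate = amplitudeDecayRate,
              waveformAsymmetry = waveformAsymmetry, baseline = baseline,
              cellHeight = cellHeight, cellWidth = cellWidth,
              seed = as.integer(seed))
  validateSyntheticConfig(cfg)
  class(cfg) <- "syntheticConfig"
  cfg
}

validateSyntheticConfig <- function(cfg) {
  cfgStop <- function(fmt, ...) {
    stop(sprintf(paste0("invalid synthetic configuration: ", fmt), ...),
         call. = FALSE)
  }
  if (!isCount(cfg$gridRows) || !isCount(cfg$gridCols)) {
    cfgStop("gridRows/gridCols must be positive integers")
  }
  if (!is.numeric(cfg$dt) || cfg$dt <= 0) cfgStop("dt must be positive")
  if (!isCount(cfg$nFrames) || cfg$nFrames < 8) {
    cfgStop("nFrames must be an integer >= 8")
  }
  fr <- vapply(cfg$clusterSpec, `[[`, numeric(1), "fraction")
  if (length(fr) > 0 && any(fr <= 0 | fr > 1)) {
    cfgStop("cluster member fractions must lie in (0, 1]")
  }
  if (cfg$nonOscillatingFraction < 0 || cfg$nonOscillatingFraction >= 1) {
    cfgStop("nonOscillatingFraction must lie in [0, 1)")
  }
  if (abs(sum(fr) + cfg$nonOscillatingFraction - 1) > 1e-9) {
    cfgStop("member fractions plus nonOscillatingFraction must sum to 1 (got %g)",
            sum(fr) + cfg$nonOscillatingFraction)
  }
  nyqMHz <- 1000 / (2 * cfg$dt)
  fq <- vapply(cfg$clusterSpec, `[[`, numeric(1), "frequency")
  if (any(fq <= 0 | fq >= nyqMHz)) {
    cfgStop("cluster frequencies must lie strictly inside (0, %g) mHz (Nyquist)",
            nyqMHz)
  }
  if (length(fq) > 0) {
    slowestPeriod <- 1000 / min(fq)
    if (cfg$nFrames * cfg$dt < 3 * slowestPeriod) {
      cfgStop("recording must cover >= 3 periods of the slowest cluster (%g s < %g s)",
              cfg$nFrames * cfg$dt, 3 * slowestPeriod)
    }
  }
  if (cfg$waveformAsymmetry <= 0 || cfg$waveformAsymmetry >= 1) {
    cfgStop("waveformAsymmetry must lie in (0, 1)")
  }
  if (cfg$amplitudeDecayRate < 0 || cfg$amplitudeDecayRate >= 1) {
    cfgStop("amplitudeDecayRate must lie in [0, 1)")
  }
  if (cfg$noiseSd < 0) cfgStop("noiseSd must be non-negative")
  invisible(TRUE)
}

# Periodic asymmetric relaxation waveform on phase u in [0, 1):
# rapid exponential drop (depolarization) over the first `asym` fraction
# of the period, slower exponential recovery (repolarization) afterwards.
# Range ~[0, 1], top = 1.
relaxationWave <- function(u, asym, steep = 5) {
  u <- u %% 1
  lo <- exp(-steep)
  depol <- exp(-steep * u / asym)
  floorAt <- lo
  rec <- 1 - (1 - floorAt) * exp(-steep * (u - asym) / (1 - asym))
  out <- ifelse(u < asym, depol, rec)
  # rescale so the depolarized floor maps near 0 and the top to 1
  (out - lo) / (1 - lo)
}

#' Generate a synthetic oscillating mitochondrial network
#'
#' Produces a [MitoSignalSet-class] and the generating ground truth.
#' Members of one cluster share a common phase and a common random-walk
#' frequency drift; individual members differ only by their static phase
#' jitter and the additive noise, so that with zero jitter and zero noise
#' within-cluster signals are identical. Non-oscillating members are
#' baseline plus noise.
#'
#' @param config A [syntheticConfig()].
#' @return A list with elements `signals` ([MitoSignalSet-class]) and
#'   `truth`, the latter a list with `labels` (integer per mitochondrion;
#'   -1 = non-oscillating), `instFrequency` (M x N matrix, mHz, NA for
#'   non-oscillating members) and `positions` (data.frame id, gridRow,
#'   gridCol, label).
#' @examples
#' sim <- simulateNetwork(syntheticConfig(gridRows = 4, gridCols = 4,
#'   nFrames = 256, seed = 7))
#' table(sim$truth$labels)
#' @export
simulateNetwork <- function(config) {
  stopifnot(inherits(config, "syntheticConfig"))
  validateSyntheticConfig(config)
  M <- config$gridRows * config$gridCols
  N <- config$nFrames
  dt <- config$dt
  K <- length(config$clusterSpec)

  withSeed(config$seed, {
    # --- membership: non-oscillators scattered at random, clusters as
    # contiguous runs (raster order) of the remaining cells.
    fr <- vapply(config$clusterSpec, `[[`, numeric(1), "fraction")
    nNon <- M - min(M, sum(round(fr * M))) # provisional
    counts <- round(fr * M)
    nNon <- M - sum(counts)
    if (nNon < 0) { # rounding overflow: trim largest cluster
      counts[which.max(counts)] <- counts[which.max(counts)] + nNon
      nNon <- 0
    }
    labels <- integer(M)
    nonIdx <- if (nNon > 0) sort(sample.int(M, nNon)) else integer(0)
    labels[nonIdx] <- -1L
    oscIdx <- setdiff(seq_len(M), nonIdx)
    pos <- 1L
    for (k in seq_len(K)) {
      take <- oscIdx[seq.int(pos, length.out = counts[k])]
      labels[take] <- k
      pos <- pos + counts[k]
    }

    # --- shared per-cluster instantaneous frequency tracks (mHz):
    # bounded random walk clipped to +/-30% of the planted value.
    clustFreq <- matrix(NA_real_, nrow = max(K, 1), ncol = N)
    for (k in seq_len(K)) {
      f0 <- config$clusterSpec[[k]]$frequency
      dsd <- config$clusterSpec[[k]]$frequencyDriftSd
      steps <- if (dsd > 0) rnorm(N, 0, dsd) else numeric(N)
      f <- f0 + cumsum(steps) - steps[1]
      clustFreq[k, ] <- pmin(pmax(f, 0.7 * f0), 1.3 * f0)
    }

    # --- per-member static phase jitter (radians)
    jitter <- numeric(M)
    for (k in seq_len(K)) {
      sdk <- config$clusterSpec[[k]]$phaseJitterSd
      mem <- which(labels == k)
      if (sdk > 0) jitter[mem] <- rnorm(length(mem), 0, sdk)
    }

    sig <- matrix(config$baseline, M, N)
    instFreq <- matrix(NA_real_, M, N)
    for (k in seq_len(K)) {
      mem <- which(labels == k)
      if (length(mem) == 0) next
      # shared phase from the integrated instantaneous frequency (Hz)
      phase <- 2 * pi * cumsum(clustFreq[k, ] / 1000) * dt
      cycles <- phase / (2 * pi)
      amp <- (1 - config$amplitudeDecayRate)^cycles
      for (m in mem) {
        u <- (phase + jitter[m]) / (2 * pi)
        sig[m, ] <- config$baseline +
          amp * relaxationWave(u, config$waveformAsymmetry)
        instFreq[m, ] <- clustFreq[k, ]
      }
    }
    if (config$noiseSd > 0) {
      sig <- sig + matrix(rnorm(M * N, 0, config$noiseSd), M, N)
    }

    gridRow <- rep(seq_len(config$gridRows), each = config$gridCols)
    gridCol <- rep(seq_len(config$gridCols), times = config$gridRows)
    npix <- config$cellHeight * config$cellWidth
    signals <- MitoSignalSet(sig, dt = dt, gridRow = gridRow,
                             gridCol = gridCol,
                             pixelCounts = rep(npix, M))
    truth <- list(
      labels = labels,
      instFrequency = instFreq,
      positions = data.frame(id = rownames(signals), gridRow = gridRow,
                             gridCol = gridCol, label = labels))
    list(signals = signals, truth = truth)
  })
}

#' Grid template for a lattice of rectangular regions
#'
#' Builds the region -> pixel-set map used to render and extract image
#' stacks: each lattice cell occupies a `cellHeight` x `cellWidth` pixel
#' block separated by `gap` background pixels.
#'
#' @param gridRows,gridCols Lattice dimensions.
#' @param cellHeight,cellWidth Pixels per region block.
#' @param gap Background pixels between blocks (and at the border).
#' @return A data.frame with columns `region`, `row`, `col` (0-based pixel
#'   coordinates) carrying the image dimensions as attributes `imageRows`
#'   and `imageCols`, plus `gridRow`/`gridCol` per region in attribute
#'   `positions`.
#' @export
makeGridTemplate <- function(gridRows, gridCols, cellHeight = 4,
                             cellWidth = 4, gap = 1) {
  rows <- integer(0); cols <- integer(0); region <- integer(0)
  id <- 0L
  posR <- integer(0); posC <- integer(0)
  for (r in seq_len(gridRows)) {
    for (c in seq_len(gridCols)) {
      id <- id + 1L
      r0 <- gap + (r - 1L) * (cellHeight + gap)
      c0 <- gap + (c - 1L) * (cellWidth + gap)
      px <- expand.grid(row = r0 + seq_len(cellHeight) - 1L,
                        col = c0 + seq_len(cellWidth) - 1L)
      rows <- c(rows, px$row); cols <- c(cols, px$col)
      region <- c(region, rep(id, nrow(px)))
      posR <- c(posR, r); posC <- c(posC, c)
    }
  }
  out <- data.frame(region = region, row = as.integer(rows),
                    col = as.integer(cols))
  attr(out, "imageRows") <- gap + gridRows * (cellHeight + gap)
  attr(out, "imageCols") <- gap + gridCols * (cellWidth + gap)
  attr(out, "positions") <- data.frame(region = seq_len(id),
                                       gridRow = posR, gridCol = posC)
  out
}

#' Render a signal set to a synthetic image stack
#'
#' Inverse of [extractSignals()]: paints each region's signal value onto
#' its pixel set frame by frame, optionally adding per-pixel noise.
#'
#' @param signals A [MitoSignalSet-class] (or numeric matrix M x N).
#' @param grid A grid template as from [makeGridTemplate()]; must contain
#'   one region per signal row, with pairwise-disjoint pixel sets.
#' @param frameNoiseSd Per-pixel additive Gaussian noise sd.
#' @param background Intensity of pixels outside every region.
#' @param seed Optional seed for the pixel noise.
#' @return A numeric array (imageRows x imageCols x N).
#' @export
renderStack <- function(signals, grid, frameNoiseSd = 0, background = 0,
                        seed = NULL) {
  sig <- if (methods::is(signals, "MitoSignalSet")) intensity(signals)
         else as.matrix(signals)
  checkGridTemplate(grid)
  regs <- sort(unique(grid$region))
  if (length(regs) != nrow(sig)) {
    stop("grid template has ", length(regs), " regions but signals have ",
         nrow(sig), " rows", call. = FALSE)
  }
  H <- attr(grid, "imageRows"); W <- attr(grid, "imageCols")
  if (is.null(H) || is.null(W)) {
    H <- max(grid$row) + 1L; W <- max(grid$col) + 1L
  }
  N <- ncol(sig)
  stack <- array(background, dim = c(H, W, N))
  lin <- grid$row + 1L + grid$col * H   # linear index within a frame
  regIdx <- match(grid$region, regs)
  withSeed(seed, {
    for (t in seq_len(N)) {
      frame <- stack[, , t]
      frame[lin] <- sig[regIdx, t]
      if (frameNoiseSd > 0) {
        frame <- frame + rnorm(H * W, 0, frameNoiseSd)
      }
      stack[, , t] <- frame
    }
  })
  stack
}

checkGridTemplate <- function(grid) {
  stopifnot(is.data.frame(grid),
            all(c("region", "row", "col") %in% names(grid)))
  key <- paste(grid$row, grid$col)
  if (anyDuplicated(key)) {
    stop("grid template regions overlap: pixel (",
         grid$row[anyDuplicated(key)], ",", grid$col[anyDuplicated(key)],
         ") assigned twice", call. = FALSE)
  }
  if (any(grid$row < 0) || any(grid$col < 0)) {
    stop("grid template has negative pixel coordinates", call. = FALSE)
  }
  invisible(TRUE)
}

#' Write ground truth tables
#'
#' Persists the generator's ground truth as plain-text artifacts: a
#' per-mitochondrion table (id, gridRow, gridCol, label) and the
#' instantaneous-frequency matrix.
#'
#' @param truth The `truth` element of [simulateNetwork()]'s result.
#' @param path Base path; writes `<path>_labels.csv` and
#'   `<path>_frequency.csv`.
#' @return Invisibly, the two file paths.
#' @export
writeGroundTruth <- function(truth, path) {
  labFile <- paste0(path, "_labels.csv")
  freqFile <- paste0(path, "_frequency.csv")
  utils::write.csv(truth$positions, labFile, row.names = FALSE)
  utils::write.csv(as.data.frame(truth$instFrequency), freqFile,
                   row.names = FALSE)
  invisible(c(labFile, freqFile))
}
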