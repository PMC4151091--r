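#' Frequency histogram of the network at one frame
#'
#' Histogram of the dominant frequencies of all unflagged mitochondria at
#' frame `t`, on fixed-width bins spanning the analysis band (default
#' 1 mHz, which resolves the 10-25 mHz oscillation band into ~15 bins).
#'
#' @param track A [FrequencyTrack-class].
#' @param frame Frame index.
#' @param binWidth Bin width, mHz.
#' @return A list of class `frequencyHistogram`: `edges` (bin edges,
#'   mHz), `mids`, `counts`, and `members` (list of mitochondrion indices
#'   per bin).
#' @export
frequencyHistogram <- function(track, frame, binWidth = 1) {
  stopifnot(methods::is(track, "FrequencyTrack"))
  b <- track@band
  edges <- seq(floor(b$nuMinMHz), ceiling(b$nuMaxMHz) + binWidth,
               by = binWidth)
  f <- track@frequency[, frame]
  keep <- which(!track@flagged[, frame] & !is.na(f))
  bin <- findInterval(f[keep], edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  counts <- tabulate(bin, nbins = nb)
  members <- lapply(seq_len(nb), function(i) keep[bin == i])
  structure(list(edges = edges, mids = edges[-length(edges)] + binWidth / 2,
                 counts = counts, members = members, frame = frame),
            class = "frequencyHistogram")
}

#' Significant histogram peaks
#'
#' Local maxima of the frequency histogram; besides the global maximum, a
#' local maximum is significant only if its count is strictly above
#' `minFrac` (default 10\%) of the maximum count. Plateau ties break
#' toward the lower-frequency bin.
#'
#' @param hist A [frequencyHistogram()].
#' @param minFrac Significance fraction of the maximum peak.
#' @return A data.frame (class `peakList`) with columns `bin`, `freqMHz`,
#'   `count`, `isMax`, ordered by frequency; zero rows when the histogram
#'   is empty (clusterless frame). Attribute `members` holds the member
#'   list per peak.
#' @export
significantPeaks <- function(hist, minFrac = 0.10) {
  stopifnot(inherits(hist, "frequencyHistogram"))
  counts <- hist$counts
  if (all(counts == 0)) {
    out <- data.frame(bin = integer(0), freqMHz = numeric(0),
                      count = integer(0), isMax = logical(0))
    attr(out, "members") <- list()
    class(out) <- c("peakList", "data.frame")
    return(out)
  }
  locmax <- localMaxima(counts)
  locmax <- locmax[counts[locmax] > 0]
  maxCount <- max(counts)
  globalBin <- locmax[which.max(counts[locmax])]
  keep <- locmax[counts[locmax] > minFrac * maxCount | locmax == globalBin]
  keep <- sort(keep)
  out <- data.frame(bin = keep, freqMHz = hist$mids[keep],
                    count = counts[keep], isMax = keep == globalBin)
  attr(out, "members") <- hist$members[keep]
  class(out) <- c("peakList", "data.frame")
  out
}

meanSignalOf <- function(sig, members, idx) {
  if (length(members) == 1L) sig[members, idx] else colMeans(sig[members, idx, drop = FALSE])
}

#' Merge adjacent frequency peaks into the maximum peak
#'
#' Starting from the maximum histogram peak, adjacent peaks are taken
#' nearest-in-frequency first, alternating sides of the maximum. An
#' adjacent peak is absorbed when the Pearson correlation between the mean
#' signal of the current merged set and the mean signal of the peak's
#' members, over the running window `Tw` centred at `frame`, is at least
#' `threshold` (default 0.95, "95\% or higher"); the first failure on a
#' side closes that side.
#'
#' @param signals [MitoSignalSet-class] or numeric matrix.
#' @param peaks A [significantPeaks()] result.
#' @param frame Centre frame of the window.
#' @param Tw Window length, seconds.
#' @param threshold Merge correlation threshold.
#' @param dt Frame interval (taken from `signals` when possible).
#' @return Integer vector of member indices of the merged maximum peak
#'   (empty when `peaks` is empty).
#' @export
mergePeaks <- function(signals, peaks, frame, Tw, threshold = 0.95,
                       dt = NULL) {
  sig <- if (methods::is(signals, "MitoSignalSet")) intensity(signals) else as.matrix(signals)
  if (is.null(dt) && methods::is(signals, "MitoSignalSet")) dt <- frameInterval(signals)
  stopifnot(inherits(peaks, "peakList"))
  if (nrow(peaks) == 0) return(integer(0))
  idx <- windowFrames(frame, ncol(sig), Tw, dt)
  if (length(idx) < 4) {
    stop("window at frame ", frame, " retains fewer than 4 samples",
         call. = FALSE)
  }
  members <- attr(peaks, "members")
  iMax <- which(peaks$isMax)
  merged <- members[[iMax]]
  left <- rev(which(peaks$freqMHz < peaks$freqMHz[iMax]))   # nearest first
  right <- which(peaks$freqMHz > peaks$freqMHz[iMax])       # nearest first
  li <- 1L; ri <- 1L
  leftOpen <- li <= length(left); rightOpen <- ri <= length(right)
  # alternate sides, nearest peak of the two heads first
  takeLeft <- function() {
    if (!leftOpen) return(FALSE)
    if (!rightOpen) return(TRUE)
    dl <- peaks$freqMHz[iMax] - peaks$freqMHz[left[li]]
    dr <- peaks$freqMHz[right[ri]] - peaks$freqMHz[iMax]
    dl <= dr
  }
  while (leftOpen || rightOpen) {
    if (takeLeft()) {
      cand <- members[[left[li]]]
      ok <- length(cand) > 0 && isTRUE(
        stats::cor(meanSignalOf(sig, merged, idx),
                   meanSignalOf(sig, cand, idx)) >= threshold)
      if (ok) { merged <- c(merged, cand); li <- li + 1L
                leftOpen <- li <= length(left) }
      else leftOpen <- FALSE
    } else {
      cand <- members[[right[ri]]]
      ok <- length(cand) > 0 && isTRUE(
        stats::cor(meanSignalOf(sig, merged, idx),
                   meanSignalOf(sig, cand, idx)) >= threshold)
      if (ok) { merged <- c(merged, cand); ri <- ri + 1L
                rightOpen <- ri <= length(right) }
      else rightOpen <- FALSE
    }
  }
  sort(merged)
}

#' Recruit highly correlated non-members into the cluster core
#'
#' Every mitochondrion outside the core is correlated (over the window
#' `Tw` centred at `frame`) against the core's mean signal; those with
#' correlation at least `threshold` join. The pass is single-sweep: the
#' core mean is not recomputed while recruiting, which makes the result
#' independent of the order in which candidates are examined.
#'
#' @inheritParams mergePeaks
#' @param core Integer vector of core member indices (non-empty).
#' @return Sorted integer vector: core plus recruited members.
#' @export
recruitMembers <- function(signals, core, frame, Tw, threshold = 0.95,
                           dt = NULL) {
  sig <- if (methods::is(signals, "MitoSignalSet")) intensity(signals) else as.matrix(signals)
  if (is.null(dt) && methods::is(signals, "MitoSignalSet")) dt <- frameInterval(signals)
  if (length(core) == 0) stop("core member set is empty", call. = FALSE)
  idx <- windowFrames(frame, ncol(sig), Tw, dt)
  coreMean <- meanSignalOf(sig, core, idx)
  outside <- setdiff(seq_len(nrow(sig)), core)
  r <- vapply(outside, function(m) {
    v <- suppressWarnings(stats::cor(coreMean, sig[m, idx]))
    if (is.na(v)) -Inf else v
  }, numeric(1))
  sort(c(core, outside[r >= threshold]))
}

#' MajorClusterSeries: the dynamic major cluster
#'
#' Time-indexed membership of the major cluster -- the set of mitochondria
#' sharing the dominant frequency-histogram peak (after peak merging)
#' plus all recruits whose signals correlate at least 95\% with its mean
#' -- together with its normalized area, mean signal and mean frequency.
#'
#' @slot frames Integer vector of evaluated frames.
#' @slot membership Logical M x length(frames) matrix.
#' @slot area Normalized dynamic area a(t) = cluster pixels / myocyte
#'   pixels, in [0, 1].
#' @slot meanSignal Mean member intensity at each evaluated frame.
#' @slot clusterFrequency Mean member dominant frequency (mHz).
#' @slot band The [frequencyBand()] parameters used.
#' @exportClass MajorClusterSeries
setClass("MajorClusterSeries",
         representation(frames = "integer", membership = "matrix",
                        area = "numeric", meanSignal = "numeric",
                        clusterFrequency = "numeric", band = "list"))

setValidity("MajorClusterSeries", function(object) {
  if (length(object@frames) != ncol(object@membership)) {
    return("membership must have one column per evaluated frame")
  }
  if (any(object@area < 0 | object@area > 1, na.rm = TRUE)) {
    return("normalized area must lie in [0, 1]")
  }
  TRUE
})

setMethod("show", "MajorClusterSeries", function(object) {
  cat(sprintf("MajorClusterSeries: %d frames; median cluster size %d of %d; median area %.2f\n",
              length(object@frames),
              as.integer(stats::median(colSums(object@membership))),
              nrow(object@membership), stats::median(object@area)))
})

#' @describeIn MajorClusterSeries-class Evaluated frame indices.
#' @param x A MajorClusterSeries.
#' @export
clusterFrames <- function(x) x@frames

#' @describeIn MajorClusterSeries-class Logical membership matrix
#'   (mitochondria x evaluated frames).
#' @export
clusterMembership <- function(x) x@membership

#' @describeIn MajorClusterSeries-class Normalized dynamic area a(t).
#' @export
clusterArea <- function(x) x@area

#' @describeIn MajorClusterSeries-class Mean member signal per frame.
#' @export
clusterMeanSignal <- function(x) x@meanSignal

#' @describeIn MajorClusterSeries-class Mean member frequency (mHz).
#' @export
clusterMeanFrequency <- function(x) x@clusterFrequency

#' Identify the major cluster at every frame
#'
#' Runs, per evaluated frame: frequency histogram ->
#' [significantPeaks()] -> [mergePeaks()] -> [recruitMembers()]. Frames
#' whose truncated window retains fewer than max(4, Tw/(2 dt)) samples
#' are skipped; clusterless frames (empty histogram) yield an empty
#' membership column.
#'
#' @param signals A [MitoSignalSet-class].
#' @param track A [FrequencyTrack-class] for the same signals.
#' @param band A [frequencyBand()]; defaults to the track's band.
#' @param frames Frames to evaluate (default: all frames with a full
#'   enough window).
#' @param binWidth Histogram bin width, mHz.
#' @param peakFrac Peak-significance fraction (default 0.10).
#' @param threshold Merge/recruit correlation threshold (default 0.95).
#' @return A [MajorClusterSeries-class].
#' @export
majorCluster <- function(signals, track, band = NULL, frames = NULL,
                         binWidth = 1, peakFrac = 0.10, threshold = 0.95) {
  stopifnot(methods::is(signals, "MitoSignalSet"),
            methods::is(track, "FrequencyTrack"))
  if (is.null(band)) band <- track@band
  dt <- frameInterval(signals)
  N <- ncol(signals)
  minSamples <- windowMinSamples(band$Tw, dt)
  if (is.null(frames)) frames <- seq_len(N)
  frames <- frames[vapply(frames, function(t) {
    length(windowFrames(t, N, band$Tw, dt)) >= minSamples
  }, logical(1))]
  frames <- as.integer(frames)
  sig <- intensity(signals)
  M <- nrow(sig)
  membership <- matrix(FALSE, M, length(frames))
  area <- rep(NA_real_, length(frames))
  meanSig <- rep(NA_real_, length(frames))
  meanFreq <- rep(NA_real_, length(frames))
  px <- pixelCounts(signals)
  for (i in seq_along(frames)) {
    t <- frames[i]
    h <- frequencyHistogram(track, t, binWidth = binWidth)
    pk <- significantPeaks(h, minFrac = peakFrac)
    if (nrow(pk) == 0) { area[i] <- 0; next }
    core <- mergePeaks(sig, pk, t, band$Tw, threshold = threshold, dt = dt)
    if (length(core) == 0) { area[i] <- 0; next }
    mem <- recruitMembers(sig, core, t, band$Tw, threshold = threshold,
                          dt = dt)
    membership[mem, i] <- TRUE
    area[i] <- sum(px[mem]) / myocytePixels(signals)
    meanSig[i] <- mean(sig[mem, t])
    fv <- track@frequency[mem, t]
    meanFreq[i] <- mean(fv, na.rm = TRUE)
  }
  methods::new("MajorClusterSeries", frames = frames,
               membership = membership, area = area, meanSignal = meanSig,
               clusterFrequency = meanFreq, band = unclass(band))
}

#' Peak-trough amplitude events of a cluster mean signal
#'
#' Detects peaks and troughs automatically: local extrema with topographic
#' prominence at least `minProminenceFrac` of the signal's interdecile
#' range and minimum separation `minSeparation` samples. Each peak is
#' paired with the following trough; the event amplitude is peak minus
#' trough, the time difference trough time minus peak time, and
#' normalized amplitudes divide by the maximum event amplitude (so the
#' largest event is exactly 1).
#'
#' @param x Numeric signal (e.g. [clusterMeanSignal()]), length >= 8.
#' @param dt Frame interval, seconds.
#' @param minProminenceFrac Prominence floor as a fraction of the
#'   interdecile range (default 0.2).
#' @param minSeparation Minimum extremum separation in samples (default
#'   4, the smallest detectable period s0 in samples).
#' @return A data.frame (class `amplitudeEvents`) with columns
#'   `peakFrame`, `troughFrame`, `peakTime`, `troughTime`, `amplitude`,
#'   `normAmplitude`, `dtime`; zero rows when no events are detectable
#'   (non-oscillating series).
#' @export
amplitudeEvents <- function(x, dt, minProminenceFrac = 0.2,
                            minSeparation = 4) {
  if (length(x) < 8) stop("signal must have at least 8 samples", call. = FALSE)
  if (anyNA(x)) x <- stats::approx(seq_along(x), x, seq_along(x), rule = 2)$y
  idr <- diff(stats::quantile(x, c(0.1, 0.9), names = FALSE))
  empty <- data.frame(peakFrame = integer(0), troughFrame = integer(0),
                      peakTime = numeric(0), troughTime = numeric(0),
                      amplitude = numeric(0), normAmplitude = numeric(0),
                      dtime = numeric(0))
  class(empty) <- c("amplitudeEvents", "data.frame")
  if (idr <= 0) return(empty)
  prom <- minProminenceFrac * idr
  peaks <- filteredPeaks(x, prom, minSeparation)
  troughs <- filteredPeaks(-x, prom, minSeparation)
  if (length(peaks) == 0 || length(troughs) == 0) return(empty)
  ev <- lapply(peaks, function(p) {
    nxtPeak <- peaks[peaks > p]
    lim <- if (length(nxtPeak)) min(nxtPeak) else length(x) + 1L
    tr <- troughs[troughs > p & troughs < lim]
    if (length(tr) == 0) return(NULL)
    tr <- tr[which.min(x[tr])]
    data.frame(peakFrame = p, troughFrame = tr)
  })
  ev <- do.call(rbind, ev)
  if (is.null(ev) || nrow(ev) == 0) return(empty)
  ev$peakTime <- (ev$peakFrame - 1) * dt
  ev$troughTime <- (ev$troughFrame - 1) * dt
  ev$amplitude <- x[ev$peakFrame] - x[ev$troughFrame]
  ev$normAmplitude <- ev$amplitude / max(ev$amplitude)
  ev$dtime <- ev$troughTime - ev$peakTime
  class(ev) <- c("amplitudeEvents", "data.frame")
  ev
}
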