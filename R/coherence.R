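#' Coherence estimation parameters
#'
#' Fixed FFT length of 2^11 samples, a 0-100 mHz analysis range divided
#' into (2^11/2) + 1 = 1025 frequency bins, Hann-tapered Welch segments
#' with 50\% overlap. Segments shorter than `nfft` are zero-padded onto
#' the `nfft` bin grid so the bin layout is independent of the window
#' length.
#'
#' @param nfft FFT length (power of two, default 2^11).
#' @param fMaxMHz Upper band edge, mHz (default 100; clipped to Nyquist).
#' @param overlap Fractional segment overlap (default 0.5).
#' @param segLength Optional fixed segment length in samples; by default
#'   min(nfft, floor(L / 3)) for a window of L samples, giving about five
#'   half-overlapping averaging segments (always at least two). Shorter
#'   segments trade frequency resolution for a smaller single-segment
#'   bias of the coherence estimate.
#' @return A list of class `coherenceParams`.
#' @export
coherenceParams <- function(nfft = 2^11, fMaxMHz = 100, overlap = 0.5,
                            segLength = NULL) {
  if (!isCount(nfft) || bitwAnd(as.integer(nfft), as.integer(nfft) - 1L) != 0L) {
    stop("nfft must be a power of two", call. = FALSE)
  }
  if (overlap < 0 || overlap >= 1) stop("overlap must lie in [0, 1)",
                                        call. = FALSE)
  structure(list(nfft = as.integer(nfft), fMaxMHz = fMaxMHz,
                 overlap = overlap, segLength = segLength),
            class = "coherenceParams")
}

# Segment start indices / length for a window of L samples.
segmentLayout <- function(L, params) {
  seg <- params$segLength
  if (is.null(seg)) seg <- min(params$nfft, floor(L / 3))
  seg <- as.integer(seg)
  if (seg < 8) {
    stop("window too short for coherence estimation (segment length ",
         seg, " < 8 samples)", call. = FALSE)
  }
  step <- max(1L, as.integer(floor(seg * (1 - params$overlap))))
  starts <- seq.int(1L, L - seg + 1L, by = step)
  if (length(starts) < 2) {
    stop("fewer than 2 averaging segments: magnitude-squared coherence ",
         "is identically 1 for a single segment; shorten segLength or ",
         "lengthen the window", call. = FALSE)
  }
  list(starts = starts, segLength = seg)
}

# FFTs of the Hann-tapered, demeaned, zero-padded segments of x.
# Returns a (nBins x nSegments) complex matrix for bins 1..nBins.
segmentFFT <- function(x, layout, nfft, nBins) {
  w <- hannWindow(layout$segLength)
  vapply(layout$starts, function(s) {
    seg <- x[s:(s + layout$segLength - 1L)]
    seg <- (seg - mean(seg)) * w
    stats::fft(c(seg, rep(0, nfft - layout$segLength)))[seq_len(nBins)]
  }, complex(nBins))
}

mscFromFFT <- function(X, Y) {
  Sxy <- rowMeans(X * Conj(Y))
  Sxx <- rowMeans(Re(X * Conj(X)))
  Syy <- rowMeans(Re(Y * Conj(Y)))
  denom <- Sxx * Syy
  msc <- ifelse(denom > 0, Mod(Sxy)^2 / denom, NA_real_)
  pmin(pmax(msc, 0), 1)
}

#' Magnitude-squared coherence between two signals
#'
#' Welch-averaged magnitude-squared coherence
#' |S_xy|^2 / (S_xx S_yy) on the 0-`fMaxMHz` frequency grid. Values lie
#' in [0, 1]: 1 means the two signals oscillate synchronously at that
#' frequency. Invariant under affine transforms of either input. At
#' least two averaging segments are required (with one segment the
#' estimator is identically 1).
#'
#' @param x,y Numeric signals of equal length.
#' @param dt Frame interval, seconds.
#' @param params A [coherenceParams()].
#' @return A data.frame with columns `freqMHz`, `coherence`; attribute
#'   `nSegments`.
#' @export
msc <- function(x, y, dt, params = coherenceParams()) {
  stopifnot(length(x) == length(y))
  layout <- segmentLayout(length(x), params)
  nyqMHz <- 1000 / (2 * dt)
  freq <- (0:(params$nfft / 2)) * 1000 / (params$nfft * dt)
  keep <- freq <= min(params$fMaxMHz, nyqMHz) + 1e-9
  nBins <- max(which(keep))
  X <- segmentFFT(x, layout, params$nfft, nBins)
  Y <- segmentFFT(y, layout, params$nfft, nBins)
  out <- data.frame(freqMHz = freq[seq_len(nBins)],
                    coherence = mscFromFFT(X, Y))
  attr(out, "nSegments") <- length(layout$starts)
  out
}

#' Mean nearest-neighbour coherence per mitochondrion
#'
#' For every mitochondrion and evaluated frame, the band-averaged (0-100
#' mHz) magnitude-squared coherence with each of its spatial lattice
#' neighbours is computed on the running window `Tw` centred at the
#' frame, then averaged over neighbours. Pairs whose windowed segments
#' carry no power (e.g. constant signals) contribute coherence 0, since
#' no oscillatory synchrony is detectable.
#'
#' @param signals A [MitoSignalSet-class].
#' @param frames Frames to evaluate (default: all with a full window).
#' @param Tw Window length, seconds.
#' @param params A [coherenceParams()].
#' @return Numeric matrix (mitochondria x evaluated frames) with the
#'   evaluated frames as attribute `frames`; isolated lattice vertices
#'   are `NA` with a warning.
#' @export
neighborCoherence <- function(signals, frames = NULL, Tw,
                              params = coherenceParams()) {
  dt <- frameInterval(signals)
  sig <- intensity(signals)
  N <- ncol(sig); M <- nrow(sig)
  A <- latticeAdjacency(signals)
  if (any(rowSums(A) == 0)) {
    warning("isolated lattice vertices get NA coherence: ",
            paste(which(rowSums(A) == 0), collapse = ", "))
  }
  minSamples <- windowMinSamples(Tw, dt)
  if (is.null(frames)) frames <- seq_len(N)
  frames <- as.integer(frames[vapply(frames, function(t) {
    length(windowFrames(t, N, Tw, dt)) >= minSamples
  }, logical(1))])
  nyqMHz <- 1000 / (2 * dt)
  freq <- (0:(params$nfft / 2)) * 1000 / (params$nfft * dt)
  nBins <- max(which(freq <= min(params$fMaxMHz, nyqMHz) + 1e-9))
  out <- matrix(NA_real_, M, length(frames))
  for (i in seq_along(frames)) {
    idx <- windowFrames(frames[i], N, Tw, dt)
    layout <- segmentLayout(length(idx), params)
    ffts <- lapply(seq_len(M), function(m) {
      segmentFFT(sig[m, idx], layout, params$nfft, nBins)
    })
    pairCache <- new.env(hash = TRUE)
    for (m in seq_len(M)) {
      nb <- which(A[m, ])
      if (length(nb) == 0) next
      vals <- vapply(nb, function(j) {
        key <- paste(min(m, j), max(m, j))
        if (!is.null(pairCache[[key]])) return(pairCache[[key]])
        co <- mscFromFFT(ffts[[m]], ffts[[j]])
        v <- mean(co, na.rm = FALSE)
        if (is.na(v)) v <- 0  # zero-power pair: no detectable synchrony
        pairCache[[key]] <- v
        v
      }, numeric(1))
      out[m, i] <- mean(vals)
    }
  }
  attr(out, "frames") <- frames
  out
}

#' Average coherence of the major cluster
#'
#' Mean of the per-mitochondrion nearest-neighbour coherence over the
#' major-cluster members at each frame where both are defined.
#'
#' @param coh Matrix from [neighborCoherence()].
#' @param cluster A [MajorClusterSeries-class].
#' @return A data.frame `frame`, `clusterCoherence` (NA when the cluster
#'   is empty at a frame).
#' @export
clusterCoherence <- function(coh, cluster) {
  cframes <- attr(coh, "frames")
  common <- intersect(cframes, clusterFrames(cluster))
  vapply(common, function(t) {
    mem <- clusterMembership(cluster)[, match(t, clusterFrames(cluster))]
    if (!any(mem)) return(NA_real_)
    mean(coh[mem, match(t, cframes)], na.rm = TRUE)
  }, numeric(1)) -> v
  data.frame(frame = common, clusterCoherence = v)
}

#' Rescale a time series onto the normalized [0, 1] time axis
#'
#' Sets the duration of the recording to 1 and linearly resamples the
#' series onto a fixed grid so that myocytes with unequal recording
#' durations can be averaged.
#'
#' @param time Time stamps (seconds, or frames).
#' @param values Series values at `time`.
#' @param nOut Number of output grid points (default 101).
#' @return A data.frame `t` (in [0, 1]) and `value`.
#' @export
normalizeTime <- function(time, values, nOut = 101) {
  stopifnot(length(time) == length(values), length(time) >= 2)
  dur <- max(time) - min(time)
  if (dur <= 0) stop("duration must be positive", call. = FALSE)
  tt <- (time - min(time)) / dur
  grid <- seq(0, 1, length.out = nOut)
  ok <- !is.na(values)
  if (sum(ok) < 2) {
    return(data.frame(t = grid, value = NA_real_))
  }
  data.frame(t = grid,
             value = stats::approx(tt[ok], values[ok], xout = grid,
                                   rule = 2)$y)
}
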