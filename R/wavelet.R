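#' Morlet wavelet scale grid
#'
#' Builds the geometric scale grid used throughout the frequency analysis:
#' scales s_j = s0 * 2^((j-1) * dj) for j = 1..j1 with
#' j1 = floor(log2(N / s0_samples) / dj) + 1, so that each octave is split
#' into 1/dj sub-scales. The smallest scale s0 defaults to 4*dt, the
#' smallest period at which one oscillation is detectable.
#'
#' @param N Number of frames.
#' @param dt Frame interval, seconds.
#' @param dj Spacing between scales (default 0.1).
#' @param s0 Smallest scale, seconds (default 4*dt).
#' @param omega0 Morlet central frequency (default 6, the standard
#'   admissible choice).
#' @return A list of class `waveletParams`: `dj`, `s0`, `j1`, `omega0`,
#'   `scales` (seconds), `freqMHz` (Fourier-equivalent frequencies) and
#'   `fourierFactor`.
#' @examples
#' p <- scaleGrid(N = 1024, dt = 0.5)
#' p$j1   # 81 scales
#' @export
scaleGrid <- function(N, dt, dj = 0.1, s0 = 4 * dt, omega0 = 6) {
  if (!isCount(N) || N < 8) stop("N must be an integer >= 8", call. = FALSE)
  if (!is.numeric(dj) || dj <= 0) stop("dj must be > 0", call. = FALSE)
  if (!is.numeric(s0) || s0 < 2 * dt) {
    stop("s0 must be at least 2*dt (Nyquist period)", call. = FALSE)
  }
  s0Samples <- s0 / dt
  j1 <- floor(log2(N / s0Samples) / dj) + 1
  if (j1 < 2) {
    stop("record too short for the requested scale grid (j1 = ", j1, " < 2)",
         call. = FALSE)
  }
  scales <- s0 * 2^((seq_len(j1) - 1) * dj)
  ff <- 4 * pi / (omega0 + sqrt(2 + omega0^2))  # period = ff * scale
  out <- list(dj = dj, s0 = s0, j1 = as.integer(j1), omega0 = omega0,
              scales = scales, fourierFactor = ff,
              freqMHz = 1000 / (ff * scales))
  class(out) <- "waveletParams"
  out
}

#' Continuous Morlet wavelet power of one signal
#'
#' Computes |W(s, t)|^2 on the scale grid via the Fourier-domain method:
#' the demeaned, zero-padded signal is multiplied in the frequency domain
#' by the Morlet transfer function
#' psi_hat(s w) = pi^(-1/4) H(w) exp(-(s w - omega0)^2 / 2), normalized by
#' sqrt(2 pi s / dt). Scales convert to Fourier-equivalent frequencies via
#' f = (omega0 + sqrt(2 + omega0^2)) / (4 pi s). Values inside the cone of
#' influence (e-folding distance sqrt(2)*s from either record edge) are
#' kept but the cone is reported for annotation.
#'
#' @param x Numeric signal of length N (all finite).
#' @param dt Frame interval, seconds.
#' @param params Optional [scaleGrid()] result; built from defaults
#'   otherwise.
#' @param ... Passed to [scaleGrid()] when `params` is `NULL`.
#' @return A list of class `powerSpectrum`: `power` (j1 x N matrix,
#'   intensity^2), `scales`, `freqMHz`, `coiScale` (largest scale free of
#'   edge effects per frame), `params`, `dt`.
#' @export
cwtPower <- function(x, dt, params = NULL, ...) {
  if (anyNA(x) || any(!is.finite(x))) {
    stop("signal contains missing or non-finite samples", call. = FALSE)
  }
  N <- length(x)
  if (is.null(params)) params <- scaleGrid(N, dt, ...)
  stopifnot(inherits(params, "waveletParams"))
  npad <- nextPow2(N)
  xd <- c(x - mean(x), rep(0, npad - N))
  xhat <- stats::fft(xd)
  k <- seq_len(npad) - 1L
  omega <- ifelse(k <= npad / 2, 2 * pi * k / (npad * dt),
                  -2 * pi * (npad - k) / (npad * dt))
  W <- matrix(0 + 0i, params$j1, N)
  norm0 <- pi^(-0.25)
  for (j in seq_len(params$j1)) {
    s <- params$scales[j]
    psihat <- norm0 * sqrt(2 * pi * s / dt) * (omega > 0) *
      exp(-((s * omega - params$omega0)^2) / 2 * (omega > 0))
    w <- stats::fft(xhat * psihat, inverse = TRUE) / npad
    W[j, ] <- w[seq_len(N)]
  }
  coiScale <- dt * pmin(seq_len(N) - 1L, N - seq_len(N)) / sqrt(2)
  out <- list(power = Mod(W)^2, scales = params$scales,
              freqMHz = params$freqMHz, coiScale = coiScale,
              params = params, dt = dt)
  class(out) <- "powerSpectrum"
  out
}

#' Frequency band and running-window parameters
#'
#' From the longest synchronized oscillation period T, the band cutoffs
#' are nu_min = 1/(1.1 T) and nu_max = 1/s0, and the running correlation
#' window is Tw = 1.1 T.
#'
#' @param T Longest synchronized oscillation period, seconds.
#' @param s0 Smallest wavelet scale, seconds (sets nu_max = 1/s0).
#' @return A list of class `frequencyBand`: `nuMinMHz`, `nuMaxMHz`,
#'   `T`, `Tw` (seconds).
#' @export
frequencyBand <- function(T, s0) {
  if (!is.numeric(T) || T <= 0) stop("T must be positive", call. = FALSE)
  if (!is.numeric(s0) || s0 <= 0) stop("s0 must be positive", call. = FALSE)
  nuMin <- 1000 / (1.1 * T)
  nuMax <- 1000 / s0
  if (nuMin >= nuMax) {
    stop("empty frequency band: 1/(1.1*T) must be below 1/s0", call. = FALSE)
  }
  structure(list(nuMinMHz = nuMin, nuMaxMHz = nuMax, T = T, Tw = 1.1 * T),
            class = "frequencyBand")
}

#' Estimate the band from the data
#'
#' Fallback when the longest synchronized period T is not supplied: the
#' dominant frequency of every mitochondrion is measured over the full
#' scale range, and T is the reciprocal of the lower quartile of the
#' per-mitochondrion median dominant frequencies (so the band's slow edge
#' sits below the bulk of the observed oscillations).
#'
#' @param signals A [MitoSignalSet-class].
#' @param dj,s0Mult,omega0 Wavelet grid parameters (s0 = s0Mult * dt).
#' @return A [frequencyBand()].
#' @export
estimateBand <- function(signals, dj = 0.1, s0Mult = 4, omega0 = 6) {
  sig <- intensity(signals)
  dt <- frameInterval(signals)
  params <- scaleGrid(ncol(sig), dt, dj = dj, s0 = s0Mult * dt,
                      omega0 = omega0)
  med <- apply(sig, 1, function(x) {
    p <- cwtPower(x, dt, params = params)
    peak <- apply(p$power, 2, which.max)
    stats::median(params$freqMHz[peak])
  })
  q1 <- stats::quantile(med, 0.25, names = FALSE)
  frequencyBand(T = 1000 / q1, s0 = s0Mult * dt)
}

#' FrequencyTrack: dominant oscillation frequency over time
#'
#' S4 container for the band-limited dominant-frequency track of every
#' mitochondrion: an M x N matrix in mHz plus a flag matrix marking
#' entries whose band power is below the detection floor (non-oscillating
#' mitochondria or empty frames).
#'
#' @slot frequency M x N numeric matrix, mHz (NA where flagged).
#' @slot flagged M x N logical matrix.
#' @slot band The [frequencyBand()] used.
#' @slot coi Logical M x N matrix, TRUE where every band scale is outside
#'   the cone of influence (edge-clean).
#' @exportClass FrequencyTrack
setClass("FrequencyTrack",
         representation(frequency = "matrix", flagged = "matrix",
                        band = "list", coi = "matrix"))

setValidity("FrequencyTrack", function(object) {
  f <- object@frequency[!object@flagged]
  b <- object@band
  tol <- 1e-9
  if (length(f) && (any(f < b$nuMinMHz - tol) || any(f > b$nuMaxMHz + tol))) {
    return("unflagged track values outside [nuMin, nuMax]")
  }
  TRUE
})

setMethod("show", "FrequencyTrack", function(object) {
  cat(sprintf("FrequencyTrack: %d mitochondria x %d frames, band %.2f-%.2f mHz; %.1f%% flagged\n",
              nrow(object@frequency), ncol(object@frequency),
              object@band$nuMinMHz, object@band$nuMaxMHz,
              100 * mean(object@flagged)))
})

#' @describeIn FrequencyTrack-class Track matrix (mHz, NA where flagged).
#' @param x A FrequencyTrack.
#' @export
trackFrequency <- function(x) x@frequency

#' @describeIn FrequencyTrack-class Logical matrix of sub-floor entries.
#' @export
trackFlagged <- function(x) x@flagged

#' Dominant-frequency track of a signal set
#'
#' For every mitochondrion and frame, the wavelet power between nu_min and
#' nu_max is interpolated onto a 0.1 mHz grid with a piecewise-cubic
#' spline and the frequency of maximum interpolated power is taken; ties
#' break toward the lower frequency. Entries are flagged when a frame has
#' zero band power; a whole mitochondrion is flagged as non-oscillating
#' when its time-averaged band power falls below `powerFloor` times the
#' myocyte-median band power.
#'
#' @param signals A [MitoSignalSet-class] (or numeric matrix with `dt`).
#' @param band A [frequencyBand()]; estimated via [estimateBand()] when
#'   `NULL`.
#' @param dt Frame interval (ignored for a MitoSignalSet).
#' @param dj,s0Mult,omega0 Wavelet grid parameters.
#' @param powerFloor Fraction of the myocyte-median band power below
#'   which a mitochondrion is flagged non-oscillating (default 0.05).
#' @param gridStepMHz Interpolation step (default 0.1 mHz).
#' @return A [FrequencyTrack-class].
#' @export
dominantFrequency <- function(signals, band = NULL, dt = NULL, dj = 0.1,
                              s0Mult = 4, omega0 = 6, powerFloor = 0.05,
                              gridStepMHz = 0.1) {
  if (methods::is(signals, "MitoSignalSet")) {
    sig <- intensity(signals)
    dt <- frameInterval(signals)
  } else {
    sig <- as.matrix(signals)
    if (is.null(dt)) stop("dt is required for a plain matrix", call. = FALSE)
  }
  M <- nrow(sig); N <- ncol(sig)
  params <- scaleGrid(N, dt, dj = dj, s0 = s0Mult * dt, omega0 = omega0)
  if (is.null(band)) {
    band <- if (methods::is(signals, "MitoSignalSet")) {
      estimateBand(signals, dj = dj, s0Mult = s0Mult, omega0 = omega0)
    } else stop("band is required for a plain matrix", call. = FALSE)
  }
  sel <- which(params$freqMHz >= band$nuMinMHz - 1e-9 &
               params$freqMHz <= band$nuMaxMHz + 1e-9)
  if (length(sel) < 2) {
    stop("frequency band [", band$nuMinMHz, ", ", band$nuMaxMHz,
         "] mHz covers fewer than two wavelet scales", call. = FALSE)
  }
  fsel <- params$freqMHz[sel]
  ord <- order(fsel)
  fGrid <- seq(max(band$nuMinMHz, min(fsel)), min(band$nuMaxMHz, max(fsel)),
               by = gridStepMHz)
  freq <- matrix(NA_real_, M, N, dimnames = dimnames(sig))
  flagged <- matrix(FALSE, M, N, dimnames = dimnames(sig))
  bandPower <- numeric(M)
  coi <- matrix(FALSE, M, N, dimnames = dimnames(sig))
  maxScale <- max(params$scales[sel])
  for (m in seq_len(M)) {
    p <- cwtPower(sig[m, ], dt, params = params)
    bp <- p$power[sel, , drop = FALSE][ord, , drop = FALSE]
    bandPower[m] <- mean(bp)
    coi[m, ] <- p$coiScale >= maxScale
    for (t in seq_len(N)) {
      y <- bp[, t]
      if (sum(y) <= 0) { flagged[m, t] <- TRUE; next }
      yi <- stats::spline(fsel[ord], y, xout = fGrid, method = "fmm")$y
      freq[m, t] <- fGrid[which.max(yi)]
    }
  }
  floorVal <- powerFloor * stats::median(bandPower)
  nonOsc <- bandPower < floorVal
  flagged[nonOsc, ] <- TRUE
  freq[flagged] <- NA_real_
  methods::new("FrequencyTrack", frequency = freq, flagged = flagged,
               band = unclass(band), coi = coi)
}

#' Frames outside the cone of influence for a whole band
#'
#' A frame is edge-clean for the band when its distance to both record
#' edges exceeds the e-folding time sqrt(2)*s of the slowest band scale
#' (the scale of nu_min).
#'
#' @param N Number of frames.
#' @param dt Frame interval, seconds.
#' @param nuMinMHz Slow edge of the band, mHz.
#' @param omega0 Morlet central frequency.
#' @return Logical vector of length N.
#' @export
coiFrames <- function(N, dt, nuMinMHz, omega0 = 6) {
  ff <- 4 * pi / (omega0 + sqrt(2 + omega0^2))
  sMax <- (1000 / nuMinMHz) / ff
  d <- dt * pmin(seq_len(N) - 1L, N - seq_len(N))
  d >= sqrt(2) * sMax
}
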