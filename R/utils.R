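# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed (when non-NULL), evaluates `expr`, and restores the
#' caller's RNG state so that seeded package functions never perturb the
#' global random stream.
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(seed)
  }
  force(expr)
}

#' Frame indices of a running window centred at a frame
#'
#' The window spans `Tw` seconds centred on `frame` and is truncated at the
#' record edges, never padded. Returns an integer vector of frame indices.
#' @noRd
windowFrames <- function(frame, nFrames, Tw, dt) {
  if (!is.numeric(Tw) || Tw <= 0) {
    stop("window length 'Tw' must be positive", call. = FALSE)
  }
  half <- round(Tw / (2 * dt))
  idx <- seq.int(max(1L, frame - half), min(nFrames, frame + half))
  idx
}

#' Minimum sample count a truncated window must retain
#' @noRd
windowMinSamples <- function(Tw, dt) {
  max(4L, as.integer(round(Tw / (2 * dt))))
}

# Symmetric Hann taper of length n with non-zero endpoints, as used for
# Welch segment averaging.
hannWindow <- function(n) {
  if (n == 1L) return(1)
  0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1L))
}

# Local maxima of a numeric vector with plateau ties broken toward the
# lowest index. Boundary runs count as maxima when the inner neighbour is
# strictly lower. Returns integer indices.
localMaxima <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nrun <- length(r$values)
  out <- integer(0)
  for (j in seq_len(nrun)) {
    left <- if (j == 1L) -Inf else r$values[j - 1L]
    right <- if (j == nrun) -Inf else r$values[j + 1L]
    if (r$values[j] > left && r$values[j] > right) {
      out <- c(out, starts[j])
    }
  }
  out
}

# Topographic prominence of the peaks at indices `peaks` of vector x.
# For each peak, walk outwards to the nearest strictly higher sample on
# each side (or the record edge); the prominence is the peak height minus
# the higher of the two intervening minima.
peakProminence <- function(x, peaks) {
  n <- length(x)
  vapply(peaks, function(p) {
    h <- x[p]
    li <- p; base_l <- h
    while (li > 1L) {
      li <- li - 1L
      if (x[li] > h) break
      base_l <- min(base_l, x[li])
    }
    ri <- p; base_r <- h
    while (ri < n) {
      ri <- ri + 1L
      if (x[ri] > h) break
      base_r <- min(base_r, x[ri])
    }
    h - max(base_l, base_r)
  }, numeric(1))
}

# Prominence- and separation-filtered local extrema.
# Returns indices of retained peaks, greedily by decreasing height.
filteredPeaks <- function(x, minProminence, minSeparation) {
  cand <- localMaxima(x)
  if (length(cand) == 0L) return(integer(0))
  prom <- peakProminence(x, cand)
  cand <- cand[prom >= minProminence]
  if (length(cand) <= 1L) return(cand)
  ord <- cand[order(x[cand], decreasing = TRUE)]
  keep <- integer(0)
  for (p in ord) {
    if (all(abs(p - keep) >= minSeparation)) keep <- c(keep, p)
  }
  sort(keep)
}

# Next power of two >= n.
nextPow2 <- function(n) {
  2^ceiling(log2(max(1, n)))
}

#' @noRd
isCount <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == round(x)
}
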