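#' Pipeline configuration
#'
#' Collects every threshold of the analysis with its standard default:
#' wavelet spacing dj = 0.1, smallest scale s0 = 4 dt, peak significance
#' 0.10, merge/recruit correlation 0.95, functional cutoff theta = 0.90,
#' running window Tw = 1.1 T, coherence FFT length 2^11 and band 0-100
#' mHz.
#'
#' @param T Longest synchronized oscillation period, seconds (estimated
#'   from the data when `NULL`).
#' @param dj,s0Mult,omega0 Wavelet parameters (s0 = s0Mult * dt).
#' @param binWidth Frequency histogram bin width, mHz.
#' @param peakFrac Histogram peak significance fraction.
#' @param mergeThreshold Merge/recruit correlation threshold.
#' @param cutoff Functional connectivity cutoff theta.
#' @param TwMult Running window multiple of T.
#' @param nfft,fMaxMHz Coherence FFT length and band edge.
#' @param nNull ER-null realizations per frame.
#' @param frameBy Evaluate the clustering/cluster stages every
#'   `frameBy`-th frame.
#' @param coherenceBy Evaluate coherence every `coherenceBy`-th frame
#'   (it is the costliest stage).
#' @param powerFloor Non-oscillating power floor fraction.
#' @param seed Integer seed governing every stochastic stage.
#' @return A validated list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(T = NULL, dj = 0.1, s0Mult = 4, omega0 = 6,
                           binWidth = 1, peakFrac = 0.10,
                           mergeThreshold = 0.95, cutoff = 0.90,
                           TwMult = 1.1, nfft = 2^11, fMaxMHz = 100,
                           nNull = 20, frameBy = 4, coherenceBy = 8,
                           powerFloor = 0.05, seed = 1L) {
  cfg <- list(T = T, dj = dj, s0Mult = s0Mult, omega0 = omega0,
              binWidth = binWidth, peakFrac = peakFrac,
              mergeThreshold = mergeThreshold, cutoff = cutoff,
              TwMult = TwMult, nfft = nfft, fMaxMHz = fMaxMHz,
              nNull = nNull, frameBy = frameBy, coherenceBy = coherenceBy,
              powerFloor = powerFloor, seed = as.integer(seed))
  if (cfg$dj <= 0 || cfg$s0Mult < 2) {
    stop("invalid configuration: dj must be > 0 and s0Mult >= 2",
         call. = FALSE)
  }
  if (cfg$cutoff <= -1 || cfg$cutoff >= 1) {
    stop("invalid configuration: cutoff must lie in (-1, 1)", call. = FALSE)
  }
  if (cfg$mergeThreshold <= 0 || cfg$mergeThreshold > 1) {
    stop("invalid configuration: mergeThreshold must lie in (0, 1]",
         call. = FALSE)
  }
  if (cfg$TwMult <= 0) stop("invalid configuration: TwMult must be > 0",
                            call. = FALSE)
  class(cfg) <- "pipelineConfig"
  cfg
}

#' ClusteringReport: full analysis bundle
#'
#' Result of [runPipeline()]: the per-frame summary (mean clustering C,
#' matched ER-null mean/sd, mean-field correlation c(t), cluster area,
#' frequency and coherence), amplitude events, the frequency track, the
#' major-cluster series, the fitted relation parameters and a manifest.
#'
#' @slot summary Per-frame data.frame.
#' @slot events Amplitude-event data.frame.
#' @slot track The [FrequencyTrack-class].
#' @slot cluster The [MajorClusterSeries-class].
#' @slot relations List of relation fits.
#' @slot config The [pipelineConfig()] used.
#' @slot manifest List: seed, band, dimensions, package version.
#' @exportClass ClusteringReport
setClass("ClusteringReport",
         representation(summary = "data.frame", events = "data.frame",
                        track = "ANY", cluster = "ANY",
                        relations = "list", config = "list",
                        manifest = "list"))

setMethod("show", "ClusteringReport", function(object) {
  s <- object@summary
  cat(sprintf("ClusteringReport: %d evaluated frames\n", nrow(s)))
  cat(sprintf("  time-averaged mean clustering C = %.3f (ER null %.3f +/- %.3f)\n",
              mean(s$C, na.rm = TRUE), mean(s$CNullMean, na.rm = TRUE),
              mean(s$CNullSd, na.rm = TRUE)))
  cat(sprintf("  time-averaged mean-field correlation c = %.3f\n",
              mean(s$meanField, na.rm = TRUE)))
})

#' @describeIn ClusteringReport-class Per-frame summary table.
#' @param x A ClusteringReport.
#' @export
reportSummary <- function(x) x@summary

#' @describeIn ClusteringReport-class Relation fit list.
#' @export
reportRelations <- function(x) x@relations

#' Run the full dynamic functional-clustering analysis
#'
#' Executes the pipeline on a signal set: frequency band estimation ->
#' wavelet dominant-frequency tracks -> dynamic major cluster ->
#' windowed-correlation functional graphs, clustering coefficients and
#' matched ER nulls -> mean-field correlation -> nearest-neighbour
#' coherence -> amplitude events -> cluster-property relation fits.
#' Fully reproducible from the configuration seed.
#'
#' @param signals A [MitoSignalSet-class], or `NULL` to simulate from
#'   `synthetic`.
#' @param config A [pipelineConfig()].
#' @param synthetic Optional [syntheticConfig()] used when `signals` is
#'   `NULL`.
#' @return A [ClusteringReport-class].
#' @export
runPipeline <- function(signals = NULL, config = pipelineConfig(),
                        synthetic = NULL) {
  stopifnot(inherits(config, "pipelineConfig"))
  if (is.null(signals)) {
    if (is.null(synthetic)) {
      stop("either signals or a synthetic configuration must be supplied",
           call. = FALSE)
    }
    signals <- simulateNetwork(synthetic)$signals
  }
  stopifnot(methods::is(signals, "MitoSignalSet"))
  dt <- frameInterval(signals)
  N <- ncol(signals)
  s0 <- config$s0Mult * dt

  band <- if (is.null(config$T)) {
    estimateBand(signals, dj = config$dj, s0Mult = config$s0Mult,
                 omega0 = config$omega0)
  } else {
    b <- frequencyBand(config$T, s0)
    b$Tw <- config$TwMult * config$T
    b
  }

  track <- dominantFrequency(signals, band = band, dj = config$dj,
                             s0Mult = config$s0Mult, omega0 = config$omega0,
                             powerFloor = config$powerFloor)
  frames <- seq(1L, N, by = config$frameBy)
  cluster <- majorCluster(signals, track, band = band, frames = frames,
                          binWidth = config$binWidth,
                          peakFrac = config$peakFrac,
                          threshold = config$mergeThreshold)
  series <- clusteringSeries(signals, frames = clusterFrames(cluster),
                             Tw = band$Tw, cutoff = config$cutoff,
                             nNull = config$nNull, seed = config$seed,
                             membership = clusterMembership(cluster))
  cohFrames <- clusterFrames(cluster)[
    seq(1L, length(clusterFrames(cluster)),
        by = max(1L, config$coherenceBy %/% config$frameBy))]
  coh <- neighborCoherence(signals, frames = cohFrames, Tw = band$Tw,
                           params = coherenceParams(nfft = config$nfft,
                                                    fMaxMHz = config$fMaxMHz))
  cc <- clusterCoherence(coh, cluster)

  summary <- series
  summary$area <- clusterArea(cluster)[match(summary$frame,
                                             clusterFrames(cluster))]
  summary$clusterFrequency <- clusterMeanFrequency(cluster)[
    match(summary$frame, clusterFrames(cluster))]
  summary$clusterCoherence <- cc$clusterCoherence[match(summary$frame,
                                                        cc$frame)]
  class(summary) <- "data.frame"

  meanSig <- clusterMeanSignal(cluster)
  events <- if (all(is.na(meanSig))) {
    amplitudeEvents(rep(0, 8), dt)[0, ]
  } else {
    amplitudeEvents(meanSig, dt * config$frameBy,
                    minSeparation = max(2, config$s0Mult %/% config$frameBy + 1))
  }
  if (nrow(events) > 0) {
    evFrame <- clusterFrames(cluster)[events$peakFrame]
    events$frame <- evFrame
    events$C <- summary$C[match(evFrame, summary$frame)]
  }
  class(events) <- "data.frame"

  relations <- relationFits(summary, events)

  manifest <- list(seed = config$seed, band = unclass(band),
                   M = nrow(signals), N = N, dt = dt,
                   package = as.character(utils::packageVersion("mitonet")))
  methods::new("ClusteringReport", summary = summary, events = events,
               track = track, cluster = cluster, relations = relations,
               config = unclass(config), manifest = manifest)
}

# Per-frame relation fits between mean clustering and the major-cluster
# properties (coherence, frequency, area linear; normalized amplitude
# exponential).
relationFits <- function(summary, events) {
  out <- list()
  tryFit <- function(expr) tryCatch(expr, error = function(e) {
    list(failed = TRUE, message = conditionMessage(e))
  })
  ok <- stats::complete.cases(summary[, c("C", "clusterCoherence")])
  if (sum(ok) >= 3 && stats::sd(summary$clusterCoherence[ok]) > 0) {
    out$coherence <- tryFit(fitLinear(summary$clusterCoherence[ok],
                                      summary$C[ok]))
  }
  ok <- stats::complete.cases(summary[, c("C", "clusterFrequency")])
  if (sum(ok) >= 3 && stats::sd(summary$clusterFrequency[ok]) > 0) {
    out$frequency <- tryFit(fitLinear(summary$clusterFrequency[ok],
                                      summary$C[ok]))
  }
  ok <- stats::complete.cases(summary[, c("C", "area")])
  if (sum(ok) >= 3 && stats::sd(summary$area[ok]) > 0) {
    out$area <- tryFit(fitLinear(summary$area[ok], summary$C[ok]))
  }
  if (nrow(events) >= 4 && !all(is.na(events$C)) &&
      stats::sd(events$normAmplitude) > 0) {
    out$amplitude <- tryFit(fitExponential(events$normAmplitude, events$C))
  }
  out
}

#' Exponential fit f(x) = a * exp(-x / b) + c
#'
#' Nonlinear least squares with multi-start initialization: c starts at
#' the right-tail mean, a at (first - last), b at the reciprocal
#' log-slope of |y - c|, each jittered by factors 0.5/1/2 (both signs of
#' b are tried). Standard errors come from the covariance at the
#' optimum.
#'
#' @param x,y Numeric vectors (at least 4 points).
#' @return A list: `estimate` (a, b, c), `se`, `residualSd`, `fitted`,
#'   `converged`.
#' @export
fitExponential <- function(x, y) {
  if (length(x) < 4) stop("at least 4 points are required", call. = FALSE)
  stopifnot(length(x) == length(y))
  ord <- order(x)
  xo <- x[ord]; yo <- y[ord]
  nTail <- max(2L, ceiling(length(yo) / 5))
  c0 <- mean(yo[(length(yo) - nTail + 1):length(yo)])
  a0 <- yo[1] - yo[length(yo)]
  if (a0 == 0) a0 <- stats::sd(yo) + 1e-8
  res <- abs(yo - c0); res[res < 1e-12] <- NA
  slope <- tryCatch(unname(stats::coef(stats::lm(log(res) ~ xo))[2]),
                    error = function(e) NA_real_)
  b0 <- if (is.finite(slope) && slope != 0) -1 / slope else diff(range(xo)) / 2
  if (!is.finite(b0) || b0 == 0) b0 <- diff(range(xo)) / 2
  starts <- expand.grid(fa = c(0.5, 1, 2), fb = c(0.5, 1, 2),
                        sb = c(1, -1))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    st <- list(a = a0 * starts$fa[i], b = b0 * starts$fb[i] * starts$sb[i],
               c = c0)
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        y ~ a * exp(-x / b) + c,
        start = st, data = data.frame(x = x, y = y),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    stop("exponential fit failed to converge from every start", call. = FALSE)
  }
  fit <- best$fit
  est <- stats::setNames(stats::coef(fit), c("a", "b", "c"))
  se <- tryCatch(stats::setNames(sqrt(diag(stats::vcov(fit))),
                                 c("a", "b", "c")),
                 error = function(e) stats::setNames(rep(NA_real_, 3),
                                                     c("a", "b", "c")))
  list(estimate = est, se = se,
       residualSd = sqrt(best$rss / max(1, length(x) - 3)),
       fitted = stats::fitted(fit), converged = TRUE,
       model = "a * exp(-x/b) + c")
}

#' Ordinary least-squares line fit
#'
#' @param x,y Numeric vectors (at least 3 points, non-constant x).
#' @return A list: `estimate` (slope, intercept), `se`, `residualSd`,
#'   `fitted`.
#' @export
fitLinear <- function(x, y) {
  if (length(x) < 3) stop("at least 3 points are required", call. = FALSE)
  stopifnot(length(x) == length(y))
  if (stats::sd(x) == 0) stop("x has zero variance", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))
  cf <- sm$coefficients
  list(estimate = c(slope = cf["x", 1], intercept = cf["(Intercept)", 1]),
       se = c(slope = cf["x", 2], intercept = cf["(Intercept)", 2]),
       residualSd = sm$sigma, fitted = stats::fitted(fit),
       model = "slope * x + intercept")
}

#' Sweep the functional connectivity cutoff
#'
#' Computes, for each cutoff of a strictly increasing grid in (0, 1),
#' the time-averaged network mean clustering coefficient, fits
#' f(theta) = a exp(-theta/b) + c through the curve, and reports the
#' cutoff at which the fitted curve crosses mean clustering 0.5. The
#' windowed correlation matrices are computed once and re-thresholded,
#' so edge-count monotonicity in the cutoff is exact by construction.
#'
#' @param signals A [MitoSignalSet-class].
#' @param cutoffs Increasing cutoff grid in (0, 1).
#' @param frames Frames to evaluate (default every 8th valid frame).
#' @param Tw Window length, seconds.
#' @return A list of class `cutoffSweep`: `curve` (data.frame cutoff,
#'   meanC, meanEdges), `fit` (see [fitExponential()]; `NULL` when it
#'   fails), `halfCrossing` (cutoff where the fitted curve = 0.5, NA if
#'   none).
#' @export
cutoffSweep <- function(signals, cutoffs = seq(0.05, 0.95, by = 0.05),
                        frames = NULL, Tw) {
  if (any(diff(cutoffs) <= 0) || any(cutoffs <= 0) || any(cutoffs >= 1)) {
    stop("cutoffs must be strictly increasing within (0, 1)", call. = FALSE)
  }
  dt <- frameInterval(signals)
  N <- ncol(signals)
  minSamples <- windowMinSamples(Tw, dt)
  if (is.null(frames)) frames <- seq(1L, N, by = 8L)
  frames <- frames[vapply(frames, function(t) {
    length(windowFrames(t, N, Tw, dt)) >= minSamples
  }, logical(1))]
  corrs <- lapply(frames, function(t) windowedCorrelation(signals, t, Tw))
  meanC <- meanE <- numeric(length(cutoffs))
  for (i in seq_along(cutoffs)) {
    Cs <- vapply(corrs, function(corr) {
      adj <- functionalGraph(corr, cutoffs[i])
      c(meanClustering(adj), sum(adj[upper.tri(adj)]))
    }, numeric(2))
    meanC[i] <- mean(Cs[1, ])
    meanE[i] <- mean(Cs[2, ])
  }
  fit <- tryCatch(fitExponential(cutoffs, meanC), error = function(e) NULL)
  half <- NA_real_
  if (!is.null(fit)) {
    f <- function(th) fit$estimate["a"] * exp(-th / fit$estimate["b"]) +
      fit$estimate["c"] - 0.5
    lo <- min(cutoffs); hi <- max(cutoffs)
    if (is.finite(f(lo)) && is.finite(f(hi)) && f(lo) * f(hi) < 0) {
      half <- stats::uniroot(f, c(lo, hi))$root
    }
  }
  structure(list(curve = data.frame(cutoff = cutoffs, meanC = meanC,
                                    meanEdges = meanE),
                 fit = fit, halfCrossing = half, frames = frames),
            class = "cutoffSweep")
}

#' Average several myocyte reports on the normalized time axis
#'
#' Each report's per-frame series is rescaled to the [0, 1] time axis
#' ([normalizeTime()]) and resampled onto a common grid; the grand mean
#' and SD across reports are returned per quantity.
#'
#' @param reports List of [ClusteringReport-class] objects.
#' @param nOut Normalized grid size (default 101).
#' @param quantities Summary columns to aggregate.
#' @return A list of data.frames (one per quantity): `t`, `mean`, `sd`.
#' @export
aggregateMyocytes <- function(reports, nOut = 101,
                              quantities = c("C", "CNullMean", "meanField",
                                             "clusterCoherence")) {
  stopifnot(length(reports) >= 1)
  out <- list()
  for (q in quantities) {
    mat <- vapply(reports, function(r) {
      s <- reportSummary(r)
      if (!q %in% names(s)) return(rep(NA_real_, nOut))
      normalizeTime(s$time, s[[q]], nOut = nOut)$value
    }, numeric(nOut))
    mat <- matrix(mat, nrow = nOut)
    out[[q]] <- data.frame(
      t = seq(0, 1, length.out = nOut),
      mean = rowMeans(mat, na.rm = TRUE),
      sd = apply(mat, 1, stats::sd, na.rm = TRUE))
  }
  out
}

#' Write a report bundle to CSV files plus a JSON manifest
#'
#' Persists the summary series, membership, amplitude events and
#' relation parameters as CSV, and the run manifest (seed, band,
#' dimensions, thresholds, package version) as JSON. Identical
#' configuration and seed produce byte-identical files.
#'
#' @param report A [ClusteringReport-class].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
writeReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "summary.csv")
  utils::write.csv(reportSummary(report), p, row.names = FALSE)
  paths <- c(paths, p)
  mem <- clusterMembership(report@cluster)
  memDf <- data.frame(
    frame = rep(clusterFrames(report@cluster), each = nrow(mem)),
    mitochondrion = rep(seq_len(nrow(mem)), ncol(mem)),
    member = as.vector(mem))
  memDf <- memDf[memDf$member, c("frame", "mitochondrion")]
  p <- file.path(dir, "membership.csv")
  utils::write.csv(memDf, p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "events.csv")
  utils::write.csv(as.data.frame(report@events), p, row.names = FALSE)
  paths <- c(paths, p)
  rel <- report@relations
  relDf <- do.call(rbind, lapply(names(rel), function(nm) {
    r <- rel[[nm]]
    if (isTRUE(r$failed)) {
      return(data.frame(relation = nm, parameter = NA, estimate = NA,
                        se = NA))
    }
    data.frame(relation = nm, parameter = names(r$estimate),
               estimate = unname(r$estimate), se = unname(r$se))
  }))
  if (is.null(relDf)) {
    relDf <- data.frame(relation = character(0), parameter = character(0),
                        estimate = numeric(0), se = numeric(0))
  }
  p <- file.path(dir, "relations.csv")
  utils::write.csv(relDf, p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "manifest.json")
  jsonlite::write_json(c(report@manifest, list(config = report@config)),
                       p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, p)
  invisible(paths)
}
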