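#' Windowed Pearson correlation matrix
#'
#' Pairwise Pearson correlation of all signals over the running window
#' `Tw` centred at `frame` (truncated at record edges, never padded).
#' Zero-lag, raw segments. Rows with zero variance in the window yield
#' `NA` off-diagonal entries, which downstream stages treat as
#' non-connected.
#'
#' @param signals A [MitoSignalSet-class] or numeric M x N matrix.
#' @param frame Centre frame.
#' @param Tw Window length, seconds.
#' @param dt Frame interval (taken from the object when possible).
#' @return Symmetric M x M correlation matrix with unit diagonal.
#' @export
windowedCorrelation <- function(signals, frame, Tw, dt = NULL) {
  sig <- if (methods::is(signals, "MitoSignalSet")) intensity(signals) else as.matrix(signals)
  if (is.null(dt) && methods::is(signals, "MitoSignalSet")) dt <- frameInterval(signals)
  idx <- windowFrames(frame, ncol(sig), Tw, dt)
  if (length(idx) < 4) {
    stop("window at frame ", frame, " retains fewer than 4 samples",
         call. = FALSE)
  }
  seg <- t(sig[, idx, drop = FALSE])
  suppressWarnings(C <- stats::cor(seg))
  diag(C) <- 1
  C
}

#' Threshold a correlation matrix into a functional graph
#'
#' Two mitochondria are functionally connected when their windowed
#' correlation strictly exceeds the cutoff (default 0.90). Negative or
#' undefined (`NA`) correlations never create edges.
#'
#' @param corr Symmetric correlation matrix.
#' @param cutoff Correlation cutoff theta in (-1, 1).
#' @return Logical symmetric adjacency matrix with `FALSE` diagonal.
#' @export
functionalGraph <- function(corr, cutoff = 0.90) {
  if (!is.numeric(cutoff) || length(cutoff) != 1 ||
      cutoff <= -1 || cutoff >= 1) {
    stop("cutoff must lie in (-1, 1)", call. = FALSE)
  }
  A <- !is.na(corr) & corr > cutoff
  diag(A) <- FALSE
  A | t(A)
}

#' Local clustering coefficients
#'
#' Watts-Strogatz local clustering: for vertex m with m_N graph
#' neighbours and L_m realized links among them,
#' C_m = 2 L_m / (m_N (m_N - 1)). Vertices of degree 0 or 1 score 0 by
#' convention and are included in the network mean C = (1/M) sum C_m
#' (set `excludeLowDegree = TRUE` to average over degree >= 2 vertices
#' only).
#'
#' @param adj Logical/0-1 symmetric adjacency matrix.
#' @return `localClustering`: numeric vector C_m in [0, 1];
#'   `meanClustering`: scalar C.
#' @export
localClustering <- function(adj) {
  A <- matrix(as.numeric(adj), nrow(adj))
  diag(A) <- 0
  deg <- rowSums(A)
  # L_m = number of edges among the neighbours of m = (A^3)_{mm} / 2
  L <- diag(A %*% A %*% A) / 2
  C <- ifelse(deg >= 2, 2 * L / (deg * (deg - 1)), 0)
  as.numeric(C)
}

#' @rdname localClustering
#' @param excludeLowDegree Average only vertices with degree >= 2.
#' @export
meanClustering <- function(adj, excludeLowDegree = FALSE) {
  C <- localClustering(adj)
  if (excludeLowDegree) {
    deg <- rowSums(matrix(as.numeric(adj), nrow(adj)))
    C <- C[deg >= 2]
    if (length(C) == 0) return(0)
  }
  mean(C)
}

#' Matched Erdos-Renyi null graphs
#'
#' Uniformly random simple graphs on the same M vertices with exactly the
#' real graph's edge count E(t) -- the G(n, m) realization of the dynamic
#' connection probability p(t) = sum_m D_m(t) / (M (M - 1)) -- so the
#' null preserves the number of connections at every time point.
#' Independent-Bernoulli G(n, p) sampling is available for sensitivity
#' checks.
#'
#' @param adj Real adjacency matrix (or `NULL` when `M`/`nEdges` given).
#' @param M,nEdges Vertex and edge counts (derived from `adj` when
#'   omitted).
#' @param n Number of realizations.
#' @param seed Integer seed for reproducibility.
#' @param mode `"gnm"` (exact edge count, default) or `"gnp"`.
#' @return A list of logical adjacency matrices of length `n`.
#' @export
erNull <- function(adj = NULL, M = NULL, nEdges = NULL, n = 1,
                   seed = NULL, mode = c("gnm", "gnp")) {
  mode <- match.arg(mode)
  if (!is.null(adj)) {
    M <- nrow(adj)
    nEdges <- sum(adj[upper.tri(adj)] != 0)
  }
  if (is.null(M) || M < 2) stop("M must be >= 2", call. = FALSE)
  maxE <- M * (M - 1) / 2
  if (nEdges > maxE) stop("edge count exceeds M(M-1)/2", call. = FALSE)
  p <- nEdges / maxE
  withSeed(seed, {
    lapply(seq_len(n), function(i) {
      g <- if (mode == "gnm") igraph::sample_gnm(M, nEdges)
           else igraph::sample_gnp(M, p)
      A <- as.matrix(igraph::as_adjacency_matrix(g)) > 0
      dimnames(A) <- NULL
      A
    })
  })
}

#' Mean clustering of matched null graphs
#'
#' @inheritParams erNull
#' @return A list with `mean`, `sd` and the per-realization `values` of
#'   the network mean clustering coefficient.
#' @export
erNullClustering <- function(adj = NULL, M = NULL, nEdges = NULL,
                             n = 100, seed = NULL) {
  gs <- erNull(adj, M, nEdges, n = n, seed = seed)
  v <- vapply(gs, meanClustering, numeric(1))
  list(mean = mean(v), sd = stats::sd(v), values = v)
}

#' Mean-field neighbour correlation
#'
#' In analogy to mean-field coupling, each mitochondrion m is summarized
#' by the average windowed correlation c_i^(m)(t) with its N_m spatial
#' lattice neighbours; the network mean c(t) averages these
#' per-mitochondrion values over all non-isolated mitochondria.
#'
#' @param signals A [MitoSignalSet-class].
#' @param frame Centre frame.
#' @param Tw Window length, seconds.
#' @param corr Optional precomputed windowed correlation matrix for this
#'   frame (avoids recomputation inside pipelines).
#' @return A list: `perMito` (numeric M vector, NA for isolated
#'   vertices), `mean` (scalar c(t)).
#' @export
meanField <- function(signals, frame, Tw, corr = NULL) {
  A <- latticeAdjacency(signals)
  if (is.null(corr)) corr <- windowedCorrelation(signals, frame, Tw)
  M <- nrow(A)
  nm <- rowSums(A)
  if (any(nm == 0)) {
    warning("isolated lattice vertices excluded from the mean-field mean: ",
            paste(which(nm == 0), collapse = ", "))
  }
  per <- rep(NA_real_, M)
  for (m in which(nm > 0)) {
    per[m] <- mean(corr[m, A[m, ]], na.rm = TRUE)
  }
  list(perMito = per, mean = mean(per, na.rm = TRUE))
}

#' Time-resolved functional clustering series
#'
#' For each evaluated frame: windowed correlation matrix -> functional
#' graph at the cutoff -> local/mean clustering -> matched ER null
#' statistics -> mean-field correlation. The workhorse behind the
#' clustering-vs-null comparison.
#'
#' @param signals A [MitoSignalSet-class].
#' @param frames Frames to evaluate (default: all with a full window).
#' @param Tw Window length, seconds.
#' @param cutoff Functional connectivity cutoff (default 0.90).
#' @param nNull ER-null realizations per frame.
#' @param seed Base seed; frame t uses `seed + t` so the series is
#'   reproducible regardless of which frames are evaluated.
#' @param membership Optional logical membership matrix (e.g. from
#'   [clusterMembership()]) aligned with `frames`, for the subgroup mean.
#' @return A data.frame (class `clusteringSeries`): `frame`, `time`, `C`,
#'   `CNullMean`, `CNullSd`, `meanField`, `nEdges`, and `CCluster` when
#'   membership is given. Per-vertex coefficients are in attribute
#'   `localC` (M x nframes matrix); correlation matrices in attribute
#'   `correlations` when `keepCorrelations`.
#' @param keepCorrelations Keep the per-frame correlation matrices.
#' @export
clusteringSeries <- function(signals, frames = NULL, Tw, cutoff = 0.90,
                             nNull = 20, seed = 1L, membership = NULL,
                             keepCorrelations = FALSE) {
  dt <- frameInterval(signals)
  N <- ncol(signals)
  minSamples <- windowMinSamples(Tw, dt)
  if (is.null(frames)) frames <- seq_len(N)
  frames <- as.integer(frames[vapply(frames, function(t) {
    length(windowFrames(t, N, Tw, dt)) >= minSamples
  }, logical(1))])
  M <- nrow(signals)
  nf <- length(frames)
  C <- nullMean <- nullSd <- mf <- nE <- CClust <- rep(NA_real_, nf)
  localC <- matrix(NA_real_, M, nf)
  corrs <- if (keepCorrelations) vector("list", nf) else NULL
  for (i in seq_len(nf)) {
    t <- frames[i]
    corr <- windowedCorrelation(signals, t, Tw)
    adj <- functionalGraph(corr, cutoff)
    localC[, i] <- localClustering(adj)
    C[i] <- mean(localC[, i])
    nE[i] <- sum(adj[upper.tri(adj)])
    nullStats <- erNullClustering(adj, n = nNull, seed = seed + t)
    nullMean[i] <- nullStats$mean
    nullSd[i] <- nullStats$sd
    mf[i] <- suppressWarnings(meanField(signals, t, Tw, corr = corr)$mean)
    if (!is.null(membership)) {
      mem <- membership[, i]
      CClust[i] <- if (any(mem)) mean(localC[mem, i]) else NA_real_
    }
    if (keepCorrelations) corrs[[i]] <- corr
  }
  out <- data.frame(frame = frames, time = (frames - 1) * dt, C = C,
                    CNullMean = nullMean, CNullSd = nullSd,
                    meanField = mf, nEdges = nE)
  if (!is.null(membership)) out$CCluster <- CClust
  attr(out, "localC") <- localC
  attr(out, "cutoff") <- cutoff
  if (keepCorrelations) attr(out, "correlations") <- corrs
  class(out) <- c("clusteringSeries", "data.frame")
  out
}

#' Spatial correlation map by piecewise-linear interpolation
#'
#' Places per-mitochondrion values (e.g. mean-field correlations) at the
#' mitochondria's pixel positions and fills the inter-mitochondrial
#' pixels by piecewise-linear (barycentric) interpolation over the
#' triangulated lattice of positions. Pixels outside the convex hull of
#' the lattice remain `NA` (masked).
#'
#' @param values Numeric vector, one value per mitochondrion.
#' @param positions Data.frame with pixel positions `row`, `col` and
#'   lattice indices `gridRow`, `gridCol` (the triangulation splits each
#'   unit lattice cell into two triangles).
#' @param shape Output image dimensions c(rows, cols).
#' @return Numeric matrix `shape[1]` x `shape[2]` with `NA` outside the
#'   interpolated region.
#' @export
correlationMap <- function(values, positions, shape) {
  stopifnot(length(values) == nrow(positions),
            all(c("row", "col", "gridRow", "gridCol") %in% names(positions)))
  if (nrow(positions) < 3) {
    stop("at least 3 positions are required", call. = FALSE)
  }
  P <- cbind(positions$row, positions$col)
  if (qr(sweep(P, 2, colMeans(P)))$rank < 2) {
    stop("positions are collinear; cannot interpolate a 2D map",
         call. = FALSE)
  }
  key <- paste(positions$gridRow, positions$gridCol, sep = ",")
  lookup <- stats::setNames(seq_len(nrow(positions)), key)
  tris <- list()
  for (r in sort(unique(positions$gridRow))) {
    for (c in sort(unique(positions$gridCol))) {
      v00 <- lookup[paste(r, c, sep = ",")]
      v01 <- lookup[paste(r, c + 1, sep = ",")]
      v10 <- lookup[paste(r + 1, c, sep = ",")]
      v11 <- lookup[paste(r + 1, c + 1, sep = ",")]
      if (!anyNA(c(v00, v01, v10))) tris[[length(tris) + 1]] <- c(v00, v01, v10)
      if (!anyNA(c(v11, v01, v10))) tris[[length(tris) + 1]] <- c(v11, v10, v01)
    }
  }
  out <- matrix(NA_real_, shape[1], shape[2])
  px <- expand.grid(row = seq_len(shape[1]) - 1L, col = seq_len(shape[2]) - 1L)
  for (tri in tris) {
    a <- P[tri[1], ]; b <- P[tri[2], ]; cc <- P[tri[3], ]
    det <- (b[1] - a[1]) * (cc[2] - a[2]) - (cc[1] - a[1]) * (b[2] - a[2])
    if (abs(det) < 1e-12) next
    inBox <- px$row >= min(a[1], b[1], cc[1]) & px$row <= max(a[1], b[1], cc[1]) &
             px$col >= min(a[2], b[2], cc[2]) & px$col <= max(a[2], b[2], cc[2])
    sub <- px[inBox, ]
    l1 <- ((b[1] - sub$row) * (cc[2] - sub$col) -
           (cc[1] - sub$row) * (b[2] - sub$col)) / det
    l2 <- ((cc[1] - sub$row) * (a[2] - sub$col) -
           (a[1] - sub$row) * (cc[2] - sub$col)) / det
    l3 <- 1 - l1 - l2
    ok <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    v <- l1 * values[tri[1]] + l2 * values[tri[2]] + l3 * values[tri[3]]
    out[cbind(sub$row[ok] + 1L, sub$col[ok] + 1L)] <- v[ok]
  }
  out
}
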