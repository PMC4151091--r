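#' MitoSignalSet: per-mitochondrion intensity time series
#'
#' An S4 container for a recording of M mitochondrial regions over N
#' frames, extending \linkS4class{SummarizedExperiment}. The single assay
#' \code{"intensity"} holds the M x N signal matrix (arbitrary fluorescence
#' units, e.g. TMRE). Row metadata carries the region geometry: lattice
#' position (\code{gridRow}, \code{gridCol}) and per-region pixel count.
#' Object metadata carries the frame interval \code{dt} (seconds), the
#' spatial nearest-neighbour lattice edges, and the total myocyte pixel
#' count used to normalize cluster areas.
#'
#' @slot .  Inherits all slots from \code{SummarizedExperiment}.
#'
#' @seealso [MitoSignalSet()] for construction, [intensity()],
#'   [frameInterval()], [latticeAdjacency()] for access.
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass MitoSignalSet
setClass("MitoSignalSet", contains = "SummarizedExperiment")

.validMitoSignalSet <- function(object) {
  msg <- NULL
  a <- SummarizedExperiment::assays(object)
  if (!"intensity" %in% names(a)) {
    msg <- c(msg, "assay 'intensity' is required")
  } else {
    x <- a[["intensity"]]
    if (!is.numeric(x)) msg <- c(msg, "'intensity' must be numeric")
    if (anyNA(x) || any(!is.finite(x))) {
      msg <- c(msg, "'intensity' must contain no missing/non-finite values")
    }
    if (nrow(x) < 2L) msg <- c(msg, "at least 2 mitochondria are required")
    if (ncol(x) < 8L) msg <- c(msg, "at least 8 frames are required")
  }
  md <- S4Vectors::metadata(object)
  if (is.null(md$dt) || !is.numeric(md$dt) || md$dt <= 0) {
    msg <- c(msg, "metadata 'dt' (seconds/frame) must be a positive number")
  }
  e <- md$latticeEdges
  if (!is.null(e)) {
    if (!is.matrix(e) || ncol(e) != 2L) {
      msg <- c(msg, "latticeEdges must be a 2-column matrix")
    } else if (nrow(e) > 0L) {
      if (any(e < 1L) || any(e > nrow(object))) {
        msg <- c(msg, "latticeEdges reference unknown vertices")
      }
      if (any(e[, 1L] == e[, 2L])) {
        msg <- c(msg, "lattice adjacency must be irreflexive")
      }
      key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
      if (anyDuplicated(key)) {
        msg <- c(msg, "duplicate lattice edges")
      }
    }
  }
  pc <- SummarizedExperiment::rowData(object)$pixelCount
  if (!is.null(pc) && (anyNA(pc) || any(pc < 1))) {
    msg <- c(msg, "pixelCount must be >= 1 for every region")
  }
  if (is.null(msg)) TRUE else msg
}
setValidity("MitoSignalSet", .validMitoSignalSet)

#' Construct a MitoSignalSet
#'
#' @param intensity Numeric M x N matrix of per-region mean intensities
#'   (rows = mitochondria, columns = frames).
#' @param dt Frame interval in seconds.
#' @param gridRow,gridCol Integer lattice coordinates of each region
#'   (1-based). When supplied and `latticeEdges` is `NULL`, a 4-connected
#'   nearest-neighbour lattice is derived from them.
#' @param pixelCounts Pixels per region (defaults to 1 each).
#' @param latticeEdges Optional 2-column integer matrix of undirected
#'   spatial neighbour pairs.
#' @param myocytePixels Total pixel count of the myocyte; defaults to
#'   `sum(pixelCounts)`.
#' @param ids Region identifiers (row names).
#' @return A [MitoSignalSet-class] object.
#' @examples
#' x <- MitoSignalSet(matrix(rnorm(4 * 16), 4), dt = 0.5,
#'                    gridRow = c(1, 1, 2, 2), gridCol = c(1, 2, 1, 2))
#' frameInterval(x)
#' @export
MitoSignalSet <- function(intensity, dt, gridRow = NULL, gridCol = NULL,
                          pixelCounts = NULL, latticeEdges = NULL,
                          myocytePixels = NULL, ids = NULL) {
  intensity <- as.matrix(intensity)
  storage.mode(intensity) <- "double"
  M <- nrow(intensity)
  if (is.null(ids)) {
    ids <- if (!is.null(rownames(intensity))) rownames(intensity)
           else sprintf("m%03d", seq_len(M))
  }
  rownames(intensity) <- ids
  if (is.null(pixelCounts)) pixelCounts <- rep(1L, M)
  if (is.null(myocytePixels)) myocytePixels <- sum(pixelCounts)
  rd <- S4Vectors::DataFrame(pixelCount = as.integer(pixelCounts))
  if (!is.null(gridRow)) rd$gridRow <- as.integer(gridRow)
  if (!is.null(gridCol)) rd$gridCol <- as.integer(gridCol)
  rownames(rd) <- ids
  if (is.null(latticeEdges) && !is.null(gridRow) && !is.null(gridCol)) {
    latticeEdges <- latticeEdgesFromGrid(gridRow, gridCol)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = rd,
    metadata = list(dt = dt, latticeEdges = latticeEdges,
                    myocytePixels = myocytePixels))
  methods::new("MitoSignalSet", se)
}

#' 4-connected lattice edges from integer grid coordinates
#'
#' @param gridRow,gridCol Integer lattice coordinates, one per region.
#' @return 2-column integer matrix of undirected neighbour index pairs
#'   (each pair once, smaller index first).
#' @export
latticeEdgesFromGrid <- function(gridRow, gridCol) {
  M <- length(gridRow)
  key <- paste(gridRow, gridCol, sep = ",")
  lookup <- stats::setNames(seq_len(M), key)
  edges <- matrix(integer(0), ncol = 2)
  for (m in seq_len(M)) {
    for (d in list(c(1L, 0L), c(0L, 1L))) {
      nb <- lookup[paste(gridRow[m] + d[1], gridCol[m] + d[2], sep = ",")]
      if (!is.na(nb)) edges <- rbind(edges, c(m, unname(nb)))
    }
  }
  storage.mode(edges) <- "integer"
  colnames(edges) <- c("from", "to")
  edges
}

#' @describeIn MitoSignalSet-accessors Intensity matrix (M x N).
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))
#' @rdname MitoSignalSet-accessors
#' @export
setMethod("intensity", "MitoSignalSet", function(x) {
  SummarizedExperiment::assay(x, "intensity")
})

#' @describeIn MitoSignalSet-accessors Frame interval dt in seconds.
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname MitoSignalSet-accessors
#' @export
setMethod("frameInterval", "MitoSignalSet", function(x) {
  S4Vectors::metadata(x)$dt
})

#' @describeIn MitoSignalSet-accessors Per-region pixel counts.
#' @export
setGeneric("pixelCounts", function(x) standardGeneric("pixelCounts"))
#' @rdname MitoSignalSet-accessors
#' @export
setMethod("pixelCounts", "MitoSignalSet", function(x) {
  SummarizedExperiment::rowData(x)$pixelCount
})

#' @describeIn MitoSignalSet-accessors Total myocyte pixel count.
#' @export
setGeneric("myocytePixels", function(x) standardGeneric("myocytePixels"))
#' @rdname MitoSignalSet-accessors
#' @export
setMethod("myocytePixels", "MitoSignalSet", function(x) {
  S4Vectors::metadata(x)$myocytePixels
})

#' @describeIn MitoSignalSet-accessors Undirected lattice edge matrix.
#' @export
setGeneric("latticeEdges", function(x) standardGeneric("latticeEdges"))
#' @rdname MitoSignalSet-accessors
#' @export
setMethod("latticeEdges", "MitoSignalSet", function(x) {
  S4Vectors::metadata(x)$latticeEdges
})

#' @describeIn MitoSignalSet-accessors Symmetric logical adjacency matrix
#'   of the spatial lattice.
#' @export
setGeneric("latticeAdjacency", function(x) standardGeneric("latticeAdjacency"))
#' @rdname MitoSignalSet-accessors
#' @export
setMethod("latticeAdjacency", "MitoSignalSet", function(x) {
  M <- nrow(x)
  A <- matrix(FALSE, M, M, dimnames = list(rownames(x), rownames(x)))
  e <- latticeEdges(x)
  if (!is.null(e) && nrow(e) > 0L) {
    A[e] <- TRUE
    A[e[, 2:1, drop = FALSE]] <- TRUE
  }
  A
})

#' Accessors for MitoSignalSet
#'
#' @param x A [MitoSignalSet-class].
#' @name MitoSignalSet-accessors
NULL

#' @importMethodsFrom methods show
setMethod("show", "MitoSignalSet", function(object) {
  cat(sprintf("MitoSignalSet: %d mitochondria x %d frames (dt = %g s, %.1f s total)\n",
              nrow(object), ncol(object), frameInterval(object),
              ncol(object) * frameInterval(object)))
  e <- latticeEdges(object)
  cat(sprintf("  lattice edges: %d; myocyte pixels: %d\n",
              if (is.null(e)) 0L else nrow(e), myocytePixels(object)))
})
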