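#' Extract per-mitochondrion signals from an image stack
#'
#' Computes, for every region of the grid template and every frame, the
#' mean pixel intensity -- the raw TMRE-like signal. No detrending or
#' normalization is applied here. Optionally an integer (dx, dy) shift is
#' applied to the template per frame to follow in-plane motion of the
#' myocyte (the grid moves, pixel intensities are untouched).
#'
#' @param stack Numeric array (rows x cols x frames) or list of frame
#'   matrices.
#' @param grid Grid template: data.frame with columns `region`, `row`,
#'   `col` (0-based pixel coordinates), e.g. from [makeGridTemplate()] or
#'   [readGridTemplate()].
#' @param dt Frame interval, seconds.
#' @param nAvg Number of initial frames averaged into the QC reference
#'   image (returned as attribute `averagedImage`). Choose `nAvg * dt` at
#'   most equal to the smallest expected oscillation period; a warning is
#'   emitted if the caller-supplied `minPeriod` says otherwise.
#' @param shifts Optional integer matrix (frames x 2) of per-frame
#'   (dRow, dCol) template shifts, e.g. from [estimateShifts()].
#' @param minPeriod Optional smallest expected oscillation period
#'   (seconds) used only for the `nAvg` sanity warning.
#' @return A [MitoSignalSet-class]; lattice positions are inferred from
#'   region centroids when the template is grid-organized.
#' @export
extractSignals <- function(stack, grid, dt, nAvg = 8, shifts = NULL,
                           minPeriod = NULL) {
  stack <- asStackArray(stack)
  checkGridTemplate(grid)
  H <- dim(stack)[1]; W <- dim(stack)[2]; N <- dim(stack)[3]
  regs <- sort(unique(grid$region))
  M <- length(regs)
  if (M == 0) stop("grid template has no regions", call. = FALSE)
  cnt <- table(factor(grid$region, levels = regs))
  if (any(cnt == 0)) {
    stop("empty region in grid template: ", regs[which(cnt == 0)[1]],
         call. = FALSE)
  }
  if (!is.null(minPeriod) && nAvg * dt > minPeriod) {
    warning("nAvg * dt (", nAvg * dt, " s) exceeds the smallest expected ",
            "oscillation period (", minPeriod, " s)")
  }
  if (!is.null(shifts)) {
    shifts <- as.matrix(shifts)
    stopifnot(nrow(shifts) == N, ncol(shifts) == 2)
  }
  regIdx <- match(grid$region, regs)
  sig <- matrix(NA_real_, M, N)
  for (t in seq_len(N)) {
    r <- grid$row; c <- grid$col
    if (!is.null(shifts)) {
      r <- r + shifts[t, 1]; c <- c + shifts[t, 2]
    }
    if (any(r < 0) || any(r >= H) || any(c < 0) || any(c >= W)) {
      stop("shift at frame ", t, " pushes the template out of image bounds",
           call. = FALSE)
    }
    vals <- stack[, , t][r + 1L + c * H]
    sig[, t] <- as.numeric(tapply(vals, regIdx, mean))
  }
  pos <- gridPositionsFromTemplate(grid, regs)
  out <- MitoSignalSet(sig, dt = dt,
                       gridRow = pos$gridRow, gridCol = pos$gridCol,
                       pixelCounts = as.integer(cnt),
                       myocytePixels = H * W,
                       ids = as.character(regs))
  attr(out, "averagedImage") <- apply(
    stack[, , seq_len(min(nAvg, N)), drop = FALSE], c(1, 2), mean)
  out
}

# Lattice coordinates from region centroids. Exact for regular grids
# (centroids fall on distinct rows/cols); otherwise ranks of the rounded
# centroid coordinates are used.
gridPositionsFromTemplate <- function(grid, regs) {
  p <- attr(grid, "positions")
  if (!is.null(p) && all(regs %in% p$region)) {
    p <- p[match(regs, p$region), ]
    return(data.frame(gridRow = p$gridRow, gridCol = p$gridCol))
  }
  cr <- tapply(grid$row, factor(grid$region, levels = regs), mean)
  cc <- tapply(grid$col, factor(grid$region, levels = regs), mean)
  data.frame(gridRow = as.integer(factor(round(cr))),
             gridCol = as.integer(factor(round(cc))))
}

asStackArray <- function(stack) {
  if (is.list(stack)) {
    stack <- simplify2array(stack)
  }
  if (length(dim(stack)) == 2L) dim(stack) <- c(dim(stack), 1L)
  if (length(dim(stack)) != 3L) {
    stop("stack must be a rows x cols x frames array", call. = FALSE)
  }
  storage.mode(stack) <- "double"
  stack
}

#' Estimate per-frame integer template shifts
#'
#' Finds, for every frame, the integer (dRow, dCol) translation that
#' maximizes the Pearson correlation of the overlapping region with a
#' reference frame. Returns the shift of the image content; moving the
#' grid template by the same amount keeps it on the same structures.
#'
#' @param stack Image stack (array or list of matrices).
#' @param referenceFrame Index of the reference frame (shift (0, 0)).
#' @param maxShift Search radius in pixels.
#' @return Integer matrix (frames x 2), columns `dRow`, `dCol`, with
#'   attribute `score` (peak correlation per frame). Constant frames get
#'   shift (0, 0) with a warning.
#' @export
estimateShifts <- function(stack, referenceFrame = 1, maxShift = 5) {
  stack <- asStackArray(stack)
  N <- dim(stack)[3]
  if (N < 2) stop("at least two frames are required", call. = FALSE)
  ref <- stack[, , referenceFrame]
  if (stats::sd(ref) == 0) {
    warning("reference frame is constant; shifts are undefined, returning (0, 0)")
    out <- matrix(0L, N, 2, dimnames = list(NULL, c("dRow", "dCol")))
    attr(out, "score") <- rep(NA_real_, N)
    return(out)
  }
  H <- dim(stack)[1]; W <- dim(stack)[2]
  out <- matrix(0L, N, 2, dimnames = list(NULL, c("dRow", "dCol")))
  score <- rep(NA_real_, N)
  lowConfidence <- FALSE
  for (t in seq_len(N)) {
    if (t == referenceFrame) { score[t] <- 1; next }
    frame <- stack[, , t]
    if (stats::sd(frame) == 0) {
      warning("frame ", t, " is constant; shift undefined, using (0, 0)")
      next
    }
    best <- c(0L, 0L); bestr <- -Inf
    for (dr in -maxShift:maxShift) {
      r1 <- max(1, 1 + dr):min(H, H + dr)
      r0 <- r1 - dr
      for (dc in -maxShift:maxShift) {
        c1 <- max(1, 1 + dc):min(W, W + dc)
        c0 <- c1 - dc
        a <- ref[r0, c0]; b <- frame[r1, c1]
        if (stats::sd(a) == 0 || stats::sd(b) == 0) next
        r <- stats::cor(as.vector(a), as.vector(b))
        if (r > bestr) { bestr <- r; best <- c(dr, dc) }
      }
    }
    out[t, ] <- best
    score[t] <- bestr
    if (is.finite(bestr) && bestr < 0.3) lowConfidence <- TRUE
  }
  if (lowConfidence) {
    warning("low-confidence shift estimates (peak correlation < 0.3) for ",
            "some frames; frames may be uncorrelated with the reference")
  }
  attr(out, "score") <- score
  out
}

#' Read / write a MitoSignalSet as CSV + JSON sidecar
#'
#' The signal table is a CSV whose first column (`id`) identifies the
#' mitochondrion and whose remaining columns are frames. Metadata that the
#' matrix cannot carry -- the frame interval `dt`, per-region pixel
#' counts, lattice positions/edges and the myocyte pixel count -- lives in
#' a JSON sidecar next to the CSV (same path, extension `.json`).
#'
#' @param x A [MitoSignalSet-class].
#' @param path CSV file path.
#' @return `writeSignalSet` invisibly returns `path`; `readSignalSet`
#'   returns the reconstructed [MitoSignalSet-class].
#' @export
writeSignalSet <- function(x, path) {
  stopifnot(methods::is(x, "MitoSignalSet"))
  m <- intensity(x)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  colnames(df) <- c("id", sprintf("f%d", seq_len(ncol(m))))
  utils::write.csv(df, path, row.names = FALSE)
  rd <- SummarizedExperiment::rowData(x)
  meta <- list(dt = frameInterval(x),
               pixelCounts = as.integer(pixelCounts(x)),
               myocytePixels = myocytePixels(x),
               gridRow = rd$gridRow, gridCol = rd$gridCol,
               latticeEdges = latticeEdges(x))
  jsonlite::write_json(meta, sidecarPath(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecarPath <- function(path) {
  sub("\\.[^.]*$", "", path) |> paste0(".json")
}

#' @rdname writeSignalSet
#' @export
readSignalSet <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  if (ncol(df) < 2) stop("signal CSV needs an id column plus frames",
                         call. = FALSE)
  ids <- df[[1]]
  raw <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(raw), nrow(raw), ncol(raw)))
  bad <- which(is.na(num) & !(toupper(trimws(raw)) %in% c("NA", "NAN")),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("non-numeric cell '%s' at row %d, column %d of %s",
                 raw[bad[1, 1], bad[1, 2]], bad[1, 1], bad[1, 2] + 1L,
                 path), call. = FALSE)
  }
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)
    stop(sprintf("missing value at row %d, column %d of %s",
                 bad[1, 1], bad[1, 2] + 1L, path), call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecarPath(path), simplifyVector = TRUE)
  edges <- meta$latticeEdges
  if (!is.null(edges)) {
    edges <- matrix(as.integer(as.matrix(edges)), ncol = 2,
                    dimnames = list(NULL, c("from", "to")))
  }
  MitoSignalSet(num, dt = meta$dt, gridRow = meta$gridRow,
                gridCol = meta$gridCol, pixelCounts = meta$pixelCounts,
                latticeEdges = edges, myocytePixels = meta$myocytePixels,
                ids = ids)
}

#' Read / write a grid template CSV
#'
#' A grid template CSV has columns `region`, `row`, `col` with 0-based
#' pixel coordinates, one pixel per line.
#'
#' @param grid Grid template data.frame.
#' @param path File path.
#' @export
writeGridTemplate <- function(grid, path) {
  utils::write.csv(grid[, c("region", "row", "col")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname writeGridTemplate
#' @export
readGridTemplate <- function(path) {
  g <- utils::read.csv(path)
  stopifnot(all(c("region", "row", "col") %in% names(g)))
  checkGridTemplate(g)
  attr(g, "imageRows") <- max(g$row) + 1L
  attr(g, "imageCols") <- max(g$col) + 1L
  g
}

#' Read / write a multi-page grayscale TIFF stack
#'
#' Intensities are stored as 32-bit float samples scaled into [0, 1] by
#' `scale` (recorded in a JSON sidecar and undone on read).
#'
#' @param stack Numeric array rows x cols x frames.
#' @param path TIFF file path.
#' @param scale Intensity value mapped to 1.0; defaults to the stack
#'   maximum.
#' @export
writeStack <- function(stack, path, scale = NULL) {
  stack <- asStackArray(stack)
  if (is.null(scale)) scale <- max(stack)
  if (scale <= 0) scale <- 1
  frames <- lapply(seq_len(dim(stack)[3]),
                   function(t) pmin(pmax(stack[, , t] / scale, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  jsonlite::write_json(list(scale = scale), sidecarPath(path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeStack
#' @export
readStack <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  scale <- 1
  sc <- sidecarPath(path)
  if (file.exists(sc)) {
    scale <- jsonlite::read_json(sc, simplifyVector = TRUE)$scale
  }
  simplify2array(frames) * scale
}
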