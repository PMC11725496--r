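## Export to chunked stores with access-optimized chunking. Per-feature
## access (one gene across all cells) is fastest when each chunk holds
## many observations and few features; per-observation access is the
## transposed mirror; "balanced" splits both axes.

.obsCapDefault <- 4096L
.smallFDefault <- 10L

#' Plan a chunk geometry for an observation-by-feature matrix
#'
#' @param nObs,nFeatures Matrix dimensions (>= 1 allowed to be 0 for
#'   degenerate matrices; chunk dims are clamped to at least 1).
#' @param targetPattern `"per-feature"` (tall chunks: obsPerChunk =
#'   `min(nObs, obsCap)`, featuresPerChunk = `min(nFeatures, smallF)`),
#'   `"per-observation"` (the transpose-optimal mirror), or `"balanced"`.
#' @param obsCap,smallF Caps for the large and small chunk axis.
#' @param compression Codec name (`"zlib"` or `"none"`).
#' @param level Compression level.
#' @return A chunk plan: list with `chunkShape`, `compression`, `level`,
#'   `targetPattern`.
#' @export
planChunks <- function(nObs, nFeatures,
                       targetPattern = c("per-feature", "per-observation",
                                         "balanced"),
                       obsCap = .obsCapDefault, smallF = .smallFDefault,
                       compression = "zlib", level = 5L) {
  targetPattern <- match.arg(targetPattern)
  clamp1 <- function(x) max(1L, as.integer(x))
  shape <- switch(targetPattern,
    "per-feature" = c(clamp1(min(nObs, obsCap)), clamp1(min(nFeatures, smallF))),
    "per-observation" = c(clamp1(min(nObs, smallF)), clamp1(min(nFeatures, obsCap))),
    "balanced" = c(clamp1(min(nObs, ceiling(sqrt(obsCap * smallF)))),
                   clamp1(min(nFeatures, ceiling(sqrt(obsCap * smallF))))))
  list(chunkShape = shape, compression = compression, level = as.integer(level),
       targetPattern = targetPattern)
}

#' Number of chunks a one-feature (or one-observation) fetch touches
#' @param nObs,nFeatures Matrix dims.
#' @param plan A chunk plan.
#' @return List with `perFeatureFetchChunks`, `perObservationFetchChunks`,
#'   `chunkCount`.
#' @export
planFetchCost <- function(nObs, nFeatures, plan) {
  cs <- plan$chunkShape
  gr <- max(1L, as.integer(ceiling(nObs / cs[1])))
  gc <- max(1L, as.integer(ceiling(nFeatures / cs[2])))
  list(perFeatureFetchChunks = gr, perObservationFetchChunks = gc,
       chunkCount = gr * gc)
}

#' Export a matrix to a chunked store
#'
#' The store is a directory of static objects (servable with no server
#' logic); re-opening with [openMatrixHandle] and loading fully recovers
#' the input exactly. Non-finite values are refused before any write.
#'
#' @param matrix Numeric or integer matrix.
#' @param obsIds,featureIds Identifier vectors (default taken from
#'   dimnames, else generated).
#' @param plan Chunk plan from [planChunks].
#' @param path Output store directory.
#' @return `path`, invisibly.
#' @export
exportMatrix <- function(matrix, path, plan = NULL, obsIds = NULL,
                         featureIds = NULL) {
  if (is.null(plan)) plan <- planChunks(nrow(matrix), ncol(matrix))
  if (length(matrix) > 0 && any(!is.finite(matrix))) {
    stop("matrix contains non-finite values; refusing to export")
  }
  if (is.null(obsIds)) {
    obsIds <- rownames(matrix)
    if (is.null(obsIds)) obsIds <- sprintf("obs-%d", seq_len(nrow(matrix)))
  }
  if (is.null(featureIds)) {
    featureIds <- colnames(matrix)
    if (is.null(featureIds)) featureIds <- sprintf("feat-%d", seq_len(ncol(matrix)))
  }
  dtype <- if (is.integer(matrix)) "<i4" else "<f8"
  compressor <- if (identical(plan$compression, "none")) NULL else "zlib"
  m <- matrix; dimnames(m) <- NULL
  writeZarrArray(m, path, chunks = plan$chunkShape, dtype = dtype,
                 compressor = compressor, level = plan$level,
                 attrs = list(obsIds = as.list(obsIds),
                              featureIds = as.list(featureIds)))
  invisible(path)
}

## 2x2 mean reduction (intensities) of a matrix, ceil-halved dims
.reduceMean2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  or <- ceiling(nr / 2); oc <- ceiling(nc / 2)
  rbin <- (seq_len(nr) + 1L) %/% 2L
  cbin <- (seq_len(nc) + 1L) %/% 2L
  sums <- rowsum(t(rowsum(m, rbin)), cbin)          # oc x or
  cnt <- tcrossprod(tabulate(cbin, oc), tabulate(rbin, or))
  t(sums / cnt)
}

## top-left stride sampling (labels are categorical, never averaged)
.reduceStride2 <- function(m) {
  m[seq(1, nrow(m), by = 2), seq(1, ncol(m), by = 2), drop = FALSE]
}

#' Export a multiscale image (or bitmask) pyramid
#'
#' Level 0 equals the input; level L has dims `ceiling(dim / 2^L)` and is
#' the 2x2 mean (intensities) or top-left stride (bitmask labels)
#' reduction of the previous level. Each level is stored chunked with
#' chunk = tile.
#'
#' @param image `(C, Y, X)` numeric array, or `(Y, X)` matrix for a
#'   bitmask.
#' @param path Output directory.
#' @param nLevels Number of levels (>= 1); a level whose downsample
#'   factor exceeds both spatial dims (an empty level) is an error.
#' @param tileSize Tile edge, pixels.
#' @param bitmask Store as integer label image with stride reduction.
#' @return `path`, invisibly.
#' @export
exportImagePyramid <- function(image, path, nLevels = 1L, tileSize = 64L,
                               bitmask = FALSE) {
  if (bitmask && length(dim(image)) == 2) {
    yx <- dim(image)
  } else if (!bitmask && length(dim(image)) == 3) {
    yx <- dim(image)[2:3]
  } else {
    stop("image must be (C, Y, X); bitmask must be (Y, X)")
  }
  if (nLevels < 1) stop("nLevels must be >= 1")
  if (2^(nLevels - 1) > max(yx)) {
    stop("nLevels = ", nLevels, " gives an empty level for a ",
         yx[1], " x ", yx[2], " image")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  datasets <- lapply(0:(nLevels - 1L), function(l) list(path = as.character(l)))
  attrs <- list(multiscales = list(list(
                  version = "0.4",
                  axes = if (bitmask) list("y", "x") else list("c", "y", "x"),
                  datasets = datasets)),
                bitmask = bitmask)
  writeLines(canonicalJSON(attrs), file.path(path, ".zattrs"), useBytes = TRUE)
  cur <- image
  for (l in 0:(nLevels - 1L)) {
    lp <- file.path(path, as.character(l))
    if (bitmask) {
      m <- cur; storage.mode(m) <- "integer"
      writeZarrArray(m, lp, chunks = c(tileSize, tileSize), dtype = "<i4")
      if (l < nLevels - 1L) cur <- .reduceStride2(cur)
    } else {
      writeZarrArray(cur, lp, chunks = c(1L, tileSize, tileSize), dtype = "<f8")
      if (l < nLevels - 1L) {
        nxt <- array(0, dim = c(dim(cur)[1], ceiling(dim(cur)[2] / 2),
                                ceiling(dim(cur)[3] / 2)))
        for (ch in seq_len(dim(cur)[1])) nxt[ch, , ] <- .reduceMean2(cur[ch, , ])
        cur <- nxt
      }
    }
  }
  invisible(path)
}

#' Size and access-cost report for a matrix store
#'
#' Compares the chunked store's on-disk bytes with an actual
#' delimited-text serialization of the same matrix (full-precision float
#' repr, for fairness), and reports the analytic per-feature /
#' per-observation fetch costs of the plan.
#'
#' @param store Store directory written by [exportMatrix].
#' @param matrix The matrix that was exported.
#' @return List: `storedBytes`, `equivalentDelimitedTextBytes`,
#'   `chunkCount`, `perFeatureFetchChunks`, `perObservationFetchChunks`.
#' @export
storeSizeReport <- function(store, matrix) {
  arr <- openZarrArray(store)
  files <- list.files(store, all.files = TRUE, full.names = TRUE,
                      recursive = TRUE, no.. = TRUE)
  storedBytes <- sum(file.size(files[!dir.exists(files)]))
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp), add = TRUE)
  df <- as.data.frame(matrix)
  utils::write.table(df, tmp, sep = ",", row.names = TRUE, col.names = NA,
                     qmethod = "double")
  txtBytes <- file.size(tmp)
  cost <- planFetchCost(arr$shape[1], arr$shape[2],
                        list(chunkShape = arr$chunks))
  list(storedBytes = as.numeric(storedBytes),
       equivalentDelimitedTextBytes = as.numeric(txtBytes),
       chunkCount = cost$chunkCount,
       perFeatureFetchChunks = cost$perFeatureFetchChunks,
       perObservationFetchChunks = cost$perObservationFetchChunks)
}
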