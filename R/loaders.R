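## File-type loaders: a required full-load path per file type, optional
## subset loading for chunked stores, and chunk-access accounting so that
## laziness is testable. All indexing is 0-based with half-open ranges;
## image origin is top-left with y increasing downward.

.ioError <- function(msg) {
  stop(structure(class = c("ioError", "error", "condition"),
                 list(message = msg, call = NULL)))
}
.validationError <- function(msg) {
  stop(structure(class = c("validationError", "error", "condition"),
                 list(message = msg, call = NULL)))
}

## ChunkedMatrixHandle ---------------------------------------------------

#' ChunkedMatrixHandle: lazily readable observation-by-feature matrix
#'
#' Wraps a chunked directory store. Values are fetched chunk-wise on
#' demand; every chunk fetch (not cache hit) is appended to an access log,
#' making load laziness observable. A small per-handle LRU cache keyed by
#' chunk index avoids re-reading hot chunks.
#'
#' @slot store Store directory.
#' @slot shape `(nObs, nFeatures)`.
#' @slot chunkShape `(obsPerChunk, featuresPerChunk)`.
#' @slot obsIds,featureIds Identifier vectors.
#' @slot env Mutable state: access log, LRU cache.
#' @export
setClass("ChunkedMatrixHandle", representation(
  store = "character", shape = "integer", chunkShape = "integer",
  obsIds = "character", featureIds = "character", env = "environment"))

setValidity("ChunkedMatrixHandle", function(object) {
  msgs <- character(0)
  if (length(object@shape) != 2 || length(object@chunkShape) != 2)
    msgs <- c(msgs, "shape and chunkShape must have length 2")
  if (any(object@chunkShape < 1L))
    msgs <- c(msgs, "chunk dimensions must be >= 1")
  if (length(object@obsIds) != object@shape[1])
    msgs <- c(msgs, "obsIds length must equal nObs")
  if (length(object@featureIds) != object@shape[2])
    msgs <- c(msgs, "featureIds length must equal nFeatures")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ChunkedMatrixHandle", function(object) {
  cat("ChunkedMatrixHandle ", object@shape[1], " x ", object@shape[2],
      " (chunks ", object@chunkShape[1], " x ", object@chunkShape[2],
      "), ", nrow(accessLog(object)), " chunk fetches logged\n", sep = "")
})

setMethod("dim", "ChunkedMatrixHandle", function(x) as.integer(x@shape))

#' Open a chunked matrix store as a lazy handle
#'
#' @param store Store directory (a chunked array plus `.zattrs` carrying
#'   `obsIds` and `featureIds`), or a parent store with `path` naming the
#'   array sub-path.
#' @param path Optional sub-path of the array within `store`.
#' @param cacheChunks LRU cache capacity in chunks.
#' @return A [ChunkedMatrixHandle-class].
#' @export
openMatrixHandle <- function(store, path = NULL, cacheChunks = 64L) {
  arrPath <- if (is.null(path) || !nzchar(path)) store else file.path(store, path)
  if (!dir.exists(arrPath)) .ioError(paste0("store not found: ", arrPath))
  arr <- openZarrArray(arrPath)
  if (length(arr$shape) != 2) .validationError("matrix store must be 2-D")
  ## ids live on the array attrs, or on the parent store root for joint stores
  attrs <- arr$attrs
  if (is.null(attrs$obsIds)) {
    rootAttrsFile <- file.path(store, ".zattrs")
    if (file.exists(rootAttrsFile)) {
      attrs <- parseJSON(paste(readLines(rootAttrsFile, warn = FALSE),
                               collapse = "\n"))
    }
  }
  obsIds <- as.character(unlist(attrs$obsIds))
  featureIds <- as.character(unlist(attrs$featureIds))
  if (length(obsIds) != arr$shape[1])
    .validationError("obsIds attribute missing or wrong length")
  if (length(featureIds) != arr$shape[2])
    .validationError("featureIds attribute missing or wrong length")
  env <- new.env(parent = emptyenv())
  env$arr <- arr
  env$log <- list()
  env$cache <- list()
  env$cacheCap <- as.integer(cacheChunks)
  new("ChunkedMatrixHandle", store = arrPath, shape = arr$shape,
      chunkShape = arr$chunks, obsIds = obsIds, featureIds = featureIds,
      env = env)
}

#' Chunk-access log of a handle
#' @param handle A [ChunkedMatrixHandle-class] or ImagePyramid.
#' @return Matrix of 0-based chunk indices, one row per fetch, in order.
#' @export
accessLog <- function(handle) {
  log <- handle@env$log
  if (length(log) == 0) {
    return(matrix(integer(0), ncol = if (methods::is(handle, "ImagePyramid")) 4L else 2L))
  }
  do.call(rbind, log)
}

## fetch one chunk through cache + log
.fetchChunk <- function(env, idx) {
  key <- paste(idx, collapse = ".")
  hit <- env$cache[[key]]
  if (!is.null(hit)) {
    ## refresh LRU position
    env$cache <- c(env$cache[setdiff(names(env$cache), key)],
                   stats::setNames(list(hit), key))
    return(hit)
  }
  block <- .readZarrChunk(env$arr, idx)
  env$log[[length(env$log) + 1L]] <- matrix(as.integer(idx), nrow = 1)
  env$cache[[key]] <- block
  if (length(env$cache) > env$cacheCap) {
    env$cache <- env$cache[-1L]
  }
  block
}

#' Load a dense block of a chunked matrix
#'
#' Fetches exactly the chunks intersecting the requested rows x columns,
#' each at most once per request (and not at all when cached). Returned
#' values equal the corresponding entries of the full matrix.
#'
#' @param handle A [ChunkedMatrixHandle-class].
#' @param featureIds Character vector of feature ids (subset of
#'   `handle@featureIds`), or NULL for all.
#' @param obsRange 0-based half-open `c(start, end)` row range, or NULL
#'   for all observations.
#' @return Dense numeric matrix with obs/feature dimnames.
#' @export
loadMatrixSubset <- function(handle, featureIds = NULL, obsRange = NULL) {
  if (is.null(featureIds)) featureIds <- handle@featureIds
  cols0 <- match(featureIds, handle@featureIds) - 1L
  if (anyNA(cols0)) {
    stop("unknown feature id(s): ",
         paste(featureIds[is.na(cols0)], collapse = ", "))
  }
  if (is.null(obsRange)) obsRange <- c(0L, handle@shape[1])
  obsRange <- as.integer(obsRange)
  if (obsRange[1] < 0L || obsRange[2] > handle@shape[1] ||
      obsRange[1] > obsRange[2]) {
    stop("obsRange out of bounds")
  }
  nR <- obsRange[2] - obsRange[1]
  isInt <- identical(handle@env$arr$dtype, "<i4")
  out <- matrix(if (isInt) NA_integer_ else NA_real_,
                nrow = nR, ncol = length(cols0))
  if (nR == 0 || length(cols0) == 0) {
    dimnames(out) <- list(character(0), featureIds)
    return(out)
  }
  cs <- handle@chunkShape
  rowChunks <- (obsRange[1] %/% cs[1]):((obsRange[2] - 1L) %/% cs[1])
  colChunks <- sort(unique(cols0 %/% cs[2]))
  for (rc in rowChunks) {
    for (cc in colChunks) {
      block <- .fetchChunk(handle@env, c(rc, cc))
      ## rows of this chunk within request
      r0 <- max(rc * cs[1], obsRange[1]); r1 <- min((rc + 1L) * cs[1], obsRange[2])
      inRows <- (r0 - rc * cs[1] + 1L):(r1 - rc * cs[1])
      outRows <- (r0 - obsRange[1] + 1L):(r1 - obsRange[1])
      ## requested columns living in this chunk column
      sel <- which(cols0 %/% cs[2] == cc)
      inCols <- cols0[sel] - cc * cs[2] + 1L
      out[outRows, sel] <- block[inRows, inCols, drop = FALSE]
    }
  }
  dimnames(out) <- list(handle@obsIds[(obsRange[1] + 1L):obsRange[2]],
                        featureIds)
  out
}

## ImagePyramid ----------------------------------------------------------

#' ImagePyramid: multiscale, multichannel raster loaded tile-wise
#'
#' Levels are power-of-two downsampled rasters (`downsampleFactor = 2^index`),
#' each stored chunked with chunk = tile, so loading a tile reads exactly
#' one chunk object per selected channel. Bitmask pyramids hold integer
#' observation labels (0 = background) and are 2-D per level.
#'
#' @slot store Pyramid directory.
#' @slot levels List of open level arrays (highest resolution first).
#' @slot nChannels Number of channels (1 for bitmasks).
#' @slot tileSize Tile edge in pixels.
#' @slot bitmask Whether this is a label image.
#' @slot env Mutable state: access log.
#' @export
setClass("ImagePyramid", representation(
  store = "character", levels = "list", nChannels = "integer",
  tileSize = "integer", bitmask = "logical", env = "environment"))

setValidity("ImagePyramid", function(object) {
  if (length(object@levels) < 1) return("pyramid must have >= 1 level")
  TRUE
})

setMethod("show", "ImagePyramid", function(object) {
  l0 <- object@levels[[1]]
  cat(if (object@bitmask) "Bitmask" else "Image", " pyramid: ",
      length(object@levels), " level(s), base ",
      paste(l0$shape, collapse = " x "), ", tile ", object@tileSize,
      ", ", object@nChannels, " channel(s)\n", sep = "")
})

#' Per-level metadata of a pyramid
#' @param pyramid An [ImagePyramid-class].
#' @return data.frame with level index, downsampleFactor, height, width,
#'   tilesY, tilesX.
#' @export
pyramidLevels <- function(pyramid) {
  n <- length(pyramid@levels)
  yx <- t(vapply(pyramid@levels, function(l) {
    s <- l$shape
    if (length(s) == 3) s[2:3] else s
  }, integer(2)))
  data.frame(level = 0:(n - 1), downsampleFactor = 2^(0:(n - 1)),
             height = yx[, 1], width = yx[, 2],
             tilesY = as.integer(ceiling(yx[, 1] / pyramid@tileSize)),
             tilesX = as.integer(ceiling(yx[, 2] / pyramid@tileSize)))
}

#' Open a multiscale image or bitmask pyramid store
#' @param path Pyramid directory with multiscale metadata in `.zattrs`.
#' @return An [ImagePyramid-class].
#' @export
openImagePyramid <- function(path) {
  attrsFile <- file.path(path, ".zattrs")
  if (!file.exists(attrsFile)) .ioError(paste0("not a pyramid store: ", path))
  attrs <- parseJSON(paste(readLines(attrsFile, warn = FALSE), collapse = "\n"))
  ms <- attrs$multiscales[[1]]
  levelPaths <- vapply(ms$datasets, function(d) d$path, character(1))
  levels <- lapply(levelPaths, function(p) openZarrArray(file.path(path, p)))
  bitmask <- isTRUE(attrs$bitmask)
  l0 <- levels[[1]]
  nChannels <- if (length(l0$shape) == 3) l0$shape[1] else 1L
  tileSize <- l0$chunks[length(l0$chunks)]
  env <- new.env(parent = emptyenv())
  env$log <- list()
  new("ImagePyramid", store = path, levels = levels,
      nChannels = as.integer(nChannels), tileSize = as.integer(tileSize),
      bitmask = bitmask, env = env)
}

#' Load one tile of a pyramid level
#'
#' Reads only the chunk objects backing the requested tile (one per
#' selected channel); every read is appended to the pyramid's access log
#' as (level, channel, tileY, tileX). Edge tiles are returned at their
#' true (smaller) size.
#'
#' @param pyramid An [ImagePyramid-class].
#' @param level 0-based level index.
#' @param tileX,tileY 0-based tile grid indices.
#' @param channels 0-based channel indices (NULL = all; ignored for
#'   bitmasks).
#' @return Numeric array `(channels, th, tw)`, or matrix `(th, tw)` for a
#'   bitmask.
#' @export
loadImageTile <- function(pyramid, level, tileX, tileY, channels = NULL) {
  nl <- length(pyramid@levels)
  if (level < 0 || level >= nl) stop("level out of range: ", level)
  arr <- pyramid@levels[[level + 1L]]
  is3d <- length(arr$shape) == 3
  yx <- if (is3d) arr$shape[2:3] else arr$shape
  ts <- pyramid@tileSize
  gridY <- ceiling(yx[1] / ts); gridX <- ceiling(yx[2] / ts)
  if (tileY < 0 || tileY >= gridY || tileX < 0 || tileX >= gridX) {
    stop("tile index out of grid: (", tileX, ", ", tileY, ") at level ", level)
  }
  th <- min(ts, yx[1] - tileY * ts)
  tw <- min(ts, yx[2] - tileX * ts)
  logFetch <- function(ch) {
    pyramid@env$log[[length(pyramid@env$log) + 1L]] <-
      matrix(as.integer(c(level, ch, tileY, tileX)), nrow = 1)
  }
  if (!is3d) {
    logFetch(0L)
    block <- .readZarrChunk(arr, c(tileY, tileX))
    return(block[seq_len(th), seq_len(tw), drop = FALSE])
  }
  if (is.null(channels)) channels <- 0:(arr$shape[1] - 1L)
  channels <- as.integer(channels)
  if (any(channels < 0L | channels >= arr$shape[1])) {
    stop("channel selection out of range")
  }
  out <- array(NA_real_, dim = c(length(channels), th, tw))
  for (i in seq_along(channels)) {
    ch <- channels[i]
    logFetch(ch)
    block <- .readZarrChunk(arr, c(ch, tileY, tileX))
    out[i, , ] <- block[1, seq_len(th), seq_len(tw)]
  }
  out
}

## Eager loaders ---------------------------------------------------------

.readCsv <- function(url) {
  if (!file.exists(url)) .ioError(paste0("cannot read file: ", url))
  utils::read.csv(url, stringsAsFactors = FALSE, check.names = FALSE)
}

.loadMatrixCsv <- function(url) {
  df <- .readCsv(url)
  if (ncol(df) < 1) .validationError("matrix CSV needs an observation-id column")
  obsIds <- as.character(df[[1]])
  if (anyDuplicated(obsIds)) .validationError("duplicate observation ids in CSV")
  featureIds <- colnames(df)[-1]
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) > 0 && !is.numeric(m)) {
    .validationError("matrix CSV has non-numeric feature values")
  }
  storage.mode(m) <- "double"
  dimnames(m) <- list(obsIds, featureIds)
  list(matrix = m, obsIds = obsIds, featureIds = featureIds)
}

.loadTableCsv <- function(url, minDims, what) {
  df <- .readCsv(url)
  if (ncol(df) < 1 + minDims) {
    .validationError(paste0(what, " CSV needs obs-id plus >= ", minDims,
                            " coordinate columns"))
  }
  obsIds <- as.character(df[[1]])
  if (anyDuplicated(obsIds)) .validationError("duplicate observation ids in CSV")
  coords <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(coords) > 0 && !is.numeric(coords)) {
    .validationError(paste0(what, " CSV has non-numeric coordinates"))
  }
  storage.mode(coords) <- "double"
  rownames(coords) <- obsIds
  list(obsIds = obsIds, coords = coords)
}

## Set hierarchies -------------------------------------------------------

.walkSetTree <- function(node, path, rootObs, problems) {
  nm <- node$name
  if (is.null(nm) || !nzchar(nm)) {
    problems$msgs <- c(problems$msgs, "set node without a name")
    return(invisible(NULL))
  }
  if (nm %in% path) {
    .validationError(paste0("cycle in set hierarchy: node '", nm,
                            "' repeats along its own path"))
  }
  if (!is.null(node$children) && !is.null(node$set)) {
    .validationError(paste0("node '", nm, "' has both children and a set"))
  }
  if (!is.null(node$children)) {
    for (ch in node$children) .walkSetTree(ch, c(path, nm), rootObs, problems)
  } else {
    ids <- as.character(unlist(node$set))
    dup <- intersect(ids, rootObs$seen)
    if (length(dup)) {
      .validationError(paste0("observation id(s) in more than one leaf of root '",
                              path[1], "': ", paste(utils::head(dup, 3),
                                                    collapse = ", ")))
    }
    rootObs$seen <- c(rootObs$seen, ids)
  }
  invisible(NULL)
}

#' Validate and load a hierarchical set annotation (JSON)
#'
#' Tree of named nodes; leaves carry observation-id lists and optional
#' RGB colors. Within one root, no observation may appear in more than
#' one leaf; a node name repeating along its own path is rejected as a
#' cycle.
#'
#' @param url JSON file path.
#' @return The parsed hierarchy (list with `tree`).
#' @export
loadSetHierarchy <- function(url) {
  if (!file.exists(url)) .ioError(paste0("cannot read file: ", url))
  doc <- parseJSON(paste(readLines(url, warn = FALSE), collapse = "\n"))
  if (is.null(doc$tree)) .validationError("set hierarchy JSON lacks 'tree'")
  for (root in doc$tree) {
    rootObs <- new.env(parent = emptyenv()); rootObs$seen <- character(0)
    problems <- new.env(parent = emptyenv()); problems$msgs <- character(0)
    .walkSetTree(root, character(0), rootObs, problems)
    if (length(problems$msgs)) .validationError(problems$msgs[1])
  }
  doc
}

#' Leaves of a set hierarchy as a flat table
#' @param sets Result of [loadSetHierarchy].
#' @return data.frame with columns obsId, set, root; attribute `colors`
#'   (named list set -> RGB vector).
#' @export
setHierarchyLeaves <- function(sets) {
  rows <- list(); colors <- list()
  visit <- function(node, root) {
    if (!is.null(node$children)) {
      for (ch in node$children) visit(ch, root)
    } else {
      ids <- as.character(unlist(node$set))
      if (length(ids)) {
        rows[[length(rows) + 1L]] <<- data.frame(
          obsId = ids, set = node$name, root = root, stringsAsFactors = FALSE)
      }
      if (!is.null(node$color)) colors[[node$name]] <<- as.numeric(unlist(node$color))
    }
  }
  for (root in sets$tree) visit(root, root$name)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(obsId = character(0), set = character(0), root = character(0))
  attr(out, "colors") <- colors
  out
}

## Dispatch --------------------------------------------------------------

#' Load the data payload behind an accessor
#'
#' Accessors come from [expandJointFileType] / [datasetManifest]. Chunked
#' stores are opened lazily (handles); CSV and JSON are loaded eagerly
#' and validated.
#'
#' @param accessor Accessor descriptor (dataType, url, options, fileType).
#' @param root Optional directory that relative urls are resolved against.
#' @return Payload: matrix list or [ChunkedMatrixHandle-class] for
#'   obsFeatureMatrix, coordinate table for obsLocations/obsEmbedding,
#'   hierarchy for obsSets, [ImagePyramid-class] for image /
#'   obsSegmentations.
#' @export
loadData <- function(accessor, root = NULL) {
  url <- accessor$url
  if (!is.null(root) && !grepl("^(/|[A-Za-z]:)", url)) {
    url <- file.path(root, url)
  }
  opts <- accessor$options
  switch(accessor$dataType,
    obsFeatureMatrix = {
      if (grepl("\\.csv$", url)) .loadMatrixCsv(url)
      else openMatrixHandle(url, path = opts$path)
    },
    obsLocations = {
      if (grepl("\\.csv$", url)) .loadTableCsv(url, 2, "locations")
      else .loadZarrTable(url, opts$path)
    },
    obsEmbedding = {
      out <- if (grepl("\\.csv$", url)) .loadTableCsv(url, 2, "embedding")
             else .loadZarrTable(url, opts$path)
      out$embeddingType <- opts$embeddingType
      out
    },
    obsSets = loadSetHierarchy(if (grepl("\\.json$", url)) url else
                                 file.path(url, opts$path)),
    image = openImagePyramid(url),
    obsSegmentations = openImagePyramid(url),
    stop("no loader for data type: ", accessor$dataType)
  )
}

## nObs x k array plus obs ids, from a sub-array of a joint store
.loadZarrTable <- function(store, path) {
  arr <- openZarrArray(file.path(store, path))
  coords <- readZarrRegion(arr, NULL)
  rootAttrsFile <- file.path(store, ".zattrs")
  obsIds <- if (file.exists(rootAttrsFile)) {
    as.character(unlist(parseJSON(paste(readLines(rootAttrsFile, warn = FALSE),
                                        collapse = "\n"))$obsIds))
  } else as.character(seq_len(nrow(coords)))
  if (length(obsIds) != nrow(coords)) {
    .validationError("obsIds attribute length does not match coordinate rows")
  }
  rownames(coords) <- obsIds
  list(obsIds = obsIds, coords = coords)
}

#' Fully materialize a payload
#'
#' The required full-load operation: dense matrix for matrix handles, the
#' base-resolution array for pyramids, identity for eager payloads.
#' @param x Payload or handle.
#' @return Dense data.
#' @export
loadFull <- function(x) {
  if (methods::is(x, "ChunkedMatrixHandle")) {
    m <- loadMatrixSubset(x, NULL, NULL)
    return(m)
  }
  if (methods::is(x, "ImagePyramid")) {
    return(readZarrFull(x@levels[[1]]))
  }
  x
}
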