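## Minimal Zarr-v2-compatible chunked directory store.
##
## Layout: one array per directory; `.zarray` holds shape/chunks/dtype/codec
## metadata, optional `.zattrs` holds free-form attributes, and each chunk
## lives in a file named by its 0-based grid indices joined with ".".
## Edge chunks are padded to the full chunk shape with the fill value
## (Zarr convention), values are C-order, little-endian. Codecs: "zlib"
## (DEFLATE via memCompress) or NULL for raw.

.zarrDtypes <- list(
  "<f8" = list(what = "double", size = 8L),
  "<i4" = list(what = "integer", size = 4L)
)

.chunkKey <- function(idx) paste(idx, collapse = ".")

## C-order (row-major) flatten / unflatten
.cFlatten <- function(a) as.vector(aperm(a, rev(seq_along(dim(a)))))
.cUnflatten <- function(v, shape) {
  aperm(array(v, dim = rev(shape)), rev(seq_along(shape)))
}

#' Write an array to a Zarr-compatible directory store
#'
#' @param x Numeric or integer array (2-D or 3-D).
#' @param path Directory to create (must not already contain an array).
#' @param chunks Integer vector, chunk shape (same length as `dim(x)`).
#' @param dtype `"<f8"` (float64) or `"<i4"` (int32).
#' @param compressor `"zlib"` or `NULL` (raw bytes).
#' @param level Compression level 1-9.
#' @param attrs Optional named list written to `.zattrs`.
#' @param fill Fill value used to pad ragged edge chunks.
#' @return `path`, invisibly.
#' @export
writeZarrArray <- function(x, path, chunks, dtype = "<f8",
                           compressor = "zlib", level = 5L,
                           attrs = NULL, fill = 0) {
  shape <- dim(x)
  if (is.null(shape)) stop("x must be an array with dim()")
  chunks <- as.integer(chunks)
  if (length(chunks) != length(shape)) stop("chunks must match dimensionality of x")
  if (any(chunks < 1L)) stop("chunk dimensions must be >= 1")
  dt <- .zarrDtypes[[dtype]]
  if (is.null(dt)) stop("unsupported dtype: ", dtype)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)

  meta <- list(
    zarr_format = 2,
    shape = as.list(as.numeric(shape)),
    chunks = as.list(as.numeric(chunks)),
    dtype = dtype,
    compressor = if (is.null(compressor)) NULL else
      list(id = "zlib", level = as.numeric(level)),
    fill_value = as.numeric(fill),
    order = "C",
    filters = NULL,
    dimension_separator = "."
  )
  writeLines(canonicalJSON(meta), file.path(path, ".zarray"), useBytes = TRUE)
  if (!is.null(attrs)) {
    writeLines(canonicalJSON(attrs), file.path(path, ".zattrs"), useBytes = TRUE)
  }

  if (any(shape == 0L)) return(invisible(path))   # degenerate: metadata only
  grid <- pmax(1L, as.integer(ceiling(shape / chunks)))
  idxList <- lapply(grid, function(g) 0:(g - 1L))
  allIdx <- as.matrix(expand.grid(idxList, KEEP.OUT.ATTRS = FALSE))
  storage.mode(x) <- if (dtype == "<i4") "integer" else "double"

  for (r in seq_len(nrow(allIdx))) {
    idx <- as.integer(allIdx[r, ])
    starts <- idx * chunks + 1L
    ends <- pmin(starts + chunks - 1L, shape)
    sel <- mapply(function(s, e) s:e, starts, ends, SIMPLIFY = FALSE)
    block <- do.call(`[`, c(list(x), sel, list(drop = FALSE)))
    if (any(dim(block) < chunks)) {
      full <- array(if (dtype == "<i4") as.integer(fill) else as.numeric(fill),
                    dim = chunks)
      fsel <- lapply(dim(block), function(d) 1:d)
      full <- do.call(`[<-`, c(list(full), fsel, list(value = block)))
      block <- full
    }
    bytes <- writeBin(.cFlatten(block), raw(), size = dt$size, endian = "little")
    if (!is.null(compressor)) {
      bytes <- memCompress(bytes, type = "gzip")
    }
    writeBin(bytes, file.path(path, .chunkKey(idx)))
  }
  invisible(path)
}

#' Open a Zarr-compatible array directory (metadata only; no chunk reads)
#'
#' @param path Array directory containing `.zarray`.
#' @return A list with shape, chunks, dtype, compressor, fill, grid, attrs.
#' @export
openZarrArray <- function(path) {
  metaFile <- file.path(path, ".zarray")
  if (!file.exists(metaFile)) {
    stop(structure(class = c("ioError", "error", "condition"),
                   list(message = paste0("not a chunked array store: ", path),
                        call = NULL)))
  }
  meta <- parseJSON(paste(readLines(metaFile, warn = FALSE), collapse = "\n"))
  shape <- as.integer(unlist(meta$shape))
  chunks <- as.integer(unlist(meta$chunks))
  attrsFile <- file.path(path, ".zattrs")
  attrs <- if (file.exists(attrsFile)) {
    parseJSON(paste(readLines(attrsFile, warn = FALSE), collapse = "\n"))
  } else NULL
  list(
    path = path, shape = shape, chunks = chunks,
    dtype = meta$dtype,
    compressed = !is.null(meta$compressor),
    fill = meta$fill_value,
    grid = pmax(1L, as.integer(ceiling(shape / chunks))),
    attrs = attrs
  )
}

## Read one chunk, returned at full (padded) chunk shape.
.readZarrChunk <- function(arr, idx) {
  f <- file.path(arr$path, .chunkKey(idx))
  dt <- .zarrDtypes[[arr$dtype]]
  n <- prod(arr$chunks)
  if (!file.exists(f)) {
    v <- rep(if (arr$dtype == "<i4") as.integer(arr$fill) else as.numeric(arr$fill), n)
    return(.cUnflatten(v, arr$chunks))
  }
  bytes <- readBin(f, raw(), n = file.size(f))
  if (arr$compressed) bytes <- memDecompress(bytes, type = "gzip")
  v <- readBin(bytes, dt$what, n = n, size = dt$size, endian = "little")
  .cUnflatten(v, arr$chunks)
}

#' Read a rectangular region of a chunked array
#'
#' Reads only the chunks intersecting the requested region. Ranges are
#' 0-based, half-open `c(start, end)`; `NULL` means the full axis.
#'
#' @param arr Result of [openZarrArray].
#' @param ranges List of per-axis ranges (or NULLs).
#' @param onFetch Optional callback `function(idx)` invoked once per chunk
#'   actually read (used for access accounting).
#' @return Array of the requested shape.
#' @export
readZarrRegion <- function(arr, ranges = NULL, onFetch = NULL) {
  nd <- length(arr$shape)
  if (is.null(ranges)) ranges <- vector("list", nd)
  rng <- lapply(seq_len(nd), function(d) {
    r <- ranges[[d]]
    if (is.null(r)) c(0L, arr$shape[d]) else as.integer(r)
  })
  for (d in seq_len(nd)) {
    if (rng[[d]][1] < 0L || rng[[d]][2] > arr$shape[d] || rng[[d]][1] > rng[[d]][2]) {
      stop("region out of bounds on axis ", d)
    }
  }
  outShape <- vapply(rng, function(r) r[2] - r[1], integer(1))
  out <- array(if (arr$dtype == "<i4") NA_integer_ else NA_real_, dim = pmax(outShape, 1L))
  if (any(outShape == 0L)) {
    return(array(vector(mode = if (arr$dtype == "<i4") "integer" else "double"),
                 dim = outShape))
  }
  chunkIdx <- lapply(seq_len(nd), function(d) {
    lo <- rng[[d]][1] %/% arr$chunks[d]
    hi <- (rng[[d]][2] - 1L) %/% arr$chunks[d]
    lo:hi
  })
  idxGrid <- as.matrix(expand.grid(chunkIdx, KEEP.OUT.ATTRS = FALSE))
  for (r in seq_len(nrow(idxGrid))) {
    idx <- as.integer(idxGrid[r, ])
    if (!is.null(onFetch)) onFetch(idx)
    block <- .readZarrChunk(arr, idx)
    cStart <- idx * arr$chunks                 # 0-based data start of chunk
    selIn <- vector("list", nd); selOut <- vector("list", nd)
    for (d in seq_len(nd)) {
      s <- max(cStart[d], rng[[d]][1]); e <- min(cStart[d] + arr$chunks[d], rng[[d]][2])
      selIn[[d]] <- (s - cStart[d] + 1L):(e - cStart[d])
      selOut[[d]] <- (s - rng[[d]][1] + 1L):(e - rng[[d]][1])
    }
    piece <- do.call(`[`, c(list(block), selIn, list(drop = FALSE)))
    out <- do.call(`[<-`, c(list(out), selOut, list(value = piece)))
  }
  out
}

#' Read a full chunked array into memory
#' @param arr Result of [openZarrArray] or a path.
#' @return The dense array.
#' @export
readZarrFull <- function(arr) {
  if (is.character(arr)) arr <- openZarrArray(arr)
  readZarrRegion(arr, NULL)
}
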