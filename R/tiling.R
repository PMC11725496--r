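## Viewport mathematics shared by image and heatmap rendering: pyramid
## level selection, visible-tile enumeration, anti-aliasing aggregation of
## matrix blocks to pixel grids, and axis tick thinning. Pure functions;
## zoom is log2 of screen pixels per data unit (zoom 0: 1 data px = 1
## screen px; negative zoom: zoomed out).

#' Construct a viewport
#' @param targetX,targetY Data-space center.
#' @param zoom log2(screen pixels per data unit).
#' @param widthPx,heightPx Screen size in pixels (>= 1).
#' @param channels Optional C/T/Z channel selection carried to loaders.
#' @return Viewport (list).
#' @export
Viewport <- function(targetX = 0, targetY = 0, zoom = 0,
                     widthPx = 512L, heightPx = 512L, channels = NULL) {
  stopifnot(widthPx >= 1, heightPx >= 1)
  list(targetX = targetX, targetY = targetY, zoom = zoom,
       widthPx = as.integer(widthPx), heightPx = as.integer(heightPx),
       channels = channels)
}

## data-space rectangle [x0,x1) x [y0,y1) covered by a viewport
.viewportRect <- function(viewport) {
  s <- 2^viewport$zoom
  halfW <- viewport$widthPx / (2 * s); halfH <- viewport$heightPx / (2 * s)
  c(x0 = viewport$targetX - halfW, x1 = viewport$targetX + halfW,
    y0 = viewport$targetY - halfH, y1 = viewport$targetY + halfH)
}

#' Select the pyramid level matching a viewport's resolution
#'
#' Returns the highest-resolution level whose downsample factor is at
#' least the number of data pixels per screen pixel (never fetch more
#' resolution than is displayable), clamped to the deepest available
#' level when the viewport is zoomed out beyond it.
#'
#' @param viewport A [Viewport].
#' @param factors Strictly increasing downsample factors of the available
#'   levels (e.g. `2^(0:(n-1))`).
#' @return 0-based index into `factors`.
#' @export
selectPyramidLevel <- function(viewport, factors) {
  stopifnot(length(factors) >= 1, !is.unsorted(factors, strictly = TRUE))
  need <- 2^(-viewport$zoom)       # data px per screen px
  ok <- which(factors >= need)
  if (length(ok) == 0) return(length(factors) - 1L)
  ok[1] - 1L
}

#' Enumerate the tiles visible in a viewport at a level
#'
#' Exactly the tiles whose data-space footprint intersects the viewport
#' rectangle, clamped to the level's tile grid.
#'
#' @param viewport A [Viewport].
#' @param levelShape `(height, width)` of the level in level pixels.
#' @param downsampleFactor Data pixels per level pixel.
#' @param tileSize Tile edge in level pixels.
#' @return Matrix with columns `tileX`, `tileY` (0-based), ordered
#'   row-major (tileY, then tileX); zero rows when nothing is visible.
#' @export
visibleTiles <- function(viewport, levelShape, downsampleFactor, tileSize) {
  r <- .viewportRect(viewport)
  span <- tileSize * downsampleFactor   # data units per tile
  gridY <- ceiling(levelShape[1] / tileSize)
  gridX <- ceiling(levelShape[2] / tileSize)
  tx0 <- max(0L, as.integer(floor(r["x0"] / span)))
  tx1 <- min(gridX - 1L, as.integer(ceiling(r["x1"] / span) - 1L))
  ty0 <- max(0L, as.integer(floor(r["y0"] / span)))
  ty1 <- min(gridY - 1L, as.integer(ceiling(r["y1"] / span) - 1L))
  if (tx1 < tx0 || ty1 < ty0) {
    return(matrix(integer(0), ncol = 2,
                  dimnames = list(NULL, c("tileX", "tileY"))))
  }
  g <- expand.grid(tileX = tx0:tx1, tileY = ty0:ty1)
  as.matrix(g[order(g$tileY, g$tileX), c("tileX", "tileY"), drop = FALSE])
}

## proportional integer partition: bin k (0-based) covers indices
## floor(k*n/p) .. floor((k+1)*n/p) - 1; exact partition, no resampling
.binStarts <- function(n, p) floor((0:p) * n / p)

.binAssign <- function(n, p) {
  starts <- .binStarts(n, p)
  findInterval(0:(n - 1), starts[seq_len(p)])  # 1-based bin per index
}

#' Aggregate a matrix block onto a coarser pixel grid
#'
#' Anti-aliasing reduction used by the heatmap at low zoom: pixel (i, j)
#' is `aggFn` over a contiguous bin of matrix cells; the bins partition
#' the block exactly (no cell dropped or double-counted), so a constant
#' matrix yields a constant pixel grid at every zoom. If the requested
#' grid is finer than the block on an axis, that axis passes through
#' unaggregated.
#'
#' @param block Numeric matrix.
#' @param pixelRows,pixelCols Target grid size.
#' @param aggFn `"mean"`, `"max"` or `"min"`.
#' @return `pixelRows x pixelCols` numeric matrix (clamped to block dims).
#' @export
aggregateMatrixToPixels <- function(block, pixelRows, pixelCols,
                                    aggFn = c("mean", "max", "min")) {
  aggFn <- match.arg(aggFn)
  n <- nrow(block); m <- ncol(block)
  if (n == 0 || m == 0) return(matrix(numeric(0), nrow = n, ncol = m))
  p <- min(as.integer(pixelRows), n)
  q <- min(as.integer(pixelCols), m)
  rbin <- .binAssign(n, p)
  cbin <- .binAssign(m, q)
  if (aggFn == "mean") {
    sums <- rowsum(t(rowsum(block, rbin, reorder = TRUE)), cbin,
                   reorder = TRUE)                       # q x p
    cnt <- tcrossprod(tabulate(cbin, q), tabulate(rbin, p))
    return(unname(t(sums / cnt)))
  }
  f <- if (aggFn == "max") max else min
  out <- matrix(NA_real_, p, q)
  rIdx <- split(seq_len(n), rbin); cIdx <- split(seq_len(m), cbin)
  for (i in seq_len(p)) {
    sub <- block[rIdx[[i]], , drop = FALSE]
    for (j in seq_len(q)) out[i, j] <- f(sub[, cIdx[[j]]])
  }
  out
}

#' Choose which axis labels to draw at a zoom level
#'
#' Thins labels so that, at a fixed per-character pixel width, drawn
#' labels never overlap: with per-item extent `axisLengthPx * 2^zoom / n`
#' labels are drawn every `ceiling(maxLabelPx / itemPx)` items. Doubling
#' the zoom never decreases the number of drawn labels.
#'
#' @param zoom log2 scale factor of the axis.
#' @param labels Character vector of item labels.
#' @param axisLengthPx On-screen axis length at zoom 0.
#' @param charPx Per-character pixel width (7 px default).
#' @return 1-based indices of the labels to draw (possibly just 1).
#' @export
axisTickPolicy <- function(zoom, labels, axisLengthPx, charPx = 7) {
  n <- length(labels)
  if (n == 0) return(integer(0))
  maxLabelPx <- max(nchar(labels)) * charPx
  itemPx <- axisLengthPx * 2^zoom / n
  if (itemPx <= 0 || !is.finite(itemPx)) return(1L)
  step <- max(1L, as.integer(ceiling(maxLabelPx / itemPx)))
  seq.int(1L, n, by = step)
}
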