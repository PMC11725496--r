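## Static snapshot renderer. Each view type rasterizes from its resolved
## coordination state and matched data; panels are composed on the layout
## grid. CPU reference semantics: nearest-neighbour viewport sampling,
## additive channel blending for images, painter-style markers.

.layerKinds <- c("image", "segmentations", "spots", "points")
.layerOrder <- c(image = 1, segmentations = 2, spots = 3, points = 4)

.channelPalette <- list(
  c(255, 0, 0), c(0, 255, 0), c(0, 0, 255),
  c(255, 255, 0), c(0, 255, 255), c(255, 0, 255), c(255, 255, 255))

.fitViewport <- function(extentW, extentH, widthPx, heightPx,
                         zoomDelta = 0, dx = 0, dy = 0) {
  fitZoom <- log2(min(widthPx / max(extentW, 1e-9),
                      heightPx / max(extentH, 1e-9)))
  Viewport(targetX = extentW / 2 + dx, targetY = extentH / 2 + dy,
           zoom = fitZoom + zoomDelta, widthPx = widthPx, heightPx = heightPx)
}

## screen-pixel centers mapped to data space (x axis; same math for y)
.screenToData <- function(viewport, nPx, target) {
  target + ((seq_len(nPx) - 0.5) - nPx / 2) / 2^viewport$zoom
}

## assemble the level window covering the viewport from tiles; returns
## list(data = array, y0, x0) with 0-based level-pixel offsets
.assembleWindow <- function(pyramid, level, viewport) {
  info <- pyramidLevels(pyramid)
  shape <- c(info$height[level + 1], info$width[level + 1])
  factor <- info$downsampleFactor[level + 1]
  ts <- pyramid@tileSize
  tiles <- visibleTiles(viewport, shape, factor, ts)
  if (nrow(tiles) == 0) return(NULL)
  ty <- range(tiles[, "tileY"]); tx <- range(tiles[, "tileX"])
  y0 <- ty[1] * ts; x0 <- tx[1] * ts
  h <- min((ty[2] + 1) * ts, shape[1]) - y0
  w <- min((tx[2] + 1) * ts, shape[2]) - x0
  is3d <- !pyramid@bitmask
  win <- if (is3d) array(0, dim = c(pyramid@nChannels, h, w)) else
    matrix(0L, h, w)
  for (r in seq_len(nrow(tiles))) {
    tY <- tiles[r, "tileY"]; tX <- tiles[r, "tileX"]
    tile <- loadImageTile(pyramid, level, tX, tY)
    ry <- (tY * ts - y0) + seq_len(if (is3d) dim(tile)[2] else nrow(tile))
    rx <- (tX * ts - x0) + seq_len(if (is3d) dim(tile)[3] else ncol(tile))
    if (is3d) win[, ry, rx] <- tile else win[ry, rx] <- tile
  }
  list(data = win, y0 = y0, x0 = x0, factor = factor, shape = shape)
}

## per-axis sample indices into a window; idx NA when outside the image
.sampleIndex <- function(dataCoords, factor, off0, extent, winExtent) {
  lev <- floor(dataCoords / factor)
  idx <- lev - off0 + 1
  idx[lev < 0 | lev >= extent | idx < 1 | idx > winExtent] <- NA
  idx
}

.renderImageLayer <- function(pyramid, viewport, opacity = 1, channels = NULL,
                              channelColors = NULL, channelWindows = NULL) {
  w <- viewport$widthPx; h <- viewport$heightPx
  out <- newRaster(w, h)
  lvl <- selectPyramidLevel(viewport, 2^(0:(length(pyramid@levels) - 1)))
  win <- .assembleWindow(pyramid, lvl, viewport)
  if (is.null(win)) return(out)
  dx <- .screenToData(viewport, w, viewport$targetX)
  dy <- .screenToData(viewport, h, viewport$targetY)
  ix <- .sampleIndex(dx, win$factor, win$x0, win$shape[2], dim(win$data)[3])
  iy <- .sampleIndex(dy, win$factor, win$y0, win$shape[1], dim(win$data)[2])
  okx <- !is.na(ix); oky <- !is.na(iy)
  if (!any(okx) || !any(oky)) return(out)
  if (is.null(channels)) channels <- 0:(pyramid@nChannels - 1)
  channels <- as.integer(channels)
  acc <- array(0, dim = c(h, w, 3))
  for (i in seq_along(channels)) {
    ch <- channels[i] + 1L
    plane <- win$data[ch, iy[oky], ix[okx], drop = TRUE]
    plane <- matrix(plane, nrow = sum(oky))
    cw <- channelWindows[[as.character(channels[i])]]
    if (is.null(cw)) {
      lo <- min(plane); hi <- max(plane)
      if (hi <= lo) hi <- lo + 1
    } else { lo <- cw[[1]]; hi <- cw[[2]] }
    t <- pmin(1, pmax(0, (plane - lo) / (hi - lo)))
    col <- channelColors[[as.character(channels[i])]]
    if (is.null(col)) col <- .channelPalette[[(i - 1) %% 7 + 1]]
    col <- as.numeric(unlist(col))
    for (p in 1:3) {
      sub <- acc[oky, okx, p]
      acc[oky, okx, p] <- sub + t * col[p]
    }
  }
  for (p in 1:3) out[, , p] <- pmin(255, acc[, , p])
  alpha <- matrix(0, h, w)
  alpha[oky, okx] <- 255 * opacity
  out[, , 4] <- alpha
  out
}

.renderSegmentationLayer <- function(pyramid, viewport, labelColors,
                                     opacity = 1) {
  w <- viewport$widthPx; h <- viewport$heightPx
  out <- newRaster(w, h)
  lvl <- selectPyramidLevel(viewport, 2^(0:(length(pyramid@levels) - 1)))
  win <- .assembleWindow(pyramid, lvl, viewport)
  if (is.null(win)) return(out)
  dx <- .screenToData(viewport, w, viewport$targetX)
  dy <- .screenToData(viewport, h, viewport$targetY)
  ix <- .sampleIndex(dx, win$factor, win$x0, win$shape[2], ncol(win$data))
  iy <- .sampleIndex(dy, win$factor, win$y0, win$shape[1], nrow(win$data))
  okx <- !is.na(ix); oky <- !is.na(iy)
  if (!any(okx) || !any(oky)) return(out)
  lab <- win$data[iy[oky], ix[okx], drop = FALSE]
  n <- nrow(labelColors)
  valid <- lab > 0 & lab <= n
  idx <- pmin(pmax(lab, 1L), n)
  for (p in 1:3) {
    plane <- matrix(labelColors[idx, p], nrow = nrow(lab))
    plane[!valid] <- 0
    full <- matrix(0, h, w); full[oky, okx] <- plane
    out[, , p] <- full
  }
  aplane <- matrix(0, nrow(lab), ncol(lab)); aplane[valid] <- 255 * opacity
  alpha <- matrix(0, h, w); alpha[oky, okx] <- aplane
  out[, , 4] <- alpha
  out
}

.renderMarkerLayer <- function(coords, colors, viewport, radius = 1,
                               opacity = 1) {
  w <- viewport$widthPx; h <- viewport$heightPx
  out <- newRaster(w, h)
  if (nrow(coords) == 0) return(out)
  s <- 2^viewport$zoom
  cx <- floor((coords[, 1] - viewport$targetX) * s + w / 2) + 1
  cy <- floor((coords[, 2] - viewport$targetY) * s + h / 2) + 1
  r <- max(0, radius - 1)
  offs <- expand.grid(dx = -ceiling(r):ceiling(r), dy = -ceiling(r):ceiling(r))
  offs <- offs[offs$dx^2 + offs$dy^2 <= r^2 + 1e-9, , drop = FALSE]
  for (k in seq_len(nrow(offs))) {
    px <- cx + offs$dx[k]; py <- cy + offs$dy[k]
    ok <- px >= 1 & px <= w & py >= 1 & py <= h
    if (!any(ok)) next
    for (p in 1:3) {
      out[cbind(py[ok], px[ok], p)] <- colors[ok, p]
    }
    out[cbind(py[ok], px[ok], 4)] <- 255 * opacity
  }
  out
}

#' Render a spatial layer stack to a raster
#'
#' Layers (points, spots, segmentations, images) are composited
#' back-to-front with alpha in a fixed z-order: images at the bottom,
#' then segmentations, spots, points. Segmentation bitmask pixels take
#' the encoded color of their observation label; label 0 is transparent.
#' Image channels are blended additively after per-channel contrast
#' windowing, clipped at 255.
#'
#' @param layers List of layers. Each layer is a list with `kind` (one of
#'   `"image"`, `"segmentations"`, `"spots"`, `"points"`), `data` (an
#'   [ImagePyramid-class] for image/segmentations; an `(n x 2)` coordinate
#'   matrix for spots/points), and optionally `opacity`, `visible`,
#'   `colors` (per-observation / per-label RGB matrix), `radius`,
#'   `channels`, `channelColors`, `channelWindows`.
#' @param widthPx,heightPx Output size.
#' @param viewport Optional [Viewport]; default fits the data extent.
#' @return RGBA raster (transparent background).
#' @export
renderSpatial <- function(layers, widthPx, heightPx, viewport = NULL) {
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    if (!is.list(l) || is.null(l$kind) || !(l$kind %in% .layerKinds)) {
      stop("layer ", i, ": unknown layer kind")
    }
    if (l$kind %in% c("image", "segmentations")) {
      if (!methods::is(l$data, "ImagePyramid")) {
        stop("layer ", i, " (", l$kind, "): data is not an image pyramid")
      }
      if (l$kind == "segmentations" && !l$data@bitmask) {
        stop("layer ", i, " (segmentations): pyramid is not a bitmask")
      }
    } else if (!is.matrix(l$data) || ncol(l$data) < 2) {
      stop("layer ", i, " (", l$kind, "): data is not a coordinate matrix")
    }
  }
  if (is.null(viewport)) {
    extW <- 0; extH <- 0
    for (l in layers) {
      if (l$kind %in% c("image", "segmentations")) {
        info <- pyramidLevels(l$data)
        extW <- max(extW, info$width[1]); extH <- max(extH, info$height[1])
      } else if (nrow(l$data) > 0) {
        extW <- max(extW, max(l$data[, 1]) + 1)
        extH <- max(extH, max(l$data[, 2]) + 1)
      }
    }
    viewport <- .fitViewport(extW, extH, widthPx, heightPx)
  }
  viewport$widthPx <- as.integer(widthPx)
  viewport$heightPx <- as.integer(heightPx)
  ord <- order(.layerOrder[vapply(layers, `[[`, character(1), "kind")])
  out <- newRaster(widthPx, heightPx)
  for (i in ord) {
    l <- layers[[i]]
    visible <- if (is.null(l$visible)) TRUE else isTRUE(l$visible)
    opacity <- if (is.null(l$opacity)) 1 else l$opacity
    if (!visible || opacity <= 0) next
    lr <- switch(l$kind,
      image = .renderImageLayer(l$data, viewport, opacity, l$channels,
                                l$channelColors, l$channelWindows),
      segmentations = .renderSegmentationLayer(l$data, viewport, l$colors,
                                               opacity),
      spots = .renderMarkerLayer(l$data, l$colors, viewport,
                                 if (is.null(l$radius)) 4 else l$radius,
                                 opacity),
      points = .renderMarkerLayer(l$data, l$colors, viewport,
                                  if (is.null(l$radius)) 1 else l$radius,
                                  opacity))
    out <- compositeOver(out, lr)
  }
  out
}

## Per-observation color resolution driven by coordination state --------

.featureMatrixValues <- function(matrixPayload, feature) {
  if (methods::is(matrixPayload, "ChunkedMatrixHandle")) {
    as.numeric(loadMatrixSubset(matrixPayload, feature))
  } else {
    as.numeric(matrixPayload$matrix[, feature])
  }
}

.matrixFeatureIds <- function(matrixPayload) {
  if (methods::is(matrixPayload, "ChunkedMatrixHandle")) matrixPayload@featureIds
  else matrixPayload$featureIds
}

.matrixObsIds <- function(matrixPayload) {
  if (methods::is(matrixPayload, "ChunkedMatrixHandle")) matrixPayload@obsIds
  else matrixPayload$obsIds
}

## colors for obsIds under the view's resolved coordination state
.obsColors <- function(state, obsIds, matrixPayload = NULL,
                       setsPayload = NULL) {
  mode <- state$obsColorEncoding
  if (is.null(mode)) mode <- "setMembership"
  feature <- NA_character_
  if (mode == "featureValue" && !is.null(matrixPayload)) {
    sel <- unlist(state$featureSelection)
    avail <- intersect(sel, .matrixFeatureIds(matrixPayload))
    if (length(avail) > 0) {
      feature <- avail[1]
      vals <- .featureMatrixValues(matrixPayload, feature)
      names(vals) <- .matrixObsIds(matrixPayload)
      v <- vals[obsIds]
      rng <- range(v[is.finite(v)], finite = TRUE)
      frac <- state$featureValueColormapRange
      lo <- if (is.null(frac$min)) 0 else frac$min
      hi <- if (is.null(frac$max)) 1 else frac$max
      dom <- c(rng[1] + lo * diff(rng), rng[1] + hi * diff(rng))
      enc <- if (dom[1] < dom[2]) {
        colorEncoding("featureValue",
                      colormap = if (is.null(state$featureValueColormap))
                        "viridis" else state$featureValueColormap,
                      domain = dom)
      } else {
        colorEncoding("featureValue",
                      colormap = if (is.null(state$featureValueColormap))
                        "viridis" else state$featureValueColormap)
      }
      return(list(colors = mapValuesToColors(v, enc), feature = feature,
                  mode = mode))
    }
    mode <- "setMembership"   # no selected feature in this modality
  }
  if (mode == "setMembership" && !is.null(setsPayload)) {
    leaves <- setHierarchyLeaves(setsPayload)
    setNames <- unique(leaves$set)
    declared <- attr(leaves, "colors")
    pal <- .setPalette(length(setNames))
    colors <- matrix(rep(.missingColor, each = length(obsIds)), ncol = 3)
    obsSet <- leaves$set[match(obsIds, leaves$obsId)]
    for (k in seq_along(setNames)) {
      col <- declared[[setNames[k]]]
      if (is.null(col)) col <- pal[k, ]
      hit <- which(obsSet == setNames[k])
      if (length(hit)) colors[hit, ] <- matrix(rep(col, each = length(hit)),
                                               ncol = 3)
    }
    return(list(colors = colors, feature = feature, mode = "setMembership"))
  }
  list(colors = mapValuesToColors(numeric(length(obsIds)),
                                  colorEncoding("static")),
       feature = feature, mode = "static")
}

## Heatmap ---------------------------------------------------------------

## aggregate (coarser) or replicate (finer) a matrix window to p x q
.resampleMatrix <- function(m, p, q, aggFn = "mean") {
  n1 <- nrow(m); n2 <- ncol(m)
  if (n1 == 0 || n2 == 0) return(matrix(numeric(0), p, q))
  agg <- aggregateMatrixToPixels(m, min(p, n1), min(q, n2), aggFn)
  ri <- floor((seq_len(p) - 1) * nrow(agg) / p) + 1
  ci <- floor((seq_len(q) - 1) * ncol(agg) / q) + 1
  agg[ri, ci, drop = FALSE]
}

#' Render a heatmap view
#'
#' The visible matrix window is aggregated onto the pixel grid (mean
#' reduction, eliminating aliasing at low zoom) and colored through the
#' quantitative colormap; drawing is clipped to the matrix body, with
#' tick marks thinned by [axisTickPolicy].
#'
#' @param state Resolved view state (see [resolveViewState]).
#' @param matrixPayload Matrix payload or [ChunkedMatrixHandle-class].
#' @param widthPx,heightPx Output size.
#' @return Opaque RGBA raster.
#' @export
renderHeatmap <- function(state, matrixPayload, widthPx, heightPx) {
  m <- if (methods::is(matrixPayload, "ChunkedMatrixHandle"))
    loadFull(matrixPayload) else matrixPayload$matrix
  if (length(m) == 0) stop("heatmap requires a nonempty matrix")
  featureIds <- colnames(m)
  nO <- nrow(m); nF <- ncol(m)
  margin <- if (widthPx > 40 && heightPx > 40) 10L else 0L
  bodyW <- widthPx - margin; bodyH <- heightPx - margin
  zx <- if (is.null(state$heatmapZoomX)) 0 else state$heatmapZoomX
  zy <- if (is.null(state$heatmapZoomY)) 0 else state$heatmapZoomY
  winCols <- if (zx <= 0) seq_len(nF) else {
    nv <- max(1L, round(nF / 2^zx))
    start <- min(max(0, round(state$heatmapTargetX * nF - nv / 2)), nF - nv)
    seq.int(start + 1L, start + nv)
  }
  winRows <- if (zy <= 0) seq_len(nO) else {
    nv <- max(1L, round(nO / 2^zy))
    start <- min(max(0, round(state$heatmapTargetY * nO - nv / 2)), nO - nv)
    seq.int(start + 1L, start + nv)
  }
  win <- m[winRows, winCols, drop = FALSE]
  body <- .resampleMatrix(win, bodyH, bodyW, "mean")
  rng <- range(m[is.finite(m)])
  enc <- if (rng[1] < rng[2]) {
    colorEncoding("featureValue",
                  colormap = if (is.null(state$featureValueColormap))
                    "viridis" else state$featureValueColormap,
                  domain = rng)
  } else {
    colorEncoding("featureValue",
                  colormap = if (is.null(state$featureValueColormap))
                    "viridis" else state$featureValueColormap)
  }
  cols <- mapValuesToColors(as.numeric(body), enc)
  out <- newRaster(widthPx, heightPx)
  out[, , 4] <- 255
  for (p in 1:3) {
    plane <- matrix(245, heightPx, widthPx)   # light margin
    plane[(margin + 1):heightPx, (margin + 1):widthPx] <-
      matrix(cols[, p], nrow(body), ncol(body))
    out[, , p] <- plane
  }
  if (margin > 0 && length(featureIds)) {
    ticks <- axisTickPolicy(zx, featureIds[winCols], bodyW)
    px <- margin + floor((ticks - 0.5) / length(winCols) * bodyW) + 1L
    px <- px[px >= 1 & px <= widthPx]
    for (p in 1:3) out[1:margin, px, p] <- 64
    oticks <- axisTickPolicy(zy, rownames(m)[winRows], bodyH)
    py <- margin + floor((oticks - 0.5) / length(winRows) * bodyH) + 1L
    py <- py[py >= 1 & py <= heightPx]
    for (p in 1:3) out[py, 1:margin, p] <- 64
  }
  out
}

## Scatterplot -----------------------------------------------------------

#' Render a scatterplot (embedding) view
#'
#' Points are placed under the embedding camera transform; colors follow
#' the resolved color encoding (feature value, set membership or static),
#' so changing the selected feature recolors without repositioning.
#'
#' @param state Resolved view state.
#' @param embeddingPayload Coordinate payload (list with `coords`,
#'   `obsIds`).
#' @param matrixPayload,setsPayload Optional payloads for coloring.
#' @param widthPx,heightPx Output size.
#' @return RGBA raster.
#' @export
renderScatterplot <- function(state, embeddingPayload, matrixPayload = NULL,
                              setsPayload = NULL, widthPx, heightPx) {
  if (is.null(embeddingPayload)) {
    stop(structure(class = c("noMatchingData", "error", "condition"),
                   list(message = "no matching data: embedding absent",
                        call = NULL)))
  }
  coords <- embeddingPayload$coords[, 1:2, drop = FALSE]
  obsIds <- embeddingPayload$obsIds
  encoded <- .obsColors(state, obsIds, matrixPayload, setsPayload)
  extW <- if (nrow(coords)) diff(range(coords[, 1])) else 1
  extH <- if (nrow(coords)) diff(range(coords[, 2])) else 1
  off <- if (nrow(coords)) c(min(coords[, 1]), min(coords[, 2])) else c(0, 0)
  shifted <- sweep(coords, 2, off)
  pad <- 0.05 * max(extW, extH, 1e-9)
  vp <- .fitViewport(extW + 2 * pad, extH + 2 * pad, widthPx, heightPx,
                     zoomDelta = state$embeddingZoom,
                     dx = state$embeddingTargetX - pad,
                     dy = state$embeddingTargetY - pad)
  r <- if (is.null(state$embeddingPointRadius)) 1 else state$embeddingPointRadius
  op <- if (is.null(state$embeddingPointOpacity)) 1 else state$embeddingPointOpacity
  raster <- .renderMarkerLayer(shifted, encoded$colors, vp, radius = r,
                               opacity = op)
  attr(raster, "feature") <- encoded$feature
  raster
}

## Statistical views -----------------------------------------------------

.drawBars <- function(widthPx, heightPx, heights, colors) {
  out <- newRaster(widthPx, heightPx)
  out[, , 4] <- 255
  for (p in 1:3) out[, , p] <- 255
  k <- length(heights)
  if (k == 0) return(out)
  starts <- .binStarts(widthPx, k)
  hmax <- max(heights, 1e-9)
  for (i in seq_len(k)) {
    x0 <- starts[i] + 1L; x1 <- max(starts[i + 1] - 1L, x0)
    hh <- round(heights[i] / hmax * (heightPx - 2))
    if (hh < 1) next
    rows <- (heightPx - hh + 1):heightPx
    for (p in 1:3) out[rows, x0:x1, p] <- colors[i, p]
  }
  out
}

.renderObsSetSizes <- function(state, setsPayload, widthPx, heightPx) {
  leaves <- setHierarchyLeaves(setsPayload)
  sel <- unlist(state$obsSetSelection)
  setNames <- unique(leaves$set)
  if (length(sel)) setNames <- intersect(setNames, sel)
  sizes <- vapply(setNames, function(s) sum(leaves$set == s), numeric(1))
  declared <- attr(leaves, "colors")
  pal <- .setPalette(max(length(setNames), 1L))
  colors <- t(vapply(seq_along(setNames), function(k) {
    col <- declared[[setNames[k]]]
    if (is.null(col)) pal[k, ] else as.numeric(col)
  }, numeric(3)))
  if (length(setNames) == 0) colors <- matrix(numeric(0), 0, 3)
  .drawBars(widthPx, heightPx, sizes, colors)
}

.renderFeatureHistogram <- function(state, matrixPayload, widthPx, heightPx) {
  sel <- unlist(state$featureSelection)
  ids <- .matrixFeatureIds(matrixPayload)
  feature <- if (length(intersect(sel, ids))) intersect(sel, ids)[1] else ids[1]
  v <- .featureMatrixValues(matrixPayload, feature)
  v <- v[is.finite(v)]
  nb <- 24L
  if (length(v) == 0) return(.drawBars(widthPx, heightPx, numeric(0),
                                       matrix(numeric(0), 0, 3)))
  br <- seq(min(v), max(v), length.out = nb + 1)
  if (br[1] == br[nb + 1]) br <- br[1] + c(-0.5, 0.5)
  counts <- graphics::hist(v, breaks = br, plot = FALSE)$counts
  .drawBars(widthPx, heightPx, counts,
            matrix(rep(c(100, 100, 110), each = length(counts)), ncol = 3))
}

.renderViolin <- function(state, matrixPayload, setsPayload, widthPx,
                          heightPx) {
  leaves <- setHierarchyLeaves(setsPayload)
  setNames <- unique(leaves$set)
  sel <- unlist(state$featureSelection)
  ids <- .matrixFeatureIds(matrixPayload)
  feature <- if (length(intersect(sel, ids))) intersect(sel, ids)[1] else ids[1]
  vals <- .featureMatrixValues(matrixPayload, feature)
  names(vals) <- .matrixObsIds(matrixPayload)
  declared <- attr(leaves, "colors")
  pal <- .setPalette(max(length(setNames), 1L))
  out <- newRaster(widthPx, heightPx)
  out[, , 4] <- 255
  for (p in 1:3) out[, , p] <- 255
  if (length(setNames) == 0) return(out)
  starts <- .binStarts(widthPx, length(setNames))
  rng <- range(vals[is.finite(vals)])
  if (rng[1] == rng[2]) rng <- rng + c(-0.5, 0.5)
  grid <- seq(rng[1], rng[2], length.out = heightPx)
  for (k in seq_along(setNames)) {
    v <- vals[leaves$obsId[leaves$set == setNames[k]]]
    v <- v[is.finite(v)]
    if (length(v) < 2) next
    d <- stats::density(v, from = rng[1], to = rng[2], n = heightPx)
    wHalf <- d$y / max(d$y, 1e-12) * ((starts[k + 1] - starts[k]) / 2 - 1)
    cx <- (starts[k] + starts[k + 1]) / 2
    col <- declared[[setNames[k]]]
    if (is.null(col)) col <- pal[k, ]
    for (row in seq_len(heightPx)) {
      hw <- round(wHalf[heightPx - row + 1])
      if (hw < 1) next
      xs <- max(1, round(cx - hw)):min(widthPx, round(cx + hw))
      for (p in 1:3) out[row, xs, p] <- col[p]
    }
  }
  out
}
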