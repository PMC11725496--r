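## Snapshot composition: wire a validated ViewConfig to loaded data and
## rasterize every layout panel onto the grid. All visual encodings are
## driven by each view's resolved coordination state, so views linked on
## a scope render from identical values.

.payloadFor <- function(accessor, root, cache) {
  key <- paste(accessor$url, accessor$dataType,
               paste(unlist(accessor$options), collapse = "|"), sep = "@")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  payload <- loadData(accessor, root = root)
  cache[[key]] <- payload
  payload
}

.spatialLayersFromData <- function(state, payloads) {
  layers <- list()
  img <- payloads$image
  if (!is.null(img)) {
    chSel <- state$imageChannelSelection
    layers <- c(layers, list(list(
      kind = "image", data = img,
      visible = state$imageLayerVisible, opacity = state$imageLayerOpacity,
      channels = if (is.null(chSel)) NULL else as.integer(unlist(chSel)),
      channelColors = state$imageChannelColor,
      channelWindows = state$imageChannelWindow)))
  }
  seg <- payloads$obsSegmentations
  loc <- payloads$obsLocations
  matrixP <- payloads$obsFeatureMatrix
  setsP <- payloads$obsSets
  obsIds <- NULL
  if (!is.null(loc)) obsIds <- loc$obsIds
  if (is.null(obsIds) && !is.null(matrixP)) obsIds <- .matrixObsIds(matrixP)
  encoded <- if (!is.null(obsIds)) {
    .obsColors(state, obsIds, matrixP, setsP)
  } else NULL
  if (!is.null(seg)) {
    segColors <- if (!is.null(encoded)) encoded$colors else
      matrix(rep(c(200, 120, 60), each = 1), ncol = 3)
    layers <- c(layers, list(list(
      kind = "segmentations", data = seg, colors = segColors,
      visible = state$segmentationLayerVisible,
      opacity = state$segmentationLayerOpacity)))
  }
  if (!is.null(loc)) {
    kind <- if (identical(state$obsType, "molecule")) "points" else "spots"
    layers <- c(layers, list(list(
      kind = kind, data = loc$coords[, 1:2, drop = FALSE],
      colors = encoded$colors,
      radius = if (kind == "spots") state$spotRadius else state$pointRadius,
      visible = if (kind == "spots") state$spotLayerVisible else
        state$pointLayerVisible,
      opacity = if (kind == "spots") state$spotLayerOpacity else
        state$pointLayerOpacity)))
  }
  attr(layers, "feature") <- if (!is.null(encoded)) encoded$feature else NA_character_
  layers
}

#' Render one view of a config to a raster
#'
#' Resolves the view's coordination state, matches it to the dataset's
#' accessors by entity triple, loads the matched payloads (lazily where
#' the format allows) and dispatches on the view type. Controller views
#' carry coordination state only and render as blank panels.
#'
#' @param config A valid `ViewConfig`.
#' @param viewId Layout item uid.
#' @param root Directory that relative file urls resolve against.
#' @param widthPx,heightPx Output size.
#' @param cache Optional environment reusing payloads across panels.
#' @return RGBA raster, with attribute `"feature"` naming the feature
#'   used for coloring (NA when none).
#' @export
renderView <- function(config, viewId, root = NULL, widthPx = 200L,
                       heightPx = 200L, cache = new.env(parent = emptyenv())) {
  state <- resolveViewState(config, viewId)
  item <- .layoutItem(config, viewId)
  dsUid <- if (!is.null(state$dataset)) state$dataset else item$dataset
  ds <- config@datasets[[.datasetIndex(config, dsUid)]]
  manifest <- datasetManifest(ds)
  entity <- list(obsType = state$obsType, featureType = state$featureType,
                 featureValueType = state$featureValueType)
  matched <- matchViewToData(item$component, manifest, entity)
  payloads <- lapply(matched$matches, .payloadFor, root = root, cache = cache)
  comp <- item$component
  if (comp == "scatterplot") {
    emb <- payloads$obsEmbedding
    want <- state$embeddingType
    if (!is.null(want) && !is.null(emb$embeddingType) &&
        !identical(emb$embeddingType, want)) {
      stop(structure(class = c("noMatchingData", "error", "condition"),
                     list(message = paste0("no matching data: embedding type '",
                                           want, "' absent"), call = NULL)))
    }
    return(renderScatterplot(state, emb, payloads$obsFeatureMatrix,
                             payloads$obsSets, widthPx, heightPx))
  }
  if (comp == "spatial") {
    layers <- .spatialLayersFromData(state, payloads)
    raster <- renderSpatial(layers, widthPx, heightPx,
                            viewport = NULL)
    attr(raster, "feature") <- attr(layers, "feature")
    return(raster)
  }
  if (comp == "heatmap") {
    return(renderHeatmap(state, payloads$obsFeatureMatrix, widthPx, heightPx))
  }
  if (comp == "obsSetSizes") {
    return(.renderObsSetSizes(state, payloads$obsSets, widthPx, heightPx))
  }
  if (comp == "featureValueHistogram") {
    return(.renderFeatureHistogram(state, payloads$obsFeatureMatrix,
                                   widthPx, heightPx))
  }
  if (comp == "obsSetFeatureValueDistribution") {
    return(.renderViolin(state, payloads$obsFeatureMatrix, payloads$obsSets,
                         widthPx, heightPx))
  }
  ## controller / list views: coordination state only
  out <- newRaster(widthPx, heightPx)
  for (p in 1:3) out[, , p] <- 235
  out[, , 4] <- 255
  out
}

#' Render a full config snapshot
#'
#' One panel per layout item, placed proportionally to its `(x, y, w, h)`
#' grid rectangle. Views linked on a coordination scope render with
#' identical resolved values for it. A failing panel is reported in the
#' result's `failures` table (and as a warning) while the remaining
#' panels still render.
#'
#' @param config A valid `ViewConfig`.
#' @param root Directory that relative file urls resolve against.
#' @param pxPerUnit Pixels per grid unit (default 200).
#' @return List of class `viewSnapshot`: `raster` (opaque RGBA, white
#'   background), `panels` (data.frame of placements and the feature each
#'   panel colored by), `failures` (data.frame viewId/message).
#' @export
renderSnapshot <- function(config, root = NULL, pxPerUnit = 200L) {
  rep <- validateConfig(config)
  if (any(rep$severity == "error")) {
    stop("config invalid; see validateConfig()")
  }
  items <- config@layout
  if (length(items) == 0) {
    return(structure(list(raster = array(0, dim = c(0, 0, 4)),
                          panels = data.frame(), failures = data.frame()),
                     class = "viewSnapshot"))
  }
  gw <- max(vapply(items, function(v) v$x + v$w, numeric(1)))
  gh <- max(vapply(items, function(v) v$y + v$h, numeric(1)))
  W <- as.integer(gw * pxPerUnit); H <- as.integer(gh * pxPerUnit)
  big <- newRaster(W, H)
  big[, , 4] <- 255
  for (p in 1:3) big[, , p] <- 255
  cache <- new.env(parent = emptyenv())
  panels <- list(); failures <- list()
  for (v in items) {
    pw <- as.integer(v$w * pxPerUnit); ph <- as.integer(v$h * pxPerUnit)
    raster <- tryCatch(
      renderView(config, v$uid, root = root, widthPx = pw, heightPx = ph,
                 cache = cache),
      error = function(e) e)
    if (inherits(raster, "error")) {
      failures[[length(failures) + 1L]] <- data.frame(
        viewId = v$uid, message = conditionMessage(raster),
        stringsAsFactors = FALSE)
      next
    }
    flat <- flattenRaster(raster)
    rows <- (v$y * pxPerUnit + 1):(v$y * pxPerUnit + ph)
    cols <- (v$x * pxPerUnit + 1):(v$x * pxPerUnit + pw)
    big[rows, cols, ] <- flat
    ## 1-px panel border
    for (p in 1:3) {
      big[rows[1], cols, p] <- 90; big[rows[ph], cols, p] <- 90
      big[rows, cols[1], p] <- 90; big[rows, cols[pw], p] <- 90
    }
    panels[[length(panels) + 1L]] <- data.frame(
      viewId = v$uid, component = v$component, x = v$x, y = v$y,
      w = v$w, h = v$h,
      feature = if (is.null(attr(raster, "feature"))) NA_character_ else
        attr(raster, "feature"),
      stringsAsFactors = FALSE)
  }
  failDf <- if (length(failures)) do.call(rbind, failures) else
    data.frame(viewId = character(0), message = character(0))
  if (nrow(failDf) > 0) {
    warning("snapshot: ", nrow(failDf), " panel(s) failed: ",
            paste(failDf$viewId, collapse = ", "))
  }
  structure(list(raster = big,
                 panels = if (length(panels)) do.call(rbind, panels) else
                   data.frame(),
                 failures = failDf),
            class = "viewSnapshot")
}

#' @export
print.viewSnapshot <- function(x, ...) {
  cat("viewSnapshot: ", dim(x$raster)[2], " x ", dim(x$raster)[1],
      " px, ", nrow(x$panels), " panel(s), ", nrow(x$failures),
      " failure(s)\n", sep = "")
  invisible(x)
}
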