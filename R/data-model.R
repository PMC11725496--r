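## Data model: the closed set of data types, the registry of file types
## (data type-file format pairs, including joint file types), the built-in
## view registry with its per-view data requirements, and the entity-triple
## rules that match views to data.
##
## An entity triple is the (obsType, featureType, featureValueType)
## identifier set that binds a view or file to a modality: observations are
## the entities measured (cell, spot, molecule, ...), features the measured
## characteristics (gene, protein, peak, ...), feature values the measured
## quantities (expression, count, intensity, ...).

.entityComponents <- c("obsType", "featureType", "featureValueType")
.entityDefaults <- list(obsType = "cell", featureType = "gene",
                        featureValueType = "expression")

#' Built-in data types and the entity components that identify them
#' @return Named list: data type name -> character vector of axes.
#' @export
dataTypes <- function() {
  list(
    obsFeatureMatrix = c("obsType", "featureType", "featureValueType"),
    obsLocations     = "obsType",
    obsEmbedding     = "obsType",
    obsSegmentations = "obsType",
    obsSets          = "obsType",
    image            = character(0)
  )
}

## File type registry ---------------------------------------------------

.registerBuiltinFileTypes <- function() {
  env <- new.env(parent = emptyenv())
  add <- function(name, dataTypes, options = character(0), joint = FALSE) {
    env[[name]] <- list(name = name, dataTypes = dataTypes,
                        optionKeys = options, joint = joint)
  }
  add("obsFeatureMatrix.csv", "obsFeatureMatrix")
  add("obsLocations.csv", "obsLocations")
  add("obsEmbedding.csv", "obsEmbedding", options = "embeddingType")
  add("obsSets.json", "obsSets")
  add("obsFeatureMatrix.zarr", "obsFeatureMatrix", options = "path")
  add("image.ome-zarr", "image")
  add("obsSegmentations.ome-zarr", "obsSegmentations")
  add("anndata.zarr",
      c("obsFeatureMatrix", "obsEmbedding", "obsLocations", "obsSets"),
      options = c("matrixPath", "embeddingPath", "locationsPath",
                  "setsPath", "embeddingType"),
      joint = TRUE)
  env
}

#' List registered file types
#' @return Named list of file type descriptors (name, dataTypes,
#'   optionKeys, joint).
#' @export
fileTypes <- function() {
  env <- .pkgState$fileTypes
  out <- lapply(sort(ls(env), method = "radix"), function(n) env[[n]])
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

.fileType <- function(name) {
  ft <- .pkgState$fileTypes[[name]]
  if (is.null(ft)) stop("unregistered file type: ", name)
  ft
}

.isFileTypeRegistered <- function(name) !is.null(.pkgState$fileTypes[[name]])

## View registry --------------------------------------------------------
## Each view type declares the coordination types relevant to it and its
## data requirements: which data type it consumes and which entity
## components must match for an accessor to serve it. The heatmap consults
## all three components; the feature list only featureType.

.registerBuiltinViewTypes <- function() {
  env <- new.env(parent = emptyenv())
  entity <- .entityComponents
  camera <- function(prefix) switch(prefix,
    spatial = c("spatialZoom", "spatialTargetX", "spatialTargetY",
                "spatialTargetZ", "spatialRotationX", "spatialRotationY",
                "spatialRotationZ"),
    embedding = c("embeddingType", "embeddingZoom", "embeddingTargetX",
                  "embeddingTargetY", "embeddingPointRadius",
                  "embeddingPointOpacity"),
    heatmap = c("heatmapZoomX", "heatmapZoomY", "heatmapTargetX",
                "heatmapTargetY"))
  colorish <- c("featureSelection", "obsColorEncoding", "featureValueColormap",
                "featureValueColormapRange", "obsSetSelection", "obsSetColor",
                "obsHighlight", "featureHighlight")
  req <- function(dataType, components, optional = FALSE) {
    list(dataType = dataType, components = components, optional = optional)
  }
  add <- function(name, coordinationTypes, requirements) {
    env[[name]] <- list(name = name,
                        coordinationTypes = c("dataset", entity,
                                              coordinationTypes),
                        requirements = requirements)
  }
  add("scatterplot", c(camera("embedding"), colorish),
      list(req("obsEmbedding", "obsType"),
           req("obsFeatureMatrix", entity, optional = TRUE),
           req("obsSets", "obsType", optional = TRUE)))
  add("spatial",
      c(camera("spatial"), colorish,
        "imageLayerVisible", "imageLayerOpacity", "imageChannelSelection",
        "imageChannelColor", "imageChannelWindow", "imageChannelVisible",
        "segmentationLayerVisible", "segmentationLayerOpacity",
        "segmentationFilled", "segmentationStrokeWidth",
        "pointLayerVisible", "pointLayerOpacity", "pointRadius",
        "spotLayerVisible", "spotLayerOpacity", "spotRadius"),
      list(req("image", character(0), optional = TRUE),
           req("obsSegmentations", "obsType", optional = TRUE),
           req("obsLocations", "obsType", optional = TRUE),
           req("obsFeatureMatrix", entity, optional = TRUE),
           req("obsSets", "obsType", optional = TRUE)))
  add("heatmap", c(camera("heatmap"), colorish),
      list(req("obsFeatureMatrix", entity)))
  add("obsSetSizes", c("obsSetSelection", "obsSetColor"),
      list(req("obsSets", "obsType")))
  add("featureValueHistogram", c("featureSelection", "featureValueColormap"),
      list(req("obsFeatureMatrix", entity)))
  add("obsSetFeatureValueDistribution",
      c("featureSelection", "obsSetSelection", "obsSetColor"),
      list(req("obsFeatureMatrix", entity),
           req("obsSets", "obsType")))
  ## feature list: uniquely identified by feature type alone
  add("featureList", c("featureSelection", "featureHighlight"),
      list(req("obsFeatureMatrix", "featureType")))
  ## controller views: coordination state only, no data requirement
  add("obsSetManager", c("obsSetSelection", "obsSetColor"),
      list(req("obsSets", "obsType", optional = TRUE)))
  add("layerController",
      c("imageLayerVisible", "imageLayerOpacity", "imageChannelSelection",
        "imageChannelColor", "imageChannelWindow", "imageChannelVisible",
        "segmentationLayerVisible", "segmentationLayerOpacity",
        "spotLayerVisible", "spotLayerOpacity", "spotRadius"),
      list())
  add("description", character(0), list())
  env
}

#' List registered view types
#' @return Character vector of view type names, sorted.
#' @export
viewTypes <- function() sort(ls(.pkgState$viewTypes), method = "radix")

#' Data requirements and relevant coordination types of a view type
#' @param name View type name.
#' @return List with `name`, `coordinationTypes`, `requirements`.
#' @export
viewDataRequirements <- function(name) {
  v <- .pkgState$viewTypes[[name]]
  if (is.null(v)) stop("unregistered view type: ", name)
  v
}

.isViewTypeRegistered <- function(name) !is.null(.pkgState$viewTypes[[name]])

## Entity triples -------------------------------------------------------

.fillEntity <- function(entity) {
  if (is.null(entity)) entity <- list()
  for (comp in .entityComponents) {
    if (is.null(entity[[comp]])) entity[[comp]] <- .entityDefaults[[comp]]
  }
  entity[.entityComponents]
}

.entityLabel <- function(entity) {
  paste0("(", entity$obsType, ", ", entity$featureType, ", ",
         entity$featureValueType, ")")
}

## Manifest and matching ------------------------------------------------

#' Expand a file specification into per-data-type accessors
#'
#' A joint file type exposes several data types from one file; the URL and
#' options are stated once on the file and propagated to each accessor.
#' For `anndata.zarr`, only the components whose path options are present
#' are exposed (the matrix path defaults to `"X"`).
#'
#' @param filespec List with `url`, `fileType`, optional `options`, `entity`.
#' @return List of accessors: each has `dataType`, `url`, `options`,
#'   `entity` (completed with defaults), `fileType`.
#' @export
expandJointFileType <- function(filespec) {
  ft <- .fileType(filespec$fileType)
  opts <- filespec$options
  if (is.null(opts)) opts <- list()
  bad <- setdiff(names(opts), ft$optionKeys)
  if (length(bad)) {
    stop("options not declared by file type ", ft$name, ": ",
         paste(bad, collapse = ", "))
  }
  entity <- .fillEntity(filespec$entity)
  mk <- function(dataType, extraOpts = opts) {
    list(dataType = dataType, url = filespec$url, options = extraOpts,
         entity = entity, fileType = ft$name)
  }
  if (!ft$joint) {
    return(lapply(ft$dataTypes, mk))
  }
  ## anndata-style joint store: expose a data type per configured sub-path
  out <- list()
  matrixPath <- if (is.null(opts$matrixPath)) "X" else opts$matrixPath
  out <- c(out, list(mk("obsFeatureMatrix", list(path = matrixPath))))
  if (!is.null(opts$embeddingPath)) {
    out <- c(out, list(mk("obsEmbedding",
                          list(path = opts$embeddingPath,
                               embeddingType = opts$embeddingType))))
  }
  if (!is.null(opts$locationsPath)) {
    out <- c(out, list(mk("obsLocations", list(path = opts$locationsPath))))
  }
  if (!is.null(opts$setsPath)) {
    out <- c(out, list(mk("obsSets", list(path = opts$setsPath))))
  }
  out
}

#' Build the accessor manifest of a dataset
#'
#' Expands every file of the dataset into accessors, in deterministic
#' order: file order, then data-type name. Duplicate accessors for the
#' same (dataType, entity triple) are both listed and flagged ambiguous.
#'
#' @param dataset Dataset specification (list with `uid`, `files`).
#' @return data.frame with columns fileIndex, fileType, dataType, obsType,
#'   featureType, featureValueType, url, ambiguous; accessor descriptors
#'   in the `accessor` list-column.
#' @export
datasetManifest <- function(dataset) {
  files <- dataset$files
  if (is.null(files)) files <- list()
  rows <- list()
  for (i in seq_along(files)) {
    acc <- tryCatch(expandJointFileType(files[[i]]), error = function(e) {
      stop("file ", i, " of dataset '", dataset$uid, "': ",
           conditionMessage(e), call. = FALSE)
    })
    ord <- order(vapply(acc, `[[`, character(1), "dataType"), method = "radix")
    for (a in acc[ord]) {
      rows[[length(rows) + 1L]] <- list(
        fileIndex = i, fileType = a$fileType, dataType = a$dataType,
        obsType = a$entity$obsType, featureType = a$entity$featureType,
        featureValueType = a$entity$featureValueType, url = a$url,
        accessor = a)
    }
  }
  df <- data.frame(
    fileIndex = vapply(rows, `[[`, integer(1), "fileIndex"),
    fileType = vapply(rows, `[[`, character(1), "fileType"),
    dataType = vapply(rows, `[[`, character(1), "dataType"),
    obsType = vapply(rows, `[[`, character(1), "obsType"),
    featureType = vapply(rows, `[[`, character(1), "featureType"),
    featureValueType = vapply(rows, `[[`, character(1), "featureValueType"),
    url = vapply(rows, `[[`, character(1), "url"),
    stringsAsFactors = FALSE)
  df$accessor <- lapply(rows, `[[`, "accessor")
  key <- paste(df$dataType, df$obsType, df$featureType, df$featureValueType)
  df$ambiguous <- key %in% key[duplicated(key)]
  df
}

#' Match a view to the accessors of its dataset
#'
#' An accessor matches a requirement iff, for every entity component the
#' requirement declares relevant, the accessor's component equals the
#' view's resolved component; irrelevant components are ignored. When
#' several accessors match one requirement the first in manifest order
#' wins and a warning is recorded in the result.
#'
#' @param viewType Registered view type name.
#' @param manifest Output of [datasetManifest].
#' @param entity View's resolved entity triple (list; missing components
#'   take registry defaults).
#' @return List with `matches` (named list: data type -> accessor),
#'   `warnings` (character), and `missing` (character vector of required
#'   data types with no match). A required data type with zero matches
#'   raises a condition of class `noMatchingData` naming the triple unless
#'   `strict = FALSE`.
#' @param strict If TRUE (default), error on a missing required data type.
#' @export
matchViewToData <- function(viewType, manifest, entity = list(), strict = TRUE) {
  vt <- viewDataRequirements(viewType)
  entity <- .fillEntity(entity)
  matches <- list(); warnings <- character(0); missing <- character(0)
  for (req in vt$requirements) {
    cand <- manifest[manifest$dataType == req$dataType, , drop = FALSE]
    if (nrow(cand) > 0 && length(req$components) > 0) {
      keep <- rep(TRUE, nrow(cand))
      for (comp in req$components) {
        keep <- keep & (cand[[comp]] == entity[[comp]])
      }
      cand <- cand[keep, , drop = FALSE]
    }
    if (nrow(cand) == 0) {
      if (!req$optional) {
        msg <- paste0("no matching data for view '", viewType,
                      "': data type ", req$dataType, " with entity ",
                      .entityLabel(entity))
        if (strict) {
          stop(structure(class = c("noMatchingData", "error", "condition"),
                         list(message = msg, call = NULL)))
        }
        missing <- c(missing, req$dataType)
      }
      next
    }
    if (nrow(cand) > 1) {
      warnings <- c(warnings, paste0("ambiguous match for ", req$dataType,
                                     " in view '", viewType,
                                     "': first of ", nrow(cand), " wins"))
    }
    matches[[req$dataType]] <- cand$accessor[[1]]
  }
  list(matches = matches, warnings = warnings, missing = missing)
}
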