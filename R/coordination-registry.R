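## Registry of coordination types: the named, typed properties views can be
## linked on. Each has a value kind and a default used when a view is not
## linked on that property.

.pkgState <- new.env(parent = emptyenv())

.valueKinds <- c("number", "string", "stringList", "mapping", "boolean")

.conformsToKind <- function(value, kind, nullable = TRUE) {
  if (is.null(value)) return(isTRUE(nullable))
  switch(kind,
    number = is.numeric(value) && length(value) == 1 && is.finite(value),
    string = is.character(value) && length(value) == 1 && !is.na(value),
    stringList = (is.list(value) &&
                    all(vapply(value, function(v)
                      is.character(v) && length(v) == 1, logical(1)))) ||
                 (is.character(value) && !anyNA(value)),
    mapping = is.list(value) && (length(value) == 0 ||
                (!is.null(names(value)) && all(nzchar(names(value))))),
    boolean = is.logical(value) && length(value) == 1 && !is.na(value),
    FALSE)
}

#' Register a coordination type
#'
#' @param name Identifier, unique within the registry.
#' @param valueKind One of `"number"`, `"string"`, `"stringList"`,
#'   `"mapping"`, `"boolean"`.
#' @param defaultValue Default used when a view is not linked on this type;
#'   must conform to `valueKind` (or be NULL if `nullable`).
#' @param nullable Whether NULL is an admissible value.
#' @return The registry entry, invisibly.
#' @export
registerCoordinationType <- function(name, valueKind, defaultValue = NULL,
                                     nullable = TRUE) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  valueKind <- match.arg(valueKind, .valueKinds)
  reg <- .pkgState$coordination
  if (!is.null(reg[[name]])) {
    stop("coordination type already registered: ", name)
  }
  if (!.conformsToKind(defaultValue, valueKind, nullable)) {
    stop("defaultValue does not conform to valueKind '", valueKind, "'")
  }
  entry <- list(name = name, valueKind = valueKind,
                defaultValue = defaultValue, nullable = nullable)
  reg[[name]] <- entry
  invisible(entry)
}

#' List registered coordination type names
#' @return Character vector, sorted.
#' @export
coordinationTypes <- function() {
  sort(ls(.pkgState$coordination), method = "radix")
}

#' Look up a coordination type registry entry
#' @param name Type name.
#' @return The entry (name, valueKind, defaultValue, nullable).
#' @export
coordinationType <- function(name) {
  e <- .pkgState$coordination[[name]]
  if (is.null(e)) stop("unknown coordination type: ", name)
  e
}

#' Default value of a coordination type
#' @param name Type name.
#' @export
coordinationTypeDefault <- function(name) coordinationType(name)$defaultValue

.registerBuiltinCoordinationTypes <- function() {
  reg <- function(name, kind, default = NULL, nullable = TRUE) {
    registerCoordinationType(name, kind, default, nullable)
  }
  ## entity identifiers
  reg("dataset", "string")
  reg("obsType", "string", "cell")
  reg("featureType", "string", "gene")
  reg("featureValueType", "string", "expression")
  ## spatial camera
  reg("spatialZoom", "number", 0)
  reg("spatialTargetX", "number", 0)
  reg("spatialTargetY", "number", 0)
  reg("spatialTargetZ", "number", 0)
  reg("spatialRotationX", "number", 0)
  reg("spatialRotationY", "number", 0)
  reg("spatialRotationZ", "number", 0)
  ## embedding camera
  reg("embeddingType", "string")
  reg("embeddingZoom", "number", 0)
  reg("embeddingTargetX", "number", 0)
  reg("embeddingTargetY", "number", 0)
  reg("embeddingPointRadius", "number", 1)
  reg("embeddingPointOpacity", "number", 1)
  ## heatmap camera
  reg("heatmapZoomX", "number", 0)
  reg("heatmapZoomY", "number", 0)
  reg("heatmapTargetX", "number", 0)
  reg("heatmapTargetY", "number", 0)
  ## selections / highlights / filters
  reg("featureSelection", "stringList")
  reg("featureHighlight", "string")
  reg("obsHighlight", "string")
  reg("obsSetSelection", "stringList")
  reg("obsSetHighlight", "string")
  reg("obsFilter", "stringList")
  ## color encodings
  reg("obsColorEncoding", "string", "setMembership")
  reg("featureValueColormap", "string", "viridis")
  reg("featureValueColormapRange", "mapping", list(min = 0, max = 1))
  reg("obsSetColor", "mapping")
  ## image layer
  reg("imageLayerVisible", "boolean", TRUE)
  reg("imageLayerOpacity", "number", 1)
  reg("imageChannelSelection", "stringList")
  reg("imageChannelColor", "mapping")
  reg("imageChannelWindow", "mapping")
  reg("imageChannelVisible", "boolean", TRUE)
  ## segmentation layer
  reg("segmentationLayerVisible", "boolean", TRUE)
  reg("segmentationLayerOpacity", "number", 1)
  reg("segmentationFilled", "boolean", TRUE)
  reg("segmentationStrokeWidth", "number", 1)
  ## point layer
  reg("pointLayerVisible", "boolean", TRUE)
  reg("pointLayerOpacity", "number", 1)
  reg("pointRadius", "number", 1)
  ## spot layer
  reg("spotLayerVisible", "boolean", TRUE)
  reg("spotLayerOpacity", "number", 1)
  reg("spotRadius", "number", 4)
  ## genomic camera placeholders
  reg("genomicZoomX", "number", 0)
  reg("genomicZoomY", "number", 0)
  reg("genomicTargetX", "number", 0)
  reg("genomicTargetY", "number", 0)
  ## misc view preferences
  reg("tooltipsVisible", "boolean", TRUE)
  reg("legendVisible", "boolean", TRUE)
  invisible(NULL)
}

#' Reset the coordination registry to the built-in set
#'
#' Discards any types added with [registerCoordinationType].
#' @export
resetCoordinationRegistry <- function() {
  .pkgState$coordination <- new.env(parent = emptyenv())
  .registerBuiltinCoordinationTypes()
  invisible(NULL)
}
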