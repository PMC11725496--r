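## The declarative view-configuration document: datasets and their files,
## the coordination space, and a grid layout of views. A ViewConfig is the
## complete, serializable state of a coordinated-multiple-views figure.

.supportedConfigVersions <- "spec-1.0"

#' ViewConfig: a declarative multi-view configuration
#'
#' S4 container for a view-configuration document: schema `version`, free
#' text `name`/`description`, an ordered list of datasets (each with a
#' `uid`, `name` and a list of file specifications), the coordination
#' space (coordination type -> scope name -> value), and the layout (an
#' ordered list of views placed on an abstract nonnegative integer grid).
#'
#' @slot version Schema version string.
#' @slot name,description Free text.
#' @slot datasets List of dataset specifications.
#' @slot coordinationSpace Named list: type -> named list of scope values.
#' @slot layout List of layout items.
#' @export
setClass("ViewConfig", representation(
  version = "character", name = "character", description = "character",
  datasets = "list", coordinationSpace = "list", layout = "list"))

setValidity("ViewConfig", function(object) {
  rep <- validateConfig(object)
  errs <- rep[rep$severity == "error", , drop = FALSE]
  if (nrow(errs) == 0) TRUE else paste(errs$path, errs$message, sep = ": ")
})

#' Create an empty ViewConfig
#' @param name,description Free text.
#' @param version Schema version (only `"spec-1.0"` is supported).
#' @return A `ViewConfig` with no datasets and an empty layout.
#' @export
ViewConfig <- function(name = "", description = "", version = "spec-1.0") {
  new("ViewConfig", version = version, name = name, description = description,
      datasets = list(), coordinationSpace = structure(list(), names = character(0)),
      layout = list())
}

setMethod("show", "ViewConfig", function(object) {
  cat("ViewConfig '", object@name, "' (version ", object@version, ")\n",
      sep = "")
  cat("  datasets: ", length(object@datasets), "  views: ",
      length(object@layout), "  coordination types in space: ",
      length(object@coordinationSpace), "\n", sep = "")
})

#' @describeIn ViewConfig List of dataset specifications.
#' @param config A `ViewConfig`.
#' @export
configDatasets <- function(config) config@datasets

#' @describeIn ViewConfig List of layout items.
#' @export
configLayout <- function(config) config@layout

#' @describeIn ViewConfig The coordination space (type -> scope -> value).
#' @export
coordinationSpace <- function(config) config@coordinationSpace

#' @describeIn ViewConfig Layout item uids, in layout order.
#' @export
viewIds <- function(config) {
  vapply(config@layout, function(v) v$uid, character(1))
}

## Document conversion --------------------------------------------------

.emptyObject <- function() structure(list(), names = character(0))

.asNamedList <- function(x) {
  if (is.null(x) || length(x) == 0) return(.emptyObject())
  x
}

#' Convert a ViewConfig to its plain JSON-like document
#' @param config A `ViewConfig`.
#' @return Named list mirroring the JSON schema.
#' @export
asConfigDocument <- function(config) {
  list(
    version = config@version,
    name = config@name,
    description = config@description,
    datasets = lapply(config@datasets, function(d) {
      list(uid = d$uid, name = if (is.null(d$name)) "" else d$name,
           files = lapply(d$files, function(f) {
             out <- list(url = f$url, fileType = f$fileType)
             if (!is.null(f$options) && length(f$options)) out$options <- f$options
             if (!is.null(f$entity) && length(f$entity)) out$entity <- f$entity
             out
           }))
    }),
    coordinationSpace = .asNamedList(lapply(config@coordinationSpace, .asNamedList)),
    layout = lapply(config@layout, function(v) {
      list(uid = v$uid, component = v$component, dataset = v$dataset,
           x = v$x, y = v$y, w = v$w, h = v$h,
           coordinationScopes = .asNamedList(v$coordinationScopes))
    })
  )
}

#' Build a ViewConfig from a parsed document
#'
#' Validates first; any schema violation of severity "error" aborts with
#' the report attached to the condition (`report` field).
#' @param doc Parsed JSON-like mapping.
#' @return A `ViewConfig`.
#' @export
configFromDocument <- function(doc) {
  rep <- validateConfig(doc)
  errs <- rep[rep$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0) {
    stop(structure(class = c("configValidationError", "error", "condition"),
                   list(message = paste0("invalid configuration (",
                                         nrow(errs), " violation(s)); first: ",
                                         errs$path[1], " ", errs$message[1]),
                        call = NULL, report = rep)))
  }
  space <- doc$coordinationSpace
  if (is.null(space) || length(space) == 0) space <- .emptyObject()
  space <- lapply(space, function(s) if (length(s) == 0) .emptyObject() else s)
  vc <- new("ViewConfig",
    version = doc$version,
    name = if (is.null(doc$name)) "" else doc$name,
    description = if (is.null(doc$description)) "" else doc$description,
    datasets = lapply(doc$datasets, function(d) {
      list(uid = d$uid, name = if (is.null(d$name)) "" else d$name,
           files = lapply(if (is.null(d$files)) list() else d$files, function(f) {
             list(url = f$url, fileType = f$fileType,
                  options = f$options, entity = f$entity)
           }))
    }),
    coordinationSpace = space,
    layout = lapply(seq_along(doc$layout), function(i) {
      v <- doc$layout[[i]]
      list(uid = if (is.null(v$uid)) paste0("view-", i) else v$uid,
           component = v$component, dataset = v$dataset,
           x = as.numeric(v$x), y = as.numeric(v$y),
           w = as.numeric(v$w), h = as.numeric(v$h),
           coordinationScopes =
             if (is.null(v$coordinationScopes) || length(v$coordinationScopes) == 0)
               .emptyObject() else v$coordinationScopes)
    }))
  vc
}

## Validation -----------------------------------------------------------

.violation <- function(path, message, severity = "error") {
  data.frame(path = path, message = message, severity = severity,
             stringsAsFactors = FALSE)
}

.isString <- function(x) is.character(x) && length(x) == 1 && !is.na(x)
.isCount <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x >= 0 && x == floor(x)

#' Validate a view-configuration document
#'
#' Checks the full schema and all referential invariants: supported
#' version, dataset uid uniqueness, registered file types and their
#' declared option keys, registered view components, layout references to
#' existing datasets, grid geometry, coordination types registered and
#' their stored values conforming to the type's value kind, and layout
#' coordination scopes existing in the coordination space. Overlapping
#' views are reported with severity "warning"; a document is valid iff it
#' has no "error" rows.
#'
#' @param document A `ViewConfig`, or a JSON-like mapping (parsed JSON).
#' @return data.frame with columns `path` (JSON-pointer style), `message`,
#'   `severity`. Zero "error" rows means valid.
#' @export
validateConfig <- function(document) {
  if (methods::is(document, "ViewConfig")) document <- asConfigDocument(document)
  reps <- list()
  add <- function(...) reps[[length(reps) + 1L]] <<- .violation(...)
  if (!is.list(document) || is.null(names(document))) {
    return(.violation("/", "document must be a JSON object"))
  }
  if (is.null(document$version)) {
    add("/version", "missing required key 'version'")
  } else if (!.isString(document$version) ||
             !(document$version %in% .supportedConfigVersions)) {
    add("/version", paste0("unsupported schema version; supported: ",
                           paste(.supportedConfigVersions, collapse = ", ")))
  }
  ## datasets
  uids <- character(0)
  if (is.null(document$datasets)) {
    add("/datasets", "missing required key 'datasets'")
  } else if (!is.list(document$datasets)) {
    add("/datasets", "must be an array")
  } else {
    for (i in seq_along(document$datasets)) {
      d <- document$datasets[[i]]
      p <- paste0("/datasets/", i - 1)
      if (!is.list(d)) { add(p, "dataset must be an object"); next }
      if (!.isString(d$uid) || !nzchar(d$uid)) {
        add(paste0(p, "/uid"), "uid must be a nonempty string")
      } else if (d$uid %in% uids) {
        add(paste0(p, "/uid"), paste0("duplicate dataset uid '", d$uid, "'"))
      } else uids <- c(uids, d$uid)
      files <- d$files
      if (is.null(files)) files <- list()
      if (!is.list(files)) { add(paste0(p, "/files"), "must be an array"); next }
      for (j in seq_along(files)) {
        f <- files[[j]]
        fp <- paste0(p, "/files/", j - 1)
        if (!is.list(f)) { add(fp, "file must be an object"); next }
        if (!.isString(f$url)) add(paste0(fp, "/url"), "url must be a string")
        if (!.isString(f$fileType)) {
          add(paste0(fp, "/fileType"), "fileType must be a string")
        } else if (!.isFileTypeRegistered(f$fileType)) {
          add(paste0(fp, "/fileType"),
              paste0("unregistered file type '", f$fileType, "'"))
        } else {
          ft <- .fileType(f$fileType)
          if (!is.null(f$options)) {
            bad <- setdiff(names(f$options), ft$optionKeys)
            if (length(bad)) {
              add(paste0(fp, "/options"),
                  paste0("option keys not declared by file type '", f$fileType,
                         "': ", paste(bad, collapse = ", ")))
            }
          }
        }
        if (!is.null(f$entity)) {
          bad <- setdiff(names(f$entity), .entityComponents)
          if (length(bad)) {
            add(paste0(fp, "/entity"),
                paste0("unknown entity components: ", paste(bad, collapse = ", ")))
          }
          for (comp in intersect(names(f$entity), .entityComponents)) {
            if (!.isString(f$entity[[comp]]) || !nzchar(f$entity[[comp]])) {
              add(paste0(fp, "/entity/", comp), "must be a nonempty identifier")
            }
          }
        }
      }
    }
  }
  ## coordination space
  space <- document$coordinationSpace
  if (!is.null(space)) {
    if (!is.list(space) || (length(space) > 0 && is.null(names(space)))) {
      add("/coordinationSpace", "must be an object")
      space <- NULL
    } else {
      for (ctype in names(space)) {
        cp <- paste0("/coordinationSpace/", ctype)
        entry <- tryCatch(coordinationType(ctype), error = function(e) NULL)
        if (is.null(entry)) {
          add(cp, paste0("unregistered coordination type '", ctype, "'"))
          next
        }
        scopes <- space[[ctype]]
        if (!is.list(scopes) || (length(scopes) > 0 && is.null(names(scopes)))) {
          add(cp, "scopes must be an object")
          next
        }
        for (s in names(scopes)) {
          if (!.conformsToKind(scopes[[s]], entry$valueKind, entry$nullable)) {
            add(paste0(cp, "/", s),
                paste0("value does not conform to kind '", entry$valueKind, "'"))
          }
        }
      }
    }
  }
  ## layout
  if (is.null(document$layout)) {
    add("/layout", "missing required key 'layout'")
  } else if (!is.list(document$layout)) {
    add("/layout", "must be an array")
  } else {
    rects <- list()
    for (i in seq_along(document$layout)) {
      v <- document$layout[[i]]
      p <- paste0("/layout/", i - 1)
      if (!is.list(v)) { add(p, "layout item must be an object"); next }
      if (!.isString(v$component)) {
        add(paste0(p, "/component"), "component must be a string")
      } else if (!.isViewTypeRegistered(v$component)) {
        add(paste0(p, "/component"),
            paste0("unregistered view type '", v$component, "'"))
      }
      if (!.isString(v$dataset)) {
        add(paste0(p, "/dataset"), "dataset must be a string")
      } else if (!(v$dataset %in% uids)) {
        add(paste0(p, "/dataset"),
            paste0("references unknown dataset uid '", v$dataset, "'"))
      }
      for (k in c("x", "y", "w", "h")) {
        if (!.isCount(v[[k]])) {
          add(paste0(p, "/", k), "must be a nonnegative integer")
        }
      }
      if (.isCount(v$w) && v$w == 0) add(paste0(p, "/w"), "w must be > 0")
      if (.isCount(v$h) && v$h == 0) add(paste0(p, "/h"), "h must be > 0")
      if (all(vapply(c("x", "y", "w", "h"), function(k) .isCount(v[[k]]),
                     logical(1))) && v$w > 0 && v$h > 0) {
        for (r in rects) {
          if (v$x < r$x + r$w && r$x < v$x + v$w &&
              v$y < r$y + r$h && r$y < v$y + v$h) {
            add(p, paste0("overlaps layout item ", r$i - 1), severity = "warning")
            break
          }
        }
        rects[[length(rects) + 1L]] <- list(i = i, x = v$x, y = v$y,
                                            w = v$w, h = v$h)
      }
      scopes <- v$coordinationScopes
      if (!is.null(scopes) && length(scopes) > 0) {
        if (!is.list(scopes) || is.null(names(scopes))) {
          add(paste0(p, "/coordinationScopes"), "must be an object")
        } else {
          for (ctype in names(scopes)) {
            sp <- paste0(p, "/coordinationScopes/", ctype)
            entry <- tryCatch(coordinationType(ctype), error = function(e) NULL)
            if (is.null(entry)) {
              add(sp, paste0("unregistered coordination type '", ctype, "'"))
              next
            }
            sname <- scopes[[ctype]]
            if (!.isString(sname)) { add(sp, "scope name must be a string"); next }
            have <- !is.null(space) && ctype %in% names(space) &&
              sname %in% names(space[[ctype]])
            if (!have) {
              add(sp, paste0("references scope '", sname,
                             "' absent from coordinationSpace"))
            }
          }
        }
      }
    }
  }
  if (length(reps) == 0) {
    return(data.frame(path = character(0), message = character(0),
                      severity = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, reps)
}

## Serialization --------------------------------------------------------

#' Serialize a ViewConfig to canonical JSON
#'
#' Canonical form (sorted keys, no whitespace) is deterministic:
#' structurally equal configs serialize to byte-identical text, and
#' `deserializeConfig(serializeConfig(c))` is structurally equal to `c`.
#' An invalid config is refused with its validation report attached.
#'
#' @param config A `ViewConfig`.
#' @return JSON text (single string).
#' @export
serializeConfig <- function(config) {
  doc <- asConfigDocument(config)
  rep <- validateConfig(doc)
  errs <- rep[rep$severity == "error", , drop = FALSE]
  if (nrow(errs) > 0) {
    stop(structure(class = c("configValidationError", "error", "condition"),
                   list(message = paste0("refusing to serialize invalid config; ",
                                         "first violation: ", errs$path[1], " ",
                                         errs$message[1]),
                        call = NULL, report = rep)))
  }
  canonicalJSON(doc)
}

#' Deserialize a ViewConfig from JSON text
#' @param text JSON text.
#' @return A `ViewConfig`.
#' @export
deserializeConfig <- function(text) {
  configFromDocument(parseJSON(text))
}

#' Read / write a ViewConfig JSON file
#' @param path File path.
#' @rdname configIO
#' @export
readConfig <- function(path) {
  deserializeConfig(paste(readLines(path, warn = FALSE), collapse = "\n"))
}

#' @param config A `ViewConfig`.
#' @rdname configIO
#' @export
writeConfig <- function(config, path) {
  writeLines(serializeConfig(config), path, useBytes = TRUE)
  invisible(path)
}

## Share URLs -----------------------------------------------------------
## The config travels in the URL fragment: canonical JSON, DEFLATE
## compressed, base64url encoded. Self-contained and server-free. The
## compressed bytes are framed with their length and an Adler-32
## checksum so that a truncated or tampered payload is detected before
## any decompression is attempted.

.adler32 <- function(bytes) {
  MOD <- 65521
  a <- 1; b <- 0
  x <- as.integer(bytes)
  # process in blocks to keep the running sums exact in doubles
  for (i in seq(1, length(x), by = 3000)) {
    blk <- x[i:min(i + 2999, length(x))]
    n <- length(blk)
    b <- (b + n * a + sum(cumsum(blk))) %% MOD
    a <- (a + sum(blk)) %% MOD
  }
  as.integer(c((b %/% 256) %% 256, b %% 256, (a %/% 256) %% 256, a %% 256))
}

.uint32Bytes <- function(n) {
  as.integer(c(n %/% 256^3, n %/% 256^2, n %/% 256, n) %% 256)
}

#' Encode a ViewConfig into a shareable URL
#' @param config A valid `ViewConfig`.
#' @param base Base URL; must not already carry a fragment.
#' @return URL string with the config embedded in the fragment.
#' @export
toShareURL <- function(config, base) {
  if (grepl("#", base, fixed = TRUE)) {
    stop("base URL must not contain a fragment")
  }
  z <- memCompress(charToRaw(serializeConfig(config)), type = "gzip")
  framed <- as.raw(c(.uint32Bytes(length(z)), .adler32(z), as.integer(z)))
  paste0(base, "#conf=", jsonlite::base64url_enc(framed))
}

#' Decode a ViewConfig from a share URL
#' @param url URL produced by [toShareURL].
#' @return A `ViewConfig`.
#' @export
fromShareURL <- function(url) {
  m <- regmatches(url, regexpr("#conf=.*$", url))
  if (length(m) == 0) {
    stop(structure(class = c("noEmbeddedConfig", "error", "condition"),
                   list(message = "URL carries no embedded config", call = NULL)))
  }
  payload <- substring(m, nchar("#conf=") + 1L)
  decodeError <- function(why) {
    stop(structure(class = c("shareURLDecodeError", "error", "condition"),
                   list(message = paste0("cannot decode share-URL payload: ",
                                         why), call = NULL)))
  }
  framed <- tryCatch(jsonlite::base64url_dec(payload),
                     error = function(e) decodeError(conditionMessage(e)))
  if (length(framed) < 9) decodeError("payload too short")
  len <- sum(as.integer(framed[1:4]) * 256^(3:0))
  z <- framed[-(1:8)]
  if (length(z) != len) decodeError("length mismatch (truncated payload)")
  if (!identical(as.integer(framed[5:8]), .adler32(z))) {
    decodeError("checksum mismatch (corrupted payload)")
  }
  text <- tryCatch(rawToChar(memDecompress(z, type = "gzip")),
                   error = function(e) decodeError(conditionMessage(e)))
  deserializeConfig(text)
}

## Builder --------------------------------------------------------------

.datasetIndex <- function(config, uid) {
  for (i in seq_along(config@datasets)) {
    if (config@datasets[[i]]$uid == uid) return(i)
  }
  stop("unknown dataset uid '", uid, "'")
}

#' Add a dataset to a config
#' @param config A `ViewConfig`.
#' @param uid Dataset identifier, unique within the config.
#' @param name Free text.
#' @return Updated `ViewConfig`.
#' @export
addDataset <- function(config, uid, name = "") {
  stopifnot(.isString(uid), nzchar(uid))
  if (uid %in% vapply(config@datasets, `[[`, character(1), "uid")) {
    stop("dataset uid already present: '", uid, "'")
  }
  config@datasets <- c(config@datasets,
                       list(list(uid = uid, name = name, files = list())))
  config
}

#' Add a file to a dataset
#' @param config A `ViewConfig`.
#' @param dataset Existing dataset uid.
#' @param fileType Registered file type name.
#' @param url File locator (path or URL).
#' @param options File-type-specific options (named list).
#' @param entity Partial entity triple (named list with any of obsType,
#'   featureType, featureValueType).
#' @return Updated `ViewConfig`.
#' @export
addFile <- function(config, dataset, fileType, url, options = NULL,
                    entity = NULL) {
  i <- .datasetIndex(config, dataset)
  if (!.isFileTypeRegistered(fileType)) {
    stop("unregistered file type: ", fileType)
  }
  config@datasets[[i]]$files <- c(config@datasets[[i]]$files,
    list(list(url = url, fileType = fileType, options = options,
              entity = entity)))
  config
}

#' Add a view to the layout
#' @param config A `ViewConfig`.
#' @param component Registered view type name.
#' @param dataset Existing dataset uid.
#' @param x,y,w,h Grid placement (nonnegative integers; w, h > 0).
#' @param uid Optional view id; auto-assigned `view-<n>` otherwise.
#' @return Updated `ViewConfig`.
#' @export
addView <- function(config, component, dataset, x = 0, y = 0, w = 1, h = 1,
                    uid = NULL) {
  .datasetIndex(config, dataset)  # errors on unknown uid
  if (!.isViewTypeRegistered(component)) {
    stop("unregistered view type: ", component)
  }
  existing <- viewIds(config)
  if (is.null(uid)) {
    n <- length(existing) + 1L
    while (paste0("view-", n) %in% existing) n <- n + 1L
    uid <- paste0("view-", n)
  } else if (uid %in% existing) {
    stop("view uid already present: '", uid, "'")
  }
  config@layout <- c(config@layout,
    list(list(uid = uid, component = component, dataset = dataset,
              x = x, y = y, w = w, h = h,
              coordinationScopes = .emptyObject())))
  config
}
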