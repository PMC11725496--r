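## Coordinated multiple views: views are never linked to each other
## directly, but to named values (scopes) of typed properties
## (coordination types). Two views are coordinated on a property exactly
## when they reference the same scope of that property. Propagation is
## pure state resolution: there is no event loop.

## Excel-style scope names in creation order: A, B, ..., Z, AA, AB, ...
.scopeNameFor <- function(k) {
  name <- ""
  k <- k - 1L
  repeat {
    name <- paste0(LETTERS[k %% 26L + 1L], name)
    k <- k %/% 26L - 1L
    if (k < 0L) break
  }
  name
}

.nextScopeName <- function(existing) {
  k <- 1L
  repeat {
    nm <- .scopeNameFor(k)
    if (!(nm %in% existing)) return(nm)
    k <- k + 1L
  }
}

#' Link views on a coordination type through a fresh scope
#'
#' Creates a new scope of `ctype` holding `initial` and points every view
#' in `ids` at it. The new scope's name (auto-assigned `"A"`, `"B"`, ...
#' per type, in creation order) is attached to the returned config as
#' attribute `"scopeName"`.
#'
#' @param config A `ViewConfig`.
#' @param ids Character vector of view uids (see [viewIds]).
#' @param ctype Registered coordination type name.
#' @param initial Initial scope value; must conform to the type's kind.
#' @return Updated `ViewConfig` with attribute `"scopeName"`.
#' @export
linkViews <- function(config, ids, ctype, initial = NULL) {
  entry <- coordinationType(ctype)  # errors on unknown type
  if (missing(initial)) initial <- entry$defaultValue
  if (!.conformsToKind(initial, entry$valueKind, entry$nullable)) {
    stop("initial value does not conform to kind '", entry$valueKind,
         "' of coordination type '", ctype, "'")
  }
  all <- viewIds(config)
  unknown <- setdiff(ids, all)
  if (length(unknown)) {
    stop("unknown view id(s): ", paste(unknown, collapse = ", "))
  }
  space <- config@coordinationSpace
  scopes <- if (ctype %in% names(space)) space[[ctype]] else .emptyObject()
  scopeName <- .nextScopeName(names(scopes))
  scopes[[scopeName]] <- initial
  space[[ctype]] <- scopes
  config@coordinationSpace <- space
  for (i in seq_along(config@layout)) {
    if (config@layout[[i]]$uid %in% ids) {
      cs <- config@layout[[i]]$coordinationScopes
      cs[[ctype]] <- scopeName
      config@layout[[i]]$coordinationScopes <- cs
    }
  }
  attr(config, "scopeName") <- scopeName
  config
}

#' Set the value of an existing coordination scope
#'
#' All views linked to `(ctype, scope)` will resolve to `value`; views
#' linked to other scopes of the same type are unaffected.
#'
#' @param config A `ViewConfig`.
#' @param ctype Coordination type name.
#' @param scope Existing scope name of that type.
#' @param value New value; must conform to the type's value kind.
#' @return Updated `ViewConfig`.
#' @export
setCoordinationValue <- function(config, ctype, scope, value) {
  entry <- coordinationType(ctype)
  space <- config@coordinationSpace
  if (!(ctype %in% names(space)) || !(scope %in% names(space[[ctype]]))) {
    stop("unknown coordination scope '", scope, "' of type '", ctype, "'")
  }
  if (!.conformsToKind(value, entry$valueKind, entry$nullable)) {
    stop("value does not conform to kind '", entry$valueKind, "'")
  }
  space[[ctype]][scope] <- list(value)  # keeps NULL values
  config@coordinationSpace <- space
  config
}

.layoutItem <- function(config, viewId) {
  for (v in config@layout) if (v$uid == viewId) return(v)
  stop("unknown view id '", viewId, "'")
}

#' Resolve the full coordination state of one view
#'
#' For every coordination type relevant to the view's type: if the view is
#' linked to a scope, the scope's current value; otherwise the registry
#' default. A reference to a scope that no longer exists in the
#' coordination space is an explicit error (condition class
#' `danglingScope`), never a silent fallback to the default. The `dataset`
#' property falls back to the layout item's dataset uid.
#'
#' @param config A `ViewConfig`.
#' @param viewId View uid.
#' @return Named list: coordination type -> resolved value.
#' @export
resolveViewState <- function(config, viewId) {
  item <- .layoutItem(config, viewId)
  vt <- viewDataRequirements(item$component)
  space <- config@coordinationSpace
  resolved <- list()
  ## the types declared relevant by the view type, plus any the view is
  ## explicitly linked on (an explicit link makes a property relevant)
  relevant <- union(vt$coordinationTypes, names(item$coordinationScopes))
  for (ctype in relevant) {
    scopes <- item$coordinationScopes
    if (!is.null(scopes) && ctype %in% names(scopes)) {
      sname <- scopes[[ctype]]
      if (!(ctype %in% names(space)) || !(sname %in% names(space[[ctype]]))) {
        stop(structure(class = c("danglingScope", "error", "condition"),
          list(message = paste0("view '", viewId, "' is linked to scope '",
                                sname, "' of type '", ctype,
                                "', which does not exist"), call = NULL)))
      }
      resolved[ctype] <- list(space[[ctype]][[sname]])
    } else if (ctype == "dataset") {
      resolved[ctype] <- list(item$dataset)
    } else {
      resolved[ctype] <- list(coordinationTypeDefault(ctype))
    }
  }
  resolved
}

#' Snapshot the full coordination state as canonical JSON
#'
#' The snapshot is the canonical serialization of the config itself, so
#' deserializing it and re-resolving every view reproduces identical view
#' states.
#'
#' @param config A valid `ViewConfig`.
#' @return Canonical JSON text.
#' @export
configSnapshot <- function(config) serializeConfig(config)
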