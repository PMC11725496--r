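## Canonical JSON: sorted object keys, UTF-8, no insignificant whitespace.
## Numbers use the shortest decimal representation that round-trips the
## double exactly, so serialize -> parse -> serialize is byte-stable.

.jsonEscape <- function(s) {
  s <- enc2utf8(s)
  s <- gsub("\\", "\\\\", s, fixed = TRUE)
  s <- gsub("\"", "\\\"", s, fixed = TRUE)
  s <- gsub("\n", "\\n", s, fixed = TRUE)
  s <- gsub("\r", "\\r", s, fixed = TRUE)
  s <- gsub("\t", "\\t", s, fixed = TRUE)
  # remaining control characters
  for (code in 1:31) {  # NUL cannot occur in an R string
    ch <- intToUtf8(code)
    if (ch %in% c("\n", "\r", "\t")) next
    if (grepl(ch, s, fixed = TRUE, useBytes = TRUE)) {
      s <- gsub(ch, sprintf("\\\\u%04x", code), s, fixed = TRUE)
    }
  }
  paste0("\"", s, "\"")
}

.jsonNumber <- function(x) {
  if (!is.finite(x)) {
    stop("non-finite numeric value cannot be represented in JSON", call. = FALSE)
  }
  if (x == floor(x) && abs(x) < 2^53) {
    return(sprintf("%.0f", x))
  }
  s <- sprintf("%.15g", x)
  if (as.numeric(s) == x) s else sprintf("%.17g", x)
}

.isJsonObject <- function(x) {
  is.list(x) && !is.null(names(x)) && all(nzchar(names(x)))
}

#' Serialize an R structure to canonical JSON text
#'
#' Canonical form: object keys sorted bytewise, no whitespace, numbers in
#' shortest exact decimal form, strings escaped minimally. Named lists map
#' to objects, unnamed lists and atomic vectors of length != 1 to arrays,
#' length-1 atomics to scalars. `NULL` maps to `null`. An empty named list
#' (`structure(list(), names = character(0))`) maps to `{}`.
#'
#' @param x R structure (lists, atomic vectors, NULL).
#' @return A single character string of JSON text.
#' @export
canonicalJSON <- function(x) {
  if (is.null(x)) return("null")
  if (.isJsonObject(x) || (is.list(x) && length(x) == 0 && !is.null(names(x)))) {
    keys <- sort(names(x), method = "radix")
    parts <- vapply(keys, function(k) {
      paste0(.jsonEscape(k), ":", canonicalJSON(x[[k]]))
    }, character(1))
    return(paste0("{", paste(parts, collapse = ","), "}"))
  }
  if (is.list(x)) {
    parts <- vapply(x, canonicalJSON, character(1))
    return(paste0("[", paste(parts, collapse = ","), "]"))
  }
  if (length(x) != 1) {
    parts <- vapply(seq_along(x), function(i) canonicalJSON(x[[i]]), character(1))
    return(paste0("[", paste(parts, collapse = ","), "]"))
  }
  if (is.character(x)) return(.jsonEscape(x))
  if (is.logical(x)) {
    if (is.na(x)) stop("NA logical cannot be represented in JSON", call. = FALSE)
    return(if (x) "true" else "false")
  }
  if (is.numeric(x)) return(.jsonNumber(as.numeric(x)))
  stop("cannot serialize object of class ", class(x)[1], " to JSON", call. = FALSE)
}

#' Parse JSON text without vector simplification
#'
#' Thin wrapper over [jsonlite::fromJSON] that keeps objects as named lists
#' and arrays as unnamed lists. A syntax error raises a condition of class
#' `jsonParseError`, distinct from any validation failure.
#'
#' @param text JSON text (single string).
#' @return Parsed R structure.
#' @export
parseJSON <- function(text) {
  tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) {
      stop(structure(
        class = c("jsonParseError", "error", "condition"),
        list(message = paste0("JSON parse error: ", conditionMessage(e)),
             call = NULL)
      ))
    }
  )
}

#' Structural equality of two JSON-like structures
#'
#' Compares canonical serializations, so 2L and 2.0 are equal and object
#' key order is irrelevant.
#' @param a,b JSON-like R structures.
#' @return TRUE or FALSE.
#' @export
jsonEqual <- function(a, b) {
  identical(canonicalJSON(a), canonicalJSON(b))
}
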