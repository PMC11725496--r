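## Quantitative colormaps and value -> color mapping (the CPU counterpart
## of a GPU colormap shader): piecewise-linear interpolation through a
## fixed color table, with clamping at the domain ends.

.missingColor <- c(128, 128, 128)   # mid-grey for NaN / unannotated

#' A named colormap as an n x 3 RGB table (0-255)
#' @param name One of `"viridis"`, `"plasma"`, `"inferno"`, `"greys"`.
#' @param n Number of entries (default 256).
#' @return `n x 3` integer matrix.
#' @export
getColormap <- function(name = "viridis", n = 256L) {
  pal <- switch(name,
    viridis = grDevices::hcl.colors(n, "viridis"),
    plasma = grDevices::hcl.colors(n, "plasma"),
    inferno = grDevices::hcl.colors(n, "inferno"),
    greys = grDevices::gray.colors(n, start = 0, end = 1, gamma = 1),
    stop("unknown colormap: ", name))
  unname(t(grDevices::col2rgb(pal)))
}

## categorical palette for set membership coloring
.setPalette <- function(k) {
  base <- t(grDevices::col2rgb(grDevices::hcl.colors(max(k, 3L), "Dark 3")))
  base[seq_len(k), , drop = FALSE]
}

#' Construct a color encoding
#'
#' @param mode `"featureValue"` (continuous colormap over a selected
#'   feature), `"setMembership"` (categorical by set), or `"static"`.
#' @param colormap Colormap name for featureValue mode.
#' @param domain Numeric `c(min, max)` value domain, or NULL to derive
#'   one from `quantiles` of the data.
#' @param quantiles Quantile pair used when `domain` is NULL.
#' @param staticColor RGB triple for static mode.
#' @param table Optional explicit `k x 3` RGB table overriding `colormap`.
#' @return Encoding descriptor (list).
#' @export
colorEncoding <- function(mode = c("featureValue", "setMembership", "static"),
                          colormap = "viridis", domain = NULL,
                          quantiles = c(0, 1), staticColor = c(70, 130, 180),
                          table = NULL) {
  mode <- match.arg(mode)
  if (!is.null(domain)) {
    stopifnot(length(domain) == 2)
    if (!(domain[1] < domain[2])) stop("encoding domain must have min < max")
  }
  list(mode = mode, colormap = colormap, domain = domain,
       quantiles = quantiles, staticColor = staticColor, table = table)
}

#' Map per-observation values to colors
#'
#' Values at or below the domain minimum take the first colormap entry,
#' at or above the maximum the last; in between, piecewise-linear
#' interpolation through the table. NaN maps to the missing-value color.
#' A degenerate domain (all values equal under a quantile domain) maps
#' everything to the first entry.
#'
#' @param values Numeric vector.
#' @param encoding From [colorEncoding] (featureValue mode).
#' @return `length(values) x 3` integer RGB matrix.
#' @export
mapValuesToColors <- function(values, encoding = colorEncoding()) {
  if (encoding$mode == "static") {
    return(matrix(rep(as.integer(encoding$staticColor), each = length(values)),
                  ncol = 3))
  }
  if (encoding$mode == "featureValue" && is.null(values)) {
    stop("featureValue encoding requires a selected feature's values")
  }
  cmap <- if (!is.null(encoding$table)) encoding$table else
    getColormap(encoding$colormap)
  k <- nrow(cmap)
  dom <- encoding$domain
  if (is.null(dom)) {
    ok <- values[is.finite(values)]
    dom <- if (length(ok)) as.numeric(stats::quantile(ok, encoding$quantiles,
                                                      names = FALSE)) else c(0, 1)
  }
  out <- matrix(NA_integer_, length(values), 3)
  nan <- !is.finite(values)
  if (dom[2] <= dom[1]) {
    out[!nan, ] <- matrix(rep(cmap[1, ], each = sum(!nan)), ncol = 3)
  } else {
    t <- pmin(1, pmax(0, (values[!nan] - dom[1]) / (dom[2] - dom[1])))
    pos <- t * (k - 1)
    lo <- pmin(floor(pos), k - 2)
    frac <- pos - lo
    out[!nan, ] <- round((1 - frac) * cmap[lo + 1, , drop = FALSE] +
                         frac * cmap[lo + 2, , drop = FALSE])
  }
  out[nan, ] <- matrix(rep(.missingColor, each = sum(nan)), ncol = 3)
  storage.mode(out) <- "integer"
  out
}

## Rasters ---------------------------------------------------------------
## A raster is an (h, w, 4) numeric array of RGBA values in 0..255,
## straight (non-premultiplied) alpha.

#' Allocate a transparent raster
#' @param widthPx,heightPx Pixel dimensions.
#' @return `(h, w, 4)` zero array.
#' @export
newRaster <- function(widthPx, heightPx) {
  array(0, dim = c(heightPx, widthPx, 4))
}

#' Alpha-composite one raster over another
#' @param bottom,top Rasters of equal size.
#' @return Composited raster.
#' @export
compositeOver <- function(bottom, top) {
  sA <- top[, , 4] / 255; dA <- bottom[, , 4] / 255
  outA <- sA + dA * (1 - sA)
  out <- bottom
  safe <- outA > 0
  for (ch in 1:3) {
    num <- top[, , ch] * sA + bottom[, , ch] * dA * (1 - sA)
    plane <- out[, , ch]
    plane[safe] <- (num / pmax(outA, 1e-12))[safe]
    plane[!safe] <- 0
    out[, , ch] <- plane
  }
  out[, , 4] <- outA * 255
  out
}

#' Flatten a raster onto an opaque background
#' @param raster RGBA raster.
#' @param background RGB triple (default white).
#' @return Opaque RGBA raster.
#' @export
flattenRaster <- function(raster, background = c(255, 255, 255)) {
  a <- raster[, , 4] / 255
  out <- raster
  for (ch in 1:3) {
    out[, , ch] <- raster[, , ch] * a + background[ch] * (1 - a)
  }
  out[, , 4] <- 255
  out
}

#' Write a raster to a PNG file
#' @param raster RGBA raster (0..255).
#' @param path Output file.
#' @export
writeRasterPNG <- function(raster, path) {
  png::writePNG(raster / 255, path)
  invisible(path)
}
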