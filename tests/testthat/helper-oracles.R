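# Brute-force oracles and shared fixtures, independent of the package's
# own code paths wherever they stand as the expected value.

# chunks intersecting a request: enumerate every requested cell
bruteChunksForRequest <- function(chunkShape, cols0, obsRange) {
  if (obsRange[2] <= obsRange[1] || length(cols0) == 0) {
    return(matrix(integer(0), ncol = 2))
  }
  rows <- obsRange[1]:(obsRange[2] - 1L)
  cells <- expand.grid(r = rows, c = cols0)
  unique(cbind(cells$r %/% chunkShape[1], cells$c %/% chunkShape[2]))
}

# bin-loop aggregation with the proportional integer partition
bruteAggregate <- function(m, p, q, fn) {
  p <- min(p, nrow(m)); q <- min(q, ncol(m))
  rs <- floor((0:p) * nrow(m) / p); cs <- floor((0:q) * ncol(m) / q)
  out <- matrix(NA_real_, p, q)
  for (i in seq_len(p)) {
    for (j in seq_len(q)) {
      out[i, j] <- fn(m[(rs[i] + 1):rs[i + 1], (cs[j] + 1):cs[j + 1]])
    }
  }
  out
}

# tile-by-tile intersection test against the viewport rectangle
bruteVisibleTiles <- function(viewport, levelShape, factor, tileSize) {
  s <- 2^viewport$zoom
  x0 <- viewport$targetX - viewport$widthPx / (2 * s)
  x1 <- viewport$targetX + viewport$widthPx / (2 * s)
  y0 <- viewport$targetY - viewport$heightPx / (2 * s)
  y1 <- viewport$targetY + viewport$heightPx / (2 * s)
  span <- tileSize * factor
  gridY <- ceiling(levelShape[1] / tileSize)
  gridX <- ceiling(levelShape[2] / tileSize)
  hits <- list()
  for (ty in 0:(gridY - 1)) {
    for (tx in 0:(gridX - 1)) {
      if (tx * span < x1 && (tx + 1) * span > x0 &&
          ty * span < y1 && (ty + 1) * span > y0) {
        hits[[length(hits) + 1L]] <- c(tileX = tx, tileY = ty)
      }
    }
  }
  if (length(hits) == 0) return(matrix(integer(0), ncol = 2,
                                       dimnames = list(NULL, c("tileX", "tileY"))))
  do.call(rbind, hits)
}

# admissible-level enumeration: smallest factor covering the screen scale
bruteSelectLevel <- function(viewport, factors) {
  need <- 2^(-viewport$zoom)
  adm <- which(factors >= need)
  if (length(adm) == 0) length(factors) - 1L else adm[1] - 1L
}

# a random valid config built through the public builder
randomValidConfig <- function(seed) {
  set.seed(seed)
  vc <- ViewConfig(name = paste0("random-", seed))
  nD <- sample(1:3, 1)
  for (d in seq_len(nD)) {
    uid <- paste0("ds", d)
    vc <- addDataset(vc, uid, name = paste0("dataset ", d))
    for (f in seq_len(sample(0:3, 1))) {
      ft <- sample(c("obsFeatureMatrix.csv", "obsLocations.csv",
                     "obsSets.json", "obsFeatureMatrix.zarr"), 1)
      vc <- addFile(vc, uid, ft, paste0("file", d, "-", f, ".dat"),
                    entity = if (stats::runif(1) < 0.5)
                      list(featureType = sample(c("gene", "protein"), 1))
                    else NULL)
    }
  }
  comps <- c("scatterplot", "heatmap", "spatial", "obsSetSizes", "featureList")
  nV <- sample(1:5, 1)
  for (v in seq_len(nV)) {
    vc <- addView(vc, sample(comps, 1), paste0("ds", sample(nD, 1)),
                  x = (v - 1) * 2, y = 0, w = 2, h = sample(1:3, 1))
  }
  for (l in seq_len(sample(0:3, 1))) {
    ids <- sample(viewIds(vc), sample(nV, 1))
    pick <- sample(c("featureSelection", "spatialZoom", "obsColorEncoding"), 1)
    init <- switch(pick,
      featureSelection = as.list(paste0("g", sample(100, sample(1:3, 1)))),
      spatialZoom = stats::rnorm(1),
      obsColorEncoding = sample(c("featureValue", "setMembership", "static"), 1))
    vc <- linkViews(vc, ids, pick, init)
  }
  vc
}

# the standard small fixture, generated once per test session
sharedFixtureDir <- local({
  dir <- NULL
  function() {
    if (is.null(dir) || !file.exists(file.path(dir, "fixture.json"))) {
      dir <<- file.path(tempdir(), "coordview-fixture")
      unlink(dir, recursive = TRUE)
      generateDataset(FixtureSpec(nCells = 80, nGenes = 40, nProteins = 10,
                                  imageSize = c(96L, 96L), nChannels = 3L,
                                  nClusters = 4L, seed = 7L), dir)
    }
    dir
  }
})

# stable content digest of a directory tree
.dirDigests <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, all.files = TRUE,
                           no.. = TRUE))
  sums <- tools::md5sum(file.path(dir, files))
  names(sums) <- files
  sums
}

# small chunked matrix store written to a temp dir; returns a fresh handle
tempMatrixHandle <- function(m, chunkShape) {
  path <- tempfile("store")
  exportMatrix(m, path, plan = list(chunkShape = as.integer(chunkShape),
                                    compression = "zlib", level = 5L,
                                    targetPattern = "per-feature"))
  openMatrixHandle(path)
}
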