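## Deterministic synthetic multimodal single-cell dataset plus matching
## view configs, so every module is exercisable without downloads. Cells
## fall into Gaussian cluster blobs in physical space and in a 2-D
## embedding; counts follow a Gamma-Poisson (negative-binomial-like)
## model with per-cluster marker genes; the multichannel image and the
## segmentation bitmask are drawn from the same cell geometry.

#' Specification of a synthetic fixture dataset
#'
#' @param nCells,nGenes,nProteins Entity counts (all >= 1).
#' @param imageSize `(Y, X)` pixel dims of image and bitmask.
#' @param nChannels Image channels.
#' @param nClusters Cell clusters.
#' @param seed Integer seed fixing all randomness.
#' @param diskRadius Segmentation disk radius, pixels.
#' @return FixtureSpec (list).
#' @export
FixtureSpec <- function(nCells = 100L, nGenes = 60L, nProteins = 12L,
                        imageSize = c(128L, 128L), nChannels = 3L,
                        nClusters = 4L, seed = 1L, diskRadius = 3L) {
  stopifnot(nCells >= 1, nGenes >= 1, nProteins >= 1, nChannels >= 1,
            nClusters >= 1, all(imageSize >= 1))
  list(nCells = as.integer(nCells), nGenes = as.integer(nGenes),
       nProteins = as.integer(nProteins), imageSize = as.integer(imageSize),
       nChannels = as.integer(nChannels), nClusters = as.integer(nClusters),
       seed = as.integer(seed), diskRadius = as.integer(diskRadius))
}

.markerFold <- 5        # cluster mean shift on marker features
.markersPerCluster <- 3

## Gamma-Poisson counts: E[x] = mu, overdispersed
.rnbCounts <- function(n, mu, theta = 2) {
  stats::rpois(n, mu * stats::rgamma(n, shape = theta, rate = theta))
}

.clusterCenters <- function(k, sizeY, sizeX, margin) {
  g <- ceiling(sqrt(k))
  cy <- sizeY / g; cx <- sizeX / g
  centers <- matrix(NA_real_, k, 2)
  for (i in seq_len(k)) {
    ry <- (i - 1) %/% g; rx <- (i - 1) %% g
    centers[i, ] <- c(
      min(max((rx + 0.5) * cx + stats::runif(1, -0.1, 0.1) * cx, margin),
          sizeX - margin),
      min(max((ry + 0.5) * cy + stats::runif(1, -0.1, 0.1) * cy, margin),
          sizeY - margin))
  }
  centers  # (x, y)
}

#' Generate a synthetic multimodal dataset on disk
#'
#' Writes: gene expression and protein chunked matrix stores
#' (per-feature chunk plan), spatial coordinates and 2-D embedding CSVs,
#' a hierarchical cell-set JSON (one root, one leaf per cluster, with
#' colors), a multichannel image pyramid whose channels track cluster
#' marker expression, and a segmentation bitmask pyramid with disk
#' labels 1..nCells (0 = background, overlapping disks resolved
#' later-label-wins). The same seed yields byte-identical output.
#'
#' @param spec A [FixtureSpec].
#' @param outDir Output directory (created).
#' @return `outDir`, invisibly.
#' @export
generateDataset <- function(spec, outDir) {
  r <- spec$diskRadius
  sizeY <- spec$imageSize[1]; sizeX <- spec$imageSize[2]
  if (spec$nCells * (2 * r + 1)^2 > sizeY * sizeX) {
    stop("cell disks exceed image capacity; increase imageSize ",
         "(need > ", spec$nCells * (2 * r + 1)^2, " px)")
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)
  n <- spec$nCells; k <- spec$nClusters
  cellIds <- sprintf("cell_%d", seq_len(n))
  geneIds <- sprintf("gene_%d", seq_len(spec$nGenes))
  protIds <- sprintf("protein_%d", seq_len(spec$nProteins))
  cluster <- sample(rep(seq_len(k), length.out = n))

  ## spatial coordinates: jittered-grid cluster blobs, clamped inside disks
  centers <- .clusterCenters(k, sizeY, sizeX, margin = r + 1)
  sd <- min(sizeY, sizeX) / (4 * ceiling(sqrt(k)))
  xy <- cbind(
    pmin(pmax(centers[cluster, 1] + stats::rnorm(n, 0, sd), r + 1), sizeX - r - 1),
    pmin(pmax(centers[cluster, 2] + stats::rnorm(n, 0, sd), r + 1), sizeY - r - 1))

  ## embedding: cluster blobs on a circle
  ang <- 2 * pi * (seq_len(k) - 1) / k
  emb <- cbind(10 * cos(ang)[cluster] + stats::rnorm(n),
               10 * sin(ang)[cluster] + stats::rnorm(n))

  ## marker assignment: disjoint blocks, wrapping if needed
  markerOf <- function(nFeat, per) {
    lapply(seq_len(k), function(c)
      ((c - 1) * per + seq_len(per) - 1) %% nFeat + 1)
  }
  geneMarkers <- markerOf(spec$nGenes, .markersPerCluster)
  protMarkers <- markerOf(spec$nProteins, 1L)

  counts <- function(nFeat, markers) {
    mu0 <- stats::rgamma(nFeat, shape = 2, rate = 1)
    m <- matrix(0, n, nFeat)
    for (c in seq_len(k)) {
      idx <- which(cluster == c)
      fold <- rep(1, nFeat); fold[markers[[c]]] <- .markerFold
      for (f in seq_len(nFeat)) {
        m[idx, f] <- .rnbCounts(length(idx), mu0[f] * fold[f])
      }
    }
    m
  }
  expr <- counts(spec$nGenes, geneMarkers)
  prot <- counts(spec$nProteins, protMarkers)

  dimnames(expr) <- list(cellIds, geneIds)
  dimnames(prot) <- list(cellIds, protIds)
  exportMatrix(expr, file.path(outDir, "expression.matrix.zarr"),
               planChunks(n, spec$nGenes, "per-feature"))
  exportMatrix(prot, file.path(outDir, "protein.matrix.zarr"),
               planChunks(n, spec$nProteins, "per-feature"))

  writeCsv <- function(df, file) {
    utils::write.csv(df, file.path(outDir, file), row.names = FALSE,
                     quote = FALSE)
  }
  writeCsv(data.frame(obsId = cellIds, x = xy[, 1], y = xy[, 2]),
           "locations.csv")
  writeCsv(data.frame(obsId = cellIds, dim1 = emb[, 1], dim2 = emb[, 2]),
           "embedding.csv")

  pal <- .setPalette(k)
  setsDoc <- list(version = "0.1", tree = list(list(
    name = "Cell types",
    children = lapply(seq_len(k), function(c) {
      list(name = sprintf("Cluster %d", c),
           set = as.list(cellIds[cluster == c]),
           color = as.list(as.numeric(pal[c, ])))
    }))))
  writeLines(canonicalJSON(setsDoc), file.path(outDir, "cell_sets.json"),
             useBytes = TRUE)

  ## segmentation bitmask: disks labelled 1..n, later label wins
  disk <- expand.grid(dy = -r:r, dx = -r:r)
  disk <- disk[disk$dx^2 + disk$dy^2 <= r^2, , drop = FALSE]
  bitmask <- matrix(0L, sizeY, sizeX)
  px <- round(xy[, 1]); py <- round(xy[, 2])
  for (i in seq_len(n)) {
    ys <- py[i] + disk$dy + 1L; xs <- px[i] + disk$dx + 1L
    ok <- ys >= 1 & ys <= sizeY & xs >= 1 & xs <= sizeX
    bitmask[cbind(ys[ok], xs[ok])] <- i
  }

  ## image channels: background noise plus marker-scaled cell disks
  img <- array(0, dim = c(spec$nChannels, sizeY, sizeX))
  for (ch in seq_len(spec$nChannels)) {
    markerGene <- geneMarkers[[(ch - 1) %% k + 1]][1]
    base <- matrix(stats::runif(sizeY * sizeX, 0, 10), sizeY, sizeX)
    lvl <- expr[, markerGene]
    for (i in seq_len(n)) {
      ys <- py[i] + disk$dy + 1L; xs <- px[i] + disk$dx + 1L
      ok <- ys >= 1 & ys <= sizeY & xs >= 1 & xs <= sizeX
      base[cbind(ys[ok], xs[ok])] <- 20 + 10 * lvl[i]
    }
    img[ch, , ] <- base
  }
  nLevels <- max(1L, floor(log2(max(sizeY, sizeX) / 32)) + 1L)
  exportImagePyramid(img, file.path(outDir, "image.pyramid.zarr"),
                     nLevels = nLevels, tileSize = 64L)
  exportImagePyramid(bitmask, file.path(outDir, "segmentation.pyramid.zarr"),
                     nLevels = nLevels, tileSize = 64L, bitmask = TRUE)

  writeLines(canonicalJSON(list(spec = spec,
                                files = list(
                                  expression = "expression.matrix.zarr",
                                  protein = "protein.matrix.zarr",
                                  locations = "locations.csv",
                                  embedding = "embedding.csv",
                                  sets = "cell_sets.json",
                                  image = "image.pyramid.zarr",
                                  segmentation = "segmentation.pyramid.zarr"))),
             file.path(outDir, "fixture.json"), useBytes = TRUE)
  invisible(outDir)
}

.fixtureFile <- function(dir, what) {
  manifest <- parseJSON(paste(readLines(file.path(dir, "fixture.json"),
                                        warn = FALSE), collapse = "\n"))
  f <- manifest$files[[what]]
  if (is.null(f) || !file.exists(file.path(dir, f))) {
    stop("fixture at '", dir, "' is missing its ", what, " component")
  }
  f
}

#' Build a ViewConfig for a generated fixture
#'
#' Templates mirror common assay shapes:
#' \describe{
#'   \item{smfish-like}{one spatial view stacking image, segmentation and
#'     cell-centroid spots, plus a heatmap, linked on `featureSelection`.}
#'   \item{citeseq-like}{gene and protein matrices as two datasets, two
#'     scatterplots plus a heatmap linked on `featureSelection` across
#'     the modalities.}
#'   \item{visium-like}{spot observations: spatial spots, scatterplot and
#'     heatmap linked on `featureSelection`, plus a set-size bar chart.}
#' }
#'
#' @param dir Fixture directory from [generateDataset].
#' @param template One of `"smfish-like"`, `"citeseq-like"`,
#'   `"visium-like"`.
#' @return A valid `ViewConfig` (relative file urls, resolve with
#'   `root = dir`).
#' @export
generateConfig <- function(dir, template = c("smfish-like", "citeseq-like",
                                             "visium-like")) {
  template <- match.arg(template)
  f <- function(what) .fixtureFile(dir, what)
  if (template == "smfish-like") {
    vc <- ViewConfig(name = "smFISH-like fixture")
    vc <- addDataset(vc, "fx", "fixture")
    vc <- addFile(vc, "fx", "image.ome-zarr", f("image"))
    vc <- addFile(vc, "fx", "obsSegmentations.ome-zarr", f("segmentation"))
    vc <- addFile(vc, "fx", "obsLocations.csv", f("locations"))
    vc <- addFile(vc, "fx", "obsFeatureMatrix.zarr", f("expression"))
    vc <- addFile(vc, "fx", "obsSets.json", f("sets"))
    vc <- addView(vc, "spatial", "fx", 0, 0, 6, 8)
    vc <- addView(vc, "heatmap", "fx", 6, 0, 6, 8)
    vc <- linkViews(vc, viewIds(vc), "featureSelection",
                    list("gene_1", "gene_4"))
    vc <- linkViews(vc, viewIds(vc), "obsColorEncoding", "featureValue")
    return(vc)
  }
  if (template == "citeseq-like") {
    vc <- ViewConfig(name = "CITE-seq-like fixture")
    vc <- addDataset(vc, "rna", "gene expression")
    vc <- addFile(vc, "rna", "obsFeatureMatrix.zarr", f("expression"))
    vc <- addFile(vc, "rna", "obsEmbedding.csv", f("embedding"))
    vc <- addFile(vc, "rna", "obsSets.json", f("sets"))
    vc <- addDataset(vc, "adt", "protein abundance")
    vc <- addFile(vc, "adt", "obsFeatureMatrix.zarr", f("protein"),
                  entity = list(featureType = "protein",
                                featureValueType = "intensity"))
    vc <- addFile(vc, "adt", "obsEmbedding.csv", f("embedding"))
    vc <- addFile(vc, "adt", "obsSets.json", f("sets"))
    vc <- addView(vc, "scatterplot", "rna", 0, 0, 4, 6, uid = "scatter-rna")
    vc <- addView(vc, "scatterplot", "adt", 4, 0, 4, 6, uid = "scatter-adt")
    vc <- addView(vc, "heatmap", "rna", 8, 0, 4, 6, uid = "heatmap-rna")
    vc <- linkViews(vc, viewIds(vc), "featureSelection",
                    list("gene_1", "protein_1"))
    vc <- linkViews(vc, c("scatter-rna", "scatter-adt"), "obsColorEncoding",
                    "featureValue")
    vc <- linkViews(vc, "scatter-adt", "featureType", "protein")
    vc <- linkViews(vc, "scatter-adt", "featureValueType", "intensity")
    return(vc)
  }
  ## visium-like: spot observations
  vc <- ViewConfig(name = "Visium-like fixture")
  vc <- addDataset(vc, "sp", "spots")
  vc <- addFile(vc, "sp", "obsFeatureMatrix.zarr", f("expression"),
                entity = list(obsType = "spot"))
  vc <- addFile(vc, "sp", "obsLocations.csv", f("locations"),
                entity = list(obsType = "spot"))
  vc <- addFile(vc, "sp", "obsEmbedding.csv", f("embedding"),
                entity = list(obsType = "spot"))
  vc <- addFile(vc, "sp", "obsSets.json", f("sets"),
                entity = list(obsType = "spot"))
  vc <- addView(vc, "spatial", "sp", 0, 0, 4, 6, uid = "spatial-sp")
  vc <- addView(vc, "scatterplot", "sp", 4, 0, 4, 6, uid = "scatter-sp")
  vc <- addView(vc, "heatmap", "sp", 8, 0, 4, 6, uid = "heatmap-sp")
  vc <- addView(vc, "obsSetSizes", "sp", 0, 6, 4, 3, uid = "sizes-sp")
  vc <- linkViews(vc, viewIds(vc), "obsType", "spot")
  vc <- linkViews(vc, c("spatial-sp", "scatter-sp", "heatmap-sp"),
                  "featureSelection", list("gene_1"))
  vc <- linkViews(vc, c("spatial-sp", "scatter-sp"), "obsColorEncoding",
                  "featureValue")
  vc
}
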