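test_that("value-to-color mapping clamps at the domain and handles NaN", {
  cmap <- getColormap("viridis")
  enc <- colorEncoding("featureValue", domain = c(0, 10))
  got <- mapValuesToColors(c(0, -5, 10, 99, NaN), enc)
  expect_identical(got[1, ], cmap[1, ])
  expect_identical(got[2, ], cmap[1, ])
  expect_identical(got[3, ], cmap[256, ])
  expect_identical(got[4, ], cmap[256, ])
  expect_identical(got[5, ], c(128L, 128L, 128L))
  # all-equal values under a quantile domain: one color, no error
  same <- mapValuesToColors(rep(4.2, 9), colorEncoding("featureValue"))
  expect_identical(nrow(unique(same)), 1L)
  expect_error(mapValuesToColors(NULL, colorEncoding("featureValue")),
               "selected feature")
})

test_that("interpolation through a 10-entry colormap equals the direct oracle", {
  set.seed(20)
  tab <- matrix(sample(0:255, 30, replace = TRUE), 10, 3)
  enc <- colorEncoding("featureValue", domain = c(-2, 3), table = tab)
  v <- runif(200, -3, 4)
  got <- mapValuesToColors(v, enc)
  t <- pmin(1, pmax(0, (v - (-2)) / 5))
  pos <- t * 9
  lo <- pmin(floor(pos), 8); frac <- pos - lo
  want <- round((1 - frac) * tab[lo + 1, ] + frac * tab[lo + 2, ])
  storage.mode(want) <- "integer"
  expect_identical(got, want)
})

.twoLabelBitmask <- function() {
  lab <- matrix(0L, 32, 32)
  lab[5:12, 5:12] <- 1L
  lab[20:28, 18:27] <- 2L
  p <- tempfile("bm2")
  exportImagePyramid(lab, p, nLevels = 1, tileSize = 32, bitmask = TRUE)
  list(pyramid = openImagePyramid(p), labels = lab)
}

test_that("segmentation rendering uses exactly the encoded label colors", {
  fx <- .twoLabelBitmask()
  colors <- rbind(c(255L, 0L, 0L), c(0L, 0L, 255L))   # red, blue
  layers <- list(list(kind = "segmentations", data = fx$pyramid,
                      colors = colors))
  raster <- flattenRaster(renderSpatial(layers, 32, 32))
  px <- unique(cbind(as.vector(raster[, , 1]), as.vector(raster[, , 2]),
                     as.vector(raster[, , 3])))
  pxKeys <- apply(px, 1, paste, collapse = ",")
  expect_setequal(pxKeys, c("255,255,255", "255,0,0", "0,0,255"))
  # pixel counts match the label image
  expect_identical(sum(raster[, , 1] == 255 & raster[, , 3] == 0),
                   sum(fx$labels == 1))
  expect_identical(sum(raster[, , 3] == 255 & raster[, , 1] == 0),
                   sum(fx$labels == 2))
})

test_that("a zero-opacity top layer leaves the composition unchanged", {
  fx <- .twoLabelBitmask()
  colors <- rbind(c(200L, 40L, 40L), c(40L, 200L, 40L))
  base <- list(list(kind = "segmentations", data = fx$pyramid,
                    colors = colors))
  spots <- matrix(c(8, 8, 24, 22), 2, 2, byrow = TRUE)
  withTop <- c(base, list(list(kind = "spots", data = spots,
                               colors = rbind(c(1L, 1L, 1L), c(2L, 2L, 2L)),
                               opacity = 0)))
  expect_identical(renderSpatial(withTop, 32, 32), renderSpatial(base, 32, 32))
})

test_that("superimposed layers equal juxtaposed per-layer renders, composed", {
  fx <- .twoLabelBitmask()
  set.seed(21)
  img <- array(runif(1 * 32 * 32, 0, 50), dim = c(1, 32, 32))
  pimg <- tempfile("img1")
  exportImagePyramid(img, pimg, nLevels = 1, tileSize = 32)
  ipyr <- openImagePyramid(pimg)
  colors <- rbind(c(255L, 0L, 0L), c(0L, 0L, 255L))
  imgLayer <- list(kind = "image", data = ipyr)
  segLayer <- list(kind = "segmentations", data = fx$pyramid, colors = colors)
  super <- renderSpatial(list(imgLayer, segLayer), 32, 32)
  juxI <- renderSpatial(list(imgLayer), 32, 32)
  juxS <- renderSpatial(list(segLayer), 32, 32)
  expect_identical(super, compositeOver(juxI, juxS))
  # kind/data mismatch errors name the layer index
  expect_error(renderSpatial(list(list(kind = "segmentations", data = ipyr)),
                             32, 32), "layer 1")
  expect_error(renderSpatial(list(imgLayer, list(kind = "image",
                                                 data = matrix(1, 2, 2))),
                             32, 32), "layer 2")
})

.denseMatrixPayload <- function(m) {
  list(matrix = m, obsIds = rownames(m), featureIds = colnames(m))
}

test_that("heatmaps are flat for constant matrices and follow the aggregate-then-color pipeline", {
  m <- matrix(5, 30, 20,
              dimnames = list(sprintf("c%d", 1:30), sprintf("g%d", 1:20)))
  state <- list(heatmapZoomX = 0, heatmapZoomY = 0,
                heatmapTargetX = 0, heatmapTargetY = 0)
  r <- renderHeatmap(state, .denseMatrixPayload(m), 24, 24)   # no margin
  expect_identical(nrow(unique(cbind(as.vector(r[, , 1]), as.vector(r[, , 2]),
                                     as.vector(r[, , 3])))), 1L)
  # 2x2 matrix at 4x4 px: four blocks in cell order
  m2 <- matrix(c(0, 10, 20, 30), 2, 2,
               dimnames = list(c("a", "b"), c("f", "g")))
  r2 <- renderHeatmap(state, .denseMatrixPayload(m2), 4, 4)
  cmap <- getColormap("viridis")
  want <- mapValuesToColors(as.numeric(m2),
                            colorEncoding("featureValue", domain = c(0, 30)))
  expect_identical(r2[1, 1, 1:3], as.numeric(want[1, ]))  # m2[1,1]
  expect_identical(r2[3, 1, 1:3], as.numeric(want[2, ]))  # m2[2,1]
  expect_identical(r2[1, 3, 1:3], as.numeric(want[3, ]))  # m2[1,2]
  expect_identical(r2[3, 3, 1:3], as.numeric(want[4, ]))  # m2[2,2]

  # coarse random render equals aggregate-then-color, pixel for pixel
  set.seed(22)
  m3 <- matrix(rnorm(57 * 23), 57, 23,
               dimnames = list(sprintf("c%d", 1:57), sprintf("g%d", 1:23)))
  r3 <- renderHeatmap(state, .denseMatrixPayload(m3), 20, 30)
  agg <- aggregateMatrixToPixels(m3, 30, 20, "mean")
  cols <- mapValuesToColors(as.numeric(agg),
                            colorEncoding("featureValue",
                                          domain = range(m3)))
  for (ch in 1:3) {
    expect_identical(r3[, , ch], matrix(as.numeric(cols[, ch]), 30, 20))
  }
})

test_that("scatterplots recolor without repositioning when the selected feature changes", {
  set.seed(23)
  n <- 40
  emb <- list(obsIds = sprintf("c%d", 1:n),
              coords = cbind(rnorm(n), rnorm(n)))
  rownames(emb$coords) <- emb$obsIds
  m <- matrix(c(rnorm(n, 0), rnorm(n, 10)), n, 2,
              dimnames = list(emb$obsIds, c("GZMB", "PRF1")))
  st <- function(feat) list(obsColorEncoding = "featureValue",
                            featureSelection = list(feat),
                            featureValueColormap = "viridis",
                            featureValueColormapRange = list(min = 0, max = 1),
                            embeddingZoom = 0, embeddingTargetX = 0,
                            embeddingTargetY = 0, embeddingPointRadius = 1,
                            embeddingPointOpacity = 1)
  r1 <- renderScatterplot(st("GZMB"), emb, .denseMatrixPayload(m),
                          widthPx = 64, heightPx = 64)
  r2 <- renderScatterplot(st("PRF1"), emb, .denseMatrixPayload(m),
                          widthPx = 64, heightPx = 64)
  expect_identical(r1[, , 4], r2[, , 4])          # identical positions
  expect_false(identical(r1[, , 1:3], r2[, , 1:3]))  # different colors
  expect_identical(attr(r1, "feature"), "GZMB")
  # one point at the extent center lands at the raster center
  single <- list(obsIds = "c1", coords = matrix(c(0, 0), 1, 2))
  rs <- renderScatterplot(st("GZMB"), single,
                          .denseMatrixPayload(m[1, , drop = FALSE]),
                          widthPx = 21, heightPx = 21)
  expect_gt(rs[11, 11, 4], 0)
  expect_identical(sum(rs[, , 4] > 0), 1L)
})

test_that("set-membership coloring uses at most one color per set", {
  n <- 30
  emb <- list(obsIds = sprintf("c%d", 1:n),
              coords = cbind(seq_len(n), rep(1:6, 5)))
  sets <- list(tree = list(list(name = "root", children = list(
    list(name = "s1", set = as.list(sprintf("c%d", 1:10)),
         color = list(255, 0, 0)),
    list(name = "s2", set = as.list(sprintf("c%d", 11:20)),
         color = list(0, 255, 0)),
    list(name = "s3", set = as.list(sprintf("c%d", 21:30)),
         color = list(0, 0, 255))))))
  st <- list(obsColorEncoding = "setMembership", embeddingZoom = 0,
             embeddingTargetX = 0, embeddingTargetY = 0,
             embeddingPointRadius = 1, embeddingPointOpacity = 1)
  r <- renderScatterplot(st, emb, NULL, sets, widthPx = 80, heightPx = 80)
  on <- r[, , 4] > 0
  px <- unique(cbind(r[, , 1][on], r[, , 2][on], r[, , 3][on]))
  expect_lte(nrow(px), 3L)
})

test_that("snapshots propagate linked coordination into every panel", {
  d <- sharedFixtureDir()
  vc <- generateConfig(d, "smfish-like")
  snap <- renderSnapshot(vc, root = d, pxPerUnit = 30)
  expect_identical(nrow(snap$failures), 0L)
  expect_identical(nrow(snap$panels), 2L)
  # both views resolve the identical featureSelection scope value
  states <- lapply(viewIds(vc), function(id) resolveViewState(vc, id))
  expect_identical(states[[1]]$featureSelection, states[[2]]$featureSelection)
  # the spatial panel colored by the first linked gene
  expect_identical(snap$panels$feature[snap$panels$component == "spatial"],
                   "gene_1")
})

test_that("an empty layout yields an empty figure without error", {
  vc <- addDataset(ViewConfig(name = "empty"), "A")
  snap <- renderSnapshot(vc)
  expect_identical(dim(snap$raster), c(0L, 0L, 4L))
  expect_identical(nrow(snap$failures), 0L)
})

test_that("a failing panel is reported while the others still render", {
  d <- sharedFixtureDir()
  vc <- ViewConfig(name = "partial")
  vc <- addDataset(vc, "fx")
  vc <- addFile(vc, "fx", "obsFeatureMatrix.zarr", "expression.matrix.zarr")
  vc <- addView(vc, "heatmap", "fx", 0, 0, 2, 2, uid = "ok")
  vc <- addView(vc, "obsSetSizes", "fx", 2, 0, 2, 2, uid = "broken")
  expect_warning(snap <- renderSnapshot(vc, root = d, pxPerUnit = 20),
                 "broken")
  expect_identical(snap$failures$viewId, "broken")
  expect_match(snap$failures$message, "no matching data")
  expect_identical(snap$panels$viewId, "ok")
})
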