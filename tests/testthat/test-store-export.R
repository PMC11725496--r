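test_that("per-feature chunk plans put many observations and few features per chunk", {
  p <- planChunks(10000, 2000, "per-feature")
  expect_lte(p$chunkShape[2], 10)
  expect_gte(p$chunkShape[1], 1000)
  expect_lte(planFetchCost(10000, 2000, p)$perFeatureFetchChunks,
             ceiling(10000 / p$chunkShape[1]))
  # tiny matrices clamp to their own dims
  p2 <- planChunks(5, 5, "per-feature")
  expect_identical(p2$chunkShape[1], 5L)
  expect_lte(p2$chunkShape[2], 5L)
  # per-observation is the transpose-optimal mirror
  pf <- planChunks(300, 200, "per-feature")
  po <- planChunks(200, 300, "per-observation")
  expect_identical(pf$chunkShape, rev(po$chunkShape))
})

test_that("integer and float matrices round-trip chunked stores exactly", {
  set.seed(5)
  mi <- matrix(sample.int(1000L, 100 * 20, replace = TRUE), 100, 20,
               dimnames = list(sprintf("c%d", 1:100), sprintf("g%d", 1:20)))
  pi <- tempfile("si")
  exportMatrix(mi, pi, planChunks(100, 20, "per-feature"))
  back <- loadFull(openMatrixHandle(pi))
  expect_identical(storage.mode(back), "integer")
  expect_identical(unname(back), unname(mi))
  expect_identical(dimnames(back), dimnames(mi))

  mf <- matrix(rnorm(57 * 13), 57, 13,
               dimnames = list(sprintf("c%d", 1:57), sprintf("g%d", 1:13)))
  for (comp in c("zlib", "none")) {
    pf <- tempfile("sf")
    exportMatrix(mf, pf, planChunks(57, 13, "balanced", compression = comp))
    expect_identical(unname(loadFull(openMatrixHandle(pf))), unname(mf))
  }
})

test_that("degenerate and non-finite inputs are handled before writing", {
  m0 <- matrix(numeric(0), 0, 4,
               dimnames = list(NULL, sprintf("g%d", 1:4)))
  p <- tempfile("s0")
  exportMatrix(m0, p)
  h <- openMatrixHandle(p)
  expect_identical(dim(h), c(0L, 4L))
  bad <- matrix(c(1, NaN, 3, 4), 2, 2)
  expect_error(exportMatrix(bad, tempfile()), "non-finite")
  expect_false(dir.exists(file.path(tempdir(), "never-written")))
})

test_that("python zarr reads our stores (independent format oracle)", {
  set.seed(6)
  m <- matrix(rnorm(30 * 7), 30, 7,
              dimnames = list(sprintf("c%d", 1:30), sprintf("g%d", 1:7)))
  p <- tempfile("pyz")
  exportMatrix(m, p, planChunks(30, 7, "per-feature"))
  out <- tryCatch(
    system2("python", c("-c", shQuote(paste0(
      "import zarr, numpy as np; z = zarr.open_array('", p, "', mode='r');",
      "print(float(np.asarray(z).sum()))"))), stdout = TRUE, stderr = TRUE),
    warning = function(w) NA_character_, error = function(e) NA_character_)
  expect_false(is.na(out[length(out)]))
  expect_equal(as.numeric(out[length(out)]), sum(m), tolerance = 1e-10)
})

test_that("per-feature fetch cost follows the chunk-grid formula and is monotone", {
  nObs <- 1200; nFeat <- 40
  prev <- Inf
  for (obsPerChunk in c(50, 100, 300, 600, 1200)) {
    plan <- list(chunkShape = c(as.integer(obsPerChunk), 5L))
    cost <- planFetchCost(nObs, nFeat, plan)$perFeatureFetchChunks
    expect_identical(cost, as.integer(ceiling(nObs / obsPerChunk)))
    expect_lte(cost, prev)
    prev <- cost
  }
  # wide chunk column: still ceil(nObs/obsPerChunk), never 1 unless one row chunk
  plan <- list(chunkShape = c(300L, as.integer(nFeat)))
  expect_identical(planFetchCost(nObs, nFeat, plan)$perFeatureFetchChunks, 4L)
})

test_that("size reports measure real bytes and the grid arithmetic", {
  m <- matrix(7, 200, 30,
              dimnames = list(sprintf("c%d", 1:200), sprintf("g%d", 1:30)))
  p <- tempfile("sz")
  exportMatrix(m, p, planChunks(200, 30, "per-feature"))
  rep <- storeSizeReport(p, m)
  expect_identical(rep$chunkCount,
                   as.integer(ceiling(200 / 200) * ceiling(30 / 10)))
  expect_identical(rep$perFeatureFetchChunks, 1L)
  expect_identical(rep$perObservationFetchChunks, 3L)
  # a compressed constant matrix beats its delimited-text serialization
  expect_lt(rep$storedBytes, rep$equivalentDelimitedTextBytes)
  expect_gt(rep$equivalentDelimitedTextBytes, 0)
})

test_that("pyramids ceil-halve dims, conserve mean intensity, and keep labels closed", {
  img <- array(7, dim = c(1, 4, 4))
  p <- tempfile("pc")
  exportImagePyramid(img, p, nLevels = 2, tileSize = 4)
  pyr <- openImagePyramid(p)
  l1 <- loadImageTile(pyr, 1, 0, 0)
  expect_identical(dim(l1), c(1L, 2L, 2L))
  expect_true(all(l1 == 7))

  set.seed(7)
  img2 <- array(runif(2 * 64 * 64, 0, 100), dim = c(2, 64, 64))
  p2 <- tempfile("pm")
  exportImagePyramid(img2, p2, nLevels = 3, tileSize = 32)
  pyr2 <- openImagePyramid(p2)
  info <- pyramidLevels(pyr2)
  expect_identical(info$height, c(64L, 32L, 16L))
  for (l in 1:2) {
    a <- readZarrFull(pyr2@levels[[l]])
    b <- readZarrFull(pyr2@levels[[l + 1]])
    expect_equal(mean(a), mean(b), tolerance = 1e-6)
  }
  # 100x100 with 3 levels: 100, 50, 25
  img3 <- array(0, dim = c(1, 100, 100))
  p3 <- tempfile("p3")
  exportImagePyramid(img3, p3, nLevels = 3, tileSize = 64)
  expect_identical(pyramidLevels(openImagePyramid(p3))$width, c(100L, 50L, 25L))
  # too many levels: empty-level error
  expect_error(exportImagePyramid(img, tempfile(), nLevels = 4, tileSize = 4),
               "empty level")
  # bitmask stride reduction stays within the label set
  lab <- matrix(sample(0:2, 48 * 48, replace = TRUE), 48, 48)
  p4 <- tempfile("p4")
  exportImagePyramid(lab, p4, nLevels = 3, tileSize = 16, bitmask = TRUE)
  bp <- openImagePyramid(p4)
  for (l in 0:2) {
    vals <- readZarrFull(bp@levels[[l + 1]])
    expect_true(all(vals %in% 0:2))
  }
})
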