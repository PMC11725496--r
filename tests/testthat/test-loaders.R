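.writeMatrixCsv <- function(m, path) {
  df <- data.frame(obsId = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

test_that("CSV matrices load with validated shape and identifiers", {
  m <- matrix(rpois(500, 4), 50, 10,
              dimnames = list(sprintf("c%d", 1:50), sprintf("g%d", 1:10)))
  p <- .writeMatrixCsv(m, tempfile(fileext = ".csv"))
  got <- loadData(list(dataType = "obsFeatureMatrix", url = p))
  expect_identical(dim(got$matrix), c(50L, 10L))
  expect_equal(unname(got$matrix), unname(m))
  expect_identical(got$obsIds, rownames(m))
  # header-only CSV: shape (0, k), no error
  writeLines("obsId,g1,g2,g3", p2 <- tempfile(fileext = ".csv"))
  empty <- loadData(list(dataType = "obsFeatureMatrix", url = p2))
  expect_identical(dim(empty$matrix), c(0L, 3L))
  # I/O errors are distinct from validation errors
  expect_error(loadData(list(dataType = "obsFeatureMatrix",
                             url = "no/such/file.csv")), class = "ioError")
  writeLines(c("obsId,g1", "a,1", "a,2"), p3 <- tempfile(fileext = ".csv"))
  expect_error(loadData(list(dataType = "obsFeatureMatrix", url = p3)),
               class = "validationError")
})

test_that("set hierarchies are validated: cycles and duplicated leaves rejected", {
  ok <- list(version = "0.1", tree = list(list(
    name = "root", children = list(
      list(name = "a", set = list("c1", "c2")),
      list(name = "b", set = list("c3"))))))
  p <- tempfile(fileext = ".json")
  writeLines(canonicalJSON(ok), p)
  sets <- loadSetHierarchy(p)
  leaves <- setHierarchyLeaves(sets)
  expect_identical(nrow(leaves), 3L)

  cyc <- list(tree = list(list(name = "root", children = list(
    list(name = "root", set = list("c1"))))))
  writeLines(canonicalJSON(cyc), p)
  expect_error(loadSetHierarchy(p), class = "validationError")

  dup <- list(tree = list(list(name = "root", children = list(
    list(name = "a", set = list("c1")),
    list(name = "b", set = list("c1"))))))
  writeLines(canonicalJSON(dup), p)
  expect_error(loadSetHierarchy(p), class = "validationError")
})

test_that("single-feature fetches touch exactly one chunk column", {
  set.seed(1)
  m <- matrix(rnorm(1000 * 100), 1000, 100,
              dimnames = list(sprintf("c%d", 1:1000), sprintf("g%d", 1:100)))
  h <- tempMatrixHandle(m, c(250, 10))
  sub <- loadMatrixSubset(h, "g3")
  expect_identical(nrow(accessLog(h)), 4L)  # ceil(1000/250)
  expect_equal(unname(sub[, 1]), unname(m[, "g3"]))
  # second feature in the same chunk column: no new chunks
  h2 <- tempMatrixHandle(m, c(250, 10))
  loadMatrixSubset(h2, c("g3", "g7"))
  expect_identical(nrow(accessLog(h2)), 4L)
  expect_error(loadMatrixSubset(h, c("g3", "nope")), "unknown feature")
})

test_that("subset loads equal full-load slices and fetch exactly the intersecting chunks", {
  set.seed(2)
  for (trial in 1:20) {
    nO <- sample(8:60, 1); nF <- sample(4:25, 1)
    m <- matrix(rnorm(nO * nF), nO, nF,
                dimnames = list(sprintf("c%d", 1:nO), sprintf("g%d", 1:nF)))
    cs <- c(sample(1:nO, 1), sample(1:nF, 1))
    h <- tempMatrixHandle(m, cs)
    feats <- sample(colnames(m), sample(1:nF, 1))
    r0 <- sample(0:(nO - 1), 1); r1 <- r0 + sample.int(nO - r0, 1)
    sub <- loadMatrixSubset(h, feats, c(r0, r1))
    expect_identical(unname(sub), unname(m[(r0 + 1):r1, feats, drop = FALSE]))
    oracle <- bruteChunksForRequest(cs, match(feats, colnames(m)) - 1L,
                                    c(r0, r1))
    log <- accessLog(h)
    expect_identical(nrow(log), nrow(oracle))
    expect_identical(nrow(unique(log)), nrow(log))  # each chunk at most once
    key <- function(x) sort(paste(x[, 1], x[, 2]))
    expect_identical(key(log), key(oracle))
  }
})

test_that("the chunk cache suppresses re-fetches without changing values", {
  set.seed(3)
  m <- matrix(rnorm(40 * 8), 40, 8,
              dimnames = list(sprintf("c%d", 1:40), sprintf("g%d", 1:8)))
  h <- tempMatrixHandle(m, c(10, 4))
  a <- loadMatrixSubset(h, "g1")
  n1 <- nrow(accessLog(h))
  b <- loadMatrixSubset(h, "g1")       # fully cached
  expect_identical(nrow(accessLog(h)), n1)
  expect_identical(a, b)
})

test_that("image tiles equal crops of the source; bitmasks load by the same path", {
  set.seed(4)
  img <- array(runif(2 * 100 * 90, 0, 255), dim = c(2, 100, 90))
  p <- tempfile("pyr")
  exportImagePyramid(img, p, nLevels = 2, tileSize = 32)
  pyr <- openImagePyramid(p)
  expect_identical(length(pyr@levels), 2L)
  t00 <- loadImageTile(pyr, 0, 0, 0)
  expect_equal(t00, img[, 1:32, 1:32, drop = FALSE])
  # ragged edge tile is smaller
  tEdge <- loadImageTile(pyr, 0, 2, 3)
  expect_identical(dim(tEdge), c(2L, 4L, 26L))
  expect_equal(tEdge, img[, 97:100, 65:90, drop = FALSE])
  # channel selection reads only those channels
  n0 <- nrow(accessLog(pyr))
  loadImageTile(pyr, 0, 1, 1, channels = 1L)
  expect_identical(nrow(accessLog(pyr)), n0 + 1L)
  expect_error(loadImageTile(pyr, 0, 9, 0), "out of grid")
  expect_error(loadImageTile(pyr, 5, 0, 0), "level out of range")

  lab <- matrix(sample(0:5, 64 * 64, replace = TRUE), 64, 64)
  pb <- tempfile("bm")
  exportImagePyramid(lab, pb, nLevels = 2, tileSize = 32, bitmask = TRUE)
  bpyr <- openImagePyramid(pb)
  expect_true(bpyr@bitmask)
  expect_identical(loadImageTile(bpyr, 0, 1, 1), lab[33:64, 33:64])
  # stride-reduced level keeps only original label values
  l1 <- loadImageTile(bpyr, 1, 0, 0)
  expect_true(all(l1 %in% 0:5))
})

test_that("anndata-style joint stores load matrix, embedding and locations", {
  root <- tempfile("ann")
  n <- 12
  X <- matrix(rpois(n * 5, 3), n, 5)
  emb <- cbind(rnorm(n), rnorm(n))
  dir.create(root)
  writeZarrArray(X, file.path(root, "X"), chunks = c(6, 2), dtype = "<f8")
  writeZarrArray(emb, file.path(root, "obsm/umap"), chunks = c(n, 2))
  writeLines(canonicalJSON(list(obsIds = as.list(sprintf("c%d", 1:n)),
                                featureIds = as.list(sprintf("g%d", 1:5)))),
             file.path(root, ".zattrs"))
  acc <- expandJointFileType(list(
    url = root, fileType = "anndata.zarr",
    options = list(matrixPath = "X", embeddingPath = "obsm/umap",
                   embeddingType = "UMAP")))
  payloads <- lapply(acc, loadData)
  names(payloads) <- vapply(acc, `[[`, character(1), "dataType")
  expect_s4_class(payloads$obsFeatureMatrix, "ChunkedMatrixHandle")
  expect_equal(unname(loadFull(payloads$obsFeatureMatrix)), X)
  expect_equal(unname(payloads$obsEmbedding$coords), emb)
  expect_identical(payloads$obsEmbedding$embeddingType, "UMAP")
})
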