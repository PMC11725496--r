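.mkManifest <- function(files) {
  datasetManifest(list(uid = "ds", files = files))
}

test_that("joint file types expand to accessors sharing one URL", {
  fs <- list(url = "store.zarr", fileType = "anndata.zarr",
             options = list(matrixPath = "X", embeddingPath = "obsm/umap",
                            locationsPath = "obsm/spatial"))
  acc <- expandJointFileType(fs)
  expect_identical(length(acc), 3L)
  expect_setequal(vapply(acc, `[[`, character(1), "dataType"),
                  c("obsFeatureMatrix", "obsEmbedding", "obsLocations"))
  expect_identical(unique(vapply(acc, `[[`, character(1), "url")), "store.zarr")
  # omitting the embedding path just drops that accessor
  fs$options$embeddingPath <- NULL
  expect_identical(length(expandJointFileType(fs)), 2L)
  # a simple file type yields exactly one accessor
  one <- expandJointFileType(list(url = "m.csv",
                                  fileType = "obsFeatureMatrix.csv"))
  expect_identical(length(one), 1L)
  expect_identical(one[[1]]$dataType, "obsFeatureMatrix")
  expect_error(expandJointFileType(list(url = "x", fileType = "nope.fmt")),
               "unregistered file type")
  expect_error(expandJointFileType(list(url = "x", fileType = "obsSets.json",
                                        options = list(bogus = 1))),
               "not declared")
})

test_that("joint expansion equals the union of its constituent simple types", {
  joint <- expandJointFileType(list(
    url = "s.zarr", fileType = "anndata.zarr",
    options = list(matrixPath = "X", locationsPath = "obsm/spatial")))
  simpleMatrix <- expandJointFileType(list(
    url = "s.zarr", fileType = "obsFeatureMatrix.zarr",
    options = list(path = "X")))
  key <- function(a) paste(a$dataType, a$url, a$options$path)
  expect_setequal(vapply(joint, key, character(1)),
                  c(key(simpleMatrix[[1]]), "obsLocations s.zarr obsm/spatial"))
})

test_that("manifests are deterministic, ordered, and flag duplicates", {
  files <- list(
    list(url = "m.csv", fileType = "obsFeatureMatrix.csv"),
    list(url = "img.zarr", fileType = "image.ome-zarr"),
    list(url = "sets.json", fileType = "obsSets.json"))
  mf <- .mkManifest(files)
  expect_identical(nrow(mf), 3L)
  expect_identical(mf$fileIndex, 1:3)
  expect_identical(mf$dataType, c("obsFeatureMatrix", "image", "obsSets"))
  expect_false(any(mf$ambiguous))
  # entity defaults fill in the dominant single-cell case
  expect_identical(mf$obsType[1], "cell")
  expect_identical(mf$featureType[1], "gene")
  expect_identical(mf$featureValueType[1], "expression")
  # zero files -> empty table
  expect_identical(nrow(.mkManifest(list())), 0L)
  # duplicate (dataType, triple) accessors are both listed and flagged
  dup <- .mkManifest(list(
    list(url = "a.csv", fileType = "obsFeatureMatrix.csv"),
    list(url = "b.csv", fileType = "obsFeatureMatrix.csv")))
  expect_identical(nrow(dup), 2L)
  expect_true(all(dup$ambiguous))
})

test_that("the heatmap consults all three entity identifiers, the feature list only featureType", {
  files <- list(
    list(url = "rna.csv", fileType = "obsFeatureMatrix.csv",
         entity = list(obsType = "cell", featureType = "gene",
                       featureValueType = "expression")),
    list(url = "adt.csv", fileType = "obsFeatureMatrix.csv",
         entity = list(obsType = "cell", featureType = "protein",
                       featureValueType = "intensity")))
  mf <- .mkManifest(files)
  hm <- matchViewToData("heatmap", mf,
                        list(obsType = "cell", featureType = "gene",
                             featureValueType = "expression"))
  expect_identical(hm$matches$obsFeatureMatrix$url, "rna.csv")
  # full-triple mismatch on any one component -> no match
  expect_error(
    matchViewToData("heatmap", mf,
                    list(obsType = "cell", featureType = "gene",
                         featureValueType = "intensity")),
    class = "noMatchingData")
  # the feature list ignores obsType and featureValueType
  nucFiles <- list(list(url = "nuc.csv", fileType = "obsFeatureMatrix.csv",
                        entity = list(obsType = "nucleus",
                                      featureType = "gene",
                                      featureValueType = "count")))
  fl <- matchViewToData("featureList", .mkManifest(nucFiles),
                        list(obsType = "cell", featureType = "gene",
                             featureValueType = "expression"))
  expect_identical(fl$matches$obsFeatureMatrix$url, "nuc.csv")
  # the declared requirement tables mirror this
  hmReq <- viewDataRequirements("heatmap")$requirements[[1]]
  expect_setequal(hmReq$components,
                  c("obsType", "featureType", "featureValueType"))
  flReq <- viewDataRequirements("featureList")$requirements[[1]]
  expect_identical(flReq$components, "featureType")
})

test_that("an empty dataset yields a no-matching-data diagnostic naming the triple", {
  mf <- .mkManifest(list())
  err <- tryCatch(matchViewToData("heatmap", mf,
                                  list(obsType = "spot")),
                  error = function(e) e)
  expect_s3_class(err, "noMatchingData")
  expect_match(conditionMessage(err), "spot")
  soft <- matchViewToData("heatmap", mf, strict = FALSE)
  expect_identical(soft$missing, "obsFeatureMatrix")
})

test_that("matching is invariant to permutations of irrelevant manifest rows", {
  set.seed(9)
  files <- list(
    list(url = "rna.csv", fileType = "obsFeatureMatrix.csv"),
    list(url = "img.zarr", fileType = "image.ome-zarr"),
    list(url = "loc.csv", fileType = "obsLocations.csv"),
    list(url = "sets.json", fileType = "obsSets.json"),
    list(url = "adt.csv", fileType = "obsFeatureMatrix.csv",
         entity = list(featureType = "protein")))
  mf <- .mkManifest(files)
  ref <- matchViewToData("heatmap", mf)$matches$obsFeatureMatrix$url
  for (p in 1:20) {
    perm <- mf[sample(nrow(mf)), , drop = FALSE]
    got <- matchViewToData("heatmap", perm)
    expect_identical(got$matches$obsFeatureMatrix$url, ref)
  }
})
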