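test_that("the built-in registry covers at least 51 coordination types", {
  expect_gte(length(coordinationTypes()), 51L)
  # spot checks across the declared categories
  expect_true(all(c("obsType", "featureType", "featureValueType",
                    "spatialZoom", "spatialTargetX", "spatialRotationZ",
                    "embeddingType", "embeddingZoom", "heatmapZoomX",
                    "featureSelection", "obsSetSelection", "obsFilter",
                    "obsColorEncoding", "featureValueColormap",
                    "imageLayerOpacity", "spotRadius", "genomicZoomX") %in%
                  coordinationTypes()))
})

test_that("registering types enforces uniqueness and kind conformance", {
  on.exit(resetCoordinationRegistry())
  registerCoordinationType("customThing", "number", 3)
  expect_identical(coordinationTypeDefault("customThing"), 3)
  expect_error(registerCoordinationType("customThing", "number", 0),
               "already registered")
  expect_error(registerCoordinationType("spatialZoom", "number", 0),
               "already registered")
  expect_error(registerCoordinationType("badDefault", "number", "a"),
               "conform")
})

.linkedPair <- function() {
  vc <- addDataset(ViewConfig(), "A")
  vc <- addView(vc, "scatterplot", "A", 0, 0, 2, 2, uid = "sc")
  vc <- addView(vc, "heatmap", "A", 2, 0, 2, 2, uid = "hm")
  vc
}

test_that("linked views resolve the shared scope value; wrong-kind values refused", {
  vc <- .linkedPair()
  vc <- linkViews(vc, c("sc", "hm"), "featureSelection", list("Lamp5", "Rorb"))
  expect_identical(resolveViewState(vc, "sc")$featureSelection,
                   list("Lamp5", "Rorb"))
  expect_identical(resolveViewState(vc, "hm")$featureSelection,
                   list("Lamp5", "Rorb"))
  # a scope of size 1 is fine
  vc2 <- linkViews(.linkedPair(), "sc", "spatialZoom", 2.5)
  expect_identical(resolveViewState(vc2, "sc")$spatialZoom, 2.5)
  expect_error(linkViews(.linkedPair(), "sc", "featureSelection", 5),
               "conform")
  expect_error(linkViews(.linkedPair(), c("sc", "ghost"), "spatialZoom", 0),
               "unknown view id")
  expect_error(linkViews(.linkedPair(), "sc", "noSuchType", 0),
               "unknown coordination type")
})

test_that("setting a scope changes exactly the views linked to it", {
  vc <- addDataset(ViewConfig(), "A")
  for (i in 1:4) vc <- addView(vc, "scatterplot", "A", (i - 1) * 2, 0, 2, 2,
                               uid = paste0("v", i))
  vc <- linkViews(vc, c("v1", "v2", "v3"), "spatialZoom", 1)
  sA <- attr(vc, "scopeName")
  vc <- linkViews(vc, "v4", "spatialZoom", 7)
  before <- lapply(paste0("v", 1:4), function(id)
    resolveViewState(vc, id)$spatialZoom)
  vc2 <- setCoordinationValue(vc, "spatialZoom", sA, 3)
  after <- lapply(paste0("v", 1:4), function(id)
    resolveViewState(vc2, id)$spatialZoom)
  expect_identical(before, list(1, 1, 1, 7))
  expect_identical(after, list(3, 3, 3, 7))
  # idempotence: writing the current value leaves the space unchanged
  vc3 <- setCoordinationValue(vc2, "spatialZoom", sA, 3)
  expect_identical(canonicalJSON(asConfigDocument(vc3)),
                   canonicalJSON(asConfigDocument(vc2)))
  expect_error(setCoordinationValue(vc, "spatialZoom", "Q", 0),
               "unknown coordination scope")
})

test_that("unlinked views resolve registry defaults; dangling scopes error", {
  vc <- .linkedPair()
  st <- resolveViewState(vc, "sc")
  expect_identical(st$obsType, "cell")
  expect_identical(st$featureType, "gene")
  expect_identical(st$featureValueType, "expression")
  expect_identical(st$embeddingZoom, 0)
  expect_identical(st$dataset, "A")  # falls back to the layout item
  vc <- linkViews(vc, "sc", "featureSelection", list("CD56"))
  expect_identical(resolveViewState(vc, "sc")$featureSelection, list("CD56"))
  # delete the scope behind the view's back
  vc@coordinationSpace$featureSelection <-
    structure(list(), names = character(0))
  expect_error(resolveViewState(vc, "sc"), class = "danglingScope")
  expect_error(resolveViewState(vc, "nobody"), "unknown view id")
})

test_that("snapshots restore identical view states and are valid configs", {
  vc <- .linkedPair()
  vc <- linkViews(vc, c("sc", "hm"), "featureSelection", list("GZMB"))
  snap <- configSnapshot(vc)
  restored <- deserializeConfig(snap)
  rep <- validateConfig(restored)
  expect_identical(nrow(rep[rep$severity == "error", ]), 0L)
  for (id in c("sc", "hm")) {
    expect_identical(resolveViewState(restored, id), resolveViewState(vc, id))
  }
  # mutate then restore: states return to the original
  mutated <- setCoordinationValue(vc, "featureSelection",
                                  attr(vc, "scopeName"), list("PRF1"))
  expect_false(identical(resolveViewState(mutated, "sc")$featureSelection,
                         resolveViewState(restored, "sc")$featureSelection))
})

test_that("a snapshot after set_value differs exactly at the changed scope", {
  vc <- .linkedPair()
  vc <- linkViews(vc, c("sc", "hm"), "spatialZoom", 1)
  scope <- attr(vc, "scopeName")
  before <- parseJSON(configSnapshot(vc))
  after <- parseJSON(configSnapshot(
    setCoordinationValue(vc, "spatialZoom", scope, 4)))
  # JSON diff oracle: replacing the one scope value reconciles the trees
  expect_false(jsonEqual(before, after))
  patched <- before
  patched$coordinationSpace$spatialZoom[[scope]] <- 4
  expect_true(jsonEqual(patched, after))
})

test_that("coordination is symmetric and transitive through scopes (property)", {
  set.seed(42)
  for (trial in 1:500) {
    vc <- addDataset(ViewConfig(), "A")
    nV <- sample(2:5, 1)
    for (i in seq_len(nV)) {
      vc <- addView(vc, "scatterplot", "A", (i - 1) * 2, 0, 2, 2,
                    uid = paste0("v", i))
    }
    nScopes <- sample(1:3, 1)
    assignment <- sample(0:nScopes, nV, replace = TRUE)  # 0 = unlinked
    scopeNames <- character(nScopes)
    for (s in seq_len(nScopes)) {
      members <- paste0("v", which(assignment == s), recycle0 = TRUE)
      value <- 100 + s   # distinct per scope, distinct from the default
      if (length(members)) {
        vc <- linkViews(vc, members, "spatialZoom", value)
        scopeNames[s] <- attr(vc, "scopeName")
      }
    }
    states <- lapply(seq_len(nV), function(i)
      resolveViewState(vc, paste0("v", i))$spatialZoom)
    for (i in seq_len(nV)) {
      for (j in seq_len(nV)) {
        sameScope <- assignment[i] == assignment[j]
        expect_identical(identical(states[[i]], states[[j]]), sameScope)
      }
    }
  }
})
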