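# CoordView

Coordinated multiple views for multimodal and spatially resolved
single-cell data — the data, configuration and coordination core of a
visualization framework, implemented in R.

Single-cell and spatial assays produce a patchwork of modalities:
cell-by-gene expression matrices, surface-protein panels, spatial
coordinates, dimensionality-reduction embeddings, hierarchical cell-type
annotations, multichannel microscopy images and cell-segmentation label
images. Exploring them together requires several views (scatterplot,
spatial plot, heatmap, set summaries) whose state — selected genes,
selected cell sets, cameras, color encodings — stays in sync. CoordView
is for tool builders and analysts who need that linked-view state model
with reproducible, serializable, shareable state, plus the storage and
viewport mathematics that make large matrices and images loadable on
demand.

## What the package implements

* **Declarative view configurations.** A JSON document (schema version
  `spec-1.0`) lists datasets and their files, a coordination space, and a
  grid layout of views. `validateConfig()` reports every violation with a
  JSON-pointer path; serialization is canonical (sorted keys, shortest
  exact number representation), so equal configs are byte-identical and
  `deserializeConfig(serializeConfig(c))` is the identity.
  `toShareURL()` embeds a config in a URL fragment (DEFLATE + base64url,
  length/Adler-32 framed), making a figure reproducible from a link alone.
* **The coordination model.** Views are never linked to each other;
  each view references named *coordination scopes* — named values of
  typed *coordination types* (`spatialZoom`, `featureSelection`,
  `obsSetSelection`, per-layer opacities, ...; 53 built-in types). Views
  are coordinated on a property exactly when they reference the same
  scope: `resolveViewState()` is a pure function of the config, so a
  snapshot of the document is a snapshot of the entire interactive state.
* **Type-based view–data matching.** Files and views carry an *entity
  triple* — (observation type, feature type, feature-value type), e.g.
  (cell, gene, expression). A view requests data types (matrix,
  locations, embedding, segmentations, sets, image) and is matched to a
  dataset's accessors by comparing only the components relevant to that
  view: the heatmap consults all three, a feature list only the feature
  type. Joint file types (AnnData-style stores) expose several data
  types from one URL.
* **Chunked stores and lazy loading.** Matrices live in Zarr-compatible
  directory stores (`.zarray` metadata, C-order zlib chunks — readable
  by `zarr`-python). A `ChunkedMatrixHandle` fetches only the chunks
  intersecting a request and logs every fetch, so laziness is testable:
  fetching one gene across all cells under a per-feature chunk plan
  (many observations × few features per chunk) costs
  `ceil(nObs / obsPerChunk)` chunk reads. Images and segmentation
  bitmasks are multiscale pyramids loaded tile by tile.
* **Viewport mathematics.** Pyramid level selection (never fetch more
  resolution than a screen pixel can show), visible-tile enumeration,
  anti-aliasing aggregation of matrix windows onto pixel grids
  (proportional integer partition; constant input ⇒ constant output at
  every zoom), and zoom-aware axis-tick thinning.
* **Static snapshot renderer.** `renderSnapshot()` rasterizes every
  layout panel — scatterplot, spatial (image / segmentation / spot /
  point layers, juxtaposed or superimposed), heatmap, bar chart,
  histogram, violin — driven entirely by resolved coordination state.
  Rendering is deterministic: same config and fixture seed, same bytes.
* **Synthetic fixtures.** `generateDataset()` writes a complete
  multimodal dataset (expression + protein stores, coordinates,
  embedding, cell-set hierarchy, image and bitmask pyramids) from a
  seeded Gamma-Poisson cluster model; `generateConfig()` builds matching
  smFISH-like, CITE-seq-like and Visium-like configurations.

## Worked example

```r
library(CoordView)

fx <- file.path(tempdir(), "fx")
generateDataset(FixtureSpec(nCells = 100, nGenes = 60, seed = 1), fx)

h <- openMatrixHandle(file.path(fx, "expression.matrix.zarr"))
h
#> ChunkedMatrixHandle 100 x 60 (chunks 100 x 10), 0 chunk fetches logged
v <- loadMatrixSubset(h, "gene_1")   # one gene, all cells
h
#> ChunkedMatrixHandle 100 x 60 (chunks 100 x 10), 1 chunk fetches logged
mean(v)
#> [1] 7.48

vc <- generateConfig(fx, "smfish-like")
vc
#> ViewConfig 'smFISH-like fixture' (version spec-1.0)
#>   datasets: 1  views: 2  coordination types in space: 2
resolveViewState(vc, viewIds(vc)[1])$featureSelection
#> [[1]] "gene_1"  [[2]] "gene_4"     # shared scope: heatmap resolves the same

snap <- renderSnapshot(vc, root = fx, pxPerUnit = 50)
snap
#> viewSnapshot: 600 x 400 px, 2 panel(s), 0 failure(s)
writeRasterPNG(snap$raster, "snapshot.png")
```

The one-gene subset touched a single chunk because the per-feature plan
stores all 100 observations of 10 features per chunk; the two panels are
linked on a `featureSelection` scope holding `gene_1`/`gene_4`, so the
spatial segmentation colors and the heatmap annotation derive from
identical resolved state.

A thin CLI wraps the same functions
(`inst/scripts/viz validate|list-filetypes|convert|make-fixture|snapshot`).

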