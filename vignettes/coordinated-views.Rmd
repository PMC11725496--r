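---
title: "Coordinated multiple views: model, data access and rendering semantics"
author: "CoordView"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordinated multiple views: model, data access and rendering semantics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CoordView)
```

# The problem and the model

Multimodal and spatial single-cell experiments are explored through
several simultaneous views — scatterplots over embeddings, spatial plots
over tissue coordinates and images, heatmaps over observation-by-feature
matrices, and summaries over annotated cell sets. The scientific value
of such a figure comes from *linking*: selecting a gene should recolor
the embedding, the tissue view and the heatmap together; panning one
spatial panel may or may not move another, depending on the analyst's
intent.

CoordView expresses linking with a coordination model in which views are
never wired to each other. Instead, a *coordination type* is a named,
typed property (a zoom, a selected-feature list, a color encoding, a
layer opacity), and a *coordination scope* is a named value of one type.
Each view references at most one scope per type; two views are
coordinated on a property exactly when they reference the same scope.
This makes propagation a pure function — `resolveViewState(config, id)`
returns, for every property relevant to the view, the scope value if
linked and the registry default otherwise — and it makes the whole
interactive state a document: the configuration *is* the state, so
snapshots, undo, and URL sharing fall out of serialization.

The registry ships `r length(coordinationTypes())` coordination types
covering entity identifiers, spatial/embedding/heatmap cameras,
selections and highlights, color encodings, per-layer display properties
for image/segmentation/spot/point layers, and genomic-camera
placeholders. The inventory is a reconstruction by category — views can
be linked on any subset of these — rather than a name-for-name copy of
any particular tool's list. Only a flat, one-level scope model is
implemented; meta-coordination (scopes of scopes) is deliberately out of
scope.

Two design points were genuinely open and were settled as follows:

* **Scope naming.** Fresh scopes are auto-named `"A"`, `"B"`, …, `"AA"`
  per type in creation order; deterministic names keep serialization
  canonical.
* **Unlinked properties.** They resolve to registry defaults rather than
  erroring, so minimal configs render. A view linked to a scope that was
  later removed, however, raises an explicit `danglingScope` error —
  silently falling back to a default would mask a broken document. For
  the same reason `validateConfig()` flags any layout reference to a
  scope absent from the coordination space. A property a view's type
  does not declare relevant becomes relevant when the view is explicitly
  linked on it.

# The configuration document

A `ViewConfig` holds a schema version (fixed `"spec-1.0"`; unknown
versions are rejected), datasets with their files, the coordination
space, and a layout of views on an unbounded nonnegative integer grid.
Overlapping panels are reported as warnings, not errors — nothing in the
model forbids them, and composition order resolves them.

Serialization is canonical: object keys sorted bytewise, no whitespace,
UTF-8, and numbers printed in the shortest decimal form that parses back
to the identical double (`%.15g`, widened to `%.17g` only when needed).
Canonical form gives two properties the tests rely on: structurally
equal configs are byte-identical, and serialize → parse → serialize is
the identity. Non-finite numbers are refused — JSON cannot represent
them.

Share URLs embed the canonical JSON in the fragment:
DEFLATE-compressed, framed with the compressed length and an Adler-32
checksum, base64url-encoded. The frame exists because decompression must
never run on truncated input; a tampered payload fails the checksum with
a clean `shareURLDecodeError` instead of a partial config. The encoding
scheme is this package's own choice — a self-contained, server-free
format consistent with a client-only design.

# Matching views to data

Observations are the measured entities (cells, nuclei, spots,
molecules), features the measured characteristics (genes, proteins,
peaks), feature values the measured quantities (expression, counts,
intensities). Files and views both carry this *entity triple*; a view's
triple comes from its resolved coordination state
(`obsType`/`featureType`/`featureValueType`, defaulting to
cell/gene/expression — the dominant single-cell case, so minimal configs
work).

Each view type declares which data types it needs and which triple
components are relevant per data type: the heatmap consults all three
(a heatmap is uniquely identified by them), the feature list only the
feature type. An accessor matches iff it agrees on every relevant
component; irrelevant components are ignored, which is what lets one
`featureSelection` scope drive a gene scatterplot and a protein
scatterplot simultaneously. When several accessors match, the first in
manifest order wins and a warning is recorded (the manifest order —
file order, then data-type name — is deterministic, so the tie-break
is too). Matching is restricted to the view's declared dataset.

Joint file types expose several data types from one file: an
AnnData-style store states its URL once and sub-paths
(`matrixPath`, `embeddingPath`, `locationsPath`, `setsPath`) select
what is exposed. The data-type set is closed; there is no runtime
plugin registry.

# Chunked stores and on-demand loading

Matrices are stored in Zarr-v2-compatible directory stores written by
this package: `.zarray` JSON metadata, C-order little-endian chunks
named by their 0-based grid indices, zlib (DEFLATE) codec at level 5 by
default, edge chunks padded to full chunk shape. The layout is verified
against `zarr`-python in the test suite. No HDF5 path is provided; the
chunked-directory contract (plain static files, no server logic) is the
point.

Chunk geometry determines access cost. The per-feature plan stores
many observations and few features per chunk — defaults
`obsPerChunk = min(nObs, 4096)`, `featuresPerChunk = min(nFeatures, 10)`;
the direction is principled, the caps are this package's defaults —
so fetching one feature across all observations costs
`ceil(nObs / obsPerChunk)` chunk reads, while the mirrored
per-observation plan optimizes the transposed access. `ChunkedMatrixHandle`
records every chunk *fetch* (not cache hit) in an append-only access
log; a small per-handle LRU cache (64 chunks) is an engineering choice
the underlying contract does not constrain. All indexing is 0-based
with half-open ranges, matching the on-disk chunk keys; images use the
raster convention (origin top-left, y downward).

Image and bitmask pyramids ceil-halve their spatial dims per level.
Intensity levels reduce by 2×2 mean (which conserves total mean
intensity to float tolerance on even dims); bitmask levels reduce by
top-left stride sampling, never averaging — labels are categorical and
a stride-sampled pixel still holds a valid observation id. Levels are
chunked with chunk = tile, so loading a tile reads exactly one object
per selected channel.

# Viewport mathematics

Zoom is `log2(screen pixels per data unit)`. Level selection returns
the highest-resolution level whose downsample factor is at least the
data-pixels-per-screen-pixel ratio — never fetch more resolution than
the screen can show — clamped to the deepest level; it is monotone in
zoom. Visible tiles are exactly those whose data-space footprint
intersects the viewport rectangle.

Heatmap aggregation maps a matrix window onto the pixel grid with a
proportional integer partition: bin *k* of *p* over *n* items covers
rows `floor(k·n/p)` to `floor((k+1)·n/p) − 1`. Bins partition the
window exactly — no cell dropped or double-counted — which is the
anti-aliasing criterion: a constant matrix renders as a constant raster
at every zoom, eliminating the Moiré patterning that naive subsampling
produces on large matrices. Mean is the default aggregation (max/min
are available for sparse-signal emphasis); which function a GPU
implementation would use is not externally fixed, so the choice is
exposed. Axis ticks are thinned by `ceiling(maxLabelPx / itemPx)` at a
fixed 7 px per character, so drawn labels never overlap and zooming in
never hides a label that was visible.

# Rendering semantics

The renderer is a CPU reference implementation of the drawing contract,
not a GPU engine. Conventions, chosen here and stated as such:

* Spatial layer z-order is fixed: images bottom, then segmentations,
  spots, points; compositing is back-to-front straight-alpha "over".
* Image channels are windowed (`(v − lo)/(hi − lo)`, clamped), tinted by
  their channel color, summed additively and clipped at 255 — the
  standard multiplexed-image composite. Channel windows default to the
  visible window's range.
* Segmentation bitmask pixels take the encoded color of their label's
  observation; label 0 (background) is transparent.
* Feature values map to colors by piecewise-linear interpolation through
  a 256-entry colormap (viridis default, computed from
  `grDevices::hcl.colors`), clamped at the domain ends; NaN maps to
  mid-grey. A degenerate domain (all values equal) maps everything to
  the first entry rather than erroring.
* Spots default to 4 px radius, points to 1 px, panels to 200 px per
  grid unit; cameras fit the data extent and the zoom/target
  coordination values displace from that fit, so minimal configs render
  sensibly while linked cameras still move views together.

Determinism is a contract: no rendering path consults time, locale or
ambient randomness, so identical configs and fixture seeds produce
byte-identical rasters — which is how snapshot tests assert coordination
fidelity.

# The synthetic fixture generator

`generateDataset()` emulates the shape of a multimodal experiment
without imitating any real dataset: cells fall into Gaussian cluster
blobs on a jittered spatial grid and around circle-anchored embedding
centroids; counts are Gamma-Poisson (negative-binomial-like, shape 2),
with 3 marker genes per cluster elevated 5-fold (1 marker per cluster
for the protein panel) — realistic sparsity and separable clusters
without fitting data. The segmentation bitmask draws radius-3 disks
labelled 1..nCells (later label wins on overlap; a spec whose disks
exceed the image area is refused with advice to enlarge it), and image
channels track one marker gene per channel over a uniform noise floor.

What the fixtures do **not** emulate: batch effects, spatial expression
gradients independent of clusters, segmentation errors, imaging
artifacts, or realistic library-size variation. Tests passing on these
fixtures therefore demonstrate the correctness of the state model,
storage, matching and rendering contracts — not robustness of any
biological inference, of which the package makes none.

Test and acceptance problem sizes are deliberately desk-scale (tens of
cells, tens of features, ≤ 128 px images, 100–200 randomized trials per
property); every property checked is size-independent, and the brute
force oracles the results are compared against are exact at any size.

# Known limitations

* No interactivity: propagation is pure state resolution; there is no
  event loop, observer system or widget layer.
* No genome-browser view, no 3-D volume rendering, no HDF5-backed
  stores, no runtime plugin registration.
* Remote URLs are treated like local paths by the loaders' contract
  (static objects fetched wholesale); no range requests or retry logic.
* The renderer's text handling is minimal (tick marks, not labels), and
  controller views render as blank panels carrying coordination state
  only.
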