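Package: CoordView
Title: Coordinated Multiple Views for Multimodal and Spatial Single-Cell Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data, configuration and coordination core of a multimodal and
    spatially resolved single-cell visualization framework. Provides a
    declarative JSON view-configuration schema with validation and
    URL-based sharing, a coordinated-multiple-views state model built on
    named coordination scopes, type-based matching of views to data via
    (observation type, feature type, feature-value type) identifiers,
    lazy chunk- and tile-based loading from Zarr-compatible directory
    stores and multiscale image pyramids, access-optimized chunked store
    export, viewport and heatmap-aggregation mathematics, a static
    multi-panel snapshot renderer, and a deterministic synthetic
    multimodal fixture generator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    png
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
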