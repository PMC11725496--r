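.initRegistries <- function() {
  .pkgState$coordination <- new.env(parent = emptyenv())
  .registerBuiltinCoordinationTypes()
  .pkgState$fileTypes <- .registerBuiltinFileTypes()
  .pkgState$viewTypes <- .registerBuiltinViewTypes()
}

.onLoad <- function(libname, pkgname) {
  .initRegistries()
}
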