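#' @rdname BacAssembly-class
#' @param x,object a `BacAssembly` or `ReadPairs` object.
#' @export
setGeneric("bacId", function(x) standardGeneric("bacId"))

#' @rdname BacAssembly-class
#' @export
setGeneric("contigs", function(x) standardGeneric("contigs"))

#' @rdname BacAssembly-class
#' @export
setGeneric("contigData", function(x) standardGeneric("contigData"))

#' @rdname BacAssembly-class
#' @export
setGeneric("stage", function(x) standardGeneric("stage"))

#' @rdname ReadPairs-class
#' @export
setGeneric("mate1", function(x) standardGeneric("mate1"))

#' @rdname ReadPairs-class
#' @export
setGeneric("mate2", function(x) standardGeneric("mate2"))

#' @rdname ReadPairs-class
#' @export
setGeneric("libraryTag", function(x) standardGeneric("libraryTag"))
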