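#' @rdname BacAssembly-class
#' @export
setMethod("bacId", "BacAssembly", function(x) x@bacId)

#' @rdname BacAssembly-class
#' @export
setMethod("contigs", "BacAssembly", function(x) x@contigs)

#' @rdname BacAssembly-class
#' @export
setMethod("contigData", "BacAssembly", function(x) x@contigData)

#' @rdname BacAssembly-class
#' @export
setMethod("stage", "BacAssembly", function(x) x@stage)

#' @rdname BacAssembly-class
#' @export
setMethod("length", "BacAssembly", function(x) length(x@contigs))

#' @rdname BacAssembly-class
#' @export
setMethod("names", "BacAssembly", function(x) names(x@contigs))

#' @rdname BacAssembly-class
#' @param i index for contig subsetting.
setMethod("[", "BacAssembly", function(x, i) {
  initialize(x, contigs = x@contigs[i], contigData = x@contigData[i, , drop = FALSE])
})

setMethod("show", "BacAssembly", function(object) {
  w <- Biostrings::width(object@contigs)
  cat("BacAssembly '", object@bacId, "' [", object@stage, "]: ",
      length(w), " sequence(s), ", sum(w), " bp",
      if (length(w)) sprintf(", largest %d bp", max(w)) else "", "\n", sep = "")
  nb <- sum(object@contigData$bacEndLeft | object@contigData$bacEndRight)
  if (nb) cat("  BAC-end contigs:", nb, "\n")
  if (any(!is.na(object@contigData$coverage)))
    cat("  coverage: ", paste(round(object@contigData$coverage, 1), collapse = ", "),
        "\n", sep = "")
})

#' @rdname ReadPairs-class
#' @export
setMethod("mate1", "ReadPairs", function(x) x@mate1)

#' @rdname ReadPairs-class
#' @export
setMethod("mate2", "ReadPairs", function(x) x@mate2)

#' @rdname ReadPairs-class
#' @export
setMethod("libraryTag", "ReadPairs", function(x) x@libraryTag)

#' @rdname ReadPairs-class
#' @export
setMethod("length", "ReadPairs", function(x) length(x@mate1))

#' @rdname ReadPairs-class
#' @export
setMethod("names", "ReadPairs", function(x) names(x@mate1))

#' @rdname ReadPairs-class
#' @param i index for pair subsetting.
setMethod("[", "ReadPairs", function(x, i) {
  initialize(x, mate1 = x@mate1[i], mate2 = x@mate2[i])
})

setMethod("show", "ReadPairs", function(object) {
  cat("ReadPairs [", object@libraryTag, "]: ", length(object@mate1),
      " pair(s)\n", sep = "")
})
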