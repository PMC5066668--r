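#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom Biostrings XStringSet DNAStringSet QualityScaledXStringSet QualityScaledDNAStringSet
#' @importClassesFrom S4Vectors DataFrame
#' @useDynLib bacplex, .registration = TRUE
NULL

setClassUnion("XStringSetOrNULL", c("XStringSet", "NULL"))

#' Paired sequencing reads
#'
#' Container for a set of read pairs from one library. Mates are stored as two
#' parallel [Biostrings::XStringSet] objects (plain `DNAStringSet` or
#' `QualityScaledDNAStringSet` when Phred qualities are attached); element `i`
#' of `mate1` and `mate2` form pair `i`, and the shared `names()` are the pair
#' identifiers.
#'
#' @slot mate1,mate2 `XStringSet` of identical length and names; forward and
#'   reverse mate of each pair.
#' @slot libraryTag single string identifying the library type, e.g. `"pe"`,
#'   `"mp_miseq"`, `"mp_hiseq"`.
#'
#' @examples
#' rp <- ReadPairs(Biostrings::DNAStringSet(c(p1 = "ACGT")),
#'                 Biostrings::DNAStringSet(c(p1 = "TTGC")))
#' length(rp)
#' @export
setClass("ReadPairs",
  representation(mate1 = "XStringSet", mate2 = "XStringSet",
                 libraryTag = "character"))

setValidity("ReadPairs", function(object) {
  msg <- character()
  if (length(object@mate1) != length(object@mate2))
    msg <- c(msg, "mate1 and mate2 must have the same length")
  if (is.null(names(object@mate1)) && length(object@mate1) > 0)
    msg <- c(msg, "pairs must be named (pair ids)")
  if (!is.null(names(object@mate1)) && anyDuplicated(names(object@mate1)))
    msg <- c(msg, "pair ids must be unique")
  if (!is.null(names(object@mate1)) && !is.null(names(object@mate2)) &&
      !identical(names(object@mate1), names(object@mate2)))
    msg <- c(msg, "mate1 and mate2 must carry identical pair ids")
  if (length(object@libraryTag) != 1L)
    msg <- c(msg, "libraryTag must be a single string")
  if (length(msg)) msg else TRUE
})

#' @param mate1,mate2 `XStringSet` objects of equal length carrying the two
#'   mates; names are pair ids (generated when missing).
#' @param libraryTag library label.
#' @rdname ReadPairs-class
#' @export
ReadPairs <- function(mate1, mate2, libraryTag = "pe") {
  if (is.null(names(mate1))) {
    nm <- sprintf("pair%d", seq_along(mate1))
    names(mate1) <- nm
  }
  names(mate2) <- names(mate1)
  new("ReadPairs", mate1 = mate1, mate2 = mate2, libraryTag = libraryTag)
}

#' Per-clone assembly
#'
#' A set of contigs (or scaffolds) belonging to one BAC clone, together with
#' per-contig annotations accumulated by the post-processing stages: BAC-end
#' flags set when vector sequence was clipped from a contig end, and read-back
#' coverage. `stage` records where in the pipeline the object stands.
#'
#' @slot bacId single string, the clone identifier.
#' @slot contigs `DNAStringSet` of contig sequences, uniquely named.
#' @slot contigData `DataFrame` parallel to `contigs` with columns
#'   `bacEndLeft`, `bacEndRight` (logical) and `coverage` (numeric, `NA` until
#'   computed).
#' @slot stage one of `"raw"`, `"postprocessed"`, `"scaffolded"`.
#' @export
setClass("BacAssembly",
  representation(bacId = "character", contigs = "DNAStringSet",
                 contigData = "DataFrame", stage = "character"))

setValidity("BacAssembly", function(object) {
  msg <- character()
  if (length(object@bacId) != 1L) msg <- c(msg, "bacId must be a single string")
  if (length(object@contigs) > 0 &&
      (is.null(names(object@contigs)) || anyDuplicated(names(object@contigs))))
    msg <- c(msg, "contigs must be uniquely named")
  if (nrow(object@contigData) != length(object@contigs))
    msg <- c(msg, "contigData must be parallel to contigs")
  need <- c("bacEndLeft", "bacEndRight", "coverage")
  if (!all(need %in% colnames(object@contigData)))
    msg <- c(msg, paste("contigData needs columns", paste(need, collapse = ", ")))
  if (!object@stage %in% c("raw", "postprocessed", "scaffolded"))
    msg <- c(msg, "stage must be raw, postprocessed or scaffolded")
  cov <- object@contigData$coverage
  if (any(!is.na(cov) & cov < 0)) msg <- c(msg, "coverage must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @param bacId clone identifier.
#' @param contigs named `DNAStringSet` (or character vector) of contigs.
#' @param stage pipeline stage label.
#' @param bacEndLeft,bacEndRight logical vectors, recycled, marking contigs
#'   whose left/right end abutted vector sequence.
#' @param coverage numeric per-contig read-back coverage (`NA` if unknown).
#' @rdname BacAssembly-class
#' @export
BacAssembly <- function(bacId, contigs, stage = "raw",
                        bacEndLeft = FALSE, bacEndRight = FALSE,
                        coverage = NA_real_) {
  if (!is(contigs, "DNAStringSet")) contigs <- Biostrings::DNAStringSet(contigs)
  n <- length(contigs)
  cd <- S4Vectors::DataFrame(bacEndLeft = rep_len(bacEndLeft, n),
                             bacEndRight = rep_len(bacEndRight, n),
                             coverage = rep_len(as.numeric(coverage), n))
  rownames(cd) <- names(contigs)
  new("BacAssembly", bacId = bacId, contigs = contigs, contigData = cd,
      stage = stage)
}
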