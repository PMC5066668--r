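#' Duplicate-pair removal
#'
#' Identifies and discards duplicate read pairs. Two pairs are duplicates
#' when both mates are byte-identical full-length sequences; the first
#' occurrence is kept. The duplication rate is `1 - nUnique/nInput` (0 for
#' empty input).
#'
#' @param pairs `ReadPairs`.
#' @return list with `pairs` (unique pairs) and `report` (`nInputPairs`,
#'   `nUniquePairs`, `duplicationRate`).
#' @export
dedupPairs <- function(pairs) {
  key <- paste(as.character(mate1(pairs)), as.character(mate2(pairs)),
               sep = "\r")
  dup <- duplicated(key)
  n <- length(pairs); nu <- sum(!dup)
  list(pairs = pairs[!dup],
       report = data.frame(nInputPairs = n, nUniquePairs = nu,
                           duplicationRate = if (n) 1 - nu / n else 0))
}

#' Nextera junction-adapter clipping
#'
#' Searches each mate for the leftmost occurrence of the junction adapter or
#' its reverse complement, allowing up to `maxMismatch` mismatches, and
#' truncates the read to the bases 5' of the match start (the junction marks
#' the circularization point; bases beyond it belong to the distal fragment
#' end). Mates without a match are unchanged. A mate shorter than
#' `minSurvivorLen` after clipping is dropped, and a pair losing either mate
#' is discarded entirely.
#'
#' @param pairs `ReadPairs`.
#' @param adapterSeq junction adapter sequence (character or `DNAString`).
#' @param maxMismatch allowed mismatches in the adapter match, default 2.
#' @param minSurvivorLen minimum surviving mate length, default 16 bp
#'   (reads longer than 15 bp are kept).
#' @return list with `pairs` (clipped, surviving pairs) and `report`
#'   (`nInputPairs`, `nClippedMates`, `nDroppedPairs`).
#' @export
clipJunction <- function(pairs, adapterSeq, maxMismatch = 2L,
                         minSurvivorLen = 16L) {
  adapterSeq <- as.character(adapterSeq)
  stopifnot(nzchar(adapterSeq))
  rcAdapter <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(adapterSeq)))
  clipTo <- function(reads) {
    ch <- as.character(reads)
    p1 <- leftmost_inexact_match(ch, adapterSeq, as.integer(maxMismatch))
    p2 <- leftmost_inexact_match(ch, rcAdapter, as.integer(maxMismatch))
    pos <- pmin(p1, p2, na.rm = TRUE)  # NA only when neither matches
    cut <- ifelse(is.na(pos), Biostrings::width(reads), pos - 1L)
    list(reads = IRanges::narrow(reads, start = 1L, width = cut),
         clipped = !is.na(pos))
  }
  c1 <- clipTo(mate1(pairs)); c2 <- clipTo(mate2(pairs))
  ok <- Biostrings::width(c1$reads) >= minSurvivorLen &
    Biostrings::width(c2$reads) >= minSurvivorLen
  out <- ReadPairs(c1$reads[ok], c2$reads[ok], libraryTag(pairs))
  list(pairs = out,
       report = data.frame(nInputPairs = length(pairs),
                           nClippedMates = sum(c1$clipped) + sum(c2$clipped),
                           nDroppedPairs = sum(!ok)))
}

#' Mate-pair library preprocessing
#'
#' Fixed preprocessing order for a Nextera mate-pair library: duplicate-pair
#' removal first (duplicates are judged on raw sequence), then junction
#' adapter clipping, then quality trimming and optional host/vector removal
#' reusing the paired-end machinery.
#'
#' @param pairs raw `ReadPairs` (with qualities if trimming is wanted).
#' @param adapterSeq junction adapter.
#' @param vectorSeq,hostSeq optional screens, see [peReadQc()]; reads hitting
#'   either are removed (no cloning-site exception for mate pairs, pass
#'   `cloningSite = NA` to disable the window).
#' @param cloningSite,window see [screenReads()].
#' @inheritParams clipJunction
#' @param errorLimit quality-trim limit; `NULL` skips trimming.
#' @return list with `pairs` and `report` (counts per step).
#' @export
mpPrep <- function(pairs, adapterSeq, maxMismatch = 2L, minSurvivorLen = 16L,
                   errorLimit = 0.05, vectorSeq = NULL, hostSeq = NULL,
                   cloningSite = NA, window = 0L) {
  dd <- dedupPairs(pairs)
  cj <- clipJunction(dd$pairs, adapterSeq, maxMismatch, minSurvivorLen)
  p <- cj$pairs
  if (!is.null(errorLimit) && is(mate1(p), "QualityScaledXStringSet")) {
    t1 <- qualityTrim(mate1(p), errorLimit)
    t2 <- qualityTrim(mate2(p), errorLimit)
    ok <- Biostrings::width(t1) >= minSurvivorLen &
      Biostrings::width(t2) >= minSurvivorLen
    p <- ReadPairs(t1[ok], t2[ok], libraryTag(p))
  }
  if (!is.null(vectorSeq) || !is.null(hostSeq)) {
    nm <- names(p)
    reads <- Biostrings::DNAStringSet(c(
      stats::setNames(Biostrings::DNAStringSet(mate1(p)), paste0(nm, "/1")),
      stats::setNames(Biostrings::DNAStringSet(mate2(p)), paste0(nm, "/2"))))
    vAln <- if (is.null(vectorSeq)) alignmentTable()
            else mapReads(reads, vectorSeq)
    hAln <- if (is.null(hostSeq)) alignmentTable()
            else mapReads(reads, hostSeq)
    v <- screenReads(names(reads), hAln, vAln,
                     cloningSite = if (is.na(cloningSite)) -1e9 else cloningSite,
                     window = window)
    keepV <- c("keep", "keep_vector_near_site")
    p <- p[v[paste0(nm, "/1")] %in% keepV & v[paste0(nm, "/2")] %in% keepV]
  }
  list(pairs = p,
       report = data.frame(nInputPairs = length(pairs),
                           duplicationRate = dd$report$duplicationRate,
                           nClippedMates = cj$report$nClippedMates,
                           nDroppedShort = cj$report$nDroppedPairs,
                           nOutputPairs = length(p)))
}
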