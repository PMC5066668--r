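#' Classify misassembly breakpoints
#'
#' Applies the Plantagora-style rules to reference alignments of an assembly.
#' Alignments shorter than `minAln` are discarded; within each query,
#' alignments are sorted by query start and every boundary between
#' consecutive alignments is a breakpoint. If the two flanks align to
#' different strands the call is global with reason `strand`; otherwise the
#' signed reference separation of the flanks' inner boundaries is computed
#' (positive = gap, negative = overlap): a separation greater than
#' `distThresh` is global (`distance`), an overlap greater than `distThresh`
#' is global (`overlap`), anything else (same strand, at most `distThresh`
#' apart) is a local misassembly. Queries with a single alignment yield no
#' calls.
#'
#' @param aln [alignmentTable()] of assembly sequences against a reference.
#' @param minAln minimum alignment length in bp, default 100.
#' @param distThresh distance/overlap threshold in bp, default 1000 (strict:
#'   exactly 1000 bp apart is still local).
#' @return list with `calls` (`data.frame`: `queryId`, `queryPosition`,
#'   `klass`, `reason`) and `summary` (`nGlobal`, `nLocal`).
#' @export
classifyMisassemblies <- function(aln, minAln = 100L, distThresh = 1000L) {
  a <- aln[aln$alnLen >= minAln, , drop = FALSE]
  calls <- list()
  for (q in unique(a$qname)) {
    x <- a[a$qname == q, , drop = FALSE]
    x <- x[order(x$qstart), , drop = FALSE]
    if (nrow(x) < 2L) next
    for (i in seq_len(nrow(x) - 1L)) {
      L <- x[i, ]; R <- x[i + 1L, ]
      if (L$strand != R$strand) {
        klass <- "global"; reason <- "strand"; sep <- NA_real_
      } else {
        sep <- if (L$strand == "+") R$tstart - L$tend else L$tstart - R$tend
        if (sep > distThresh) { klass <- "global"; reason <- "distance" }
        else if (-sep > distThresh) { klass <- "global"; reason <- "overlap" }
        else { klass <- "local"; reason <- if (sep >= 0) "distance" else "overlap" }
      }
      calls[[length(calls) + 1]] <-
        data.frame(queryId = q, queryPosition = L$qend, klass = klass,
                   reason = reason, separation = sep)
    }
  }
  calls <- if (length(calls)) do.call(rbind, calls)
           else data.frame(queryId = character(), queryPosition = integer(),
                           klass = character(), reason = character(),
                           separation = numeric())
  list(calls = calls,
       summary = data.frame(nGlobal = sum(calls$klass == "global"),
                            nLocal = sum(calls$klass == "local")))
}

#' Genome fraction
#'
#' Percentage of a reference covered by at least one assembly alignment
#' (union of covered reference intervals).
#'
#' @param aln [alignmentTable()] targeting a single reference sequence.
#' @param referenceLength length of the reference in bp (> 0).
#' @return percentage in `[0, 100]`.
#' @export
genomeFraction <- function(aln, referenceLength) {
  if (referenceLength <= 0) stop("reference length must be positive")
  if (!nrow(aln)) return(0)
  if (length(unique(aln$tname)) > 1L)
    stop("alignments must target a single reference")
  cov <- IRanges::reduce(IRanges::IRanges(aln$tstart + 1L, aln$tend))
  100 * sum(BiocGenerics::width(cov)) / referenceLength
}

#' Canonical k-mer index
#'
#' Tallies canonical k-mers (lexicographic minimum of a k-mer and its
#' reverse complement) across a set of sequences; k-mers containing
#' ambiguous bases are skipped. Used as the abundance index for
#' [kmerMask()].
#'
#' @param seqs `DNAStringSet`.
#' @param k k-mer size, default 21.
#' @return `data.table` with columns `kmer`, `count`.
#' @export
buildKmerIndex <- function(seqs, k = 21L) {
  all <- lapply(seq_along(seqs), function(i) .canonicalKmers(seqs[[i]], k))
  dt <- data.table::data.table(kmer = unlist(all, use.names = FALSE))
  dt <- dt[!is.na(dt$kmer)]
  dt[, list(count = .N), by = "kmer"]
}

.canonicalKmers <- function(seq, k) {
  ch <- as.character(seq)
  n <- nchar(ch)
  if (n < k) return(character())
  starts <- seq_len(n - k + 1L)
  fwd <- substring(ch, starts, starts + k - 1L)
  rcch <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(ch)))
  rstarts <- n - k + 1L - starts + 1L
  rev <- substring(rcch, rstarts, rstarts + k - 1L)
  canon <- ifelse(fwd <= rev, fwd, rev)
  canon[grepl("[^ACGT]", fwd)] <- NA_character_
  canon
}

#' K-mer repeat masking
#'
#' Masks the repetitive portion of a sequence: a base is masked when at
#' least one k-mer overlapping it has abundance of at least `minCount` in
#' the reference k-mer index. Maximal masked runs are merged into intervals.
#' Sequences shorter than k yield no intervals and fraction 0.
#'
#' @param seq single sequence (`DNAString`/character).
#' @param kmerIndex index from [buildKmerIndex()] (columns `kmer`, `count`).
#' @param k k-mer size (must match the index), default 21.
#' @param minCount abundance threshold.
#' @return list with `intervals` (`data.frame` of 0-based half-open
#'   `start`, `end`, sorted and disjoint) and `maskedFraction`.
#' @export
kmerMask <- function(seq, kmerIndex, k = 21L, minCount) {
  ch <- as.character(seq)
  n <- nchar(ch)
  empty <- list(intervals = data.frame(start = integer(), end = integer()),
                maskedFraction = 0)
  if (n < k) return(empty)
  canon <- .canonicalKmers(Biostrings::DNAString(ch), k)
  cnt <- kmerIndex$count[match(canon, kmerIndex$kmer)]
  hot <- which(!is.na(cnt) & cnt >= minCount)
  if (!length(hot)) return(empty)
  ir <- IRanges::reduce(IRanges::IRanges(hot, hot + k - 1L))
  list(intervals = data.frame(start = BiocGenerics::start(ir) - 1L,
                              end = BiocGenerics::end(ir)),
       maskedFraction = sum(BiocGenerics::width(ir)) / n)
}

#' Identity-stratified overlap of masked repeats
#'
#' For each identity threshold, the fraction of repeat-masked bases covered
#' by at least one alignment with identity at or above the threshold. The
#' result is non-increasing in the threshold. With zero masked bases all
#' fractions are reported as 0 and `undefined` is flagged.
#'
#' @param masked result of [kmerMask()] (or any list with an `intervals`
#'   data.frame of 0-based half-open `start`, `end`).
#' @param aln [alignmentTable()] of, e.g., whole-genome-shotgun contigs
#'   against the masked sequence (target coordinates on that sequence).
#' @param thresholds identity thresholds in percent, default `80:99`.
#' @return `data.frame` with `threshold`, `fraction`, and attribute-free
#'   column `undefined` (constant flag).
#' @export
repeatOverlapFraction <- function(masked, aln, thresholds = 80:99) {
  iv <- masked$intervals
  mIr <- IRanges::IRanges(iv$start + 1L, iv$end)
  mTot <- sum(BiocGenerics::width(mIr))
  undef <- mTot == 0
  frac <- vapply(thresholds, function(t) {
    if (undef) return(0)
    a <- aln[aln$identity >= t / 100, , drop = FALSE]
    if (!nrow(a)) return(0)
    cov <- IRanges::reduce(IRanges::IRanges(a$tstart + 1L, a$tend))
    sum(BiocGenerics::width(IRanges::intersect(mIr, cov))) / mTot
  }, 0)
  data.frame(threshold = thresholds, fraction = frac, undefined = undef)
}

#' Export masked intervals as BED
#'
#' @param masked result of [kmerMask()].
#' @param seqId sequence name for the BED records.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeMaskBed <- function(masked, seqId, path) {
  iv <- masked$intervals
  lines <- sprintf("%s\t%d\t%d", seqId, iv$start, iv$end)
  writeLines(lines, path)
  invisible(path)
}
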