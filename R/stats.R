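#' Assembly summary statistics
#'
#' Computes the standard per-assembly summary used for BAC projects:
#' number of sequences, total length, L50, largest sequence, and the length
#' contained in sequences of at least 1 kb and at least 10 kb (inclusive
#' thresholds).
#'
#' The L50 is the maximum value L such that 50% of the assembly length is
#' contained in sequences whose size is greater than or equal to L. An empty
#' input yields all-zero statistics.
#'
#' @param x `DNAStringSet`, `BacAssembly`, or numeric vector of lengths.
#' @return one-row `data.frame` with columns `nSequences`, `totalLen`, `l50`,
#'   `largest`, `lenGe1kb`, `lenGe10kb`.
#' @examples
#' assemblyStats(c(50, 30, 20))$l50  # 50
#' @export
assemblyStats <- function(x) {
  len <- if (is(x, "BacAssembly")) Biostrings::width(contigs(x))
         else if (is(x, "XStringSet")) Biostrings::width(x)
         else as.numeric(x)
  stopifnot(all(len >= 1) || length(len) == 0)
  data.frame(nSequences = length(len), totalLen = sum(len), l50 = l50(len),
             largest = if (length(len)) max(len) else 0,
             lenGe1kb = sum(len[len >= 1000]),
             lenGe10kb = sum(len[len >= 10000]))
}

#' @rdname assemblyStats
#' @param lengths numeric vector of sequence lengths.
#' @export
l50 <- function(lengths) {
  if (!length(lengths)) return(0)
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' Multiplex sequencing depth arithmetic
#'
#' Per-clone bookkeeping for a multiplexed BAC lane: the mean number of reads
#' assigned per clone and the implied mean read depth over the genomic
#' insert.
#'
#' @param totalReads total reads deconvoluted across the lane.
#' @param nBacs number of multiplexed clones.
#' @param readLen read length in bp.
#' @param insertSize mean genomic insert size in bp.
#' @return list with `readsPerBac` and `meanDepth`.
#' @examples
#' multiplexDepth(417613642, 668, 100, 145000)
#' @export
multiplexDepth <- function(totalReads, nBacs, readLen, insertSize) {
  rpb <- totalReads / nBacs
  list(readsPerBac = rpb, meanDepth = rpb * readLen / insertSize)
}

#' Removal and retention fractions
#'
#' @param nBefore,nRemoved counts before filtering and removed by it.
#' @return percentage removed.
#' @export
removalPercent <- function(nBefore, nRemoved) 100 * nRemoved / nBefore

#' Write a per-stage assembly statistics report
#'
#' One TSV row per assembly with columns `bac_id`, `stage`, `n_sequences`,
#' `total_len`, `l50`, `largest`, `len_ge_1kb`, `len_ge_10kb`.
#'
#' @param assemblies list of `BacAssembly`.
#' @param path output TSV path.
#' @return the table, invisibly.
#' @export
writeStatsReport <- function(assemblies, path) {
  rows <- lapply(assemblies, function(a) {
    st <- assemblyStats(a)
    data.frame(bac_id = bacId(a), stage = stage(a),
               n_sequences = st$nSequences, total_len = st$totalLen,
               l50 = st$l50, largest = st$largest,
               len_ge_1kb = st$lenGe1kb, len_ge_10kb = st$lenGe10kb)
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}
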