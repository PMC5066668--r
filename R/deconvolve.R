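#' Deconvolute mate pairs onto clones
#'
#' Assigns unbarcoded read pairs to individual BACs from their mapping
#' against the concatenated set of per-clone assemblies. A pair is assigned
#' to clone `b` only when every best-scoring alignment of each mate lies on
#' contigs of `b` and neither mate is tied (mapping quality >= 1; the
#' internal mapper reports mapq 0 for tied best hits, mirroring BWA-MEM
#' semantics where mapq 0 means multi-mapped). Otherwise the pair is left
#' unassigned with a reason: a mate without hits gives `unmapped`, a tied
#' mate gives `ambiguous`, and untied mates pointing at different clones give
#' `cross_bac`.
#'
#' @param pairIds character vector of all pair ids (every id receives exactly
#'   one row in the result).
#' @param aln1,aln2 [alignmentTable()]s of mate 1 and mate 2 against the
#'   concatenated assemblies, with `qname` equal to the pair id.
#' @param contig2bac named character vector mapping contig (target) id to
#'   clone id; must cover every aligned target.
#' @return `data.frame` with columns `pairId`, `bacId` (`NA` unless unique)
#'   and `reason` (`unique`, `ambiguous`, `cross_bac`, `unmapped`).
#' @export
assignPairs <- function(pairIds, aln1, aln2, contig2bac) {
  mateState <- function(aln) {
    # per pair id: "bac" if uniquely placed (value = clone), "tied", or absent
    if (!nrow(aln))
      return(data.frame(pairId = character(), bac = character(),
                        tied = logical()))
    bac <- contig2bac[aln$tname]
    if (anyNA(bac))
      stop("alignment target missing from contig->bac map: ",
           aln$tname[which(is.na(bac))[1]])
    dt <- data.table::data.table(pairId = aln$qname, bac = bac,
                                 score = aln$score, mapq = aln$mapq)
    dt[, .best := score == max(score), by = "pairId"]
    b <- dt[dt$.best == TRUE,
            list(tied = any(mapq < 1L) | length(unique(bac)) > 1L,
                 bac = bac[1]), by = "pairId"]
    as.data.frame(b[, c("pairId", "bac", "tied")])
  }
  s1 <- mateState(aln1); s2 <- mateState(aln2)
  i1 <- match(pairIds, s1$pairId); i2 <- match(pairIds, s2$pairId)
  reason <- character(length(pairIds))
  bacOut <- rep(NA_character_, length(pairIds))
  unmapped <- is.na(i1) | is.na(i2)
  tied <- !unmapped & (s1$tied[i1] | s2$tied[i2])
  same <- !unmapped & !tied & s1$bac[i1] == s2$bac[i2]
  reason[unmapped] <- "unmapped"
  reason[tied] <- "ambiguous"
  reason[!unmapped & !tied & !same] <- "cross_bac"
  reason[same] <- "unique"
  bacOut[same] <- s1$bac[i1[same]]
  data.frame(pairId = pairIds, bacId = bacOut, reason = reason)
}

#' Insert-size estimation
#'
#' Estimates the library insert size from high-quality pairs: only pairs
#' whose mates map to the same contig with mapping quality at least
#' `minMapq` on both mates are used. The span of a pair is the distance from
#' its smallest to its largest outer coordinate on the shared contig; the
#' library standard deviation is set to 50% of the mean span.
#'
#' @param aln1,aln2 best-hit [alignmentTable()]s (one row per pair id).
#' @param minMapq mapping-quality filter, default 40.
#' @param libraryTag label stored in the result.
#' @return list with `libraryTag`, `insertMean`, `insertSd`
#'   (`= 0.5 * insertMean`), `nPairsUsed`, `orientation`.
#' @export
estimateInsert <- function(aln1, aln2, minMapq = 40L, libraryTag = "mp") {
  j <- merge(aln1, aln2, by = "qname", suffixes = c(".1", ".2"))
  q <- j[j$tname.1 == j$tname.2 & j$mapq.1 >= minMapq & j$mapq.2 >= minMapq, ,
         drop = FALSE]
  if (!nrow(q)) stop("no qualifying pairs for insert-size estimation")
  span <- pmax(q$tend.1, q$tend.2) - pmin(q$tstart.1, q$tstart.2)
  m <- mean(span)
  list(libraryTag = libraryTag, insertMean = m, insertSd = 0.5 * m,
       nPairsUsed = nrow(q), orientation = "inward")
}
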