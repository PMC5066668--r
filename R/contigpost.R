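#' Clip vector sequence off contig ends
#'
#' Vector hits intersecting the first or last `endZone` bp of a contig are
#' clipped off together with everything between the hit and that contig end,
#' and the corresponding BAC-end flag is raised (the clipped end marks the
#' boundary of the genomic insert). Hits entirely interior to the contig are
#' left untouched but reported as warnings. A contig clipped away completely
#' is removed.
#'
#' @param assembly `BacAssembly`.
#' @param vectorHits hit table with columns `tname`, `tstart`, `tend`
#'   (0-based half-open on the contig), e.g. from [tileMap()] of the vector
#'   against the contigs.
#' @param endZone size of the terminal zone in bp, default 1000.
#' @return list with `assembly` (clipped) and `report` (per input contig:
#'   `id`, `lenBefore`, `lenAfter`, `clippedLeft`, `clippedRight`, `removed`).
#' @export
clipVector <- function(assembly, vectorHits, endZone = 1000L) {
  ctg <- contigs(assembly)
  len <- Biostrings::width(ctg)
  ids <- names(ctg)
  clipL <- integer(length(ctg)); clipR <- len
  endL <- logical(length(ctg)); endR <- logical(length(ctg))
  for (i in seq_along(ctg)) {
    h <- vectorHits[vectorHits$tname == ids[i], , drop = FALSE]
    if (!nrow(h)) next
    left <- h$tstart < endZone
    right <- h$tend > len[i] - endZone
    internal <- !left & !right
    if (any(internal))
      warning("internal vector hit left unclipped on contig ", ids[i])
    both <- left & right
    nearerLeft <- h$tstart <= len[i] - h$tend
    left[both] <- nearerLeft[both]
    right[both] <- !nearerLeft[both]
    if (any(left)) { clipL[i] <- max(h$tend[left]); endL[i] <- TRUE }
    if (any(right)) { clipR[i] <- min(h$tstart[right]); endR[i] <- TRUE }
  }
  newLen <- pmax(clipR - clipL, 0L)
  keep <- newLen >= 1L
  newSeq <- Biostrings::subseq(ctg[keep], start = clipL[keep] + 1L,
                               width = newLen[keep])
  out <- BacAssembly(bacId(assembly), newSeq, stage = stage(assembly),
                     bacEndLeft = endL[keep], bacEndRight = endR[keep],
                     coverage = contigData(assembly)$coverage[keep])
  report <- data.frame(id = ids, lenBefore = len,
                       lenAfter = ifelse(keep, newLen, 0L),
                       clippedLeft = clipL, clippedRight = len - clipR,
                       removed = !keep)
  list(assembly = out, report = report)
}

#' Length filter
#'
#' Retains contigs with length at least `minLen` (inclusive), preserving
#' order.
#'
#' @param assembly `BacAssembly`.
#' @param minLen minimum length in bp, default 500.
#' @return filtered `BacAssembly`.
#' @export
filterLength <- function(assembly, minLen = 500L) {
  assembly[Biostrings::width(contigs(assembly)) >= minLen]
}

#' Read-back contig coverage
#'
#' Coverage of a contig is the summed full length of all reads whose best
#' mapping hit lies on that contig, divided by the contig length; contigs
#' that attract no reads get coverage 0. Best hits should come from
#' [bestHits()] over a mapping of the clone's cleaned reads against this
#' contig set.
#'
#' @param assembly `BacAssembly`.
#' @param best one-best-hit-per-read [alignmentTable()].
#' @param readLengths named vector of full read lengths.
#' @return `BacAssembly` with the `coverage` column filled in.
#' @export
contigCoverage <- function(assembly, best, readLengths) {
  ids <- names(contigs(assembly))
  cov <- stats::setNames(numeric(length(ids)), ids)
  if (nrow(best)) {
    rl <- readLengths[best$qname]
    if (anyNA(rl)) stop("read length missing for some mapped reads")
    s <- rowsum(as.numeric(rl), group = best$tname)
    hit <- intersect(rownames(s), ids)
    cov[hit] <- s[hit, 1]
  }
  cov <- cov / Biostrings::width(contigs(assembly))
  a <- assembly
  a@contigData$coverage <- as.numeric(cov)
  methods::validObject(a)
  a
}

#' Trimmed-mean coverage filter
#'
#' Removes probable cross-contamination: the `trimFrac` fraction (floor) of
#' contigs with the lowest coverage is set aside, the arithmetic mean
#' coverage of the remaining contigs is computed, and every contig --
#' including the set-aside ones -- is retained only if its coverage is at
#' least `safety * halfFactor * mean`. With the defaults the threshold is
#' half the trimmed-mean coverage; `safety = 0.9` gives the more permissive
#' variant (90% of half the average).
#'
#' @param assembly `BacAssembly` with coverage set on all contigs.
#' @param trimFrac fraction of lowest-coverage contigs excluded from the
#'   averaging set, default 0.10.
#' @param halfFactor,safety threshold factors, defaults 0.5 and 1.0.
#' @return list with `assembly` (retained contigs), `threshold`, and
#'   `removed` (ids of discarded contigs).
#' @export
coverageFilter <- function(assembly, trimFrac = 0.10, halfFactor = 0.5,
                           safety = 1.0) {
  cov <- contigData(assembly)$coverage
  if (length(cov) == 0L) stop("coverage filter on empty assembly")
  if (anyNA(cov)) stop("coverage not set on all contigs")
  ids <- names(contigs(assembly))
  nTrim <- floor(trimFrac * length(cov))
  o <- order(cov, ids)
  avgSet <- o[seq_len(length(cov) - nTrim) + nTrim]
  m <- mean(cov[avgSet])
  thr <- safety * halfFactor * m
  keep <- cov >= thr
  list(assembly = assembly[keep], threshold = thr, removed = ids[!keep])
}

#' Contaminant screen of contigs
#'
#' Applies qualifying contaminant hits (identity at least `minIdentity` and
#' length at least `minLen`): a hit intersecting a terminal `endZone` clips
#' the contig to the hit's inner boundary; a fully internal qualifying hit
#' removes the whole contig; and any contig shorter than `minContigLen`
#' after clipping is removed.
#'
#' @param assembly `BacAssembly`.
#' @param contamHits hit table (`tname`, `tstart`, `tend`, `identity`), e.g.
#'   from [tileMap()] of known contaminants against the contigs.
#' @param minIdentity,minLen qualifying thresholds (0.90, 100 bp).
#' @param minContigLen minimum surviving contig length, default 500 bp.
#' @param endZone terminal zone in bp, default 1000.
#' @return list with `assembly` and `report` (per input contig: `id`,
#'   `lenBefore`, `lenAfter`, `action` in kept/clipped/contaminant/short).
#' @export
contaminantScreen <- function(assembly, contamHits, minIdentity = 0.90,
                              minLen = 100L, minContigLen = 500L,
                              endZone = 1000L) {
  h <- contamHits[contamHits$identity >= minIdentity &
                    (contamHits$tend - contamHits$tstart) >= minLen, ,
                  drop = FALSE]
  ctg <- contigs(assembly)
  len <- Biostrings::width(ctg)
  ids <- names(ctg)
  action <- rep("kept", length(ctg))
  clipL <- integer(length(ctg)); clipR <- len
  for (i in seq_along(ctg)) {
    hi <- h[h$tname == ids[i], , drop = FALSE]
    if (!nrow(hi)) next
    left <- hi$tstart < endZone
    right <- hi$tend > len[i] - endZone
    if (any(!left & !right)) { action[i] <- "contaminant"; next }
    # a hit inside both zones (short contig) clips toward its nearer end
    both <- left & right
    nearerLeft <- hi$tstart <= len[i] - hi$tend
    left[both] <- nearerLeft[both]
    right[both] <- !nearerLeft[both]
    if (any(left)) clipL[i] <- max(hi$tend[left])
    if (any(right)) clipR[i] <- min(hi$tstart[right])
    action[i] <- "clipped"
  }
  newLen <- pmax(clipR - clipL, 0L)
  # terminal hits covering the whole contig leave nothing: that is a
  # contaminant contig, not a clipping casualty
  action[action == "clipped" & newLen == 0L] <- "contaminant"
  short <- action != "contaminant" & newLen < minContigLen
  action[short & action == "clipped"] <- "short"
  # an unclipped contig cannot become short here (length filter ran before)
  keep <- action %in% c("kept", "clipped") & newLen >= minContigLen
  newSeq <- Biostrings::subseq(ctg[keep], start = clipL[keep] + 1L,
                               width = newLen[keep])
  out <- BacAssembly(bacId(assembly), newSeq, stage = stage(assembly),
                     bacEndLeft = contigData(assembly)$bacEndLeft[keep],
                     bacEndRight = contigData(assembly)$bacEndRight[keep],
                     coverage = contigData(assembly)$coverage[keep])
  report <- data.frame(id = ids, lenBefore = len,
                       lenAfter = ifelse(keep, newLen, 0L),
                       clippedLeft = clipL, clippedRight = len - clipR,
                       action = action)
  list(assembly = out, report = report)
}

#' Post-process a raw per-clone assembly
#'
#' Runs the fixed post-processing cascade on a raw contig set: vector
#' clipping with BAC-end flagging, length filter, read-back coverage
#' (mapping the clone's cleaned reads with the internal mapper, or using
#' supplied alignments), trimmed-mean coverage filter, contaminant screen,
#' and a final length filter.
#'
#' @param assembly raw `BacAssembly`.
#' @param reads cleaned reads of this clone (`ReadPairs` or `DNAStringSet`).
#' @param vectorSeq cloning-vector `DNAStringSet` (or `NULL` to skip).
#' @param contaminantSeqs known-contaminant `DNAStringSet` (or `NULL`).
#' @param readAln optional externally produced [alignmentTable()] of the
#'   reads against the *clipped, length-filtered* contigs; when `NULL` the
#'   internal mapper is used.
#' @param trimFrac,halfFactor,safety coverage-filter parameters.
#' @param minContigLen length filter in bp, default 500.
#' @param endZone terminal zone for clipping, default 1000 bp.
#' @param seedLen internal mapper seed length.
#' @return list with `assembly` (stage `postprocessed`), `threshold`, and
#'   `report` (per-contig `id`, `lenBefore`, `lenAfter`, `coverage`,
#'   `threshold`, `action` in kept/clipped/low_coverage/contaminant/short).
#' @export
postprocessAssembly <- function(assembly, reads, vectorSeq = NULL,
                                contaminantSeqs = NULL, readAln = NULL,
                                trimFrac = 0.10, halfFactor = 0.5,
                                safety = 1.0, minContigLen = 500L,
                                endZone = 1000L, seedLen = 21L) {
  ids0 <- names(contigs(assembly))
  len0 <- stats::setNames(Biostrings::width(contigs(assembly)), ids0)
  act <- stats::setNames(rep("kept", length(ids0)), ids0)
  clipL <- stats::setNames(integer(length(ids0)), ids0)
  clipR <- stats::setNames(integer(length(ids0)), ids0)

  vHits <- if (is.null(vectorSeq)) alignmentTable()[, c("tname", "tstart", "tend")]
           else tileMap(vectorSeq, contigs(assembly))
  cv <- clipVector(assembly, vHits, endZone)
  clipL[cv$report$id] <- clipL[cv$report$id] + cv$report$clippedLeft
  clipR[cv$report$id] <- clipR[cv$report$id] + cv$report$clippedRight
  act[cv$report$id[cv$report$removed]] <- "short"
  clipped <- cv$report$id[!cv$report$removed &
                            (cv$report$clippedLeft > 0 | cv$report$clippedRight > 0)]
  act[clipped] <- "clipped"
  a <- filterLength(cv$assembly, minContigLen)
  act[setdiff(names(contigs(cv$assembly)), names(contigs(a)))] <- "short"

  rds <- if (is(reads, "ReadPairs")) {
    Biostrings::DNAStringSet(c(
      stats::setNames(Biostrings::DNAStringSet(mate1(reads)),
                      paste0(names(reads), "/1")),
      stats::setNames(Biostrings::DNAStringSet(mate2(reads)),
                      paste0(names(reads), "/2"))))
  } else Biostrings::DNAStringSet(reads)
  aln <- if (is.null(readAln)) mapReads(rds, contigs(a), seedLen) else readAln
  best <- bestHits(aln)
  a <- contigCoverage(a, best, stats::setNames(Biostrings::width(rds), names(rds)))
  covAll <- stats::setNames(rep(NA_real_, length(ids0)), ids0)
  covAll[names(contigs(a))] <- contigData(a)$coverage

  cf <- coverageFilter(a, trimFrac, halfFactor, safety)
  act[cf$removed] <- "low_coverage"
  a <- cf$assembly

  cHits <- if (is.null(contaminantSeqs)) NULL
           else tileMap(contaminantSeqs, contigs(a))
  if (!is.null(cHits)) {
    cs <- contaminantScreen(a, cHits, minContigLen = minContigLen,
                            endZone = endZone)
    bad <- cs$report$action %in% c("contaminant", "short")
    act[cs$report$id[bad]] <- cs$report$action[bad]
    act[cs$report$id[cs$report$action == "clipped"]] <- "clipped"
    clipL[cs$report$id] <- clipL[cs$report$id] + cs$report$clippedLeft
    clipR[cs$report$id] <- clipR[cs$report$id] + cs$report$clippedRight
    a <- cs$assembly
  }
  aFinal <- filterLength(a, minContigLen)
  act[setdiff(names(contigs(a)), names(contigs(aFinal)))] <- "short"
  a <- aFinal
  a@stage <- "postprocessed"

  lenAfter <- stats::setNames(rep(0L, length(ids0)), ids0)
  lenAfter[names(contigs(a))] <- Biostrings::width(contigs(a))
  report <- data.frame(id = ids0, lenBefore = as.integer(len0),
                       lenAfter = as.integer(lenAfter),
                       clippedLeft = as.integer(clipL),
                       clippedRight = as.integer(clipR),
                       coverage = as.numeric(covAll),
                       threshold = cf$threshold, action = unname(act))
  list(assembly = a, threshold = cf$threshold, report = report)
}
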