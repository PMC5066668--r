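#' Lightweight internal read mapper
#'
#' Seed-and-extend mapper used by all screening, coverage and deconvolution
#' steps when no external SAM/PAF alignments are supplied. Exact `seedLen`-mer
#' seeds are taken from up to three positions of each query (both strands) and
#' located in the targets with [Biostrings::matchPDict]; every distinct
#' implied placement is scored by ungapped comparison of the query against the
#' target window (compiled kernel), and placements whose identity falls below
#' `minIdentity` are suppressed.
#'
#' Mapping quality is synthetic, reflecting only uniqueness: the single best
#' scoring placement of a query gets `mapq` 60; if the best score is tied
#' across two or more placements all tied hits get `mapq` 0; sub-optimal hits
#' also get 0. `score` is the number of matching bases. Queries shorter than
#' `seedLen`, or without any exact seed hit, yield no alignments.
#'
#' @param queries,targets `DNAStringSet` (quality-scaled accepted); targets
#'   must be non-empty and named.
#' @param seedLen exact seed length (default 21 bp).
#' @param minIdentity minimum identity of reported hits, default 0.9.
#' @return [alignmentTable()] `data.frame`.
#' @examples
#' t <- Biostrings::DNAStringSet(c(chr = paste(rep("ACGTT", 60), collapse = "")))
#' q <- Biostrings::DNAStringSet(c(r1 = substr(as.character(t), 11, 60)))
#' mapReads(q, t)
#' @export
mapReads <- function(queries, targets, seedLen = 21L, minIdentity = 0.9) {
  stopifnot(length(targets) > 0)
  if (is.null(names(targets))) stop("targets must be named")
  if (is.null(names(queries)))
    names(queries) <- sprintf("q%d", seq_along(queries))
  qnames <- names(queries)
  w <- Biostrings::width(queries)
  keep <- which(w >= seedLen)
  if (!length(keep) || length(queries) == 0L) return(alignmentTable())

  qchar <- as.character(queries)
  rcchar <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(queries)))
  tchar <- as.character(targets)
  tlen <- nchar(tchar)

  # seed table: three anchor offsets per query and strand
  offs <- function(wi) unique(c(1L, (wi - seedLen) %/% 2L + 1L, wi - seedLen + 1L))
  offL <- lapply(w[keep], offs)
  nOff <- lengths(offL)
  qidx <- rep(keep, nOff)
  off1 <- unlist(offL)
  seedTab <- data.table::data.table(
    qidx = c(qidx, qidx),
    strand = rep(c("+", "-"), each = length(qidx)),
    off = c(off1, off1))
  src <- ifelse(seedTab$strand == "+", qchar[seedTab$qidx], rcchar[seedTab$qidx])
  seedStr <- substring(src, seedTab$off, seedTab$off + seedLen - 1L)
  ok <- !grepl("[^ACGT]", seedStr)
  seedTab <- seedTab[ok]
  seedStr <- seedStr[ok]
  if (!nrow(seedTab)) return(alignmentTable())
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seedStr))

  cand <- vector("list", length(targets))
  for (ti in seq_along(targets)) {
    m <- Biostrings::matchPDict(pd, targets[[ti]])
    cnt <- S4Vectors::elementNROWS(m)
    hit <- which(cnt > 0L)
    if (!length(hit)) next
    starts <- unlist(Biostrings::startIndex(m)[hit], use.names = FALSE)
    pat <- rep.int(hit, cnt[hit])
    cand[[ti]] <- data.table::data.table(
      qidx = seedTab$qidx[pat], strand = seedTab$strand[pat],
      tidx = ti, rstart = starts - (seedTab$off[pat] - 1L))
  }
  cand <- data.table::rbindlist(cand)
  if (!nrow(cand)) return(alignmentTable())
  cand <- unique(cand)

  wq <- w[cand$qidx]
  s1 <- pmax(cand$rstart, 1L)
  e1 <- pmin(cand$rstart + wq - 1L, tlen[cand$tidx])
  ov <- e1 - s1 + 1L
  sel <- ov >= seedLen
  cand <- cand[sel]; wq <- wq[sel]; s1 <- s1[sel]; e1 <- e1[sel]; ov <- ov[sel]
  if (!nrow(cand)) return(alignmentTable())

  roff <- s1 - cand$rstart + 1L
  src <- ifelse(cand$strand == "+", qchar[cand$qidx], rcchar[cand$qidx])
  rsub <- substring(src, roff, roff + ov - 1L)
  tsub <- substring(tchar[cand$tidx], s1, e1)
  matches <- pair_match_count(rsub, tsub)
  ident <- matches / ov
  sel <- ident >= minIdentity
  if (!any(sel)) return(alignmentTable())
  cand <- cand[sel]; wq <- wq[sel]; s1 <- s1[sel]; e1 <- e1[sel]; ov <- ov[sel]
  roff <- roff[sel]; matches <- matches[sel]; ident <- ident[sel]

  qs <- ifelse(cand$strand == "+", roff - 1L, wq - (roff - 1L + ov))
  qe <- qs + ov
  aln <- data.table::data.table(
    qname = qnames[cand$qidx], tname = names(targets)[cand$tidx],
    qstart = as.integer(qs), qend = as.integer(qe),
    tstart = s1 - 1L, tend = e1,
    strand = cand$strand, matches = as.integer(matches),
    alnLen = as.integer(ov), identity = ident, score = as.numeric(matches))
  best <- aln[, list(bestScore = max(score), nBest = sum(score == max(score))),
              by = "qname"]
  aln <- best[aln, on = "qname"]
  aln$mapq <- ifelse(aln$score == aln$bestScore & aln$nBest == 1L, 60L, 0L)
  data.table::setorder(aln, qname, tname, tstart)
  alignmentTable(qname = aln$qname, tname = aln$tname,
                 qstart = aln$qstart, qend = aln$qend,
                 tstart = aln$tstart, tend = aln$tend,
                 strand = aln$strand, matches = aln$matches,
                 alnLen = aln$alnLen, identity = aln$identity,
                 mapq = aln$mapq, score = aln$score)
}

#' Best hit per query
#'
#' Selects, for every query present in `aln`, the alignment with maximal
#' score; ties are broken by lexicographic target id, then smallest target
#' start. Queries without hits are simply absent from the result.
#'
#' @param aln [alignmentTable()] `data.frame`.
#' @return one row per query, same columns as `aln`.
#' @export
bestHits <- function(aln) {
  if (!nrow(aln)) return(aln)
  dt <- data.table::as.data.table(aln)
  data.table::setorder(dt, qname, -score, tname, tstart)
  as.data.frame(dt[!duplicated(dt$qname)])
}

#' Locate a long reference on contigs by window tiling
#'
#' Finds local occurrences of a (possibly long) reference sequence, e.g. the
#' cloning vector or a contaminant, on a set of contigs. The reference is cut
#' into overlapping windows which are mapped individually with [mapReads()];
#' windows passing `minIdentity` are merged per contig into maximal hit
#' intervals.
#'
#' @param ref single reference sequence (`DNAStringSet` of length >= 1; all
#'   elements are tiled).
#' @param targets named `DNAStringSet` of contigs.
#' @param window,step tiling window size and stride in bp.
#' @param minIdentity per-window identity threshold.
#' @return `data.frame` with columns `tname`, `tstart`, `tend` (0-based
#'   half-open on the contig), `identity` (match-weighted mean across merged
#'   windows).
#' @export
tileMap <- function(ref, targets, window = 500L, step = 250L,
                    minIdentity = 0.9) {
  if (!is(ref, "DNAStringSet")) ref <- Biostrings::DNAStringSet(ref)
  tiles <- list()
  for (i in seq_along(ref)) {
    L <- Biostrings::width(ref)[i]
    if (L < window) starts <- 1L
    else starts <- unique(c(seq(1L, L - window + 1L, by = step), L - window + 1L))
    tl <- Biostrings::DNAStringSet(substring(as.character(ref[[i]]), starts,
                                             pmin(starts + window - 1L, L)))
    names(tl) <- sprintf("tile_%d_%d", i, starts)
    tiles[[i]] <- tl
  }
  tiles <- do.call(c, tiles)
  aln <- mapReads(tiles, targets, minIdentity = minIdentity)
  if (!nrow(aln)) {
    return(data.frame(tname = character(), tstart = integer(),
                      tend = integer(), identity = numeric()))
  }
  out <- lapply(split(aln, aln$tname), function(a) {
    ir <- IRanges::reduce(IRanges::IRanges(a$tstart + 1L, a$tend))
    hits <- IRanges::findOverlaps(IRanges::IRanges(a$tstart + 1L, a$tend), ir)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    idw <- rowsum(as.numeric(a$matches[qh]), sh)[, 1] /
      rowsum(as.numeric(a$alnLen[qh]), sh)[, 1]
    data.frame(tname = a$tname[1], tstart = BiocGenerics::start(ir) - 1L,
               tend = BiocGenerics::end(ir), identity = as.numeric(idw))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
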