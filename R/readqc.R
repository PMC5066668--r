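#' Quality trimming (modified-Mott)
#'
#' Trims each read to the contiguous substring maximizing the running sum of
#' `errorLimit - p_error(base)`, where `p_error = 10^(-Q/10)` for Phred score
#' Q. Bases better than the error limit contribute positively, worse bases
#' negatively; the best-scoring window is kept (all of a uniformly good read,
#' nothing of a uniformly bad one). Ties are resolved to the window with the
#' smallest start and then the largest end; if no window has a positive score
#' the read becomes empty.
#'
#' @param x `QualityScaledDNAStringSet`.
#' @param errorLimit error-probability limit, default 0.05.
#' @return `QualityScaledDNAStringSet` of trimmed (possibly zero-width) reads.
#' @seealso [mottTrimRanges()] for the retained windows.
#' @export
qualityTrim <- function(x, errorLimit = 0.05) {
  if (!is(x, "QualityScaledXStringSet"))
    stop("qualityTrim requires reads with qualities")
  r <- mottTrimRanges(phredScores(x), errorLimit)
  IRanges::narrow(x, start = r[, "start"], width = r[, "end"] - r[, "start"] + 1L)
}

#' @rdname qualityTrim
#' @param quals list of integer Phred vectors (one per read).
#' @return for `mottTrimRanges`: integer matrix with columns `start`, `end`
#'   (1-based closed; an empty result is encoded as `start = 1`, `end = 0`).
#' @export
mottTrimRanges <- function(quals, errorLimit = 0.05) {
  wv <- lengths(quals)
  n <- length(wv)
  if (n == 0L) return(matrix(integer(), 0, 2, dimnames = list(NULL, c("start", "end"))))
  W <- max(wv, 1L)
  qm <- matrix(NA_real_, n, W)
  if (any(wv > 0))
    qm[cbind(rep(seq_len(n), wv), sequence(wv))] <- unlist(quals, use.names = FALSE)
  xm <- errorLimit - 10^(-qm / 10)

  P <- numeric(n); minP <- numeric(n); minIdx <- integer(n)
  best <- numeric(n); bestS <- integer(n); bestE <- integer(n)
  for (j in seq_len(W)) {
    act <- wv >= j
    P[act] <- P[act] + xm[act, j]
    cand <- P - minP
    upd <- act & cand > best
    best[upd] <- cand[upd]; bestS[upd] <- minIdx[upd]; bestE[upd] <- j
    ext <- act & !upd & cand == best & minIdx == bestS & j > bestE
    bestE[ext] <- j
    nm <- act & P < minP
    minP[nm] <- P[nm]; minIdx[nm] <- j
  }
  empty <- best <= 0
  cbind(start = ifelse(empty, 1L, bestS + 1L),
        end = ifelse(empty, 0L, bestE))
}

#' Host/vector screening of reads
#'
#' Classifies reads by their qualifying hits (identity >= `minIdentity` and
#' aligned length >= `minLen`) against the host genome and the cloning
#' vector. A host hit drops the read; a vector hit whose vector interval
#' intersects the window of `window` bp up- or downstream of the cloning site
#' keeps it (such reads carry the insert/vector junction needed to flag BAC
#' ends), any other vector hit drops it. Host takes precedence over vector.
#'
#' @param readIds character vector of read ids to classify.
#' @param hostAln,vectorAln [alignmentTable()]s of the reads against host and
#'   vector references.
#' @param cloningSite 0-based position of the cloning site on the vector.
#' @param window half-width of the retained window around the cloning site,
#'   default 2000 bp.
#' @param minIdentity,minLen qualifying-hit thresholds (0.9, 50 bp).
#' @return character vector of verdicts (`keep`, `keep_vector_near_site`,
#'   `drop_host`, `drop_vector`), named by `readIds`.
#' @export
screenReads <- function(readIds, hostAln, vectorAln, cloningSite,
                        window = 2000L, minIdentity = 0.9, minLen = 50L) {
  qual <- function(a) a[a$identity >= minIdentity & a$alnLen >= minLen, ,
                        drop = FALSE]
  hostAln <- qual(hostAln); vectorAln <- qual(vectorAln)
  verdict <- structure(rep("keep", length(readIds)), names = readIds)
  near <- vectorAln$tstart <= cloningSite + window &
    vectorAln$tend >= cloningSite - window
  vNear <- unique(vectorAln$qname[near])
  vAny <- unique(vectorAln$qname)
  verdict[intersect(vAny, readIds)] <- "drop_vector"
  verdict[intersect(vNear, readIds)] <- "keep_vector_near_site"
  verdict[intersect(unique(hostAln$qname), readIds)] <- "drop_host"
  verdict
}

#' Keep only intact pairs
#'
#' @param pairs `ReadPairs`.
#' @param keep1,keep2 logical per pair: did each mate survive its per-read
#'   processing? Pairs are retained only when both mates survived and both
#'   are non-empty.
#' @return subsetted `ReadPairs`.
#' @export
filterIntactPairs <- function(pairs, keep1, keep2) {
  ok <- keep1 & keep2 &
    Biostrings::width(mate1(pairs)) > 0L & Biostrings::width(mate2(pairs)) > 0L
  pairs[ok]
}

#' Paired-end read quality control
#'
#' Full per-clone preprocessing of a paired-end library: modified-Mott quality
#' trimming of each mate, host and vector screening with the cloning-site
#' window (mapping with the internal mapper), and intact-pair filtering.
#'
#' @param pairs `ReadPairs` with qualities.
#' @param vectorSeq,hostSeq named `DNAStringSet` references (may be `NULL` to
#'   skip a screen).
#' @inheritParams screenReads
#' @param errorLimit trim limit, see [qualityTrim()].
#' @param seedLen mapper seed length.
#' @return list with `pairs` (cleaned `ReadPairs`), `verdict1`, `verdict2`
#'   (per input pair) and `report` (verdict counts).
#' @export
peReadQc <- function(pairs, vectorSeq, hostSeq, cloningSite, window = 2000L,
                     errorLimit = 0.05, minIdentity = 0.9, minLen = 50L,
                     seedLen = 21L) {
  t1 <- qualityTrim(mate1(pairs), errorLimit)
  t2 <- qualityTrim(mate2(pairs), errorLimit)
  nm <- names(pairs)
  ids1 <- paste0(nm, "/1"); ids2 <- paste0(nm, "/2")
  reads <- Biostrings::DNAStringSet(c(
    stats::setNames(Biostrings::DNAStringSet(t1), ids1),
    stats::setNames(Biostrings::DNAStringSet(t2), ids2)))
  vAln <- if (is.null(vectorSeq)) alignmentTable()
          else mapReads(reads, vectorSeq, seedLen, minIdentity)
  hAln <- if (is.null(hostSeq)) alignmentTable()
          else mapReads(reads, hostSeq, seedLen, minIdentity)
  v <- screenReads(names(reads), hAln, vAln, cloningSite, window,
                   minIdentity, minLen)
  v[names(reads)[Biostrings::width(reads) == 0L]] <- "drop_quality"
  v1 <- stats::setNames(v[ids1], nm); v2 <- stats::setNames(v[ids2], nm)
  keepV <- c("keep", "keep_vector_near_site")
  trimmed <- ReadPairs(t1, t2, libraryTag(pairs))
  out <- filterIntactPairs(trimmed, v1 %in% keepV, v2 %in% keepV)
  lev <- c("keep", "keep_vector_near_site", "drop_host", "drop_vector",
           "drop_quality")
  report <- data.frame(verdict = lev,
                       mate1 = as.integer(table(factor(v1, lev))),
                       mate2 = as.integer(table(factor(v2, lev))))
  list(pairs = out, verdict1 = v1, verdict2 = v2, report = report)
}
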