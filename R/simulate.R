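#' Simulation configuration
#'
#' Parameters of the synthetic multiplexed BAC sequencing experiment the
#' generators emulate: a repeat-containing genome from which clone inserts
#' are drawn, a cloning vector with a defined cloning site, a host (E. coli
#' stand-in) decoy, a short-insert paired-end library per clone and pooled
#' long-insert mate-pair libraries with Nextera-style junction adapters,
#' duplicates and cross-well contamination.
#'
#' @param seed RNG seed; every generator is deterministic given the seed.
#' @param genomeLen genome length in bp (default 2 Mb).
#' @param nBacs number of clones (default 8).
#' @param insertLenMean,insertLenSd genomic insert size (default 145 kb).
#' @param vectorLen,cloningSite vector backbone length and 0-based cloning
#'   site position.
#' @param hostLen host decoy length.
#' @param peInsertMean,peInsertSd paired-end fragment size (500 +/- 50 bp).
#' @param readLenPe paired-end read length (100 bp).
#' @param errorRate per-base substitution error rate.
#' @param dupRate duplicate-pair fraction injected into mate-pair libraries.
#' @param contaminationRate fraction of paired-end pairs drawn from other
#'   clones (cross-well contamination).
#' @param vectorReadRate,hostReadRate fractions of paired-end pairs drawn
#'   from the vector backbone and the host genome.
#' @param lowQualityRate fraction of pairs given uniformly bad qualities.
#' @param junctionAdapter Nextera junction adapter sequence.
#' @param mpAdapterRate fraction of mate-pair mates that read through the
#'   junction adapter.
#' @param repeatFamilies,repeatCopies,repeatLen,repeatIdentity planted
#'   repeat families: count, copies each, element length, per-family copy
#'   identity.
#' @return list of class `bacplexConfig`.
#' @export
simulationConfig <- function(seed = 1L, genomeLen = 2e6L, nBacs = 8L,
                             insertLenMean = 145000L, insertLenSd = 5000L,
                             vectorLen = 7500L, cloningSite = 3000L,
                             hostLen = 50000L,
                             peInsertMean = 500, peInsertSd = 50,
                             readLenPe = 100L, errorRate = 0.005,
                             dupRate = 0.05, contaminationRate = 0.05,
                             vectorReadRate = 0.08, hostReadRate = 0.08,
                             lowQualityRate = 0.03,
                             junctionAdapter = "CTGTCTCTTATACACATCTAGATGTGTATAAGAGACAG",
                             mpAdapterRate = 0.15,
                             repeatFamilies = 3L, repeatCopies = 8L,
                             repeatLen = 3000L,
                             repeatIdentity = c(0.85, 0.92, 0.98)) {
  cfg <- as.list(environment())
  for (f in c("genomeLen", "nBacs", "insertLenMean", "insertLenSd",
              "vectorLen", "cloningSite", "hostLen", "readLenPe",
              "repeatFamilies", "repeatCopies", "repeatLen"))
    cfg[[f]] <- as.integer(cfg[[f]])
  stopifnot(cfg$genomeLen > 0, cfg$nBacs >= 0,
            cfg$insertLenMean <= cfg$genomeLen,
            all(c(cfg$errorRate, cfg$dupRate, cfg$contaminationRate,
                  cfg$vectorReadRate, cfg$hostReadRate,
                  cfg$lowQualityRate, cfg$mpAdapterRate) >= 0),
            all(c(cfg$dupRate, cfg$contaminationRate) <= 1))
  class(cfg) <- "bacplexConfig"
  cfg
}

.randSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

.mutateSeq <- function(ch, rate) {
  n <- nchar(ch)
  k <- stats::rbinom(1, n, rate)
  if (k == 0) return(ch)
  pos <- sample.int(n, k)
  v <- strsplit(ch, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) v[p] <- sample(setdiff(bases, v[p]), 1)
  paste(v, collapse = "")
}

.addErrors <- function(chv, rate) {
  if (rate <= 0) return(chv)
  nerr <- stats::rbinom(length(chv), nchar(chv), rate)
  idx <- which(nerr > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    v <- strsplit(chv[i], "", fixed = TRUE)[[1]]
    for (p in sample.int(length(v), nerr[i])) v[p] <- sample(setdiff(bases, v[p]), 1)
    chv[i] <- paste(v, collapse = "")
  }
  chv
}

.qualString <- function(quals) intToUtf8(quals + 33L)

.makeQSet <- function(seqs, qualStrings) {
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs),
    Biostrings::PhredQuality(Biostrings::BStringSet(qualStrings)))
}

#' Synthetic reference set
#'
#' Builds the substrate of a simulated experiment: a random genome with
#' planted repeat families (copies mutated to the configured identities),
#' a cloning vector with recorded cloning site, a host decoy, a small
#' contaminant reference (adapter-concatemer stand-in), and `nBacs` clone
#' inserts sampled from the genome. Fully deterministic under the seed.
#'
#' @param config [simulationConfig()].
#' @return list with `genome`, `vector`, `host`, `contaminants`
#'   (`DNAStringSet`), `inserts` (`DNAStringSet`, one per clone), `config`
#'   and `truth` (repeat and insert coordinates).
#' @export
makeReferenceSet <- function(config) {
  set.seed(config$seed)
  g <- .randSeq(config$genomeLen)
  repTruth <- list()
  if (config$repeatFamilies > 0) {
    slots <- config$repeatFamilies * config$repeatCopies
    starts <- sort(sample.int(config$genomeLen - config$repeatLen, slots))
    # enforce non-overlap by dropping crowded starts
    keep <- c(TRUE, diff(starts) > config$repeatLen)
    starts <- starts[keep]
    fam <- rep(seq_len(config$repeatFamilies), length.out = length(starts))
    for (f in seq_len(config$repeatFamilies)) {
      elem <- .randSeq(config$repeatLen)
      for (s in starts[fam == f]) {
        copy <- .mutateSeq(elem, 1 - config$repeatIdentity[[
          ((f - 1) %% length(config$repeatIdentity)) + 1]])
        substr(g, s, s + config$repeatLen - 1L) <- copy
        repTruth[[length(repTruth) + 1]] <-
          data.frame(family = f, start = s - 1L,
                     end = s - 1L + config$repeatLen)
      }
    }
  }
  inserts <- character(config$nBacs)
  insTruth <- list()
  if (config$nBacs > 0) {
    lens <- pmax(1000L, round(stats::rnorm(config$nBacs, config$insertLenMean,
                                           config$insertLenSd)))
    lens <- pmin(lens, config$genomeLen)
    # inserts occupy jittered, essentially non-overlapping slots, as clones
    # along a minimum tiling path: most of each insert is unique to its clone
    slot <- config$genomeLen %/% config$nBacs
    if (max(lens) > slot)
      stop("inserts do not fit the genome: increase genomeLen or lower nBacs")
    starts <- vapply(seq_len(config$nBacs), function(i) {
      (i - 1L) * slot + sample.int(slot - lens[i] + 1L, 1)
    }, 0L)
    for (i in seq_len(config$nBacs)) {
      inserts[i] <- substr(g, starts[i], starts[i] + lens[i] - 1L)
      insTruth[[i]] <- data.frame(bac = sprintf("bac%d", i),
                                  start = starts[i] - 1L,
                                  end = starts[i] - 1L + lens[i])
    }
  }
  insertSet <- Biostrings::DNAStringSet(inserts)
  names(insertSet) <- sprintf("bac%d", seq_len(config$nBacs))
  list(genome = Biostrings::DNAStringSet(c(genome = g)),
       vector = Biostrings::DNAStringSet(c(vector = .randSeq(config$vectorLen))),
       host = Biostrings::DNAStringSet(c(host = .randSeq(config$hostLen))),
       contaminants = Biostrings::DNAStringSet(c(adapter_concatemer = .randSeq(600L))),
       inserts = insertSet,
       config = config,
       truth = list(repeats = if (length(repTruth)) do.call(rbind, repTruth)
                              else data.frame(),
                    inserts = do.call(rbind, insTruth)))
}

.drawFragments <- function(srcChar, n, mean, sd, minLen = 50L) {
  L <- nchar(srcChar)
  fl <- pmin(pmax(round(stats::rnorm(n, mean, sd)), minLen), L)
  fs <- vapply(L - fl + 1L, function(m) sample.int(m, 1), 0L)
  list(start = fs, len = fl,
       seq = substring(srcChar, fs, fs + fl - 1L))
}

#' Simulate a paired-end library for one clone
#'
#' Draws inward-oriented read pairs from the clone insert mixed with the
#' configured contamination sources: cross-contamination from windows of
#' other clones, vector backbone fragments (uniform over the vector, so a
#' share falls near the cloning site), host fragments, and uniformly
#' low-quality pairs. Substitution errors are applied at the configured
#' rate; ground truth records the provenance of every pair.
#'
#' @param refs reference set from [makeReferenceSet()].
#' @param bacId clone to simulate (name in `refs$inserts`).
#' @param nPairs number of pairs.
#' @param crossWindows optional `data.frame` (`bac`, `start`, `end`,
#'   0-based half-open) of the windows cross-contaminating reads are drawn
#'   from; by default whole other inserts.
#' @param seed optional seed (`NULL` continues the current RNG stream).
#' @return list with `pairs` (`ReadPairs` with qualities) and `truth`
#'   (per pair: `pairId`, `source`, `sourceBac`, `fragStart`, `fragEnd`,
#'   `vectorNear`, `lowQuality`).
#' @export
simulatePeReads <- function(refs, bacId, nPairs, crossWindows = NULL,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- refs$config
  rl <- cfg$readLenPe
  src <- sample(c("insert", "cross", "vector", "host"), nPairs, replace = TRUE,
                prob = c(1 - cfg$contaminationRate - cfg$vectorReadRate -
                           cfg$hostReadRate,
                         cfg$contaminationRate, cfg$vectorReadRate,
                         cfg$hostReadRate))
  insertChar <- as.character(refs$inserts[[bacId]])
  vectorChar <- as.character(refs$vector[[1]])
  hostChar <- as.character(refs$host[[1]])
  others <- setdiff(names(refs$inserts), bacId)
  if (is.null(crossWindows) && length(others)) {
    crossWindows <- data.frame(bac = others, start = 0L,
                               end = Biostrings::width(refs$inserts[others]))
  }
  frag <- character(nPairs); fragStart <- integer(nPairs)
  srcBac <- rep(NA_character_, nPairs)
  for (what in unique(src)) {
    i <- which(src == what)
    if (what == "insert") {
      d <- .drawFragments(insertChar, length(i), cfg$peInsertMean,
                          cfg$peInsertSd, minLen = rl)
      frag[i] <- d$seq; fragStart[i] <- d$start; srcBac[i] <- bacId
    } else if (what == "vector") {
      d <- .drawFragments(vectorChar, length(i), cfg$peInsertMean,
                          cfg$peInsertSd, minLen = rl)
      frag[i] <- d$seq; fragStart[i] <- d$start
    } else if (what == "host") {
      d <- .drawFragments(hostChar, length(i), cfg$peInsertMean,
                          cfg$peInsertSd, minLen = rl)
      frag[i] <- d$seq; fragStart[i] <- d$start
    } else if (length(others)) {
      wi <- sample.int(nrow(crossWindows), length(i), replace = TRUE)
      for (k in seq_along(i)) {
        w <- crossWindows[wi[k], ]
        ch <- substr(as.character(refs$inserts[[w$bac]]), w$start + 1L, w$end)
        d <- .drawFragments(ch, 1L, cfg$peInsertMean, cfg$peInsertSd,
                            minLen = rl)
        frag[i[k]] <- d$seq
        fragStart[i[k]] <- w$start + d$start
        srcBac[i[k]] <- w$bac
      }
    } else {
      src[i] <- "insert"
      d <- .drawFragments(insertChar, length(i), cfg$peInsertMean,
                          cfg$peInsertSd, minLen = rl)
      frag[i] <- d$seq; fragStart[i] <- d$start; srcBac[i] <- bacId
    }
  }
  fl <- nchar(frag)
  r1 <- substring(frag, 1L, pmin(rl, fl))
  r2raw <- substring(frag, pmax(1L, fl - rl + 1L), fl)
  r2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(r2raw)))
  r1 <- .addErrors(r1, cfg$errorRate)
  r2 <- .addErrors(r2, cfg$errorRate)
  lowQ <- stats::runif(nPairs) < cfg$lowQualityRate
  goodProfile <- .qualString(40L - (seq_len(rl) - 1L) %/% 25L)
  q1 <- ifelse(lowQ, vapply(nchar(r1), function(w) .qualString(rep(2L, w)), ""),
               substring(goodProfile, 1L, nchar(r1)))
  q2 <- ifelse(lowQ, vapply(nchar(r2), function(w) .qualString(rep(2L, w)), ""),
               substring(goodProfile, 1L, nchar(r2)))
  ids <- sprintf("%s_p%05d", bacId, seq_len(nPairs))
  m1 <- .makeQSet(r1, q1); names(m1) <- ids
  m2 <- .makeQSet(r2, q2); names(m2) <- ids
  vecNear <- src == "vector" &
    fragStart - 1L <= refs$config$cloningSite + 2000L &
    fragStart - 1L + fl >= refs$config$cloningSite - 2000L
  truth <- data.frame(pairId = ids, source = src, sourceBac = srcBac,
                      fragStart = fragStart - 1L,
                      fragEnd = fragStart - 1L + fl,
                      vectorNear = vecNear, lowQuality = lowQ)
  list(pairs = ReadPairs(m1, m2, "pe"), truth = truth)
}

#' Simulate a Nextera mate-pair library
#'
#' Emulates mate-pair circularization over a pool of clones: long fragments
#' are drawn per clone, the two reads face inward across the fragment, and a
#' configurable fraction of mates reads through the junction adapter (the
#' adapter is embedded in the read, followed by off-fragment filler, so that
#' correct clipping restores the inward orientation). Exact duplicate pairs
#' are injected at `dupRate`.
#'
#' @param refs reference set from [makeReferenceSet()].
#' @param nPairsPerBac pairs drawn from each clone before duplication.
#' @param insertMean,insertSd fragment size of the library.
#' @param readLen read length (e.g. 250 for MiSeq, 100 for HiSeq).
#' @param libraryTag library label.
#' @param seed optional seed.
#' @return list with `pairs` (`ReadPairs`) and `truth` (per pair: `pairId`,
#'   `bac`, `fragStart`, `fragEnd`, `adapter1`, `adapter2` (clip positions,
#'   `NA` when absent), `isDuplicate`).
#' @export
simulateMatepairs <- function(refs, nPairsPerBac, insertMean, insertSd,
                              readLen, libraryTag = "mp", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cfg <- refs$config
  adapter <- cfg$junctionAdapter
  alen <- nchar(adapter)
  bacs <- names(refs$inserts)
  rows <- list()
  for (b in bacs) {
    ch <- as.character(refs$inserts[[b]])
    d <- .drawFragments(ch, nPairsPerBac, insertMean, insertSd,
                        minLen = 2L * readLen)
    rows[[b]] <- data.frame(bac = b, fragStart = d$start, fragLen = d$len,
                            frag = d$seq)
  }
  rows <- do.call(rbind, rows)
  n <- nrow(rows)
  r1 <- substring(rows$frag, 1L, readLen)
  r2 <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(
    substring(rows$frag, rows$fragLen - readLen + 1L, rows$fragLen))))
  mkReadThrough <- function(reads) {
    thru <- stats::runif(n) < cfg$mpAdapterRate
    cut <- rep(NA_integer_, n)
    hi <- max(3L, readLen - alen)
    cut[thru] <- sample(3:hi, sum(thru), replace = TRUE)
    i <- which(thru)
    reads[i] <- substring(paste0(substring(reads[i], 1L, cut[i]), adapter,
                                 vapply(i, function(z) .randSeq(readLen), "")),
                          1L, readLen)
    list(reads = reads, cut = cut)
  }
  t1 <- mkReadThrough(r1); t2 <- mkReadThrough(r2)
  r1 <- .addErrors(t1$reads, cfg$errorRate)
  r2 <- .addErrors(t2$reads, cfg$errorRate)
  truth <- data.frame(bac = rows$bac, fragStart = rows$fragStart - 1L,
                      fragEnd = rows$fragStart - 1L + rows$fragLen,
                      adapter1 = t1$cut, adapter2 = t2$cut,
                      isDuplicate = FALSE)
  nDup <- round(cfg$dupRate * n / (1 - cfg$dupRate))
  if (nDup > 0) {
    di <- sample.int(n, nDup, replace = TRUE)
    r1 <- c(r1, r1[di]); r2 <- c(r2, r2[di])
    truth <- rbind(truth, transform(truth[di, ], isDuplicate = TRUE))
  }
  ntot <- length(r1)
  ord <- sample.int(ntot)
  r1 <- r1[ord]; r2 <- r2[ord]; truth <- truth[ord, ]
  ids <- sprintf("%s_%05d", libraryTag, seq_len(ntot))
  truth <- cbind(pairId = ids, truth)
  rownames(truth) <- NULL
  q <- .qualString(rep(37L, readLen))
  m1 <- .makeQSet(r1, substring(q, 1L, nchar(r1))); names(m1) <- ids
  m2 <- .makeQSet(r2, substring(q, 1L, nchar(r2))); names(m2) <- ids
  list(pairs = ReadPairs(m1, m2, libraryTag), truth = truth)
}

#' Fragment an insert into draft contigs
#'
#' Stand-in for the de novo assembler: cuts a clone insert into `nFragments`
#' contigs separated by true (unassembled) gaps, optionally planting
#' misassembly events inside chosen contigs. An `inversion` reverse-
#' complements an internal block; a `relocation` deletes `len` bases so the
#' flanks align `len` apart on the reference; an `overlap` duplicates the
#' `len` bases preceding the event point. Ground truth includes, for every
#' contig, its collinear alignment segments against the insert in
#' [alignmentTable()] form.
#'
#' @param insert clone insert (`DNAString`/character).
#' @param bacId clone id used for contig names.
#' @param nFragments number of contigs.
#' @param events list of events, each
#'   `list(frag =, type = c("inversion","relocation","overlap"), at =, len =)`
#'   with `at`, `len` in fragment-local coordinates.
#' @param gapMean,gapSd true gap size between adjacent contigs.
#' @param fragWeights optional relative fragment lengths.
#' @param seed optional seed.
#' @return list with `contigs` (`DNAStringSet`), `truth` (`contigs`
#'   data.frame and `segments` alignment table), `gaps` (true gap sizes).
#' @export
fragmentAssembly <- function(insert, bacId, nFragments, events = list(),
                             gapMean = 800, gapSd = 150, fragWeights = NULL,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(nFragments >= 1)
  ch <- as.character(insert)
  L <- nchar(ch)
  gaps <- if (nFragments > 1)
    pmax(100L, round(stats::rnorm(nFragments - 1L, gapMean, gapSd)))
  else integer()
  if (is.null(fragWeights)) fragWeights <- rep(1, nFragments)
  stopifnot(length(fragWeights) == nFragments)
  usable <- L - sum(gaps)
  fl <- floor(usable * fragWeights / sum(fragWeights))
  fl[nFragments] <- usable - sum(fl[-nFragments])
  fs <- cumsum(c(1L, fl[-nFragments] + gaps))  # 1-based fragment starts
  ctg <- character(nFragments)
  segRows <- list(); ctgRows <- list()
  for (i in seq_len(nFragments)) {
    s <- substr(ch, fs[i], fs[i] + fl[i] - 1L)
    f0 <- fs[i] - 1L  # 0-based ref offset
    ev <- Filter(function(e) e$frag == i, events)
    nm <- sprintf("%s_c%d", bacId, i)
    if (length(ev) == 0) {
      segRows[[length(segRows) + 1]] <- data.frame(
        qname = nm, qstart = 0L, qend = fl[i], tstart = f0, tend = f0 + fl[i],
        strand = "+", event = "none")
      evLabel <- "none"
    } else {
      if (length(ev) > 1) stop("at most one event per fragment")
      e <- ev[[1]]
      a <- e$at; len <- e$len
      stopifnot(a > 0)
      if (e$type == "overlap") stopifnot(len <= a, a <= fl[i])
      else stopifnot(a + len < fl[i])
      if (e$type == "inversion") {
        blk <- substr(s, a + 1L, a + len)
        rc <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(blk)))
        s <- paste0(substr(s, 1L, a), rc, substr(s, a + len + 1L, fl[i]))
        segRows[[length(segRows) + 1]] <- data.frame(
          qname = nm,
          qstart = c(0L, a, a + len),
          qend = c(a, a + len, fl[i]),
          tstart = f0 + c(0L, a, a + len),
          tend = f0 + c(a, a + len, fl[i]),
          strand = c("+", "-", "+"), event = "inversion")
      } else if (e$type == "relocation") {
        s <- paste0(substr(s, 1L, a), substr(s, a + len + 1L, fl[i]))
        segRows[[length(segRows) + 1]] <- data.frame(
          qname = nm,
          qstart = c(0L, a), qend = c(a, fl[i] - len),
          tstart = f0 + c(0L, a + len), tend = f0 + c(a, fl[i]),
          strand = "+", event = "relocation")
      } else if (e$type == "overlap") {
        dupblk <- substr(s, a - len + 1L, a)
        s <- paste0(substr(s, 1L, a), dupblk, substr(s, a + 1L, fl[i]))
        segRows[[length(segRows) + 1]] <- data.frame(
          qname = nm,
          qstart = c(0L, a, a + len), qend = c(a, a + len, fl[i] + len),
          tstart = f0 + c(0L, a - len, a), tend = f0 + c(a, a, fl[i]),
          strand = "+", event = "overlap")
      } else stop("unknown event type: ", e$type)
      evLabel <- e$type
    }
    ctg[i] <- s
    ctgRows[[i]] <- data.frame(contig = nm, fragStart = f0,
                               fragEnd = f0 + fl[i], event = evLabel)
  }
  segs <- do.call(rbind, segRows)
  w <- segs$qend - segs$qstart
  segTable <- alignmentTable(qname = segs$qname, tname = "insert",
                             qstart = segs$qstart, qend = segs$qend,
                             tstart = segs$tstart, tend = segs$tend,
                             strand = segs$strand, matches = w, alnLen = w,
                             identity = 1, mapq = 60L, score = w)
  segTable$event <- segs$event
  out <- Biostrings::DNAStringSet(ctg)
  names(out) <- sprintf("%s_c%d", bacId, seq_len(nFragments))
  list(contigs = out,
       truth = list(contigs = do.call(rbind, ctgRows), segments = segTable),
       gaps = gaps)
}
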