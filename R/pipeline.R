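#' Assemble a raw per-clone contig set with realistic artefacts
#'
#' Combines the draft contigs of one clone with the artefacts the
#' post-processing stages are designed to remove: vector backbone padding
#' the two insert-boundary contigs (adjacent to the cloning site, as on the
#' circular clone), a short sequencing-adapter contaminant pad on one
#' internal contig end, cross-contamination contigs copied from windows of
#' another clone, and one host-derived contig.
#'
#' @param refs reference set from [makeReferenceSet()].
#' @param bacId clone id.
#' @param fragAsm result of [fragmentAssembly()] for this clone.
#' @param crossWindows `data.frame` (`bac`, `start`, `end`) of
#'   cross-contamination source windows (may have zero rows).
#' @param vectorPad vector padding length per insert end, default 1500 bp.
#' @param adapterPadLen contaminant pad length, default 150 bp.
#' @param adapterPadContig index of the contig whose right end is padded
#'   with contaminant (default 3; use `NA` to skip).
#' @param hostContigLen length of the host-derived contig (0 to skip).
#' @return list with `assembly` (raw `BacAssembly`) and `truth` (elements
#'   `contamOnly`: ids of contigs carrying no clone sequence; `vectorPad`;
#'   `adapterContig`; `adapterPadLen`).
#' @export
buildRawAssembly <- function(refs, bacId, fragAsm, crossWindows,
                             vectorPad = 1500L, adapterPadLen = 150L,
                             adapterPadContig = 3L, hostContigLen = 5000L) {
  ctg <- as.character(fragAsm$contigs)
  names(ctg) <- names(fragAsm$contigs)
  vchar <- as.character(refs$vector[[1]])
  site <- refs$config$cloningSite
  n <- length(ctg)
  ctg[1] <- paste0(substr(vchar, site - vectorPad + 1L, site), ctg[1])
  ctg[n] <- paste0(ctg[n], substr(vchar, site + 1L, site + vectorPad))
  adapterContig <- NA_character_
  if (!is.na(adapterPadContig) && adapterPadContig <= n) {
    cchar <- as.character(refs$contaminants[[1]])
    ctg[adapterPadContig] <- paste0(ctg[adapterPadContig],
                                    substr(cchar, 1L, adapterPadLen))
    adapterContig <- names(ctg)[adapterPadContig]
  }
  contam <- character(0)
  if (nrow(crossWindows)) {
    x <- vapply(seq_len(nrow(crossWindows)), function(k) {
      w <- crossWindows[k, ]
      substr(as.character(refs$inserts[[w$bac]]), w$start + 1L, w$end)
    }, "")
    names(x) <- sprintf("%s_x%d", bacId, seq_along(x))
    contam <- c(contam, x)
  }
  if (hostContigLen > 0) {
    h <- substr(as.character(refs$host[[1]]), 10001L, 10000L + hostContigLen)
    names(h) <- sprintf("%s_h1", bacId)
    contam <- c(contam, h)
  }
  all <- c(ctg, contam)
  list(assembly = BacAssembly(bacId, Biostrings::DNAStringSet(all)),
       truth = list(contamOnly = names(contam),
                    vectorPad = vectorPad,
                    adapterContig = adapterContig,
                    adapterPadLen = adapterPadLen))
}

#' Shift truth alignment segments after end clipping
#'
#' Post-processing clips vector and contaminant padding off contig ends,
#' shifting the contigs' coordinate systems. This helper translates the
#' simulator's truth alignment segments onto the clipped contigs, clamping
#' forward-strand terminal segments when slightly too much or too little
#' was clipped (induced events are kept away from contig ends by the
#' fixture design, so clamping never touches a reverse-strand segment).
#'
#' @param segments truth [alignmentTable()] from [fragmentAssembly()].
#' @param clippedLeft,clippedRight named integer vectors of clip amounts
#'   per contig id (e.g. from the [postprocessAssembly()] report).
#' @param newLen named integer vector of post-clip contig lengths.
#' @return adjusted alignment table restricted to surviving contigs.
#' @export
adjustTruthSegments <- function(segments, clippedLeft, clippedRight, newLen) {
  s <- segments[segments$qname %in% names(newLen), , drop = FALSE]
  if (!nrow(s)) return(s)
  cl <- clippedLeft[s$qname]
  nl <- newLen[s$qname]
  q0 <- s$qstart - cl
  q1 <- s$qend - cl
  over <- q0 < 0
  s$tstart[over & s$strand == "+"] <- s$tstart[over & s$strand == "+"] -
    q0[over & s$strand == "+"]
  q0[over] <- 0L
  past <- q1 > nl
  s$tend[past & s$strand == "+"] <- s$tend[past & s$strand == "+"] -
    (q1 - nl)[past & s$strand == "+"]
  q1[past] <- nl[past]
  s$qstart <- as.integer(q0)
  s$qend <- as.integer(q1)
  keep <- s$qend - s$qstart > 0 & s$tend - s$tstart > 0
  s <- s[keep, , drop = FALSE]
  w <- pmin(s$qend - s$qstart, s$tend - s$tstart)
  s$matches <- as.integer(w); s$alnLen <- as.integer(w); s$score <- w
  s
}

#' Canonical non-N sequence content
#'
#' Decomposes sequences into their maximal N-free runs and returns each run
#' in canonical orientation (lexicographic minimum of the run and its
#' reverse complement), sorted. Two assemblies have equal content exactly
#' when scaffolding only reordered, reoriented and gapped the contigs.
#'
#' @param seqs `DNAStringSet`.
#' @return sorted character vector.
#' @export
sequenceContent <- function(seqs) {
  runs <- unlist(lapply(as.character(seqs), function(s)
    strsplit(s, "N+")[[1]]), use.names = FALSE)
  runs <- runs[nzchar(runs)]
  if (!length(runs)) return(character())
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(runs)))
  sort(pmin(runs, rc))
}

#' Run the full synthetic BAC pipeline
#'
#' End-to-end execution of the whole toolkit on a simulated experiment:
#' reference construction, per-clone paired-end simulation and read QC,
#' draft-contig construction with planted misassembly events and
#' contamination artefacts, contig post-processing, two mate-pair libraries
#' (MiSeq-like 2x250 at k = 10, then HiSeq-like 2x100 at k = 20) with
#' preprocessing, deconvolution and iterative scaffolding, and reference
#' based evaluation of the post-processed contigs. Ground truth for every
#' stage is returned alongside the results.
#'
#' @param config [simulationConfig()].
#' @param peDepth paired-end depth per clone (default 25x).
#' @param crossDepthFrac depth of cross-contamination contigs relative to
#'   native depth, default 0.1.
#' @param nCrossWindows cross-contamination windows per clone.
#' @param mpLibs list describing the mate-pair libraries in processing
#'   order (`tag`, `insertMean`, `insertSd`, `readLen`, `kMin`,
#'   `nPairsPerBac`).
#' @param nFragments draft contigs per clone.
#' @return list with elements `refs`, `perBac` (per clone: truth tables,
#'   QC output, post-processing report, evaluation), `scaffold`
#'   (assemblies, layouts, library stats), `mp` (library truths and prep
#'   reports) and `summary` (per-clone stage statistics).
#' @export
runBacPipeline <- function(config = simulationConfig(),
                           peDepth = 25, crossDepthFrac = 0.1,
                           nCrossWindows = 3L,
                           mpLibs = list(
                             list(tag = "mp_miseq", insertMean = 5500,
                                  insertSd = 550, readLen = 250L, kMin = 10L,
                                  nPairsPerBac = 900L),
                             list(tag = "mp_hiseq", insertMean = 6000,
                                  insertSd = 600, readLen = 100L, kMin = 20L,
                                  nPairsPerBac = 1500L)),
                           nFragments = 5L) {
  refs <- makeReferenceSet(config)
  bacs <- names(refs$inserts)
  nB <- length(bacs)
  rl <- config$readLenPe
  events <- rep(list(list()), nB)
  weights <- rep(list(rep(1, nFragments)), nB)
  if (nB >= 1) events[[1]] <- list(list(frag = 2L, type = "inversion",
                                        at = 5000L, len = 2000L))
  if (nB >= 2) events[[2]] <- list(list(frag = 2L, type = "relocation",
                                        at = 5000L, len = 500L))
  if (nB >= 3) {
    events[[3]] <- list(list(frag = 1L, type = "relocation",
                             at = 9000L, len = 40000L))
    weights[[3]] <- c(3, rep(1, nFragments - 1L))
  }
  if (nB >= 4) events[[4]] <- list(list(frag = 2L, type = "overlap",
                                        at = 6000L, len = 1500L))

  perBac <- list()
  postAsm <- list()
  for (i in seq_len(nB)) {
    b <- bacs[i]
    insLen <- Biostrings::width(refs$inserts)[i]
    nPairs <- round(peDepth * insLen / (2 * rl))
    srcBac <- bacs[(i %% nB) + 1L]
    cw <- data.frame(bac = character(), start = integer(), end = integer())
    if (nB > 1 && config$contaminationRate > 0) {
      crossBases <- config$contaminationRate * nPairs * 2 * rl
      wlen <- round(crossBases / (crossDepthFrac * peDepth) / nCrossWindows)
      srcLen <- stats::setNames(Biostrings::width(refs$inserts),
                                names(refs$inserts))[srcBac]
      starts <- floor(seq(0.05, 0.65, length.out = nCrossWindows) *
                        (srcLen - wlen))
      cw <- data.frame(bac = srcBac, start = as.integer(starts),
                       end = as.integer(starts + wlen))
    }
    pe <- simulatePeReads(refs, b, nPairs, crossWindows = cw)
    qc <- peReadQc(pe$pairs, refs$vector, refs$host, config$cloningSite)
    fa <- fragmentAssembly(refs$inserts[[b]], b, nFragments,
                           events = events[[i]], fragWeights = weights[[i]])
    raw <- buildRawAssembly(refs, b, fa, cw)
    post <- postprocessAssembly(raw$assembly, qc$pairs, refs$vector,
                                refs$contaminants)
    rep <- post$report
    adj <- adjustTruthSegments(
      fa$truth$segments,
      stats::setNames(rep$clippedLeft, rep$id),
      stats::setNames(rep$clippedRight, rep$id),
      stats::setNames(Biostrings::width(contigs(post$assembly)),
                      names(contigs(post$assembly))))
    ev <- classifyMisassemblies(adj)
    gf <- genomeFraction(adj, insLen)
    perBac[[b]] <- list(insertLen = insLen, peTruth = pe$truth, qc = qc,
                        fragTruth = fa$truth, gaps = fa$gaps,
                        rawTruth = raw$truth, rawAssembly = raw$assembly,
                        post = post, adjSegments = adj,
                        misassembly = ev, genomeFraction = gf,
                        crossWindows = cw)
    postAsm[[b]] <- post$assembly
  }

  mp <- list()
  libs <- list()
  for (ml in mpLibs) {
    sim <- simulateMatepairs(refs, ml$nPairsPerBac, ml$insertMean,
                             ml$insertSd, ml$readLen, libraryTag = ml$tag)
    prep <- mpPrep(sim$pairs, config$junctionAdapter)
    mp[[ml$tag]] <- list(truth = sim$truth, prep = prep$report,
                         spec = ml)
    libs[[length(libs) + 1]] <- list(pairs = prep$pairs, kMin = ml$kMin)
  }
  sc <- iterativeScaffold(postAsm, libs)

  summary <- do.call(rbind, lapply(bacs, function(b) {
    pre <- assemblyStats(postAsm[[b]])
    post <- assemblyStats(sc$assemblies[[b]])
    data.frame(bac = b, nContigs = pre$nSequences, contigL50 = pre$l50,
               nScaffolds = post$nSequences, scaffoldL50 = post$l50,
               genomeFraction = perBac[[b]]$genomeFraction,
               nGlobal = perBac[[b]]$misassembly$summary$nGlobal,
               nLocal = perBac[[b]]$misassembly$summary$nLocal)
  }))
  list(refs = refs, perBac = perBac, postAssemblies = postAsm,
       scaffold = sc, mp = mp, summary = summary)
}
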