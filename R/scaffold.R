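#' Build the mate-pair link graph of one clone
#'
#' Every deconvoluted pair whose two mates map uniquely to *different*
#' contigs of the clone contributes one link between the two contig ends the
#' mates point toward: a mate on the forward strand points toward the
#' contig's tail (3') end, a reverse-strand mate toward its head. The
#' per-pair gap estimate is `insertMean - dA - dB`, where `d` is the
#' distance from the mate's outermost aligned base to the linked contig end.
#' Links are grouped by the canonical (contigA, endA, contigB, endB) key
#' with `contigA < contigB`.
#'
#' @param assembly `BacAssembly` of the clone.
#' @param aln1,aln2 best-hit [alignmentTable()]s (one row per pair id,
#'   restricted to pairs assigned to this clone).
#' @param insertMean library insert size in bp (see [estimateInsert()]).
#' @return `data.frame` with columns `contigA`, `endA`, `contigB`, `endB`,
#'   `nLinks`, `gapMean` and list-column `gaps`.
#' @export
buildLinks <- function(assembly, aln1, aln2, insertMean) {
  emptyLinks <- data.frame(contigA = character(), endA = character(),
                           contigB = character(), endB = character(),
                           nLinks = integer(), gapMean = numeric())
  emptyLinks$gaps <- list()
  j <- merge(aln1, aln2, by = "qname", suffixes = c(".1", ".2"))
  ids <- names(contigs(assembly))
  len <- stats::setNames(Biostrings::width(contigs(assembly)), ids)
  j <- j[j$tname.1 %in% ids & j$tname.2 %in% ids &
           j$tname.1 != j$tname.2 & j$mapq.1 >= 1L & j$mapq.2 >= 1L, ,
         drop = FALSE]
  if (!nrow(j)) return(emptyLinks)
  endOf <- function(strand) ifelse(strand == "+", "tail", "head")
  dOf <- function(strand, tname, tstart, tend)
    ifelse(strand == "+", len[tname] - tstart, tend)
  e1 <- endOf(j$strand.1); e2 <- endOf(j$strand.2)
  d1 <- dOf(j$strand.1, j$tname.1, j$tstart.1, j$tend.1)
  d2 <- dOf(j$strand.2, j$tname.2, j$tstart.2, j$tend.2)
  gap <- insertMean - d1 - d2
  swap <- j$tname.1 > j$tname.2
  ca <- ifelse(swap, j$tname.2, j$tname.1)
  ea <- ifelse(swap, e2, e1)
  cb <- ifelse(swap, j$tname.1, j$tname.2)
  eb <- ifelse(swap, e1, e2)
  dt <- data.table::data.table(contigA = ca, endA = ea, contigB = cb,
                               endB = eb, gap = gap)
  g <- dt[, list(nLinks = .N, gapMean = mean(gap), gaps = list(gap)),
          by = c("contigA", "endA", "contigB", "endB")]
  data.table::setorder(g, contigA, endA, contigB, endB)
  as.data.frame(g)
}

.flipParts <- function(s) {
  n <- nrow(s)
  data.frame(contig = rev(s$contig),
             orient = rev(chartr("+-", "-+", s$orient)),
             gapAfter = c(rev(s$gapAfter[-n]), NA_real_),
             gapEst = c(rev(s$gapEst[-n]), NA_real_))
}

.leftEnd <- function(s)
  paste(s$contig[1], ifelse(s$orient[1] == "+", "head", "tail"), sep = "|")
.rightEnd <- function(s) {
  n <- nrow(s)
  paste(s$contig[n], ifelse(s$orient[n] == "+", "tail", "head"), sep = "|")
}

#' Greedy link-graph scaffolding
#'
#' SSPACE-style greedy joining: links supported by fewer than `kMin` pairs
#' are discarded; remaining links are taken in order of decreasing support
#' (ties by lexicographic contig ids). A link is skipped when either of its
#' contig ends has a competing live link whose support ratio exceeds
#' `ratio` (the end is marked ambiguous and takes no further part), when an
#' end has already been consumed by an accepted join, or when the join would
#' close a cycle. Accepted joins merge the two scaffolds through their
#' exposed ends, flipping a scaffold when needed, and insert a gap of
#' `max(round(gapMean), minGap)` unknown bases; the raw (possibly negative)
#' estimate is kept in the layout.
#'
#' @param assembly `BacAssembly`.
#' @param links link table from [buildLinks()].
#' @param kMin minimum number of supporting pairs per link.
#' @param ratio ambiguity ratio, default 0.7.
#' @param minGap minimum rendered gap in bp, default 1.
#' @return list with `assembly` (stage `scaffolded`, scaffold sequences),
#'   `layout` (`scaffoldId`, `contigId`, `orientation`, `gapAfter`,
#'   `gapEstimate`) and `log` (skipped links and reasons).
#' @export
greedyScaffold <- function(assembly, links, kMin, ratio = 0.7, minGap = 1L) {
  ids <- names(contigs(assembly))
  lk <- links[links$nLinks >= kMin, , drop = FALSE]
  if (nrow(lk))
    lk <- lk[order(-lk$nLinks, lk$contigA, lk$contigB, lk$endA, lk$endB), ,
             drop = FALSE]
  scafOf <- stats::setNames(seq_along(ids), ids)
  scafs <- lapply(ids, function(id)
    data.frame(contig = id, orient = "+", gapAfter = NA_real_,
               gapEst = NA_real_))
  used <- character(); ambig <- character()
  logRows <- list()
  keyA <- paste(lk$contigA, lk$endA, sep = "|")
  keyB <- paste(lk$contigB, lk$endB, sep = "|")
  accepted <- rep(FALSE, nrow(lk))
  dead <- rep(FALSE, nrow(lk))
  for (i in seq_len(nrow(lk))) {
    if (dead[i]) next
    ea <- keyA[i]; eb <- keyB[i]
    if (ea %in% used || eb %in% used || ea %in% ambig || eb %in% ambig) {
      logRows[[length(logRows) + 1]] <-
        data.frame(contigA = lk$contigA[i], contigB = lk$contigB[i],
                   nLinks = lk$nLinks[i], reason = "end_unavailable")
      next
    }
    live <- !accepted & !dead & seq_len(nrow(lk)) != i &
      !(keyA %in% used) & !(keyB %in% used)
    comp <- live & (keyA == ea | keyB == ea | keyA == eb | keyB == eb)
    if (any(comp) && max(lk$nLinks[comp]) / lk$nLinks[i] > ratio) {
      for (e in c(ea, eb)) {
        ce <- comp & (keyA == e | keyB == e)
        if (any(ce) && max(lk$nLinks[ce]) / lk$nLinks[i] > ratio)
          ambig <- c(ambig, e)
      }
      logRows[[length(logRows) + 1]] <-
        data.frame(contigA = lk$contigA[i], contigB = lk$contigB[i],
                   nLinks = lk$nLinks[i], reason = "ambiguous")
      next
    }
    sa <- scafOf[lk$contigA[i]]; sb <- scafOf[lk$contigB[i]]
    if (sa == sb) {
      logRows[[length(logRows) + 1]] <-
        data.frame(contigA = lk$contigA[i], contigB = lk$contigB[i],
                   nLinks = lk$nLinks[i], reason = "cycle")
      next
    }
    A <- scafs[[sa]]; B <- scafs[[sb]]
    if (.rightEnd(A) != ea) {
      if (.leftEnd(A) == ea) A <- .flipParts(A)
      else stop("internal error: link end not exposed")  # nocov
    }
    if (.leftEnd(B) != eb) {
      if (.rightEnd(B) == eb) B <- .flipParts(B)
      else stop("internal error: link end not exposed")  # nocov
    }
    A$gapAfter[nrow(A)] <- max(round(lk$gapMean[i]), minGap)
    A$gapEst[nrow(A)] <- lk$gapMean[i]
    merged <- rbind(A, B)
    scafs[[sa]] <- merged
    scafs[[sb]] <- NULL_DF
    scafOf[B$contig] <- sa
    used <- c(used, ea, eb)
    accepted[i] <- TRUE
  }
  alive <- which(vapply(scafs, nrow, 0L) > 0L)
  ctg <- contigs(assembly)
  totLen <- vapply(alive, function(s)
    sum(Biostrings::width(ctg[scafs[[s]]$contig])), 0)
  alive <- alive[order(-totLen, vapply(alive, function(s) scafs[[s]]$contig[1], ""))]
  seqs <- character(length(alive))
  layout <- list()
  for (k in seq_along(alive)) {
    s <- scafs[[alive[k]]]
    pieces <- character(0)
    for (r in seq_len(nrow(s))) {
      x <- as.character(ctg[[s$contig[r]]])
      if (s$orient[r] == "-")
        x <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(x)))
      pieces <- c(pieces, x)
      if (r < nrow(s))
        pieces <- c(pieces, strrep("N", as.integer(s$gapAfter[r])))
    }
    seqs[k] <- paste(pieces, collapse = "")
    layout[[k]] <- data.frame(scaffoldId = sprintf("%s_s%d", bacId(assembly), k),
                              contigId = s$contig, orientation = s$orient,
                              gapAfter = s$gapAfter, gapEstimate = s$gapEst)
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("%s_s%d", bacId(assembly), seq_along(alive))
  list(assembly = BacAssembly(bacId(assembly), out, stage = "scaffolded"),
       layout = do.call(rbind, layout),
       log = if (length(logRows)) do.call(rbind, logRows)
             else data.frame(contigA = character(), contigB = character(),
                             nLinks = integer(), reason = character()))
}

NULL_DF <- data.frame(contig = character(), orient = character(),
                      gapAfter = numeric(), gapEst = numeric())

#' Iterative multi-library scaffolding
#'
#' Runs the full per-library scaffolding scheme: for each library in order,
#' mate pairs are (re-)deconvoluted by mapping against the *current*
#' assemblies of all clones, the library insert size is estimated from
#' high-quality same-contig pairs, and every clone is scaffolded
#' independently from its own links. Later libraries therefore see the
#' scaffolds produced by earlier ones (the lower-coverage, longer-read
#' library should come first).
#'
#' @param assemblies named list of `BacAssembly` (names = clone ids; contig
#'   names must be unique across clones).
#' @param libraries list of libraries, each a list with elements `pairs`
#'   (`ReadPairs`), `kMin`, and optionally `insertMean` (estimated from the
#'   data when absent).
#' @param ratio,minGap see [greedyScaffold()].
#' @param minMapq insert-estimation quality filter, default 40.
#' @param seedLen internal mapper seed length.
#' @return list with `assemblies` (stage `scaffolded`), `layouts`, and
#'   `libraryStats` (one entry per library).
#' @export
iterativeScaffold <- function(assemblies, libraries, ratio = 0.7,
                              minGap = 1L, minMapq = 40L, seedLen = 21L) {
  layouts <- list()
  libStats <- list()
  for (li in seq_along(libraries)) {
    lib <- libraries[[li]]
    pairs <- lib$pairs
    targets <- do.call(c, unname(lapply(assemblies, contigs)))
    contig2bac <- stats::setNames(
      rep(vapply(assemblies, bacId, ""), vapply(assemblies, length, 0L)),
      names(targets))
    aln1 <- mapReads(Biostrings::DNAStringSet(mate1(pairs)), targets, seedLen)
    aln2 <- mapReads(Biostrings::DNAStringSet(mate2(pairs)), targets, seedLen)
    asg <- assignPairs(names(pairs), aln1, aln2, contig2bac)
    b1 <- bestHits(aln1); b2 <- bestHits(aln2)
    st <- estimateInsert(b1, b2, minMapq = minMapq,
                         libraryTag = libraryTag(pairs))
    insertMean <- if (!is.null(lib$insertMean)) lib$insertMean else st$insertMean
    libStats[[li]] <- c(st, list(kMin = lib$kMin, insertMeanUsed = insertMean,
                                 assignment = table(asg$reason)))
    for (bn in names(assemblies)) {
      a <- assemblies[[bn]]
      mine <- asg$pairId[!is.na(asg$bacId) & asg$bacId == bacId(a)]
      lks <- buildLinks(a, b1[b1$qname %in% mine, , drop = FALSE],
                        b2[b2$qname %in% mine, , drop = FALSE], insertMean)
      gs <- greedyScaffold(a, lks, lib$kMin, ratio, minGap)
      assemblies[[bn]] <- gs$assembly
      layouts[[paste(li, bn, sep = "_")]] <- gs$layout
    }
  }
  list(assemblies = assemblies, layouts = layouts, libraryStats = libStats)
}
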