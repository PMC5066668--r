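# Shared fixtures and independent oracles for the test suite.

randDna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

dnaSet <- function(...) {
  x <- c(...)
  Biostrings::DNAStringSet(x)
}

qreads <- function(seqs, quals) {
  # quals: list of integer vectors or single integer recycled per read
  if (!is.list(quals))
    quals <- lapply(nchar(seqs), function(w) rep(quals, w))
  Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs),
    Biostrings::PhredQuality(Biostrings::BStringSet(
      vapply(quals, function(q) intToUtf8(q + 33L), ""))))
}

revcomp <- function(s) as.character(
  Biostrings::reverseComplement(Biostrings::DNAString(s)))

# --- independent oracles -----------------------------------------------------

# L50: try every observed length as candidate L, keep the largest that still
# contains half the assembly.
l50Oracle <- function(lengths) {
  if (!length(lengths)) return(0)
  half <- sum(lengths) / 2
  cand <- sort(unique(lengths), decreasing = TRUE)
  ok <- vapply(cand, function(L) sum(lengths[lengths >= L]) >= half, TRUE)
  max(cand[ok])
}

# Modified-Mott trimming: exhaustive enumeration of all substrings via
# prefix-sum differences. Returns the optimum window, its objective, and the
# margin to the best window with different boundaries (for tie detection).
mottOracle <- function(q, limit = 0.05) {
  x <- limit - 10^(-q / 10)
  n <- length(x)
  P <- cumsum(c(0, x))
  M <- outer(P, P, "-")          # M[e+1, s+1] = sum over (s, e]
  valid <- row(M) > col(M)
  vals <- M[valid]
  if (!length(vals) || max(vals) <= 0)
    return(list(start = 1L, end = 0L, value = 0, margin = Inf))
  vmax <- max(vals)
  idx <- which(valid & M == vmax, arr.ind = TRUE)
  s <- min(idx[, "col"])                      # smallest start
  e <- max(idx[idx[, "col"] == s, "row"]) - 1L  # then largest end
  M2 <- M; M2[!valid] <- -Inf; M2[e + 1L, s] <- -Inf
  margin <- vmax - max(M2)
  list(start = as.integer(s), end = as.integer(e), value = vmax,
       margin = margin)
}

# Misassembly classification: literal per-boundary reimplementation working
# on explicit flank pairs.
misassemblyOracle <- function(aln, minAln = 100, dist = 1000) {
  a <- aln[aln$alnLen >= minAln, , drop = FALSE]
  out <- list()
  for (q in unique(a$qname)) {
    x <- a[a$qname == q, , drop = FALSE]
    x <- x[order(x$qstart), , drop = FALSE]
    if (nrow(x) < 2) next
    for (i in seq_len(nrow(x) - 1)) {
      lf <- x[i, ]; rf <- x[i + 1, ]
      if (lf$strand != rf$strand) {
        kl <- "global"; rs <- "strand"
      } else if (lf$strand == "+") {
        gap <- rf$tstart - lf$tend
        if (gap > dist) { kl <- "global"; rs <- "distance" }
        else if (gap < -dist) { kl <- "global"; rs <- "overlap" }
        else { kl <- "local"; rs <- if (gap >= 0) "distance" else "overlap" }
      } else {
        gap <- lf$tstart - rf$tend
        if (gap > dist) { kl <- "global"; rs <- "distance" }
        else if (gap < -dist) { kl <- "global"; rs <- "overlap" }
        else { kl <- "local"; rs <- if (gap >= 0) "distance" else "overlap" }
      }
      out[[length(out) + 1]] <- data.frame(queryId = q,
                                           queryPosition = lf$qend,
                                           klass = kl, reason = rs)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(queryId = character(), queryPosition = integer(),
                  klass = character(), reason = character())
}

# --- cached end-to-end run ---------------------------------------------------

.e2eCache <- new.env(parent = emptyenv())

e2eResult <- function() {
  if (is.null(.e2eCache$res)) {
    set.seed(1)
    .e2eCache$res <- runBacPipeline(simulationConfig(seed = 1L))
  }
  .e2eCache$res
}

# truth-based count of mate pairs usable as spanning support for each
# adjacency of each clone (non-duplicate, both mates mappable after clipping,
# each mate fully inside its flanking contig)
truthSpanningSupport <- function(res, lib) {
  truth <- res$mp[[lib]]$truth
  readLen <- res$mp[[lib]]$spec$readLen
  out <- list()
  for (b in names(res$perBac)) {
    tc <- res$perBac[[b]]$fragTruth$contigs
    tr <- truth[truth$bac == b & !truth$isDuplicate, , drop = FALSE]
    m1len <- ifelse(is.na(tr$adapter1), readLen, tr$adapter1)
    m2len <- ifelse(is.na(tr$adapter2), readLen, tr$adapter2)
    mappable <- m1len >= 21 & m2len >= 21
    for (i in seq_len(nrow(tc) - 1)) {
      inLeft <- tr$fragStart >= tc$fragStart[i] &
        tr$fragStart + m1len <= tc$fragEnd[i]
      inRight <- tr$fragEnd - m2len >= tc$fragStart[i + 1] &
        tr$fragEnd <= tc$fragEnd[i + 1]
      out[[length(out) + 1]] <- data.frame(
        bac = b, adjacency = i, support = sum(mappable & inLeft & inRight))
    }
  }
  do.call(rbind, out)
}
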