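#' Alignment tables
#'
#' All mapping and screening steps in bacplex exchange alignments as plain
#' `data.frame`s with one row per hit and a fixed set of columns:
#'
#' * `qname`, `tname` — query and target sequence ids;
#' * `qstart`, `qend`, `tstart`, `tend` — 0-based half-open intervals on the
#'   query forward strand and on the target;
#' * `strand` — `"+"` or `"-"`; `"-"` means the query aligns
#'   reverse-complemented relative to the target;
#' * `matches` — number of identical aligned bases;
#' * `alnLen` — aligned columns (`>= matches`);
#' * `identity` — `matches / alnLen` in `[0, 1]`;
#' * `mapq` — mapping quality, 0–60;
#' * `score` — alignment score (the internal mapper uses `matches`).
#'
#' `alignmentTable()` builds such a table from vectors and validates the
#' invariants; an empty call returns the empty prototype.
#'
#' @param qname,tname,qstart,qend,tstart,tend,strand,matches,alnLen,identity,mapq,score
#'   column vectors, recycled to a common length.
#' @return `data.frame` with the columns above.
#' @export
alignmentTable <- function(qname = character(), tname = character(),
                           qstart = integer(), qend = integer(),
                           tstart = integer(), tend = integer(),
                           strand = character(), matches = integer(),
                           alnLen = integer(), identity = numeric(),
                           mapq = integer(), score = numeric()) {
  df <- data.frame(qname = as.character(qname), tname = as.character(tname),
                   qstart = as.integer(qstart), qend = as.integer(qend),
                   tstart = as.integer(tstart), tend = as.integer(tend),
                   strand = as.character(strand), matches = as.integer(matches),
                   alnLen = as.integer(alnLen), identity = as.numeric(identity),
                   mapq = as.integer(mapq), score = as.numeric(score),
                   stringsAsFactors = FALSE)
  if (nrow(df)) {
    stopifnot(all(df$qstart >= 0L), all(df$qstart < df$qend),
              all(df$tstart >= 0L), all(df$tstart < df$tend),
              all(df$strand %in% c("+", "-")),
              all(df$identity >= 0 & df$identity <= 1),
              all(df$alnLen >= df$matches))
  }
  df
}

#' Read sequences from FASTA or FASTQ
#'
#' Thin wrapper over the Biostrings readers. FASTQ files yield a
#' [Biostrings::QualityScaledDNAStringSet] with Phred+33 qualities; FASTA a
#' plain `DNAStringSet`. Records keep their order and ids; duplicate ids or a
#' base/quality length mismatch raise an error.
#'
#' @param path file path.
#' @param format `"fasta"` or `"fastq"`; default guessed from the extension.
#' @return `DNAStringSet` or `QualityScaledDNAStringSet`.
#' @export
readSeqFile <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  x <- if (format == "fastq") {
    # Biostrings warns about dropping its own metadata columns here
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  } else {
    Biostrings::readDNAStringSet(path, format = "fasta")
  }
  # Biostrings keeps full description lines; ids are the first word
  if (length(x)) names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop("duplicate sequence ids in ", path)
  x
}

#' Write sequences to FASTA or FASTQ
#'
#' @param x `DNAStringSet` (FASTA) or `QualityScaledDNAStringSet` (either).
#' @param path output path.
#' @param format `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
writeSeqFile <- function(x, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "fastq") {
    if (!is(x, "QualityScaledXStringSet"))
      stop("FASTQ output requires quality-scaled reads")
    Biostrings::writeQualityScaledXStringSet(x, path)
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta")
  }
  invisible(path)
}

#' Phred scores of quality-scaled reads
#'
#' @param x `QualityScaledDNAStringSet`.
#' @return list of integer vectors, one per read.
#' @export
phredScores <- function(x) {
  as(Biostrings::quality(x), "IntegerList")
}

#' Import alignments from SAM or PAF
#'
#' Normalizes externally produced alignments to the bacplex
#' [alignmentTable()] convention (0-based half-open coordinates on the query
#' forward strand and the target). SAM text is converted through
#' `Rsamtools`; unmapped records are skipped, reference-consuming CIGAR width
#' gives the target interval and the `NM` tag (when present) the mismatch
#' count, otherwise identity 1 is assumed. PAF is the standard 12+ column
#' minimap2 format, already carrying both intervals and match counts.
#'
#' @param path input file.
#' @param dialect `"sam"` or `"paf"` (default from extension).
#' @param targetLengths optional named vector of target lengths used to check
#'   coordinate bounds; records outside bounds raise an error naming them.
#' @return [alignmentTable()]-style `data.frame`.
#' @export
readAlignments <- function(path, dialect = c("auto", "sam", "paf"),
                           targetLengths = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "paf"
  aln <- if (dialect == "sam") .readSam(path) else .readPaf(path)
  if (!is.null(targetLengths) && nrow(aln)) {
    tl <- targetLengths[aln$tname]
    bad <- which(is.na(tl) | aln$tend > tl)
    if (length(bad))
      stop("alignment outside target bounds: query ", aln$qname[bad[1]],
           " on ", aln$tname[bad[1]])
  }
  aln
}

.readSam <- function(path) {
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "mapq", "flag", "cigar", "seq"),
    tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  r <- Rsamtools::scanBam(bam, param = p)[[1]]
  n <- length(r$qname)
  if (n == 0L) return(alignmentTable())
  twidth <- GenomicAlignments::cigarWidthAlongReferenceSpace(r$cigar)
  # aligned query span in full-read coordinates (soft clips excluded from the
  # span but included in the offset)
  qrl <- GenomicAlignments::cigarRangesAlongQuerySpace(r$cigar,
                                                       ops = c("M", "I", "=", "X"))
  qr <- unlist(range(qrl), use.names = FALSE)
  alnLen <- GenomicAlignments::cigarWidthAlongQuerySpace(r$cigar,
                                                         after.soft.clipping = TRUE)
  qstart0 <- BiocGenerics::start(qr) - 1L
  qend0 <- BiocGenerics::end(qr)
  qlen <- GenomicAlignments::cigarWidthAlongQuerySpace(r$cigar,
                                                       after.soft.clipping = FALSE)
  rev <- bitwAnd(r$flag, 16L) != 0L
  # SAM stores reverse-strand reads reverse-complemented; flip the query
  # interval back onto the forward strand of the original read
  qs <- ifelse(rev, qlen - qend0, qstart0)
  qe <- ifelse(rev, qlen - qstart0, qend0)
  nm <- r$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, n)
  matches <- ifelse(is.na(nm), alnLen, pmax(0L, alnLen - nm))
  alignmentTable(qname = r$qname, tname = as.character(r$rname),
                 qstart = qs, qend = qe,
                 tstart = r$pos - 1L, tend = r$pos - 1L + twidth,
                 strand = ifelse(rev, "-", "+"),
                 matches = matches, alnLen = alnLen,
                 identity = matches / alnLen,
                 mapq = ifelse(is.na(r$mapq), 0L, r$mapq), score = matches)
}

.readPaf <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(alignmentTable())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 12L)
  if (length(short)) stop("malformed PAF record at line ", short[1])
  f <- function(i) vapply(parts, `[[`, "", i)
  strand <- f(5)
  if (!all(strand %in% c("+", "-")))
    stop("malformed PAF strand at line ", which(!strand %in% c("+", "-"))[1])
  matches <- as.integer(f(10))
  alnLen <- as.integer(f(11))
  alignmentTable(qname = f(1), tname = f(6),
                 qstart = as.integer(f(3)), qend = as.integer(f(4)),
                 tstart = as.integer(f(8)), tend = as.integer(f(9)),
                 strand = strand, matches = matches, alnLen = alnLen,
                 identity = matches / alnLen, mapq = as.integer(f(12)),
                 score = matches)
}

#' Export alignments as PAF
#'
#' @param aln [alignmentTable()] `data.frame`.
#' @param queryLengths,targetLengths named vectors of sequence lengths.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePaf <- function(aln, queryLengths, targetLengths, path) {
  lines <- sprintf("%s\t%d\t%d\t%d\t%s\t%s\t%d\t%d\t%d\t%d\t%d\t%d",
                   aln$qname, as.integer(queryLengths[aln$qname]),
                   aln$qstart, aln$qend, aln$strand,
                   aln$tname, as.integer(targetLengths[aln$tname]),
                   aln$tstart, aln$tend, aln$matches, aln$alnLen, aln$mapq)
  writeLines(lines, path)
  invisible(path)
}
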