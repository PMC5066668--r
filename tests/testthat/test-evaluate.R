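seg <- function(q, qs, qe, ts, te, strand = "+", alnLen = qe - qs) {
  alignmentTable(qname = q, tname = "ref", qstart = qs, qend = qe,
                 tstart = ts, tend = te, strand = strand,
                 matches = alnLen, alnLen = alnLen, identity = 1,
                 mapq = 60, score = alnLen)
}

test_that("breakpoints classify by strand, distance and overlap with strict 1 kb bounds", {
  # strand switch
  a <- rbind(seg("q", 0, 5000, 0, 5000, "+"), seg("q", 5000, 9000, 5000, 9000, "-"))
  cl <- classifyMisassemblies(a)$calls
  expect_equal(cl$klass, "global"); expect_equal(cl$reason, "strand")
  # 40 kb relocation
  a <- rbind(seg("q", 0, 5000, 0, 5000), seg("q", 5000, 9000, 45000, 49000))
  cl <- classifyMisassemblies(a)$calls
  expect_equal(cl$reason, "distance"); expect_equal(cl$klass, "global")
  # 200 bp apart: local
  a <- rbind(seg("q", 0, 5000, 0, 5000), seg("q", 5000, 9000, 5200, 9200))
  expect_equal(classifyMisassemblies(a)$calls$klass, "local")
  # exactly 1000 bp: still local (strict reading of "over 1 kb")
  a <- rbind(seg("q", 0, 5000, 0, 5000), seg("q", 5000, 9000, 6000, 10000))
  expect_equal(classifyMisassemblies(a)$calls$klass, "local")
  expect_equal(classifyMisassemblies(a, distThresh = 999L)$calls$klass, "global")
  # overlap > 1 kb: global
  a <- rbind(seg("q", 0, 5000, 0, 5000), seg("q", 5000, 9000, 3500, 7500))
  cl <- classifyMisassemblies(a)$calls
  expect_equal(cl$klass, "global"); expect_equal(cl$reason, "overlap")
  # one spanning alignment: no calls; short alignments filtered before pairing
  expect_equal(nrow(classifyMisassemblies(seg("q", 0, 9000, 0, 9000))$calls), 0L)
  a <- rbind(seg("q", 0, 5000, 0, 5000), seg("q", 5000, 5050, 40000, 40050),
             seg("q", 5050, 9000, 5050, 9000))
  expect_equal(nrow(classifyMisassemblies(a)$calls), 1L)  # middle flank dropped
})

test_that("the classifier agrees with an independent pairwise oracle", {
  set.seed(80)
  ok <- vapply(1:1000, function(i) {
    k <- sample(1:5, 1)
    qs <- sort(sample.int(50000, k))
    lens <- sample(c(80, 150, 400, 2000), k, replace = TRUE)
    a <- do.call(rbind, lapply(seq_len(k), function(j) {
      ts <- sample.int(60000, 1)
      seg(sprintf("q%d", i), qs[j], qs[j] + lens[j],
          ts = ts, te = ts + lens[j], strand = sample(c("+", "-"), 1),
          alnLen = lens[j])
    }))
    got <- classifyMisassemblies(a)$calls
    want <- misassemblyOracle(a)
    isTRUE(all.equal(got[, c("queryId", "queryPosition", "klass", "reason")],
                     want, check.attributes = FALSE))
  }, TRUE)
  expect_true(all(ok))
})

test_that("genome fraction is the union of covered reference intervals", {
  a <- rbind(seg("q1", 0, 600, 0, 600), seg("q2", 0, 600, 400, 1000))
  expect_equal(genomeFraction(a, 1000), 100)
  expect_equal(genomeFraction(seg("q", 0, 990, 5, 995), 1000), 99)
  expect_error(genomeFraction(a, 0), "positive")
  # brute-force per-base comparison on random instances
  set.seed(81)
  for (i in 1:50) {
    n <- sample(1:6, 1)
    ts <- sample.int(900, n)
    te <- pmin(ts + sample.int(300, n), 1000)
    a <- do.call(rbind, lapply(seq_len(n), function(j)
      seg(sprintf("q%d", j), 0, te[j] - ts[j], ts[j], te[j])))
    covered <- logical(1000)
    for (j in seq_len(n)) covered[(ts[j] + 1):te[j]] <- TRUE
    expect_equal(genomeFraction(a, 1000), 100 * mean(covered))
  }
})

test_that("k-mer masking flags exactly the bases under abundant k-mers", {
  set.seed(82)
  uniqueSeq <- randDna(300)
  idx <- buildKmerIndex(dnaSet(x = strrep(randDna(21), 50)), k = 21)
  expect_equal(kmerMask(uniqueSeq, idx, minCount = 5)$maskedFraction, 0)
  # a pure tandem repeat with an abundant index is fully masked
  unit <- randDna(21)
  tandem <- strrep(unit, 10)
  idx2 <- buildKmerIndex(dnaSet(x = strrep(unit, 60)), k = 21)
  m <- kmerMask(tandem, idx2, minCount = 10)
  expect_equal(m$maskedFraction, 1.0)
  # one abundant 21-mer in unique context masks exactly 21 bases
  hot <- randDna(21)
  idx3 <- buildKmerIndex(dnaSet(x = strrep(hot, 30)), k = 21)
  s <- paste0(uniqueSeq, hot, randDna(300))
  m3 <- kmerMask(s, idx3, minCount = 10)
  expect_equal(m3$intervals$start, 300)
  expect_equal(m3$intervals$end, 321)
  # reverse complement counts toward the same canonical k-mer
  m4 <- kmerMask(paste0(uniqueSeq, revcomp(hot), randDna(300)), idx3,
                 minCount = 10)
  expect_equal(nrow(m4$intervals), 1L)
  # shorter than k
  expect_equal(kmerMask("ACGT", idx3, minCount = 1)$maskedFraction, 0)
})

test_that("repeat overlap fractions honour identity thresholds and are monotone", {
  masked <- list(intervals = data.frame(start = c(0, 500), end = c(200, 800)))
  mkAln <- function(ts, te, id) alignmentTable(
    qname = "w", tname = "s", qstart = 0, qend = te - ts, tstart = ts,
    tend = te, strand = "+", matches = round(id * (te - ts)),
    alnLen = te - ts, identity = id, mapq = 60, score = te - ts)
  # a single 85%-identity alignment covering everything
  f <- repeatOverlapFraction(masked, mkAln(0, 1000, 0.85))
  expect_equal(f$fraction[f$threshold == 80], 1.0)
  expect_equal(f$fraction[f$threshold == 99], 0.0)
  expect_true(all(diff(f$fraction) <= 0))
  # no alignments
  f0 <- repeatOverlapFraction(masked, mkAln(0, 10, 1)[0, ])
  expect_true(all(f0$fraction == 0))
  # full coverage at identity 1
  f1 <- repeatOverlapFraction(masked, mkAln(0, 1000, 1))
  expect_true(all(f1$fraction == 1))
  # zero masked bases: flagged undefined
  fU <- repeatOverlapFraction(list(intervals = data.frame(start = integer(),
                                                          end = integer())),
                              mkAln(0, 1000, 1))
  expect_true(all(fU$undefined))
  # partial coverage, mixed identities, random instances stay monotone
  set.seed(83)
  for (i in 1:20) {
    n <- sample(1:5, 1)
    ts <- sample.int(900, n); te <- pmin(ts + sample.int(400, n), 1000)
    ids <- runif(n, 0.75, 1)
    a <- do.call(rbind, lapply(seq_len(n), function(j) mkAln(ts[j], te[j], ids[j])))
    fr <- repeatOverlapFraction(masked, a)$fraction
    expect_true(all(diff(fr) <= 1e-12))
  }
})

test_that("masked intervals export as 3-column BED", {
  m <- list(intervals = data.frame(start = c(10, 50), end = c(31, 99)))
  f <- tempfile(fileext = ".bed")
  writeMaskBed(m, "ctg1", f)
  expect_equal(readLines(f), c("ctg1\t10\t31", "ctg1\t50\t99"))
})
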