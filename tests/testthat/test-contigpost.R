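hitRow <- function(tname, tstart, tend, identity = 1) {
  data.frame(tname = tname, tstart = tstart, tend = tend, identity = identity)
}

test_that("terminal vector hits are clipped with BAC-end flags; internal hits warn", {
  set.seed(30)
  a <- BacAssembly("b", dnaSet(c1 = randDna(5000), c2 = randDna(4000),
                               c3 = randDna(6000)))
  hits <- rbind(hitRow("c1", 0, 300),
                hitRow("c3", 0, 250), hitRow("c3", 5600, 6000),
                hitRow("c2", 1800, 2000))  # internal
  expect_warning(cv <- clipVector(a, hits), "internal")
  out <- cv$assembly
  expect_equal(Biostrings::width(contigs(out)), c(4700L, 4000L, 5350L))
  cd <- contigData(out)
  expect_true(cd["c1", "bacEndLeft"] && !cd["c1", "bacEndRight"])
  expect_false(cd["c2", "bacEndLeft"] || cd["c2", "bacEndRight"])
  expect_true(cd["c3", "bacEndLeft"] && cd["c3", "bacEndRight"])
  # clipped sequence is a suffix of the original (no base invented)
  expect_identical(as.character(contigs(out)[["c1"]]),
                   substr(as.character(contigs(a)[["c1"]]), 301, 5000))
  # no hits: untouched
  cv2 <- clipVector(a, hits[0, ])
  expect_identical(as.character(contigs(cv2$assembly)),
                   as.character(contigs(a)))
})

test_that("length filter keeps 500 bp and drops 499 bp", {
  a <- BacAssembly("b", dnaSet(ok = strrep("A", 500), no = strrep("C", 499)))
  expect_equal(names(filterLength(a)), "ok")
  expect_length(filterLength(BacAssembly("b", dnaSet())), 0)
})

test_that("coverage is summed full read length over contig length", {
  a <- BacAssembly("b", dnaSet(c1 = strrep("A", 1000), c2 = strrep("C", 970)))
  best <- alignmentTable(qname = sprintf("r%d", 1:10), tname = "c1",
                         qstart = 0, qend = 100, tstart = 0, tend = 100,
                         strand = "+", matches = 100, alnLen = 100,
                         identity = 1, mapq = 60, score = 100)
  rl <- stats::setNames(rep(100, 10), sprintf("r%d", 1:10))
  out <- contigCoverage(a, best, rl)
  expect_equal(contigData(out)$coverage, c(1.0, 0))
  # 97 bp reads on a 9700 bp contig at 10x
  a2 <- BacAssembly("b", dnaSet(c1 = strrep("A", 9700)))
  best2 <- alignmentTable(qname = sprintf("r%d", 1:1000), tname = "c1",
                          qstart = 0, qend = 97, tstart = 0, tend = 97,
                          strand = "+", matches = 97, alnLen = 97,
                          identity = 1, mapq = 60, score = 97)
  out2 <- contigCoverage(a2, best2,
                         stats::setNames(rep(97, 1000), sprintf("r%d", 1:1000)))
  expect_equal(contigData(out2)$coverage, 10.0)
})

test_that("coverage filter uses the trimmed mean and applies the threshold to all", {
  mk <- function(cov) {
    n <- length(cov)
    BacAssembly("b", dnaSet(stats::setNames(
      vapply(seq_len(n), function(i) randDna(600), ""),
      sprintf("c%02d", seq_len(n)))), coverage = cov)
  }
  set.seed(31)
  # [100 x9, 5]: one trimmed, mean 100, T = 50, the cov-5 contig removed
  cf <- coverageFilter(mk(c(rep(100, 9), 5)))
  expect_equal(cf$threshold, 50)
  expect_equal(cf$removed, "c10")
  # trimmed-set mean 306 -> threshold 153
  cov <- c(300, 312, 306, 306, 306, 306, 306, 306, 306, 306, 10)
  cf2 <- coverageFilter(mk(cov))
  expect_equal(cf2$threshold, 153)
  expect_equal(cf2$removed, "c11")
  # equal coverage: T = 0.5c, nothing removed
  cf3 <- coverageFilter(mk(rep(40, 6)))
  expect_length(cf3$removed, 0)
  # methods variant
  cf4 <- coverageFilter(mk(c(rep(100, 9), 5)), safety = 0.9)
  expect_equal(cf4$threshold, 45)
  expect_error(coverageFilter(BacAssembly("b", dnaSet())), "empty")
})

test_that("contaminant screen clips ends, removes internal hits and short leftovers", {
  set.seed(32)
  a <- BacAssembly("b", dnaSet(phix = randDna(800), weak = randDna(2000),
                               edge = randDna(600), okc = randDna(3000)))
  hits <- rbind(hitRow("phix", 0, 800),            # fully covered -> removed
                hitRow("weak", 500, 700, 0.89),    # below identity -> ignored
                hitRow("edge", 450, 600))          # clip to 450 -> short
  cs <- contaminantScreen(a, hits)
  expect_equal(names(contigs(cs$assembly)), c("weak", "okc"))
  rep <- cs$report
  expect_equal(rep$action[rep$id == "phix"], "contaminant")
  expect_equal(rep$action[rep$id == "edge"], "short")
  expect_equal(rep$action[rep$id == "weak"], "kept")
  # an internal qualifying hit removes the whole contig
  cs2 <- contaminantScreen(a, hitRow("okc", 1400, 1600))
  expect_false("okc" %in% names(contigs(cs2$assembly)))
})

test_that("cross-contamination contigs are purged and true contigs kept end to end", {
  cfg <- simulationConfig(seed = 44, genomeLen = 3e5, nBacs = 2,
                          insertLenMean = 40000, insertLenSd = 500)
  res <- runBacPipeline(cfg, peDepth = 15,
                        mpLibs = list(list(tag = "mp", insertMean = 5500,
                                           insertSd = 550, readLen = 250L,
                                           kMin = 10L, nPairsPerBac = 300L)),
                        nFragments = 3L)
  for (b in names(res$perBac)) {
    rep <- res$perBac[[b]]$post$report
    contam <- res$perBac[[b]]$rawTruth$contamOnly
    kept <- rep$id[rep$lenAfter > 0]
    expect_length(intersect(contam, kept), 0)
    expect_setequal(setdiff(rep$id, contam), kept)
    # retained sequence is always a substring of the input contig
    post <- contigs(res$perBac[[b]]$post$assembly)
    raw <- contigs(res$perBac[[b]]$rawAssembly)
    for (id in names(post))
      expect_true(grepl(as.character(post[[id]]), as.character(raw[[id]]),
                        fixed = TRUE))
  }
})
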