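# A two-contig clone with a known gap, spanning pairs built by construction.
spanningFixture <- function(seed = 70, lenA = 20000, lenB = 15000, gap = 800,
                            nSpan = 30, insertMean = 6000) {
  set.seed(seed)
  ref <- randDna(lenA + gap + lenB)
  ctgA <- substr(ref, 1, lenA)
  ctgB <- substr(ref, lenA + gap + 1, lenA + gap + lenB)
  asm <- BacAssembly("bacS", dnaSet(cA = ctgA, cB = ctgB))
  frags <- round(rnorm(nSpan, insertMean, insertMean * 0.05))
  # place fragments across the gap so both mates land on contigs
  fs <- lenA - round(runif(nSpan, 0.3, 0.7) * frags)
  m1 <- substring(ref, fs, fs + 99)
  m2 <- vapply(substring(ref, fs + frags - 100, fs + frags - 1), revcomp, "")
  names(m1) <- names(m2) <- sprintf("sp%03d", seq_len(nSpan))
  list(assembly = asm,
       aln1 = bestHits(mapReads(Biostrings::DNAStringSet(m1), contigs(asm))),
       aln2 = bestHits(mapReads(Biostrings::DNAStringSet(m2), contigs(asm))),
       gap = gap, insertMean = insertMean, trueFrags = frags)
}

test_that("spanning pairs form one tail-head link with a sane gap estimate", {
  fx <- spanningFixture()
  lk <- buildLinks(fx$assembly, fx$aln1, fx$aln2, fx$insertMean)
  expect_equal(nrow(lk), 1L)
  expect_equal(lk$nLinks, 30L)
  expect_equal(lk$contigA, "cA"); expect_equal(lk$endA, "tail")
  expect_equal(lk$contigB, "cB"); expect_equal(lk$endB, "head")
  # gap recovered within 3 standard errors (fragment sd propagates to gaps)
  se <- sd(unlist(lk$gaps)) / sqrt(lk$nLinks)
  expect_lt(abs(lk$gapMean - fx$gap), 3 * se + 1)
  # no pairs -> no links
  expect_equal(nrow(buildLinks(fx$assembly, fx$aln1[0, ], fx$aln2[0, ], 6000)), 0L)
})

test_that("links below the support threshold leave contigs separate", {
  fx <- spanningFixture(nSpan = 5)
  lk <- buildLinks(fx$assembly, fx$aln1, fx$aln2, fx$insertMean)
  gs <- greedyScaffold(fx$assembly, lk, kMin = 10)
  expect_equal(length(contigs(gs$assembly)), 2L)
  gs2 <- greedyScaffold(fx$assembly, lk, kMin = 5)
  expect_equal(length(contigs(gs2$assembly)), 1L)
})

test_that("an accepted join renders an N gap and conserves sequence content", {
  fx <- spanningFixture(nSpan = 25)
  lk <- buildLinks(fx$assembly, fx$aln1, fx$aln2, fx$insertMean)
  gs <- greedyScaffold(fx$assembly, lk, kMin = 20)
  sc <- contigs(gs$assembly)
  expect_equal(length(sc), 1L)
  s <- as.character(sc[[1]])
  expect_true(grepl("N", s))
  nGap <- nchar(gsub("[ACGT]", "", s))
  expect_equal(nGap, max(round(lk$gapMean), 1))
  expect_identical(sequenceContent(sc), sequenceContent(contigs(fx$assembly)))
  expect_equal(gs$layout$contigId, c("cA", "cB"))
  expect_equal(gs$layout$orientation, c("+", "+"))
})

test_that("a consistent three-contig chain is recovered in order and orientation", {
  set.seed(72)
  lens <- c(18000, 14000, 16000)
  gaps <- c(700, 900)
  ref <- randDna(sum(lens) + sum(gaps))
  s1 <- substr(ref, 1, lens[1])
  s2 <- substr(ref, lens[1] + gaps[1] + 1, lens[1] + gaps[1] + lens[2])
  o3 <- sum(lens[1:2]) + sum(gaps)
  s3 <- substr(ref, o3 + 1, o3 + lens[3])
  # store the middle contig reverse-complemented to exercise orientation
  asm <- BacAssembly("bacC", dnaSet(k1 = s1, k2 = revcomp(s2), k3 = s3))
  n <- 120
  frags <- round(rnorm(n, 6000, 300))
  fs <- sample.int(nchar(ref) - max(frags) - 1, n)
  m1 <- substring(ref, fs, fs + 99)
  m2 <- vapply(substring(ref, fs + frags - 100, fs + frags - 1), revcomp, "")
  names(m1) <- names(m2) <- sprintf("p%03d", seq_len(n))
  a1 <- bestHits(mapReads(Biostrings::DNAStringSet(m1), contigs(asm)))
  a2 <- bestHits(mapReads(Biostrings::DNAStringSet(m2), contigs(asm)))
  lk <- buildLinks(asm, a1, a2, 6000)
  gs <- greedyScaffold(asm, lk, kMin = 5)
  expect_equal(length(contigs(gs$assembly)), 1L)
  lay <- gs$layout
  ok <- identical(lay$contigId, c("k1", "k2", "k3")) &&
    identical(lay$orientation, c("+", "-", "+"))
  okRev <- identical(lay$contigId, c("k3", "k2", "k1")) &&
    identical(lay$orientation, c("-", "+", "-"))
  expect_true(ok || okRev)
  # scaffold L50 never drops below contig L50
  expect_gte(assemblyStats(gs$assembly)$l50, assemblyStats(asm)$l50)
})

test_that("each contig end joins at most once and cycles are refused", {
  lk <- data.frame(contigA = c("a", "a", "b"), endA = c("tail", "tail", "head"),
                   contigB = c("b", "c", "c"), endB = c("head", "head", "tail"),
                   nLinks = c(30L, 29L, 25L), gapMean = c(100, 100, 100))
  lk$gaps <- list(100, 100, 100)
  asm <- BacAssembly("bacX", dnaSet(a = strrep("A", 600), b = strrep("C", 600),
                                    c = strrep("G", 600)))
  gs <- greedyScaffold(asm, lk, kMin = 1, ratio = 0.999)
  # a:tail-b:head accepted; a:tail-c:head blocked (end used);
  # b:head-c:tail blocked (end used)
  expect_equal(nrow(gs$layout[gs$layout$scaffoldId == gs$layout$scaffoldId[1], ]),
               2L)
  expect_true(all(c("end_unavailable") %in% gs$log$reason))
  # cycle: joining the two ends of one scaffold
  lk2 <- data.frame(contigA = c("a", "a"), endA = c("tail", "head"),
                    contigB = c("b", "b"), endB = c("head", "tail"),
                    nLinks = c(30L, 20L), gapMean = c(100, 100))
  lk2$gaps <- list(100, 100)
  gs2 <- greedyScaffold(asm[c("a", "b")], lk2, kMin = 1, ratio = 0.5)
  expect_true("cycle" %in% gs2$log$reason)
  expect_equal(length(contigs(gs2$assembly)), 1L)
})

test_that("competing links above the ambiguity ratio block a join", {
  lk <- data.frame(contigA = c("a", "a"), endA = c("tail", "tail"),
                   contigB = c("b", "c"), endB = c("head", "head"),
                   nLinks = c(30L, 28L), gapMean = c(100, 100))
  lk$gaps <- list(100, 100)
  asm <- BacAssembly("bacY", dnaSet(a = strrep("A", 600), b = strrep("C", 600),
                                    c = strrep("G", 600)))
  gs <- greedyScaffold(asm, lk, kMin = 1, ratio = 0.7)
  expect_equal(length(contigs(gs$assembly)), 3L)  # nothing joined
  expect_true("ambiguous" %in% gs$log$reason)
  # with a permissive ratio the strongest link wins
  gs2 <- greedyScaffold(asm, lk, kMin = 1, ratio = 0.95)
  expect_equal(length(contigs(gs2$assembly)), 2L)
})

test_that("single-library iteration equals one greedy round and empty input is identity", {
  fx <- spanningFixture(nSpan = 25)
  out <- iterativeScaffold(list(bacS = fx$assembly), list())
  expect_identical(out$assemblies$bacS, fx$assembly)
})
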