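test_that("generators are byte-identical under the same seed", {
  cfg <- simulationConfig(seed = 90, genomeLen = 1e5, nBacs = 2,
                          insertLenMean = 30000, insertLenSd = 300)
  r1 <- makeReferenceSet(cfg)
  r2 <- makeReferenceSet(cfg)
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  expect_identical(as.character(r1$inserts), as.character(r2$inserts))
  p1 <- simulatePeReads(r1, "bac1", 200, seed = 7)
  p2 <- simulatePeReads(r2, "bac1", 200, seed = 7)
  expect_identical(as.character(mate1(p1$pairs)), as.character(mate1(p2$pairs)))
  expect_identical(p1$truth, p2$truth)
  m1 <- simulateMatepairs(r1, 50, 5500, 550, 100, seed = 8)
  m2 <- simulateMatepairs(r2, 50, 5500, 550, 100, seed = 8)
  expect_identical(as.character(mate2(m1$pairs)), as.character(mate2(m2$pairs)))
})

test_that("zero clones give an empty insert set", {
  cfg <- simulationConfig(seed = 91, genomeLen = 5e4, nBacs = 0,
                          insertLenMean = 10000)
  expect_length(makeReferenceSet(cfg)$inserts, 0)
})

test_that("planted repeat copies carry the configured identity", {
  cfg <- simulationConfig(seed = 92, genomeLen = 2e5, nBacs = 0,
                          insertLenMean = 10000, repeatFamilies = 1L,
                          repeatCopies = 6L, repeatLen = 2000L,
                          repeatIdentity = 0.90)
  refs <- makeReferenceSet(cfg)
  reps <- refs$truth$repeats
  g <- as.character(refs$genome[[1]])
  copies <- substring(g, reps$start + 1L, reps$end)
  # measure pairwise identity of planted copies by direct comparison
  pid <- combn(copies, 2, function(p) {
    mean(strsplit(p[1], "")[[1]] == strsplit(p[2], "")[[1]])
  })
  # two copies each at 90% to the ancestor: expected pairwise ~0.81 + chance
  expect_gt(min(pid), 0.75)
  expect_lt(max(pid), 0.88)
})

test_that("error-free uncontaminated reads are exact substrings of their source", {
  cfg <- simulationConfig(seed = 93, genomeLen = 1e5, nBacs = 1,
                          insertLenMean = 40000, insertLenSd = 100,
                          errorRate = 0, contaminationRate = 0,
                          lowQualityRate = 0)
  refs <- makeReferenceSet(cfg)
  pe <- simulatePeReads(refs, "bac1", 300)
  src <- list(insert = as.character(refs$inserts[[1]]),
              vector = as.character(refs$vector[[1]]),
              host = as.character(refs$host[[1]]))
  m1 <- as.character(mate1(pe$pairs))
  for (i in seq_len(nrow(pe$truth))) {
    tr <- pe$truth[i, ]
    expect_identical(m1[[tr$pairId]],
                     substr(src[[tr$source]], tr$fragStart + 1L,
                            tr$fragStart + nchar(m1[[tr$pairId]])))
  }
})

test_that("simulated source fractions match their nominal rates", {
  cfg <- simulationConfig(seed = 94, genomeLen = 2e5, nBacs = 2,
                          insertLenMean = 60000, insertLenSd = 100,
                          contaminationRate = 0.05)
  refs <- makeReferenceSet(cfg)
  pe <- simulatePeReads(refs, "bac1", 10000)
  expect_equal(mean(pe$truth$source == "cross"), 0.05, tolerance = 0.2)
  spans <- pe$truth$fragEnd - pe$truth$fragStart
  expect_equal(mean(spans), cfg$peInsertMean, tolerance = 0.01)
})

test_that("mate-pair truth marks adapters and read-through obeys the rate", {
  cfg <- simulationConfig(seed = 95, genomeLen = 1.2e5, nBacs = 1,
                          insertLenMean = 60000, insertLenSd = 100,
                          mpAdapterRate = 0, dupRate = 0, errorRate = 0,
                          repeatFamilies = 0L)
  refs <- makeReferenceSet(cfg)
  sim <- simulateMatepairs(refs, 500, 5500, 550, 100)
  expect_true(all(is.na(sim$truth$adapter1)))
  reads <- Biostrings::DNAStringSet(mate1(sim$pairs))
  expect_true(all(Biostrings::vcountPattern(cfg$junctionAdapter, reads) == 0))
  # clipped reads map back inward across the true fragment
  ins <- refs$inserts
  b1 <- bestHits(mapReads(reads, ins))
  tr <- sim$truth[match(b1$qname, sim$truth$pairId), ]
  expect_true(all(b1$tstart == tr$fragStart))
  expect_true(all(b1$strand == "+"))
})

test_that("fragmented contigs reconstruct the insert up to recorded gaps", {
  set.seed(96)
  ins <- Biostrings::DNAString(randDna(50000))
  fa <- fragmentAssembly(ins, "bacF", 5)
  expect_length(fa$contigs, 5)
  tc <- fa$truth$contigs
  ch <- as.character(ins)
  for (i in seq_len(5))
    expect_identical(as.character(fa$contigs[[i]]),
                     substr(ch, tc$fragStart[i] + 1L, tc$fragEnd[i]))
  expect_equal(tc$fragStart[-1] - tc$fragEnd[-5], fa$gaps)
  # single fragment, no events: the contig is the insert
  fa1 <- fragmentAssembly(ins, "bacF", 1)
  expect_identical(as.character(fa1$contigs[[1]]), ch)
  # an induced inversion is seen by the classifier on the truth alignments
  fa2 <- fragmentAssembly(ins, "bacF", 2,
                          events = list(list(frag = 1, type = "inversion",
                                             at = 4000, len = 2000)))
  cl <- classifyMisassemblies(fa2$truth$segments)$calls
  expect_gte(sum(cl$klass == "global" & cl$reason == "strand"), 1)
})
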