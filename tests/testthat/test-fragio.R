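test_that("a sequence-through pair curates to the reverse read's end", {
  # forward read 1001-1150, reverse read 1001-1140: the forward read ran
  # through the 140 bp fragment into adapter; the fragment is 1001-1140.
  sam <- writeSam(samPair("p1", "chr1", 1001L, 150L, 1001L, 140L))
  fs <- readBam(sam)
  fr <- fragments(fs)
  expect_equal(length(fr), 1L)
  expect_equal(GenomicRanges::start(fr), 1001L)
  expect_equal(GenomicRanges::end(fr), 1140L)
  expect_equal(GenomicRanges::width(fr), 140L)
})

test_that("problematicLength reports the outermost span", {
  sam <- writeSam(c(
    samPair("a", "chr1", 1001L, 150L, 1001L, 140L),   # sequence-through: 150
    samPair("b", "chr1", 1001L, 150L, 1201L, 150L)))  # long fragment: 350
  rp <- readPairs(sam)
  pl <- setNames(problematicLength(rp$pairs), rp$pairs$qname)
  expect_equal(unname(pl["a"]), 150L)
  expect_equal(unname(pl["b"]), 350L)
  # the curated length of the long fragment agrees with the naive span
  cur <- curatePairs(rp$pairs, c(chr1 = 200000L))
  expect_equal(cur$length[cur$qname == "b"], 350L)
  expect_equal(cur$length[cur$qname == "a"], 140L)
})

test_that("QC policy rejects on mapq, flags, and proper-pair on request", {
  sam <- writeSam(c(
    samPair("ok", "chr1", 1001L, 100L, 1101L, 100L),
    samPair("lowq", "chr1", 2001L, 100L, 2101L, 100L, mapq2 = 29L),
    samPair("edge", "chr1", 3001L, 100L, 3101L, 100L, mapq1 = 30L),
    samPair("dup", "chr1", 4001L, 100L, 4101L, 100L,
            flag1 = FWD1 + 1024L, flag2 = REV2 + 1024L),
    samPair("sec", "chr1", 5001L, 100L, 5101L, 100L,
            flag1 = FWD1 + 256L, flag2 = REV2 + 256L),
    samPair("noprop", "chr1", 6001L, 100L, 6101L, 100L,
            flag1 = FWD1 - 2L, flag2 = REV2 - 2L)))
  rp <- readPairs(sam)
  qc <- setNames(applyQC(rp$pairs), rp$pairs$qname)
  expect_equal(unname(qc["ok"]), "pass")
  expect_equal(unname(qc["lowq"]), "MAPQ")
  expect_equal(unname(qc["edge"]), "pass")   # mapq 30 passes at minMapq 30
  expect_equal(unname(qc["dup"]), "DUPLICATE")
  expect_equal(unname(qc["sec"]), "SECONDARY")
  expect_equal(unname(qc["noprop"]), "pass") # proper-pair filter off
  qc2 <- setNames(applyQC(rp$pairs, qcPolicy(requireProperPair = TRUE)),
                  rp$pairs$qname)
  expect_equal(unname(qc2["noprop"]), "PROPER_PAIR")
})

test_that("curation rejects discordant, same-strand, and outward pairs", {
  sam <- writeSam(c(
    samPair("disc", "chr1", 1001L, 100L, 1101L, 100L, chrom2 = "chr2"),
    samPair("same", "chr1", 2001L, 100L, 2101L, 100L,
            flag1 = 1L + 2L + 64L, flag2 = 1L + 2L + 128L),  # both forward
    samPair("outw", "chr1", 3001L, 100L, 3201L, 100L,
            flag1 = 1L + 16L + 64L, flag2 = 1L + 32L + 128L),
    samPair("ok", "chr1", 4001L, 100L, 4101L, 100L)),
    contigs = c(chr1 = 200000L, chr2 = 200000L))
  fs <- readBam(sam)
  rej <- rejectionCounts(fs)
  expect_equal(unname(rej["SEQNAME_DISCORDANT"]), 1L)
  expect_equal(unname(rej["NO_STRAND"]), 1L)
  expect_equal(unname(rej["NOT_INWARD"]), 1L)
  expect_equal(length(fragments(fs)), 1L)
  expect_equal(pairsIn(fs), 4L)
})

test_that("curatePairs flags out-of-bound fragments and unknown contigs", {
  sam <- writeSam(samPair("p", "chr1", 1001L, 100L, 1101L, 100L))
  rp <- readPairs(sam)
  expect_error(curatePairs(rp$pairs, c(chrZ = 1000L)), "unknown contig")
  cur <- curatePairs(rp$pairs, c(chr1 = 1150L))  # rev end 1200 > 1150
  expect_equal(cur$outcome, "OUT_OF_BOUND")
})

test_that("orphan records are counted, not dropped silently", {
  rec <- samRecord("lonely", FWD1, "chr1", 1001L, 60L, "100M", len = 100L)
  sam <- writeSam(c(rec, samPair("p", "chr1", 2001L, 100L, 2101L, 100L)))
  rp <- readPairs(sam)
  expect_equal(nrow(rp$pairs), 1L)
  expect_equal(nrow(rp$orphans), 1L)
  expect_equal(rp$orphans$qname, "lonely")
  fs <- readBam(sam)
  expect_equal(orphanCount(fs), 1L)
  expect_equal(pairsIn(fs), 1L)
})

test_that("streaming with a small yieldSize matches one-shot reading", {
  sim <- artifactSim()
  small <- readBam(sim$files$bam, yieldSize = 257L)
  big <- readBam(sim$files$bam, yieldSize = 1000000L)
  expect_identical(rejectionCounts(small), rejectionCounts(big))
  expect_equal(pairsIn(small), pairsIn(big))
  frS <- fragments(small)
  frB <- fragments(big)
  o1 <- order(S4Vectors::mcols(frS)$qname)
  o2 <- order(S4Vectors::mcols(frB)$qname)
  expect_identical(as.character(frS[o1]), as.character(frB[o2]))
})

test_that("region queries recover pairs whose mate lies outside the window", {
  sim <- cleanSim()
  win <- GenomicRanges::GRanges("chr1", IRanges::IRanges(20000L, 30000L))
  rp <- readPairs(sim$files$bam, region = win)
  expect_gt(nrow(rp$pairs), 0L)
  # every returned pair has both mates (no NA coordinates)
  expect_false(anyNA(rp$pairs$start1))
  expect_false(anyNA(rp$pairs$start2))
})

test_that("non-paired input is refused", {
  # single-end records sharing query names (e.g. merged technical replicates)
  rec <- c(
    samRecord("s1", 0L, "chr1", 1001L, 60L, "50M", len = 50L),
    samRecord("s1", 16L, "chr1", 1101L, 60L, "50M", len = 50L),
    samRecord("s2", 0L, "chr1", 2001L, 60L, "50M", len = 50L),
    samRecord("s2", 16L, "chr1", 2101L, 60L, "50M", len = 50L))
  sam <- writeSam(rec)
  expect_error(readPairs(sam), "paired-end")
})

test_that("readFragTSV converts 0-based half-open rows and filters on mapq", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chr1\t1000\t1140\t60\t+",
               "chr1\t5000\t5167\t29\t-",
               "chr2\t100\t434\t35\t+"), path)
  fs <- readFragTSV(path)
  fr <- fragments(fs)
  expect_equal(length(fr), 2L)
  expect_equal(GenomicRanges::start(fr)[1], 1001L)
  expect_equal(GenomicRanges::end(fr)[1], 1140L)
  expect_equal(GenomicRanges::width(fr)[1], 140L)
  expect_equal(unname(rejectionCounts(fs)["MAPQ"]), 1L)
  expect_equal(pairsIn(fs), 3L)
})

test_that("readFragTSV handles headers and reports bad rows by line", {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tmapq\tstrand",
               "chr1\t1000\t1140\t60\t+",
               "chr1\toops\t2000\t60\t+"), path)
  expect_error(readFragTSV(path), "line 3")
  path2 <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tstart\tend\tmapq\tstrand",
               "chr1\t1000\t1140\t60\t+"), path2)
  fs <- readFragTSV(path2)
  expect_equal(GenomicRanges::width(fragments(fs)), 140L)
})

test_that("downsampleBam keeps mates together and is seed-deterministic", {
  sim <- cleanSim()
  out1 <- downsampleBam(sim$files$bam, dest = tempfile(), fraction = 0.4,
                        seed = 7)
  out2 <- downsampleBam(sim$files$bam, dest = tempfile(), fraction = 0.4,
                        seed = 7)
  fs1 <- readBam(out1)
  expect_equal(orphanCount(fs1), 0L)
  q1 <- sort(unique(S4Vectors::mcols(fragments(fs1))$qname))
  q2 <- sort(unique(S4Vectors::mcols(fragments(readBam(out2)))$qname))
  expect_identical(q1, q2)
  expect_error(downsampleBam(sim$files$bam, coverage = 1e6),
               "exceeds current")
})
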