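test_that("classifyOverlap is total over the five categories", {
  out <- classifyOverlap(baseFwd = c("T", "T", NA, "T", "A", NA),
                         baseRev = c("T", NA, "T", "A", "A", NA),
                         alt = "T")
  expect_equal(out, c("CO", "SO", "SO", "DO", "REF_ONLY", "NO_COVER"))
})

test_that("annotateMutations classifies crafted read pairs", {
  pos <- 1050L
  mkseq <- function(len, off, base) {
    s <- strrep("A", len)
    if (!is.na(off)) substr(s, off, off) <- base
    s
  }
  lowq <- strrep("I", 100); substr(lowq, 50, 50) <- "!"
  sam <- writeSam(c(
    samPair("co", "chr1", 1001L, 100L, 1021L, 100L,
            seq1 = mkseq(100, 50, "T"), seq2 = mkseq(100, 30, "T")),
    samPair("so", "chr1", 1001L, 40L, 1041L, 100L,
            seq2 = mkseq(100, 10, "T")),
    samPair("do", "chr1", 1001L, 100L, 1021L, 100L,
            seq1 = mkseq(100, 50, "T")),
    samPair("ref", "chr1", 1001L, 100L, 1021L, 100L),
    samPair("lowbq", "chr1", 1001L, 100L, 1021L, 100L,
            seq1 = mkseq(100, 50, "T"), seq2 = mkseq(100, 30, "T"),
            qual1 = lowq)))
  loci <- data.frame(chrom = "chr1", pos = pos, ref = "A", alt = "T")
  ann <- annotateMutations(sam, loci)
  cats <- setNames(ann$category, ann$qname)
  expect_equal(unname(cats["co"]), "CO")
  expect_equal(unname(cats["so"]), "SO")
  expect_equal(unname(cats["do"]), "DO")
  expect_equal(unname(cats["ref"]), "REF_ONLY")
  # a low-quality forward base does not cover: the pair degrades to SO
  expect_equal(unname(cats["lowbq"]), "SO")
  expect_true(all(ann$both_reads_cover[ann$qname %in% c("co", "do", "ref")]))
  expect_false(ann$both_reads_cover[ann$qname == "so"])
})

test_that("aggregateSupport tallies per-locus allele support", {
  ann <- data.frame(
    qname = paste0("f", 1:10),
    locus = "chr1:100:A>T", chrom = "chr1", pos = 100L, ref = "A",
    alt = "T",
    category = c(rep("CO", 3), rep("SO", 2), "DO", rep("REF_ONLY", 4)),
    stringsAsFactors = FALSE)
  agg <- aggregateSupport(ann)
  expect_equal(agg$n_co, 3L)
  expect_equal(agg$n_so, 2L)
  expect_equal(agg$n_do, 1L)
  expect_equal(agg$n_ref_only, 4L)
  expect_equal(agg$alt_count, 5L)   # DO excluded by default
  expect_equal(agg$ref_count, 4L)
  agg2 <- aggregateSupport(ann, includeDiscordant = TRUE)
  expect_equal(agg2$alt_count, 6L)
  expect_equal(nrow(aggregateSupport(ann[0, ])), 0L)
})

test_that("sbsContext maps loci to pyrimidine-centric labels", {
  #                                      123456789
  ref <- Biostrings::DNAStringSet(c(chr1 = "AACGTTGCA"))
  # pyrimidine reference base: direct read-off
  expect_equal(sbsContext(data.frame(chrom = "chr1", pos = 3L, ref = "C",
                                     alt = "T"), ref), "A[C>T]G")
  # purine reference base: reverse-complemented strand
  # pos 7 = G, trinucleotide TGC; revcomp GCA -> G[C>.]A with alt A -> T
  expect_equal(sbsContext(data.frame(chrom = "chr1", pos = 7L, ref = "G",
                                     alt = "A"), ref), "G[C>T]A")
  expect_error(sbsContext(data.frame(chrom = "chr1", pos = 3L, ref = "G",
                                     alt = "A"), ref), "mismatch at chr1:3")
  expect_error(sbsContext(data.frame(chrom = "chr1", pos = 1L, ref = "A",
                                     alt = "T"), ref), "flanking")
})

test_that("callTrinucleotide stratifies fragment-weighted profiles", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "AACGTAGCA"))
  ann <- data.frame(
    qname = paste0("f", 1:4),
    locus = c("l1", "l1", "l2", "l1"),
    chrom = "chr1", pos = c(3L, 3L, 6L, 3L),
    ref = c("C", "C", "A", "C"), alt = c("T", "T", "G", "T"),
    category = c("CO", "CO", "SO", "DO"),
    stringsAsFactors = FALSE)
  profs <- callTrinucleotide(ann, ref, strata = c("ALL", "CO", "DO"))
  # locus l1 context A[C>T]G; locus l2: pos 6 = A, tri TAG -> revcomp CTA,
  # alt G complements to C -> C[T>C]A
  expect_equal(unname(sbsCounts(profs$ALL)["A[C>T]G"]), 3)
  expect_equal(unname(sbsCounts(profs$ALL)["C[T>C]A"]), 1)
  expect_equal(sum(sbsCounts(profs$ALL)), 4)
  expect_equal(unname(sbsCounts(profs$CO)["A[C>T]G"]), 2)
  expect_equal(sum(sbsCounts(profs$DO)), 1)
  # locus weighting collapses multiplicity
  profL <- callTrinucleotide(ann, ref, strata = "ALL", weighting = "locus")
  expect_equal(unname(sbsCounts(profL$ALL)["A[C>T]G"]), 1)
  # subtraction removes the DO stratum and clips at zero
  rem <- sbsSubtract(profs$ALL, profs$DO)
  expect_equal(unname(sbsCounts(rem)["A[C>T]G"]), 2)
  expect_equal(stratumLabel(rem), "ALL-DO")
  expect_warning(callTrinucleotide(ann[ann$category == "CO", , drop = FALSE],
                                   ref, strata = "DO"), "empty stratum")
})

test_that("cosineSimilarity matches hand-computed oracles", {
  expect_equal(cosineSimilarity(c(1, 0), c(1, 1)), 1 / sqrt(2))
  expect_equal(cosineSimilarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosineSimilarity(c(2, 4), c(1, 2)), 1)
  expect_warning(r <- cosineSimilarity(c(0, 0), c(1, 1)), "zero profile")
  expect_true(is.na(r))
})

test_that("readVariants accepts TSV and VCF-lite inputs", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tref\talt",
               "chr1\t100\ta\tt",
               "chr1\t200\tAC\tA"), tsv)
  expect_message(v <- readVariants(tsv), "non-SNV")
  expect_equal(nrow(v), 1L)
  expect_equal(v$ref, "A")
  expect_equal(v$alt, "T")
  vcf <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT",
               "chr2\t300\t.\tG\tC"), vcf)
  v2 <- readVariants(vcf)
  expect_equal(v2$chrom, "chr2")
  expect_equal(v2$pos, 300L)
  expect_equal(v2$alt, "C")
})

test_that("pileupMismatches guards against double-counting mate overlaps", {
  set.seed(99)
  chrseq <- paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
                  collapse = "")
  ref <- Biostrings::DNAStringSet(c(chr1 = chrseq))
  refAt <- function(s, e) substr(chrseq, s, e)
  other <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]
  plant <- function(seq, start, pos, base) {
    substr(seq, pos - start + 1L, pos - start + 1L) <- base
    seq
  }
  alt200 <- other(refAt(200, 200))
  alt220 <- other(refAt(220, 220))
  alt420 <- other(refAt(420, 420))
  sam <- writeSam(c(
    # concordant mismatch at 200 on both mates of an overlapping pair
    samPair("p1", "chr1", 101L, 150L, 151L, 150L,
            seq1 = plant(refAt(101, 250), 101L, 200L, alt200),
            seq2 = plant(refAt(151, 300), 151L, 200L, alt200)),
    # mates disagree at 220: fragment removed from depth there
    samPair("p2", "chr1", 101L, 150L, 151L, 150L,
            seq1 = plant(refAt(101, 250), 101L, 220L, alt220),
            seq2 = refAt(151, 300)),
    # single-read mismatch at 420 outside the mate overlap
    samPair("p3", "chr1", 401L, 150L, 601L, 150L,
            seq1 = plant(refAt(401, 550), 401L, 420L, alt420),
            seq2 = refAt(601, 750))),
    contigs = c(chr1 = 3000L))
  mm <- pileupMismatches(sam, ref)
  expect_equal(nrow(mm), 2L)
  r200 <- mm[mm$pos == 200L, ]
  expect_equal(r200$alt, alt200)
  expect_equal(r200$alt_count, 1L)   # one fragment, not two reads
  expect_equal(r200$ref_count, 1L)   # p2 covers 200 and matches reference
  expect_false(220L %in% mm$pos)     # discordant mates yield no call
  r420 <- mm[mm$pos == 420L, ]
  expect_equal(r420$alt, alt420)
  expect_equal(r420$alt_count, 1L)
  expect_equal(r420$discarded, 0L)
})
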