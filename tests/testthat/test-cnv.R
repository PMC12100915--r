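test_that("binFragments assigns fragments to bins by midpoint", {
  sl <- c(chr1 = 100000L)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(100L, 9500L, 10100L, 25000L),
    width = c(200L, 200L, 200L, 200L)), seqlengths = sl)
  bins <- binFragments(gr, binSize = 10000L)
  expect_equal(length(bins), 10L)
  raw <- S4Vectors::mcols(bins)$raw
  expect_equal(raw[1], 2L)   # midpoints 199 and 9599
  expect_equal(raw[2], 1L)   # midpoint 10199
  expect_equal(raw[3], 1L)   # midpoint 25099
  expect_equal(sum(raw), length(gr))   # fragments conserved
  expect_warning(binFragments(gr, binSize = 5000), "sparse")
  expect_error(binFragments(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(1, 100))), "seqlengths")
})

test_that("gcCorrect leaves uniform counts unchanged and validates input", {
  cfg <- simConfig(seed = 77, chromosomes = data.frame(
    name = "chr1", length = 500000L, gc = 0.45))
  ref <- makeReference(cfg, dir = tempfile())
  sl <- c(chr1 = 500000L)
  mids <- seq(5000L, 495000L, by = 10000L)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    rep(mids, each = 5) - 50L, width = 100L), seqlengths = sl)
  bins <- binFragments(gr, binSize = 10000L)
  expect_true(all(S4Vectors::mcols(bins)$raw == 5L))
  cor <- gcCorrect(bins, ref)
  ok <- !S4Vectors::mcols(cor)$excluded
  expect_true(any(ok))
  expect_true(all(S4Vectors::mcols(cor)$corrected[ok] == 5))
  expect_true(all(S4Vectors::mcols(cor)$gc > 0.3 &
                    S4Vectors::mcols(cor)$gc < 0.6, na.rm = TRUE))
  # degenerate inputs are refused
  few <- bins[1:10]
  expect_error(gcCorrect(few, ref), "20 bins")
  zero <- bins
  S4Vectors::mcols(zero)$raw <- 0L
  expect_error(gcCorrect(zero, ref), "zero")
})

test_that("callStates thresholds log2 ratios against the autosomal median", {
  bins <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = seq(1L, by = 1000L, length.out = 50L), width = 1000L))
  S4Vectors::mcols(bins)$corrected <- c(rep(100, 40), rep(150, 5), rep(50, 5))
  S4Vectors::mcols(bins)$excluded <- rep(FALSE, 50)
  st <- callStates(bins)
  lr <- S4Vectors::mcols(st)$log2_ratio
  state <- S4Vectors::mcols(st)$state
  expect_equal(lr[1], 0)
  expect_equal(lr[41], log2(1.5))
  expect_equal(lr[46], log2(0.5))
  expect_equal(state[1], "neutral")
  expect_equal(state[41], "gain")
  expect_equal(state[46], "loss")
  # excluded bins stay excluded with NA ratios
  S4Vectors::mcols(bins)$excluded[1] <- TRUE
  st2 <- callStates(bins)
  expect_equal(S4Vectors::mcols(st2)$state[1], "excluded")
  expect_true(is.na(S4Vectors::mcols(st2)$log2_ratio[1]))
})

test_that("annotateGenes reports bins, mutations and fragment counts", {
  sl <- c(chr1 = 100000L)
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(1000L, 2000L, 50000L), width = 200L), seqlengths = sl)
  bins <- binFragments(gr, binSize = 10000L)
  S4Vectors::mcols(bins)$corrected <- S4Vectors::mcols(bins)$raw + 1
  S4Vectors::mcols(bins)$excluded <- rep(FALSE, length(bins))
  bins <- callStates(bins)
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500L, 3000L))
  S4Vectors::mcols(genes)$name <- "GENE1"
  support <- data.frame(locus = "chr1:1500:A>T", chrom = "chr1",
                        pos = 1500L, ref = "A", alt = "T", n_co = 2L,
                        n_so = 1L, n_do = 0L, n_ref_only = 5L,
                        alt_count = 3L, ref_count = 5L)
  res <- annotateGenes(bins, genes, support = support, fragments = gr)
  expect_equal(res$gene, "GENE1")
  expect_equal(res$n_bins, 1L)
  expect_equal(res$mutated_fragments, 3L)
  expect_equal(res$total_fragments, 2L)
  # genes on unknown contigs are skipped with a warning
  g2 <- GenomicRanges::GRanges(c("chr1", "chrZ"),
                               IRanges::IRanges(c(500L, 1L), width = 100L))
  S4Vectors::mcols(g2)$name <- c("GENE1", "GENEZ")
  expect_warning(res2 <- annotateGenes(bins, g2, fragments = gr), "GENEZ")
  expect_equal(nrow(res2), 1L)
})

test_that("a planted gain region is recovered end to end", {
  ## depth chosen so the +/-0.2 log2 thresholds sit > 4 sd from Poisson
  ## noise in neutral bins (~1000 fragments/bin), making false gain/loss
  ## calls negligible rather than merely unlikely
  cfg <- simConfig(seed = 303, nFragments = 60000,
                   chromosomes = data.frame(name = "chr1",
                                            length = 5000000L, gc = 0.41),
                   cnvRegions = data.frame(chrom = "chr1", start = 1000001L,
                                           end = 2000000L, multiplier = 2))
  sim <- simulateDataset(cfg, dir = tempfile())
  fs <- readBam(sim$files$bam)
  bins <- binFragments(fs, binSize = 100000L)
  bins <- callStates(gcCorrect(bins, sim$reference))
  inGain <- GenomicRanges::start(bins) >= 1000001L &
    GenomicRanges::end(bins) <= 2000000L
  st <- S4Vectors::mcols(bins)$state
  expect_true(mean(st[inGain] == "gain", na.rm = TRUE) >= 0.8)
  expect_true(all(st[!inGain & !S4Vectors::mcols(bins)$excluded] !=
                    "loss"))
})
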