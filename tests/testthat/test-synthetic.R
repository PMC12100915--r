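test_that("simConfig validates its inputs", {
  expect_error(simConfig(duplicateRate = 1.5), "rates")
  expect_error(simConfig(lengthMixture = data.frame(
    weight = c(0.5, 0.4), mean = c(167, 334), sd = c(10, 20))), "sum to 1")
  expect_error(simConfig(chromosomes = data.frame(
    name = "chr1", length = 500L, gc = 0.4)), "1 kb")
  expect_error(simConfig(variantSpikes = data.frame(
    chrom = "chr1", pos = 1e9, ref = "A", alt = "T", vaf = 0.1,
    discordantRate = 0)), "within contig bounds")
  expect_s4_class(simConfig(seed = 2), "SimConfig")
})

test_that("makeReference is deterministic and hits the GC target", {
  cfg <- simConfig(seed = 42)
  r1 <- makeReference(cfg, dir = tempfile())
  r2 <- makeReference(cfg, dir = tempfile())
  expect_identical(as.character(r1$sequences), as.character(r2$sequences))
  expect_true(file.exists(r1$fasta))
  expect_true(file.exists(r1$index))
  gc <- Biostrings::letterFrequency(r1$sequences, c("G", "C"),
                                    as.prob = TRUE)
  expect_lt(abs(sum(gc[1, ]) - 0.41), 0.02)   # chr1 row
})

test_that("simulateFragments plants exact artifact and mito counts", {
  sim <- artifactSim()
  tf <- truthFragments(sim$truth)
  expect_equal(nrow(tf), 2000L)
  tab <- table(tf$artifact)
  for (cls in c("duplicate", "low_mapq", "secondary", "unmapped",
                "discordant_chrom", "outward"))
    expect_equal(unname(tab[cls]), 100L, info = cls)
  expect_equal(sum(tf$chrom == "chrM"), 40L)
  expect_true(all(tf$true_length >= 30L))
  expect_true(all(tf$true_length == tf$true_end - tf$true_start + 1L))
  # fragments never leave their contig
  ch <- sim$truth@config@chromosomes
  expect_true(all(tf$true_start >= 1L))
  expect_true(all(tf$true_end <= ch$length[match(tf$chrom, ch$name)]))
})

test_that("overhang is planted only on eligible sequence-through pairs", {
  cfg <- simConfig(seed = 33, nFragments = 1000, overhangRate = 0.5,
                   overhangLength = 10L)
  ref <- makeReference(cfg, dir = tempfile())
  truth <- simulateFragments(cfg, ref)
  tf <- truthFragments(truth)
  oh <- tf[tf$overhang > 0L, ]
  expect_gt(nrow(oh), 0L)
  expect_true(all(oh$overhang == 10L))
  expect_true(all(oh$true_length < 150L))
  expect_true(all(oh$artifact == "none"))
  # exact count among eligible fragments
  ch <- truth@config@chromosomes
  eligible <- sum(tf$artifact == "none" & tf$true_length < 150L &
                    150L - tf$true_length >= 10L &
                    tf$true_end + 10L <= ch$length[match(tf$chrom, ch$name)])
  expect_equal(nrow(oh), round(0.5 * eligible))
})

test_that("emitAlignments is deterministic and writes a readable BAM", {
  cfg <- simConfig(seed = 9, nFragments = 200)
  d1 <- simulateDataset(cfg, dir = tempfile(), format = "sam")
  d2 <- simulateDataset(cfg, dir = tempfile(), format = "sam")
  expect_identical(readLines(d1$files$sam), readLines(d2$files$sam))
})

test_that("spiked variants plant exact carrier and discordant counts", {
  cfg0 <- simConfig(seed = 55, nFragments = 4000)
  ref <- makeReference(cfg0, dir = tempfile())
  pos <- 50000L
  rb <- cfFrag:::.refWindow(ref$sequences, "chr1", pos, pos)
  alt <- setdiff(c("A", "C", "G", "T"), rb)[1]
  cfg <- simConfig(seed = 55, nFragments = 4000,
                   variantSpikes = data.frame(
                     chrom = "chr1", pos = pos, ref = rb, alt = alt,
                     vaf = 0.25, discordantRate = 0.2))
  truth <- simulateFragments(cfg, ref)
  ls <- truthLocusSupport(truth)
  expect_gt(nrow(ls), 0L)
  # carriers are an exact count among read-covering fragments
  readCov <- ls$planted_category != "NO_COVER"
  expect_equal(sum(ls$carrier), round(0.25 * sum(readCov)))
  carBoth <- sum(ls$carrier & ls$both_reads_cover)
  expect_equal(sum(ls$discordant), round(0.2 * carBoth))
  # planted categories follow the definitions
  expect_true(all(ls$planted_category[ls$discordant] == "DO"))
  expect_true(all(ls$planted_category[ls$carrier & !ls$both_reads_cover] ==
                    "SO"))
  expect_true(all(ls$planted_category[!ls$carrier] %in%
                    c("REF_ONLY", "NO_COVER")))
  # discordant carriers put the alt base on exactly one read
  expect_true(all(ls$alt_read[ls$discordant] %in% c("fwd", "rev")))
})
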