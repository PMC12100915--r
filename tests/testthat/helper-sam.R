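# Helpers for crafting small SAM files with exactly known content.

samHeader <- function(contigs) {
  c("@HD\tVN:1.6\tSO:unknown",
    paste0("@SQ\tSN:", names(contigs), "\tLN:", contigs))
}

# One SAM record. `len` controls the SEQ/QUAL width; `seq`/`qual` override.
samRecord <- function(qname, flag, rname, pos, mapq, cigar,
                      rnext = "=", pnext = pos, tlen = 0, len = 10,
                      seq = strrep("A", len), qual = strrep("I", nchar(seq)),
                      nm = NULL) {
  rec <- paste(qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen,
               seq, qual, sep = "\t")
  if (!is.null(nm)) rec <- paste0(rec, "\tNM:i:", nm)
  rec
}

# Flags for a plain inward pair: mate 1 forward, mate 2 reverse.
FWD1 <- 1L + 2L + 32L + 64L    # paired, proper, mate-reverse, first
REV2 <- 1L + 2L + 16L + 128L   # paired, proper, reverse, second

# An inward read pair with given per-mate spans (M-only CIGARs).
samPair <- function(qname, chrom, start1, len1, start2, len2,
                    mapq1 = 60, mapq2 = 60, flag1 = FWD1, flag2 = REV2,
                    chrom2 = chrom, seq1 = NULL, seq2 = NULL,
                    qual1 = NULL, qual2 = NULL, nm1 = NULL, nm2 = NULL) {
  if (is.null(seq1)) seq1 <- strrep("A", len1)
  if (is.null(seq2)) seq2 <- strrep("A", len2)
  if (is.null(qual1)) qual1 <- strrep("I", len1)
  if (is.null(qual2)) qual2 <- strrep("I", len2)
  c(samRecord(qname, flag1, chrom, start1, mapq1, paste0(len1, "M"),
              ifelse(chrom2 == chrom, "=", chrom2), start2,
              seq = seq1, qual = qual1, nm = nm1),
    samRecord(qname, flag2, chrom2, start2, mapq2, paste0(len2, "M"),
              ifelse(chrom2 == chrom, "=", chrom), start1,
              seq = seq2, qual = qual2, nm = nm2))
}

writeSam <- function(records, contigs = c(chr1 = 200000L),
                     path = tempfile(fileext = ".sam")) {
  writeLines(c(samHeader(contigs), records), path)
  path
}
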