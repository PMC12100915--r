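## Descriptive alignment-file metrics.

#' Summarise an alignment file
#'
#' Computes descriptive metrics over primary records only (secondary and
#' supplementary alignments excluded, so fractions are per sequenced read):
#' the unmapped-read fraction, the fraction of mapped reads on
#' mitochondrion-like contigs, the mismatch fraction (sum of edit-distance
#' tags over aligned reference-consuming bases; `NA` when the tag is
#' absent), per-read GC content moments (ambiguous bases excluded from the
#' denominator), and mean coverage (aligned bases over genome length).
#'
#' @param file BAM/SAM path.
#' @param mitoNames Contig names treated as mitochondrial.
#' @param includeMito Include mitochondrion-like contigs in the coverage
#'   computation (default yes).
#' @return A [BamSummary-class].
#' @examples
#' sim <- simulateDataset(simConfig(seed = 11, nFragments = 200))
#' summariseBam(sim$files$bam)
#' @export
summariseBam <- function(file, mitoNames = c("chrM", "MT"),
                         includeMito = TRUE) {
  file <- .sam2bam(file)
  hdr <- Rsamtools::scanBamHeader(file)[[1]]$targets
  p <- Rsamtools::ScanBamParam(
    what = c("flag", "rname", "pos", "cigar", "seq"), tag = "NM")
  res <- Rsamtools::scanBam(file, param = p)[[1]]
  bits <- Rsamtools::bamFlagAsBitMatrix(res$flag)

  primary <- bits[, "isSecondaryAlignment"] == 0L &
    bits[, "isSupplementaryAlignment"] == 0L
  unmapped <- bits[, "isUnmappedQuery"] == 1L
  totalPrimary <- sum(primary)
  mappedP <- primary & !unmapped
  unmFrac <- if (totalPrimary) sum(primary & unmapped) / totalPrimary else
    NA_real_
  mitoFrac <- if (sum(mappedP))
    sum(as.character(res$rname)[mappedP] %in% mitoNames) / sum(mappedP) else
      NA_real_

  cig <- res$cigar[mappedP]
  alnW <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig)
  nm <- res$tag$NM[mappedP]
  mmFrac <- if (all(is.na(nm))) NA_real_ else
    sum(nm, na.rm = TRUE) / sum(alnW)

  seqs <- res$seq[primary]
  gcN <- rowSums(Biostrings::letterFrequency(seqs, c("G", "C")))
  acgt <- rowSums(Biostrings::letterFrequency(seqs, c("A", "C", "G", "T")))
  gc <- gcN / acgt
  gc <- gc[is.finite(gc)]

  glen <- hdr
  mitoMask <- names(glen) %in% mitoNames
  alnOn <- as.character(res$rname)[mappedP]
  if (!includeMito) {
    keep <- !alnOn %in% mitoNames
    covNum <- sum(alnW[keep])
    covDen <- sum(as.numeric(glen[!mitoMask]))
  } else {
    covNum <- sum(alnW)
    covDen <- sum(as.numeric(glen))
  }

  new("BamSummary",
      totalRecords = length(res$flag),
      totalPrimary = as.integer(totalPrimary),
      mappedPrimary = as.integer(sum(mappedP)),
      unmappedFraction = unmFrac,
      mitoFraction = mitoFrac,
      mismatchFraction = mmFrac,
      meanReadGC = mean(gc),
      sdReadGC = stats::sd(gc),
      meanCoverage = covNum / covDen)
}
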