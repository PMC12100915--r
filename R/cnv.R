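## Simplified binned copy number: midpoint binning, GC-decile median
## correction, per-bin log2 ratios and gain/neutral/loss states, plus
## gene-level mutation annotation.
##
## This is a deliberately minimal, transparent backend: it omits
## segmentation, mappability and blacklist correction, so it is NOT
## equivalent to full binned-CN callers; it exists to make the per-bin
## state/annotation surface testable without external references.

#' Count fragments per fixed genomic bin
#'
#' Tiles each contig with fixed-width bins (last bin truncated) and assigns
#' every fragment to the bin containing its midpoint, using half-open bins
#' so that a midpoint exactly on a boundary goes to the right bin. Counts
#' conserve fragments on binned contigs.
#'
#' @param x A [FragmentSet-class] or `GRanges` of fragments.
#' @param binSize Bin width in bp (default 1 Mb).
#' @param seqlengths Named contig lengths; taken from `x` if absent.
#' @return `GRanges` of bins with metadata column `raw`.
#' @export
binFragments <- function(x, binSize = 1e6, seqlengths = NULL) {
  gr <- .asFragGRanges(x)
  if (binSize < 1e4)
    warning("binSize below 10 kb: counts will be sparse")
  if (is.null(seqlengths)) {
    seqlengths <- GenomeInfoDb::seqlengths(gr)
    if (anyNA(seqlengths))
      stop("fragments carry no seqlengths; supply them explicitly")
  }
  bins <- GenomicRanges::tileGenome(seqlengths, tilewidth = binSize,
                                    cut.last.tile.in.chrom = TRUE)
  mid <- (GenomicRanges::start(gr) + GenomicRanges::end(gr)) %/% 2L
  midGR <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                  IRanges::IRanges(mid, mid),
                                  seqlengths = seqlengths)
  hits <- GenomicRanges::countOverlaps(bins, midGR)
  mcols(bins)$raw <- hits
  bins
}

#' GC-stratified median correction of bin counts
#'
#' Computes the reference GC fraction of each bin and rescales raw counts so
#' that every GC decile has the same median as the genome-wide median:
#' `corrected = raw * median(all) / median(same GC decile)`. Deciles holding
#' fewer than 3 bins (or with zero median) are marked excluded.
#'
#' @param bins `GRanges` from [binFragments()].
#' @param reference Reference sequence set.
#' @return The bins with added metadata columns `gc`, `corrected`,
#'   `excluded`.
#' @export
gcCorrect <- function(bins, reference) {
  ref <- if (is.list(reference)) reference$sequences else
    .loadReference(reference)
  if (length(bins) < 20L)
    stop("need at least 20 bins for GC correction")
  if (all(mcols(bins)$raw == 0L))
    stop("all bin counts are zero")
  seqs <- .refWindow(ref, as.character(GenomicRanges::seqnames(bins)),
                     GenomicRanges::start(bins), GenomicRanges::end(bins))
  dss <- Biostrings::DNAStringSet(seqs)
  gc <- rowSums(Biostrings::letterFrequency(dss, c("G", "C"))) /
    rowSums(Biostrings::letterFrequency(dss, c("A", "C", "G", "T")))
  breaks <- unique(stats::quantile(gc, probs = seq(0, 1, 0.1), na.rm = TRUE))
  stratum <- if (length(breaks) > 1L)
    cut(gc, breaks = breaks, include.lowest = TRUE) else factor(rep(1, length(gc)))
  raw <- mcols(bins)$raw
  globalMed <- stats::median(raw)
  corrected <- rep(NA_real_, length(bins))
  excluded <- rep(FALSE, length(bins))
  for (lv in levels(stratum)) {
    i <- which(stratum == lv)
    if (length(i) < 3L) {
      excluded[i] <- TRUE
      next
    }
    m <- stats::median(raw[i])
    if (m == 0) {
      excluded[i] <- TRUE
      next
    }
    corrected[i] <- raw[i] * globalMed / m
  }
  excluded[is.na(gc)] <- TRUE
  mcols(bins)$gc <- gc
  mcols(bins)$corrected <- corrected
  mcols(bins)$excluded <- excluded
  bins
}

#' Call per-bin copy-number states
#'
#' Computes `log2(corrected / median of autosomal corrected counts)` and
#' thresholds it into gain (`>= gainThr`), loss (`<= lossThr`) or neutral.
#' Excluded bins keep the state `"excluded"`. Sex and mitochondrion-like
#' contigs are left out of the reference median.
#'
#' @param bins `GRanges` from [gcCorrect()].
#' @param gainThr,lossThr Log2-ratio thresholds (defaults +0.2 / -0.2; with
#'   a diploid background a single-copy gain sits at `log2(1.5) ~ 0.585`).
#' @return The bins with added metadata columns `log2_ratio` and `state`.
#' @export
callStates <- function(bins, gainThr = 0.2, lossThr = -0.2) {
  stopifnot(!is.null(mcols(bins)$corrected))
  auto <- !as.character(GenomicRanges::seqnames(bins)) %in%
    c(.MITO_NAMES, .SEX_NAMES)
  usable <- auto & !mcols(bins)$excluded
  med <- stats::median(mcols(bins)$corrected[usable])
  if (is.na(med) || med == 0)
    stop("autosomal median of corrected counts is zero")
  lr <- log2(mcols(bins)$corrected / med)
  state <- rep("neutral", length(bins))
  state[lr >= gainThr] <- "gain"
  state[lr <= lossThr] <- "loss"
  state[mcols(bins)$excluded] <- "excluded"
  lr[mcols(bins)$excluded] <- NA_real_
  mcols(bins)$log2_ratio <- lr
  mcols(bins)$state <- state
  bins
}

#' Annotate genes with copy-number bins and mutated-fragment counts
#'
#' For each gene interval reports the bins it intersects, the number of
#' alternative-allele-supporting fragments at loci within the gene, and the
#' total number of curated fragments overlapping the gene span.
#'
#' @param bins `GRanges` from [callStates()].
#' @param genes `GRanges` with a `name` metadata column, or a BED path
#'   (0-based half-open, converted on read).
#' @param support Per-locus support from [aggregateSupport()] (optional).
#' @param fragments A [FragmentSet-class] or `GRanges` of fragments.
#' @return data.frame: gene, n_bins, bin_states, mutated_fragments,
#'   total_fragments.
#' @export
annotateGenes <- function(bins, genes, support = NULL, fragments) {
  if (is.character(genes))
    genes <- rtracklayer::import(genes, format = "BED")
  gname <- if (!is.null(mcols(genes)$name)) mcols(genes)$name else
    paste0("gene", seq_along(genes))
  fr <- .asFragGRanges(fragments)
  known <- as.character(GenomicRanges::seqnames(genes)) %in%
    GenomeInfoDb::seqlevels(bins)
  if (any(!known)) {
    warning("skipping gene(s) on unknown contig: ",
            paste(gname[!known], collapse = ", "))
    genes <- genes[known]
    gname <- gname[known]
  }
  res <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    bi <- which(IRanges::overlapsAny(bins, g))
    mut <- 0L
    if (!is.null(support) && nrow(support)) {
      inGene <- support$chrom ==
        as.character(GenomicRanges::seqnames(g)) &
        support$pos >= GenomicRanges::start(g) &
        support$pos <= GenomicRanges::end(g)
      mut <- sum(support$alt_count[inGene])
    }
    tot <- sum(IRanges::overlapsAny(fr, g))
    data.frame(gene = gname[i], n_bins = length(bi),
               bin_states = paste(mcols(bins)$state[bi], collapse = ","),
               mutated_fragments = mut, total_fragments = tot,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
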