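## Reading paired-end alignments, QC, and curation of read pairs into
## correctly defined cfDNA fragments.
##
## Coordinates are 1-based inclusive throughout; length = end - start + 1.
## Alignment ends are computed from CIGAR reference consumption (soft clips
## excluded). The curated fragment runs from the forward read's start to the
## reverse read's end; this differs from the naive outermost-boundary span
## exactly when a sequence-through pair carries a 3' overhang.

.PAIR_WHAT <- c("qname", "flag", "rname", "strand", "pos", "mapq", "cigar",
                "seq", "qual")

.sam2bam <- function(file) {
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    file <- Rsamtools::asBam(file, dest, overwrite = TRUE,
                             indexDestination = TRUE)
  }
  file
}

## Decode one scanBam chunk into a per-record data.frame.
.chunkToRecords <- function(res) {
  flag <- res$flag
  bits <- Rsamtools::bamFlagAsBitMatrix(flag)
  cig <- res$cigar
  refw <- rep(NA_integer_, length(flag))
  ok <- !is.na(cig)
  if (any(ok))
    refw[ok] <- GenomicAlignments::cigarWidthAlongReferenceSpace(cig[ok])
  data.frame(
    qname = res$qname,
    rname = as.character(res$rname),
    strand = as.character(res$strand),
    start = res$pos,
    end = res$pos + refw - 1L,
    mapq = res$mapq,
    cigar = cig,
    seq = as.character(res$seq),
    qual = as.character(res$qual),
    paired = bits[, "isPaired"] == 1L,
    proper = bits[, "isProperPair"] == 1L,
    unmapped = bits[, "isUnmappedQuery"] == 1L,
    mate_unmapped = bits[, "hasUnmappedMate"] == 1L,
    secondary = bits[, "isSecondaryAlignment"] == 1L,
    supplementary = bits[, "isSupplementaryAlignment"] == 1L,
    duplicate = bits[, "isDuplicate"] == 1L,
    first_in_pair = bits[, "isFirstMateRead"] == 1L,
    nm = if (!is.null(res$tag$NM)) res$tag$NM else NA_integer_,
    stringsAsFactors = FALSE)
}

.emptyRecords <- function() {
  .chunkToRecords(list(
    qname = character(0), flag = integer(0), rname = factor(),
    strand = factor(), pos = integer(0), mapq = integer(0),
    cigar = character(0), seq = Biostrings::DNAStringSet(),
    qual = Biostrings::BStringSet(), tag = list(NM = integer(0))))
}

.emptyPairs <- function() {
  rec <- .emptyRecords()
  pairs <- data.frame(qname = character(0), stringsAsFactors = FALSE)
  for (col in setdiff(names(rec), "qname")) {
    pairs[[paste0(col, "1")]] <- rec[[col]]
    pairs[[paste0(col, "2")]] <- rec[[col]]
  }
  pairs
}

## Join complete qname groups into one pair row; return leftovers.
.assemblePairs <- function(rec) {
  if (!nrow(rec))
    return(list(pairs = NULL, leftover = rec, dropped = 0L))
  tab <- table(rec$qname)
  complete <- names(tab)[tab == 2L]
  over <- names(tab)[tab > 2L]
  dropped <- 0L
  if (length(over)) {
    ## keep the two primary records; drop extra secondary/supplementary ones
    keepIdx <- unlist(lapply(over, function(q) {
      i <- which(rec$qname == q)
      prim <- i[!rec$secondary[i] & !rec$supplementary[i]]
      if (length(prim) >= 2L) prim[1:2] else i[1:2]
    }))
    dropped <- sum(tab[over]) - 2L * length(over)
    rec <- rec[c(which(rec$qname %in% setdiff(names(tab), over)), keepIdx), ]
    complete <- c(complete, over)
  }
  isC <- rec$qname %in% complete
  comp <- rec[isC, ]
  leftover <- rec[!isC, ]
  if (!nrow(comp))
    return(list(pairs = NULL, leftover = leftover, dropped = dropped))
  comp <- comp[order(comp$qname, !comp$first_in_pair), ]
  a <- comp[seq(1L, nrow(comp), by = 2L), ]
  b <- comp[seq(2L, nrow(comp), by = 2L), ]
  pairs <- data.frame(qname = a$qname, stringsAsFactors = FALSE)
  for (col in setdiff(names(a), "qname")) {
    pairs[[paste0(col, "1")]] <- a[[col]]
    pairs[[paste0(col, "2")]] <- b[[col]]
  }
  list(pairs = pairs, leftover = leftover, dropped = dropped)
}

#' Read paired-end alignments into a pair table
#'
#' Assembles records sharing a query name into read pairs, streaming the
#' file in chunks so memory is bounded by the number of simultaneously open
#' (mate-not-yet-seen) pairs. Records whose mate never appears are returned
#' as orphans, not silently dropped. With `region`, only pairs with at least
#' one record overlapping the window are returned (the missing mates are
#' fetched by a targeted second query; requires an indexed BAM).
#'
#' @param file Path to a BAM (or SAM) file.
#' @param region Optional `GRanges` of length 1 restricting the query.
#' @param yieldSize Records per streaming chunk.
#' @return List with `pairs` (one row per pair; per-mate columns suffixed
#'   `1`/`2`, mate 1 = first-in-pair), `orphans` (records without a mate)
#'   and `extraDropped` (surplus multi-mapping records discarded).
#' @export
readPairs <- function(file, region = NULL, yieldSize = 100000L) {
  file <- .sam2bam(file)
  what <- .PAIR_WHAT
  tags <- "NM"

  if (!is.null(region)) {
    stopifnot(is(region, "GRanges"))
    p <- Rsamtools::ScanBamParam(what = what, tag = tags, which = region)
    res <- Rsamtools::scanBam(file, param = p)
    rec <- do.call(rbind, lapply(res, .chunkToRecords))
    rec <- rec[!duplicated(paste(rec$qname, rec$first_in_pair)), ]
    asm <- .assemblePairs(rec)
    lo <- asm$leftover
    if (nrow(lo)) {
      ## fetch missing mates at their recorded positions
      p2 <- Rsamtools::ScanBamParam(
        what = c(what, "mrnm", "mpos"), tag = tags,
        which = region)
      mateInfo <- Rsamtools::scanBam(
        file, param = Rsamtools::ScanBamParam(what = c("qname", "mrnm", "mpos"),
                                              which = region))[[1]]
      miss <- match(lo$qname, mateInfo$qname)
      mrn <- as.character(mateInfo$mrnm)[miss]
      mpo <- mateInfo$mpos[miss]
      okm <- !is.na(mrn) & !is.na(mpo)
      if (any(okm)) {
        wh <- GenomicRanges::GRanges(mrn[okm],
                                     IRanges::IRanges(mpo[okm], mpo[okm]))
        p3 <- Rsamtools::ScanBamParam(what = what, tag = tags,
                                      which = GenomicRanges::reduce(wh))
        res3 <- Rsamtools::scanBam(file, param = p3)
        rec3 <- do.call(rbind, lapply(res3, .chunkToRecords))
        rec3 <- rec3[rec3$qname %in% lo$qname, ]
        rec3 <- rec3[!duplicated(paste(rec3$qname, rec3$first_in_pair)), ]
        ## drop records already present
        key <- paste(lo$qname, lo$first_in_pair)
        rec3 <- rec3[!paste(rec3$qname, rec3$first_in_pair) %in% key, ]
        asm2 <- .assemblePairs(rbind(lo, rec3))
        asm$pairs <- rbind(asm$pairs, asm2$pairs)
        asm$leftover <- asm2$leftover
      }
    }
    pairs <- asm$pairs
    orphans <- asm$leftover
    extraDropped <- asm$dropped
  } else {
    bf <- Rsamtools::BamFile(file, yieldSize = yieldSize)
    open(bf)
    on.exit(close(bf))
    p <- Rsamtools::ScanBamParam(what = what, tag = tags)
    pairsList <- list()
    leftover <- NULL
    extraDropped <- 0L
    repeat {
      res <- Rsamtools::scanBam(bf, param = p)[[1]]
      if (!length(res$qname)) break
      rec <- .chunkToRecords(res)
      if (!is.null(leftover)) rec <- rbind(leftover, rec)
      asm <- .assemblePairs(rec)
      if (!is.null(asm$pairs)) pairsList[[length(pairsList) + 1L]] <- asm$pairs
      leftover <- asm$leftover
      extraDropped <- extraDropped + asm$dropped
    }
    pairs <- if (length(pairsList)) do.call(rbind, pairsList) else NULL
    orphans <- leftover
  }

  if (is.null(pairs)) pairs <- .emptyPairs()
  if (is.null(orphans)) orphans <- .emptyRecords()

  if (nrow(pairs) && mean(pairs$paired1) < 0.5)
    stop("input does not look paired-end: records lack the paired flag")

  list(pairs = pairs, orphans = orphans, extraDropped = extraDropped)
}

#' Apply the pair-level QC policy
#'
#' A pair fails if either mate violates any enabled rule. The first violated
#' rule in the fixed order unmapped, mapq, duplicate, secondary,
#' supplementary, proper-pair is reported. Proper-pair filtering is off by
#' default: cfDNA fragment lengths are multimodal (di-/tri-nucleosomal
#' peaks) and the aligner's insert-size model would discard genuine long
#' fragments.
#'
#' @param pairs Pair table from [readPairs()].
#' @param policy A [QCPolicy-class].
#' @return Character vector: `"pass"` or the first failing reason.
#' @export
applyQC <- function(pairs, policy = qcPolicy()) {
  stopifnot(is(policy, "QCPolicy"))
  n <- nrow(pairs)
  reason <- rep("pass", n)
  stamp <- function(bad, r) {
    hit <- bad & reason == "pass"
    reason[hit] <<- r
  }
  if (policy@dropUnmapped)
    stamp(pairs$unmapped1 | pairs$unmapped2, "UNMAPPED")
  stamp(pairs$mapq1 < policy@minMapq | pairs$mapq2 < policy@minMapq, "MAPQ")
  if (policy@dropDuplicates)
    stamp(pairs$duplicate1 | pairs$duplicate2, "DUPLICATE")
  if (policy@dropSecondary)
    stamp(pairs$secondary1 | pairs$secondary2, "SECONDARY")
  if (policy@dropSupplementary)
    stamp(pairs$supplementary1 | pairs$supplementary2, "SUPPLEMENTARY")
  if (policy@requireProperPair)
    stamp(!pairs$proper1 | !pairs$proper2, "PROPER_PAIR")
  reason
}

#' Curate QC-passing read pairs into fragments
#'
#' Implements the cfDNA fragment definition: after rejecting pairs whose
#' mates map to different contigs (`SEQNAME_DISCORDANT`), lack opposite
#' strands (`NO_STRAND`), or are not inwardly directed (`NOT_INWARD`:
#' forward-read start must not exceed reverse-read end), the fragment runs
#' from the forward read's start to the reverse read's end. Fragments
#' extending outside their contig are rejected as `OUT_OF_BOUND`.
#'
#' @param pairs Pair table from [readPairs()] (QC-passing rows).
#' @param contigLengths Named integer vector of contig lengths.
#' @return data.frame with one row per input pair: `qname`, `outcome`
#'   (`"fragment"` or a rejection reason), and for fragments `chrom`,
#'   `start`, `end`, `length`.
#' @export
curatePairs <- function(pairs, contigLengths) {
  n <- nrow(pairs)
  outcome <- rep("fragment", n)
  chrom <- pairs$rname1
  unknown <- setdiff(unique(c(pairs$rname1, pairs$rname2)),
                     c(names(contigLengths), NA))
  if (length(unknown))
    stop("unknown contig(s) in alignment: ", paste(unknown, collapse = ", "))

  discord <- pairs$rname1 != pairs$rname2
  outcome[discord] <- "SEQNAME_DISCORDANT"

  noStrand <- !(pairs$strand1 %in% c("+", "-")) |
    !(pairs$strand2 %in% c("+", "-")) |
    pairs$strand1 == pairs$strand2
  outcome[outcome == "fragment" & noStrand] <- "NO_STRAND"

  fwdIs1 <- pairs$strand1 == "+"
  fstart <- ifelse(fwdIs1, pairs$start1, pairs$start2)
  rend <- ifelse(fwdIs1, pairs$end2, pairs$end1)
  outcome[outcome == "fragment" & fstart > rend] <- "NOT_INWARD"

  clen <- unname(contigLengths[chrom])
  outcome[outcome == "fragment" &
            (fstart < 1L | rend > clen)] <- "OUT_OF_BOUND"

  res <- data.frame(qname = pairs$qname, outcome = outcome,
                    chrom = chrom, start = fstart, end = rend,
                    stringsAsFactors = FALSE)
  bad <- res$outcome != "fragment"
  res$chrom[bad] <- NA
  res$start[bad] <- NA
  res$end[bad] <- NA
  res$length <- res$end - res$start + 1L
  res
}

#' Naive (problematic) fragment length of a read pair
#'
#' The span between the outermost boundaries of the two reads:
#' `max(end1, end2) - min(start1, start2) + 1`. For non-overlapping inward
#' pairs this equals the curated length, but for sequence-through pairs with
#' a 3' overhang it over-estimates the true fragment length by the overhang.
#' Provided for diagnostics only; never used by the feature callers.
#'
#' @param pairs Pair table from [readPairs()].
#' @return Integer vector of outermost-boundary spans.
#' @export
problematicLength <- function(pairs) {
  if (any(pairs$rname1 != pairs$rname2, na.rm = TRUE))
    stop("problematicLength requires both mates on the same contig")
  pmax(pairs$end1, pairs$end2) - pmin(pairs$start1, pairs$start2) + 1L
}

#' Read an alignment file into curated fragments
#'
#' The main entry point of the package: streams a paired-end BAM/SAM file,
#' applies the QC policy, curates passing pairs into fragments, and returns
#' a [FragmentSet-class] with exact rejection accounting. With
#' `curate = FALSE` the naive outermost-boundary definition is used instead
#' (for side-by-side diagnostics of the sequence-through ambiguity); only
#' the contig-concordance check is applied in that mode.
#'
#' @param file Path to a BAM (or SAM) file.
#' @param policy A [QCPolicy-class].
#' @param region Optional `GRanges` restricting the query (indexed BAM).
#' @param sampleId Sample label (defaults to the file name).
#' @param curate Use the curated fragment definition (default) or the
#'   outermost-boundary span.
#' @param yieldSize Records per streaming chunk.
#' @return A [FragmentSet-class].
#' @examples
#' sim <- simulateDataset(simConfig(seed = 3, nFragments = 200))
#' fs <- readBam(sim$files$bam)
#' fs
#' @export
readBam <- function(file, policy = qcPolicy(), region = NULL,
                    sampleId = basename(file), curate = TRUE,
                    yieldSize = 100000L) {
  bam <- .sam2bam(file)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  rp <- readPairs(bam, region = region, yieldSize = yieldSize)
  pairs <- rp$pairs
  nIn <- nrow(pairs)

  qc <- applyQC(pairs, policy)
  rej <- table(factor(qc[qc != "pass"], levels = .ALL_REASONS))
  keep <- pairs[qc == "pass", , drop = FALSE]

  if (curate) {
    cur <- curatePairs(keep, hdr)
  } else {
    ## diagnostic mode: outermost boundaries, contig concordance only
    outcome <- ifelse(keep$rname1 != keep$rname2, "SEQNAME_DISCORDANT",
                      "fragment")
    cur <- data.frame(qname = keep$qname, outcome = outcome,
                      chrom = keep$rname1,
                      start = pmin(keep$start1, keep$start2),
                      end = pmax(keep$end1, keep$end2),
                      stringsAsFactors = FALSE)
    cur$length <- cur$end - cur$start + 1L
    cur[cur$outcome != "fragment",
        c("chrom", "start", "end", "length")] <- NA
  }
  crej <- table(factor(cur$outcome[cur$outcome != "fragment"],
                       levels = .ALL_REASONS))
  rej <- rej + crej

  ok <- cur[cur$outcome == "fragment", , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = ok$chrom,
    ranges = IRanges::IRanges(ok$start, ok$end),
    seqlengths = hdr)
  mcols(gr)$qname <- ok$qname
  mcols(gr)$length <- GenomicRanges::width(gr)

  .FragmentSet(fragments = gr, sampleId = sampleId, pairsIn = nIn,
               orphans = nrow(rp$orphans), rejections = as.integer(rej) |>
                 setNames(names(rej)))
}

#' Read a FinaleDB-style fragment coordinate table
#'
#' Tab-separated columns chrom, start, end, mapq, strand, with 0-based
#' half-open coordinates (BED-like; `zeroBased = FALSE` overrides).
#' Converted to the internal 1-based inclusive convention; fragments below
#' `minMapq` are dropped and counted.
#'
#' @param path Path to the TSV (header optional).
#' @param minMapq Mapping-quality filter.
#' @param zeroBased Input uses 0-based half-open coordinates (default).
#' @param sampleId Sample label.
#' @return A [FragmentSet-class].
#' @export
readFragTSV <- function(path, minMapq = 30L, zeroBased = TRUE,
                        sampleId = basename(path)) {
  first <- readLines(path, n = 1L)
  hasHeader <- length(first) == 1L &&
    is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1]][2])))
  if (length(first) == 0L ||
      (hasHeader && length(readLines(path, n = 2L)) < 2L)) {
    df <- data.frame(chrom = character(0), start = integer(0),
                     end = integer(0), mapq = integer(0),
                     strand = character(0), stringsAsFactors = FALSE)
  } else {
    df <- utils::read.table(path, sep = "\t", header = hasHeader,
                            stringsAsFactors = FALSE,
                            colClasses = "character")
    names(df) <- c("chrom", "start", "end", "mapq",
                   "strand")[seq_along(df)]
  }
  if (nrow(df)) {
    numStart <- suppressWarnings(as.integer(df$start))
    numEnd <- suppressWarnings(as.integer(df$end))
    numMapq <- suppressWarnings(as.integer(df$mapq))
    bad <- which(is.na(numStart) | is.na(numEnd))
    if (length(bad))
      stop("non-numeric coordinates at line ",
           bad[1] + as.integer(hasHeader))
    df$start <- numStart + if (zeroBased) 1L else 0L
    df$end <- numEnd
    df$mapq <- numMapq
  }
  n <- nrow(df)
  keep <- if (n) df$mapq >= minMapq else logical(0)
  kept <- df[keep, , drop = FALSE]
  gr <- GenomicRanges::GRanges(kept$chrom,
                               IRanges::IRanges(kept$start, kept$end),
                               strand = kept$strand)
  mcols(gr)$qname <- if (nrow(kept))
    paste0("tsv", seq_len(nrow(kept))) else character(0)
  mcols(gr)$length <- GenomicRanges::width(gr)
  .FragmentSet(fragments = gr, sampleId = sampleId, pairsIn = n,
               orphans = 0L, rejections = c(MAPQ = sum(!keep)))
}

#' Downsample an alignment file, preserving read pairs
#'
#' Pairs are kept or dropped together: retention is decided per query name
#' (a seeded uniform draw over the sorted unique query names), so the
#' result is deterministic given the seed and independent of record order,
#' and no orphaned mates are produced. In coverage mode the retention
#' fraction is `coverage / meanCoverage(file)` as computed by
#' [summariseBam()].
#'
#' @param file Input BAM.
#' @param dest Output BAM path (without `.bam` extension).
#' @param fraction Retention fraction in (0, 1].
#' @param coverage Target mean coverage (alternative to `fraction`).
#' @param seed Seed for the retention draw.
#' @return Path to the downsampled BAM.
#' @export
downsampleBam <- function(file, dest = tempfile(), fraction = NULL,
                          coverage = NULL, seed = 1L) {
  file <- .sam2bam(file)
  if (is.null(fraction)) {
    if (is.null(coverage))
      stop("supply either fraction or coverage")
    cur <- summariseBam(file)@meanCoverage
    if (coverage > cur)
      stop(sprintf("target coverage %.3g exceeds current %.3g",
                   coverage, cur))
    fraction <- coverage / cur
  }
  stopifnot(fraction > 0, fraction <= 1)
  qn <- Rsamtools::scanBam(
    file, param = Rsamtools::ScanBamParam(what = "qname"))[[1]]$qname
  u <- sort(unique(qn))
  set.seed(as.integer(seed))
  keepSet <- u[stats::runif(length(u)) < fraction]
  env <- new.env(parent = emptyenv())
  env$keep <- keepSet
  rule <- S4Vectors::FilterRules(list(pairkeep = function(x) {
    x$qname %in% env$keep
  }))
  Rsamtools::filterBam(file, paste0(dest, ".bam"), filter = rule,
                       param = Rsamtools::ScanBamParam(what = "qname"),
                       indexDestination = TRUE)
}
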