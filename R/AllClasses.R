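#' @import methods
#' @importFrom S4Vectors mcols mcols<-
#' @importFrom GenomicRanges GRanges seqnames start end width
NULL

## ---------------------------------------------------------------------------
## QCPolicy
## ---------------------------------------------------------------------------

#' Quality-control policy for read pairs
#'
#' Encodes the pair-level QC rules applied before fragment curation: a
#' minimum mapping quality, the requirement that reads be paired, and flags
#' for dropping duplicates, secondary/supplementary alignments and unmapped
#' reads. Proper-pair filtering is deliberately OFF by default: aligners
#' assign the proper-pair flag from a unimodal insert-size model, which
#' mis-labels genuine di-nucleosomal cfDNA fragments.
#'
#' @slot minMapq Minimum mapping quality (reads below are discarded).
#' @slot requirePaired Require the paired flag on every record.
#' @slot requireProperPair Filter on the aligner's proper-pair flag
#'   (default `FALSE`).
#' @slot dropDuplicates,dropSecondary,dropSupplementary,dropUnmapped
#'   Drop pairs where either mate carries the corresponding flag.
#' @export
setClass("QCPolicy", representation(
  minMapq = "integer",
  requirePaired = "logical",
  requireProperPair = "logical",
  dropDuplicates = "logical",
  dropSecondary = "logical",
  dropSupplementary = "logical",
  dropUnmapped = "logical"
))

setValidity("QCPolicy", function(object) {
  if (object@minMapq < 0L || object@minMapq > 255L)
    return("minMapq must be in [0, 255]")
  TRUE
})

#' Construct a QC policy
#'
#' @param minMapq Minimum mapping quality; mates below it fail QC.
#' @param requirePaired Require paired-end records.
#' @param requireProperPair Enable proper-pair filtering (off by default;
#'   see [QCPolicy-class]).
#' @param dropDuplicates,dropSecondary,dropSupplementary,dropUnmapped
#'   Flag-based exclusion rules, all on by default.
#' @return A [QCPolicy-class] object.
#' @examples
#' qcPolicy()                     # defaults: mapq >= 30, no proper-pair filter
#' qcPolicy(requireProperPair = TRUE)
#' @export
qcPolicy <- function(minMapq = 30L, requirePaired = TRUE,
                     requireProperPair = FALSE, dropDuplicates = TRUE,
                     dropSecondary = TRUE, dropSupplementary = TRUE,
                     dropUnmapped = TRUE) {
  new("QCPolicy", minMapq = as.integer(minMapq),
      requirePaired = requirePaired, requireProperPair = requireProperPair,
      dropDuplicates = dropDuplicates, dropSecondary = dropSecondary,
      dropSupplementary = dropSupplementary, dropUnmapped = dropUnmapped)
}

setMethod("show", "QCPolicy", function(object) {
  cat("QCPolicy: minMapq >=", object@minMapq,
      "| properPair:", ifelse(object@requireProperPair, "required", "ignored"),
      "| drop dup/sec/supp/unmapped:",
      paste(c(object@dropDuplicates, object@dropSecondary,
              object@dropSupplementary, object@dropUnmapped),
            collapse = "/"), "\n")
})

## Fixed rejection-reason vocabulary, in evaluation order (QC before curation).
.QC_REASONS <- c("UNMAPPED", "MAPQ", "DUPLICATE", "SECONDARY",
                 "SUPPLEMENTARY", "PROPER_PAIR")
.CURATION_REASONS <- c("SEQNAME_DISCORDANT", "NO_STRAND", "NOT_INWARD",
                       "OUT_OF_BOUND")
.ALL_REASONS <- c(.QC_REASONS, .CURATION_REASONS)

## ---------------------------------------------------------------------------
## FragmentSet
## ---------------------------------------------------------------------------

#' A set of curated cfDNA fragments with rejection accounting
#'
#' The central container produced by [readBam()]: one `GRanges` of curated
#' fragments (1-based, inclusive; `length = end - start + 1`) with per-pair
#' metadata, plus exact accounting of every read pair that did not become a
#' fragment, broken down by QC and curation rejection reason. The accounting
#' identity `pairsIn == length(fragments) + sum(rejections)` is enforced by
#' the validity method; orphan (mate-missing) records are counted separately
#' because they never form pairs.
#'
#' @slot fragments `GRanges` of curated fragments; metadata columns include
#'   `qname` and `length`.
#' @slot sampleId Sample identifier.
#' @slot pairsIn Number of read pairs assembled from the input.
#' @slot orphans Number of records whose mate was missing.
#' @slot rejections Named integer vector over the fixed rejection reasons.
#' @export
setClass("FragmentSet", representation(
  fragments = "GRanges",
  sampleId = "character",
  pairsIn = "integer",
  orphans = "integer",
  rejections = "integer"
))

setValidity("FragmentSet", function(object) {
  msg <- character()
  if (!identical(names(object@rejections), .ALL_REASONS))
    msg <- c(msg, "rejections must be named by the fixed reason vocabulary")
  if (any(object@rejections < 0L))
    msg <- c(msg, "rejection counts must be non-negative")
  if (object@pairsIn !=
      length(object@fragments) + sum(object@rejections))
    msg <- c(msg, "accounting identity violated: pairsIn != fragments + rejections")
  if (length(object@fragments) &&
      any(GenomicRanges::width(object@fragments) < 1L))
    msg <- c(msg, "fragments must have length >= 1")
  if (length(msg)) msg else TRUE
})

.FragmentSet <- function(fragments, sampleId, pairsIn, orphans, rejections) {
  rej <- setNames(integer(length(.ALL_REASONS)), .ALL_REASONS)
  rej[names(rejections)] <- as.integer(rejections)
  new("FragmentSet", fragments = fragments, sampleId = sampleId,
      pairsIn = as.integer(pairsIn), orphans = as.integer(orphans),
      rejections = rej)
}

#' @describeIn FragmentSet-class the curated fragments as a `GRanges`.
#' @param x,object A `FragmentSet`.
#' @export
fragments <- function(x) {
  stopifnot(is(x, "FragmentSet"))
  x@fragments
}

#' @describeIn FragmentSet-class named rejection counts (QC + curation).
#' @export
rejectionCounts <- function(x) {
  stopifnot(is(x, "FragmentSet"))
  x@rejections
}

#' @describeIn FragmentSet-class number of mate-missing records.
#' @export
orphanCount <- function(x) {
  stopifnot(is(x, "FragmentSet"))
  x@orphans
}

#' @describeIn FragmentSet-class number of read pairs assembled from input.
#' @export
pairsIn <- function(x) {
  stopifnot(is(x, "FragmentSet"))
  x@pairsIn
}

#' @describeIn FragmentSet-class sample identifier (also works for
#'   `LengthDist` and `MotifTable`).
#' @export
sampleId <- function(x) {
  stopifnot(is(x, "FragmentSet") || is(x, "LengthDist") ||
              is(x, "MotifTable"))
  x@sampleId
}

setMethod("show", "FragmentSet", function(object) {
  cat("FragmentSet '", object@sampleId, "': ",
      length(object@fragments), " fragments from ", object@pairsIn,
      " pairs (", sum(object@rejections), " rejected, ",
      object@orphans, " orphan records)\n", sep = "")
  rej <- object@rejections[object@rejections > 0L]
  if (length(rej))
    cat("  rejections:", paste(names(rej), rej, sep = "=", collapse = " "),
        "\n")
})

## ---------------------------------------------------------------------------
## LengthDist
## ---------------------------------------------------------------------------

#' Fragment-length distribution over a retention window
#'
#' Dense per-integer-length counts over `[minLen, maxLen]` (zero-count
#' lengths included), with the number of fragments excluded by the retention
#' window. The default window of 50-450 bp retains the mono- through
#' tri-nucleosomal range while excluding degraded and concatemeric material.
#'
#' @slot sampleId Sample identifier.
#' @slot minLen,maxLen Retention window bounds (bp, inclusive).
#' @slot counts Integer counts, one per length, named by length.
#' @slot excluded Number of fragments outside the window.
#' @export
setClass("LengthDist", representation(
  sampleId = "character",
  minLen = "integer",
  maxLen = "integer",
  counts = "integer",
  excluded = "integer"
))

setValidity("LengthDist", function(object) {
  msg <- character()
  if (object@minLen > object@maxLen)
    msg <- c(msg, "minLen must be <= maxLen")
  if (length(object@counts) != object@maxLen - object@minLen + 1L)
    msg <- c(msg, "counts must cover every length in [minLen, maxLen]")
  if (any(object@counts < 0L))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @describeIn LengthDist-class dense counts named by fragment length.
#' @param x,object A `LengthDist`.
#' @export
lengthCounts <- function(x) {
  stopifnot(is(x, "LengthDist"))
  x@counts
}

#' @describeIn LengthDist-class normalized fractions (NA when total is 0).
#' @export
lengthFractions <- function(x) {
  stopifnot(is(x, "LengthDist"))
  tot <- sum(x@counts)
  if (tot == 0L)
    return(setNames(rep(NA_real_, length(x@counts)), names(x@counts)))
  x@counts / tot
}

#' @describeIn LengthDist-class fragments excluded by the retention window.
#' @export
excludedCount <- function(x) {
  if (is(x, "LengthDist")) return(x@excluded)
  if (is(x, "MotifTable")) return(x@excludedN)
  stop("no exclusion counter for this class")
}

setMethod("show", "LengthDist", function(object) {
  tot <- sum(object@counts)
  cat("LengthDist '", object@sampleId, "': ", tot, " fragments in [",
      object@minLen, ", ", object@maxLen, "] bp (", object@excluded,
      " excluded)", sep = "")
  if (tot > 0L)
    cat("; modal length ",
        names(object@counts)[which.max(object@counts)], " bp", sep = "")
  cat("\n")
})

## ---------------------------------------------------------------------------
## MotifTable
## ---------------------------------------------------------------------------

#' Fragment end-motif frequency table
#'
#' Counts over all `4^k` DNA k-mers for one motif specification: side
#' `u` (upstream of the fragment start), `s` (at the start), `e` (at the
#' end) or `d` (downstream of the end), and motif length `k`. The mono
#' aliases umono/smono/emono/dmono are side + `k = 1`. Motifs are read from
#' the reference genome on the forward strand; windows containing `N` are
#' excluded from the table and tallied in `excludedN`.
#'
#' @slot side One of `"u"`, `"s"`, `"e"`, `"d"`.
#' @slot k Motif length.
#' @slot counts Integer counts over all `4^k` motifs in lexicographic order.
#' @slot excludedN Number of fragments whose window contained `N`.
#' @slot sampleId Sample identifier.
#' @export
setClass("MotifTable", representation(
  side = "character",
  k = "integer",
  counts = "integer",
  excludedN = "integer",
  sampleId = "character"
))

setValidity("MotifTable", function(object) {
  msg <- character()
  if (!object@side %in% c("u", "s", "e", "d"))
    msg <- c(msg, "side must be one of u/s/e/d")
  if (object@k < 1L || object@k > 10L)
    msg <- c(msg, "k must be in [1, 10]")
  if (length(object@counts) != 4L^object@k)
    msg <- c(msg, "counts must have exactly 4^k entries")
  if (any(object@counts < 0L))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @describeIn MotifTable-class counts over all `4^k` motifs.
#' @param x,object A `MotifTable`.
#' @export
motifCounts <- function(x) {
  stopifnot(is(x, "MotifTable"))
  x@counts
}

#' @describeIn MotifTable-class normalized fractions (NA when empty).
#' @export
motifFractions <- function(x) {
  stopifnot(is(x, "MotifTable"))
  tot <- sum(x@counts)
  if (tot == 0L)
    return(setNames(rep(NA_real_, length(x@counts)), names(x@counts)))
  x@counts / tot
}

setMethod("show", "MotifTable", function(object) {
  cat("MotifTable '", object@sampleId, "': ", object@side, object@k,
      " motifs, ", sum(object@counts), " fragments (", object@excludedN,
      " excluded with N)\n", sep = "")
})

## ---------------------------------------------------------------------------
## SBSProfile
## ---------------------------------------------------------------------------

#' 96-context single-base-substitution profile
#'
#' Counts over the 96 pyrimidine-centric trinucleotide substitution contexts,
#' labelled with the overlap stratum the counts were drawn from (`ALL`, `CO`,
#' `SO`, `DO`, `CO_SO`, or a derived label such as `ALL-DO`).
#'
#' @slot counts Numeric vector of length 96 named by context.
#' @slot stratum Stratum label.
#' @export
setClass("SBSProfile", representation(
  counts = "numeric",
  stratum = "character"
))

setValidity("SBSProfile", function(object) {
  msg <- character()
  if (length(object@counts) != 96L ||
      !identical(names(object@counts), sbsContextLevels()))
    msg <- c(msg, "counts must be named by the 96 canonical contexts")
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' @describeIn SBSProfile-class the 96 context counts.
#' @param x,object An `SBSProfile`.
#' @export
sbsCounts <- function(x) {
  stopifnot(is(x, "SBSProfile"))
  x@counts
}

#' @describeIn SBSProfile-class the stratum label.
#' @export
stratumLabel <- function(x) {
  stopifnot(is(x, "SBSProfile"))
  x@stratum
}

setMethod("show", "SBSProfile", function(object) {
  nz <- sum(object@counts > 0)
  cat("SBSProfile [", object@stratum, "]: ", sum(object@counts),
      " substitutions over ", nz, " contexts\n", sep = "")
})

## ---------------------------------------------------------------------------
## BamSummary
## ---------------------------------------------------------------------------

#' Descriptive alignment-file metrics
#'
#' One-sample summary of an alignment file, computed over primary records
#' only: totals, unmapped and mitochondrial read fractions, the mismatch
#' fraction (sum of edit distances over aligned reference-consuming bases),
#' per-read GC content moments, and mean coverage.
#'
#' @slot totalRecords All records in the file.
#' @slot totalPrimary Primary (non-secondary, non-supplementary) records.
#' @slot mappedPrimary Mapped primary records.
#' @slot unmappedFraction Unmapped primary / total primary.
#' @slot mitoFraction Mapped primary on mitochondrion-like contigs / mapped
#'   primary.
#' @slot mismatchFraction Sum of edit-distance tags over aligned bases
#'   (`NA` if the tag is absent).
#' @slot meanReadGC,sdReadGC Moments of per-read GC content.
#' @slot meanCoverage Sum of aligned bases over genome length.
#' @export
setClass("BamSummary", representation(
  totalRecords = "integer",
  totalPrimary = "integer",
  mappedPrimary = "integer",
  unmappedFraction = "numeric",
  mitoFraction = "numeric",
  mismatchFraction = "numeric",
  meanReadGC = "numeric",
  sdReadGC = "numeric",
  meanCoverage = "numeric"
))

setValidity("BamSummary", function(object) {
  msg <- character()
  fr <- c(object@unmappedFraction, object@mitoFraction)
  fr <- fr[!is.na(fr)]
  if (length(fr) && (any(fr < 0) || any(fr > 1)))
    msg <- c(msg, "fractions must be in [0, 1]")
  if (object@mappedPrimary > object@totalPrimary)
    msg <- c(msg, "mapped primary reads cannot exceed primary reads")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BamSummary", function(object) {
  cat("BamSummary:", object@totalPrimary, "primary reads,",
      object@mappedPrimary, "mapped\n")
  cat(sprintf("  unmapped %.4g | mito %.4g | mismatch %s | GC %.4g +/- %.4g | coverage %.4gx\n",
              object@unmappedFraction, object@mitoFraction,
              ifelse(is.na(object@mismatchFraction), "NA",
                     sprintf("%.4g", object@mismatchFraction)),
              object@meanReadGC, object@sdReadGC, object@meanCoverage))
})

#' @describeIn BamSummary-class coerce the summary to a one-row data.frame.
#' @param x,object A `BamSummary`.
#' @export
bamSummaryTable <- function(x) {
  stopifnot(is(x, "BamSummary"))
  data.frame(
    total_records = x@totalRecords,
    total_primary = x@totalPrimary,
    mapped_primary = x@mappedPrimary,
    unmapped_fraction = x@unmappedFraction,
    mito_fraction = x@mitoFraction,
    mismatch_fraction = x@mismatchFraction,
    mean_read_gc = x@meanReadGC,
    sd_read_gc = x@sdReadGC,
    mean_coverage = x@meanCoverage
  )
}
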