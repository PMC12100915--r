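## Fragment-length distributions, retention window, range fractions and
## cross-sample median profiles.

.asFragGRanges <- function(x) {
  if (is(x, "FragmentSet")) return(fragments(x))
  if (is(x, "GRanges")) return(x)
  stop("expected a FragmentSet or GRanges of fragments")
}

#' Fragment-length distribution
#'
#' Tabulates curated fragment lengths over the retention window
#' `[minLen, maxLen]` (default 50-450 bp). Fragments outside the window are
#' excluded and counted; the returned vector is dense, with zero-count
#' lengths present.
#'
#' @param x A [FragmentSet-class] or `GRanges` of fragments.
#' @param minLen,maxLen Retention window (bp, inclusive).
#' @param sampleId Sample label (taken from `x` when available).
#' @return A [LengthDist-class].
#' @examples
#' gr <- GenomicRanges::GRanges("chr1",
#'   IRanges::IRanges(c(1, 100, 200), width = c(167, 167, 334)))
#' callLength(gr)
#' @export
callLength <- function(x, minLen = 50L, maxLen = 450L,
                       sampleId = if (is(x, "FragmentSet"))
                         x@sampleId else "sample") {
  if (minLen > maxLen) stop("minLen must be <= maxLen")
  gr <- .asFragGRanges(x)
  w <- GenomicRanges::width(gr)
  inWin <- w >= minLen & w <= maxLen
  counts <- tabulate(w[inWin] - minLen + 1L, nbins = maxLen - minLen + 1L)
  new("LengthDist", sampleId = sampleId, minLen = as.integer(minLen),
      maxLen = as.integer(maxLen),
      counts = setNames(as.integer(counts), minLen:maxLen),
      excluded = sum(!inWin))
}

#' Fraction of fragments in biologically motivated length ranges
#'
#' Sums the normalized length fractions over inclusive ranges. The defaults
#' partition the cfDNA length landscape into sub-mononucleosomal (50-99 bp),
#' short mononucleosomal (100-150 bp), mononucleosomal (151-220 bp) and
#' di-nucleosomal (300-380 bp) ranges; ranges need not tile the window.
#'
#' @param dist A [LengthDist-class].
#' @param ranges Two-column matrix or list of `c(lo, hi)` pairs (bp,
#'   inclusive).
#' @return Named numeric vector of per-range fractions.
#' @export
rangeFractions <- function(dist,
                           ranges = list(c(50L, 99L), c(100L, 150L),
                                         c(151L, 220L), c(300L, 380L))) {
  stopifnot(is(dist, "LengthDist"))
  if (is.matrix(ranges))
    ranges <- lapply(seq_len(nrow(ranges)), function(i) ranges[i, ])
  lo <- vapply(ranges, `[`, numeric(1), 1L)
  hi <- vapply(ranges, `[`, numeric(1), 2L)
  if (any(lo < dist@minLen | hi > dist@maxLen))
    stop("ranges must lie within the distribution window")
  ## overlap check (allowed, but worth flagging)
  ord <- order(lo)
  if (any(lo[ord][-1] <= hi[ord][-length(hi)]))
    warning("ranges overlap")
  fr <- lengthFractions(dist)
  lens <- as.integer(names(fr))
  out <- vapply(seq_along(lo), function(i) {
    sum(fr[lens >= lo[i] & lens <= hi[i]])
  }, numeric(1))
  names(out) <- paste0(lo, "-", hi)
  out
}

#' Element-wise median length profile across samples
#'
#' The per-length median of the normalized fractions of several samples
#' (even counts use the mean of the central pair). The result need not sum
#' to 1: the median is taken independently at each length.
#'
#' @param dists List of [LengthDist-class] objects on an identical window.
#' @return Named numeric vector (one median fraction per length).
#' @export
medianLengthProfile <- function(dists) {
  stopifnot(length(dists) >= 1L,
            all(vapply(dists, is, logical(1), "LengthDist")))
  mins <- vapply(dists, function(d) d@minLen, integer(1))
  maxs <- vapply(dists, function(d) d@maxLen, integer(1))
  if (length(unique(mins)) > 1L || length(unique(maxs)) > 1L)
    stop("length distributions are on mismatched windows")
  mat <- vapply(dists, lengthFractions,
                numeric(maxs[1] - mins[1] + 1L))
  apply(mat, 1L, stats::median)
}
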