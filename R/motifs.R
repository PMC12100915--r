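## Fragment end-motif extraction and frequency profiles.
##
## Motifs are read from the REFERENCE genome at fragment coordinates (never
## from read bases), which immunizes them against sequencing error. Four
## sides are supported relative to the fragment on the genomic forward
## strand: u (k bases immediately upstream of the start), s (first k bases),
## e (last k bases), d (k bases immediately downstream of the end). By
## default no reverse-complementing is applied to e/d motifs; a 5'-centric
## reverse-complemented convention is available via `revcompEnd` for
## comparison with other end-motif literature.

#' Parse a motif specification
#'
#' Accepts `"s3"`, `"u1"`, ... or the mono aliases `"smono"`, `"umono"`,
#' `"emono"`, `"dmono"`.
#' @param spec Motif spec string.
#' @return List with `side` and `k`.
#' @export
motifSpec <- function(spec) {
  if (grepl("^[used]mono$", spec))
    return(list(side = substr(spec, 1, 1), k = 1L))
  m <- regmatches(spec, regexec("^([used])([0-9]+)$", spec))[[1]]
  if (length(m) != 3L)
    stop("malformed motif spec: ", spec)
  k <- as.integer(m[3])
  if (k < 1L || k > 10L) stop("motif length must be in [1, 10]")
  list(side = m[2], k = k)
}

#' Extract end motifs for fragments from the reference
#'
#' Returns, for each fragment, the reference bases (uppercased, forward
#' strand) in the window defined by the motif side and length. Windows that
#' extend past the contig ends are N-padded to full width.
#'
#' @param x A [FragmentSet-class] or `GRanges` of fragments.
#' @param reference `DNAStringSet`, `FaFile`, FASTA path, or the result of
#'   [makeReference()].
#' @param spec Motif spec string (e.g. `"s3"`, `"umono"`).
#' @param revcompEnd Report e/d motifs reverse-complemented (5'-centric
#'   convention); off by default.
#' @return Character vector over `{A,C,G,T,N}` of width `k`.
#' @export
extractMotif <- function(x, reference, spec = "s3", revcompEnd = FALSE) {
  gr <- .asFragGRanges(x)
  ref <- if (is.list(reference)) reference$sequences else
    .loadReference(reference)
  sp <- motifSpec(spec)
  s <- GenomicRanges::start(gr)
  e <- GenomicRanges::end(gr)
  k <- sp$k
  win <- switch(sp$side,
                s = cbind(s, s + k - 1L),
                e = cbind(e - k + 1L, e),
                u = cbind(s - k, s - 1L),
                d = cbind(e + 1L, e + k))
  out <- .refWindow(ref, as.character(GenomicRanges::seqnames(gr)),
                    win[, 1L], win[, 2L])
  if (revcompEnd && sp$side %in% c("e", "d")) out <- .revComp(out)
  out
}

#' Build a motif frequency table
#'
#' Tabulates one motif per fragment over all `4^k` motifs (zero-count rows
#' present, fixed lexicographic order). Motifs containing `N` are excluded
#' from the table and tallied separately. Apply the fragment-length
#' retention window upstream (see [callLength()]).
#'
#' @inheritParams extractMotif
#' @param motifType Motif side, one of `"u"`, `"s"`, `"e"`, `"d"`.
#' @param motifLength Motif length `k`.
#' @param sampleId Sample label.
#' @return A [MotifTable-class].
#' @examples
#' sim <- simulateDataset(simConfig(seed = 5, nFragments = 300))
#' fs <- readBam(sim$files$bam)
#' callMotif(fs, sim$reference, motifType = "s", motifLength = 3)
#' @export
callMotif <- function(x, reference, motifType = "s", motifLength = 3L,
                      revcompEnd = FALSE,
                      sampleId = if (is(x, "FragmentSet"))
                        x@sampleId else "sample") {
  spec <- paste0(motifType, motifLength)
  motifs <- extractMotif(x, reference, spec, revcompEnd = revcompEnd)
  hasN <- grepl("N", motifs, fixed = TRUE)
  lev <- .allKmers(as.integer(motifLength))
  counts <- table(factor(motifs[!hasN], levels = lev))
  new("MotifTable", side = motifType, k = as.integer(motifLength),
      counts = setNames(as.integer(counts), lev),
      excludedN = sum(hasN), sampleId = sampleId)
}

#' Sum of motif fractions by leading base
#'
#' Groups the `4^k` motif fractions of a start-side table by their first
#' character; the four sums add to 1.
#'
#' @param table A [MotifTable-class] (start side).
#' @return Named numeric vector for A, C, G, T.
#' @export
firstBaseFractions <- function(table) {
  stopifnot(is(table, "MotifTable"))
  fr <- motifFractions(table)
  lead <- substr(names(fr), 1L, 1L)
  vapply(.BASES, function(b) sum(fr[lead == b]), numeric(1))
}

.motifVector <- function(x) {
  if (is(x, "MotifTable")) motifFractions(x) else as.numeric(x)
}

#' Pearson correlation between motif profiles
#'
#' Correlates two motif fraction vectors in the fixed lexicographic motif
#' order. Either argument may be a [MotifTable-class] or a plain numeric
#' profile (e.g. a median profile from [medianMotifProfile()]).
#' Zero-variance input yields `NA` with a warning rather than an error.
#'
#' @param a,b Motif tables or numeric fraction vectors of equal length.
#' @return Pearson correlation coefficient, or `NA` if undefined.
#' @export
motifCorrelation <- function(a, b) {
  if (is(a, "MotifTable") && is(b, "MotifTable") &&
      (a@side != b@side || a@k != b@k))
    stop("motif tables have different specs")
  va <- .motifVector(a)
  vb <- .motifVector(b)
  if (length(va) != length(vb))
    stop("profiles have different lengths")
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    warning("zero-variance motif profile: correlation undefined")
    return(NA_real_)
  }
  stats::cor(va, vb)
}

#' Element-wise median motif profile across samples
#'
#' @param tables List of [MotifTable-class] objects with identical specs.
#' @return Named numeric vector of median fractions (need not sum to 1).
#' @export
medianMotifProfile <- function(tables) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, is, logical(1), "MotifTable")))
  sides <- vapply(tables, function(t) t@side, character(1))
  ks <- vapply(tables, function(t) t@k, integer(1))
  if (length(unique(sides)) > 1L || length(unique(ks)) > 1L)
    stop("motif tables have mismatched specs")
  mat <- vapply(tables, motifFractions, numeric(4L^ks[1]))
  apply(mat, 1L, stats::median)
}

#' Export a samples x motifs fraction matrix
#'
#' Convenience for correlation heatmaps or PCA done elsewhere.
#'
#' @param tables List of [MotifTable-class] objects with identical specs.
#' @return Numeric matrix, rows = samples, columns = motifs.
#' @export
motifMatrix <- function(tables) {
  stopifnot(all(vapply(tables, is, logical(1), "MotifTable")))
  mat <- t(vapply(tables, motifFractions,
                  numeric(4L^tables[[1]]@k)))
  rownames(mat) <- vapply(tables, function(t) t@sampleId, character(1))
  mat
}
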