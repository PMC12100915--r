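## Internal helpers shared across modules.

.BASES <- c("A", "C", "G", "T")

#' All k-mers over the DNA alphabet in lexicographic order
#'
#' @param k Motif length (>= 1).
#' @return Character vector of length `4^k`, sorted lexicographically.
#' @keywords internal
.allKmers <- function(k) {
  stopifnot(k >= 1L, k <= 10L)
  grid <- do.call(expand.grid,
                  c(rep(list(.BASES), k), stringsAsFactors = FALSE))
  sort(do.call(paste0, grid))
}

#' Reverse-complement of DNA strings (IUPAC-aware)
#' @keywords internal
.revComp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' The 96 single-base-substitution context labels
#'
#' Pyrimidine-centric labels in the conventional column order: substitution
#' classes C>A, C>G, C>T, T>A, T>C, T>G, each expanded over the sixteen
#' flanking-base combinations sorted by 5' then 3' flank.
#'
#' @return Character vector of length 96, e.g. `"A[C>A]A"`.
#' @export
sbsContextLevels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  flank <- expand.grid(three = .BASES, five = .BASES,
                       stringsAsFactors = FALSE)
  flank <- flank[order(flank$five, flank$three), ]
  unlist(lapply(subs, function(s) {
    paste0(flank$five, "[", s, "]", flank$three)
  }), use.names = FALSE)
}

## Mitochondrion-like and sex contig name sets used when selecting autosomes.
.MITO_NAMES <- c("chrM", "MT", "chrMT", "M")
.SEX_NAMES <- c("chrX", "chrY", "X", "Y")

#' Extract subsequences from an in-memory reference, N-padding out-of-bounds
#'
#' Windows may extend past either contig end; the returned strings are padded
#' with `N` so they always have width `end - start + 1`.
#' @keywords internal
.refWindow <- function(ref, chrom, start, end) {
  stopifnot(length(chrom) == length(start), length(start) == length(end))
  out <- character(length(start))
  if (!all(chrom %in% names(ref))) {
    bad <- setdiff(unique(chrom), names(ref))
    stop("unknown contig(s): ", paste(bad, collapse = ", "))
  }
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    len <- length(ref[[ch]])
    s <- pmax(start[i], 1L)
    e <- pmin(end[i], len)
    seqs <- character(length(i))
    ok <- s <= e
    if (any(ok)) {
      seqs[ok] <- as.character(Biostrings::extractAt(
        ref[[ch]], IRanges::IRanges(s[ok], e[ok])))
    }
    pre <- pmax(1L - start[i], 0L)
    post <- pmax(end[i] - len, 0L)
    seqs <- paste0(strrep("N", pre), seqs, strrep("N", post))
    out[i] <- seqs
  }
  toupper(out)
}

#' Load a reference as a named DNAStringSet
#'
#' Accepts a `DNAStringSet`, an `Rsamtools::FaFile`, or a path to a FASTA
#' file. Names are truncated at the first whitespace, as in SAM headers.
#' @keywords internal
.loadReference <- function(ref) {
  if (is(ref, "DNAStringSet")) {
    x <- ref
  } else if (is(ref, "FaFile")) {
    x <- Biostrings::readDNAStringSet(Rsamtools::path(ref))
  } else if (is.character(ref) && length(ref) == 1L) {
    x <- Biostrings::readDNAStringSet(ref)
  } else {
    stop("reference must be a DNAStringSet, FaFile, or FASTA path")
  }
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Seeded uniform draw helper: derive a child seed below 2^31
#' @keywords internal
.childSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + as.numeric(offset)) %%
               .Machine$integer.max)
}
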