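## Mutation-overlap annotation of read pairs against a priori variant loci,
## de novo mismatch candidates, and stratified 96-context SBS profiles.
##
## A cfDNA fragment sequenced as an overlapping read pair observes a variant
## locus up to twice. Three informative categories follow: concordant
## overlap (CO, both reads support the same variant base), single-read
## overlap (SO, only one read covers the locus and it carries the variant),
## and discordant overlap (DO, the covering reads disagree). DO gauges the
## per-locus noise; removing DO events can sharpen mutational-signature
## profiles.

#' Read a variant-locus list
#'
#' Tab-separated columns chrom, pos (1-based), ref, alt; header optional.
#' A VCF is accepted as a convenience (only CHROM/POS/REF/ALT are used;
#' multi-allelic and non-SNV rows are dropped with a message).
#'
#' @param path Path to the TSV or VCF.
#' @return data.frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @export
readVariants <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    ln <- readLines(path)
    ln <- ln[!startsWith(ln, "#")]
    f <- strsplit(ln, "\t")
    df <- data.frame(chrom = vapply(f, `[`, "", 1L),
                     pos = as.integer(vapply(f, `[`, "", 2L)),
                     ref = toupper(vapply(f, `[`, "", 4L)),
                     alt = toupper(vapply(f, `[`, "", 5L)),
                     stringsAsFactors = FALSE)
  } else {
    first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
    hasHeader <- is.na(suppressWarnings(as.integer(first[2])))
    df <- utils::read.table(path, sep = "\t", header = hasHeader,
                            stringsAsFactors = FALSE)
    names(df)[1:4] <- c("chrom", "pos", "ref", "alt")
    df$ref <- toupper(df$ref)
    df$alt <- toupper(df$alt)
  }
  keep <- df$ref %in% .BASES & df$alt %in% .BASES & df$ref != df$alt
  if (any(!keep))
    message("dropping ", sum(!keep), " non-SNV or malformed variant rows")
  df[keep, c("chrom", "pos", "ref", "alt")]
}

## Read base at a reference position, walking the CIGAR. Returns NA when the
## read does not span the position, a deletion/skip covers it, or the base
## quality is below the threshold.
.baseAtRefPos <- function(start, cigar, seq, qual, refpos, minBQ = 20L) {
  if (is.na(start) || is.na(cigar) || cigar == "*") return(NA_character_)
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1]]
  refcur <- start
  qcur <- 1L
  for (i in seq_along(ops)) {
    op <- ops[i]
    len <- lens[i]
    if (op %in% c("M", "=", "X")) {
      if (refpos >= refcur && refpos <= refcur + len - 1L) {
        qpos <- qcur + (refpos - refcur)
        bq <- utf8ToInt(substr(qual, qpos, qpos)) - 33L
        if (length(bq) && !is.na(bq) && bq < minBQ) return(NA_character_)
        return(substr(seq, qpos, qpos))
      }
      refcur <- refcur + len
      qcur <- qcur + len
    } else if (op %in% c("I", "S")) {
      qcur <- qcur + len
    } else if (op %in% c("D", "N")) {
      if (refpos >= refcur && refpos <= refcur + len - 1L)
        return(NA_character_)  # deletion spans the locus
      refcur <- refcur + len
    }
    ## H and P consume neither sequence
  }
  NA_character_
}

#' Classify the overlap category of per-read base support
#'
#' Vectorized, total classification: both reads cover and show the
#' alternative base -> `CO`; exactly one read covers and shows it -> `SO`;
#' both cover and exactly one shows it -> `DO`; covered but no alternative
#' base observed -> `REF_ONLY`; no covering read -> `NO_COVER`.
#'
#' @param baseFwd,baseRev Observed base per read (`NA` = does not cover).
#' @param alt The alternative allele.
#' @return Character vector of categories.
#' @export
classifyOverlap <- function(baseFwd, baseRev, alt) {
  coverF <- !is.na(baseFwd)
  coverR <- !is.na(baseRev)
  altF <- coverF & baseFwd == alt
  altR <- coverR & baseRev == alt
  nCover <- coverF + coverR
  nAlt <- altF + altR
  out <- rep("NO_COVER", length(nCover))
  out[nCover > 0L] <- "REF_ONLY"
  out[nCover == 1L & nAlt == 1L] <- "SO"
  out[nCover == 2L & nAlt == 1L] <- "DO"
  out[nCover == 2L & nAlt == 2L] <- "CO"
  out
}

#' Annotate fragments overlapping a priori variant loci
#'
#' Reads a paired-end alignment file, applies QC and curation, and for each
#' spiked/known locus inspects the bases observed by the two reads of every
#' overlapping fragment, classifying the fragment into CO / SO / DO /
#' REF_ONLY. Bases below `minBaseQuality` are treated as not covering.
#'
#' @param file BAM/SAM path.
#' @param loci data.frame with columns chrom, pos, ref, alt (see
#'   [readVariants()]).
#' @param policy A [QCPolicy-class].
#' @param minBaseQuality Minimum base quality for a read observation.
#' @param region Optional `GRanges` restricting the read query.
#' @return data.frame with one row per overlapping fragment x locus:
#'   `qname`, `locus`, `chrom`, `pos`, `ref`, `alt`, `base_fwd`, `base_rev`,
#'   `both_reads_cover`, `category`, plus the fragment coordinates.
#' @export
annotateMutations <- function(file, loci, policy = qcPolicy(),
                              minBaseQuality = 20L, region = NULL) {
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(loci)))
  bam <- .sam2bam(file)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  rp <- readPairs(bam, region = region)
  pairs <- rp$pairs
  pairs <- pairs[applyQC(pairs, policy) == "pass", , drop = FALSE]
  cur <- curatePairs(pairs, hdr)
  ok <- cur$outcome == "fragment"
  pairs <- pairs[ok, , drop = FALSE]
  cur <- cur[ok, , drop = FALSE]

  rows <- vector("list", nrow(loci))
  for (j in seq_len(nrow(loci))) {
    pos <- loci$pos[j]
    hit <- which(cur$chrom == loci$chrom[j] & cur$start <= pos &
                   cur$end >= pos)
    if (!length(hit)) next
    fwdIs1 <- pairs$strand1[hit] == "+"
    baseF <- baseR <- character(length(hit))
    for (u in seq_along(hit)) {
      i <- hit[u]
      if (fwdIs1[u]) {
        baseF[u] <- .baseAtRefPos(pairs$start1[i], pairs$cigar1[i],
                                  pairs$seq1[i], pairs$qual1[i], pos,
                                  minBaseQuality)
        baseR[u] <- .baseAtRefPos(pairs$start2[i], pairs$cigar2[i],
                                  pairs$seq2[i], pairs$qual2[i], pos,
                                  minBaseQuality)
      } else {
        baseF[u] <- .baseAtRefPos(pairs$start2[i], pairs$cigar2[i],
                                  pairs$seq2[i], pairs$qual2[i], pos,
                                  minBaseQuality)
        baseR[u] <- .baseAtRefPos(pairs$start1[i], pairs$cigar1[i],
                                  pairs$seq1[i], pairs$qual1[i], pos,
                                  minBaseQuality)
      }
    }
    rows[[j]] <- data.frame(
      qname = cur$qname[hit],
      locus = paste0(loci$chrom[j], ":", pos, ":", loci$ref[j], ">",
                     loci$alt[j]),
      chrom = loci$chrom[j], pos = pos, ref = loci$ref[j],
      alt = loci$alt[j],
      base_fwd = baseF, base_rev = baseR,
      both_reads_cover = !is.na(baseF) & !is.na(baseR),
      category = classifyOverlap(baseF, baseR, loci$alt[j]),
      frag_start = cur$start[hit], frag_end = cur$end[hit],
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(qname = character(0), locus = character(0),
                      chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      base_fwd = character(0), base_rev = character(0),
                      both_reads_cover = logical(0),
                      category = character(0),
                      frag_start = integer(0), frag_end = integer(0))
  out
}

#' Aggregate per-fragment annotations into per-locus allele support
#'
#' By default discordant-overlap fragments are NOT counted toward the
#' alternative-allele count: a discordant pair gauges the noise at a locus
#' rather than supporting the variant. Set `includeDiscordant = TRUE` to
#' count them.
#'
#' @param annotations data.frame from [annotateMutations()].
#' @param includeDiscordant Count DO fragments in `alt_count`.
#' @return data.frame with one row per locus: category tallies, `alt_count`
#'   and `ref_count`.
#' @export
aggregateSupport <- function(annotations, includeDiscordant = FALSE) {
  if (!nrow(annotations)) {
    out <- data.frame(locus = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0),
                      alt = character(0), n_co = integer(0),
                      n_so = integer(0), n_do = integer(0),
                      n_ref_only = integer(0))
    out$alt_count <- integer(0)
    out$ref_count <- integer(0)
    return(out)
  }
  loci <- unique(annotations[c("locus", "chrom", "pos", "ref", "alt")])
  tal <- table(annotations$locus,
               factor(annotations$category,
                      levels = c("CO", "SO", "DO", "REF_ONLY", "NO_COVER")))
  idx <- match(loci$locus, rownames(tal))
  out <- data.frame(loci,
                    n_co = as.integer(tal[idx, "CO"]),
                    n_so = as.integer(tal[idx, "SO"]),
                    n_do = as.integer(tal[idx, "DO"]),
                    n_ref_only = as.integer(tal[idx, "REF_ONLY"]),
                    stringsAsFactors = FALSE)
  out$alt_count <- out$n_co + out$n_so +
    if (includeDiscordant) out$n_do else 0L
  out$ref_count <- out$n_ref_only
  rownames(out) <- NULL
  out
}

#' Call de novo mismatch candidate loci from an alignment file
#'
#' Mate-aware pileup with a fragment-level double-count guard: each
#' QC-passing, curated fragment contributes at most one observation per
#' position (the consensus of its covering reads; reads that disagree at a
#' position remove the fragment from the depth there). Positions where some
#' non-reference base is supported by at least `minAltFragments` fragments
#' are emitted.
#'
#' @param file BAM/SAM path.
#' @param reference Reference (`DNAStringSet`, `FaFile`, path or
#'   [makeReference()] result).
#' @param region Optional `GRanges` restricting the scan.
#' @param minBaseQuality,minMapq Quality thresholds.
#' @param minAltFragments Minimum alt-supporting fragments to emit a locus.
#' @return data.frame: chrom, pos, ref, alt, alt_count, ref_count,
#'   discarded (discordant fragments removed from depth).
#' @export
pileupMismatches <- function(file, reference, region = NULL,
                             minBaseQuality = 20L, minMapq = 30L,
                             minAltFragments = 1L) {
  ref <- if (is.list(reference)) reference$sequences else
    .loadReference(reference)
  bam <- .sam2bam(file)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!is.null(region)) {
    bad <- !as.character(GenomicRanges::seqnames(region)) %in% names(hdr)
    if (any(bad)) stop("region outside the reference contigs")
  }
  rp <- readPairs(bam, region = region)
  pairs <- rp$pairs
  pairs <- pairs[applyQC(pairs, qcPolicy(minMapq = minMapq)) == "pass", ,
                 drop = FALSE]
  cur <- curatePairs(pairs, hdr)
  ok <- cur$outcome == "fragment"
  pairs <- pairs[ok, , drop = FALSE]
  cur <- cur[ok, , drop = FALSE]
  if (!nrow(pairs))
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      alt_count = integer(0), ref_count = integer(0),
                      discarded = integer(0)))

  ## shortlist reads carrying mismatches (NM tag when present)
  nmKnown <- !all(is.na(pairs$nm1)) || !all(is.na(pairs$nm2))
  events <- list()
  for (mate in 1:2) {
    st <- pairs[[paste0("start", mate)]]
    en <- pairs[[paste0("end", mate)]]
    rn <- pairs[[paste0("rname", mate)]]
    sq <- pairs[[paste0("seq", mate)]]
    ql <- pairs[[paste0("qual", mate)]]
    nm <- pairs[[paste0("nm", mate)]]
    cand <- if (nmKnown) which(!is.na(nm) & nm > 0L) else seq_along(st)
    for (i in cand) {
      refseg <- .refWindow(ref, rn[i], st[i], en[i])
      a <- utf8ToInt(sq[i])
      b <- utf8ToInt(refseg)
      if (length(a) != length(b)) next  # indel-containing read: skip scan
      d <- which(a != b)
      if (!length(d)) next
      bq <- utf8ToInt(ql[i]) - 33L
      d <- d[bq[d] >= minBaseQuality]
      if (!length(d)) next
      events[[length(events) + 1L]] <- data.frame(
        pairIdx = i, mate = mate, chrom = rn[i], pos = st[i] + d - 1L,
        base = substring(sq[i], d, d), stringsAsFactors = FALSE)
    }
  }
  if (!length(events))
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      alt_count = integer(0), ref_count = integer(0),
                      discarded = integer(0)))
  ev <- do.call(rbind, events)

  ## restrict to the query region if given
  if (!is.null(region)) {
    gr <- GenomicRanges::GRanges(ev$chrom, IRanges::IRanges(ev$pos, ev$pos))
    ev <- ev[IRanges::overlapsAny(gr, region), , drop = FALSE]
  }

  ## per fragment x position consensus among event-carrying fragments
  key <- paste(ev$pairIdx, ev$chrom, ev$pos)
  cons <- lapply(split(seq_len(nrow(ev)), key), function(ii) {
    e <- ev[ii, ]
    i <- e$pairIdx[1]
    pos <- e$pos[1]
    ## does the other mate cover this position?
    otherMate <- setdiff(1:2, e$mate)
    baseHere <- setNames(e$base, e$mate)
    getBase <- function(m) {
      if (as.character(m) %in% names(baseHere))
        return(baseHere[[as.character(m)]])
      st <- pairs[[paste0("start", m)]][i]
      en <- pairs[[paste0("end", m)]][i]
      rn <- pairs[[paste0("rname", m)]][i]
      if (!is.na(st) && rn == e$chrom[1] && pos >= st && pos <= en)
        substr(.refWindow(ref, rn, pos, pos), 1L, 1L)  # matches reference
      else NA_character_
    }
    b1 <- getBase(1)
    b2 <- getBase(2)
    status <- if (!is.na(b1) && !is.na(b2)) {
      if (b1 == b2) "agree" else "discord"
    } else "single"
    data.frame(pairIdx = i, chrom = e$chrom[1], pos = pos,
               base = if (status == "discord") NA_character_ else
                 if (!is.na(b1)) b1 else b2,
               status = status, stringsAsFactors = FALSE)
  })
  cons <- do.call(rbind, cons)

  ## fragment depth at each candidate position
  candPos <- unique(cons[c("chrom", "pos")])
  fragGR <- GenomicRanges::GRanges(cur$chrom,
                                   IRanges::IRanges(cur$start, cur$end))
  posGR <- GenomicRanges::GRanges(candPos$chrom,
                                  IRanges::IRanges(candPos$pos, candPos$pos))
  depth <- GenomicRanges::countOverlaps(posGR, fragGR)

  out <- lapply(seq_len(nrow(candPos)), function(r) {
    cc <- cons[cons$chrom == candPos$chrom[r] & cons$pos == candPos$pos[r], ]
    refBase <- substr(.refWindow(ref, candPos$chrom[r], candPos$pos[r],
                                 candPos$pos[r]), 1L, 1L)
    disc <- sum(cc$status == "discord")
    altTab <- table(cc$base[!is.na(cc$base) & cc$base != refBase])
    if (!length(altTab) || max(altTab) < minAltFragments) return(NULL)
    alt <- names(altTab)[which.max(altTab)]
    altN <- as.integer(max(altTab))
    data.frame(chrom = candPos$chrom[r], pos = candPos$pos[r],
               ref = refBase, alt = alt, alt_count = altN,
               ref_count = depth[r] - nrow(cc),
               discarded = disc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      alt_count = integer(0), ref_count = integer(0),
                      discarded = integer(0))
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Trinucleotide substitution context of variant loci
#'
#' Maps each locus to one of the 96 pyrimidine-centric context labels. When
#' the reference base is a purine the substitution is reported from the
#' opposite strand: the alternative base is complemented and the flanks are
#' complemented and swapped.
#'
#' @param loci data.frame with chrom, pos, ref, alt.
#' @param reference Reference sequence set.
#' @return Character vector of context labels (e.g. `"A[C>T]G"`).
#' @export
sbsContext <- function(loci, reference) {
  ref <- if (is.list(reference)) reference$sequences else
    .loadReference(reference)
  tri <- .refWindow(ref, loci$chrom, loci$pos - 1L, loci$pos + 1L)
  mid <- substr(tri, 2L, 2L)
  bad <- mid != loci$ref
  if (any(bad))
    stop("reference base mismatch at ", loci$chrom[bad][1], ":",
         loci$pos[bad][1], " (reference has ", mid[bad][1], ", locus says ",
         loci$ref[bad][1], ")")
  if (any(grepl("N", tri)))
    stop("flanking base unavailable (contig boundary) for a locus")
  pyr <- loci$ref %in% c("C", "T")
  out <- character(nrow(loci))
  out[pyr] <- paste0(substr(tri[pyr], 1, 1), "[", loci$ref[pyr], ">",
                     loci$alt[pyr], "]", substr(tri[pyr], 3, 3))
  if (any(!pyr)) {
    rcTri <- .revComp(tri[!pyr])
    rcAlt <- .revComp(loci$alt[!pyr])
    out[!pyr] <- paste0(substr(rcTri, 1, 1), "[", substr(rcTri, 2, 2), ">",
                        rcAlt, "]", substr(rcTri, 3, 3))
  }
  out
}

#' Build stratified 96-context SBS profiles
#'
#' Each locus contributes to a stratum's profile with weight equal to the
#' number of fragments in that stratum supporting the alternative allele
#' (`weighting = "fragment"`, the default, which preserves the CO/SO/DO
#' stratification semantics), or 0/1 per locus (`weighting = "locus"`).
#' The `ALL` stratum pools CO, SO and DO; a DO-removed profile is
#' `sbsSubtract(profiles$ALL, profiles$DO)`.
#'
#' @param annotations data.frame from [annotateMutations()].
#' @param reference Reference sequence set.
#' @param strata Subset of `c("ALL", "CO", "SO", "DO", "CO_SO")`.
#' @param weighting `"fragment"` or `"locus"`.
#' @return Named list of [SBSProfile-class] objects, one per stratum.
#' @export
callTrinucleotide <- function(annotations, reference,
                              strata = c("ALL", "CO", "SO", "DO", "CO_SO"),
                              weighting = c("fragment", "locus")) {
  weighting <- match.arg(weighting)
  strata <- match.arg(strata, several.ok = TRUE)
  lev <- sbsContextLevels()
  loci <- unique(annotations[c("locus", "chrom", "pos", "ref", "alt")])
  ctx <- if (nrow(loci)) sbsContext(loci, reference) else character(0)
  names(ctx) <- loci$locus
  sets <- list(ALL = c("CO", "SO", "DO"), CO = "CO", SO = "SO", DO = "DO",
               CO_SO = c("CO", "SO"))
  out <- lapply(strata, function(s) {
    sub <- annotations[annotations$category %in% sets[[s]], , drop = FALSE]
    counts <- setNames(numeric(96L), lev)
    if (nrow(sub)) {
      w <- table(sub$locus)
      if (weighting == "locus") w[w > 0] <- 1
      cx <- ctx[names(w)]
      add <- tapply(as.numeric(w), factor(cx, levels = lev), sum)
      add[is.na(add)] <- 0
      counts <- counts + as.numeric(add)
      names(counts) <- lev
    } else {
      warning("empty stratum: ", s)
    }
    new("SBSProfile", counts = counts, stratum = s)
  })
  names(out) <- strata
  out
}

#' Subtract one SBS profile from another (clipped at zero)
#'
#' @param a,b [SBSProfile-class] objects.
#' @return An [SBSProfile-class] labelled `"<a>-<b>"`.
#' @export
sbsSubtract <- function(a, b) {
  stopifnot(is(a, "SBSProfile"), is(b, "SBSProfile"))
  new("SBSProfile", counts = pmax(sbsCounts(a) - sbsCounts(b), 0),
      stratum = paste0(stratumLabel(a), "-", stratumLabel(b)))
}

#' Cosine similarity between substitution profiles
#'
#' Scale-invariant similarity `sum(p*q) / (||p|| * ||q||)` between two
#' non-negative 96-context vectors (or [SBSProfile-class] objects).
#' A zero vector yields `NA` with a warning.
#'
#' @param p,q Profiles or non-negative numeric vectors of equal length.
#' @return Numeric in `[0, 1]`, or `NA` if undefined.
#' @export
cosineSimilarity <- function(p, q) {
  vp <- if (is(p, "SBSProfile")) sbsCounts(p) else as.numeric(p)
  vq <- if (is(q, "SBSProfile")) sbsCounts(q) else as.numeric(q)
  stopifnot(length(vp) == length(vq))
  np <- sqrt(sum(vp^2))
  nq <- sqrt(sum(vq^2))
  if (np == 0 || nq == 0) {
    warning("zero profile: cosine similarity undefined")
    return(NA_real_)
  }
  sum(vp * vq) / (np * nq)
}
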