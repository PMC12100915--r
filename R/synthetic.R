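## Synthetic paired-end alignment generator with exhaustive ground truth.
##
## Emulates the data a cfDNA fragmentomics pipeline sees after alignment:
## fragments drawn from a nucleosome-like length mixture, sequence-through
## read pairs with optional 3' overhang artifacts (untrimmed adapter aligned
## past the true fragment end), planted end-motif bias, QC-violating records
## of every class, and spiked variants with controllable concordant /
## discordant read-pair support.

#' Configuration for the synthetic alignment generator
#'
#' @slot seed Master seed; all randomness derives from it.
#' @slot chromosomes data.frame with columns `name`, `length` (bp) and `gc`
#'   (target GC fraction), including one mitochondrion-like contig (`chrM`).
#' @slot nFragments Number of cfDNA molecules to simulate.
#' @slot lengthMixture data.frame with columns `weight`, `mean`, `sd`:
#'   Gaussian mixture over fragment lengths (weights sum to 1).
#' @slot readLength Sequenced read length (bp).
#' @slot overhangRate Fraction of eligible sequence-through pairs whose
#'   forward read is extended past the fragment end.
#' @slot overhangLength 3' overhang length (bp).
#' @slot substitutionErrorRate Per-base substitution error rate.
#' @slot duplicateRate,lowMapqRate,secondaryRate,unmappedRate,discordantChromRate,outwardRate
#'   Fractions of pairs planted with each QC/curation-violating artifact.
#' @slot mitoFraction Fraction of fragments placed on the mitochondrion-like
#'   contig (exact count, deterministic).
#' @slot variantSpikes data.frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `vaf`, `discordantRate`.
#' @slot motifBias Named numeric sampling weights over start bases
#'   (length 0 = unbiased).
#' @slot cnvRegions data.frame with columns `chrom`, `start`, `end`,
#'   `multiplier`: regions sampled at `multiplier` times the background rate.
#' @export
setClass("SimConfig", representation(
  seed = "integer",
  chromosomes = "data.frame",
  nFragments = "integer",
  lengthMixture = "data.frame",
  readLength = "integer",
  overhangRate = "numeric",
  overhangLength = "integer",
  substitutionErrorRate = "numeric",
  duplicateRate = "numeric",
  lowMapqRate = "numeric",
  secondaryRate = "numeric",
  unmappedRate = "numeric",
  discordantChromRate = "numeric",
  outwardRate = "numeric",
  mitoFraction = "numeric",
  variantSpikes = "data.frame",
  motifBias = "numeric",
  cnvRegions = "data.frame"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  ch <- object@chromosomes
  if (!all(c("name", "length", "gc") %in% names(ch)))
    msg <- c(msg, "chromosomes needs columns name, length, gc")
  else {
    if (any(ch$length < 1000))
      msg <- c(msg, "chromosome lengths must be >= 1 kb")
    if (any(ch$gc <= 0 | ch$gc >= 1))
      msg <- c(msg, "GC targets must be in (0, 1)")
  }
  mx <- object@lengthMixture
  if (!all(c("weight", "mean", "sd") %in% names(mx)))
    msg <- c(msg, "lengthMixture needs columns weight, mean, sd")
  else if (abs(sum(mx$weight) - 1) > 1e-8)
    msg <- c(msg, "lengthMixture weights must sum to 1")
  rates <- c(object@overhangRate, object@substitutionErrorRate,
             object@duplicateRate, object@lowMapqRate, object@secondaryRate,
             object@unmappedRate, object@discordantChromRate,
             object@outwardRate, object@mitoFraction)
  if (any(rates < 0 | rates > 1))
    msg <- c(msg, "all rates must be in [0, 1]")
  vs <- object@variantSpikes
  if (nrow(vs)) {
    if (!all(c("chrom", "pos", "ref", "alt", "vaf", "discordantRate")
             %in% names(vs)))
      msg <- c(msg, "variantSpikes needs chrom,pos,ref,alt,vaf,discordantRate")
    else {
      idx <- match(vs$chrom, ch$name)
      if (anyNA(idx) || any(vs$pos < 1 | vs$pos > ch$length[idx]))
        msg <- c(msg, "spike positions must lie within contig bounds")
      if (any(!vs$ref %in% .BASES | !vs$alt %in% .BASES | vs$ref == vs$alt))
        msg <- c(msg, "spike ref/alt must be distinct A/C/G/T")
    }
  }
  if (length(object@motifBias) &&
      (is.null(names(object@motifBias)) ||
       !all(names(object@motifBias) %in% .BASES) ||
       any(object@motifBias < 0)))
    msg <- c(msg, "motifBias must be non-negative weights named by A/C/G/T")
  if (length(msg)) msg else TRUE
})

#' Construct a generator configuration
#'
#' Defaults encode the study conditions used throughout: a small
#' multi-chromosome reference with one mitochondrion-like contig, read
#' length 150 bp, and a nucleosome-like length mixture with a
#' mono-nucleosomal mode at 167 bp, a di-nucleosomal component in the
#' 300-380 bp range and a sub-150 bp component.
#'
#' @param seed Master seed (integer).
#' @param chromosomes data.frame(name, length, gc).
#' @param nFragments Number of fragments.
#' @param lengthMixture data.frame(weight, mean, sd).
#' @param readLength Read length in bp.
#' @param overhangRate,overhangLength 3' overhang artifact controls for
#'   sequence-through pairs.
#' @param substitutionErrorRate Per-base substitution error rate.
#' @param duplicateRate,lowMapqRate,secondaryRate,unmappedRate
#'   Artifact-pair fractions (flag-based QC violations).
#' @param discordantChromRate,outwardRate Curation-violating pair fractions.
#' @param mitoFraction Fraction of fragments on `chrM` (placed as an exact
#'   count).
#' @param variantSpikes data.frame(chrom, pos, ref, alt, vaf, discordantRate).
#' @param motifBias Named sampling weights over fragment start bases.
#' @param cnvRegions data.frame(chrom, start, end, multiplier).
#' @return A [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 1, nFragments = 1000)
#' @export
simConfig <- function(seed = 1L,
                      chromosomes = data.frame(
                        name = c("chr1", "chr2", "chrM"),
                        length = c(100000L, 100000L, 16000L),
                        gc = c(0.41, 0.41, 0.44)),
                      nFragments = 10000L,
                      lengthMixture = data.frame(
                        weight = c(0.7, 0.2, 0.1),
                        mean = c(167, 334, 90),
                        sd = c(10, 20, 15)),
                      readLength = 150L,
                      overhangRate = 0, overhangLength = 10L,
                      substitutionErrorRate = 0,
                      duplicateRate = 0, lowMapqRate = 0, secondaryRate = 0,
                      unmappedRate = 0, discordantChromRate = 0,
                      outwardRate = 0, mitoFraction = 0,
                      variantSpikes = data.frame(),
                      motifBias = numeric(0),
                      cnvRegions = data.frame()) {
  new("SimConfig", seed = as.integer(seed), chromosomes = chromosomes,
      nFragments = as.integer(nFragments), lengthMixture = lengthMixture,
      readLength = as.integer(readLength),
      overhangRate = overhangRate,
      overhangLength = as.integer(overhangLength),
      substitutionErrorRate = substitutionErrorRate,
      duplicateRate = duplicateRate, lowMapqRate = lowMapqRate,
      secondaryRate = secondaryRate, unmappedRate = unmappedRate,
      discordantChromRate = discordantChromRate, outwardRate = outwardRate,
      mitoFraction = mitoFraction, variantSpikes = variantSpikes,
      motifBias = motifBias, cnvRegions = cnvRegions)
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: seed", object@seed, "|", object@nFragments,
      "fragments over",
      paste(object@chromosomes$name, collapse = ","), "\n")
})

#' Ground truth for one simulated dataset
#'
#' @slot fragments Per-fragment truth: `id`, `chrom`, `true_start`,
#'   `true_end` (1-based inclusive), `true_length`, mixture `component`,
#'   planted `artifact` label, realized `overhang` (bp).
#' @slot locusSupport Per fragment x spiked locus truth: coverage geometry,
#'   carrier status, discordance, which read carries the alternative base,
#'   and the planted overlap category.
#' @slot config The generating [SimConfig-class].
#' @export
setClass("TruthTable", representation(
  fragments = "data.frame",
  locusSupport = "data.frame",
  config = "SimConfig"
))

setValidity("TruthTable", function(object) {
  fr <- object@fragments
  if (nrow(fr) &&
      !all(fr$true_length == fr$true_end - fr$true_start + 1L))
    return("true_length must equal true_end - true_start + 1")
  TRUE
})

#' @describeIn TruthTable-class per-fragment truth table.
#' @param x,object A `TruthTable`.
#' @export
truthFragments <- function(x) {
  stopifnot(is(x, "TruthTable"))
  x@fragments
}

#' @describeIn TruthTable-class per fragment x locus truth table.
#' @export
truthLocusSupport <- function(x) {
  stopifnot(is(x, "TruthTable"))
  x@locusSupport
}

setMethod("show", "TruthTable", function(object) {
  cat("TruthTable:", nrow(object@fragments), "fragments,",
      nrow(object@locusSupport), "fragment x locus truth rows\n")
})

## ---------------------------------------------------------------------------
## Reference synthesis
## ---------------------------------------------------------------------------

.randomContig <- function(length, gc) {
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  rawToChar(sample(charToRaw("ACGT"), length, replace = TRUE, prob = probs))
}

#' Generate a reference genome for simulation
#'
#' Writes a FASTA file (plus `.fai` index) with one record per configured
#' chromosome, at the requested GC composition. Deterministic given the
#' config seed.
#'
#' @param config A [SimConfig-class].
#' @param dir Output directory (created if missing).
#' @return List with `fasta` (path), `index` (path) and `sequences`
#'   (`DNAStringSet`).
#' @examples
#' ref <- makeReference(simConfig(seed = 7), dir = tempfile())
#' names(ref$sequences)
#' @export
makeReference <- function(config, dir = tempfile("ref")) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(.childSeed(config@seed, 0L))
  ch <- config@chromosomes
  seqs <- Biostrings::DNAStringSet(
    vapply(seq_len(nrow(ch)),
           function(i) .randomContig(ch$length[i], ch$gc[i]),
           character(1)))
  names(seqs) <- ch$name
  fasta <- file.path(dir, "reference.fa")
  Biostrings::writeXStringSet(seqs, fasta)
  Rsamtools::indexFa(fasta)
  list(fasta = fasta, index = paste0(fasta, ".fai"), sequences = seqs)
}

## ---------------------------------------------------------------------------
## Fragment simulation
## ---------------------------------------------------------------------------

## Pick exactly round(rate * n) indices from `pool`, without replacement.
.pickExact <- function(pool, rate, n) {
  k <- min(round(rate * n), length(pool))
  if (k == 0L) return(integer(0))
  pool[sample.int(length(pool), k)]
}

#' Simulate cfDNA fragments on a reference
#'
#' Draws fragment lengths from the configured Gaussian mixture (clipped to
#' >= 30 bp), places starts uniformly within contig bounds (honouring
#' optional copy-number multiplier regions and start-base motif bias via
#' rejection sampling), assigns each QC/curation artifact class to an exact
#' `round(rate * n)` count of pairs, plants 3' overhangs on eligible
#' sequence-through pairs, and spikes variants with controlled concordant /
#' discordant read support. Deterministic given the config seed.
#'
#' @param config A [SimConfig-class].
#' @param reference Result of [makeReference()] (or a `DNAStringSet`).
#' @return A [TruthTable-class].
#' @export
simulateFragments <- function(config, reference) {
  stopifnot(is(config, "SimConfig"))
  ref <- if (is.list(reference)) reference$sequences else .loadReference(reference)
  ch <- config@chromosomes
  n <- config@nFragments
  rl <- config@readLength
  set.seed(.childSeed(config@seed, 1L))

  ## lengths from the mixture, clipped at 30 bp. Within a component the
  ## lengths are a stratified quantile grid (randomly permuted) rather than
  ## iid draws: the realized length spectrum then matches the mixture shape
  ## to within one count per length, so planted spectral features (e.g. the
  ## mono-nucleosomal mode) are reproduced exactly instead of being at the
  ## mercy of sampling noise between adjacent integer lengths.
  mx <- config@lengthMixture
  comp <- sample.int(nrow(mx), n, replace = TRUE, prob = mx$weight)
  len <- integer(n)
  for (k in seq_len(nrow(mx))) {
    i <- which(comp == k)
    if (!length(i)) next
    q <- stats::qnorm((seq_along(i) - 0.5) / length(i), mx$mean[k],
                      mx$sd[k])
    vals <- as.integer(pmax(30, round(q)))
    len[i] <- vals[sample.int(length(vals))]
  }

  ## contig assignment: exact mito count, remainder length-weighted
  isMito <- ch$name %in% .MITO_NAMES
  chromIdx <- integer(n)
  nMito <- round(config@mitoFraction * n)
  mitoIdx <- if (nMito > 0L) sample.int(n, nMito) else integer(0)
  if (nMito > 0L && !any(isMito))
    stop("mitoFraction > 0 but no mitochondrion-like contig configured")
  chromIdx[mitoIdx] <- which(isMito)[1L]
  rest <- setdiff(seq_len(n), mitoIdx)

  ## sampling segments over non-mito contigs: background + CNV extra weight
  segs <- data.frame(chrom = which(!isMito),
                     start = 1L,
                     end = ch$length[!isMito],
                     weight = as.numeric(ch$length[!isMito]))
  cnv <- config@cnvRegions
  if (nrow(cnv)) {
    ci <- match(cnv$chrom, ch$name)
    if (anyNA(ci)) stop("cnvRegions on unknown contig")
    extra <- data.frame(chrom = ci, start = as.integer(cnv$start),
                        end = as.integer(cnv$end),
                        weight = (cnv$multiplier - 1) *
                          (cnv$end - cnv$start + 1))
    if (any(extra$weight < 0))
      stop("cnv multipliers below 1 are not supported")
    segs <- rbind(segs, extra)
  }
  segIdx <- sample.int(nrow(segs), length(rest), replace = TRUE,
                       prob = segs$weight)
  chromIdx[rest] <- segs$chrom[segIdx]

  drawStart <- function(i, seg) {
    ## uniform start within the segment, keeping the fragment in bounds
    L <- ch$length[chromIdx[i]]
    lo <- segs$start[seg]
    hi <- pmin(segs$end[seg], L - len[i] + 1L)
    bad <- hi < lo
    if (any(bad)) hi[bad] <- lo[bad]  # contig guaranteed >= 1 kb >> lengths
    as.integer(lo + floor(stats::runif(length(i)) * (hi - lo + 1L)))
  }

  start <- integer(n)
  start[rest] <- drawStart(rest, segIdx)
  if (nMito > 0L) {
    Lm <- ch$length[which(isMito)[1L]]
    start[mitoIdx] <- as.integer(1L + floor(
      stats::runif(nMito) * (Lm - len[mitoIdx] + 1L)))
  }

  ## motif bias: rejection sampling on the reference base at the start
  if (length(config@motifBias)) {
    w <- setNames(numeric(4), .BASES)
    w[names(config@motifBias)] <- config@motifBias
    w <- w / max(w)
    todo <- rest
    segOf <- integer(n); segOf[rest] <- segIdx
    for (iter in seq_len(200L)) {
      if (!length(todo)) break
      base <- .refWindow(ref, ch$name[chromIdx[todo]], start[todo],
                         start[todo])
      acc <- stats::runif(length(todo)) < w[base]
      acc[is.na(acc)] <- FALSE  # N base: reject
      todo <- todo[!acc]
      if (length(todo)) start[todo] <- drawStart(todo, segOf[todo])
    }
    if (length(todo))
      stop("motif-bias rejection sampling did not converge")
  }

  end <- start + len - 1L
  frag <- data.frame(
    id = sprintf("frag%07d", seq_len(n)),
    chrom = ch$name[chromIdx],
    true_start = start, true_end = end, true_length = len,
    component = comp, artifact = "none",
    overhang = 0L, stringsAsFactors = FALSE)

  ## artifact classes: exact counts, at most one label per pair
  pool <- seq_len(n)
  for (cls in c("duplicate", "low_mapq", "secondary", "unmapped",
                "discordant_chrom", "outward")) {
    rate <- switch(cls,
                   duplicate = config@duplicateRate,
                   low_mapq = config@lowMapqRate,
                   secondary = config@secondaryRate,
                   unmapped = config@unmappedRate,
                   discordant_chrom = config@discordantChromRate,
                   outward = config@outwardRate)
    pick <- .pickExact(pool, rate, n)
    frag$artifact[pick] <- cls
    pool <- setdiff(pool, pick)
  }

  ## outward pairs need room for the diverging right-hand read
  outIdx <- which(frag$artifact == "outward")
  if (length(outIdx)) {
    L <- ch$length[chromIdx[outIdx]]
    over <- frag$true_end[outIdx] + rl > L
    if (any(over)) {
      i <- outIdx[over]
      frag$true_start[i] <- pmax(1L, ch$length[chromIdx[i]] -
                                    frag$true_length[i] - rl + 1L)
      frag$true_end[i] <- frag$true_start[i] + frag$true_length[i] - 1L
    }
  }

  ## 3' overhang: eligible sequence-through pairs only (overhang fully
  ## realizable within the read length and the contig)
  eligible <- which(frag$artifact == "none" &
                      len < rl &
                      rl - len >= config@overhangLength &
                      end + config@overhangLength <=
                        ch$length[chromIdx])
  if (config@overhangRate > 0 && length(eligible)) {
    k <- round(config@overhangRate * length(eligible))
    if (k > 0L) {
      pick <- eligible[sample.int(length(eligible), k)]
      frag$overhang[pick] <- config@overhangLength
    }
  }

  ## variant spikes
  loci <- config@variantSpikes
  lsRows <- list()
  if (nrow(loci)) {
    for (j in seq_len(nrow(loci))) {
      pos <- loci$pos[j]
      cover <- which(frag$artifact == "none" & frag$chrom == loci$chrom[j] &
                       frag$true_start <= pos & frag$true_end >= pos)
      if (!length(cover)) next
      fwdCovers <- pos <= frag$true_start[cover] + rl - 1L
      revCovers <- pos >= frag$true_end[cover] - rl + 1L
      both <- fwdCovers & revCovers
      ## long fragments can hold the locus in the unsequenced middle gap;
      ## only read-covering fragments are eligible to carry the variant
      readCov <- fwdCovers | revCovers
      covPool <- cover[readCov]
      nAlt <- round(loci$vaf[j] * length(covPool))
      carriers <- if (nAlt > 0L)
        covPool[sample.int(length(covPool), nAlt)] else integer(0)
      isCar <- cover %in% carriers
      carBoth <- cover[isCar & both]
      nDo <- round(loci$discordantRate[j] * length(carBoth))
      doIds <- if (nDo > 0L) carBoth[sample.int(length(carBoth), nDo)] else integer(0)
      altRead <- rep("none", length(cover))
      altRead[isCar & both] <- "both"
      altRead[isCar & !both & fwdCovers] <- "fwd"
      altRead[isCar & !both & !fwdCovers] <- "rev"
      isDo <- cover %in% doIds
      ## discordant carriers: a random single read carries the alt base
      altRead[isDo] <- sample(c("fwd", "rev"), sum(isDo), replace = TRUE)
      cat_ <- rep("REF_ONLY", length(cover))
      cat_[!readCov] <- "NO_COVER"
      cat_[isCar & both & !isDo] <- "CO"
      cat_[isCar & !both] <- "SO"
      cat_[isDo] <- "DO"
      lsRows[[j]] <- data.frame(
        fragment_id = frag$id[cover],
        locus = paste0(loci$chrom[j], ":", pos, ":", loci$ref[j], ">",
                       loci$alt[j]),
        chrom = loci$chrom[j], pos = pos,
        ref = loci$ref[j], alt = loci$alt[j],
        both_reads_cover = both, carrier = isCar, discordant = isDo,
        alt_read = altRead, planted_category = cat_,
        stringsAsFactors = FALSE)
    }
  }
  ls <- if (length(lsRows)) do.call(rbind, lsRows) else
    data.frame(fragment_id = character(0), locus = character(0),
               chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), both_reads_cover = logical(0),
               carrier = logical(0), discordant = logical(0),
               alt_read = character(0), planted_category = character(0))

  new("TruthTable", fragments = frag, locusSupport = ls, config = config)
}

## ---------------------------------------------------------------------------
## Alignment emission
## ---------------------------------------------------------------------------

.FLAG <- c(paired = 1L, proper = 2L, unmapped = 4L, munmapped = 8L,
           reverse = 16L, mreverse = 32L, first = 64L, second = 128L,
           secondary = 256L, duplicate = 1024L)

#' Emit a paired-end alignment file from a truth table
#'
#' For each fragment one inward read pair is written: the forward read
#' covers `[start, min(start + readLength - 1, end + overhang)]` and the
#' reverse read `[max(start, end - readLength + 1), end]`. Artifact pairs
#' are emitted per their planted label (duplicate / secondary flags, MAPQ 5,
#' one unmapped mate, mates on different contigs, or swapped strand flags
#' for outward orientation). Spiked variants alter read bases according to
#' the planted per-read support; substitution errors are added at the
#' configured rate and reflected in the `NM` tag. Output is
#' coordinate-sorted; base qualities are constant high.
#'
#' @param truth A [TruthTable-class] from [simulateFragments()].
#' @param config The same [SimConfig-class] used to build `truth`.
#' @param reference Result of [makeReference()] (or a `DNAStringSet`).
#' @param dir Output directory.
#' @param format `"bam"` (sorted + indexed, via a SAM intermediate) or
#'   `"sam"`.
#' @return List with paths: `sam`, `bam` (if requested), `truthFragments`,
#'   `truthLoci`.
#' @export
emitAlignments <- function(truth, config, reference, dir = tempfile("aln"),
                           format = c("bam", "sam")) {
  stopifnot(is(truth, "TruthTable"), is(config, "SimConfig"))
  format <- match.arg(format)
  ref <- if (is.list(reference)) reference$sequences else .loadReference(reference)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(.childSeed(config@seed, 2L))

  fr <- truth@fragments
  ch <- config@chromosomes
  n <- nrow(fr)
  rl <- config@readLength

  ## read spans (1-based inclusive, reference space)
  s1 <- fr$true_start
  e1 <- pmin(fr$true_start + rl - 1L, fr$true_end + fr$overhang)
  s2 <- pmax(fr$true_start, fr$true_end - rl + 1L)
  e2 <- fr$true_end
  rname1 <- fr$chrom
  rname2 <- fr$chrom

  art <- fr$artifact
  mapq <- ifelse(art == "low_mapq", 5L, 60L)

  ## discordant-chromosome pairs: move the reverse read to the next
  ## non-mitochondrial contig (so planted mito fractions stay exact)
  disc <- which(art == "discordant_chrom")
  if (length(disc)) {
    ci <- match(fr$chrom[disc], ch$name)
    pool <- which(!ch$name %in% .MITO_NAMES)
    if (length(pool) < 2L) pool <- seq_len(nrow(ch))
    j <- match(ci, pool)
    j[is.na(j)] <- 0L
    ci2 <- pool[(j %% length(pool)) + 1L]
    rname2[disc] <- ch$name[ci2]
    w2 <- e2[disc] - s2[disc] + 1L
    s2[disc] <- pmin(pmax(s2[disc], 1L), ch$length[ci2] - w2 + 1L)
    e2[disc] <- s2[disc] + w2 - 1L
  }

  ## strand of the record occupying each span; outward pairs swap strands
  strand1 <- ifelse(art == "outward", "-", "+")
  strand2 <- ifelse(art == "outward", "+", "-")

  ## outward pairs additionally diverge: the '+' record starts strictly to
  ## the right of the '-' record's end, so the inwardness rule always fails
  ## (strand swap alone is undetectable when the read spans overlap)
  outw <- which(art == "outward")
  if (length(outw)) {
    w2o <- e2[outw] - s2[outw] + 1L
    s2[outw] <- e1[outw] + 1L
    e2[outw] <- s2[outw] + w2o - 1L
  }

  unm <- art == "unmapped"     # reverse mate unmapped
  proper <- !(art %in% c("discordant_chrom", "unmapped", "outward"))

  seq1 <- .refWindow(ref, rname1, s1, e1)
  seq2 <- .refWindow(ref, rname2, s2, e2)
  nm1 <- integer(n)
  nm2 <- integer(n)

  ## spiked variant bases
  ls <- truth@locusSupport
  if (nrow(ls)) {
    ls2 <- ls[ls$alt_read != "none", , drop = FALSE]
    if (nrow(ls2)) {
      fi <- match(ls2$fragment_id, fr$id)
      for (r in seq_len(nrow(ls2))) {
        i <- fi[r]
        pos <- ls2$pos[r]
        if (ls2$alt_read[r] %in% c("both", "fwd") &&
            pos >= s1[i] && pos <= e1[i]) {
          substr(seq1[i], pos - s1[i] + 1L, pos - s1[i] + 1L) <- ls2$alt[r]
          nm1[i] <- nm1[i] + 1L
        }
        if (ls2$alt_read[r] %in% c("both", "rev") &&
            pos >= s2[i] && pos <= e2[i]) {
          substr(seq2[i], pos - s2[i] + 1L, pos - s2[i] + 1L) <- ls2$alt[r]
          nm2[i] <- nm2[i] + 1L
        }
      }
    }
  }

  ## substitution errors
  if (config@substitutionErrorRate > 0) {
    for (mate in 1:2) {
      seqs <- if (mate == 1L) seq1 else seq2
      wid <- nchar(seqs)
      nerr <- stats::rbinom(n, wid, config@substitutionErrorRate)
      for (i in which(nerr > 0L)) {
        p <- sample.int(wid[i], nerr[i])
        for (q in p) {
          cur <- substr(seqs[i], q, q)
          substr(seqs[i], q, q) <- sample(setdiff(.BASES, cur), 1L)
        }
      }
      if (mate == 1L) { seq1 <- seqs; nm1 <- nm1 + nerr }
      else { seq2 <- seqs; nm2 <- nm2 + nerr }
    }
  }

  mkFlag <- function(first) {
    f <- rep(.FLAG[["paired"]], n)
    f <- f + ifelse(proper, .FLAG[["proper"]], 0L)
    if (first) {
      f <- f + .FLAG[["first"]]
      f <- f + ifelse(strand1 == "-", .FLAG[["reverse"]], 0L)
      f <- f + ifelse(unm, .FLAG[["munmapped"]],
                      ifelse(strand2 == "-", .FLAG[["mreverse"]], 0L))
    } else {
      f <- f + .FLAG[["second"]]
      f <- f + ifelse(unm, .FLAG[["unmapped"]],
                      ifelse(strand2 == "-", .FLAG[["reverse"]], 0L))
      f <- f + ifelse(strand1 == "-", .FLAG[["mreverse"]], 0L)
    }
    f <- f + ifelse(art == "duplicate", .FLAG[["duplicate"]], 0L)
    f <- f + ifelse(art == "secondary", .FLAG[["secondary"]], 0L)
    f
  }

  w1 <- e1 - s1 + 1L
  w2 <- e2 - s2 + 1L
  tlen <- ifelse(rname1 == rname2 & !unm,
                 pmax(e1, e2) - pmin(s1, s2) + 1L, 0L)

  ## unmapped mates sit at the mapped mate's coordinate with '*' CIGAR
  pos2 <- ifelse(unm, s1, s2)
  rn2out <- ifelse(unm, rname1, rname2)
  cig2 <- ifelse(unm, "*", paste0(w2, "M"))
  mq2 <- ifelse(unm, 0L, mapq)

  rec1 <- paste(fr$id, mkFlag(TRUE), rname1, s1, mapq, paste0(w1, "M"),
                ifelse(rn2out == rname1, "=", rn2out), pos2,
                ifelse(s1 <= pos2, tlen, -tlen),
                seq1, strrep("I", w1), paste0("NM:i:", nm1), sep = "\t")
  rec2 <- paste(fr$id, mkFlag(FALSE), rn2out, pos2, mq2, cig2,
                ifelse(rname1 == rn2out, "=", rname1), s1,
                ifelse(pos2 <= s1 & tlen != 0L, tlen, -tlen),
                seq2, strrep("I", w2), paste0("NM:i:", nm2), sep = "\t")

  recs <- c(rec1, rec2)
  recRname <- c(rname1, rn2out)
  recPos <- c(s1, pos2)
  ord <- order(match(recRname, ch$name), recPos,
               c(fr$id, fr$id), c(rep(1L, n), rep(2L, n)))

  header <- c("@HD\tVN:1.6\tSO:coordinate",
              paste0("@SQ\tSN:", ch$name, "\tLN:", ch$length))
  samPath <- file.path(dir, "reads.sam")
  writeLines(c(header, recs[ord]), samPath)

  out <- list(sam = samPath)
  if (format == "bam") {
    bamPath <- file.path(dir, "reads")
    out$bam <- Rsamtools::asBam(samPath, bamPath, overwrite = TRUE,
                                indexDestination = TRUE)
  }

  tf <- file.path(dir, "truth_fragments.tsv")
  utils::write.table(fr, tf, sep = "\t", quote = FALSE, row.names = FALSE)
  tl <- file.path(dir, "truth_locus_support.tsv")
  utils::write.table(truth@locusSupport, tl, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  out$truthFragments <- tf
  out$truthLoci <- tl
  out
}

#' Generate a complete synthetic dataset in one call
#'
#' Convenience wrapper running [makeReference()], [simulateFragments()] and
#' [emitAlignments()].
#'
#' @param config A [SimConfig-class].
#' @param dir Output directory.
#' @param format Alignment output format, `"bam"` or `"sam"`.
#' @return List with `reference`, `truth` and `files`.
#' @export
simulateDataset <- function(config, dir = tempfile("sim"),
                            format = c("bam", "sam")) {
  format <- match.arg(format)
  reference <- makeReference(config, file.path(dir, "ref"))
  truth <- simulateFragments(config, reference)
  files <- emitAlignments(truth, config, reference, file.path(dir, "aln"),
                          format = format)
  list(reference = reference, truth = truth, files = files)
}
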