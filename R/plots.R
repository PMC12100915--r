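## Minimal visualizations. These are intentionally plain ggplot2 objects the
## user can restyle; publication aesthetics are out of scope.

#' Plot a fragment-length distribution
#'
#' @param dist A [LengthDist-class].
#' @return A ggplot object.
#' @export
plotLength <- function(dist) {
  stopifnot(is(dist, "LengthDist"))
  df <- data.frame(length = as.integer(names(lengthCounts(dist))),
                   fraction = lengthFractions(dist))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length, y = .data$fraction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "fragment length (bp)", y = "fraction",
                  title = dist@sampleId)
}

#' Plot a motif frequency table
#'
#' Motifs appear in fixed lexicographic order on the x axis.
#'
#' @param table A [MotifTable-class].
#' @return A ggplot object.
#' @export
plotMotif <- function(table) {
  stopifnot(is(table, "MotifTable"))
  df <- data.frame(motif = factor(names(motifCounts(table)),
                                  levels = names(motifCounts(table))),
                   fraction = motifFractions(table))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$motif, y = .data$fraction,
                                   group = 1)) +
    ggplot2::geom_line() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       size = 6)) +
    ggplot2::labs(x = paste0(table@side, table@k, " motif"), y = "fraction",
                  title = table@sampleId)
}

#' Plot genome-wide copy-number states
#'
#' Gain, neutral and loss bins are drawn in orange, grey and blue.
#'
#' @param bins `GRanges` from [callStates()].
#' @return A ggplot object.
#' @export
plotCNV <- function(bins) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(bins)),
                   mid = (GenomicRanges::start(bins) +
                            GenomicRanges::end(bins)) / 2,
                   log2_ratio = mcols(bins)$log2_ratio,
                   state = mcols(bins)$state)
  df <- df[df$state != "excluded", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$log2_ratio,
                                   colour = .data$state)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::scale_colour_manual(values = c(gain = "darkorange",
                                            neutral = "grey50",
                                            loss = "steelblue")) +
    ggplot2::labs(x = "genomic position", y = "log2 ratio")
}
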