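# ggplot2 views of the platform signals and cohort summary.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

chrom_offsets <- function(genome) {
  off <- c(0, cumsum(as.numeric(genome$length)))[seq_len(nrow(genome))]
  names(off) <- genome$chrom
  off
}

#' Plot an SNP-array signal
#'
#' Whole-genome LogR and BAF panels, markers ordered by genomic position
#' with chromosome boundaries marked — the view used to judge BAF scatter
#' and LogR shifts.
#'
#' @param object A `snp_signal`.
#' @param genome Genome model tibble.
#' @param downsample Maximum markers plotted (default 30000).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.snp_signal <- function(object, genome = genome_model(),
                                downsample = 30000, ...) {
  off <- chrom_offsets(genome)
  df <- tibble::as_tibble(object)
  df <- df[df$chrom %in% names(off), ]
  if (nrow(df) > downsample)
    df <- df[seq(1, nrow(df), length.out = downsample), ]
  df$x <- off[df$chrom] + df$pos
  long <- tidyr::pivot_longer(df, c("logr", "baf"), names_to = "channel")
  long$channel <- factor(long$channel, c("logr", "baf"),
                         c("LogR", "BAF"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$value)) +
    ggplot2::geom_point(size = 0.1, alpha = 0.4) +
    ggplot2::geom_vline(xintercept = unname(off), linewidth = 0.2,
                        colour = "grey70") +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "genome position", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an NGS copy-number profile
#'
#' Per-bin copy-number estimates (2 x GC-normalized ratio) across the
#' genome, with the mosaic/aneuploid classification interval bounds drawn
#' as horizontal guides.
#'
#' @param object An `ngs_signal`.
#' @param genome Genome model tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ngs_signal <- function(object, genome = genome_model(), ...) {
  norm <- gc_normalize(object)
  off <- chrom_offsets(genome)
  norm <- norm[norm$chrom %in% names(off), ]
  norm$x <- off[norm$chrom] + norm$start
  ggplot2::ggplot(norm, ggplot2::aes(x = .data$x, y = 2 * .data$ratio)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = c(1.2, 1.8, 2.2, 2.8),
                        linetype = "dashed", colour = "steelblue",
                        linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = unname(off), linewidth = 0.2,
                        colour = "grey70") +
    ggplot2::labs(x = "genome position", y = "CNV value") +
    ggplot2::theme_minimal()
}

#' Plot a cohort summary
#'
#' Bar chart of the five-way concordance accounting.
#'
#' @param object A `cohort_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_summary <- function(object, ...) {
  df <- object$concordance
  df$category <- factor(df$category, levels = df$category)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category,
                                   y = .data$rate_percent)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = paste0(.data$n, " (",
                                                   .data$rate_percent, "%)")),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "% of embryos",
                  title = "Between-platform concordance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
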