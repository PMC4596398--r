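#' Plot benchmark accuracy against expression level
#'
#' One line per exon-count category: the fraction of genes whose point of
#' first failure lies below each RPKE level, i.e. the fraction reliably
#' identified at that expression level.
#'
#' @param x A `txtile_benchmark` from [benchmark_assembly()].
#' @return A ggplot object.
#' @export
plot_benchmark_accuracy <- function(x) {
  stopifnot(inherits(x, "txtile_benchmark"))
  ggplot(x$accuracy_curve,
         aes(x = .data$rpke, y = .data$accuracy,
             colour = factor(.data$category))) +
    geom_line() +
    geom_point() +
    geom_vline(xintercept = x$at_rpke, linetype = "dashed", colour = "grey40") +
    scale_y_continuous(labels = function(v) paste0(100 * v, "%"),
                       limits = c(0, 1)) +
    labs(x = "Expression level (RPKE)", y = "Genes correctly assembled",
         colour = "Exons per gene",
         title = "Assembly accuracy by read depth (point of first failure)") +
    theme_minimal()
}

#' Plot the discrepancy category histogram
#'
#' @param x A `txtile_evaluation` from [evaluate_assembly()].
#' @return A ggplot object.
#' @export
plot_discrepancy_categories <- function(x) {
  stopifnot(inherits(x, "txtile_evaluation"))
  ggplot(x$category_counts, aes(x = .data$category, y = .data$n)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "Matched gene pairs",
         title = "Assembled vs reference transcript structure") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}

#' Plot transcript start/termination offset distributions
#'
#' Positive offsets mean the assembled gene extends beyond the reference;
#' negative offsets mean it is shorter.
#'
#' @param x A `txtile_evaluation` from [evaluate_assembly()].
#' @param binwidth Histogram bin width in nt.
#' @return A ggplot object.
#' @export
plot_offsets <- function(x, binwidth = 25) {
  stopifnot(inherits(x, "txtile_evaluation"))
  long <- dplyr::bind_rows(
    dplyr::transmute(x$offsets$offsets, offset = .data$start_offset,
                     site = "transcription start"),
    dplyr::transmute(x$offsets$offsets, offset = .data$end_offset,
                     site = "transcription termination")
  )
  ggplot(long, aes(x = .data$offset)) +
    geom_histogram(binwidth = binwidth, fill = "steelblue", colour = "white") +
    facet_wrap(~site, ncol = 1, scales = "free_y") +
    labs(x = "Offset from reference (nt; positive = assembled gene longer)",
         y = "Gene pairs") +
    theme_minimal()
}

#' Plot the ORF codon-length histogram
#'
#' @param calls Classified ORF calls from [classify_coding()].
#' @return A ggplot object.
#' @export
plot_orf_lengths <- function(calls) {
  ggplot(calls, aes(x = .data$length_bin, fill = .data$class)) +
    geom_bar() +
    labs(x = "Longest ORF length (codons)", y = "Genes", fill = NULL,
         title = "Predicted ORF lengths") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 45, hjust = 1))
}
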