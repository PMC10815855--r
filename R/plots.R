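# ggplot2 displays for the result objects.

#' Plot a genome scan
#'
#' LRS profile along the genome, one panel per chromosome, with optional
#' horizontal lines at the permutation thresholds.
#'
#' @param object A `qtl_scan`.
#' @param thresholds Optional one-row tibble from
#'   [permutation_thresholds()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.qtl_scan <- function(object, thresholds = NULL, ...) {
  d <- tidy(object)
  d <- d[!d$skipped, , drop = FALSE]
  d$chrom <- factor(d$chrom, levels = unique(d$chrom))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$pos_mb, y = .data$lrs)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x", switch = "x") +
    ggplot2::labs(x = "position (Mb)", y = "LRS") +
    ggplot2::theme_minimal() +
    ggplot2::theme(panel.spacing.x = ggplot2::unit(0.5, "pt"),
                   axis.text.x = ggplot2::element_blank())
  if (!is.null(thresholds)) {
    p <- p +
      ggplot2::geom_hline(yintercept = thresholds$significant_lrs,
                          linetype = "dashed", colour = "red") +
      ggplot2::geom_hline(yintercept = thresholds$suggestive_lrs,
                          linetype = "dotted", colour = "grey40")
  }
  p
}

#' Plot per-group infiltration scores
#'
#' Boxplots of ssGSEA enrichment scores by group, one panel per cell
#' type.
#'
#' @param object An `infiltration_scores` tibble with a `group` column.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.infiltration_scores <- function(object, ...) {
  if (!"group" %in% names(object)) abort("scores need a 'group' column to plot")
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$group, y = .data$es,
                               fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$cell_type), scales = "free_y") +
    ggplot2::labs(x = NULL, y = "enrichment score") +
    ggplot2::theme_minimal()
}

#' Plot an over-representation result
#'
#' Horizontal bars of -log10(FDR) for the top sets, coloured by
#' significance.
#'
#' @param object An `ora_result` tibble.
#' @param top Number of sets to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ora_result <- function(object, top = 20, ...) {
  d <- head(object, top)
  d$set <- factor(d$set, levels = rev(d$set))
  ggplot2::ggplot(d, ggplot2::aes(x = -log10(.data$fdr), y = .data$set,
                                  fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = expression(-log[10] ~ FDR), y = NULL,
                  fill = "FDR < threshold") +
    ggplot2::theme_minimal()
}

#' Plot candidate scores
#'
#' Ranked bars of candidate totals, coloured by selection status.
#'
#' @param object A `candidate_scores` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.candidate_scores <- function(object, ...) {
  d <- tidy(object)
  d <- d[order(-d$total), , drop = FALSE]
  d$gene_id <- factor(d$gene_id, levels = rev(d$gene_id))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$total, y = .data$gene_id,
                                  fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "total score", y = NULL, fill = "selected") +
    ggplot2::theme_minimal()
}
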