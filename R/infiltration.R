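# ssGSEA per-sample scoring of cell-type signature sets, group-wise
# differential infiltration, and gene-infiltration correlation.

#' Single-sample GSEA enrichment score
#'
#' Rank-based per-sample enrichment score in the integrated
#' (Barbie-style) form. Genes are ordered by expression, descending, with
#' ties averaged; the in-set running sum weights each member by its rank
#' raised to `alpha` (higher expression, larger rank weight), the out-set
#' running sum steps uniformly by `1 / (N - K)`; the score is the sum of
#' the running-sum differences over all positions:
#' `ES = sum_i (P_in(i) - P_out(i))`.
#'
#' The score depends on expression only through within-sample ranks, so
#' any strictly increasing transform of the sample leaves it unchanged.
#'
#' @param values Named numeric vector: one sample's expression over all
#'   measured genes.
#' @param gene_set Character vector of set members; at least one must be
#'   measured.
#' @param alpha Rank-weight exponent (default 0.25; 0 gives unweighted
#'   steps).
#' @param set_name Label used in error messages.
#' @return Numeric enrichment score.
#' @export
ssgsea_score <- function(values, gene_set, alpha = 0.25,
                         set_name = "gene set") {
  if (is.null(names(values))) abort("expression values must be named by gene")
  in_set <- names(values) %in% gene_set
  if (!any(in_set)) {
    abort(sprintf("no member of %s is measured in the sample", set_name))
  }
  N <- length(values)
  K <- sum(in_set)
  if (K == N) abort("gene set covers the whole universe; ES undefined")
  rnk <- rank(values, ties.method = "average")  # highest expression -> N
  ord <- order(values, decreasing = TRUE)
  w <- abs(rnk[ord])^alpha * in_set[ord]
  p_in <- cumsum(w) / sum(w)
  p_out <- cumsum(!in_set[ord]) / (N - K)
  sum(p_in - p_out)
}

#' ssGSEA scores for every sample and signature set
#'
#' @param expression Expression tibble (genes x samples).
#' @param signatures Gene-set tibble (`set`, `description`, `genes`),
#'   e.g. cell-type marker signatures from [read_gmt()].
#' @param groups Optional tibble `sample`, `group` carried into the
#'   result.
#' @param alpha Rank-weight exponent.
#' @return An `infiltration_scores` tibble in long form: `sample`,
#'   `group`, `cell_type`, `es`.
#' @export
infiltration_matrix <- function(expression, signatures, groups = NULL,
                                alpha = 0.25) {
  validate_expression(expression)
  M <- expr_matrix(expression)
  grid <- tidyr::expand_grid(sample = colnames(M), cell_type = signatures$set)
  sets <- setNames(signatures$genes, signatures$set)
  out <- dplyr::mutate(grid, es = purrr::map2_dbl(
    .data$sample, .data$cell_type,
    function(s, ct) ssgsea_score(M[, s], sets[[ct]], alpha, set_name = ct)))
  if (!is.null(groups)) {
    out <- dplyr::left_join(out, groups, by = "sample")
    out <- dplyr::relocate(out, "sample", "group")
  }
  class(out) <- c("infiltration_scores", class(out))
  out
}

#' Differential infiltration between two groups
#'
#' Two-sided Wilcoxon rank-sum test per cell type (exact when the
#' combined group size is at most 20 and no ties; normal approximation
#' with tie correction otherwise). A Welch t-test is available as an
#' alternative.
#'
#' @param scores An `infiltration_scores` tibble with a `group` column
#'   (two groups, each with at least 3 samples).
#' @param test `"wilcoxon"` (default) or `"t"`.
#' @param p_threshold Significance flag cutoff.
#' @return Tibble per cell type: group medians, `p`, `significant`.
#' @export
differential_infiltration <- function(scores, test = c("wilcoxon", "t"),
                                      p_threshold = 0.05) {
  test <- match.arg(test)
  if (!"group" %in% names(scores)) abort("scores need a 'group' column")
  labs <- sort(unique(scores$group))
  if (length(labs) != 2) abort("exactly two groups are required")
  counts <- table(unique(scores[, c("sample", "group")])$group)
  if (any(counts < 3)) abort("each group needs at least 3 samples")
  by_ct <- split(scores, scores$cell_type)
  purrr::map(by_ct, function(d) {
    x <- d$es[d$group == labs[1]]
    y <- d$es[d$group == labs[2]]
    p <- if (test == "wilcoxon") {
      suppressWarnings(
        wilcox.test(x, y, exact = (length(x) + length(y)) <= 20))$p.value
    } else {
      stats::t.test(x, y)$p.value
    }
    tibble::tibble(
      cell_type = d$cell_type[1],
      median_1 = median(x), median_2 = median(y), p = p)
  }) |>
    purrr::list_rbind() |>
    (function(d) {
      names(d)[names(d) == "median_1"] <- paste0("median_", labs[1])
      names(d)[names(d) == "median_2"] <- paste0("median_", labs[2])
      d
    })() |>
    dplyr::mutate(significant = .data$p < p_threshold) |>
    dplyr::arrange(.data$p)
}

#' Correlate gene expression with infiltration scores
#'
#' Pearson correlation (via the correlation module) between each listed
#' gene's expression and each cell type's per-sample enrichment score.
#'
#' @param expression Expression tibble.
#' @param scores An `infiltration_scores` tibble.
#' @param gene_list Genes to correlate (must be measured).
#' @param p_threshold Significance mark cutoff.
#' @return Tibble: `gene_id`, `cell_type`, `r`, `p`, `n`, `significant`.
#' @export
correlate_genes_with_infiltration <- function(expression, scores, gene_list,
                                              p_threshold = 0.05) {
  validate_expression(expression)
  M <- expr_matrix(expression)
  missing <- setdiff(gene_list, rownames(M))
  if (length(missing) > 0) {
    abort(sprintf("gene(s) not in expression matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(scores, "sample", "cell_type", "es"),
    names_from = "cell_type", values_from = "es")
  cts <- setdiff(names(wide), "sample")
  grid <- tidyr::expand_grid(gene_id = gene_list, cell_type = cts)
  res <- purrr::pmap(grid, function(gene_id, cell_type) {
    pearson_core(M[gene_id, wide$sample], wide[[cell_type]])
  })
  dplyr::mutate(grid,
                r = purrr::map_dbl(res, "r"),
                p = purrr::map_dbl(res, "p"),
                n = purrr::map_int(res, ~ as.integer(.x$n)),
                significant = .data$p < p_threshold)
}
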