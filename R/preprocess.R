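# Normalization and the steps preceding differential expression:
# per-gene 2Z+8 rescaling, clustering-based sample exclusion, Welch tests
# with Benjamini-Hochberg correction.

#' 2Z + 8 normalization
#'
#' Rescales every gene row to mean 8 and standard deviation 2 (sample,
#' n-1 convention): `2 * z + 8` where `z` is the row z-score. The shift to
#' 8 keeps all values positive on the log2 intensity scale. Constant rows
#' cannot be z-scored and map to all 8s.
#'
#' @param expression An expression tibble with at least 2 samples.
#' @return The expression tibble with rescaled sample columns.
#' @export
normalize_2z8 <- function(expression) {
  validate_expression(expression)
  samples <- sample_ids(expression)
  if (length(samples) < 2) abort("2Z+8 normalization needs at least 2 samples")
  M <- expr_matrix(expression)
  mu <- rowMeans(M)
  s <- apply(M, 1, sd)
  Z <- (M - mu) / ifelse(s > 0, s, 1)
  Z[s == 0, ] <- 0
  out <- expression
  out[, samples] <- tibble::as_tibble(2 * Z + 8)
  out
}

#' Exclude samples that cluster with the wrong group
#'
#' Clusters samples by Euclidean distance between their expression columns
#' (agglomerative clustering, average linkage by default), cuts the tree
#' into two clusters, assigns each cluster the majority group label among
#' its members, and excludes every sample whose own label disagrees with
#' its cluster's majority.
#'
#' @param expression Expression tibble.
#' @param groups Tibble with `sample` and `group` columns; exactly two
#'   group labels must be present.
#' @param linkage Linkage method passed to [stats::hclust()].
#' @return A tibble with one row per sample: `sample`, `group`, `cluster`,
#'   `cluster_label` and `excluded`.
#' @export
exclude_outlier_samples <- function(expression, groups,
                                    linkage = "average") {
  validate_expression(expression)
  samples <- sample_ids(expression)
  groups <- dplyr::filter(groups, .data$sample %in% samples)
  if (length(unique(groups$group)) != 2) {
    abort("exactly two group labels are required")
  }
  M <- expr_matrix(expression)[, groups$sample, drop = FALSE]
  d <- dist(t(M))
  if (max(d) < sqrt(.Machine$double.eps)) {
    abort("all samples are identical: no two-cluster structure to cut")
  }
  cl <- cutree(hclust(d, method = linkage), k = 2)
  out <- dplyr::mutate(groups, cluster = unname(cl[.data$sample]))
  maj <- purrr::map_chr(split(out$group, out$cluster), function(g) {
    tab <- sort(table(g), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) {
      abort("tied majority label within a cluster: manual review required")
    }
    names(tab)[1]
  })
  dplyr::mutate(out,
                cluster_label = unname(maj[as.character(.data$cluster)]),
                excluded = .data$group != .data$cluster_label)
}

#' Per-gene differential expression (Welch t-test, BH-corrected)
#'
#' Two-sided Welch t-test for each gene between the two groups, with
#' Benjamini-Hochberg adjustment across all genes and a significance flag
#' at the chosen FDR. The mean difference is reported on the log2 scale as
#' first group minus second group (alphabetical label order).
#'
#' @param expression Expression tibble.
#' @param groups Tibble with `sample` and `group` (two labels, each with at
#'   least 2 samples).
#' @param fdr Significance threshold on the adjusted p-value.
#' @return A tibble: `gene_id`, `mean_diff`, `t`, `df`, `p`, `fdr`,
#'   `significant`, sorted by adjusted p.
#' @export
differential_expression <- function(expression, groups, fdr = 0.05) {
  validate_expression(expression)
  labs <- sort(unique(groups$group))
  if (length(labs) != 2) abort("exactly two group labels are required")
  M <- expr_matrix(expression)
  s1 <- groups$sample[groups$group == labs[1]]
  s2 <- groups$sample[groups$group == labs[2]]
  if (length(s1) < 2 || length(s2) < 2) {
    abort("each group needs at least 2 samples for a Welch test")
  }
  X1 <- M[, s1, drop = FALSE]; X2 <- M[, s2, drop = FALSE]
  n1 <- ncol(X1); n2 <- ncol(X2)
  m1 <- rowMeans(X1); m2 <- rowMeans(X2)
  v1 <- apply(X1, 1, stats::var); v2 <- apply(X2, 1, stats::var)
  se2 <- v1 / n1 + v2 / n2
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  # genes constant and equal in both groups: no evidence of difference
  degenerate <- se2 == 0
  tstat[degenerate & (m1 == m2)] <- 0
  df[degenerate] <- n1 + n2 - 2
  p <- 2 * pt(-abs(tstat), df)
  p[degenerate & (m1 != m2)] <- .Machine$double.xmin
  out <- tibble::tibble(
    gene_id = rownames(M),
    mean_diff = unname(m1 - m2),
    t = unname(tstat), df = unname(df), p = unname(p),
    fdr = p.adjust(unname(p), method = "BH"))
  out$significant <- out$fdr < fdr
  dplyr::arrange(out, .data$fdr, .data$p, .data$gene_id)
}
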