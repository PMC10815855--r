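# Pearson correlation screens: focal gene vs transcriptome, genes vs
# traits, and the strain-range fold-difference summary.

pearson_core <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("pairwise-complete n must be at least 3")
  if (sd(x) == 0 || sd(y) == 0) abort("undefined correlation: constant vector")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  r <- max(-1, min(1, r))
  denom <- 1 - r^2
  if (denom <= .Machine$double.eps) {
    p <- .Machine$double.xmin
  } else {
    tstat <- r * sqrt((n - 2) / denom)
    p <- 2 * pt(-abs(tstat), n - 2)
    p <- max(p, .Machine$double.xmin)
  }
  list(r = r, p = p, n = n)
}

#' Pearson correlation with a two-sided p-value
#'
#' Product-moment correlation on pairwise-complete observations; the
#' p-value comes from `t = r * sqrt((n - 2) / (1 - r^2))` against a
#' Student t distribution with `n - 2` degrees of freedom, two-sided.
#' `r = +-1` clamps the p-value at the smallest positive double rather
#' than underflowing to zero.
#'
#' @param x,y Numeric vectors of equal length; `NA`s are dropped pairwise.
#' @return One-row tibble with `r`, `p` and the pairwise-complete `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  res <- pearson_core(x, y)
  tibble::tibble(r = res$r, p = res$p, n = res$n)
}

# vectorized: correlation of every row of M against vector y, pairwise
# complete; returns tibble(r, p, n) aligned to rows of M
row_pearson <- function(M, y) {
  res <- purrr::map(seq_len(nrow(M)), function(i) {
    out <- tryCatch(pearson_core(M[i, ], y), error = function(e) NULL)
    out %||% list(r = NA_real_, p = NA_real_, n = sum(is.finite(M[i, ]) & is.finite(y)))
  })
  tibble::tibble(
    r = purrr::map_dbl(res, "r"),
    p = purrr::map_dbl(res, "p"),
    n = purrr::map_int(res, ~ as.integer(.x$n)))
}

#' Correlate every gene with a focal gene
#'
#' Screens the transcriptome against one focal gene. A partner passes the
#' filter when its nominal p-value is below `p_threshold`, its mean
#' expression strictly exceeds `min_mean`, and `|r|` is at least
#' `r_threshold`. The defaults are the mouse-mode screen (mean > 7, no
#' `|r|` gate); a human GTEx-style screen uses `r_threshold = 0.5`. The
#' focal gene itself is excluded from the output.
#'
#' @param expression Expression tibble.
#' @param focal_gene Gene id present in `expression`.
#' @param p_threshold Nominal two-sided p-value cutoff.
#' @param min_mean Strict lower bound on partner mean expression.
#' @param r_threshold Inclusive lower bound on `|r|`.
#' @param adjust Apply Benjamini-Hochberg to the screen p-values before
#'   filtering (off by default: the screen is nominal).
#' @return Tibble with `gene_id`, `mean_expression`, `r`, `p`, `n`,
#'   `passes_filter`, sorted by decreasing `|r|`.
#' @export
correlate_focal_gene <- function(expression, focal_gene, p_threshold = 0.05,
                                 min_mean = 7, r_threshold = 0,
                                 adjust = FALSE) {
  validate_expression(expression)
  M <- expr_matrix(expression)
  if (!focal_gene %in% rownames(M)) {
    abort(sprintf("focal gene '%s' not found in expression matrix", focal_gene))
  }
  y <- M[focal_gene, ]
  others <- setdiff(rownames(M), focal_gene)
  Mo <- M[others, , drop = FALSE]
  res <- row_pearson(Mo, y)
  p_use <- if (adjust) p.adjust(res$p, method = "BH") else res$p
  out <- tibble::tibble(
    gene_id = others,
    mean_expression = unname(rowMeans(Mo, na.rm = TRUE)),
    r = res$r, p = res$p, n = res$n,
    passes_filter = !is.na(res$r) & p_use < p_threshold &
      .data$mean_expression > min_mean & abs(res$r) >= r_threshold)
  dplyr::arrange(out, dplyr::desc(abs(.data$r)))
}

#' Correlate genes with traits
#'
#' Pairwise-complete Pearson correlation for every requested (gene, trait)
#' pair, joined on strain/sample names. Missing trait values reduce the
#' pairwise `n` for their pairs only.
#'
#' @param expression Expression tibble (samples named by strain).
#' @param traits Trait tibble (`strain` column plus trait columns).
#' @param gene_list Genes to correlate; defaults to all genes.
#' @param p_threshold Significance mark threshold.
#' @return Tibble with `gene_id`, `trait`, `r`, `p`, `n`, `significant`.
#' @export
correlate_genes_with_traits <- function(expression, traits, gene_list = NULL,
                                        p_threshold = 0.05) {
  validate_expression(expression)
  M <- expr_matrix(expression)
  gene_list <- gene_list %||% rownames(M)
  missing <- setdiff(gene_list, rownames(M))
  if (length(missing) > 0) {
    abort(sprintf("gene(s) not in expression matrix: %s",
                  paste(missing, collapse = ", ")))
  }
  shared <- intersect(colnames(M), traits$strain)
  if (length(shared) == 0) abort("no overlapping strains between expression and traits")
  trait_names <- setdiff(names(traits), "strain")
  tv <- traits[match(shared, traits$strain), , drop = FALSE]
  grid <- tidyr::expand_grid(gene_id = gene_list, trait = trait_names)
  res <- purrr::pmap(grid, function(gene_id, trait) {
    tryCatch(pearson_core(M[gene_id, shared], tv[[trait]]),
             error = function(e) list(r = NA_real_, p = NA_real_, n = NA_integer_))
  })
  dplyr::mutate(grid,
                r = purrr::map_dbl(res, "r"),
                p = purrr::map_dbl(res, "p"),
                n = purrr::map_int(res, ~ as.integer(.x$n)),
                significant = !is.na(.data$p) & .data$p < p_threshold)
}

#' Fold difference across strains on the log2 scale
#'
#' Antilog-2 of the range of per-strain means:
#' `fold = 2 ^ (max - min)`.
#'
#' @param values Named numeric vector of per-strain log2 means, or a
#'   two-column data frame (`strain`, `value`).
#' @return One-row tibble: `min_strain`, `max_strain`, `min_value`,
#'   `max_value`, `fold`.
#' @export
fold_difference <- function(values) {
  if (is.data.frame(values)) {
    values <- setNames(values[[2]], values[[1]])
  }
  values <- values[is.finite(values)]
  if (length(values) == 0) abort("fold_difference needs at least one value")
  if (is.null(names(values))) names(values) <- as.character(seq_along(values))
  i_min <- which.min(values); i_max <- which.max(values)
  tibble::tibble(
    min_strain = names(values)[i_min],
    max_strain = names(values)[i_max],
    min_value = unname(values[i_min]),
    max_value = unname(values[i_max]),
    fold = 2 ^ (unname(values[i_max]) - unname(values[i_min])))
}
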