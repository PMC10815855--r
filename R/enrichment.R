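# Over-representation analysis: hypergeometric upper-tail test of a
# query gene list against a gene-set collection, Benjamini-Hochberg
# corrected, with enrichment ratios.

#' Hypergeometric over-representation test for one gene set
#'
#' Tests whether the overlap between a query list and a gene set, within
#' a fixed universe, is larger than expected:
#' `p = P(X >= k)` for `X ~ Hypergeometric(N, K, n)` with `N` universe
#' genes, `K` set members in the universe, `n` (deduplicated) query genes
#' in the universe and `k` the observed overlap. The enrichment ratio is
#' `(k / n) / (K / N)`.
#'
#' @param query Character vector of query genes (duplicates removed;
#'   genes outside the universe dropped with a warning).
#' @param gene_set Character vector of set members.
#' @param universe Character vector of all measurable genes.
#' @param set_name Optional label carried into the result.
#' @return One-row tibble: `set`, `k`, `n`, `K`, `N`, `p`,
#'   `enrichment_ratio`.
#' @export
ora_hypergeometric <- function(query, gene_set, universe,
                               set_name = NA_character_) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warn(sprintf("%d query gene(s) outside the universe dropped",
                 length(outside)))
    query <- intersect(query, universe)
  }
  set_in <- intersect(unique(gene_set), universe)
  if (length(set_in) == 0) abort("gene set has no members in the universe")
  N <- length(universe)
  K <- length(set_in)
  n <- length(query)
  k <- length(intersect(query, set_in))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble::tibble(
    set = set_name, k = k, n = n, K = K, N = N, p = p,
    enrichment_ratio = if (n > 0) (k / n) / (K / N) else NA_real_)
}

#' Over-representation analysis across a gene-set collection
#'
#' Runs [ora_hypergeometric()] for every set with at least `min_set`
#' members in the universe, adjusts p-values by Benjamini-Hochberg across
#' all tested sets, and sorts by FDR, then raw p, then set name.
#'
#' @param query Character vector of query genes.
#' @param collection Gene-set tibble from [read_gmt()] (`set`,
#'   `description`, `genes`).
#' @param universe Character vector of all measurable genes (typically
#'   the rows of the expression matrix).
#' @param fdr_threshold Significance cutoff on the adjusted p.
#' @param min_set Minimum set size (within the universe) to test.
#' @return An `ora_result` tibble: one row per tested set with `k`, `n`,
#'   `K`, `N`, `p`, `fdr`, `enrichment_ratio`, `significant`.
#' @export
enrich_collection <- function(query, collection, universe,
                              fdr_threshold = 0.05, min_set = 3) {
  if (nrow(collection) == 0) {
    out <- tibble::tibble(
      set = character(), description = character(), k = integer(),
      n = integer(), K = integer(), N = integer(), p = numeric(),
      fdr = numeric(), enrichment_ratio = numeric(),
      significant = logical())
    class(out) <- c("ora_result", class(out))
    return(out)
  }
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  rows <- purrr::pmap(collection, function(set, description, genes, ...) {
    if (length(intersect(genes, universe)) < min_set) return(NULL)
    res <- suppressWarnings(
      ora_hypergeometric(query, genes, universe, set_name = set))
    res$description <- description
    res
  })
  out <- purrr::list_rbind(purrr::compact(rows))
  if (nrow(out) == 0) abort("no gene set has enough members in the universe")
  out$fdr <- p.adjust(out$p, method = "BH")
  out$significant <- out$fdr < fdr_threshold
  out <- dplyr::arrange(out, .data$fdr, .data$p, .data$set)
  out <- dplyr::relocate(out, "set", "description")
  class(out) <- c("ora_result", class(out))
  out
}
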