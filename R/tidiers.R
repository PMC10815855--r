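# broom-style tidiers for the result objects.

#' Tidy a QTL scan
#'
#' @param x A `qtl_scan`.
#' @param ... Unused.
#' @return A plain tibble of per-marker statistics.
#' @exportS3Method generics::tidy
tidy.qtl_scan <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "qtl_scan")
  tibble::as_tibble(out)
}

#' One-row summary of a QTL scan
#'
#' @param x A `qtl_scan`.
#' @param ... Unused.
#' @return Tibble: marker counts, genome-wide top marker and its LRS/LOD.
#' @exportS3Method generics::glance
glance.qtl_scan <- function(x, ...) {
  ok <- !x$skipped
  i <- which(ok)[which.max(x$lrs[ok])]
  tibble::tibble(
    n_markers = nrow(x),
    n_skipped = sum(x$skipped),
    top_marker = x$marker[i],
    top_chrom = x$chrom[i],
    top_pos_mb = x$pos_mb[i],
    max_lrs = x$lrs[i],
    max_lod = lrs_to_lod(x$lrs[i]))
}

#' Tidy candidate scores
#'
#' @param x A `candidate_scores` tibble.
#' @param ... Unused.
#' @return A plain tibble.
#' @exportS3Method generics::tidy
tidy.candidate_scores <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "candidate_scores")
  tibble::as_tibble(out)
}

#' One-row summary of candidate scoring
#'
#' @param x A `candidate_scores` tibble.
#' @param ... Unused.
#' @return Tibble: gene counts, selected count, top gene and score.
#' @exportS3Method generics::glance
glance.candidate_scores <- function(x, ...) {
  i <- which.max(x$total)
  tibble::tibble(
    n_genes = nrow(x),
    n_selected = sum(x$selected),
    top_gene = x$gene_id[i],
    top_total = x$total[i])
}

#' One-row summary of an over-representation analysis
#'
#' @param x An `ora_result` tibble.
#' @param ... Unused.
#' @return Tibble: tested and significant set counts, top set.
#' @exportS3Method generics::glance
glance.ora_result <- function(x, ...) {
  tibble::tibble(
    n_sets = nrow(x),
    n_significant = sum(x$significant),
    top_set = if (nrow(x) > 0) x$set[1] else NA_character_,
    min_fdr = if (nrow(x) > 0) min(x$fdr) else NA_real_)
}
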