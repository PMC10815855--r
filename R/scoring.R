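# The 0-10 weighted candidate-regulator prioritization: five evidence
# parameters (heart expression, coding variant, cis-regulation,
# correlation with the focal gene, functional relevance) scored and
# summed per gene inside a QTL support interval.

FUNCTIONAL_SOURCES <- c(RGD_causal = 2, GWAS_catalog = 2, MGI = 1,
                        IMPC = 1, KEGG = 1, Alliance = 1, other = 1)

CODING_CONSEQUENCES <- c("nonsynonymous", "nonsyn", "non-synonymous",
                         "missense", "frameshift", "frame_shift",
                         "stop_gained", "stop_gain", "stop_lost", "stop_loss")

#' Candidate scoring weights
#'
#' Default weights of the five-parameter prioritization: heart expression
#' gate (mean >= 8) scores 1, a coding-sequence variant 1, cis-regulation
#' 1, significant correlation with the focal gene 2, and functional
#' evidence up to a cap of 5 with disease-causal sources (RGD causal,
#' GWAS Catalog) weighted 2 and other sources (MGI, IMPC, KEGG, Alliance,
#' generic `other`) weighted 1. Maximum attainable total: 10.
#'
#' @param expression,variant,cis,correlation Sub-scores for the four
#'   indicator parameters.
#' @param functional Named vector of per-source functional weights.
#' @param functional_cap Upper bound on the functional sub-score.
#' @param expression_gate Mean-expression threshold (inclusive).
#' @param select_threshold Selection cutoff on the total.
#' @return A list of class `scoring_weights`.
#' @export
scoring_weights <- function(expression = 1, variant = 1, cis = 1,
                            correlation = 2,
                            functional = FUNCTIONAL_SOURCES,
                            functional_cap = 5,
                            expression_gate = 8,
                            select_threshold = 5) {
  w <- list(expression = expression, variant = variant, cis = cis,
            correlation = correlation, functional = functional,
            functional_cap = functional_cap,
            expression_gate = expression_gate,
            select_threshold = select_threshold,
            max_total = expression + variant + cis + correlation + functional_cap)
  structure(w, class = "scoring_weights")
}

normalize_sources <- function(sources) {
  if (is.null(sources)) return(character())
  if (is.list(sources)) sources <- unlist(sources)
  sources <- sources[!is.na(sources) & nzchar(sources)]
  unique(sources)
}

#' Assemble per-gene evidence for candidate scoring
#'
#' Builds the evidence table for genes in a QTL support interval: mean
#' expression from the matrix, a coding-variant flag from the variant
#' table (non-synonymous, frameshift, stop gain/loss consequences only),
#' cis-regulation from each gene's own eQTL peak, significant correlation
#' with the focal gene from a [correlate_focal_gene()] screen, and
#' functional sources from a curated annotation table.
#'
#' @param interval_genes Character vector of gene ids to score.
#' @param expression Expression tibble (a gene missing here gets
#'   `mean_expression = NA` and a warning; its expression gate then
#'   fails).
#' @param variant_table Optional tibble `gene_id`, `consequence`.
#' @param gene_peaks Optional tibble of each gene's own eQTL peak: either
#'   a precomputed `regulation` column, or `peak_chrom` + `peak_pos_mb`
#'   to be classified against the gene annotation in `expression`.
#' @param focal_correlations Optional output of [correlate_focal_gene()].
#' @param functional_table Optional tibble `gene_id`, `source` with
#'   sources among `r paste(names(FUNCTIONAL_SOURCES), collapse = ", ")`.
#' @param p_threshold Correlation significance cutoff.
#' @param window_mb Cis window for classification when `gene_peaks` gives
#'   raw peak positions.
#' @return Evidence tibble: `gene_id`, `chrom`, `pos_mb`,
#'   `mean_expression`, `has_coding_variant`, `is_cis_regulated`,
#'   `sig_corr_with_focal`, `functional_sources` (list-column).
#' @export
build_evidence <- function(interval_genes, expression,
                           variant_table = NULL, gene_peaks = NULL,
                           focal_correlations = NULL,
                           functional_table = NULL,
                           p_threshold = 0.05, window_mb = 10) {
  M <- expr_matrix(expression)
  absent <- setdiff(interval_genes, rownames(M))
  if (length(absent) > 0) {
    warn(sprintf("gene(s) missing from expression matrix (expression gate fails): %s",
                 paste(absent, collapse = ", ")))
  }
  ann <- expression[match(interval_genes, expression$gene_id), , drop = FALSE]
  has_variant <- function(g) {
    if (is.null(variant_table)) return(FALSE)
    cons <- tolower(variant_table$consequence[variant_table$gene_id == g])
    any(gsub("[ -]", "_", cons) %in% gsub("[ -]", "_", CODING_CONSEQUENCES))
  }
  is_cis <- function(g, chrom, pos) {
    if (is.null(gene_peaks)) return(FALSE)
    row <- gene_peaks[gene_peaks$gene_id == g, , drop = FALSE]
    if (nrow(row) == 0) return(FALSE)
    if ("regulation" %in% names(row)) return(row$regulation[1] == "cis")
    if (is.na(chrom) || is.na(pos)) return(FALSE)
    peak <- tibble::tibble(chrom = row$peak_chrom[1], peak_pos_mb = row$peak_pos_mb[1])
    classify_cis_trans(peak, chrom, pos, window_mb) == "cis"
  }
  sig_corr <- function(g) {
    if (is.null(focal_correlations)) return(FALSE)
    p <- focal_correlations$p[focal_correlations$gene_id == g]
    length(p) > 0 && !is.na(p[1]) && p[1] < p_threshold
  }
  sources_of <- function(g) {
    if (is.null(functional_table)) return(character())
    normalize_sources(functional_table$source[functional_table$gene_id == g])
  }
  tibble::tibble(
    gene_id = interval_genes,
    chrom = if ("chrom" %in% names(ann)) as.character(ann$chrom) else NA_character_,
    pos_mb = if ("pos_mb" %in% names(ann)) ann$pos_mb else NA_real_,
    mean_expression = unname(rowMeans(M)[interval_genes]),
    has_coding_variant = purrr::map_lgl(interval_genes, has_variant),
    is_cis_regulated = purrr::pmap_lgl(
      list(interval_genes, .data$chrom, .data$pos_mb), is_cis),
    sig_corr_with_focal = purrr::map_lgl(interval_genes, sig_corr),
    functional_sources = purrr::map(interval_genes, sources_of))
}

#' Score candidate genes
#'
#' Applies the weighted scheme to each evidence row: expression sub-score
#' when mean expression meets the gate (>= 8 by default), variant and cis
#' sub-scores from their flags, correlation sub-score from the
#' significant-correlation flag, and a functional sub-score equal to the
#' capped sum of source weights. Sub-scores are summed into `total`
#' (range 0 to 10 with default weights) and `selected` marks totals at or
#' above the selection threshold.
#'
#' @param evidence Evidence tibble from [build_evidence()] (or any tibble
#'   with the same columns; `functional_sources` may be a list-column or
#'   comma-separated strings).
#' @param weights A [scoring_weights()].
#' @return A `candidate_scores` tibble with per-parameter sub-scores,
#'   `total` and `selected`.
#' @export
score_candidates <- function(evidence, weights = scoring_weights()) {
  src <- evidence$functional_sources
  if (!is.list(src)) src <- strsplit(as.character(src %||% ""), ",\\s*")
  func_score <- purrr::map_dbl(src, function(s) {
    s <- normalize_sources(s)
    known <- intersect(s, names(weights$functional))
    unknown <- setdiff(s, names(weights$functional))
    if (length(unknown) > 0) {
      warn(sprintf("unknown functional source(s) ignored: %s",
                   paste(unknown, collapse = ", ")))
    }
    min(weights$functional_cap, sum(weights$functional[known]))
  })
  out <- tibble::tibble(
    gene_id = evidence$gene_id,
    score_expression = ifelse(
      !is.na(evidence$mean_expression) &
        evidence$mean_expression >= weights$expression_gate,
      weights$expression, 0),
    score_variant = ifelse(evidence$has_coding_variant, weights$variant, 0),
    score_cis = ifelse(evidence$is_cis_regulated, weights$cis, 0),
    score_correlation = ifelse(evidence$sig_corr_with_focal,
                               weights$correlation, 0),
    score_functional = func_score)
  out$total <- out$score_expression + out$score_variant + out$score_cis +
    out$score_correlation + out$score_functional
  out$selected <- out$total >= weights$select_threshold
  for (col in c("chrom", "pos_mb")) {
    if (col %in% names(evidence)) out[[col]] <- evidence[[col]]
  }
  class(out) <- c("candidate_scores", class(out))
  out
}

#' @rdname score_candidates
#' @param ... Passed to [score_candidates()].
#' @export
score_gene <- function(evidence, ...) {
  score_candidates(evidence, ...)
}

#' Select and rank candidate genes
#'
#' Keeps genes whose total meets the threshold and ranks them by total
#' (descending), then genomic order (chromosome, position); ties are
#' preserved stably.
#'
#' @param scores A `candidate_scores` tibble.
#' @param threshold Selection cutoff on the total (default 5, half the
#'   maximum).
#' @return The selected rows, ranked.
#' @export
select_candidates <- function(scores, threshold = 5) {
  keep <- scores[scores$total >= threshold, , drop = FALSE]
  if (nrow(keep) == 0) return(keep)
  if ("chrom" %in% names(keep)) {
    ord <- order(-keep$total, chrom_rank(keep$chrom),
                 if ("pos_mb" %in% names(keep)) keep$pos_mb else seq_len(nrow(keep)))
  } else {
    ord <- order(-keep$total)
  }
  keep[ord, , drop = FALSE]
}

#' Published candidate-gene indicator table
#'
#' The printed indicator columns of the twelve candidate regulators of
#' *Rpl3l* shortlisted from the Chr 11 and Chr 13 trans-eQTL support
#' intervals in BXD heart: mean expression, coding-variant status,
#' cis-regulation, significant correlation with *Rpl3l*, RGD causal
#' evidence and generic functional evidence. Totals are not stored; they
#' are recomputed by [score_candidates()].
#'
#' @return A tibble of indicator columns, one row per gene.
#' @export
candidate_indicators_example <- function() {
  path <- system.file("extdata", "rpl3l_candidate_indicators.tsv",
                      package = "sysgen", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Convert printed indicator columns to an evidence table
#'
#' Translates a table of printed candidate indicators (mean expression,
#' `Nonsyn`/`--` variant column, `Y`/`--` flags for cis-regulation,
#' significant correlation and RGD causal evidence, and a generic `Y`/`--`
#' functional column) into the evidence representation used by
#' [score_candidates()]. RGD causal maps to the weight-2 `RGD_causal`
#' source; the generic functional column maps to one weight-1 `other`
#' source.
#'
#' @param indicators Tibble with columns `gene_id`, `mean_expression`,
#'   `coding_variant`, `cis_regulation`, `sig_corr`, `rgd_causal`,
#'   `functional` and optionally `chrom`, `pos_mb`.
#' @return An evidence tibble.
#' @export
evidence_from_indicators <- function(indicators) {
  yes <- function(x) !is.na(x) & !(as.character(x) %in% c("--", "-", "", "N", "no", "FALSE"))
  tibble::tibble(
    gene_id = indicators$gene_id,
    chrom = if ("chrom" %in% names(indicators)) as.character(indicators$chrom) else NA_character_,
    pos_mb = if ("pos_mb" %in% names(indicators)) indicators$pos_mb else NA_real_,
    mean_expression = indicators$mean_expression,
    has_coding_variant = yes(indicators$coding_variant),
    is_cis_regulated = yes(indicators$cis_regulation),
    sig_corr_with_focal = yes(indicators$sig_corr),
    functional_sources = purrr::map2(
      yes(indicators$rgd_causal), yes(indicators$functional),
      function(rgd, fun) c(if (rgd) "RGD_causal", if (fun) "other")))
}
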