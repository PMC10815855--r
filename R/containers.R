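# Tabular containers. Everything is a plain tibble with reserved metadata
# columns; the remaining columns are strains (genotypes) or samples
# (expression). This keeps every object pipeable through dplyr verbs.

GENO_META <- c("marker", "chrom", "pos_mb", "pos_cm")
EXPR_META <- c("gene_id", "chrom", "pos_mb")

#' Strain columns of a genotype table
#'
#' A genotype table is a tibble with metadata columns `marker`, `chrom`,
#' `pos_mb` (and optionally `pos_cm`); every other column is one recombinant
#' inbred strain coded 0 (B-allele homozygote) or 1 (D-allele homozygote).
#'
#' @param genotypes A genotype tibble.
#' @return Character vector of strain column names.
#' @export
strain_ids <- function(genotypes) {
  setdiff(names(genotypes), GENO_META)
}

#' Sample columns of an expression table
#'
#' An expression table is a tibble with a `gene_id` column, optional `chrom`
#' and `pos_mb` gene annotation, and one numeric column per sample holding
#' log2-scale values.
#'
#' @param expression An expression tibble.
#' @return Character vector of sample column names.
#' @export
sample_ids <- function(expression) {
  setdiff(names(expression), EXPR_META)
}

#' Genotype codes as a strains-by-markers matrix
#'
#' @param genotypes A genotype tibble.
#' @return Integer matrix, strains in rows, markers in columns.
#' @export
geno_matrix <- function(genotypes) {
  strains <- strain_ids(genotypes)
  m <- t(as.matrix(genotypes[, strains, drop = FALSE]))
  dimnames(m) <- list(strains, genotypes$marker)
  storage.mode(m) <- "integer"
  m
}

#' Expression values as a genes-by-samples matrix
#'
#' @param expression An expression tibble.
#' @return Numeric matrix with gene ids as row names.
#' @export
expr_matrix <- function(expression) {
  samples <- sample_ids(expression)
  m <- as.matrix(expression[, samples, drop = FALSE])
  rownames(m) <- expression$gene_id
  m
}

# natural chromosome order: numeric labels first in numeric order, then
# non-numeric (X, Y, MT) alphabetically
chrom_order <- function(chrom) {
  chrom <- as.character(chrom)
  num <- suppressWarnings(as.numeric(chrom))
  order(is.na(num), num, chrom)
}

chrom_rank <- function(chrom) {
  u <- unique(as.character(chrom))
  u <- u[chrom_order(u)]
  match(as.character(chrom), u)
}

#' Validate a genotype table
#'
#' Checks the recombinant-inbred invariants: codes are homozygous 0/1 only,
#' and markers are sorted by (chromosome, position) with strictly increasing
#' positions within each chromosome.
#'
#' @param genotypes A genotype tibble.
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_genotypes <- function(genotypes) {
  req <- c("marker", "chrom", "pos_mb")
  miss <- setdiff(req, names(genotypes))
  if (length(miss) > 0) {
    abort(paste0("genotype table is missing column(s): ",
                 paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(genotypes$marker)) {
    abort("duplicate marker ids in genotype table")
  }
  strains <- strain_ids(genotypes)
  if (length(strains) == 0) abort("genotype table has no strain columns")
  codes <- as.matrix(genotypes[, strains, drop = FALSE])
  bad <- which(!(codes %in% c(0L, 1L)), arr.ind = FALSE)
  if (length(bad) > 0) {
    i <- arrayInd(bad[1], dim(codes))
    abort(sprintf(
      "invalid genotype code %s at marker '%s', strain '%s': RI strains are homozygous, codes must be 0 or 1",
      codes[bad[1]], genotypes$marker[i[1]], strains[i[2]]))
  }
  ord <- order(chrom_rank(genotypes$chrom), genotypes$pos_mb)
  if (!identical(ord, seq_len(nrow(genotypes)))) {
    abort("markers must be sorted by (chromosome, position)")
  }
  by_chrom <- split(genotypes$pos_mb, genotypes$chrom)
  for (ch in names(by_chrom)) {
    if (any(diff(by_chrom[[ch]]) <= 0)) {
      abort(sprintf("marker positions not strictly increasing on chromosome %s", ch))
    }
  }
  invisible(genotypes)
}

#' Validate an expression table
#'
#' @param expression An expression tibble.
#' @return The input, invisibly, if valid; otherwise an error.
#' @export
validate_expression <- function(expression) {
  if (!"gene_id" %in% names(expression)) abort("expression table needs a 'gene_id' column")
  if (anyDuplicated(expression$gene_id)) abort("gene_ids must be unique")
  samples <- sample_ids(expression)
  if (length(samples) == 0) abort("expression table has no sample columns")
  vals <- as.matrix(expression[, samples, drop = FALSE])
  if (any(!is.finite(vals))) abort("expression values must be finite")
  if ("chrom" %in% names(expression)) {
    annotated <- !is.na(expression$chrom)
    if (!"pos_mb" %in% names(expression) || any(annotated & is.na(expression$pos_mb))) {
      abort("annotated genes must have both chromosome and position")
    }
  }
  invisible(expression)
}

# sort markers into canonical map order
sort_markers <- function(genotypes) {
  genotypes[order(chrom_rank(genotypes$chrom), genotypes$pos_mb), , drop = FALSE]
}
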