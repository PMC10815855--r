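# Single-trait genome scan on RI genotypes: per-marker likelihood ratio
# statistics, permutation thresholds, 1.5-LOD support intervals and
# cis/trans classification. Scans are taken at genotyped markers only;
# with dense homozygous RI genotypes, interval mapping at marker
# positions reduces to the two-class mean model fitted here.

LOD_DIVISOR <- 2 * log(10)  # LRS -> LOD

#' LRS and additive effect at one marker
#'
#' Fits the normal-errors two-class mean model at a biallelic homozygous
#' marker: `LRS = n * ln(SS0 / SS1)` where `SS0` is the total sum of
#' squares about the grand mean and `SS1` the pooled within-genotype-class
#' sum of squares. The additive effect is `mean(y | g = 1) - mean(y | g =
#' 0)` (D minus B allele) in log2 units.
#'
#' A monomorphic marker is not an error: the result carries
#' `skipped = TRUE` with `NA` statistics. A perfect fit (`SS1 = 0`) clamps
#' the LRS at `ceiling` with a warning. A constant trait gives `LRS = 0`.
#'
#' @param y Per-strain trait or expression vector.
#' @param g Per-strain genotype codes in `{0, 1}`.
#' @param ceiling LRS cap for perfect fits.
#' @return One-row tibble: `lrs`, `additive`, `skipped`.
#' @export
marker_lrs <- function(y, g, ceiling = 1e6) {
  if (length(y) != length(g)) abort("y and g must have equal length")
  ok <- is.finite(y) & !is.na(g)
  y <- y[ok]; g <- g[ok]
  n <- length(y)
  if (n < 4) abort("marker_lrs needs at least 4 strains")
  n1 <- sum(g == 1); n0 <- sum(g == 0)
  if (n1 == 0 || n0 == 0) {
    return(tibble::tibble(lrs = NA_real_, additive = NA_real_, skipped = TRUE))
  }
  ss0 <- sum((y - mean(y))^2)
  m1 <- mean(y[g == 1]); m0 <- mean(y[g == 0])
  ss1 <- sum((y[g == 1] - m1)^2) + sum((y[g == 0] - m0)^2)
  if (ss0 <= .Machine$double.eps) {
    lrs <- 0
  } else if (ss1 <= ss0 * .Machine$double.eps) {
    warn("perfect genotype fit: LRS clamped at ceiling")
    lrs <- ceiling
  } else {
    lrs <- min(n * log(ss0 / ss1), ceiling)
  }
  tibble::tibble(lrs = lrs, additive = m1 - m0, skipped = FALSE)
}

# vectorized scan core: y (length n), G strains x markers -> lrs/additive
# per marker; monomorphic markers NA
scan_core <- function(y, G, ceiling = 1e6) {
  n <- length(y)
  n1 <- colSums(G)
  n0 <- n - n1
  poly <- n1 > 0 & n0 > 0
  s1 <- as.numeric(crossprod(G, y))
  tot <- sum(y)
  m1 <- s1 / n1
  m0 <- (tot - s1) / n0
  ybar <- tot / n
  ss0 <- sum((y - ybar)^2)
  ssb <- n1 * (m1 - ybar)^2 + n0 * (m0 - ybar)^2
  ss1 <- pmax(ss0 - ssb, 0)
  lrs <- rep(NA_real_, length(n1))
  if (ss0 <= .Machine$double.eps) {
    lrs[poly] <- 0
  } else {
    perfect <- poly & ss1 <= ss0 * .Machine$double.eps
    normal <- poly & !perfect
    lrs[normal] <- pmin(n * log(ss0 / ss1[normal]), ceiling)
    lrs[perfect] <- ceiling
  }
  additive <- m1 - m0
  additive[!poly] <- NA_real_
  list(lrs = lrs, additive = additive, skipped = !poly)
}

# max LRS per column of a permuted trait matrix Y (n x n_perm)
perm_max_lrs <- function(Y, G, ceiling = 1e6) {
  n <- nrow(Y)
  n1 <- colSums(G); n0 <- n - n1
  poly <- n1 > 0 & n0 > 0
  G <- G[, poly, drop = FALSE]
  n1 <- n1[poly]; n0 <- n0[poly]
  S1 <- crossprod(G, Y)                       # markers x perms
  tot <- colSums(Y)                           # per perm
  ybar <- tot / n
  ss0 <- colSums(Y^2) - n * ybar^2            # per perm
  M1 <- sweep(S1, 1, n1, "/")
  M0 <- sweep(sweep(-S1, 2, tot, "+"), 1, n0, "/")
  SSB <- sweep(sweep(M1, 2, ybar, "-")^2, 1, n1, "*") +
    sweep(sweep(M0, 2, ybar, "-")^2, 1, n0, "*")
  SS1 <- pmax(sweep(-SSB, 2, ss0, "+"), 0)
  RATIO <- sweep(1 / pmax(SS1, .Machine$double.xmin), 2, ss0, "*")
  LRS <- pmin(n * log(pmax(RATIO, 1)), ceiling)
  apply(LRS, 2, max)
}

#' Genome-wide LRS scan
#'
#' Computes [marker_lrs()] at every marker in map order. Monomorphic
#' markers are flagged `skipped` with `NA` statistics.
#'
#' @param y Per-strain trait/expression vector, named by strain or aligned
#'   to the genotype strain order.
#' @param genotypes Genotype tibble.
#' @param ceiling LRS cap for perfect fits.
#' @return A `qtl_scan` tibble: `marker`, `chrom`, `pos_mb`, `lrs`,
#'   `additive`, `skipped`.
#' @export
genome_scan <- function(y, genotypes, ceiling = 1e6) {
  validate_genotypes(genotypes)
  G <- geno_matrix(genotypes)
  if (!is.null(names(y))) {
    missing <- setdiff(rownames(G), names(y))
    if (length(missing) > 0) {
      abort(sprintf("trait vector missing strain(s): %s",
                    paste(head(missing, 3), collapse = ", ")))
    }
    y <- y[rownames(G)]
  }
  if (length(y) != nrow(G)) abort("y must have one value per strain")
  res <- scan_core(y, G, ceiling)
  if (all(res$skipped)) abort("no polymorphic markers in genotype table")
  out <- tibble::tibble(
    marker = genotypes$marker, chrom = genotypes$chrom,
    pos_mb = genotypes$pos_mb,
    lrs = res$lrs, additive = res$additive, skipped = res$skipped)
  class(out) <- c("qtl_scan", class(out))
  attr(out, "n_strains") <- length(y)
  out
}

#' Permutation thresholds for a genome scan
#'
#' Permutes the trait across strains `n_perm` times, records the
#' genome-wide maximum LRS of each permuted scan, and returns empirical
#' quantiles of that null distribution: the significant threshold at
#' genome-wide `alpha_sig` (default 0.05) and the suggestive threshold at
#' `alpha_sug` (default 0.63, the one-false-positive-per-scan
#' convention). Quantiles are type 7 (linear interpolation).
#'
#' @param y Per-strain trait vector.
#' @param genotypes Genotype tibble.
#' @param n_perm Number of permutations (values below 100 warn).
#' @param alpha_sig,alpha_sug Genome-wide type-I error rates.
#' @param seed Integer seed for the permutation stream (mandatory).
#' @return One-row tibble: `significant_lrs`, `suggestive_lrs`, `n_perm`,
#'   `seed`.
#' @export
permutation_thresholds <- function(y, genotypes, n_perm = 1000,
                                   alpha_sig = 0.05, alpha_sug = 0.63,
                                   seed) {
  if (missing(seed) || is.null(seed)) abort("seed is mandatory for permutations")
  if (n_perm < 100) warn("fewer than 100 permutations: thresholds will be unstable")
  validate_genotypes(genotypes)
  G <- geno_matrix(genotypes)
  if (!is.null(names(y))) y <- y[rownames(G)]
  set.seed(seed)
  Y <- vapply(seq_len(n_perm), function(i) sample(y), numeric(length(y)))
  max_lrs <- perm_max_lrs(Y, G)
  qs <- quantile(max_lrs, probs = 1 - c(alpha_sig, alpha_sug), type = 7,
                 names = FALSE)
  tibble::tibble(
    significant_lrs = qs[1], suggestive_lrs = qs[2],
    n_perm = as.integer(n_perm), seed = as.integer(seed))
}

#' LOD support interval around the top peak on a chromosome
#'
#' Finds the maximum-LRS marker on the chromosome (ties broken toward the
#' smaller position) and extends the interval to the outermost contiguous
#' run of markers whose LOD stays within `drop_lod` of the peak LOD, then
#' includes one additional flanking marker on each side (the first marker
#' failing the drop), clipped at the chromosome ends.
#'
#' @param scan A `qtl_scan` from [genome_scan()].
#' @param chromosome Chromosome label present in the scan.
#' @param drop_lod LOD drop defining the support interval (default 1.5).
#' @return A one-row `qtl_peak` tibble: `chrom`, `peak_marker`,
#'   `peak_pos_mb`, `peak_lrs`, `peak_lod`, `interval_start_mb`,
#'   `interval_end_mb`.
#' @export
support_interval <- function(scan, chromosome, drop_lod = 1.5) {
  rows <- scan[scan$chrom == as.character(chromosome) & !scan$skipped, ,
               drop = FALSE]
  if (nrow(rows) == 0) {
    abort(sprintf("chromosome '%s' not present in scan", chromosome))
  }
  rows <- rows[order(rows$pos_mb), , drop = FALSE]
  lod <- rows$lrs / LOD_DIVISOR
  peak_i <- which(lod == max(lod))[1]
  cutoff <- lod[peak_i] - drop_lod
  keep <- lod >= cutoff
  lo <- peak_i
  while (lo > 1 && keep[lo - 1]) lo <- lo - 1
  hi <- peak_i
  while (hi < nrow(rows) && keep[hi + 1]) hi <- hi + 1
  lo <- max(1, lo - 1)                 # one flanking marker each side
  hi <- min(nrow(rows), hi + 1)
  out <- tibble::tibble(
    chrom = rows$chrom[peak_i],
    peak_marker = rows$marker[peak_i],
    peak_pos_mb = rows$pos_mb[peak_i],
    peak_lrs = rows$lrs[peak_i],
    peak_lod = lod[peak_i],
    interval_start_mb = rows$pos_mb[lo],
    interval_end_mb = rows$pos_mb[hi])
  class(out) <- c("qtl_peak", class(out))
  out
}

#' Convert between LRS and LOD
#'
#' `LOD = LRS / (2 ln 10) = LRS / 4.60517`.
#'
#' @param lrs,lod Numeric vectors.
#' @return Numeric vector.
#' @export
lrs_to_lod <- function(lrs) lrs / LOD_DIVISOR

#' @rdname lrs_to_lod
#' @export
lod_to_lrs <- function(lod) lod * LOD_DIVISOR

#' Classify a QTL peak as cis- or trans-acting for a gene
#'
#' A peak is cis when it lies on the gene's own chromosome within
#' `window_mb` of the gene position (inclusive), trans otherwise.
#'
#' @param peak A `qtl_peak` row (or anything with `chrom` and
#'   `peak_pos_mb`).
#' @param gene_chrom,gene_pos_mb Gene annotation.
#' @param window_mb Flanking window, default 10 Mb.
#' @return `"cis"` or `"trans"`.
#' @export
classify_cis_trans <- function(peak, gene_chrom, gene_pos_mb,
                               window_mb = 10) {
  if (is.na(gene_chrom) || is.na(gene_pos_mb)) {
    abort("gene annotation (chromosome and position) is required")
  }
  same <- as.character(peak$chrom) == as.character(gene_chrom)
  if (same && abs(peak$peak_pos_mb - gene_pos_mb) <= window_mb) "cis" else "trans"
}
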