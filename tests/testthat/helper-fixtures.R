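# Small in-code fixtures shared across tests.

# 2 strains x 3 markers, two chromosomes
tiny_genotypes <- function() {
  tibble::tibble(
    marker = c("m1", "m2", "m3"),
    chrom = c("1", "1", "2"),
    pos_mb = c(10, 20, 5),
    S1 = c(0L, 1L, 0L),
    S2 = c(1L, 1L, 1L))
}

# expression tibble from a genes x samples matrix
expr_from_matrix <- function(M, chrom = NULL, pos_mb = NULL) {
  out <- tibble::tibble(gene_id = rownames(M))
  if (!is.null(chrom)) {
    out$chrom <- chrom
    out$pos_mb <- pos_mb
  }
  dplyr::bind_cols(out, tibble::as_tibble(M))
}

# two-group expression with a configurable shift on some genes
two_group_expression <- function(n_genes = 50, n_per_group = 10, delta = 0,
                                 n_shifted = 0, sd = 0.5, seed = 1) {
  set.seed(seed)
  samples <- c(sprintf("case%02d", seq_len(n_per_group)),
               sprintf("ctrl%02d", seq_len(n_per_group)))
  M <- matrix(rnorm(n_genes * 2 * n_per_group, 8, sd), nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)), samples))
  if (n_shifted > 0) {
    M[seq_len(n_shifted), seq_len(n_per_group)] <-
      M[seq_len(n_shifted), seq_len(n_per_group)] + delta
  }
  list(expression = expr_from_matrix(M),
       groups = tibble::tibble(
         sample = samples,
         group = rep(c("case", "control"), each = n_per_group)))
}

# independent brute-force LRS oracle: explicit Gaussian log-likelihoods
oracle_lrs <- function(y, g) {
  n <- length(y)
  sigma0 <- sqrt(mean((y - mean(y))^2))
  ll0 <- sum(stats::dnorm(y, mean(y), sigma0, log = TRUE))
  m <- tapply(y, g, mean)
  fitted <- m[as.character(g)]
  sigma1 <- sqrt(mean((y - fitted)^2))
  ll1 <- sum(stats::dnorm(y, fitted, sigma1, log = TRUE))
  unname(2 * (ll1 - ll0))
}

# exhaustive hypergeometric upper tail by enumeration
oracle_hyper_upper <- function(k, K, N, n) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# step-by-step ssGSEA oracle following the running-sum definition
oracle_ssgsea <- function(values, gene_set, alpha) {
  ord <- order(values, decreasing = TRUE)
  genes <- names(values)[ord]
  rnk <- rank(values, ties.method = "average")[ord]
  in_set <- genes %in% gene_set
  N <- length(genes); K <- sum(in_set)
  p_in <- 0; p_out <- 0; es <- 0
  denom <- sum(abs(rnk[in_set])^alpha)
  for (i in seq_len(N)) {
    if (in_set[i]) p_in <- p_in + abs(rnk[i])^alpha / denom
    else p_out <- p_out + 1 / (N - K)
    es <- es + (p_in - p_out)
  }
  unname(es)
}
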