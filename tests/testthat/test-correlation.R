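test_that("pearson_with_p matches the closed formulas and handles extremes", {
  expect_equal(pearson_with_p(c(1, 2, 4), c(1, 2, 4))$r, 1)
  res0 <- pearson_with_p(c(1, 2, 3), c(1, 0, 1))
  expect_equal(res0$r, 0, tolerance = 1e-15)
  expect_equal(res0$p, 1)

  set.seed(5)
  x <- rnorm(10); y <- rnorm(10)
  res <- pearson_with_p(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt(8 / (1 - r_hand^2))
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 8), tolerance = 1e-12)
  # cross-check against the stock implementation
  ct <- cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)

  expect_gt(pearson_with_p(1:10, 1:10)$p, 0)  # underflow clamp, not zero
  expect_error(pearson_with_p(rep(1, 5), rnorm(5)), "undefined correlation")
  expect_error(pearson_with_p(c(1, 2, NA), c(1, NA, 3)), "at least 3")
})

test_that("pearson is symmetric and affine-equivariant", {
  set.seed(6)
  for (i in 1:20) {
    x <- rnorm(15); y <- rnorm(15)
    a <- pearson_with_p(x, y)
    expect_equal(pearson_with_p(y, x)$r, a$r, tolerance = 1e-12)
    expect_equal(pearson_with_p(2 * x + 3, y)$r, a$r, tolerance = 1e-12)
    expect_equal(pearson_with_p(-x, y)$r, -a$r, tolerance = 1e-12)
    expect_equal(pearson_with_p(-x, y)$p, a$p, tolerance = 1e-12)
  }
})

test_that("focal-gene screen applies the p, mean and |r| gates", {
  set.seed(10)
  n <- 40
  focal <- rnorm(n, 8)
  M <- rbind(
    focal = focal,
    copy = focal,                    # r = 1, passes
    dim = focal + rnorm(n, 0, 0.1))  # correlated but dim: mean 6.5
  M["dim", ] <- M["dim", ] - mean(M["dim", ]) + 6.5
  M <- rbind(M, noise = rnorm(n, 8))
  colnames(M) <- paste0("s", seq_len(n))
  res <- correlate_focal_gene(expr_from_matrix(M), "focal")
  expect_false("focal" %in% res$gene_id)
  expect_equal(res$r[res$gene_id == "copy"], 1)
  expect_true(res$passes_filter[res$gene_id == "copy"])
  # mean gate: strongly correlated but below mean 7 fails
  expect_lt(res$p[res$gene_id == "dim"], 1e-6)
  expect_false(res$passes_filter[res$gene_id == "dim"])
  # human-mode |r| gate is inclusive at 0.5
  res2 <- correlate_focal_gene(expr_from_matrix(M), "focal", r_threshold = 0.5)
  expect_true(res2$passes_filter[res2$gene_id == "copy"])
  expect_error(correlate_focal_gene(expr_from_matrix(M), "absent"), "absent")
})

test_that("filter pass counts are monotone in the thresholds", {
  cfg <- sim_config(n_strains = 40, n_chrom = 2, markers_per_chrom = 5,
                    planted_eqtls = NULL, n_null_genes = 80, block_size = 20,
                    seed = 77)
  g <- simulate_ri_genotypes(cfg)
  e <- simulate_expression(g, cfg)
  focal <- e$gene_id[1]
  n_pass <- function(p_threshold, min_mean) {
    sum(correlate_focal_gene(e, focal, p_threshold = p_threshold,
                             min_mean = min_mean)$passes_filter)
  }
  expect_gte(n_pass(0.05, 7), n_pass(0.01, 7))
  expect_gte(n_pass(0.05, 7), n_pass(0.05, 8))
})

test_that("correlated block genes are recovered by the screen", {
  # block of 50 genes at rho 0.6 with the first block gene as focal
  hits <- vapply(1:25, function(i) {
    cfg <- sim_config(n_strains = 40, n_chrom = 2, markers_per_chrom = 5,
                      planted_eqtls = NULL, n_null_genes = 100,
                      block_size = 50, block_rho = 0.6, seed = 200 + i)
    g <- simulate_ri_genotypes(cfg)
    e <- simulate_expression(g, cfg)
    res <- correlate_focal_gene(e, "blk_g001", min_mean = 0)
    planted <- res[grepl("^blk_", res$gene_id), ]
    sum(planted$p < 0.05)
  }, numeric(1))
  # pairwise rho 0.6 at n = 40 gives power near 1; demand 45/49 on average
  expect_gte(mean(hits >= 45), 0.9)
})

test_that("gene-trait correlation is pairwise complete", {
  M <- matrix(rnorm(40, 8), nrow = 2,
              dimnames = list(c("g1", "g2"), paste0("s", 1:20)))
  traits <- tibble::tibble(strain = paste0("s", 1:20),
                           t1 = M["g1", ] * 2 + 1, t2 = rnorm(20))
  traits$t2[3] <- NA
  res <- correlate_genes_with_traits(expr_from_matrix(M), traits)
  expect_equal(res$r[res$gene_id == "g1" & res$trait == "t1"], 1)
  expect_equal(res$n[res$trait == "t2"], c(19L, 19L))
  expect_equal(res$n[res$trait == "t1"], c(20L, 20L))
  bad <- tibble::tibble(strain = c("x1", "x2"), t1 = c(1, 2))
  expect_error(correlate_genes_with_traits(expr_from_matrix(M), bad),
               "no overlapping strains")
})

test_that("null gene-trait correlations stay small at large n", {
  set.seed(30)
  inside <- vapply(1:40, function(i) {
    x <- rnorm(1000); y <- rnorm(1000)
    abs(pearson_with_p(x, y)$r) < 0.1
  }, logical(1))
  expect_gte(mean(inside), 0.95)
})

test_that("fold difference is the antilog2 range", {
  res <- fold_difference(c(BXD49 = 11.31, BXD44 = 12.16))
  expect_equal(round(res$fold, 2), 1.80)
  expect_identical(res$min_strain, "BXD49")
  expect_identical(res$max_strain, "BXD44")
  expect_equal(fold_difference(c(a = 3, b = 3))$fold, 1)
  expect_equal(fold_difference(c(a = 0, b = 1))$fold, 2)
  expect_error(fold_difference(numeric()), "at least one")
})
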