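test_that("RI adjacent-marker flip frequency follows the sib-mating expansion", {
  # d = 0 -> identical codes everywhere
  cfg0 <- sim_config(n_strains = 200, n_chrom = 1, markers_per_chrom = 3,
                     spacing_cm = 0, seed = 11)
  g0 <- geno_matrix(simulate_ri_genotypes(cfg0))
  expect_true(all(g0[, 1] == g0[, 2]))
  expect_true(all(g0[, 2] == g0[, 3]))

  # d = 10 cM: r = 0.0906, R = 4r/(1+6r) = 0.2346 within +-0.01
  cfg10 <- sim_config(n_strains = 10000, n_chrom = 1, markers_per_chrom = 2,
                      spacing_cm = 10, seed = 12)
  g10 <- geno_matrix(simulate_ri_genotypes(cfg10))
  flip10 <- mean(g10[, 1] != g10[, 2])
  r <- (1 - exp(-2 * 10 / 100)) / 2
  expect_equal(flip10, 4 * r / (1 + 6 * r), tolerance = 0.01 / 0.2346)

  # unlinked (huge d): R -> 0.5 within +-0.02
  cfgU <- sim_config(n_strains = 10000, n_chrom = 1, markers_per_chrom = 2,
                     spacing_cm = 1e6, seed = 13)
  gU <- geno_matrix(simulate_ri_genotypes(cfgU))
  expect_equal(mean(gU[, 1] != gU[, 2]), 0.5, tolerance = 0.02 / 0.5)
})

test_that("marker allele frequencies approach one half", {
  cfg <- sim_config(n_strains = 10000, n_chrom = 2, markers_per_chrom = 5,
                    seed = 21)
  G <- geno_matrix(simulate_ri_genotypes(cfg))
  expect_true(all(abs(colMeans(G) - 0.5) < 0.02))
})

test_that("planted eQTL produces the closed-form gene-marker correlation", {
  base <- function(beta, n, seed) {
    cfg <- sim_config(
      n_strains = n, n_chrom = 2, markers_per_chrom = 5,
      planted_eqtls = tibble::tibble(gene = "tg", marker = "c1_m03",
                                     beta = beta, type = "trans"),
      n_null_genes = 0, block_size = 0, seed = seed)
    g <- simulate_ri_genotypes(cfg)
    e <- simulate_expression(g, cfg)
    cor(expr_matrix(e)["tg", ], geno_matrix(g)[, "c1_m03"])
  }
  # beta = 0: no association
  expect_lt(abs(base(0, 1000, 31)), 0.05)
  # beta = 1, sd = 1: r = 0.5 / sqrt(1.25) = 0.447 within +-0.03
  expect_equal(base(1, 2000, 32), 0.5 / sqrt(1.25), tolerance = 0.03 / 0.447)
})

test_that("vanishing residual noise makes the planted gene affine in genotype", {
  cfg <- sim_config(
    n_strains = 50, n_chrom = 1, markers_per_chrom = 4,
    planted_eqtls = tibble::tibble(gene = "tg", marker = "c1_m02",
                                   beta = 1, type = "cis"),
    residual_sd = 1e-9, n_null_genes = 0, block_size = 0, seed = 41)
  g <- simulate_ri_genotypes(cfg)
  e <- simulate_expression(g, cfg)
  r <- cor(expr_matrix(e)["tg", ], geno_matrix(g)[, "c1_m02"])
  expect_equal(r, 1, tolerance = 1e-6)
  # cis annotation lands within 10 Mb of the marker
  ann <- e[e$gene_id == "tg", ]
  mrow <- g[g$marker == "c1_m02", ]
  expect_identical(ann$chrom, mrow$chrom)
  expect_lte(abs(ann$pos_mb - mrow$pos_mb), 10)
})

test_that("planted marker must exist and configs validate", {
  cfg <- sim_config(planted_eqtls = tibble::tibble(
    gene = "tg", marker = "no_such", beta = 1, type = "trans"))
  g <- simulate_ri_genotypes(sim_config(n_strains = 5))
  expect_error(simulate_expression(g, cfg), "planted marker")
  expect_error(sim_config(n_strains = 0), "config error")
  expect_error(sim_config(block_rho = 1), "rho")
  expect_error(sim_config(residual_sd = 0), "residual_sd")
})

test_that("trait loadings are recoverable by correlation", {
  mk <- function(w, noise_sd, seed, n = 1000) {
    cfg <- sim_config(
      n_strains = n, n_chrom = 1, markers_per_chrom = 2,
      planted_eqtls = tibble::tibble(gene = "tg", marker = "c1_m01",
                                     beta = 1, type = "trans"),
      n_null_genes = 0, block_size = 0,
      trait_loadings = list(tr = list(weights = c(tg = w),
                                      noise_sd = noise_sd)),
      seed = seed)
    g <- simulate_ri_genotypes(cfg)
    e <- simulate_expression(g, cfg)
    tt <- simulate_traits(e, cfg)
    cor(expr_matrix(e)["tg", ], tt$tr)
  }
  expect_equal(mk(1, 1e-12, 51, n = 50), 1, tolerance = 1e-6)
  expect_equal(mk(-1, 1e-12, 52, n = 50), -1, tolerance = 1e-6)
  # noise sd equal to the gene sd (~ sqrt(1.25) with beta 1): |r| ~ 1/sqrt(2)
  expect_equal(abs(mk(1, sqrt(1.25), 53)), 1 / sqrt(2),
               tolerance = 0.05 / 0.707)
})

test_that("cohort construction places signatures in proportion and is valid", {
  cfg <- sim_config(cohort = list(noise_sd = 1e-12, n_case = 4, n_control = 4,
                                  concentration = 1e9), seed = 61)
  ch <- simulate_cohort(cfg)
  M <- expr_matrix(ch$expression)
  # near-deterministic: equal group proportions -> case01 and case02 identical
  expect_equal(M[, "case01"], M[, "case02"], tolerance = 1e-4)
  expect_equal(rowSums(as.matrix(ch$proportions[, -1])), rep(1, 8),
               ignore_attr = TRUE, tolerance = 1e-9)

  # explicit one-hot mixture: that sample maximizes its own cell type score
  cfg2 <- sim_config(cohort = list(
    noise_sd = 1e-6, n_case = 1, n_control = 3, concentration = 1e9,
    case_props = c(0.996, 0.001, 0.001, 0.001, 0.001),
    control_props = rep(0.2, 5)), seed = 62)
  ch2 <- simulate_cohort(cfg2)
  scores <- infiltration_matrix(ch2$expression, ch2$signatures,
                                groups = ch2$groups)
  ct1 <- scores[scores$cell_type == "CT1", ]
  expect_equal(ct1$sample[which.max(ct1$es)], "case01")
})

test_that("invalid mixing proportions are rejected", {
  cfg <- sim_config(seed = 1)
  cfg$cohort$case_props <- c(0.5, 0.2, 0.1, 0.1, 0.2)  # sums to 1.1
  expect_error(validate_sim_config(cfg), "sum to 1")
})

test_that("generators are bit-for-bit reproducible from the config", {
  cfg <- sim_config(n_strains = 20, seed = 99)
  expect_identical(simulate_ri_genotypes(cfg), simulate_ri_genotypes(cfg))
  g <- simulate_ri_genotypes(cfg)
  expect_identical(simulate_expression(g, cfg), simulate_expression(g, cfg))
  expect_identical(simulate_cohort(cfg)$expression,
                   simulate_cohort(cfg)$expression)
})
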