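test_that("published indicator rows reproduce every printed total", {
  ind <- candidate_indicators_example()
  scores <- score_candidates(evidence_from_indicators(ind))
  expected <- c(Myl4 = 7, Ace = 5, Kpna2 = 5, Golm1 = 5, Zfp367 = 5,
                Zfp712 = 5, Zfp759 = 5, Zfp874a = 5, Zfp729a = 5,
                Mtrr = 5, Sdha = 6, Rhobtb3 = 5)
  expect_equal(setNames(scores$total, scores$gene_id), expected)
  sel <- select_candidates(scores)
  expect_equal(nrow(sel), 12)
  expect_equal(sum(sel$chrom == "13"), 9)
  expect_equal(sum(sel$chrom == "11"), 3)
  # top two candidates score 7 and 6
  expect_equal(sel$gene_id[1:2], c("Myl4", "Sdha"))
  expect_equal(sel$total[1:2], c(7, 6))
})

test_that("sub-scores follow the weighted scheme", {
  ev <- tibble::tibble(
    gene_id = c("allfalse", "saturated", "gate_edge", "below_gate"),
    mean_expression = c(2, 14, 8, 7.99),
    has_coding_variant = c(FALSE, TRUE, FALSE, FALSE),
    is_cis_regulated = c(FALSE, TRUE, FALSE, FALSE),
    sig_corr_with_focal = c(FALSE, TRUE, FALSE, FALSE),
    functional_sources = list(
      character(),
      c("RGD_causal", "GWAS_catalog", "MGI", "IMPC", "KEGG", "Alliance"),
      character(), character()))
  sc <- score_candidates(ev)
  expect_equal(sc$total, c(0, 10, 1, 0))  # cap at 5 keeps the ceiling at 10
  expect_equal(sc$score_functional[2], 5)
  expect_true(sc$selected[2])
  expect_false(sc$selected[1])
})

test_that("scoring is monotone in flags and sources", {
  base <- tibble::tibble(
    gene_id = "g", mean_expression = 9, has_coding_variant = FALSE,
    is_cis_regulated = FALSE, sig_corr_with_focal = FALSE,
    functional_sources = list(character()))
  t0 <- score_candidates(base)$total
  for (col in c("has_coding_variant", "is_cis_regulated",
                "sig_corr_with_focal")) {
    up <- base
    up[[col]] <- TRUE
    expect_gt(score_candidates(up)$total, t0)
  }
  for (src in c("RGD_causal", "MGI", "KEGG")) {
    up <- base
    up$functional_sources <- list(src)
    expect_gt(score_candidates(up)$total, t0)
  }
  # functional sub-score never exceeds the cap
  up <- base
  up$functional_sources <- list(names(scoring_weights()$functional))
  expect_equal(score_candidates(up)$score_functional, 5)
})

test_that("synonymous-only variants do not count as coding evidence", {
  M <- matrix(rnorm(20, 9), nrow = 2,
              dimnames = list(c("g1", "g2"), paste0("s", 1:10)))
  ev <- build_evidence(
    c("g1", "g2"), expr_from_matrix(M),
    variant_table = tibble::tibble(gene_id = c("g1", "g2"),
                                   consequence = c("synonymous", "missense")))
  expect_false(ev$has_coding_variant[1])
  expect_true(ev$has_coding_variant[2])
})

test_that("build_evidence wires the parameter sources together", {
  cfg <- sim_config(
    n_strains = 40, n_chrom = 2, markers_per_chrom = 6,
    planted_eqtls = tibble::tibble(
      gene = c("cisg", "focal"), marker = c("c1_m03", "c1_m03"),
      beta = c(2, 1.5), type = c("cis", "trans")),
    n_null_genes = 20, block_size = 0, seed = 71)
  g <- simulate_ri_genotypes(cfg)
  e <- simulate_expression(g, cfg)
  corr <- correlate_focal_gene(e, "focal", min_mean = 0)
  M <- expr_matrix(e)
  sc <- genome_scan(M["cisg", ], g)
  i <- which.max(sc$lrs)
  peaks <- tibble::tibble(gene_id = "cisg", peak_chrom = sc$chrom[i],
                          peak_pos_mb = sc$pos_mb[i])
  ev <- build_evidence(c("cisg", "null_g0001"), e,
                       gene_peaks = peaks, focal_correlations = corr,
                       functional_table = tibble::tibble(
                         gene_id = "cisg", source = "RGD_causal"))
  row <- ev[ev$gene_id == "cisg", ]
  expect_true(row$is_cis_regulated)       # planted cis-eQTL, beta = 2
  expect_true(row$sig_corr_with_focal)    # shares the planted marker
  expect_equal(row$functional_sources[[1]], "RGD_causal")
  null_row <- ev[ev$gene_id == "null_g0001", ]
  expect_false(any(null_row$has_coding_variant, null_row$is_cis_regulated))
  expect_equal(null_row$functional_sources[[1]], character())
})

test_that("genes absent from the expression matrix fail the gate with warning", {
  M <- matrix(rnorm(10, 9), nrow = 1,
              dimnames = list("g1", paste0("s", 1:10)))
  expect_warning(ev <- build_evidence(c("g1", "ghost"), expr_from_matrix(M)),
                 "ghost")
  expect_true(is.na(ev$mean_expression[2]))
  expect_equal(score_candidates(ev)$score_expression[2], 0)
})

test_that("selection ranks by total then genomic position and handles empties", {
  sc <- score_candidates(tibble::tibble(
    gene_id = c("a", "b", "c", "d"),
    chrom = c("2", "1", "11", "2"),
    pos_mb = c(50, 10, 5, 20),
    mean_expression = c(9, 9, 9, 2),
    has_coding_variant = TRUE, is_cis_regulated = TRUE,
    sig_corr_with_focal = c(TRUE, TRUE, TRUE, FALSE),
    functional_sources = list(character(), character(), character(),
                              character())))
  sel <- select_candidates(sc)
  expect_equal(sel$gene_id, c("b", "a", "c"))  # ties by natural chrom order; d = 2 dropped
  expect_equal(nrow(select_candidates(sc[0, ])), 0)
})

test_that("candidate score tidiers summarize selection", {
  sc <- score_candidates(evidence_from_indicators(candidate_indicators_example()))
  gl <- glance(sc)
  expect_equal(gl$n_selected, 12)
  expect_identical(gl$top_gene, "Myl4")
  expect_equal(gl$top_total, 7)
})
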