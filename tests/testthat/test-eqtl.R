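test_that("marker_lrs reproduces the worked sums-of-squares example", {
  res <- marker_lrs(c(1, 2, 3, 4), c(0, 0, 1, 1))
  expect_equal(res$lrs, 4 * log(5), tolerance = 1e-12)  # SS0 = 5, SS1 = 1
  expect_equal(res$additive, 2)
  expect_false(res$skipped)
})

test_that("marker_lrs equals the likelihood-ratio oracle on random instances", {
  set.seed(14)
  for (i in 1:100) {
    n <- sample(6:30, 1)
    g <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    y <- rnorm(n)
    expect_lt(abs(marker_lrs(y, g)$lrs - oracle_lrs(y, g)), 1e-9)
  }
})

test_that("marker_lrs handles degenerate inputs per contract", {
  expect_equal(marker_lrs(rep(2, 6), rep(0:1, 3))$lrs, 0)
  expect_true(marker_lrs(rnorm(6), rep(1, 6))$skipped)
  expect_warning(res <- marker_lrs(c(1, 1, 2, 2), c(0, 0, 1, 1)), "clamped")
  expect_equal(res$lrs, 1e6)
  expect_error(marker_lrs(c(1, 2), c(0, 1)), "at least 4")
})

test_that("LRS is location invariant and scale invariant", {
  set.seed(15)
  y <- rnorm(12); g <- rep(0:1, 6)
  base <- marker_lrs(y, g)$lrs
  expect_equal(marker_lrs(y + 100, g)$lrs, base, tolerance = 1e-9)
  expect_equal(marker_lrs(y * -3.7, g)$lrs, base, tolerance = 1e-9)
})

test_that("genome_scan agrees with per-marker calls and flags monomorphics", {
  g <- tibble::tibble(
    marker = c("m1", "m2", "m3"), chrom = "1", pos_mb = c(1, 2, 3),
    A = c(0L, 1L, 1L), B = c(1L, 0L, 1L), C = c(0L, 1L, 1L),
    D = c(1L, 0L, 1L), E = c(0L, 0L, 1L), F = c(1L, 1L, 1L))
  y <- setNames(rnorm(6, 8), LETTERS[1:6])
  scan <- genome_scan(y, g)
  expect_s3_class(scan, "qtl_scan")
  expect_true(scan$skipped[3])  # m3 monomorphic
  for (m in c("m1", "m2")) {
    expect_equal(scan$lrs[scan$marker == m],
                 marker_lrs(y, geno_matrix(g)[, m])$lrs, tolerance = 1e-9)
  }
  g_mono <- g
  g_mono[LETTERS[1:6]] <- lapply(LETTERS[1:6], function(...) rep(1L, 3))
  expect_error(genome_scan(y, g_mono), "no polymorphic")
})

test_that("single-marker genome reduces to marker_lrs", {
  g <- tibble::tibble(marker = "m1", chrom = "1", pos_mb = 1,
                      A = 0L, B = 1L, C = 0L, D = 1L)
  y <- c(A = 1, B = 5, C = 2, D = 6)
  scan <- genome_scan(y, g)
  expect_equal(nrow(scan), 1)
  expect_equal(scan$lrs, marker_lrs(y, c(0, 1, 0, 1))$lrs)
})

test_that("permutation thresholds are ordered, deterministic and seeded", {
  cfg <- sim_config(n_strains = 30, n_chrom = 3, markers_per_chrom = 8,
                    seed = 16)
  g <- simulate_ri_genotypes(cfg)
  y <- rnorm(30)
  th1 <- permutation_thresholds(y, g, n_perm = 200, seed = 4)
  th2 <- permutation_thresholds(y, g, n_perm = 200, seed = 4)
  expect_identical(th1, th2)
  expect_gte(th1$significant_lrs, th1$suggestive_lrs)
  th3 <- permutation_thresholds(y, g, n_perm = 200, seed = 5)
  expect_false(identical(th1$significant_lrs, th3$significant_lrs))
  expect_warning(permutation_thresholds(y, g, n_perm = 50, seed = 1),
                 "unstable")
  expect_error(permutation_thresholds(y, g, n_perm = 200), "seed")
})

test_that("permuted-scan maxima match a brute-force scan of shuffled traits", {
  cfg <- sim_config(n_strains = 20, n_chrom = 2, markers_per_chrom = 5,
                    seed = 17)
  g <- simulate_ri_genotypes(cfg)
  y <- rnorm(20)
  set.seed(8)
  max_direct <- vapply(1:20, function(i) {
    ys <- sample(y)
    max(genome_scan(ys, g)$lrs, na.rm = TRUE)
  }, numeric(1))
  suppressWarnings(th <- permutation_thresholds(y, g, n_perm = 20, seed = 8))
  # same seed stream -> same permutations -> identical quantiles
  expect_equal(th$significant_lrs,
               unname(quantile(max_direct, 0.95, type = 7)), tolerance = 1e-9)
})

test_that("support interval follows the drop-plus-one-flank convention", {
  scan <- tibble::tibble(
    marker = paste0("m", 1:5), chrom = "1",
    pos_mb = c(10, 20, 30, 40, 50),
    lrs = lod_to_lrs(c(0.5, 2, 4, 2, 0.5)),
    additive = 0, skipped = FALSE)
  class(scan) <- c("qtl_scan", class(scan))
  pk <- support_interval(scan, "1")
  expect_equal(pk$peak_pos_mb, 30)
  expect_equal(pk$peak_lod, 4, tolerance = 1e-12)
  expect_equal(c(pk$interval_start_mb, pk$interval_end_mb), c(20, 40))

  # flat profile spans the chromosome
  scan$lrs <- rep(5, 5)
  pk2 <- support_interval(scan, "1")
  expect_equal(c(pk2$interval_start_mb, pk2$interval_end_mb), c(10, 50))
  expect_error(support_interval(scan, "9"), "not present")
})

test_that("LRS/LOD conversion uses 2 ln 10", {
  expect_equal(lrs_to_lod(4.60517), 1, tolerance = 1e-5)
  expect_equal(lod_to_lrs(lrs_to_lod(13.7)), 13.7, tolerance = 1e-12)
})

test_that("cis/trans classification uses the 10 Mb window on the same chromosome", {
  peak_chr11 <- tibble::tibble(chrom = "11", peak_pos_mb = 104.768)
  expect_identical(classify_cis_trans(peak_chr11, "17", 24.728), "trans")
  peak_chr17 <- tibble::tibble(chrom = "17", peak_pos_mb = 24.7)
  expect_identical(classify_cis_trans(peak_chr17, "17", 24.728), "cis")
  far <- tibble::tibble(chrom = "17", peak_pos_mb = 39.8)
  expect_identical(classify_cis_trans(far, "17", 24.8), "trans")
  edge <- tibble::tibble(chrom = "17", peak_pos_mb = 34.8)
  expect_identical(classify_cis_trans(edge, "17", 24.8), "cis")  # inclusive
  expect_error(classify_cis_trans(far, NA, 1), "annotation")
})

test_that("scan tidiers summarize the top marker", {
  cfg <- sim_config(n_strains = 20, n_chrom = 2, markers_per_chrom = 4,
                    seed = 19)
  g <- simulate_ri_genotypes(cfg)
  scan <- genome_scan(rnorm(20), g)
  td <- tidy(scan)
  expect_false(inherits(td, "qtl_scan"))
  gl <- glance(scan)
  expect_equal(gl$max_lrs, max(scan$lrs, na.rm = TRUE))
  expect_equal(gl$n_markers, 8)
})
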