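# End-to-end orchestration: simulate -> normalize -> correlate -> scan ->
# score -> enrich -> infiltrate, from one config, with a provenance
# manifest. Stage outputs are plain TSV/JSON.

#' Pipeline configuration
#'
#' Collects every threshold of the analysis with its standard default:
#' nominal correlation p < 0.05, mean-expression screen gate > 7,
#' candidate expression gate >= 8, FDR 0.05, selection score >= 5, 10 Mb
#' cis window, 1.5-LOD support drop, and permutation settings. The seed
#' is mandatory whenever any stochastic stage runs (`n_perm > 0` or
#' simulation).
#'
#' @param sim A [sim_config()] for the synthetic study.
#' @param regulator Planted-regulator settings for [simulate_focal_study()]:
#'   `marker`, `beta_cis`, `gamma`, `n_interval_decoys`.
#' @param p_threshold,min_mean,r_threshold Correlation screen settings.
#' @param expression_gate,select_threshold Candidate scoring settings.
#' @param fdr FDR for differential expression/enrichment.
#' @param window_mb,drop_lod eQTL interval settings.
#' @param n_perm,alpha_sig,alpha_sug Permutation threshold settings.
#' @param seed Integer seed (defaults to the simulation seed).
#' @param out_dir Output directory for [run_pipeline()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            regulator = list(marker = "c13_m13",
                                             beta_cis = 2, gamma = 1,
                                             n_interval_decoys = 10),
                            p_threshold = 0.05, min_mean = 7,
                            r_threshold = 0, expression_gate = 8,
                            fdr = 0.05, select_threshold = 5,
                            window_mb = 10, drop_lod = 1.5,
                            n_perm = 1000, alpha_sig = 0.05,
                            alpha_sug = 0.63, seed = sim$seed,
                            out_dir = tempfile("sysgen_run_")) {
  cfg <- list(sim = sim, regulator = regulator, p_threshold = p_threshold,
              min_mean = min_mean, r_threshold = r_threshold,
              expression_gate = expression_gate, fdr = fdr,
              select_threshold = select_threshold, window_mb = window_mb,
              drop_lod = drop_lod, n_perm = n_perm, alpha_sig = alpha_sig,
              alpha_sug = alpha_sug, seed = seed, out_dir = out_dir)
  if (is.null(cfg$seed) && n_perm > 0) {
    abort("validation error: seed is mandatory when n_perm > 0")
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys map to [pipeline_config()] arguments; the optional
#' `sim` and `regulator` maps override [sim_config()] fields and the
#' planted-regulator settings.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  sim_args <- raw$sim %||% list()
  args <- raw[setdiff(names(raw), "sim")]
  args$sim <- do.call(sim_config, sim_args)
  do.call(pipeline_config, args)
}

#' Simulate a focal-gene study with one planted upstream regulator
#'
#' Builds the recovery scenario the pipeline is designed to solve: a
#' regulator gene with a strong cis-eQTL at a chosen marker, a focal gene
#' whose expression loads on the regulator (so the focal gene acquires a
#' trans-eQTL at that marker), decoy genes inside the eventual support
#' interval, background genes, and evidence tables flagging the
#' regulator's coding variant and disease-causal annotation.
#'
#' @param config A [sim_config()].
#' @param regulator List: `marker` (planted locus), `beta_cis` (regulator
#'   cis effect, log2 units), `gamma` (focal-gene loading on the
#'   regulator), `n_interval_decoys` (genes placed within 10 Mb of the
#'   marker).
#' @return List: `genotypes`, `expression`, `variant_table`,
#'   `functional_table`, `truth` (focal gene, regulator, planted marker).
#' @export
simulate_focal_study <- function(config,
                                 regulator = list(marker = "c13_m13",
                                                  beta_cis = 2, gamma = 1,
                                                  n_interval_decoys = 10)) {
  genotypes <- simulate_ri_genotypes(config)
  set.seed(config$seed + 505L)
  G <- geno_matrix(genotypes)
  if (!regulator$marker %in% colnames(G)) {
    abort(sprintf("config error: planted marker '%s' not in genotypes",
                  regulator$marker))
  }
  n <- nrow(G)
  strains <- rownames(G)
  mrow <- genotypes[genotypes$marker == regulator$marker, ]
  g <- G[, regulator$marker]
  reg <- (8 - regulator$beta_cis / 2) + regulator$beta_cis * g +
    rnorm(n, 0, config$residual_sd)
  focal_chrom <- as.character((as.integer(mrow$chrom) %% config$n_chrom) + 1L)
  focal <- 8 + regulator$gamma * (reg - mean(reg)) + rnorm(n, 0, config$residual_sd)
  nd <- regulator$n_interval_decoys
  decoys <- matrix(rnorm(nd * n, 0, config$residual_sd), nrow = nd) +
    rnorm(nd, 8, 0.5)
  chrom_len <- max(genotypes$pos_mb[genotypes$chrom == mrow$chrom])
  decoy_pos <- round(runif(nd, max(1, mrow$pos_mb - 10),
                           min(chrom_len, mrow$pos_mb + 10)), 3)
  nb <- config$n_null_genes
  bg <- matrix(rnorm(nb * n, 0, config$residual_sd), nrow = nb) +
    rnorm(nb, 8, 0.5)
  vals <- rbind(focal, reg, decoys, bg)
  colnames(vals) <- strains
  bg_place <- place_genes(nb, genotypes)
  expression <- dplyr::bind_cols(
    tibble::tibble(
      gene_id = c("Focal", "Reg1", sprintf("decoy_g%02d", seq_len(nd)),
                  sprintf("null_g%04d", seq_len(nb))),
      chrom = c(focal_chrom, mrow$chrom, rep(mrow$chrom, nd), bg_place$chrom),
      pos_mb = c(config$spacing_mb * ceiling(config$markers_per_chrom / 2),
                 mrow$pos_mb + 0.5, decoy_pos, bg_place$pos_mb)),
    tibble::as_tibble(vals))
  validate_expression(expression)
  list(genotypes = genotypes, expression = expression,
       variant_table = tibble::tibble(gene_id = "Reg1",
                                      consequence = "nonsynonymous"),
       functional_table = tibble::tibble(gene_id = "Reg1",
                                         source = "RGD_causal"),
       truth = list(focal = "Focal", regulator = "Reg1",
                    marker = regulator$marker))
}

# genome-wide top peak of one gene's own scan, for cis classification
top_peak <- function(y, genotypes) {
  scan <- genome_scan(y, genotypes)
  ok <- !scan$skipped
  i <- which(ok)[which.max(scan$lrs[ok])]
  tibble::tibble(peak_chrom = scan$chrom[i], peak_pos_mb = scan$pos_mb[i])
}

#' Map, shortlist and score candidate regulators of a focal gene
#'
#' The analytical core of the pipeline: scans the focal gene's expression
#' genome-wide, shortlists every chromosome whose peak LRS reaches the
#' suggestive permutation threshold (falling back to the genome-wide top
#' chromosome when none does), takes the 1.5-LOD support interval around
#' each shortlisted peak, and pools the annotated genes inside the
#' trans-acting intervals — upstream-regulator candidates sit at loci
#' distant from the focal gene, so intervals classified cis for the focal
#' gene are set aside unless they are all there is. Each pooled gene's
#' evidence is then derived (own eQTL scan for cis-regulation, the focal
#' correlation screen, variant and functional tables), scored and
#' ranked.
#'
#' @param genotypes Genotype tibble.
#' @param expression Annotated expression tibble containing the focal
#'   gene.
#' @param focal_gene Focal gene id.
#' @param variant_table,functional_table Evidence inputs (see
#'   [build_evidence()]).
#' @param config A [pipeline_config()] supplying thresholds; permutation
#'   thresholds are computed only when `config$n_perm > 0`.
#' @return List: `scan`, `thresholds` (or `NULL`), `peaks` (one row per
#'   shortlisted interval with its cis/trans label for the focal gene),
#'   `interval_genes`, `evidence`, `scores`, `candidates`.
#' @export
rank_focal_candidates <- function(genotypes, expression, focal_gene,
                                  variant_table = NULL,
                                  functional_table = NULL,
                                  config = pipeline_config()) {
  M <- expr_matrix(expression)
  if (!focal_gene %in% rownames(M)) {
    abort(sprintf("focal gene '%s' not in expression matrix", focal_gene))
  }
  y <- M[focal_gene, ]
  scan <- genome_scan(y, genotypes)
  thresholds <- NULL
  if (config$n_perm > 0) {
    thresholds <- permutation_thresholds(
      y, genotypes, n_perm = config$n_perm, alpha_sig = config$alpha_sig,
      alpha_sug = config$alpha_sug, seed = config$seed)
  }
  ok <- !scan$skipped
  focal_ann <- expression[expression$gene_id == focal_gene, ]
  all_peaks <- purrr::map(unique(scan$chrom[ok]), function(ch) {
    pk <- support_interval(scan, ch, drop_lod = config$drop_lod)
    pk$regulation <- classify_cis_trans(pk, focal_ann$chrom,
                                        focal_ann$pos_mb, config$window_mb)
    pk
  }) |> purrr::list_rbind()
  # regulator hunting follows the trans loci: keep the two highest
  # trans-acting peaks plus any further ones above the suggestive
  # threshold; a purely cis architecture falls back to the top peak
  trans_all <- all_peaks[all_peaks$regulation == "trans", , drop = FALSE]
  if (nrow(trans_all) > 0) {
    trans_all <- trans_all[order(-trans_all$peak_lrs), , drop = FALSE]
    keep <- seq_len(nrow(trans_all)) <= 2
    if (!is.null(thresholds)) {
      keep <- keep | trans_all$peak_lrs >= thresholds$suggestive_lrs
    }
    trans_peaks <- trans_all[keep, , drop = FALSE]
  } else {
    trans_peaks <- all_peaks[which.max(all_peaks$peak_lrs), , drop = FALSE]
  }
  peaks <- trans_peaks
  in_interval <- purrr::pmap(trans_peaks, function(chrom, interval_start_mb,
                                                   interval_end_mb, ...) {
    which(!is.na(expression$chrom) & expression$chrom == chrom &
            expression$pos_mb >= interval_start_mb &
            expression$pos_mb <= interval_end_mb &
            expression$gene_id != focal_gene)
  })
  interval_genes <- expression$gene_id[sort(unique(unlist(in_interval)))]
  corr <- correlate_focal_gene(expression, focal_gene,
                               p_threshold = config$p_threshold,
                               min_mean = config$min_mean,
                               r_threshold = config$r_threshold)
  gene_peaks <- purrr::map(interval_genes, function(g) {
    dplyr::bind_cols(tibble::tibble(gene_id = g),
                     top_peak(M[g, ], genotypes))
  }) |> purrr::list_rbind()
  evidence <- build_evidence(
    interval_genes, expression, variant_table = variant_table,
    gene_peaks = gene_peaks, focal_correlations = corr,
    functional_table = functional_table,
    p_threshold = config$p_threshold, window_mb = config$window_mb)
  weights <- scoring_weights(expression_gate = config$expression_gate,
                             select_threshold = config$select_threshold)
  scores <- score_candidates(evidence, weights)
  candidates <- select_candidates(scores, threshold = config$select_threshold)
  list(scan = scan, thresholds = thresholds, peaks = peaks,
       interval_genes = interval_genes, correlations = corr,
       evidence = evidence, scores = scores, candidates = candidates)
}

write_stage <- function(files, manifest, stage) {
  manifest$stages[[stage]] <- files
  manifest
}

#' Run the full pipeline from one configuration
#'
#' Executes the seven stages in order on a simulated study — simulate,
#' normalize (2Z+8), correlate (focal screen), scan (eQTL mapping with
#' permutation thresholds and support interval), score (candidate
#' prioritization), enrich (over-representation of the screen hits
#' against chromosome gene sets), infiltrate (cohort ssGSEA +
#' differential infiltration) — writing per-stage TSV/JSON outputs and a
#' provenance manifest with parameter echo, seed and md5 checksums.
#' Rerunning with the same config reproduces byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly, with the in-memory stage results
#'   attached as attribute `results`.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$seed)) abort("validation error: config has no seed")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  manifest <- list(stages = list(),
                   params = config[setdiff(names(config), c("sim", "regulator"))],
                   seed = config$seed)

  # 1: simulate
  study <- simulate_focal_study(config$sim, config$regulator)
  cohort <- simulate_cohort(config$sim)
  traits <- simulate_traits(
    study$expression,
    utils::modifyList(config$sim, list(trait_loadings = list(
      heart_trait = list(weights = c(Focal = 1), noise_sd = 1)))))
  write_genotypes(study$genotypes, out("genotypes.tsv"))
  write_genotypes(study$genotypes, out("genotypes.geno"), dialect = "geno")
  write_results(study$expression, out("expression.tsv"))
  write_results(traits, out("traits.tsv"))
  write_results(cohort$expression, out("cohort.tsv"))
  jsonlite::write_json(study$truth, out("truth.json"), auto_unbox = TRUE)
  manifest <- write_stage(c("genotypes.tsv", "genotypes.geno",
                            "expression.tsv", "traits.tsv", "cohort.tsv",
                            "truth.json"), manifest, "simulate")

  # 2: normalize
  normalized <- normalize_2z8(study$expression)
  write_results(normalized, out("normalized.tsv"))
  manifest <- write_stage("normalized.tsv", manifest, "normalize")

  # 3: correlate
  corr <- correlate_focal_gene(normalized, study$truth$focal,
                               p_threshold = config$p_threshold,
                               min_mean = config$min_mean,
                               r_threshold = config$r_threshold)
  write_results(corr, out("correlations.tsv"))
  manifest <- write_stage("correlations.tsv", manifest, "correlate")

  # 4-5: scan and score (on the unnormalized scale; LRS is affine-invariant)
  res <- rank_focal_candidates(
    study$genotypes, study$expression, study$truth$focal,
    variant_table = study$variant_table,
    functional_table = study$functional_table, config = config)
  write_results(tidy(res$scan), out("scan.tsv"))
  peaks <- tibble::as_tibble(res$peaks)
  if (!is.null(res$thresholds)) {
    peaks <- dplyr::bind_cols(
      peaks, res$thresholds[rep(1, nrow(peaks)), c("significant_lrs", "suggestive_lrs")])
  }
  jsonlite::write_json(peaks, out("peaks.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  manifest <- write_stage(c("scan.tsv", "peaks.json"), manifest, "scan")
  write_results(tibble::as_tibble(res$scores), out("scores.tsv"))
  write_results(tibble::as_tibble(res$candidates), out("candidates.tsv"))
  manifest <- write_stage(c("scores.tsv", "candidates.tsv"), manifest, "score")

  # 6: enrichment of screen hits against chromosome gene sets
  universe <- study$expression$gene_id
  chrom_sets <- study$expression |>
    dplyr::filter(!is.na(.data$chrom)) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(genes = list(.data$gene_id), .groups = "drop") |>
    dplyr::transmute(set = paste0("chr", .data$chrom),
                     description = paste("genes on chromosome", .data$chrom),
                     genes = .data$genes)
  query <- corr$gene_id[corr$passes_filter]
  enr <- enrich_collection(query, chrom_sets, universe,
                           fdr_threshold = config$fdr)
  write_results(tibble::as_tibble(enr), out("enrichment.tsv"))
  manifest <- write_stage("enrichment.tsv", manifest, "enrich")

  # 7: infiltration on the cohort
  scores_inf <- infiltration_matrix(cohort$expression, cohort$signatures,
                                    groups = cohort$groups)
  dinf <- differential_infiltration(scores_inf)
  ginf <- correlate_genes_with_infiltration(
    cohort$expression, scores_inf,
    gene_list = cohort$signatures$genes[[1]][1])
  write_results(tibble::as_tibble(scores_inf), out("infiltration.tsv"))
  write_results(dinf, out("differential_infiltration.tsv"))
  write_results(ginf, out("gene_infiltration_correlation.tsv"))
  manifest <- write_stage(c("infiltration.tsv",
                            "differential_infiltration.tsv",
                            "gene_infiltration_correlation.tsv"),
                          manifest, "infiltrate")

  files <- unlist(manifest$stages, use.names = FALSE)
  manifest$checksums <- as.list(tools::md5sum(file.path(config$out_dir, files)))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  results <- list(study = study, cohort = cohort, correlations = corr,
                  analysis = res, enrichment = enr,
                  infiltration = scores_inf,
                  differential_infiltration = dinf)
  attr(manifest, "results") <- results
  invisible(manifest)
}
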