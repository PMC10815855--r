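# Synthetic study generator: recombinant-inbred genotypes under sib-mating
# map expansion, expression with planted cis/trans eQTLs and a correlated
# gene block, linear trait panels, and a case/control cohort mixed from
# cell-type signature profiles.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generators. Defaults describe a
#' BXD-like study: 40 strains typed at 500 markers (20 chromosomes x 25
#' markers, 5 cM / 5 Mb spacing), one planted trans-eQTL with additive
#' effect 1 on the log2 scale against residual noise of sd 1, a block of 50
#' genes exchangeably correlated at rho = 0.6 plus 500 independent null
#' genes, and a 15 + 15 case/control cohort mixed from 5 cell-type
#' signatures with a 0.2 case shift in the first cell type's proportion.
#'
#' @param n_strains Number of RI strains.
#' @param n_chrom,markers_per_chrom,spacing_cm,spacing_mb Marker map:
#'   chromosomes, markers per chromosome, inter-marker genetic (cM) and
#'   physical (Mb) spacing.
#' @param planted_eqtls Tibble with columns `gene`, `marker`, `beta`
#'   (additive effect, log2 units) and `type` (`"cis"` places the gene next
#'   to its marker, `"trans"` on another chromosome).
#' @param residual_sd Residual sd of expression noise (log2 units).
#' @param n_null_genes Independent background genes.
#' @param block_size,block_rho Size and exchangeable correlation of the
#'   correlated background block (single-factor construction).
#' @param trait_loadings Named list; each element is
#'   `list(weights = c(gene = w, ...), noise_sd = s)` defining a trait as a
#'   linear combination of gene expression plus Gaussian noise.
#' @param cohort List of cohort settings: `n_case`, `n_control`,
#'   `n_cell_types`, `genes_per_signature`, `n_background_genes`,
#'   `amplitude` (signature elevation at proportion 1), `baseline`,
#'   `noise_sd`, `concentration` (Dirichlet concentration of per-sample
#'   mixing proportions), `case_shift` (added to the shifted cell type's
#'   mean proportion in cases) and `shifted_cell` (index). Optional
#'   `control_props` / `case_props` override the mean mixing vectors; they
#'   must each sum to 1.
#' @param seed Integer seed; every generator derives its own stream from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_strains = 40,
                       n_chrom = 20,
                       markers_per_chrom = 25,
                       spacing_cm = 5,
                       spacing_mb = 5,
                       planted_eqtls = tibble::tibble(
                         gene = "Tgt1", marker = "c13_m13",
                         beta = 1, type = "trans"),
                       residual_sd = 1,
                       n_null_genes = 500,
                       block_size = 50,
                       block_rho = 0.6,
                       trait_loadings = list(
                         heart_trait = list(weights = c(Tgt1 = 1), noise_sd = 1)),
                       cohort = list(),
                       seed = 1) {
  cohort_defaults <- list(
    n_case = 15, n_control = 15, n_cell_types = 5,
    genes_per_signature = 30, n_background_genes = 350,
    amplitude = 4, baseline = 6, noise_sd = 0.5,
    concentration = 25, case_shift = 0.2, shifted_cell = 1L)
  cohort <- utils::modifyList(cohort_defaults, cohort)
  cfg <- list(
    n_strains = n_strains, n_chrom = n_chrom,
    markers_per_chrom = markers_per_chrom,
    spacing_cm = spacing_cm, spacing_mb = spacing_mb,
    planted_eqtls = planted_eqtls, residual_sd = residual_sd,
    n_null_genes = n_null_genes, block_size = block_size,
    block_rho = block_rho, trait_loadings = trait_loadings,
    cohort = cohort, seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_strains < 1) abort("config error: need at least one strain")
  if (cfg$n_chrom < 1 || cfg$markers_per_chrom < 1) {
    abort("config error: marker map must be non-empty")
  }
  if (!is.null(cfg$planted_eqtls) && nrow(cfg$planted_eqtls) > 0 &&
      any(!is.finite(cfg$planted_eqtls$beta))) {
    abort("config error: planted effect sizes must be finite")
  }
  if (cfg$residual_sd <= 0) abort("config error: residual_sd must be positive")
  if (cfg$block_rho < 0 || cfg$block_rho >= 1) {
    abort("config error: block correlation must satisfy 0 <= rho < 1")
  }
  for (nm in c("control_props", "case_props")) {
    p <- cfg$cohort[[nm]]
    if (!is.null(p) && abs(sum(p) - 1) > 1e-8) {
      abort(sprintf("config error: %s must sum to 1", nm))
    }
  }
  if (is.null(cfg$seed)) abort("config error: seed is mandatory")
  invisible(cfg)
}

# Haldane map function and RI (sib-mating) map expansion
haldane_r <- function(d_cm) (1 - exp(-2 * d_cm / 100)) / 2

ri_flip_prob <- function(d_cm) {
  r <- haldane_r(d_cm)
  4 * r / (1 + 6 * r)
}

#' Simulate recombinant-inbred genotypes
#'
#' Per strain and chromosome, the first marker is drawn 0/1 with
#' probability 1/2; each subsequent marker flips relative to its neighbour
#' with probability `R = 4r / (1 + 6r)` (sib-mating RI map expansion),
#' where `r` is the Haldane recombination fraction
#' `r = (1 - exp(-2 d / 100)) / 2` for inter-marker distance `d` cM.
#' Chromosomes and strains are independent.
#'
#' @param config A [sim_config()].
#' @return A validated genotype tibble.
#' @export
simulate_ri_genotypes <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 101L)
  n <- config$n_strains
  strains <- sprintf("BXD%03d", seq_len(n))
  flip_p <- ri_flip_prob(config$spacing_cm)
  chroms <- purrr::map(seq_len(config$n_chrom), function(ch) {
    m <- config$markers_per_chrom
    first <- rbinom(n, 1L, 0.5)
    if (m > 1) {
      flips <- matrix(rbinom(n * (m - 1L), 1L, flip_p), nrow = n)
      steps <- cbind(first, flips)
      codes <- t(apply(steps, 1, cumsum)) %% 2L
    } else {
      codes <- matrix(first, ncol = 1)
    }
    codes <- t(codes)  # markers x strains
    colnames(codes) <- strains
    dplyr::bind_cols(
      tibble::tibble(
        marker = sprintf("c%d_m%02d", ch, seq_len(m)),
        chrom = as.character(ch),
        pos_mb = config$spacing_mb * seq_len(m),
        pos_cm = config$spacing_cm * seq_len(m)),
      tibble::as_tibble(codes))
  })
  out <- purrr::list_rbind(chroms)
  out <- dplyr::mutate(out, dplyr::across(dplyr::all_of(strains), as.integer))
  validate_genotypes(out)
  out
}

# uniform gene placement on the genotype map
place_genes <- function(n, genotypes) {
  lens <- dplyr::summarise(
    dplyr::group_by(genotypes, .data$chrom),
    len = max(.data$pos_mb), .groups = "drop")
  idx <- sample.int(nrow(lens), n, replace = TRUE)
  tibble::tibble(
    chrom = lens$chrom[idx],
    pos_mb = round(runif(n, 1, lens$len[idx]), 3))
}

#' Simulate expression with planted eQTLs
#'
#' Planted target genes follow `baseline + beta * code + e`,
#' `e ~ N(0, residual_sd)`, with the baseline offset so the gene mean sits
#' near 8 (the 2Z+8 scale convention). Background genes come as one block
#' with exchangeable correlation `block_rho` (single shared factor) plus
#' independent null genes; per-gene baselines are drawn near 8. Gene
#' annotation places cis targets within 10 Mb of their marker and trans
#' targets on a different chromosome.
#'
#' @param genotypes Genotype tibble holding every planted marker.
#' @param config A [sim_config()].
#' @return An expression tibble with `chrom`/`pos_mb` annotation.
#' @export
simulate_expression <- function(genotypes, config) {
  validate_sim_config(config)
  set.seed(config$seed + 202L)
  G <- geno_matrix(genotypes)
  strains <- rownames(G)
  n <- length(strains)
  eqtls <- config$planted_eqtls
  if (!is.null(eqtls) && nrow(eqtls) > 0) {
    missing <- setdiff(eqtls$marker, colnames(G))
    if (length(missing) > 0) {
      abort(sprintf("config error: planted marker(s) not in genotypes: %s",
                    paste(missing, collapse = ", ")))
    }
  }
  rows <- list()
  if (!is.null(eqtls) && nrow(eqtls) > 0) {
    minfo <- genotypes[match(eqtls$marker, genotypes$marker), c("chrom", "pos_mb")]
    planted_vals <- purrr::map(seq_len(nrow(eqtls)), function(i) {
      g <- G[, eqtls$marker[i]]
      (8 - eqtls$beta[i] / 2) + eqtls$beta[i] * g + rnorm(n, 0, config$residual_sd)
    })
    ann <- purrr::map(seq_len(nrow(eqtls)), function(i) {
      if (eqtls$type[i] == "cis") {
        tibble::tibble(chrom = minfo$chrom[i], pos_mb = minfo$pos_mb[i] + 0.5)
      } else {
        other <- as.character((as.integer(minfo$chrom[i]) %% config$n_chrom) + 1L)
        tibble::tibble(chrom = other,
                       pos_mb = config$spacing_mb * ceiling(config$markers_per_chrom / 2))
      }
    }) |> purrr::list_rbind()
    vals <- do.call(rbind, planted_vals)
    colnames(vals) <- strains
    rows$planted <- dplyr::bind_cols(
      tibble::tibble(gene_id = eqtls$gene), ann, tibble::as_tibble(vals))
  }
  if (config$block_size > 0) {
    f <- rnorm(n)
    base <- rnorm(config$block_size, 8, 0.5)
    rho <- config$block_rho
    vals <- vapply(seq_len(config$block_size), function(i) {
      base[i] + config$residual_sd *
        (sqrt(rho) * f + sqrt(1 - rho) * rnorm(n))
    }, numeric(n))
    vals <- t(vals)
    colnames(vals) <- strains
    rows$block <- dplyr::bind_cols(
      tibble::tibble(gene_id = sprintf("blk_g%03d", seq_len(config$block_size))),
      place_genes(config$block_size, genotypes),
      tibble::as_tibble(vals))
  }
  if (config$n_null_genes > 0) {
    base <- rnorm(config$n_null_genes, 8, 0.5)
    vals <- base + matrix(rnorm(config$n_null_genes * n, 0, config$residual_sd),
                          nrow = config$n_null_genes)
    colnames(vals) <- strains
    rows$null <- dplyr::bind_cols(
      tibble::tibble(gene_id = sprintf("null_g%04d", seq_len(config$n_null_genes))),
      place_genes(config$n_null_genes, genotypes),
      tibble::as_tibble(vals))
  }
  out <- purrr::list_rbind(unname(rows))
  validate_expression(out)
  out
}

#' Simulate traits as linear loadings on gene expression
#'
#' Each configured trait is `sum_g w_g * expr_g + N(0, noise_sd)` across
#' strains, so the sign of a planted loading is recoverable by
#' correlation.
#'
#' @param expression Expression tibble containing every loaded gene.
#' @param config A [sim_config()].
#' @return A trait tibble (`strain` column plus one column per trait).
#' @export
simulate_traits <- function(expression, config) {
  validate_sim_config(config)
  set.seed(config$seed + 303L)
  M <- expr_matrix(expression)
  samples <- colnames(M)
  out <- tibble::tibble(strain = samples)
  for (trait in names(config$trait_loadings)) {
    spec <- config$trait_loadings[[trait]]
    genes <- names(spec$weights)
    missing <- setdiff(genes, rownames(M))
    if (length(missing) > 0) {
      abort(sprintf("config error: trait '%s' loads on unknown gene(s): %s",
                    trait, paste(missing, collapse = ", ")))
    }
    vals <- as.numeric(spec$weights %*% M[genes, , drop = FALSE]) +
      rnorm(length(samples), 0, spec$noise_sd)
    out[[trait]] <- vals
  }
  out
}

# Dirichlet draws via normalized gammas
rdirichlet_rows <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}

#' Simulate a case/control cohort from cell-type signature mixtures
#'
#' Each sample's expression is a proportion-weighted mixture of per-cell-type
#' signature profiles plus Gaussian noise: a signature gene of cell type `c`
#' takes value `baseline + amplitude * p_c` in a sample with mixing weight
#' `p_c`, so signature genes rise in rank with their cell type's abundance.
#' Per-sample proportions are Dirichlet around group means; cases shift the
#' configured cell type's mean proportion up by `case_shift`.
#'
#' @param config A [sim_config()]; see the `cohort` element.
#' @return A list: `expression` (genes x samples tibble), `groups`
#'   (`sample`, `group`), `proportions` (true per-sample mixing weights)
#'   and `signatures` (a GMT-style tibble of the cell-type marker sets).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed + 404L)
  ch <- config$cohort
  k <- ch$n_cell_types
  cells <- sprintf("CT%d", seq_len(k))
  control_mean <- ch$control_props %||% rep(1 / k, k)
  case_mean <- ch$case_props %||% {
    p <- rep(NA_real_, k)
    p[ch$shifted_cell] <- control_mean[ch$shifted_cell] + ch$case_shift
    p[-ch$shifted_cell] <- (1 - p[ch$shifted_cell]) / (k - 1)
    p
  }
  for (p in list(control_mean, case_mean)) {
    if (abs(sum(p) - 1) > 1e-8) abort("config error: mixing proportions must sum to 1")
  }
  props <- rbind(
    rdirichlet_rows(ch$n_case, case_mean * ch$concentration),
    rdirichlet_rows(ch$n_control, control_mean * ch$concentration))
  colnames(props) <- cells
  samples <- c(sprintf("case%02d", seq_len(ch$n_case)),
               sprintf("ctrl%02d", seq_len(ch$n_control)))
  groups <- tibble::tibble(
    sample = samples,
    group = rep(c("case", "control"), c(ch$n_case, ch$n_control)))

  sig_genes <- purrr::map(seq_len(k), function(c_i) {
    sprintf("%s_g%02d", cells[c_i], seq_len(ch$genes_per_signature))
  })
  bg_genes <- sprintf("bg_g%04d", seq_len(ch$n_background_genes))
  genes <- c(unlist(sig_genes), bg_genes)
  n_samp <- length(samples)
  # signature part: baseline + amplitude * p_c for genes of cell type c
  sig_block <- purrr::map(seq_len(k), function(c_i) {
    matrix(rep(ch$baseline + ch$amplitude * props[, c_i],
               each = ch$genes_per_signature),
           nrow = ch$genes_per_signature)
  })
  bg_base <- runif(ch$n_background_genes, 4, 8)
  bg_block <- matrix(rep(bg_base, times = n_samp), ncol = n_samp)
  vals <- rbind(do.call(rbind, sig_block), bg_block)
  vals <- vals + matrix(rnorm(length(vals), 0, ch$noise_sd), nrow = nrow(vals))
  colnames(vals) <- samples
  expression <- dplyr::bind_cols(tibble::tibble(gene_id = genes),
                                 tibble::as_tibble(vals))
  signatures <- tibble::tibble(
    set = cells,
    description = sprintf("synthetic signature of cell type %s", cells),
    genes = sig_genes)
  list(expression = expression, groups = groups,
       proportions = dplyr::bind_cols(tibble::tibble(sample = samples),
                                      tibble::as_tibble(props)),
       signatures = signatures)
}
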