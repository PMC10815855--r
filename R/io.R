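# Readers and writers for the external formats: genotype TSV and
# GeneNetwork-style .geno, expression/trait TSV matrices, GMT gene sets,
# and TSV/JSON result tables.

ALLELE_MAP <- c(B = 0L, b = 0L, "0" = 0L, D = 1L, d = 1L, "1" = 1L)

decode_alleles <- function(values, marker, strains) {
  out <- ALLELE_MAP[as.character(values)]
  if (anyNA(out)) {
    j <- which(is.na(out))[1]
    sym <- as.character(values)[j]
    msg <- sprintf("unknown allele symbol '%s' at marker '%s', strain '%s'",
                   sym, marker, strains[j])
    if (sym %in% c("H", "h")) {
      msg <- paste0(msg, ": heterozygote not supported in an RI panel")
    }
    abort(msg)
  }
  unname(out)
}

#' Read a genotype table
#'
#' Reads either a plain TSV (columns `marker`, `chrom`, `pos_mb`, optional
#' `pos_cm`, then one column per strain) or a GeneNetwork-like `.geno`
#' layout (`Chr`, `Locus`, `cM`, `Mb`, then strain columns; `#` comment and
#' `@` metadata lines ignored). Allele codes may be letters (`B`/`D`) or
#' numerals (`0`/`1`); heterozygote codes are rejected because recombinant
#' inbred strains are homozygous at every locus.
#'
#' @param path File path.
#' @param dialect `"auto"` (default, decided from the header), `"tsv"` or
#'   `"geno"`.
#' @return A validated genotype tibble in map order.
#' @export
read_genotypes <- function(path, dialect = c("auto", "tsv", "geno")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("genotype file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^[#@]", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2) abort("genotype file has no data rows")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (dialect == "auto") {
    dialect <- if (identical(tolower(header[1:2]), c("chr", "locus"))) "geno" else "tsv"
  }
  rows <- strsplit(lines[-1], "\t", fixed = TRUE)
  if (dialect == "geno") {
    n_meta <- 4L
    strains <- header[-(1:n_meta)]
    parse_row <- function(f, i) {
      if (length(f) != n_meta + length(strains)) {
        abort(sprintf("line %d: expected %d fields, found %d",
                      i + 1L, n_meta + length(strains), length(f)))
      }
      tibble::tibble_row(
        marker = f[2], chrom = f[1],
        pos_mb = as.numeric(f[4]), pos_cm = as.numeric(f[3]))
    }
  } else {
    meta_cols <- intersect(c("marker", "chrom", "pos_mb", "pos_cm"), header)
    if (!all(c("marker", "chrom", "pos_mb") %in% meta_cols)) {
      abort("TSV genotype header must contain marker, chrom, pos_mb")
    }
    strains <- setdiff(header, meta_cols)
    parse_row <- function(f, i) {
      if (length(f) != length(header)) {
        abort(sprintf("line %d: expected %d fields, found %d",
                      i + 1L, length(header), length(f)))
      }
      named <- setNames(f[match(meta_cols, header)], meta_cols)
      tibble::tibble_row(
        marker = named[["marker"]], chrom = named[["chrom"]],
        pos_mb = as.numeric(named[["pos_mb"]]),
        pos_cm = if ("pos_cm" %in% meta_cols) as.numeric(named[["pos_cm"]]) else NA_real_)
    }
  }
  meta <- purrr::imap(rows, parse_row) |> purrr::list_rbind()
  strain_idx <- if (dialect == "geno") -(1:4) else match(strains, header)
  codes <- purrr::imap(rows, function(f, i) {
    decode_alleles(f[strain_idx], meta$marker[i], strains)
  })
  codes <- do.call(rbind, codes)
  colnames(codes) <- strains
  out <- dplyr::bind_cols(meta, tibble::as_tibble(codes))
  if (all(is.na(out$pos_cm))) out$pos_cm <- NULL
  out <- sort_markers(out)
  validate_genotypes(out)
  out
}

#' Write a genotype table
#'
#' @param genotypes A genotype tibble.
#' @param path Output path.
#' @param dialect `"tsv"` (metadata columns then strains, numeric codes) or
#'   `"geno"` (GeneNetwork-like layout with `B`/`D` letter codes).
#' @return The path, invisibly.
#' @export
write_genotypes <- function(genotypes, path, dialect = c("tsv", "geno")) {
  dialect <- match.arg(dialect)
  validate_genotypes(genotypes)
  strains <- strain_ids(genotypes)
  if (dialect == "tsv") {
    readr::write_tsv(genotypes, path)
  } else {
    codes <- as.matrix(genotypes[, strains, drop = FALSE])
    letters_ <- matrix(c("B", "D")[codes + 1L], nrow = nrow(codes))
    colnames(letters_) <- strains
    out <- dplyr::bind_cols(
      tibble::tibble(
        Chr = genotypes$chrom, Locus = genotypes$marker,
        cM = if ("pos_cm" %in% names(genotypes)) genotypes$pos_cm else genotypes$pos_mb,
        Mb = genotypes$pos_mb),
      tibble::as_tibble(letters_))
    readr::write_tsv(out, path)
  }
  invisible(path)
}

#' Read an expression or trait matrix from TSV
#'
#' Expression files have a `gene_id` column (plus optional `chrom`,
#' `pos_mb` annotation) and one numeric column per sample; trait files have
#' a `strain` column and one numeric column per trait (missing values
#' allowed and kept as `NA`).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(sprintf("expression file not found: %s", path))
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_expression(out)
  out
}

#' @rdname read_expression
#' @export
read_traits <- function(path) {
  if (!file.exists(path)) abort(sprintf("trait file not found: %s", path))
  out <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"strain" %in% names(out)) abort("trait table needs a 'strain' column")
  out
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: one set per line as
#' `name <TAB> description <TAB> member1 <TAB> member2 ...`. Duplicate
#' members within a line are removed with a warning.
#'
#' @param path File path.
#' @return A tibble with columns `set`, `description` and a list-column
#'   `genes`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(sprintf("GMT file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(set = character(), description = character(),
                          genes = list()))
  }
  parsed <- purrr::imap(lines, function(line, i) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      abort(sprintf("GMT line %d: expected at least 3 tab-separated fields, found %d",
                    i, length(f)))
    }
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (anyDuplicated(members)) {
      warn(sprintf("GMT line %d (set '%s'): duplicate members removed", i, f[1]))
      members <- unique(members)
    }
    if (length(members) == 0) abort(sprintf("GMT line %d: set '%s' is empty", i, f[1]))
    tibble::tibble(set = f[1], description = f[2], genes = list(members))
  })
  purrr::list_rbind(parsed)
}

#' Write a gene-set collection in GMT format
#'
#' @param collection Tibble with `set`, `description`, `genes` columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_gmt <- function(collection, path) {
  lines <- purrr::pmap_chr(collection, function(set, description, genes, ...) {
    paste(c(set, description, genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}

# round numeric columns to 6 significant digits for serialization
round_signif <- function(df, digits = 6) {
  dplyr::mutate(df, dplyr::across(dplyr::where(is.numeric), ~ signif(.x, digits)))
}

#' Write a result table to TSV or JSON
#'
#' Serialization is lossless up to 6 significant digits on numeric columns
#' and preserves row order. List-columns (e.g. gene-set members) are
#' collapsed to comma-separated strings in TSV and kept as arrays in JSON.
#'
#' @param table A data frame of results.
#' @param path Output path.
#' @param format `"tsv"` or `"json"` (default taken from the file
#'   extension).
#' @return The path, invisibly.
#' @export
write_results <- function(table, path, format = NULL) {
  format <- format %||% (if (grepl("\\.json$", path)) "json" else "tsv")
  if (!format %in% c("tsv", "json")) abort("format must be 'tsv' or 'json'")
  table <- round_signif(tibble::as_tibble(table))
  if (format == "json") {
    jsonlite::write_json(table, path, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null")
  } else {
    flat <- dplyr::mutate(table, dplyr::across(
      dplyr::where(is.list), ~ purrr::map_chr(.x, paste, collapse = ",")))
    readr::write_tsv(flat, path)
  }
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path File path.
#' @param format `"tsv"` or `"json"`; default from the extension.
#' @return A tibble.
#' @export
read_results <- function(path, format = NULL) {
  format <- format %||% (if (grepl("\\.json$", path)) "json" else "tsv")
  if (format == "json") {
    tibble::as_tibble(jsonlite::fromJSON(path))
  } else {
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  }
}
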