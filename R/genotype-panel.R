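#' Construct a genotype panel
#'
#' A genotype panel couples an individuals-by-SNPs effect-allele dosage
#' matrix (values in `[0, 2]`, `NA` for missing; fractional dosages from
#' imputation are allowed) with per-SNP metadata.  Row names of the dosage
#' matrix are sample ids; columns align with `snp_meta$snp_id`.
#'
#' @param dosage Numeric matrix, individuals x SNPs, with row and column
#'   names.
#' @param snp_meta Data frame with at least `snp_id`, `effect_allele`,
#'   `other_allele`; optionally `chrom`, `pos`, `maf`, `call_rate`,
#'   `imputation_quality`.
#' @return An object of class `genotype_panel`: a list with elements
#'   `dosage`, `snp_meta` (tibble) and `sample_ids`.
#' @export
genotype_panel <- function(dosage, snp_meta) {
  dosage <- as.matrix(dosage)
  snp_meta <- tibble::as_tibble(snp_meta)
  if (ncol(dosage) != nrow(snp_meta)) {
    abort("dosage column count must equal the number of snp_meta rows")
  }
  if (is.null(rownames(dosage))) abort("dosage must carry sample ids as rownames")
  bad <- dosage < 0 | dosage > 2
  if (any(bad, na.rm = TRUE)) abort("dosages must lie in [0, 2] or be NA")
  if (is.null(colnames(dosage))) colnames(dosage) <- snp_meta$snp_id
  if (!"maf" %in% names(snp_meta)) {
    af <- colMeans(dosage, na.rm = TRUE) / 2
    snp_meta$maf <- pmin(af, 1 - af)
  }
  structure(
    list(dosage = dosage, snp_meta = snp_meta, sample_ids = rownames(dosage)),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d samples x %d SNPs (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$dosage)

#' Subset a genotype panel by sample and/or SNP
#'
#' @param x A [genotype_panel].
#' @param samples,snps Character ids or logical/integer indices; `NULL`
#'   keeps everything.
#' @return A [genotype_panel].
#' @export
panel_subset <- function(x, samples = NULL, snps = NULL) {
  stopifnot(inherits(x, "genotype_panel"))
  si <- if (is.null(samples)) seq_len(nrow(x$dosage)) else samples
  if (is.character(si)) si <- match(si, rownames(x$dosage))
  vi <- if (is.null(snps)) seq_len(ncol(x$dosage)) else snps
  if (is.character(vi)) vi <- match(vi, x$snp_meta$snp_id)
  genotype_panel(x$dosage[si, vi, drop = FALSE], x$snp_meta[vi, , drop = FALSE])
}

#' Read and write dosage matrices as TSV
#'
#' The TSV layout is one row per individual, first column `id`, one column
#' per SNP holding the effect-allele dosage.  SNP metadata travels in a
#' sidecar TSV (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#' `maf`).
#'
#' @param panel A [genotype_panel].
#' @param path Dosage TSV path.
#' @param meta_path Sidecar metadata TSV path; defaults to
#'   `<path base>.snps.tsv`.
#' @return `read_dosage_tsv()` returns a [genotype_panel];
#'   `write_dosage_tsv()` returns `path` invisibly.
#' @export
write_dosage_tsv <- function(panel, path,
                             meta_path = paste0(sub("\\.tsv$", "", path),
                                                ".snps.tsv")) {
  stopifnot(inherits(panel, "genotype_panel"))
  tab <- tibble::as_tibble(panel$dosage)
  tab <- dplyr::bind_cols(tibble::tibble(id = panel$sample_ids), tab)
  readr::write_tsv(tab, path)
  readr::write_tsv(panel$snp_meta, meta_path)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path,
                            meta_path = paste0(sub("\\.tsv$", "", path),
                                               ".snps.tsv")) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  meta <- readr::read_tsv(meta_path, show_col_types = FALSE,
                          col_types = readr::cols(
                            snp_id = "c", chrom = "c",
                            effect_allele = "c", other_allele = "c",
                            .default = readr::col_double()
                          ))
  dosage <- as.matrix(tab[, -1, drop = FALSE])
  rownames(dosage) <- tab$id
  genotype_panel(dosage, meta)
}

#' Read a PLINK `.raw`-style dosage table
#'
#' Accepts the additive-recode layout (`FID IID PAT MAT SEX PHENOTYPE`
#' followed by one `SNP_A` column per variant, where the `_A` suffix names
#' the counted allele).
#'
#' @param path Path to the `.raw`-style whitespace-separated table.
#' @return A [genotype_panel]; the counted allele becomes the effect allele
#'   and the other allele is recorded as `"?"` (the `.raw` format does not
#'   carry it).
#' @export
read_dosage_raw <- function(path) {
  tab <- readr::read_table(path, show_col_types = FALSE)
  fixed <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                     names(tab))
  snp_cols <- setdiff(names(tab), fixed)
  parts <- regmatches(snp_cols, regexpr("_[^_]+$", snp_cols))
  snp_id <- sub("_[^_]+$", "", snp_cols)
  effect <- sub("^_", "", parts)
  dosage <- as.matrix(tab[, snp_cols, drop = FALSE])
  rownames(dosage) <- as.character(tab$IID)
  colnames(dosage) <- snp_id
  genotype_panel(dosage, tibble::tibble(
    snp_id = snp_id, chrom = NA_character_, pos = NA_real_,
    effect_allele = effect, other_allele = "?"
  ))
}

#' Write and read dosage genotypes as VCF 4.2 with a `DS` FORMAT field
#'
#' `write_vcf_dosage()` emits a minimal VCF 4.2 whose ALT allele is the
#' panel's effect allele and whose single FORMAT field `DS` holds the
#' effect-allele dosage (missing calls become `.`).  `read_vcf_dosage()`
#' parses such a file through \pkg{VariantAnnotation}.
#'
#' @param panel A [genotype_panel] with `chrom` and `pos` metadata.
#' @param path VCF path (uncompressed text).
#' @return `read_vcf_dosage()` returns a [genotype_panel];
#'   `write_vcf_dosage()` returns `path` invisibly.
#' @export
write_vcf_dosage <- function(panel, path) {
  stopifnot(inherits(panel, "genotype_panel"))
  m <- panel$snp_meta
  if (any(is.na(m$chrom)) || any(is.na(m$pos))) {
    abort("snp_meta must carry chrom and pos to write VCF")
  }
  ds <- t(panel$dosage)  # SNPs x samples
  body <- matrix(format(round(ds, 4), trim = TRUE), nrow(ds), ncol(ds))
  body[is.na(ds)] <- "."
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Effect allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t"),
    paste(m$chrom, as.integer(m$pos), m$snp_id, m$other_allele,
          m$effect_allele, ".", "PASS", ".", "DS",
          apply(body, 1, paste, collapse = "\t"), sep = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_vcf_dosage
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    abort("read_vcf_dosage() needs the VariantAnnotation package")
  }
  vcf <- VariantAnnotation::readVcf(path)
  ds0 <- VariantAnnotation::geno(vcf)$DS
  if (is.null(ds0)) abort("VCF has no DS FORMAT field")
  ds <- matrix(suppressWarnings(as.numeric(ds0)), nrow(ds0), ncol(ds0))
  rr <- as.data.frame(SummarizedExperiment::rowRanges(vcf))
  meta <- tibble::tibble(
    snp_id = rownames(ds0),
    chrom = as.character(rr$seqnames),
    pos = rr$start,
    effect_allele = as.character(unlist(VariantAnnotation::alt(vcf))),
    other_allele = as.character(VariantAnnotation::ref(vcf))
  )
  dosage <- t(ds)
  rownames(dosage) <- colnames(ds0)
  colnames(dosage) <- meta$snp_id
  genotype_panel(dosage, meta)
}

#' Read a polygenic-score weight table
#'
#' The expected layout mirrors published breast-cancer PRS weight files:
#' a TSV with header columns `snp_id`, `chrom`, `pos`, `effect_allele`,
#' `other_allele` and three log-odds weight columns `beta_overall`,
#' `beta_erneg`, `beta_erpos` (overall, estrogen-receptor-negative and
#' -positive disease).
#'
#' @param path Weight TSV path.
#' @return A tibble with those columns.
#' @export
read_prs_weights <- function(path) {
  w <- readr::read_tsv(path, show_col_types = FALSE)
  for (col in intersect(c("snp_id", "chrom", "effect_allele",
                          "other_allele"), names(w))) {
    w[[col]] <- as.character(w[[col]])
  }
  need <- c("snp_id", "effect_allele", "beta_overall", "beta_erneg",
            "beta_erpos")
  miss <- setdiff(need, names(w))
  if (length(miss)) abort(paste("weight file lacks columns:",
                                paste(miss, collapse = ", ")))
  w
}

#' Simulate a polygenic-score weight table for a panel
#'
#' Draws log-odds weights for every SNP in the panel, one column per
#' disease endpoint, with the three endpoints' weights correlated (overall
#' weights are a blend of the two receptor-subtype weights, as in published
#' breast-cancer scores).
#'
#' @param panel A [genotype_panel].
#' @param sd_beta Standard deviation of the per-SNP log-odds weights.
#' @param seed Integer seed.
#' @return A weight tibble as in [read_prs_weights()].
#' @export
simulate_weights <- function(panel, sd_beta = 0.08, seed = NULL) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!is.null(seed)) set.seed(seed)
  m <- panel$snp_meta
  erneg <- rnorm(nrow(m), 0, sd_beta)
  erpos <- rnorm(nrow(m), 0, sd_beta)
  tibble::tibble(
    snp_id = m$snp_id, chrom = m$chrom, pos = m$pos,
    effect_allele = m$effect_allele, other_allele = m$other_allele,
    beta_overall = 0.3 * erneg + 0.7 * erpos +
      rnorm(nrow(m), 0, sd_beta / 4),
    beta_erneg = erneg, beta_erpos = erpos
  )
}
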