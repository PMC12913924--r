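# header comment lines stamped on every output file
.file_header <- function(seed = NA, extra = NULL) {
  c(
    paste0("# igeprs ", as.character(packageVersion("igeprs"))),
    paste0("# seed=", seed),
    if (!is.null(extra)) paste0("# ", extra)
  )
}

.write_tsv_with_header <- function(df, path, seed = NA, extra = NULL) {
  writeLines(.file_header(seed, extra), path)
  suppressMessages(readr::write_tsv(df, path, append = TRUE, col_names = TRUE))
  invisible(path)
}

.read_tsv_commented <- function(path, ...) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE, ...)
}

#' Read genotypes from VCF or dosage TSV
#'
#' VCF: dosage is the ALT allele count from the GT field (`./.` is
#' missing); multi-allelic records are skipped with a reported count.
#' Dosage TSV: first column is the sample id, remaining columns are SNPs
#' with literal 0/1/2/NA values; SNP metadata (chr, pos, alleles) is read
#' from a `<path>.snps` sidecar when present.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"vcf"`, or `"dosage"`.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  }
  if (format == "vcf") .read_vcf(path) else .read_dosage_tsv(path)
}

.read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT) | is.na(fix$ALT)
  if (any(multi))
    inform(paste0("read_genotypes: skipped ", sum(multi), " multi-allelic record(s)."))
  keep <- which(!multi)
  if (length(keep) == 0) abort("no biallelic records in VCF.")
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  count_alt <- function(s) {
    out <- rep(NA_real_, length(s))
    ok <- !is.na(s) & !grepl("\\.", s)
    alleles <- strsplit(s[ok], "[/|]")
    out[ok] <- vapply(alleles, function(a) sum(a == "1"), numeric(1))
    out
  }
  d <- apply(gt, 2, count_alt)
  if (is.null(dim(d))) d <- matrix(d, nrow = 1, dimnames = list(NULL, colnames(gt)))
  d <- t(d)
  ids <- fix$ID[keep]
  ids[is.na(ids) | ids == "."] <- paste0(
    fix$CHROM[keep], ":", fix$POS[keep]
  )[is.na(ids) | ids == "."]
  colnames(d) <- ids
  snps <- tibble::tibble(
    snp = ids, chr = fix$CHROM[keep],
    pos = as.integer(fix$POS[keep]),
    a1 = fix$ALT[keep], a2 = fix$REF[keep]
  )
  geno_matrix(d, snps)
}

.read_dosage_tsv <- function(path) {
  tb <- .read_tsv_commented(path)
  ids <- as.character(tb[[1]])
  d <- as.matrix(tb[-1])
  storage.mode(d) <- "double"
  rownames(d) <- ids
  sidecar <- paste0(path, ".snps")
  if (file.exists(sidecar)) {
    snps <- .read_tsv_commented(sidecar)
  } else {
    snps <- tibble::tibble(
      snp = colnames(d), chr = NA_character_, pos = NA_integer_,
      a1 = NA_character_, a2 = NA_character_
    )
  }
  geno_matrix(d, snps[match(colnames(d), snps$snp), ])
}

#' Write genotypes
#'
#' `write_genotypes_vcf()` writes a minimal VCF 4.2 with GT-only genotype
#' fields (positions 1-based). `write_genotypes_tsv()` writes the dosage
#' matrix plus a `<path>.snps` metadata sidecar.
#'
#' @param genotypes A [geno_matrix()].
#' @param path Output file path.
#' @param seed Seed recorded in the file header.
#' @return The path, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path, seed = NA) {
  d <- genotypes$dosage
  s <- genotypes$snps
  gt_map <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=igeprs ", as.character(packageVersion("igeprs")), " seed=", seed),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", rownames(d)
    ), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(d)), function(j) {
    g <- d[, j]
    calls <- ifelse(is.na(g), "./.", gt_map[as.character(g)])
    paste(c(
      s$chr[j], s$pos[j], s$snp[j], s$a2[j], s$a1[j], ".", "PASS", ".",
      "GT", calls
    ), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' @rdname write_genotypes_vcf
#' @export
write_genotypes_tsv <- function(genotypes, path, seed = NA) {
  df <- tibble::tibble(sample = sample_ids(genotypes))
  df <- dplyr::bind_cols(df, tibble::as_tibble(genotypes$dosage))
  .write_tsv_with_header(df, path, seed = seed)
  .write_tsv_with_header(genotypes$snps, paste0(path, ".snps"), seed = seed)
  invisible(path)
}

#' Write/read summary statistics
#'
#' TSV round trip is lossless to full double precision (`p`, `beta`, `se`
#' written with 17 significant digits).
#'
#' @param stats Summary-statistics tibble.
#' @param path File path.
#' @param seed Seed recorded in the header.
#' @return `write_summary_stats()` the path; `read_summary_stats()` the
#'   tibble.
#' @export
write_summary_stats <- function(stats, path, seed = NA) {
  old <- options(digits = 17, scipen = 0)
  on.exit(options(old))
  .write_tsv_with_header(stats, path, seed = seed)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  .read_tsv_commented(path)
}

#' Write/read a cohort phenotype table
#' @param cohort Cohort tibble.
#' @inheritParams write_summary_stats
#' @return The path / the tibble.
#' @export
write_cohort <- function(cohort, path, seed = NA) {
  .write_tsv_with_header(cohort, path, seed = seed)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  .read_tsv_commented(path)
}

#' Serialize a PRS model (or a list of fold models) to JSON
#'
#' @param model A [prs_model()] or list of them.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_prs_model <- function(model, path) {
  ser <- function(m) {
    list(
      snps = m$snps, threshold = m$threshold, r2_max = m$r2_max,
      window_kb = m$window_kb, fold = m$fold,
      trace = if (!is.null(m$trace)) m$trace else NULL
    )
  }
  obj <- if (inherits(model, "prs_model")) ser(model) else lapply(model, ser)
  jsonlite::write_json(obj, path,
    auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_prs_model
#' @export
read_prs_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows_to_tibble <- function(rows) {
    dplyr::bind_rows(lapply(rows, function(r) {
      tibble::as_tibble(lapply(r, function(v) v %||% NA))
    }))
  }
  de <- function(o) {
    prs_model(
      rows_to_tibble(o$snps),
      threshold = o$threshold,
      r2_max = o$r2_max %||% NA_real_,
      window_kb = o$window_kb %||% NA_real_,
      fold = o$fold %||% NA_integer_,
      trace = if (!is.null(o$trace)) rows_to_tibble(o$trace) else NULL
    )
  }
  if (!is.null(obj$snps)) de(obj) else lapply(obj, de)
}
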