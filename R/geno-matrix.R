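#' Genotype dosage container
#'
#' A `geno_matrix` holds a samples-by-SNPs dosage matrix (counts of the
#' recorded effect allele: 0, 1, 2, or `NA` for a missing call) together with
#' per-SNP metadata. Dosage rows are named by sample id and columns by SNP id.
#'
#' @param dosage Numeric matrix, samples in rows, SNPs in columns. Values must
#'   be 0, 1, 2 or `NA`. Row and column names are required.
#' @param snps A data frame with one row per SNP column:
#'   `snp`, `chr`, `pos` (1-based), `a1` (the counted/effect allele) and
#'   `a2` (the other allele). Order must match the dosage columns.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosage, snps) {
  if (!is.matrix(dosage)) abort("`dosage` must be a matrix.")
  if (is.null(rownames(dosage)) || is.null(colnames(dosage)))
    abort("`dosage` must have sample row names and SNP column names.")
  snps <- tibble::as_tibble(snps)
  need <- c("snp", "chr", "pos", "a1", "a2")
  miss <- setdiff(need, names(snps))
  if (length(miss))
    abort(paste0("`snps` is missing column(s): ", paste(miss, collapse = ", ")))
  if (nrow(snps) != ncol(dosage))
    abort("`snps` must have one row per dosage column.")
  if (!identical(as.character(snps$snp), colnames(dosage)))
    abort("`snps$snp` must match the dosage column names, in order.")
  bad <- dosage[!is.na(dosage) & !(dosage %in% c(0, 1, 2))]
  if (length(bad))
    abort("dosages must be 0, 1, 2 or NA.")
  structure(list(dosage = dosage, snps = snps), class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d samples x %d SNPs (%.2f%% missing)\n",
    nrow(x$dosage), ncol(x$dosage),
    100 * mean(is.na(x$dosage))
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

#' Sample and SNP ids of a genotype matrix
#' @param x A [geno_matrix()].
#' @return Character vector of ids.
#' @export
sample_ids <- function(x) rownames(x$dosage)

#' @rdname sample_ids
#' @export
snp_ids <- function(x) colnames(x$dosage)

#' Subset a genotype matrix
#'
#' @param x A [geno_matrix()].
#' @param samples,snps Character vectors of ids to keep (default: all).
#'   Order of the result follows the order given here.
#' @return A `geno_matrix`.
#' @export
geno_subset <- function(x, samples = NULL, snps = NULL) {
  samples <- samples %||% sample_ids(x)
  snps <- snps %||% snp_ids(x)
  missing_s <- setdiff(samples, sample_ids(x))
  if (length(missing_s))
    abort(paste0("unknown sample id(s): ", paste(head(missing_s, 5), collapse = ", ")))
  missing_v <- setdiff(snps, snp_ids(x))
  if (length(missing_v))
    abort(paste0("unknown SNP id(s): ", paste(head(missing_v, 5), collapse = ", ")))
  d <- x$dosage[samples, snps, drop = FALSE]
  geno_matrix(d, x$snps[match(snps, x$snps$snp), , drop = FALSE])
}

#' Bind two genotype matrices over samples
#'
#' Both matrices must describe the same SNP panel.
#' @param x,y [geno_matrix()] objects with identical SNP metadata.
#' @return A `geno_matrix` with the samples of `x` followed by those of `y`.
#' @export
geno_rbind <- function(x, y) {
  if (!identical(x$snps$snp, y$snps$snp))
    abort("SNP panels differ; cannot bind samples.")
  dup <- intersect(sample_ids(x), sample_ids(y))
  if (length(dup))
    abort(paste0("duplicated sample id(s): ", paste(head(dup, 5), collapse = ", ")))
  geno_matrix(rbind(x$dosage, y$dosage), x$snps)
}
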