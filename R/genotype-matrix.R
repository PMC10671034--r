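#' Accession-by-SNP genotype matrix for inbred lines
#'
#' Container for homozygous-coded genotypes of fully inbred accessions.
#' Allele codes are 0 (reference homozygote), 2 (alternate homozygote),
#' 1 (residual heterozygote, treated as missing by the analysis) and NA.
#'
#' @param geno integer matrix, accessions in rows (rownames = accession ids),
#'   SNPs in columns (colnames = SNP ids), values in \{0, 1, 2, NA\}.
#' @param map data.frame with columns `snp`, `chrom`, `pos` (1-based bp),
#'   one row per column of `geno`, positions strictly increasing within each
#'   chromosome.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, map) {
  geno <- as.matrix(geno)
  if (is.null(rownames(geno)) || is.null(colnames(geno)))
    stop("'geno' needs accession rownames and SNP colnames")
  if (!all(colnames(geno) == map$snp))
    stop("'map' rows must match 'geno' columns (same SNPs, same order)")
  bad <- !(geno %in% c(0L, 1L, 2L) | is.na(geno))
  if (any(bad)) {
    idx <- which(bad)[1]
    stop(sprintf("invalid allele code at accession '%s', SNP '%s'",
                 rownames(geno)[(idx - 1) %% nrow(geno) + 1],
                 colnames(geno)[(idx - 1) %/% nrow(geno) + 1]))
  }
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (any(diff(p) <= 0))
      stop(sprintf("positions not strictly increasing on chromosome %s", ch))
  }
  structure(list(geno = geno, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d accessions x %d SNPs on %d chromosome(s)\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chrom))))
  miss <- mean(is.na(x$geno) | x$geno == 1L)
  cat(sprintf("  missing-or-heterozygous rate: %.3f\n", miss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$geno)

#' Per-SNP summary rates
#'
#' Missing rate, heterozygosity rate and minor-allele frequency per SNP.
#' MAF is computed from homozygous calls only (inbred encoding).
#'
#' @param g a [genotype_matrix()].
#' @return data.frame with columns `snp`, `missing`, `het`, `maf`.
#' @export
snp_rates <- function(g) {
  gm <- g$geno
  n <- nrow(gm)
  het <- colSums(gm == 1L, na.rm = TRUE) / n
  missing <- colSums(is.na(gm)) / n
  hom <- gm
  hom[hom == 1L] <- NA
  p <- colMeans(hom == 2L, na.rm = TRUE)
  p[is.nan(p)] <- NA_real_
  maf <- pmin(p, 1 - p)
  data.frame(snp = g$map$snp, missing = missing, het = het, maf = maf,
             row.names = NULL)
}
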