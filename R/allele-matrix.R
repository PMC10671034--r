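#' Assemble the QTL-allele matrix
#'
#' Builds the loci-by-accessions matrix of allele effects: each cell is the
#' estimated effect of the haplotype allele that accession carries at that
#' locus.  Together with the population intercept the matrix represents the
#' genetic structure of the whole population and of each accession.
#'
#' @param scan a `qtl_scan` (loci with main effects and allele effects).
#' @param markers the `snpldb_set` the scan was run on (provides the
#'   per-accession allele assignments).
#' @return object of class `qtl_allele_matrix`: `effects` (loci x
#'   accessions), `alleles` (matching matrix of allele labels), `mu`
#'   (population intercept), `loci` (data.frame qtl/marker/chrom/pos).
#' @export
build_allele_matrix <- function(scan, markers) {
  stopifnot(inherits(scan, "qtl_scan"), inherits(markers, "snpldb_set"))
  if (is.null(scan$allele_effects) || nrow(scan$allele_effects) == 0)
    stop("scan contains no main-effect loci; allele matrix is empty")
  eff <- scan$allele_effects
  loci <- unique(eff[, c("qtl", "marker")])
  loci <- merge(loci, scan$records[, c("qtl", "chrom", "pos")], by = "qtl")
  loci <- loci[order(loci$chrom, loci$pos), ]
  acc <- markers$accessions
  ids <- vapply(markers$markers, `[[`, "", "id")
  E <- matrix(NA_real_, nrow(loci), length(acc),
              dimnames = list(loci$qtl, acc))
  A <- matrix(NA_character_, nrow(loci), length(acc),
              dimnames = list(loci$qtl, acc))
  for (i in seq_len(nrow(loci))) {
    m <- markers$markers[[match(loci$marker[i], ids)]]
    e <- eff[eff$marker == loci$marker[i], ]
    carried <- as.character(m$assign)
    miss <- is.na(carried)
    if (any(miss))
      stop(sprintf("accession '%s' has no allele call at locus %s",
                   acc[which(miss)[1]], loci$qtl[i]))
    E[i, ] <- e$effect[match(carried, e$allele)]
    A[i, ] <- carried
  }
  structure(list(effects = E, alleles = A, mu = scan$mu, loci = loci),
            class = "qtl_allele_matrix")
}

#' @export
print.qtl_allele_matrix <- function(x, ...) {
  cat(sprintf("qtl_allele_matrix: %d loci x %d accessions (mu = %.2f)\n",
              nrow(x$effects), ncol(x$effects), x$mu))
  invisible(x)
}

#' Per-accession summary of the QTL-allele matrix
#'
#' Column sum of allele effects and counts of negative and positive effects
#' (zero effects are counted in neither).  Negative alleles lower the trait
#' (more resistant); the accession's predicted genotypic value is
#' `mu + sum`.
#'
#' @param m a `qtl_allele_matrix`.
#' @param accession one accession id, or NULL for all.
#' @return data.frame `accession`, `sum`, `n_negative`, `n_positive`,
#'   `predicted`.
#' @export
accession_summary <- function(m, accession = NULL) {
  stopifnot(inherits(m, "qtl_allele_matrix"))
  acc <- accession %||% colnames(m$effects)
  bad <- setdiff(acc, colnames(m$effects))
  if (length(bad)) stop(sprintf("unknown accession '%s'", bad[1]))
  E <- m$effects[, acc, drop = FALSE]
  data.frame(accession = acc,
             sum = colSums(E),
             n_negative = colSums(E < 0),
             n_positive = colSums(E > 0),
             predicted = m$mu + colSums(E),
             row.names = NULL)
}

#' Column subset of a QTL-allele matrix
#'
#' Selects a subset of accessions (e.g. one resistance group), preserving
#' locus order, so the matrix can be separated into group sub-matrices.
#'
#' @param m a `qtl_allele_matrix`.
#' @param accessions accession ids to keep.
#' @return a `qtl_allele_matrix` restricted to those columns.
#' @export
submatrix <- function(m, accessions) {
  stopifnot(inherits(m, "qtl_allele_matrix"))
  if (length(accessions) == 0) stop("empty accession subset")
  bad <- setdiff(accessions, colnames(m$effects))
  if (length(bad)) stop(sprintf("unknown accession id '%s'", bad[1]))
  structure(list(effects = m$effects[, accessions, drop = FALSE],
                 alleles = m$alleles[, accessions, drop = FALSE],
                 mu = m$mu, loci = m$loci),
            class = "qtl_allele_matrix")
}
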