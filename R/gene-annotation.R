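#' Genes within a flanking window of a SNPLDB marker
#'
#' Returns the genes whose span intersects the closed interval
#' [marker start - window, marker end + window] on the marker's
#' chromosome.  Distance is measured from the SNPLDB span (first to last
#' member SNP), not its midpoint; a gene abutting the window edge exactly
#' is included.
#'
#' @param genes data.frame `gene`, `chrom`, `start`, `end` (1-based
#'   inclusive) and any annotation columns.
#' @param marker a marker from a `snpldb_set` (or any list with `chrom`,
#'   `start`, `end`).
#' @param window flanking window in bp (default 50,000).
#' @return subset of `genes` (possibly empty).
#' @export
genes_near_marker <- function(genes, marker, window = 5e4) {
  if (nrow(genes) == 0) return(genes[0, , drop = FALSE])
  if (any(genes$start > genes$end)) stop("gene start > end")
  q_start <- max(1, marker$start - window)
  q_end <- marker$end + window
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(genes$chrom),
    ranges = IRanges::IRanges(genes$start, genes$end))
  qr <- GenomicRanges::GRanges(
    seqnames = as.character(marker$chrom),
    ranges = IRanges::IRanges(q_start, q_end))
  hits <- GenomicRanges::findOverlaps(gr, qr)
  genes[S4Vectors::queryHits(hits), , drop = FALSE]
}

#' Chi-square association between a SNPLDB marker and a SNP
#'
#' Contingency chi-square (no continuity correction) between the marker's
#' haplotype alleles and a SNP's genotype classes across accessions, after
#' dropping missing calls.  A warning flag is set when any expected cell
#' count falls below 5.
#'
#' @param marker_alleles factor (or character) of haplotype alleles per
#'   accession.
#' @param snp_genotypes vector of SNP genotype codes per accession
#'   (0/2/NA).
#' @return list `statistic`, `df`, `p`, `low_expected` (logical), or NULL
#'   if the table is degenerate (fewer than two classes on either side).
#' @export
snp_gene_association <- function(marker_alleles, snp_genotypes) {
  ok <- !is.na(marker_alleles) & !is.na(snp_genotypes)
  a <- droplevels(factor(marker_alleles[ok]))
  s <- droplevels(factor(snp_genotypes[ok]))
  if (nlevels(a) < 2 || nlevels(s) < 2) return(NULL)
  tab <- table(a, s)
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value),
       low_expected = any(ct$expected < 5))
}

#' Candidate genes for a set of detected loci
#'
#' For each detected QTL marker: collect the genes within the flanking
#' window, test each gene's SNPs (member SNPs of the genotype matrix
#' falling inside the gene span) for association with the marker's
#' haplotype alleles, and retain genes whose most significant SNP reaches
#' `alpha`.  No multiple-testing correction is applied across genes unless
#' `bonferroni = TRUE`.
#'
#' @param scan a `qtl_scan` (or data.frame of records with `qtl` and
#'   `marker` columns).
#' @param markers the `snpldb_set` used in the scan.
#' @param genes gene table (`gene`, `chrom`, `start`, `end`, optional
#'   `category`, `go_description`).
#' @param genotypes the QC'd [genotype_matrix()] (source of gene SNPs).
#' @param window flanking window in bp (default 50,000).
#' @param alpha significance level (default 0.05).
#' @param bonferroni divide alpha by the number of genes tested per QTL.
#' @return data.frame, one row per retained (qtl, gene) pair: `qtl`,
#'   `marker`, `gene`, `category`, `chisq`, `p`, `n_snps_tested`,
#'   `best_snp`, ordered by qtl then p.
#' @export
select_candidates <- function(scan, markers, genes, genotypes,
                              window = 5e4, alpha = 0.05,
                              bonferroni = FALSE) {
  records <- if (inherits(scan, "qtl_scan")) scan$records else scan
  if (is.null(records) || nrow(records) == 0)
    return(data.frame())
  ids <- vapply(markers$markers, `[[`, "", "id")
  rows <- list()
  for (i in seq_len(nrow(records))) {
    mk <- markers$markers[[match(records$marker[i], ids)]]
    near <- genes_near_marker(genes, mk, window)
    if (nrow(near) == 0) next
    thr <- if (bonferroni) alpha / nrow(near) else alpha
    for (gi in seq_len(nrow(near))) {
      snp_in <- which(genotypes$map$chrom == near$chrom[gi] &
                        genotypes$map$pos >= near$start[gi] &
                        genotypes$map$pos <= near$end[gi])
      if (length(snp_in) == 0) next
      best <- NULL
      for (sj in snp_in) {
        as_ <- snp_gene_association(mk$assign, genotypes$geno[, sj])
        if (is.null(as_)) next
        if (is.null(best) || as_$p < best$p) {
          best <- as_
          best$snp <- genotypes$map$snp[sj]
        }
      }
      if (!is.null(best) && best$p <= thr) {
        rows[[length(rows) + 1]] <- data.frame(
          qtl = records$qtl[i], marker = records$marker[i],
          gene = near$gene[gi],
          category = if ("category" %in% names(near))
            near$category[gi] else NA_character_,
          chisq = best$statistic, p = best$p,
          n_snps_tested = length(snp_in), best_snp = best$snp)
      }
    }
  }
  if (length(rows) == 0) return(data.frame())
  out <- do.call(rbind, rows)
  out <- out[order(out$qtl, out$p), ]
  rownames(out) <- NULL
  out
}

#' Tally candidate genes by biological-process category
#'
#' Counts genes per category I-VIII; counts sum to the number of genes.
#'
#' @param genes data.frame with a `category` column (one row per gene), or
#'   a character vector of categories.
#' @return named integer vector over categories I-VIII.
#' @export
category_tally <- function(genes) {
  cats <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII")
  v <- if (is.data.frame(genes)) genes$category else genes
  v <- v[!is.na(v)]
  if (length(v) && !all(v %in% cats))
    stop(sprintf("unknown category label '%s'", setdiff(v, cats)[1]))
  tab <- table(factor(v, levels = cats))
  setNames(as.integer(tab), cats)
}
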