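#' SNP quality control for inbred genotypes
#'
#' Removes SNPs exceeding the missing-rate or heterozygosity thresholds or
#' falling below the minimum allele frequency, then recodes residual
#' heterozygous calls as missing (inbred encoding: haplotypes are read from
#' homozygotes).
#'
#' @param g a [genotype_matrix()].
#' @param max_missing maximum per-SNP missing fraction (default 0.20).
#' @param max_het maximum per-SNP heterozygosity fraction (default 0.20).
#' @param min_maf minimum allele frequency (default 0.01).
#' @return Filtered [genotype_matrix()] with heterozygotes set to NA and a
#'   removal report in attribute `"qc_report"`.
#' @export
qc_filter <- function(g, max_missing = 0.2, max_het = 0.2, min_maf = 0.01) {
  stopifnot(inherits(g, "genotype_matrix"))
  for (thr in c(max_missing, max_het, min_maf))
    if (thr < 0 || thr > 1) stop("thresholds must be in [0, 1]")
  rt <- snp_rates(g)
  fail_missing <- rt$missing > max_missing
  fail_het <- rt$het > max_het
  fail_maf <- is.na(rt$maf) | rt$maf < min_maf
  keep <- !(fail_missing | fail_het | fail_maf)
  if (!any(keep)) stop("all SNPs removed by QC")
  geno <- g$geno[, keep, drop = FALSE]
  geno[geno == 1L] <- NA_integer_
  out <- genotype_matrix(geno, g$map[keep, , drop = FALSE])
  attr(out, "qc_report") <- data.frame(
    criterion = c("missing", "heterozygosity", "maf", "kept"),
    n = c(sum(fail_missing), sum(fail_het), sum(fail_maf), sum(keep)))
  out
}

#' Fill residual missing genotypes with the per-SNP mode
#'
#' A simple imputation fallback applied before block construction so every
#' accession has a complete haplotype at every block.
#'
#' @param g a [genotype_matrix()] (post-QC, heterozygotes already NA).
#' @return complete [genotype_matrix()].
#' @export
impute_mode <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  geno <- g$geno
  geno[geno == 1L] <- NA_integer_
  for (j in seq_len(ncol(geno))) {
    na <- is.na(geno[, j])
    if (any(na)) {
      tab <- table(geno[!na, j])
      if (length(tab) == 0) stop(sprintf("SNP '%s' entirely missing",
                                         colnames(geno)[j]))
      geno[na, j] <- as.integer(names(tab)[which.max(tab)])
    }
  }
  genotype_matrix(geno, g$map)
}

#' Pairwise D-prime between two biallelic SNPs of inbred lines
#'
#' Haplotypes are read directly from the homozygous genotypes
#' (pairwise-complete observations).  D' = |p_AB - p_A p_B| / D_max with the
#' standard D_max; symmetric in its arguments; in [0, 1].
#'
#' @param a,b genotype vectors coded 0/2/NA.
#' @return D' or NA (with a warning) if either column is monomorphic or
#'   fewer than two complete haplotypes are observed.
#' @export
pairwise_dprime <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) {
    warning("fewer than 2 complete haplotype observations")
    return(NA_real_)
  }
  a <- a[ok] == 2L
  b <- b[ok] == 2L
  pA <- mean(a); pB <- mean(b)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    warning("monomorphic column: D' undefined")
    return(NA_real_)
  }
  pAB <- mean(a & b)
  D <- pAB - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  if (dmax == 0) return(0)
  abs(D) / dmax
}

#' Greedy construction of SNP linkage-disequilibrium blocks
#'
#' Scans each chromosome left to right, extending the current block by the
#' next SNP iff its D' with every SNP already in the block exceeds
#' `d_threshold` and the block span stays within `max_span`.  SNPs that do
#' not merge become singleton (biallelic) markers.  Every SNP belongs to
#' exactly one block.
#'
#' @param g QC-passed [genotype_matrix()].
#' @param d_threshold D' threshold (default 0.7).
#' @param max_span maximum block span in bp (default 200 kb).
#' @return data.frame, one row per SNP: `snp`, `chrom`, `pos`, `block`
#'   (integer block id, consecutive in genome order).
#' @export
build_blocks <- function(g, d_threshold = 0.7, max_span = 2e5) {
  stopifnot(inherits(g, "genotype_matrix"))
  map <- g$map
  block <- integer(nrow(map))
  bid <- 0L
  for (ch in unique(map$chrom)) {
    idx <- which(map$chrom == ch)
    members <- integer(0)
    for (i in idx) {
      ok <- length(members) > 0 &&
        (map$pos[i] - map$pos[members[1]]) <= max_span
      if (ok) {
        for (m in members) {
          dp <- suppressWarnings(pairwise_dprime(g$geno[, m], g$geno[, i]))
          if (is.na(dp) || dp <= d_threshold) { ok <- FALSE; break }
        }
      }
      if (ok) {
        members <- c(members, i)
      } else {
        bid <- bid + 1L
        members <- i
      }
      block[i] <- bid
    }
  }
  data.frame(snp = map$snp, chrom = map$chrom, pos = map$pos, block = block)
}

#' Multi-allelic haplotype alleles of one LD block
#'
#' Enumerates the distinct haplotype strings over the block's member SNPs,
#' collapsing haplotypes rarer than `min_freq` into a single `"rare"`
#' allele.  Frequencies sum to 1.
#'
#' @param geno complete genotype submatrix (accessions x member SNPs).
#' @param min_freq collapse threshold (default 0.01, mirroring the MAF
#'   filter).
#' @return list with `assign` (factor of allele labels per accession,
#'   levels a1, a2, ... by decreasing frequency, plus `"rare"`) and
#'   `alleles` (data.frame `allele`, `haplotype`, `freq`), or NULL if fewer
#'   than two alleles remain after collapsing (marker dropped).
#' @export
haplotype_alleles <- function(geno, min_freq = 0.01) {
  hap <- apply(geno, 1, paste0, collapse = "")
  tab <- sort(table(hap), decreasing = TRUE)
  freq <- as.numeric(tab) / length(hap)
  common <- freq >= min_freq
  labels <- character(length(tab))
  labels[common] <- paste0("a", seq_len(sum(common)))
  labels[!common] <- "rare"
  # a rare class below threshold even after pooling is still kept as one
  # allele; degenerate single-allele markers are dropped by the caller
  lev <- unique(labels)
  if (length(lev) < 2L) return(NULL)
  assign <- factor(labels[match(hap, names(tab))], levels = lev)
  af <- tapply(rep(1 / length(hap), length(hap)), assign, sum)
  alleles <- data.frame(
    allele = lev,
    haplotype = vapply(lev, function(l) {
      h <- names(tab)[labels == l]
      if (length(h) == 1) h else "rare"
    }, character(1)),
    freq = as.numeric(af[lev]), row.names = NULL)
  list(assign = assign, alleles = alleles)
}

#' Build the full SNPLDB marker set
#'
#' QC'd genotypes are mode-imputed, partitioned into LD blocks
#' ([build_blocks()]), and each block is converted into a multi-allelic
#' SNPLDB marker via [haplotype_alleles()].  Blocks left with a single
#' allele after rare-haplotype collapsing are dropped (logged in the
#' `dropped` attribute).
#'
#' @inheritParams build_blocks
#' @param min_freq rare-haplotype collapse threshold.
#' @return object of class `snpldb_set`: list of markers, each with `id`,
#'   `chrom`, `start`, `end`, `snps`, `alleles`, `assign`; plus
#'   `accessions`.
#' @export
build_snpldb <- function(g, d_threshold = 0.7, max_span = 2e5,
                         min_freq = 0.01) {
  gi <- impute_mode(g)
  blk <- build_blocks(gi, d_threshold = d_threshold, max_span = max_span)
  markers <- list()
  dropped <- character(0)
  for (b in unique(blk$block)) {
    idx <- which(blk$block == b)
    sub <- gi$geno[, idx, drop = FALSE]
    ha <- haplotype_alleles(sub, min_freq = min_freq)
    id <- sprintf("LDB_%02d_%d", blk$chrom[idx[1]], blk$pos[idx[1]])
    if (is.null(ha)) {
      dropped <- c(dropped, id)
      next
    }
    markers[[length(markers) + 1]] <- list(
      id = id, chrom = blk$chrom[idx[1]],
      start = blk$pos[idx[1]], end = blk$pos[idx[length(idx)]],
      snps = blk$snp[idx], alleles = ha$alleles, assign = ha$assign)
  }
  structure(list(markers = markers,
                 accessions = rownames(gi$geno),
                 blocks = blk),
            class = "snpldb_set", dropped = dropped)
}

#' @export
print.snpldb_set <- function(x, ...) {
  k <- vapply(x$markers, function(m) nrow(m$alleles), integer(1))
  cat(sprintf("snpldb_set: %d markers (%d haplotype alleles) on %d accessions\n",
              length(x$markers), sum(k), length(x$accessions)))
  cat(sprintf("  alleles per marker: %d-%d (mean %.1f)\n",
              min(k), max(k), mean(k)))
  invisible(x)
}

#' Genetic similarity matrix from SNPLDB alleles
#'
#' Similarity between two accessions is the proportion of SNPLDB markers at
#' which they carry the same (identical-in-state) haplotype allele.
#' Symmetric with unit diagonal and positive semidefinite up to numerical
#' tolerance.
#'
#' @param snpldb a `snpldb_set`.
#' @return object of class `similarity_matrix`: `sim` (n x n), plus
#'   eigenvalues/eigenvectors computed lazily by [structure_covariates()].
#' @export
similarity_matrix <- function(snpldb) {
  stopifnot(inherits(snpldb, "snpldb_set"))
  n <- length(snpldb$accessions)
  S <- matrix(0, n, n)
  for (m in snpldb$markers) {
    A <- model.matrix(~ 0 + m$assign)
    S <- S + tcrossprod(A)
  }
  S <- S / length(snpldb$markers)
  dimnames(S) <- list(snpldb$accessions, snpldb$accessions)
  structure(list(sim = S), class = "similarity_matrix")
}

#' Population-structure covariates from the similarity matrix
#'
#' The top-k eigenvectors of the genetic similarity matrix, used as fixed
#' covariates in the association scan to absorb population structure.
#'
#' @param sim a `similarity_matrix`.
#' @param k number of eigenvectors (default 10, capped at n - 1).
#' @return matrix n x k with accession rownames.
#' @export
structure_covariates <- function(sim, k = 10) {
  stopifnot(inherits(sim, "similarity_matrix"))
  if (k <= 0) stop("'k' must be positive")
  n <- nrow(sim$sim)
  k <- min(k, n - 1L)
  eg <- eigen(sim$sim, symmetric = TRUE)
  ev <- eg$vectors[, seq_len(k), drop = FALSE]
  rownames(ev) <- rownames(sim$sim)
  colnames(ev) <- paste0("PC", seq_len(k))
  ev
}
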