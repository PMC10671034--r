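#' Simulate an inbred landrace population with planted multi-allelic QTLs
#'
#' Generates fully homozygous genotypes with block-structured local LD, a
#' set of planted multi-allelic QTLs whose alleles are the haplotypes of
#' designated LD blocks, and a multi-environment replicated plot phenotype
#' with additive QTL effects, fixed environment effects, genotype-by-
#' environment deviations and residual noise scaled so realised broad-sense
#' heritability matches the configured target.
#'
#' LD is induced by a block-copy model: each chromosome is cut into segments
#' with exponential lengths; each segment carries a small set of founder
#' haplotypes built by single-mutation descent (every SNP mutates on exactly
#' one founder-tree edge), so within a block any SNP pair shows at most
#' three gametes and D' = 1, while blocks assort independently.  Each
#' accession copies one founder haplotype per block.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_population` with elements
#'   \describe{
#'     \item{genotypes}{a [genotype_matrix()]}
#'     \item{phenotypes}{data.frame `accession`, `env`, `rep`, `value`
#'       (plot values, percent)}
#'     \item{truth}{ground truth: per-SNP block ids, planted QTL table,
#'       accession-by-QTL allele assignment, per-QTL allele effects,
#'       genotypic values, variance partition and realised heritability}
#'   }
#' @examples
#' pop <- simulate_population(sim_config(n_accessions = 60,
#'   n_chromosomes = 4, snps_per_chromosome = 30, n_true_qtls = 2,
#'   master_seed = 7))
#' pop$truth$realized_h2
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  cfg <- config

  acc <- sprintf("ACC%03d", seq_len(cfg$n_accessions))

  ## ---- genotypes ----------------------------------------------------------
  set.seed(child_seed(cfg$master_seed, 1L))
  map_list <- vector("list", cfg$n_chromosomes)
  geno_list <- vector("list", cfg$n_chromosomes)
  block_tbl <- vector("list", cfg$n_chromosomes)
  block_counter <- 0L
  block_id_of_snp <- integer(0)
  block_assign <- list()   # per block: accession -> founder haplotype index

  for (ch in seq_len(cfg$n_chromosomes)) {
    m <- cfg$snps_per_chromosome
    pos <- sort(sample.int(cfg$chromosome_length, m))
    # block boundaries: exponential segment lengths along the chromosome
    brks <- cumsum(rexp(ceiling(cfg$chromosome_length /
                                  cfg$ld_block_mean_span) + m,
                        rate = 1 / cfg$ld_block_mean_span))
    blk_local <- findInterval(pos, brks) + 1L
    blk_local <- match(blk_local, unique(blk_local))  # consecutive ids
    geno_ch <- matrix(0L, cfg$n_accessions, m)
    for (b in unique(blk_local)) {
      idx <- which(blk_local == b)
      nf <- min(sample(2:4, 1), length(idx) + 1L)
      founders <- founder_haplotypes(nf, length(idx))
      freq <- founder_freqs(nf)
      z <- sample.int(nf, cfg$n_accessions, replace = TRUE, prob = freq)
      geno_ch[, idx] <- founders[z, , drop = FALSE]
      block_counter <- block_counter + 1L
      block_assign[[block_counter]] <- z
      block_tbl[[ch]] <- rbind(block_tbl[[ch]],
        data.frame(block = block_counter, chrom = ch,
                   start = pos[idx[1]], end = pos[idx[length(idx)]],
                   n_snps = length(idx), n_haplotypes = nf))
      block_id_of_snp <- c(block_id_of_snp, rep(block_counter, length(idx)))
    }
    geno_list[[ch]] <- geno_ch
    map_list[[ch]] <- data.frame(
      snp = sprintf("S%02d_%07d", ch, pos), chrom = ch, pos = pos)
  }
  geno <- do.call(cbind, geno_list)
  map <- do.call(rbind, map_list)
  rownames(geno) <- acc
  colnames(geno) <- map$snp
  g <- genotype_matrix(geno, map)
  blocks <- do.call(rbind, block_tbl)

  ## ---- planted QTLs -------------------------------------------------------
  set.seed(child_seed(cfg$master_seed, 2L))
  lo <- cfg$alleles_per_qtl[1]; hi <- cfg$alleles_per_qtl[2]
  eligible <- blocks$block[blocks$n_haplotypes >= lo &
                             blocks$n_haplotypes <= hi &
                             blocks$n_snps >= 2L]
  if (cfg$n_true_qtls > length(eligible))
    stop("configuration error: not enough eligible LD blocks for the ",
         "requested number of planted QTLs")
  qtl_blocks <- sort(sample(eligible, cfg$n_true_qtls))
  effects <- vector("list", cfg$n_true_qtls)
  assign_mat <- matrix(NA_integer_, cfg$n_accessions, cfg$n_true_qtls,
                       dimnames = list(acc, NULL))
  gval <- rep(0, cfg$n_accessions)
  for (q in seq_len(cfg$n_true_qtls)) {
    b <- qtl_blocks[q]
    k <- blocks$n_haplotypes[blocks$block == b]
    if (!is.null(cfg$qtl_effect_values)) {
      e <- rep_len(cfg$qtl_effect_values[[((q - 1) %%
                     length(cfg$qtl_effect_values)) + 1]], k)
      e <- e - mean(e)                      # allele effects sum to zero
    } else {
      # standardise each planted QTL to the same nominal allele-effect
      # spread so every locus is a well-defined signal; realised
      # contributions still vary through allele frequencies
      e <- rnorm(k)
      e <- e - mean(e)
      e <- e / sd(e) * cfg$effect_scale
    }
    effects[[q]] <- e
    z <- block_assign[[b]]
    assign_mat[, q] <- z
    gval <- gval + e[z]
  }
  names(gval) <- acc

  ## ---- noise partition ----------------------------------------------------
  s2g <- if (cfg$n_true_qtls > 0) var(gval) else 0
  h2 <- cfg$heritability_target
  n <- cfg$n_environments; r <- cfg$n_replicates
  if (cfg$n_true_qtls > 0 && s2g > 0) {
    s2ge <- cfg$gxe_variance_fraction * s2g
    if (n > 1) {
      s2e <- n * r * (s2g / h2 - s2g - s2ge / n)
    } else {
      s2ge <- 0
      s2e <- r * s2g * (1 / h2 - 1)
    }
    if (s2e < -1e-9)
      stop("configuration error: heritability_target unreachable")
    s2e <- max(s2e, 0)
  } else {
    s2ge <- 0
    s2e <- cfg$effect_scale^2   # null trait: pure noise
  }

  ## ---- phenotypes ---------------------------------------------------------
  set.seed(child_seed(cfg$master_seed, 3L))
  env_eff <- if (n > 1) rnorm(n, 0, cfg$env_sd) else 0
  if (n > 1) env_eff <- env_eff - mean(env_eff)
  ge <- matrix(if (s2ge > 0) rnorm(cfg$n_accessions * n, 0, sqrt(s2ge))
               else 0, cfg$n_accessions, n)
  ph <- expand.grid(rep = seq_len(r), env = seq_len(n),
                    accession = acc, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE)
  ph <- ph[, c("accession", "env", "rep")]
  ia <- match(ph$accession, acc)
  ph$value <- cfg$mu + gval[ia] + env_eff[ph$env] +
    ge[cbind(ia, ph$env)] +
    if (s2e > 0) rnorm(nrow(ph), 0, sqrt(s2e)) else 0
  ph$env <- sprintf("E%d", ph$env)
  rownames(ph) <- NULL

  truth <- list(
    blocks = blocks,
    block_id_of_snp = block_id_of_snp,
    qtls = blocks[blocks$block %in% qtl_blocks, , drop = FALSE],
    allele_assignment = assign_mat,
    allele_effects = effects,
    genotypic_values = gval,
    mu = cfg$mu,
    sigma2 = c(g = s2g, ge = s2ge, e = s2e),
    target_h2 = h2)

  ## realised broad-sense heritability from the simulated replicate structure
  if (cfg$n_true_qtls > 0) {
    vc <- anova_components(ph)
    truth$realized_h2 <- vc$h2
  } else {
    truth$realized_h2 <- 0
  }

  structure(list(genotypes = g, phenotypes = ph, truth = truth,
                 config = cfg),
            class = "sim_population")
}

# founder haplotypes by single-mutation descent on a random tree:
# founder 1 is all-reference; each later founder copies an earlier one and
# flips a unique subset of SNPs (every SNP flips on exactly one edge), so all
# pairwise SNP tables have <= 3 gametes and within-block D' is 1.
founder_haplotypes <- function(n_founders, n_snps) {
  H <- matrix(0L, n_founders, n_snps)
  if (n_founders == 1L) return(H)
  edge_of_snp <- sample(rep_len(seq_len(n_founders - 1L), n_snps))
  for (f in 2:n_founders) {
    parent <- if (f == 2L) 1L else sample.int(f - 1L, 1L)
    H[f, ] <- H[parent, ]
    mut <- which(edge_of_snp == f - 1L)
    H[f, mut] <- 2L - H[f, mut]
  }
  H
}

founder_freqs <- function(k) {
  w <- rexp(k) + 0.4   # floor keeps all haplotypes reasonably common
  w / sum(w)
}

#' @export
print.sim_population <- function(x, ...) {
  cat(sprintf(paste0("sim_population: %d accessions, %d SNPs, %d planted ",
                     "QTLs, %d env x %d rep\n"),
              nrow(x$genotypes$geno), ncol(x$genotypes$geno),
              x$config$n_true_qtls, x$config$n_environments,
              x$config$n_replicates))
  cat(sprintf("  realised h2 = %.3f (target %.2f)\n",
              x$truth$realized_h2, x$truth$target_h2))
  invisible(x)
}
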