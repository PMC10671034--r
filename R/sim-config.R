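#' Simulation design for a multi-environment inbred-population trial
#'
#' Bundles the study-design constants the synthetic-data generator emulates:
#' a landrace-style population of fully inbred accessions genotyped with
#' dense biallelic SNPs carrying local LD blocks, a handful of multi-allelic
#' QTLs with additive haplotype effects, and a damaged-leaf-percentage (DLP)
#' phenotype scored in several environments with replicates, genotype-by-
#' environment deviations, and residual noise calibrated to a target
#' broad-sense heritability.
#'
#' Defaults mirror the trial design the package targets: 370 accessions from
#' 20 chromosomes scored in 3 environments x 3 replicates with heritability
#' near 0.77 and a population mean DLP of 44.5 percent; marker density and
#' chromosome length are reduced-scale standins (100 SNPs on 3 Mb per
#' chromosome) so the full pipeline runs in seconds.
#'
#' @param n_accessions number of fully homozygous accessions.
#' @param n_chromosomes number of chromosomes.
#' @param snps_per_chromosome biallelic SNPs simulated per chromosome.
#' @param chromosome_length chromosome length in bp.
#' @param ld_block_mean_span mean LD-block span in bp (exponential lengths).
#' @param n_true_qtls number of planted QTLs (may be 0 for a null trait).
#' @param alleles_per_qtl integer range (length 2) of haplotype alleles per
#'   planted QTL; realised counts are capped by block SNP content.
#' @param effect_scale standard deviation (phenotype units, i.e. percent
#'   DLP) of per-allele effects before centering.
#' @param heritability_target broad-sense heritability the noise partition is
#'   solved for, in (0, 1].
#' @param n_environments,n_replicates trial layout.
#' @param gxe_variance_fraction sigma^2_ge as a fraction of sigma^2_g.
#' @param mu population mean of the trait (percent).
#' @param env_sd standard deviation of fixed environment effects (percent).
#' @param qtl_effect_values optional list of numeric effect vectors, one per
#'   planted QTL, overriding the random draws (used to plant exact effects).
#' @param master_seed integer master seed; all component streams derive from
#'   it deterministically.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_accessions = 370,
                       n_chromosomes = 20,
                       snps_per_chromosome = 100,
                       chromosome_length = 3e6,
                       ld_block_mean_span = 1e5,
                       n_true_qtls = 10,
                       alleles_per_qtl = c(2L, 6L),
                       effect_scale = 3,
                       heritability_target = 0.77,
                       n_environments = 3,
                       n_replicates = 3,
                       gxe_variance_fraction = 0.2,
                       mu = 44.5,
                       env_sd = 3,
                       qtl_effect_values = NULL,
                       master_seed = 20230101) {
  cfg <- list(n_accessions = as.integer(n_accessions),
              n_chromosomes = as.integer(n_chromosomes),
              snps_per_chromosome = as.integer(snps_per_chromosome),
              chromosome_length = as.numeric(chromosome_length),
              ld_block_mean_span = as.numeric(ld_block_mean_span),
              n_true_qtls = as.integer(n_true_qtls),
              alleles_per_qtl = as.integer(range(alleles_per_qtl)),
              effect_scale = as.numeric(effect_scale),
              heritability_target = as.numeric(heritability_target),
              n_environments = as.integer(n_environments),
              n_replicates = as.integer(n_replicates),
              gxe_variance_fraction = as.numeric(gxe_variance_fraction),
              mu = as.numeric(mu),
              env_sd = as.numeric(env_sd),
              qtl_effect_values = qtl_effect_values,
              master_seed = as.integer(master_seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_accessions", "n_chromosomes", "snps_per_chromosome",
              "n_environments", "n_replicates")
  for (nm in counts)
    if (cfg[[nm]] < 1L) stop(sprintf("'%s' must be >= 1", nm))
  if (cfg$n_true_qtls < 0L) stop("'n_true_qtls' must be >= 0")
  if (cfg$heritability_target <= 0 || cfg$heritability_target > 1)
    stop("'heritability_target' must be in (0, 1]")
  if (cfg$gxe_variance_fraction < 0 || cfg$gxe_variance_fraction > 1)
    stop("'gxe_variance_fraction' must be in [0, 1]")
  if (cfg$alleles_per_qtl[1] < 2L)
    stop("'alleles_per_qtl' lower bound must be >= 2")
  if (cfg$chromosome_length < cfg$snps_per_chromosome)
    stop("'chromosome_length' too short for requested SNP count")
  # the noise partition must be solvable: sigma2_e >= 0 requires
  # f <= n * (1/h2 - 1) where f is the GxE fraction of sigma2_g
  h2 <- cfg$heritability_target
  if (cfg$n_true_qtls > 0 &&
      cfg$gxe_variance_fraction > cfg$n_environments * (1 / h2 - 1) + 1e-12)
    stop("configuration error: heritability_target unreachable with the ",
         "requested GxE variance fraction (residual variance would be ",
         "negative)")
  invisible(cfg)
}
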