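# Shared small simulated population, built once per test run.
.pop_cache <- new.env(parent = emptyenv())

tiny_pop <- function() {
  if (is.null(.pop_cache$pop)) {
    .pop_cache$pop <- simulate_population(sim_config(
      n_accessions = 80, n_chromosomes = 4, snps_per_chromosome = 40,
      n_true_qtls = 3, master_seed = 42))
  }
  .pop_cache$pop
}

tiny_scan <- function() {
  if (is.null(.pop_cache$scan)) {
    pop <- tiny_pop()
    g <- qc_filter(pop$genotypes)
    ldb <- build_snpldb(g)
    cov <- structure_covariates(similarity_matrix(ldb), 5)
    pre <- stage1_scan(ldb, pop$phenotypes, cov)
    scan <- stage2_stepwise(ldb, pre, pop$phenotypes, cov,
      scan_settings(heritability_cap = pop$truth$realized_h2))
    .pop_cache$scan <- list(geno_qc = g, ldb = ldb, cov = cov,
                            pre = pre, scan = scan)
  }
  .pop_cache$scan
}

# brute-force D' oracle from explicit haplotype counts
dprime_oracle <- function(n_AB, n_Ab, n_aB, n_ab) {
  n <- n_AB + n_Ab + n_aB + n_ab
  pA <- (n_AB + n_Ab) / n
  pB <- (n_AB + n_aB) / n
  D <- n_AB / n - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  if (dmax == 0) 0 else abs(D) / dmax
}

# genotype columns (0/2 coding) realising given haplotype counts
haplo_columns <- function(n_AB, n_Ab, n_aB, n_ab) {
  a <- rep(c(2L, 2L, 0L, 0L), c(n_AB, n_Ab, n_aB, n_ab))
  b <- rep(c(2L, 0L, 2L, 0L), c(n_AB, n_Ab, n_aB, n_ab))
  list(a = a, b = b)
}
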