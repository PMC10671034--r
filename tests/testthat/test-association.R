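test_that("stage 1 retains a strong marker and drops constant phenotypes", {
  s <- tiny_scan()
  pop <- tiny_pop()
  # a marker splitting the phenotype with a huge gap is retained with tiny p
  expect_true(nrow(s$pre) > 0)
  expect_lt(min(s$pre$p), 1e-6)
  # constant phenotype: nothing survives
  ph0 <- pop$phenotypes
  ph0$value <- 50
  pre0 <- stage1_scan(s$ldb, ph0, s$cov)
  expect_equal(nrow(pre0), 0)
})

test_that("stage-1 F-test matches lm() on a single marker", {
  s <- tiny_scan()
  pop <- tiny_pop()
  m <- s$ldb$markers[[1]]
  ph <- aggregate(value ~ accession + env, pop$phenotypes, mean)
  ph <- ph[order(ph$accession, ph$env), ]
  allele <- m$assign[match(ph$accession, s$ldb$accessions)]
  fit0 <- lm(ph$value ~ factor(ph$env))
  fit1 <- lm(ph$value ~ factor(ph$env) + allele)
  ftab <- anova(fit0, fit1)
  pre <- stage1_scan(s$ldb, pop$phenotypes, covariates = NULL)
  all_tab <- attr(pre, "all")
  got <- all_tab[all_tab$marker == m$id, ]
  expect_equal(got$F, ftab$F[2], tolerance = 1e-8)
  expect_equal(got$p, ftab$`Pr(>F)`[2], tolerance = 1e-8)
})

test_that("under permuted phenotypes stage 1 retains about alpha of markers", {
  s <- tiny_scan()
  pop <- tiny_pop()
  # permute accession means (independent rows) so the single-marker F test
  # is calibrated; within-accession correlation across environments would
  # otherwise inflate its size, which is why preselection is liberal
  means <- aggregate(value ~ accession, pop$phenotypes, mean)
  set.seed(77)
  n_mark <- length(s$ldb$markers)
  rates <- replicate(10, {
    ph <- data.frame(accession = sample(means$accession), env = "E1",
                     value = means$value)
    pre <- stage1_scan(s$ldb, ph, covariates = NULL)
    nrow(pre) / nrow(attr(pre, "all"))
  })
  tol <- 3 * sqrt(0.05 * 0.95 / (n_mark * 10))
  expect_lt(abs(mean(rates) - 0.05), tol + 0.02)
})

test_that("stepwise recovers the planted QTLs with few extras", {
  s <- tiny_scan()
  pop <- tiny_pop()
  rec <- s$scan$records
  qtls <- pop$truth$qtls
  hit <- vapply(seq_len(nrow(qtls)), function(i) {
    any(rec$chrom == qtls$chrom[i] &
          abs(rec$pos - qtls$start[i]) < 2e5)
  }, logical(1))
  expect_true(all(hit))
  expect_lte(nrow(rec) - sum(hit), 1)
})

test_that("every retained locus beats the removal threshold and the model
           respects the heritability cap", {
  s <- tiny_scan()
  sc <- s$scan
  thr <- sc$settings$remove_alpha / sc$n_preselected
  main_p <- 10^(-sc$records$main_log10p[!is.na(sc$records$main_log10p)])
  expect_true(all(main_p <= sc$settings$remove_alpha))
  expect_lte(sc$genetic_r2 / 100,
             sc$settings$heritability_cap + 1e-8)
})

test_that("duplicate markers cannot both enter (collinearity guard)", {
  pop <- tiny_pop()
  g <- impute_mode(qc_filter(pop$genotypes))
  ldb <- build_snpldb(g)
  # duplicate the strongest marker under a new id at a later position
  s <- tiny_scan()
  best <- s$scan$records$marker[which.max(s$scan$records$main_r2)]
  ids <- vapply(ldb$markers, `[[`, "", "id")
  dup <- ldb$markers[[match(best, ids)]]
  dup$id <- "DUP_MARKER"
  dup$start <- dup$start + 1
  ldb$markers[[length(ldb$markers) + 1]] <- dup
  pre <- stage1_scan(ldb, pop$phenotypes, s$cov)
  sc <- stage2_stepwise(ldb, pre, pop$phenotypes, s$cov,
                        scan_settings(heritability_cap = 0.9))
  expect_lte(sum(sc$records$marker %in% c(best, "DUP_MARKER")), 1)
})

test_that("allele effects satisfy the sum-to-zero constraint and match a
           direct least-squares oracle", {
  s <- tiny_scan()
  eff <- s$scan$allele_effects
  for (q in unique(eff$qtl))
    expect_equal(sum(eff$effect[eff$qtl == q]), 0, tolerance = 1e-9)
  # balanced biallelic toy: group means mu +/- 5 give effects +/- 5
  set.seed(5)
  n <- 40
  assign <- factor(rep(c("a1", "a2"), each = n / 2))
  geno <- cbind(s1 = ifelse(assign == "a1", 0L, 2L))
  rownames(geno) <- sprintf("A%02d", 1:n)
  map <- data.frame(snp = "s1", chrom = 1, pos = 100)
  ldb <- build_snpldb(genotype_matrix(geno, map))
  ph <- data.frame(accession = rep(rownames(geno), 2),
                   env = rep(c("E1", "E2"), each = n),
                   value = rep(ifelse(assign == "a1", 45, 55), 2))
  sc <- stage2_stepwise(ldb, vapply(ldb$markers, `[[`, "", "id"), ph,
                        settings = scan_settings(correction = "none"))
  e <- allele_effects(sc, sc$records$qtl[1])
  expect_equal(sort(e$effect), c(-5, 5), tolerance = 1e-9)
})

test_that("multi-allele effects match the normal-equations oracle", {
  # 3-allele locus with known group means; unweighted sum-to-zero
  n_per <- c(a1 = 12, a2 = 20, a3 = 8)
  means <- c(a1 = 40, a2 = 50, a3 = 58)
  assign <- factor(rep(names(n_per), n_per))
  hap <- list(a1 = c(0L, 0L), a2 = c(2L, 2L), a3 = c(0L, 2L))
  geno <- t(vapply(as.character(assign), function(a) hap[[a]],
                   integer(2)))
  rownames(geno) <- sprintf("A%02d", seq_along(assign))
  colnames(geno) <- c("s1", "s2")
  map <- data.frame(snp = c("s1", "s2"), chrom = 1, pos = c(100, 200))
  ldb <- build_snpldb(genotype_matrix(geno, map), min_freq = 0)
  ph <- data.frame(accession = rownames(geno), env = "E1",
                   value = means[as.character(assign)])
  sc <- stage2_stepwise(ldb, vapply(ldb$markers, `[[`, "", "id"), ph,
                        settings = scan_settings(correction = "none"))
  e <- allele_effects(sc, sc$records$qtl[1])
  oracle <- means - mean(means)   # balanced-free LS solution per group
  got <- setNames(e$effect, e$allele)
  # map haplotype labels back to generating groups via frequencies
  expect_equal(sort(unname(got)), sort(unname(oracle)), tolerance = 1e-9)
})

test_that("R2 partition is exact for a noise-free single locus and
           orthogonal designs add up", {
  # single locus, no noise: locus explains all phenotypic variance
  n <- 30
  assign <- rep(c("x", "y"), each = n / 2)
  geno <- cbind(s1 = ifelse(assign == "x", 0L, 2L))
  rownames(geno) <- sprintf("A%02d", 1:n)
  map <- data.frame(snp = "s1", chrom = 1, pos = 10)
  ldb <- build_snpldb(genotype_matrix(geno, map))
  ph <- data.frame(accession = rownames(geno), env = "E1",
                   value = ifelse(assign == "x", 40, 60))
  sc <- stage2_stepwise(ldb, vapply(ldb$markers, `[[`, "", "id"), ph,
                        settings = scan_settings(correction = "none"))
  expect_equal(sc$records$main_r2, 100, tolerance = 1e-6)
  # two orthogonal loci: partial R2 equals sequential R2
  set.seed(8)
  f1 <- rep(rep(c(0L, 2L), each = 8), 2)
  f2 <- rep(c(0L, 2L), 16)
  geno2 <- cbind(s1 = f1, s2 = f2)
  rownames(geno2) <- sprintf("B%02d", 1:32)
  map2 <- data.frame(snp = c("s1", "s2"), chrom = c(1, 2), pos = c(10, 10))
  ldb2 <- build_snpldb(genotype_matrix(geno2, map2))
  ph2 <- data.frame(accession = rownames(geno2), env = "E1",
                    value = 50 + 4 * (f1 == 2) - 6 * (f2 == 2) +
                      rnorm(32, 0, 1))
  sc2 <- stage2_stepwise(ldb2, vapply(ldb2$markers, `[[`, "", "id"), ph2,
                         settings = scan_settings(correction = "none"))
  y <- ph2$value
  tss <- sum((y - mean(y))^2)
  seq_r2 <- function(f) {
    r0 <- sum(lm(y ~ 1)$residuals^2)
    r1 <- sum(lm(y ~ factor(f))$residuals^2)
    100 * (r0 - r1) / tss
  }
  rec <- sc2$records[order(sc2$records$chrom), ]
  expect_equal(rec$main_r2, c(seq_r2(f1), seq_r2(f2)), tolerance = 1e-6)
})

test_that("contribution classes use the inclusive 1% boundary", {
  expect_equal(classify_contribution(c(5.16, 0.08, 1.00, 0.99)),
               c("LC", "SC", "LC", "SC"))
})

test_that("locus names follow the chromosome-rank convention", {
  expect_equal(name_qtl(12, 4), "q-DLP-12-4")
  expect_equal(name_qtl(1, 1), "q-DLP-01-1")
  expect_equal(name_qtl(c(3, 3), c(1, 2)), c("q-DLP-03-1", "q-DLP-03-2"))
  # ranks in scan output ascend with position within chromosome
  s <- tiny_scan()
  rec <- s$scan$records
  for (ch in unique(rec$chrom)) {
    sub <- rec[rec$chrom == ch, ]
    expect_equal(sub$qtl,
                 name_qtl(sub$chrom, rank(sub$pos)))
  }
})

test_that("QEI terms are found when an interaction is planted", {
  set.seed(31)
  n <- 120
  assign <- factor(rep(c("a1", "a2"), each = n / 2))
  geno <- cbind(s1 = ifelse(assign == "a1", 0L, 2L),
                s2 = sample(c(0L, 2L), n, TRUE))
  rownames(geno) <- sprintf("A%03d", 1:n)
  map <- data.frame(snp = c("s1", "s2"), chrom = c(1, 2), pos = c(10, 10))
  ldb <- build_snpldb(genotype_matrix(geno, map))
  envs <- c("E1", "E2", "E3")
  ph <- expand.grid(accession = rownames(geno), env = envs,
                    stringsAsFactors = FALSE)
  a <- assign[match(ph$accession, rownames(geno))]
  # allele effect flips sign across environments: pure QEI, no main effect
  ph$value <- 50 + ifelse(a == "a1", 1, -1) *
    ifelse(ph$env == "E1", 6, ifelse(ph$env == "E2", -6, 0)) +
    rnorm(nrow(ph), 0, 1)
  sc <- stage2_stepwise(ldb, vapply(ldb$markers, `[[`, "", "id"), ph,
                        settings = scan_settings(correction = "none"))
  rec <- sc$records
  expect_true(any(!is.na(rec$qei_log10p) & rec$chrom == 1))
})
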