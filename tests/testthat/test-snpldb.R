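test_that("QC removes SNPs violating missing/het/MAF thresholds", {
  geno <- rbind(ACC1 = c(0L, 0L, 1L, 0L, NA),
                ACC2 = c(2L, 0L, 1L, 0L, NA),
                ACC3 = c(0L, 0L, 1L, 2L, 0L),
                ACC4 = c(2L, 0L, 0L, 0L, 2L))
  colnames(geno) <- paste0("s", 1:5)
  map <- data.frame(snp = paste0("s", 1:5), chrom = 1, pos = 1:5 * 100)
  g <- genotype_matrix(geno, map)
  # s2 monomorphic (MAF 0), s3 het 75%, s5 missing 50%
  out <- qc_filter(g, max_missing = 0.2, max_het = 0.2, min_maf = 0.01)
  expect_equal(out$map$snp, c("s1", "s4"))
  rep_ <- attr(out, "qc_report")
  expect_equal(rep_$n[rep_$criterion == "kept"], 2)
  # clean matrix passes through unchanged
  clean <- genotype_matrix(geno[, c(1, 4)], map[c(1, 4), ])
  expect_equal(qc_filter(clean)$geno, clean$geno)
  expect_error(qc_filter(g, min_maf = 0.6), "all SNPs removed")
})

test_that("D-prime matches the haplotype-count oracle", {
  h <- haplo_columns(4, 1, 1, 4)
  expect_equal(pairwise_dprime(h$a, h$b), 0.6)
  expect_equal(dprime_oracle(4, 1, 1, 4), 0.6)
  # identical columns are in complete LD
  expect_equal(pairwise_dprime(h$a, h$a), 1)
  # exact product frequencies give D' = 0
  h0 <- haplo_columns(4, 4, 4, 4)
  expect_equal(pairwise_dprime(h0$a, h0$b), 0)
  # symmetric, and equal to the oracle on exhaustive small tables
  for (nAB in 0:3) for (nAb in 0:3) for (naB in 0:3) for (nab in 0:3) {
    n <- nAB + nAb + naB + nab
    if (n < 2) next
    pA <- nAB + nAb; pB <- nAB + naB
    if (pA %in% c(0, n) || pB %in% c(0, n)) next
    hc <- haplo_columns(nAB, nAb, naB, nab)
    d1 <- pairwise_dprime(hc$a, hc$b)
    expect_equal(d1, dprime_oracle(nAB, nAb, naB, nab), tolerance = 1e-12)
    expect_equal(d1, pairwise_dprime(hc$b, hc$a))
  }
})

test_that("D-prime flags degenerate inputs", {
  expect_warning(d <- pairwise_dprime(c(0L, NA), c(NA, 2L)), "fewer than 2")
  expect_true(is.na(d))
  expect_warning(d2 <- pairwise_dprime(c(0L, 0L, 0L), c(0L, 2L, 0L)),
                 "monomorphic")
  expect_true(is.na(d2))
})

test_that("block partition covers every SNP once and respects D'", {
  pop <- tiny_pop()
  g <- qc_filter(pop$genotypes)
  gi <- impute_mode(g)
  blk <- build_blocks(gi)
  expect_equal(nrow(blk), ncol(gi$geno))
  expect_true(all(table(blk$snp) == 1))
  # all within-block pairwise D' above threshold by construction
  for (b in unique(blk$block)) {
    idx <- which(blk$block == b)
    if (length(idx) < 2) next
    for (i in idx[-1]) {
      expect_gt(pairwise_dprime(gi$geno[, idx[1]], gi$geno[, i]), 0.7)
    }
  }
})

test_that("perfect-LD trios merge and independent SNPs stay singletons", {
  set.seed(9)
  n <- 60
  base <- sample(c(0L, 2L), n, replace = TRUE)
  geno <- cbind(s1 = base, s2 = base, s3 = base,
                s4 = sample(c(0L, 2L), n, replace = TRUE),
                s5 = sample(c(0L, 2L), n, replace = TRUE))
  rownames(geno) <- sprintf("A%02d", 1:n)
  map <- data.frame(snp = colnames(geno), chrom = 1,
                    pos = c(100, 200, 300, 100400, 200500))
  g <- genotype_matrix(geno, map)
  blk <- build_blocks(g)
  expect_equal(blk$block[1:3], rep(blk$block[1], 3))
  expect_true(blk$block[4] != blk$block[3])
  ldb <- build_snpldb(g)
  first <- ldb$markers[[1]]
  expect_equal(length(first$snps), 3)
  expect_equal(nrow(first$alleles), 2)  # two haplotypes only
})

test_that("block recovery matches the generator truth on >= 90% of SNP pairs", {
  pop <- tiny_pop()
  g <- impute_mode(qc_filter(pop$genotypes))
  blk <- build_blocks(g)
  truth <- pop$truth$block_id_of_snp[match(blk$snp, pop$genotypes$map$snp)]
  agree <- 0; total <- 0
  for (ch in unique(blk$chrom)) {
    i <- which(blk$chrom == ch)
    same_true <- diff(truth[i]) == 0
    same_est <- diff(blk$block[i]) == 0
    agree <- agree + sum(same_true == same_est)
    total <- total + length(same_true)
  }
  expect_gte(agree / total, 0.9)
})

test_that("haplotype alleles collapse rare classes and drop monomorphic", {
  geno <- rbind(matrix(rep(c(0L, 0L), 60), 60, 2, byrow = TRUE),
                matrix(rep(c(2L, 2L), 30), 30, 2, byrow = TRUE),
                matrix(rep(c(0L, 2L), 5), 5, 2, byrow = TRUE),
                matrix(rep(c(2L, 0L), 5), 5, 2, byrow = TRUE))
  ha <- haplotype_alleles(geno, min_freq = 0.1)
  expect_equal(nrow(ha$alleles), 3)
  expect_true("rare" %in% ha$alleles$allele)
  expect_equal(sum(ha$alleles$freq), 1, tolerance = 1e-9)
  expect_equal(ha$alleles$freq[ha$alleles$allele == "rare"], 0.1)
  # all-identical accessions: marker dropped
  expect_null(haplotype_alleles(matrix(0L, 10, 2)))
})

test_that("marker allele frequencies always sum to one", {
  s <- tiny_scan()
  for (m in s$ldb$markers)
    expect_equal(sum(m$alleles$freq), 1, tolerance = 1e-9)
})

test_that("similarity matrix is a valid IIS-sharing matrix", {
  s <- tiny_scan()
  S <- similarity_matrix(s$ldb)$sim
  expect_equal(diag(S), setNames(rep(1, nrow(S)), rownames(S)))
  expect_equal(S, t(S))
  expect_true(all(S >= 0 & S <= 1))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-8)  # PSD up to tolerance
})

test_that("structure eigenvectors separate planted subpopulations", {
  set.seed(21)
  n <- 60; m <- 40
  subpop <- rep(c(0, 1), each = n / 2)
  geno <- sapply(seq_len(m), function(j) {
    p <- ifelse(subpop == 1, 0.95, 0.05)
    2L * rbinom(n, 1, p)
  })
  rownames(geno) <- sprintf("A%02d", 1:n)
  colnames(geno) <- sprintf("s%02d", 1:m)
  map <- data.frame(snp = colnames(geno), chrom = 1, pos = 1:m * 1e6)
  ldb <- build_snpldb(genotype_matrix(geno, map))
  cov <- structure_covariates(similarity_matrix(ldb), 3)
  # the Perron eigenvector of an uncentered similarity matrix is near
  # constant; the subpopulation split loads on one of the top two axes
  r <- max(abs(cor(cov[, 1], subpop)), abs(cor(cov[, 2], subpop)))
  expect_gt(r, 0.9)
  expect_error(structure_covariates(similarity_matrix(ldb), 0), "positive")
})

test_that("identical and disjoint accessions hit the similarity bounds", {
  geno <- rbind(A1 = c(0L, 0L, 2L), A2 = c(0L, 0L, 2L),
                A3 = c(2L, 2L, 0L))
  colnames(geno) <- paste0("s", 1:3)
  map <- data.frame(snp = paste0("s", 1:3), chrom = 1,
                    pos = c(1, 2e5, 6e5) + 100)
  ldb <- build_snpldb(genotype_matrix(geno, map), min_freq = 0)
  S <- similarity_matrix(ldb)$sim
  expect_equal(S["A1", "A2"], 1)
  expect_equal(S["A1", "A3"], 0)
})
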