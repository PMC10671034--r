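# small hand-built allele matrix for cross tests
toy_matrix <- function(effects, alleles, chrom = NULL, pos = NULL,
                       mu = 50) {
  L <- nrow(effects)
  loci <- data.frame(qtl = rownames(effects),
                     marker = paste0("M", seq_len(L)),
                     chrom = chrom %||% seq_len(L),
                     pos = pos %||% rep(1e6, L))
  structure(list(effects = effects, alleles = alleles, mu = mu,
                 loci = loci), class = "qtl_allele_matrix")
}

test_that("map arithmetic: cM conversion, Haldane, RIL transform", {
  expect_equal(physical_to_genetic(1e6, 1), 1)
  expect_equal(physical_to_genetic(0), 0)
  expect_equal(physical_to_genetic(24526775), 24.526775)
  expect_error(physical_to_genetic(1, rate = 0), "positive")
  expect_equal(ril_recomb_fraction(0), 0)
  expect_equal(ril_recomb_fraction(0.5), 0.5)
  expect_equal(ril_recomb_fraction(0.25), 1 / 3)
  expect_error(ril_recomb_fraction(0.7), "0.5")
})

test_that("genetic map derives adjacent recombination fractions", {
  E <- matrix(c(1, -1, 2, -2), 2, 2,
              dimnames = list(c("q1", "q2"), c("P1", "P2")))
  A <- matrix(c("a1", "a2", "a1", "a2"), 2, 2,
              dimnames = dimnames(E))
  m <- toy_matrix(E, A, chrom = c(1, 1), pos = c(1e6, 11e6))
  gm <- genetic_map(m, rate = 1)
  expect_true(is.na(gm$r[1]))
  expect_equal(gm$r[2], 0.5 * (1 - exp(-2 * 10 / 100)))
  expect_equal(gm$R[2], ril_recomb_fraction(gm$r[2]))
})

test_that("identical parents give zero progeny variance", {
  E <- matrix(c(3, -2, 3, -2), 2, 2,
              dimnames = list(c("q1", "q2"), c("P1", "P2")))
  A <- matrix("a1", 2, 2, dimnames = dimnames(E))
  m <- toy_matrix(E, A)
  v <- simulate_cross(m, "P1", "P2", n_progeny = 500, seed = 3)
  expect_equal(var(v), 0)
  expect_equal(v[1], m$mu + 3 - 2)
})

test_that("two unlinked loci in repulsion give four classes at 1/4", {
  # parents: P1 = (+a, -b), P2 = (-a, +b); unlinked (different chromosomes)
  a <- 4; b <- 6
  E <- matrix(c(a, -b, -a, b), 2, 2,
              dimnames = list(c("q1", "q2"), c("P1", "P2")))
  A <- matrix(c("a1", "a1", "a2", "a2"), 2, 2, dimnames = dimnames(E))
  m <- toy_matrix(E, A, chrom = c(1, 2))
  n <- 2000
  v <- simulate_cross(m, "P1", "P2", n_progeny = n, seed = 11)
  classes <- table(round(v - m$mu, 6))
  expected <- sort(c(a - b, a + b, -a - b, -a + b)) + 0
  expect_equal(as.numeric(names(classes)), expected)
  # frequencies within 3 sigma of 1/4 (exhaustive enumeration oracle)
  tol <- 3 * sqrt(0.25 * 0.75 / n)
  expect_true(all(abs(as.numeric(classes) / n - 0.25) < tol))
  # mean matches midparent expectation within Monte-Carlo error
  expect_lt(abs(mean(v) - m$mu), 4 * sqrt((a^2 + b^2) / n))
})

test_that("complete linkage in coupling yields only parental classes", {
  E <- matrix(c(2, 3, -2, -3), 2, 2,
              dimnames = list(c("q1", "q2"), c("P1", "P2")))
  A <- matrix(c("a1", "a1", "a2", "a2"), 2, 2, dimnames = dimnames(E))
  m <- toy_matrix(E, A, chrom = c(1, 1), pos = c(1e6, 1e6 + 10))
  v <- simulate_cross(m, "P1", "P2", n_progeny = 1000, seed = 5)
  expect_true(all(round(v - m$mu, 6) %in% c(5, -5)))
})

test_that("linkage model at r = 0.5 matches the independent model", {
  s <- tiny_scan()
  am <- build_allele_matrix(s$scan, s$ldb)
  gm <- genetic_map(am)
  gm$r[] <- 0.5
  gm$R[] <- 0.5
  acc <- colnames(am$effects)
  p <- accession_summary(am)
  pick <- c(which.min(p$sum), which.max(p$sum))
  v1 <- simulate_cross(am, acc[pick[1]], acc[pick[2]], gm, 2000,
                       "linkage", seed = 21)
  v2 <- simulate_cross(am, acc[pick[1]], acc[pick[2]], gm, 2000,
                       "independent", seed = 22)
  expect_gt(suppressWarnings(stats::ks.test(v1, v2)$p.value), 0.01)
})

test_that("progeny allele frequencies at segregating loci are near 1/2", {
  E <- matrix(c(5, -5), 1, 2, dimnames = list("q1", c("P1", "P2")))
  A <- matrix(c("a1", "a2"), 1, 2, dimnames = dimnames(E))
  m <- toy_matrix(E, A)
  n <- 2000
  v <- simulate_cross(m, "P1", "P2", n_progeny = n, seed = 9)
  f <- mean(v > m$mu)
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / n))
})

test_that("percentiles follow the type-7 convention and are ordered", {
  expect_equal(unname(cross_percentiles(rep(7, 10))),
               c(7, 7, 7, 7, 7))
  q <- cross_percentiles(1:100)
  expect_equal(q[["p25"]], 25.75)
  expect_equal(q[["p50"]], 50.5)
  expect_error(cross_percentiles(numeric(0)), "empty")
  set.seed(13)
  for (i in 1:20) {
    q <- cross_percentiles(rnorm(50))
    expect_true(q[["p20"]] <= q[["p25"]] &&
                  q[["p25"]] <= q[["p50"]] &&
                  q[["p50"]] <= q[["p75"]])
    expect_gte(q[["mean"]], min(rnorm(0), q[["p20"]] - 10))
  }
})

test_that("all-pairs prediction is complete, deterministic and bounded
           below by the best-recombinant value", {
  s <- tiny_scan()
  am <- build_allele_matrix(s$scan, s$ldb)
  amp <- submatrix(am, colnames(am$effects)[1:8])
  pr1 <- predict_all_crosses(amp, n_progeny = 300, master_seed = 4)
  pr2 <- predict_all_crosses(amp, n_progeny = 300, master_seed = 4)
  expect_equal(nrow(pr1), 8 * 7 / 2)
  expect_identical(pr1, pr2)
  pr3 <- predict_all_crosses(amp, n_progeny = 300, master_seed = 5)
  expect_false(identical(pr1$p25, pr3$p25))
  # best possible recombinant bound on P25
  for (k in seq_len(nrow(pr1))) {
    lo <- amp$mu + sum(pmin(amp$effects[, pr1$parent1[k]],
                            amp$effects[, pr1$parent2[k]]))
    expect_gte(pr1$p25[k], lo - 1e-9)
  }
})

test_that("a planted complementary pair ranks first among optimal crosses", {
  # P1 and P2 carry disjoint strong negative alleles; their cross can
  # stack both, so it beats every cross involving the neutral P3/P4
  E <- matrix(c(-8, 0, -1, -6, 0, 0, 0, 0), 2, 4,
              dimnames = list(c("q1", "q2"), c("P1", "P2", "P3", "P4")))
  A <- matrix(c("a1", "b1", "a2", "b2", "a3", "b1", "a3", "b1"), 2, 4,
              dimnames = dimnames(E))
  m <- toy_matrix(E, A, chrom = c(1, 2))
  pr <- predict_all_crosses(m, n_progeny = 2000, master_seed = 6)
  best <- optimal_crosses(pr, threshold = m$mu)
  expect_equal(sort(c(best$parent1[1], best$parent2[1])), c("P1", "P2"))
  expect_equal(nrow(optimal_crosses(pr, threshold = -Inf)), 0)
  expect_equal(nrow(optimal_crosses(pr, threshold = Inf)), nrow(pr))
})

test_that("recombination potential arithmetic matches the definition", {
  rp <- recombination_potential(44.5, 17.2, p25_mean = 37.0, p25_min = 3.0)
  expect_equal(unname(rp["average"]), 7.5)
  expect_equal(unname(rp["max_improvement"]), 41.5)
  expect_equal(unname(rp["max_transgression"]), 14.2)
  rp2 <- recombination_potential(50, 20, p25 = c(20, 30, 40))
  expect_equal(unname(rp2["max_transgression"]), 0)
})

test_that("group summaries split crosses within and between groups", {
  E <- matrix(c(-2, 2, 0, 0), 1, 4,
              dimnames = list("q1", c("P1", "P2", "P3", "P4")))
  A <- matrix(c("a1", "a2", "a3", "a3"), 1, 4, dimnames = dimnames(E))
  m <- toy_matrix(E, A)
  pr <- predict_all_crosses(m, n_progeny = 200, master_seed = 2)
  groups <- setNames(c("G1", "G1", "G2", "G2"), colnames(E))
  gs <- cross_group_summary(pr, groups, c(All = 49, G1 = 49, G2 = 49))
  expect_equal(gs$n_crosses[gs$group == "Within"], 2)
  expect_equal(gs$n_crosses[gs$group == "Between"], 4)
  expect_equal(gs$n_crosses[gs$group == "All"], 6)
})
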