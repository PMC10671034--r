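#' Physical to genetic positions
#'
#' Linear conversion at a constant recombination rate (default 1 cM/Mb);
#' no genetic map accompanies the marker set, so this documented stand-in
#' provides the distances the linkage model needs.
#'
#' @param positions_bp physical positions.
#' @param rate cM per Mb (> 0).
#' @return positions in cM.
#' @export
physical_to_genetic <- function(positions_bp, rate = 1) {
  if (rate <= 0) stop("'rate' must be positive")
  positions_bp * rate / 1e6
}

# Haldane map function: cM distance -> per-meiosis recombination fraction
haldane_r <- function(d_cm) 0.5 * (1 - exp(-2 * d_cm / 100))

#' Recombination fraction between inbred-line genotypes
#'
#' For recombinant inbred lines derived by continued selfing, the
#' probability that two loci with per-meiosis recombination fraction r end
#' up in recombinant phase is R = 2r / (1 + 2r).
#'
#' @param r per-meiosis recombination fraction in [0, 0.5].
#' @return R in [0, 0.5].
#' @export
ril_recomb_fraction <- function(r) {
  if (any(r < 0 | r > 0.5, na.rm = TRUE)) stop("'r' must be in [0, 0.5]")
  2 * r / (1 + 2 * r)
}

#' Genetic map over the loci of a QTL-allele matrix
#'
#' Derives cM positions from physical positions, adjacent-locus
#' recombination fractions (Haldane) and their inbred-line equivalents.
#'
#' @param m a `qtl_allele_matrix`.
#' @param rate cM per Mb.
#' @return data.frame `qtl`, `chrom`, `pos`, `cm`, `r` (to the previous
#'   locus on the same chromosome, NA for the first), `R` (inbred-line
#'   fraction).
#' @export
genetic_map <- function(m, rate = 1) {
  stopifnot(inherits(m, "qtl_allele_matrix"))
  gm <- m$loci[, c("qtl", "chrom", "pos")]
  gm <- gm[order(gm$chrom, gm$pos), ]
  gm$cm <- physical_to_genetic(gm$pos, rate)
  gm$r <- NA_real_
  for (ch in unique(gm$chrom)) {
    i <- which(gm$chrom == ch)
    if (length(i) > 1)
      gm$r[i[-1]] <- haldane_r(diff(gm$cm[i]))
  }
  gm$R <- ril_recomb_fraction(gm$r)
  rownames(gm) <- NULL
  gm
}

#' Simulate inbred progenies of one cross
#'
#' Draws `n_progeny` fully homozygous recombinant inbred progenies of two
#' parents from the QTL-allele matrix.  Per chromosome, parental origin
#' follows a Markov chain over the loci: the first locus comes from either
#' parent with probability 1/2 and each subsequent locus switches parental
#' origin with probability R (linkage model) or 1/2 (independent
#' assortment).  Loci where the parents carry the same allele are fixed.
#' The progeny value is mu plus the sum of chosen allele effects (pure
#' genotypic values; no residual noise).
#'
#' @param m a `qtl_allele_matrix`.
#' @param parent1,parent2 accession ids.
#' @param map output of [genetic_map()] (required for the linkage model).
#' @param n_progeny progenies to draw (default 2000).
#' @param model `"linkage"` or `"independent"`.
#' @param seed integer seed.
#' @return numeric vector of progeny genotypic values (percent).
#' @export
simulate_cross <- function(m, parent1, parent2, map = NULL,
                           n_progeny = 2000,
                           model = c("linkage", "independent"),
                           seed = 1L) {
  stopifnot(inherits(m, "qtl_allele_matrix"))
  model <- match.arg(model)
  for (p in c(parent1, parent2))
    if (!p %in% colnames(m$effects)) stop(sprintf("unknown parent '%s'", p))
  if (is.null(map)) map <- genetic_map(m)
  ord <- match(map$qtl, rownames(m$effects))
  if (any(is.na(ord))) stop("locus mismatch between matrix and map")
  e1 <- m$effects[ord, parent1]
  e2 <- m$effects[ord, parent2]
  L <- length(ord)
  set.seed(seed)
  switch_p <- if (model == "independent") rep(0.5, L)
              else ifelse(is.na(map$R), 0.5, map$R)
  switch_p[is.na(map$r)] <- 0.5   # chromosome starts: fresh 1/2 draw
  U <- matrix(runif(n_progeny * L), n_progeny, L)
  S <- U < matrix(switch_p, n_progeny, L, byrow = TRUE)
  # cumulative switches mod 2 give parental origin along the chromosome;
  # the chromosome-start columns use probability 1/2 so the chain restarts
  cum <- S * 1L
  if (L > 1) for (j in 2:L) cum[, j] <- cum[, j - 1] + cum[, j]
  origin <- (cum %% 2) == 1
  vals <- m$mu + as.numeric(
    origin %*% e1 + (!origin) %*% e2)
  vals
}

#' Percentile summary of a progeny sample
#'
#' Linear-interpolation (type 7) quantiles at the 20th, 25th, 50th and 75th
#' percentiles plus the mean.  The 25th percentile serves as the predicted
#' cross value.
#'
#' @param values progeny values.
#' @return named numeric: `mean`, `p20`, `p25`, `p50`, `p75`.
#' @export
cross_percentiles <- function(values) {
  if (length(values) == 0) stop("empty progeny sample")
  q <- quantile(values, probs = c(0.2, 0.25, 0.5, 0.75), type = 7,
                names = FALSE)
  c(mean = mean(values), p20 = q[1], p25 = q[2], p50 = q[3], p75 = q[4])
}

#' Predict progeny distributions for all parent pairs
#'
#' Simulates all N(N-1)/2 unordered crosses among the accessions of the
#' QTL-allele matrix and summarises each by its percentile profile.
#' Per-cross child seeds derive deterministically from the sorted parent
#' indices and the master seed, so results do not depend on execution
#' order.
#'
#' @param m a `qtl_allele_matrix`.
#' @param map a [genetic_map()] (default derived at 1 cM/Mb).
#' @param model `"linkage"` or `"independent"`.
#' @param n_progeny progenies per cross (default 2000).
#' @param master_seed master seed.
#' @param transgression_threshold optional observed population minimum; if
#'   given, crosses with p25 below it are flagged transgressive.
#' @return data.frame `parent1`, `parent2`, `model`, `mean`, `p20`, `p25`,
#'   `p50`, `p75` (+ `transgressive` when a threshold is given).
#' @export
predict_all_crosses <- function(m, map = NULL,
                                model = c("linkage", "independent"),
                                n_progeny = 2000, master_seed = 1L,
                                transgression_threshold = NULL) {
  stopifnot(inherits(m, "qtl_allele_matrix"))
  model <- match.arg(model)
  if (is.null(map)) map <- genetic_map(m)
  acc <- colnames(m$effects)
  n <- length(acc)
  if (n < 2) stop("need at least two accessions")
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  out <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1]; j <- pairs[k, 2]
    sd_k <- child_seed(master_seed, i * 100003L + j)
    v <- simulate_cross(m, acc[i], acc[j], map, n_progeny, model,
                        seed = sd_k)
    out[[k]] <- c(cross_percentiles(v))
  }
  res <- as.data.frame(do.call(rbind, out))
  res <- cbind(data.frame(parent1 = acc[pairs[, 1]],
                          parent2 = acc[pairs[, 2]],
                          model = model), res)
  if (!is.null(transgression_threshold))
    res$transgressive <- res$p25 < transgression_threshold
  res
}

#' Optimal crosses below a threshold
#'
#' Crosses whose predicted 25th-percentile value falls below the observed
#' population minimum (or any supplied threshold), sorted ascending -- the
#' transgressive crosses a breeding program would shortlist.
#'
#' @param predictions output of [predict_all_crosses()].
#' @param threshold usually the observed population minimum.
#' @param top_k optionally return only the first `top_k` rows.
#' @return sorted subset of `predictions`.
#' @export
optimal_crosses <- function(predictions, threshold, top_k = NULL) {
  out <- predictions[predictions$p25 < threshold, , drop = FALSE]
  out <- out[order(out$p25), , drop = FALSE]
  if (!is.null(top_k)) out <- head(out, top_k)
  rownames(out) <- NULL
  out
}

#' Recombination potential of a population
#'
#' From the distribution of predicted 25th-percentile cross values:
#' the average potential (population mean minus mean predicted value), the
#' maximum improvement (population mean minus the best predicted value) and
#' the maximum transgression (observed population minimum minus the best
#' predicted value).
#'
#' @param population_mean observed population mean (percent).
#' @param population_min observed population minimum (percent).
#' @param p25 vector of per-cross 25th percentiles (or use the two summary
#'   arguments).
#' @param p25_mean,p25_min summary statistics of p25 (defaulting to the
#'   vector's mean and min).
#' @return named numeric: `average`, `max_improvement`,
#'   `max_transgression`.
#' @export
recombination_potential <- function(population_mean, population_min,
                                    p25 = NULL,
                                    p25_mean = mean(p25),
                                    p25_min = min(p25)) {
  if (is.null(p25) && (missing(p25_mean) || missing(p25_min)))
    stop("supply 'p25' or both 'p25_mean' and 'p25_min'")
  c(average = population_mean - p25_mean,
    max_improvement = population_mean - p25_min,
    max_transgression = population_min - p25_min)
}

#' Group summary of cross predictions
#'
#' Summarises the 25th-percentile cross values within and between
#' user-supplied accession groups (e.g. ecoregions): number of crosses,
#' mean/min/max of p25 and the count of optimal crosses below each group's
#' observed minimum.
#'
#' @param predictions output of [predict_all_crosses()].
#' @param groups named vector mapping accession -> group label.
#' @param group_min named vector of observed minima per group label; a
#'   `"All"` entry is used for the overall rows.
#' @return data.frame, one row per group plus `Within`, `Between`, `All`.
#' @export
cross_group_summary <- function(predictions, groups, group_min) {
  g1 <- groups[predictions$parent1]
  g2 <- groups[predictions$parent2]
  all_min <- group_min[["All"]]
  row_of <- function(label, sel, thr) {
    p <- predictions$p25[sel]
    data.frame(group = label, n_crosses = sum(sel),
               p25_mean = mean(p), p25_min = min(p), p25_max = max(p),
               n_optimal = sum(p < thr))
  }
  rows <- lapply(sort(unique(groups)), function(gl)
    row_of(gl, g1 == gl & g2 == gl, group_min[[gl]] %||% all_min))
  within <- g1 == g2
  rows <- c(rows, list(row_of("Within", within, all_min),
                       row_of("Between", !within, all_min),
                       row_of("All", rep(TRUE, nrow(predictions)),
                              all_min)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
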