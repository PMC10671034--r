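#' Evaluate a scan against simulated ground truth
#'
#' For simulation studies: matches detected loci to the planted QTLs of a
#' [simulate_population()] run and summarises detection and effect
#' recovery.  A planted QTL counts as detected when a locus in the final
#' model lies within `window` bp of its block on the same chromosome.
#' Effect recovery is the Pearson correlation, pooled over accessions and
#' detected loci, between each accession's true allele effect and the
#' estimated effect of the allele it carries at the matched marker.
#'
#' @param pop a `sim_population`.
#' @param scan a `qtl_scan` run on markers built from `pop`.
#' @param markers the `snpldb_set` used in the scan.
#' @param window matching window in bp (default 200 kb).
#' @return list: `detected` (logical per planted QTL), `detection_rate`,
#'   `effect_correlation`, `n_extra` (model loci matching no planted QTL).
#' @export
scan_recovery <- function(pop, scan, markers, window = 2e5) {
  stopifnot(inherits(pop, "sim_population"), inherits(scan, "qtl_scan"))
  qtls <- pop$truth$qtls
  rec <- scan$records
  if (is.null(rec) || nrow(rec) == 0) {
    return(list(detected = rep(FALSE, nrow(qtls)), detection_rate = 0,
                effect_correlation = NA_real_, n_extra = 0L))
  }
  matched_rec <- rep(NA_integer_, nrow(qtls))
  for (i in seq_len(nrow(qtls))) {
    cand <- which(rec$chrom == qtls$chrom[i] &
                    rec$pos >= qtls$start[i] - window &
                    rec$pos <= qtls$end[i] + window)
    if (length(cand))
      matched_rec[i] <- cand[which.min(abs(rec$pos[cand] - qtls$start[i]))]
  }
  detected <- !is.na(matched_rec)
  n_extra <- nrow(rec) - length(unique(stats::na.omit(matched_rec)))

  eff_corr <- NA_real_
  if (any(detected) && !is.null(scan$allele_effects)) {
    ids <- vapply(markers$markers, `[[`, "", "id")
    true_v <- list(); est_v <- list()
    for (i in which(detected)) {
      r <- rec[matched_rec[i], ]
      e <- scan$allele_effects[scan$allele_effects$marker == r$marker, ]
      if (nrow(e) == 0) next
      m <- markers$markers[[match(r$marker, ids)]]
      est <- e$effect[match(as.character(m$assign), e$allele)]
      tru <- pop$truth$allele_effects[[i]][
        pop$truth$allele_assignment[markers$accessions, i]]
      ok <- !is.na(est)
      true_v[[length(true_v) + 1]] <- tru[ok]
      est_v[[length(est_v) + 1]] <- est[ok]
    }
    if (length(true_v)) {
      tv <- unlist(true_v); ev <- unlist(est_v)
      if (sd(tv) > 0 && sd(ev) > 0) eff_corr <- stats::cor(tv, ev)
    }
  }
  list(detected = detected,
       detection_rate = mean(detected),
       effect_correlation = eff_corr,
       n_extra = as.integer(n_extra))
}
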