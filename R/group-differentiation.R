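#' Assign accessions to resistance groups by phenotype quantiles
#'
#' Ranks accessions by trait value (ascending; lower DLP = more resistant)
#' and assigns the bottom fraction to RV (resistant varieties), the top
#' fraction to SV (susceptible varieties), and the remainder to MRV
#' (moderately resistant varieties).  Group sizes are floor(p * N) for the
#' two tails; ties are broken by accession id so the split is
#' deterministic.
#'
#' @param phenotypes named numeric vector of per-accession trait means.
#' @param proportions fractions (RV, MRV, SV) summing to 1 (default
#'   0.2/0.6/0.2).
#' @return object of class `resistance_groups`: `group` (named factor with
#'   levels RV, MRV, SV) and `ranges` (per-group min/max of the trait).
#' @export
assign_groups <- function(phenotypes, proportions = c(0.2, 0.6, 0.2)) {
  if (length(phenotypes) < 5) stop("need at least 5 accessions")
  if (abs(sum(proportions) - 1) > 1e-8)
    stop("'proportions' must sum to 1")
  if (is.null(names(phenotypes))) stop("'phenotypes' must be named")
  n <- length(phenotypes)
  ord <- order(phenotypes, names(phenotypes))
  n_rv <- floor(proportions[1] * n)
  n_sv <- floor(proportions[3] * n)
  lab <- rep("MRV", n)
  lab[seq_len(n_rv)] <- "RV"
  lab[seq(n - n_sv + 1, n)] <- "SV"
  group <- factor(lab[order(ord)], levels = c("RV", "MRV", "SV"))
  names(group) <- names(phenotypes)
  ranges <- do.call(rbind, lapply(levels(group), function(gl) {
    v <- phenotypes[group == gl]
    data.frame(group = gl, n = length(v), min = min(v), max = max(v))
  }))
  structure(list(group = group, ranges = ranges),
            class = "resistance_groups")
}

#' @export
print.resistance_groups <- function(x, ...) {
  cat("resistance_groups:\n")
  print(x$ranges, row.names = FALSE)
  invisible(x)
}

#' Per-group allele carrier frequencies
#'
#' For each locus allele, the percentage of carriers within the entire
#' population, each resistance group and the pooled MRV + RV set.
#'
#' @param m a `qtl_allele_matrix` (its `alleles` matrix supplies the
#'   carried allele per locus and accession).
#' @param groups a `resistance_groups` over the same accessions.
#' @return data.frame `qtl`, `allele`, `freq_entire`, `freq_sv`,
#'   `freq_mrv`, `freq_rv`, `freq_mrv_rv` (percent).
#' @export
group_allele_frequencies <- function(m, groups) {
  stopifnot(inherits(m, "qtl_allele_matrix"),
            inherits(groups, "resistance_groups"))
  acc <- colnames(m$alleles)
  g <- groups$group[acc]
  if (any(is.na(g))) stop("groups missing for some accessions")
  if (any(table(g) == 0)) stop("empty resistance group")
  sets <- list(entire = rep(TRUE, length(acc)),
               sv = g == "SV", mrv = g == "MRV", rv = g == "RV",
               mrv_rv = g %in% c("MRV", "RV"))
  rows <- list()
  for (i in seq_len(nrow(m$alleles))) {
    al <- m$alleles[i, ]
    for (a in sort(unique(al))) {
      fr <- vapply(sets, function(s) 100 * mean(al[s] == a), numeric(1))
      rows[[length(rows) + 1]] <- data.frame(
        qtl = rownames(m$alleles)[i], allele = a,
        freq_entire = fr[["entire"]], freq_sv = fr[["sv"]],
        freq_mrv = fr[["mrv"]], freq_rv = fr[["rv"]],
        freq_mrv_rv = fr[["mrv_rv"]])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify an allele's change between two groups
#'
#' Presence rule: an allele is `increased` in the derived group iff it is
#' absent from the reference group but present in the derived one,
#' `decreased` iff present in the reference but absent from the derived,
#' and `inherent` otherwise.  This is a presence/absence rule -- frequency
#' shifts that do not cross zero are inherent.
#'
#' @param freq_reference,freq_derived carrier frequencies (any common
#'   scale), vectorised.
#' @return factor with levels `increased`, `decreased`, `inherent`.
#' @export
classify_change <- function(freq_reference, freq_derived) {
  if (any(freq_reference < 0 | freq_derived < 0, na.rm = TRUE))
    stop("frequencies must be non-negative")
  out <- ifelse(freq_reference == 0 & freq_derived > 0, "increased",
         ifelse(freq_reference > 0 & freq_derived == 0, "decreased",
                "inherent"))
  factor(out, levels = c("increased", "decreased", "inherent"))
}

# classification of each record for one named comparison
comparison_class <- function(records, comparison) {
  switch(comparison,
    "MRV vs SV" = classify_change(records$freq_sv, records$freq_mrv),
    "RV vs MRV" = classify_change(records$freq_mrv, records$freq_rv),
    "RV vs SV"  = classify_change(records$freq_sv, records$freq_rv),
    "MRV+RV vs SV" = {
      a <- classify_change(records$freq_sv, records$freq_mrv)
      b <- classify_change(records$freq_sv, records$freq_rv)
      out <- ifelse(a == "increased" | b == "increased", "increased",
             ifelse(a == "decreased" | b == "decreased", "decreased",
                    "inherent"))
      factor(out, levels = c("increased", "decreased", "inherent"))
    },
    stop(sprintf("unknown comparison '%s'", comparison)))
}

#' Summarise allele changes between resistance groups
#'
#' Applies the presence rule to every allele record for the requested
#' comparisons and tallies changed/increased/decreased alleles with their
#' negative/positive effect breakdown and distinct-locus counts.  The
#' union comparison `"MRV+RV vs SV"` classifies an allele as changed if it
#' changed in either the MRV-vs-SV or the RV-vs-SV comparison.
#'
#' @param records data.frame with columns `qtl`, `allele`, `effect`,
#'   `freq_sv`, `freq_mrv`, `freq_rv` (e.g. [group_allele_frequencies()]
#'   merged with effects, or the packaged `allele_changes` reference
#'   table).
#' @param comparisons character vector among `"MRV vs SV"`, `"RV vs MRV"`,
#'   `"RV vs SV"`, `"MRV+RV vs SV"`.
#' @return data.frame of counts, one row per comparison: changed /
#'   increased / decreased allele and locus counts, with negative/positive
#'   splits.
#' @export
change_summary <- function(records,
                           comparisons = c("MRV vs SV", "RV vs MRV",
                                           "RV vs SV", "MRV+RV vs SV")) {
  rows <- lapply(comparisons, function(cmp) {
    cl <- comparison_class(records, cmp)
    inc <- cl == "increased"; dec <- cl == "decreased"
    data.frame(
      comparison = cmp,
      changed_alleles = sum(inc | dec),
      changed_loci = length(unique(records$qtl[inc | dec])),
      increased_alleles = sum(inc),
      increased_negative = sum(inc & records$effect < 0),
      increased_positive = sum(inc & records$effect > 0),
      increased_loci = length(unique(records$qtl[inc])),
      decreased_alleles = sum(dec),
      decreased_negative = sum(dec & records$effect < 0),
      decreased_positive = sum(dec & records$effect > 0),
      decreased_loci = length(unique(records$qtl[dec])))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Integrate gene annotations with allele changes
#'
#' Joins changed-allele records to a gene table keyed by QTL and tallies
#' the gene-backed subset: distinct annotated genes, changed alleles on
#' annotated loci, increased-negative and decreased-positive allele counts
#' (union comparison) with distinct-locus counts, and per-category
#' breakdowns.
#'
#' @param records as in [change_summary()]; only rows changed under the
#'   union comparison are integrated.
#' @param genes data.frame with columns `qtl`, `gene`, `category` (rows
#'   with missing gene are ignored).
#' @return list with `records` (annotated changed alleles), `counts`
#'   (named numeric summary) and `category_alleles` / `category_genes`
#'   tallies.
#' @export
integrate_genes <- function(records, genes) {
  cl <- comparison_class(records, "MRV+RV vs SV")
  changed <- records[cl != "inherent", , drop = FALSE]
  changed$change <- droplevels(cl[cl != "inherent"])
  # the gene table is the single source of annotations: drop any gene
  # columns the records may already carry
  changed <- changed[, setdiff(names(changed), c("gene", "category")),
                     drop = FALSE]
  gmap <- genes[!is.na(genes$gene) & genes$gene != "", ]
  gmap <- gmap[!duplicated(gmap$qtl), c("qtl", "gene", "category")]
  ann <- merge(changed, gmap, by = "qtl", all.x = TRUE,
               suffixes = c("", ".gene"))
  has_gene <- !is.na(ann$gene)
  inc_neg <- ann$change == "increased" & ann$effect < 0 & has_gene
  dec_pos <- ann$change == "decreased" & ann$effect > 0 & has_gene
  counts <- c(
    changed_alleles = nrow(ann),
    changed_loci = length(unique(ann$qtl)),
    annotated_alleles = sum(has_gene),
    annotated_genes = length(unique(ann$gene[has_gene])),
    annotated_loci = length(unique(ann$qtl[has_gene])),
    increased_negative_alleles = sum(inc_neg),
    increased_negative_loci = length(unique(ann$qtl[inc_neg])),
    decreased_positive_alleles = sum(dec_pos),
    decreased_positive_loci = length(unique(ann$qtl[dec_pos])))
  cat_alleles <- table(ann$category[has_gene])
  cat_genes <- table(gmap$category[match(unique(ann$gene[has_gene]),
                                         gmap$gene)])
  list(records = ann, counts = counts,
       category_alleles = cat_alleles, category_genes = cat_genes)
}
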