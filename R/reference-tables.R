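#' Published reference tables for the soybean antixenosis QTL-allele study
#'
#' Loads the packaged reference tables transcribed from the published
#' analysis of antixenosis (damaged leaf percentage, DLP) against the
#' common cutworm in a 370-accession Chinese soybean landrace population.
#' They anchor the package's regression tests: derived counts recomputed
#' from these tables must reproduce the study's printed summaries.
#'
#' Available tables:
#' \describe{
#'   \item{`qtl_scan`}{the 86 detected DLP QTLs: allele number (AN),
#'     main-effect and QTL-by-environment -log10 p and R-squared (percent).}
#'   \item{`candidate_genes`}{per-QTL physical position and the annotated
#'     candidate gene with its GO biological-process description and
#'     category (I-VIII); 62 of the 86 QTLs carry a gene.}
#'   \item{`allele_changes`}{the 32 QTL-alleles whose presence changes
#'     between resistance groups: effect, frequencies (percent) in the
#'     entire population and the SV/MRV/RV groups, and the linked gene.}
#'   \item{`population_stats`}{population and per-ecoregion descriptive
#'     statistics of DLP (n, mean, min, max, F, h2, GCV, CV).}
#'   \item{`cross_summary`}{per-ecoregion summaries of the 25th-percentile
#'     DLP of all simulated crosses under the linkage and independent
#'     assortment models, with optimal-cross counts.}
#' }
#'
#' @param name one of `"qtl_scan"`, `"candidate_genes"`, `"allele_changes"`,
#'   `"population_stats"`, `"cross_summary"`.
#' @return data.frame.
#' @examples
#' nrow(load_reference_table("qtl_scan"))   # 86
#' @export
load_reference_table <- function(name = c("qtl_scan", "candidate_genes",
                                          "allele_changes",
                                          "population_stats",
                                          "cross_summary")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".csv"),
                      package = "qtlallele", mustWork = TRUE)
  read.csv(path, na.strings = c("NA", ""), stringsAsFactors = FALSE)
}
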