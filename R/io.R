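#' Write genotypes as VCF
#'
#' Homozygous-coded inbred genotypes written as a minimal VCF 4.2 file
#' (0 -> 0/0, 2 -> 1/1, 1 -> 0/1, NA -> ./.).
#'
#' @param g a [genotype_matrix()].
#' @param path output path (plain text).
#' @export
write_genotypes_vcf <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  acc <- rownames(g$geno)
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", ncol(g$geno), nrow(g$geno))
  for (v in c(0L, 1L, 2L))
    gt[t(g$geno == v & !is.na(g$geno))] <- code[[as.character(v)]]
  body <- paste(g$map$chrom, g$map$pos, g$map$snp, "A", "T", ".", "PASS",
                ".", "GT", apply(gt, 1, paste, collapse = "\t"),
                sep = "\t")
  writeLines(c("##fileformat=VCFv4.2",
               "##source=qtlallele",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT", acc), collapse = "\t")),
             path)
  cat(body, file = path, sep = "\n", append = TRUE)
  invisible(path)
}

#' Write genotypes as accession x SNP CSV (with a map sidecar)
#'
#' Accessions in rows, SNPs in columns, homozygous codes 0/2 (1 =
#' heterozygous, empty = missing).  The SNP map (chromosome, position) is
#' written alongside as `<path>.map.csv`.
#'
#' @param g a [genotype_matrix()].
#' @param path output CSV path.
#' @export
write_genotypes_csv <- function(g, path) {
  stopifnot(inherits(g, "genotype_matrix"))
  df <- data.frame(accession = rownames(g$geno), g$geno,
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  write.csv(g$map, paste0(path, ".map.csv"), row.names = FALSE)
  invisible(path)
}

#' Read genotypes from VCF or CSV
#'
#' VCF input is parsed with `vcfR`; genotype strings 0/0, 1/1, 0/1 (any
#' separator) and ./. map to 0, 2, 1, NA.  CSV input expects the dialect of
#' [write_genotypes_csv()] with its `.map.csv` sidecar.
#'
#' @param path input path.
#' @param format `"vcf"` or `"csv"` (default guessed from the extension).
#' @param map_path map sidecar path for CSV input.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = NULL,
                           map_path = paste0(path, ".map.csv")) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (file.size(path) == 0) stop(sprintf("empty file: %s", path))
  format <- format %||%
    if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "csv"
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    gt <- vcfR::extract.gt(v)
    num <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    num[gt %in% c("0/0", "0|0")] <- 0L
    num[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    num[gt %in% c("1/1", "1|1")] <- 2L
    map <- data.frame(snp = v@fix[, "ID"],
                      chrom = type.convert(v@fix[, "CHROM"], as.is = TRUE),
                      pos = as.integer(v@fix[, "POS"]))
    genotype_matrix(t(num), map)
  } else {
    df <- read.csv(path, check.names = FALSE, na.strings = "")
    if (!"accession" %in% names(df))
      stop("genotype CSV must have an 'accession' column")
    geno <- as.matrix(df[, -1, drop = FALSE])
    bad <- !(geno %in% c("0", "1", "2") | is.na(geno))
    if (any(bad)) {
      idx <- which(bad)[1]
      stop(sprintf("unknown allele symbol '%s' at row %d, column '%s'",
                   geno[idx], (idx - 1) %% nrow(geno) + 1,
                   colnames(geno)[(idx - 1) %/% nrow(geno) + 1]))
    }
    mode(geno) <- "integer"
    rownames(geno) <- df$accession
    map <- read.csv(map_path)
    genotype_matrix(geno, map)
  }
}

#' Read or write tidy phenotype tables
#'
#' Tidy observation CSV: `accession`, `env`, `rep`, `time`, `value`
#' (plot-value tables omit `time`).
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  df <- read.csv(path)
  need <- c("accession", "env", "rep", "value")
  if (!all(need %in% names(df)))
    stop("phenotype CSV must have columns accession, env, rep, value")
  df
}

#' @rdname read_phenotypes
#' @param x phenotype data.frame.
#' @export
write_phenotypes <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Write a gene table as a GFF3-like file
#'
#' One `gene` feature per row with `ID`, `category` and `description`
#' attributes.
#'
#' @param genes data.frame `gene`, `chrom`, `start`, `end`, `category`,
#'   optional `go_description`.
#' @param path output path.
#' @export
write_genes_gff <- function(genes, path) {
  attrs <- paste0("ID=", genes$gene, ";category=", genes$category,
                  if (!is.null(genes$go_description))
                    paste0(";description=", gsub("[;=]", " ",
                                                 genes$go_description))
                  else "")
  lines <- paste(genes$chrom, "qtlallele", "gene", genes$start, genes$end,
                 ".", "+", ".", attrs, sep = "\t")
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

#' Read a GFF3-like gene table
#'
#' Parses `gene` features, extracting `ID`, `category` and `description`
#' attributes.
#'
#' @param path GFF3 path.
#' @return data.frame `gene`, `chrom`, `start`, `end`, `category`,
#'   `go_description`.
#' @export
read_genes_gff <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  if (length(ln) == 0)
    return(data.frame(gene = character(), chrom = integer(),
                      start = integer(), end = integer(),
                      category = character(),
                      go_description = character()))
  f <- do.call(rbind, strsplit(ln, "\t", fixed = TRUE))
  attr_val <- function(attrs, key) {
    m <- regmatches(attrs, regexec(paste0("(^|;)", key, "=([^;]*)"), attrs))
    vapply(m, function(x) if (length(x) >= 3) x[3] else NA_character_,
           character(1))
  }
  data.frame(gene = attr_val(f[, 9], "ID"),
             chrom = type.convert(f[, 1], as.is = TRUE),
             start = as.integer(f[, 4]), end = as.integer(f[, 5]),
             category = attr_val(f[, 9], "category"),
             go_description = attr_val(f[, 9], "description"))
}

#' Run the full QTL-allele analysis pipeline
#'
#' Orchestrates the stages end to end: CV-weighted plot values, variance
#' components and heritability, SNP QC, SNPLDB construction, structure
#' covariates, the two-stage multi-locus scan, QTL-allele matrix assembly,
#' cross prediction, resistance-group allele-change analysis and
#' candidate-gene annotation.  All table outputs and a machine-readable
#' run manifest (parameters, seeds, package version) are written to
#' `out_dir`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param observations tidy observation data.frame (`accession`, `env`,
#'   `rep`, `time`, `value`) or a plot-value table without `time`.
#' @param genes optional gene table for candidate annotation.
#' @param out_dir output directory (created if missing).
#' @param params list of stage parameters; recognised entries (with
#'   defaults): `max_missing` 0.2, `max_het` 0.2, `min_maf` 0.01,
#'   `d_threshold` 0.7, `max_span` 2e5, `min_hap_freq` 0.01, `k_covariates`
#'   10, `preselect_alpha` 0.05, `enter_alpha` 0.05, `remove_alpha` 0.05,
#'   `correction` "bonferroni", `heritability_cap` NULL (use the estimated
#'   h2), `window` 5e4, `gene_alpha` 0.05, `cm_per_mb` 1, `n_progeny` 2000,
#'   `proportions` c(0.2, 0.6, 0.2), `max_cross_parents` 60, `seed` 1.
#' @return invisible list with every stage result.
#' @export
run_pipeline <- function(genotypes, observations, genes = NULL,
                         out_dir = tempfile("qtlallele_run"),
                         params = list()) {
  p <- modifyList(list(
    max_missing = 0.2, max_het = 0.2, min_maf = 0.01,
    d_threshold = 0.7, max_span = 2e5, min_hap_freq = 0.01,
    k_covariates = 10, preselect_alpha = 0.05, enter_alpha = 0.05,
    remove_alpha = 0.05, correction = "bonferroni",
    heritability_cap = NULL, window = 5e4, gene_alpha = 0.05,
    cm_per_mb = 1, n_progeny = 2000, proportions = c(0.2, 0.6, 0.2),
    max_cross_parents = 60, seed = 1L), params)
  if (p$min_maf >= 0.5)
    stop("configuration error: min_maf >= 0.5 removes every SNP")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  ## phenotype
  plots <- stage("phenotype", {
    if ("time" %in% names(observations)) plot_values(observations)
    else observations
  })
  vc <- stage("phenotype", anova_components(plots))
  acc_means <- tapply(plots$value, plots$accession, mean)
  desc <- stage("phenotype", descriptive_stats(as.numeric(acc_means)))
  write.csv(data.frame(desc$stats, f_value = desc$f_value,
                       h2 = vc$h2, gcv = vc$GCV, cv = vc$CV),
            file.path(out_dir, "population_summary.csv"),
            row.names = FALSE)

  ## markers
  gqc <- stage("qc", qc_filter(genotypes, p$max_missing, p$max_het,
                               p$min_maf))
  ldb <- stage("snpldb", build_snpldb(gqc, p$d_threshold, p$max_span,
                                      p$min_hap_freq))
  sim <- stage("snpldb", similarity_matrix(ldb))
  cov <- stage("snpldb", structure_covariates(sim, p$k_covariates))
  marker_tab <- do.call(rbind, lapply(ldb$markers, function(m)
    data.frame(id = m$id, chrom = m$chrom, start = m$start, end = m$end,
               n_snps = length(m$snps), n_alleles = nrow(m$alleles),
               alleles = paste(m$alleles$allele, collapse = ","),
               freqs = paste(signif(m$alleles$freq, 4), collapse = ","))))
  write.table(marker_tab, file.path(out_dir, "snpldb_markers.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)

  ## association
  settings <- scan_settings(
    preselect_alpha = p$preselect_alpha, enter_alpha = p$enter_alpha,
    remove_alpha = p$remove_alpha, correction = p$correction,
    heritability_cap = p$heritability_cap %||% min(max(vc$h2, 0.05), 1))
  pre <- stage("scan", stage1_scan(ldb, plots, cov, settings))
  write.csv(attr(pre, "all"), file.path(out_dir, "marker_pvalues.csv"),
            row.names = FALSE)
  scan <- stage("scan", {
    if (nrow(pre) == 0) NULL
    else stage2_stepwise(ldb, pre, plots, cov, settings)
  })
  result <- list(plots = plots, variance_components = vc, snpldb = ldb,
                 preselection = pre, scan = scan, params = p)
  if (!is.null(scan) && !is.null(scan$records)) {
    write.table(scan$records, file.path(out_dir, "qtl_records.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(scan$allele_effects))
      write.csv(scan$allele_effects,
                file.path(out_dir, "allele_effects.csv"),
                row.names = FALSE)
  }

  ## downstream stages need at least one main-effect locus
  if (!is.null(scan) && !is.null(scan$allele_effects) &&
      nrow(scan$allele_effects) > 0) {
    am <- stage("matrix", build_allele_matrix(scan, ldb))
    write.csv(data.frame(qtl = rownames(am$effects), am$effects,
                         check.names = FALSE),
              file.path(out_dir, "qtl_allele_matrix.csv"),
              row.names = FALSE)
    result$allele_matrix <- am

    gmap <- genetic_map(am, p$cm_per_mb)
    parents <- colnames(am$effects)
    if (length(parents) > p$max_cross_parents) {
      set.seed(child_seed(p$seed, 11L))
      parents <- sort(sample(parents, p$max_cross_parents))
    }
    amp <- submatrix(am, parents)
    preds <- stage("crosses", predict_all_crosses(
      amp, gmap, "linkage", p$n_progeny, p$seed,
      transgression_threshold = min(acc_means)))
    write.csv(preds, file.path(out_dir, "cross_predictions.csv"),
              row.names = FALSE)
    result$cross_predictions <- preds
    result$recombination_potential <- recombination_potential(
      mean(acc_means), min(acc_means), preds$p25)

    grp <- stage("groups", assign_groups(
      setNames(as.numeric(acc_means), names(acc_means)), p$proportions))
    freqs <- stage("groups", group_allele_frequencies(am, grp))
    freqs <- merge(freqs, scan$allele_effects[, c("qtl", "allele",
                                                  "effect")],
                   by = c("qtl", "allele"))
    chg <- stage("groups", change_summary(freqs))
    write.csv(freqs, file.path(out_dir, "group_allele_frequencies.csv"),
              row.names = FALSE)
    write.csv(chg, file.path(out_dir, "allele_change_summary.csv"),
              row.names = FALSE)
    result$groups <- grp
    result$group_frequencies <- freqs
    result$change_summary <- chg

    if (!is.null(genes) && nrow(genes) > 0) {
      cand <- stage("genes", select_candidates(
        scan, ldb, genes, gqc, p$window, p$gene_alpha))
      write.table(cand, file.path(out_dir, "candidate_genes.tsv"),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      result$candidates <- cand
      if (nrow(cand) > 0) {
        top <- cand[!duplicated(cand$qtl), ]
        result$category_tally <- category_tally(top)
      }
    }
  }

  manifest <- list(
    package = "qtlallele",
    version = as.character(utils::packageVersion("qtlallele")),
    date = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
    parameters = p[setdiff(names(p), "proportions")],
    proportions = p$proportions,
    seed = p$seed,
    n_accessions = nrow(genotypes$geno),
    n_snps_input = ncol(genotypes$geno),
    n_snps_qc = ncol(gqc$geno),
    n_markers = length(ldb$markers),
    n_preselected = nrow(pre),
    n_loci = if (!is.null(scan$records)) nrow(scan$records) else 0L,
    h2 = vc$h2)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  result$out_dir <- out_dir
  invisible(result)
}
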