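#' Simulate a gene-model table tied to the planted QTLs
#'
#' Builds a gene table for candidate-gene annotation tests: each planted
#' QTL block gets one gene overlapping its span (so the gene contains SNPs
#' in perfect association with the QTL haplotypes), and background genes
#' are scattered away from all markers.  Each gene carries one of the eight
#' biological-process category labels (I-VIII).
#'
#' @param pop a `sim_population`.
#' @param n_background background genes per chromosome.
#' @param gene_length gene span in bp.
#' @param seed integer seed (defaults to a child of the population's master
#'   seed).
#' @return data.frame `gene`, `chrom`, `start`, `end`, `category`,
#'   `go_description`.
#' @export
simulate_gene_annotation <- function(pop, n_background = 5,
                                     gene_length = 2000, seed = NULL) {
  stopifnot(inherits(pop, "sim_population"))
  set.seed(seed %||% child_seed(pop$config$master_seed, 5L))
  cats <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII")
  descr <- c(I = "Response to stress", II = "Secondary metabolism",
             III = "Primary metabolism", IV = "Signal transduction",
             V = "Transport", VI = "Cell growth", VII = "DNA metabolism",
             VIII = "Unknown process")
  rows <- list()
  qtls <- pop$truth$qtls
  for (i in seq_len(nrow(qtls))) {
    ct <- sample(cats, 1)
    rows[[length(rows) + 1]] <- data.frame(
      gene = sprintf("Gene%02dg%05d", qtls$chrom[i],
                     qtls$start[i] %/% 1000),
      chrom = qtls$chrom[i],
      start = max(1, qtls$start[i] - 500),
      end = qtls$end[i] + 500,
      category = ct, go_description = unname(descr[ct]))
  }
  map <- pop$genotypes$map
  for (ch in unique(map$chrom)) {
    pos <- map$pos[map$chrom == ch]
    for (b in seq_len(n_background)) {
      # keep background genes clear of every marker (> 60 kb)
      for (try in 1:50) {
        st <- sample.int(pop$config$chromosome_length - gene_length, 1)
        if (all(abs(pos - st) > 6e4 & abs(pos - (st + gene_length)) > 6e4))
          break
        st <- NA
      }
      if (is.na(st)) next
      ct <- sample(cats, 1)
      rows[[length(rows) + 1]] <- data.frame(
        gene = sprintf("Gene%02dg%05db%d", ch, st %/% 1000, b),
        chrom = ch, start = st, end = st + gene_length,
        category = ct, go_description = unname(descr[ct]))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$chrom, out$start), ]
  rownames(out) <- NULL
  out
}
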