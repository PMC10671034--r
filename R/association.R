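#' Settings for the two-stage multi-locus association scan
#'
#' @param preselect_alpha single-marker preselection threshold (stage 1),
#'   unadjusted (default 0.05).
#' @param enter_alpha forward-selection entry threshold (stage 2).
#' @param remove_alpha backward-deletion retention threshold (stage 2).
#' @param correction multiple-test correction for the stage-2 thresholds:
#'   `"bonferroni"` divides the alphas by the total number of markers
#'   scanned in stage 1 (experimentwise control over the genome scan --
#'   dividing only by the preselected subset would not control the
#'   family-wise rate, because preselection already conditions on small
#'   p-values); `"none"` uses them unadjusted.
#' @param heritability_cap cumulative genetic R-squared bound (fraction of
#'   phenotypic variance); stepwise accretion stops at the trait's
#'   broad-sense heritability so the fitted QTL system cannot absorb more
#'   variance than is genetic.
#' @param max_iter iteration cap for the forward/backward loop.
#' @return list of class `scan_settings`.
#' @export
scan_settings <- function(preselect_alpha = 0.05, enter_alpha = 0.05,
                          remove_alpha = 0.05,
                          correction = c("bonferroni", "none"),
                          heritability_cap = 1, max_iter = 50L) {
  correction <- match.arg(correction)
  for (a in c(preselect_alpha, enter_alpha, remove_alpha))
    if (a <= 0 || a > 1) stop("alphas must be in (0, 1]")
  if (heritability_cap <= 0 || heritability_cap > 1)
    stop("'heritability_cap' must be in (0, 1]")
  structure(list(preselect_alpha = preselect_alpha,
                 enter_alpha = enter_alpha, remove_alpha = remove_alpha,
                 correction = correction,
                 heritability_cap = heritability_cap,
                 max_iter = as.integer(max_iter)),
            class = "scan_settings")
}

# residual sum of squares and rank of a least-squares fit
fit_rss <- function(X, y) {
  q <- qr(X)
  list(rss = sum(qr.resid(q, y)^2), rank = q$rank, qr = q)
}

# F test comparing nested designs (X0 within X1); a perfect fit that
# removes residual variance is reported as p = 0
nested_f <- function(rss0, rank0, rss1, rank1, nobs) {
  df1 <- rank1 - rank0
  df2 <- nobs - rank1
  if (df1 <= 0 || df2 <= 0)
    return(list(F = NA_real_, p = NA_real_, df1 = df1, df2 = df2))
  eps <- 1e-12 * max(rss0, 1)
  if (rss1 <= eps) {
    if (rss0 - rss1 > eps)
      return(list(F = Inf, p = 0, df1 = df1, df2 = df2))
    return(list(F = NA_real_, p = NA_real_, df1 = df1, df2 = df2))
  }
  Fv <- ((rss0 - rss1) / df1) / (rss1 / df2)
  list(F = Fv, p = pf(Fv, df1, df2, lower.tail = FALSE), df1 = df1,
       df2 = df2)
}

# align phenotype (accession x env means) and build the base design and the
# per-marker accession-level dummy blocks
scan_frame <- function(markers, phenotype, covariates = NULL) {
  stopifnot(inherits(markers, "snpldb_set"))
  ph <- phenotype
  if (!all(c("accession", "env", "value") %in% names(ph)))
    stop("'phenotype' needs columns accession, env, value")
  if ("rep" %in% names(ph)) {
    ph <- aggregate(value ~ accession + env, data = ph, FUN = mean)
  }
  acc <- markers$accessions
  ph <- ph[ph$accession %in% acc, ]
  used <- sort(unique(ph$accession))
  if (length(used) < 3) stop("too few accessions shared between phenotype ",
                             "and genotypes")
  ph <- ph[order(ph$accession, ph$env), ]
  ia <- match(ph$accession, acc)
  env <- factor(ph$env)
  X0 <- if (nlevels(env) > 1) model.matrix(~ env)
        else matrix(1, length(ph$value), 1,
                    dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (is.null(rownames(cv))) stop("'covariates' needs accession rownames")
    X0 <- cbind(X0, cv[ph$accession, , drop = FALSE])
  }
  env_contr <- if (nlevels(env) > 1)
    model.matrix(~ env)[, -1, drop = FALSE] else NULL
  list(y = ph$value, X0 = X0, acc_index = ia, env = env,
       accessions = acc, phenotype = ph)
}

# accession-level allele dummies (k - 1 columns) for one marker
marker_block <- function(m) {
  a <- m$assign
  if (nlevels(droplevels(a)) < 2) return(NULL)
  model.matrix(~ droplevels(a))[, -1, drop = FALSE]
}

# expand an accession-level block to observation rows; optionally cross with
# environment dummies (QEI columns)
expand_block <- function(block, frame, qei = FALSE) {
  Xb <- block[frame$acc_index, , drop = FALSE]
  if (!qei) return(Xb)
  env <- frame$env
  if (nlevels(env) < 2) stop("QEI terms need at least two environments")
  E <- model.matrix(~ env)[, -1, drop = FALSE]
  out <- do.call(cbind, lapply(seq_len(ncol(E)),
                               function(j) Xb * E[, j]))
  out
}

#' Stage 1: single-marker preselection scan
#'
#' Tests each multi-allelic SNPLDB marker one at a time in a fixed-effect
#' model with environment and structure covariates; markers whose F-test of
#' the allele term reaches `preselect_alpha` (unadjusted) are retained,
#' ordered by p-value.
#'
#' @param markers a `snpldb_set`.
#' @param phenotype data.frame `accession`, `env`, `value` (plot or
#'   accession-by-environment means; a `rep` column is averaged out).
#' @param covariates optional accession-level covariate matrix (e.g.
#'   [structure_covariates()]).
#' @param settings a [scan_settings()].
#' @return data.frame `marker`, `chrom`, `pos`, `F`, `p`, `log10p`,
#'   preselected rows only, ordered by p; full per-marker results in
#'   attribute `"all"` (Manhattan-ready).
#' @export
stage1_scan <- function(markers, phenotype, covariates = NULL,
                        settings = scan_settings()) {
  fr <- scan_frame(markers, phenotype, covariates)
  base <- fit_rss(fr$X0, fr$y)
  nobs <- length(fr$y)
  res <- lapply(markers$markers, function(m) {
    blk <- marker_block(m)
    if (is.null(blk)) return(NULL)   # single allele class: skipped
    X1 <- cbind(fr$X0, expand_block(blk, fr))
    f1 <- fit_rss(X1, fr$y)
    ft <- nested_f(base$rss, base$rank, f1$rss, f1$rank, nobs)
    data.frame(marker = m$id, chrom = m$chrom, pos = m$start,
               F = ft$F, p = ft$p)
  })
  res <- do.call(rbind, res)
  res$log10p <- -log10(res$p)
  res <- res[order(res$p, res$chrom, res$pos), ]
  rownames(res) <- NULL
  keep <- res[!is.na(res$p) & res$p <= settings$preselect_alpha, ]
  attr(keep, "all") <- res
  keep
}

#' Stage 2: stepwise multi-locus model with heritability control
#'
#' Builds the multi-locus model by forward selection and backward deletion
#' over the preselected markers.  A forward step adds the candidate with the
#' smallest partial-F p-value if it reaches the (possibly Bonferroni-
#' corrected) entry threshold and the cumulative genetic R-squared stays
#' within the heritability cap; backward steps delete any included marker
#' whose partial-F p-value exceeds the retention threshold.  After the
#' main-effect model stabilises, marker-by-environment (QEI) terms are
#' scanned the same way with the main effects held in the model.  A locus
#' may carry a main effect, a QEI effect, or both.
#'
#' @param markers a `snpldb_set`.
#' @param preselected output of [stage1_scan()] (or a character vector of
#'   marker ids).
#' @param phenotype,covariates as in [stage1_scan()].
#' @param settings a [scan_settings()].
#' @param trait_prefix prefix for locus names (default `"DLP"`).
#' @param n_tests number of tests the Bonferroni correction divides by;
#'   defaults to the full stage-1 scan size when `preselected` carries it
#'   (the `"all"` attribute), else the number of preselected markers.
#' @return object of class `qtl_scan` with elements `records` (one row per
#'   detected locus: name, marker, chrom, position, allele number AN,
#'   main/QEI -log10 p and R-squared in percent, contribution class),
#'   `allele_effects` (per-locus per-allele effects under a sum-to-zero
#'   constraint), `mu` (fitted intercept / grand mean), `settings`, and the
#'   selected marker ids.
#' @export
stage2_stepwise <- function(markers, preselected, phenotype,
                            covariates = NULL, settings = scan_settings(),
                            trait_prefix = "DLP", n_tests = NULL) {
  ids <- if (is.data.frame(preselected)) preselected$marker else preselected
  if (length(ids) == 0) stop("empty preselection")
  if (is.null(n_tests)) {
    all_tab <- attr(preselected, "all")
    n_tests <- if (!is.null(all_tab)) nrow(all_tab) else length(ids)
  }
  fr <- scan_frame(markers, phenotype, covariates)
  nobs <- length(fr$y)
  tss <- sum((fr$y - mean(fr$y))^2)
  mk <- markers$markers[match(ids, vapply(markers$markers, `[[`, "", "id"))]
  blocks <- lapply(mk, marker_block)
  okb <- !vapply(blocks, is.null, logical(1))
  mk <- mk[okb]; blocks <- blocks[okb]
  minfo <- data.frame(id = vapply(mk, `[[`, "", "id"),
                      chrom = vapply(mk, `[[`, 0, "chrom"),
                      pos = vapply(mk, `[[`, 0, "start"))
  mmain <- lapply(blocks, function(b) NULL)  # filled lazily
  get_main <- function(i) {
    if (is.null(mmain[[i]])) mmain[[i]] <<- expand_block(blocks[[i]], fr)
    mmain[[i]]
  }
  m_total <- nrow(minfo)
  enter <- settings$enter_alpha
  remove <- settings$remove_alpha
  if (settings$correction == "bonferroni") {
    enter <- enter / n_tests
    remove <- remove / n_tests
  }

  base <- fit_rss(fr$X0, fr$y)
  terms <- list()   # each: list(idx, type, X)
  model_X <- function() {
    if (length(terms) == 0) return(fr$X0)
    cbind(fr$X0, do.call(cbind, lapply(terms, `[[`, "X")))
  }
  cur <- base
  genetic_r2 <- function(fit) (base$rss - fit$rss) / tss

  term_key <- function(t) paste(t$type, t$idx)
  has_term <- function(idx, type)
    any(vapply(terms, function(t) t$idx == idx && t$type == type,
               logical(1)))

  try_candidates <- function(type) {
    cand <- setdiff(seq_len(m_total),
                    vapply(Filter(function(t) t$type == type, terms),
                           `[[`, 0L, "idx"))
    if (length(cand) == 0) return(NULL)
    ps <- rep(NA_real_, length(cand))
    fits <- vector("list", length(cand))
    for (j in seq_along(cand)) {
      Xc <- tryCatch(
        if (type == "main") get_main(cand[j])
        else expand_block(blocks[[cand[j]]], fr, qei = TRUE),
        error = function(e) NULL)
      if (is.null(Xc)) next
      f1 <- fit_rss(cbind(model_X(), Xc), fr$y)
      ft <- nested_f(cur$rss, cur$rank, f1$rss, f1$rank, nobs)
      ps[j] <- ft$p
      fits[[j]] <- f1
    }
    ok <- !is.na(ps)
    if (!any(ok)) return(NULL)
    ordc <- order(ps, minfo$chrom[cand], minfo$pos[cand])
    best <- ordc[1]
    list(idx = cand[best], p = ps[best], fit = fits[[best]])
  }

  backward_pass <- function(type) {
    repeat {
      tidx <- which(vapply(terms, function(t) t$type == type, logical(1)))
      if (length(tidx) == 0) return(invisible(NULL))
      worst_p <- -1; worst <- NA
      for (ti in tidx) {
        Xr <- if (length(terms) > 1)
          cbind(fr$X0, do.call(cbind, lapply(terms[-ti], `[[`, "X")))
        else fr$X0
        f0 <- fit_rss(Xr, fr$y)
        ft <- nested_f(f0$rss, f0$rank, cur$rss, cur$rank, nobs)
        if (!is.na(ft$p) && ft$p > worst_p) { worst_p <- ft$p; worst <- ti }
      }
      if (!is.na(worst) && worst_p > remove) {
        terms[[worst]] <<- NULL
        cur <<- fit_rss(model_X(), fr$y)
      } else return(invisible(NULL))
    }
  }

  run_phase <- function(type) {
    for (it in seq_len(settings$max_iter)) {
      changed <- FALSE
      cb <- try_candidates(type)
      if (!is.null(cb) && !is.na(cb$p) && cb$p <= enter &&
          genetic_r2(cb$fit) <= settings$heritability_cap + 1e-9) {
        terms[[length(terms) + 1]] <<- list(
          idx = cb$idx, type = type,
          X = if (type == "main") get_main(cb$idx)
              else expand_block(blocks[[cb$idx]], fr, qei = TRUE))
        cur <<- cb$fit
        changed <- TRUE
      }
      n_before <- length(terms)
      backward_pass(type)
      if (length(terms) != n_before) changed <- TRUE
      if (!changed) return(invisible(NULL))
    }
    warning("stepwise selection did not converge within the iteration cap")
  }

  run_phase("main")
  if (nlevels(fr$env) > 1) run_phase("qei")

  ## ---- summarise the final model -----------------------------------------
  full <- fit_rss(model_X(), fr$y)
  loci_idx <- sort(unique(vapply(terms, `[[`, 0L, "idx")))
  records <- NULL
  effects_tab <- NULL
  if (length(loci_idx) > 0) {
    # Type-III partial tests and R2 per term
    part <- lapply(seq_along(terms), function(ti) {
      Xr <- if (length(terms) > 1)
        cbind(fr$X0, do.call(cbind, lapply(terms[-ti], `[[`, "X")))
      else fr$X0
      f0 <- fit_rss(Xr, fr$y)
      ft <- nested_f(f0$rss, f0$rank, full$rss, full$rank, nobs)
      c(p = ft$p, r2 = 100 * (f0$rss - full$rss) / tss)
    })
    rec_rows <- lapply(loci_idx, function(i) {
      main_ti <- which(vapply(terms, function(t)
        t$idx == i && t$type == "main", logical(1)))
      qei_ti <- which(vapply(terms, function(t)
        t$idx == i && t$type == "qei", logical(1)))
      data.frame(
        marker = minfo$id[i], chrom = minfo$chrom[i], pos = minfo$pos[i],
        an = nrow(mk[[i]]$alleles),
        main_log10p = if (length(main_ti))
          -log10(part[[main_ti]]["p"]) else NA_real_,
        main_r2 = if (length(main_ti)) part[[main_ti]]["r2"] else NA_real_,
        qei_log10p = if (length(qei_ti))
          -log10(part[[qei_ti]]["p"]) else NA_real_,
        qei_r2 = if (length(qei_ti)) part[[qei_ti]]["r2"] else NA_real_)
    })
    records <- do.call(rbind, rec_rows)
    records <- records[order(records$chrom, records$pos), ]
    rank_on_chrom <- stats::ave(records$pos, records$chrom,
                                FUN = seq_along)
    records$qtl <- name_qtl(records$chrom, rank_on_chrom, trait_prefix)
    records$class <- classify_contribution(pmax(records$main_r2,
                                                records$qei_r2,
                                                na.rm = TRUE))
    records <- records[, c("qtl", "marker", "chrom", "pos", "an",
                           "main_log10p", "main_r2", "qei_log10p",
                           "qei_r2", "class")]
    rownames(records) <- NULL

    # per-allele effects of loci with a main effect
    qf <- qr(model_X())
    beta <- qr.coef(qf, fr$y)
    colptr <- ncol(fr$X0)
    eff_rows <- list()
    for (t in terms) {
      w <- ncol(t$X)
      cols <- colptr + seq_len(w)
      colptr <- colptr + w
      if (t$type != "main") next
      m <- mk[[t$idx]]
      b <- beta[cols]
      if (any(is.na(b))) warning(sprintf(
        "aliased allele at marker %s; its effect is not estimable", m$id))
      lev <- levels(droplevels(m$assign))
      raw <- c(0, b)
      eff <- raw - mean(raw, na.rm = TRUE)
      eff_rows[[length(eff_rows) + 1]] <- data.frame(
        marker = m$id, allele = lev, effect = eff,
        freq = m$alleles$freq[match(lev, m$alleles$allele)])
    }
    if (length(eff_rows)) {
      effects_tab <- do.call(rbind, eff_rows)
      effects_tab$qtl <- records$qtl[match(effects_tab$marker,
                                           records$marker)]
      effects_tab <- effects_tab[, c("qtl", "marker", "allele", "effect",
                                     "freq")]
      rownames(effects_tab) <- NULL
    }
  }

  structure(list(records = records, allele_effects = effects_tab,
                 mu = mean(fr$y), tss = tss,
                 genetic_r2 = 100 * genetic_r2(full),
                 selected = minfo$id[loci_idx],
                 settings = settings, n_preselected = m_total),
            class = "qtl_scan")
}

#' @export
print.qtl_scan <- function(x, ...) {
  nr <- if (is.null(x$records)) 0L else nrow(x$records)
  cat(sprintf("qtl_scan: %d loci (of %d preselected markers), total genetic R2 = %.2f%%\n",
              nr, x$n_preselected, x$genetic_r2))
  if (nr) print(head(x$records, 10))
  invisible(x)
}

#' Per-allele effects of a locus in a fitted scan
#'
#' Least-squares haplotype-allele effects under an unweighted sum-to-zero
#' constraint per locus.  Negative effects are resistance-increasing
#' (they lower the damaged leaf percentage).
#'
#' @param scan a `qtl_scan`.
#' @param locus a locus name (e.g. `"q-DLP-01-1"`) or marker id.
#' @return data.frame `allele`, `effect`, `freq`.
#' @export
allele_effects <- function(scan, locus) {
  stopifnot(inherits(scan, "qtl_scan"))
  if (is.null(scan$allele_effects)) stop("no loci with main effects in scan")
  tab <- scan$allele_effects
  out <- tab[tab$qtl == locus | tab$marker == locus,
             c("allele", "effect", "freq")]
  if (nrow(out) == 0) stop(sprintf("locus '%s' not in model", locus))
  rownames(out) <- NULL
  out
}

#' Contribution class of a locus
#'
#' Large-contribution (LC) loci explain at least 1 percent of the
#' phenotypic variance; the boundary is inclusive.
#'
#' @param r2_percent R-squared in percent.
#' @return character vector, `"LC"` or `"SC"`.
#' @export
classify_contribution <- function(r2_percent) {
  ifelse(is.na(r2_percent), NA_character_,
         ifelse(r2_percent >= 1, "LC", "SC"))
}

#' Systematic locus names
#'
#' Builds names of the form `q-<trait>-<chrom>-<rank>`, with the chromosome
#' zero-padded to two digits and the rank given by ascending physical
#' position within the chromosome.
#'
#' @param chromosome integer chromosome numbers.
#' @param rank_on_chromosome rank by ascending bp within each chromosome.
#' @param trait_prefix trait tag (default `"DLP"`).
#' @return character vector of names.
#' @examples
#' name_qtl(12, 4)   # "q-DLP-12-4"
#' @export
name_qtl <- function(chromosome, rank_on_chromosome, trait_prefix = "DLP") {
  sprintf("q-%s-%02d-%d", trait_prefix, as.integer(chromosome),
          as.integer(rank_on_chromosome))
}
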