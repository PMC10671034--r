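#' CV-based observation weights
#'
#' Weight for each observation time, proportional to the coefficient of
#' variation of the trait across accessions at that time:
#' P_i = CV_i / sum(CV_i).  Times at which the population spreads out more
#' receive more weight in the plot score.
#'
#' @param cv_values numeric vector of per-time CVs (>= 2 values, all >= 0).
#' @return numeric weights summing to 1.
#' @examples
#' observation_weights(c(0.1, 0.2, 0.3))  # 1/6, 1/3, 1/2
#' @export
observation_weights <- function(cv_values) {
  if (length(cv_values) < 2L) stop("need at least two observation times")
  if (any(cv_values < 0)) stop("CVs must be non-negative")
  s <- sum(cv_values)
  if (s == 0) {
    warning("all CVs are zero; using equal weights")
    return(rep(1 / length(cv_values), length(cv_values)))
  }
  cv_values / s
}

#' Weighted plot value
#'
#' PM = sum(P_i * Y_i): the CV-weighted average of the repeated observations
#' of one plot.
#'
#' @param y per-time observed values (percent).
#' @param p per-time weights (from [observation_weights()]).
#' @return the weighted plot value.
#' @export
plot_dlp <- function(y, p) {
  if (length(y) != length(p)) stop("'y' and 'p' must have the same length")
  sum(p * y)
}

#' Collapse repeated observations to CV-weighted plot values
#'
#' For each environment, computes the CV of the observed values across all
#' plots at each observation time, converts the CVs to weights, and returns
#' one weighted value per plot.  CVs are computed within environment: the
#' dispersion across accessions is what distinguishes observation times.
#'
#' @param obs data.frame with columns `accession`, `env`, `rep`, `time`,
#'   `value`.
#' @return data.frame `accession`, `env`, `rep`, `value` (one row per plot),
#'   with the per-environment weights in attribute `"weights"`.
#' @export
plot_values <- function(obs) {
  need <- c("accession", "env", "rep", "time", "value")
  if (!all(need %in% names(obs))) stop("missing columns in 'obs'")
  out <- list(); wts <- list()
  for (e in unique(obs$env)) {
    oe <- obs[obs$env == e, ]
    times <- sort(unique(oe$time))
    wide <- sapply(times, function(t) {
      ot <- oe[oe$time == t, ]
      ot$value[order(ot$accession, ot$rep)]
    })
    key <- oe[oe$time == times[1], c("accession", "rep")]
    key <- key[order(key$accession, key$rep), ]
    cv <- apply(wide, 2, function(v) {
      m <- mean(v)
      if (m == 0) 0 else sd(v) / m
    })
    p <- suppressWarnings(observation_weights(cv))
    wts[[as.character(e)]] <- setNames(p, times)
    out[[as.character(e)]] <- data.frame(
      accession = key$accession, env = e, rep = key$rep,
      value = as.numeric(wide %*% p))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "weights") <- wts
  res
}

#' Variance components from a genotype x environment plot table
#'
#' Method-of-moments estimates from the expected mean squares of the
#' balanced two-way layout with replication: genotype, genotype-by-
#' environment and residual strata.  With a single environment the one-way
#' formulas are used and the G-by-E component is undefined.  Negative
#' estimates are truncated at zero and flagged.  Genotype is tested against
#' the G-by-E mean square (environments treated as a random sample of test
#' conditions), G-by-E against the residual.
#'
#' @param plots data.frame `accession`, `env`, `rep`, `value`.
#' @return Object of class `variance_components`: sigma2_g, sigma2_ge,
#'   sigma2_e, n (environments), r (replicates), mu, h2 (broad sense), GCV,
#'   CV (error CV), F statistics and p-values, truncation flags.
#' @export
anova_components <- function(plots) {
  need <- c("accession", "env", "rep", "value")
  if (!all(need %in% names(plots))) stop("missing columns in 'plots'")
  a <- length(unique(plots$accession))
  n <- length(unique(plots$env))
  r <- length(unique(plots$rep))
  if (nrow(plots) != a * n * r)
    warning("layout is not balanced; expected-mean-square estimates are ",
            "approximate")
  y <- plots$value
  mu <- mean(y)
  tot <- sum((y - mu)^2)
  gm <- tapply(y, plots$accession, mean)
  em <- tapply(y, plots$env, mean)
  cm <- tapply(y, list(plots$accession, plots$env), mean)

  if (n > 1) {
    ss_g <- n * r * sum((gm - mu)^2)
    ss_e_env <- a * r * sum((em - mu)^2)
    inter <- sweep(sweep(cm, 1, gm), 2, em) + mu
    ss_ge <- r * sum(inter^2)
    ss_err <- tot - ss_g - ss_e_env - ss_ge
    df_g <- a - 1; df_ge <- (a - 1) * (n - 1); df_err <- a * n * (r - 1)
    ms_g <- ss_g / df_g; ms_ge <- ss_ge / df_ge
    ms_err <- if (df_err > 0) ss_err / df_err else NA_real_
    s2e <- ms_err
    s2ge <- (ms_ge - ms_err) / r
    s2g <- (ms_g - ms_ge) / (n * r)
    F_g <- ms_g / ms_ge
    p_g <- pf(F_g, df_g, df_ge, lower.tail = FALSE)
    F_ge <- ms_ge / ms_err
    p_ge <- pf(F_ge, df_ge, df_err, lower.tail = FALSE)
  } else {
    ss_g <- r * sum((gm - mu)^2)
    ss_err <- tot - ss_g
    df_g <- a - 1; df_err <- a * (r - 1); df_ge <- NA_integer_
    ms_g <- ss_g / df_g
    ms_err <- if (df_err > 0) ss_err / df_err else NA_real_
    s2e <- ms_err
    s2ge <- NA_real_
    s2g <- (ms_g - ms_err) / r
    F_g <- ms_g / ms_err
    p_g <- pf(F_g, df_g, df_err, lower.tail = FALSE)
    F_ge <- NA_real_; p_ge <- NA_real_
  }

  truncated <- character(0)
  if (!is.na(s2g) && s2g < 0) { s2g <- 0; truncated <- c(truncated, "g") }
  if (!is.na(s2ge) && s2ge < 0) { s2ge <- 0; truncated <- c(truncated, "ge") }
  if (!is.na(s2e) && s2e < 0) { s2e <- 0; truncated <- c(truncated, "e") }

  vc <- list(sigma2_g = unname(s2g), sigma2_ge = unname(s2ge),
             sigma2_e = unname(s2e), n = n, r = r, mu = mu,
             F_g = unname(F_g), p_g = unname(p_g),
             F_ge = unname(F_ge), p_ge = unname(p_ge),
             truncated = truncated)
  vc$h2 <- tryCatch(heritability(vc, multi_env = n > 1),
                    error = function(e) NA_real_)
  vc$GCV <- if (mu != 0) sqrt(max(vc$sigma2_g, 0)) / mu else NA_real_
  vc$CV <- if (mu != 0 && !is.na(s2e)) sqrt(max(s2e, 0)) / mu else NA_real_
  class(vc) <- "variance_components"
  vc
}

#' @export
print.variance_components <- function(x, ...) {
  cat("variance components (expected mean squares):\n")
  cat(sprintf("  sigma2_g  = %.4f\n", x$sigma2_g))
  if (!is.na(x$sigma2_ge)) cat(sprintf("  sigma2_ge = %.4f\n", x$sigma2_ge))
  cat(sprintf("  sigma2_e  = %.4f\n", x$sigma2_e))
  cat(sprintf("  h2 = %.3f   GCV = %.3f   CV = %.3f   (n = %d, r = %d)\n",
              x$h2, x$GCV, x$CV, x$n, x$r))
  if (length(x$truncated))
    cat("  note: components truncated at zero:",
        paste(x$truncated, collapse = ", "), "\n")
  invisible(x)
}

#' Broad-sense heritability on an accession-mean basis
#'
#' Multi-environment: h2 = sigma2_g / (sigma2_g + sigma2_ge/n +
#' sigma2_e/(n r)); single environment: h2 = sigma2_g / (sigma2_g +
#' sigma2_e/r).
#'
#' @param vc a `variance_components` object, or a list with fields
#'   `sigma2_g`, `sigma2_ge`, `sigma2_e`, `n`, `r`.
#' @param multi_env use the multi-environment formula?
#' @return heritability in [0, 1].
#' @export
heritability <- function(vc, multi_env = TRUE) {
  s2g <- max(vc$sigma2_g, 0)
  s2e <- max(vc$sigma2_e, 0)
  if (multi_env) {
    s2ge <- if (is.na(vc$sigma2_ge)) 0 else max(vc$sigma2_ge, 0)
    den <- s2g + s2ge / vc$n + s2e / (vc$n * vc$r)
  } else {
    den <- s2g + s2e / vc$r
  }
  if (den == 0) stop("all variance components are zero; h2 undefined")
  s2g / den
}

#' Descriptive statistics with 5-percent frequency classes
#'
#' Mean, minimum, maximum and binned frequency counts (classes centred on
#' multiples of the bin width), overall and per group, plus a one-way F-test
#' of group differences and Duncan multiple-range letters on group means.
#'
#' @param values per-accession trait means (percent).
#' @param groups optional group labels (e.g. ecoregions).
#' @param bin_width class width (default 5 percent).
#' @param alpha significance level for the Duncan letters.
#' @param method `"duncan"` (new multiple range test, studentized-range
#'   based) or `"tukey"` (HSD) for the letters.
#' @return list with `stats` (per-group n/mean/min/max), `bins` (counts per
#'   class midpoint, groups in rows), `f_value`, `p_value`, `letters`.
#' @export
descriptive_stats <- function(values, groups = NULL, bin_width = 5,
                              alpha = 0.05,
                              method = c("duncan", "tukey")) {
  method <- match.arg(method)
  if (length(values) == 0) stop("'values' is empty")
  if (is.null(groups)) groups <- rep("All", length(values))
  groups <- as.factor(groups)
  if (any(tapply(values, groups, length) == 0)) stop("empty group")

  mids <- seq(floor(min(values) / bin_width) * bin_width,
              ceiling(max(values) / bin_width) * bin_width, by = bin_width)
  bin_of <- function(v) mids[pmin(pmax(round(v / bin_width) -
                                         mids[1] / bin_width + 1, 1),
                                  length(mids))]
  bins <- table(groups, factor(bin_of(values), levels = mids))

  stats <- do.call(rbind, lapply(levels(groups), function(gl) {
    v <- values[groups == gl]
    data.frame(group = gl, n = length(v), mean = mean(v),
               min = min(v), max = max(v))
  }))

  f_value <- p_value <- NA_real_
  letters <- setNames(rep("a", nlevels(groups)), levels(groups))
  if (nlevels(groups) > 1) {
    fit <- aov(values ~ groups)
    ftab <- anova(fit)
    f_value <- ftab$`F value`[1]
    p_value <- ftab$`Pr(>F)`[1]
    letters <- range_test_letters(
      means = tapply(values, groups, mean),
      n_per = tapply(values, groups, length),
      ms_error = ftab$`Mean Sq`[2], df_error = ftab$Df[2],
      alpha = alpha, method = method)
  }
  list(stats = stats, bins = unclass(bins), f_value = f_value,
       p_value = p_value, letters = letters)
}

# Multiple-comparison letters from the studentized range.  Duncan's new
# multiple range test uses the protection level 1 - (1 - alpha)^(p - 1) for
# means p steps apart; Tukey HSD uses the full-range critical value for all
# comparisons.  Harmonic-mean replication is used when group sizes differ.
range_test_letters <- function(means, n_per, ms_error, df_error,
                               alpha = 0.05, method = "duncan") {
  k <- length(means)
  ord <- order(means, decreasing = TRUE)
  m <- means[ord]
  nh <- 1 / mean(1 / n_per)
  se <- sqrt(ms_error / nh)
  crit <- function(p) {
    if (method == "duncan") {
      qtukey(1 - (1 - (1 - alpha)^(p - 1)), p, df_error) * se
    } else {
      qtukey(1 - alpha, k, df_error) * se
    }
  }
  # maximal non-significant stretches of the ordered means
  spans <- list()
  for (i in seq_len(k)) {
    j <- i
    while (j < k && (m[i] - m[j + 1]) < crit(j + 1 - i + 1)) j <- j + 1
    spans[[i]] <- c(i, j)
  }
  spans <- unique(spans)
  keep <- vapply(seq_along(spans), function(s) {
    !any(vapply(spans[-s], function(t)
      t[1] <= spans[[s]][1] && spans[[s]][2] <= t[2] &&
        !identical(t, spans[[s]]), logical(1)))
  }, logical(1))
  spans <- spans[keep]
  lab <- rep("", k)
  for (s in seq_along(spans)) {
    rng <- spans[[s]][1]:spans[[s]][2]
    lab[rng] <- paste0(lab[rng], letters[(s - 1) %% 26 + 1])
  }
  setNames(lab[order(ord)], names(means))
}
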