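#' Simulate repeated damage observations with time-varying dispersion
#'
#' Expands plot values into `n_times` per-plot observations whose
#' coefficient of variation across plots differs by observation time (the
#' damage spread widens as feeding progresses), constructed so that the
#' CV-weighted average of [plot_values()] recovers the intended plot value
#' exactly.  Within each environment the observations are an affine
#' transform of the standardised plot values, Y_it = c_t + s_t * Z_i, with
#' c_t and s_t solved so the empirical per-time CVs equal `cv_profile` and
#' the weighted combination reproduces the plot value.
#'
#' @param plots data.frame `accession`, `env`, `rep`, `value` (e.g. the
#'   `phenotypes` element of [simulate_population()]).
#' @param n_times number of observation times (>= 2).
#' @param cv_profile relative dispersion profile per time, recycled to
#'   `n_times`: realised per-time CVs are proportional to it (scaled by the
#'   plot values' own CV), so only its ratios matter -- they determine the
#'   recovered weights.  The default rises over time as damage accumulates
#'   unevenly across accessions.
#' @return data.frame `accession`, `env`, `rep`, `time`, `value` with the
#'   intended plot table stored in attribute `"intended"`.
#' @export
simulate_dlp_observations <- function(plots, n_times = 3,
                                      cv_profile = c(0.8, 1, 1.25)) {
  if (n_times < 2) stop("'n_times' must be >= 2")
  rel <- rep_len(cv_profile, n_times)
  if (any(rel <= 0)) stop("'cv_profile' must be positive")
  out <- list()
  for (e in unique(plots$env)) {
    pe <- plots[plots$env == e, ]
    pm <- pe$value
    m <- mean(pm); s <- sd(pm)
    if (is.na(s) || s == 0 || sd(rel) == 0 || m <= 0) {
      # degenerate: constant plot values (or flat CV profile) -- repeat the
      # plot value at every time; weights become equal and recovery is exact
      y <- matrix(pm, nrow(pe), n_times)
    } else {
      z <- (pm - m) / s
      # realised per-time CVs v_t are proportional to the profile and are
      # normalised so their weight-averaged value equals the plot values'
      # own CV s/m; then every time mean is m, the time spread is m * v_t,
      # and the CV-weighted average returns the plot value exactly:
      # sum_t P_t (m + m v_t z_i) = m + s z_i = PM_i
      p <- rel / sum(rel)
      v <- (s / m) * rel / sum(p * rel)
      y <- outer(z, m * v) + m
    }
    if (any(y < 0 | y > 100))
      warning("some simulated observations fall outside [0, 100]")
    out[[as.character(e)]] <- data.frame(
      accession = rep(pe$accession, n_times),
      env = e,
      rep = rep(pe$rep, n_times),
      time = rep(seq_len(n_times), each = nrow(pe)),
      value = as.numeric(y))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "intended") <- plots
  res
}
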