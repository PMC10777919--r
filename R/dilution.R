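#' Default in-silico mixing fractions
#'
#' Ten mixing levels spanning 3e-5 to 1 in half-decade steps, the series
#' used for limit-of-quantification titrations.
#'
#' @return Numeric vector of mixing fractions.
#' @export
dilution_levels <- function() {
  c(3e-5, 1e-4, 3e-4, 1e-3, 3e-3, 1e-2, 3e-2, 1e-1, 3e-1, 1)
}

#' Mix cancer and background pattern counts at a nominal fraction
#'
#' Count-level analogue of mixing two sequencing runs: per DMR the mixture
#' keeps the background sample's depth, and each retained fragment comes
#' from the cancer sample with probability proportional to `r` and the
#' cancer sample's local coverage,
#' `p_i = r * n_c_i / (r * n_c_i + (1 - r) * n_b_i)`; fragments drawn from
#' either source match the pattern at that source's empirical rate
#' (binomial thinning). `r = 1` returns the cancer counts unchanged, so
#' the neat end of a series is the undiluted sample itself.
#'
#' @param cancer,background counts data frames (`dmr_id`, `k`, `n`) on the
#'   same DMR panel, in the same order.
#' @param r nominal mixing fraction in `(0, 1]`.
#' @param seed optional integer seed for a reproducible draw.
#' @return Counts data frame of the mixture.
#' @export
mix_counts <- function(cancer, background, r, seed = NULL) {
  if (!identical(cancer$dmr_id, background$dmr_id))
    stop("cancer and background counts are on different DMR panels")
  if (!(r > 0 && r <= 1)) stop("mixing fraction r must lie in (0,1]")
  if (r == 1) return(cancer)
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
  }
  nc <- cancer$n; kc <- cancer$k
  nb <- background$n; kb <- background$k
  denom <- r * nc + (1 - r) * nb
  p_can <- ifelse(denom > 0, r * nc / denom, 0)
  m <- stats::rbinom(length(nb), nb, p_can)            # fragments from cancer
  rate_c <- ifelse(nc > 0, kc / nc, 0)
  rate_b <- ifelse(nb > 0, kb / nb, 0)
  k <- stats::rbinom(length(nb), m, rate_c) +
       stats::rbinom(length(nb), nb - m, rate_b)
  data.frame(dmr_id = cancer$dmr_id, k = k, n = nb, stringsAsFactors = FALSE)
}

# save/restore the global RNG state so seeded helpers do not disturb the
# caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Coverage-corrected mixing fraction
#'
#' A nominal fraction `r` mixes datasets, not genomes: when the undiluted
#' cancer and background samples differ in mean depth, the realized
#' cancer share of fragments is
#' `r * cov_cancer / (r * cov_cancer + (1 - r) * cov_background)`.
#'
#' @param r nominal mixing fraction in `(0, 1]`.
#' @param cov_cancer,cov_background mean per-region depths of the
#'   undiluted samples (both positive).
#' @return The corrected fraction, strictly increasing in `r` and in
#'   `cov_cancer`, equal to `r` at equal coverage.
#' @export
corrected_fraction <- function(r, cov_cancer, cov_background) {
  if (any(cov_cancer <= 0) || any(cov_background <= 0))
    stop("coverages must be positive")
  r * cov_cancer / (r * cov_cancer + (1 - r) * cov_background)
}

#' Run one dilution series and estimate TMeF at every level
#'
#' Mixes a cancer sample into a background sample at each level, estimates
#' TMeF for every mixture, and pairs each observation with its expected
#' value `r_corrected * neat_tmef`, where the neat TMeF is the estimate of
#' the undiluted cancer sample (`r = 1`).
#'
#' @param cancer,background counts data frames on the shared panel.
#' @param annotations refined DMR annotation data frame.
#' @param r_levels mixing fractions (default [dilution_levels()]).
#' @param grid a [tf_grid()].
#' @param h heterozygosity factor.
#' @return Data frame with `r_nominal`, `r_corrected`, `expected_tmef`,
#'   `observed_tmef`.
#' @export
dilution_series <- function(cancer, background, annotations,
                            r_levels = dilution_levels(), grid = tf_grid(),
                            h = 0.5) {
  cov_c <- mean(cancer$n); cov_b <- mean(background$n)
  res <- data.frame(r_nominal = r_levels,
                    r_corrected = corrected_fraction(r_levels, cov_c, cov_b),
                    expected_tmef = NA_real_, observed_tmef = NA_real_)
  for (i in seq_along(r_levels)) {
    mixed <- mix_counts(cancer, background, r_levels[i])
    res$observed_tmef[i] <- estimate_tmef(mixed, annotations, grid, h)$tmef
  }
  neat <- if (any(r_levels == 1)) res$observed_tmef[r_levels == 1][1]
          else estimate_tmef(cancer, annotations, grid, h)$tmef
  res$expected_tmef <- res$r_corrected * neat
  res
}

#' Linearity and accuracy of dilution series at fixed expected levels
#'
#' For each fixed expected TMeF level, every series' observed TMeF is
#' interpolated at that expected value (linear in log-log space along the
#' series); the report gives the fraction of series whose interpolated
#' observation falls within 0.5- to 2-fold of the expected value and the
#' median absolute log2 fold deviation (0 for a perfect series; 1 equals
#' a two-fold deviation). Series whose expected range does not bracket a
#' level are excluded there and counted.
#'
#' @param results data frame with `series_id`, `expected_tmef`,
#'   `observed_tmef` (stack of [dilution_series()] outputs).
#' @param levels expected TMeF values at which to interpolate.
#' @return Data frame with one row per level: `expected_level`,
#'   `fraction_within_2fold`, `median_fold_deviation`, `n_series`,
#'   `n_excluded`.
#' @export
linearity_report <- function(results, levels) {
  if (nrow(results) == 0L) stop("no dilution results supplied")
  series <- split(results, results$series_id)
  out <- data.frame(expected_level = levels, fraction_within_2fold = NA_real_,
                    median_fold_deviation = NA_real_,
                    n_series = NA_integer_, n_excluded = NA_integer_)
  for (i in seq_along(levels)) {
    lv <- levels[i]
    obs <- vapply(series, function(s) {
      s <- s[is.finite(s$expected_tmef) & is.finite(s$observed_tmef) &
             s$expected_tmef > 0 & s$observed_tmef > 0, , drop = FALSE]
      if (nrow(s) < 2L || lv < min(s$expected_tmef) || lv > max(s$expected_tmef))
        return(NA_real_)
      exp(stats::approx(log(s$expected_tmef), log(s$observed_tmef),
                        xout = log(lv), ties = "ordered")$y)
    }, numeric(1))
    excluded <- sum(is.na(obs))
    obs <- obs[!is.na(obs)]
    ratio <- obs / lv
    out$fraction_within_2fold[i] <- mean(ratio >= 0.5 & ratio <= 2)
    out$median_fold_deviation[i] <- stats::median(abs(log2(ratio)))
    out$n_series[i] <- length(obs)
    out$n_excluded[i] <- excluded
  }
  out
}
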