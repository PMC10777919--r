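#' Log-spaced tumor-fraction grid
#'
#' The estimator scores candidate tumor fractions on a fixed log-spaced
#' grid. The default floor of `1e-6` leaves margin below the ~`1e-5`
#' level where quantification tapers off.
#'
#' @param tf_min smallest grid value (default `1e-6`).
#' @param tf_max largest grid value (default `1`).
#' @param n number of grid points (default 501).
#' @param prior per-point prior mass (default uniform); must sum to 1.
#' @return A `tf_grid` object with `values` (strictly increasing) and
#'   `prior`.
#' @export
tf_grid <- function(tf_min = 1e-6, tf_max = 1, n = 501L, prior = NULL) {
  if (!(tf_min > 0 && tf_min < tf_max && tf_max <= 1)) stop("need 0 < tf_min < tf_max <= 1")
  values <- exp(seq(log(tf_min), log(tf_max), length.out = n))
  if (is.null(prior)) prior <- rep(1 / n, n)
  if (length(prior) != n || abs(sum(prior) - 1) > 1e-9 || any(prior < 0))
    stop("prior must be a length-n non-negative vector summing to 1")
  structure(list(values = values, prior = prior), class = "tf_grid")
}

# Align a counts table with a DMR annotation table by dmr_id; errors on
# any mismatch so silent misjoins cannot happen.
.align_counts <- function(counts, annotations) {
  need_c <- c("dmr_id", "k", "n"); need_a <- c("dmr_id", "noise_rate",
                                               "prevalence", "efficiency")
  if (!all(need_c %in% names(counts))) stop("counts need columns dmr_id, k, n")
  if (!all(need_a %in% names(annotations)))
    stop("annotations need columns dmr_id, noise_rate, prevalence, efficiency")
  idx <- match(counts$dmr_id, annotations$dmr_id)
  if (anyNA(idx))
    stop("counts contain DMR ids missing from annotations: ",
         paste(utils::head(counts$dmr_id[is.na(idx)], 5L), collapse = ", "))
  if (any(counts$k < 0 | counts$k > counts$n)) stop("need 0 <= k <= n")
  list(k = as.integer(counts$k), n = as.integer(counts$n),
       eps = annotations$noise_rate[idx], eff = annotations$efficiency[idx],
       rho = annotations$prevalence[idx])
}

#' Aggregate log-likelihood of a tumor fraction across DMR loci
#'
#' For each refined DMR `i` the sample's counts follow the carrier
#' mixture
#' \deqn{\rho_i \mathrm{Binom}(k_i; n_i, \min(1, tf \cdot e_i + \epsilon_i))
#'      + (1-\rho_i) \mathrm{Binom}(k_i; n_i, \epsilon_i)}
#' and loci are independent. Probabilities are clamped to
#' `[1e-12, 1 - 1e-12]`, and all accumulation is in log space, so the
#' result is finite for depths up to `1e6`.
#'
#' @param tf tumor fraction(s) to score.
#' @param counts data frame with `dmr_id`, `k`, `n` for one sample.
#' @param annotations refined DMR data frame with `dmr_id`, `noise_rate`,
#'   `prevalence`, `efficiency`.
#' @return Numeric vector of log-likelihoods, one per element of `tf`.
#' @export
loglik_tf <- function(tf, counts, annotations) {
  al <- .align_counts(counts, annotations)
  cpp_grid_loglik(as.numeric(tf), al$k, al$n, al$eps, al$eff, al$rho)
}

#' Posterior over tumor fraction for one plasma sample
#'
#' Normalizes `prior * exp(loglik)` over the grid; the point estimate is
#' the posterior median and the 95% credible interval the 2.5/97.5
#' percentiles, all obtained by linear interpolation of the cumulative
#' mass in log-TF.
#'
#' @inheritParams loglik_tf
#' @param grid a [tf_grid()].
#' @return A `tf_posterior` object: `grid`, `log_lik`, `mass`,
#'   `tf_median`, `tf_lo`, `tf_hi`, `n_dmrs`.
#' @export
posterior_tf <- function(counts, annotations, grid = tf_grid()) {
  if (!inherits(grid, "tf_grid")) stop("grid must be a tf_grid object")
  ll <- loglik_tf(grid$values, counts, annotations)
  lp <- ll + log(grid$prior)
  m <- max(lp)
  if (!is.finite(m)) stop("likelihood vanished at every grid point")
  mass <- exp(lp - m)
  mass <- mass / sum(mass)
  lg <- log(grid$values)
  q <- exp(.grid_quantile(lg, mass, c(0.025, 0.5, 0.975)))
  structure(list(grid = grid, log_lik = ll, mass = mass,
                 tf_median = q[2], tf_lo = q[1], tf_hi = q[3],
                 n_dmrs = nrow(counts)),
            class = "tf_posterior")
}

#' Convert a TF posterior to a TMeF estimate
#'
#' TMeF rescales the tumor fraction to an allele-fraction scale: a typical
#' cancer-derived small variant is heterozygous, occupying one of two
#' tumor alleles, so the default heterozygosity factor is `h = 0.5`.
#'
#' @param post a [posterior_tf()] result.
#' @param h heterozygosity factor in `(0, 1]`.
#' @param cutoff optional non-cancer background cutoff (on the TMeF
#'   scale); estimates below it are flagged `below_cutoff`.
#' @return A `tmef_estimate` object: `tmef`, `ci` (`lo`, `hi`), `tf_median`,
#'   `tf_lo`, `tf_hi`, `het_factor`, `below_cutoff`.
#' @export
tf_to_tmef <- function(post, h = 0.5, cutoff = NULL) {
  if (!(h > 0 && h <= 1)) stop("h must lie in (0,1]")
  tmef <- post$tf_median * h
  structure(list(tmef = tmef, ci = c(lo = post$tf_lo * h, hi = post$tf_hi * h),
                 tf_median = post$tf_median, tf_lo = post$tf_lo,
                 tf_hi = post$tf_hi, het_factor = h,
                 below_cutoff = if (is.null(cutoff)) NA else tmef < cutoff),
            class = "tmef_estimate")
}

#' One-call TMeF estimation for a sample
#'
#' Convenience wrapper: [posterior_tf()] followed by [tf_to_tmef()].
#'
#' @inheritParams posterior_tf
#' @inheritParams tf_to_tmef
#' @return A `tmef_estimate`.
#' @export
estimate_tmef <- function(counts, annotations, grid = tf_grid(), h = 0.5,
                          cutoff = NULL) {
  tf_to_tmef(posterior_tf(counts, annotations, grid), h = h, cutoff = cutoff)
}

#' Non-cancer background cutoff for TMeF
#'
#' The empirical `q`-quantile (linear interpolation) of TMeF values from a
#' non-cancer cohort; estimates below it are flagged as less accurate.
#'
#' @param noncancer_tmefs numeric vector (at least 2 values).
#' @param q quantile (default 0.98).
#' @return The cutoff value.
#' @export
background_cutoff <- function(noncancer_tmefs, q = 0.98) {
  if (length(noncancer_tmefs) < 2L) stop("need at least 2 non-cancer TMeF values")
  unname(stats::quantile(noncancer_tmefs, probs = q, type = 7))
}

#' Stratify TMeF values into reporting bins
#'
#' Half-open, left-closed bins: `[0, 1e-4)`, `[1e-4, 1e-3)`,
#' `[1e-3, 1e-2)`, `[1e-2, Inf)`.
#'
#' @param tmefs non-negative numeric vector.
#' @return Factor with levels `"<1e-4"`, `"1e-4-1e-3"`, `"1e-3-1e-2"`,
#'   `">1e-2"`.
#' @export
stratify_tmef <- function(tmefs) {
  if (any(tmefs < 0)) stop("TMeF values must be non-negative")
  lv <- c("<1e-4", "1e-4-1e-3", "1e-3-1e-2", ">1e-2")
  bin <- findInterval(tmefs, c(1e-4, 1e-3, 1e-2)) + 1L
  factor(lv[bin], levels = lv)
}

#' @export
print.tf_posterior <- function(x, ...) {
  cat("Tumor-fraction posterior on", length(x$grid$values), "grid points\n")
  cat(sprintf("  loci: %d\n  TF median: %.3g  (95%% CrI %.3g - %.3g)\n",
              x$n_dmrs, x$tf_median, x$tf_lo, x$tf_hi))
  invisible(x)
}

#' @export
coef.tf_posterior <- function(object, ...) {
  c(tf_median = object$tf_median, tf_lo = object$tf_lo, tf_hi = object$tf_hi)
}

#' @export
summary.tf_posterior <- function(object, ...) {
  lg <- log(object$grid$values)
  q <- exp(.grid_quantile(lg, object$mass, c(0.025, 0.25, 0.5, 0.75, 0.975)))
  names(q) <- c("2.5%", "25%", "50%", "75%", "97.5%")
  structure(list(n_dmrs = object$n_dmrs, quantiles = q,
                 map = object$grid$values[which.max(object$mass)]),
            class = "summary.tf_posterior")
}

#' @export
print.summary.tf_posterior <- function(x, ...) {
  cat("Tumor-fraction posterior summary\n")
  cat(sprintf("  loci: %d   posterior mode: %.3g\n", x$n_dmrs, x$map))
  print(signif(x$quantiles, 3))
  invisible(x)
}

#' @export
plot.tf_posterior <- function(x, ...) {
  plot(x$grid$values, x$mass, type = "l", log = "x",
       xlab = "tumor fraction", ylab = "posterior mass", ...)
  graphics::abline(v = x$tf_median, lty = 2)
  graphics::abline(v = c(x$tf_lo, x$tf_hi), lty = 3)
  invisible(x)
}

#' @export
print.tmef_estimate <- function(x, ...) {
  cat(sprintf("TMeF estimate: %.3g  (95%% CrI %.3g - %.3g; h = %g)\n",
              x$tmef, x$ci[["lo"]], x$ci[["hi"]], x$het_factor))
  if (!is.na(x$below_cutoff) && x$below_cutoff)
    cat("  below the non-cancer background cutoff (less accurate)\n")
  invisible(x)
}
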