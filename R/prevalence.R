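#' Bayesian posterior for DMR prevalence within a cancer label
#'
#' Prevalence `rho` is the expected fraction of tumors of a label that
#' carry a given DMR. Each training plasma sample `j` with (estimated,
#' here fixed) tumor fraction `TF_j` contributes the marginal likelihood
#' of a two-component binomial mixture over carrier status:
#' \deqn{L_j(\rho) = \rho \, \mathrm{Binom}(k_j; n_j, p_j)
#'                 + (1-\rho)\, \mathrm{Binom}(k_j; n_j, \epsilon)}
#' with `p_j = min(1, TF_j * e + eps)`. The posterior is
#' `prior(rho) * prod_j L_j(rho)` on a uniform grid over `[0, 1]`,
#' accumulated in log space. TF uncertainty is not propagated.
#'
#' @param k,n integer vectors of per-sample matching / covering fragment
#'   counts for the DMR.
#' @param tf per-sample tumor fractions in `[0, 1]`.
#' @param noise DMR noise rate `eps`.
#' @param efficiency DMR pull-down efficiency `e`.
#' @param prior `c(a, b)` of a Beta prior (default uniform `c(1, 1)`).
#' @param grid_size number of uniform grid points (default 1001).
#' @param dmr_id optional identifier carried into the result.
#' @return A `prevalence_posterior` object: `grid`, `mass` (normalized),
#'   `median`, plus the inputs. With no samples the posterior equals the
#'   prior.
#' @export
prevalence_posterior <- function(k, n, tf, noise, efficiency,
                                 prior = c(1, 1), grid_size = 1001L,
                                 dmr_id = NULL) {
  if (length(k) != length(n) || length(k) != length(tf))
    stop("k, n and tf must be aligned by sample")
  if (any(tf < 0 | tf > 1)) stop("tumor fractions must lie in [0,1]")
  if (any(k < 0 | k > n)) stop("need 0 <= k <= n")
  grid <- seq(0, 1, length.out = grid_size)
  log_post <- stats::dbeta(grid, prior[1], prior[2], log = TRUE)
  if (length(k) > 0L) {
    p_sig <- .clamp_p(pmin(1, tf * efficiency + noise))
    a <- stats::dbinom(k, n, p_sig, log = TRUE)              # carrier term
    b <- stats::dbinom(k, n, .clamp_p(noise), log = TRUE)    # non-carrier term
    lr <- log(grid); l1r <- log1p(-grid)
    for (j in seq_along(k)) {
      t1 <- lr + a[j]; t2 <- l1r + b[j]
      hi <- pmax(t1, t2)
      # at the rho = 0 / 1 endpoints one branch is -Inf and drops out
      term <- hi + log1p(exp(pmin(t1, t2) - hi))
      log_post <- log_post + term
    }
  }
  m <- max(log_post)
  mass <- exp(log_post - m)
  mass <- mass / sum(mass)
  structure(list(dmr_id = dmr_id, grid = grid, mass = mass,
                 median = .grid_quantile(grid, mass, 0.5),
                 prior = prior, n_samples = length(k)),
            class = "prevalence_posterior")
}

# Quantiles of a discrete grid posterior by linear interpolation of the
# cumulative mass along `x` (callers pass rho, or log tf). Each point's
# mass is centred at its grid value (midpoint convention), so a uniform
# posterior on a symmetric grid has median exactly at the centre.
.grid_quantile <- function(x, mass, probs) {
  cs <- cumsum(mass) - mass / 2
  out <- numeric(length(probs))
  for (i in seq_along(probs)) {
    p <- probs[i]
    j <- findInterval(p, cs) + 1L
    if (j <= 1L) { out[i] <- x[1L]; next }
    if (j > length(x)) { out[i] <- x[length(x)]; next }
    c0 <- cs[j - 1L]; c1 <- cs[j]
    w <- if (c1 > c0) (p - c0) / (c1 - c0) else 0
    out[i] <- x[j - 1L] + w * (x[j] - x[j - 1L])
  }
  out
}

#' @export
print.prevalence_posterior <- function(x, ...) {
  cat("DMR prevalence posterior",
      if (!is.null(x$dmr_id)) paste0(" (", x$dmr_id, ")"), "\n", sep = "")
  cat(sprintf("  samples: %d   grid: %d points\n  posterior median rho: %.4f\n",
              x$n_samples, length(x$grid), x$median))
  invisible(x)
}

#' @export
summary.prevalence_posterior <- function(object, ...) {
  q <- .grid_quantile(object$grid, object$mass, c(0.025, 0.25, 0.5, 0.75, 0.975))
  names(q) <- c("2.5%", "25%", "50%", "75%", "97.5%")
  structure(list(dmr_id = object$dmr_id, n_samples = object$n_samples,
                 quantiles = q), class = "summary.prevalence_posterior")
}

#' @export
print.summary.prevalence_posterior <- function(x, ...) {
  cat("DMR prevalence posterior quantiles\n")
  print(round(x$quantiles, 4))
  invisible(x)
}

#' @export
plot.prevalence_posterior <- function(x, ...) {
  plot(x$grid, x$mass, type = "l", xlab = expression(rho),
       ylab = "posterior mass", ...)
  graphics::abline(v = x$median, lty = 2)
  invisible(x)
}
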