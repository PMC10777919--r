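#' Log-log scaling of TMeF with primary tumor size
#'
#' Fits `log(tmef) ~ log(size)` by ordinary least squares and confirms the
#' fit with Huber M-estimation. The slope is the shedding scaling factor:
#' a value near 2 is consistent with shedding proportional to tumor
#' surface area, near 3 with tumor volume; a slope below 1 with `p >=
#' 0.05` indicates no association. Natural logs are used; the base
#' cancels in the slope.
#'
#' @param tmefs per-sample TMeF values (positive).
#' @param sizes per-sample maximum tumor dimension in cm (positive).
#' @param cutoff optional background cutoff; samples with TMeF below it
#'   are excluded (their count is reported) since those estimates are
#'   less accurate.
#' @return A `scaling_fit` object: `beta`, `intercept`, `se_beta`,
#'   `p_value`, `beta_robust`, `se_beta_robust`, `n`, `n_excluded`,
#'   `interpretation`, plus the underlying `lm` fit (`ols`).
#' @export
fit_scaling <- function(tmefs, sizes, cutoff = NULL) {
  if (length(tmefs) != length(sizes)) stop("tmefs and sizes must be paired")
  keep <- stats::complete.cases(tmefs, sizes)
  tmefs <- tmefs[keep]; sizes <- sizes[keep]
  if (any(tmefs <= 0) || any(sizes <= 0))
    stop("tmefs and sizes must be positive for the log-log fit")
  n_excluded <- 0L
  if (!is.null(cutoff)) {
    below <- tmefs < cutoff
    n_excluded <- sum(below)
    tmefs <- tmefs[!below]; sizes <- sizes[!below]
  }
  if (length(tmefs) < 3L) stop("need at least 3 pairs above the cutoff")
  d <- data.frame(ly = log(tmefs), lx = log(sizes))
  ols <- stats::lm(ly ~ lx, data = d)
  sm <- summary(ols)$coefficients
  rob <- MASS::rlm(ly ~ lx, data = d, psi = MASS::psi.huber, maxit = 100)
  beta <- unname(sm["lx", "Estimate"])
  p <- unname(sm["lx", "Pr(>|t|)"])
  interp <- if (beta < 1 && p >= 0.05) "no association"
            else if (abs(beta - 2) <= 0.5) "surface-area-proportional shedding"
            else if (abs(beta - 3) <= 0.5) "volume-proportional shedding"
            else sprintf("scaling factor %.2f", beta)
  structure(list(beta = beta, intercept = unname(sm["(Intercept)", "Estimate"]),
                 se_beta = unname(sm["lx", "Std. Error"]), p_value = p,
                 beta_robust = unname(coef(rob)[["lx"]]),
                 se_beta_robust = unname(summary(rob)$coefficients["lx", "Std. Error"]),
                 n = length(tmefs), n_excluded = n_excluded,
                 interpretation = interp, ols = ols),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat("TMeF ~ tumor size log-log scaling fit\n")
  cat(sprintf("  n = %d (%d excluded below cutoff)\n", x$n, x$n_excluded))
  cat(sprintf("  scaling factor (OLS):   %.3f  (SE %.3f, p = %.3g)\n",
              x$beta, x$se_beta, x$p_value))
  cat(sprintf("  scaling factor (Huber): %.3f  (SE %.3f)\n",
              x$beta_robust, x$se_beta_robust))
  cat("  interpretation:", x$interpretation, "\n")
  invisible(x)
}

#' @export
coef.scaling_fit <- function(object, ...) {
  c(intercept = object$intercept, beta = object$beta,
    beta_robust = object$beta_robust)
}

#' @export
summary.scaling_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
plot.scaling_fit <- function(x, ...) {
  d <- x$ols$model
  plot(exp(d$lx), exp(d$ly), log = "xy", xlab = "tumor size (cm)",
       ylab = "TMeF", ...)
  sz <- seq(min(d$lx), max(d$lx), length.out = 50)
  graphics::lines(exp(sz), exp(x$intercept + x$beta * sz), lty = 2)
  invisible(x)
}
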