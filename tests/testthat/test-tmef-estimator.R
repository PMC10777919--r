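test_that("at tf = 0 the likelihood collapses to the noise-only binomial", {
  set.seed(601)
  ann <- random_annotations(50)
  cnt <- random_counts(ann, 0.01)
  got <- loglik_tf(0, cnt, ann)
  eps <- pmin(pmax(ann$noise_rate, 1e-12), 1 - 1e-12)
  want <- sum(dbinom(cnt$k, cnt$n, eps, log = TRUE))
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("a single clean locus is maximized at the binomial MLE", {
  ann <- dmr_records("L", "chr01", 100L, "MMMMM", noise_rate = 0,
                     prevalence = 1, efficiency = 1)
  cnt <- data.frame(dmr_id = ann$dmr_id, k = 10L, n = 100L)
  tfs <- seq(0.001, 0.999, length.out = 2000)
  ll <- loglik_tf(tfs, cnt, ann)
  expect_equal(tfs[which.max(ll)], 0.1, tolerance = 2e-3)
})

test_that("aggregate log-likelihood equals a naive per-locus summation", {
  set.seed(602)
  ann <- random_annotations(1000)
  cnt <- random_counts(ann, 0.02)
  tfs <- c(1e-6, 1e-4, 0.02, 0.5, 1)
  got <- loglik_tf(tfs, cnt, ann)
  clamp <- function(p) pmin(pmax(p, 1e-12), 1 - 1e-12)
  for (t in seq_along(tfs)) {
    tot <- 0
    for (j in seq_len(nrow(cnt))) {
      p1 <- clamp(tfs[t] * ann$efficiency[j] + ann$noise_rate[j])
      p0 <- clamp(ann$noise_rate[j])
      tot <- tot + log(ann$prevalence[j] * dbinom(cnt$k[j], cnt$n[j], p1) +
                       (1 - ann$prevalence[j]) * dbinom(cnt$k[j], cnt$n[j], p0))
    }
    expect_equal(got[t], tot, tolerance = 1e-9)
  }
})

test_that("misaligned count/annotation ids error rather than misjoin", {
  ann <- random_annotations(10, seed = 603)
  cnt <- random_counts(ann, 0.01)
  cnt$dmr_id[3] <- "nonsense"
  expect_error(loglik_tf(0.1, cnt, ann), "missing from annotations")
})

test_that("posterior normalizes, brackets its median, and floors on pure noise", {
  set.seed(604)
  # panel at the default scale: the no-signal plateau must end close
  # enough to the grid floor for the median to sit within 3x of it
  ann <- random_annotations(2000)
  grid <- tf_grid()
  pure_noise <- data.frame(dmr_id = ann$dmr_id,
                           k = as.integer(round(1000 * ann$noise_rate)),
                           n = 1000L)
  post <- posterior_tf(pure_noise, ann, grid)
  expect_equal(sum(post$mass), 1, tolerance = 1e-9)
  expect_lte(post$tf_lo, post$tf_median)
  expect_lte(post$tf_median, post$tf_hi)
  expect_lt(post$tf_median, 3 * grid$values[1])  # within 3x of the grid floor

  for (tf in c(0.003, 0.05)) {
    p <- posterior_tf(random_counts(ann, tf), ann, grid)
    expect_equal(sum(p$mass), 1, tolerance = 1e-9)
    expect_lte(p$tf_lo, p$tf_median)
    expect_lte(p$tf_median, p$tf_hi)
  }
})

test_that("tf_median never decreases when a matching fragment is added", {
  # monotone likelihood ratio holds for the pure binomial case (rho = 1);
  # with rho < 1 the carrier mixture can legitimately move the median
  # either way (an extra fragment at a near-zero-noise, low-prevalence
  # locus argues for carriage at a *lower* TF), so monotonicity is
  # asserted where the model guarantees it
  set.seed(605)
  ann <- random_annotations(100)
  ann$prevalence <- 1
  cnt <- random_counts(ann, 0.01, presence = rep(1L, 100))
  base <- posterior_tf(cnt, ann)$tf_median
  for (rep in 1:8) {
    cnt2 <- cnt
    j <- sample(which(cnt2$k < cnt2$n), 1)
    cnt2$k[j] <- cnt2$k[j] + 1L
    expect_gte(posterior_tf(cnt2, ann)$tf_median, base * (1 - 1e-12))
  }
})

test_that("TMeF conversion scales the posterior summaries by h", {
  set.seed(606)
  ann <- random_annotations(200)
  post <- posterior_tf(random_counts(ann, 0.04), ann)
  est <- tf_to_tmef(post, h = 0.5)
  expect_equal(est$tmef, post$tf_median * 0.5)
  expect_equal(unname(est$ci), c(post$tf_lo, post$tf_hi) * 0.5)
  expect_lte(est$ci[["lo"]], est$tmef)
  expect_lte(est$tmef, est$ci[["hi"]])

  ident <- tf_to_tmef(post, h = 1)
  expect_equal(ident$tmef, post$tf_median)
  expect_error(tf_to_tmef(post, h = 0), "\\(0,1\\]")
  expect_error(tf_to_tmef(post, h = 1.5), "\\(0,1\\]")

  # tf_median = 0.02 with h = 0.5 gives TMeF 0.01
  fake <- post; fake$tf_median <- 0.02; fake$tf_lo <- 0.01; fake$tf_hi <- 0.04
  expect_equal(tf_to_tmef(fake, 0.5)$tmef, 0.01)
})

test_that("background cutoff is the interpolated 98th percentile", {
  set.seed(607)
  x <- runif(100)
  cut <- background_cutoff(x, 0.98)
  expect_equal(cut, unname(quantile(x, 0.98, type = 7)))
  srt <- sort(x, decreasing = TRUE)
  expect_gte(cut, srt[3]); expect_lte(cut, srt[2])
  expect_equal(background_cutoff(rep(0.3, 10)), 0.3)
  expect_error(background_cutoff(0.5), "at least 2")
})

test_that("TMeF strata use left-closed half-open bins", {
  expect_equal(as.character(stratify_tmef(5e-4)), "1e-4-1e-3")
  expect_equal(as.character(stratify_tmef(1e-3)), "1e-3-1e-2")  # boundary
  expect_equal(as.character(stratify_tmef(c(0, 9.99e-5, 1e-4, 0.5))),
               c("<1e-4", "<1e-4", "1e-4-1e-3", ">1e-2"))
  expect_error(stratify_tmef(-1e-5), "non-negative")

  set.seed(608)
  x <- 10^runif(500, -6, 0)
  got <- table(stratify_tmef(x))
  naive <- c(sum(x < 1e-4), sum(x >= 1e-4 & x < 1e-3),
             sum(x >= 1e-3 & x < 1e-2), sum(x >= 1e-2))
  expect_equal(unname(as.integer(got)), naive)
})

test_that("grid construction validates its contract", {
  g <- tf_grid()
  expect_equal(length(g$values), 501L)
  expect_true(all(diff(g$values) > 0))
  expect_equal(sum(g$prior), 1, tolerance = 1e-12)
  expect_equal(g$values[1], 1e-6)
  expect_equal(g$values[501], 1)
  expect_error(tf_grid(tf_min = 0), "tf_min")
  expect_error(tf_grid(prior = rep(1, 501)), "summing to 1")
})
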