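# Shared fixtures and independent oracles. The oracles are deliberately
# naive (per-fragment loops, direct dbinom sums) so they share no code
# path with the implementation they check.

# map with one CpG every 10 bp on chr1 starting at 100
linear_map <- function(n = 20L, chrom = "chr1", start = 100L, by = 10L) {
  cpg_map(rep(chrom, n), start + by * (seq_len(n) - 1L))
}

frag <- function(states, first_ord, map, sample_id = "s1") {
  n <- nchar(states)
  data.frame(sample_id = sample_id, chrom = map$chrom[first_ord],
             start = map$pos[first_ord],
             end = map$pos[first_ord + n - 1L] + 1L,
             states = states, first_ord = first_ord,
             stringsAsFactors = FALSE)
}

frags <- function(...) do.call(rbind, list(...))

random_fragments <- function(n, map, sample_id = "s1", max_len = 8L) {
  S <- nrow(map)
  len <- sample.int(max_len, n, replace = TRUE)
  f0 <- sample.int(S, n, replace = TRUE)
  len <- pmin(len, S - f0 + 1L)
  states <- vapply(len, function(l)
    paste(sample(c("M", "U", "N"), l, replace = TRUE, prob = c(.45, .45, .1)),
          collapse = ""), "")
  data.frame(sample_id = sample_id, chrom = map$chrom[f0],
             start = map$pos[f0], end = map$pos[f0 + len - 1L] + 1L,
             states = states, first_ord = f0, stringsAsFactors = FALSE)
}

# per-fragment scan with no vectorization: the count_pattern oracle
naive_count_pattern <- function(fr, first_ord, pattern) {
  k <- 0L; n <- 0L
  for (i in seq_len(nrow(fr))) {
    f0 <- fr$first_ord[i]
    if (is.na(f0)) next
    last <- f0 + nchar(fr$states[i]) - 1L
    if (f0 > first_ord || last < first_ord + 4L) next
    sub <- substr(fr$states[i], first_ord - f0 + 1L, first_ord - f0 + 5L)
    if (grepl("N", sub)) next
    n <- n + 1L
    if (sub == pattern) k <- k + 1L
  }
  list(k = k, n = n)
}

# direct per-grid-point posterior via dbinom: the posterior_tf oracle
naive_posterior_mass <- function(counts, ann, grid) {
  idx <- match(counts$dmr_id, ann$dmr_id)
  ll <- vapply(grid$values, function(tf) {
    tot <- 0
    for (j in seq_len(nrow(counts))) {
      i <- idx[j]
      p1 <- min(max(tf * ann$efficiency[i] + ann$noise_rate[i], 1e-12), 1 - 1e-12)
      p0 <- min(max(ann$noise_rate[i], 1e-12), 1 - 1e-12)
      l <- ann$prevalence[i] * dbinom(counts$k[j], counts$n[j], p1) +
        (1 - ann$prevalence[i]) * dbinom(counts$k[j], counts$n[j], p0)
      tot <- tot + log(l)
    }
    tot
  }, numeric(1))
  lp <- ll + log(grid$prior)
  w <- exp(lp - max(lp))
  w / sum(w)
}

# random annotated panel at count level (no fragment layer), for
# estimator tests
random_annotations <- function(n_dmr, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dmr_records(label = "Synthetic", chrom = "chr01",
              first_cpg_pos = 1000L + 50L * seq_len(n_dmr),
              pattern = sample(c("MMMMM", "UUUUU"), n_dmr, replace = TRUE),
              noise_rate = 1e-3 * rbeta(n_dmr, 0.5, 24.5),
              prevalence = rbeta(n_dmr, 0.8, 1.8),
              efficiency = rbeta(n_dmr, 8, 2))
}

random_counts <- function(ann, tf, depth_mean = 500, presence = NULL) {
  D <- nrow(ann)
  if (is.null(presence)) presence <- rbinom(D, 1, ann$prevalence)
  n <- rnbinom(D, mu = depth_mean, size = 10)
  p <- pmin(1 - 1e-12, tf * ann$efficiency * presence + ann$noise_rate)
  data.frame(dmr_id = ann$dmr_id, k = rbinom(D, n, p), n = n,
             stringsAsFactors = FALSE)
}
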