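test_that("thresholds gate calls exactly as specified", {
  map <- linear_map(10)
  # background: 2000 covering fragments, 1 carrying the candidate pattern
  bg <- do.call(rbind, c(replicate(1999, frag("UUUUU", 1L, map), simplify = FALSE),
                         list(frag("MMMMM", 1L, map))))
  # cancer sample: 25% of covering fragments carry the pattern
  ca <- do.call(rbind, c(replicate(15, frag("UUUUU", 1L, map), simplify = FALSE),
                         replicate(5, frag("MMMMM", 1L, map), simplify = FALSE)))
  calls <- call_sample_dmrs(ca, bg, map)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$pattern, "MMMMM")
  expect_equal(calls$noise_rate, 5e-4)
  expect_equal(calls$cancer_freq, 0.25)

  # background rate 0.002 fails condition (1) regardless of cancer freq
  bg2 <- do.call(rbind, c(replicate(1996, frag("UUUUU", 1L, map), simplify = FALSE),
                          replicate(4, frag("MMMMM", 1L, map), simplify = FALSE)))
  expect_equal(nrow(call_sample_dmrs(ca, bg2, map)), 0L)

  # insufficient background depth makes the window unusable
  bg3 <- do.call(rbind, replicate(50, frag("UUUUU", 1L, map), simplify = FALSE))
  expect_equal(nrow(call_sample_dmrs(ca, bg3, map)), 0L)

  # empty cancer sample gives an empty call set
  expect_equal(nrow(call_sample_dmrs(ca[0, ], bg, map)), 0L)
})

test_that("planted DMRs are recovered exactly on clean synthetic data", {
  set.seed(301)
  cfg <- sim_config(n_regions = 50L, per_cpg_error = 0, nocall_rate = 0,
                    partial_fraction = 0.2, pool_frag_per_region = 400,
                    tissue_frag_per_region = 60)
  panel <- simulate_panel(cfg)
  pool <- simulate_background_pool(panel)
  tumor <- simulate_tissue_sample(panel, "t1", carried = rep(1L, 50))
  calls <- call_sample_dmrs(tumor, pool, panel$map)
  got <- paste(calls$first_ord, calls$pattern)
  want <- paste(panel$dmrs$first_ord, panel$dmrs$pattern)
  expect_setequal(got, want)   # recall 1, false positives 0
})

test_that("calls are invariant to fragment order", {
  set.seed(302)
  cfg <- sim_config(n_regions = 20L, pool_frag_per_region = 300,
                    tissue_frag_per_region = 50)
  panel <- simulate_panel(cfg)
  pool <- simulate_background_pool(panel)
  tumor <- simulate_tissue_sample(panel, "t1")
  a <- call_sample_dmrs(tumor, pool, panel$map)
  b <- call_sample_dmrs(tumor[sample.int(nrow(tumor)), ], pool, panel$map)
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("label merging computes prevalence and frequency as fractions of samples", {
  map <- linear_map(12)
  mk_call <- function(w, pat) data.frame(
    chrom = "chr1", first_cpg_pos = map$pos[w], first_ord = w, pattern = pat,
    cancer_freq = 0.5, cancer_n = 10L, noise_rate = 0, background_n = 500L,
    stringsAsFactors = FALSE)
  calls <- c(lapply(1:3, function(i) mk_call(1L, "MMMMM")),
             lapply(4:10, function(i) mk_call(1L, "MMMMM")[0, ]))
  names(calls) <- sprintf("s%02d", 1:10)
  manifest <- data.frame(sample_id = names(calls), cancer_label = "Lung",
                         stringsAsFactors = FALSE)
  sets <- merge_label_dmrs(calls, manifest)
  expect_equal(sets$Lung$dmrs$empirical_prevalence, 0.3)

  # a single-sample label can only have prevalence 0 or 1
  one <- merge_label_dmrs(calls["s01"],
                          manifest[manifest$sample_id == "s01", , drop = FALSE])
  expect_true(all(one$Lung$dmrs$empirical_prevalence %in% c(0, 1)))

  expect_error(merge_label_dmrs(calls,
                                data.frame(sample_id = "zz", cancer_label = "Lung")),
               "without a cancer label")
})

test_that("planted prevalence spectrum is recovered as a wide distribution", {
  set.seed(303)
  cfg <- sim_config(n_regions = 60L, n_tissue_samples_per_label = 12L,
                    prevalence_shape = c(0.25, 0.25), per_cpg_error = 0,
                    nocall_rate = 0, partial_fraction = 0,
                    pool_frag_per_region = 300, tissue_frag_per_region = 50)
  panel <- simulate_panel(cfg)
  pool <- background_index(simulate_background_pool(panel))
  calls <- list(); frags <- list()
  for (s in 1:12) {
    sid <- sprintf("t%02d", s)
    fr <- simulate_tissue_sample(panel, sid)
    frags[[sid]] <- fr
    calls[[sid]] <- call_sample_dmrs(fr, pool, panel$map)
  }
  manifest <- data.frame(sample_id = names(calls), cancer_label = "Colon",
                         stringsAsFactors = FALSE)
  sets <- merge_label_dmrs(calls, manifest, frags_by_sample = frags)
  prev <- sets$Colon$dmrs$empirical_prevalence
  expect_gt(max(prev), 0.9)
  expect_lt(min(prev), 0.2)
  fm <- sets$Colon$frequency_matrix
  expect_true(all(fm >= 0 & fm <= 1))
})

test_that("top_prevalent selects k DMRs with deterministic tie-breaking", {
  set.seed(304)
  mk_set <- function(prev) {
    n <- length(prev)
    structure(list(label = "L", dmrs = data.frame(
      chrom = "chr1", first_cpg_pos = 10L * seq_len(n), first_ord = seq_len(n),
      pattern = "MMMMM", dmr_id = sprintf("L:chr1:%d:MMMMM", 10L * seq_len(n)),
      empirical_prevalence = prev, stringsAsFactors = FALSE)),
      class = "label_dmr_set")
  }
  distinct <- mk_set(sample(seq(0.01, 1, length.out = 100)))
  top <- top_prevalent(distinct, 50L)
  expect_equal(nrow(top), 50L)
  expect_equal(sort(top$empirical_prevalence, decreasing = TRUE),
               sort(distinct$dmrs$empirical_prevalence, decreasing = TRUE)[1:50])

  small <- mk_set(c(0.2, 0.5, 0.9))
  expect_equal(nrow(top_prevalent(small, 50L)), 3L)
  expect_error(top_prevalent(small, 0L), "positive")

  # heavy ties at the cutoff resolved by genomic order, stable under
  # input permutation
  tied <- mk_set(rep(c(0.9, 0.5), each = 50))
  t1 <- top_prevalent(tied, 60L)
  shuffled <- tied
  perm <- sample.int(100)
  shuffled$dmrs <- tied$dmrs[perm, ]
  t2 <- top_prevalent(shuffled, 60L)
  rownames(t1) <- rownames(t2) <- NULL
  expect_identical(t1, t2)
  expect_equal(t1$first_ord[51:60], 51:60)
})

test_that("cosine similarity behaves on identical, disjoint and overlapping labels", {
  mk <- function(label, ords, prev) structure(list(label = label, dmrs = data.frame(
    chrom = "chr1", first_cpg_pos = 10L * ords, first_ord = ords,
    pattern = "MMMMM", dmr_id = sprintf("%s:%d", label, ords),
    empirical_prevalence = prev, stringsAsFactors = FALSE)),
    class = "label_dmr_set")
  a <- mk("A", 1:4, rep(0.5, 4))
  b <- mk("B", 1:4, rep(0.5, 4))
  d <- mk("D", 11:14, rep(0.5, 4))
  S <- label_cosine_similarity(list(a, b, d))
  expect_equal(S["A", "B"], 1)
  expect_equal(S["A", "D"], 0)
  expect_equal(diag(S), c(A = 1, B = 1, D = 1))
  expect_equal(S, t(S))
  expect_true(all(S >= 0 & S <= 1))

  # half-shared mass, hand-computed: v1 = (1,1,0), v2 = (0,1,1)
  h1 <- mk("H1", 1:2, c(1, 1)); h2 <- mk("H2", 2:3, c(1, 1))
  S2 <- label_cosine_similarity(list(h1, h2))
  expect_equal(S2["H1", "H2"], 1 / 2)

  z <- mk("Z", 21:22, c(0, 0))
  S3 <- label_cosine_similarity(list(a, z))
  expect_equal(S3["A", "Z"], 0)
})

test_that("heatmap leaf orders come from the specified distances", {
  set.seed(305)
  m <- matrix(runif(5 * 6), nrow = 5,
              dimnames = list(sprintf("s%d", 1:5), sprintf("d%d", 1:6)))
  m[2, ] <- m[1, ]  # identical samples: Manhattan distance 0
  labs <- rep("L", 5)
  ord <- cluster_heatmap_order(m, labs)
  i1 <- which(ord$sample_order == "s1"); i2 <- which(ord$sample_order == "s2")
  expect_equal(abs(i1 - i2), 1L)  # adjacent leaves

  # labels whose mean profiles are monotone transforms have Spearman
  # distance 0 and cluster together first
  base <- seq(0.1, 0.9, length.out = 6)
  M <- rbind(matrix(rep(base, 2), 2, byrow = TRUE),
             matrix(rep(base^2, 2), 2, byrow = TRUE),
             matrix(rep(rev(base), 2), 2, byrow = TRUE))
  rownames(M) <- sprintf("s%d", 1:6); colnames(M) <- sprintf("d%d", 1:6)
  labs2 <- rep(c("A", "B", "C"), each = 2)
  ord2 <- cluster_heatmap_order(M, labs2)
  ab <- match(c("A", "B"), ord2$label_order)
  expect_equal(abs(diff(ab)), 1L)
})

test_that("average-linkage heights match a brute-force agglomeration", {
  naive_upgma_heights <- function(d) {
    d <- as.matrix(d)
    active <- as.list(seq_len(nrow(d)))
    heights <- numeric(0)
    pts <- d
    while (length(active) > 1L) {
      best <- c(NA, NA); bh <- Inf
      for (i in seq_along(active)) for (j in seq_along(active)) {
        if (i >= j) next
        h <- mean(pts[active[[i]], active[[j]]])
        if (h < bh) { bh <- h; best <- c(i, j) }
      }
      heights <- c(heights, bh)
      active[[best[1]]] <- c(active[[best[1]]], active[[best[2]]])
      active[[best[2]]] <- NULL
    }
    heights
  }
  set.seed(306)
  m <- matrix(runif(20 * 30), nrow = 20)
  d <- dist(m, method = "manhattan")
  hc <- hclust(d, method = "average")
  expect_equal(sort(hc$height), sort(naive_upgma_heights(d)), tolerance = 1e-10)
})
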