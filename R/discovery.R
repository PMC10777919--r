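#' Discovery thresholds for per-sample DMR calling
#'
#' Defaults mirror the calling rule for short cancer-indicative DMRs: the
#' candidate pattern must occur in less than 0.1% of pooled non-cancer
#' plasma fragments covering the window (background noise) and in at least
#' 20% of the covering fragments of at least one cancer sample.
#'
#' @param max_noise maximum background pattern frequency (default `0.001`).
#' @param min_cancer_freq minimum within-sample pattern frequency
#'   (default `0.20`).
#' @param window_width window width in CpGs; fixed at 5.
#' @param min_background_n minimum covering fragments required in the
#'   non-cancer pool for the noise estimate to be meaningful (default 100).
#' @return A `discovery_thresholds` list.
#' @export
discovery_thresholds <- function(max_noise = 0.001, min_cancer_freq = 0.20,
                                 window_width = 5L, min_background_n = 100L) {
  if (window_width != 5L) stop("window width is fixed at 5")
  if (!(max_noise > 0 && max_noise < min_cancer_freq && min_cancer_freq <= 1))
    stop("need 0 < max_noise < min_cancer_freq <= 1")
  structure(list(max_noise = max_noise, min_cancer_freq = min_cancer_freq,
                 window_width = 5L, min_background_n = as.integer(min_background_n)),
            class = "discovery_thresholds")
}

#' Call DMRs for one cancer sample against a non-cancer background
#'
#' Enumerates every 5-CpG window (sliding by one ordinal) and every
#' methylation pattern actually observed in the cancer sample at that
#' window, and keeps (window, pattern) pairs whose background frequency in
#' the pooled non-cancer fragments is below `max_noise` (with at least
#' `min_background_n` covering background fragments) and whose frequency
#' among the sample's covering fragments is at least `min_cancer_freq`.
#' When several patterns pass at one window, the one with the highest
#' cancer frequency is kept (ties: lower noise, then lexicographic
#' pattern).
#'
#' @param sample_frags fragment data frame for one cancer sample.
#' @param background pooled non-cancer fragments, or a prebuilt
#'   [background_index()].
#' @param map the shared [cpg_map()].
#' @param thresholds a [discovery_thresholds()].
#' @return Data frame of called DMRs: `chrom`, `first_cpg_pos`,
#'   `first_ord`, `pattern`, `cancer_freq`, `cancer_n`, `noise_rate`,
#'   `background_n`, sorted by genomic position. Empty input gives an
#'   empty frame.
#' @export
call_sample_dmrs <- function(sample_frags, background, map,
                             thresholds = discovery_thresholds()) {
  bg <- if (inherits(background, "background_index")) background
        else background_index(background)
  cw <- .window_pattern_counts(sample_frags)
  empty <- data.frame(chrom = character(0), first_cpg_pos = integer(0),
                      first_ord = integer(0), pattern = character(0),
                      cancer_freq = numeric(0), cancer_n = integer(0),
                      noise_rate = numeric(0), background_n = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(cw$patterns) == 0L) return(empty)
  cand <- cw$patterns
  wkey <- as.character(cand$first_ord)
  cand$cancer_n <- as.integer(cw$totals[wkey])
  cand$cancer_freq <- cand$count / cand$cancer_n
  cand <- cand[cand$cancer_freq >= thresholds$min_cancer_freq, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  # windows must not straddle a chromosome boundary of the ordinal index
  chrom_first <- map$chrom[cand$first_ord]
  chrom_last <- map$chrom[cand$first_ord + 4L]
  cand <- cand[!is.na(chrom_last) & chrom_first == chrom_last, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  bkey <- as.character(cand$first_ord)
  bg_n <- bg$totals[bkey]
  bg_n[is.na(bg_n)] <- 0L
  pkey <- paste(cand$first_ord, cand$pattern, sep = "|")
  bg_pat <- stats::setNames(bg$patterns$count,
                            paste(bg$patterns$first_ord, bg$patterns$pattern, sep = "|"))
  bg_k <- bg_pat[pkey]
  bg_k[is.na(bg_k)] <- 0L
  rate <- ifelse(bg_n > 0L, bg_k / bg_n, NA_real_)
  keep <- bg_n >= thresholds$min_background_n & !is.na(rate) &
    rate < thresholds$max_noise
  cand <- cand[keep, , drop = FALSE]
  rate <- rate[keep]; bg_n <- bg_n[keep]
  if (nrow(cand) == 0L) return(empty)
  out <- data.frame(chrom = map$chrom[cand$first_ord],
                    first_cpg_pos = map$pos[cand$first_ord],
                    first_ord = cand$first_ord, pattern = cand$pattern,
                    cancer_freq = cand$cancer_freq, cancer_n = cand$cancer_n,
                    noise_rate = as.numeric(rate),
                    background_n = as.integer(bg_n),
                    stringsAsFactors = FALSE)
  # one pattern per window: highest cancer frequency, tie-broken by lower
  # noise then lexicographic pattern for determinism
  out <- out[order(out$first_ord, -out$cancer_freq, out$noise_rate, out$pattern), ]
  out <- out[!duplicated(out$first_ord), , drop = FALSE]
  out <- out[order(out$chrom, out$first_cpg_pos, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Merge per-sample DMR calls into per-label sets
#'
#' The label set is the union of (window, pattern) pairs called in any of
#' the label's tissue samples. Empirical prevalence of a DMR is the
#' fraction of the label's samples in which it was called; the frequency
#' matrix holds the observed pattern frequency (`k/n`, 0 when no fragment
#' covers the window — such cells are flagged) of every DMR in every
#' sample.
#'
#' @param calls named list (by sample id) of [call_sample_dmrs()] outputs.
#' @param manifest manifest data frame with `sample_id` and `cancer_label`
#'   for every calling sample.
#' @param frags_by_sample named list of fragment data frames, used to fill
#'   the frequency matrix; `NULL` omits it.
#' @return Named list of `label_dmr_set` objects, each with `label`,
#'   `dmrs` (window table with `empirical_prevalence`) and
#'   `frequency_matrix` (samples x DMRs; attribute `no_coverage` marks
#'   cells with `n = 0`).
#' @export
merge_label_dmrs <- function(calls, manifest, frags_by_sample = NULL) {
  ids <- names(calls)
  lab <- manifest$cancer_label[match(ids, manifest$sample_id)]
  if (anyNA(lab))
    stop("samples without a cancer label in manifest: ",
         paste(ids[is.na(lab)], collapse = ", "))
  out <- list()
  for (L in unique(lab)) {
    sids <- ids[lab == L]
    per <- calls[sids]
    all_calls <- do.call(rbind, per)
    if (is.null(all_calls) || nrow(all_calls) == 0L) {
      dmrs <- data.frame(chrom = character(0), first_cpg_pos = integer(0),
                         first_ord = integer(0), pattern = character(0),
                         dmr_id = character(0), empirical_prevalence = numeric(0),
                         stringsAsFactors = FALSE)
      out[[L]] <- structure(list(label = L, dmrs = dmrs, frequency_matrix = NULL),
                            class = "label_dmr_set")
      next
    }
    key <- paste(all_calls$first_ord, all_calls$pattern, sep = "|")
    uniq <- !duplicated(key)
    dmrs <- all_calls[uniq, c("chrom", "first_cpg_pos", "first_ord", "pattern")]
    ukey <- key[uniq]
    per_keys <- lapply(per, function(cc)
      unique(paste(cc$first_ord, cc$pattern, sep = "|")))
    tab <- table(unlist(per_keys, use.names = FALSE))
    called_in <- as.integer(tab[ukey])
    dmrs$dmr_id <- paste(L, dmrs$chrom, dmrs$first_cpg_pos, dmrs$pattern, sep = ":")
    dmrs$empirical_prevalence <- called_in / length(sids)
    ord <- order(dmrs$chrom, dmrs$first_cpg_pos, dmrs$pattern)
    dmrs <- dmrs[ord, , drop = FALSE]
    rownames(dmrs) <- NULL
    fm <- NULL
    if (!is.null(frags_by_sample)) {
      fm <- matrix(0, nrow = length(sids), ncol = nrow(dmrs),
                   dimnames = list(sids, dmrs$dmr_id))
      nocov <- matrix(FALSE, nrow = length(sids), ncol = nrow(dmrs),
                      dimnames = dimnames(fm))
      for (s in sids) {
        for (j in seq_len(nrow(dmrs))) {
          cnt <- count_pattern(frags_by_sample[[s]], dmrs$first_ord[j],
                               dmrs$pattern[j])
          if (cnt$n == 0L) nocov[s, j] <- TRUE else fm[s, j] <- cnt$k / cnt$n
        }
      }
      attr(fm, "no_coverage") <- nocov
    }
    out[[L]] <- structure(list(label = L, dmrs = dmrs, frequency_matrix = fm),
                          class = "label_dmr_set")
  }
  out
}

#' Most prevalent DMRs of a label set
#'
#' @param set a `label_dmr_set`.
#' @param k number of DMRs to keep (default 50); fewer are returned when
#'   the set is smaller. Ties at the cutoff are broken by
#'   (chrom, first_cpg_pos, pattern) ascending, so the result is stable.
#' @return The `dmrs` data frame rows of the top-`k` DMRs by empirical
#'   prevalence.
#' @export
top_prevalent <- function(set, k = 50L) {
  if (k <= 0L) stop("k must be positive")
  d <- set$dmrs
  ord <- order(-d$empirical_prevalence, d$chrom, d$first_cpg_pos, d$pattern)
  out <- d[ord[seq_len(min(k, nrow(d)))], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cosine similarity between label prevalence profiles
#'
#' Per-label prevalence vectors are laid out over the union of all DMR ids
#' across the sets (a DMR absent from a label contributes 0); an all-zero
#' vector has similarity 0 with every other label.
#'
#' @param sets list of `label_dmr_set` objects (at least 2).
#' @return Symmetric label-by-label matrix with unit diagonal.
#' @export
label_cosine_similarity <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 label sets")
  labels <- vapply(sets, function(s) s$label, "")
  # identity across labels is the window, not the label-qualified id
  wkey <- lapply(sets, function(s) paste(s$dmrs$first_ord, s$dmrs$pattern, sep = "|"))
  univ <- unique(unlist(wkey))
  V <- matrix(0, nrow = length(sets), ncol = length(univ),
              dimnames = list(labels, univ))
  for (i in seq_along(sets))
    V[i, wkey[[i]]] <- sets[[i]]$dmrs$empirical_prevalence
  nrm <- sqrt(rowSums(V^2))
  S <- matrix(0, length(sets), length(sets), dimnames = list(labels, labels))
  for (i in seq_along(sets)) for (j in seq_along(sets)) {
    S[i, j] <- if (nrm[i] == 0 || nrm[j] == 0) 0
               else sum(V[i, ] * V[j, ]) / (nrm[i] * nrm[j])
  }
  diag(S) <- 1
  S
}

#' Leaf orders for the DMR frequency heatmap
#'
#' Samples (within each cancer label) and DMRs are clustered with
#' Manhattan distance; cancer labels with Spearman distance (1 minus the
#' Spearman correlation) on the label-mean frequency profiles. Average
#' (UPGMA) linkage throughout. A label pair with a constant profile has an
#' undefined Spearman correlation; its distance is set to 1 and reported.
#'
#' @param freq_matrix samples x DMRs frequency matrix with row and column
#'   names.
#' @param sample_labels cancer label of each row.
#' @return List with `sample_order`, `dmr_order`, `label_order` (character
#'   vectors of names in leaf order) and `spearman_undefined` (count of
#'   label pairs whose distance was imputed).
#' @export
cluster_heatmap_order <- function(freq_matrix, sample_labels) {
  stopifnot(nrow(freq_matrix) == length(sample_labels))
  leaf_order <- function(m, distfun) {
    if (nrow(m) <= 2L) return(rownames(m))
    hc <- stats::hclust(distfun(m), method = "average")
    rownames(m)[hc$order]
  }
  manhattan <- function(m) stats::dist(m, method = "manhattan")
  dmr_order <- leaf_order(t(freq_matrix), manhattan)
  labs <- unique(sample_labels)
  means <- t(vapply(labs, function(L) {
    colMeans(freq_matrix[sample_labels == L, , drop = FALSE])
  }, numeric(ncol(freq_matrix))))
  rownames(means) <- labs
  undefined <- 0L
  if (length(labs) > 2L) {
    rho <- suppressWarnings(stats::cor(t(means), method = "spearman"))
    d <- 1 - rho
    undefined <- sum(is.na(d[upper.tri(d)]))
    d[is.na(d)] <- 1
    diag(d) <- 0
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    label_order <- labs[hc$order]
  } else label_order <- labs
  sample_order <- unlist(lapply(label_order, function(L) {
    rows <- rownames(freq_matrix)[sample_labels == L]
    leaf_order(freq_matrix[rows, , drop = FALSE], manhattan)
  }), use.names = FALSE)
  list(sample_order = sample_order, dmr_order = dmr_order,
       label_order = label_order, spearman_undefined = undefined)
}
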