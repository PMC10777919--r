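#' Synthetic cohort generator configuration
#'
#' Defaults describe the targeted-methylation regime the pipeline is built
#' for: a refined panel of 5,000 DMR regions, a mean depth of 1,000
#' fragments per region (negative binomial across regions), per-DMR
#' targeted-assay noise rates drawn from a Beta scaled to `[0, 1e-3]`
#' with mean `2e-5`, pull-down efficiencies with mean 0.8, and a wide
#' prevalence distribution. With these settings the estimator's
#' quantification floor lands near a tumor fraction of `1e-5`.
#'
#' @param n_regions number of panel regions (one DMR each).
#' @param cpgs_per_region CpGs per region (>= 5; the default 5 makes each
#'   region exactly one window).
#' @param n_labels number of cancer labels for tissue cohorts.
#' @param n_tissue_samples_per_label tissue WGBS samples per label.
#' @param prevalence_shape Beta shape parameters for DMR prevalence.
#' @param noise_shape Beta shape parameters for noise rates.
#' @param noise_scale upper bound of the scaled noise distribution.
#' @param efficiency_shape Beta shape parameters for pull-down efficiency.
#' @param depth_mean,depth_dispersion negative-binomial depth per region
#'   (mean fragments and size parameter).
#' @param per_cpg_error per-CpG bisulfite miscall (state flip) rate.
#' @param nocall_rate per-CpG no-call (`N`) rate in fragment data.
#' @param partial_fraction fraction of fragments covering only a
#'   sub-interval of their region.
#' @param tissue_frag_per_region mean fragments per region in tissue
#'   samples.
#' @param tissue_dmr_freq within-sample frequency of a carried DMR
#'   pattern in tissue fragments.
#' @param pool_frag_per_region mean fragments per region in the pooled
#'   non-cancer plasma background.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_regions = 5000L, cpgs_per_region = 5L, n_labels = 2L,
                       n_tissue_samples_per_label = 10L,
                       prevalence_shape = c(0.8, 1.8),
                       noise_shape = c(0.5, 24.5), noise_scale = 1e-3,
                       efficiency_shape = c(8, 2),
                       depth_mean = 1000, depth_dispersion = 10,
                       per_cpg_error = 0.003, nocall_rate = 0.01,
                       partial_fraction = 0.2,
                       tissue_frag_per_region = 60, tissue_dmr_freq = 0.4,
                       pool_frag_per_region = 300) {
  if (cpgs_per_region < 5L) stop("cpgs_per_region must be at least 5")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic DMR panel with ground-truth annotations
#'
#' Lays regions out over 22 autosomes (zero-padded names so lexicographic
#' chromosome order matches numeric order), plants one strong-pattern DMR
#' per region at a known window, and draws ground-truth noise,
#' prevalence and efficiency per DMR. Each region also receives a fixed
#' non-cancer background state vector (the complement of the DMR pattern
#' at the window sites) used by the fragment-level generators.
#'
#' @param config a [sim_config()].
#' @param seed optional integer seed; generation is deterministic given
#'   it.
#' @return A `tmef_panel` list: `map` ([cpg_map()]), `dmrs` (annotation
#'   table with ground truth and `first_ord`), `regions` (per-region
#'   layout with background states), `config`.
#' @export
simulate_panel <- function(config = sim_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  R <- config$n_regions; W <- config$cpgs_per_region
  chrom_of_region <- sprintf("chr%02d", 1L + (seq_len(R) - 1L) %% 22L)
  # regions are laid out chromosome-major so the map is sorted
  ord <- order(chrom_of_region)
  chrom_of_region <- chrom_of_region[ord]
  within <- stats::ave(seq_len(R), chrom_of_region, FUN = seq_along)
  region_start <- (within - 1L) * 2000L + 1000L
  pos <- as.integer(rep(region_start, each = W) + 10L * (seq_len(W) - 1L))
  map <- cpg_map(rep(chrom_of_region, each = W), pos)
  region_first_ord <- (seq_len(R) - 1L) * W + 1L
  win_offset <- sample.int(W - 4L, R, replace = TRUE) - 1L
  pattern <- sample(c("MMMMM", "UUUUU"), R, replace = TRUE)
  noise <- config$noise_scale * stats::rbeta(R, config$noise_shape[1],
                                             config$noise_shape[2])
  prevalence <- stats::rbeta(R, config$prevalence_shape[1],
                             config$prevalence_shape[2])
  efficiency <- stats::rbeta(R, config$efficiency_shape[1],
                             config$efficiency_shape[2])
  # region background: complement of the DMR pattern at window sites,
  # random elsewhere (fixed once so the pool is internally consistent)
  background <- character(R)
  flip <- c(M = "U", U = "M")
  for (i in seq_len(R)) {
    st <- sample(c("M", "U"), W, replace = TRUE)
    w <- win_offset[i] + seq_len(5L)
    st[w] <- flip[strsplit(pattern[i], "")[[1]]]
    background[i] <- paste(st, collapse = "")
  }
  first_ord <- region_first_ord + win_offset
  dmrs <- dmr_records(label = "Synthetic", chrom = chrom_of_region,
                      first_cpg_pos = map$pos[first_ord], pattern = pattern,
                      noise_rate = noise, prevalence = prevalence,
                      efficiency = efficiency, first_ord = first_ord)
  regions <- data.frame(region = seq_len(R), chrom = chrom_of_region,
                        first_ord = region_first_ord, n_cpgs = W,
                        win_offset = win_offset, background = background,
                        stringsAsFactors = FALSE)
  structure(list(map = map, dmrs = dmrs, regions = regions, config = config),
            class = "tmef_panel")
}

#' Draw per-tumor DMR carrier status
#'
#' A tumor either carries a DMR or it does not; the draw is Bernoulli in
#' the DMR's ground-truth prevalence and is shared across everything
#' generated for that tumor (replicate dilutions included).
#'
#' @param panel a [simulate_panel()] result.
#' @return Integer 0/1 vector, one per panel DMR.
#' @export
draw_presence <- function(panel) {
  stats::rbinom(nrow(panel$dmrs), 1L, panel$dmrs$prevalence)
}

#' Simulate targeted-methylation plasma pattern counts
#'
#' Per DMR: depth `n` is negative binomial; the matching count `k` is
#' binomial with success rate `min(1, tf * e + eps)` when the tumor
#' carries the DMR and `eps` otherwise. `tf = 0` gives a non-cancer
#' sample (statistically identical to background regardless of
#' `presence`).
#'
#' @param panel a [simulate_panel()] result.
#' @param tf tumor fraction in `[0, 1]`.
#' @param presence optional 0/1 carrier vector (see [draw_presence()]);
#'   drawn fresh when `NULL` and `tf > 0`.
#' @return Counts data frame (`dmr_id`, `k`, `n`) with the carrier vector
#'   in `attr(, "presence")`.
#' @export
simulate_plasma_counts <- function(panel, tf, presence = NULL) {
  if (tf < 0 || tf > 1) stop("tf must lie in [0,1]")
  d <- panel$dmrs; cfg <- panel$config
  if (is.null(presence)) presence <- if (tf > 0) draw_presence(panel)
                                     else integer(nrow(d))
  n <- stats::rnbinom(nrow(d), mu = cfg$depth_mean, size = cfg$depth_dispersion)
  p <- .clamp_p(pmin(1, tf * d$efficiency * presence + d$noise_rate))
  k <- stats::rbinom(nrow(d), n, p)
  out <- data.frame(dmr_id = d$dmr_id, k = k, n = n, stringsAsFactors = FALSE)
  attr(out, "presence") <- presence
  out
}

# Emit fragments for one region: `n_frag` fragments, `carrier_freq` of
# which carry the DMR pattern at the window, with per-CpG miscalls,
# no-calls, and a fraction covering only a sub-interval.
.region_fragments <- function(sample_id, region, pattern, map, cfg,
                              n_frag, carrier_freq) {
  if (n_frag == 0L) return(NULL)
  W <- region$n_cpgs
  base <- strsplit(region$background, "")[[1]]
  dmr_states <- base
  dmr_states[region$win_offset + seq_len(5L)] <- strsplit(pattern, "")[[1]]
  carries <- stats::runif(n_frag) < carrier_freq
  mat <- matrix(rep(base, n_frag), nrow = n_frag, byrow = TRUE)
  if (any(carries))
    mat[carries, ] <- matrix(rep(dmr_states, sum(carries)), ncol = W, byrow = TRUE)
  # bisulfite miscalls flip M <-> U; no-calls overwrite with N
  flips <- matrix(stats::runif(n_frag * W) < cfg$per_cpg_error, nrow = n_frag)
  if (any(flips)) mat[flips] <- c(M = "U", U = "M")[mat[flips]]
  ncalls <- matrix(stats::runif(n_frag * W) < cfg$nocall_rate, nrow = n_frag)
  mat[ncalls] <- "N"
  lo <- rep(1L, n_frag); hi <- rep(W, n_frag)
  partial <- stats::runif(n_frag) < cfg$partial_fraction
  if (any(partial)) {
    np <- sum(partial)
    a <- sample.int(W, np, replace = TRUE)
    b <- sample.int(W, np, replace = TRUE)
    lo[partial] <- pmin(a, b); hi[partial] <- pmax(a, b)
  }
  ords_lo <- region$first_ord + lo - 1L
  ords_hi <- region$first_ord + hi - 1L
  states <- vapply(seq_len(n_frag), function(i)
    paste(mat[i, lo[i]:hi[i]], collapse = ""), "")
  data.frame(sample_id = sample_id, chrom = region$chrom,
             start = map$pos[ords_lo], end = map$pos[ords_hi] + 1L,
             states = states, first_ord = ords_lo, stringsAsFactors = FALSE)
}

#' Simulate a tissue WGBS sample at the fragment level
#'
#' For each region the sample carries the region's DMR with probability
#' equal to its ground-truth prevalence (or per the supplied carrier
#' vector); carried DMRs emit pattern-matching fragments at frequency
#' `tissue_dmr_freq`, comfortably above the discovery threshold.
#'
#' @param panel a [simulate_panel()] result.
#' @param sample_id sample identifier.
#' @param carried optional 0/1 carrier vector per region.
#' @return Fragment data frame (with `first_ord`) plus the carrier vector
#'   in `attr(, "carried")`.
#' @export
simulate_tissue_sample <- function(panel, sample_id, carried = NULL) {
  cfg <- panel$config
  R <- nrow(panel$regions)
  if (is.null(carried)) carried <- stats::rbinom(R, 1L, panel$dmrs$prevalence)
  n_frag <- stats::rpois(R, cfg$tissue_frag_per_region)
  parts <- vector("list", R)
  for (i in seq_len(R)) {
    parts[[i]] <- .region_fragments(sample_id, panel$regions[i, ],
                                    panel$dmrs$pattern[i], panel$map, cfg,
                                    n_frag[i],
                                    if (carried[i] == 1L) cfg$tissue_dmr_freq else 0)
  }
  out <- do.call(rbind, parts)
  if (is.null(out)) out <- data.frame(sample_id = character(0), chrom = character(0),
                                      start = integer(0), end = integer(0),
                                      states = character(0), first_ord = integer(0),
                                      stringsAsFactors = FALSE)
  attr(out, "carried") <- carried
  out
}

#' Simulate the pooled non-cancer plasma background
#'
#' Background fragments show each region's fixed non-cancer methylation
#' states (never the planted DMR pattern, short of coincident per-CpG
#' miscalls), at `pool_frag_per_region` mean depth.
#'
#' @param panel a [simulate_panel()] result.
#' @param sample_id identifier for the pooled fragments.
#' @return Fragment data frame.
#' @export
simulate_background_pool <- function(panel, sample_id = "noncancer_pool") {
  cfg <- panel$config
  R <- nrow(panel$regions)
  n_frag <- stats::rpois(R, cfg$pool_frag_per_region)
  parts <- vector("list", R)
  for (i in seq_len(R)) {
    parts[[i]] <- .region_fragments(sample_id, panel$regions[i, ],
                                    panel$dmrs$pattern[i], panel$map, cfg,
                                    n_frag[i], 0)
  }
  do.call(rbind, parts)
}

#' Simulate a TMeF-versus-size shedding cohort
#'
#' TMeF follows a power law in tumor size with lognormal noise:
#' `tmef = c * size^beta * exp(N(0, sigma^2))`.
#'
#' @param n cohort size.
#' @param beta true scaling factor.
#' @param sigma lognormal noise standard deviation (natural-log scale).
#' @param size_range tumor size range in cm (log-uniform draw).
#' @param base_coef multiplicative constant `c`.
#' @return Data frame with `size_cm` and `tmef`.
#' @export
simulate_shedding_cohort <- function(n = 100L, beta = 2, sigma = 0.5,
                                     size_range = c(1, 10), base_coef = 1e-5) {
  size <- exp(stats::runif(n, log(size_range[1]), log(size_range[2])))
  tmef <- base_coef * size^beta * exp(stats::rnorm(n, 0, sigma))
  data.frame(size_cm = size, tmef = tmef)
}

#' Run the full synthetic dilution experiment
#'
#' Generates a cancer cohort with tumor fractions log-uniform over
#' `tf_range` and a non-cancer cohort on the panel, refines the panel
#' annotations, builds the requested number of dilution series per
#' cancer sample at the standard mixing levels (carrier status shared
#' across a tumor's series), estimates TMeF for every mixture, and
#' summarizes linearity at the requested expected TMeF levels.
#'
#' @param panel a [simulate_panel()] result, or `NULL` for the default
#'   panel.
#' @param n_cancer number of cancer samples (titratable samples need
#'   `tf > 0.005`, which `tf_range` guarantees).
#' @param n_background number of non-cancer samples to draw series
#'   partners from.
#' @param n_backgrounds_per_cancer dilution series per cancer sample.
#' @param tf_range tumor-fraction range for the cancer cohort.
#' @param r_levels mixing fractions.
#' @param levels_eval expected TMeF levels for the linearity report.
#' @param grid a [tf_grid()].
#' @param h heterozygosity factor.
#' @param seed master seed; every draw in the experiment follows from it.
#' @return List with `series` (stacked per-series results incl.
#'   `series_id`), `linearity` (the [linearity_report()]), and
#'   `annotations` (the refined panel used).
#' @export
dilution_experiment <- function(panel = NULL, n_cancer = 100L,
                                n_background = 300L,
                                n_backgrounds_per_cancer = 3L,
                                tf_range = c(0.005, 0.3),
                                r_levels = dilution_levels(),
                                levels_eval = c(1e-3, 1e-4),
                                grid = tf_grid(), h = 0.5, seed = 1L) {
  set.seed(seed)
  if (is.null(panel)) panel <- simulate_panel(sim_config())
  ann <- refine_dmrs(panel$dmrs)
  sub <- function(counts) counts[match(ann$dmr_id, counts$dmr_id), , drop = FALSE]
  backgrounds <- lapply(seq_len(n_background), function(i)
    sub(simulate_plasma_counts(panel, 0)))
  tfs <- exp(stats::runif(n_cancer, log(tf_range[1]), log(tf_range[2])))
  all <- vector("list", n_cancer * n_backgrounds_per_cancer)
  idx <- 0L
  for (i in seq_len(n_cancer)) {
    presence <- draw_presence(panel)
    cancer <- sub(simulate_plasma_counts(panel, tfs[i], presence = presence))
    bg_ids <- sample.int(n_background, n_backgrounds_per_cancer)
    for (b in bg_ids) {
      res <- dilution_series(cancer, backgrounds[[b]], ann,
                             r_levels = r_levels, grid = grid, h = h)
      res$series_id <- sprintf("c%03d_b%03d", i, b)
      res$tf_true <- tfs[i]
      idx <- idx + 1L
      all[[idx]] <- res
    }
  }
  series <- do.call(rbind, all)
  list(series = series,
       linearity = linearity_report(series, levels_eval),
       annotations = ann)
}
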