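#' End-to-end synthetic benchmark of the TMeF pipeline
#'
#' Runs every stage on generated data: fragment-level DMR discovery
#' against a pooled non-cancer background, label merging,
#' hematopoietic-lineage filtering, refinement, per-DMR prevalence
#' estimation, TMeF estimation with a non-cancer background cutoff, the
#' synthetic dilution linearity experiment, and the tumor-size scaling
#' fit. Writes TSV tables plus a machine-readable `summary.json` to
#' `out_dir`; two runs with the same seed produce byte-identical
#' summaries.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed.
#' @param discovery_config [sim_config()] for the fragment-level
#'   discovery stage (small by default: fragment scanning is the
#'   expensive part).
#' @param panel_config [sim_config()] for the count-level panel stages.
#' @param n_cancer,n_background dilution-experiment cohort sizes.
#' @param n_noncancer_cutoff non-cancer samples for the background
#'   cutoff.
#' @return Invisibly, the summary list written to `summary.json`.
#' @export
tmef_bench <- function(out_dir, seed = 1L,
                       discovery_config = sim_config(
                         n_regions = 120L, n_labels = 2L,
                         n_tissue_samples_per_label = 6L,
                         pool_frag_per_region = 200,
                         tissue_frag_per_region = 40),
                       panel_config = sim_config(n_regions = 1500L),
                       n_cancer = 10L, n_background = 40L,
                       n_noncancer_cutoff = 60L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)

  ## discovery on fragment-level tissue data
  disc_panel <- simulate_panel(discovery_config)
  pool <- simulate_background_pool(disc_panel)
  bg_idx <- background_index(pool)
  labels <- c("Lung", "Lymphoid Lineage")[seq_len(discovery_config$n_labels)]
  manifest <- NULL; calls <- list(); frags <- list()
  for (L in labels) {
    for (s in seq_len(discovery_config$n_tissue_samples_per_label)) {
      sid <- sprintf("%s_t%02d", gsub(" ", "_", L), s)
      fr <- simulate_tissue_sample(disc_panel, sid)
      frags[[sid]] <- fr
      calls[[sid]] <- call_sample_dmrs(fr, bg_idx, disc_panel$map)
      manifest <- rbind(manifest, data.frame(
        sample_id = sid, group = "cancer_tissue", cancer_label = L,
        stage = NA, tumor_size_cm = NA, assay = "wgbs",
        stringsAsFactors = FALSE))
    }
  }
  sets <- merge_label_dmrs(calls, manifest, frags_by_sample = frags)
  heme_sets <- lapply(sets[intersect(names(sets), HEME_LABELS)],
                      function(s) s$dmrs)
  filt <- lapply(names(sets), function(L) {
    d <- sets[[L]]$dmrs
    d$label <- L
    if (L %in% HEME_LABELS || length(heme_sets) == 0L)
      list(dmrs = d, fraction_removed = 0)
    else heme_filter(d, heme_sets)
  })
  names(filt) <- names(sets)
  heme_summary <- data.frame(
    label = names(sets),
    unfiltered = vapply(sets, function(s) nrow(s$dmrs), integer(1)),
    filtered = vapply(filt, function(f) nrow(f$dmrs), integer(1)),
    stringsAsFactors = FALSE)
  heme_summary$fraction_removed <-
    removal_fraction(heme_summary$unfiltered, heme_summary$filtered)
  utils::write.table(heme_summary, file.path(out_dir, "heme_filter.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## count-level panel: prevalence recovery, cutoff, dilutions, scaling
  panel <- simulate_panel(panel_config)
  ann <- refine_dmrs(panel$dmrs)
  write_dmr_table(ann, file.path(out_dir, "panel_refined.tsv"))

  n_prev <- 50L
  tfs <- exp(stats::runif(n_prev, log(0.01), log(0.3)))
  target <- which.max(ann$prevalence * (ann$prevalence < 0.9))
  kk <- integer(n_prev); nn <- integer(n_prev)
  for (j in seq_len(n_prev)) {
    cnt <- simulate_plasma_counts(panel, tfs[j])
    row <- match(ann$dmr_id[target], cnt$dmr_id)
    kk[j] <- cnt$k[row]; nn[j] <- cnt$n[row]
  }
  prev_post <- prevalence_posterior(kk, nn, tfs, ann$noise_rate[target],
                                    ann$efficiency[target],
                                    dmr_id = ann$dmr_id[target])
  prev_tab <- data.frame(dmr_id = ann$dmr_id[target],
                         rho_true = ann$prevalence[target],
                         rho_posterior_median = prev_post$median)
  utils::write.table(prev_tab, file.path(out_dir, "prevalence.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  sub <- function(counts) counts[match(ann$dmr_id, counts$dmr_id), , drop = FALSE]
  nc_tmef <- vapply(seq_len(n_noncancer_cutoff), function(i)
    estimate_tmef(sub(simulate_plasma_counts(panel, 0)), ann)$tmef, numeric(1))
  cutoff <- background_cutoff(nc_tmef)

  dil <- dilution_experiment(panel = panel, n_cancer = n_cancer,
                             n_background = n_background,
                             seed = seed + 1L)
  utils::write.table(dil$series, file.path(out_dir, "dilutions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dil$linearity, file.path(out_dir, "linearity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  shed <- simulate_shedding_cohort(n = 100L, beta = 2, sigma = 0.5)
  scal <- fit_scaling(shed$tmef, shed$size_cm)

  summary <- list(
    seed = seed,
    discovery = list(
      n_windows_called_total = sum(vapply(calls, nrow, integer(1))),
      labels = names(sets)),
    heme_filter = list(median_fraction_removed_solid =
      stats::median(heme_summary$fraction_removed[
        !(heme_summary$label %in% HEME_LABELS)])),
    prevalence = list(rho_true = prev_tab$rho_true,
                      rho_posterior_median = prev_tab$rho_posterior_median),
    background_cutoff = cutoff,
    linearity = dil$linearity,
    scaling = list(beta = scal$beta, beta_robust = scal$beta_robust,
                   p_value = scal$p_value))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(summary)
}
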