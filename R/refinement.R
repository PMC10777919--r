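#' Hematopoietic-lineage labels
#'
#' Labels whose DMR sets define the heme filter and which the filter never
#' reduces.
#' @export
HEME_LABELS <- c("Lymphoid Lineage", "Myeloid Lineage", "Plasma Cell Lineage")

#' Removal fraction of a filtering step
#'
#' @param total DMR count before filtering.
#' @param kept DMR count after filtering.
#' @return `(total - kept) / total` (0 for an empty input), unrounded;
#'   round for display only.
#' @export
removal_fraction <- function(total, kept) {
  ifelse(total == 0, 0, (total - kept) / total)
}

#' Filter solid-tumor DMRs overlapping hematopoietic-lineage DMRs
#'
#' Removes from a solid cancer label every DMR whose 5-CpG window shares
#' at least one CpG ordinal with any DMR window of the lymphoid, myeloid
#' or plasma-cell lineage sets, regardless of pattern. This suppresses
#' interference from blood conditions and from hematopoietic cells
#' resident in tissue biopsies. Heme-lineage labels pass through
#' unchanged.
#'
#' @param solid DMR data frame (needs `label` and `first_ord` columns, plus
#'   `chrom` to guard ordinal adjacency across chromosome boundaries).
#' @param heme_sets list of DMR data frames for the heme lineages (each
#'   needs `first_ord` and `chrom`).
#' @param heme_labels labels treated as hematopoietic.
#' @return List with `dmrs` (the filtered data frame) and
#'   `fraction_removed`.
#' @export
heme_filter <- function(solid, heme_sets, heme_labels = HEME_LABELS) {
  total <- nrow(solid)
  if (total > 0L && all(solid$label %in% heme_labels))
    return(list(dmrs = solid, fraction_removed = 0))
  if (total == 0L) return(list(dmrs = solid, fraction_removed = 0))
  heme <- do.call(rbind, lapply(heme_sets, function(h)
    h[, c("chrom", "first_ord"), drop = FALSE]))
  if (is.null(heme) || nrow(heme) == 0L)
    return(list(dmrs = solid, fraction_removed = 0))
  # windows [a, a+4] overlap iff |a - b| <= 4 and same chromosome
  hit <- logical(total)
  for (ch in unique(solid$chrom)) {
    hb <- sort(heme$first_ord[heme$chrom == ch])
    if (length(hb) == 0L) next
    si <- which(solid$chrom == ch)
    a <- solid$first_ord[si]
    j <- findInterval(a + 4L, hb)            # last heme start <= a + 4
    hit[si] <- j >= 1L & (a - hb[pmax(j, 1L)]) <= 4L
  }
  kept <- solid[!hit, , drop = FALSE]
  rownames(kept) <- NULL
  list(dmrs = kept, fraction_removed = removal_fraction(total, nrow(kept)))
}

#' Refinement criteria for TMeF-grade DMRs
#'
#' Defaults keep only highly informative regions: background noise below
#' 1/10,000, a strong pattern (completely methylated or unmethylated),
#' autosomal location, and a passing assay-performance flag.
#'
#' @param max_noise maximum noise rate (default `1e-4`).
#' @param require_strong_pattern drop non-all-M/all-U patterns
#'   (default `TRUE`).
#' @param exclude_sex_chroms drop chrX/chrY windows (default `TRUE`).
#' @param require_assay_ok drop DMRs failing panel QC (default `TRUE`).
#' @return A `refinement_criteria` list.
#' @export
refinement_criteria <- function(max_noise = 1e-4, require_strong_pattern = TRUE,
                                exclude_sex_chroms = TRUE,
                                require_assay_ok = TRUE) {
  if (!(max_noise > 0 && max_noise < 1)) stop("max_noise must be in (0,1)")
  structure(list(max_noise = max_noise,
                 require_strong_pattern = require_strong_pattern,
                 exclude_sex_chroms = exclude_sex_chroms,
                 require_assay_ok = require_assay_ok),
            class = "refinement_criteria")
}

#' Refine an annotated DMR table for TMeF estimation
#'
#' @param records DMR data frame with `noise_rate`, `strong_pattern`,
#'   `sex_chrom` and `assay_ok` populated for every row; a missing
#'   annotation is an error naming the DMR.
#' @param criteria a [refinement_criteria()].
#' @return The surviving rows. Idempotent: refining a refined table is a
#'   no-op.
#' @export
refine_dmrs <- function(records, criteria = refinement_criteria()) {
  need <- c("noise_rate", "strong_pattern", "sex_chrom", "assay_ok")
  for (col in need) {
    if (is.null(records[[col]]) || anyNA(records[[col]])) {
      bad <- if (is.null(records[[col]])) records$dmr_id
             else records$dmr_id[is.na(records[[col]])]
      stop("missing ", col, " annotation for DMR(s): ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  keep <- records$noise_rate < criteria$max_noise
  if (criteria$require_strong_pattern) keep <- keep & records$strong_pattern
  if (criteria$exclude_sex_chroms) keep <- keep & !records$sex_chrom
  if (criteria$require_assay_ok) keep <- keep & records$assay_ok
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
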