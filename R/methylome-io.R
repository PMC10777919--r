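#' Construct a CpG site map
#'
#' A CpG map is the ordered catalogue of CpG sites the assay covers. Sites
#' are indexed by a consecutive ordinal (1-based row number) and window
#' contiguity everywhere in the package is defined on this ordinal index,
#' not on genomic distance. Positions are 0-based coordinates of the C on
#' the forward strand; reverse-strand calls are assumed pre-collapsed by
#' upstream processing.
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 0-based CpG positions.
#' @return A `cpg_map` data frame with columns `chrom` and `pos`, strictly
#'   sorted by (chrom, pos), one row per site; the row number is the
#'   site's ordinal.
#' @export
cpg_map <- function(chrom, pos) {
  if (length(chrom) != length(pos)) stop("chrom and pos must have equal length")
  pos <- as.integer(pos)
  if (anyNA(chrom) || anyNA(pos)) stop("CpG map may not contain missing values")
  ord <- order(chrom, pos)
  map <- data.frame(chrom = as.character(chrom)[ord], pos = pos[ord],
                    stringsAsFactors = FALSE)
  if (anyDuplicated(map)) stop("duplicate CpG sites in map")
  class(map) <- c("cpg_map", "data.frame")
  map
}

#' Read a CpG map from a sorted BED3 file
#'
#' Expects `chrom`, `start`, `end` columns with `end == start + 1` (one row
#' per CpG site); `#` comment lines are skipped.
#'
#' @param path file path (plain text or gzip).
#' @return A [cpg_map()].
#' @export
read_cpg_map <- function(path) {
  bed <- utils::read.table(path, sep = "\t", comment.char = "#",
                           col.names = c("chrom", "start", "end"),
                           colClasses = c("character", "integer", "integer"))
  if (any(bed$end != bed$start + 1L))
    stop("CpG map BED rows must be single positions (end == start + 1)")
  cpg_map(bed$chrom, bed$start)
}

#' Ordinals of CpG sites falling in a genomic interval
#'
#' @param map a [cpg_map()].
#' @param chrom chromosome name.
#' @param start,end 0-based half-open interval.
#' @return Integer vector of ordinals (possibly empty), in increasing order.
#' @export
cpg_ordinals <- function(map, chrom, start, end) {
  which(map$chrom == chrom & map$pos >= start & map$pos < end)
}

#' Ordinal of one CpG site
#'
#' @inheritParams cpg_ordinals
#' @param pos exact 0-based CpG position.
#' @return Integer ordinal, or `NA` if the site is not in the map.
#' @export
cpg_ordinal <- function(map, chrom, pos) {
  i <- which(map$chrom == chrom & map$pos == pos)
  if (length(i) == 0L) NA_integer_ else i[1L]
}

# Internal: attach first-covered ordinal + state count checks to a raw
# fragment table. Fragments are data frames with columns
# sample_id, chrom, start, end, states; `first_ord` is derived.
.index_fragments <- function(frags, map, lines = NULL) {
  n <- nrow(frags)
  first_ord <- rep(NA_integer_, n)
  bad <- character(0)
  for (i in seq_len(n)) {
    ords <- cpg_ordinals(map, frags$chrom[i], frags$start[i], frags$end[i])
    where <- if (is.null(lines)) sprintf("row %d", i) else sprintf("line %d", lines[i])
    if (length(ords) != nchar(frags$states[i])) {
      bad <- c(bad, sprintf("%s: %d states but %d covered CpGs",
                            where, nchar(frags$states[i]), length(ords)))
      next
    }
    if (length(ords) > 0L) first_ord[i] <- ords[1L]
  }
  no_mun <- grepl("[^MUN]", frags$states)
  if (any(no_mun)) {
    where <- if (is.null(lines)) which(no_mun) else lines[no_mun]
    bad <- c(bad, sprintf("%s %s: state characters outside {M,U,N}",
                          if (is.null(lines)) "row" else "line", where))
  }
  if (length(bad) > 0L)
    stop("malformed fragment rows:\n  ", paste(bad, collapse = "\n  "))
  frags$first_ord <- first_ord
  frags
}

#' Read fragment-level methylation calls
#'
#' The fragment dialect is a tab-separated file with columns
#' `sample_id`, `chrom`, `start`, `end`, `states`; coordinates are 0-based
#' half-open and `states` is a string over `{M,U,N}` (methylated,
#' unmethylated, no-call) with one character per CpG-map site covered by
#' `[start, end)`, in ordinal order. Lines starting with `#` are comments.
#'
#' @param path file path (plain text or gzip).
#' @param map the [cpg_map()] the fragments are indexed against.
#' @return A data frame of fragments with columns `sample_id`, `chrom`,
#'   `start`, `end`, `states` and the derived `first_ord` (ordinal of the
#'   first covered CpG; `NA` when the fragment covers none). Malformed rows
#'   raise an error naming their line numbers.
#' @export
read_fragments <- function(path, map) {
  raw <- readLines(path)
  keep <- !startsWith(raw, "#") & nzchar(raw)
  lines <- which(keep)
  fields <- strsplit(raw[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (length(nf) > 0 && any(nf != 5L))
    stop("fragment file format error: expected 5 columns, got ",
         nf[nf != 5L][1L], " at line ", lines[nf != 5L][1L])
  m <- matrix(unlist(fields), ncol = 5L, byrow = TRUE,
              dimnames = list(NULL, c("sample_id", "chrom", "start", "end", "states")))
  frags <- data.frame(sample_id = m[, "sample_id"], chrom = m[, "chrom"],
                      start = as.integer(m[, "start"]), end = as.integer(m[, "end"]),
                      states = m[, "states"], stringsAsFactors = FALSE)
  if (nrow(frags) == 0L)
    frags <- data.frame(sample_id = character(0), chrom = character(0),
                        start = integer(0), end = integer(0),
                        states = character(0), stringsAsFactors = FALSE)
  .index_fragments(frags, map, lines = lines)
}

#' Write fragments in the package's TSV dialect
#'
#' @param frags fragment data frame (see [read_fragments()]).
#' @param path output path; `.gz` suffix writes gzip.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(frags, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines("# sample_id\tchrom\tstart\tend\tstates", con)
  if (nrow(frags) > 0L)
    writeLines(paste(frags$sample_id, frags$chrom, frags$start, frags$end,
                     frags$states, sep = "\t"), con)
  invisible(path)
}

.DMR_COLS <- c("dmr_id", "label", "chrom", "first_cpg_pos", "pattern",
               "noise_rate", "prevalence", "efficiency",
               "sex_chrom", "strong_pattern", "heme_overlap", "assay_ok")
.DMR_NUM <- c("noise_rate", "prevalence", "efficiency")
.DMR_LGL <- c("sex_chrom", "strong_pattern", "heme_overlap", "assay_ok")

#' Validate a 5-CpG DMR window definition
#'
#' A window is 5 contiguous CpG ordinals on one chromosome plus a binary
#' methylation pattern; this checks both against a map.
#'
#' @param map a [cpg_map()].
#' @param first_ord ordinal of the first window site.
#' @param pattern length-5 string over `{M,U}`.
#' @param width window width; fixed at 5.
#' @return `first_ord`, invisibly; errors on violation.
#' @export
validate_window <- function(map, first_ord, pattern, width = 5L) {
  if (width != 5L) stop("window width is fixed at 5")
  if (!grepl("^[MU]{5}$", pattern)) stop("pattern must match ^[MU]{5}$: ", pattern)
  if (is.na(first_ord) || first_ord < 1L || first_ord + 4L > nrow(map))
    stop("window off the CpG map: first_ord = ", first_ord)
  chroms <- map$chrom[first_ord:(first_ord + 4L)]
  if (length(unique(chroms)) != 1L)
    stop("window spans a chromosome boundary at ordinal ", first_ord)
  invisible(first_ord)
}

#' Assemble a DMR record table
#'
#' @param label cancer label.
#' @param chrom,first_cpg_pos window location (position of the first CpG).
#' @param pattern length-5 strings over `{M,U}`.
#' @param noise_rate,prevalence,efficiency per-DMR annotations
#'   (`eps` in `[0,1]`, `rho` in `[0,1]`, `e` in `(0,1]`).
#' @param sex_chrom,heme_overlap,assay_ok filter flags; `strong_pattern` is
#'   derived (`TRUE` iff the pattern is all-M or all-U).
#' @param first_ord optional window ordinals (kept as an extra column when
#'   supplied; recomputable from a map).
#' @return A `data.frame` in the DMR-table dialect, one row per DMR, with
#'   `dmr_id = label:chrom:first_cpg_pos:pattern`.
#' @export
dmr_records <- function(label, chrom, first_cpg_pos, pattern,
                        noise_rate, prevalence, efficiency,
                        sex_chrom = FALSE, heme_overlap = FALSE,
                        assay_ok = TRUE, first_ord = NULL) {
  n_rec <- length(first_cpg_pos)
  if (n_rec == 0L) {
    d <- data.frame(dmr_id = character(0), label = character(0),
                    chrom = character(0), first_cpg_pos = integer(0),
                    pattern = character(0), noise_rate = numeric(0),
                    prevalence = numeric(0), efficiency = numeric(0),
                    sex_chrom = logical(0), strong_pattern = logical(0),
                    heme_overlap = logical(0), assay_ok = logical(0),
                    stringsAsFactors = FALSE)
    if (!is.null(first_ord)) d$first_ord <- integer(0)
    return(d)
  }
  if (any(!grepl("^[MU]{5}$", pattern))) stop("patterns must match ^[MU]{5}$")
  bad_range <- function(x) any(!is.na(x) & (x < 0 | x > 1))
  if (bad_range(noise_rate)) stop("noise_rate outside [0,1]")
  if (bad_range(prevalence)) stop("prevalence outside [0,1]")
  if (any(!is.na(efficiency) & (efficiency <= 0 | efficiency > 1)))
    stop("efficiency outside (0,1]")
  d <- data.frame(
    dmr_id = paste(label, chrom, first_cpg_pos, pattern, sep = ":"),
    label = label, chrom = chrom, first_cpg_pos = as.integer(first_cpg_pos),
    pattern = pattern, noise_rate = noise_rate, prevalence = prevalence,
    efficiency = efficiency, sex_chrom = sex_chrom,
    strong_pattern = pattern %in% c("MMMMM", "UUUUU"),
    heme_overlap = heme_overlap, assay_ok = assay_ok,
    stringsAsFactors = FALSE)
  if (!is.null(first_ord)) d$first_ord <- as.integer(first_ord)
  d
}

#' Write a DMR table as TSV
#'
#' Writes full float precision (`%.17g`) so that [read_dmr_table()] inverts
#' it bit-identically. Column order is fixed to the dialect.
#'
#' @param records DMR data frame (see [dmr_records()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dmr_table <- function(records, path) {
  missing_cols <- setdiff(.DMR_COLS, names(records))
  if (length(missing_cols) > 0)
    stop("DMR table missing columns: ", paste(missing_cols, collapse = ", "))
  out <- records[, .DMR_COLS, drop = FALSE]
  for (col in .DMR_NUM) out[[col]] <- sprintf("%.17g", out[[col]])
  for (col in .DMR_LGL) out[[col]] <- ifelse(out[[col]], "TRUE", "FALSE")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a DMR table TSV
#'
#' @param path file written by [write_dmr_table()].
#' @return DMR data frame in the dialect's column order.
#' @export
read_dmr_table <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c(dmr_id = "character", label = "character",
                                        chrom = "character", first_cpg_pos = "integer",
                                        pattern = "character", noise_rate = "numeric",
                                        prevalence = "numeric", efficiency = "numeric",
                                        sex_chrom = "logical", strong_pattern = "logical",
                                        heme_overlap = "logical", assay_ok = "logical"),
                         stringsAsFactors = FALSE)
  d
}

#' Read a sample manifest CSV
#'
#' Columns: `sample_id`, `group` (one of `cancer_tissue`, `cancer_plasma`,
#' `noncancer_plasma`, `control`), `cancer_label`, `stage`,
#' `tumor_size_cm`, `assay` (`wgbs` or `targeted`). A cancer label is
#' required exactly for the cancer groups.
#'
#' @param path CSV file path.
#' @return Manifest data frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.table(path, sep = ",", header = TRUE, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  groups <- c("cancer_tissue", "cancer_plasma", "noncancer_plasma", "control")
  if (!all(m$group %in% groups))
    stop("unknown group values: ",
         paste(unique(setdiff(m$group, groups)), collapse = ", "))
  is_cancer <- startsWith(m$group, "cancer")
  if (any(is_cancer & (is.na(m$cancer_label) | m$cancer_label == "none")))
    stop("cancer samples require a cancer_label")
  if (!all(m$assay %in% c("wgbs", "targeted")))
    stop("assay must be 'wgbs' or 'targeted'")
  m
}
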