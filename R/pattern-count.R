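#' Count fragments matching a DMR pattern
#'
#' A fragment contributes to the denominator `n` only when it covers all
#' five window sites with a definite M/U call (any no-call `N` at a window
#' site excludes it from both `k` and `n`); it contributes to `k` when its
#' five states equal the pattern exactly.
#'
#' @param frags fragment data frame with `first_ord` (see
#'   [read_fragments()]).
#' @param first_ord ordinal of the first window CpG.
#' @param pattern length-5 string over `{M,U}`.
#' @param map optional [cpg_map()]; when given, the window is validated
#'   against it.
#' @return List with integer components `k` and `n`, `0 <= k <= n`.
#' @export
count_pattern <- function(frags, first_ord, pattern, map = NULL) {
  if (!is.null(map)) validate_window(map, first_ord, pattern)
  if (!grepl("^[MU]{5}$", pattern)) stop("pattern must match ^[MU]{5}$")
  f0 <- frags$first_ord
  len <- nchar(frags$states)
  covers <- !is.na(f0) & f0 <= first_ord & (f0 + len - 1L) >= first_ord + 4L
  if (!any(covers)) return(list(k = 0L, n = 0L))
  off <- first_ord - f0[covers]
  sub <- substr(frags$states[covers], off + 1L, off + 5L)
  valid <- !grepl("N", sub, fixed = TRUE)
  list(k = sum(sub[valid] == pattern), n = sum(valid))
}

#' Background noise rate of a window pattern in a non-cancer pool
#'
#' @param pool pooled non-cancer fragment data frame.
#' @inheritParams count_pattern
#' @return List with `rate` (`k/n`; `NA` and `usable = FALSE` when `n = 0`),
#'   `k`, `n` and `usable`.
#' @export
background_noise <- function(pool, first_ord, pattern, map = NULL) {
  cnt <- count_pattern(pool, first_ord, pattern, map = map)
  list(rate = if (cnt$n == 0L) NA_real_ else cnt$k / cnt$n,
       k = cnt$k, n = cnt$n, usable = cnt$n > 0L)
}

#' Tabulate per-sample pattern counts over a DMR panel
#'
#' @param frags fragment data frame for one sample.
#' @param dmrs DMR data frame with `first_ord` and `pattern` columns.
#' @return Counts data frame with `dmr_id`, `k`, `n`.
#' @export
count_panel <- function(frags, dmrs) {
  kk <- integer(nrow(dmrs)); nn <- integer(nrow(dmrs))
  for (i in seq_len(nrow(dmrs))) {
    cnt <- count_pattern(frags, dmrs$first_ord[i], dmrs$pattern[i])
    kk[i] <- cnt$k; nn[i] <- cnt$n
  }
  data.frame(dmr_id = dmrs$dmr_id, k = kk, n = nn, stringsAsFactors = FALSE)
}

# Expand fragments into one row per (5-CpG window, observed pattern) and
# aggregate. Returns total covering fragments per window and per-pattern
# counts; the workhorse behind discovery and the background index.
.window_pattern_counts <- function(frags) {
  f0 <- frags$first_ord
  len <- nchar(frags$states)
  keep <- !is.na(f0) & len >= 5L
  f0 <- f0[keep]; len <- len[keep]; states <- frags$states[keep]
  if (length(f0) == 0L)
    return(list(totals = integer(0),
                patterns = data.frame(first_ord = integer(0), pattern = character(0),
                                      count = integer(0), stringsAsFactors = FALSE)))
  nwin <- len - 4L
  rep_i <- rep.int(seq_along(f0), nwin)
  off <- sequence(nwin) - 1L
  win <- f0[rep_i] + off
  sub <- substr(rep.int(states, nwin), off + 1L, off + 5L)
  ok <- !grepl("N", sub, fixed = TRUE)
  win <- win[ok]; sub <- sub[ok]
  totals_tab <- table(win)
  totals <- as.integer(totals_tab)
  names(totals) <- names(totals_tab)
  key <- paste(win, sub, sep = "|")
  ptab <- table(key)
  parts <- strsplit(names(ptab), "|", fixed = TRUE)
  patterns <- data.frame(
    first_ord = as.integer(vapply(parts, `[`, "", 1L)),
    pattern = vapply(parts, `[`, "", 2L),
    count = as.integer(ptab), stringsAsFactors = FALSE)
  list(totals = totals, patterns = patterns)
}

#' Precompute a background window-pattern index
#'
#' Aggregates a pooled non-cancer fragment set once so that
#' [call_sample_dmrs()] can score many cancer samples against the same
#' background without rescanning it.
#'
#' @param pool pooled non-cancer fragment data frame.
#' @return A `background_index` object.
#' @export
background_index <- function(pool) {
  idx <- .window_pattern_counts(pool)
  class(idx) <- "background_index"
  idx
}
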