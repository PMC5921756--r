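## Chromosomal organization and duplication-pair evolution.

#' Per-chromosome distribution of a gene family
#'
#' Counts placed genes per chromosome and reports each chromosome's share of
#' the mapped family. Unplaced genes are counted separately and excluded from
#' the fractions.
#'
#' @param records a `gene_table`.
#' @return List with `counts` (named integer vector, decreasing), `fractions`
#'   (same names, proportions of mapped genes), `percent` (fractions as
#'   percentages rounded to 1 decimal), `mapped_total`, `unplaced`.
#' @export
chromosome_distribution <- function(records) {
  placed <- records[records$chromosome != UNPLACED, ]
  if (nrow(placed) == 0) stop("no placed records: distribution undefined")
  counts <- sort(table(placed$chromosome), decreasing = TRUE)
  counts <- stats::setNames(as.integer(counts), names(counts))
  fr <- counts / sum(counts)
  list(counts = counts,
       fractions = fr,
       percent = round(100 * fr, 1),
       mapped_total = sum(counts),
       unplaced = nrow(records) - nrow(placed))
}

#' Isoform census of a gene family
#'
#' Alternative-splicing census: the histogram of per-gene isoform counts and
#' the total number of predicted transcripts.
#'
#' @param records a `gene_table` (needs `isoform_count`).
#' @return List with `total` (sum of isoform counts) and `histogram` (named
#'   vector: number of genes per isoform count).
#' @export
isoform_census <- function(records) {
  if (nrow(records) == 0) return(list(total = 0L, histogram = integer(0)))
  stopifnot(!anyNA(records$isoform_count))
  h <- table(records$isoform_count)
  list(total = as.integer(sum(records$isoform_count)),
       histogram = stats::setNames(as.integer(h), names(h)))
}

#' Detect tandem-duplicated gene clusters
#'
#' Within each chromosome, genes are sorted by start coordinate and maximal
#' runs are formed in which every consecutive inter-gene gap (next start minus
#' previous end, 1-based closed coordinates) is below the window; runs of at
#' least two genes are reported as clusters. The result is independent of the
#' input row order. Overlapping neighbors (negative gap) are treated as gap 0
#' with a warning.
#'
#' @param records a `gene_table`.
#' @param window maximum inter-gene gap in base pairs (default 250000; the
#'   usual "sliding window < 250 kb" tandem rule).
#' @return List of clusters, each a list with `chromosome`, `members` (gene
#'   names ordered by start), `span` (first start to last end, bp), `max_gap`.
#' @export
detect_tandem_clusters <- function(records, window = 250000) {
  placed <- records[records$chromosome != UNPLACED, ]
  placed <- placed[order(placed$chromosome, placed$start, placed$name), ]
  out <- list()
  for (chr in unique(placed$chromosome)) {
    g <- placed[placed$chromosome == chr, ]
    if (nrow(g) < 2) next
    gaps <- g$start[-1] - g$end[-nrow(g)]
    if (any(gaps < 0)) {
      warning("overlapping genes on ", chr, "; negative gaps treated as 0")
      gaps <- pmax(gaps, 0)
    }
    run_id <- cumsum(c(0, gaps >= window))
    for (id in unique(run_id)) {
      idx <- which(run_id == id)
      if (length(idx) < 2) next
      gg <- gaps[idx[-length(idx)]]
      out[[length(out) + 1]] <- list(
        chromosome = chr,
        members = g$name[idx],
        span = g$end[idx[length(idx)]] - g$start[idx[1]] + 1,
        max_gap = max(gg)
      )
    }
  }
  out
}

#' Date a duplication event from its synonymous divergence
#'
#' T = Ks / (2 gamma), with gamma the synonymous substitution rate per site
#' per year. Reported in million years at full precision; round only for
#' presentation.
#'
#' @param ks synonymous substitutions per synonymous site (vectorized).
#' @param gamma substitution rate per site per year (default 6.1e-9, the
#'   standard eudicot clock).
#' @return Divergence time(s) in million years.
#' @export
divergence_time <- function(ks, gamma = 6.1e-9) {
  stopifnot(gamma > 0)
  if (any(ks < 0, na.rm = TRUE)) stop("ks must be nonnegative")
  ks / (2 * gamma) / 1e6
}

#' Classify the selection mode of a duplicate pair
#'
#' Ka/Ks > 1 indicates positive selection, < 1 purifying selection on at
#' least one copy (or drift), and = 1 neutral evolution. Because exact
#' equality is measure-zero, a tolerance band around 1 is called neutral.
#'
#' @param ka,ks substitution rates (scalars).
#' @param neutral_tol half-width of the neutral band on the ratio (default 0.05).
#' @return List with `ratio` and `mode` (`"positive"`, `"purifying_or_drift"`,
#'   `"neutral"`, or `NA` with `undefined = TRUE` when ks = 0).
#' @export
selection_mode <- function(ka, ks, neutral_tol = 0.05) {
  stopifnot(ka >= 0, ks >= 0)
  if (ks == 0) {
    return(list(ratio = NA_real_, mode = NA_character_, undefined = TRUE))
  }
  ratio <- ka / ks
  mode <- if (abs(ratio - 1) <= neutral_tol) "neutral"
          else if (ratio > 1 + neutral_tol) "positive"
          else "purifying_or_drift"
  list(ratio = ratio, mode = mode, undefined = FALSE)
}

#' Summarize a set of duplicate pairs
#'
#' @param pairs data.frame with columns `ka`, `ks` (e.g. from
#'   [read_kaks_pairs()] or [gen_kaks_pairs()]).
#' @param gamma clock rate for dating (see [divergence_time()]).
#' @param neutral_tol passed to [selection_mode()].
#' @return List with `mean_ratio`, `ratio_range`, `time_mya` (per pair),
#'   `time_histogram` (counts in 10-Mya bins), `modes` (table of calls),
#'   `n_undefined` (pairs with ks = 0).
#' @export
duplication_summary <- function(pairs, gamma = 6.1e-9, neutral_tol = 0.05) {
  stopifnot(nrow(pairs) > 0)
  defined <- pairs$ks > 0
  if (!any(defined)) stop("all Ka/Ks ratios undefined (ks = 0 everywhere)")
  ratio <- pairs$ka[defined] / pairs$ks[defined]
  tm <- divergence_time(pairs$ks[defined], gamma)
  breaks <- seq(0, 10 * ceiling(max(tm) / 10 + 1e-9), by = 10)
  if (length(breaks) < 2) breaks <- c(0, 10)
  hist_t <- table(cut(tm, breaks, right = FALSE))
  modes <- vapply(which(defined), function(i) {
    selection_mode(pairs$ka[i], pairs$ks[i], neutral_tol)$mode
  }, character(1))
  list(mean_ratio = mean(ratio),
       ratio_range = range(ratio),
       time_mya = tm,
       time_histogram = hist_t,
       modes = table(modes),
       n_undefined = sum(!defined))
}
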