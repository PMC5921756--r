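## RT-qPCR analytics: amplification efficiency, geNorm/qBase reference-gene
## stability, efficiency-corrected multi-reference normalization (NRQ) with
## error propagation, 3':5' RNA-integrity QC, and expression-matrix
## ordination and clustering.

#' Amplification efficiency from a dilution-series slope
#'
#' (1 + E) = 10^slope, where slope is the log-fluorescence regression slope
#' per cycle; E = 1 means perfect doubling.
#'
#' @param slope regression slope (log10 fluorescence per cycle).
#' @return List with `E` (fraction) and `slope`; a `flag` notes efficiencies
#'   outside the sanity range (0, 1.2].
#' @export
efficiency_from_slope <- function(slope) {
  stopifnot(is.finite(slope))
  E <- 10^slope - 1
  flag <- if (E <= 0 || E > 1.2) "efficiency outside (0, 1.2]" else NA_character_
  if (!is.na(flag)) warning(flag, ": E = ", signif(E, 4))
  list(E = E, slope = slope, flag = flag)
}

#' Efficiency-corrected relative quantity
#'
#' RQ = (1 + E)^(calibrator Cq - Cq): one cycle earlier than the calibrator
#' at E = 1 doubles the quantity.
#'
#' @param cq quantification cycle(s).
#' @param calibrator_cq calibrator sample's Cq for the same assay.
#' @param E amplification efficiency (fraction).
#' @return Relative quantity (NA propagates from missing Cq).
#' @export
relative_quantity <- function(cq, calibrator_cq, E) {
  stopifnot(E > -1)
  (1 + E)^(calibrator_cq - cq)
}

#' geNorm expression-stability values and qBase coefficients of variation
#'
#' For each candidate reference j, M_j is the mean over the other candidates
#' k of the standard deviation across samples of log2(q_j / q_k); stable
#' references have low M. Candidates are eliminated iteratively (worst M
#' first) down to a final pair. The CV of each assay is computed on its
#' quantities normalized by the geometric mean of the selected reference set.
#' Heterogeneous sample panels typically accept references with M < 1 and
#' CV < 0.5.
#'
#' @param quantities numeric matrix, samples x assays, all > 0 (relative
#'   quantities, e.g. from [relative_quantity()]).
#' @return List with `M` (full-set stability values), `CV` (vs the selected
#'   pair), `ranking` (best to worst), `selected` (the final pair),
#'   `elimination` (order of removal, worst first).
#' @export
genorm_m <- function(quantities) {
  q <- as.matrix(quantities)
  stopifnot(ncol(q) >= 2, nrow(q) >= 2)
  if (any(!is.finite(q)) || any(q <= 0)) {
    bad <- which(!is.finite(q) | q <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive/missing quantity at sample %s, assay %s",
                 rownames(q)[bad[1]] %||% bad[1],
                 colnames(q)[bad[2]] %||% bad[2]))
  }
  lq <- log2(q)
  m_values <- function(cols) {
    vapply(cols, function(j) {
      mean(vapply(setdiff(cols, j),
                  function(k) sd(lq[, j] - lq[, k]), numeric(1)))
    }, numeric(1))
  }
  all_cols <- colnames(q) %||% as.character(seq_len(ncol(q)))
  colnames(lq) <- colnames(q) <- all_cols
  M_full <- stats::setNames(m_values(all_cols), all_cols)
  active <- all_cols
  eliminated <- character(0)
  while (length(active) > 2) {
    M <- m_values(active)
    worst <- active[which.max(M)]
    eliminated <- c(eliminated, worst)
    active <- setdiff(active, worst)
  }
  selected <- active
  nf <- exp(rowMeans(log(q[, selected, drop = FALSE])))
  nrq <- q / nf
  CV <- apply(nrq, 2, function(x) sd(x) / mean(x))
  list(M = M_full, CV = CV,
       ranking = c(selected[order(M_full[selected])], rev(eliminated)),
       selected = selected, elimination = eliminated)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble a replicate-structured Cq table
#'
#' @param df data.frame with columns `sample`, `assay`, `replicate`, `cq`
#'   (long format; `cq` NA = no amplification within 40 cycles, treated as
#'   not detected and excluded from means, never imputed).
#' @return The validated data.frame, of class `cq_table`.
#' @export
cq_table <- function(df) {
  need <- c("sample", "assay", "replicate", "cq")
  if (!all(need %in% names(df))) {
    stop("Cq table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$cq <= 0, na.rm = TRUE)) stop("Cq values must be positive")
  class(df) <- c("cq_table", "data.frame")
  df
}

#' Read a Cq table from CSV
#'
#' Long format (`sample, assay, replicate, cq`) or wide format (first column
#' `sample`, remaining columns one per assay, one row per sample-replicate).
#'
#' @param path CSV path.
#' @return A `cq_table`.
#' @export
read_cq_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (all(c("sample", "assay", "replicate", "cq") %in% names(df))) {
    return(cq_table(df))
  }
  if (!("sample" %in% names(df))) stop("Cq CSV needs a 'sample' column")
  assays <- setdiff(names(df), "sample")
  long <- do.call(rbind, lapply(assays, function(a) {
    data.frame(sample = df$sample, assay = a,
               replicate = stats::ave(seq_along(df$sample), df$sample,
                                      FUN = seq_along),
               cq = df[[a]])
  }))
  cq_table(long)
}

## Replicate summary: mean Cq per sample x assay, plus the standard error of
## that mean. Technical (replicate) variance is pooled per assay across
## samples -- with 2-3 replicates a per-cell SD is too noisy to propagate,
## while technical noise is a property of the assay, not the sample. The
## per-cell SE is then sqrt(pooled variance / replicate count).
summarize_cq <- function(tab) {
  mu <- stats::aggregate(cq ~ sample + assay, data = tab, FUN = mean,
                         na.action = stats::na.omit)
  names(mu)[3] <- "cq_mean"
  nn <- stats::aggregate(cq ~ sample + assay, data = tab,
                         FUN = function(x) sum(!is.na(x)))
  names(nn)[3] <- "n_rep"
  vv <- stats::aggregate(cq ~ sample + assay, data = tab,
                         FUN = function(x) {
                           x <- x[!is.na(x)]
                           if (length(x) < 2) NA_real_ else var(x)
                         })
  names(vv)[3] <- "cq_var"
  out <- merge(merge(mu, nn, by = c("sample", "assay")),
               vv, by = c("sample", "assay"))
  pooled <- vapply(split(out, out$assay), function(d) {
    df <- d$n_rep - 1
    ok <- !is.na(d$cq_var) & df > 0
    if (!any(ok)) 0 else sum(d$cq_var[ok] * df[ok]) / sum(df[ok])
  }, numeric(1))
  out$cq_se <- sqrt(pooled[out$assay] / out$n_rep)
  out
}

#' Normalized relative quantities with error propagation
#'
#' Implements the advanced relative-quantification model: replicate Cqs are
#' averaged per sample and assay; each assay's relative quantity is computed
#' with its own amplification efficiency against the calibrator sample;
#' each target is divided by the geometric mean of the reference-gene
#' quantities in the same sample (so sample-wise loading differences
#' cancel); the calibrator sample's NRQ is 1 by construction. Standard
#' errors combine, in quadrature on the log2 scale, the replicate Cq
#' standard errors of the target and of each reference in both the sample
#' and the calibrator, scaled by log2(1 + E) per assay; technical variance
#' is pooled per assay across samples before propagation (a per-cell SD from
#' 2-3 replicates is too unstable to propagate); linear-scale SEs follow by
#' the delta method.
#'
#' @param tab a `cq_table`.
#' @param efficiencies named numeric vector of per-assay E values (fraction;
#'   assays missing from it default to E = 1).
#' @param reference_assays character vector of reference gene assays (>= 1).
#' @param calibrator sample name all NRQs are rescaled to.
#' @return List with matrices `nrq` and `se` (samples x target assays;
#'   NA where a target or reference Cq is missing) plus `log2_se`.
#' @export
nrq <- function(tab, efficiencies, reference_assays, calibrator) {
  stopifnot(inherits(tab, "cq_table"), length(reference_assays) >= 1)
  if (!(calibrator %in% tab$sample)) stop("calibrator sample not in table")
  if (!all(reference_assays %in% tab$assay)) {
    stop("reference assay(s) missing from table: ",
         paste(setdiff(reference_assays, tab$assay), collapse = ", "))
  }
  sm <- summarize_cq(tab)
  samples <- unique(tab$sample)
  assays <- unique(tab$assay)
  targets <- setdiff(assays, reference_assays)
  eff <- function(a) if (a %in% names(efficiencies)) efficiencies[[a]] else 1
  cell <- function(s, a, what) {
    v <- sm[sm$sample == s & sm$assay == a, what]
    if (length(v) == 0) NA_real_ else v
  }
  nref <- length(reference_assays)
  nrq_m <- se_m <- lse_m <- matrix(
    NA_real_, length(samples), length(targets),
    dimnames = list(samples, targets))
  for (s in samples) {
    for (t in targets) {
      ct <- cell(s, t, "cq_mean"); ct0 <- cell(calibrator, t, "cq_mean")
      if (is.na(ct) || is.na(ct0)) next
      rq_t <- relative_quantity(ct, ct0, eff(t))
      rq_refs <- vapply(reference_assays, function(r) {
        cr <- cell(s, r, "cq_mean"); cr0 <- cell(calibrator, r, "cq_mean")
        relative_quantity(cr, cr0, eff(r))
      }, numeric(1))
      if (anyNA(rq_refs)) {
        log_msg("reference missing in sample %s; NRQ(%s,%s) set NA", s, s, t)
        next
      }
      val <- rq_t / exp(mean(log(rq_refs)))
      ct_var <- (log2(1 + eff(t)))^2 *
        (cell(s, t, "cq_se")^2 + cell(calibrator, t, "cq_se")^2)
      ref_var <- sum(vapply(reference_assays, function(r) {
        (log2(1 + eff(r)))^2 *
          (cell(s, r, "cq_se")^2 + cell(calibrator, r, "cq_se")^2)
      }, numeric(1))) / nref^2
      lse <- sqrt(ct_var + ref_var)
      nrq_m[s, t] <- val
      lse_m[s, t] <- lse
      se_m[s, t] <- val * log(2) * lse
    }
  }
  list(nrq = nrq_m, se = se_m, log2_se = lse_m,
       calibrator = calibrator, reference_assays = reference_assays)
}

#' 3':5' RNA-integrity ratio by the comparative Cq method
#'
#' ratio = 2^(Cq5' - Cq3') for two amplicons near a transcript's 5' and 3'
#' ends (assumes E = 1 for both fragments). An intact template amplifies
#' both regions equally (ratio near 1); degradation inflates the 5' Cq.
#' Verdicts: OK below 3.8, INADEQUATE above 4.4, BORDERLINE in between.
#'
#' @param cq_5prime,cq_3prime quantification cycles of the 5' and 3' assays.
#' @return List with `ratio` and `verdict` (NA verdict on missing input).
#' @export
integrity_ratio <- function(cq_5prime, cq_3prime) {
  if (is.na(cq_5prime) || is.na(cq_3prime)) {
    return(list(ratio = NA_real_, verdict = NA_character_))
  }
  ratio <- 2^(cq_5prime - cq_3prime)
  verdict <- if (ratio < 3.8) "OK" else if (ratio > 4.4) "INADEQUATE" else "BORDERLINE"
  list(ratio = ratio, verdict = verdict)
}

#' Log2 expression matrix from NRQs
#'
#' @param nrq_matrix positive matrix (samples x targets).
#' @return log2-transformed matrix.
#' @export
expression_matrix <- function(nrq_matrix) {
  stopifnot(all(nrq_matrix > 0, na.rm = TRUE))
  log2(nrq_matrix)
}

#' Hierarchical clustering of an expression matrix
#'
#' Correlation distance (1 - Pearson) between rows, average linkage.
#'
#' @param mat numeric matrix (rows are the items to cluster).
#' @param method linkage method passed to [hclust()] (default "average").
#' @return An `hclust` object.
#' @export
hier_cluster <- function(mat, method = "average") {
  d <- as.dist(1 - cor(t(mat)))
  hclust(d, method = method)
}

#' Ordination of samples by singular value decomposition
#'
#' Principal components of the column-centered matrix: sample coordinates
#' are U S and variance-explained fractions are s_i^2 / sum(s^2).
#'
#' @param mat numeric matrix, samples x variables (>= 3 samples).
#' @return List with `coordinates` (samples x components) and
#'   `variance_fraction` (non-increasing, sums to 1 over the full rank).
#' @export
svd_ordination <- function(mat) {
  stopifnot(nrow(mat) >= 3)
  x <- scale(mat, center = TRUE, scale = FALSE)
  if (all(abs(x) < 1e-12)) stop("constant matrix: ordination undefined")
  sv <- svd(x)
  frac <- sv$d^2 / sum(sv$d^2)
  coords <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  rownames(coords) <- rownames(mat)
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  list(coordinates = coords, variance_fraction = frac)
}
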