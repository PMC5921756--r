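## Distance-based phylogeny: p-distances with pairwise deletion, Poisson
## correction, hand-rolled deterministic neighbor joining, nonparametric
## bootstrap supports, sister-pair calling, and the exon-count group contrast.

GAP_CHARS <- c("-", ".")

#' Build an alignment matrix from aligned sequences
#'
#' @param seqs named character vector of equal-length aligned sequences
#'   (protein or DNA; `-` and `.` are gap symbols).
#' @return Character matrix (taxa x columns, uppercase) of class `alignment`.
#' @export
as_alignment <- function(seqs) {
  stopifnot(length(seqs) >= 2, !is.null(names(seqs)))
  L <- unique(nchar(seqs))
  if (length(L) != 1) stop("aligned sequences must have equal length")
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(m) <- names(seqs)
  class(m) <- c("alignment", class(m))
  m
}

#' Proportion of differing sites between two aligned sequences
#'
#' Pairwise deletion: columns where either taxon carries a gap are dropped;
#' the distance is the fraction of remaining columns that differ.
#'
#' @param alignment an `alignment` matrix (see [as_alignment()]).
#' @param a,b taxon names or row indices.
#' @return p in [0, 1].
#' @export
p_distance <- function(alignment, a, b) {
  x <- alignment[a, ]; y <- alignment[b, ]
  ok <- !(x %in% GAP_CHARS) & !(y %in% GAP_CHARS)
  if (!any(ok)) stop("no comparable (ungapped) columns for this pair")
  mean(x[ok] != y[ok])
}

#' All pairwise p-distances of an alignment
#'
#' @param alignment an `alignment` matrix.
#' @return Symmetric matrix of proportions with zero diagonal.
#' @export
p_distance_matrix <- function(alignment) {
  n <- nrow(alignment)
  d <- matrix(0, n, n, dimnames = list(rownames(alignment), rownames(alignment)))
  gap <- matrix(alignment %in% GAP_CHARS, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- !gap[i, ] & !gap[j, ]
    if (!any(ok)) stop("no comparable columns for pair ",
                       rownames(alignment)[i], "/", rownames(alignment)[j])
    d[i, j] <- d[j, i] <- mean(alignment[i, ok] != alignment[j, ok])
  }
  d
}

#' Poisson-correct a proportion of differing sites
#'
#' d = -ln(1 - p), the expected number of substitutions per site under a
#' Poisson model of equal-rate substitution. Saturated pairs (p >= 1) map to
#' Inf and must be handled before tree building.
#'
#' @param p proportion(s) in [0, 1].
#' @return Corrected distance(s), substitutions per site (`Inf` if p >= 1).
#' @export
poisson_correct <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  out <- -log(1 - p)
  if (any(p >= 1)) {
    warning("saturated pair(s) (p >= 1): distance set to Inf")
    out[p >= 1] <- Inf
  }
  out
}

fmt_bl <- function(x) sprintf("%.10g", x)

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: at each step the pair minimizing
#' Q(i,j) = (r-2) d(i,j) - R(i) - R(j) is joined, with the usual
#' branch-length formulas. Ties in the Q minimum are broken by the lowest
#' (row, column) index pair in the current matrix ordering, making runs
#' deterministic. Negative branch lengths are clamped to zero with the
#' deficit moved to the sibling edge so path lengths are preserved. On an
#' additive matrix the generating topology is recovered exactly.
#'
#' @param d symmetric numeric matrix with taxon dimnames, zero diagonal,
#'   finite entries.
#' @return An unrooted `phylo` tree (ape) with branch lengths.
#' @export
nj_tree <- function(d) {
  stopifnot(is.matrix(d), nrow(d) >= 3, isTRUE(all.equal(d, t(d))),
            all(diag(d) == 0))
  if (any(!is.finite(d))) {
    stop("distance matrix has non-finite entries; handle saturation first ",
         "(e.g. drop or re-estimate saturated pairs)")
  }
  labs <- rownames(d)
  if (is.null(labs)) labs <- paste0("t", seq_len(nrow(d)))
  nwk <- labs  # growing newick fragment per active node
  D <- unname(d)
  while (nrow(D) > 3) {
    r <- nrow(D)
    R <- rowSums(D)
    Q <- (r - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    Q[lower.tri(Q)] <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE][1, ]  # lowest-pair tie-break
    i <- idx[1]; j <- idx[2]
    vi <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (r - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    newdist <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    merged <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt_bl(vi), nwk[j], fmt_bl(vj))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], newdist[keep]),
               c(newdist[keep], 0))
    nwk <- c(nwk[keep], merged)
  }
  # resolve the final three nodes around the central vertex (three-point formulas)
  va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  v <- pmax(c(va, vb, vc), 0)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 nwk[1], fmt_bl(v[1]), nwk[2], fmt_bl(v[2]), nwk[3], fmt_bl(v[3]))
  ape::read.tree(text = txt)
}

#' Full distance pipeline: alignment to NJ tree
#'
#' p-distance (pairwise deletion), Poisson correction, neighbor joining.
#'
#' @param alignment an `alignment` matrix.
#' @return An unrooted `phylo`.
#' @export
distance_tree <- function(alignment) {
  nj_tree(suppressWarnings(poisson_correct(p_distance_matrix(alignment))))
}

#' Bootstrap supports for the NJ tree of an alignment
#'
#' Columns are resampled with replacement; the whole pipeline (p-distance,
#' Poisson correction, NJ) is re-run per replicate; the support of each
#' internal edge of the full-data tree is the percentage of usable replicates
#' whose tree contains the same bipartition. Replicates in which some pair
#' has no comparable columns or is saturated are skipped and counted.
#'
#' @param alignment an `alignment` matrix.
#' @param replicates number of bootstrap replicates (default 1000).
#' @param seed integer seed (mandatory for reproducibility).
#' @return The full-data `phylo` with `node.label` set to support percentages
#'   (root label NA), plus attributes `replicates_used` and `replicates_skipped`.
#' @export
bootstrap_supports <- function(alignment, replicates = 1000, seed) {
  stopifnot(replicates >= 1, !missing(seed))
  tree <- distance_tree(alignment)
  L <- ncol(alignment)
  boots <- vector("list", replicates)
  skipped <- 0L
  with_substream(seed, "bootstrap", {
    for (b in seq_len(replicates)) {
      cols <- sample.int(L, L, replace = TRUE)
      tb <- tryCatch(distance_tree(alignment[, cols, drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(tb)) skipped <- skipped + 1L else boots[[b]] <- tb
    }
  })
  boots <- boots[!vapply(boots, is.null, logical(1))]
  used <- length(boots)
  if (used == 0) stop("every bootstrap replicate failed")
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  supp <- round(100 * counts / used, 1)
  tree$node.label <- as.character(supp)
  attr(tree, "replicates_used") <- used
  attr(tree, "replicates_skipped") <- skipped
  tree
}

#' Sister pairs of a supported tree
#'
#' Cherries (two-leaf clades) whose subtending internal node has bootstrap
#' support strictly above the threshold.
#'
#' @param tree a `phylo` with numeric `node.label` supports (0-100).
#' @param threshold support percentage; strictly-greater rule (default 65).
#' @return data.frame with columns `taxon_a`, `taxon_b`, `support` (possibly
#'   zero rows).
#' @export
sister_pairs <- function(tree, threshold = 65) {
  if (is.null(tree$node.label)) stop("tree has no support values")
  n <- length(tree$tip.label)
  supp <- suppressWarnings(as.numeric(tree$node.label))
  out <- data.frame(taxon_a = character(0), taxon_b = character(0),
                    support = numeric(0))
  for (node in (n + 1):(n + tree$Nnode)) {
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    if (length(kids) == 2 && all(kids <= n)) {
      s <- supp[node - n]
      if (!is.na(s) && s > threshold) {
        tips <- sort(tree$tip.label[kids])
        out <- rbind(out, data.frame(taxon_a = tips[1], taxon_b = tips[2],
                                     support = s))
      }
    }
  }
  out
}

#' Contrast exon counts between two phylogenetic groups
#'
#' Two-sided Welch t-test on per-gene exon counts between groups I and II.
#' Group membership is supplied (it comes from the tree, not derived here).
#'
#' @param records a `gene_table`.
#' @param membership named character vector mapping gene names to `"I"` or
#'   `"II"`; genes absent from it are ignored.
#' @return List with `means` (named, groups I and II), `t`, `p_value`, `df`
#'   (test entries NA when either group has fewer than 2 members).
#' @export
exon_group_contrast <- function(records, membership) {
  stopifnot(all(membership %in% c("I", "II")))
  keep <- records$name %in% names(membership)
  grp <- membership[records$name[keep]]
  ex <- records$exon_count[keep]
  if (!all(c("I", "II") %in% grp)) stop("both groups must be nonempty")
  mI <- mean(ex[grp == "I"]); mII <- mean(ex[grp == "II"])
  if (sum(grp == "I") < 2 || sum(grp == "II") < 2) {
    return(list(means = c(I = mI, II = mII), t = NA_real_,
                p_value = NA_real_, df = NA_real_))
  }
  tt <- t.test(ex[grp == "I"], ex[grp == "II"], var.equal = FALSE)
  list(means = c(I = mI, II = mII), t = unname(tt$statistic),
       p_value = tt$p.value, df = unname(tt$parameter))
}
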