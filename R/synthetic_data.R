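## Seeded synthetic-data generators. Each generator draws from its own named
## substream of the user seed, so adding one generator to a script never
## shifts another's output, and identical seeds reproduce identical data.
## Outputs satisfy the consuming module's preconditions without modification.

#' Generate a synthetic promoter set
#'
#' i.i.d. background bases at a stated G+C composition, with optional motif
#' planting: each planted copy is a concrete realization of the (possibly
#' degenerate) pattern written at a uniformly drawn position inside a
#' TSS-relative window, never overlapping another planted copy.
#'
#' @param n number of promoters (default 23).
#' @param length promoter length in bp (default 1500; covers -length ... -1).
#' @param gc G+C fraction (default 0.28).
#' @param plant optional named list: for each motif pattern (name = pattern),
#'   a list with `copies` (per promoter) and `window` (TSS-relative
#'   `c(lower, upper)` for match starts, e.g. `c(-600, -400)`).
#' @param seed integer seed (mandatory).
#' @return Named character vector of promoter sequences (`prom01`, ...).
#' @export
gen_promoters <- function(n = 23, length = 1500, gc = 0.28, plant = NULL,
                          seed) {
  stopifnot(!missing(seed), n >= 1, length >= 1)
  bg <- background_model(gc)
  with_substream(seed, "gen_promoters", {
    mat <- matrix(sample(BASES, n * length, replace = TRUE, prob = bg$probs),
                  n, length)
    if (!is.null(plant)) {
      for (pat in names(plant)) {
        spec <- plant[[pat]]
        m <- nchar(pat)
        sets <- expand_iupac(pat)
        win <- spec$window %||% c(-length, -1)
        lo <- win[1] + length + 1          # sequence index of earliest start
        hi <- min(win[2] + length + 1, length - m + 1)
        if (hi < lo) stop("planting window does not fit the promoter")
        for (i in seq_len(n)) {
          taken <- integer(0)
          for (cp in seq_len(spec$copies)) {
            ok <- FALSE
            for (try in 1:200) {
              s <- sample(lo:hi, 1)
              if (!any(abs(s - taken) < m)) { ok <- TRUE; break }
            }
            if (!ok) stop("infeasible planting: too many copies for window")
            taken <- c(taken, s)
            inst <- vapply(sets, function(b) if (length(b) == 1) b
                           else sample(b, 1), character(1))
            mat[i, s:(s + m - 1)] <- inst
          }
        }
      }
    }
    seqs <- apply(mat, 1, paste, collapse = "")
    names(seqs) <- sprintf("prom%02d", seq_len(n))
    seqs
  })
}

## Sample a sequence fragment from a named residue-frequency profile
## (residues absent from the profile get probability 0).
sample_profile <- function(len, profile) {
  paste(sample(names(profile), len, replace = TRUE, prob = profile),
        collapse = "")
}

#' Generate a synthetic protein family with prescribed architectures
#'
#' Builds proteins with the canonical layout (B3 then AUX_RESP subdomains, a
#' middle region, and optionally CTD subdomains III/IV) according to an
#' architecture schedule, with middle regions drawn from activator-like
#' (Q/S/L-rich) or repressor-like (S/P/G/L-rich, or G-rich for DBD-only
#' proteins) composition profiles. Running the architecture and
#' regulatory-role classifiers on the output recovers the schedule exactly.
#'
#' @param schedule named counts per class, e.g.
#'   `c(FULL = 15, TRUNCATED_III_ONLY = 3, DBD_ONLY = 6)`.
#' @param n_activators how many of the CTD-bearing proteins (FULL first)
#'   receive the activator MR profile (default 7).
#' @param profiles optional list overriding the `activator`, `repressor`, and
#'   `g_rich` MR frequency profiles (named numeric vectors over residues).
#' @param seed integer seed (mandatory).
#' @return List with `seqs` (named protein sequences), `annotations` (domain
#'   spans per protein), `expected_roles`, `expected_architecture`.
#' @export
gen_protein_family <- function(schedule = c(FULL = 15, TRUNCATED_III_ONLY = 3,
                                            DBD_ONLY = 6),
                               n_activators = 7, profiles = NULL, seed) {
  stopifnot(!missing(seed), all(schedule >= 0))
  defaults <- list(
    activator = c(Q = 0.30, S = 0.18, L = 0.15,
                  stats::setNames(rep(0.37 / 17, 17),
                                  setdiff(AA20, c("Q", "S", "L")))),
    repressor = c(S = 0.20, P = 0.16, G = 0.13, L = 0.16, Q = 0.01,
                  stats::setNames(rep(0.34 / 15, 15),
                                  setdiff(AA20, c("S", "P", "G", "L", "Q")))),
    g_rich = c(G = 0.35, Q = 0.01,
               stats::setNames(rep(0.64 / 18, 18), setdiff(AA20, c("G", "Q"))))
  )
  profiles <- modifyList(defaults, profiles %||% list())
  for (p in profiles) {
    if (!all(c("Q", "S", "G", "L", "P") %in% names(p))) {
      stop("profile must assign a frequency to Q, S, G, L and P")
    }
  }
  classes <- rep(names(schedule), schedule)
  n_ctd <- sum(schedule[c("FULL", "TRUNCATED_III_ONLY")], na.rm = TRUE)
  stopifnot(n_activators <= n_ctd)
  with_substream(seed, "gen_protein_family", {
    seqs <- character(0); anns <- list()
    roles <- archs <- character(0)
    ctd_seen <- 0
    for (i in seq_along(classes)) {
      cls <- classes[i]
      id <- sprintf("prot%02d", i)
      L <- switch(cls, FULL = 850 + sample(-40:40, 1),
                  TRUNCATED_III_ONLY = 700 + sample(-20:20, 1),
                  DBD_ONLY = 560 + sample(-30:30, 1))
      b3 <- c(115, 219); ar <- c(229, 313)
      ann <- list(B3 = b3, AUX_RESP = ar)
      if (cls != "DBD_ONLY") ann$III <- c(L - 84, L - 59)
      if (cls == "FULL") ann$IV <- c(L - 45, L - 8)
      if (cls == "DBD_ONLY") {
        role <- "REPRESSOR_NO_CTD"; prof <- profiles$g_rich
      } else {
        ctd_seen <- ctd_seen + 1
        if (ctd_seen <= n_activators) {
          role <- "ACTIVATOR_QSL"; prof <- profiles$activator
        } else {
          role <- "REPRESSOR_SPGL"; prof <- profiles$repressor
        }
      }
      mr_from <- ar[2] + 1
      mr_to <- if (is.null(ann$III)) L else ann$III[1] - 1
      unif <- stats::setNames(rep(1 / 20, 20), AA20)
      seq <- paste0(sample_profile(mr_from - 1, unif),
                    sample_profile(mr_to - mr_from + 1, prof),
                    sample_profile(L - mr_to, unif))
      stopifnot(nchar(seq) == L)
      seqs[id] <- seq; anns[[id]] <- ann
      roles <- c(roles, role); archs <- c(archs, cls)
    }
    names(roles) <- names(archs) <- names(seqs)
    list(seqs = seqs, annotations = anns, expected_roles = roles,
         expected_architecture = archs)
  })
}

#' Evolve a protein alignment along a tree under a Poisson model
#'
#' The root sequence is uniform over the 20 amino acids; along each branch of
#' length b (substitutions per site) every site independently substitutes to
#' a uniformly chosen different residue with probability 1 - exp(-b * 20/19),
#' which makes the expected Poisson-corrected pairwise distance converge to
#' the tree path length as the number of columns grows. The uniform-exchange
#' model matches the Poisson correction used on the analysis side.
#'
#' @param tree an ape `phylo` with branch lengths (binary; an unrooted basal
#'   trichotomy is accepted).
#' @param length number of alignment columns.
#' @param seed integer seed (mandatory).
#' @return An `alignment` matrix over the tree's tips.
#' @export
gen_alignment_on_tree <- function(tree, length, seed) {
  stopifnot(!missing(seed), inherits(tree, "phylo"),
            !is.null(tree$edge.length), all(tree$edge.length >= 0))
  if (!ape::is.binary(tree)) stop("tree must be binary")
  ntip <- length(tree$tip.label)
  root <- ntip + 1
  with_substream(seed, "gen_alignment_on_tree", {
    seqmat <- matrix(NA_integer_, ntip + tree$Nnode, length)
    seqmat[root, ] <- sample.int(20L, length, replace = TRUE)
    edges <- tree$edge[order(tree$edge[, 1]), , drop = FALSE]
    # preorder traversal: parents always precede children in cladewise order
    ord <- ape::reorder.phylo(tree, "cladewise")$edge
    for (e in seq_len(nrow(ord))) {
      par <- ord[e, 1]; child <- ord[e, 2]
      b <- tree$edge.length[which(tree$edge[, 1] == par &
                                  tree$edge[, 2] == child)]
      p_sub <- 1 - exp(-b * 20 / 19)
      s <- seqmat[par, ]
      hit <- runif(length) < p_sub
      if (any(hit)) {
        # uniform among the 19 other residues
        shift <- sample.int(19L, sum(hit), replace = TRUE)
        s[hit] <- ((s[hit] - 1 + shift) %% 20L) + 1L
      }
      seqmat[child, ] <- s
    }
    tips <- seqmat[seq_len(ntip), , drop = FALSE]
    m <- matrix(AA20[tips], ntip, length)
    rownames(m) <- tree$tip.label
    class(m) <- c("alignment", class(m))
    m
  })
}

#' Generate a Cq table from known expression ratios
#'
#' Inverts the quantification model: each sample gets a lognormal loading
#' shared by all assays (which the reference normalization must cancel),
#' targets additionally carry their true NRQ, and Cq values follow
#' Cq = Cq0(assay) - log_(1+E)(quantity) plus Gaussian replicate noise.
#' Cqs drifting above 40 cycles are marked not detected (NA).
#'
#' @param true_nrq numeric matrix (samples x targets) of true normalized
#'   relative quantities; the calibrator row should be 1.
#' @param reference_assays names of the reference assays to synthesize.
#' @param efficiencies named per-assay E (defaults to 1 for missing assays).
#' @param replicate_sd Gaussian Cq noise per technical replicate (cycles).
#' @param replicates technical replicates per sample-assay (default 3).
#' @param loading_sd sd of the per-sample log2 loading (default 0.5).
#' @param seed integer seed (mandatory).
#' @return A `cq_table`.
#' @export
gen_cq_table <- function(true_nrq, reference_assays = c("PP2A", "TFIIA"),
                         efficiencies = NULL, replicate_sd = 0.1,
                         replicates = 3, loading_sd = 0.5, seed) {
  stopifnot(!missing(seed), all(true_nrq > 0), replicate_sd >= 0,
            replicates >= 1)
  samples <- rownames(true_nrq) %||% paste0("S", seq_len(nrow(true_nrq)))
  targets <- colnames(true_nrq) %||% paste0("T", seq_len(ncol(true_nrq)))
  eff <- function(a) {
    if (!is.null(efficiencies) && a %in% names(efficiencies))
      efficiencies[[a]] else 1
  }
  cq0 <- c(stats::setNames(rep(20, length(reference_assays)), reference_assays),
           stats::setNames(rep(24, length(targets)), targets))
  with_substream(seed, "gen_cq_table", {
    loading <- 2^rnorm(length(samples), 0, loading_sd)
    names(loading) <- samples
    rows <- list()
    for (s in samples) for (a in c(reference_assays, targets)) {
      q <- if (a %in% reference_assays) loading[s]
           else true_nrq[s, a] * loading[s]
      mu <- cq0[a] - log(q) / log(1 + eff(a))
      cqs <- mu + rnorm(replicates, 0, replicate_sd)
      cqs[cqs > 40] <- NA
      rows[[length(rows) + 1]] <- data.frame(
        sample = s, assay = a, replicate = seq_len(replicates), cq = cqs)
    }
    cq_table(do.call(rbind, rows))
  })
}

#' Generate duplicate pairs with a known selection-mode mixture
#'
#' Ks is drawn uniformly over `ks_range`; the Ka/Ks ratio is drawn around
#' `mean_ratio` (purifying regime) except for a `prop_positive` fraction of
#' pairs drawn around `positive_ratio` (> 1).
#'
#' @param n number of pairs.
#' @param mean_ratio mean Ka/Ks of the purifying component (default 0.19).
#' @param ratio_sd sd of the ratio draw (default 0.04, truncated at 0.001).
#' @param prop_positive fraction of positively selected pairs (default 0).
#' @param positive_ratio mean ratio of the positive component (default 1.5).
#' @param ks_range range of Ks (default `c(0.59, 1.64)`).
#' @param seed integer seed (mandatory).
#' @return data.frame with `gene_a`, `gene_b`, `ka`, `ks`, `true_mode`.
#' @export
gen_kaks_pairs <- function(n, mean_ratio = 0.19, ratio_sd = 0.04,
                           prop_positive = 0, positive_ratio = 1.5,
                           ks_range = c(0.59, 1.64), seed) {
  stopifnot(!missing(seed), n >= 1, all(ks_range > 0))
  with_substream(seed, "gen_kaks_pairs", {
    pos <- runif(n) < prop_positive
    ratio <- ifelse(pos,
                    pmax(rnorm(n, positive_ratio, ratio_sd), 1.06),
                    pmax(rnorm(n, mean_ratio, ratio_sd), 0.001))
    ks <- runif(n, ks_range[1], ks_range[2])
    data.frame(gene_a = sprintf("geneA%03d", seq_len(n)),
               gene_b = sprintf("geneB%03d", seq_len(n)),
               ka = ratio * ks, ks = ks,
               true_mode = ifelse(pos, "positive", "purifying_or_drift"))
  })
}
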