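test_that("p-distance with pairwise deletion", {
  aln <- as_alignment(c(a = "AAAA", b = "AAAT", c = "AAAA", d = "AA-A"))
  expect_equal(p_distance(aln, "a", "c"), 0)
  expect_equal(p_distance(aln, "a", "b"), 0.25)
  # difference hidden behind a gap does not count
  aln2 <- as_alignment(c(x = "ACGT", y = "AC-A"))
  expect_equal(p_distance(aln2, "x", "y"), 1 / 3)
  aln3 <- as_alignment(c(x = "----AC", y = "GG----"))
  expect_error(p_distance(aln3, "x", "y"), "comparable")
  D <- p_distance_matrix(aln)
  expect_equal(D["a", "b"], 0.25)
  expect_true(isSymmetric(D))
})

test_that("Poisson correction: closed form, monotone, saturation", {
  expect_equal(poisson_correct(0), 0)
  expect_equal(poisson_correct(0.5), 0.6931, tolerance = 1e-4)
  expect_equal(poisson_correct(0.1), 0.10536, tolerance = 1e-5)
  p <- seq(0, 0.95, by = 0.05)
  d <- poisson_correct(p)
  expect_true(all(diff(d) > 0))
  expect_true(all(d >= p))
  expect_warning(ds <- poisson_correct(1), "saturated")
  expect_equal(ds, Inf)
})

test_that("NJ solves the 3-taxon three-point equations", {
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(d)
  bl <- stats::setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("a", "b", "c")], c(a = 1, b = 2, c = 3))
})

test_that("NJ picks the least-squares quartet topology on additive data", {
  # brute-force oracle: fit all three quartet topologies by ordinary least
  # squares on the 6 pairwise distances and keep the best
  quartet_ls <- function(d) {
    taxa <- rownames(d)
    splits <- list(c(1, 2), c(1, 3), c(1, 4))  # partner of taxon 1
    resid <- vapply(splits, function(sp) {
      pair1 <- sp; pair2 <- setdiff(1:4, sp)
      # design: edges e1..e4 (pendant) + internal e5
      rows <- t(combn(4, 2))
      X <- t(apply(rows, 1, function(ij) {
        v <- numeric(5); v[ij] <- 1
        same <- (all(ij %in% pair1)) || (all(ij %in% pair2))
        v[5] <- if (same) 0 else 1
        v
      }))
      y <- apply(rows, 1, function(ij) d[ij[1], ij[2]])
      sum(stats::lm.fit(X, y)$residuals^2)
    }, numeric(1))
    sisters <- splits[[which.min(resid)]]
    sort(taxa[sisters])
  }
  set.seed(17)
  for (i in 1:25) {
    ra <- random_additive(4)
    est <- nj_tree(ra$d)
    best <- quartet_ls(ra$d)
    other <- setdiff(rownames(ra$d), best)
    oracle_tree <- ape::read.tree(text = sprintf("((%s,%s),(%s,%s));",
                                                 best[1], best[2],
                                                 other[1], other[2]))
    expect_equal(ape::dist.topo(est, ape::unroot(oracle_tree)), 0,
                 ignore_attr = TRUE)
  }
})

test_that("NJ recovers ultrametric and additive topologies, any taxon order", {
  set.seed(23)
  for (i in 1:20) {
    ra <- random_additive(sample(5:8, 1))
    est <- nj_tree(ra$d)
    expect_equal(ape::dist.topo(ape::unroot(ra$tree), est), 0,
                 ignore_attr = TRUE)
    expect_true(all(est$edge.length >= 0))
    # invariance under taxon permutation of the matrix
    perm <- sample(nrow(ra$d))
    est2 <- nj_tree(ra$d[perm, perm])
    expect_equal(ape::dist.topo(est, est2), 0, ignore_attr = TRUE)
  }
  # ultrametric case: coalescent tree heights are ultrametric
  tr <- ape::rcoal(5)
  D <- ape::cophenetic.phylo(tr)
  est <- nj_tree(D)
  expect_equal(ape::dist.topo(ape::unroot(tr), est), 0, ignore_attr = TRUE)
  expect_true(all(est$edge.length >= -1e-12))
})

test_that("NJ refuses non-finite distances", {
  d <- matrix(c(0, Inf, 1, Inf, 0, 1, 1, 1, 0), 3)
  dimnames(d) <- list(letters[1:3], letters[1:3])
  expect_error(nj_tree(d), "saturation")
})

test_that("bootstrap supports: signal, no-signal, determinism", {
  tr <- ape::read.tree(text = "((a:0.05,b:0.05):0.4,(c:0.05,d:0.05):0.4);")
  aln <- gen_alignment_on_tree(ape::unroot(tr), 800, seed = 31)
  bs <- bootstrap_supports(aln, replicates = 100, seed = 7)
  supp <- suppressWarnings(as.numeric(bs$node.label))
  expect_gte(max(supp, na.rm = TRUE), 95)  # long internal edge: strong support
  bs2 <- bootstrap_supports(aln, replicates = 100, seed = 7)
  expect_identical(bs$node.label, bs2$node.label)

  # star-like data: internal supports well below 100
  star <- ape::read.tree(text =
    "((a:0.5,b:0.5):0.0001,(c:0.5,d:0.5):0.0001,(e:0.5,f:0.5):0.0001);")
  aln_s <- gen_alignment_on_tree(star, 300, seed = 32)
  bs_s <- bootstrap_supports(aln_s, replicates = 100, seed = 8)
  supp_s <- suppressWarnings(as.numeric(bs_s$node.label))
  # cherries on long branches stay supported; the star-adjacent edges do not
  expect_lt(min(supp_s, na.rm = TRUE), 90)
})

test_that("sister pairs use a strict support threshold", {
  tr <- ape::read.tree(text = "((a:1,b:1)90:1,(c:1,d:1)65:1,(e:1,f:1)10:1);")
  # node labels already carry supports (root label empty)
  sp <- sister_pairs(tr, threshold = 65)
  expect_equal(nrow(sp), 1)
  expect_equal(c(sp$taxon_a, sp$taxon_b), c("a", "b"))
  # caterpillar with no strong cherry
  cat_tr <- ape::read.tree(text = "(((a:1,b:1)10:1,c:1)20:1,(d:1,e:1)30:1);")
  expect_equal(nrow(sister_pairs(cat_tr, 65)), 0)
})

test_that("exon group contrast: Welch test and degenerate groups", {
  tab <- toy_gene_table()[c(1, 1, 1, 1, 1, 1), ]
  tab$name <- paste0("g", 1:6)
  tab$exon_count <- c(2, 3, 4, 14, 15, 16)
  memb <- stats::setNames(c("II", "II", "II", "I", "I", "I"), tab$name)
  res <- exon_group_contrast(tab, memb)
  expect_equal(unname(res$means), c(15, 3))
  expect_lt(res$p_value, 0.01)
  # identical groups: t = 0, p = 1
  tab$exon_count <- c(2, 3, 4, 2, 3, 4)
  res0 <- exon_group_contrast(tab, memb)
  expect_equal(res0$t, 0)
  expect_equal(res0$p_value, 1)
  # singleton group: means only
  memb1 <- stats::setNames(c("I", rep("II", 5)), tab$name)
  res1 <- exon_group_contrast(tab, memb1)
  expect_true(is.na(res1$p_value))
  expect_equal(unname(res1$means["I"]), 2)
})
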