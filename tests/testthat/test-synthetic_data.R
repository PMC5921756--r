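test_that("promoter generator: reproducibility, composition, planting", {
  a <- gen_promoters(5, 300, 0.28, seed = 101)
  b <- gen_promoters(5, 300, 0.28, seed = 101)
  expect_identical(a, b)
  expect_false(identical(a, gen_promoters(5, 300, 0.28, seed = 102)))

  # realized GC within 3 binomial SDs of the target
  big <- gen_promoters(23, 1500, 0.28, seed = 103)
  nt <- table(strsplit(paste(big, collapse = ""), "")[[1]])
  gc <- sum(nt[c("G", "C")]) / sum(nt)
  n <- 23 * 1500
  expect_lt(abs(gc - 0.28), 3 * sqrt(0.28 * 0.72 / n))

  # planted copies recovered in the window
  pl <- gen_promoters(10, 800, 0.28,
                      plant = list(TGTCTC = list(copies = 2,
                                                 window = c(-600, -400))),
                      seed = 104)
  hits <- vapply(pl, function(s) length(scan_promoter(s, "TGTCTC")),
                 integer(1))
  expect_true(all(hits >= 2))
  expect_error(gen_promoters(2, 100, 0.28,
                             plant = list(CAACA = list(copies = 40,
                                                       window = c(-60, -40))),
                             seed = 1),
               "planting")
})

test_that("null promoter sets cross-validate the Bernoulli expectation", {
  bg <- background_model(0.28)
  totals <- vapply(1:60, function(i) {
    proms <- gen_promoters(6, 400, 0.28, seed = 200 + i)
    sum(vapply(proms, function(s) length(scan_promoter(s, "CAACA")),
               integer(1)))
  }, numeric(1))
  expected <- expected_occurrences("CAACA", bg, rep(400, 6))
  se <- sd(totals) / sqrt(length(totals))
  expect_lt(abs(mean(totals) - expected), 3 * se)
})

test_that("protein family generator recovers its own schedule", {
  fam <- gen_protein_family(seed = 301)
  expect_identical(fam$seqs, gen_protein_family(seed = 301)$seqs)
  calls <- classify_family(fam$seqs, fam$annotations)
  expect_equal(stats::setNames(calls$architecture, calls$protein_id),
               fam$expected_architecture)
  expect_equal(stats::setNames(calls$role, calls$protein_id),
               fam$expected_roles)
  tallies <- table(calls$role)
  expect_equal(unname(tallies["ACTIVATOR_QSL"]), 7L)
  expect_equal(sum(tallies[c("REPRESSOR_SPGL", "REPRESSOR_NO_CTD")]), 17L)
  # all-activator degenerate schedule
  allact <- gen_protein_family(schedule = c(FULL = 4), n_activators = 4,
                               seed = 302)
  ca <- classify_family(allact$seqs, allact$annotations,
                        background = stats::setNames(rep(0.05, 20),
                                                     arfkit:::AA20))
  expect_true(all(ca$role == "ACTIVATOR_QSL"))
})

test_that("alignment evolution: degenerate branches and distance consistency", {
  tr0 <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  aln0 <- gen_alignment_on_tree(ape::unroot(tr0), 100, seed = 401)
  expect_equal(max(p_distance_matrix(aln0)), 0)

  tr <- ape::read.tree(text = "((a:0.2,b:0.3):0.15,(c:0.25,d:0.1):0.15);")
  utr <- ape::unroot(tr)
  aln <- gen_alignment_on_tree(utr, 10000, seed = 402)
  D <- poisson_correct(p_distance_matrix(aln))
  path <- ape::cophenetic.phylo(utr)[rownames(D), colnames(D)]
  off <- row(D) != col(D)
  expect_lt(max(abs(D[off] - path[off]) / path[off]), 0.10)
  expect_identical(aln, gen_alignment_on_tree(utr, 10000, seed = 402))
  # polytomies beyond the unrooted basal trichotomy are rejected
  poly <- ape::read.tree(text = "((a:1,b:1,c:1):1,(d:1,e:1):1);")
  expect_error(gen_alignment_on_tree(poly, 10, seed = 1), "binary")
})

test_that("Cq generator inverts the quantification model", {
  true <- matrix(c(1, 2, 0.5, 1, 4, 1.5), 3, 2,
                 dimnames = list(c("Ctrl", "S1", "S2"), c("g1", "g2")))
  tab0 <- gen_cq_table(true, replicate_sd = 0, seed = 501)
  res0 <- nrq(tab0, NULL, c("PP2A", "TFIIA"), "Ctrl")
  expect_equal(res0$nrq, true, tolerance = 1e-10)
  expect_identical(gen_cq_table(true, replicate_sd = 0.1, seed = 502),
                   gen_cq_table(true, replicate_sd = 0.1, seed = 502))
  # assay-specific efficiencies still invert exactly without noise
  eff <- c(g1 = 0.9, g2 = 0.8, PP2A = 1, TFIIA = 0.95)
  tabE <- gen_cq_table(true, efficiencies = eff, replicate_sd = 0, seed = 503)
  resE <- nrq(tabE, eff, c("PP2A", "TFIIA"), "Ctrl")
  expect_equal(resE$nrq, true, tolerance = 1e-10)
})

test_that("Ka/Ks generator: construction-level summaries", {
  pairs <- gen_kaks_pairs(1000, mean_ratio = 0.19, ratio_sd = 0.03,
                          seed = 601)
  s <- duplication_summary(pairs)
  expect_lt(abs(s$mean_ratio - 0.19), 0.01)
  expect_true(all(s$time_mya >= 48 & s$time_mya <= 135))
  # mode mixture respected
  mixed <- gen_kaks_pairs(2000, prop_positive = 0.10, seed = 602)
  sm <- duplication_summary(mixed)
  frac_pos <- sm$modes[["positive"]] / sum(sm$modes)
  expect_lt(abs(frac_pos - 0.10), 0.03)
  expect_equal(mixed$true_mode[mixed$ka / mixed$ks > 1.06],
               rep("positive", sum(mixed$ka / mixed$ks > 1.06)))
})
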