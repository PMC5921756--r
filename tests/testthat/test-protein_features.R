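test_that("molecular weight matches residue-mass arithmetic and is additive", {
  expect_equal(molecular_weight("G"), 0.07507, tolerance = 1e-4)
  expect_equal(molecular_weight("GG"), 0.13212, tolerance = 1e-4)
  expect_error(molecular_weight(""), "empty")
  expect_error(molecular_weight("GXZ"), "position 2")
  set.seed(3)
  for (i in 1:10) {
    a <- random_protein(30); b <- random_protein(50)
    expect_equal(molecular_weight(paste0(a, b)),
                 molecular_weight(a) + molecular_weight(b) - 18.01524 / 1000,
                 tolerance = 1e-10)
  }
})

test_that("isoelectric point: ordering, terminal bounds, grid oracle", {
  polyA <- strrep("A", 10)
  pa <- isoelectric_point(polyA)
  # only the termini ionize: pI strictly between the two terminal pKa values
  expect_gt(pa, 3.55)
  expect_lt(pa, 7.59)
  expect_lt(isoelectric_point("DDDD"), isoelectric_point("KKKK"))

  # independent oracle: exhaustive 0.001-grid scan of the charge function
  grid_pi <- function(seq) {
    ch <- strsplit(seq, "")[[1]]
    counts <- stats::setNames(integer(20), arfkit:::AA20)
    tb <- table(ch); counts[names(tb)] <- as.integer(tb)
    grid <- seq(0, 14, by = 0.001)
    qs <- vapply(grid, function(p) {
      arfkit:::protein_charge(counts, ch[1], ch[length(ch)], p)
    }, numeric(1))
    grid[which.min(abs(qs))]
  }
  set.seed(8)
  for (i in 1:5) {
    s <- random_protein(200)
    expect_equal(isoelectric_point(s), grid_pi(s), tolerance = 0.002)
  }
})

test_that("net charge is strictly decreasing in pH", {
  set.seed(9)
  s <- random_protein(120)
  ch <- strsplit(s, "")[[1]]
  counts <- stats::setNames(integer(20), arfkit:::AA20)
  tb <- table(ch); counts[names(tb)] <- as.integer(tb)
  q <- vapply(seq(0, 14, 0.25), function(p) {
    arfkit:::protein_charge(counts, ch[1], ch[length(ch)], p)
  }, numeric(1))
  expect_true(all(diff(q) < 0))
})

test_that("architecture classification partitions and rejects IV-only", {
  full <- list(B3 = c(10, 100), AUX_RESP = c(120, 200),
               III = c(300, 330), IV = c(350, 380))
  expect_equal(classify_architecture(full), "FULL")
  expect_equal(classify_architecture(full[c("B3", "AUX_RESP", "III")]),
               "TRUNCATED_III_ONLY")
  expect_equal(classify_architecture(full[c("B3", "AUX_RESP")]), "DBD_ONLY")
  expect_error(classify_architecture(full[c("B3", "AUX_RESP", "IV")]),
               "IV present without III")
  expect_error(classify_architecture(list(B3 = c(1, 50))), "AUX_RESP")
  overlapping <- list(B3 = c(10, 130), AUX_RESP = c(120, 200))
  expect_error(classify_architecture(overlapping), "non-overlapping")
})

test_that("middle-region extraction follows the domain intervals", {
  seq250 <- random_protein(250)
  ann <- list(B3 = c(1, 50), AUX_RESP = c(60, 100), III = c(201, 250))
  expect_equal(extract_mr(seq250, ann), substr(seq250, 101, 200))
  seq300 <- random_protein(300)
  expect_equal(extract_mr(seq300, list(B3 = c(1, 50), AUX_RESP = c(60, 150))),
               substr(seq300, 151, 300))
  expect_error(
    extract_mr(seq250, list(B3 = c(1, 50), AUX_RESP = c(60, 100),
                            III = c(101, 140))), "empty middle region")
})

test_that("regulatory-role classification by MR composition", {
  bg <- stats::setNames(rep(1 / 20, 20), arfkit:::AA20)
  allQ <- classify_regulatory_role(strrep("Q", 100), "FULL", bg)
  expect_equal(allQ$role, "ACTIVATOR_QSL")
  expect_equal(sum(allQ$frequencies), 1)
  allG <- classify_regulatory_role(strrep("G", 100), "DBD_ONLY", bg)
  expect_equal(allG$role, "REPRESSOR_NO_CTD")
  spgl <- classify_regulatory_role(strrep("SPGL", 25), "FULL", bg)
  expect_equal(spgl$role, "REPRESSOR_SPGL")
  expect_error(classify_regulatory_role("QQQ", "FULL", bg[-which(names(bg) == "Q")]),
               "background lacks")
})

test_that("table extrema report values and tied genes", {
  t1 <- load_fixture("table1")$payload
  pi_ex <- table_extrema(t1, "pi")
  expect_equal(pi_ex$min, 5.55); expect_equal(pi_ex$min_genes, "CaARF11")
  expect_equal(pi_ex$max, 8.56); expect_equal(pi_ex$max_genes, "CaARF4")
  ex <- table_extrema(t1, "exon_count")
  expect_equal(ex$min, 2); expect_equal(ex$max, 16)
  expect_equal(ex$max_genes, c("CaARF12", "CaARF19"))
  const <- toy_gene_table(); const$pi <- 7
  cx <- table_extrema(const, "pi")
  expect_equal(cx$min, cx$max)
  expect_error(table_extrema(t1, "nope"), "unknown column")
})

test_that("synthetic stand-in domain annotation matches the length rules", {
  t1 <- load_fixture("table1")$payload
  anns <- read_domain_spans(system.file("extdata", "domain_spans_synthetic.tsv",
                                        package = "arfkit"))
  arch <- vapply(anns, classify_architecture, character(1))
  expect_equal(as.integer(table(arch)[c("FULL", "TRUNCATED_III_ONLY",
                                        "DBD_ONLY")]),
               c(15L, 3L, 6L))
  expect_equal(sort(names(arch)[arch == "TRUNCATED_III_ONLY"]),
               c("CaARF10", "CaARF18", "CaARF4"))
  len <- stats::setNames(t1$protein_length, t1$name)
  # every protein under 670 aa shows only the DBD; every protein over 725 aa
  # carries a CTD
  expect_true(all(arch[names(len)[len < 670]] == "DBD_ONLY"))
  expect_true(all(arch[names(len)[len > 725]] %in%
                  c("FULL", "TRUNCATED_III_ONLY")))
})
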