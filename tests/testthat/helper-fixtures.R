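# Shared helpers: small builders used across test files. All synthetic data
# is generated in code; nothing is read from outside the package.

toy_gene_table <- function() {
  df <- data.frame(
    name = c("g1", "g2", "g3"),
    locus_id = c("L1", "L2", "L3"),
    protein_id = c("P1", "P2", "P3"),
    chromosome = c("Ca1", "Ca1", "UNPLACED"),
    start = c(100, 5000, NA),
    end = c(900, 6200, NA),
    strand = c("+", "-", "unknown"),
    protein_length = c(100, 200, 150),
    pi = c(6.0, 7.2, 5.1),
    mol_wt = c(11.1, 22.2, 16.5),
    exon_count = c(2, 5, 3),
    isoform_count = c(1, 2, 1),
    stringsAsFactors = FALSE
  )
  class(df) <- c("gene_table", "data.frame")
  df
}

write_toy_gene_tsv <- function(df = toy_gene_table()) {
  path <- tempfile(fileext = ".tsv")
  arfkit::write_gene_table(df, path)
  path
}

random_dna <- function(n, len, gc = 0.4) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(names(probs), len, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
}

random_protein <- function(len) {
  paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], len,
               replace = TRUE), collapse = "")
}

# Independent brute-force IUPAC scanner used as the oracle against the
# package scanner: regex character classes with a lookahead so overlapping
# matches are all reported.
oracle_scan <- function(seq, pattern) {
  sets <- arfkit::expand_iupac(pattern)
  rx <- paste0("(?=", paste0("[", vapply(sets, paste, character(1),
                                         collapse = ""), "]",
                             collapse = ""), ")")
  m <- gregexpr(rx, toupper(seq), perl = TRUE)[[1]]
  if (m[1] == -1) integer(0) else as.integer(m)
}

# random additive distance matrix plus its generating tree
random_additive <- function(ntaxa) {
  tr <- ape::rtree(ntaxa, br = function(k) runif(k, 0.05, 1))
  D <- ape::cophenetic.phylo(tr)
  list(tree = tr, d = D[tr$tip.label, tr$tip.label])
}
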