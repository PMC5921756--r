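## Promoter cis-regulatory element (CRE) analysis: IUPAC motif scanning on
## the forward strand, a zero-order GC background model, Bernoulli expected
## counts, enrichment factors, Monte-Carlo p-values from simulated control
## promoter sets, and 100-bp positional density with a null envelope.
##
## Positions are TSS-relative and negative upstream: a promoter of length L
## covers -L ... -1, with -1 immediately upstream of the initiation codon.

BASES <- c("A", "C", "G", "T")

#' Expand an IUPAC pattern into per-position base sets
#'
#' @param pattern IUPAC nucleotide string (e.g. `"TTTGACY"`).
#' @return List of character vectors, one allowed-base set per position.
#' @export
expand_iupac <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1)
  if (nchar(pattern) == 0) stop("empty motif pattern")
  ch <- strsplit(toupper(pattern), "")[[1]]
  bad <- which(!(ch %in% names(IUPAC_DNA)))
  if (length(bad)) {
    stop(sprintf("invalid IUPAC code '%s' at position %d", ch[bad[1]], bad[1]))
  }
  unname(IUPAC_DNA[ch])
}

#' The i.i.d. GC background model
#'
#' Zero-order background with p(G) = p(C) = gc/2 and p(A) = p(T) = (1-gc)/2.
#'
#' @param gc G+C fraction in [0, 1] (default 0.28, the reference promoter
#'   set's average).
#' @return List with `gc` and `probs` (named over A, C, G, T), of class
#'   `background_model`.
#' @export
background_model <- function(gc = 0.28) {
  stopifnot(gc >= 0, gc <= 1)
  structure(list(gc = gc,
                 probs = c(A = (1 - gc) / 2, C = gc / 2,
                           G = gc / 2, T = (1 - gc) / 2)),
            class = "background_model")
}

## Integer encoding (A=1, C=2, G=3, T=4; ambiguity codes in a *subject*
## sequence become NA and never match).
encode_dna <- function(seq) {
  m <- match(strsplit(toupper(seq), "")[[1]], BASES)
  m
}

sets_to_int <- function(sets) lapply(sets, function(s) match(s, BASES))

## Core counting engine on an integer-coded sequence matrix (rows =
## sequences, NA = ambiguity). Returns the logical match matrix
## (rows x windows); overlapping matches each count.
match_windows <- function(mat, sets_int) {
  m <- length(sets_int)
  L <- ncol(mat)
  if (L < m) return(matrix(FALSE, nrow(mat), 0))
  w <- L - m + 1
  acc <- matrix(TRUE, nrow(mat), w)
  for (k in seq_len(m)) {
    sub <- mat[, k:(w + k - 1), drop = FALSE]
    acc <- acc & matrix(sub %in% sets_int[[k]], nrow(mat), w)
  }
  acc
}

#' Scan a promoter sequence for an IUPAC motif
#'
#' Forward-strand scan, motif read 5'->3' on the promoter strand;
#' case-insensitive; overlapping matches each reported. IUPAC ambiguity codes
#' in the subject never match (warned once per sequence).
#'
#' @param seq DNA sequence (length >= motif length).
#' @param motif IUPAC pattern string.
#' @return Integer vector of 1-based match start positions.
#' @export
scan_promoter <- function(seq, motif) {
  sets <- expand_iupac(motif)
  if (nchar(seq) < length(sets)) stop("sequence shorter than motif")
  enc <- encode_dna(seq)
  if (anyNA(enc)) {
    warning("subject sequence contains ambiguity codes; they never match")
  }
  acc <- match_windows(matrix(enc, 1), sets_to_int(sets))
  which(acc[1, ])
}

#' Per-window match probability of a motif under a background model
#'
#' Product over motif positions of the summed background probabilities of
#' each allowed base set.
#'
#' @param motif IUPAC pattern string.
#' @param background a [background_model()].
#' @return Probability that a random background window matches.
#' @export
motif_probability <- function(motif, background) {
  sets <- expand_iupac(motif)
  prod(vapply(sets, function(s) sum(background$probs[s]), numeric(1)))
}

#' Expected total motif occurrences in a promoter set by chance
#'
#' Bernoulli expectation: match probability times the total number of scan
#' windows, sum over promoters of (L_i - m + 1).
#'
#' @param motif IUPAC pattern string.
#' @param background a [background_model()].
#' @param lengths promoter lengths in bp (one per promoter).
#' @return Expected total occurrence count.
#' @export
expected_occurrences <- function(motif, background, lengths) {
  m <- nchar(motif)
  if (length(lengths) == 0) return(0)
  stopifnot(all(lengths >= m))
  motif_probability(motif, background) * sum(lengths - m + 1)
}

#' Enrichment factor
#'
#' Observed total occurrences divided by the chance expectation.
#'
#' @param observed_total observed occurrence count.
#' @param expected expected count (> 0; returns NA with a warning at 0).
#' @return Dimensionless ratio.
#' @export
enrichment_factor <- function(observed_total, expected) {
  stopifnot(observed_total >= 0)
  if (expected <= 0) {
    warning("expected count is zero: enrichment undefined")
    return(NA_real_)
  }
  observed_total / expected
}

## Simulate null control sets and return the per-set total occurrence counts
## for each motif (rows = motifs, columns = simulations). Shared across
## motifs so a whole enrichment table reuses one stream of control sets.
simulate_null_totals <- function(patterns, n_promoters, length, background,
                                 n_sims, seed) {
  sets_int <- lapply(patterns, function(p) sets_to_int(expand_iupac(p)))
  totals <- matrix(0L, length(patterns), n_sims)
  with_substream(seed, "mc_control_sets", {
    for (s in seq_len(n_sims)) {
      mat <- matrix(sample.int(4L, n_promoters * length, replace = TRUE,
                               prob = background$probs),
                    n_promoters, length)
      for (k in seq_along(patterns)) {
        totals[k, s] <- sum(match_windows(mat, sets_int[[k]]))
      }
    }
  })
  totals
}

#' Monte-Carlo p-value for a motif's total occurrence count
#'
#' Simulates `n_sims` control sets of `n_promoters` i.i.d. background
#' sequences of the given length, takes the set-level total occurrence count
#' as the statistic, and returns the add-one upper-tail p-value
#' p = (1 + #\{sets with total >= observed\}) / (1 + n_sims).
#'
#' @param motif IUPAC pattern string.
#' @param observed_total observed total count in the real set.
#' @param n_promoters,length control-set geometry (defaults 23 x 1500 bp).
#' @param background a [background_model()].
#' @param n_sims number of simulations (default 2000).
#' @param seed integer seed (mandatory).
#' @return p-value in (0, 1].
#' @export
mc_pvalue <- function(motif, observed_total, n_promoters = 23, length = 1500,
                      background = background_model(), n_sims = 2000, seed) {
  stopifnot(n_sims >= 1, !missing(seed))
  totals <- simulate_null_totals(list(motif), n_promoters, length,
                                 background, n_sims, seed)
  (1 + sum(totals[1, ] >= observed_total)) / (1 + n_sims)
}

#' Enrichment table over a promoter set
#'
#' One row per motif: promoters with at least one hit, total occurrences,
#' average occurrences per promoter, Bernoulli expectation, enrichment
#' factor, and Monte-Carlo p-value (all motifs share one stream of simulated
#' control sets). Rows are sorted by enrichment factor, descending.
#'
#' @param promoters named character vector of promoter sequences (written
#'   5'->3', ending at position -1 relative to the initiation codon).
#' @param motifs data.frame with columns `name`, `pattern` (default: the
#'   packaged 10-element set).
#' @param background a [background_model()].
#' @param n_sims Monte-Carlo simulations (default 2000).
#' @param seed integer seed (mandatory).
#' @return data.frame with columns `name`, `pattern`, `promoters_with_hit`,
#'   `total_observed`, `avg_per_promoter`, `expected`, `enrichment_factor`,
#'   `mc_pvalue`.
#' @export
enrichment_table <- function(promoters, motifs = read_motifs(),
                             background = background_model(), n_sims = 2000,
                             seed) {
  stopifnot(!missing(seed))
  if (nrow(motifs) == 0) {
    return(data.frame(name = character(0), pattern = character(0),
                      promoters_with_hit = integer(0),
                      total_observed = integer(0),
                      avg_per_promoter = numeric(0), expected = numeric(0),
                      enrichment_factor = numeric(0), mc_pvalue = numeric(0)))
  }
  lens <- nchar(promoters)
  encs <- lapply(promoters, encode_dna)
  rows <- lapply(seq_len(nrow(motifs)), function(k) {
    sets <- sets_to_int(expand_iupac(motifs$pattern[k]))
    per_seq <- vapply(encs, function(e) {
      if (length(e) < length(sets)) return(0L)
      sum(match_windows(matrix(e, 1), sets))
    }, integer(1))
    total <- sum(per_seq)
    expd <- expected_occurrences(motifs$pattern[k], background, lens)
    data.frame(name = motifs$name[k], pattern = motifs$pattern[k],
               promoters_with_hit = sum(per_seq > 0),
               total_observed = total,
               avg_per_promoter = total / length(promoters),
               expected = expd,
               enrichment_factor = enrichment_factor(total, expd))
  })
  out <- do.call(rbind, rows)
  # common promoter length for the control-set geometry; mixed lengths use the max
  nulls <- simulate_null_totals(as.list(out$pattern), length(promoters),
                                max(lens), background, n_sims, seed)
  out$mc_pvalue <- vapply(seq_len(nrow(out)), function(k) {
    (1 + sum(nulls[k, ] >= out$total_observed[k])) / (1 + n_sims)
  }, numeric(1))
  out[order(-out$enrichment_factor), , drop = FALSE]
}

## Sequence-index match starts -> TSS-relative coordinates (promoter of
## length L covers -L ... -1).
tss_positions <- function(starts, promoter_length) {
  starts - promoter_length - 1
}

#' Positional density of motif matches in 100-bp promoter bins
#'
#' Aggregates TSS-relative match start positions over promoters (and over a
#' motif selection, typically the most enriched ones) into fixed-width bins
#' spanning the promoter window. Optionally computes a Monte-Carlo control
#' envelope: the per-bin 95th percentile of binned counts over simulated
#' background sets scanned with the same motifs.
#'
#' @param positions list (one element per promoter) of TSS-relative match
#'   start positions (negative integers), or a single vector.
#' @param bin bin width in bp (default 100).
#' @param window c(lower, upper) TSS-relative window (default c(-1500, -1)).
#' @param motifs,background,n_sims,seed if all supplied, the control envelope
#'   is simulated (same set geometry as `positions`: number of promoters from
#'   the list length, promoter length from the window).
#' @param envelope_prob percentile for the envelope (default 0.95).
#' @return data.frame with `bin_start`, `bin_end`, `count`, and `envelope`
#'   (NA when not simulated).
#' @export
positional_density <- function(positions, bin = 100, window = c(-1500, -1),
                               motifs = NULL, background = NULL,
                               n_sims = 200, seed = NULL,
                               envelope_prob = 0.95) {
  if (!is.list(positions)) positions <- list(positions)
  pos <- unlist(positions, use.names = FALSE)
  if (length(pos) && (any(pos < window[1]) || any(pos > window[2]))) {
    stop("match position outside the promoter window")
  }
  L <- window[2] - window[1] + 1
  nb <- ceiling(L / bin)
  edges <- window[1] + bin * (0:nb)
  bin_of <- function(p) pmin(floor((p - window[1]) / bin) + 1, nb)
  counts <- tabulate(bin_of(pos), nbins = nb)
  env <- rep(NA_real_, nb)
  if (!is.null(motifs) && !is.null(background) && !is.null(seed)) {
    sets_int <- lapply(motifs$pattern, function(p) sets_to_int(expand_iupac(p)))
    n_prom <- length(positions)
    sims <- matrix(0, n_sims, nb)
    with_substream(seed, "density_envelope", {
      for (s in seq_len(n_sims)) {
        mat <- matrix(sample.int(4L, n_prom * L, replace = TRUE,
                                 prob = background$probs), n_prom, L)
        allpos <- integer(0)
        for (si in sets_int) {
          hits <- which(match_windows(mat, si), arr.ind = TRUE)
          if (nrow(hits)) allpos <- c(allpos, tss_positions(hits[, 2], L))
        }
        sims[s, ] <- tabulate(bin_of(allpos), nbins = nb)
      }
    })
    env <- apply(sims, 2, quantile, probs = envelope_prob)
  }
  data.frame(bin_start = edges[-(nb + 1)],
             bin_end = pmin(edges[-1] - 1, window[2]),
             count = counts, envelope = env)
}

#' Scan a promoter set and return TSS-relative match positions
#'
#' @param promoters named character vector of promoter sequences.
#' @param motifs data.frame with `name`, `pattern`.
#' @return List (one element per promoter) of TSS-relative match start
#'   positions pooled over the motifs.
#' @export
scan_promoter_set <- function(promoters, motifs) {
  lapply(promoters, function(s) {
    L <- nchar(s)
    pos <- integer(0)
    for (p in motifs$pattern) {
      st <- suppressWarnings(scan_promoter(s, p))
      if (length(st)) pos <- c(pos, tss_positions(st, L))
    }
    sort(pos)
  })
}
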