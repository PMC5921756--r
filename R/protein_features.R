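## Protein physicochemistry and domain/middle-region classification.
##
## The canonical family architecture is DBD (B3 + AUX_RESP subdomains), a
## variable middle region (MR), and a C-terminal dimerization domain (CTD,
## subdomains III + IV). The MR composition separates activators
## (glutamine/serine/leucine-rich) from repressors (serine/proline/glycine/
## leucine-rich with a CTD, glycine-rich without).

#' Average molecular weight of a protein
#'
#' Sum of average residue masses plus one water (18.015 Da), in kilodaltons.
#'
#' @param seq amino-acid sequence (one-letter codes; case-insensitive).
#' @return Mass in kDa.
#' @export
molecular_weight <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (nchar(seq) == 0) stop("empty sequence")
  ch <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!(ch %in% names(AA_RESIDUE_MASS)))
  if (length(bad)) {
    stop(sprintf("unknown residue '%s' at position %d", ch[bad[1]], bad[1]))
  }
  (sum(AA_RESIDUE_MASS[ch]) + WATER_MASS) / 1000
}

## Net charge of a protein at a given pH under the Bjellqvist pKa set
## (positive groups: N-terminus, H, K, R; negative: C-terminus, C, D, E, Y).
protein_charge <- function(counts, nterm_res, cterm_res, pH) {
  pos_pka <- c(nterm = unname(
                 if (nterm_res %in% names(PKA_NTERM)) PKA_NTERM[nterm_res]
                 else PKA_NTERM_DEFAULT),
               H = PKA_SIDE[["H"]], K = PKA_SIDE[["K"]], R = PKA_SIDE[["R"]])
  pos_n <- c(1, counts["H"], counts["K"], counts["R"])
  neg_pka <- c(cterm = unname(
                 if (cterm_res %in% names(PKA_CTERM)) PKA_CTERM[cterm_res]
                 else PKA_CTERM_DEFAULT),
               C = PKA_SIDE[["C"]], D = PKA_SIDE[["D"]],
               E = PKA_SIDE[["E"]], Y = PKA_SIDE[["Y"]])
  neg_n <- c(1, counts["C"], counts["D"], counts["E"], counts["Y"])
  sum(pos_n / (1 + 10^(pH - pos_pka))) - sum(neg_n / (1 + 10^(neg_pka - pH)))
}

#' Theoretical isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge over the termini and the
#' ionizable side chains (D, E, C, Y, H, K, R) crosses zero, with the
#' Bjellqvist pKa set (the set behind the ExPASy Compute pI tool). The charge
#' is strictly decreasing in pH, so the root is found by bisection.
#'
#' @param seq amino-acid sequence.
#' @param tol bisection tolerance in pH units (default 0.001).
#' @return pI (pH units).
#' @export
isoelectric_point <- function(seq, tol = 0.001) {
  stopifnot(is.character(seq), length(seq) == 1)
  if (nchar(seq) == 0) stop("empty sequence")
  ch <- strsplit(toupper(seq), "")[[1]]
  bad <- which(!(ch %in% AA20))
  if (length(bad)) {
    stop(sprintf("unknown residue '%s' at position %d", ch[bad[1]], bad[1]))
  }
  counts <- stats::setNames(integer(length(AA20)), AA20)
  tb <- table(ch)
  counts[names(tb)] <- as.integer(tb)
  lo <- 0; hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (protein_charge(counts, ch[1], ch[length(ch)], mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Classify a protein's domain architecture
#'
#' Requires the family-identity domains B3 and AUX_RESP; classifies by the
#' presence of the CTD subdomains: both III and IV = `FULL`, III alone =
#' `TRUNCATED_III_ONLY`, neither = `DBD_ONLY`. IV without III violates the
#' ordered-domain invariant and is an error.
#'
#' @param annotation named list of `c(start, end)` spans keyed by domain
#'   (`B3`, `AUX_RESP`, optionally `III`, `IV`), as from [read_domain_spans()].
#' @return One of `"FULL"`, `"TRUNCATED_III_ONLY"`, `"DBD_ONLY"`.
#' @export
classify_architecture <- function(annotation) {
  if (!all(c("B3", "AUX_RESP") %in% names(annotation))) {
    stop("annotation lacks the identity domains B3 and AUX_RESP")
  }
  has3 <- "III" %in% names(annotation)
  has4 <- "IV" %in% names(annotation)
  if (has4 && !has3) stop("domain IV present without III: invalid annotation")
  present <- annotation[intersect(c("B3", "AUX_RESP", "III", "IV"), names(annotation))]
  starts <- vapply(present, `[`, numeric(1), 1)
  ends <- vapply(present, `[`, numeric(1), 2)
  if (any(ends < starts)) stop("domain span with end < start")
  if (any(diff(starts) <= 0) || any(utils::head(ends, -1) >= utils::tail(starts, -1))) {
    stop("domain spans must be ordered and non-overlapping (B3 < AUX_RESP < III < IV)")
  }
  if (has3 && has4) "FULL" else if (has3) "TRUNCATED_III_ONLY" else "DBD_ONLY"
}

#' Extract the middle region of a protein
#'
#' Residues strictly between the end of AUX_RESP and the start of subdomain
#' III; for proteins without a CTD, from the AUX_RESP end to the C-terminus.
#'
#' @param seq amino-acid sequence.
#' @param annotation domain spans (see [classify_architecture()]).
#' @return The MR subsequence.
#' @export
extract_mr <- function(seq, annotation) {
  if (!("AUX_RESP" %in% names(annotation))) stop("annotation lacks AUX_RESP")
  from <- annotation$AUX_RESP[2] + 1
  to <- if ("III" %in% names(annotation)) annotation$III[1] - 1 else nchar(seq)
  if (to > nchar(seq)) stop("domain span extends beyond sequence length")
  if (from > to) stop("degenerate annotation: empty middle region")
  substr(seq, from, to)
}

#' Classify a protein's regulatory role from its middle-region composition
#'
#' For each composite residue set the signature score is the summed observed
#' MR frequency of its residues divided by the summed background frequency.
#' The protein is called an activator (`ACTIVATOR_QSL`) when the {Q,S,L}
#' score is the strict maximum of the three scores AND the observed glutamine
#' frequency exceeds its background (glutamine enrichment being the hallmark
#' of activators); otherwise it is a repressor: `REPRESSOR_SPGL` when any
#' CTD subdomain is present, `REPRESSOR_NO_CTD` for DBD-only proteins.
#'
#' @param mr middle-region sequence.
#' @param architecture `"FULL"`, `"TRUNCATED_III_ONLY"`, or `"DBD_ONLY"`.
#' @param background named per-residue background frequencies (must cover
#'   every residue present in the MR; see [residue_frequencies()]).
#' @return List with `frequencies` (MR residue proportions, summing to 1),
#'   `signature_scores` (QSL, SPGL, G), and `role`.
#' @export
classify_regulatory_role <- function(mr, architecture, background) {
  stopifnot(nchar(mr) > 0,
            architecture %in% c("FULL", "TRUNCATED_III_ONLY", "DBD_ONLY"))
  ch <- strsplit(toupper(mr), "")[[1]]
  missing_bg <- setdiff(unique(ch), names(background))
  if (length(missing_bg)) {
    stop("background lacks residue(s) present in MR: ",
         paste(missing_bg, collapse = ", "))
  }
  freq <- stats::setNames(numeric(length(AA20)), AA20)
  tb <- table(ch) / length(ch)
  freq[names(tb)] <- as.numeric(tb)
  sets <- list(QSL = c("Q", "S", "L"), SPGL = c("S", "P", "G", "L"), G = "G")
  scores <- vapply(sets, function(s) sum(freq[s]) / sum(background[s]), numeric(1))
  q_enriched <- freq[["Q"]] > background[["Q"]]
  is_act <- scores[["QSL"]] > max(scores[["SPGL"]], scores[["G"]]) && q_enriched
  if (!is_act && scores[["QSL"]] == max(scores)) {
    log_msg("signature-score tie resolved conservatively to repressor")
  }
  role <- if (is_act) "ACTIVATOR_QSL"
          else if (architecture == "DBD_ONLY") "REPRESSOR_NO_CTD"
          else "REPRESSOR_SPGL"
  list(frequencies = freq, signature_scores = scores, role = role)
}

#' Mean residue frequencies of a protein set
#'
#' The default background for [classify_regulatory_role()]: per-residue
#' frequencies pooled over all sequences.
#'
#' @param seqs named character vector of protein sequences.
#' @return Named frequency vector over the 20 amino acids (sums to 1).
#' @export
residue_frequencies <- function(seqs) {
  ch <- unlist(strsplit(toupper(paste(seqs, collapse = "")), ""))
  freq <- stats::setNames(numeric(length(AA20)), AA20)
  tb <- table(ch[ch %in% AA20])
  freq[names(tb)] <- as.numeric(tb)
  freq / sum(freq)
}

#' Column extrema of a gene table
#'
#' @param records a `gene_table`.
#' @param column numeric column name.
#' @return List with `min`, `min_genes`, `max`, `max_genes` (ties reported in
#'   gene-name order).
#' @export
table_extrema <- function(records, column) {
  if (!(column %in% names(records))) stop("unknown column: ", column)
  v <- records[[column]]
  if (!is.numeric(v)) stop("column is not numeric: ", column)
  ok <- !is.na(v)
  lo <- min(v[ok]); hi <- max(v[ok])
  list(min = lo, min_genes = sort(records$name[ok & v == lo]),
       max = hi, max_genes = sort(records$name[ok & v == hi]))
}

#' Classify a whole annotated family
#'
#' Convenience wrapper: architecture plus regulatory role for each protein.
#'
#' @param seqs named protein sequences.
#' @param annotations named list of domain annotations (see
#'   [read_domain_spans()]); names must cover `names(seqs)`.
#' @param background optional background frequencies; defaults to the mean
#'   residue frequencies of `seqs`.
#' @return data.frame with columns `protein_id`, `architecture`, `role` and
#'   the three signature scores.
#' @export
classify_family <- function(seqs, annotations, background = NULL) {
  if (is.null(background)) background <- residue_frequencies(seqs)
  rows <- lapply(names(seqs), function(id) {
    ann <- annotations[[id]]
    if (is.null(ann)) stop("no annotation for protein ", id)
    arch <- classify_architecture(ann)
    res <- classify_regulatory_role(extract_mr(seqs[[id]], ann), arch, background)
    data.frame(protein_id = id, architecture = arch, role = res$role,
               score_QSL = res$signature_scores[["QSL"]],
               score_SPGL = res$signature_scores[["SPGL"]],
               score_G = res$signature_scores[["G"]])
  })
  do.call(rbind, rows)
}
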