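## File readers/writers and packaged fixtures.
##
## Conventions: genomic coordinates are 1-based and fully closed (start and
## end both inclusive), matching the family table as printed. Chromosome
## labels are free strings; genes without an assembly placement carry the
## reserved sentinel "UNPLACED" (never an empty string) and NA coordinates.

GENE_TABLE_COLUMNS <- c("name", "locus_id", "protein_id", "chromosome",
                        "start", "end", "strand", "protein_length", "pi",
                        "mol_wt", "exon_count", "isoform_count")

#' Read a gene-family annotation table
#'
#' Reads a TSV whose dialect mirrors the family table of a genome-wide gene
#' family survey: one row per gene with locus/protein identifiers, chromosome
#' placement (1-based closed coordinates), strand, and deduced-protein
#' statistics (length, isoelectric point, molecular weight) plus exon and
#' isoform counts.
#'
#' @param path path to a tab-separated file with a header row naming at least
#'   the columns `name, locus_id, protein_id, chromosome, start, end, strand,
#'   protein_length, pi, mol_wt, exon_count, isoform_count`.
#' @return A `data.frame` of class `gene_table`, one row per input row, input
#'   order preserved. Unplaced rows have `chromosome == "UNPLACED"` and NA
#'   coordinates.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  missing_cols <- setdiff(GENE_TABLE_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("gene table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[, GENE_TABLE_COLUMNS]
  num_cols <- c("start", "end", "protein_length", "pi", "mol_wt",
                "exon_count", "isoform_count")
  for (cc in num_cols) {
    raw <- gsub(",", "", df[[cc]])
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & raw != "" & raw != "NA" & is.na(val))
    if (length(bad)) {
      stop(sprintf("non-numeric value '%s' in column '%s' at line %d",
                   raw[bad[1]], cc, bad[1] + 1L))
    }
    df[[cc]] <- val
  }
  unplaced <- is.na(df$chromosome) | df$chromosome == "" | df$chromosome == UNPLACED
  df$chromosome[unplaced] <- UNPLACED
  df$start[unplaced] <- NA_real_
  df$end[unplaced] <- NA_real_
  validate_gene_table(df)
  class(df) <- c("gene_table", "data.frame")
  df
}

validate_gene_table <- function(df) {
  placed <- df$chromosome != UNPLACED
  if (any(placed & (is.na(df$start) | is.na(df$end)))) {
    stop("placed gene with missing coordinates: ",
         paste(df$name[placed & (is.na(df$start) | is.na(df$end))], collapse = ", "))
  }
  if (any(placed & df$start > df$end)) stop("start > end for a placed gene")
  stopifnot(all(df$protein_length > 0), all(df$exon_count >= 1),
            all(df$isoform_count >= 1))
  invisible(df)
}

#' Write a gene table
#'
#' Emits the same TSV dialect [read_gene_table()] consumes; reading the output
#' back reproduces the table (byte-identical re-emission for placed records).
#'
#' @param records a `gene_table`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gene_table <- function(records, path) {
  df <- as.data.frame(records)
  # Integer-valued numerics are printed without decorations so that
  # write-then-read is the identity.
  for (cc in c("start", "end", "protein_length", "exon_count", "isoform_count")) {
    df[[cc]] <- ifelse(is.na(df[[cc]]), "NA", format(df[[cc]], scientific = FALSE, trim = TRUE))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sequences from a FASTA file
#'
#' Thin validated wrapper around Biostrings: ids must be unique, sequences
#' non-empty. Case is preserved; downstream comparisons are case-insensitive.
#'
#' @param path FASTA file.
#' @return Named character vector of sequences (names are record ids, the
#'   first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  names(seqs) <- ids
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  if (any(nchar(seqs) == 0)) {
    stop("empty sequence for id(s): ",
         paste(ids[nchar(seqs) == 0], collapse = ", "))
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param records named character vector (names become headers).
#' @param path output path.
#' @param width line-wrap width in characters (default 60).
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60) {
  stopifnot(length(records) > 0, !is.null(names(records)),
            all(nzchar(names(records))))
  if (any(nchar(records) == 0)) stop("refusing to write empty sequence")
  if (anyDuplicated(names(records))) {
    stop("duplicate FASTA ids: ",
         paste(unique(names(records)[duplicated(names(records))]), collapse = ", "))
  }
  set <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Load a packaged fixture
#'
#' The package ships hand-curated plain-text transcriptions of the reference
#' family's printed tables so that every analysis is exercisable offline:
#' \describe{
#'   \item{`table1`}{the 24-gene chickpea ARF family table (coordinates,
#'     strand, protein statistics, exon and isoform counts).}
#'   \item{`table2_motifs`}{the 10 promoter cis-regulatory elements with their
#'     IUPAC patterns and the printed occurrence/enrichment entries. Printed
#'     expected counts that are internally inconsistent with the printed
#'     enrichment factor are recorded as NA.}
#'   \item{`mor_primers`}{the malate oxidoreductase 5'/3' RNA-integrity assay
#'     primers with amplicon sizes and distances from the transcript 3' end.}
#' }
#'
#' @param name one of `"table1"`, `"table2_motifs"`, `"mor_primers"`.
#' @return A list with elements `name` and `payload` (a data.frame), of class
#'   `fixture`. For `table1` the payload is a `gene_table`.
#' @export
load_fixture <- function(name) {
  known <- c("table1", "table2_motifs", "mor_primers")
  if (!is.character(name) || length(name) != 1 || !(name %in% known)) {
    stop("unknown fixture '", paste(name, collapse = ","),
         "'; available: ", paste(known, collapse = ", "))
  }
  path <- system.file("extdata", paste0(name, ".tsv"), package = "arfkit",
                      mustWork = TRUE)
  payload <- if (name == "table1") {
    read_gene_table(path)
  } else {
    read.delim(path, stringsAsFactors = FALSE)
  }
  if (name == "table1" && nrow(payload) != 24) stop("corrupt table1 fixture")
  if (name == "table2_motifs" && nrow(payload) != 10) stop("corrupt motif fixture")
  structure(list(name = name, payload = payload), class = "fixture")
}

#' @export
print.fixture <- function(x, ...) {
  cat("<fixture>", x$name, "-", nrow(x$payload), "rows\n")
  print(utils::head(x$payload), ...)
  invisible(x)
}

#' Read a motif definition table
#'
#' Two-column (or wider) TSV with columns `name` and `pattern` (IUPAC codes).
#'
#' @param path TSV path; if missing, the packaged 10-element motif set is used.
#' @return data.frame with columns `name`, `pattern` (extra columns kept).
#' @export
read_motifs <- function(path = NULL) {
  if (is.null(path)) return(load_fixture("table2_motifs")$payload)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("name", "pattern") %in% names(df))) {
    stop("motif table needs columns 'name' and 'pattern'")
  }
  invisible(lapply(df$pattern, expand_iupac))  # validates patterns
  df
}

#' Read a domain-span annotation table
#'
#' Long-format TSV with columns `protein_id`, `domain` (one of B3, AUX_RESP,
#' III, IV), `start`, `end` (1-based inclusive residue coordinates).
#'
#' @param path TSV path.
#' @return A named list of domain-annotation lists, one per protein, each a
#'   list of `c(start, end)` spans keyed by domain name.
#' @export
read_domain_spans <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "domain", "start", "end")
  if (!all(need %in% names(df))) {
    stop("domain table needs columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(df$domain), c("B3", "AUX_RESP", "III", "IV"))
  if (length(bad)) stop("unknown domain name(s): ", paste(bad, collapse = ", "))
  out <- lapply(split(df, df$protein_id), function(d) {
    spans <- lapply(seq_len(nrow(d)), function(i) c(d$start[i], d$end[i]))
    names(spans) <- d$domain
    spans
  })
  out
}

#' Read a duplicate-pair (Ka/Ks) table
#'
#' @param path TSV with columns `gene_a`, `gene_b`, `ka`, `ks`.
#' @return data.frame with those columns.
#' @export
read_kaks_pairs <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "ka", "ks")
  if (!all(need %in% names(df))) {
    stop("pair table needs columns: ", paste(need, collapse = ", "))
  }
  stopifnot(all(df$ka >= 0, na.rm = TRUE), all(df$ks >= 0, na.rm = TRUE))
  df
}
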