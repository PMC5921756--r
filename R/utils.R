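#' @keywords internal
"_PACKAGE"

#' @importFrom stats sd cor hclust dist as.dist t.test qnorm quantile rnorm runif var
#' @importFrom utils read.delim write.table modifyList head tail
NULL

## Sentinel chromosome label for genes without an assembly placement.
UNPLACED <- "UNPLACED"

#' Emit a timestamped log line to stderr
#'
#' Logging is silent unless `options(arfkit.verbose = TRUE)` is set (the CLI
#' sets it for `--verbose`).
#'
#' @param ... passed to [sprintf()] (first argument is the format string).
#' @param level label printed with the message.
#' @return Invisibly, the formatted message.
#' @export
log_msg <- function(..., level = "INFO") {
  msg <- sprintf(...)
  if (isTRUE(getOption("arfkit.verbose", FALSE))) {
    message(sprintf("[%s] %s %s", level, format(Sys.time(), "%H:%M:%S"), msg))
  }
  invisible(msg)
}

#' Read a key-value configuration file
#'
#' Lines of the form `key = value` (or `key: value`); `#` starts a comment.
#' Recognized keys (all optional): `gc_background`, `n_sims`, `seed`,
#' `tandem_window`, `gamma`, `bootstrap_replicates`, `sister_threshold`.
#' Values are converted to numeric when possible.
#'
#' @param path path to the configuration file.
#' @return Named list of settings merged over the package defaults.
#' @export
read_config <- function(path) {
  defaults <- list(
    gc_background = 0.28, n_sims = 2000, seed = 1L, tandem_window = 250000,
    gamma = 6.1e-9, bootstrap_replicates = 1000, sister_threshold = 65
  )
  if (missing(path) || is.null(path)) return(defaults)
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  got <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "[=:]", fixed = FALSE)[[1]]
    if (length(kv) < 2) stop("config line not of the form 'key = value': ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    num <- suppressWarnings(as.numeric(val))
    got[[key]] <- if (!is.na(num)) num else val
  }
  modifyList(defaults, got)
}

## Deterministic per-generator substream: every synthetic generator derives its
## own seed from (user seed, generator name) so adding a generator to a script
## does not shift the draws of the others.
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, !is.na(seed))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(seed) * 2654435 + h * 97) %% .Machine$integer.max)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}

## IUPAC nucleotide degeneracy table (DNA).
IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

## The 20 standard amino acids, one-letter codes.
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V")

## Average (isotope-averaged) residue masses in daltons; a peptide adds one
## water (18.01524 Da) to the sum of its residue masses.
AA_RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  Q = 128.1307, E = 129.1155, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

## Bjellqvist pKa values as used by the ExPASy Compute pI tool. Side chains
## plus free termini; the N-terminal pKa depends on the first residue.
PKA_SIDE <- c(C = 9.0, D = 4.05, E = 4.45, H = 5.98, K = 10.0, R = 12.0, Y = 10.0)
PKA_NTERM <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82, V = 7.44, E = 7.70)
PKA_NTERM_DEFAULT <- 7.5
PKA_CTERM <- c(D = 4.55, E = 4.75)
PKA_CTERM_DEFAULT <- 3.55

is_protein_seq <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  all(ch %in% AA20)
}
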