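# Shared sequence helpers. Nucleotide sequences are plain uppercase character
# scalars throughout; Biostrings objects are used at the I/O and translation
# boundaries only.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_CODES <- names(IUPAC_SETS)

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Reverse complement of a nucleotide string
#'
#' IUPAC ambiguity codes are complemented according to the standard table
#' (e.g. R <-> Y, B <-> V); case is preserved as uppercase.
#'
#' @param x single nucleotide string.
#' @return the reverse complement as a character scalar.
#' @export
#' @examples
#' revcomp("ACGTR")
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", toupper(x))
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' Translate a nucleotide sequence with the standard genetic code
#'
#' Translation starts at the first base of `x` and proceeds in frame;
#' a trailing partial codon is dropped. Stop codons translate to `*`.
#'
#' @param x nucleotide string (length >= 3).
#' @return amino-acid string, possibly containing `*`.
#' @export
translate_dna <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  n <- nchar(x) - nchar(x) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(x, 1L, n)),
                                     no.init.codon = TRUE))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# All 64 codons; optionally excluding stops and/or ATG.
codon_alphabet <- function(exclude_stops = TRUE, exclude_atg = FALSE) {
  b <- c("A", "C", "G", "T")
  cods <- as.vector(outer(outer(b, b, paste0), b, paste0))
  if (exclude_stops) cods <- setdiff(cods, STOP_CODONS)
  if (exclude_atg) cods <- setdiff(cods, "ATG")
  cods
}

random_codons <- function(n_codons, alphabet = codon_alphabet()) {
  paste(sample(alphabet, n_codons, replace = TRUE), collapse = "")
}
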