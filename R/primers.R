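# Degenerate-primer arithmetic and in-silico PCR.
#
# A degenerate primer is an oligonucleotide mixture written with IUPAC
# ambiguity codes; its degeneracy is the number of concrete sequences it
# encodes. Matching is exact IUPAC-compatibility with zero mismatches;
# reverse primers are supplied 5'->3' on the antisense strand and matched as
# their reverse complement on the template (standard PCR convention).

check_primer <- function(primer) {
  stopifnot(is.character(primer), length(primer) == 1L)
  p <- toupper(gsub("[ \t]", "", primer))
  if (!nzchar(p)) stop("empty primer")
  chars <- strsplit(p, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% IUPAC_CODES)
  if (length(bad))
    stop("invalid IUPAC code '", chars[bad[1L]], "' at position ", bad[1L])
  p
}

#' Degeneracy of an IUPAC primer
#'
#' The number of distinct concrete sequences a degenerate primer encodes:
#' the product over positions of the IUPAC ambiguity-set size (A/C/G/T = 1;
#' R,Y,S,W,K,M = 2; B,D,H,V = 3; N = 4). Whitespace in the primer text is
#' ignored, so primers can be given in the spaced notation of primer tables.
#'
#' @param primer IUPAC nucleotide string, 5'->3'.
#' @return integer degeneracy.
#' @export
#' @examples
#' degeneracy("CARTTYCARCANGARGTNGAAATGAT")  # 256
degeneracy <- function(primer) {
  p <- check_primer(primer)
  chars <- strsplit(p, "", fixed = TRUE)[[1L]]
  prod(vapply(IUPAC_SETS[chars], length, integer(1)))
}

#' Length of the specific (non-degenerate) 3' run of a primer
#'
#' The maximal suffix containing only A/C/G/T — the bases that anchor the
#' 3' end of the primer during extension.
#'
#' @inheritParams degeneracy
#' @return integer count (0 for a fully degenerate primer).
#' @export
specific_3prime_run <- function(primer) {
  p <- check_primer(primer)
  chars <- rev(strsplit(p, "", fixed = TRUE)[[1L]])
  run <- 0L
  for (ch in chars) {
    if (ch %in% c("A", "C", "G", "T")) run <- run + 1L else break
  }
  run
}

#' Expand a degenerate primer into its concrete sequences
#'
#' @inheritParams degeneracy
#' @param cap refuse to expand primers with degeneracy above this bound.
#' @return character vector of all concrete expansions, lexicographic order;
#'   length equals [degeneracy()].
#' @export
expand <- function(primer, cap = 65536L) {
  p <- check_primer(primer)
  d <- degeneracy(p)
  if (d > cap)
    stop("degeneracy ", d, " exceeds cap ", cap)
  sets <- IUPAC_SETS[strsplit(p, "", fixed = TRUE)[[1L]]]
  out <- ""
  for (s in sets) out <- as.vector(t(outer(out, s, paste0)))
  sort(out)
}

# TRUE where the primer (IUPAC) matches the template window starting at each
# position; template N matches any primer base (permissive: genomic drafts
# contain N runs).
iupac_match_starts <- function(template, primer) {
  hits <- Biostrings::matchPattern(Biostrings::DNAString(primer),
                                   Biostrings::DNAString(template),
                                   fixed = FALSE)
  BiocGenerics::start(hits)
}

#' In-silico PCR with degenerate primers
#'
#' The forward primer is matched IUPAC-compatibly on the given strand of the
#' template; the reverse primer (5'->3' antisense) is matched as its reverse
#' complement downstream. Every compatible primer pair within
#' `max_product_bp` is reported.
#'
#' @param template concrete nucleotide string.
#' @param fwd_primer,rev_primer IUPAC primer strings, 5'->3'.
#' @param max_product_bp maximum amplicon size reported.
#' @return data frame with columns `fwd_match_start`, `rev_match_start`,
#'   `amplicon_length` (bp, inclusive of both primer footprints), sorted by
#'   length; zero rows when no amplicon is predicted.
#' @export
insilico_pcr <- function(template, fwd_primer, rev_primer,
                         max_product_bp = 5000L) {
  template <- toupper(template)
  fwd <- check_primer(fwd_primer)
  rev_site <- revcomp(check_primer(rev_primer))
  f_starts <- iupac_match_starts(template, fwd)
  r_starts <- iupac_match_starts(template, rev_site)
  out <- data.frame(fwd_match_start = integer(0), rev_match_start = integer(0),
                    amplicon_length = integer(0))
  for (f in f_starts) {
    for (r in r_starts) {
      if (r < f) next
      len <- (r + nchar(rev_site) - 1L) - f + 1L
      if (len > 0L && len <= max_product_bp)
        out[nrow(out) + 1L, ] <- c(f, r, len)
    }
  }
  out[order(out$amplicon_length, out$fwd_match_start), , drop = FALSE]
}

#' The study's printed degenerate primers
#'
#' Reads the four degenerate primers used to amplify SERK kinase-domain
#' fragments (two forward, two reverse) bundled with the package as a TSV.
#'
#' @return data frame with columns `name`, `sequence`, `orientation`.
#' @export
serk_degenerate_primers <- function() {
  path <- system.file("extdata", "degenerate_primers.tsv", package = "serkdup")
  read.delim(path, stringsAsFactors = FALSE)
}
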