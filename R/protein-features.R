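# SERK-diagnostic motif scanning and ProtParam-style protein statistics.
#
# The leucine-zipper consensus used as a SERK diagnostic is
# Leu-X6-Leu-X6-Leu-X6-Leu (literal leucines; X any residue), a 22-residue
# window. The SPP motif of the extracellular juxtamembrane domain defaults
# to the literal tripeptide "SPP" and is configurable. Molecular weight uses
# average isotopic residue masses + one water; pI solves net charge = 0 by
# bisection with the Bjellqvist pKa set, emulating the ExPASy ProtParam tool.

AA_LETTERS <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

# Average residue masses (Da); free amino acid = residue + 18.0153 (water).
AA_AVG_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.0153

# Bjellqvist pKa values: side chains, C-terminus, and residue-dependent
# N-terminal pKa.
PKA_SIDE <- c(D = 4.05, E = 4.45, H = 5.98, C = 9.0, Y = 10.0, K = 10.0,
              R = 12.0)
PKA_CTERM <- 3.55
PKA_NTERM <- c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82, V = 7.44,
               E = 7.70, G = 7.50)
PKA_NTERM_DEFAULT <- 7.50

check_protein <- function(protein, allow_nonstandard = FALSE) {
  stopifnot(is.character(protein), length(protein) == 1L)
  p <- toupper(protein)
  if (!nzchar(p)) stop("empty protein sequence")
  chars <- strsplit(p, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% AA_LETTERS)
  if (length(bad)) {
    if (!allow_nonstandard)
      stop("unknown residue '", chars[bad[1L]], "' at position ", bad[1L])
    warning("non-standard residue(s) treated as X: ",
            paste(unique(chars[bad]), collapse = ", "))
  }
  p
}

#' Scan a protein for the SERK leucine-zipper consensus
#'
#' Reports every 22-residue window matching Leu-X6-Leu-X6-Leu-X6-Leu
#' (overlapping windows included) and a summary status: `"full"` when at
#' least one full window matches, `"partial"` when only some Leu-X6-Leu
#' stretch is present, `"absent"` otherwise. Non-standard residues are
#' treated as X with a warning.
#'
#' @param protein amino-acid string.
#' @return list with `status` and `hits` (data frame `start`,
#'   `matched_text`; 1-based positions).
#' @export
find_leucine_zipper <- function(protein) {
  p <- check_protein(protein, allow_nonstandard = TRUE)
  full_re <- "(?=(L.{6}L.{6}L.{6}L))"
  part_re <- "(?=(L.{6}L))"
  full <- gregexpr(full_re, p, perl = TRUE)[[1L]]
  hits <- data.frame(start = integer(0), matched_text = character(0))
  status <- "absent"
  if (full[1L] != -1L) {
    status <- "full"
    hits <- data.frame(start = as.integer(full),
                       matched_text = substring(p, full, full + 21L),
                       stringsAsFactors = FALSE)
  } else if (gregexpr(part_re, p, perl = TRUE)[[1L]][1L] != -1L) {
    status <- "partial"
  }
  list(status = status, hits = hits)
}

#' Scan a protein for the SPP motif
#'
#' The SERK-characteristic serine-proline-proline signature; the pattern is
#' configurable because the study's exact highlighted residues are an
#' interpretation.
#'
#' @param protein amino-acid string.
#' @param pattern literal motif to search for (default `"SPP"`).
#' @return list with `present` flag and `hits` data frame (`start`,
#'   `matched_text`).
#' @export
find_spp_motif <- function(protein, pattern = "SPP") {
  p <- check_protein(protein, allow_nonstandard = TRUE)
  if (!nzchar(pattern)) stop("empty motif pattern")
  pat <- toupper(pattern)
  starts <- gregexpr(paste0("(?=", pat, ")"), p, perl = TRUE)[[1L]]
  if (starts[1L] == -1L)
    return(list(present = FALSE,
                hits = data.frame(start = integer(0),
                                  matched_text = character(0))))
  list(present = TRUE,
       hits = data.frame(start = as.integer(starts),
                         matched_text = substring(p, starts,
                                                  starts + nchar(pat) - 1L),
                         stringsAsFactors = FALSE))
}

# Net charge of the protein at a given pH under the Bjellqvist pKa set.
protein_net_charge <- function(chars, pH) {
  nterm_pka <- PKA_NTERM[chars[1L]]
  if (is.na(nterm_pka)) nterm_pka <- PKA_NTERM_DEFAULT
  pos <- 1 / (1 + 10^(pH - nterm_pka))
  for (res in c("H", "K", "R"))
    pos <- pos + sum(chars == res) / (1 + 10^(pH - PKA_SIDE[[res]]))
  neg <- 1 / (1 + 10^(PKA_CTERM - pH))
  for (res in c("D", "E", "C", "Y"))
    neg <- neg + sum(chars == res) / (1 + 10^(PKA_SIDE[[res]] - pH))
  pos - neg
}

#' ProtParam-style protein statistics
#'
#' Molecular weight is the sum of average residue masses plus one water;
#' the isoelectric point solves net charge = 0 by bisection on pH (0..14)
#' to 0.001 pH units, with the Bjellqvist pKa set (N/C termini plus
#' D, E, C, Y, H, K, R side chains).
#'
#' @param protein amino-acid string over the 20 standard residues.
#' @return list with `length` (aa), `mw` (Da) and `pi`.
#' @export
protein_stats <- function(protein) {
  p <- check_protein(protein, allow_nonstandard = FALSE)
  chars <- strsplit(p, "", fixed = TRUE)[[1L]]
  mw <- sum(AA_AVG_MASS[chars]) + WATER_MASS
  lo <- 0; hi <- 14
  while (hi - lo > 0.001) {
    mid <- (lo + hi) / 2
    if (protein_net_charge(chars, mid) > 0) lo <- mid else hi <- mid
  }
  list(length = length(chars), mw = unname(mw), pi = (lo + hi) / 2)
}
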