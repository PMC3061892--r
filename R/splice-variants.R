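# Splice-variant analysis: map clean transcripts back onto a gene model,
# classify the alternative-splicing events (whole-intron retention and
# whole-exon skipping), predict the encoded protein from the annotated start
# codon, flag premature termination codons, and group variants by protein.

#' Map a transcript onto a gene model by exact segment matching
#'
#' Greedy left-to-right matching of the transcript against the ordered
#' genomic segments (exon 1, intron 1, exon 2, ...): each exon is either
#' matched in full or skipped in full; an intron matched in full between two
#' matched exons is retained. Suitable for error-free (synthetic or curated)
#' transcripts whose variation consists of whole-intron retentions and
#' whole-exon skips.
#'
#' @param model a [gene_model()].
#' @param genome genomic sequence; defaults to the model's.
#' @param transcript_seq transcript nucleotide string.
#' @return a [transcript_structure()].
#' @export
map_transcript <- function(model, genome = model$sequence, transcript_seq) {
  if (!identical(genome, model$sequence))
    model <- gene_model(model$gene_id, model$seq_id, model$exons, genome,
                        model$strand, model$cds_start_offset)
  tx <- toupper(transcript_seq)
  p <- 1L
  kept <- integer(0)
  retained <- integer(0)
  matches_at <- function(text) {
    nchar(text) > 0L && substr(tx, p, p + nchar(text) - 1L) == text
  }
  for (i in seq_len(n_exons(model))) {
    intron_retained <- FALSE
    if (i > 1L && length(kept) && kept[length(kept)] == i - 1L) {
      itx <- intron_seq(model, i - 1L)
      if (matches_at(itx)) {
        intron_retained <- TRUE
        retained <- c(retained, i - 1L)
        p <- p + nchar(itx)
      }
    }
    etx <- exon_seq(model, i)
    if (matches_at(etx)) {
      kept <- c(kept, i)
      p <- p + nchar(etx)
    } else if (intron_retained) {
      stop("mapping error at transcript offset ", p, ": retained intron ",
           i - 1L, " is not followed by exon ", i)
    }
  }
  if (p != nchar(tx) + 1L)
    stop("mapping error at transcript offset ", p,
         ": transcript does not match any exon/intron segment arrangement")
  if (!length(kept)) stop("mapping error: no exon matched")
  transcript_structure(kept, retained)
}

#' Classify the splicing events of a transcript structure
#'
#' @param structure a [transcript_structure()].
#' @param model a [gene_model()].
#' @return list with `canonical` flag, `retained_introns`, `skipped_exons`
#'   and `events` (character labels, one per event:
#'   `intron_retention:<i>` / `exon_skipping:<i>`).
#' @export
classify <- function(structure, model) {
  check_structure(structure, model)
  skipped <- setdiff(seq_len(n_exons(model)), structure$kept_exons)
  retained <- structure$retained_introns
  list(
    canonical = length(skipped) == 0L && length(retained) == 0L,
    retained_introns = retained,
    skipped_exons = skipped,
    events = c(if (length(retained)) paste0("intron_retention:", retained),
               if (length(skipped)) paste0("exon_skipping:", skipped))
  )
}

# Genomic coordinate of transcript position `tpos` (1-based), given the
# variant's segment list.
transcript_pos_to_genomic <- function(segs, tpos) {
  off <- 0L
  for (s in segs) {
    w <- nchar(s$text)
    if (tpos <= off + w) return(s$gstart + (tpos - off - 1L))
    off <- off + w
  }
  NA_integer_
}

# Which retained intron (if any) contains genomic position gpos.
genomic_pos_intron <- function(model, structure, gpos) {
  for (i in structure$retained_introns) {
    b <- intron_bounds(model, i)
    if (gpos >= b["start"] && gpos <= b["end"]) return(i)
  }
  NA_integer_
}

#' Predict the ORF and protein of a splice variant
#'
#' Translation starts at the annotated start codon (the canonical ATG mapped
#' into the variant) and runs in frame to the first stop. A premature
#' termination codon (PTC) is a stop whose genomic position differs from the
#' canonical stop; when its first base lies inside a retained intron the
#' intron index is reported. The secondary ORF is the longest ATG-initiated
#' ORF (any frame) beginning after the primary stop.
#'
#' @param model a [gene_model()].
#' @param transcript_seq the variant transcript (as produced by [splice()]).
#' @param structure the variant's [transcript_structure()].
#' @return list with `orf` (protein string, no `*`), `protein_length`, `ptc`
#'   flag, `ptc_intron` (NA unless the stop lies in a retained intron),
#'   `secondary_orf` (protein string or NA) and `start_found` flag.
#' @export
predict_orf <- function(model, transcript_seq, structure) {
  check_structure(structure, model)
  tx <- toupper(transcript_seq)
  segs <- transcript_segments(model, structure)
  stopifnot(identical(paste(vapply(segs, `[[`, character(1), "text"),
                            collapse = ""), tx))

  # genomic position of the annotated start (offset within canonical mRNA)
  can_segs <- transcript_segments(model, canonical_structure(model))
  g_start <- transcript_pos_to_genomic(can_segs, model$cds_start_offset + 1L)
  # locate it in the variant transcript
  t_start <- NA_integer_
  off <- 0L
  for (s in segs) {
    w <- nchar(s$text)
    if (g_start >= s$gstart && g_start <= s$gstart + w - 1L) {
      t_start <- off + (g_start - s$gstart) + 1L
      break
    }
    off <- off + w
  }
  if (is.na(t_start) || substr(tx, t_start, t_start + 2L) != "ATG")
    return(list(orf = NA_character_, protein_length = NA_integer_,
                ptc = NA, ptc_intron = NA_integer_,
                secondary_orf = NA_character_, start_found = FALSE))

  aa <- translate_dna(substr(tx, t_start, nchar(tx)))
  stop_idx <- regexpr("*", aa, fixed = TRUE)
  if (stop_idx > 0) {
    orf <- substr(aa, 1L, stop_idx - 1L)
    stop_tpos <- t_start + (stop_idx - 1L) * 3L
    g_stop <- transcript_pos_to_genomic(segs, stop_tpos)
  } else {
    orf <- aa
    g_stop <- NA_integer_
  }

  # canonical stop: first stop of the canonical reading
  can_tx <- paste(vapply(can_segs, `[[`, character(1), "text"), collapse = "")
  can_aa <- translate_dna(substr(can_tx, model$cds_start_offset + 1L,
                                 nchar(can_tx)))
  can_stop_idx <- regexpr("*", can_aa, fixed = TRUE)
  g_can_stop <- if (can_stop_idx > 0)
    transcript_pos_to_genomic(can_segs,
                              model$cds_start_offset + (can_stop_idx - 1L) * 3L + 1L)
  else NA_integer_

  ptc <- !is.na(g_stop) && !is.na(g_can_stop) && g_stop != g_can_stop
  ptc_intron <- if (ptc) genomic_pos_intron(model, structure, g_stop)
  else NA_integer_

  secondary <- NA_character_
  if (stop_idx > 0) {
    after <- substr(tx, stop_tpos + 3L, nchar(tx))
    secondary <- longest_downstream_orf(after)
  }

  list(orf = orf, protein_length = nchar(orf), ptc = ptc,
       ptc_intron = ptc_intron, secondary_orf = secondary,
       start_found = TRUE)
}

# Longest ATG-initiated ORF in any frame of `x`; returns the translated
# protein (no stop) or NA when there is none. An ORF must terminate at an
# in-frame stop within the sequence.
longest_downstream_orf <- function(x) {
  best <- NA_character_
  starts <- gregexpr("ATG", x, fixed = TRUE)[[1L]]
  if (starts[1L] == -1L) return(best)
  for (s in starts) {
    aa <- translate_dna(substr(x, s, nchar(x)))
    k <- regexpr("*", aa, fixed = TRUE)
    if (k > 0) {
      prot <- substr(aa, 1L, k - 1L)
      if (is.na(best) || nchar(prot) > nchar(best)) best <- prot
    }
  }
  best
}

#' Full report for one splice variant
#'
#' Convenience wrapper running [map_transcript()], [classify()] and
#' [predict_orf()].
#'
#' @param model a [gene_model()].
#' @param transcript_seq variant transcript string.
#' @param variant_id label used in reports.
#' @return list (class `serk_variant_report`) combining structure,
#'   classification and ORF fields.
#' @export
variant_report <- function(model, transcript_seq, variant_id = "variant") {
  structure_ <- map_transcript(model, transcript_seq = transcript_seq)
  cls <- classify(structure_, model)
  orf <- predict_orf(model, transcript_seq, structure_)
  structure(c(list(variant_id = variant_id, structure = structure_), cls, orf),
            class = "serk_variant_report")
}

#' Group variant reports by identical predicted protein
#'
#' @param reports list of [variant_report()] results (or any lists with
#'   `variant_id` and `orf` fields).
#' @return list with `groups` (list of variant-id vectors) and `n_distinct`.
#' @export
group_by_protein <- function(reports) {
  stopifnot(length(reports) >= 1L)
  prot <- vapply(reports, function(r) {
    if (is.na(r$orf)) paste0("<no-orf:", r$variant_id, ">") else r$orf
  }, character(1))
  ids <- vapply(reports, `[[`, character(1), "variant_id")
  groups <- split(ids, factor(prot, levels = unique(prot)))
  names(groups) <- paste0("protein_group_", seq_along(groups))
  list(groups = groups, n_distinct = length(groups))
}

#' Tabulate variant reports
#'
#' @param reports list of [variant_report()] results.
#' @return data frame, one row per variant: events, protein length (aa),
#'   PTC flag and intron, protein group id.
#' @export
variant_table <- function(reports) {
  grouping <- group_by_protein(reports)
  gid <- setNames(rep(names(grouping$groups),
                      lengths(grouping$groups)),
                  unlist(grouping$groups, use.names = FALSE))
  data.frame(
    variant_id = vapply(reports, `[[`, character(1), "variant_id"),
    canonical = vapply(reports, `[[`, logical(1), "canonical"),
    retained_introns = vapply(reports, function(r)
      paste(r$retained_introns, collapse = ";"), character(1)),
    skipped_exons = vapply(reports, function(r)
      paste(r$skipped_exons, collapse = ";"), character(1)),
    protein_length_aa = vapply(reports, `[[`, integer(1), "protein_length"),
    ptc = vapply(reports, `[[`, logical(1), "ptc"),
    ptc_intron = vapply(reports, `[[`, integer(1), "ptc_intron"),
    protein_group = unname(gid[vapply(reports, `[[`, character(1),
                                      "variant_id")]),
    stringsAsFactors = FALSE)
}
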