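# Gene-model handling: FASTA/GFF3 I/O, validation, intron extraction,
# transcript splicing and tandem-cluster geometry.
#
# Conventions: externally (FASTA/GFF3) coordinates are 1-based inclusive per
# the GFF3 standard; internally exon tables keep that representation and all
# arithmetic is done on it (conversion is isolated here). Intron i is the gap
# between exon i and exon i+1, so "intron 5" precedes exon 6. Minus-strand
# genes are normalised at load (sequence reverse-complemented, coordinates
# remapped) so every downstream module is strand-free.

#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are uppercased on read and validated against the IUPAC
#' nucleotide alphabet; softmasked (lowercase) input is accepted.
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase sequences, one per record,
#'   in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("not a readable FASTA file: ", path, " (",
                             conditionMessage(e), ")")
  )
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  for (i in seq_along(seqs)) {
    bad <- regmatches(seqs[[i]], regexpr(paste0("[^", paste(IUPAC_CODES, collapse = ""), "]"),
                                         seqs[[i]]))
    if (length(bad) && nzchar(bad))
      stop("record '", ids[[i]], "' contains non-IUPAC character '", bad, "'")
    if (!nzchar(seqs[[i]])) stop("record '", ids[[i]], "' has an empty sequence")
  }
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct and validate a gene model
#'
#' @param gene_id,seq_id identifiers.
#' @param exons two-column matrix (start, end) of exon coordinates, 1-based
#'   inclusive on the (normalised) genomic sequence, sorted ascending.
#' @param sequence the genomic sequence the coordinates refer to, already
#'   strand-normalised (the gene reads left to right).
#' @param strand original strand annotation, `"+"` or `"-"`; informational
#'   after normalisation.
#' @param cds_start_offset 0-based offset of the ATG within the spliced
#'   canonical transcript.
#' @return an object of class `serk_gene_model`.
#' @export
gene_model <- function(gene_id, seq_id, exons, sequence, strand = "+",
                       cds_start_offset = 0L) {
  exons <- matrix(as.integer(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L) stop("gene '", gene_id, "': needs at least one exon")
  if (any(exons[, "start"] > exons[, "end"]))
    stop("gene '", gene_id, "': exon start > end")
  if (is.unsorted(exons[, "start"], strictly = TRUE))
    stop("gene '", gene_id, "': exons not sorted ascending")
  if (nrow(exons) > 1L) {
    gaps <- exons[-1L, "start"] - exons[-nrow(exons), "end"] - 1L
    if (any(gaps < 1L))
      stop("gene '", gene_id, "': overlapping exons or zero-length intron ",
           "(intron ", which(gaps < 1L)[1L], ")")
  }
  if (min(exons) < 1L || max(exons) > nchar(sequence))
    stop("gene '", gene_id, "': exon outside sequence bounds (length ",
         nchar(sequence), ")")
  structure(
    list(gene_id = gene_id, seq_id = seq_id, strand = strand,
         exons = exons, sequence = toupper(sequence),
         cds_start_offset = as.integer(cds_start_offset)),
    class = "serk_gene_model"
  )
}

#' @export
print.serk_gene_model <- function(x, ...) {
  cat("Gene model", x$gene_id, "on", x$seq_id, paste0("(", x$strand, ")"),
      "\n  exons:", nrow(x$exons),
      " introns:", nrow(x$exons) - 1L,
      " span:", x$exons[1L, 1L], "-", x$exons[nrow(x$exons), 2L], "nt\n")
  invisible(x)
}

n_exons <- function(model) nrow(model$exons)
n_introns <- function(model) nrow(model$exons) - 1L

exon_seq <- function(model, i) {
  substr(model$sequence, model$exons[i, "start"], model$exons[i, "end"])
}

intron_bounds <- function(model, i) {
  c(start = unname(model$exons[i, "end"]) + 1L,
    end = unname(model$exons[i + 1L, "start"]) - 1L)
}

intron_seq <- function(model, i) {
  b <- intron_bounds(model, i)
  substr(model$sequence, b["start"], b["end"])
}

#' Read gene models from a GFF3 file
#'
#' Expects gene/mRNA/exon features with standard `ID`/`Parent` attributes and
#' 1-based inclusive coordinates. One model is returned per mRNA. Minus-strand
#' genes are normalised on load: the chromosome sequence is
#' reverse-complemented and exon coordinates remapped, so that every returned
#' model reads left to right and downstream logic is strand-free.
#'
#' @param gff_path path to a GFF3 file.
#' @param sequences named character vector of genomic sequences (e.g. from
#'   [read_fasta()]).
#' @return named list of [gene_model()] objects, one per mRNA.
#' @export
read_gff3 <- function(gff_path, sequences) {
  if (!file.exists(gff_path)) stop("GFF3 file not found: ", gff_path)
  gr <- rtracklayer::import(gff_path, format = "gff3")
  meta <- S4Vectors::mcols(gr)
  type <- as.character(meta$type)
  mrnas <- which(type == "mRNA")
  if (!length(mrnas)) stop("no mRNA features in ", gff_path)
  exn <- which(type == "exon")
  exon_parent <- vapply(meta$Parent[exn], function(p) {
    if (!length(p)) stop("exon without a Parent attribute in ", gff_path)
    as.character(p[[1L]])
  }, character(1))
  cds <- which(type == "CDS")
  cds_parent <- if (length(cds))
    vapply(meta$Parent[cds], function(p) as.character(p[[1L]]), character(1))
  else character(0)

  models <- list()
  for (k in mrnas) {
    mid <- as.character(meta$ID[k])
    chrom <- as.character(GenomicRanges::seqnames(gr)[k])
    if (!chrom %in% names(sequences))
      stop("mRNA '", mid, "' refers to unknown sequence '", chrom, "'")
    chrom_seq <- sequences[[chrom]]
    strand <- as.character(BiocGenerics::strand(gr)[k])
    mine <- exn[exon_parent == mid]
    if (!length(mine)) stop("mRNA '", mid, "' has no exon children")
    st <- GenomicRanges::start(gr)[mine]
    en <- GenomicRanges::end(gr)[mine]
    if (max(en) > nchar(chrom_seq) || min(st) < 1L)
      stop("mRNA '", mid, "': exon outside sequence '", chrom,
           "' (length ", nchar(chrom_seq), ")")
    o <- order(st)
    st <- st[o]; en <- en[o]
    seq_use <- chrom_seq
    if (strand == "-") {
      # remap onto the reverse complement so the gene reads left to right
      L <- nchar(chrom_seq)
      new_st <- L - en + 1L
      new_en <- L - st + 1L
      o2 <- order(new_st)
      st <- new_st[o2]; en <- new_en[o2]
      seq_use <- revcomp(chrom_seq)
    }
    cds_off <- 0L
    mycds <- if (length(cds)) cds[cds_parent == mid] else integer(0)
    if (length(mycds)) {
      cs <- GenomicRanges::start(gr)[mycds]; ce <- GenomicRanges::end(gr)[mycds]
      first <- if (strand == "-") nchar(chrom_seq) - max(ce) + 1L else min(cs)
      # offset of the CDS start within the spliced transcript
      off <- 0L
      for (i in seq_along(st)) {
        if (first >= st[i] && first <= en[i]) { off <- off + (first - st[i]); break }
        off <- off + (en[i] - st[i] + 1L)
      }
      cds_off <- off
    }
    models[[mid]] <- gene_model(mid, chrom, cbind(st, en), seq_use,
                                strand = strand, cds_start_offset = cds_off)
  }
  models
}

#' Write gene models to a GFF3 file
#'
#' Emits gene/mRNA/exon (and optionally CDS-start-bearing) features on the
#' plus strand of the normalised sequence, suitable for round-tripping with
#' [read_gff3()].
#'
#' @param models list of [gene_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (m in models) {
    span <- c(m$exons[1L, 1L], m$exons[nrow(m$exons), 2L])
    gid <- paste0(m$gene_id, ".gene")
    lines <- c(lines,
      sprintf("%s\tserkdup\tgene\t%d\t%d\t.\t+\t.\tID=%s", m$seq_id,
              span[1L], span[2L], gid),
      sprintf("%s\tserkdup\tmRNA\t%d\t%d\t.\t+\t.\tID=%s;Parent=%s", m$seq_id,
              span[1L], span[2L], m$gene_id, gid))
    for (i in seq_len(nrow(m$exons))) {
      lines <- c(lines,
        sprintf("%s\tserkdup\texon\t%d\t%d\t.\t+\t.\tID=%s.exon%d;Parent=%s",
                m$seq_id, m$exons[i, 1L], m$exons[i, 2L], m$gene_id, i,
                m$gene_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Extract intron sequences from a gene model
#'
#' Intron i is the genomic text strictly between exon i and exon i+1.
#'
#' @param model a [gene_model()].
#' @param sequence genomic sequence; defaults to the one stored in the model.
#' @return named character vector `intron_1 .. intron_{n-1}` (empty for a
#'   single-exon model).
#' @export
extract_introns <- function(model, sequence = model$sequence) {
  stopifnot(inherits(model, "serk_gene_model"))
  if (!identical(sequence, model$sequence))
    model <- gene_model(model$gene_id, model$seq_id, model$exons, sequence,
                        model$strand, model$cds_start_offset)
  k <- n_introns(model)
  if (k == 0L) return(setNames(character(0), character(0)))
  out <- vapply(seq_len(k), function(i) intron_seq(model, i), character(1))
  names(out) <- paste0("intron_", seq_len(k))
  out
}

#' Describe a transcript as kept exons plus retained introns
#'
#' @param kept_exons strictly increasing exon indices present in the
#'   transcript.
#' @param retained_introns intron indices retained in the mature transcript;
#'   retaining intron i requires exons i and i+1 both kept.
#' @return an object of class `serk_transcript_structure`.
#' @export
transcript_structure <- function(kept_exons, retained_introns = integer(0)) {
  kept_exons <- as.integer(kept_exons)
  retained_introns <- as.integer(retained_introns)
  if (!length(kept_exons) || is.unsorted(kept_exons, strictly = TRUE))
    stop("kept_exons must be non-empty and strictly increasing")
  for (i in retained_introns) {
    if (!(i %in% kept_exons) || !((i + 1L) %in% kept_exons))
      stop("retained intron ", i, " requires exons ", i, " and ", i + 1L,
           " both kept")
  }
  structure(list(kept_exons = kept_exons,
                 retained_introns = sort(retained_introns)),
            class = "serk_transcript_structure")
}

#' Canonical structure (all exons, no retained introns) for a model
#' @param model a [gene_model()].
#' @return a [transcript_structure()].
#' @export
canonical_structure <- function(model) {
  transcript_structure(seq_len(n_exons(model)))
}

check_structure <- function(structure, model) {
  stopifnot(inherits(structure, "serk_transcript_structure"))
  if (max(structure$kept_exons) > n_exons(model))
    stop("structure refers to exon ", max(structure$kept_exons),
         " but model has ", n_exons(model))
  invisible(structure)
}

# Ordered (type, index, genomic start, text) segments making up a transcript.
transcript_segments <- function(model, structure) {
  check_structure(structure, model)
  segs <- list()
  kept <- structure$kept_exons
  for (i in kept) {
    segs[[length(segs) + 1L]] <- list(
      type = "exon", index = i,
      gstart = model$exons[i, "start"], text = exon_seq(model, i))
    if (i %in% structure$retained_introns) {
      b <- intron_bounds(model, i)
      segs[[length(segs) + 1L]] <- list(
        type = "intron", index = i,
        gstart = unname(b["start"]), text = intron_seq(model, i))
    }
  }
  segs
}

#' Splice a transcript from a gene model
#'
#' Concatenates, in genomic order, the kept exon texts with each retained
#' intron's text inserted between its flanking exons.
#'
#' @param model a [gene_model()].
#' @param sequence genomic sequence; defaults to the model's.
#' @param structure a [transcript_structure()]; default canonical.
#' @return transcript nucleotide string.
#' @export
splice <- function(model, sequence = model$sequence,
                   structure = canonical_structure(model)) {
  if (!identical(sequence, model$sequence))
    model <- gene_model(model$gene_id, model$seq_id, model$exons, sequence,
                        model$strand, model$cds_start_offset)
  segs <- transcript_segments(model, structure)
  paste(vapply(segs, `[[`, character(1), "text"), collapse = "")
}

#' Span and geometry of a tandem gene cluster
#'
#' @param gene_positions two-column numeric matrix or data frame of
#'   (start, end) positions in kbp, one row per gene; row names are gene
#'   names when available.
#' @return list with `span_kb` (max(end) - min(start), rounded to the nearest
#'   integer kb), `gene_order` (names sorted by start) and `gaps_kb`
#'   (inter-gene gaps, end of one gene to start of the next; negative values
#'   indicate overlap and raise a warning).
#' @export
tandem_cluster_span <- function(gene_positions) {
  pos <- as.matrix(gene_positions)
  if (nrow(pos) < 2L) stop("need at least two genes")
  if (!is.numeric(pos)) stop("positions must be numeric")
  starts <- pos[, 1L]; ends <- pos[, 2L]
  nm <- rownames(pos)
  if (is.null(nm)) nm <- paste0("gene", seq_len(nrow(pos)))
  o <- order(starts)
  gaps <- starts[o][-1L] - ends[o][-length(o)]
  if (any(gaps < 0))
    warning("overlapping genes: ",
            paste(nm[o][which(gaps < 0)], nm[o][which(gaps < 0) + 1L],
                  sep = "/", collapse = ", "))
  list(span_kb = round(max(ends) - min(starts)),
       gene_order = nm[o],
       gaps_kb = setNames(gaps, paste(nm[o][-length(o)], nm[o][-1L], sep = "..")))
}
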