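# Seeded synthetic-data generators. Each generator emulates the statistical
# structure one analysis stage assumes: a tandem family descending from timed
# duplication events under a Jukes-Cantor clock; an 11-exon SERK-like gene
# with the seven observed splice variants; and exponential/logistic qPCR
# amplification curves with known efficiency. All are byte-reproducible
# under a fixed seed.

# One Jukes-Cantor step of duration dt years at rate mu: with probability
# 1 - exp(-4*mu*dt/3) a site is resampled uniformly over the four bases, so
# the probability of an observed change is (3/4)(1 - exp(-4*mu*dt/3)) ~ mu*dt
# and the expected pairwise p-distance of two lineages separated by time T
# tends to 2*mu*T at shallow divergence.
jc_evolve <- function(seqs, dt, mu) {
  p_resample <- 1 - exp(-4 * mu * dt / 3)
  lapply(seqs, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1L]]
    hit <- runif(length(chars)) < p_resample
    if (any(hit))
      chars[hit] <- sample(c("A", "C", "G", "T"), sum(hit), replace = TRUE)
    paste(chars, collapse = "")
  })
}

apply_deletions <- function(seqs, dt, indel_rate, mean_len = 3) {
  if (indel_rate <= 0) return(seqs)
  lapply(seqs, function(s) {
    n_ev <- rpois(1L, indel_rate * nchar(s) * dt)
    for (k in seq_len(n_ev)) {
      if (nchar(s) < 10L) break
      len <- rgeom(1L, 1 / mean_len) + 1L
      pos <- sample.int(nchar(s) - len, 1L)
      s <- paste0(substr(s, 1L, pos - 1L), substr(s, pos + len, nchar(s)))
    }
    s
  })
}

#' Simulate a tandem gene family from timed duplication events
#'
#' A caterpillar genealogy: the oldest event splits off `gene1`, the next
#' `gene2`, and so on; the final event yields the last two genes. Ancestral
#' introns are uniform random nucleotides; each lineage evolves by
#' Jukes-Cantor substitution at rate `mu`, with optional deletion events.
#' The expected pairwise age of `gene_i` and `gene_j` equals
#' `event_times[min(i, j)]`.
#'
#' @param event_times duplication times in years, sorted descending
#'   (default the four inferred SERK-cluster events: 3.25, 3.05, 2.65 and
#'   2.2 Myr). An empty vector yields a single gene.
#' @param mu substitution rate per site per year (default 3e-10).
#' @param n_introns introns per gene (default 10).
#' @param intron_length_range introns are drawn uniform in this range
#'   (default 400..1600 nt).
#' @param indel_rate deletion events per site per year (default 0; the clock
#'   signal is substitutional).
#' @param seed RNG seed; the output is byte-reproducible given
#'   (arguments, seed).
#' @return list with `genes` (named list of intron-sequence vectors),
#'   `truth` (event times, mu, expected age matrix, seed).
#' @export
simulate_duplication_history <- function(event_times = c(3.25e6, 3.05e6,
                                                         2.65e6, 2.2e6),
                                         mu = 3e-10, n_introns = 10L,
                                         intron_length_range = c(400L, 1600L),
                                         indel_rate = 0, seed = 1L) {
  if (any(event_times < 0) || mu <= 0 || indel_rate < 0)
    stop("rates and times must be non-negative (mu > 0)")
  if (is.unsorted(rev(event_times)))
    stop("event_times must be sorted descending (oldest first)")
  with_seed(seed, {
    lens <- sample(seq(intron_length_range[1L], intron_length_range[2L]),
                   n_introns, replace = TRUE)
    anc <- lapply(lens, random_dna)
    n_ev <- length(event_times)
    genes <- list()
    if (n_ev == 0L) {
      genes[["gene1"]] <- unlist(anc)
    } else {
      state <- anc  # ancestral state at the oldest event
      for (k in seq_len(n_ev)) {
        leaf <- jc_evolve(state, event_times[k], mu)
        leaf <- apply_deletions(leaf, event_times[k], indel_rate)
        genes[[paste0("gene", k)]] <- unlist(leaf)
        if (k < n_ev)
          state <- jc_evolve(state, event_times[k] - event_times[k + 1L], mu)
      }
      last <- jc_evolve(state, event_times[n_ev], mu)
      last <- apply_deletions(last, event_times[n_ev], indel_rate)
      genes[[paste0("gene", n_ev + 1L)]] <- unlist(last)
    }
    n_g <- length(genes)
    expected <- matrix(0, n_g, n_g,
                       dimnames = list(names(genes), names(genes)))
    if (n_g > 1L)
      for (i in seq_len(n_g - 1L))
        for (j in seq(i + 1L, n_g))
          expected[i, j] <- expected[j, i] <- event_times[min(i, j)]
    list(genes = genes,
         truth = list(event_times = event_times, mu = mu,
                      expected_age_matrix = expected,
                      intron_lengths = lens, seed = seed))
  })
}

# Fixed CDS exon lengths (nt) of the synthetic 11-exon SERK-like gene; all
# multiples of 3 so exon boundaries are codon boundaries, with exon 3 = 72 nt
# (24 aa) so skipping it preserves frame.
SV_EXON_LENGTHS <- c(150L, 150L, 72L, 75L, 75L, 96L, 96L, 96L, 300L, 300L,
                     351L)

#' Synthetic splice-variant fixture: an 11-exon gene and its seven variants
#'
#' Builds a SERK-like gene whose canonical CDS is 1761 nt (586 aa + stop).
#' Exon 1 begins with the annotated ATG and exon 11 ends in the canonical
#' stop. Intron 5 opens with four non-stop codons then TGA; intron 8 opens
#' with one non-stop codon then TAA — so retaining either intron introduces
#' an in-frame premature stop. Exon and intron bodies are drawn from codons
#' excluding stops and ATG, and exon 9 opens with a planted ATG, making the
#' downstream "second transcript" start deterministic. The seven transcripts
#' mirror the observed variant structures: SV1 canonical; SV2 retains intron
#' 8; SV3 skips exon 3; SV4 skips exon 3 and retains intron 8; SV5 skips
#' exon 3 and retains introns 5 and 6; SV6 skips exon 3 and retains introns
#' 5 and 8; SV7 skips exon 3 and retains intron 5.
#'
#' @param seed RNG seed.
#' @param flank length of random genomic flank either side of the gene.
#' @return list with `model` (a [gene_model()]), `genome` (named sequence
#'   vector), `transcripts` (named SV1..SV7 character vector), `structures`
#'   (named list of [transcript_structure()]) and `truth` (planted stop
#'   introns and expected protein lengths).
#' @export
make_sv_fixture <- function(seed = 1L, flank = 50L) {
  with_seed(seed, {
    body_alpha <- codon_alphabet(exclude_stops = TRUE, exclude_atg = TRUE)
    exons <- character(11L)
    for (i in 1:11) {
      n_cod <- SV_EXON_LENGTHS[i] / 3L
      body <- random_codons(n_cod, body_alpha)
      if (i == 1L) body <- paste0("ATG", substr(body, 4L, nchar(body)))
      if (i == 9L) body <- paste0("ATG", substr(body, 4L, nchar(body)))
      if (i == 11L)
        body <- paste0(substr(body, 1L, nchar(body) - 3L), "TAA")
      exons[i] <- body
    }
    intron_len <- 3L * sample(20:40, 10L, replace = TRUE)
    introns <- vapply(seq_len(10L), function(i) {
      n_cod <- intron_len[i] / 3L
      body <- random_codons(n_cod, body_alpha)
      if (i == 5L)
        body <- paste0(random_codons(4L, body_alpha), "TGA",
                       substr(body, 16L, nchar(body)))
      if (i == 8L)
        body <- paste0(random_codons(1L, body_alpha), "TAA",
                       substr(body, 7L, nchar(body)))
      body
    }, character(1))

    pieces <- character(0)
    starts <- integer(11L)
    pos <- flank + 1L
    for (i in 1:11) {
      starts[i] <- pos
      pieces <- c(pieces, exons[i])
      pos <- pos + nchar(exons[i])
      if (i < 11L) {
        pieces <- c(pieces, introns[i])
        pos <- pos + nchar(introns[i])
      }
    }
    genome_seq <- paste0(random_dna(flank), paste(pieces, collapse = ""),
                         random_dna(flank))
    ex <- cbind(starts, starts + SV_EXON_LENGTHS - 1L)
    model <- gene_model("MtSERK3like", "chr_synthetic", ex, genome_seq,
                        strand = "+", cds_start_offset = 0L)
    structures <- list(
      SV1 = transcript_structure(1:11),
      SV2 = transcript_structure(1:11, retained_introns = 8L),
      SV3 = transcript_structure(c(1:2, 4:11)),
      SV4 = transcript_structure(c(1:2, 4:11), retained_introns = 8L),
      SV5 = transcript_structure(c(1:2, 4:11), retained_introns = c(5L, 6L)),
      SV6 = transcript_structure(c(1:2, 4:11), retained_introns = c(5L, 8L)),
      SV7 = transcript_structure(c(1:2, 4:11), retained_introns = 5L))
    transcripts <- vapply(structures, function(st) splice(model, structure = st),
                          character(1))
    list(model = model,
         genome = setNames(genome_seq, "chr_synthetic"),
         transcripts = transcripts,
         structures = structures,
         truth = list(
           stop_intron = c(SV1 = NA, SV2 = 8L, SV3 = NA, SV4 = 8L, SV5 = 5L,
                           SV6 = 5L, SV7 = 5L),
           protein_lengths = c(SV1 = 586L, SV2 = 271L, SV3 = 562L,
                               SV4 = 247L, SV5 = 154L, SV6 = 154L,
                               SV7 = 154L),
           seed = seed))
  })
}

#' Write an SV fixture to FASTA + GFF3 + transcript FASTA files
#'
#' @param fixture output of [make_sv_fixture()].
#' @param dir output directory (created if needed).
#' @return named character vector of the three file paths.
#' @export
sv_fixture_files <- function(fixture, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genome_fa <- file.path(dir, "genome.fasta")
  gff <- file.path(dir, "gene_models.gff3")
  tx_fa <- file.path(dir, "transcripts.fasta")
  write_fasta(fixture$genome, genome_fa)
  write_gff3(list(fixture$model), gff)
  write_fasta(fixture$transcripts, tx_fa)
  c(genome = genome_fa, gff3 = gff, transcripts = tx_fa)
}

#' Simulate a qPCR amplification curve with known efficiency
#'
#' Logistic-saturating model F_c = plateau / (1 + (plateau/F0 - 1) E^-c),
#' which is exponential (F0 * E^c) while far below the plateau, plus
#' optional multiplicative Gaussian noise.
#'
#' @param E_true per-cycle amplification factor, in `[1, 2.2]`.
#' @param F0 initial template signal.
#' @param n_cycles number of cycles (curve covers 1..n_cycles).
#' @param plateau saturation fluorescence.
#' @param noise_sd multiplicative noise standard deviation (0 = noiseless).
#' @param seed RNG seed (only used when `noise_sd > 0`).
#' @param well_id label attached to the curve.
#' @return list with `well_id`, `cycles`, `fluorescence`.
#' @export
simulate_qpcr <- function(E_true = 1.9, F0 = 1e-6, n_cycles = 40L,
                          plateau = 100, noise_sd = 0, seed = 1L,
                          well_id = "well1") {
  if (E_true < 1 || E_true > 2.2) stop("E_true must be in [1, 2.2]")
  if (F0 <= 0 || plateau <= F0 || n_cycles < 8L || noise_sd < 0)
    stop("invalid curve parameters")
  cycles <- seq_len(n_cycles)
  f <- plateau / (1 + (plateau / F0 - 1) * E_true^(-cycles))
  if (noise_sd > 0)
    f <- with_seed(seed, f * (1 + rnorm(n_cycles, 0, noise_sd)))
  f <- pmax(f, 0)
  list(well_id = well_id, cycles = cycles, fluorescence = f)
}

#' Simulate a Ct table with planted fold-changes
#'
#' Inverse of the Pfaffl computation: given per-gene fold-changes at each
#' timepoint (relative to the calibrator), Ct values are constructed so that
#' [timecourse_expression()] recovers the planted fold-changes exactly when
#' `noise_sd = 0`.
#'
#' @param fold_changes matrix (genes x timepoints) of planted expression
#'   ratios; the calibrator column must be 1.
#' @param efficiency shared amplification factor E (default 2).
#' @param reference_gene name for the constant reference gene row added to
#'   the table.
#' @param n_repeats biological repeats per cell (default 3).
#' @param base_ct calibrator Ct for every target gene.
#' @param ref_ct Ct of the reference gene (constant).
#' @param noise_sd additive Gaussian Ct noise.
#' @param seed RNG seed (only used when `noise_sd > 0`).
#' @return list with `ct_table` (data frame gene/timepoint/repeat_id/ct) and
#'   `efficiencies` (named vector, ready for [timecourse_expression()]).
#' @export
simulate_ct_table <- function(fold_changes, efficiency = 2,
                              reference_gene = "GAPDH", n_repeats = 3L,
                              base_ct = 25, ref_ct = 18, noise_sd = 0,
                              seed = 1L) {
  genes <- rownames(fold_changes)
  tps <- colnames(fold_changes)
  stopifnot(!is.null(genes), !is.null(tps), all(fold_changes > 0))
  rows <- NULL
  with_seed(if (noise_sd > 0) seed else NULL, {
    for (g in genes) {
      for (tp in tps) {
        # ratio = E^(ct_cal - ct) with a constant reference
        ct <- base_ct - log(fold_changes[g, tp], base = efficiency)
        for (r in seq_len(n_repeats)) {
          noise <- if (noise_sd > 0) rnorm(1L, 0, noise_sd) else 0
          rows <- rbind(rows, data.frame(
            gene = g, timepoint = tp, repeat_id = paste0("rep", r),
            ct = ct + noise, stringsAsFactors = FALSE))
        }
      }
    }
    for (tp in tps) {
      for (r in seq_len(n_repeats)) {
        rows <- rbind(rows, data.frame(
          gene = reference_gene, timepoint = tp,
          repeat_id = paste0("rep", r), ct = ref_ct,
          stringsAsFactors = FALSE))
      }
    }
  })
  effs <- setNames(rep(efficiency, length(genes) + 1L),
                   c(genes, reference_gene))
  list(ct_table = rows, efficiencies = effs)
}
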