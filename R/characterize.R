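# Composed pipeline: gene-model validation -> intron extraction -> pairwise
# dating -> event inference, with optional splice-variant and qPCR stages.
# The effective configuration (every switchable design decision) is echoed
# into the output bundle for provenance.

#' Pipeline configuration
#'
#' Collects every tunable setting of the composed pipeline. Unknown keys are
#' rejected. The object is serialisable to/from a single JSON document.
#'
#' @param alignment an [alignment_params()].
#' @param clock a [clock_config()].
#' @param spp_pattern motif pattern for [find_spp_motif()].
#' @param calibrator_timepoint,reference_gene qPCR options.
#' @param seed RNG seed for any stochastic stage.
#' @return object of class `serk_pipeline_config`.
#' @export
pipeline_config <- function(alignment = alignment_params(),
                            clock = clock_config(),
                            spp_pattern = "SPP",
                            calibrator_timepoint = "week0",
                            reference_gene = "GAPDH",
                            seed = 1L) {
  structure(list(alignment = alignment, clock = clock,
                 spp_pattern = spp_pattern,
                 calibrator_timepoint = calibrator_timepoint,
                 reference_gene = reference_gene, seed = seed),
            class = "serk_pipeline_config")
}

#' Serialise / restore a pipeline configuration as JSON
#'
#' @param config a [pipeline_config()].
#' @param path JSON file path.
#' @return `config_to_json` returns `path` invisibly; `config_from_json`
#'   returns a `serk_pipeline_config`.
#' @export
config_to_json <- function(config, path) {
  stopifnot(inherits(config, "serk_pipeline_config"))
  plain <- list(alignment = unclass(config$alignment),
                clock = unclass(config$clock),
                spp_pattern = config$spp_pattern,
                calibrator_timepoint = config$calibrator_timepoint,
                reference_gene = config$reference_gene,
                seed = config$seed)
  jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname config_to_json
#' @export
config_from_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("alignment", "clock", "spp_pattern", "calibrator_timepoint",
             "reference_gene", "seed")
  extra <- setdiff(names(x), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  pipeline_config(
    alignment = do.call(alignment_params, x$alignment),
    clock = do.call(clock_config, x$clock),
    spp_pattern = x$spp_pattern %||% "SPP",
    calibrator_timepoint = x$calibrator_timepoint %||% "week0",
    reference_gene = x$reference_gene %||% "GAPDH",
    seed = x$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the composed characterisation pipeline
#'
#' Validates gene models against the genome, extracts introns, dates every
#' gene pair, infers the duplication-event history, and optionally analyses
#' splice variants and a qPCR Ct table. Writes TSV/JSON/Newick outputs into
#' `out_dir` and returns the bundle invisibly.
#'
#' @param config a [pipeline_config()].
#' @param gff,fasta paths to the gene models and genome.
#' @param transcripts optional FASTA of variant transcripts; every
#'   transcript is mapped against the first gene model.
#' @param ct_table optional TSV (gene, timepoint, repeat_id, ct) plus a
#'   `efficiencies` named vector for the qPCR stage.
#' @param efficiencies named per-gene efficiency vector (needed with
#'   `ct_table`).
#' @param out_dir output directory.
#' @return list with `age_matrix`, `history`, `variants` (or NULL),
#'   `expression` (or NULL) and the paths written.
#' @export
run_characterize <- function(config = pipeline_config(), gff, fasta,
                             transcripts = NULL, ct_table = NULL,
                             efficiencies = NULL, out_dir = tempfile("serk_")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(config = file.path(out_dir, "config.json"))
  config_to_json(config, paths[["config"]])

  seqs <- read_fasta(fasta)
  models <- read_gff3(gff, seqs)
  introns <- lapply(models, extract_introns)
  n_int <- vapply(introns, length, integer(1))

  age_matrix <- NULL; history <- NULL
  if (length(models) >= 2L && length(unique(n_int)) == 1L && n_int[[1L]] > 0L) {
    age_matrix <- pairwise_age_matrix(introns, config$alignment, config$clock)
    history <- infer_events(age_matrix)
    paths[["ages"]] <- file.path(out_dir, "age_matrix.tsv")
    write.table(data.frame(gene = rownames(age_matrix), age_matrix,
                           check.names = FALSE),
                paths[["ages"]], sep = "\t", quote = FALSE, row.names = FALSE)
    paths[["events"]] <- file.path(out_dir, "events.tsv")
    write.table(history$events, paths[["events"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths[["newick"]] <- file.path(out_dir, "history.nwk")
    writeLines(to_newick(history), paths[["newick"]])
  }

  variants <- NULL
  if (!is.null(transcripts)) {
    tx <- read_fasta(transcripts)
    model <- models[[1L]]
    reports <- lapply(names(tx), function(id)
      variant_report(model, tx[[id]], id))
    variants <- variant_table(reports)
    paths[["variants"]] <- file.path(out_dir, "variants.tsv")
    write.table(variants, paths[["variants"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  expression <- NULL
  if (!is.null(ct_table)) {
    tab <- if (is.character(ct_table)) read.delim(ct_table) else ct_table
    expression <- timecourse_expression(tab, efficiencies,
                                        config$reference_gene,
                                        config$calibrator_timepoint)
    paths[["expression"]] <- file.path(out_dir, "expression.tsv")
    write.table(expression, paths[["expression"]], sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  invisible(list(age_matrix = age_matrix, history = history,
                 variants = variants, expression = expression,
                 paths = paths, out_dir = out_dir))
}
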