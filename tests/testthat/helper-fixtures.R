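# Shared test helpers. The splice-variant fixture is deterministic given the
# seed and moderately expensive, so it is built once per test run.

sv_fixture_cached <- local({
  fx <- NULL
  function() {
    if (is.null(fx)) fx <<- make_sv_fixture(seed = 1L)
    fx
  }
})

sv_reports_cached <- local({
  reps <- NULL
  function() {
    if (is.null(reps)) {
      fx <- sv_fixture_cached()
      reps <<- lapply(names(fx$transcripts), function(id)
        variant_report(fx$model, fx$transcripts[[id]], id))
    }
    reps
  }
})

random_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = "")

# Build a minimal alignment-like object from two aligned strings, classifying
# columns the same way global_align() does; used to feed count_mutations()
# with hand-constructed alignments.
aligned_pair <- function(aligned_a, aligned_b) {
  ca <- strsplit(aligned_a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(aligned_b, "", fixed = TRUE)[[1L]]
  stopifnot(length(ca) == length(cb))
  classes <- ifelse(ca == "-", "gap_a",
             ifelse(cb == "-", "gap_b",
             ifelse(ca == cb & ca != "N", "match", "mismatch")))
  list(aligned_a = aligned_a, aligned_b = aligned_b, column_classes = classes)
}

write_temp_fasta <- function(seqs, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "seqs.fasta")
  writeLines(unlist(lapply(names(seqs), function(id)
    c(paste0(">", id), seqs[[id]]))), path)
  path
}
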