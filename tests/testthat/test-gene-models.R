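test_that("read_fasta parses records in order, uppercases, and validates", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "a.fasta")

  writeLines(c(">a", "acgt"), path)
  seqs <- read_fasta(path)
  expect_identical(seqs, c(a = "ACGT"))

  writeLines(c(">a", "ACGT", ">b desc text", "TTNN", "ACGT"), path)
  seqs <- read_fasta(path)
  expect_identical(names(seqs), c("a", "b"))
  expect_identical(unname(seqs[2]), "TTNNACGT")

  writeLines(c(">a", "ACGX"), path)
  expect_error(read_fasta(path), "X")

  writeLines(c(">a", "ACGT", ">a", "GGGG"), path)
  expect_error(read_fasta(path), "duplicate")

  writeLines(character(0), path)
  expect_error(read_fasta(path))
})

test_that("FASTA survives a write/read round trip", {
  set.seed(11)
  seqs <- setNames(vapply(c(3, 80, 301), random_nt, character(1)),
                   c("s1", "s2", "s3"))
  path <- file.path(withr::local_tempdir(), "rt.fasta")
  write_fasta(seqs, path)
  expect_identical(read_fasta(path), seqs)
})

test_that("gene_model enforces exon geometry invariants", {
  s <- strrep("ACGT", 30)
  expect_error(gene_model("g", "c", rbind(c(10, 5)), s), "start > end")
  expect_error(gene_model("g", "c", rbind(c(1, 20), c(15, 30)), s),
               "overlapping|zero-length")
  expect_error(gene_model("g", "c", rbind(c(1, 20), c(21, 30)), s),
               "zero-length|overlapping")  # abutting exons leave no intron
  expect_error(gene_model("g", "c", rbind(c(1, 200)), s), "bounds")
  m <- gene_model("g", "c", rbind(c(1, 20), c(31, 40)), s)
  expect_s3_class(m, "serk_gene_model")
})

test_that("read_gff3 builds models and normalises the minus strand", {
  dir <- withr::local_tempdir()
  set.seed(5)
  genome <- random_nt(300)
  seqs <- c(chr1 = genome)
  gff <- file.path(dir, "toy.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t11\t250\t.\t+\t.\tID=g1",
    "chr1\ttoy\tmRNA\t11\t250\t.\t+\t.\tID=m1;Parent=g1",
    "chr1\ttoy\texon\t11\t70\t.\t+\t.\tID=e1;Parent=m1",
    "chr1\ttoy\texon\t101\t160\t.\t+\t.\tID=e2;Parent=m1",
    "chr1\ttoy\texon\t201\t250\t.\t+\t.\tID=e3;Parent=m1"), gff)
  models <- read_gff3(gff, seqs)
  expect_length(models, 1L)
  m <- models[["m1"]]
  expect_equal(nrow(m$exons), 3L)
  plus_tx <- splice(m)

  # the same gene annotated on the minus strand of the reverse-complemented
  # chromosome must yield the identical spliced transcript
  genome_rc <- revcomp(genome)
  L <- nchar(genome)
  coords <- rbind(c(11, 70), c(101, 160), c(201, 250))
  rc_coords <- cbind(L - coords[, 2] + 1L, L - coords[, 1] + 1L)
  rc_coords <- rc_coords[order(rc_coords[, 1]), ]
  gff2 <- file.path(dir, "toy_minus.gff3")
  writeLines(c(
    "##gff-version 3",
    "chrR\ttoy\tgene\t51\t290\t.\t-\t.\tID=g1",
    "chrR\ttoy\tmRNA\t51\t290\t.\t-\t.\tID=m1;Parent=g1",
    sprintf("chrR\ttoy\texon\t%d\t%d\t.\t-\t.\tID=e%d;Parent=m1",
            rc_coords[, 1], rc_coords[, 2], 1:3)), gff2)
  models2 <- read_gff3(gff2, c(chrR = genome_rc))
  expect_identical(splice(models2[["m1"]]), plus_tx)

  # exon beyond sequence bounds is rejected
  gff3 <- file.path(dir, "bad.gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttoy\tmRNA\t11\t400\t.\t+\t.\tID=m1",
    "chr1\ttoy\texon\t11\t400\t.\t+\t.\tID=e1;Parent=m1"), gff3)
  expect_error(read_gff3(gff3, seqs), "outside sequence")
})

test_that("gene models survive a GFF3 write/read round trip", {
  fx <- sv_fixture_cached()
  dir <- withr::local_tempdir()
  files <- sv_fixture_files(fx, dir)
  seqs <- read_fasta(files[["genome"]])
  models <- read_gff3(files[["gff3"]], seqs)
  m <- models[[fx$model$gene_id]]
  expect_equal(unname(m$exons), unname(fx$model$exons))
  expect_identical(splice(m), splice(fx$model))
})

test_that("extract_introns returns the text strictly between exons", {
  m <- gene_model("g", "c", rbind(c(1, 3), c(7, 9)), "AAATTTGGG")
  expect_identical(extract_introns(m), c(intron_1 = "TTT"))

  fx <- sv_fixture_cached()
  intr <- extract_introns(fx$model)
  expect_length(intr, 10L)
  expect_true(all(nchar(intr) >= 60))

  single <- gene_model("g", "c", rbind(c(2, 9)), "AAATTTGGGC")
  expect_length(extract_introns(single), 0L)
})

test_that("splice concatenates kept exons and retained introns verbatim", {
  s <- "AAACCCGGGTTTAAACCC"
  m <- gene_model("g", "c", rbind(c(1, 3), c(7, 9), c(13, 15)), s)
  expect_identical(splice(m), "AAAGGGAAA")
  expect_identical(
    splice(m, structure = transcript_structure(1:2, retained_introns = 1L)),
    "AAACCCGGG")
  # skipping exon 2 simply omits its text
  expect_identical(splice(m, structure = transcript_structure(c(1L, 3L))),
                   "AAAAAA")
  expect_error(transcript_structure(c(1L, 3L), retained_introns = 1L),
               "retained intron")
})

test_that("variant length arithmetic: canonical + retained - skipped", {
  fx <- sv_fixture_cached()
  m <- fx$model
  can_len <- nchar(splice(m))
  intr_len <- nchar(extract_introns(m))
  exon_len <- m$exons[, "end"] - m$exons[, "start"] + 1L
  for (nm in names(fx$structures)) {
    st <- fx$structures[[nm]]
    skipped <- setdiff(seq_len(nrow(m$exons)), st$kept_exons)
    expect_equal(nchar(fx$transcripts[[nm]]),
                 can_len + sum(intr_len[st$retained_introns]) -
                   sum(exon_len[skipped]),
                 info = nm)
  }
  # the fixture's SV3 is shorter than canonical by exactly exon 3
  expect_equal(nchar(fx$transcripts[["SV1"]]) - nchar(fx$transcripts[["SV3"]]),
               unname(exon_len[3]))
})

test_that("tandem cluster span reproduces the chromosome-2 geometry", {
  pos <- as.matrix(read.delim(
    system.file("extdata", "mtserk_cluster_positions.tsv",
                package = "serkdup"), row.names = 1))
  expect_warning(res <- tandem_cluster_span(pos), "overlapping")
  expect_identical(res$span_kb, 33)
  expect_identical(res$gene_order,
                   c("MtSERK2", "MtSERK3", "MtSERK4", "MtSERK5", "MtSERK6"))

  expect_warning(res2 <- tandem_cluster_span(rbind(c(0, 10), c(0, 10))))
  expect_identical(res2$span_kb, 10)

  res3 <- tandem_cluster_span(rbind(c(0, 1), c(5, 6), c(9, 12)))
  expect_identical(res3$span_kb, 12)
  expect_equal(unname(res3$gaps_kb), c(4, 3))

  expect_error(tandem_cluster_span(rbind(c(0, 10))), "two genes")
})
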