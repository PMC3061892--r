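test_that("map_transcript recovers canonical and retained-intron structures", {
  fx <- sv_fixture_cached()
  m <- fx$model

  st <- map_transcript(m, transcript_seq = splice(m))
  expect_identical(st$kept_exons, 1:11)
  expect_length(st$retained_introns, 0L)

  tx <- splice(m, structure = transcript_structure(1:2, retained_introns = 1L))
  st2 <- map_transcript(m, transcript_seq = tx)
  expect_identical(st2$kept_exons, 1:2)
  expect_identical(st2$retained_introns, 1L)

  # the variant retaining intron 8 and lacking exon 3
  st4 <- map_transcript(m, transcript_seq = fx$transcripts[["SV4"]])
  expect_identical(setdiff(1:11, st4$kept_exons), 3L)
  expect_identical(st4$retained_introns, 8L)

  expect_error(
    map_transcript(m, transcript_seq = paste0("GGGG", splice(m))),
    "mapping error")
})

test_that("splice then map is the identity on random structures", {
  fx <- sv_fixture_cached()
  m <- fx$model
  set.seed(501)
  for (k in 1:40) {
    kept <- sort(sample(1:11, sample(2:11, 1)))
    eligible <- kept[(kept + 1L) %in% kept]
    n_ret <- sample.int(length(eligible) + 1L, 1L) - 1L
    retained <- sort(eligible[sample.int(length(eligible), n_ret)])
    st <- transcript_structure(kept, retained)
    tx <- splice(m, structure = st)
    back <- map_transcript(m, transcript_seq = tx)
    expect_identical(back$kept_exons, st$kept_exons)
    expect_identical(back$retained_introns, st$retained_introns)
  }
})

test_that("classify labels retention and skipping events", {
  fx <- sv_fixture_cached()
  m <- fx$model

  sv1 <- classify(fx$structures$SV1, m)
  expect_true(sv1$canonical)
  expect_length(sv1$events, 0L)

  sv3 <- classify(fx$structures$SV3, m)
  expect_false(sv3$canonical)
  expect_identical(sv3$events, "exon_skipping:3")

  sv7 <- classify(fx$structures$SV7, m)
  expect_identical(sv7$skipped_exons, 3L)
  expect_identical(sv7$retained_introns, 5L)
  expect_setequal(sv7$events, c("intron_retention:5", "exon_skipping:3"))
})

test_that("ORF prediction finds premature stops inside retained introns", {
  fx <- sv_fixture_cached()
  reps <- sv_reports_cached()
  names(reps) <- vapply(reps, `[[`, character(1), "variant_id")

  expect_false(reps$SV1$ptc)
  expect_equal(reps$SV1$protein_length, 586L)

  expect_true(reps$SV2$ptc)
  expect_equal(reps$SV2$ptc_intron, 8L)
  expect_equal(reps$SV2$protein_length, 271L)

  expect_false(reps$SV3$ptc)  # same genomic stop as canonical
  expect_equal(reps$SV3$protein_length, 562L)

  expect_true(all(vapply(reps[c("SV5", "SV6", "SV7")], `[[`, logical(1),
                         "ptc")))
  expect_identical(unique(vapply(reps[c("SV5", "SV6", "SV7")], `[[`,
                                 numeric(1), "ptc_intron")), 5)
  expect_identical(
    unique(vapply(reps[c("SV5", "SV6", "SV7")], `[[`, character(1), "orf")),
    reps$SV5$orf)
  expect_equal(nchar(reps$SV5$orf), 154L)
})

test_that("a transcript lacking the start exon reports no ORF", {
  fx <- sv_fixture_cached()
  tx <- splice(fx$model, structure = transcript_structure(2:11))
  rep <- predict_orf(fx$model, tx, transcript_structure(2:11))
  expect_false(rep$start_found)
  expect_true(is.na(rep$orf))
})

test_that("the downstream secondary ORF starts at the exon-9 ATG", {
  fx <- sv_fixture_cached()
  reps <- sv_reports_cached()
  names(reps) <- vapply(reps, `[[`, character(1), "variant_id")
  m <- fx$model
  # translation of exons 9..11 from the planted ATG, minus the final stop
  tail_tx <- paste0(substr(m$sequence, m$exons[9, 1], m$exons[9, 2]),
                    substr(m$sequence, m$exons[10, 1], m$exons[10, 2]),
                    substr(m$sequence, m$exons[11, 1], m$exons[11, 2]))
  expected <- sub("\\*$", "", translate_dna(tail_tx))
  for (sv in c("SV2", "SV4", "SV5", "SV6", "SV7"))
    expect_identical(reps[[sv]]$secondary_orf, expected, info = sv)
  expect_equal(nchar(expected), 316L)
})

test_that("the seven variants encode five distinct proteins", {
  reps <- sv_reports_cached()
  grouping <- group_by_protein(reps)
  expect_equal(grouping$n_distinct, 5L)

  same <- lapply(1:3, function(i) list(variant_id = paste0("v", i),
                                       orf = "MKLV"))
  expect_equal(group_by_protein(same)$n_distinct, 1L)

  distinct <- lapply(1:4, function(i) list(variant_id = paste0("v", i),
                                           orf = strrep("A", i)))
  expect_equal(group_by_protein(distinct)$n_distinct, 4L)
})

test_that("frame arithmetic: skipping the 72-nt exon shifts lengths by 24 aa", {
  reps <- sv_reports_cached()
  names(reps) <- vapply(reps, `[[`, character(1), "variant_id")
  expect_equal(reps$SV1$protein_length - reps$SV3$protein_length, 24L)
  expect_equal(reps$SV2$protein_length - reps$SV4$protein_length, 24L)
})

test_that("variants retaining the same stop-bearing intron after identical
           upstream segments encode identical proteins", {
  fx <- sv_fixture_cached()
  m <- fx$model
  # construct three structures sharing kept exons 1,2,4,5 and retained
  # intron 5 but differing downstream
  sts <- list(
    transcript_structure(c(1:2, 4:11), retained_introns = 5L),
    transcript_structure(c(1:2, 4:11), retained_introns = c(5L, 7L)),
    transcript_structure(c(1:2, 4:9), retained_introns = c(5L, 8L)))
  prots <- vapply(sts, function(st)
    predict_orf(m, splice(m, structure = st), st)$orf, character(1))
  expect_identical(unique(prots), prots[1])
})

test_that("variant_table summarises the fixture as reported", {
  reps <- sv_reports_cached()
  tab <- variant_table(reps)
  expect_equal(nrow(tab), 7L)
  expect_equal(sum(tab$ptc), 5L)
  expect_true(all(tab$ptc_intron[tab$ptc] %in% c(5L, 8L)))
  expect_equal(length(unique(tab$protein_group)), 5L)
  expect_equal(tab$protein_length_aa,
               c(586L, 271L, 562L, 247L, 154L, 154L, 154L))
})
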