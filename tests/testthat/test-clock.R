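test_that("count_mutations classifies columns and maximal gap runs", {
  c1 <- count_mutations(aligned_pair("ACGT", "ACGA"))
  expect_equal(c1[c("substitutions", "indel_events", "matched_columns")],
               list(substitutions = 1L, indel_events = 0L,
                    matched_columns = 4L))

  c2 <- count_mutations(aligned_pair("ACGT", "AC-T"))
  expect_equal(c2[c("substitutions", "indel_events", "matched_columns")],
               list(substitutions = 0L, indel_events = 1L,
                    matched_columns = 3L))

  # two maximal runs on opposite strands; hand count
  c3 <- count_mutations(aligned_pair("AC--GT", "ACTTG-"))
  expect_equal(c3[c("substitutions", "indel_events", "matched_columns",
                    "gap_columns")],
               list(substitutions = 0L, indel_events = 2L,
                    matched_columns = 3L, gap_columns = 3L))
})

test_that("estimate_age implements K = M/sites and T = K/(2 mu)", {
  cfg <- clock_config()  # mu = 3e-10, subs + indel events, raw p

  z <- estimate_age(list(substitutions = 0L, indel_events = 0L,
                         matched_columns = 500L), cfg)
  expect_equal(z$K, 0)
  expect_equal(z$T_years, 0)

  # closed form at the magnitude of the oldest duplication event
  expect_equal(1.95e-3 / (2 * 3e-10), 3.25e6)

  est <- estimate_age(list(substitutions = 2L, indel_events = 1L,
                           matched_columns = 997L), cfg)
  expect_equal(est$site_count, 998L)
  expect_equal(est$K, 3 / 998)
  expect_equal(est$T_years, (3 / 998) / (2 * 3e-10))

  only <- estimate_age(list(substitutions = 2L, indel_events = 1L,
                            matched_columns = 997L),
                       clock_config(mutation_mode = "subs_only"))
  expect_equal(only$K, 2 / 998)

  expect_error(estimate_age(list(substitutions = 0L, indel_events = 0L,
                                 matched_columns = 0L), cfg), "sites")
  expect_error(
    estimate_age(list(substitutions = 800L, indel_events = 0L,
                      matched_columns = 1000L),
                 clock_config(correction = "jc69")), "undefined")
})

test_that("age is linear in substitutions at fixed sites (raw p)", {
  cfg <- clock_config()
  t1 <- estimate_age(list(substitutions = 5L, indel_events = 0L,
                          matched_columns = 10000L), cfg)$T_years
  t2 <- estimate_age(list(substitutions = 10L, indel_events = 0L,
                          matched_columns = 10000L), cfg)$T_years
  expect_equal(t2, 2 * t1)
})

test_that("JC69 dominates raw p and agrees closely at shallow divergence", {
  for (subs in c(1L, 3L, 20L, 200L, 2000L)) {
    counts <- list(substitutions = subs, indel_events = 0L,
                   matched_columns = 10000L)
    raw <- estimate_age(counts, clock_config(correction = "raw_p"))$K
    jc <- estimate_age(counts, clock_config(correction = "jc69"))$K
    expect_gte(jc, raw)
    if (raw < 0.005) expect_lt((jc - raw) / raw, 0.01)
  }
})

test_that("pairwise age matrix contracts hold", {
  set.seed(201)
  introns <- replicate(4, random_nt(300))
  genes <- list(g1 = introns, g2 = introns)
  ages <- pairwise_age_matrix(genes)
  expect_equal(ages[1, 2], 0)

  g3 <- list(a = introns, b = introns,
             c = vapply(introns, function(s) {
               chars <- strsplit(s, "")[[1]]
               chars[c(3, 50)] <- c("A", "C")[(chars[c(3, 50)] == "A") + 1]
               paste(chars, collapse = "")
             }, character(1), USE.NAMES = FALSE))
  m3 <- pairwise_age_matrix(g3)
  expect_equal(m3, t(m3))
  expect_equal(unname(diag(m3)), rep(0, 3))
  expect_true(all(m3 >= 0))

  expect_error(
    pairwise_age_matrix(list(a = introns, b = introns[1:2])),
    "intron count mismatch")
})

test_that("pooled clock estimator recovers a simulated divergence time", {
  # At T = 3e6 a 10-kb pair carries only ~18 expected mutations (~24%
  # counting noise per replicate), so unbiasedness is tested at T = 3e7
  # where each replicate holds ~180 counts (7.5% noise; mean of 20
  # replicates has ~1.7% SE, making the 10% band a strong bias test) while
  # divergence stays shallow (p < 0.02, multiple-hit bias ~1%).
  mu <- 3e-10; T_true <- 3e7
  est <- vapply(1:20, function(r) {
    sim <- simulate_duplication_history(event_times = T_true, mu = mu,
                                        seed = 300 + r)
    pairwise_age_matrix(sim$genes)[1, 2]
  }, numeric(1))
  expect_lt(abs(mean(est) - T_true) / T_true, 0.10)
})

test_that("deletions register as indel events and contribute to the age", {
  # expected deletion events: rate * L * T * introns * lineages ~ 21
  sim <- simulate_duplication_history(event_times = 3e6, n_introns = 5L,
                                      intron_length_range = c(500L, 900L),
                                      indel_rate = 1e-9, seed = 77)
  tot <- c(substitutions = 0L, indel_events = 0L)
  for (r in seq_along(sim$genes[[1]])) {
    cnt <- count_mutations(global_align(sim$genes[[1]][r], sim$genes[[2]][r]))
    tot <- tot + c(cnt$substitutions, cnt$indel_events)
  }
  expect_gt(tot[["indel_events"]], 0L)
})
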