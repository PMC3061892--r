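# The two printed degenerate primers used for the kinase-domain PCR; spaced
# 5'->3' notation as in primer tables (whitespace is ignored on parse).
FWD1 <- "CAR TTY CAR CAN GAR GTN GAA ATG AT"
REV1 <- "CC RTA NCC RAA NAC RTC NGT YTT TTC"

test_that("degeneracy is the product of IUPAC set sizes", {
  expect_identical(degeneracy(FWD1), 256)
  expect_identical(degeneracy(REV1), 1024)
  expect_identical(degeneracy("ACGT"), 1)
  expect_identical(degeneracy("NN"), 16)
  expect_error(degeneracy("ACXT"), "position 3")
  expect_error(degeneracy(""), "empty")
})

test_that("specific 3' runs match the primer-design counts", {
  expect_identical(specific_3prime_run(FWD1), 8L)
  expect_identical(specific_3prime_run(REV1), 5L)
  expect_identical(specific_3prime_run("NNNN"), 0L)
  expect_identical(specific_3prime_run("ACGT"), 4L)
})

test_that("expand enumerates exactly the encoded sequences", {
  expect_identical(expand("AR"), c("AA", "AG"))
  expect_identical(expand("ACGT"), "ACGT")
  ex <- expand(FWD1)
  expect_length(ex, 256L)
  expect_identical(anyDuplicated(ex), 0L)
  expect_error(expand("NNNNNNNNN", cap = 1000L), "262144")
})

test_that("every expansion is IUPAC-compatible; off-set bases are not", {
  set.seed(21)
  codes <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "B", "D",
             "H", "V", "N")
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
               W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
               B = c("C", "G", "T"), D = c("A", "G", "T"),
               H = c("A", "C", "T"), V = c("A", "C", "G"),
               N = c("A", "C", "G", "T"))
  for (rep in 1:20) {
    primer <- paste(sample(codes, 6, replace = TRUE), collapse = "")
    chars <- strsplit(primer, "")[[1]]
    for (seq in expand(primer)) {
      schars <- strsplit(seq, "")[[1]]
      expect_true(all(mapply(function(p, s) s %in% sets[[p]], chars, schars)),
                  info = paste(primer, seq))
      # mutate one non-degenerate position to a base outside its set
      fixed_pos <- which(chars %in% c("A", "C", "G", "T"))
      if (length(fixed_pos)) {
        k <- fixed_pos[1]
        bad <- setdiff(c("A", "C", "G", "T"), chars[k])[1]
        mutated <- seq
        substr(mutated, k, k) <- bad
        expect_false(mutated %in% expand(primer))
      }
    }
  }
})

test_that("in-silico PCR finds planted amplicons", {
  set.seed(31)
  fwd <- "CARTTY"
  rev <- "GGYTTR"
  fwd_site <- expand(fwd)[2]   # degeneracy 4: R and Y
  rev_site <- revcomp(expand(rev)[3])
  spacer <- random_nt(50)
  template <- paste0("AAA", fwd_site, spacer, rev_site, "TTT")
  hits <- insilico_pcr(template, fwd, rev)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$fwd_match_start, 4L)
  expect_equal(hits$amplicon_length, 6L + 50L + 6L)

  # no reverse site -> no amplicon
  expect_equal(nrow(insilico_pcr(paste0("AAA", fwd_site, spacer), fwd, rev)),
               0L)

  # two reverse sites -> two amplicons, sorted by length
  template2 <- paste0(fwd_site, spacer, rev_site, random_nt(30), rev_site)
  hits2 <- insilico_pcr(template2, fwd, rev)
  expect_equal(nrow(hits2), 2L)
  expect_true(all(diff(hits2$amplicon_length) > 0))
})

test_that("in-silico PCR agrees with a brute-force expansion scan", {
  set.seed(32)
  fwd <- "CAYAAR"
  rev <- "TGGSAA"
  for (rep in 1:10) {
    template <- random_nt(400)
    hits <- insilico_pcr(template, fwd, rev, max_product_bp = 400L)
    # oracle: scan every offset for literal membership in the expansion sets
    fwd_set <- expand(fwd)
    rev_set <- vapply(expand(rev), revcomp, character(1))
    f_hits <- which(vapply(seq_len(nchar(template) - 5L), function(i)
      substr(template, i, i + 5L) %in% fwd_set, logical(1)))
    r_hits <- which(vapply(seq_len(nchar(template) - 5L), function(i)
      substr(template, i, i + 5L) %in% rev_set, logical(1)))
    combos <- expand.grid(f = f_hits, r = r_hits)
    combos <- combos[combos$r >= combos$f, , drop = FALSE]
    expect_equal(nrow(hits), nrow(combos))
    if (nrow(hits))
      expect_setequal(hits$amplicon_length, combos$r + 5L - combos$f + 1L)
  }
})

test_that("template N is permissive in matching", {
  fwd <- "ACGTAC"
  rev <- "TTTCCC"
  template <- paste0("ACGNAC", random_nt(40), revcomp(rev))
  hits <- insilico_pcr(template, fwd, rev)
  expect_equal(nrow(hits), 1L)
})

test_that("the bundled primer table carries the printed primers", {
  tab <- serk_degenerate_primers()
  expect_setequal(tab$name, c("Forward1", "Forward2", "Reverse1", "Reverse2"))
  expect_identical(
    sort(unique(vapply(tab$sequence[tab$orientation == "forward"],
                       degeneracy, numeric(1), USE.NAMES = FALSE))), 256)
  expect_identical(
    sort(unique(vapply(tab$sequence[tab$orientation == "reverse"],
                       degeneracy, numeric(1), USE.NAMES = FALSE))), 1024)
})
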