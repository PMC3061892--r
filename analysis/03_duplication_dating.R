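#!/usr/bin/env Rscript

# Intron-based molecular-clock dating of the tandem duplications.
#
# The five cluster genes are modelled as descendants of four timed
# duplication events (3.25, 3.05, 2.65 and 2.2 Myr ago). Because each copy
# accumulates mutations independently after a duplication, the pairwise
# divergence of corresponding introns converts to an age T = K/(2*mu) with
# mu = 3e-10 substitutions/site/year. This driver simulates the family under
# those conditions, aligns corresponding introns (match 2, mismatch -3, gap
# open 5, extend 2), pools mutation counts per gene pair, and infers the
# event order by average-linkage clustering of the age matrix.
#
# With ~10 kb of introns per gene the youngest pair carries only ~13
# expected mutations, so single-run ages wobble by ~25%; the event *order*
# and rough magnitudes are the recoverable signal, which is why the driver
# also reports the spread over a handful of replicate simulations.

library(serkdup)

dir.create("results", showWarnings = FALSE)

truth <- c(3.25e6, 3.05e6, 2.65e6, 2.2e6)

sim <- simulate_duplication_history(event_times = truth, seed = 42)
ages <- pairwise_age_matrix(sim$genes)
write.table(data.frame(gene = rownames(ages), round(ages),
                       check.names = FALSE),
            "results/age_matrix_years.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

history <- infer_events(ages)
write.table(history$events, "results/duplication_events.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
writeLines(to_newick(history), "results/duplication_history.nwk")

cat("Single-run inferred events (seed 42):\n")
print(history)
cat("ultrametricity cv:", round(history$ultrametricity_cv, 3), "\n\n")

# replicate spread of the recovered root age and merge order
reps <- lapply(1:10, function(r) {
  s <- simulate_duplication_history(event_times = truth, seed = 100 + r)
  infer_events(pairwise_age_matrix(s$genes))
})
root_ages <- vapply(reps, function(h) max(h$events$time_years), numeric(1))
orders_ok <- vapply(reps, function(h)
  identical(h$events$clade[1], "gene4,gene5"), logical(1))
cat("Across 10 replicate simulations:\n")
cat("  root-age range:", paste(round(range(root_ages) / 1e6, 2),
                               collapse = " - "), "Myr",
    "(truth 3.25)\n")
cat("  first merge = youngest true pair in", sum(orders_ok), "of 10 runs\n")
summary_tab <- data.frame(replicate = 1:10,
                          root_age_myr = round(root_ages / 1e6, 3),
                          first_merge_correct = orders_ok)
write.table(summary_tab, "results/dating_replicates.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
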