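#!/usr/bin/env Rscript
# Simulate the screens used throughout the analysis: a full-design
# 200x200 reciprocal screen, a desk-scale 50x50 screen under the study
# conditions, and a matched retest of the desk-scale screen (same
# planted truth, fresh noise). Writes long-format TSVs plus truth
# tables under results/simulated/.

suppressPackageStartupMessages(library(ecia))

seed <- 20260926L
out <- "results/simulated"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

# full family-wide design: 200 proteins, 40,000 ordered wells
full <- simulate_screen(sim_config(n_proteins = 200L,
                                   n_true_pairs = 560L, seed = seed))
write_screen(full$records, file.path(out, "full_screen.tsv"))
write.table(full$truth, file.path(out, "full_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# desk-scale study conditions: 50x50, 30 symmetric plants at 8x noise,
# with plate controls
desk_cfg <- sim_config(seed = seed + 1L, include_controls = TRUE)
desk <- simulate_screen(desk_cfg)
write_screen(desk$records, file.path(out, "primary_screen.tsv"))
write.table(desk$truth, file.path(out, "primary_truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(desk$controls, file.path(out, "primary_controls.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

# retest: identical planted truth, independent preparations and noise
null2 <- simulate_screen(sim_config(n_true_pairs = 0L, seed = seed + 2L))
retest <- null2$records
key <- paste(retest$bait, retest$prey)
for (r in seq_len(nrow(desk$truth))) {
  a <- desk$truth$id_a[r]
  b <- desk$truth$id_b[r]
  sel <- key %in% paste(c(a, b), c(b, a))
  retest$absorbance[sel] <- retest$absorbance[sel] + desk$truth$effect[r]
}
write_screen(retest, file.path(out, "retest_screen.tsv"))

cat(sprintf("simulated: full %d wells, primary %d wells (+%d control wells), retest %d wells\n",
            nrow(full$records), nrow(desk$records), nrow(desk$controls),
            nrow(retest)))
cat(sprintf("planted: %d pairs in the full screen, %d in the primary/retest pair\n",
            nrow(full$truth), nrow(desk$truth)))
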