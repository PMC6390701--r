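#!/usr/bin/env Rscript
# Confirmation of the primary hits against the retest screen: pair the
# screens, IQR-normalize each, derive the confirmation threshold from
# the primary bidirectional set, confirm, and quantify reproducibility.

suppressPackageStartupMessages(library(ecia))

hits_scores <- read_matrix("results/primary_analysis/scores.tsv")
hits <- call_hits(hits_scores, cutoff = 2.5)
truth <- read.delim("results/simulated/primary_truth.tsv")

val <- run_validation("results/simulated/primary_screen.tsv",
                      "results/simulated/retest_screen.tsv",
                      hits, out_dir = "results/validation")

d <- val$detail
planted <- paste(d$id_a, d$id_b) %in% paste(truth$id_a, truth$id_b)
cat(sprintf("\nconfirmation threshold (min normalized geo-mean over primary bidirectional set): %.6f\n",
            val$threshold))
cat(sprintf("confirmation rate over predicted hits: %.3f (%d/%d)\n",
            val$confirmation_rate,
            sum(d$confirmed & d$is_predicted_hit),
            sum(d$is_predicted_hit)))
cat(sprintf("confirmation rate over planted pairs:  %.3f (%d/%d)\n",
            mean(d$confirmed[planted]), sum(d$confirmed & planted),
            sum(planted)))
cat(sprintf("Spearman rho, primary vs retest geo-means: %.3f\n",
            val$spearman_rho))

# hit values vs pooled prey-only negative controls
controls <- read.delim("results/simulated/primary_controls.tsv")
neg <- controls$absorbance[controls$type == "negative"]
primary <- read_screen("results/simulated/primary_screen.tsv")
m <- assemble_matrix(primary)
hit_wells <- c(m[cbind(truth$id_a, truth$id_b)],
               m[cbind(truth$id_b, truth$id_a)])
bg_pairs <- d[!planted, ]
bg_wells <- m[cbind(bg_pairs$id_a, bg_pairs$id_b)]
cmp_hit <- compare_distributions(hit_wells, neg)
cmp_bg <- compare_distributions(bg_wells, neg)
cat(sprintf("planted-hit wells vs pooled negative controls: U = %.1f, p = %.2e\n",
            cmp_hit$U, cmp_hit$p_value))
cat(sprintf("non-interacting wells vs pooled negative controls: U = %.1f, p = %.3f\n",
            cmp_bg$U, cmp_bg$p_value))
write.table(
  data.frame(comparison = c("hits_vs_controls", "background_vs_controls"),
             U = c(cmp_hit$U, cmp_bg$U),
             p_value = c(cmp_hit$p_value, cmp_bg$p_value)),
  "results/validation/distribution_tests.tsv", sep = "\t",
  quote = FALSE, row.names = FALSE)
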