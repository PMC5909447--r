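#!/usr/bin/env Rscript
# Dicodon-context codon-usage test on the synthetic cohort: A use at site 3
# versus site 6 of Ile|Ile and Val|Val repeats followed by a C/T-starting
# codon, with and without the A/T-ending (GC3-controlled) restriction, plus
# a planted-bias demonstration.
#
# Run after 01_synthesize_cohort.R.

library(oscexcess)

coh <- read_cohort("results/cohort_t11")
out <- run_dicodon_pipeline(coh$genomes, out_dir = "results/dicodon")
print(out$tests[, c("config", "target", "n", "mean_a3", "mean_a6", "p",
                    "rho_gc3")], digits = 3)
cat("Exchangeable third sites: site-3 and site-6 usage match in expectation.\n")

# planted +0.1 site-3 bias in Ile repeats: the paired test picks it up
set.seed(20260104)
cfg <- dicodon_config("Ile")
rows <- do.call(rbind, lapply(1:60, function(i) {
  u <- sample_codon_usage(runif(1, 0.25, 0.75))
  g <- generate_genome(sprintf("bias%02d", i), u, n_cds = 60)
  g <- inject_context_bias(g, u, cfg, 0.1)
  genome_site_usage(g, cfg)
}))
pt <- paired_context_test(rows)
write_tsv_table(rows, "results/dicodon/dicodon_planted_usage.tsv")
cat(sprintf("planted bias: mean A3 - A6 = %.3f (p = %.2e, %d/%d genomes A3 > A6)\n",
            pt$mean_a3 - pt$mean_a6, pt$p, pt$n_greater, pt$n))
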