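#!/usr/bin/env Rscript

# Stereological extrapolation and the summed-labeling check, computed from
# the per-condition summaries of 01_simulate_cohort.R and, for reference,
# from the design means themselves.
# Writes results/extrapolation.json.

suppressPackageStartupMessages(library(fatemapr))

if (!file.exists("results/summaries.csv"))
  stop("run analysis/01_simulate_cohort.R first")
sm <- read.csv("results/summaries.csv")
spec <- extrapolation_spec()  # 100 um sampled of 440 um, bilateral

neu <- sm[sm$cell_class == "neuron", ]
e95 <- neu$mean_count[neu$tamoxifen_day == "E9.5"]
const <- neu$mean_count[neu$genotype == "constitutive"]

est_e95 <- extrapolate_total(e95, spec)
est_const <- extrapolate_total(const, spec)
cat(sprintf("E9.5 mean of %.1f neurons/test volume -> ~%d neurons in the whole structure\n",
            e95, est_e95$display))
cat(sprintf("Constitutive mean of %.1f -> ~%d Dbx1-derived neurons total\n",
            const, est_const$display))

## design-mean reference: 63 neurons -> 63 x 4.4 x 2 = 554.4
cat(sprintf("Design-mean reference: %d x %.1f x %d = %.1f (displayed ~%d)\n",
            63, spec$rostrocaudal_extent / spec$sampled_depth,
            spec$bilateral_factor, extrapolate_total(63, spec)$estimate,
            extrapolate_total(63, spec)$display))

sums <- lapply(c(neuron = "neuron", glia = "glia"), function(cl) {
  s <- sm[sm$cell_class == cl, ]
  labeling_sum_check(s$mean_count[s$genotype == "inducible"],
                     s$mean_count[s$genotype == "constitutive"])
})
cat(sprintf("Summed per-day labeling: neurons %.1f%%, glia %.1f%% of the constitutive line\n",
            sums$neuron, sums$glia))
cat("Both sums exceed 100%: single tamoxifen doses at successive days label\noverlapping subsets of the lineage.\n")

jsonlite::write_json(list(
  e9p5_estimate = est_e95$estimate, constitutive_estimate = est_const$estimate,
  design_reference_estimate = extrapolate_total(63, spec)$estimate,
  neuron_labeling_sum_pct = sums$neuron, glia_labeling_sum_pct = sums$glia),
  "results/extrapolation.json", auto_unbox = TRUE, digits = NA)
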