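# Small fixtures shared across test files; everything is generated in code.

# A reduced three-condition design for fast pipeline tests.
small_design <- function(n_animals = 2) {
  cohort_design(data.frame(
    genotype = c("constitutive", "inducible", "inducible"),
    tamoxifen_day = c("none", "E9.5", "E11.5"),
    neuron_mean = c(10, 9, 2), neuron_sd = c(1, 1, 1),
    glia_mean = c(12, 6, 5), glia_sd = c(2, 1, 1),
    stringsAsFactors = FALSE), n_animals = n_animals)
}

# The reference design with all SDs zeroed (degenerate generator).
sd_zero_design <- function() {
  d <- prebotc_cohort_design()
  d$conditions$neuron_sd <- 0
  d$conditions$glia_sd <- 0
  d
}

# Match each ground-truth cell to the nearest recovered record; returns the
# recovered row index per truth row.
match_cells <- function(truth, recovered) {
  vapply(seq_len(nrow(truth)), function(i) {
    d2 <- (recovered$x - truth$x[i])^2 + (recovered$y - truth$y[i])^2 +
      (recovered$z - truth$z[i])^2
    which.min(d2)
  }, integer(1))
}

# Exact CDF of a per-day mean distribution from exact_permutation_oracle.
oracle_cdf <- function(dist) {
  function(q) vapply(q, function(x) sum(dist$prob[dist$mean <= x + 1e-9]),
                     numeric(1))
}
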