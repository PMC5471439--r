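test_that("cohort summaries compute mean, sample SD and percentages", {
  co <- data.frame(
    animal_id = paste0("a", 1:6),
    genotype = rep(c("constitutive", "inducible"), each = 3),
    tamoxifen_day = rep(c("none", "E9.5"), each = 3),
    neuron_count = c(70, 70, 70, 59, 63, 67),
    glia_count = c(92, 92, 92, 42, 42, 42))
  sm <- summarize_cohort(co)
  e95n <- sm[sm$tamoxifen_day == "E9.5" & sm$cell_class == "neuron", ]
  expect_equal(e95n$mean_count, 63)
  expect_equal(e95n$sd_count, 4)
  expect_equal(e95n$pct_of_constitutive, 100 * 63 / 70)
  e95g <- sm[sm$tamoxifen_day == "E9.5" & sm$cell_class == "glia", ]
  expect_equal(e95g$sd_count, 0)
  expect_equal(e95g$pct_of_constitutive, 100 * 42 / 92)
  expect_error(summarize_cohort(co[0, ]), "empty")
})

test_that("summaries of an SD-zero cohort equal the design means exactly", {
  sm <- summarize_cohort(generate_cohort(sd_zero_design(), seed = 4))
  cond <- prebotc_cohort_design()$conditions
  for (i in seq_len(nrow(cond))) {
    got <- sm$mean_count[sm$tamoxifen_day == cond$tamoxifen_day[i] &
                           sm$cell_class == "neuron"]
    expect_equal(got, cond$neuron_mean[i])
  }
})

test_that("percent of constitutive is the unrounded ratio", {
  expect_equal(percent_of_constitutive(26, 70), 100 * 26 / 70)
  expect_equal(round(percent_of_constitutive(26, 70)), 37)
  expect_equal(percent_of_constitutive(70, 70), 100)
  expect_equal(percent_of_constitutive(23, 70), 100 * 23 / 70,
               tolerance = 1e-12)
  expect_error(percent_of_constitutive(10, 0), "> 0")
})

test_that("resampling test on identical counts collapses its bands", {
  cbd <- list(E7.5 = rep(30, 3), E8.5 = rep(30, 3), E9.5 = rep(30, 3),
              E10.5 = rep(30, 3), E11.5 = rep(30, 3))
  r <- resampling_test(cbd, n_resamples = 500, seed = 1)
  expect_equal(r$per_day$ci_lower, rep(30, 5))
  expect_equal(r$per_day$ci_upper, rep(30, 5))
  expect_false(any(r$per_day$significant_high))
  expect_false(any(r$per_day$significant_low))
  expect_equal(r$per_day$empirical_p, rep(1, 5))
  expect_equal(r$per_day$empirical_p_pooled, rep(1, 5))
})

test_that("resampling test rejects unbalanced or degenerate designs", {
  expect_error(resampling_test(list(a = 1:3, b = 1:2)), "same number")
  expect_error(resampling_test(list(a = 1:3)), ">= 2 groups")
  expect_error(resampling_test(list(a = 1:3, b = 4:6), alpha = 1.5), "alpha")
})

test_that("every resample is a permutation of the pooled counts (conservation)", {
  pool <- c(22, 23, 24, 31, 38, 45, 59, 63, 67, 23, 26, 29, 6, 9, 12)
  withr::with_seed(5, {
    for (i in 1:50) {
      m <- fatemapr:::resample_assignment(pool, 3, 5)
      expect_identical(sort(as.numeric(m)), sort(pool))
    }
  })
})

test_that("all days share the same null distribution (exchangeability)", {
  co <- generate_cohort(prebotc_cohort_design(), seed = 6)
  r <- resampling_test(counts_by_day(co, "neuron"), n_resamples = 20000,
                       seed = 2)
  # per-day CI bounds agree within Monte-Carlo tolerance
  expect_lt(diff(range(r$per_day$ci_upper)), 2)
  expect_lt(diff(range(r$per_day$ci_lower)), 2)
})

test_that("exact oracle enumerates tiny group structures correctly", {
  or <- exact_permutation_oracle(list(a = 1, b = 2))
  expect_identical(or$n_assignments, 2L)
  expect_equal(or$distributions$a, data.frame(mean = c(1, 2),
                                              prob = c(0.5, 0.5)))

  or2 <- exact_permutation_oracle(list(g1 = c(1, 2), g2 = c(9, 10)))
  expect_identical(or2$n_assignments, 6L)
  expect_equal(sum(or2$distributions$g1$prob), 1)
  # support bounds are the extreme achievable means
  expect_equal(min(or2$distributions$g1$mean), 1.5)
  expect_equal(max(or2$distributions$g1$mean), 9.5)

  expect_error(exact_permutation_oracle(list(a = 1:7, b = 8:14)),
               "refusing")
})

test_that("Monte-Carlo quantiles converge to the exact enumeration", {
  cbd <- list(g1 = c(1, 2, 3), g2 = c(4, 5, 6), g3 = c(10, 11, 12))
  or <- exact_permutation_oracle(cbd)
  r <- resampling_test(cbd, n_resamples = 20000, seed = 3,
                       keep_resamples = TRUE)
  for (d in names(cbd)) {
    cdf <- oracle_cdf(or$distributions[[d]])
    # evaluate just right of each support point: stored support values are
    # rounded, Monte-Carlo means are not
    pts <- or$distributions[[d]]$mean + 1e-6
    emp <- ecdf(r$resampled_means[, d])
    expect_lt(max(abs(emp(pts) - cdf(pts))), 0.05)
  }
})

test_that("the reference neuron design flags E9.5 high and E11.5 low", {
  co <- generate_cohort(prebotc_cohort_design(), seed = 10)
  r <- resampling_test(counts_by_day(co, "neuron"), n_resamples = 10000,
                       alpha = 0.01, seed = 10)
  pd <- r$per_day
  expect_true(pd$significant_high[pd$day == "E9.5"])
  expect_true(pd$significant_low[pd$day == "E11.5"])
  expect_lt(pd$empirical_p[pd$day == "E9.5"], 0.01)
  expect_lt(pd$empirical_p[pd$day == "E11.5"], 0.01)
})

test_that("soma-area comparison handles typical and degenerate inputs", {
  same <- c(10, 10, 10)
  expect_equal(soma_area_comparison(same, same),
               list(t = 0, p = 1, df = NA_real_, method = "degenerate"))

  a <- generate_soma_areas(37, 34, seed = 12)
  res <- soma_area_comparison(a$area_um2[a$true_class == "neuron"],
                              a$area_um2[a$true_class == "glia"])
  expect_lt(res$p, 1e-4)
  expect_gt(res$t, 0)
  expect_error(soma_area_comparison(1, c(2, 3)), ">= 2")
})

test_that("t-test P agrees with an exact permutation P on small samples", {
  x <- c(3.1, 4.2, 5.0, 4.4)
  y <- c(5.9, 6.4, 7.2, 5.5)
  tt <- soma_area_comparison(x, y, var_equal = TRUE)
  # exact two-sided permutation test on |difference of means|
  pool <- c(x, y)
  obs <- abs(mean(x) - mean(y))
  splits <- combn(8, 4, simplify = FALSE)
  devs <- vapply(splits, function(s) abs(mean(pool[s]) - mean(pool[-s])),
                 numeric(1))
  p_perm <- mean(devs >= obs - 1e-12)
  expect_lt(abs(tt$p - p_perm), 0.1)
})
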