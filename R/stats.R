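#' Summarize a cohort by condition and cell class
#'
#' Computes per-condition mean and sample SD of the per-animal neuron and
#' glia counts, and expresses each condition as a percentage of the
#' constitutive-line mean of the same class (the cumulative-lineage 100%
#' reference). Percentages are unrounded; displayed values are conventionally
#' rounded to whole percent.
#'
#' @param cohort Cohort data frame ([generate_cohort()] /
#'   [read_cohort_csv()]).
#' @return Data frame with one row per (genotype, tamoxifen_day, cell_class):
#'   `n_animals`, `mean_count`, `sd_count`, `pct_of_constitutive` (NA when no
#'   constitutive condition is present).
#' @export
summarize_cohort <- function(cohort) {
  req <- c("genotype", "tamoxifen_day", "neuron_count", "glia_count")
  if (!is.data.frame(cohort) || !all(req %in% names(cohort)))
    stop_arg("`cohort` must have columns %s", paste(req, collapse = ", "))
  if (nrow(cohort) == 0) stop_arg("empty cohort")

  key <- interaction(cohort$genotype, cohort$tamoxifen_day, drop = TRUE)
  out <- lapply(levels(key), function(k) {
    rows <- cohort[key == k, , drop = FALSE]
    do.call(rbind, lapply(c("neuron", "glia"), function(cl) {
      counts <- rows[[paste0(cl, "_count")]]
      data.frame(genotype = rows$genotype[1],
                 tamoxifen_day = rows$tamoxifen_day[1],
                 cell_class = cl,
                 n_animals = nrow(rows),
                 mean_count = mean(counts),
                 sd_count = if (nrow(rows) > 1) sd(counts) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  day_order <- c("none", "E7.5", "E8.5", "E9.5", "E10.5", "E11.5")
  out <- out[order(match(out$tamoxifen_day, day_order), out$cell_class), ]
  rownames(out) <- NULL

  out$pct_of_constitutive <- NA_real_
  for (cl in c("neuron", "glia")) {
    ref <- out$mean_count[out$genotype == "constitutive" &
                            out$cell_class == cl]
    if (length(ref) == 1 && ref > 0) {
      sel <- out$cell_class == cl
      out$pct_of_constitutive[sel] <-
        percent_of_constitutive(out$mean_count[sel], ref)
    }
  }
  out
}

#' Express a condition mean as percent of the constitutive reference
#'
#' @param condition_mean Mean count in the condition of interest.
#' @param constitutive_mean Mean count in the constitutive (cumulative
#'   lineage) line; must be > 0.
#' @return `100 * condition_mean / constitutive_mean`, unrounded.
#' @examples
#' percent_of_constitutive(26, 70)  # 37.1..., displayed as 37%
#' @export
percent_of_constitutive <- function(condition_mean, constitutive_mean) {
  if (!is.numeric(condition_mean) || any(!is.finite(condition_mean)) ||
      any(condition_mean < 0))
    stop_arg("`condition_mean` must be finite and >= 0")
  check_number(constitutive_mean, "constitutive_mean")
  if (constitutive_mean <= 0) stop_arg("`constitutive_mean` must be > 0")
  100 * condition_mean / constitutive_mean
}

#' Extract per-day count lists from a cohort
#'
#' Convenience accessor producing the `counts_by_day` structure consumed by
#' [resampling_test()]: the inducible-line per-animal counts of one cell
#' class, split by tamoxifen day.
#'
#' @param cohort Cohort data frame.
#' @param cell_class `"neuron"` or `"glia"`.
#' @return Named list, one integer vector per tamoxifen day, in embryonic-day
#'   order.
#' @export
counts_by_day <- function(cohort, cell_class = c("neuron", "glia")) {
  cell_class <- match.arg(cell_class)
  ind <- cohort[cohort$genotype == "inducible", , drop = FALSE]
  if (nrow(ind) == 0) stop_arg("cohort has no inducible-line animals")
  day_order <- c("E7.5", "E8.5", "E9.5", "E10.5", "E11.5")
  days <- intersect(day_order, unique(ind$tamoxifen_day))
  col <- paste0(cell_class, "_count")
  stats::setNames(lapply(days, function(d) ind[[col]][ind$tamoxifen_day == d]),
                  days)
}

# One random reassignment of the pooled counts to groups (a uniform
# permutation split into consecutive blocks), returned as a size x n_groups
# matrix. Shared by resampling_test and the conservation property test.
resample_assignment <- function(pool, size, n_groups) {
  matrix(pool[sample.int(length(pool))], nrow = size, ncol = n_groups)
}

#' Shuffle-and-resample significance test for timed counts
#'
#' The significance procedure for tamoxifen-timing experiments: the
#' per-animal counts are detached from their tamoxifen-administration day,
#' pooled, and repeatedly reassigned at random (sampling the pooled values
#' without replacement, i.e. a fresh uniform permutation per resample) to the
#' days, preserving group sizes. Each day's resampled means form its null
#' distribution; the empirical `alpha/2` and `1 - alpha/2` quantiles
#' (linear-interpolation quantiles) give the `1 - alpha` confidence band. A
#' day is flagged significantly high (low) when its observed mean lies
#' strictly above (below) the band.
#'
#' Two empirical P values are reported per day, both with the add-one
#' correction so that no P is exactly zero:
#' * `empirical_p` -- two-sided by tail doubling,
#'   `min(1, 2 * min(p_lo, p_hi))` with
#'   `p_hi = (1 + #\{resampled >= observed\}) / (1 + n_resamples)`;
#' * `empirical_p_pooled` -- two-sided on deviations from the pooled grand
#'   mean, `(1 + #\{|resampled - grand| >= |observed - grand|\}) / (1 +
#'   n_resamples)`.
#'
#' `empirical_p` matches the confidence-band flags (a day outside the
#' `1 - alpha` band has `empirical_p` near or below `alpha`);
#' `empirical_p_pooled` measures each day's deviation on the scale of the
#' most extreme deviations any day can produce, and is the more conservative
#' of the two for days at the low end of a wide count range.
#'
#' @param counts_by_day Named list of equal-length integer vectors, one per
#'   tamoxifen day (see [counts_by_day()]).
#' @param n_resamples Number of random reassignments (default 10000).
#' @param alpha Significance level (default 0.01, i.e. 99% band).
#' @param seed Integer seed.
#' @param keep_resamples Also return the full matrix of resampled per-day
#'   means (`n_resamples` x days), e.g. for plotting or convergence checks.
#' @return An object of class `resampling_result`: list with `per_day` (data
#'   frame: `day`, `observed_mean`, `ci_lower`, `ci_upper`,
#'   `significant_high`, `significant_low`, `empirical_p`,
#'   `empirical_p_pooled`), `grand_mean`, `n_resamples`, `alpha`, `seed`,
#'   and, when requested, `resampled_means`.
#' @export
resampling_test <- function(counts_by_day, n_resamples = 10000, alpha = 0.01,
                            seed = NULL, keep_resamples = FALSE) {
  if (!is.list(counts_by_day) || length(counts_by_day) < 2)
    stop_arg("`counts_by_day` must be a list of >= 2 groups")
  if (is.null(names(counts_by_day)) || any(names(counts_by_day) == ""))
    stop_arg("`counts_by_day` must be named by day")
  sizes <- lengths(counts_by_day)
  if (length(unique(sizes)) != 1)
    stop_arg("all days must have the same number of animals (balanced design); got sizes %s",
             paste(sizes, collapse = ", "))
  size <- sizes[[1]]
  if (size < 1) stop_arg("each day needs at least one count")
  check_number(n_resamples, "n_resamples", positive = TRUE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_arg("`alpha` must be in (0, 1)")

  g <- length(counts_by_day)
  pool <- as.numeric(unlist(counts_by_day, use.names = FALSE))
  if (any(!is.finite(pool))) stop_arg("counts must be finite")
  obs <- vapply(counts_by_day, mean, numeric(1))
  grand <- mean(pool)
  B <- as.integer(n_resamples)

  res <- with_seed_or_current(seed, {
    m <- matrix(0, nrow = B, ncol = g)
    for (b in seq_len(B))
      m[b, ] <- colMeans(resample_assignment(pool, size, g))
    m
  })

  ci_lower <- apply(res, 2, quantile, probs = alpha / 2, names = FALSE)
  ci_upper <- apply(res, 2, quantile, probs = 1 - alpha / 2, names = FALSE)
  p_hi <- (1 + colSums(res >= rep(obs, each = B))) / (1 + B)
  p_lo <- (1 + colSums(res <= rep(obs, each = B))) / (1 + B)
  p_two <- pmin(1, 2 * pmin(p_hi, p_lo))
  dev <- abs(res - grand)
  p_pooled <- (1 + colSums(dev >= rep(abs(obs - grand), each = B))) / (1 + B)

  out <- structure(list(
    per_day = data.frame(
      day = names(counts_by_day),
      observed_mean = unname(obs),
      ci_lower = ci_lower, ci_upper = ci_upper,
      significant_high = unname(obs) > ci_upper,
      significant_low = unname(obs) < ci_lower,
      empirical_p = unname(p_two),
      empirical_p_pooled = unname(p_pooled),
      stringsAsFactors = FALSE),
    grand_mean = grand, n_resamples = B, alpha = alpha, seed = seed),
    class = "resampling_result")
  if (keep_resamples) {
    colnames(res) <- names(counts_by_day)
    out$resampled_means <- res
  }
  out
}

#' @export
print.resampling_result <- function(x, ...) {
  cat(sprintf("Shuffle-and-resample test: %d resamples, alpha = %g (%.0f%% band), grand mean %.2f\n",
              x$n_resamples, x$alpha, 100 * (1 - x$alpha), x$grand_mean))
  print(x$per_day, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Exact permutation distribution of per-day group means
#'
#' Brute-force oracle for [resampling_test()]: enumerates every distinct
#' assignment of the pooled counts (as labeled values, so each assignment is
#' equally likely) into the given group structure and tabulates the exact
#' probability distribution of each group's mean. Intended for small inputs
#' only; refuses more than `max_values` pooled values.
#'
#' @param counts_by_day Named list of count vectors (defines the group sizes
#'   and the pooled multiset).
#' @param max_values Size guard on the pooled count (default 12; the number
#'   of assignments grows multinomially).
#' @return List with `days`, `distributions` (per day, a data frame of
#'   `mean` and `prob` summing to 1) and `n_assignments`.
#' @export
exact_permutation_oracle <- function(counts_by_day, max_values = 12) {
  if (!is.list(counts_by_day) || length(counts_by_day) < 2)
    stop_arg("`counts_by_day` must be a list of >= 2 groups")
  pool <- as.numeric(unlist(counts_by_day, use.names = FALSE))
  n <- length(pool)
  if (n > max_values)
    stop_arg("refusing to enumerate %d pooled values (limit %d): use resampling_test",
             n, max_values)
  sizes <- lengths(counts_by_day)
  g <- length(sizes)

  # recursively split the index set into ordered groups of the given sizes
  assignments <- list()
  recurse <- function(remaining, chosen) {
    d <- length(chosen) + 1L
    if (d > g) {
      assignments[[length(assignments) + 1L]] <<- chosen
      return(invisible())
    }
    # index-based to dodge combn's scalar-x behavior
    picks <- combn(seq_along(remaining), sizes[d], simplify = FALSE)
    for (p in picks)
      recurse(remaining[-p], c(chosen, list(remaining[p])))
  }
  recurse(seq_len(n), list())
  n_assign <- length(assignments)

  # index-level assignments are NOT all distinct as multisets when values
  # repeat, but they are equiprobable, which is what matters for the
  # distribution
  distributions <- lapply(seq_len(g), function(d) {
    means <- vapply(assignments, function(a) mean(pool[a[[d]]]), numeric(1))
    tab <- table(round(means, 12))
    data.frame(mean = as.numeric(names(tab)),
               prob = as.numeric(tab) / n_assign)
  })
  names(distributions) <- names(counts_by_day)
  list(days = names(counts_by_day), distributions = distributions,
       n_assignments = n_assign)
}

#' Two-sample comparison of neuron and glia soma areas
#'
#' Unpaired t test on soma areas, Welch's form by default (the two
#' populations have very different variances); set `var_equal = TRUE` for the
#' pooled-variance form. Degenerate inputs (both groups constant) return
#' `t = 0, p = 1` when the means agree, by convention.
#'
#' @param neuron_areas,glia_areas Numeric vectors of soma areas, length >= 2
#'   each.
#' @param var_equal Use the pooled-variance t test.
#' @return List with `t`, `p`, `df`, `method`.
#' @export
soma_area_comparison <- function(neuron_areas, glia_areas,
                                 var_equal = FALSE) {
  if (length(neuron_areas) < 2 || length(glia_areas) < 2)
    stop_arg("need >= 2 areas per group")
  if (sd(neuron_areas) == 0 && sd(glia_areas) == 0) {
    if (mean(neuron_areas) == mean(glia_areas))
      return(list(t = 0, p = 1, df = NA_real_, method = "degenerate"))
    return(list(t = sign(mean(neuron_areas) - mean(glia_areas)) * Inf,
                p = 0, df = NA_real_, method = "degenerate"))
  }
  ht <- t.test(neuron_areas, glia_areas, var.equal = var_equal)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), method = ht$method)
}
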