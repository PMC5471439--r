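#' Geometry for stereological extrapolation
#'
#' The sampled test volume covers the full transverse extent of the structure
#' but only `sampled_depth` of its `rostrocaudal_extent`, and only one side
#' of a bilateral structure when counts were acquired unilaterally
#' (`bilateral_factor = 2`). The transverse extent cancels out of the
#' extrapolation and is carried for documentation only.
#'
#' @param sampled_depth Rostrocaudal depth of the sampled volume, um.
#' @param rostrocaudal_extent Full rostrocaudal span of the structure, um.
#' @param bilateral_factor 2 when counts are unilateral and the structure is
#'   bilateral, 1 otherwise.
#' @export
extrapolation_spec <- function(sampled_depth = 100,
                               rostrocaudal_extent = 440,
                               bilateral_factor = 2) {
  check_number(sampled_depth, "sampled_depth", positive = TRUE)
  check_number(rostrocaudal_extent, "rostrocaudal_extent", positive = TRUE)
  if (!bilateral_factor %in% c(1, 2))
    stop_arg("`bilateral_factor` must be 1 or 2")
  structure(list(sampled_depth = sampled_depth,
                 rostrocaudal_extent = rostrocaudal_extent,
                 bilateral_factor = as.integer(bilateral_factor),
                 transverse_extent_note = "350 x 350 um (cancels out)"),
            class = "extrapolation_spec")
}

#' Extrapolate a test-volume count to the whole structure
#'
#' Scales the mean cell count observed in the sampled test volume by the
#' ratio of the structure's rostrocaudal extent to the sampled depth, and by
#' the bilateral factor, assuming uniform density along the axis. With the
#' defaults (100 um sampled of a 440 um, bilateral structure) a mean count of
#' 63 gives `63 * 4.4 * 2 = 554.4`, displayed as ~554.
#'
#' @param mean_count_per_volume Mean cell count in the sampled volume
#'   (>= 0).
#' @param spec An [extrapolation_spec()].
#' @return List with `estimate` (unrounded) and `display` (rounded to the
#'   nearest whole cell).
#' @export
extrapolate_total <- function(mean_count_per_volume,
                              spec = extrapolation_spec()) {
  check_number(mean_count_per_volume, "mean_count_per_volume", nonneg = TRUE)
  if (!inherits(spec, "extrapolation_spec"))
    stop_arg("`spec` must be an extrapolation_spec")
  est <- mean_count_per_volume *
    (spec$rostrocaudal_extent / spec$sampled_depth) * spec$bilateral_factor
  list(estimate = est, display = round(est))
}

#' Summed labeling across tamoxifen timepoints, as percent of constitutive
#'
#' Sums the per-day mean counts of the inducible line and expresses the sum
#' as a percentage of the constitutive-line mean. A sum above 100% indicates
#' that single tamoxifen doses at successive days label overlapping subsets
#' of the lineage (recombinase activity persisting beyond one day).
#'
#' @param per_day_means Numeric vector of per-day mean counts.
#' @param constitutive_mean Constitutive-line mean (> 0).
#' @return The summed percentage, unrounded.
#' @examples
#' labeling_sum_check(c(23, 38, 63, 26, 9), 70)  # 227.1%
#' @export
labeling_sum_check <- function(per_day_means, constitutive_mean) {
  if (length(per_day_means) < 1)
    stop_arg("`per_day_means` must be non-empty")
  percent_of_constitutive(sum(per_day_means), constitutive_mean)
}
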