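#' Define a fate-mapping cohort design
#'
#' A cohort design is the experimental layout of a Cre/lox fate-mapping count
#' experiment: one row per condition (genotype x tamoxifen day) with the mean
#' and SD of the per-animal neuron and glia counts, plus the number of animals
#' per condition.
#'
#' @param conditions Data frame with columns `genotype` (`"constitutive"` or
#'   `"inducible"`), `tamoxifen_day` (`"none"` for the constitutive line, else
#'   one of `"E7.5"`..`"E11.5"`), `neuron_mean`, `neuron_sd`, `glia_mean`,
#'   `glia_sd`.
#' @param n_animals Animals per condition (default 3).
#' @return An object of class `cohort_design`.
#' @seealso [prebotc_cohort_design()] for the reference preBotzinger-complex
#'   design, [generate_cohort()] to simulate a cohort from a design.
#' @export
cohort_design <- function(conditions, n_animals = 3) {
  req <- c("genotype", "tamoxifen_day", "neuron_mean", "neuron_sd",
           "glia_mean", "glia_sd")
  if (!is.data.frame(conditions) || !all(req %in% names(conditions)))
    stop_arg("`conditions` must be a data frame with columns %s",
             paste(req, collapse = ", "))
  check_number(n_animals, "n_animals", positive = TRUE)
  if (n_animals != round(n_animals)) stop_arg("`n_animals` must be an integer")
  bad_geno <- !conditions$genotype %in% c("constitutive", "inducible")
  if (any(bad_geno)) stop_arg("genotype must be 'constitutive' or 'inducible'")
  days <- c("none", "E7.5", "E8.5", "E9.5", "E10.5", "E11.5")
  if (!all(conditions$tamoxifen_day %in% days))
    stop_arg("tamoxifen_day must be one of %s", paste(days, collapse = ", "))
  if (any(conditions$genotype == "constitutive" &
          conditions$tamoxifen_day != "none"))
    stop_arg("constitutive conditions must have tamoxifen_day = 'none'")
  if (any(conditions$genotype == "inducible" &
          conditions$tamoxifen_day == "none"))
    stop_arg("inducible conditions must have an embryonic tamoxifen_day")
  num <- c("neuron_mean", "neuron_sd", "glia_mean", "glia_sd")
  for (nm in num) {
    v <- conditions[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0))
      stop_arg("`%s` values must be finite and >= 0", nm)
  }
  if (anyDuplicated(conditions[c("genotype", "tamoxifen_day")]))
    stop_arg("duplicated conditions in design")
  structure(list(conditions = as.data.frame(conditions),
                 n_animals = as.integer(n_animals)),
            class = "cohort_design")
}

#' Reference preBotzinger-complex fate-mapping design
#'
#' The six-condition design of the tamoxifen-timing experiment: a constitutive
#' Cre line (the cumulative-lineage, 100% reference) and an inducible CreERT2
#' line dosed at one of five embryonic days, with the published per-condition
#' mean +/- SD tdTomato-labeled neuron and glia counts in the
#' 350 x 350 x 100 um test volume and n = 3 animals per condition.
#'
#' @param n_animals Animals per condition (default 3, as in the reference
#'   experiment).
#' @return A [cohort_design()].
#' @export
prebotc_cohort_design <- function(n_animals = 3) {
  cohort_design(data.frame(
    genotype = c("constitutive", rep("inducible", 5)),
    tamoxifen_day = c("none", "E7.5", "E8.5", "E9.5", "E10.5", "E11.5"),
    neuron_mean = c(70, 23, 38, 63, 26, 9),
    neuron_sd = c(1, 1, 7, 4, 3, 3),
    glia_mean = c(92, 47, 30, 42, 38, 34),
    glia_sd = c(4, 7, 6, 1, 3, 3),
    stringsAsFactors = FALSE), n_animals = n_animals)
}

#' Simulate a cohort of per-animal counts from a design
#'
#' Each animal's neuron and glia counts are drawn from a normal with the
#' condition's mean and SD, rounded to the nearest integer and truncated below
#' at zero. The design gives only mean +/- SD per condition (no distributional
#' claim), so the rounded normal is the minimal generative assumption.
#'
#' @param design A [cohort_design()].
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return A data frame (one row per animal) with columns `animal_id`,
#'   `genotype`, `tamoxifen_day`, `neuron_count`, `glia_count`.
#' @export
generate_cohort <- function(design, seed = NULL) {
  if (!inherits(design, "cohort_design"))
    stop_arg("`design` must be a cohort_design")
  cond <- design$conditions
  n <- design$n_animals
  with_seed_or_current(seed, {
    rows <- lapply(seq_len(nrow(cond)), function(i) {
      data.frame(
        animal_id = sprintf("%s_%s_a%d",
                            cond$genotype[i],
                            gsub("\\.", "p", cond$tamoxifen_day[i]),
                            seq_len(n)),
        genotype = cond$genotype[i],
        tamoxifen_day = cond$tamoxifen_day[i],
        neuron_count = pmax(0L, as.integer(round(
          rnorm(n, cond$neuron_mean[i], cond$neuron_sd[i])))),
        glia_count = pmax(0L, as.integer(round(
          rnorm(n, cond$glia_mean[i], cond$glia_sd[i])))),
        stringsAsFactors = FALSE)
    })
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  })
}

#' Read or write a cohort count table
#'
#' CSV with columns animal_id, genotype, tamoxifen_day, neuron_count,
#' glia_count.
#'
#' @param cohort Cohort data frame as returned by [generate_cohort()].
#' @param path File path.
#' @return `read_cohort_csv()` returns the cohort data frame;
#'   `write_cohort_csv()` returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(is.data.frame(cohort))
  write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  if (!file.exists(path)) stop_arg("no such file: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal_id", "genotype", "tamoxifen_day", "neuron_count",
           "glia_count")
  if (!all(req %in% names(df)))
    stop_arg("cohort CSV must have columns %s", paste(req, collapse = ", "))
  df
}
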