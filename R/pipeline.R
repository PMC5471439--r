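#' Assemble a validated run configuration
#'
#' Bundles every tunable of the end-to-end analysis. The defaults are the
#' reference study conditions: the published cohort design, the
#' 350 x 350 x 100 um test volume, the 200 um^2 classification cutoff,
#' 10,000 resamples at alpha = 0.01, and the 440-um bilateral extrapolation.
#'
#' @param seed Integer master seed for the run.
#' @param output_dir Directory for pipeline outputs (created if missing).
#' @param cohort_design A [cohort_design()].
#' @param area_model An [area_model()].
#' @param imaging_volume An [imaging_volume()].
#' @param classification_rule A [classification_rule()].
#' @param extrapolation An [extrapolation_spec()].
#' @param n_resamples,alpha Resampling-test settings.
#' @param blur_sigma,noise_scale,intensity_threshold,min_voxels Imaging
#'   settings used by [run_imaging_pipeline()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1, output_dir = tempfile("fatemap_run_"),
                       cohort_design = prebotc_cohort_design(),
                       area_model = fatemapr::area_model(),
                       imaging_volume = fatemapr::imaging_volume(),
                       classification_rule = fatemapr::classification_rule(),
                       extrapolation = extrapolation_spec(),
                       n_resamples = 10000, alpha = 0.01,
                       blur_sigma = 1, noise_scale = 0,
                       intensity_threshold = 0.5, min_voxels = 50) {
  check_number(seed, "seed")
  stopifnot(inherits(cohort_design, "cohort_design"),
            inherits(area_model, "area_model"),
            inherits(imaging_volume, "imaging_volume"),
            inherits(classification_rule, "classification_rule"),
            inherits(extrapolation, "extrapolation_spec"))
  check_number(n_resamples, "n_resamples", positive = TRUE)
  if (alpha <= 0 || alpha >= 1) stop_arg("`alpha` must be in (0, 1)")
  structure(list(seed = as.integer(seed), output_dir = output_dir,
                 cohort_design = cohort_design, area_model = area_model,
                 imaging_volume = imaging_volume,
                 classification_rule = classification_rule,
                 extrapolation = extrapolation,
                 n_resamples = as.integer(n_resamples), alpha = alpha,
                 blur_sigma = blur_sigma, noise_scale = noise_scale,
                 intensity_threshold = intensity_threshold,
                 min_voxels = min_voxels),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Every omitted field falls back to the reference study conditions, so a
#' minimal config can override just a seed or a threshold. Recognized blocks:
#' `area_model`, `cohort_design` (`conditions` table + `n_animals`),
#' `imaging_volume`, `classification_rule` (`threshold`), `extrapolation`,
#' and scalar fields `seed`, `output_dir`, `n_resamples`, `alpha`,
#' `blur_sigma`, `noise_scale`, `intensity_threshold`, `min_voxels`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_arg("no such file: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop_arg("config must be .yaml, .yml or .json (got .%s)", ext))
  if (!is.list(raw)) stop_arg("malformed config file")

  args <- list()
  scalars <- c("seed", "output_dir", "n_resamples", "alpha", "blur_sigma",
               "noise_scale", "intensity_threshold", "min_voxels")
  for (s in intersect(scalars, names(raw))) args[[s]] <- raw[[s]]
  if (!is.null(raw$area_model))
    args$area_model <- do.call(area_model, raw$area_model)
  if (!is.null(raw$imaging_volume))
    args$imaging_volume <- do.call(imaging_volume, raw$imaging_volume)
  if (!is.null(raw$classification_rule))
    args$classification_rule <- do.call(classification_rule,
                                        raw$classification_rule)
  if (!is.null(raw$extrapolation))
    args$extrapolation <- do.call(extrapolation_spec, raw$extrapolation)
  if (!is.null(raw$cohort_design)) {
    cd <- raw$cohort_design
    conditions <- as.data.frame(cd$conditions, stringsAsFactors = FALSE)
    args$cohort_design <- cohort_design(
      conditions, n_animals = if (is.null(cd$n_animals)) 3 else cd$n_animals)
  }
  do.call(run_config, args)
}

run_stage <- function(stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE))
  message(sprintf("[%s] done in %.2fs", stage, proc.time()[["elapsed"]] - t0))
  out
}

fmt_num <- function(x, digits = 2) formatC(x, format = "f", digits = digits)

#' Run the count-based analysis pipeline
#'
#' Chains cohort generation, per-condition summaries, percent-of-constitutive
#' computation, the shuffle-and-resample significance test (neuron counts,
#' and the same machinery applied to glia counts, clearly labeled), the
#' summed-labeling check, and stereological extrapolation. Writes
#' `counts.csv`, `summaries.csv`, `resampling.json` and `report.md` into
#' `config$output_dir`. Identical config and seed give byte-identical
#' outputs.
#'
#' @param config A [run_config()].
#' @param cohort Optional pre-existing cohort data frame (e.g. recovered from
#'   imaging); when `NULL` a cohort is generated from the design.
#' @return Invisibly, a list with `cohort`, `summaries`, `resampling`
#'   (neuron and glia results), `extrapolation`, `labeling_sum`, and the
#'   output `files`.
#' @export
run_counts_pipeline <- function(config, cohort = NULL) {
  if (!inherits(config, "run_config")) stop_arg("`config` must be a run_config")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(config$output_dir,
                     c(counts = "counts.csv", summaries = "summaries.csv",
                       resampling = "resampling.json", report = "report.md"))
  names(files) <- c("counts", "summaries", "resampling", "report")

  if (nrow(config$cohort_design$conditions) == 0 && is.null(cohort)) {
    writeLines("# Fate-mapping count pipeline\n\nEmpty design: no conditions.",
               files[["report"]])
    return(invisible(list(cohort = NULL, summaries = NULL, resampling = NULL,
                          extrapolation = NULL, labeling_sum = NULL,
                          files = files[["report"]])))
  }

  if (is.null(cohort))
    cohort <- run_stage("generate_cohort",
                        generate_cohort(config$cohort_design,
                                        seed = config$seed))
  run_stage("write_counts", write_cohort_csv(cohort, files[["counts"]]))
  summaries <- run_stage("summarize", summarize_cohort(cohort))
  write.csv(summaries, files[["summaries"]], row.names = FALSE, quote = FALSE)

  resampling <- run_stage("resampling_test", {
    out <- list()
    for (cl in c("neuron", "glia")) {
      cbd <- tryCatch(counts_by_day(cohort, cl), error = function(e) NULL)
      out[[cl]] <- if (!is.null(cbd) && length(cbd) >= 2)
        resampling_test(cbd, n_resamples = config$n_resamples,
                        alpha = config$alpha, seed = config$seed)
      else NULL
    }
    out
  })
  jsonlite::write_json(
    lapply(resampling, function(r) if (is.null(r)) NULL else
      list(per_day = r$per_day, grand_mean = r$grand_mean,
           n_resamples = r$n_resamples, alpha = r$alpha)),
    files[["resampling"]], auto_unbox = TRUE, digits = NA, null = "null")

  extrapolation <- run_stage("extrapolate", {
    neu <- summaries[summaries$cell_class == "neuron", , drop = FALSE]
    lapply(stats::setNames(seq_len(nrow(neu)), paste0(
      neu$genotype, "_", neu$tamoxifen_day)), function(i)
        extrapolate_total(neu$mean_count[i], config$extrapolation))
  })

  labeling_sum <- run_stage("labeling_sum", {
    out <- list()
    for (cl in c("neuron", "glia")) {
      s <- summaries[summaries$cell_class == cl, , drop = FALSE]
      const <- s$mean_count[s$genotype == "constitutive"]
      ind <- s$mean_count[s$genotype == "inducible"]
      out[[cl]] <- if (length(const) == 1 && const > 0 && length(ind) > 0)
        labeling_sum_check(ind, const) else NA_real_
    }
    out
  })

  run_stage("report", write_counts_report(files[["report"]], config, cohort,
                                          summaries, resampling,
                                          extrapolation, labeling_sum))
  invisible(list(cohort = cohort, summaries = summaries,
                 resampling = resampling, extrapolation = extrapolation,
                 labeling_sum = labeling_sum, files = files))
}

write_counts_report <- function(path, config, cohort, summaries, resampling,
                                extrapolation, labeling_sum) {
  ln <- c(
    "# Fate-mapping count pipeline report",
    "",
    sprintf("Seed: %d. Animals: %d across %d conditions.",
            config$seed, nrow(cohort),
            nrow(unique(cohort[c("genotype", "tamoxifen_day")]))),
    "",
    "## Condition summaries (mean +/- SD counts per test volume)",
    "",
    "| genotype | day | class | n | mean | sd | % of constitutive |",
    "|---|---|---|---|---|---|---|",
    vapply(seq_len(nrow(summaries)), function(i) {
      s <- summaries[i, ]
      sprintf("| %s | %s | %s | %d | %s | %s | %s |",
              s$genotype, s$tamoxifen_day, s$cell_class, s$n_animals,
              fmt_num(s$mean_count), if (is.na(s$sd_count)) "-" else
                fmt_num(s$sd_count),
              if (is.na(s$pct_of_constitutive)) "-" else
                paste0(round(s$pct_of_constitutive), "%"))
    }, character(1)),
    "")
  for (cl in c("neuron", "glia")) {
    r <- resampling[[cl]]
    if (is.null(r)) next
    ln <- c(ln,
      sprintf("## Resampling test, %s counts (%d resamples, %.0f%% band)",
              cl, r$n_resamples, 100 * (1 - r$alpha)),
      "",
      "| day | observed mean | band | flag | empirical P |",
      "|---|---|---|---|---|",
      vapply(seq_len(nrow(r$per_day)), function(i) {
        d <- r$per_day[i, ]
        flag <- if (d$significant_high) "HIGH" else
          if (d$significant_low) "LOW" else "-"
        sprintf("| %s | %s | [%s, %s] | %s | %s |", d$day,
                fmt_num(d$observed_mean), fmt_num(d$ci_lower),
                fmt_num(d$ci_upper), flag, fmt_num(d$empirical_p, 4))
      }, character(1)),
      "")
  }
  ln <- c(ln, "## Summed labeling across tamoxifen days", "")
  for (cl in c("neuron", "glia"))
    if (!is.na(labeling_sum[[cl]]))
      ln <- c(ln, sprintf("- %s: %s%% of the constitutive line", cl,
                          fmt_num(labeling_sum[[cl]], 1)))
  ln <- c(ln, "", "## Extrapolated totals (neurons)", "",
          sprintf("Scaling: x%.1f (rostrocaudal) x%d (bilateral).",
                  config$extrapolation$rostrocaudal_extent /
                    config$extrapolation$sampled_depth,
                  config$extrapolation$bilateral_factor),
          "",
          vapply(names(extrapolation), function(nm)
            sprintf("- %s: %s (displayed ~%d)", nm,
                    fmt_num(extrapolation[[nm]]$estimate, 1),
                    extrapolation[[nm]]$display), character(1)),
          "")
  writeLines(ln, path)
  invisible(path)
}

#' Run the imaging-based analysis pipeline
#'
#' For every animal of the generated cohort, renders a synthetic image stack
#' containing that animal's neuron and glia counts, segments it, classifies
#' the segmented cells by soma area, and counts them; the recovered counts
#' then feed the same summary/resampling/extrapolation stages as
#' [run_counts_pipeline()]. The report additionally states the count-recovery
#' error against ground truth. Stacks are written as multi-page TIFFs with
#' ground-truth sidecar CSVs under `stacks/`.
#'
#' Rendering every animal of the full reference design at the native volume
#' is compute-heavy; for routine use configure a smaller
#' `imaging_volume`/design (see the vignette).
#'
#' @param config A [run_config()].
#' @param write_stacks Write per-animal TIFF + ground-truth files (default
#'   TRUE).
#' @return Invisibly, the [run_counts_pipeline()] result plus `recovery`
#'   (per-animal true vs recovered counts).
#' @export
run_imaging_pipeline <- function(config, write_stacks = TRUE) {
  if (!inherits(config, "run_config")) stop_arg("`config` must be a run_config")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  if (nrow(config$cohort_design$conditions) == 0) {
    rp <- file.path(config$output_dir, "report.md")
    writeLines("# Fate-mapping imaging pipeline\n\nEmpty design: no conditions.",
               rp)
    return(invisible(list(recovery = NULL, files = rp)))
  }
  truth <- run_stage("generate_cohort",
                     generate_cohort(config$cohort_design, seed = config$seed))
  stack_dir <- file.path(config$output_dir, "stacks")
  if (write_stacks) dir.create(stack_dir, showWarnings = FALSE)

  min_vox <- config$min_voxels / config$imaging_volume$voxel_size^3
  recovery <- run_stage("imaging", {
    rows <- lapply(seq_len(nrow(truth)), function(i) {
      seed_i <- config$seed + 1000L + i
      cells <- place_cells(truth$neuron_count[i], truth$glia_count[i],
                           volume = config$imaging_volume,
                           model = config$area_model, seed = seed_i)
      stk <- render_stack(cells, config$imaging_volume,
                          blur_sigma = config$blur_sigma,
                          noise_scale = config$noise_scale, seed = seed_i)
      if (write_stacks)
        write_stack(stk, file.path(stack_dir,
                                   paste0(truth$animal_id[i], ".tif")),
                    file.path(stack_dir,
                              paste0(truth$animal_id[i], "_truth.csv")))
      rec <- segment_stack(stk, config$intensity_threshold, min_vox)
      cnt <- count_cells(classify_cells(rec, config$classification_rule))
      data.frame(animal_id = truth$animal_id[i],
                 genotype = truth$genotype[i],
                 tamoxifen_day = truth$tamoxifen_day[i],
                 true_neurons = truth$neuron_count[i],
                 true_glia = truth$glia_count[i],
                 neuron_count = unname(cnt["neuron_count"]),
                 glia_count = unname(cnt["glia_count"]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })

  cohort <- recovery[c("animal_id", "genotype", "tamoxifen_day",
                       "neuron_count", "glia_count")]
  out <- run_counts_pipeline(config, cohort = cohort)
  write.csv(recovery, file.path(config$output_dir, "recovery.csv"),
            row.names = FALSE, quote = FALSE)

  err_n <- sum(abs(recovery$neuron_count - recovery$true_neurons))
  err_g <- sum(abs(recovery$glia_count - recovery$true_glia))
  cat(sprintf("\n## Count recovery vs ground truth\n\nTotal absolute error: %d neurons, %d glia over %d animals.\n",
              err_n, err_g, nrow(recovery)),
      file = out$files[["report"]], append = TRUE)
  invisible(c(out, list(recovery = recovery)))
}
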