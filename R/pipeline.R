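#' Load and validate a cohort table
#'
#' Reads a per-lesion cohort CSV (one row per lesion) and validates it:
#' `patient_id`, `lesion_id` and `stage` are required, lesion ids must be
#' unique, and every stage must be 1, 2 or 3. Metric columns, when present,
#' ride along unchanged.
#'
#' The package ships a transcription of a 21-patient / 23-lesion mandibular
#' osteonecrosis cohort as
#' `system.file("extdata", "table1_cohort.csv", package = "bonespectq")`.
#'
#' @param path CSV file.
#' @return A validated cohort `data.frame`.
#' @export
load_cohort_table <- function(path) {
  if (!file.exists(path))
    stop_bonespectq(sprintf("file not found: %s", path), "parse_error")
  tab <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                  error = function(e)
                    stop_bonespectq(sprintf("malformed CSV: %s",
                                            conditionMessage(e)),
                                    "parse_error"))
  if (nrow(tab) == 0L)
    stop_bonespectq("empty cohort table", "parse_error")
  for (col in c("patient_id", "lesion_id", "stage"))
    if (!col %in% names(tab))
      stop_bonespectq(sprintf("missing required column: %s", col),
                      "parse_error")
  if (any(is.na(tab$stage)))
    stop_bonespectq(sprintf("missing stage in row(s) %s",
                            paste(which(is.na(tab$stage)), collapse = ", ")),
                    "parse_error")
  if (!all(tab$stage %in% 1:3))
    stop_bonespectq("stage must be one of 1, 2, 3", "parse_error")
  dup <- tab$lesion_id[duplicated(tab$lesion_id)]
  if (length(dup))
    stop_bonespectq(sprintf("duplicate lesion id(s): %s",
                            paste(unique(dup), collapse = ", ")),
                    "parse_error")
  tab
}

config_hash <- function(obj) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  jsonlite::write_json(obj, tf, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tf))
}

#' Quantify one lesion from a volume, sidecar and region definitions
#'
#' The full single-lesion pipeline: read the activity volume and acquisition
#' sidecar, compute the SUV map, segment the lesion VOI with the
#' histogram-threshold method, materialise the control VOI, compute
#' lesion/ratio metrics, and append one row to `metrics.csv` in
#' `output_dir`. A provenance JSON (threshold estimate, config echo and
#' hash, package version) is written alongside, sufficient to re-run the
#' command.
#'
#' @param volume_path NIfTI activity volume (Bq/mL).
#' @param meta_path JSON/YAML acquisition sidecar.
#' @param regions_path JSON with one `lesion_target_range` region and one
#'   `control` region.
#' @param output_dir Output directory (created if absent).
#' @param params A [threshold_params()].
#' @param percent Keep the x100 SUV percent scale.
#' @param lesion_id,stage Identifiers recorded in the output row.
#' @return The metrics row (`data.frame`), invisibly.
#' @export
run_quantify <- function(volume_path, meta_path, regions_path, output_dir,
                         params = threshold_params(), percent = TRUE,
                         lesion_id = "L01", stage = NA_integer_) {
  vol <- read_volume(volume_path, "activity_Bq_per_mL")
  meta <- load_acquisition_meta(meta_path)
  regions <- read_regions(regions_path)
  roles <- vapply(regions, `[[`, "", "role")
  lesion_seed <- regions[roles == "lesion_target_range"]
  control_seed <- regions[roles == "control"]
  if (length(lesion_seed) != 1L)
    stop_bonespectq("exactly one lesion_target_range region required",
                    "input_error")
  if (length(control_seed) != 1L)
    stop_bonespectq("missing control region", "control_region_error")
  suv <- compute_suv_map(vol, meta, percent = percent)
  voi <- segment_lesion_voi(suv, lesion_seed[[1]], params)
  lesion_m <- compute_voi_metrics(suv, voi)
  ctrl_m <- compute_voi_metrics(suv, define_control_voi(suv, control_seed[[1]]))
  ratios <- compute_ratio_metrics(lesion_m, ctrl_m)
  row <- metrics_row(meta$patient_id, lesion_id, stage, lesion_m, ratios)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(output_dir, "metrics.csv")
  utils::write.table(row, csv, sep = ",", row.names = FALSE,
                     col.names = !file.exists(csv), append = file.exists(csv))
  config <- list(volume = volume_path, meta = meta_path,
                 regions = regions_path, n_bins = params$n_bins,
                 sd_multiplier = params$sd_multiplier,
                 base_rule = params$base_rule, sd_scope = params$sd_scope,
                 percent = percent)
  prov <- list(threshold = voi$threshold_used[c("mode_value", "base_value",
                                                "sd", "threshold")],
               config = config, config_hash = config_hash(config),
               version = as.character(utils::packageVersion("bonespectq")))
  jsonlite::write_json(prov,
                       file.path(output_dir,
                                 paste0("provenance_", lesion_id, ".json")),
                       auto_unbox = TRUE, digits = NA)
  message(sprintf("quantify: lesion %s threshold %.4g, MBV %.4g cm3",
                  lesion_id, voi$threshold_used$threshold, lesion_m$mbv))
  invisible(row)
}

report_markdown <- function(report) {
  lines <- character(0)
  for (m in names(report)) {
    lines <- c(lines, sprintf("## %s", m), "",
               "| stage | n | median [IQR] |", "|---|---|---|")
    s <- report[[m]]$summary
    for (i in seq_len(nrow(s)))
      lines <- c(lines, sprintf("| %s | %d | %s |", s$stage[i], s$n[i],
                                s$formatted[i]))
    kw <- report[[m]]$kw
    lines <- c(lines, "",
               sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g%s", kw$H,
                       kw$df, kw$p,
                       if (report[[m]]$significant) " (significant)" else ""),
               "", "| pair | t | adjusted p |", "|---|---|---|")
    ph <- report[[m]]$posthoc
    for (i in seq_len(nrow(ph)))
      lines <- c(lines, sprintf("| %s vs %s | %.4g | %.4g |", ph$group_a[i],
                                ph$group_b[i], ph$t_statistic[i],
                                ph$p_adjusted[i]))
    lines <- c(lines, "")
  }
  paste(lines, collapse = "\n")
}

#' Stage-comparison statistics for a cohort CSV
#'
#' Runs [stage_comparison_report()] over a cohort CSV and writes a summary
#' CSV, a pairwise post hoc CSV, a long-format (stage, metric, value) CSV
#' for boxplot-style plotting, a Markdown report, and a provenance JSON to
#' `output_dir`.
#'
#' @param cohort_csv Cohort CSV (see [load_cohort_table()]) with metric
#'   columns.
#' @param metrics Metric columns to compare.
#' @param output_dir Output directory.
#' @param alpha Significance level.
#' @param posthoc_method `"asymptotic"` or `"permutation"`.
#' @param seed Seed for the permutation path (recorded in provenance).
#' @return The `stage_report`, invisibly.
#' @export
run_cohort_stats <- function(cohort_csv,
                             metrics = c("rsuv_max", "rsuv_mean", "mbv_cm3",
                                         "rtbu"),
                             output_dir, alpha = 0.05,
                             posthoc_method = "asymptotic", seed = NULL) {
  cohort <- load_cohort_table(cohort_csv)
  report <- stage_comparison_report(cohort, metrics, alpha = alpha,
                                    posthoc_method = posthoc_method,
                                    seed = seed)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  summ <- do.call(rbind, lapply(names(report), function(m)
    cbind(metric = m, report[[m]]$summary,
          kw_p = report[[m]]$kw$p, significant = report[[m]]$significant)))
  posthoc <- do.call(rbind, lapply(names(report), function(m)
    cbind(metric = m, as.data.frame(report[[m]]$posthoc))))
  utils::write.csv(summ, file.path(output_dir, "stage_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(posthoc, file.path(output_dir, "posthoc.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort_long(cohort, metrics),
                   file.path(output_dir, "long_values.csv"),
                   row.names = FALSE)
  writeLines(report_markdown(report), file.path(output_dir, "report.md"))
  config <- list(cohort_csv = cohort_csv, metrics = metrics, alpha = alpha,
                 posthoc_method = posthoc_method, seed = seed)
  jsonlite::write_json(
    list(config = config, config_hash = config_hash(config),
         version = as.character(utils::packageVersion("bonespectq"))),
    file.path(output_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(report)
}
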