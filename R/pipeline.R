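#' Per-patient metric extraction for a paired-algorithm cohort
#'
#' For every patient and every arm: splits the target by lung membership,
#' computes cumulative DVHs, and extracts Dmean, D2% and D98% for the whole
#' target and both sub-volumes, D95% for the whole target, and the logistic
#' TCP of the whole-target DVH. A sub-volume left empty by the split (a
#' target entirely in one tissue) is reported absent, with a warning
#' message, rather than as zero.
#'
#' @param cohort a [simulate_cohort()] / [read_cohort_dir()] cohort.
#' @param config a `run_config` (see [default_run_config()]).
#' @param verbose emit per-patient progress messages.
#' @return Long-format [cohort_records()] `data.frame`.
#' @export
cohort_metrics <- function(cohort, config = default_run_config(),
                           verbose = FALSE) {
  scheme <- config_scheme(config)
  params <- config_tcp_params(config)
  bw <- config$dvh$bin_width_gy
  cover <- config$radiobiology$coverage_percent
  rows <- lapply(cohort, function(p) {
    if (verbose)
      message(sprintf("[metrics] %s: PTV %.1f cc, lung fraction %.2f",
                      p$patient_id, mask_volume_cc(p$phantom$ptv_mask),
                      p$achieved_lung_fraction))
    parts <- split_target(p$phantom$ptv_mask, p$phantom$lung_mask)
    regions <- list(PTV_Whole = p$phantom$ptv_mask,
                    PTV_Lung = parts$ptv_lung,
                    PTV_SoftTissue = parts$ptv_soft)
    out <- list()
    for (arm in names(p$doses)) {
      dose <- p$doses[[arm]]
      for (region in names(regions)) {
        mask <- regions[[region]]
        if (!any(mask$values)) {
          if (arm == names(p$doses)[1L])
            message(sprintf("WARN [metrics] %s: empty %s after split; metrics absent",
                            p$patient_id, region))
          next
        }
        dvh <- compute_cumulative_dvh(dose, mask, bw)
        vals <- c(Dmean = mean_dose(dose, mask),
                  D2 = dose_at_volume(dvh, 2),
                  D98 = dose_at_volume(dvh, 98))
        if (region == "PTV_Whole") {
          vals <- c(vals, D95 = dose_at_volume(dvh, 95),
                    TCP = tcp_from_dvh(dvh, scheme, params, cover))
        }
        out[[length(out) + 1L]] <- data.frame(
          patient_id = p$patient_id, region = region,
          metric = names(vals), arm = arm, value = unname(vals),
          stringsAsFactors = FALSE)
      }
    }
    do.call(rbind, out)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  cohort_records(df$patient_id, df$region, df$metric, df$arm, df$value)
}

fmt_num <- function(x, decimals) {
  ifelse(is.na(x), "", sprintf(paste0("%.", decimals, "f"), x))
}

#' Write the paired-summary table (clinical-table shape) as CSV
#'
#' Percent columns are rounded to `decimals` places (default 1, matching
#' clinical reporting precision); p-values keep 4 significant digits.
#'
#' @param summary result of [summarize_cohort()].
#' @param path destination path.
#' @param decimals decimal places for percent columns.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summary, path, decimals = 1) {
  lines <- c(
    "region,metric,comparison,mean_ratio_percent,sd_ratio_percent,p_value,method,n",
    sprintf("%s,%s,%s,%s,%s,%.4g,%s,%d",
            summary$region, summary$metric, summary$comparison,
            fmt_num(summary$mean_ratio_percent, decimals),
            fmt_num(summary$sd_ratio_percent, decimals),
            summary$p_value, summary$method, summary$n))
  writeLines(lines, path)
  invisible(path)
}

#' Write the per-patient TCP-vs-D95 comparison (scatter shape) as CSV
#'
#' @param tcp_table result of [tcp_comparison_table()].
#' @param path destination path.
#' @param decimals decimal places for percent columns.
#' @return `path`, invisibly.
#' @export
write_figure_csv <- function(tcp_table, path, decimals = 1) {
  per <- tcp_table$per_patient
  lines <- c("patient_id,comparison,pct_diff_d95,pct_diff_tcp",
             sprintf("%s,%s,%s,%s", per$patient_id, per$comparison,
                     fmt_num(per$pct_diff_d95, decimals),
                     fmt_num(per$pct_diff_tcp, decimals)))
  writeLines(lines, path)
  invisible(path)
}

#' Write the headline JSON report
#'
#' Full-precision cohort headline numbers (mean and max percent TCP
#' difference per comparison, median TCP per arm) with the configuration
#' and seed embedded so every report is regenerable from `(config, seed)`.
#'
#' @param tcp_table result of [tcp_comparison_table()].
#' @param config the `run_config` used.
#' @param seed the master seed used.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_headline_json <- function(tcp_table, config, seed, path) {
  payload <- list(seed = seed,
                  headline = tcp_table$headline,
                  config = unclass(config))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Run the full paired-algorithm analysis pipeline
#'
#' Simulates (or accepts) a cohort, extracts per-patient metrics for the
#' three regions, four dose metrics and three arms, computes TCP per arm,
#' and writes the report bundle: `metrics.csv` (long records, full
#' precision), `summary.csv` (paired ratio summary with Wilcoxon p-values),
#' `figure_tcp_vs_d95.csv` (per-patient percent differences), and
#' `headline.json` (cohort headline numbers with config echo and seed).
#' The bundle is a pure function of `(config, seed)`.
#'
#' @param config a `run_config` (see [default_run_config()],
#'   [read_run_config()]).
#' @param out_dir output directory for the report bundle; `NULL` skips
#'   writing. Defaults to `config$report$out_dir`.
#' @param seed master seed (default `config$synthetic$seed`).
#' @param cohort optionally, a pre-built cohort (e.g. from
#'   [read_cohort_dir()]); when supplied the synthetic block is not used.
#' @param verbose emit stage-level progress messages.
#' @return Invisibly, a list with `records`, `summary`, `tcp_table`,
#'   `headline`, and `paths` of the written files.
#' @export
run_pipeline <- function(config = default_run_config(),
                         out_dir = config$report$out_dir,
                         seed = config$synthetic$seed,
                         cohort = NULL, verbose = TRUE) {
  seed <- as.integer(seed)
  if (is.null(cohort)) {
    if (verbose)
      message(sprintf("[simulate] %d patients, seed %d",
                      config$synthetic$n_patients, seed))
    cohort <- simulate_cohort(config_cohort(config), seed)
  }
  if (verbose) message("[metrics] extracting DVH metrics and TCP")
  records <- cohort_metrics(cohort, config, verbose = verbose)
  if (verbose) message("[compare] paired summaries and Wilcoxon tests")
  summary <- summarize_cohort(records)
  tcp_table <- tcp_comparison_table(records)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dec <- config$report$percent_decimals
    paths <- list(
      metrics = file.path(out_dir, "metrics.csv"),
      summary = file.path(out_dir, "summary.csv"),
      figure = file.path(out_dir, "figure_tcp_vs_d95.csv"),
      headline = file.path(out_dir, "headline.json"))
    write_records_csv(records, paths$metrics)
    write_summary_csv(summary, paths$summary, dec)
    write_figure_csv(tcp_table, paths$figure, dec)
    write_headline_json(tcp_table, config, seed, paths$headline)
    if (verbose) message(sprintf("[report] bundle written to %s", out_dir))
  }
  invisible(list(records = records, summary = summary, tcp_table = tcp_table,
                 headline = tcp_table$headline, paths = paths))
}
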