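# Canonical orderings used for summary tables (mirrors the clinical report
# shape: soft-tissue part, lung part, whole target; D95 for the whole only).
REGIONS <- c("PTV_SoftTissue", "PTV_Lung", "PTV_Whole")
METRICS <- c("Dmean", "D2", "D98", "D95")
ARMS <- c("AAA", "AXB_Dm", "AXB_Dw")
COMPARISONS <- c(AXB_Dm = "Dm/AAA", AXB_Dw = "Dw/AAA")

#' Ratio of two paired values, as a percentage
#'
#' `100 * value_axb / value_aaa` — the ratio-as-percent convention of
#' per-patient algorithm comparisons (100 means identical).
#'
#' @param value_axb numerator value (vectorised).
#' @param value_aaa reference (denominator) value, `> 0`.
#' @return Percentage.
#' @export
ratio_percent <- function(value_axb, value_aaa) {
  if (any(!is.finite(value_aaa)) || any(value_aaa <= 0))
    stop("reference value must be > 0", call. = FALSE)
  100 * value_axb / value_aaa
}

#' Percentage difference relative to the reference arm
#'
#' `100 * (value_aaa - value_axb) / value_aaa`: positive when the second
#' algorithm reports a lower value. Satisfies
#' `percent_difference == 100 - ratio_percent` identically.
#'
#' @param value_aaa reference value, `> 0` (vectorised).
#' @param value_axb comparison value.
#' @return Percentage difference.
#' @examples
#' percent_difference(46.8, 42.9)  # about 8.33
#' @export
percent_difference <- function(value_aaa, value_axb) {
  if (any(!is.finite(value_aaa)) || any(value_aaa <= 0))
    stop("reference value must be > 0", call. = FALSE)
  100 * (value_aaa - value_axb) / value_aaa
}

#' Assemble long-format cohort records
#'
#' @param patient_id,region,metric,arm,value equal-length vectors; `region`
#'   in `PTV_Whole`/`PTV_Lung`/`PTV_SoftTissue`, `metric` in
#'   `Dmean`/`D2`/`D95`/`D98`/`TCP`, `arm` in `AAA`/`AXB_Dm`/`AXB_Dw`.
#' @return A `data.frame` of cohort records (one row per patient, region,
#'   metric, arm).
#' @export
cohort_records <- function(patient_id, region, metric, arm, value) {
  df <- data.frame(patient_id = as.character(patient_id),
                   region = as.character(region),
                   metric = as.character(metric),
                   arm = as.character(arm),
                   value = as.numeric(value),
                   stringsAsFactors = FALSE)
  bad <- !df$region %in% REGIONS
  if (any(bad)) stop("unknown region: ", df$region[bad][1L], call. = FALSE)
  bad <- !df$metric %in% c(METRICS, "TCP")
  if (any(bad)) stop("unknown metric: ", df$metric[bad][1L], call. = FALSE)
  bad <- !df$arm %in% ARMS
  if (any(bad)) stop("unknown arm: ", df$arm[bad][1L], call. = FALSE)
  if (anyDuplicated(df[c("patient_id", "region", "metric", "arm")]))
    stop("duplicate (patient, region, metric, arm) records", call. = FALSE)
  df
}

# Wide view of one (region, metric) cell: one row per patient with the
# reference arm and the requested comparison arm; errors if an arm is
# missing for any patient.
cell_pairs <- function(records, region, metric, arm) {
  cell <- records[records$region == region & records$metric == metric, ]
  ref <- cell[cell$arm == "AAA", c("patient_id", "value")]
  cmp <- cell[cell$arm == arm, c("patient_id", "value")]
  merged <- merge(ref, cmp, by = "patient_id", suffixes = c("_aaa", "_axb"),
                  all = TRUE)
  miss <- merged$patient_id[is.na(merged$value_aaa) | is.na(merged$value_axb)]
  if (length(miss))
    stop(sprintf("patient '%s' is missing an arm for %s %s", miss[1L],
                 region, metric), call. = FALSE)
  merged[order(merged$patient_id), ]
}

#' Paired per-cell summary of a cohort (clinical-table shape)
#'
#' For every (region, metric, comparison) cell present in the records:
#' the mean and sample SD of the per-patient `100 * AXB / AAA` ratios, and
#' the two-sided Wilcoxon signed-rank p-value on the raw paired values.
#' Rows are emitted in the canonical report order (soft tissue, lung, whole;
#' Dmean, D2%, D98%, then D95% where present). A cell whose paired
#' differences are all zero is flagged `degenerate` and reported with
#' `p = 1` rather than aborting the report.
#'
#' @param records long-format cohort records (see [cohort_records()]),
#'   restricted internally to dose metrics (TCP is summarised by
#'   [tcp_comparison_table()]).
#' @param exact_limit passed to [wilcoxon_signed_rank()].
#' @return A `data.frame` with columns `region`, `metric`, `comparison`,
#'   `mean_ratio_percent`, `sd_ratio_percent`, `p_value`, `method`, `n`,
#'   `degenerate`.
#' @export
summarize_cohort <- function(records, exact_limit = 20L) {
  records <- records[records$metric != "TCP", ]
  rows <- list()
  for (region in REGIONS) {
    for (metric in METRICS) {
      cell <- records[records$region == region & records$metric == metric, ]
      if (!nrow(cell)) next
      for (arm in names(COMPARISONS)) {
        if (!any(cell$arm == arm)) next
        pairs <- cell_pairs(records, region, metric, arm)
        ratios <- ratio_percent(pairs$value_axb, pairs$value_aaa)
        degenerate <- all(pairs$value_axb == pairs$value_aaa)
        if (degenerate) {
          test <- list(statistic = NA_real_, p_value = 1, method = "degenerate")
        } else {
          test <- wilcoxon_signed_rank(pairs$value_axb, pairs$value_aaa,
                                       exact_limit = exact_limit)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          region = region, metric = metric,
          comparison = COMPARISONS[[arm]],
          mean_ratio_percent = mean(ratios),
          sd_ratio_percent = if (length(ratios) > 1L) stats::sd(ratios) else 0,
          p_value = test$p_value, method = test$method,
          n = nrow(pairs), degenerate = degenerate,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) stop("no summarisable cells in records", call. = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-patient TCP versus D95% comparison (scatter-plot shape)
#'
#' One row per patient per comparison with the percentage differences in
#' D95% of the whole target and in TCP, both relative to the reference arm;
#' plus cohort headline summaries (mean and max %dTCP per comparison and
#' median TCP per arm).
#'
#' @param records long-format cohort records containing `TCP` and `D95`
#'   values (region `PTV_Whole`) for all arms.
#' @return A list with `per_patient` (`data.frame`: `patient_id`,
#'   `comparison`, `pct_diff_d95`, `pct_diff_tcp`) and `headline` (a list
#'   with `mean_pct_diff_tcp`, `max_pct_diff_tcp` per comparison and
#'   `median_tcp_percent` per arm).
#' @export
tcp_comparison_table <- function(records) {
  per <- list()
  for (arm in names(COMPARISONS)) {
    d95 <- cell_pairs(records, "PTV_Whole", "D95", arm)
    tcp <- cell_pairs(records, "PTV_Whole", "TCP", arm)
    merged <- merge(d95, tcp, by = "patient_id", suffixes = c("_d95", "_tcp"))
    per[[length(per) + 1L]] <- data.frame(
      patient_id = merged$patient_id,
      comparison = COMPARISONS[[arm]],
      pct_diff_d95 = percent_difference(merged$value_aaa_d95,
                                        merged$value_axb_d95),
      pct_diff_tcp = percent_difference(merged$value_aaa_tcp,
                                        merged$value_axb_tcp),
      stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, per)
  tcp_rec <- records[records$metric == "TCP" & records$region == "PTV_Whole", ]
  med <- vapply(ARMS, function(arm) {
    v <- tcp_rec$value[tcp_rec$arm == arm]
    if (length(v)) 100 * stats::median(v) else NA_real_
  }, numeric(1))
  headline <- list(
    mean_pct_diff_tcp = vapply(unname(COMPARISONS), function(cc)
      mean(per$pct_diff_tcp[per$comparison == cc]), numeric(1)) |>
      stats::setNames(unname(COMPARISONS)),
    max_pct_diff_tcp = vapply(unname(COMPARISONS), function(cc)
      max(per$pct_diff_tcp[per$comparison == cc]), numeric(1)) |>
      stats::setNames(unname(COMPARISONS)),
    median_tcp_percent = med)
  list(per_patient = per, headline = headline)
}
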