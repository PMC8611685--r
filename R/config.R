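#' Default run configuration
#'
#' The run configuration is a nested list with four blocks. All published
#' model constants live here as defaults and are never hard-coded in
#' computation paths:
#' \describe{
#'   \item{radiobiology}{`d50_bed_gy` (75.5), `gamma` (1.22),
#'     `alpha_beta_gy` (10), `n_fractions` (5), `coverage_percent` (95).}
#'   \item{dvh}{`bin_width_gy` (0.05).}
#'   \item{synthetic}{cohort size, prescription pool, target volume and
#'     lung-fraction ranges, voxel spacing, master `seed`, and the
#'     dose-to-medium (`dm_*`) / dose-to-water (`dw_*`) discrepancy-model
#'     parameters.}
#'   \item{report}{`out_dir`, `percent_decimals` (1).}
#' }
#'
#' @return A list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    radiobiology = list(d50_bed_gy = 75.5, gamma = 1.22, alpha_beta_gy = 10,
                        n_fractions = 5, coverage_percent = 95),
    dvh = list(bin_width_gy = 0.05),
    synthetic = list(
      n_patients = 23,
      prescription_pool_gy = c(27.5, 30, 35, 40, 45, 50),
      ptv_volume_range_cc = c(15.4, 664),
      lung_fraction_range = c(0.05, 0.6),
      spacing_mm = 2.5,
      seed = 1,
      dm_soft_ratio_mean = 0.985, dm_soft_ratio_sd = 0.002,
      dm_lung_deficit_amplitude_mean = 0.045,
      dm_lung_deficit_amplitude_sd = 0.045,
      dm_deficit_length_mm = 15, dm_noise_sd = 0.005,
      dw_soft_ratio_mean = 0.998, dw_soft_ratio_sd = 0.002,
      dw_lung_deficit_amplitude_mean = 0.060,
      dw_lung_deficit_amplitude_sd = 0.045,
      dw_deficit_length_mm = 15, dw_noise_sd = 0.005),
    report = list(out_dir = "results", percent_decimals = 1)),
    class = "run_config")
}

#' Read a run configuration from a sectioned key-value file
#'
#' The format is a flat INI-style text file: `[section]` headers, `key =
#' value` lines, `#` comments. Values are numeric (comma-separated for
#' vectors) except `report.out_dir`. Keys absent from the file keep their
#' defaults; unknown sections or keys are rejected with a named error.
#'
#' @param path file path.
#' @return A list of class `run_config`.
#' @export
read_run_config <- function(path) {
  template <- default_run_config()
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  config <- template
  section <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln)) next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- sub("^\\[(.*)\\]$", "\\1", ln)
      if (!section %in% names(template))
        stop(sprintf("unknown config section '%s' (line %d)", section, i),
             call. = FALSE)
      next
    }
    if (!grepl("=", ln, fixed = TRUE))
      stop(sprintf("malformed config line %d: '%s'", i, ln), call. = FALSE)
    if (is.null(section))
      stop(sprintf("key outside any [section] at line %d", i), call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (!key %in% names(template[[section]]))
      stop(sprintf("unknown config key '%s.%s' (line %d)", section, key, i),
           call. = FALSE)
    if (is.character(template[[section]][[key]])) {
      config[[section]][[key]] <- val
    } else {
      num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1L]]))
      if (anyNA(num))
        stop(sprintf("non-numeric value for '%s.%s' (line %d)", section, key, i),
             call. = FALSE)
      config[[section]][[key]] <- num
    }
  }
  config
}

#' Write a run configuration in the sectioned key-value format
#'
#' Round-trips with [read_run_config()].
#'
#' @param config a `run_config` list.
#' @param path destination file path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  out <- character(0)
  for (section in names(config)) {
    out <- c(out, sprintf("[%s]", section))
    for (key in names(config[[section]])) {
      v <- config[[section]][[key]]
      v <- if (is.character(v)) v else paste(sprintf("%.10g", v), collapse = ",")
      out <- c(out, sprintf("%s = %s", key, v))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

# Derived model objects from a run_config --------------------------------

config_scheme <- function(config) {
  fractionation_scheme(config$radiobiology$n_fractions,
                       config$radiobiology$alpha_beta_gy)
}

config_tcp_params <- function(config) {
  tcp_params(config$radiobiology$d50_bed_gy, config$radiobiology$gamma)
}

config_cohort <- function(config) {
  s <- config$synthetic
  model <- function(prefix) {
    perturbation_model(
      soft_ratio_mean = s[[paste0(prefix, "_soft_ratio_mean")]],
      soft_ratio_sd = s[[paste0(prefix, "_soft_ratio_sd")]],
      lung_deficit_amplitude_mean = s[[paste0(prefix, "_lung_deficit_amplitude_mean")]],
      lung_deficit_amplitude_sd = s[[paste0(prefix, "_lung_deficit_amplitude_sd")]],
      deficit_length_mm = s[[paste0(prefix, "_deficit_length_mm")]],
      noise_sd = s[[paste0(prefix, "_noise_sd")]])
  }
  cohort_config(n_patients = s$n_patients,
                prescription_pool_gy = s$prescription_pool_gy,
                ptv_volume_range_cc = s$ptv_volume_range_cc,
                lung_fraction_range = s$lung_fraction_range,
                spacing_mm = s$spacing_mm,
                model_dm = model("dm"), model_dw = model("dw"))
}
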